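test_that("gen_dose_response hits the exact Hill values at zero noise", {
  rec <- gen_dose_response(100, 2, doses = c(100), noise_sd = 0, seed = 1)
  expect_equal(rec$block, 0.5)
  rec8 <- gen_dose_response(100, 1, doses = 10^seq(0, 3, length.out = 8),
                            noise_sd = 0, n_rep = 3, seed = 2)
  expect_equal(nrow(rec8), 24)
  expect_error(gen_dose_response(100, 1, doses = numeric(0)), "non-empty")
})

test_that("gen_variability_pool produces the requested layout, seeded", {
  drugs <- fixture_drugs()[1:2, ]
  pool <- gen_variability_pool(drugs, per_drug = 5, length = 50, seed = 3)
  expect_equal(dim(pool), c(10, 50))
  expect_equal(sort(unique(pool$meta$multiplier)), 1:4)
  pool2 <- gen_variability_pool(drugs, per_drug = 5, length = 50, seed = 3)
  expect_identical(pool$values, pool2$values)

  spec0 <- synthetic_class_spec(sd = c(0, 0, 0), alternans = c(0, 0, 0),
                                drug_offset_sd = 0)
  cpool <- gen_variability_pool(drugs, spec0, per_drug = 2, length = 30, seed = 4)
  expect_equal(unname(apply(cpool$values, 1, var)), rep(0, 4))
  expect_equal(unique(cpool$values[1, ]),
               unname(synthetic_class_spec()$mean[["high"]]))

  bad <- drugs
  bad$risk <- c("high", "none")
  expect_error(gen_variability_pool(bad, per_drug = 2, length = 10, seed = 1),
               "risk")
})

test_that("generated series reproduce the requested lag-1 autocorrelation", {
  drugs <- tibble::tibble(drug = "x", risk = "intermediate")
  spec <- synthetic_class_spec(ar1 = c(0.5, 0.5, 0.5),
                               alternans = c(0, 0, 0))
  pool <- gen_variability_pool(drugs, spec, per_drug = 100, length = 500,
                               seed = 5)
  ac1 <- apply(pool$values, 1, function(x) {
    stats::acf(x, lag.max = 1, plot = FALSE)$acf[2]
  })
  expect_lt(abs(mean(ac1) - 0.5), 0.1)
})

test_that("the drug fixture matches the printed reference table", {
  d <- fixture_drugs()
  expect_equal(nrow(d), 28)
  expect_equal(sum(d$split == "train"), 12)
  expect_equal(sum(d$split == "test"), 16)
  expect_equal(as.vector(table(d$risk[d$split == "train"])), c(4, 4, 4))
  expect_equal(as.vector(table(d$risk[d$split == "test"])), c(4, 7, 5))
  dof <- d[d$drug == "Dofetilide", ]
  expect_equal(dof$cmax, 2)
  expect_equal(as.character(dof$risk), "high")
  expect_equal(dof$split, "train")
  quin <- d[d$drug == "Quinidine", ]
  expect_equal(quin$cmax, 3237)
})

test_that("pool_from_series packs long series into an aligned matrix", {
  feats <- tidyr::expand_grid(
    drug = c("a", "b"), sample_id = 1:2, multiplier = 1:2, beat = 1:10
  )
  feats$risk <- ifelse(feats$drug == "a", "high", "low")
  feats$feature <- "qinward"
  feats$value <- feats$beat + 100 * feats$sample_id
  pool <- pool_from_series(feats)
  expect_equal(dim(pool), c(8, 10))
  row1 <- pool$meta[1, ]
  expect_equal(pool$values[1, ],
               feats$value[feats$drug == row1$drug &
                           feats$sample_id == row1$sample_id &
                           feats$multiplier == row1$multiplier])
})

test_that("end-to-end: Hill fits on generated tables recover the truth", {
  doses <- 10^seq(0.5, 3, length.out = 6)
  rec <- gen_dose_response(300, 1.5, doses, noise_sd = 0.01, n_rep = 2,
                           seed = 6, channel = "ICaL")
  s <- suppressWarnings(fit_hill_samples(rec, n_samples = 400, seed = 7))
  expect_lt(abs(median(s$ic50) - 300) / 300, 0.1)
  expect_lt(abs(median(s$h) - 1.5) / 1.5, 0.1)
})
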