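test_that("hill_block matches the closed form and handles d = 0", {
  expect_equal(hill_block(100, 1, 100), 0.5)
  expect_equal(hill_block(100, 2, 0), 0)
  expect_equal(hill_block(100, 2, 200), 0.8)
  expect_error(hill_block(100, 1, -1), "non-negative")
  expect_error(hill_block(-5, 1, 10), "positive")
  expect_error(hill_block(100, 0, 10), "positive")
})

test_that("hill_block is monotone in dose with half-block at IC50", {
  withr::with_seed(7, {
    for (i in 1:20) {
      ic50 <- 10^runif(1, -2, 5)
      h <- runif(1, 0.2, 6)
      d <- sort(c(0, 10^runif(20, -3, 7)))
      b <- hill_block(ic50, h, d)
      expect_true(all(diff(b) >= 0))
      expect_true(all(b >= 0 & b <= 1))
      expect_equal(hill_block(ic50, h, ic50), 0.5)
      expect_lt(hill_block(ic50, h, ic50 * 1e-6), 0.01)
      expect_gt(hill_block(ic50, h, ic50 * 1e6), 0.99)
    }
  })
})

test_that("parse_dose_response reads rows, normalizes percent dialect, rejects bad input", {
  p <- write_dose_csv(c(
    "drug,channel,conc_nM,block,replicate",
    "drugA,IKr,10,0.1,1",
    "drugA,IKr,100,0.5,1",
    "drugA,ICaL,1000,0.9,1"
  ))
  rec <- parse_dose_response(p)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$block, c(0.1, 0.5, 0.9))

  p2 <- write_dose_csv(c(
    "drug,channel,conc_nM,block",
    "drugA,IKr,100,50",
    "drugA,IKr,200,80"
  ))
  expect_warning(rec2 <- parse_dose_response(p2), "percent")
  expect_equal(rec2$block, c(0.5, 0.8))

  p3 <- write_dose_csv(c(
    "drug,channel,conc_nM,block",
    "drugA,IKr2,100,0.5"
  ))
  expect_error(parse_dose_response(p3), "row 1")

  p4 <- write_dose_csv(c(
    "drug,channel,conc_nM,block",
    "drugA,IKr,-5,0.5"
  ))
  expect_error(parse_dose_response(p4), "concentration")
})

test_that("fit_hill_samples recovers generating parameters and is seeded", {
  doses <- 10^seq(0, 3.5, length.out = 8)
  rec <- gen_dose_response(100, 1, doses, noise_sd = 0.005, n_rep = 2, seed = 31)
  s <- fit_hill_samples(rec, n_samples = 800, seed = 32)
  expect_equal(nrow(s), 800)
  expect_lt(abs(median(s$ic50) - 100) / 100, 0.10)
  expect_lt(abs(median(s$h) - 1), 0.10)
  expect_true(all(s$ic50 > 0) && all(s$h > 0))

  s2 <- fit_hill_samples(rec, n_samples = 800, seed = 32)
  expect_identical(s$ic50, s2$ic50)
  expect_identical(s$h, s2$h)

  few <- rec[rec$conc_nM %in% doses[1:2], ]
  expect_error(fit_hill_samples(few, 10, seed = 1), "3 distinct")
})

test_that("posterior concentrates as measurement noise shrinks", {
  doses <- 10^seq(0, 3.5, length.out = 8)
  iqr_at <- function(noise) {
    rec <- gen_dose_response(100, 1, doses, noise_sd = noise, n_rep = 3, seed = 33)
    IQR(fit_hill_samples(rec, n_samples = 600, seed = 34)$ic50)
  }
  expect_lt(iqr_at(0.01), iqr_at(0.08))
})

test_that("sample_block_sets expands samples x multipliers with unmeasured channels at 0", {
  samples <- tibble::tibble(
    drug = "drugA",
    channel = rep(c("IKr", "ICaL"), each = 3),
    sample_id = rep(1:3, 2),
    ic50 = c(100, 100, 100, 500, 500, 500),
    h = rep(1, 6)
  )
  out <- sample_block_sets(samples, cmax = 100, multipliers = 1:4)
  expect_equal(nrow(out), 3 * 4)
  expect_true(all(TDP_CHANNELS %in% names(out)))
  expect_equal(out$IKr[out$multiplier == 1], rep(0.5, 3))
  expect_true(all(out$INa == 0) && all(out$IKs == 0))

  out0 <- sample_block_sets(samples, cmax = 100, multipliers = c(0, 1))
  zero <- out0[out0$multiplier == 0, TDP_CHANNELS]
  expect_true(all(as.matrix(zero) == 0))

  expect_error(sample_block_sets(samples, cmax = -1), "positive")
})

test_that("hill sample tables round-trip through CSV", {
  samples <- tibble::tibble(
    drug = "drugA", channel = "IKr", sample_id = 1:5,
    ic50 = c(90, 100, 110, 95, 105), h = seq(0.9, 1.3, 0.1)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_hill_samples(samples, path)
  back <- read_hill_samples(path)
  expect_equal(back$ic50, samples$ic50)
  expect_s3_class(back, "hill_samples")
})
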