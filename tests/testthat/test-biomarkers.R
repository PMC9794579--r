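test_that("qnet integrates the six currents and is linear", {
  b <- synthetic_beat()
  zero <- b
  zero[, c("INaL", "ICaL", "IKr", "IKs", "IK1", "Ito")] <- 0
  expect_equal(qnet(zero), 0)

  const <- zero
  const$IKr <- 1
  expect_equal(qnet(const), 2000)

  # brute-force fine-grid quadrature oracle on piecewise-linear currents
  total <- rowSums(as.matrix(b[, c("INaL", "ICaL", "IKr", "IKs", "IK1", "Ito")]))
  oracle <- oversampled_trapz(b$time, total)
  expect_equal(qnet(b), oracle, tolerance = 1e-9)

  # linearity: qnet of summed current sets = sum of qnets
  b2 <- synthetic_beat(scale = 0.4)
  bsum <- b
  for (cur in c("INaL", "ICaL", "IKr", "IKs", "IK1", "Ito")) {
    bsum[[cur]] <- b[[cur]] + b2[[cur]]
  }
  expect_equal(qnet(bsum), qnet(b) + qnet(b2), tolerance = 1e-12)

  expect_error(qnet(b[, setdiff(names(b), "IKs")]), "IKs")
})

test_that("qinward is the mean of the two inward AUC ratios", {
  ctl <- synthetic_beat()
  expect_equal(qinward(ctl, ctl), 1.0)

  half <- ctl
  half$ICaL <- 0.5 * ctl$ICaL
  half$INaL <- 0.5 * ctl$INaL
  expect_equal(qinward(half, ctl), 0.5)

  mix <- ctl
  mix$ICaL <- 0.2 * ctl$ICaL
  mix$INaL <- 0.6 * ctl$INaL
  expect_equal(qinward(mix, ctl), 0.4)

  deg <- ctl
  deg$ICaL <- 0
  expect_error(qinward(ctl, deg), "zero")
})

test_that("duration_at_fraction handles instant transitions and closed-form decays", {
  t <- seq(0, 400, by = 0.1)
  sq <- square_beat_signal(t)
  d50 <- duration_at_fraction(t, sq, 0.5)
  d90 <- duration_at_fraction(t, sq, 0.9)
  expect_equal(as.numeric(d50), 200, tolerance = 0.5)
  expect_equal(as.numeric(d90), 200, tolerance = 0.5)
  expect_true(attr(d90, "repolarized"))

  # peak +40, baseline -85, 1 mV/ms linear decay: 90% crossing 112.5 ms in
  lin <- ifelse(t < 10, -85, pmax(40 - (t - 10) * 1, -85))
  expect_equal(as.numeric(duration_at_fraction(t, lin, 0.9)), 112.5,
               tolerance = 0.5)
  expect_equal(as.numeric(duration_at_fraction(t, lin, 0.5)), 62.5,
               tolerance = 0.5)
})

test_that("durations are monotone in fraction and flag non-repolarized beats", {
  b <- synthetic_beat()
  d5 <- duration_at_fraction(b$time, b$vm, 0.5)
  d9 <- duration_at_fraction(b$time, b$vm, 0.9)
  expect_gte(as.numeric(d9), as.numeric(d5))

  t <- seq(0, 500, by = 1)
  stuck <- ifelse(t < 10, -85, 40)  # never recovers
  d <- duration_at_fraction(t, stuck, 0.9)
  expect_false(attr(d, "repolarized"))
  expect_equal(as.numeric(d), 500 - 10)
})

test_that("durations agree with a 100x-oversampled threshold oracle on smooth beats", {
  withr::with_seed(11, {
    for (i in 1:5) {
      t <- seq(0, 600, by = 1)
      apd <- runif(1, 150, 400)
      rest <- -86; peak <- 40
      u <- pmin(pmax((t - 5) / apd, 0), 1)
      vm <- rest + (peak - rest) * (1 - u^3) * (t >= 5)
      vm[t < 5] <- rest
      for (f in c(0.5, 0.9)) {
        got <- as.numeric(duration_at_fraction(t, vm, f))
        # independent fine-grid scan
        tf <- seq(0, 600, by = 0.01)
        vf <- stats::approx(t, vm, xout = tf)$y
        iup <- which.max(diff(vf)) + 1
        base <- mean(vf[tf >= tf[iup] - 10 & tf < tf[iup]])
        pk <- max(vf[iup:length(vf)])
        thr <- pk - f * (pk - base)
        ipk <- which.max(vf[iup:length(vf)]) + iup - 1
        cross <- which(vf <= thr & seq_along(vf) > ipk)[1]
        oracle <- tf[cross] - tf[iup]
        expect_equal(got, oracle, tolerance = 0.5)
      }
    }
  })
})

test_that("dvmdt_max_repol finds the extremal in-window slope", {
  t <- seq(0, 400, by = 1)
  # instant upstroke then strictly linear -1 mV/ms repolarization
  vm <- ifelse(t < 10, -85, pmax(40 - (t - 10), -85))
  expect_equal(dvmdt_max_repol(tibble::tibble(time = t, vm = vm)), -1,
               tolerance = 1e-6)

  # injected +2 mV/ms bump inside the APD30..APD90 window ([47.5, 122.5] ms
  # after the upstroke): rise +2 over [80, 90], rejoin at -3, then -1 again
  vm2 <- vm
  vm2[t > 80 & t <= 90] <- -30 + 2 * (t[t > 80 & t <= 90] - 80)
  vm2[t > 90 & t <= 105] <- -10 - 3 * (t[t > 90 & t <= 105] - 90)
  expect_equal(dvmdt_max_repol(tibble::tibble(time = t, vm = vm2)), 2,
               tolerance = 1e-6)
})

test_that("dvmdt_max_repol equals a brute-force scan on a smooth random beat", {
  withr::with_seed(13, {
    t <- seq(0, 500, by = 1)
    u <- pmin(pmax((t - 5) / 300, 0), 1)
    vm <- -86 + 126 * (1 - u^3) * (t >= 5)
    vm[t < 5] <- -86
    vm <- vm + 0.3 * sin(t / 17) * (t > 20 & t < 350)
    beat <- tibble::tibble(time = t, vm = vm)
    got <- dvmdt_max_repol(beat)
    # independent window bound computation + exhaustive difference quotients
    d30 <- as.numeric(duration_at_fraction(t, vm, 0.3))
    d90 <- as.numeric(duration_at_fraction(t, vm, 0.9))
    iup <- which.max(diff(vm)) + 1
    idx <- which(t >= t[iup] + d30 & t <= t[iup] + d90)
    oracle <- max(diff(vm[idx]) / diff(t[idx]))
    expect_equal(got, oracle)
  })
})

test_that("beat_features populates all seven biomarkers and checks inputs", {
  ctl <- synthetic_beat()
  f <- beat_features(ctl, ctl)
  expect_equal(f$qinward, 1.0)
  expect_gte(f$apd90, f$apd50)
  expect_gte(f$cad90, f$cad50)
  expect_true(all(is.finite(unlist(f[, c("qnet", "apd50", "apd90", "cad50",
                                         "cad90", "dvmdt_max_repol")]))))
  expect_error(beat_features(ctl[, setdiff(names(ctl), "cai")], ctl), "cai")
})

test_that("variability_series keeps the trailing window untransformed", {
  feats <- tibble::tibble(
    beat = 1:1000,
    qnet = sin(1:1000),
    apd90 = 300 + (1:1000) / 100
  )
  out <- variability_series(feats, window = 500)
  expect_equal(sort(unique(out$beat)), 501:1000)
  expect_equal(nrow(out), 2 * 500)
  expect_equal(out$value[out$feature == "qnet"], sin(501:1000))

  const <- tibble::tibble(beat = 1:600, qnet = rep(5, 600))
  v <- variability_series(const, window = 500)
  expect_equal(var(v$value), 0)

  expect_error(variability_series(feats[1:499, ], window = 500), "499")
})
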