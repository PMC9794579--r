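# Shared synthetic fixtures, built in code at test time.

# A square-pulse "action potential": rest until t_on, peak until t_off.
square_beat_signal <- function(times, rest = -85, peak = 40, t_on = 10,
                               t_off = 210) {
  ifelse(times >= t_on & times < t_off, peak, rest)
}

# Single-beat trace tibble with analytic piecewise-linear currents.
synthetic_beat <- function(cl = 2000, dt = 1, scale = 1) {
  t <- seq(0, cl, by = dt)
  tri <- function(peak_t, width, amp) {
    amp * pmax(0, 1 - abs(t - peak_t) / width)
  }
  u <- pmin(pmax((t - 2) / 300, 0), 1)
  tibble::tibble(
    beat = 1L,
    time = t,
    vm = ifelse(t < 2, -85, -85 + 125 * (1 - u^3)),
    cai = 1e-4 + scale * 8e-4 * pmax(0, 1 - abs(t - 80) / 120),
    INa = -tri(2, 2, 60) * scale,
    INaL = -tri(150, 150, 0.3) * scale,
    ICaL = -tri(60, 60, 2) * scale,
    IKr = tri(250, 100, 0.8) * scale,
    IKs = tri(250, 150, 0.3) * scale,
    IK1 = tri(350, 80, 0.5) * scale,
    Ito = tri(10, 15, 1.5) * scale,
    INaCa = -tri(80, 100, 0.2) * scale
  )
}

# Independent trapezoid oracle on a 100x oversampled linear interpolation
# of the sampled currents (pracma::trapz, not the package's integrator).
oversampled_trapz <- function(t, y, factor = 100) {
  tf <- seq(min(t), max(t), length.out = (length(t) - 1) * factor + 1)
  yf <- stats::approx(t, y, xout = tf)$y
  pracma::trapz(tf, yf)
}

# Tiny CNN configuration that trains in seconds.
tiny_cnn_config <- function(...) {
  cnn_config(input_length = 40, stage_convs = c(2, 1), pool = c(2, 2),
             filters = 5, hidden = 10, ...)
}

# Three-class separable series matrix for the tiny config.
tiny_separable_set <- function(n_per = 30, len = 40, sd = 0.05, seed = 42) {
  withr::with_seed(seed, {
    mk <- function(mu) matrix(stats::rnorm(n_per * len, mu, sd), n_per)
    list(
      x = rbind(mk(0.5), mk(0.75), mk(1.0)),
      labels = factor(rep(TDP_RISKS, each = n_per), levels = TDP_RISKS)
    )
  })
}

write_dose_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
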