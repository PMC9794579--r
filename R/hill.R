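#' Fractional channel block under the Hill model
#'
#' The inhibition factor of an ionic current at free drug concentration `d`
#' given the half-inhibitory concentration `ic50` and Hill coefficient `h`
#' (the slope of the dose-inhibition curve at IC50):
#' \deqn{b(d) = \frac{1}{1 + (IC_{50}/d)^h}}
#' By convention no drug means no block, so `d = 0` returns 0.
#'
#' @param ic50 Half-inhibitory concentration in nM, > 0.
#' @param h Hill coefficient, dimensionless, > 0.
#' @param d Drug concentration(s) in nM, >= 0. Vectorised.
#' @return Block fraction(s) in \[0, 1\].
#' @examples
#' hill_block(100, 1, 100)  # half block at d = IC50
#' hill_block(100, 2, 200)  # 0.8
#' @export
hill_block <- function(ic50, h, d) {
  if (!is.numeric(ic50) || length(ic50) != 1 || !is.finite(ic50) || ic50 <= 0) {
    abort("`ic50` must be a single positive number (nM)")
  }
  if (!is.numeric(h) || length(h) != 1 || !is.finite(h) || h <= 0) {
    abort("`h` must be a single positive number")
  }
  if (!is.numeric(d) || any(!is.finite(d)) || any(d < 0)) {
    abort("`d` must be non-negative drug concentration(s) in nM")
  }
  out <- numeric(length(d))
  pos <- d > 0
  out[pos] <- 1 / (1 + (ic50 / d[pos])^h)
  out
}

#' Read a dose-inhibition table
#'
#' Parses a comma-separated file with header columns `drug`, `channel`,
#' `conc_nM`, `block` (and optionally `replicate`) into one record per row.
#' Files reporting block as a percentage are auto-detected (any block value
#' above 1.5) and rescaled to fractions with a warning.
#'
#' @param path Path to a UTF-8 CSV file.
#' @return A tibble with columns `drug`, `channel`, `conc_nM`, `block`,
#'   `replicate`; `block` always a fraction in \[0, 1\].
#' @export
parse_dose_response <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("drug", "channel", "conc_nM", "block")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0) {
    abort(paste0("missing required column(s): ", paste(miss, collapse = ", ")))
  }
  if (!"replicate" %in% names(tab)) tab$replicate <- 1L
  bad_ch <- which(!tab$channel %in% TDP_CHANNELS)
  if (length(bad_ch) > 0) {
    abort(paste0(
      "unknown channel '", tab$channel[bad_ch[1]], "' in row ", bad_ch[1],
      " (channels must be one of ", paste(TDP_CHANNELS, collapse = ", "), ")"
    ))
  }
  bad_conc <- which(!is.finite(tab$conc_nM) | tab$conc_nM <= 0)
  if (length(bad_conc) > 0) {
    abort(paste0("non-positive concentration in row ", bad_conc[1]))
  }
  if (any(tab$block > 1.5)) {
    warn(paste0(
      "block values above 1.5 found in '", basename(path),
      "': interpreting the whole file as percentages and dividing by 100"
    ))
    tab$block <- tab$block / 100
  }
  if (any(tab$block < 0 | tab$block > 1)) {
    abort("block values outside [0, 1] after percent normalization")
  }
  tibble::as_tibble(tab[, c("drug", "channel", "conc_nM", "block", "replicate")])
}

# Log posterior of the Hill model on theta = (log10 IC50, h, log sigma):
# Gaussian residuals with inferred noise scale, log-uniform IC50 prior on
# [1e-3, 1e6] nM, uniform h on (0, 10], log-uniform sigma on [1e-4, 1].
hill_log_post <- function(theta, d, y) {
  if (theta[1] < -3 || theta[1] > 6) return(-Inf)
  if (theta[2] <= 0 || theta[2] > 10) return(-Inf)
  if (theta[3] < log(1e-4) || theta[3] > 0) return(-Inf)
  sig <- exp(theta[3])
  f <- 1 / (1 + (10^theta[1] / d)^theta[2])
  -length(y) * theta[3] - sum((y - f)^2) / (2 * sig^2)
}

run_hill_chain <- function(d, y, init, n_burn, n_keep, thin) {
  theta <- init
  lp <- hill_log_post(theta, d, y)
  step <- c(0.25, 0.25, 0.4)
  acc_win <- 0L
  # adaptive burn-in: rescale proposal every 50 steps towards ~30% acceptance
  for (i in seq_len(n_burn)) {
    prop <- theta + rnorm(3) * step
    lp_prop <- hill_log_post(prop, d, y)
    if (log(runif(1)) < lp_prop - lp) {
      theta <- prop; lp <- lp_prop; acc_win <- acc_win + 1L
    }
    if (i %% 50 == 0) {
      step <- step * exp((acc_win / 50 - 0.3))
      acc_win <- 0L
    }
  }
  keep <- matrix(NA_real_, n_keep, 3)
  acc <- 0L
  n_iter <- n_keep * thin
  k <- 0L
  for (i in seq_len(n_iter)) {
    prop <- theta + rnorm(3) * step
    lp_prop <- hill_log_post(prop, d, y)
    if (log(runif(1)) < lp_prop - lp) {
      theta <- prop; lp <- lp_prop; acc <- acc + 1L
    }
    if (i %% thin == 0) {
      k <- k + 1L
      keep[k, ] <- theta
    }
  }
  list(draws = keep, accept = acc / n_iter)
}

# Split-Rhat (Gelman-Rubin on split half-chains) for one parameter.
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    n <- floor(length(x) / 2)
    list(x[seq_len(n)], x[seq(length(x) - n + 1, length(x))])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  w <- mean(vars)
  b <- n * stats::var(means)
  if (w == 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Draw uncertainty-quantified Hill parameter samples for one drug x channel
#'
#' Fits the Hill dose-inhibition model to the measured block fractions of one
#' drug on one channel by Markov chain Monte Carlo and returns posterior
#' samples of (IC50, h). The likelihood is Gaussian on the block fraction with
#' an inferred noise scale; priors are log-uniform on IC50 over \[1e-3, 1e6\]
#' nM, uniform on h over (0, 10\] and log-uniform on the noise scale. Four
#' adaptive random-walk Metropolis chains are run with 1,000 burn-in steps
#' each and pooled (thinned) to exactly `n_samples` draws. Convergence is
#' reported (not enforced) through the split-Rhat diagnostic attached to the
#' result; a warning is raised when it exceeds 1.05.
#'
#' @param records Tibble of dose-response records (as from
#'   [parse_dose_response()]) for a single drug and channel, with at least 3
#'   distinct concentrations.
#' @param n_samples Number of posterior (IC50, h) samples to return
#'   (2,000 in the reference configuration).
#' @param seed Integer seed; fixed seeds give bit-identical samples.
#' @param chains,burn_in,thin MCMC controls.
#' @return A tibble of class `hill_samples` with columns `drug`, `channel`,
#'   `sample_id`, `ic50` (nM), `h`, and attributes `rhat` (named, per
#'   parameter) and `accept_rate`.
#' @export
fit_hill_samples <- function(records, n_samples = 2000, seed = NULL,
                             chains = 4, burn_in = 1000, thin = 1) {
  stopifnot(is.data.frame(records), n_samples >= 1)
  drug <- unique(records$drug)
  channel <- unique(records$channel)
  if (length(drug) != 1 || length(channel) != 1) {
    abort("`records` must cover exactly one drug and one channel")
  }
  d <- records$conc_nM
  y <- records$block
  if (length(unique(d)) < 3) {
    abort("need measurements at >= 3 distinct concentrations to fit a Hill curve")
  }
  local_seed_(seed)

  # crude initial guesses: dose closest to half-block, unit slope
  init_ic50 <- d[which.min(abs(y - 0.5))]
  init <- c(
    min(max(log10(init_ic50), -3), 6),
    1,
    log(min(max(sd(y) / 2 + 1e-3, 2e-4), 0.5))
  )
  per_chain <- ceiling(n_samples / chains)
  runs <- lapply(seq_len(chains), function(c) {
    jit <- c(rnorm(1, 0, 0.5), abs(rnorm(1, 0, 0.3)), rnorm(1, 0, 0.3))
    run_hill_chain(d, y, init + jit, burn_in, per_chain, thin)
  })
  rhat <- c(
    log10_ic50 = split_rhat(lapply(runs, function(r) r$draws[, 1])),
    h = split_rhat(lapply(runs, function(r) r$draws[, 2]))
  )
  draws <- do.call(rbind, lapply(runs, `[[`, "draws"))[seq_len(n_samples), , drop = FALSE]
  out <- tibble::tibble(
    drug = drug,
    channel = channel,
    sample_id = seq_len(n_samples),
    ic50 = 10^draws[, 1],
    h = draws[, 2]
  )
  attr(out, "rhat") <- rhat
  attr(out, "accept_rate") <- mean(vapply(runs, `[[`, 0, "accept"))
  class(out) <- c("hill_samples", class(out))
  if (any(is.finite(rhat) & rhat > 1.05)) {
    warn(paste0(
      "Hill sampler may not have converged for ", drug, " x ", channel,
      ": max split-Rhat = ", format(max(rhat), digits = 4)
    ))
  }
  out
}

#' @export
tidy.hill_samples <- function(x, ...) {
  tibble::tibble(
    term = c("ic50", "h"),
    estimate = c(median(x$ic50), median(x$h)),
    conf.low = c(quantile(x$ic50, 0.025), quantile(x$h, 0.025)),
    conf.high = c(quantile(x$ic50, 0.975), quantile(x$h, 0.975))
  )
}

#' @export
glance.hill_samples <- function(x, ...) {
  rhat <- attr(x, "rhat")
  tibble::tibble(
    drug = x$drug[1], channel = x$channel[1], n_samples = nrow(x),
    rhat_max = max(rhat), accept_rate = attr(x, "accept_rate")
  )
}

#' Per-channel block sets at multiples of Cmax
#'
#' Expands posterior Hill samples for one drug (over all measured channels)
#' into per-channel block-fraction sets at each multiple of the clinical
#' maximal plasma concentration. Channels with no measurement are taken as
#' unblocked (block 0). With 2,000 samples and multipliers 1-4 this yields the
#' 8,000 block sets per drug used by the reference pipeline.
#'
#' @param samples `hill_samples` rows for one drug (any number of channels,
#'   all with the same number of samples).
#' @param cmax Clinical Cmax in nM, > 0.
#' @param multipliers Non-empty vector of non-negative Cmax multiples
#'   (default 1:4).
#' @return A tibble with columns `drug`, `sample_id`, `multiplier` and one
#'   block-fraction column per channel (all seven of [TDP_CHANNELS]);
#'   `n_samples * length(multipliers)` rows.
#' @export
sample_block_sets <- function(samples, cmax, multipliers = 1:4) {
  stopifnot(is.data.frame(samples))
  if (!is.numeric(cmax) || length(cmax) != 1 || !is.finite(cmax) || cmax <= 0) {
    abort("`cmax` must be a single positive concentration in nM")
  }
  if (length(multipliers) == 0 || any(multipliers < 0)) {
    abort("`multipliers` must be a non-empty vector of non-negative factors")
  }
  drug <- unique(samples$drug)
  if (length(drug) != 1) abort("`samples` must cover exactly one drug")
  counts <- table(samples$channel)
  if (length(unique(counts)) != 1) {
    abort("all channels must share the same number of samples")
  }
  n <- unname(counts[1])
  grid <- tidyr::expand_grid(sample_id = seq_len(n), multiplier = multipliers)
  blocks <- matrix(0, nrow(grid), length(TDP_CHANNELS),
                   dimnames = list(NULL, TDP_CHANNELS))
  for (ch in intersect(TDP_CHANNELS, unique(samples$channel))) {
    sub <- samples[samples$channel == ch, ]
    sub <- sub[order(sub$sample_id), ]
    for (j in seq_along(multipliers)) {
      idx <- which(grid$multiplier == multipliers[j])
      d <- multipliers[j] * cmax
      blocks[idx, ch] <- if (d == 0) 0 else 1 / (1 + (sub$ic50 / d)^sub$h)
    }
  }
  dplyr::bind_cols(tibble::tibble(drug = drug), grid, tibble::as_tibble(blocks))
}

#' Write / read Hill sample tables
#'
#' CSV with columns `drug`, `channel`, `sample_id`, `ic50_nM`, `h`.
#' @param samples A `hill_samples` tibble.
#' @param path Output (input) CSV path.
#' @export
write_hill_samples <- function(samples, path) {
  out <- tibble::tibble(
    drug = samples$drug, channel = samples$channel,
    sample_id = samples$sample_id, ic50_nM = samples$ic50, h = samples$h
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_hill_samples
#' @export
read_hill_samples <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  out <- tibble::tibble(
    drug = tab$drug, channel = tab$channel, sample_id = tab$sample_id,
    ic50 = tab$ic50_nM, h = tab$h
  )
  class(out) <- c("hill_samples", class(out))
  out
}
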