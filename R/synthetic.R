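#' Synthetic dose-inhibition records with known ground truth
#'
#' Emulates a measured multi-well dose-inhibition table for one drug x
#' channel: the true Hill curve evaluated at the given doses plus Gaussian
#' measurement noise, clipped to \[0, 1\].
#'
#' @param true_ic50,true_h Generating Hill parameters.
#' @param doses Positive concentrations in nM (non-empty).
#' @param noise_sd Gaussian noise standard deviation on the block fraction.
#' @param n_rep Replicates per dose.
#' @param seed Integer seed.
#' @param drug,channel Names attached to the records.
#' @return A dose-response tibble (`drug`, `channel`, `conc_nM`, `block`,
#'   `replicate`), `length(doses) * n_rep` rows.
#' @export
gen_dose_response <- function(true_ic50, true_h, doses, noise_sd = 0.02,
                              n_rep = 1, seed = NULL,
                              drug = "drugA", channel = "IKr") {
  if (length(doses) == 0) abort("`doses` must be non-empty")
  if (any(doses <= 0)) abort("`doses` must be strictly positive (nM)")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  local_seed_(seed)
  grid <- tidyr::expand_grid(replicate = seq_len(n_rep), conc_nM = doses)
  truth <- hill_block(true_ic50, true_h, grid$conc_nM)
  block <- pmin(pmax(truth + rnorm(nrow(grid), 0, noise_sd), 0), 1)
  tibble::tibble(
    drug = drug, channel = channel, conc_nM = grid$conc_nM,
    block = block, replicate = grid$replicate
  )
}

#' Class-conditioned generator settings for synthetic variability pools
#'
#' Defines, per TdP risk class, the level, spread and serial structure of the
#' synthetic beat-indexed biomarker series produced by
#' [gen_variability_pool()]: an AR(1) process around a class mean with a
#' small even/odd-beat alternans component and a per-drug random offset. The
#' defaults emulate a qInward-like biomarker: high-risk drugs sit well below
#' 1 with the largest alternans, low-risk drugs near 1 with none, and class
#' means are separated by several within-class (drug-offset) standard
#' deviations.
#'
#' @param mean,sd,ar1,alternans Numeric vectors of length 3 (high,
#'   intermediate, low): series mean level, within-class beat-to-beat
#'   standard deviation, lag-1 autocorrelation in (-1, 1), alternans
#'   amplitude.
#' @param drug_offset_sd Standard deviation of the per-drug random offset on
#'   the class mean.
#' @return A `synthetic_class_spec` object.
#' @export
synthetic_class_spec <- function(mean = c(high = 0.55, intermediate = 0.75, low = 0.95),
                                 sd = c(0.03, 0.03, 0.03),
                                 ar1 = c(0.5, 0.5, 0.5),
                                 alternans = c(0.006, 0.003, 0),
                                 drug_offset_sd = 0.05) {
  stopifnot(length(mean) == 3, length(sd) == 3, length(ar1) == 3,
            length(alternans) == 3)
  if (any(sd < 0)) abort("standard deviations must be >= 0")
  if (any(ar1 <= -1 | ar1 >= 1)) abort("lag-1 autocorrelation must lie in (-1, 1)")
  structure(
    list(mean = setNames(as.numeric(mean), TDP_RISKS),
         sd = setNames(as.numeric(sd), TDP_RISKS),
         ar1 = setNames(as.numeric(ar1), TDP_RISKS),
         alternans = setNames(as.numeric(alternans), TDP_RISKS),
         drug_offset_sd = drug_offset_sd),
    class = "synthetic_class_spec"
  )
}

new_variability_pool <- function(meta, values) {
  stopifnot(nrow(meta) == nrow(values))
  structure(list(meta = meta, values = values), class = "variability_pool")
}

#' @export
print.variability_pool <- function(x, ...) {
  cat("<variability_pool: ", nrow(x$meta), " series x ", ncol(x$values),
      " beats, ", length(unique(x$meta$drug)), " drugs>\n", sep = "")
  invisible(x)
}

#' @export
dim.variability_pool <- function(x) dim(x$values)

#' Long-format view of a variability pool
#' @param x A `variability_pool`.
#' @param ... Unused.
#' @export
as_tibble.variability_pool <- function(x, ...) {
  long <- tidyr::expand_grid(row = seq_len(nrow(x$meta)), beat = seq_len(ncol(x$values)))
  out <- dplyr::bind_cols(x$meta[long$row, ], tibble::tibble(beat = long$beat))
  out$value <- as.vector(t(x$values))
  out
}

#' Generate a class-conditioned synthetic variability pool
#'
#' For every drug in `drugs`, draws `per_drug` beat-indexed series of the
#' requested length from the AR(1)-plus-alternans process of the drug's risk
#' class (see [synthetic_class_spec()]), with a per-drug random offset on the
#' class mean. Sample indices are spread evenly over the Cmax multipliers
#' 1-4 so the pool mirrors the (2,000 samples x 4 concentrations) layout of
#' the simulated pipeline. With 16 drugs and `per_drug = 8000` this is the
#' 128,000-series test pool of the reference configuration.
#'
#' @param drugs Drug tibble with columns `drug` and `risk` (see
#'   [fixture_drugs()]).
#' @param spec A [synthetic_class_spec()].
#' @param per_drug Series per drug.
#' @param length Beats per series (default 500).
#' @param seed Integer seed; fixed seeds give bit-identical pools.
#' @param feature Feature name recorded in the pool metadata.
#' @return A `variability_pool`: metadata tibble (`drug`, `risk`,
#'   `sample_id`, `multiplier`, `feature`) plus a `per_drug * nrow(drugs)` by
#'   `length` series matrix.
#' @export
gen_variability_pool <- function(drugs, spec = synthetic_class_spec(),
                                 per_drug = 2000, length = 500, seed = NULL,
                                 feature = "qinward") {
  stopifnot(is.data.frame(drugs), length > 0, per_drug > 0)
  assert_risk(drugs$risk)
  local_seed_(seed)
  n_drug <- nrow(drugs)
  metas <- vector("list", n_drug)
  mats <- vector("list", n_drug)
  for (i in seq_len(n_drug)) {
    risk <- as.character(drugs$risk[i])
    mu <- spec$mean[[risk]] + rnorm(1, 0, spec$drug_offset_sd)
    sdv <- spec$sd[[risk]]
    phi <- spec$ar1[[risk]]
    alt <- spec$alternans[[risk]]
    eps_sd <- sdv * sqrt(1 - phi^2)
    x <- matrix(0, per_drug, length)
    x[, 1] <- rnorm(per_drug, 0, sdv)
    for (t in seq(2, length.out = length - 1)) {
      x[, t] <- phi * x[, t - 1] + rnorm(per_drug, 0, eps_sd)
    }
    beats <- seq_len(length)
    x <- mu + x + matrix(alt * (-1)^beats, per_drug, length, byrow = TRUE)
    mats[[i]] <- x
    metas[[i]] <- tibble::tibble(
      drug = drugs$drug[i], risk = risk,
      sample_id = rep(seq_len(ceiling(per_drug / 4)), each = 4,
                      length.out = per_drug),
      multiplier = rep(1:4, length.out = per_drug),
      feature = feature
    )
  }
  new_variability_pool(dplyr::bind_rows(metas), do.call(rbind, mats))
}

#' Assemble a variability pool from simulated per-beat biomarkers
#'
#' Packs long-format variability series (as from [variability_series()],
#' one series per drug x sample x multiplier for a single feature) into the
#' matrix-backed pool container the classifier and evaluator consume.
#'
#' @param series Long tibble with columns `drug`, `risk`, `sample_id`,
#'   `multiplier`, `feature`, `beat`, `value`, covering exactly one feature
#'   and series of equal length.
#' @return A `variability_pool`.
#' @export
pool_from_series <- function(series) {
  stopifnot(is.data.frame(series))
  if (length(unique(series$feature)) != 1) {
    abort("`series` must cover exactly one feature")
  }
  series <- dplyr::arrange(series, .data$drug, .data$sample_id,
                           .data$multiplier, .data$beat)
  key <- paste(series$drug, series$sample_id, series$multiplier, sep = "\r")
  idx <- match(key, unique(key))
  lens <- table(idx)
  if (length(unique(lens)) != 1) abort("series must all have the same length")
  len <- unname(lens[1])
  first <- !duplicated(idx)
  meta <- tibble::tibble(
    drug = series$drug[first],
    risk = as.character(series$risk[first]),
    sample_id = series$sample_id[first],
    multiplier = series$multiplier[first],
    feature = series$feature[first]
  )
  values <- matrix(series$value, nrow = nrow(meta), ncol = len, byrow = TRUE)
  new_variability_pool(meta, values)
}
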