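QNET_CURRENTS <- c("INaL", "ICaL", "IKr", "IKs", "IK1", "Ito")

check_beat <- function(beat, cols) {
  miss <- setdiff(cols, names(beat))
  if (length(miss) > 0) {
    abort(paste0("beat trace is missing column(s): ", paste(miss, collapse = ", ")))
  }
  invisible(beat)
}

#' Net charge carried by the six qNet currents over one beat
#'
#' Trapezoidal integral over the beat of the pointwise sum of INaL, ICaL,
#' IKr, IKs, IK1 and Ito. Currents are in A/F with the inward-negative
#' convention and time in ms, so the result is in A/F*ms.
#'
#' @param beat A single-beat trace: tibble with a uniform `time` grid (ms) and
#'   one column per current.
#' @return qNet in A/F*ms.
#' @export
qnet <- function(beat) {
  check_beat(beat, c("time", QNET_CURRENTS))
  total <- rowSums(as.matrix(beat[, QNET_CURRENTS]))
  trapz_(beat$time, total)
}

#' Inward-charge ratio qInward of a drugged beat relative to control
#'
#' The mean of the drug/control area-under-curve ratios of the two inward
#' currents ICaL and INaL, each AUC being the trapezoidal integral of the
#' signed (inward-negative) current over the beat:
#' \deqn{qInward = \frac{1}{2}\left(\frac{AUC_{ICaL,drug}}{AUC_{ICaL,control}}
#'   + \frac{AUC_{INaL,drug}}{AUC_{INaL,control}}\right)}
#' Both areas are negative, so the ratios (and qInward) are positive; with no
#' drug effect qInward is exactly 1.
#'
#' @param drug_beat,control_beat Single-beat traces on the same time grid and
#'   beat index.
#' @return qInward, dimensionless.
#' @export
qinward <- function(drug_beat, control_beat) {
  check_beat(drug_beat, c("time", "ICaL", "INaL"))
  check_beat(control_beat, c("time", "ICaL", "INaL"))
  if (nrow(drug_beat) != nrow(control_beat) ||
      any(drug_beat$time != control_beat$time)) {
    abort("drug and control beats must share the same time grid")
  }
  auc <- function(b, cur) trapz_(b$time, b[[cur]])
  ctl_ical <- auc(control_beat, "ICaL")
  ctl_inal <- auc(control_beat, "INaL")
  if (ctl_ical == 0 || ctl_inal == 0) {
    abort("control AUC of ICaL or INaL is zero: qInward is undefined")
  }
  0.5 * (auc(drug_beat, "ICaL") / ctl_ical + auc(drug_beat, "INaL") / ctl_inal)
}

# Locate the upstroke (time of the sample ending the steepest rise) and the
# pre-upstroke baseline (mean over the 10 ms before the upstroke).
upstroke_info <- function(time, signal, baseline_ms = 10) {
  i <- which.max(diff(signal)) + 1L
  t_up <- time[i]
  pre <- time >= t_up - baseline_ms & time < t_up
  base <- if (any(pre)) mean(signal[pre]) else signal[1]
  list(index = i, t_up = t_up, baseline = base)
}

#' Duration from upstroke to fractional repolarization
#'
#' Time from the upstroke (instant of maximum first difference of the signal)
#' to the first subsequent crossing of `peak - fraction * (peak - baseline)`,
#' where the baseline is the mean signal over the 10 ms preceding the
#' upstroke and the crossing is located by linear interpolation between
#' samples. Applied to the membrane potential this yields APD50/APD90; applied
#' to the intracellular calcium transient it yields CaD50/CaD90.
#'
#' If the signal never recovers below the threshold before the end of the
#' beat the value is `end-of-beat - upstroke time` and the attached
#' `repolarized` attribute is `FALSE`.
#'
#' @param time Uniform time grid in ms.
#' @param signal Signal sampled on `time` (mV for Vm, concentration for Cai).
#' @param fraction Repolarization fraction, e.g. 0.5 or 0.9.
#' @return Duration in ms with logical attribute `repolarized`.
#' @export
duration_at_fraction <- function(time, signal, fraction) {
  stopifnot(length(time) == length(signal), length(time) >= 3)
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    abort("`fraction` must lie strictly between 0 and 1")
  }
  up <- upstroke_info(time, signal)
  after <- seq(up$index, length(signal))
  ipk <- after[which.max(signal[after])]
  peak <- signal[ipk]
  thr <- peak - fraction * (peak - up$baseline)
  below <- which(signal <= thr)
  below <- below[below > ipk]
  if (length(below) == 0) {
    out <- time[length(time)] - up$t_up
    attr(out, "repolarized") <- FALSE
    return(out)
  }
  j <- below[1]
  # linear interpolation between the last sample above and first at/below
  t_cross <- if (signal[j - 1] == signal[j]) time[j] else {
    time[j - 1] + (signal[j - 1] - thr) / (signal[j - 1] - signal[j]) *
      (time[j] - time[j - 1])
  }
  out <- t_cross - up$t_up
  attr(out, "repolarized") <- TRUE
  out
}

#' Maximal repolarization slope of the action potential
#'
#' The maximum of the first-difference quotient of Vm inside the window
#' bounded by the APD30 and APD90 crossing times. Normal monotone
#' repolarization yields a negative value (mV/ms); positive values flag
#' EAD-like re-depolarization inside the repolarization phase. The window
#' bounds are configurable.
#'
#' @param beat Single-beat trace with `time` and `vm` columns.
#' @param window Two repolarization fractions bounding the window
#'   (default `c(0.3, 0.9)`).
#' @return Slope in mV/ms.
#' @export
dvmdt_max_repol <- function(beat, window = c(0.3, 0.9)) {
  check_beat(beat, c("time", "vm"))
  up <- upstroke_info(beat$time, beat$vm)
  d_lo <- duration_at_fraction(beat$time, beat$vm, window[1])
  d_hi <- duration_at_fraction(beat$time, beat$vm, window[2])
  t_lo <- up$t_up + as.numeric(d_lo)
  t_hi <- up$t_up + as.numeric(d_hi)
  idx <- which(beat$time >= t_lo & beat$time <= t_hi)
  if (length(idx) < 2) abort("empty repolarization window")
  max(diff(beat$vm[idx]) / diff(beat$time[idx]))
}

#' All seven per-beat biomarkers for a drugged beat
#'
#' Computes qNet, qInward, APD50/APD90 (on Vm), CaD50/CaD90 (on the calcium
#' transient) and the maximal repolarization slope for one beat, pairing the
#' drugged beat with the matching control beat for qInward.
#'
#' @param drug_beat,control_beat Single-beat traces on matching grids with
#'   columns `time`, `vm`, `cai` and the six qNet currents.
#' @return A one-row tibble with columns `beat`, `qnet`, `qinward`, `apd50`,
#'   `apd90`, `cad50`, `cad90`, `dvmdt_max_repol` and `repolarized` (FALSE
#'   when the 90% Vm recovery was not reached within the beat).
#' @export
beat_features <- function(drug_beat, control_beat) {
  check_beat(drug_beat, c("time", "vm", "cai", QNET_CURRENTS))
  check_beat(control_beat, c("time", "vm", "cai", QNET_CURRENTS))
  apd90 <- duration_at_fraction(drug_beat$time, drug_beat$vm, 0.9)
  repol <- isTRUE(attr(apd90, "repolarized"))
  tibble::tibble(
    beat = if ("beat" %in% names(drug_beat)) drug_beat$beat[1] else NA_integer_,
    qnet = qnet(drug_beat),
    qinward = qinward(drug_beat, control_beat),
    apd50 = as.numeric(duration_at_fraction(drug_beat$time, drug_beat$vm, 0.5)),
    apd90 = as.numeric(apd90),
    cad50 = as.numeric(duration_at_fraction(drug_beat$time, drug_beat$cai, 0.5)),
    cad90 = as.numeric(duration_at_fraction(drug_beat$time, drug_beat$cai, 0.9)),
    dvmdt_max_repol = dvmdt_max_repol(drug_beat),
    repolarized = repol
  )
}

#' Steady-state beat-to-beat variability series
#'
#' Restricts a per-beat biomarker table to the final `window` beats (the
#' steady-state portion; beats 501-1000 in the reference protocol) and
#' returns the raw, untransformed beat-indexed series of each biomarker in
#' long format. No scaling is applied here; any normalization belongs to the
#' classifier.
#'
#' @param features Per-beat biomarker tibble (one row per beat, ordered), as
#'   built from [beat_features()].
#' @param window Number of trailing beats to keep (default 500).
#' @return Long tibble with columns `feature`, `beat`, `value` (plus any
#'   provenance columns `drug`, `risk`, `sample_id`, `multiplier` present in
#'   `features`).
#' @export
variability_series <- function(features, window = 500) {
  stopifnot(is.data.frame(features))
  if (nrow(features) < window) {
    abort(paste0(
      "need at least `window` = ", window, " beats, got ", nrow(features)
    ))
  }
  keep <- features[seq(nrow(features) - window + 1, nrow(features)), ]
  vals <- intersect(
    c("qnet", "qinward", "apd50", "apd90", "cad50", "cad90", "dvmdt_max_repol"),
    names(keep)
  )
  prov <- intersect(c("drug", "risk", "sample_id", "multiplier"), names(keep))
  out <- tidyr::pivot_longer(
    keep[, c(prov, "beat", vals)],
    cols = dplyr::all_of(vals),
    names_to = "feature", values_to = "value"
  )
  if (any(!is.finite(out$value))) {
    abort("variability series contain non-finite biomarker values")
  }
  dplyr::arrange(out[, c(prov, "feature", "beat", "value")], .data$feature, .data$beat)
}
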