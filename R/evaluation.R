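#' One-vs-rest ROC AUC (Mann-Whitney form)
#'
#' The probability that a randomly chosen positive example outranks a
#' randomly chosen negative one, with ties counted as 1/2 — equivalently the
#' area under the one-vs-rest ROC curve.
#'
#' @param labels True classes.
#' @param scores Numeric score for the positive class (e.g. its predicted
#'   probability).
#' @param positive The positive class.
#' @return AUC in \[0, 1\], or `NA` when only one class is present.
#' @examples
#' roc_auc_ovr(c("a", "a", "b", "b"), c(0.9, 0.4, 0.6, 0.2), positive = "a")
#' @export
roc_auc_ovr <- function(labels, scores, positive) {
  stopifnot(length(labels) == length(scores))
  pos <- labels == positive
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores)   # average ranks handle ties as 1/2
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Confusion metrics: per-class likelihood ratios, accuracy and F1
#'
#' One-vs-rest diagnostic likelihood ratios per risk class —
#' `LR+ = sensitivity / (1 - specificity)` and
#' `LR- = (1 - sensitivity) / specificity`, with division by zero yielding
#' `Inf` and 0/0 yielding `NA` — plus overall accuracy and the F1 score
#' (macro-averaged over the three classes by default).
#'
#' @param labels True classes (character or factor over
#'   high/intermediate/low).
#' @param predictions Hard predicted classes, aligned with `labels`.
#' @param f1 `"macro"` (default) or `"micro"` averaging.
#' @return A list with `per_class` (tibble: class, sensitivity, specificity,
#'   lr_pos, lr_neg, f1), `accuracy` and `f1`.
#' @export
confusion_metrics <- function(labels, predictions, f1 = c("macro", "micro")) {
  f1 <- match.arg(f1)
  if (length(labels) == 0) abort("`labels` must be non-empty")
  if (length(labels) != length(predictions)) {
    abort("`labels` and `predictions` must have the same length")
  }
  labels <- factor(as.character(labels), levels = TDP_RISKS)
  predictions <- factor(as.character(predictions), levels = TDP_RISKS)
  ratio_ <- function(num, den) {
    if (den > 0) num / den else if (num > 0) Inf else NA_real_
  }
  per <- lapply(TDP_RISKS, function(cl) {
    tp <- sum(labels == cl & predictions == cl)
    fn <- sum(labels == cl & predictions != cl)
    fp <- sum(labels != cl & predictions == cl)
    tn <- sum(labels != cl & predictions != cl)
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    tibble::tibble(
      class = cl, sensitivity = sens, specificity = spec,
      lr_pos = ratio_(sens, 1 - spec),
      lr_neg = ratio_(1 - sens, spec),
      f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
    )
  })
  per <- dplyr::bind_rows(per)
  f1_overall <- if (f1 == "macro") {
    mean(per$f1, na.rm = TRUE)
  } else {
    sum(labels == predictions) / length(labels)   # micro F1 = accuracy (3-class)
  }
  list(per_class = per,
       accuracy = mean(labels == predictions),
       f1 = f1_overall)
}

#' Repeated-resampling evaluation of a trained classifier
#'
#' The 10,000-test procedure: each iteration draws exactly one variability
#' series per test drug uniformly from that drug's full (sample x
#' multiplier) pool, predicts all drugs, and computes per-class one-vs-rest
#' AUC from the class probabilities together with likelihood ratios,
#' accuracy and F1 from the argmax labels. Metrics are summarized as median,
#' minimum and maximum across iterations (missing-value sentinels from
#' single-class iterations are skipped; `Inf` likelihood ratios are carried
#' on the extended real line).
#'
#' @param model A trained `tdp_cnn`.
#' @param pool A `variability_pool` of test-drug series; its series length
#'   must match the model input length.
#' @param n_iter Number of resampled test sets (default 10,000).
#' @param seed Integer seed; fixed seeds give identical summaries.
#' @param f1 F1 averaging, `"macro"` (default) or `"micro"`.
#' @return A `tdp_test_summary`: `summary` tibble (metric, class, median,
#'   min, max), per-iteration records in `iterations`, and `n_iterations`.
#' @export
run_repeated_test <- function(model, pool, n_iter = 10000, seed = NULL,
                              f1 = c("macro", "micro")) {
  f1 <- match.arg(f1)
  stopifnot(inherits(model, "tdp_cnn"), inherits(pool, "variability_pool"))
  if (n_iter < 1) abort("`n_iter` must be >= 1")
  if (ncol(pool$values) != model$config$input_length) {
    abort("pool series length does not match the model input length")
  }
  local_seed_(seed)
  drugs <- unique(pool$meta[, c("drug", "risk")])
  n_drug <- nrow(drugs)
  by_drug <- lapply(drugs$drug, function(d) which(pool$meta$drug == d))

  # draw all iterations up front, predict each distinct series once
  draw <- vapply(by_drug, function(idx) {
    idx[sample.int(length(idx), n_iter, replace = TRUE)]
  }, integer(n_iter))
  draw <- matrix(draw, nrow = n_iter)
  uniq <- sort(unique(as.vector(draw)))
  P_all <- predict_matrix_(model, pool$values[uniq, , drop = FALSE])
  lookup <- match(draw, uniq)
  dim(lookup) <- dim(draw)

  truth <- as.character(drugs$risk)
  iter_rows <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    P <- P_all[lookup[it, ], , drop = FALSE]
    hard <- TDP_RISKS[max.col(P, ties.method = "first")]
    cm <- confusion_metrics(truth, hard, f1 = f1)
    auc <- vapply(TDP_RISKS, function(cl) {
      roc_auc_ovr(truth, P[, cl], positive = cl)
    }, 0)
    iter_rows[[it]] <- c(
      iteration = it, accuracy = cm$accuracy, f1 = cm$f1,
      setNames(auc, paste0("auc_", TDP_RISKS)),
      setNames(cm$per_class$lr_pos, paste0("lr_pos_", TDP_RISKS)),
      setNames(cm$per_class$lr_neg, paste0("lr_neg_", TDP_RISKS))
    )
  }
  iters <- tibble::as_tibble(do.call(rbind, iter_rows))

  summ3 <- function(v) {
    v <- unname(v[!is.na(v)])
    if (length(v) == 0) return(c(median = NA_real_, min = NA_real_, max = NA_real_))
    c(median = unname(median(v)), min = min(v), max = max(v))
  }
  rows <- list()
  for (cl in TDP_RISKS) {
    for (metric in c("auc", "lr_pos", "lr_neg")) {
      s <- summ3(iters[[paste0(metric, "_", cl)]])
      rows[[length(rows) + 1]] <- tibble::tibble(
        metric = metric, class = cl,
        median = unname(s["median"]), min = unname(s["min"]),
        max = unname(s["max"])
      )
    }
  }
  for (metric in c("accuracy", "f1")) {
    s <- summ3(iters[[metric]])
    rows[[length(rows) + 1]] <- tibble::tibble(
      metric = metric, class = "overall",
      median = unname(s["median"]), min = unname(s["min"]),
      max = unname(s["max"])
    )
  }
  structure(
    list(summary = dplyr::bind_rows(rows), iterations = iters,
         n_iterations = as.integer(n_iter)),
    class = "tdp_test_summary"
  )
}

#' @export
print.tdp_test_summary <- function(x, ...) {
  cat("<tdp_test_summary:", x$n_iterations, "iterations>\n")
  s <- x$summary
  fmt <- function(v) ifelse(is.finite(v), sprintf("%.2f", v),
                            ifelse(is.infinite(v), "Inf", "NA"))
  lines <- paste0(
    format(s$metric, width = 9), " ", format(s$class, width = 12),
    fmt(s$median), " (", fmt(s$min), "-", fmt(s$max), ")"
  )
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
tidy.tdp_test_summary <- function(x, ...) x$summary

#' @export
glance.tdp_test_summary <- function(x, ...) {
  s <- x$summary
  val <- function(m, cl) s$median[s$metric == m & s$class == cl]
  tibble::tibble(
    n_iterations = x$n_iterations,
    auc_high = val("auc", "high"),
    auc_intermediate = val("auc", "intermediate"),
    auc_low = val("auc", "low"),
    accuracy = val("accuracy", "overall"),
    f1 = val("f1", "overall")
  )
}
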