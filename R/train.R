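#' Assemble a training set from a variability pool
#'
#' Draws `per_drug` series per training drug uniformly without replacement
#' from that drug's full (sample x multiplier) pool. With the 12 training
#' drugs and `per_drug = 50` this is the 600-row training set of the
#' reference configuration.
#'
#' @param pool A `variability_pool`.
#' @param drugs Tibble of training drugs (`drug`, `risk`).
#' @param per_drug Series drawn per drug (default 50).
#' @param seed Integer seed; fixed seeds give identical selections.
#' @return A `tdp_training_set`: series matrix `x` (rows = samples), `labels`
#'   (factor high/intermediate/low) and `drug` of origin per row.
#' @export
assemble_training_set <- function(pool, drugs, per_drug = 50, seed = NULL) {
  stopifnot(inherits(pool, "variability_pool"), is.data.frame(drugs))
  local_seed_(seed)
  rows <- lapply(seq_len(nrow(drugs)), function(i) {
    idx <- which(pool$meta$drug == drugs$drug[i])
    if (length(idx) < per_drug) {
      abort(paste0("pool has only ", length(idx), " series for drug '",
                   drugs$drug[i], "' (need ", per_drug, ")"))
    }
    sample(idx, per_drug)
  })
  idx <- unlist(rows)
  out <- list(
    x = pool$values[idx, , drop = FALSE],
    labels = factor(pool$meta$risk[idx], levels = TDP_RISKS),
    drug = pool$meta$drug[idx]
  )
  class(out) <- "tdp_training_set"
  out
}

#' @export
print.tdp_training_set <- function(x, ...) {
  cat("<tdp_training_set: ", nrow(x$x), " series x ", ncol(x$x), " beats, ",
      length(unique(x$drug)), " drugs>\n", sep = "")
  print(table(x$labels))
  invisible(x)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(p) list(m = p * 0, v = p * 0)

adam_step <- function(p, g, st, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$m <- b1 * st$m + (1 - b1) * g
  st$v <- b2 * st$v + (1 - b2) * g^2
  mhat <- st$m / (1 - b1^t)
  vhat <- st$v / (1 - b2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), st = st)
}

# initialize network weights from the current RNG stream (no re-seeding)
new_cnn_ <- function(config) {
  lens <- cnn_stage_lengths(config)
  layers <- list()
  c_in <- 1L
  for (s in seq_along(config$stage_convs)) {
    for (l in seq_len(config$stage_convs[s])) {
      layers[[length(layers) + 1L]] <- list(
        stage = s,
        # small positive bias keeps units alive for whole-series-negative
        # inputs, which would otherwise collapse to exactly tied outputs
        W = he_init_(config$kernel * c_in, config$filters),
        b = rep(0.1, config$filters)
      )
      c_in <- config$filters
    }
  }
  flat <- lens[length(lens)] * config$filters
  structure(
    list(config = config, stage_lengths = lens, flatten_dim = flat,
         conv = layers,
         bn = list(gamma = rep(1, config$filters), beta = rep(0, config$filters),
                   mean = rep(0, config$filters), var = rep(1, config$filters)),
         W1 = he_init_(flat, config$hidden), b1 = rep(0, config$hidden),
         # zero-initialized output layer: class scores start neutral, so the
         # small Adam steps of the reference learning rate immediately move
         # the decision in the gradient direction instead of having to
         # overcome a random initial argmax
         W2 = matrix(0, config$hidden, config$classes),
         b2 = rep(0, config$classes),
         labels = TDP_RISKS, center = 0, scale = 1, trained = FALSE),
    class = "tdp_cnn"
  )
}

cnn_eval_ <- function(model, X, yidx) {
  P <- predict_matrix_(model, X, standardized = TRUE)
  probs <- P[cbind(seq_len(nrow(P)), yidx)]
  list(loss = mean(-log(pmax(probs, 1e-12))),
       acc = mean(max.col(P, ties.method = "first") == yidx))
}

# One fold's full Adam schedule; the heavy loop lives in src/cnn_ops.cpp and
# draws its shuffling/dropout randomness from R's RNG stream.
train_one_ <- function(config, Xtr, ytr) {
  model <- new_cnn_(config)
  res <- cpp_cnn_train(
    Xtr, as.integer(ytr),
    lapply(model$conv, `[[`, "W"), lapply(model$conv, `[[`, "b"),
    model$bn$gamma, model$bn$beta, model$bn$mean, model$bn$var,
    model$W1, model$b1, model$W2, model$b2,
    as.integer(config$stage_convs), as.integer(config$pool),
    as.integer(config$pool_stride), as.integer(config$kernel),
    as.integer(config$classes), config$dropout, config$lr,
    as.integer(config$batch_size), as.integer(config$epochs)
  )
  for (li in seq_along(model$conv)) {
    model$conv[[li]]$W <- res$conv_W[[li]]
    model$conv[[li]]$b <- as.numeric(res$conv_b[[li]])
  }
  model$bn$gamma <- as.numeric(res$bn_gamma)
  model$bn$beta <- as.numeric(res$bn_beta)
  model$bn$mean <- as.numeric(res$bn_mean)
  model$bn$var <- as.numeric(res$bn_var)
  model$W1 <- res$W1; model$b1 <- as.numeric(res$b1)
  model$W2 <- res$W2; model$b2 <- as.numeric(res$b2)
  model
}

#' Train the CNN classifier with k-fold cross-validation
#'
#' Minimizes categorical cross-entropy with Adam at the configured learning
#' rate, batch size and epoch count; runs `config$folds`-fold sample-level
#' stratified cross-validation and retains the fold model with the highest
#' mean of training and validation accuracy (ties broken by lower validation
#' loss). Inputs are standardized by the training-set global mean/sd, stored
#' with the model. All randomness flows from `config$seed`.
#'
#' @param training_set A `tdp_training_set` from [assemble_training_set()]
#'   (or any list with `x` and `labels`); must contain at least two classes.
#' @param config A [cnn_config()].
#' @return A trained `tdp_cnn` with the cross-validation history in
#'   `$history` and the retained fold in `$selected_fold`.
#' @export
train_cnn <- function(training_set, config = cnn_config()) {
  x <- training_set$x
  labels <- factor(training_set$labels, levels = TDP_RISKS)
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  if (ncol(x) != config$input_length) {
    abort(paste0("series length ", ncol(x), " does not match config input_length ",
                 config$input_length))
  }
  if (length(unique(labels[!is.na(labels)])) < 2) {
    abort("training set is degenerate: fewer than 2 classes present")
  }
  local_seed_(config$seed)
  # global z-scoring by the training-pool mean/sd: zero-centering the pool
  # places the three class levels on both sides of zero, so each class
  # activates a different ReLU pattern and all of them stay separable at
  # the reference learning rate
  center <- if (config$standardize) mean(x) else 0
  scl <- if (config$standardize) max(sd(x), 1e-12) else 1
  Xs <- (x - center) / scl
  yidx <- as.integer(labels)
  n <- nrow(Xs)

  # sample-level stratified fold assignment
  fold_id <- integer(n)
  for (cl in unique(yidx)) {
    idx <- sample(which(yidx == cl))
    fold_id[idx] <- rep(seq_len(config$folds), length.out = length(idx))
  }

  history <- vector("list", config$folds)
  models <- vector("list", config$folds)
  for (f in seq_len(config$folds)) {
    tr <- if (config$folds == 1) seq_len(n) else which(fold_id != f)
    va <- if (config$folds == 1) seq_len(n) else which(fold_id == f)
    m <- train_one_(config, Xs[tr, , drop = FALSE], yidx[tr])
    m$center <- center; m$scale <- scl
    ev_tr <- cnn_eval_(m, Xs[tr, , drop = FALSE], yidx[tr])
    ev_va <- cnn_eval_(m, Xs[va, , drop = FALSE], yidx[va])
    models[[f]] <- m
    history[[f]] <- tibble::tibble(
      fold = f, train_loss = ev_tr$loss, train_acc = ev_tr$acc,
      val_loss = ev_va$loss, val_acc = ev_va$acc,
      mean_acc = (ev_tr$acc + ev_va$acc) / 2
    )
  }
  history <- dplyr::bind_rows(history)
  ord <- order(-history$mean_acc, history$val_loss)
  best <- history$fold[ord[1]]
  model <- models[[best]]
  model$trained <- TRUE
  model$history <- history
  model$selected_fold <- best
  model
}

predict_matrix_ <- function(model, X, standardized = FALSE, chunk = 1024L) {
  if (!standardized) X <- (X - model$center) / model$scale
  n <- nrow(X)
  out <- matrix(NA_real_, n, model$config$classes)
  b0 <- 1L
  while (b0 <= n) {
    rows <- b0:min(b0 + chunk - 1L, n)
    out[rows, ] <- cnn_forward(model, X[rows, , drop = FALSE],
                               training = FALSE)$P
    b0 <- b0 + chunk
  }
  colnames(out) <- model$labels
  out
}

#' Predict TdP-risk class probabilities
#'
#' Softmax probabilities for the three risk classes; inference is
#' deterministic (dropout disabled, batch-norm running statistics).
#'
#' @param object A trained `tdp_cnn`.
#' @param newdata A numeric series of the model's input length, a matrix of
#'   series (rows = samples), or a `variability_pool`.
#' @param type `"prob"` (default) for class probabilities, `"class"` for the
#'   argmax hard label.
#' @param ... Unused.
#' @return A tibble with columns `p_high`, `p_intermediate`, `p_low` (and
#'   `.pred_class` for `type = "class"` a factor vector instead).
#' @export
predict.tdp_cnn <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "variability_pool")) newdata <- newdata$values
  if (is.vector(newdata) && is.numeric(newdata)) newdata <- matrix(newdata, 1)
  stopifnot(is.matrix(newdata))
  if (ncol(newdata) != object$config$input_length) {
    abort(paste0("series length ", ncol(newdata),
                 " does not match the model input length ",
                 object$config$input_length))
  }
  P <- predict_matrix_(object, newdata)
  if (type == "class") {
    return(factor(object$labels[max.col(P, ties.method = "first")], levels = object$labels))
  }
  tibble::tibble(p_high = P[, "high"], p_intermediate = P[, "intermediate"],
                 p_low = P[, "low"])
}

#' @export
tidy.tdp_cnn <- function(x, ...) {
  if (is.null(x$history)) {
    abort("model has no training history (untrained)")
  }
  x$history
}

#' @export
glance.tdp_cnn <- function(x, ...) {
  h <- x$history
  sel <- if (!is.null(h)) h[h$fold == x$selected_fold, ] else NULL
  tibble::tibble(
    trained = isTRUE(x$trained),
    flatten_dim = x$flatten_dim,
    folds = x$config$folds,
    epochs = x$config$epochs,
    selected_fold = x$selected_fold %||% NA_integer_,
    train_acc = if (!is.null(sel)) sel$train_acc else NA_real_,
    val_acc = if (!is.null(sel)) sel$val_acc else NA_real_,
    val_loss = if (!is.null(sel)) sel$val_loss else NA_real_
  )
}
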