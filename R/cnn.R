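#' Configuration of the 1-D CNN TdP-risk classifier
#'
#' The printed reference architecture: six convolution stages with 4/3/2/2/1/1
#' convolution layers (13 in all), each with five filters of width 2 and
#' stride 1 without padding, ReLU activations throughout, one max-pooling
#' layer per stage (pool width 2 for stages 1-4 and 4 for stages 5-6, always
#' stride 2), batch normalization at the end of stage 1, a flatten (5 x 5 ->
#' 25 for input length 500), 20% dropout, a 10-unit ReLU hidden layer and a
#' 3-unit softmax output. Training uses categorical cross-entropy with Adam
#' at learning rate 1e-5, batch size 20, 300 epochs and 10-fold
#' cross-validation.
#'
#' @param input_length Series length fed to the network (default 500).
#' @param stage_convs Convolution layers per stage.
#' @param filters,kernel Filters per convolution and kernel width.
#' @param pool Pool width per stage (stride fixed at 2).
#' @param hidden Hidden-layer units.
#' @param dropout Dropout rate on the flattened features.
#' @param classes Number of risk classes.
#' @param lr,batch_size,epochs,folds Training hyperparameters.
#' @param standardize Standardize inputs by the training-pool mean/sd
#'   (stored with the model).
#' @param seed Seed from which all randomness (initialization, fold split,
#'   shuffling, dropout) flows.
#' @return A `cnn_config` object.
#' @export
cnn_config <- function(input_length = 500, stage_convs = c(4, 3, 2, 2, 1, 1),
                       filters = 5, kernel = 2, pool = c(2, 2, 2, 2, 4, 4),
                       hidden = 10, dropout = 0.2, classes = 3,
                       lr = 1e-5, batch_size = 20, epochs = 300, folds = 10,
                       standardize = TRUE, seed = 1) {
  stopifnot(length(stage_convs) == length(pool), input_length >= 1)
  structure(
    list(input_length = as.integer(input_length), stage_convs = stage_convs,
         filters = filters, kernel = kernel, pool = pool, pool_stride = 2,
         hidden = hidden, dropout = dropout, classes = classes, lr = lr,
         batch_size = batch_size, epochs = epochs, folds = folds,
         standardize = standardize, seed = seed),
    class = "cnn_config"
  )
}

#' Stage-wise output lengths of the CNN for a given input length
#'
#' Valid (unpadded) convolution shortens a length-L input by `kernel - 1` per
#' convolution layer; max pooling maps L to `floor((L - pool) / 2) + 1`.
#' For input length 500 the stage outputs are 248, 122, 60, 29, 13 and 5.
#'
#' @param config A [cnn_config()].
#' @return Integer vector of post-pooling lengths, one per stage.
#' @export
cnn_stage_lengths <- function(config) {
  L <- config$input_length
  out <- integer(length(config$stage_convs))
  for (s in seq_along(config$stage_convs)) {
    L <- L - config$stage_convs[s] * (config$kernel - 1)
    L <- floor((L - config$pool[s]) / config$pool_stride) + 1
    out[s] <- L
    if (L < 1) {
      abort(paste0(
        "input_length ", config$input_length, " is too short for the stage ",
        "arithmetic: stagewise lengths ",
        paste(out[seq_len(s)], collapse = ", "), " (stage ", s, " collapses)"
      ))
    }
  }
  out
}

# He initialization: variance 2/fan-in, the standard scaling for ReLU layers
he_init_ <- function(nr, nc) {
  matrix(rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
}

#' Build an untrained CNN
#'
#' Instantiates the network of a [cnn_config()], checking the stage
#' arithmetic (for input length 500 the pre-flatten tensor is 5 time steps x
#' 5 channels, flattened to 25) and drawing initial weights from the config
#' seed.
#'
#' @param config A [cnn_config()].
#' @return An untrained `tdp_cnn` model object.
#' @export
build_cnn <- function(config = cnn_config()) {
  lens <- cnn_stage_lengths(config)
  local_seed_(config$seed)
  layers <- list()
  c_in <- 1L
  for (s in seq_along(config$stage_convs)) {
    for (l in seq_len(config$stage_convs[s])) {
      layers[[length(layers) + 1L]] <- list(
        stage = s,
        W = he_init_(config$kernel * c_in, config$filters),
        b = rep(0.1, config$filters)
      )
      c_in <- config$filters
    }
  }
  flat <- lens[length(lens)] * config$filters
  model <- list(
    config = config,
    stage_lengths = lens,
    flatten_dim = flat,
    conv = layers,
    bn = list(gamma = rep(1, config$filters), beta = rep(0, config$filters),
              mean = rep(0, config$filters), var = rep(1, config$filters)),
    W1 = he_init_(flat, config$hidden), b1 = rep(0, config$hidden),
    # output layer starts at zero so initial class scores are neutral
    W2 = matrix(0, config$hidden, config$classes),
    b2 = rep(0, config$classes),
    labels = TDP_RISKS,
    center = 0, scale = 1,
    trained = FALSE
  )
  class(model) <- "tdp_cnn"
  model
}

#' @export
print.tdp_cnn <- function(x, ...) {
  cat("<tdp_cnn: input", x$config$input_length, "-> stages [",
      paste(x$stage_lengths, collapse = ", "), "] -> flatten",
      x$flatten_dim, "->", x$config$hidden, "->", x$config$classes, ">\n")
  cat(if (isTRUE(x$trained)) "  trained" else "  untrained", "\n")
  invisible(x)
}

# ---- forward / backward ----------------------------------------------------
# Activations are 3-D arrays dim (length, batch, channels); the convolution
# and pooling kernels live in src/cnn_ops.cpp.

conv_fwd <- function(A, W, b, kernel) {
  out <- cpp_conv_fwd(A, W, b, kernel)$out
  list(out = out, A = A)
}

conv_bwd <- function(cache, dOut, W, kernel) {
  r <- cpp_conv_bwd(cache$A, cache$out, dOut, W, kernel)
  list(dA = r$dA, dW = r$dW, db = as.numeric(r$db))
}

pool_fwd <- function(A, k, stride) {
  r <- cpp_pool_fwd(A, k, stride)
  list(out = r$out, arg = r$arg, L = dim(A)[1])
}

pool_bwd <- function(cache, dOut, k, stride) {
  cpp_pool_bwd(cache$arg, dOut, cache$L, k, stride)
}

bn_fwd <- function(A, bn, training, momentum = 0.9, eps = 1e-5) {
  dm <- dim(A)
  X <- matrix(A, dm[1] * dm[2], dm[3])
  if (training) {
    mu <- colMeans(X)
    v <- colMeans(sweep(X, 2, mu)^2)
    bn$mean <- momentum * bn$mean + (1 - momentum) * mu
    bn$var <- momentum * bn$var + (1 - momentum) * v
  } else {
    mu <- bn$mean
    v <- bn$var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(X, 2, mu), 2, invstd, `*`)
  Y <- sweep(sweep(xhat, 2, bn$gamma, `*`), 2, bn$beta, `+`)
  list(out = array(Y, dm), xhat = xhat, invstd = invstd, bn = bn, dimA = dm)
}

bn_bwd <- function(cache, dOut, gamma) {
  dm <- cache$dimA
  dY <- matrix(dOut, dm[1] * dm[2], dm[3])
  N <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2, gamma, `*`)
  dX <- sweep(
    (dxhat
     - rep(colSums(dxhat) / N, each = N)
     - cache$xhat * rep(colSums(dxhat * cache$xhat) / N, each = N)),
    2, cache$invstd, `*`)
  list(dA = array(dX, dm), dgamma = dgamma, dbeta = dbeta)
}

cnn_forward <- function(model, X, training = FALSE, dropout_mask = NULL) {
  cfg <- model$config
  B <- nrow(X)
  A <- array(t(X), c(cfg$input_length, B, 1))
  caches <- list()
  li <- 0L
  for (s in seq_along(cfg$stage_convs)) {
    for (l in seq_len(cfg$stage_convs[s])) {
      li <- li + 1L
      cc <- conv_fwd(A, model$conv[[li]]$W, model$conv[[li]]$b, cfg$kernel)
      caches[[length(caches) + 1L]] <- list(type = "conv", idx = li, c = cc)
      A <- cc$out
    }
    pc <- pool_fwd(A, cfg$pool[s], cfg$pool_stride)
    caches[[length(caches) + 1L]] <- list(type = "pool", k = cfg$pool[s], c = pc)
    A <- pc$out
    if (s == 1) {
      bc <- bn_fwd(A, model$bn, training)
      caches[[length(caches) + 1L]] <- list(type = "bn", c = bc)
      model$bn <- bc$bn
      A <- bc$out
    }
  }
  dmA <- dim(A)
  Xf <- t(matrix(aperm(A, c(1, 3, 2)), dmA[1] * dmA[3], dmA[2]))
  drop_mask <- NULL
  if (training && cfg$dropout > 0) {
    drop_mask <- dropout_mask %||%
      matrix(stats::rbinom(length(Xf), 1, 1 - cfg$dropout) / (1 - cfg$dropout),
             nrow(Xf), ncol(Xf))
    Xf <- Xf * drop_mask
  }
  Z1 <- Xf %*% model$W1 + rep(model$b1, each = B)
  H <- Z1 * (Z1 > 0)
  logits <- H %*% model$W2 + rep(model$b2, each = B)
  mx <- apply(logits, 1, max)
  E <- exp(logits - mx)
  P <- E / rowSums(E)
  list(P = P, model = model,
       cache = list(caches = caches, Xf = Xf, drop_mask = drop_mask,
                    Z1 = Z1, H = H, dim_flat = dmA))
}

cnn_backward <- function(model, fwd, Y) {
  cfg <- model$config
  B <- nrow(Y)
  grads <- list(conv = vector("list", length(model$conv)))
  dlogits <- (fwd$P - Y) / B
  grads$W2 <- crossprod(fwd$cache$H, dlogits)
  grads$b2 <- colSums(dlogits)
  dH <- dlogits %*% t(model$W2)
  dZ1 <- dH * (fwd$cache$Z1 > 0)
  grads$W1 <- crossprod(fwd$cache$Xf, dZ1)
  grads$b1 <- colSums(dZ1)
  dXf <- dZ1 %*% t(model$W1)
  if (!is.null(fwd$cache$drop_mask)) dXf <- dXf * fwd$cache$drop_mask
  dmA <- fwd$cache$dim_flat
  dA <- aperm(array(t(dXf), c(dmA[1], dmA[3], dmA[2])), c(1, 3, 2))
  for (i in rev(seq_along(fwd$cache$caches))) {
    entry <- fwd$cache$caches[[i]]
    if (entry$type == "bn") {
      bb <- bn_bwd(entry$c, dA, model$bn$gamma)
      grads$bn_gamma <- bb$dgamma
      grads$bn_beta <- bb$dbeta
      dA <- bb$dA
    } else if (entry$type == "pool") {
      dA <- pool_bwd(entry$c, dA, entry$k, cfg$pool_stride)
    } else {
      cb <- conv_bwd(entry$c, dA, model$conv[[entry$idx]]$W, cfg$kernel)
      grads$conv[[entry$idx]] <- list(dW = cb$dW, db = cb$db)
      dA <- cb$dA
    }
  }
  grads
}
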