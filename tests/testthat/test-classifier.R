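test_that("stage arithmetic reproduces the printed architecture for input 500", {
  cfg <- cnn_config()
  expect_equal(cnn_stage_lengths(cfg), c(248, 122, 60, 29, 13, 5))
  m <- build_cnn(cfg)
  expect_equal(m$flatten_dim, 25)
  expect_equal(m$stage_lengths[length(m$stage_lengths)], 5)  # 5 time steps
  expect_equal(cfg$filters, 5)                               # x 5 channels
  expect_equal(length(m$conv), 13)                           # 4+3+2+2+1+1
})

test_that("too-short inputs fail with the stagewise lengths reported", {
  expect_error(cnn_stage_lengths(cnn_config(input_length = 30)),
               "stagewise lengths")
})

test_that("assemble_training_set draws per-drug rows without replacement, seeded", {
  drugs <- dplyr::filter(fixture_drugs(), split == "train")
  pool <- gen_variability_pool(drugs, per_drug = 20, length = 40, seed = 51)
  ts <- assemble_training_set(pool, drugs, per_drug = 10, seed = 52)
  expect_equal(nrow(ts$x), 12 * 10)
  expect_equal(as.vector(table(ts$labels)), c(40, 40, 40))
  ts2 <- assemble_training_set(pool, drugs, per_drug = 10, seed = 52)
  expect_identical(ts$x, ts2$x)
  expect_error(assemble_training_set(pool, drugs, per_drug = 21, seed = 1),
               "Bepridil")
})

test_that("training on separable data reaches high accuracy via fold selection", {
  ts <- tiny_separable_set()
  cfg <- tiny_cnn_config(epochs = 300, folds = 3, seed = 3)
  fit <- train_cnn(ts, cfg)
  sel <- fit$history[fit$history$fold == fit$selected_fold, ]
  expect_gte(sel$train_acc, 0.95)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(tidy(fit)), 3)
})

test_that("training is deterministic under a fixed config seed", {
  ts <- tiny_separable_set(n_per = 10)
  cfg <- tiny_cnn_config(epochs = 3, folds = 2, seed = 17)
  f1 <- train_cnn(ts, cfg)
  f2 <- train_cnn(ts, cfg)
  expect_identical(f1$history$val_loss, f2$history$val_loss)
  expect_identical(f1$W2, f2$W2)
})

test_that("degenerate single-class training sets are rejected", {
  ts <- tiny_separable_set(n_per = 10)
  ts$labels <- factor(rep("high", 30), levels = TDP_RISKS)
  expect_error(train_cnn(ts, tiny_cnn_config()), "2 classes")
})

test_that("predictions are normalized, deterministic, and length-checked", {
  m <- build_cnn(tiny_cnn_config(seed = 5))
  X <- matrix(rnorm(6 * 40), 6)
  p <- predict(m, X)
  expect_equal(rowSums(as.matrix(p)), rep(1, 6), tolerance = 1e-6)
  expect_true(all(as.matrix(p) >= 0))
  expect_identical(predict(m, X), predict(m, X))
  expect_error(predict(m, matrix(rnorm(10), 1)), "length")
  cls <- predict(m, X, type = "class")
  expect_s3_class(cls, "factor")
  expect_equal(levels(cls), TDP_RISKS)
})

test_that("the C++ training step matches the R reference implementation", {
  cfg <- tiny_cnn_config(dropout = 0, epochs = 1, batch_size = 16,
                         lr = 1e-3, seed = 9)
  withr::with_seed(100, {
    X <- matrix(rnorm(16 * 40), 16)
    y <- rep(1:3, length.out = 16)
  })
  # R reference: one full-batch gradient + one Adam step
  withr::with_seed(5, m0 <- tdprisk:::new_cnn_(cfg))
  Y <- matrix(0, 16, 3); Y[cbind(1:16, y)] <- 1
  fwd <- tdprisk:::cnn_forward(m0, X, training = TRUE)
  g <- tdprisk:::cnn_backward(m0, fwd, Y)
  ref_W2 <- tdprisk:::adam_step(m0$W2, g$W2, tdprisk:::adam_init(m0$W2),
                                cfg$lr, 1)$p
  ref_c1 <- tdprisk:::adam_step(m0$conv[[1]]$W, g$conv[[1]]$dW,
                                tdprisk:::adam_init(m0$conv[[1]]$W),
                                cfg$lr, 1)$p
  withr::with_seed(5, m1 <- tdprisk:::train_one_(cfg, X, y))
  expect_equal(m1$W2, ref_W2, tolerance = 1e-12)
  expect_equal(m1$conv[[1]]$W, ref_c1, tolerance = 1e-12)
})

test_that("analytic gradients match numeric differentiation", {
  cfg <- cnn_config(input_length = 40, stage_convs = c(2, 1), pool = c(2, 2),
                    filters = 3, hidden = 4, dropout = 0, seed = 7)
  m <- build_cnn(cfg)
  withr::with_seed(8, {
    X <- matrix(rnorm(4 * 40), 4)
    Y <- diag(3)[c(1, 2, 3, 1), ]
  })
  fwd <- tdprisk:::cnn_forward(m, X, training = TRUE)
  g <- tdprisk:::cnn_backward(m, fwd, Y)
  loss_at <- function(model) {
    f <- tdprisk:::cnn_forward(model, X, training = TRUE)
    -mean(log(rowSums(f$P * Y)))
  }
  num_grad <- function(setter) {
    eps <- 1e-6
    (loss_at(setter(m, eps)) - loss_at(setter(m, -eps))) / (2 * eps)
  }
  expect_equal(num_grad(function(m, e) { m$W1[2, 1] <- m$W1[2, 1] + e; m }),
               g$W1[2, 1], tolerance = 1e-5)
  expect_equal(num_grad(function(m, e) { m$conv[[1]]$W[1, 2] <- m$conv[[1]]$W[1, 2] + e; m }),
               g$conv[[1]]$dW[1, 2], tolerance = 1e-5)
  expect_equal(num_grad(function(m, e) { m$conv[[3]]$W[2, 3] <- m$conv[[3]]$W[2, 3] + e; m }),
               g$conv[[3]]$dW[2, 3], tolerance = 1e-5)
  expect_equal(num_grad(function(m, e) { m$bn$gamma[1] <- m$bn$gamma[1] + e; m }),
               g$bn_gamma[1], tolerance = 1e-5)
})
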