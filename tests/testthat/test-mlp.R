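test_that("tansig is the hyperbolic tangent sigmoid", {
  expect_identical(tansig(0), 0)
  expect_equal(tansig(1), 2 / (1 + exp(-2)) - 1)
  expect_equal(tansig(1), 0.761594, tolerance = 1e-6)
  expect_equal(tansig(-1), -tansig(1))
  expect_equal(tansig(1e3), 1)  # saturation
})

test_that("forward pass: zero weights, nested hand example, loop oracle", {
  m0 <- mlp_init(3, 2, 2, seed = 1)
  m0$W_in[] <- 0; m0$b_in[] <- 0; m0$W_out[] <- 0; m0$b_out[] <- 0
  fw <- mlp_forward(m0, matrix(rnorm(12), 4, 3))
  expect_true(all(fw$Z == 0) && all(fw$o == 0))
  expect_true(all(fw$C_hat == 0.5))

  m1 <- mlp_init(1, 1, 1, seed = 1)
  m1$W_in[] <- 1; m1$b_in[] <- 0; m1$W_out[] <- 1; m1$b_out[] <- 0
  fw1 <- mlp_forward(m1, matrix(1, 1, 1))
  expect_equal(as.numeric(fw1$Z), tanh(1))
  expect_equal(as.numeric(fw1$o), tanh(tanh(1)))
  expect_equal(as.numeric(fw1$C_hat), (tanh(tanh(1)) + 1) / 2)
  expect_equal(as.numeric(fw1$C_hat), 0.821, tolerance = 5e-4)

  set.seed(44)
  m <- mlp_init(4, 3, 2, seed = 9)
  X <- matrix(rnorm(20), 5, 4)
  fw <- mlp_forward(m, X)
  for (i in 1:5) {
    z <- numeric(3); o <- numeric(2)
    for (mm in 1:3)
      z[mm] <- tanh(m$b_in[mm] + sum(m$W_in[mm, ] * X[i, ]))
    for (k in 1:2)
      o[k] <- tanh(m$b_out[k] + sum(m$W_out[k, ] * z))
    expect_equal(fw$Z[, i], z, tolerance = 1e-12)
    expect_equal(fw$C_hat[, i], (o + 1) / 2, tolerance = 1e-12)
  }
  expect_error(mlp_forward(m, X[, 1:3]), "expects")
})

test_that("mse objective: identity, half-scores, relabeling symmetry", {
  C <- one_hot(c(1, 2, 1, 2), 2)
  expect_identical(mse_objective(C, C), 0)
  expect_equal(mse_objective(matrix(0.5, 2, 4), C), 0.25)
  set.seed(2)
  Chat <- matrix(runif(8), 2, 4)
  expect_equal(mse_objective(Chat, C),
               mse_objective(Chat[2:1, ], C[2:1, ]))
  expect_error(mse_objective(Chat, C[, 1:3]), "shapes")
})

test_that("backpropagated gradients match central finite differences", {
  set.seed(13)
  for (rep in 1:4) {
    p <- sample(2:5, 1); M <- sample(1:3, 1); S <- sample(2:3, 1)
    n <- 6
    model <- mlp_init(p, M, S, seed = rep)
    X <- matrix(rnorm(n * p), n, p)
    C <- one_hot(sample(seq_len(S), n, TRUE), S)
    g <- mlp_gradient(model, X, C)
    w <- c(model$W_in, model$b_in, model$W_out, model$b_out)
    eps <- 1e-6
    fd <- vapply(seq_along(w), function(i) {
      wp <- w; wm <- w
      wp[i] <- wp[i] + eps; wm[i] <- wm[i] - eps
      up <- gsclassify:::mlp_unpack
      (mse_objective(mlp_forward(up(model, wp), X)$C_hat, C) -
         mse_objective(mlp_forward(up(model, wm), X)$C_hat, C)) / (2 * eps)
    }, numeric(1))
    rel <- abs(g$grad - fd) / pmax(abs(fd), 1e-8)
    expect_lt(max(rel), 1e-6)
  }
})

test_that("early-stopping bookkeeping matches the injected-trace contract", {
  tr <- early_stopping_trace(c(0.5, 0.4, 0.45, 0.5), patience = 1)
  expect_equal(tr$best_iteration, 2L)
  expect_equal(tr$stop_iteration, 4L)
  tr2 <- early_stopping_trace(c(0.5, 0.4, 0.3, 0.2), patience = 1)
  expect_equal(tr2$best_iteration, 4L)
  expect_equal(tr2$stop_iteration, 4L)
})

test_that("SCG training solves a separable toy and is deterministic", {
  set.seed(300)
  n <- 40
  X <- rbind(matrix(rnorm(n, -2), n / 2, 2), matrix(rnorm(n, 2), n / 2, 2))
  labs <- rep(1:2, each = n / 2)
  C <- one_hot(labs, 2)
  fit <- train_scg(mlp_init(2, 2, 2, seed = 1), X, C, X, C,
                   max_epochs = 400, patience = 400)
  expect_true(all(diff(fit$trace$train_mse) <= 1e-12))
  pred <- max.col(t(mlp_forward(fit$model, X)$C_hat))
  expect_equal(mean(pred == labs), 1)

  fit2 <- train_scg(mlp_init(2, 2, 2, seed = 1), X, C, X, C,
                    max_epochs = 400, patience = 400)
  expect_identical(fit$trace, fit2$trace)
  expect_identical(fit$model$W_in, fit2$model$W_in)
})

test_that("early stopping returns the minimum-validation-error weights", {
  set.seed(55)
  n <- 60; p <- 8
  X <- matrix(rnorm(n * p), n, p)
  labs <- ifelse(X[, 1] + rnorm(n, sd = 2) > 0, 2L, 1L)
  labs[1:2] <- 1:2
  C <- one_hot(labs, 2)
  tr_idx <- 1:45; va_idx <- 46:60
  fit <- train_scg(mlp_init(p, 3, 2, seed = 4), X[tr_idx, ], C[, tr_idx],
                   X[va_idx, ], C[, va_idx], max_epochs = 150, patience = 5)
  val_at_returned <- mse_objective(
    mlp_forward(fit$model, X[va_idx, ])$C_hat, C[, va_idx])
  expect_equal(val_at_returned, min(fit$trace$val_mse), tolerance = 1e-12)
  expect_gte(fit$trace$stop_iteration, fit$trace$best_iteration)
  expect_error(train_scg(mlp_init(p, 2, 2, seed = 1), X, C,
                         X[0, , drop = FALSE], C[, 0, drop = FALSE]),
               "empty|classes")
})

test_that("two-class label swap with matched init swaps score rows", {
  set.seed(17)
  n <- 30; p <- 4
  X <- matrix(rnorm(n * p), n, p)
  labs <- rep(1:2, 15)
  C <- one_hot(labs, 2)
  m <- mlp_init(p, 2, 2, seed = 8)
  m_sw <- m
  m_sw$W_out <- m$W_out[2:1, , drop = FALSE]
  m_sw$b_out <- m$b_out[2:1]
  # short run: packed-parameter order differs between the two trainings,
  # so float non-associativity makes long trajectories drift apart
  f1 <- train_scg(m, X, C, X, C, max_epochs = 5, patience = 5)
  f2 <- train_scg(m_sw, X, C[2:1, ], X, C[2:1, ], max_epochs = 5,
                  patience = 5)
  s1 <- mlp_forward(f1$model, X)$C_hat
  s2 <- mlp_forward(f2$model, X)$C_hat
  expect_equal(s1, s2[2:1, ], tolerance = 1e-6)
  expect_error(mlp_init(p, 0, 2), "M must be >= 1")
})

test_that("ensemble prediction averages replicates and reduces to one", {
  gm <- gaussian_mixture(60, d = 3, seed = 10)
  lab <- toy_labeling(gm$labels, c("a", "b"), target = 2)
  C <- one_hot(gm$labels, 2)
  Xte <- gaussian_mixture(20, d = 3, seed = 11)$X
  one <- mlp_ensemble_predict(gm$X, C, lab, Xte, M_grid = 2,
                              replicates = 1, seed = 5, max_epochs = 50)
  expect_length(one$per_replicate, 1L)
  expect_equal(unname(one$scores), unname(one$per_replicate[[1]]))
  ens <- mlp_ensemble_predict(gm$X, C, lab, Xte, M_grid = c(1, 2),
                              replicates = 3, seed = 5, max_epochs = 50)
  expect_equal(unname(ens$scores),
               unname(Reduce(`+`, ens$per_replicate) / 3), tolerance = 1e-12)
  expect_true(all(ens$chosen_M %in% c(1, 2)))
  expect_error(mlp_ensemble_predict(gm$X, C, lab, Xte, replicates = 0),
               "replicates")
})

test_that("MLP persistence round-trips", {
  m <- mlp_init(5, 3, 2, seed = 2)
  dir <- withr::local_tempdir()
  mlp_save(m, dir)
  back <- mlp_load(dir)
  expect_equal(back$W_in, m$W_in, tolerance = 1e-15)
  expect_equal(back$b_out, m$b_out, tolerance = 1e-15)
  expect_identical(back$M, m$M)
  expect_identical(back$transfer, "tansig")
})
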