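# Multilayer perceptron classifier: one tansig hidden layer (M neurons),
# one tansig output layer (S neurons), trained on mean squared error
# between the reported scores C_hat = (tansig(.) + 1)/2 in [0,1] and the
# 0/1 one-hot targets, by Moller's scaled conjugate gradient (SCG) with
# early stopping on a stratified validation split.
#
# Weight initialization is symmetric uniform scaled by fan-in
# (Nguyen-Widrow-like), seedable. SCG constants follow Moller's published
# defaults (sigma = 5e-5, lambda_1 = 5e-7).

#' Hyperbolic tangent sigmoid transfer function
#'
#' `tansig(u) = 2 / (1 + exp(-2u)) - 1`, identical to `tanh(u)`; maps the
#' real line onto (-1, 1) and saturates at the boundaries.
#'
#' @param u numeric vector or matrix.
#' @return same shape as `u`.
#' @export
tansig <- function(u) tanh(u)

#' Initialize an MLP model
#'
#' @param p number of input markers.
#' @param M hidden-neuron count (>= 1).
#' @param S number of output classes.
#' @param seed integer seed for the symmetric-uniform, fan-in-scaled draw.
#' @return An object of class `mlp_model` with `W_in` (M x p), `b_in`,
#'   `W_out` (S x M), `b_out` and shape metadata.
#' @export
mlp_init <- function(p, M, S, seed = 1L) {
  if (M < 1) gs_stop("hidden-layer size M must be >= 1")
  set.seed(child_seed(seed, "init", M))
  a_in <- 0.7 / sqrt(p)
  a_out <- 0.7 / sqrt(M)
  structure(list(
    W_in = matrix(stats::runif(M * p, -a_in, a_in), M, p),
    b_in = stats::runif(M, -a_in, a_in),
    W_out = matrix(stats::runif(S * M, -a_out, a_out), S, M),
    b_out = stats::runif(S, -a_out, a_out),
    p = as.integer(p), M = as.integer(M), S = as.integer(S),
    transfer = "tansig"
  ), class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("mlp_model: %d-%d-%d (tansig/tansig)\n", x$p, x$M, x$S))
  invisible(x)
}

#' Forward pass
#'
#' Hidden features `Z = tansig(W_in X' + b_in)` (M x n), raw outputs
#' `o = tansig(W_out Z + b_out)` in (-1,1), and reported scores
#' `C_hat = (o + 1)/2` in [0,1]. Class decisions take the per-column
#' argmax of `C_hat` (the affine map does not change it).
#'
#' @param model an `mlp_model`.
#' @param X n x p input matrix or [marker_matrix()].
#' @return `list(Z, o, C_hat)`.
#' @export
mlp_forward <- function(model, X) {
  X <- if (inherits(X, "marker_matrix")) X$values else as.matrix(X)
  storage.mode(X) <- "double"
  if (ncol(X) != model$p)
    gs_stop("input has %d markers but model expects %d", ncol(X), model$p)
  Z <- tanh(model$W_in %*% t(X) + model$b_in)
  o <- tanh(model$W_out %*% Z + model$b_out)
  list(Z = Z, o = o, C_hat = (o + 1) / 2)
}

#' Mean squared error between scores and targets
#'
#' Mean over all S*n entries of `(C_hat - C)^2`.
#'
#' @param C_hat S x n score matrix.
#' @param C S x n one-hot target matrix.
#' @return non-negative scalar.
#' @export
mse_objective <- function(C_hat, C) {
  if (!identical(dim(C_hat), dim(as.matrix(C))))
    gs_stop("score and target shapes differ")
  mean((C_hat - C)^2)
}

# ---- parameter vector packing -------------------------------------------

mlp_pack <- function(model) {
  c(model$W_in, model$b_in, model$W_out, model$b_out)
}

mlp_unpack <- function(model, w) {
  p <- model$p; M <- model$M; S <- model$S
  i <- 0
  model$W_in <- matrix(w[i + seq_len(M * p)], M, p); i <- i + M * p
  model$b_in <- w[i + seq_len(M)]; i <- i + M
  model$W_out <- matrix(w[i + seq_len(S * M)], S, M); i <- i + S * M
  model$b_out <- w[i + seq_len(S)]
  model
}

# loss and gradient of mse((o+1)/2, C) w.r.t. the packed parameter vector;
# the 0.5 factor in delta_out is dC_hat/do of the affine score map.
mlp_loss_grad <- function(model, w, X, C, want_grad = TRUE) {
  model <- mlp_unpack(model, w)
  Xt <- t(X)                           # p x n
  Z <- tanh(model$W_in %*% Xt + model$b_in)
  o <- tanh(model$W_out %*% Z + model$b_out)
  C_hat <- (o + 1) / 2
  D <- C_hat - C
  loss <- mean(D^2)
  if (!want_grad) return(list(loss = loss))
  n_ent <- length(C)
  delta_out <- (2 * D / n_ent) * 0.5 * (1 - o^2)      # S x n
  g_Wout <- tcrossprod(delta_out, Z)                  # S x M
  g_bout <- rowSums(delta_out)
  delta_hid <- crossprod(model$W_out, delta_out) * (1 - Z^2)  # M x n
  g_Win <- delta_hid %*% X                            # M x p
  g_bin <- rowSums(delta_hid)
  list(loss = loss, grad = c(g_Win, g_bin, g_Wout, g_bout))
}

#' Backpropagated gradient of the MSE objective
#'
#' Exposed for verification against finite differences.
#'
#' @param model an `mlp_model`.
#' @param X n x p inputs; `C` S x n one-hot targets.
#' @param C target matrix.
#' @return `list(loss, grad)` with `grad` the packed-parameter gradient
#'   (order: W_in, b_in, W_out, b_out, column-major).
#' @export
mlp_gradient <- function(model, X, C) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  mlp_loss_grad(model, mlp_pack(model), X, C)
}

# ---- early stopping ------------------------------------------------------

#' Early-stopping bookkeeping on a validation-error series
#'
#' Given successive validation errors, returns the best epoch (argmin; ties
#' to the earliest) and the stopping epoch: training halts at the first
#' epoch whose distance from the best epoch exceeds `patience`. E.g. the
#' series (0.5, 0.4, 0.45, 0.5) with `patience = 1` stops at epoch 4 with
#' best epoch 2.
#'
#' @param val_errors numeric vector of per-epoch validation errors.
#' @param patience tolerated epochs without improvement.
#' @return `list(best_iteration, stop_iteration)`.
#' @export
early_stopping_trace <- function(val_errors, patience) {
  best <- 1L
  stop_at <- length(val_errors)
  for (e in seq_along(val_errors)) {
    if (val_errors[e] < val_errors[best]) best <- e
    if (e - best > patience) {
      stop_at <- e
      break
    }
  }
  list(best_iteration = best, stop_iteration = stop_at)
}

#' Train an MLP by scaled conjugate gradient with early stopping
#'
#' Gradients come from backpropagation of the MSE objective; weight updates
#' follow Moller's scaled conjugate gradient scheme. After every accepted
#' update the validation MSE is evaluated; training halts when the
#' validation error has not improved for more than `patience` epochs (or at
#' `max_epochs`), and the weights of the best validation epoch are
#' returned.
#'
#' @param model an initialized `mlp_model`.
#' @param X_train,C_train training inputs (n x p) and one-hot targets
#'   (S x n).
#' @param X_val,C_val validation inputs and targets (non-empty, at least
#'   two classes present).
#' @param max_epochs epoch cap.
#' @param patience early-stopping patience (epochs past the best).
#' @return `list(model, trace)`; `trace` holds per-epoch training and
#'   validation MSE, `best_iteration` and `stop_iteration`.
#' @export
train_scg <- function(model, X_train, C_train, X_val, C_val,
                      max_epochs = 1000L, patience = 6L) {
  X_train <- as.matrix(X_train); storage.mode(X_train) <- "double"
  X_val <- as.matrix(X_val); storage.mode(X_val) <- "double"
  if (nrow(X_val) == 0) gs_stop("validation set is empty")
  if (length(unique(max.col(t(C_val)))) < 2)
    gs_stop("validation set must contain at least 2 classes")

  w <- mlp_pack(model)
  N <- length(w)
  eval_at <- function(w, want_grad = TRUE)
    mlp_loss_grad(model, w, X_train, C_train, want_grad)

  # Moller's SCG constants
  sigma0 <- 5e-5
  lambda <- 5e-7
  lambda_bar <- 0

  eg <- eval_at(w)
  if (!is.finite(eg$loss)) gs_stop("non-finite training loss at start")
  f_w <- eg$loss
  r <- -eg$grad
  p_dir <- r
  success <- TRUE
  delta <- 0

  val_model <- mlp_unpack(model, w)
  val_mse <- mse_objective(mlp_forward(val_model, X_val)$C_hat, C_val)
  train_trace <- f_w
  val_trace <- val_mse
  best_val <- val_mse
  best_w <- w
  best_epoch <- 1L
  epoch <- 1L

  while (epoch < max_epochs) {
    epoch <- epoch + 1L
    p2 <- sum(p_dir^2)
    if (p2 < 1e-300) break   # gradient vanished
    if (success) {
      sigma <- sigma0 / sqrt(p2)
      g2 <- eval_at(w + sigma * p_dir)$grad
      s <- (g2 - (-r)) / sigma        # Hessian-vector approximation
      delta <- sum(p_dir * s)
    }
    delta <- delta + (lambda - lambda_bar) * p2
    if (delta <= 0) {                 # make the Hessian approx. positive
      lambda_bar <- 2 * (lambda - delta / p2)
      delta <- -delta + lambda * p2
      lambda <- lambda_bar
    }
    mu <- sum(p_dir * r)
    alpha <- mu / delta
    w_new <- w + alpha * p_dir
    f_new <- eval_at(w_new, want_grad = FALSE)$loss
    if (!is.finite(f_new)) gs_stop("non-finite training loss (epoch %d)", epoch)
    Delta <- 2 * delta * (f_w - f_new) / mu^2
    if (Delta >= 0) {                 # accepted step
      eg <- eval_at(w_new)
      r_new <- -eg$grad
      w <- w_new
      f_w <- f_new
      lambda_bar <- 0
      success <- TRUE
      if (epoch %% N == 0) {
        p_dir <- r_new                # periodic restart
      } else {
        beta <- (sum(r_new^2) - sum(r_new * r)) / mu
        p_dir <- r_new + beta * p_dir
      }
      r <- r_new
      if (Delta >= 0.75) lambda <- lambda / 4
    } else {
      lambda_bar <- lambda
      success <- FALSE
    }
    if (Delta < 0.25) lambda <- lambda + delta * (1 - Delta) / p2
    lambda <- min(lambda, 1e100)

    val_model <- mlp_unpack(model, w)
    val_mse <- mse_objective(mlp_forward(val_model, X_val)$C_hat, C_val)
    train_trace <- c(train_trace, f_w)
    val_trace <- c(val_trace, val_mse)
    if (val_mse < best_val) {
      best_val <- val_mse
      best_w <- w
      best_epoch <- epoch
    }
    if (epoch - best_epoch > patience) break
  }

  trace <- list(train_mse = train_trace, val_mse = val_trace,
                best_iteration = best_epoch, stop_iteration = epoch)
  list(model = mlp_unpack(model, best_w), trace = trace)
}

#' Train and predict with a replicate-ensembled MLP
#'
#' Reproduces the reference training protocol for one outer partition: for
#' each replicate, a fresh stratified 88/12 inner training/validation split
#' and fresh weight initialization; the hidden-layer size is chosen from
#' `M_grid` by one-vs-rest validation ROC-AUC of the labeling's target
#' class; the early-stopped model scores the test rows; the ensemble score
#' is the mean over replicates (set `aggregate = "metrics"` to instead keep
#' per-replicate scores so downstream metrics can be averaged per
#' replicate).
#'
#' @param X_train M x p training inputs; `C_train` their one-hot targets.
#' @param C_train S x M target matrix.
#' @param lab `class_labeling` over the training rows (target class and
#'   stratification).
#' @param X_test query rows to score.
#' @param M_grid candidate hidden sizes.
#' @param replicates number of random-seed replicates.
#' @param seed base seed; replicate r uses a derived child seed.
#' @param val_frac inner validation fraction.
#' @param max_epochs,patience passed to [train_scg()].
#' @param aggregate `"scores"` (mean score matrix) or `"metrics"`.
#' @return `list(scores = S x n_test matrix, per_replicate = list of score
#'   matrices, chosen_M = integer vector)`.
#' @export
mlp_ensemble_predict <- function(X_train, C_train, lab, X_test,
                                 M_grid = c(1L, 2L, 3L, 4L),
                                 replicates = 10L, seed = 1L,
                                 val_frac = 0.12, max_epochs = 1000L,
                                 patience = 6L,
                                 aggregate = c("scores", "metrics")) {
  aggregate <- match.arg(aggregate)
  if (replicates < 1) gs_stop("replicates must be >= 1")
  if (any(M_grid < 1)) gs_stop("hidden sizes must be >= 1")
  X_train <- if (inherits(X_train, "marker_matrix")) X_train$values else
    as.matrix(X_train)
  X_test <- if (inherits(X_test, "marker_matrix")) X_test$values else
    as.matrix(X_test)
  S <- nrow(C_train)
  p <- ncol(X_train)
  per_rep <- vector("list", replicates)
  chosen_M <- integer(replicates)
  M_grid <- sort(unique(as.integer(M_grid)))
  for (r in seq_len(replicates)) {
    rseed <- child_seed(seed, "mlp_rep", r)
    sp <- inner_split(seq_len(nrow(X_train)), lab, val_frac = val_frac,
                      seed = rseed)
    Xt <- X_train[sp$train, , drop = FALSE]
    Ct <- C_train[, sp$train, drop = FALSE]
    Xv <- X_train[sp$val, , drop = FALSE]
    Cv <- C_train[, sp$val, drop = FALSE]
    val_pos <- lab$labels[sp$val] == lab$target_class
    best_auc <- -Inf
    best_fit <- NULL
    best_M <- M_grid[1]
    for (M in M_grid) {
      fit <- train_scg(mlp_init(p, M, S, seed = child_seed(rseed, "M", M)),
                       Xt, Ct, Xv, Cv,
                       max_epochs = max_epochs, patience = patience)
      if (all(val_pos) || !any(val_pos)) {
        a <- -mse_objective(mlp_forward(fit$model, Xv)$C_hat, Cv)
      } else {
        scores_v <- mlp_forward(fit$model, Xv)$C_hat[lab$target_class, ]
        a <- roc_auc(scores_v, val_pos)$area
      }
      if (a > best_auc) {       # strict: ties keep the smaller M
        best_auc <- a
        best_fit <- fit
        best_M <- M
      }
    }
    chosen_M[r] <- best_M
    per_rep[[r]] <- mlp_forward(best_fit$model, X_test)$C_hat
  }
  scores <- Reduce(`+`, per_rep) / replicates
  rownames(scores) <- rownames(C_train)
  list(scores = scores, per_replicate = per_rep, chosen_M = chosen_M,
       aggregate = aggregate)
}

#' Save / load an MLP model as delimited text
#'
#' Weight matrices and biases as CSV plus a key-value `meta.txt`
#' (shapes, transfer names). [mlp_load()] restores an identical model.
#'
#' @param model an `mlp_model`.
#' @param dir directory path.
#' @return `dir` (save) or an `mlp_model` (load).
#' @export
mlp_save <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(x, file.path(dir, f), sep = ",",
                                          row.names = FALSE,
                                          col.names = FALSE, quote = FALSE)
  wt(format(model$W_in, digits = 17), "W_in.csv")
  wt(format(model$b_in, digits = 17), "b_in.csv")
  wt(format(model$W_out, digits = 17), "W_out.csv")
  wt(format(model$b_out, digits = 17), "b_out.csv")
  writeLines(c(sprintf("p=%d", model$p), sprintf("M=%d", model$M),
               sprintf("S=%d", model$S),
               sprintf("transfer=%s", model$transfer)),
             file.path(dir, "meta.txt"))
  invisible(dir)
}

#' @rdname mlp_save
#' @export
mlp_load <- function(dir) {
  rd <- function(f) as.matrix(utils::read.table(file.path(dir, f), sep = ","))
  meta <- readLines(file.path(dir, "meta.txt"))
  kv <- strsplit(meta, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  model <- structure(list(
    W_in = unname(rd("W_in.csv")), b_in = as.numeric(rd("b_in.csv")),
    W_out = unname(rd("W_out.csv")), b_out = as.numeric(rd("b_out.csv")),
    p = as.integer(vals[["p"]]), M = as.integer(vals[["M"]]),
    S = as.integer(vals[["S"]]), transfer = vals[["transfer"]]
  ), class = "mlp_model")
  model
}
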