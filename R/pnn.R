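# Probabilistic neural network (Parzen-window Bayes classifier).
#
# Pattern layer: one Gaussian radial basis function per training individual
# (center), u_mi = b * ||x_i - c_m|| with b = sqrt(-ln 0.5)/h, so the kernel
# z_mi = exp(-u_mi^2) equals exactly 0.5 at distance h. Summation layer:
# v_ki = sum_m w_km z_mi with W the 0/1 class-indicator matrix taken from
# the training targets (classes are therefore implicitly weighted by their
# empirical priors; no per-class normalization). Output: softmax over the
# raw class sums by default, matching the reference formulation; the
# conventional Parzen normalization v_k / sum_j v_j is available via
# `posterior = "sum_normalized"`. Within a query both order the classes the
# same way, but across queries they rank differently even for S = 2
# (softmax orders queries by v_1 - v_2, the sum normalization by v_1/v_2),
# so AUC can differ between the two.
#
# Distances are plain Euclidean on the raw marker codes; no
# standardization. Fitting is a single pass (the centers are stored
# verbatim); no iterative optimization occurs.

#' Fit a probabilistic neural network
#'
#' @param X_train numeric matrix (M x p) of training inputs, or a
#'   [marker_matrix()]. Each row becomes a kernel center.
#' @param C_train S x M one-hot target matrix (see [one_hot()]).
#' @param h Gaussian bandwidth (> 0), in marker-space Euclidean distance
#'   units: the kernel value is exactly 0.5 at distance `h`.
#' @return An object of class `pnn_model` with elements `centers`, `W`,
#'   `h`, `b = sqrt(log(2))/h` and `class_names`.
#' @export
pnn_fit <- function(X_train, C_train, h) {
  X <- if (inherits(X_train, "marker_matrix")) X_train$values else
    as.matrix(X_train)
  storage.mode(X) <- "double"
  C_train <- as.matrix(C_train)
  if (!is.numeric(h) || length(h) != 1 || !is.finite(h) || h <= 0)
    gs_stop("bandwidth h must be a single positive number")
  if (ncol(C_train) != nrow(X))
    gs_stop("C_train columns (%d) must align with training rows (%d)",
            ncol(C_train), nrow(X))
  if (!all(C_train %in% c(0, 1)) || !all(colSums(C_train) == 1))
    gs_stop("C_train must be one-hot (each column sums to 1)")
  if (any(rowSums(C_train) == 0))
    gs_stop("class '%s' absent from the training targets",
            if (!is.null(rownames(C_train)))
              rownames(C_train)[which(rowSums(C_train) == 0)[1]]
            else which(rowSums(C_train) == 0)[1])
  if (nrow(X) < nrow(C_train))
    gs_stop("need at least as many training individuals as classes")
  structure(list(centers = X, W = C_train, h = h, b = sqrt(log(2)) / h,
                 class_names = rownames(C_train)),
            class = "pnn_model")
}

#' @export
print.pnn_model <- function(x, ...) {
  cat(sprintf("pnn_model: %d centers, %d classes, p = %d, h = %g\n",
              nrow(x$centers), nrow(x$W), ncol(x$centers), x$h))
  invisible(x)
}

# Euclidean cross-distance matrix (M x n), numerically floored at 0
cross_dist <- function(centers, X) {
  d2 <- outer(rowSums(centers^2), rowSums(X^2), "+") -
    2 * tcrossprod(centers, X)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Pattern- and summation-layer activations
#'
#' Computes the three layer quantities for query rows `X`:
#' `U = b * dist(X, centers)` (M x n), `Z = exp(-U^2)` and the per-class
#' sums `V = W %*% Z` (S x n). The kernel matrix may be computed in query
#' blocks (`block_size`); results are independent of the block size.
#'
#' @param model a [pnn_fit()] model.
#' @param X query matrix (n x p) or [marker_matrix()].
#' @param block_size optional number of query columns per block.
#' @return `list(U, Z, V)`.
#' @export
pnn_activations <- function(model, X, block_size = NULL) {
  X <- if (inherits(X, "marker_matrix")) X$values else as.matrix(X)
  storage.mode(X) <- "double"
  if (ncol(X) != ncol(model$centers))
    gs_stop("query has %d markers but model expects %d",
            ncol(X), ncol(model$centers))
  n <- nrow(X)
  if (is.null(block_size)) block_size <- n
  U <- matrix(0, nrow(model$centers), n)
  for (start in seq(1, n, by = block_size)) {
    idx <- start:min(start + block_size - 1, n)
    U[, idx] <- model$b * cross_dist(model$centers, X[idx, , drop = FALSE])
  }
  Z <- exp(-U^2)
  V <- model$W %*% Z
  list(U = U, Z = Z, V = V)
}

# column-wise numerically-stabilized softmax
softmax_cols <- function(V) {
  E <- exp(sweep(V, 2, apply(V, 2, max)))
  sweep(E, 2, colSums(E), "/")
}

#' Posterior class probabilities
#'
#' Applies the output transfer to the class sums V: the softmax
#' `exp(v_k)/sum_j exp(v_j)` (default, max-stabilized) or the Parzen sum
#' normalization `v_k / sum_j v_j`.
#'
#' @inheritParams pnn_activations
#' @param posterior `"softmax"` or `"sum_normalized"`.
#' @return S x n matrix of class-membership probabilities; columns sum
#'   to 1.
#' @export
pnn_predict_proba <- function(model, X,
                              posterior = c("softmax", "sum_normalized"),
                              block_size = NULL) {
  posterior <- match.arg(posterior)
  V <- pnn_activations(model, X, block_size = block_size)$V
  P <- if (posterior == "softmax") softmax_cols(V)
  else sweep(V, 2, colSums(V), "/")
  rownames(P) <- model$class_names
  P
}

#' Hard class prediction
#'
#' Argmax over posterior columns; exact ties break to the lowest class
#' index (deterministic).
#'
#' @inheritParams pnn_predict_proba
#' @return integer label vector (1..S).
#' @export
pnn_predict_class <- function(model, X, ...) {
  P <- pnn_predict_proba(model, X, ...)
  apply(P, 2, which.max)
}

#' Default bandwidth grid
#'
#' 20 log-spaced bandwidths spanning 0.01 to 10 times the median pairwise
#' Euclidean distance among the training rows, making the grid adaptive to
#' the marker space.
#'
#' @param X training matrix.
#' @param length.out grid size.
#' @param max_pairs distances are estimated from at most this many rows.
#' @return numeric vector of bandwidths.
#' @export
default_bandwidth_grid <- function(X, length.out = 20L, max_pairs = 500L) {
  X <- if (inherits(X, "marker_matrix")) X$values else as.matrix(X)
  if (nrow(X) > max_pairs) X <- X[seq_len(max_pairs), , drop = FALSE]
  d <- stats::dist(X)
  med <- stats::median(d[d > 0])
  if (!is.finite(med) || med <= 0) med <- 1
  exp(seq(log(0.01 * med), log(10 * med), length.out = length.out))
}

#' Select the PNN bandwidth by target-class validation AUC
#'
#' Splits the training rows into inner training and validation sets
#' (stratified, validation fraction `val_frac`, mirroring the MLP
#' early-stopping split), fits a PNN per candidate bandwidth on the inner
#' training rows, and scores one-vs-rest ROC-AUC of the labeling's target
#' class on the validation rows. Returns the bandwidth maximizing
#' validation AUC; ties break to the smallest bandwidth.
#'
#' @param X_train M x p training matrix (or [marker_matrix()]).
#' @param C_train S x M one-hot targets for the training rows.
#' @param lab a `class_labeling` over the training rows (its `labels` must
#'   have length M); supplies the target class.
#' @param grid candidate bandwidths; defaults to
#'   [default_bandwidth_grid()].
#' @param val_frac inner validation fraction.
#' @param seed integer seed for the inner split.
#' @param posterior passed to [pnn_predict_proba()].
#' @param metric `"auc"` (target-class validation ROC-AUC, the reference
#'   protocol's rule) or `"accuracy"` (validation classification accuracy;
#'   appropriate when the goal is the Bayes-consistent decision rule, since
#'   for large h the target-class ranking can stay informative while hard
#'   assignments collapse onto the majority class).
#' @return `list(h = <best>, table = data.frame(h, score))`.
#' @export
select_bandwidth <- function(X_train, C_train, lab, grid = NULL,
                             val_frac = 0.12, seed = 1L,
                             posterior = "softmax",
                             metric = c("auc", "accuracy")) {
  metric <- match.arg(metric)
  X <- if (inherits(X_train, "marker_matrix")) X_train$values else
    as.matrix(X_train)
  if (is.null(grid)) grid <- default_bandwidth_grid(X)
  if (!length(grid) || any(grid <= 0))
    gs_stop("bandwidth grid must be non-empty and positive")
  grid <- sort(grid)
  if (length(lab$labels) != nrow(X))
    gs_stop("labeling does not cover the training rows")
  sp <- inner_split(seq_len(nrow(X)), lab, val_frac = val_frac, seed = seed)
  val_labels <- lab$labels[sp$val]
  pos <- val_labels == lab$target_class
  if (all(pos) || !any(pos)) {
    gs_stop("validation fold is degenerate for the target class")
  }
  Ct <- C_train[, sp$train, drop = FALSE]
  Xt <- X[sp$train, , drop = FALSE]
  Xv <- X[sp$val, , drop = FALSE]
  scores <- vapply(grid, function(h) {
    P <- pnn_predict_proba(pnn_fit(Xt, Ct, h), Xv, posterior = posterior)
    if (metric == "auc") roc_auc(P[lab$target_class, ], pos)$area
    else mean(apply(P, 2, which.max) == val_labels)
  }, numeric(1))
  best <- which.max(scores)  # ties: first index = smallest h (grid sorted)
  list(h = grid[best], table = data.frame(h = grid, score = scores,
                                          metric = metric))
}

#' Save / load a PNN model as delimited text
#'
#' Writes `centers.csv`, `weights.csv` and a `meta.txt` key-value file
#' (h, b, class names) into `dir`; [pnn_load()] restores an identical
#' model.
#'
#' @param model a `pnn_model`.
#' @param dir directory path (created if needed).
#' @return `dir` (save) or a `pnn_model` (load).
#' @export
pnn_save <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(model$centers, file.path(dir, "centers.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(model$W, file.path(dir, "weights.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  writeLines(c(sprintf("h=%.17g", model$h),
               sprintf("class_names=%s",
                       paste(model$class_names, collapse = ","))),
             file.path(dir, "meta.txt"))
  invisible(dir)
}

#' @rdname pnn_save
#' @export
pnn_load <- function(dir) {
  centers <- as.matrix(utils::read.table(file.path(dir, "centers.csv"),
                                         sep = ","))
  dimnames(centers) <- NULL
  W <- as.matrix(utils::read.table(file.path(dir, "weights.csv"), sep = ","))
  dimnames(W) <- NULL
  meta <- readLines(file.path(dir, "meta.txt"))
  kv <- strsplit(meta, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  rownames(W) <- strsplit(vals[["class_names"]], ",")[[1]]
  pnn_fit(centers, W, as.numeric(vals[["h"]]))
}
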