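# Target-class evaluation: confusion-matrix metrics, ROC-AUC and
# precision-recall average precision, plus the stratified cross-validation
# harness.
#
# Conventions (documented because the source formulation is silent on
# them): predicted positive iff score > tau (strict); precision at
# tp + fp = 0 is 1, so PR curves start at recall 0; AUC ties get half
# credit (Mann-Whitney), so a constant classifier scores 0.5.

#' Confusion matrix at a score threshold
#'
#' Predicts positive iff `score > tau` (strictly) and cross-tabulates
#' against the observed binary labels.
#'
#' @param scores numeric score vector for the target class.
#' @param labels logical (or 0/1) vector, `TRUE` = target class.
#' @param tau decision threshold.
#' @return `list(tp, fp, fn, tn)` of integer counts.
#' @export
confusion_at_threshold <- function(scores, labels, tau) {
  labels <- as.logical(labels)
  if (any(!is.finite(scores))) gs_stop("non-finite scores")
  pred <- scores > tau
  list(tp = sum(pred & labels), fp = sum(pred & !labels),
       fn = sum(!pred & labels), tn = sum(!pred & !labels))
}

#' Confusion-matrix rates
#'
#' `recall = tp/(tp+fn)` (sensitivity / true positive rate),
#' `fpr = fp/(fp+tn)` and `precision = tp/(tp+fp)`. Precision is 1 by
#' convention when nothing is predicted positive; recall with no observed
#' positives is an error.
#'
#' @param cm a confusion matrix from [confusion_at_threshold()].
#' @return scalar in [0,1].
#' @export
recall <- function(cm) {
  if (cm$tp + cm$fn == 0) gs_stop("recall undefined: no observed positives")
  cm$tp / (cm$tp + cm$fn)
}

#' @rdname recall
#' @export
fpr <- function(cm) {
  if (cm$fp + cm$tn == 0) gs_stop("fpr undefined: no observed negatives")
  cm$fp / (cm$fp + cm$tn)
}

#' @rdname recall
#' @export
precision <- function(cm) {
  if (cm$tp + cm$fp == 0) return(1)
  cm$tp / (cm$tp + cm$fp)
}

# order scores decreasing and collapse ties into blocks; returns cumulative
# tp/fp after each distinct-score threshold
score_blocks <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- as.logical(labels[o])
  grp <- cumsum(!duplicated(s))
  tp <- as.numeric(tapply(l, grp, sum))
  fp <- as.numeric(tapply(!l, grp, sum))
  list(cum_tp = cumsum(tp), cum_fp = cumsum(fp),
       thresholds = s[!duplicated(s)])
}

#' ROC curve and area
#'
#' Sweeps all distinct score values as thresholds (plus sentinels so the
#' curve spans (0,0) to (1,1)), collapsing tied scores into blocks, and
#' integrates by trapezoid. The area equals the Mann-Whitney statistic
#' (probability that a random positive outranks a random negative, ties
#' counted 1/2) to machine precision.
#'
#' @param scores target-class score vector.
#' @param labels logical/0-1 labels; needs at least one positive and one
#'   negative.
#' @return `list(points = data.frame(fpr, tpr, threshold), area)`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  P <- sum(labels)
  N <- sum(!labels)
  if (P == 0 || N == 0)
    gs_stop("degenerate fold: need >= 1 positive and >= 1 negative (have %d/%d)",
            P, N)
  b <- score_blocks(scores, labels)
  x <- c(0, b$cum_fp / N)
  y <- c(0, b$cum_tp / P)
  area <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  list(points = data.frame(fpr = x, tpr = y,
                           threshold = c(Inf, b$thresholds)),
       area = area)
}

#' Precision-recall curve and average precision
#'
#' Average precision: `AP = sum_k P(k) * delta-recall(k)` over the
#' descending-score threshold sweep, tied scores processed as one block
#' (precision evaluated at the block end).
#'
#' @inheritParams roc_auc
#' @return `list(points = data.frame(recall, precision, threshold), area)`.
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  P_tot <- sum(labels)
  if (P_tot == 0) gs_stop("no observed positives: average precision undefined")
  b <- score_blocks(scores, labels)
  rec <- b$cum_tp / P_tot
  prec <- ifelse(b$cum_tp + b$cum_fp == 0, 1,
                 b$cum_tp / (b$cum_tp + b$cum_fp))
  ap <- sum(prec * diff(c(0, rec)))
  list(points = data.frame(recall = c(0, rec), precision = c(1, prec),
                           threshold = c(Inf, b$thresholds)),
       area = ap)
}

#' One-vs-rest scored binary view of a posterior matrix
#'
#' Extracts the target class's score row and binarizes the labels against
#' it.
#'
#' @param P S x n posterior/score matrix (classes in rows).
#' @param lab `class_labeling` whose `labels` cover the n columns, or an
#'   integer label vector.
#' @param target_class class index (defaults to the labeling's target).
#' @return `list(scores, labels)`.
#' @export
one_vs_rest <- function(P, lab, target_class = NULL) {
  labels <- if (inherits(lab, "class_labeling")) lab$labels else
    as.integer(lab)
  if (is.null(target_class)) {
    if (!inherits(lab, "class_labeling"))
      gs_stop("target_class required when lab is a plain vector")
    target_class <- lab$target_class
  }
  if (target_class < 1 || target_class > nrow(P))
    gs_stop("target_class %d outside 1..%d", target_class, nrow(P))
  if (length(labels) != ncol(P))
    gs_stop("labeling length does not match score columns")
  list(scores = as.numeric(P[target_class, ]),
       labels = labels == target_class)
}

#' Cross-validated evaluation of a classifier
#'
#' For every partition column of `pset`: fit the classifier on the code-1
#' (training) individuals -- with inner-validation, target-class-AUC
#' hyperparameter selection (PNN bandwidth or MLP hidden size) -- score the
#' code-2 (testing) individuals, and compute one-vs-rest target-class
#' metrics. Partitions whose test fold lacks a positive or a negative for
#' the target class are skipped with a warning and excluded from
#' aggregation. Both classifiers can consume the identical partition set.
#'
#' @param ds a `gs_dataset` from [align()] (markers + phenotype), or a
#'   plain numeric matrix of inputs.
#' @param lab `class_labeling` over the dataset's individuals.
#' @param pset a [partition_set()] consistent with the dataset.
#' @param classifier `"pnn"` or `"mlp"`.
#' @param metrics any of `"auc"`, `"aucpr"`.
#' @param seed base seed; per-partition work uses derived child seeds.
#' @param hyper classifier options: for PNN `grid`, `posterior`,
#'   `val_frac`; for MLP `M_grid`, `replicates`, `val_frac`, `max_epochs`,
#'   `patience`, `aggregate`.
#' @return A named list of `cv_result` objects (one per metric), each with
#'   `per_partition`, `mean`, `sd` (sample, n-1), `metric`, `classifier`,
#'   `target_class`, `skipped`.
#' @export
run_cv <- function(ds, lab, pset, classifier = c("pnn", "mlp"),
                   metrics = c("auc", "aucpr"), seed = 1L,
                   hyper = list()) {
  classifier <- match.arg(classifier)
  metrics <- match.arg(metrics, several.ok = TRUE)
  X <- if (inherits(ds, "gs_dataset")) ds$markers$values else
    if (inherits(ds, "marker_matrix")) ds$values else as.matrix(ds)
  storage.mode(X) <- "double"
  if (nrow(X) != pset$n)
    gs_stop("partition set is for %d individuals, dataset has %d",
            pset$n, nrow(X))
  if (length(lab$labels) != nrow(X))
    gs_stop("labeling does not cover the dataset")
  C_full <- one_hot(lab)
  vals <- matrix(NA_real_, pset$R, length(metrics),
                 dimnames = list(NULL, metrics))
  skipped <- integer(0)
  for (j in seq_len(pset$R)) {
    tr <- which(pset$codes[, j] == 1L)
    te <- which(pset$codes[, j] == 2L)
    te_pos <- lab$labels[te] == lab$target_class
    if (all(te_pos) || !any(te_pos)) {
      warning(sprintf("partition %d: test fold degenerate for target class; skipped", j))
      skipped <- c(skipped, j)
      next
    }
    lab_tr <- lab
    lab_tr$labels <- lab$labels[tr]
    lab_tr$counts <- tabulate(lab_tr$labels, length(lab$class_names))
    pseed <- child_seed(seed, "cv", j)
    if (classifier == "pnn") {
      sel <- select_bandwidth(
        X[tr, , drop = FALSE], C_full[, tr, drop = FALSE], lab_tr,
        grid = hyper$grid,
        val_frac = if (is.null(hyper$val_frac)) 0.12 else hyper$val_frac,
        seed = pseed,
        posterior = if (is.null(hyper$posterior)) "softmax" else
          hyper$posterior)
      model <- pnn_fit(X[tr, , drop = FALSE], C_full[, tr, drop = FALSE],
                       sel$h)
      P <- pnn_predict_proba(model, X[te, , drop = FALSE],
                             posterior = if (is.null(hyper$posterior))
                               "softmax" else hyper$posterior)
      scores_list <- list(P)
    } else {
      ens <- mlp_ensemble_predict(
        X[tr, , drop = FALSE], C_full[, tr, drop = FALSE], lab_tr,
        X[te, , drop = FALSE],
        M_grid = if (is.null(hyper$M_grid)) c(1L, 2L, 3L, 4L) else
          hyper$M_grid,
        replicates = if (is.null(hyper$replicates)) 10L else
          hyper$replicates,
        seed = pseed,
        val_frac = if (is.null(hyper$val_frac)) 0.12 else hyper$val_frac,
        max_epochs = if (is.null(hyper$max_epochs)) 1000L else
          hyper$max_epochs,
        patience = if (is.null(hyper$patience)) 6L else hyper$patience)
      scores_list <- if (identical(hyper$aggregate, "metrics"))
        ens$per_replicate else list(ens$scores)
    }
    for (m in metrics) {
      fun <- if (m == "auc") roc_auc else pr_auc
      per_rep <- vapply(scores_list, function(P) {
        sb <- one_vs_rest(P, lab$labels[te], lab$target_class)
        fun(sb$scores, sb$labels)$area
      }, numeric(1))
      vals[j, m] <- mean(per_rep)
    }
  }
  out <- lapply(metrics, function(m) {
    v <- vals[, m]
    v <- v[!is.na(v)]
    structure(list(per_partition = v, mean = mean(v),
                   sd = stats::sd(v), metric = m, classifier = classifier,
                   target_class = lab$class_names[lab$target_class],
                   skipped = skipped),
              class = "cv_result")
  })
  names(out) <- metrics
  out
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%s %s [target: %s]: %s over %d partitions%s\n",
              toupper(x$classifier), x$metric, x$target_class,
              format(x), length(x$per_partition),
              if (length(x$skipped))
                sprintf(" (%d skipped)", length(x$skipped)) else ""))
  invisible(x)
}

#' Format a CV result as mean(sd) to three decimals
#'
#' Mirrors the conventional genomic-selection reporting style, e.g.
#' `"0.306(0.118)"`.
#'
#' @param x a `cv_result`.
#' @param ... unused.
#' @return character scalar.
#' @export
format.cv_result <- function(x, ...) {
  sprintf("%.3f(%.3f)", x$mean, x$sd)
}
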