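# Shared fixture builders. Everything is generated in code; no stored data.

# minimal labeling object without going through a phenotype
toy_labeling <- function(labels, class_names = NULL, target = max(labels)) {
  labels <- as.integer(labels)
  S <- max(labels)
  if (is.null(class_names)) class_names <- paste0("class", seq_len(S))
  structure(list(
    scheme = list(type = if (S == 2) "two_class" else "three_class"),
    class_names = class_names, labels = labels,
    counts = tabulate(labels, S), target_class = as.integer(target),
    cut_values = numeric(0), ids = NULL
  ), class = "class_labeling")
}

# two-class, two-dimensional Gaussian mixture with Bayes accuracy pnorm(d/2)
gaussian_mixture <- function(n, d = 2, seed = 1) {
  set.seed(seed)
  labels <- sample(1:2, n, replace = TRUE)
  X <- matrix(stats::rnorm(n * 2), n, 2)
  X[labels == 2, 1] <- X[labels == 2, 1] + d
  list(X = X, labels = labels)
}

# small integer marker matrix with ids
toy_markers <- function(n = 4, p = 3, coding = "012", seed = 1) {
  set.seed(seed)
  vals <- matrix(sample(0:(if (coding == "012") 2 else 1), n * p,
                        replace = TRUE), n, p)
  marker_matrix(vals, sprintf("i%02d", seq_len(n)),
                sprintf("m%02d", seq_len(p)), coding = coding)
}

# O(n^2) Mann-Whitney pair-counting oracle for ROC-AUC with half ties
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# average precision oracle: precision recomputed at every positive's rank,
# tied scores sharing a rank block get the block-end precision
ap_rank_oracle <- function(scores, labels) {
  labels <- as.logical(labels)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  P_tot <- sum(l)
  ap <- 0
  for (v in unique(s)) {
    in_block <- s == v
    upto <- s >= v
    tp_new <- sum(l & in_block)
    if (tp_new > 0) ap <- ap + (sum(l & upto) / sum(upto)) * tp_new / P_tot
  }
  ap
}
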