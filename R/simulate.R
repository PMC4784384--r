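# Synthetic genotype-phenotype simulator.
#
# Emulates the shape and statistical structure of real genomic-selection
# panels: hundreds of individuals, 10^3..10^4 biallelic markers (dominant
# 0/1 or allele-dosage 0/1/2), optional adjacent-marker linkage
# disequilibrium via a Gaussian copula (latent AR(1) per gamete,
# thresholded at the allele frequency), and a continuous trait built from
# additive QTL effects plus pairwise (additive x additive) epistatic
# interactions with exact in-sample heritability: the noise is
# orthogonalized against the genetic values and both are rescaled so
# Var(g)/Var(y) = h2 holds as a deterministic property of the fixture, not
# just in expectation.

#' Simulation configuration
#'
#' @param n number of individuals.
#' @param p number of markers.
#' @param coding `"012"` (dosage; two latent gametes) or `"01"` (dominant).
#' @param maf_range allele-frequency range, within (0, 0.5].
#' @param ld_rho adjacent-marker latent correlation in [0, 1).
#' @param n_qtl number of causal markers (<= p).
#' @param epistasis_pairs number of interacting QTL pairs
#'   (`2 * epistasis_pairs <= n_qtl`).
#' @param h2 genetic fraction of phenotypic variance, in (0, 1).
#' @param seed integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n = 306L, p = 1717L, coding = c("012", "01"),
                       maf_range = c(0.1, 0.5), ld_rho = 0.3,
                       n_qtl = 30L, epistasis_pairs = 5L, h2 = 0.5,
                       seed = 1L) {
  coding <- match.arg(coding)
  if (any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    gs_stop("maf_range must lie in (0, 0.5]")
  if (!(ld_rho >= 0 && ld_rho < 1)) gs_stop("ld_rho must be in [0,1)")
  if (n_qtl > p) gs_stop("n_qtl exceeds marker count")
  if (2L * epistasis_pairs > n_qtl)
    gs_stop("2*epistasis_pairs must be <= n_qtl")
  if (!(h2 > 0 && h2 < 1)) gs_stop("h2 must be in (0,1)")
  structure(list(n = as.integer(n), p = as.integer(p), coding = coding,
                 maf_range = maf_range, ld_rho = ld_rho,
                 n_qtl = as.integer(n_qtl),
                 epistasis_pairs = as.integer(epistasis_pairs),
                 h2 = h2, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a biallelic marker matrix
#'
#' Allele frequencies are drawn uniformly within `maf_range`; each gamete
#' (one for `"01"`, two for `"012"`) is a latent AR(1) Gaussian vector
#' across markers with lag-1 correlation `ld_rho`, thresholded at
#' `qnorm(1 - f_j)` so marker j carries the allele with probability `f_j`.
#' Dosages are the per-individual gamete sums.
#'
#' @param cfg a [sim_config()].
#' @return A [marker_matrix()].
#' @export
simulate_genotypes <- function(cfg) {
  set.seed(child_seed(cfg$seed, "genotypes"))
  f <- stats::runif(cfg$p, cfg$maf_range[1], cfg$maf_range[2])
  thresh <- stats::qnorm(1 - f)
  gametes <- if (cfg$coding == "012") 2L else 1L
  dosage <- matrix(0L, cfg$n, cfg$p)
  for (g in seq_len(gametes)) {
    L <- matrix(stats::rnorm(cfg$n * cfg$p), cfg$n, cfg$p)
    if (cfg$ld_rho > 0) {
      for (j in 2:cfg$p)
        L[, j] <- cfg$ld_rho * L[, j - 1] +
          sqrt(1 - cfg$ld_rho^2) * L[, j]
    }
    dosage <- dosage + (L > matrix(thresh, cfg$n, cfg$p, byrow = TRUE))
  }
  marker_matrix(dosage,
                individual_ids = sprintf("ind%04d", seq_len(cfg$n)),
                marker_ids = sprintf("m%05d", seq_len(cfg$p)),
                coding = cfg$coding)
}

#' Simulate phenotypes with additive + epistatic architecture
#'
#' Draws `n_qtl` causal markers (resampled with a warning if a draw is
#' monomorphic), standard-normal additive effects, and
#' `epistasis_pairs` pairwise dosage-product interaction effects. The
#' genetic value g and an independent Gaussian residual are centered, the
#' residual is orthogonalized against g, and both are scaled so that the
#' in-sample Var(g)/Var(y) equals `h2` exactly.
#'
#' @param X a [marker_matrix()] consistent with `cfg`.
#' @param cfg a [sim_config()].
#' @return `list(phenotype = phenotype_vector, truth = sim_truth)`;
#'   `truth` stores QTL indices and effects, epistatic pairs, the genetic
#'   values `g` and the realized heritability.
#' @export
simulate_phenotypes <- function(X, cfg) {
  M <- X$values
  storage.mode(M) <- "double"
  if (ncol(M) != cfg$p || nrow(M) != cfg$n)
    gs_stop("marker matrix does not match the configuration")
  set.seed(child_seed(cfg$seed, "phenotypes"))
  poly <- which(apply(M, 2, function(v) stats::var(v) > 0))
  if (length(poly) < cfg$n_qtl)
    gs_stop("fewer than n_qtl polymorphic markers")
  qtl <- sort(sample(seq_len(cfg$p), cfg$n_qtl))
  if (!all(qtl %in% poly)) {
    warning("monomorphic QTL draw; resampling from polymorphic markers")
    qtl <- sort(sample(poly, cfg$n_qtl))
  }
  a <- stats::rnorm(cfg$n_qtl)
  g <- as.numeric(M[, qtl, drop = FALSE] %*% a)
  pairs <- NULL
  e_eff <- numeric(0)
  if (cfg$epistasis_pairs > 0) {
    pick <- sample(cfg$n_qtl, 2L * cfg$epistasis_pairs)
    pairs <- matrix(qtl[pick], ncol = 2, byrow = TRUE)
    e_eff <- stats::rnorm(cfg$epistasis_pairs)
    for (q in seq_len(cfg$epistasis_pairs))
      g <- g + e_eff[q] * M[, pairs[q, 1]] * M[, pairs[q, 2]]
  }
  if (stats::var(g) == 0) gs_stop("zero genetic variance; change the seed")
  eps <- stats::rnorm(cfg$n)
  gc <- g - mean(g)
  ec <- eps - mean(eps)
  ec <- ec - sum(ec * gc) / sum(gc^2) * gc   # orthogonalize
  gs <- gc / stats::sd(gc) * sqrt(cfg$h2)
  es <- ec / stats::sd(ec) * sqrt(1 - cfg$h2)
  y <- gs + es
  ph <- phenotype_vector(y, X$individual_ids, trait_name = "sim_trait",
                         environment = "sim_env")
  truth <- structure(list(qtl = qtl, additive_effects = a,
                          epistasis_pairs = pairs,
                          epistasis_effects = e_eff,
                          g = gs, scale = sqrt(cfg$h2) / stats::sd(gc),
                          g_raw = g,
                          realized_h2 = stats::var(gs) / stats::var(y)),
                     class = "sim_truth")
  list(phenotype = ph, truth = truth)
}

#' Write a complete synthetic fixture to disk
#'
#' Writes `markers.csv`, `phenotype.csv`, `truth.csv` and `simconfig.txt`
#' (key-value snapshot) into `out_dir`; the tables round-trip through the
#' package readers. Byte-identical for a fixed seed.
#'
#' @param cfg a [sim_config()].
#' @param out_dir writable directory (created if needed).
#' @return invisible list of written paths.
#' @export
make_fixture <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  X <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(X, cfg)
  paths <- list(
    markers = file.path(out_dir, "markers.csv"),
    phenotype = file.path(out_dir, "phenotype.csv"),
    truth = file.path(out_dir, "truth.csv"),
    config = file.path(out_dir, "simconfig.txt")
  )
  write_marker_matrix(X, paths$markers)
  write_phenotype(sim$phenotype, paths$phenotype)
  tr <- sim$truth
  truth_df <- data.frame(
    qtl = tr$qtl, additive_effect = sprintf("%.17g", tr$additive_effects))
  utils::write.table(truth_df, paths$truth, sep = ",", row.names = FALSE,
                     quote = FALSE)
  writeLines(c(sprintf("n=%d", cfg$n), sprintf("p=%d", cfg$p),
               sprintf("coding=%s", cfg$coding),
               sprintf("maf_range=%.17g,%.17g", cfg$maf_range[1],
                       cfg$maf_range[2]),
               sprintf("ld_rho=%.17g", cfg$ld_rho),
               sprintf("n_qtl=%d", cfg$n_qtl),
               sprintf("epistasis_pairs=%d", cfg$epistasis_pairs),
               sprintf("h2=%.17g", cfg$h2),
               sprintf("seed=%d", cfg$seed),
               sprintf("realized_h2=%.17g", tr$realized_h2)),
             paths$config)
  invisible(paths)
}
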