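# Domain types and delimited-text I/O for genotype, phenotype and
# partition-index data.
#
# Conventions: individuals are rows, markers are columns (X is n x p).
# Marker coding is declared, never inferred: "012" for codominant SNP allele
# dosage, "01" for dominant presence/absence markers (e.g. DArT). No
# centering or scaling is applied to marker codes.

#' Construct a marker matrix
#'
#' An n x p integer-coded genotype matrix with unique individual and marker
#' identifiers. Entries must lie in \{0,1\} (coding `"01"`) or \{0,1,2\}
#' (coding `"012"`); missing values are handled at load time (see
#' [read_marker_matrix()]).
#'
#' @param values integer matrix, individuals in rows, markers in columns.
#' @param individual_ids character vector of unique row identifiers.
#' @param marker_ids character vector of unique column identifiers.
#' @param coding `"012"` (allele dosage) or `"01"` (dominant markers).
#' @return An object of class `marker_matrix`.
#' @export
marker_matrix <- function(values, individual_ids = rownames(values),
                          marker_ids = colnames(values),
                          coding = c("012", "01")) {
  coding <- match.arg(coding)
  values <- as.matrix(values)
  if (is.null(individual_ids) || is.null(marker_ids))
    gs_stop("individual and marker ids are required")
  individual_ids <- as.character(individual_ids)
  marker_ids <- as.character(marker_ids)
  if (nrow(values) != length(individual_ids) ||
      ncol(values) != length(marker_ids))
    gs_stop("id lengths do not match matrix dimensions")
  if (nrow(values) < 2 || ncol(values) < 1)
    gs_stop("need n >= 2 individuals and p >= 1 markers")
  dup <- individual_ids[duplicated(individual_ids)]
  if (length(dup)) gs_stop("duplicate individual id: %s", dup[1])
  dup <- marker_ids[duplicated(marker_ids)]
  if (length(dup)) gs_stop("duplicate marker id: %s", dup[1])
  if (anyNA(values)) gs_stop("marker matrix contains missing values")
  if (any(values != round(values))) {
    idx <- which(values != round(values), arr.ind = TRUE)[1, ]
    gs_stop("non-integer genotype at row %d, column %d", idx[1], idx[2])
  }
  allowed <- if (coding == "012") c(0, 1, 2) else c(0, 1)
  bad <- !(values %in% allowed)
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(values)), arr.ind = TRUE)[1, ]
    gs_stop("entry %s at row %s (id %s), column %s (id %s) outside coding {%s}",
            format(values[idx[1], idx[2]]), idx[1], individual_ids[idx[1]],
            idx[2], marker_ids[idx[2]], paste(allowed, collapse = ","))
  }
  storage.mode(values) <- "integer"
  dimnames(values) <- list(individual_ids, marker_ids)
  structure(list(values = values, individual_ids = individual_ids,
                 marker_ids = marker_ids, coding = coding),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("marker_matrix: %d individuals x %d markers, coding {%s}\n",
              nrow(x$values), ncol(x$values),
              paste(seq(0, ifelse(x$coding == "012", 2, 1)), collapse = ",")))
  invisible(x)
}

#' @export
dim.marker_matrix <- function(x) dim(x$values)

#' Construct a phenotype vector
#'
#' Continuous trait values for one trait-environment combination, aligned by
#' individual identifier to a marker matrix.
#'
#' @param y numeric vector of finite trait values.
#' @param individual_ids character identifiers, same length as `y`.
#' @param trait_name,environment descriptive strings.
#' @return An object of class `phenotype_vector`.
#' @export
phenotype_vector <- function(y, individual_ids, trait_name = "trait",
                             environment = "env") {
  y <- as.numeric(y)
  individual_ids <- as.character(individual_ids)
  if (length(y) != length(individual_ids))
    gs_stop("phenotype and id lengths differ")
  if (any(!is.finite(y))) gs_stop("non-finite phenotype values")
  dup <- individual_ids[duplicated(individual_ids)]
  if (length(dup)) gs_stop("duplicate individual id: %s", dup[1])
  structure(list(y = y, individual_ids = individual_ids,
                 trait_name = trait_name, environment = environment),
            class = "phenotype_vector")
}

#' Construct a partition-index (PINDX) set
#'
#' An n x R integer matrix with entries 1 (training) or 2 (testing), one
#' column per cross-validation partition. Every column must contain both
#' codes.
#'
#' @param codes integer matrix of 1s and 2s.
#' @return An object of class `partition_set`.
#' @export
partition_set <- function(codes) {
  codes <- as.matrix(codes)
  if (!all(codes %in% c(1L, 2L)))
    gs_stop("partition codes must be 1 (training) or 2 (testing)")
  storage.mode(codes) <- "integer"
  for (j in seq_len(ncol(codes))) {
    if (!all(c(1L, 2L) %in% codes[, j]))
      gs_stop("partition column %d lacks a training or testing individual", j)
  }
  colnames(codes) <- paste0("P", seq_len(ncol(codes)))
  structure(list(codes = codes, n = nrow(codes), R = ncol(codes)),
            class = "partition_set")
}

#' Read a marker matrix from delimited text
#'
#' Expects a header row of marker ids and a first column of individual ids.
#' The coding is declared, not inferred; entries outside the declared coding
#' are rejected with their coordinates. Missing cells follow `missing`:
#' `"fail"` (default -- the classifiers' distance/score arithmetic assumes a
#' complete matrix) or `"impute_column_mode"` (replace by the column's most
#' frequent observed code).
#'
#' @param path file path.
#' @param dialect `"csv"` or `"tsv"`.
#' @inheritParams marker_matrix
#' @param missing missing-genotype policy.
#' @return A [marker_matrix()].
#' @export
read_marker_matrix <- function(path, dialect = c("csv", "tsv"),
                               coding = c("012", "01"),
                               missing = c("fail", "impute_column_mode")) {
  dialect <- match.arg(dialect)
  coding <- match.arg(coding)
  missing <- match.arg(missing)
  if (!file.exists(path)) gs_stop("file not found: %s", path)
  sep <- if (dialect == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "")
  m <- as.matrix(df)
  suppressWarnings(num <- matrix(as.numeric(m), nrow(m), ncol(m),
                                 dimnames = dimnames(m)))
  bad <- is.na(num) & !(m %in% c("", "NA"))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    gs_stop("non-numeric cell '%s' at row %d, column %d",
            m[idx[1], idx[2]], idx[1], idx[2])
  }
  if (anyNA(num)) {
    if (missing == "fail") {
      idx <- which(is.na(num), arr.ind = TRUE)[1, ]
      gs_stop("missing genotype at row %d, column %d (policy 'fail')",
              idx[1], idx[2])
    }
    n_imp <- sum(is.na(num))
    for (j in which(colSums(is.na(num)) > 0)) {
      obs <- num[!is.na(num[, j]), j]
      if (!length(obs)) gs_stop("marker column %d entirely missing", j)
      mode_val <- as.numeric(names(which.max(table(obs))))
      num[is.na(num[, j]), j] <- mode_val
    }
    gs_log(sprintf("imputed %d missing genotypes by column mode", n_imp))
  }
  marker_matrix(num, rownames(num), colnames(num), coding = coding)
}

#' Write a marker matrix to delimited text
#' @param x a [marker_matrix()].
#' @param path output file path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_marker_matrix <- function(x, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  df <- data.frame(id = x$individual_ids, x$values, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' Two-column delimited text: individual id, trait value. A header row is
#' required; extra columns are ignored.
#'
#' @inheritParams read_marker_matrix
#' @param trait_name,environment carried into the result.
#' @return A [phenotype_vector()].
#' @export
read_phenotype <- function(path, dialect = c("csv", "tsv"),
                           trait_name = "trait", environment = "env") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) gs_stop("file not found: %s", path)
  sep <- if (dialect == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, comment.char = "")
  phenotype_vector(as.numeric(df[[2]]), as.character(df[[1]]),
                   trait_name = trait_name, environment = environment)
}

#' Write a phenotype table
#' @param ph a [phenotype_vector()].
#' @inheritParams write_marker_matrix
#' @return `path`, invisibly.
#' @export
write_phenotype <- function(ph, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  df <- data.frame(id = ph$individual_ids, y = ph$y)
  names(df)[2] <- ph$trait_name
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a PINDX partition file
#'
#' One row per individual, one column per partition, entries in \{1,2\}
#' (1 = training, 2 = testing), header `P1..PR`. Write-then-read is the
#' identity on the codes.
#'
#' @param pset a [partition_set()].
#' @param path file path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path` (write) or a [partition_set()] (read).
#' @export
write_partition_set <- function(pset, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  utils::write.table(pset$codes, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_partition_set
#' @export
read_partition_set <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) gs_stop("file not found: %s", path)
  sep <- if (dialect == "csv") "," else "\t"
  first <- readLines(path, n = 1)
  has_header <- grepl("P", first, fixed = TRUE)
  m <- as.matrix(utils::read.table(path, header = has_header, sep = sep))
  if (!all(m %in% c(1, 2))) {
    bad <- m[!(m %in% c(1, 2))][1]
    gs_stop("PINDX entry '%s' is not 1 or 2", format(bad))
  }
  partition_set(m)
}

#' Align a marker matrix and a phenotype vector into a dataset
#'
#' Reorders the phenotype to the marker-row order on the intersection of
#' the id sets; individuals missing from either component are dropped and
#' the drop count logged. Idempotent.
#'
#' @param markers a [marker_matrix()].
#' @param phenotype a [phenotype_vector()].
#' @param labeling optional class labeling (see [assign_three_classes()]).
#' @return An object of class `gs_dataset` with elements `markers`,
#'   `phenotype` and (optionally) `labeling`.
#' @export
align <- function(markers, phenotype, labeling = NULL) {
  common <- markers$individual_ids[markers$individual_ids %in%
                                     phenotype$individual_ids]
  if (!length(common)) gs_stop("no individuals in common")
  dropped <- (length(markers$individual_ids) - length(common)) +
    (length(phenotype$individual_ids) - length(common))
  if (dropped > 0)
    gs_log(sprintf("align: dropped %d unmatched individual record(s)", dropped))
  mm <- marker_matrix(markers$values[common, , drop = FALSE], common,
                      markers$marker_ids, coding = markers$coding)
  idx <- match(common, phenotype$individual_ids)
  ph <- phenotype_vector(phenotype$y[idx], common,
                         trait_name = phenotype$trait_name,
                         environment = phenotype$environment)
  structure(list(markers = mm, phenotype = ph, labeling = labeling),
            class = "gs_dataset")
}
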