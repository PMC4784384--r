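#' @keywords internal
"_PACKAGE"

#' Round half away from zero
#'
#' Nearest-rank quantiles and per-class test-set sizes use conventional
#' rounding (0.5 rounds up for positive arguments), not the IEC 60559
#' banker's rounding of [base::round()].
#'
#' @param x numeric vector.
#' @return integer vector.
#' @keywords internal
round_half_up <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Derive a child seed from a base seed and a stage label
#'
#' All randomness in the package flows from a single user seed; each stage
#' (partition generation, inner splits, weight initialization, replicates)
#' draws from its own deterministic child seed so stages do not perturb each
#' other. Kept below 2^31 - 1.
#'
#' @param seed integer base seed.
#' @param ... stage labels (character or integer) hashed into the child seed.
#' @return integer seed.
#' @keywords internal
child_seed <- function(seed, ...) {
  parts <- unlist(lapply(list(...), as.character))
  h <- as.double(seed %% 2147483647L)
  for (s in parts) {
    for (ch in utf8ToInt(s)) {
      h <- (h * 31 + ch) %% 2147483629
    }
  }
  as.integer(h %% 2147483647)
}

#' Log a message to stderr
#' @keywords internal
gs_log <- function(..., level = "INFO") {
  message(sprintf("[gsclassify %s] %s", level, paste0(...)))
}

# internal: stop with a consistent error class
gs_stop <- function(fmt, ..., class = "gsclassify_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}
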