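# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed for the duration of `code` and restores the caller's RNG
#' state afterwards, so generators are reproducible without clobbering the
#' session RNG.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # force RNG initialisation
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != round(x))
    stopf("`%s` must be a single integer >= %d", name, min)
  invisible(as.integer(x))
}

check_fraction <- function(x, name, lo = 0, hi = 1, lo_open = FALSE) {
  bad <- length(x) != 1L || !is.numeric(x) || is.na(x) || x > hi ||
    (if (lo_open) x <= lo else x < lo)
  if (bad) stopf("`%s` must be a number in %s%g, %g]", name,
                 if (lo_open) "(" else "[", lo, hi)
  invisible(as.numeric(x))
}

check_matrix <- function(x, name = "matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stopf("`%s` must be a numeric matrix (features x samples)", name)
  if (anyNA(x)) stopf("`%s` contains missing values", name)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stopf("`%s` must have feature rownames and sample colnames", name)
  if (anyDuplicated(rownames(x))) stopf("`%s` has duplicated feature ids", name)
  invisible(x)
}

# row-wise sample SD (n-1 denominator)
row_sds <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  sqrt(rowSums((x - mu)^2) / (n - 1))
}
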