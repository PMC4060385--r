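# Plain-text readers and writers for the formats the pipeline exchanges:
# GMT gene sets, TSV expression matrices, CSV annotation and clinical tables.

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then tab-separated gene symbols.
#'
#' @param path Path to a GMT file.
#' @return Named list of uppercase gene-symbol vectors; descriptions kept
#'   as attribute `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stopf("malformed GMT line(s): %s",
                      paste(utils::head(which(bad), 3), collapse = ", "))
  sets <- lapply(parts, function(p) unique(toupper(p[-(1:2)])))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  attr(sets, "descriptions") <- vapply(parts, `[[`, character(1), 2L)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param genesets Named list of gene-symbol vectors.
#' @param path Output path.
#' @param descriptions Optional per-set description (recycled).
#' @export
write_gmt <- function(genesets, path, descriptions = "") {
  if (is.null(names(genesets))) stopf("`genesets` must be a named list")
  desc <- rep_len(descriptions, length(genesets))
  lines <- vapply(seq_along(genesets), function(i)
    paste(c(names(genesets)[i], desc[i], genesets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a tab-delimited expression matrix
#'
#' Features in rows (first column = feature id), samples in columns.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  check_matrix(m, basename(path))
  m
}

#' Write an expression matrix as TSV
#'
#' @param x Feature x sample matrix.
#' @param path Output path.
#' @param id_col Name of the feature-id column.
#' @export
write_expression_tsv <- function(x, path, id_col = "feature_id") {
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical trial table
#'
#' CSV with one row per patient. Required columns: `patient_id`, `arm`
#' (ADA/TCZ), `sicam1`, `cxcl13`, `acr20`, `acr50`, `acr70`. Optional:
#' `sicam1_censored`, `cxcl13_censored` (logical/0-1), `das28_change`,
#' `eular_class`.
#'
#' @param path Path to a CSV file.
#' @return Data frame of class `trial_cohort`.
#' @export
read_clinical_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "arm", "sicam1", "cxcl13", "acr20", "acr50", "acr70")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stopf("clinical table lacks required column(s): %s",
          paste(missing_cols, collapse = ", "))
  if (!all(df$arm %in% c("ADA", "TCZ")))
    stopf("`arm` must be 'ADA' or 'TCZ'")
  df$arm <- factor(df$arm, levels = c("ADA", "TCZ"))
  for (ep in c("acr20", "acr50", "acr70")) df[[ep]] <- as.logical(df[[ep]])
  for (cc in c("sicam1_censored", "cxcl13_censored"))
    if (!is.null(df[[cc]])) df[[cc]] <- as.logical(df[[cc]])
  class(df) <- c("trial_cohort", "data.frame")
  df
}

#' Write a trial cohort as CSV
#'
#' @param records Trial cohort data frame.
#' @param path Output path.
#' @export
write_clinical_csv <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}
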