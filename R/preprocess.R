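# Expression preprocessing: quantile normalization, probe filtering and
# collapse to gene symbols, variance filtering, and per-gene scaling.
#
# The filter composition is fixed and order-sensitive:
#   quality grade -> Entrez mapping -> collapse to one probe per gene ->
#   top-fraction variance filter -> center/scale
# and each stage's surviving feature count is recorded.

#' Quantile-normalize an expression matrix
#'
#' Forces every sample column onto the common distribution given by the
#' across-sample mean of order statistics (the quantile-normalization step
#' of RMA). Ties within a column share the mean of their quantile values.
#'
#' @param x Numeric matrix, features x samples, log2 scale.
#' @return Matrix of the same shape with identical column distributions.
#' @examples
#' m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
#' rownames(m) <- paste0("g", 1:3)
#' quantile_normalize(m)  # both columns become 2.5, 3.5, 4.5
#' @export
quantile_normalize <- function(x) {
  check_matrix(x, "x")
  if (ncol(x) < 2L) {
    warnf("quantile normalization needs >= 2 samples; returning input unchanged")
    return(x)
  }
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Collapse a probe-level matrix to one row per gene
#'
#' Applies the probe quality filters and the largest-variance collapse rule:
#' probes with a non-A quality grade are dropped, then probes without an
#' Entrez mapping, then for each gene only the probe with the largest
#' across-sample variance is retained. Output rows are named by (uppercased)
#' gene symbol. Variance ties are broken by probe id, lexicographically.
#'
#' @param x Probe-level matrix (probes x samples).
#' @param annotation Data frame with columns `probe_id`, `gene_symbol`,
#'   `entrez_id` (empty string or `NA` when unmapped), `quality_grade`
#'   ("A" for reliable probes).
#' @return Gene-level matrix with attribute `stage_counts`, the number of
#'   features surviving each filter stage.
#' @export
collapse_probes <- function(x, annotation) {
  check_matrix(x, "x")
  need <- c("probe_id", "gene_symbol", "entrez_id", "quality_grade")
  if (!all(need %in% names(annotation)))
    stopf("`annotation` must have columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(annotation$probe_id)) stopf("duplicated probe ids in annotation")
  idx <- match(rownames(x), annotation$probe_id)
  if (anyNA(idx)) stopf("%d probes missing from the annotation", sum(is.na(idx)))
  ann <- annotation[idx, ]

  counts <- c(input = nrow(x))
  keep <- ann$quality_grade == "A"
  if (!any(keep)) stopf("no probes after quality filter")
  x <- x[keep, , drop = FALSE]; ann <- ann[keep, ]
  counts["quality_A"] <- nrow(x)

  keep <- !is.na(ann$entrez_id) & ann$entrez_id != ""
  if (!any(keep)) stopf("no probes after Entrez filter")
  x <- x[keep, , drop = FALSE]; ann <- ann[keep, ]
  counts["entrez_mapped"] <- nrow(x)

  v <- row_sds(x)^2
  ord <- order(ann$gene_symbol, -v, ann$probe_id)
  first <- !duplicated(ann$gene_symbol[ord])
  pick <- ord[first]
  out <- x[pick, , drop = FALSE]
  rownames(out) <- toupper(ann$gene_symbol[pick])
  counts["collapsed_genes"] <- nrow(out)
  attr(out, "stage_counts") <- counts
  out
}

#' Retain the most variable genes
#'
#' Keeps the `ceiling(fraction * n_genes)` genes with the largest sample SD
#' across samples, preserving the input row order of the survivors. Ties at
#' the retention boundary are broken by feature id, lexicographically.
#'
#' @param x Gene-level matrix.
#' @param fraction Fraction of genes to retain, in (0, 1].
#' @return The filtered matrix.
#' @export
variance_filter <- function(x, fraction = 0.4) {
  check_matrix(x, "x")
  check_fraction(fraction, "fraction", lo_open = TRUE)
  n_keep <- ceiling(fraction * nrow(x))
  sds <- row_sds(x)
  ord <- order(-sds, rownames(x))
  keep <- sort(ord[seq_len(n_keep)])
  x[keep, , drop = FALSE]
}

#' Center and scale each gene
#'
#' Transforms each row to mean 0 and sample SD 1 (n - 1 denominator).
#'
#' @param x Gene-level matrix; every gene must have positive SD.
#' @return The scaled matrix, with attribute `scaled = TRUE`.
#' @export
center_scale <- function(x) {
  check_matrix(x, "x")
  sds <- row_sds(x)
  if (any(sds == 0))
    stopf("zero-SD gene(s): %s",
          paste(utils::head(rownames(x)[sds == 0], 5), collapse = ", "))
  out <- (x - rowMeans(x)) / sds
  attr(out, "scaled") <- TRUE
  out
}

#' Run the full preprocessing pipeline
#'
#' Quantile normalization, probe quality/Entrez filtering and collapse to
#' gene symbols, top-fraction variance filtering, then per-gene scaling.
#'
#' @param x Probe-level matrix (probes x samples).
#' @param annotation Probe annotation table (see [collapse_probes()]).
#' @param top_frac Fraction of genes retained by the variance filter.
#' @param quantile Apply quantile normalization first?
#' @return List with `scaled` (the analysis-ready matrix), `genes` (the
#'   unscaled gene-level matrix after collapse, used by differential
#'   expression), and `stage_counts`.
#' @export
preprocess_pipeline <- function(x, annotation, top_frac = 0.4, quantile = TRUE) {
  if (quantile) x <- quantile_normalize(x)
  genes <- collapse_probes(x, annotation)
  counts <- attr(genes, "stage_counts")
  filtered <- variance_filter(genes, top_frac)
  counts["variance_filtered"] <- nrow(filtered)
  scaled <- center_scale(filtered)
  list(scaled = scaled, genes = genes, stage_counts = counts)
}
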