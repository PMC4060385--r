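# Mapping derived signatures onto an external cohort and relating baseline
# scores to clinical response: symbol-level platform mapping, good-vs-poor
# comparison of scores, and ROC/AUC.

#' Map a gene set onto another platform's feature space
#'
#' Intersects the set with the target feature ids by uppercase gene symbol
#' and reports the mapping rate.
#'
#' @param geneset Character vector of gene symbols.
#' @param target_feature_ids Feature ids (gene symbols) of the target
#'   platform.
#' @return The mapped gene set (attribute `mapping_rate` holds the fraction
#'   retained). Empty intersections are an error.
#' @export
map_geneset_to_platform <- function(geneset, target_feature_ids) {
  geneset <- unique(toupper(geneset))
  mapped <- intersect(geneset, unique(toupper(target_feature_ids)))
  if (!length(mapped)) stopf("no genes of the set map to the target platform")
  rate <- length(mapped) / length(geneset)
  message(sprintf("mapped %d/%d genes (rate %.2f)",
                  length(mapped), length(geneset), rate))
  attr(mapped, "mapping_rate") <- rate
  mapped
}

#' Compare baseline scores between good and poor responders
#'
#' Two-sample t-test of baseline gene-set scores, good versus poor EULAR
#' response; moderate responders are excluded from the test. Positive t
#' means higher scores in good responders.
#'
#' @param scores Named numeric vector of per-sample scores.
#' @param labels Factor/character of EULAR classes ("good", "moderate",
#'   "poor"), aligned with `scores`.
#' @param var_equal Pooled-variance t-test (default) or Welch.
#' @return List: `t`, `p`, `n_good`, `n_poor`.
#' @export
compare_good_poor <- function(scores, labels, var_equal = TRUE) {
  if (length(scores) != length(labels)) stopf("scores and labels differ in length")
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("good", "moderate", "poor"))
  if (length(bad)) stopf("unknown response class(es): %s", paste(bad, collapse = ", "))
  good <- scores[labels == "good"]
  poor <- scores[labels == "poor"]
  if (!length(good) || !length(poor))
    stopf("both 'good' and 'poor' classes must be non-empty")
  if (stats::sd(good) == 0 && stats::sd(poor) == 0) {
    # degenerate constant inputs: equal means are indistinguishable
    dm <- mean(good) - mean(poor)
    t <- if (dm == 0) 0 else sign(dm) * Inf
    return(list(t = t, p = if (dm == 0) 1 else 0,
                n_good = length(good), n_poor = length(poor)))
  }
  tt <- stats::t.test(good, poor, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value,
       n_good = length(good), n_poor = length(poor))
}

#' ROC curve and AUC of a continuous score against a binary label
#'
#' The AUC is computed by the rank (Mann-Whitney) formula with midrank
#' handling of ties:
#' `AUC = (sum of positive-case midranks - n1 (n1 + 1) / 2) / (n1 * n0)`.
#' The curve enumerates every distinct score as a threshold (predict
#' positive when score >= threshold).
#'
#' @param scores Numeric vector.
#' @param labels Logical (or 0/1, or two-level factor) vector; `TRUE` is the
#'   positive class. Both classes must be present.
#' @return List of class `roc_curve`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stopf("scores and labels differ in length")
  if (is.factor(labels) || is.character(labels)) {
    lv <- sort(unique(as.character(labels)))
    if (length(lv) != 2L) stopf("labels must have exactly two classes")
    labels <- as.character(labels) == lv[2]
  }
  labels <- as.logical(labels)
  if (anyNA(labels) || anyNA(scores)) stopf("missing values in scores or labels")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stopf("both classes must be present")
  r <- rank(scores)  # midranks
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) sum(labels & scores >= t) / n1, numeric(1))
  spec <- vapply(thr, function(t) sum(!labels & scores < t) / n0, numeric(1))
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: AUC = %.3f (%d thresholds)\n",
              x$auc, length(x$thresholds)))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(1 - x$specificity, x$sensitivity, type = "s",
       xlab = "1 - specificity", ylab = "sensitivity",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
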