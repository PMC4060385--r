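# Unsupervised phenotype discovery: Ward / PAM clustering of samples,
# cluster-number selection by mean silhouette width with a k-nearest-neighbor
# agreement tie-breaker, and a hold-out resampling co-clustering matrix for
# robustness assessment.

sample_dist <- function(x) stats::dist(t(x), method = "euclidean")

# renumber clusters by decreasing size; ties by smallest member sample id
renumber_clusters <- function(cl, sample_ids) {
  sizes <- table(cl)
  first_member <- vapply(names(sizes),
                         function(g) min(sample_ids[cl == g]), character(1))
  new_order <- names(sizes)[order(-sizes, first_member)]
  as.integer(match(as.character(cl), new_order))
}

#' Cluster samples by expression profile
#'
#' Agglomerative hierarchical clustering with Ward's criterion (default
#' "ward.D2": Ward on squared Euclidean distances via the Lance-Williams
#' update, applied to plain Euclidean input) cut at `k`, or partitioning
#' around medoids (PAM) with the deterministic BUILD + SWAP algorithm.
#' Either way the result is deterministic given the data. Clusters are
#' renumbered by decreasing size (ties by smallest member sample id).
#'
#' @param x Scaled gene x sample matrix (see [center_scale()]).
#' @param k Number of clusters, between 2 and `ncol(x) - 1`.
#' @param method `"ward"` or `"pam"`.
#' @param linkage Ward variant passed to [stats::hclust()]: `"ward.D2"`
#'   (default) or `"ward.D"`.
#' @return Data frame of class `cluster_assignment` with columns
#'   `sample_id`, `cluster`; the dendrogram (Ward) or medoid ids (PAM) are
#'   attached as attributes.
#' @export
cluster_samples <- function(x, k, method = c("ward", "pam"),
                            linkage = c("ward.D2", "ward.D")) {
  check_matrix(x, "x")
  method <- match.arg(method)
  linkage <- match.arg(linkage)
  n <- ncol(x)
  if (!is.numeric(k) || length(k) != 1L || k < 2 || k > n - 1)
    stopf("`k` must lie in [2, %d]", n - 1)
  d <- sample_dist(x)
  if (method == "ward") {
    tree <- stats::hclust(d, method = linkage)
    cl <- stats::cutree(tree, k = k)
  } else {
    fit <- cluster::pam(d, k = k, diss = TRUE)
    cl <- fit$clustering
  }
  out <- data.frame(sample_id = colnames(x),
                    cluster = renumber_clusters(cl, colnames(x)),
                    stringsAsFactors = FALSE)
  if (method == "ward") attr(out, "tree") <- tree else attr(out, "medoids") <- fit$medoids
  attr(out, "method") <- method
  class(out) <- c("cluster_assignment", "data.frame")
  out
}

#' Silhouette and k-nearest-neighbor quality of a partition
#'
#' `mean_silhouette` is the mean over samples of `(b - a) / max(a, b)` where
#' `a` is the mean distance to the sample's own cluster and `b` the smallest
#' mean distance to another cluster; samples in singleton clusters
#' contribute 0. `knn_agreement` is the mean over samples of the fraction of
#' their `k_nn` nearest neighbors assigned to the same cluster.
#'
#' @param d Distance object or square symmetric matrix over samples.
#' @param assignment A [cluster_samples()] result, or an integer vector.
#' @param k_nn Neighborhood size for the agreement score (< n samples).
#' @return List of class `cluster_quality`: `k`, `mean_silhouette`,
#'   `knn_agreement`.
#' @export
cluster_quality <- function(d, assignment, k_nn = 4L) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  cl <- if (is.data.frame(assignment)) assignment$cluster else as.integer(assignment)
  if (length(cl) != n) stopf("assignment length does not match distance matrix")
  check_count(k_nn, "k_nn")
  if (k_nn >= n) stopf("`k_nn` must be smaller than the number of samples")

  ids <- sort(unique(cl))
  sil <- numeric(n)
  for (i in seq_len(n)) {
    own <- cl == cl[i]
    if (sum(own) == 1L) { sil[i] <- 0; next }
    a <- mean(dm[i, own & seq_len(n) != i])
    b <- min(vapply(ids[ids != cl[i]],
                    function(g) mean(dm[i, cl == g]), numeric(1)))
    sil[i] <- (b - a) / max(a, b)
  }
  knn <- vapply(seq_len(n), function(i) {
    nb <- order(dm[i, -i])[seq_len(k_nn)]
    nb_idx <- seq_len(n)[-i][nb]
    mean(cl[nb_idx] == cl[i])
  }, numeric(1))

  structure(list(k = length(ids), mean_silhouette = mean(sil),
                 knn_agreement = mean(knn)),
            class = "cluster_quality")
}

#' Select the number of clusters
#'
#' Clusters the samples at each k in `k_min:k_max` and picks the k
#' maximizing the mean silhouette width, with k-nearest-neighbor agreement
#' as tie-breaker. If no k reaches `structure_floor` on mean silhouette the
#' choice is flagged low-confidence.
#'
#' @param x Scaled gene x sample matrix.
#' @param k_min,k_max Range of cluster numbers to assess.
#' @param method,linkage Passed to [cluster_samples()].
#' @param k_nn Neighborhood size for [cluster_quality()].
#' @param structure_floor Mean-silhouette level below which the cohort is
#'   considered to show no convincing cluster structure.
#' @return List of class `k_selection`: `chosen_k`, `quality` (data frame
#'   over the k range), `low_confidence`.
#' @export
select_k <- function(x, k_min = 3L, k_max = 8L, method = "ward",
                     linkage = "ward.D2", k_nn = 4L, structure_floor = 0.15) {
  check_matrix(x, "x")
  if (k_max < k_min) stopf("empty k range")
  if (k_max >= ncol(x)) stopf("`k_max` must be smaller than the sample count")
  d <- sample_dist(x)
  rows <- lapply(seq.int(k_min, k_max), function(k) {
    a <- cluster_samples(x, k, method = method, linkage = linkage)
    q <- cluster_quality(d, a, k_nn = k_nn)
    data.frame(k = k, mean_silhouette = q$mean_silhouette,
               knn_agreement = q$knn_agreement)
  })
  quality <- do.call(rbind, rows)
  best <- order(-quality$mean_silhouette, -quality$knn_agreement)[1L]
  structure(list(chosen_k = quality$k[best], quality = quality,
                 low_confidence = quality$mean_silhouette[best] < structure_floor),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("Selected k = %d%s\n", x$chosen_k,
              if (x$low_confidence) " (low confidence: weak cluster structure)" else ""))
  print(x$quality, row.names = FALSE)
  invisible(x)
}

#' Fit synovial phenotype clusters
#'
#' Convenience wrapper tying cluster-number selection and clustering
#' together: selects k (unless given), clusters, and reports quality.
#'
#' @param x Scaled gene x sample matrix.
#' @param k Number of clusters, or `"auto"` to select by silhouette.
#' @param method,linkage,k_nn,... Passed to [select_k()] / [cluster_samples()].
#' @return Object of class `phenotype_fit`: `assignment`, `k`, `selection`
#'   (when automatic), `quality`.
#' @examples
#' coh <- generate_expression_cohort(expression_sim_config(seed = 3))
#' pp <- preprocess_pipeline(coh$probes, coh$annotation)
#' fit <- fit_phenotypes(pp$scaled)
#' fit
#' @export
fit_phenotypes <- function(x, k = "auto", method = "ward",
                           linkage = "ward.D2", k_nn = 4L, ...) {
  selection <- NULL
  if (identical(k, "auto")) {
    selection <- select_k(x, method = method, linkage = linkage, k_nn = k_nn, ...)
    k <- selection$chosen_k
  }
  assignment <- cluster_samples(x, k, method = method, linkage = linkage)
  quality <- cluster_quality(sample_dist(x), assignment, k_nn = k_nn)
  structure(list(assignment = assignment, k = k, selection = selection,
                 quality = quality, method = method),
            class = "phenotype_fit")
}

#' @export
print.phenotype_fit <- function(x, ...) {
  cat(sprintf("Phenotype clustering (%s), k = %d\n", x$method, x$k))
  cat(sprintf("  mean silhouette %.3f, knn agreement %.3f\n",
              x$quality$mean_silhouette, x$quality$knn_agreement))
  print(table(cluster = x$assignment$cluster))
  if (!is.null(x$selection) && x$selection$low_confidence)
    cat("  note: weak cluster structure (low-confidence k)\n")
  invisible(x)
}

#' @export
summary.phenotype_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$selection)) print(object$selection$quality, row.names = FALSE)
  invisible(object)
}

#' @export
plot.phenotype_fit <- function(x, ...) {
  tree <- attr(x$assignment, "tree")
  if (!is.null(tree)) {
    plot(tree, labels = x$assignment$sample_id, main = "Ward clustering", ...)
    stats::rect.hclust(tree, k = x$k)
  } else if (!is.null(x$selection)) {
    plot(x$selection$quality$k, x$selection$quality$mean_silhouette,
         type = "b", xlab = "k", ylab = "mean silhouette width", ...)
  }
  invisible(x)
}

#' Co-clustering frequencies under hold-out resampling
#'
#' Repeatedly drops `holdout` samples at random, re-applies the
#' top-fraction variance filter and scaling on the retained samples, runs
#' PAM with the given k, and records co-membership for every retained pair.
#' Frequencies are co-membership counts divided by co-presence counts.
#'
#' @param x Gene-level matrix *before* variance filtering and scaling (the
#'   filter is re-derived inside each resample).
#' @param n_iter Number of resampling iterations.
#' @param holdout Samples excluded per iteration.
#' @param k PAM cluster count.
#' @param top_frac Variance-filter fraction re-applied per iteration.
#' @param seed Optional seed for the hold-out draws.
#' @return List of class `cocluster`: `freq` (samples x samples frequency
#'   matrix, diagonal 1), `copresence` (pair counts), `n_iter`.
#' @export
cocluster_resample <- function(x, n_iter = 200L, holdout = 5L, k = 5L,
                               top_frac = 0.4, seed = NULL) {
  check_matrix(x, "x")
  check_count(n_iter, "n_iter")
  check_count(holdout, "holdout", min = 0L)
  n <- ncol(x)
  if (holdout >= n - k) stopf("`holdout` must be smaller than n_samples - k")
  with_seed(seed, {
    together <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
    copresent <- matrix(0, n, n, dimnames = dimnames(together))
    for (it in seq_len(n_iter)) {
      keep <- sort(sample.int(n, n - holdout))
      xs <- center_scale(variance_filter(x[, keep, drop = FALSE], top_frac))
      cl <- cluster::pam(sample_dist(xs), k = k, diss = TRUE)$clustering
      same <- outer(cl, cl, "==")
      together[keep, keep] <- together[keep, keep] + same
      copresent[keep, keep] <- copresent[keep, keep] + 1
    }
    freq <- ifelse(copresent > 0, together / pmax(copresent, 1), NA_real_)
    diag(freq)[diag(copresent) > 0] <- 1
    structure(list(freq = freq, copresence = copresent, n_iter = n_iter),
              class = "cocluster")
  })
}
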