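# Differential expression with empirical-Bayes moderated t-statistics,
# phenotype-specific signature derivation, quartile-trimmed-mean gene-set
# scoring, soluble-marker candidate ranking, and marker-based cluster
# labeling.

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of a p-value vector (monotone, capped at 1).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stopf("`p` must be p-values in [0, 1] without missing values")
  stats::p.adjust(p, method = "BH")
}

#' Estimate the empirical-Bayes variance prior
#'
#' Moment-matches the per-gene sample variances to a scaled inverse
#' chi-square prior with `d0` prior degrees of freedom and prior variance
#' `s0_sq`, via the F-distribution fit of the log variances.
#'
#' @param s2 Per-gene pooled sample variances.
#' @param df Residual degrees of freedom of each variance.
#' @return List of class `eb_params`: `d0`, `s0_sq` (`d0` may be `Inf`).
#' @export
estimate_eb_params <- function(s2, df) {
  if (any(s2 < 0)) stopf("variances must be non-negative")
  fit <- limma::fitFDist(s2, df1 = df)
  structure(list(d0 = fit$df2, s0_sq = fit$scale), class = "eb_params")
}

resolve_groups <- function(x, group_a, group_b) {
  sel <- function(g) {
    if (is.logical(g)) { if (length(g) != ncol(x)) stopf("logical group index has wrong length"); which(g) }
    else if (is.character(g)) { i <- match(g, colnames(x)); if (anyNA(i)) stopf("unknown sample id(s) in group"); i }
    else as.integer(g)
  }
  a <- sel(group_a); b <- sel(group_b)
  if (length(a) < 2L || length(b) < 2L) stopf("both groups need >= 2 samples")
  if (length(intersect(a, b))) stopf("groups overlap")
  list(a = a, b = b)
}

#' Moderated two-sample t-test per gene
#'
#' For each gene the pooled two-sample variance `s2` (df = nA + nB - 2) is
#' shrunk toward the empirical-Bayes prior:
#' `s2_tilde = (d0 * s0_sq + df * s2) / (d0 + df)`, and
#' `t = (meanA - meanB) / sqrt(s2_tilde * (1/nA + 1/nB))` is referred to a t
#' distribution on `d0 + df` degrees of freedom. With `d0 = 0` this is the
#' ordinary pooled t-test; with `d0 = Inf` every gene uses the prior
#' variance. Unless supplied, `(d0, s0_sq)` are estimated from the variance
#' distribution across all genes ([estimate_eb_params()]).
#'
#' @param x Unscaled gene-level matrix (real variances are needed).
#' @param group_a,group_b Sample ids, indices, or logical masks; disjoint,
#'   each of size >= 2.
#' @param eb Optional `eb_params` (or list with `d0`, `s0_sq`) overriding
#'   the estimated prior.
#' @return Data frame of class `de_result`, one row per gene in input
#'   order: `gene`, `lfc` (mean A - mean B, log2), `t`, `p`, `q` (BH).
#' @export
moderated_t_test <- function(x, group_a, group_b, eb = NULL) {
  check_matrix(x, "x")
  g <- resolve_groups(x, group_a, group_b)
  na <- length(g$a); nb <- length(g$b)
  df <- na + nb - 2
  ma <- rowMeans(x[, g$a, drop = FALSE])
  mb <- rowMeans(x[, g$b, drop = FALSE])
  ssa <- rowSums((x[, g$a, drop = FALSE] - ma)^2)
  ssb <- rowSums((x[, g$b, drop = FALSE] - mb)^2)
  s2 <- (ssa + ssb) / df
  if (is.null(eb)) eb <- estimate_eb_params(s2, df)
  d0 <- eb$d0; s0_sq <- eb$s0_sq
  if (is.null(d0) || (d0 > 0 && (is.null(s0_sq) || s0_sq <= 0)))
    stopf("invalid empirical-Bayes parameters")
  s2_tilde <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else
    (d0 * s0_sq + df * s2) / (d0 + df)
  se <- sqrt(s2_tilde * (1 / na + 1 / nb))
  tstat <- (ma - mb) / se
  dft <- d0 + df
  p <- 2 * stats::pt(-abs(tstat), df = dft)
  out <- data.frame(gene = rownames(x), lfc = ma - mb, t = tstat,
                    p = p, q = bh_adjust(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "eb") <- list(d0 = d0, s0_sq = s0_sq, df = df)
  class(out) <- c("de_result", "data.frame")
  out
}

split_groups <- function(assignment) {
  cl <- assignment$cluster
  split(assignment$sample_id, cl)
}

#' Derive group-specific gene signatures
#'
#' Runs moderated t-tests between every pair of groups at the given FDR.
#' A group's candidates are the genes significantly upregulated in it
#' versus at least one other group. The discard rule removes shared genes:
#' with `discard_rule = "group"` (default) any gene claimed by more than
#' one group is discarded; with `"pair"` any gene significant in more than
#' one pairwise contrast is discarded (a stricter, literal rule under which
#' a clean single-group marker in a >= 3 group design is itself discarded,
#' because it is significant against every other group). Survivors are
#' ranked by their best pairwise p-value (ties by |t| descending, then
#' symbol) and the top `top_n` retained.
#'
#' The resulting sets are pairwise disjoint under either rule.
#'
#' @param x Unscaled gene-level matrix.
#' @param assignment A [cluster_samples()] result (>= 2 groups, each with
#'   >= 2 samples).
#' @param fdr FDR cutoff on the pairwise q-values.
#' @param top_n Genes retained per group (fewer if fewer survive).
#' @param discard_rule `"group"` or `"pair"` (see Details).
#' @return Named list of gene-symbol vectors, one per group (names are the
#'   cluster ids, or phenotype labels when present in `assignment`).
#' @export
derive_group_specific_sets <- function(x, assignment, fdr = 0.01, top_n = 100L,
                                       discard_rule = c("group", "pair")) {
  check_matrix(x, "x")
  discard_rule <- match.arg(discard_rule)
  check_fraction(fdr, "fdr", lo_open = TRUE)
  check_count(top_n, "top_n")
  groups <- split_groups(assignment)
  if (length(groups) < 2L) stopf("need >= 2 groups")
  if (any(lengths(groups) < 2L)) stopf("every group needs >= 2 samples")
  gids <- names(groups)

  genes <- rownames(x)
  n_sig_pairs <- setNames(integer(length(genes)), genes)
  best <- lapply(gids, function(g)
    data.frame(gene = character(0), p = numeric(0), t = numeric(0)))
  names(best) <- gids

  for (i in seq_along(gids)[-length(gids)]) for (j in seq.int(i + 1L, length(gids))) {
    de <- moderated_t_test(x, groups[[i]], groups[[j]])
    sig <- de$q < fdr
    n_sig_pairs[de$gene[sig]] <- n_sig_pairs[de$gene[sig]] + 1L
    up_i <- sig & de$lfc > 0
    up_j <- sig & de$lfc < 0
    best[[gids[i]]] <- rbind(best[[gids[i]]],
                             data.frame(gene = de$gene[up_i], p = de$p[up_i],
                                        t = abs(de$t[up_i])))
    best[[gids[j]]] <- rbind(best[[gids[j]]],
                             data.frame(gene = de$gene[up_j], p = de$p[up_j],
                                        t = abs(de$t[up_j])))
  }

  candidates <- lapply(best, function(b) {
    if (!nrow(b)) return(b)
    b <- b[order(b$p, -b$t, b$gene), ]
    b[!duplicated(b$gene), ]
  })
  if (discard_rule == "pair") {
    shared <- names(n_sig_pairs)[n_sig_pairs > 1L]
  } else {
    claim <- table(unlist(lapply(candidates, function(b) unique(b$gene))))
    shared <- names(claim)[claim > 1L]
  }
  sets <- lapply(candidates, function(b) {
    b <- b[!b$gene %in% shared, , drop = FALSE]
    if (!nrow(b)) return(character(0))
    b <- b[order(b$p, -b$t, b$gene), ]
    utils::head(b$gene, top_n)
  })
  if (all(lengths(sets) == 0L))
    warnf("no genes passed FDR %g in any pairwise contrast; all sets empty", fdr)
  if (!is.null(assignment$phenotype))
    names(sets) <- vapply(gids, function(g)
      unique(assignment$phenotype[assignment$cluster == as.integer(g)])[1],
      character(1))
  sets
}

#' One-versus-rest differential gene lists per group
#'
#' For each group, a moderated t-test of its samples against all other
#' samples; genes with q below `fdr` are split into up- and down-regulated
#' lists (for export to external enrichment tools).
#'
#' @inheritParams derive_group_specific_sets
#' @return Named list (per group) of lists with `up` and `down` gene
#'   vectors.
#' @export
one_vs_rest_sets <- function(x, assignment, fdr = 0.01) {
  check_matrix(x, "x")
  groups <- split_groups(assignment)
  if (length(groups) < 2L) stopf("need >= 2 groups")
  if (any(lengths(groups) < 2L)) stopf("every group needs >= 2 samples")
  out <- lapply(groups, function(g) {
    rest <- setdiff(colnames(x), g)
    de <- moderated_t_test(x, g, rest)
    sig <- de$q < fdr
    list(up = de$gene[sig & de$lfc > 0], down = de$gene[sig & de$lfc < 0])
  })
  names(out) <- names(groups)
  out
}

#' Quartile-trimmed-mean gene-set score
#'
#' Per sample, the mean of the set-gene expression values lying within the
#' first-to-third-quartile range (quartiles computed per sample over the
#' set genes with the linear-interpolation quantile rule; trimming is
#' boundary-inclusive). Genes absent from the matrix are dropped with a
#' message; sets with fewer than 4 present genes fall back to the plain
#' mean.
#'
#' @param x Gene x sample matrix (gene symbols as rownames).
#' @param geneset Character vector of gene symbols.
#' @param set_name Name used in messages/errors.
#' @return Named numeric vector of per-sample scores.
#' @export
quartile_trimmed_score <- function(x, geneset, set_name = "gene set") {
  check_matrix(x, "x")
  geneset <- unique(toupper(geneset))
  present <- intersect(geneset, toupper(rownames(x)))
  if (!length(present)) stopf("no genes of %s are present in the matrix", set_name)
  if (length(present) < length(geneset))
    message(sprintf("%s: %d/%d genes absent from the matrix, dropped",
                    set_name, length(geneset) - length(present), length(geneset)))
  sub <- x[match(present, toupper(rownames(x))), , drop = FALSE]
  if (length(present) < 4L) {
    message(sprintf("%s: fewer than 4 genes present, using the plain mean", set_name))
    return(colMeans(sub))
  }
  apply(sub, 2L, function(v) {
    q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    mean(v[v >= q[1] & v <= q[2]])
  })
}

#' Score several gene sets across samples
#'
#' @param x Gene x sample matrix.
#' @param genesets Named list of gene-symbol vectors.
#' @return Samples x sets matrix of quartile-trimmed-mean scores.
#' @export
score_genesets <- function(x, genesets) {
  if (is.null(names(genesets))) stopf("`genesets` must be a named list")
  out <- vapply(names(genesets),
                function(nm) quartile_trimmed_score(x, genesets[[nm]], nm),
                numeric(ncol(x)))
  rownames(out) <- colnames(x)
  out
}

#' Test gene-set scores between phenotype groups
#'
#' One-versus-rest two-sample t-test (pooled variance) of each set's scores
#' for each group, BH-adjusted across the whole set x group family. Groups
#' with positive t (set higher inside the group) are flagged.
#'
#' @param scores Samples x sets score matrix ([score_genesets()]).
#' @param assignment A [cluster_samples()] result.
#' @param var_equal Pooled-variance t (default) or Welch.
#' @return Data frame: `set`, `group`, `t`, `p`, `q`, `positive`.
#' @export
score_group_test <- function(scores, assignment, var_equal = TRUE) {
  groups <- split_groups(assignment)
  if (length(groups) < 2L) stopf("need >= 2 groups")
  if (any(lengths(groups) < 2L)) stopf("every group needs >= 2 samples")
  rows <- list()
  for (set in colnames(scores)) for (g in names(groups)) {
    inside <- scores[groups[[g]], set]
    outside <- scores[setdiff(rownames(scores), groups[[g]]), set]
    tt <- stats::t.test(inside, outside, var.equal = var_equal)
    rows[[length(rows) + 1L]] <- data.frame(
      set = set, group = g, t = unname(tt$statistic), p = tt$p.value)
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$positive <- out$t > 0
  out
}

#' Rank soluble-biomarker candidate genes per phenotype
#'
#' Genes passing the across-group F-test (BH-adjusted) are tested pairwise
#' (moderated t) between all group pairs; a gene is a candidate for a
#' phenotype when, against *every* other group, it is significantly
#' upregulated there (BH-adjusted p below `p_cutoff`, positive t). Ranking
#' is by the worst (largest) of those adjusted pairwise p-values. An
#' optional allow-list (e.g. annotated secreted proteins) filters the
#' candidates.
#'
#' @param x Unscaled gene-level matrix.
#' @param assignment A [cluster_samples()] result with >= 3 groups.
#' @param p_cutoff Adjusted-p cutoff for the pairwise tests.
#' @param f_fdr BH FDR cutoff for the across-group F-test screen.
#' @param allow_list Optional gene symbols to which candidates are
#'   restricted.
#' @return Named list (per group) of data frames `gene`, `worst_q`, ranked.
#' @export
rank_soluble_markers <- function(x, assignment, p_cutoff = 0.001,
                                 f_fdr = 0.05, allow_list = NULL) {
  check_matrix(x, "x")
  groups <- split_groups(assignment)
  if (length(groups) < 3L) stopf("need >= 3 groups")
  cl <- factor(assignment$cluster[match(colnames(x), assignment$sample_id)])
  if (anyNA(cl)) stopf("assignment does not cover all samples")

  # vectorized one-way F-test over genes
  n <- ncol(x); kg <- nlevels(cl)
  gm <- rowMeans(x)
  ssb <- numeric(nrow(x)); ssw <- numeric(nrow(x))
  for (g in levels(cl)) {
    xg <- x[, cl == g, drop = FALSE]
    mg <- rowMeans(xg)
    ssb <- ssb + ncol(xg) * (mg - gm)^2
    ssw <- ssw + rowSums((xg - mg)^2)
  }
  fstat <- (ssb / (kg - 1)) / (ssw / (n - kg))
  f_q <- bh_adjust(stats::pf(fstat, kg - 1, n - kg, lower.tail = FALSE))
  screened <- rownames(x)[f_q < f_fdr]
  if (!length(screened)) return(setNames(
    rep(list(data.frame(gene = character(0), worst_q = numeric(0))),
        length(groups)), names(groups)))
  xs <- x[screened, , drop = FALSE]

  gids <- names(groups)
  # q[g][gene, other] = adjusted p of g-vs-other; sign constraint via t > 0
  qmat <- list(); tmat <- list()
  for (g in gids) { qmat[[g]] <- tmat[[g]] <-
    matrix(NA_real_, nrow(xs), length(gids), dimnames = list(screened, gids)) }
  all_p <- list()
  for (i in seq_along(gids)[-length(gids)]) for (j in seq.int(i + 1L, length(gids))) {
    de <- moderated_t_test(xs, groups[[i]], groups[[j]])
    all_p[[paste(i, j)]] <- de$p
  }
  qadj <- bh_adjust(unlist(all_p))
  qs <- split(qadj, rep(names(all_p), each = nrow(xs)))
  for (i in seq_along(gids)[-length(gids)]) for (j in seq.int(i + 1L, length(gids))) {
    de <- moderated_t_test(xs, groups[[i]], groups[[j]])
    qv <- qs[[paste(i, j)]]
    qmat[[gids[i]]][, gids[j]] <- qv; tmat[[gids[i]]][, gids[j]] <- de$t
    qmat[[gids[j]]][, gids[i]] <- qv; tmat[[gids[j]]][, gids[i]] <- -de$t
  }
  out <- lapply(gids, function(g) {
    others <- setdiff(gids, g)
    ok <- rowSums(qmat[[g]][, others, drop = FALSE] < p_cutoff &
                    tmat[[g]][, others, drop = FALSE] > 0) == length(others)
    genes <- screened[ok]
    if (!is.null(allow_list)) genes <- intersect(genes, toupper(allow_list))
    worst <- apply(qmat[[g]][genes, others, drop = FALSE], 1L,
                   function(r) max(r))
    res <- data.frame(gene = genes, worst_q = unname(worst))
    res[order(res$worst_q, res$gene), , drop = FALSE]
  })
  names(out) <- gids
  out
}

#' Label clusters by reference marker-set scores
#'
#' Each cluster is labeled by the reference marker set (lymphoid, myeloid,
#' fibroid) with the maximal mean score among its samples, provided that
#' score exceeds `score_floor` and dominates the runner-up by `margin`;
#' otherwise the cluster is labeled low-inflammatory (the pattern of a
#' cluster with attenuated, undifferentiated elevation of several axes).
#'
#' @param scores Samples x sets score matrix; columns must include the
#'   names in `markers`. Scores are assumed comparable across sets (e.g.
#'   computed on the scaled matrix).
#' @param assignment A [cluster_samples()] result.
#' @param markers Named character vector mapping phenotype label to score
#'   column; defaults to lymphoid/myeloid/fibroid columns of those names.
#' @param score_floor Minimum mean score for a marker to claim a cluster.
#' @param margin Required lead over the second-best marker.
#' @return The assignment with a `phenotype` column added; the
#'   cluster-to-label map is attached as attribute `label_map`.
#' @export
label_clusters <- function(scores, assignment,
                           markers = c(lymphoid = "lymphoid",
                                       myeloid = "myeloid",
                                       fibroid = "fibroid"),
                           score_floor = 0, margin = 0.25) {
  if (!all(markers %in% colnames(scores)))
    stopf("missing reference marker set(s): %s",
          paste(setdiff(markers, colnames(scores)), collapse = ", "))
  groups <- split_groups(assignment)
  label_map <- vapply(names(groups), function(g) {
    m <- colMeans(scores[groups[[g]], markers, drop = FALSE])
    o <- order(-m)
    if (m[o[1]] > score_floor &&
        (length(m) == 1L || m[o[1]] - m[o[2]] >= margin))
      names(markers)[o[1]]
    else "low_inflammatory"
  }, character(1))
  assignment$phenotype <- unname(label_map[as.character(assignment$cluster)])
  attr(assignment, "label_map") <- label_map
  assignment
}
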