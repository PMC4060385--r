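# Moderated t, BH adjustment, signature derivation, set scoring, marker
# ranking, cluster labeling.

test_that("bh_adjust implements the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(1)
  for (n in c(10, 100, 1000)) {
    p <- runif(n)
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

two_group_matrix <- function(n_genes = 60, n = 6, delta = 0, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * 2 * n), n_genes, 2 * n,
              dimnames = list(sprintf("G%03d", 1:n_genes),
                              sprintf("S%02d", 1:(2 * n))))
  m[, 1:n] <- m[, 1:n] + delta
  m
}

test_that("moderated t with d0 = 0 equals the classical pooled t", {
  x <- two_group_matrix(seed = 2)
  ga <- colnames(x)[1:6]; gb <- colnames(x)[7:12]
  de <- moderated_t_test(x, ga, gb, eb = list(d0 = 0, s0_sq = 1))
  for (i in c(1, 17, 42)) {
    tt <- t.test(x[i, ga], x[i, gb], var.equal = TRUE)
    expect_equal(de$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(de$p[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("moderated t with d0 = Inf uses the prior variance exactly", {
  x <- two_group_matrix(seed = 3)
  ga <- colnames(x)[1:6]; gb <- colnames(x)[7:12]
  s0 <- 2.5
  de <- moderated_t_test(x, ga, gb, eb = list(d0 = Inf, s0_sq = s0))
  dm <- rowMeans(x[, ga]) - rowMeans(x[, gb])
  expect_equal(de$t, unname(dm / sqrt(s0 * (2 / 6))), tolerance = 1e-12)
})

test_that("moderated t agrees with the limma empirical-Bayes pipeline", {
  x <- two_group_matrix(n_genes = 200, seed = 4, delta = 0.3)
  # heterogeneous gene variances so the prior df is moderate (limma caps
  # the total df at the pooled residual df, which only binds for huge d0)
  set.seed(44)
  x <- x * sqrt(1 / rgamma(200, shape = 3, rate = 3))
  ga <- colnames(x)[1:6]; gb <- colnames(x)[7:12]
  de <- moderated_t_test(x, ga, gb)
  design <- cbind(1, rep(c(1, 0), each = 6))
  fit <- limma::eBayes(limma::lmFit(x, design))
  expect_equal(de$t, unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(de$p, unname(fit$p.value[, 2]), tolerance = 1e-6)
})

test_that("null matrix gives near-uniform p-values and q >= p", {
  x <- two_group_matrix(n_genes = 300, seed = 5)
  de <- moderated_t_test(x, colnames(x)[1:6], colnames(x)[7:12])
  expect_gt(ks.test(de$p, "punif")$p.value, 0.01)
  expect_true(all(de$q >= de$p - 1e-12))
  expect_error(moderated_t_test(x, colnames(x)[1:6], colnames(x)[5:8]),
               "overlap")
  expect_error(moderated_t_test(x, colnames(x)[1], colnames(x)[7:12]), ">= 2")
})

test_that("a planted block dominates the top of the ranking", {
  set.seed(6)
  x <- two_group_matrix(n_genes = 400, n = 10, seed = 6)
  block <- 1:40
  x[block, 1:10] <- x[block, 1:10] + 2
  de <- moderated_t_test(x, colnames(x)[1:10], colnames(x)[11:20])
  top <- de$gene[order(de$q, de$p)][1:40]
  expect_gte(mean(top %in% rownames(x)[block]), 0.9)
})

test_that("group-specific sets recover planted blocks and stay disjoint", {
  sc <- small_cohort()
  a <- cluster_samples(sc$pp$scaled, 5)
  sets <- derive_group_specific_sets(sc$pp$genes, a)
  # pairwise disjoint
  all_genes <- unlist(sets)
  expect_false(anyDuplicated(all_genes) > 0)
  blocks <- sc$cohort$signature_blocks
  # block-owning clusters: >= 90% of each set inside one planted block
  purities <- vapply(sets, function(g) {
    if (!length(g)) return(NA_real_)
    max(vapply(blocks, function(b) mean(g %in% b), numeric(1)))
  }, numeric(1))
  expect_gte(sum(purities >= 0.9, na.rm = TRUE), 4)
})

test_that("the literal pair-discard rule drops clean one-group markers", {
  # 3 groups; gene 1 elevated in group 1 only => significant in 2 pairs
  set.seed(7)
  x <- matrix(rnorm(50 * 12, sd = 0.2), 50, 12,
              dimnames = list(sprintf("G%02d", 1:50), sprintf("S%02d", 1:12)))
  x[1, 1:4] <- x[1, 1:4] + 5
  a <- data.frame(sample_id = colnames(x), cluster = rep(1:3, each = 4))
  grp <- suppressWarnings(derive_group_specific_sets(x, a, discard_rule = "group"))
  pair <- suppressWarnings(derive_group_specific_sets(x, a, discard_rule = "pair"))
  expect_true("G01" %in% grp[["1"]])
  expect_false("G01" %in% unlist(pair))
})

test_that("shared elevation in two groups is discarded under the group rule", {
  set.seed(8)
  x <- matrix(rnorm(40 * 12, sd = 0.2), 40, 12,
              dimnames = list(sprintf("G%02d", 1:40), sprintf("S%02d", 1:12)))
  x[1, 1:8] <- x[1, 1:8] + 5   # shared by groups 1 and 2
  x[2, 1:4] <- x[2, 1:4] + 5   # specific to group 1
  a <- data.frame(sample_id = colnames(x), cluster = rep(1:3, each = 4))
  sets <- suppressWarnings(derive_group_specific_sets(x, a))
  expect_false("G01" %in% unlist(sets))
  expect_true("G02" %in% sets[["1"]])
})

test_that("empty results warn rather than error, and top_n truncates", {
  x <- two_group_matrix(n_genes = 30, seed = 9)
  a <- data.frame(sample_id = colnames(x), cluster = rep(1:2, each = 6))
  expect_warning(sets <- derive_group_specific_sets(x, a), "all sets empty")
  expect_true(all(lengths(sets) == 0))

  x[1:10, 1:6] <- x[1:10, 1:6] + 6
  sets <- derive_group_specific_sets(x, a, top_n = 3)
  expect_lte(length(sets[["1"]]), 3)
  sets_all <- derive_group_specific_sets(x, a, top_n = 500)
  expect_lte(length(sets_all[["1"]]), 30)
  expect_gte(length(sets_all[["1"]]), 10 - 2)
})

test_that("one-vs-rest lists split by direction and respect the null", {
  sc <- small_cohort()
  a <- cluster_samples(sc$pp$scaled, 5)
  ovr <- one_vs_rest_sets(sc$pp$genes, a)
  # the lymphoid-like block appears in its own cluster's up list
  truth <- sc$cohort$truth
  merged <- merge(truth, a, by = "sample_id")
  lymph_cluster <- as.character(unique(
    merged$cluster.y[merged$phenotype == "lymphoid"]))
  lymph_block <- sc$cohort$signature_blocks$lymphoid
  # a few block genes are lost to the probe quality/Entrez filters
  hits <- mean(lymph_block %in% ovr[[lymph_cluster]]$up)
  expect_gte(hits, 0.75)

  # null: no calls (up to FDR-level false positives)
  x0 <- two_group_matrix(n_genes = 200, seed = 10)
  a0 <- data.frame(sample_id = colnames(x0), cluster = rep(1:2, each = 6))
  ovr0 <- one_vs_rest_sets(x0, a0)
  expect_lte(length(ovr0[["1"]]$up) + length(ovr0[["1"]]$down), 4)
})

test_that("one-vs-rest effect sizes are antisymmetric in a 2-group design", {
  x <- two_group_matrix(n_genes = 50, seed = 11, delta = 1)
  a <- data.frame(sample_id = colnames(x), cluster = rep(1:2, each = 6))
  de1 <- moderated_t_test(x, a$sample_id[a$cluster == 1],
                          a$sample_id[a$cluster == 2])
  de2 <- moderated_t_test(x, a$sample_id[a$cluster == 2],
                          a$sample_id[a$cluster == 1])
  expect_equal(de1$lfc, -de2$lfc)
  expect_equal(de1$t, -de2$t)
})

test_that("quartile-trimmed score follows the declared trimming rule", {
  x <- matrix(c(1, 2, 3, 4, 100), 5, 1,
              dimnames = list(c("A", "B", "C", "D", "E"), "s1"))
  x <- cbind(x, s2 = 7)
  expect_equal(unname(quartile_trimmed_score(x, c("A", "B", "C", "D", "E"))),
               c(3, 7))

  # all genes equal c in a sample: score c
  xx <- matrix(5, 6, 2, dimnames = list(paste0("g", 1:6), c("s1", "s2")))
  expect_equal(unname(quartile_trimmed_score(xx, paste0("g", 1:6))), c(5, 5))

  # invariant to genes absent from the matrix
  s1 <- quartile_trimmed_score(x, c("A", "B", "C", "D", "E"))
  expect_message(
    s2 <- quartile_trimmed_score(x, c("A", "B", "C", "D", "E", "ZZZ")),
    "absent")
  expect_equal(s1, s2)

  # monotone: +delta on every set gene raises the score by delta
  set.seed(12)
  y <- rand_matrix(20, 4, seed = 12)
  base <- quartile_trimmed_score(y, rownames(y)[1:10])
  shifted <- quartile_trimmed_score(y + 0.7, rownames(y)[1:10])
  expect_equal(shifted[1:4], base[1:4] + 0.7, tolerance = 1e-12)

  # < 4 present genes: plain mean, with a message
  expect_message(s3 <- quartile_trimmed_score(y, rownames(y)[1:3]), "plain mean")
  expect_equal(unname(s3), unname(colMeans(y[1:3, ])))

  expect_error(quartile_trimmed_score(y, c("NOPE")), "present")
})

test_that("score_group_test flags the planted set only in its group", {
  sc <- small_cohort()
  a <- cluster_samples(sc$pp$scaled, 5)
  scores <- suppressMessages(
    score_genesets(sc$pp$scaled, sc$cohort$signature_blocks["myeloid"]))
  res <- score_group_test(scores, a)
  sig_pos <- res[res$q < 0.01 & res$positive, ]
  merged <- merge(sc$cohort$truth, a, by = "sample_id")
  myeloid_cluster <- as.character(unique(
    merged$cluster.y[merged$phenotype == "myeloid"]))
  expect_equal(sig_pos$group, myeloid_cluster)
})

test_that("score tests are calibrated under label permutation", {
  set.seed(13)
  x <- center_scale(rand_matrix(40, 30, seed = 13))
  scores <- suppressMessages(score_genesets(x, list(s1 = rownames(x)[1:10])))
  ps <- replicate(40, {
    a <- data.frame(sample_id = colnames(x),
                    cluster = sample(rep(1:3, each = 10)))
    min(score_group_test(scores, a)$p)
  })
  # minimum of 3 correlated tests under the null: not concentrated near 0
  expect_gt(mean(ps < 0.05), 0.0)
  expect_lt(mean(ps < 0.01), 0.25)
})

test_that("identical groups give t = 0", {
  scores <- matrix(rep(c(1, 2, 3), 2), 6, 1,
                   dimnames = list(paste0("s", 1:6), "set"))
  a <- data.frame(sample_id = paste0("s", 1:6), cluster = rep(1:2, each = 3))
  res <- score_group_test(scores, a)
  expect_equal(res$t, c(0, 0), tolerance = 1e-12)
})

test_that("soluble-marker ranking isolates single-phenotype elevation", {
  set.seed(14)
  x <- matrix(rnorm(60 * 15, sd = 0.3), 60, 15,
              dimnames = list(sprintf("G%02d", 1:60), sprintf("S%02d", 1:15)))
  x[1, 1:5] <- x[1, 1:5] + 4            # marker of group 1
  x[2, 1:10] <- x[2, 1:10] + 4          # shared groups 1+2: must be excluded
  a <- data.frame(sample_id = colnames(x), cluster = rep(1:3, each = 5))
  ranked <- rank_soluble_markers(x, a)
  expect_true("G01" %in% ranked[["1"]]$gene)
  expect_false("G01" %in% ranked[["2"]]$gene)
  expect_false("G02" %in% unlist(lapply(ranked, `[[`, "gene")))
  # flat genes are screened out by the F-test
  expect_false("G03" %in% unlist(lapply(ranked, `[[`, "gene")))
  # allow-list filtering
  ranked2 <- rank_soluble_markers(x, a, allow_list = "G05")
  expect_equal(nrow(ranked2[["1"]]), 0)
})

test_that("clusters are labeled by their dominant marker scores", {
  sc <- small_cohort()
  a <- cluster_samples(sc$pp$scaled, 5)
  scores <- suppressMessages(score_genesets(
    sc$pp$scaled, sc$cohort$signature_blocks[c("lymphoid", "myeloid", "fibroid")]))
  lab <- label_clusters(scores, a)
  merged <- merge(sc$cohort$truth, lab, by = "sample_id")
  for (ph in c("lymphoid", "myeloid", "fibroid"))
    expect_true(all(merged$phenotype.y[merged$phenotype.x == ph] == ph))
  # the low-inflammatory group must not claim a marker label
  expect_true(all(merged$phenotype.y[merged$phenotype.x == "low_inflammatory"]
                  == "low_inflammatory"))

  # all-zero scores: everything low-inflammatory
  z <- scores; z[] <- 0
  lab0 <- label_clusters(z, a)
  expect_true(all(lab0$phenotype == "low_inflammatory"))

  expect_error(label_clusters(scores[, 1:2], a), "missing reference")
})
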