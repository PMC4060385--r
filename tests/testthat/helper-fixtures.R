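# Shared fixtures built in code.

# small named matrix with given dims, reproducible
rand_matrix <- function(n_genes, n_samples, seed = 1, sd = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, sd = sd), n_genes, n_samples,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_samples))))
  m
}

# two well-separated sample groups in gene space
separated_groups <- function(n1 = 6, n2 = 6, n_genes = 40, gap = 20, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * (n1 + n2)), n_genes, n1 + n2)
  m[, seq_len(n1)] <- m[, seq_len(n1)] + gap
  dimnames(m) <- list(sprintf("G%03d", seq_len(n_genes)),
                      sprintf("S%02d", seq_len(n1 + n2)))
  list(x = m, truth = rep(1:2, c(n1, n2)))
}

# a small preprocessed synthetic cohort, cached per test file
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      coh <- generate_expression_cohort(expression_sim_config(
        seed = 42, n_signature_genes_per_block = 40, n_background_genes = 300))
      pp <- suppressMessages(preprocess_pipeline(coh$probes, coh$annotation))
      cache <<- list(cohort = coh, pp = pp)
    }
    cache
  }
})

# trial records built from explicit 2x2 counts per subgroup x arm (ACR50)
records_from_counts <- function(counts) {
  # counts: list of subgroup -> c(resp_ada, n_ada, resp_tcz, n_tcz)
  rows <- list()
  for (sg in names(counts)) {
    v <- counts[[sg]]
    mk <- function(arm, resp, n) {
      if (n == 0) return(NULL)
      data.frame(arm = arm, subgroup = sg,
                 acr50 = rep(c(TRUE, FALSE), c(resp, n - resp)),
                 stringsAsFactors = FALSE)
    }
    rows <- c(rows, list(mk("ADA", v[1], v[2]), mk("TCZ", v[3], v[4])))
  }
  df <- do.call(rbind, rows)
  df$patient_id <- sprintf("P%03d", seq_len(nrow(df)))
  df$arm <- factor(df$arm, levels = c("ADA", "TCZ"))
  df$subgroup <- factor(df$subgroup, levels = c("HL", "LH", "HH", "LL"))
  df$acr20 <- df$acr50
  df$acr70 <- df$acr50
  df$das28_change <- -2
  df
}

# independent step-up FDR oracle (direct implementation of the definition)
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# brute-force all-pairs AUC oracle with tie credit 1/2
auc_oracle <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  u <- 0
  for (p in pos) u <- u + sum(p > neg) + 0.5 * sum(p == neg)
  u / (length(pos) * length(neg))
}

# two-sided Fisher p by full enumeration of tables with the observed margins
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  amin <- max(0, c1 - r2); amax <- min(r1, c1)
  logp <- function(x) lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
  lp_obs <- logp(a)
  xs <- amin:amax
  lps <- vapply(xs, logp, numeric(1))
  sum(exp(lps[lps <= lp_obs + 1e-7]))
}
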