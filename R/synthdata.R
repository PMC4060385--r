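# Synthetic cohort generators.
#
# Two generators back the whole test surface: an expression cohort with
# planted phenotype groups carrying block-structured signature genes, and a
# two-arm trial cohort with two correlated log-normal serum biomarkers and
# subgroup-by-arm binary response probabilities.

default_phenotype_names <- c("lymphoid", "myeloid", "low_inflammatory",
                             "fibroid", "undifferentiated")

#' Configuration for the synthetic expression cohort
#'
#' Describes a cohort of samples falling into planted phenotype groups. Each
#' group except the low-inflammatory one owns a block of signature genes
#' shifted upwards by `effect_size` (log2 units) in its home group; the
#' low-inflammatory group carries all block shifts attenuated by
#' `low_inflammatory_attenuation`; background genes carry no group effect.
#' Genes are emitted at probe level with a probe annotation table (quality
#' grade, Entrez id, multiple probes per gene) so the probe-filtering stages
#' have something to do.
#'
#' Defaults emulate a 49-sample synovial cohort with five groups of sizes
#' 8/14/16/8/3 (lymphoid, myeloid, low-inflammatory, fibroid, and a small
#' fifth group). The default effect size of 4 log2 units (16-fold) against
#' unit per-gene noise, with 10% attenuation in the low-inflammatory group,
#' is calibrated so that the planted five-group structure is detectable by
#' mean silhouette width over a 3..8 cluster scan — the qualitative behavior
#' of the cohort being emulated.
#'
#' @param n_per_group Integer vector of samples per planted group.
#' @param phenotypes Character vector naming each group; must contain
#'   `"low_inflammatory"`, the group that carries attenuated shifts of every
#'   block instead of a block of its own.
#' @param n_signature_genes_per_block Signature genes per block.
#' @param n_background_genes Genes with no group effect.
#' @param effect_size Mean log2 shift of a block in its home group (>= 0;
#'   zero gives a null cohort with no group structure).
#' @param noise_sd Per-gene Gaussian noise SD (log2 units).
#' @param low_inflammatory_attenuation Multiplier in \[0, 1\] applied to all
#'   block shifts for the low-inflammatory group.
#' @param n_probes_per_gene_max Maximum probes per gene (probe count drawn
#'   uniformly from 1..max).
#' @param frac_cross_hyb_probes Fraction of probes given a non-A quality
#'   grade (flagged as cross-hybridising).
#' @param frac_no_entrez Fraction of probes left without an Entrez mapping.
#' @param seed Integer seed; identical seeds give byte-identical cohorts.
#' @return An object of class `expression_sim_config` (a validated list).
#' @export
expression_sim_config <- function(n_per_group = c(8L, 14L, 16L, 8L, 3L),
                                  phenotypes = default_phenotype_names,
                                  n_signature_genes_per_block = 100L,
                                  n_background_genes = 1000L,
                                  effect_size = 4,
                                  noise_sd = 1,
                                  low_inflammatory_attenuation = 0.1,
                                  n_probes_per_gene_max = 2L,
                                  frac_cross_hyb_probes = 0.10,
                                  frac_no_entrez = 0.05,
                                  seed = 1L) {
  if (length(n_per_group) < 2L) stopf("need at least two planted groups")
  for (ni in n_per_group) check_count(ni, "n_per_group")
  if (length(phenotypes) != length(n_per_group))
    stopf("`phenotypes` must name each group")
  if (!"low_inflammatory" %in% phenotypes)
    stopf("one group must be named 'low_inflammatory'")
  check_count(n_signature_genes_per_block, "n_signature_genes_per_block")
  check_count(n_background_genes, "n_background_genes")
  if (!is.numeric(effect_size) || effect_size < 0)
    stopf("`effect_size` must be >= 0")
  if (!is.numeric(noise_sd) || noise_sd <= 0) stopf("`noise_sd` must be > 0")
  check_fraction(low_inflammatory_attenuation, "low_inflammatory_attenuation")
  check_count(n_probes_per_gene_max, "n_probes_per_gene_max")
  check_fraction(frac_cross_hyb_probes, "frac_cross_hyb_probes")
  check_fraction(frac_no_entrez, "frac_no_entrez")
  check_count(seed, "seed", min = 0L)
  structure(list(
    n_per_group = as.integer(n_per_group),
    phenotypes = phenotypes,
    n_signature_genes_per_block = as.integer(n_signature_genes_per_block),
    n_background_genes = as.integer(n_background_genes),
    effect_size = effect_size,
    noise_sd = noise_sd,
    low_inflammatory_attenuation = low_inflammatory_attenuation,
    n_probes_per_gene_max = as.integer(n_probes_per_gene_max),
    frac_cross_hyb_probes = frac_cross_hyb_probes,
    frac_no_entrez = frac_no_entrez,
    seed = as.integer(seed)
  ), class = "expression_sim_config")
}

#' Generate a synthetic expression cohort with planted phenotype groups
#'
#' Draws a probe-level log2 expression matrix (probes x samples), its probe
#' annotation table, the true group labels, and the planted signature blocks
#' as gene sets. Per-gene baselines are uniform on 4..12 log2 units; block
#' genes are shifted by `effect_size` in their home group and by
#' `effect_size * low_inflammatory_attenuation` in the low-inflammatory
#' group. Each gene is represented by 1..`n_probes_per_gene_max` probes with
#' a probe-specific offset and noise scale, so probes of one gene differ in
#' variance and the largest-variance collapse rule is exercised.
#'
#' @param config An [expression_sim_config()].
#' @return A list of class `expression_cohort`:
#'   \describe{
#'     \item{probes}{probe-level matrix (probes x samples), log2 scale}
#'     \item{annotation}{data frame: `probe_id`, `gene_symbol`, `entrez_id`
#'       (empty string when unmapped), `quality_grade` ("A" or "B")}
#'     \item{truth}{data frame: `sample_id`, `cluster`, `phenotype`}
#'     \item{signature_blocks}{named list of planted block gene symbols}
#'   }
#' @examples
#' coh <- generate_expression_cohort(expression_sim_config(seed = 7))
#' dim(coh$probes)
#' table(coh$truth$phenotype)
#' @export
generate_expression_cohort <- function(config = expression_sim_config()) {
  if (!inherits(config, "expression_sim_config"))
    stopf("`config` must come from expression_sim_config()")
  with_seed(config$seed, {
    n_groups <- length(config$n_per_group)
    n_samples <- sum(config$n_per_group)
    group_of <- rep.int(seq_len(n_groups), config$n_per_group)
    sample_ids <- sprintf("S%02d", seq_len(n_samples))
    low_inf <- match("low_inflammatory", config$phenotypes)
    block_groups <- setdiff(seq_len(n_groups), low_inf)

    nb <- config$n_signature_genes_per_block
    block_prefix <- toupper(substr(gsub("[^A-Za-z]", "", config$phenotypes), 1, 3))
    gene_symbol <- character(0)
    gene_owner <- integer(0)  # owning group, NA for background
    for (g in block_groups) {
      gene_symbol <- c(gene_symbol, sprintf("%s%04d", block_prefix[g], seq_len(nb)))
      gene_owner <- c(gene_owner, rep.int(g, nb))
    }
    gene_symbol <- c(gene_symbol, sprintf("BKG%04d", seq_len(config$n_background_genes)))
    gene_owner <- c(gene_owner, rep.int(NA_integer_, config$n_background_genes))
    n_genes <- length(gene_symbol)

    # gene-level signal: baseline + planted shift + noise
    shift <- matrix(0, n_genes, n_samples)
    owned <- !is.na(gene_owner)
    for (j in seq_len(n_samples)) {
      g <- group_of[j]
      if (g == low_inf) {
        shift[owned, j] <- config$effect_size * config$low_inflammatory_attenuation
      } else {
        shift[owned & gene_owner == g, j] <- config$effect_size
      }
    }
    baseline <- stats::runif(n_genes, 4, 12)
    signal <- baseline + shift +
      matrix(stats::rnorm(n_genes * n_samples, sd = config$noise_sd),
             n_genes, n_samples)

    # probe layer: per gene 1..max probes, each with its own offset and noise
    n_probes_per_gene <- sample.int(config$n_probes_per_gene_max, n_genes,
                                    replace = TRUE)
    probe_gene <- rep.int(seq_len(n_genes), n_probes_per_gene)
    n_probes <- length(probe_gene)
    probe_id <- sprintf("%s_at%d", gene_symbol[probe_gene],
                        sequence(n_probes_per_gene))
    probe_offset <- stats::rnorm(n_probes, sd = 0.3)
    probe_noise_sd <- stats::runif(n_probes, 0.05, 0.4)
    probes <- signal[probe_gene, , drop = FALSE] + probe_offset +
      matrix(stats::rnorm(n_probes * n_samples), n_probes, n_samples) *
        probe_noise_sd
    dimnames(probes) <- list(probe_id, sample_ids)

    quality <- ifelse(stats::runif(n_probes) < config$frac_cross_hyb_probes,
                      "B", "A")
    entrez <- ifelse(stats::runif(n_probes) < config$frac_no_entrez, "",
                     as.character(10000L + probe_gene))
    annotation <- data.frame(
      probe_id = probe_id,
      gene_symbol = gene_symbol[probe_gene],
      entrez_id = entrez,
      quality_grade = quality,
      stringsAsFactors = FALSE
    )
    truth <- data.frame(
      sample_id = sample_ids,
      cluster = group_of,
      phenotype = config$phenotypes[group_of],
      stringsAsFactors = FALSE
    )
    blocks <- lapply(block_groups, function(g) gene_symbol[owned & gene_owner == g])
    names(blocks) <- config$phenotypes[block_groups]

    structure(list(probes = probes, annotation = annotation, truth = truth,
                   signature_blocks = blocks, config = config),
              class = "expression_cohort")
  })
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat(sprintf("Synthetic expression cohort: %d probes x %d samples\n",
              nrow(x$probes), ncol(x$probes)))
  cat("Planted groups:",
      paste(sprintf("%s (n=%d)", x$config$phenotypes, x$config$n_per_group),
            collapse = ", "), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# trial cohort

default_response_prob <- function() {
  # week-24 ACR response probabilities by biomarker subgroup and arm;
  # subgroup code: sICAM1 level then CXCL13 level (H/L)
  df <- expand.grid(subgroup = c("HL", "LH", "HH", "LL"),
                    arm = c("ADA", "TCZ"),
                    stringsAsFactors = FALSE)
  rates <- rbind(
    HL.ADA = c(73, 42, 23), LH.ADA = c(27, 13, 7),
    HH.ADA = c(50, 28, 19), LL.ADA = c(52, 24, 18),
    HL.TCZ = c(60, 20, 7),  LH.TCZ = c(81, 69, 50),
    HH.TCZ = c(58, 42, 31), LL.TCZ = c(60, 44, 24)
  ) / 100
  idx <- paste(df$subgroup, df$arm, sep = ".")
  df$acr20 <- rates[idx, 1]
  df$acr50 <- rates[idx, 2]
  df$acr70 <- rates[idx, 3]
  df
}

default_das28 <- function() {
  # mean change in DAS28-ESR at week 24 per subgroup x arm; SDs recovered
  # from reported standard errors as SE * sqrt(n)
  df <- expand.grid(subgroup = c("HL", "LH", "HH", "LL"),
                    arm = c("ADA", "TCZ"),
                    stringsAsFactors = FALSE)
  par <- rbind(
    HL.ADA = c(-2.3, 0.37, 26), LH.ADA = c(-1.1, 0.33, 15),
    HH.ADA = c(-2.1, 0.31, 32), LL.ADA = c(-2.1, 0.32, 33),
    HL.TCZ = c(-3.2, 0.37, 15), LH.TCZ = c(-3.6, 0.32, 26),
    HH.TCZ = c(-3.2, 0.37, 26), LL.TCZ = c(-2.9, 0.36, 25)
  )
  idx <- paste(df$subgroup, df$arm, sep = ".")
  df$mean <- par[idx, 1]
  df$sd <- par[idx, 2] * sqrt(par[idx, 3])
  df
}

#' Configuration for the synthetic two-arm trial cohort
#'
#' Describes a head-to-head two-arm trial (anti-TNF "ADA" vs anti-IL-6R
#' "TCZ") with two baseline serum biomarkers (sICAM1 and CXCL13, pg/ml) on
#' log-normal margins coupled by a Gaussian copula at a target Spearman rank
#' correlation, left-censoring of CXCL13 at a lower limit of quantification
#' (LLOQ), and binary ACR20/50/70 response probabilities per
#' biomarker-defined subgroup and arm.
#'
#' Defaults emulate a 198-patient biomarker population: arm split 106:92,
#' Spearman rho 0.3 between biomarkers, an LLOQ placed so that about 10% of
#' CXCL13 draws are censored, and subgroup response probabilities and DAS28
#' changes taken from the published subgroup efficacy table.
#'
#' @param n_total Total patients.
#' @param arm_ratio Probability a patient is assigned to arm "ADA".
#' @param biomarker_log_means,biomarker_log_sds Length-2 vectors of log-scale
#'   mean and SD for (sICAM1, CXCL13).
#' @param biomarker_rank_correlation Target Spearman correlation.
#' @param lloq Detection floor (pg/ml) for CXCL13; draws below are censored
#'   and carry the LLOQ as their numeric placeholder.
#' @param response_prob Data frame with columns `subgroup` (HL/LH/HH/LL:
#'   sICAM1 level then CXCL13 level), `arm`, `acr20`, `acr50`, `acr70`
#'   (probabilities).
#' @param das28 Data frame with columns `subgroup`, `arm`, `mean`, `sd` for
#'   the Gaussian change in DAS28-ESR.
#' @param seed Integer seed.
#' @return An object of class `trial_sim_config`.
#' @export
trial_sim_config <- function(n_total = 198L,
                             arm_ratio = 106 / 198,
                             biomarker_log_means = c(sicam1 = 12.2, cxcl13 = 4.6),
                             biomarker_log_sds = c(sicam1 = 0.4, cxcl13 = 0.8),
                             biomarker_rank_correlation = 0.3,
                             lloq = 35,
                             response_prob = default_response_prob(),
                             das28 = default_das28(),
                             seed = 1L) {
  check_count(n_total, "n_total")
  check_fraction(arm_ratio, "arm_ratio", lo_open = TRUE)
  if (length(biomarker_log_means) != 2L || length(biomarker_log_sds) != 2L)
    stopf("biomarker log means/sds must have length 2")
  if (any(biomarker_log_sds <= 0)) stopf("biomarker log sds must be > 0")
  check_fraction(biomarker_rank_correlation, "biomarker_rank_correlation",
                 lo = -1, hi = 1)
  if (!is.numeric(lloq) || lloq < 0) stopf("`lloq` must be >= 0")
  need <- expand.grid(subgroup = c("HL", "LH", "HH", "LL"),
                      arm = c("ADA", "TCZ"), stringsAsFactors = FALSE)
  key <- paste(response_prob$subgroup, response_prob$arm)
  if (!all(paste(need$subgroup, need$arm) %in% key))
    stopf("`response_prob` is missing a subgroup x arm combination")
  for (ep in c("acr20", "acr50", "acr70")) {
    if (is.null(response_prob[[ep]]))
      stopf("`response_prob` is missing column '%s'", ep)
    p <- response_prob[[ep]]
    if (any(p < 0 | p > 1)) stopf("response probabilities must lie in [0, 1]")
  }
  if (!all(paste(need$subgroup, need$arm) %in% paste(das28$subgroup, das28$arm)))
    stopf("`das28` is missing a subgroup x arm combination")
  check_count(seed, "seed", min = 0L)
  structure(list(
    n_total = as.integer(n_total), arm_ratio = arm_ratio,
    biomarker_log_means = biomarker_log_means,
    biomarker_log_sds = biomarker_log_sds,
    biomarker_rank_correlation = biomarker_rank_correlation,
    lloq = lloq, response_prob = response_prob, das28 = das28,
    seed = as.integer(seed)
  ), class = "trial_sim_config")
}

#' Generate a synthetic two-arm trial cohort
#'
#' Biomarkers are drawn from a Gaussian copula with Pearson correlation
#' `2 * sin(pi * rho_s / 6)` (so the realized Spearman correlation targets
#' `biomarker_rank_correlation`) on log-normal margins. CXCL13 draws below
#' the LLOQ are flagged censored and set to the LLOQ. Subgroups (HL/LH/HH/LL)
#' are defined by the *realized* within-cohort medians of the two biomarkers
#' (censored values ranking at the LLOQ), mirroring the analysis-side
#' definition. ACR endpoints are drawn from a single uniform per patient so
#' that ACR70 implies ACR50 implies ACR20 while each endpoint keeps its
#' marginal subgroup-by-arm probability. A coarse EULAR class is attached
#' from the simulated DAS28 change (good <= -2.4, poor >= -0.6, else
#' moderate) as a synthetic convenience label for response-mapping tests.
#'
#' @param config A [trial_sim_config()].
#' @return A data frame of class `trial_cohort`, one row per patient:
#'   `patient_id`, `arm`, `sicam1`, `sicam1_censored`, `cxcl13`,
#'   `cxcl13_censored`, `acr20`, `acr50`, `acr70`, `das28_change`,
#'   `eular_class`, plus the generating `subgroup` (attribute `lloq` records
#'   the floor).
#' @examples
#' trial <- generate_trial_cohort(trial_sim_config(seed = 11))
#' table(trial$arm)
#' mean(trial$cxcl13_censored)
#' @export
generate_trial_cohort <- function(config = trial_sim_config()) {
  if (!inherits(config, "trial_sim_config"))
    stopf("`config` must come from trial_sim_config()")
  with_seed(config$seed, {
    n <- config$n_total
    rho <- 2 * sin(pi * config$biomarker_rank_correlation / 6)
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    sicam1 <- exp(config$biomarker_log_means[[1]] +
                    config$biomarker_log_sds[[1]] * z1)
    cxcl13_raw <- exp(config$biomarker_log_means[[2]] +
                        config$biomarker_log_sds[[2]] * z2)
    cxcl13_censored <- cxcl13_raw < config$lloq
    cxcl13 <- ifelse(cxcl13_censored, config$lloq, cxcl13_raw)

    arm <- factor(ifelse(stats::runif(n) < config$arm_ratio, "ADA", "TCZ"),
                  levels = c("ADA", "TCZ"))

    # subgroup from realized medians (high = at or above the median)
    hi1 <- sicam1 >= stats::median(sicam1)
    hi2 <- cxcl13 >= stats::median(cxcl13)
    subgroup <- paste0(ifelse(hi1, "H", "L"), ifelse(hi2, "H", "L"))
    subgroup <- factor(subgroup, levels = c("HL", "LH", "HH", "LL"))

    rp <- config$response_prob
    rkey <- paste(rp$subgroup, rp$arm)
    idx <- match(paste(subgroup, arm), rkey)
    u <- stats::runif(n)
    acr20 <- u < rp$acr20[idx]
    acr50 <- u < rp$acr50[idx]
    acr70 <- u < rp$acr70[idx]

    dd <- config$das28
    didx <- match(paste(subgroup, arm), paste(dd$subgroup, dd$arm))
    das28_change <- stats::rnorm(n, dd$mean[didx], dd$sd[didx])
    eular_class <- cut(das28_change, c(-Inf, -2.4, -0.6, Inf),
                       labels = c("good", "moderate", "poor"))

    out <- data.frame(
      patient_id = sprintf("P%03d", seq_len(n)),
      arm = arm,
      sicam1 = sicam1, sicam1_censored = FALSE,
      cxcl13 = cxcl13, cxcl13_censored = cxcl13_censored,
      acr20 = acr20, acr50 = acr50, acr70 = acr70,
      das28_change = das28_change,
      eular_class = eular_class,
      subgroup = subgroup,
      stringsAsFactors = FALSE
    )
    attr(out, "lloq") <- config$lloq
    class(out) <- c("trial_cohort", "data.frame")
    out
  })
}
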