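# Serum-biomarker subgroup analysis of a two-arm trial: median splits with
# left-censored values, subgroup efficacy tables with ACR50 odds ratios,
# Fisher exact tests, sliding-window STEPP in one and two biomarker
# dimensions, and per-arm biomarker ROC.

#' Median split of a biomarker with left-censored values
#'
#' The cutoff is the cohort median (linear-interpolation quantile rule);
#' censored observations rank at the LLOQ placeholder they carry. A value
#' is "high" when it is at or above the cutoff.
#'
#' @param values Numeric biomarker values; censored entries must already
#'   hold the LLOQ as their numeric placeholder.
#' @param censored Optional logical flag per value (all-censored input is
#'   an error).
#' @return List: `label` (factor low/high), `cutoff`.
#' @export
median_split <- function(values, censored = NULL) {
  if (length(values) < 2L) stopf("need >= 2 values")
  if (anyNA(values)) stopf("missing biomarker values")
  if (!is.null(censored) && all(censored))
    stopf("all values are censored; no informative median")
  cutoff <- stats::median(values)
  label <- factor(ifelse(values >= cutoff, "high", "low"),
                  levels = c("low", "high"))
  list(label = label, cutoff = cutoff)
}

#' Assign biomarker-combination subgroups
#'
#' Crosses the median splits of sICAM1 and CXCL13 into the four subgroups
#' HL / LH / HH / LL (sICAM1 level first, then CXCL13 level).
#'
#' @param records Trial cohort data frame with columns `sicam1`, `cxcl13`
#'   (censored values at their LLOQ placeholder) and optional
#'   `sicam1_censored`, `cxcl13_censored` flags.
#' @return `records` with added columns `sicam1_level`, `cxcl13_level`,
#'   `subgroup` (factor HL/LH/HH/LL); cutoffs attached as attribute
#'   `cutoffs`.
#' @export
assign_subgroups <- function(records) {
  for (col in c("sicam1", "cxcl13"))
    if (is.null(records[[col]])) stopf("records lack column '%s'", col)
  s1 <- median_split(records$sicam1, records$sicam1_censored)
  s2 <- median_split(records$cxcl13, records$cxcl13_censored)
  records$sicam1_level <- s1$label
  records$cxcl13_level <- s2$label
  records$subgroup <- factor(
    paste0(ifelse(s1$label == "high", "H", "L"),
           ifelse(s2$label == "high", "H", "L")),
    levels = c("HL", "LH", "HH", "LL"))
  attr(records, "cutoffs") <- c(sicam1 = s1$cutoff, cxcl13 = s2$cutoff)
  records
}

# profile log-likelihood of the log odds ratio for a 2x2 table
# (a responders / b non-responders in arm 1; c / d in arm 2)
profile_or_ci <- function(a, b, c, d, conf = 0.95) {
  loglik <- function(psi, phi) {
    e1 <- psi + phi
    a * e1 - (a + b) * log1p(exp(e1)) + c * phi - (c + d) * log1p(exp(phi))
  }
  lp <- function(psi)
    stats::optimize(function(phi) loglik(psi, phi), c(-30, 30),
                    maximum = TRUE)$objective
  psi_hat <- log((a / b) / (c / d))
  lmax <- lp(psi_hat)
  crit <- stats::qchisq(conf, 1) / 2
  g <- function(psi) lmax - lp(psi) - crit
  find <- function(lo, hi) {
    tryCatch(stats::uniroot(g, c(lo, hi), tol = 1e-8)$root,
             error = function(e) NA_real_)
  }
  step <- 0.5
  lo <- psi_hat - step
  while (g(lo) < 0 && lo > psi_hat - 50) lo <- lo - step
  hi <- psi_hat + step
  while (g(hi) < 0 && hi < psi_hat + 50) hi <- hi + step
  c(exp(find(lo, psi_hat)), exp(find(psi_hat, hi)))
}

#' Odds ratio of a 2x2 table with confidence interval
#'
#' Cross-product odds ratio `(a d) / (b c)`; if any cell is zero the
#' Haldane-Anscombe correction (`correction`, default 0.5) is added to all
#' four cells first. The CI is either the Wald interval from the log-OR
#' standard error `sqrt(1/a + 1/b + 1/c + 1/d)` or the profile-likelihood
#' interval of the single-covariate logistic (two-binomial) likelihood
#' (default; it reproduces the asymmetric bounds a logistic regression
#' reports for small cells).
#'
#' @param a,b Responders / non-responders in the first arm.
#' @param c,d Responders / non-responders in the second arm.
#' @param method `"profile"` (default) or `"wald"`.
#' @param conf Confidence level.
#' @param correction Haldane-Anscombe constant added to all cells iff any
#'   cell is zero (this covers all-responder / no-responder margins; an
#'   empty arm is an error).
#' @return List: `or`, `ci_low`, `ci_high`, `method`, `corrected`.
#' @examples
#' odds_ratio_ci(11, 15, 3, 12)  # OR 2.93, CI approximately (0.72, 15.2)
#' @export
odds_ratio_ci <- function(a, b, c, d, method = c("profile", "wald"),
                          conf = 0.95, correction = 0.5) {
  method <- match.arg(method)
  cells <- c(a, b, c, d)
  if (any(cells < 0) || anyNA(cells)) stopf("cell counts must be non-negative")
  if (a + b == 0 || c + d == 0)
    stopf("an arm of the 2x2 table is empty; odds ratio undefined")
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + correction
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  or <- (a * d) / (b * c)
  if (method == "wald") {
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    z <- stats::qnorm(1 - (1 - conf) / 2)
    ci <- exp(log(or) + c(-1, 1) * z * se)
  } else {
    ci <- profile_or_ci(a, b, c, d, conf)
  }
  list(or = or, ci_low = ci[1], ci_high = ci[2], method = method,
       corrected = corrected)
}

#' Two-sided Fisher exact test of a 2x2 table
#'
#' Two-sided p-value by summation of all hypergeometric table probabilities
#' not exceeding that of the observed table (at the observed margins).
#'
#' @param a,b,c,d Cell counts (first row a, b; second row c, d).
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stopf("cell counts must be non-negative integers")
  stats::fisher.test(matrix(cells, nrow = 2, byrow = TRUE))$p.value
}

or_cells <- function(records, endpoint, arm1, arm2) {
  y <- records[[endpoint]]
  c(a = sum(records$arm == arm1 & y), b = sum(records$arm == arm1 & !y),
    c = sum(records$arm == arm2 & y), d = sum(records$arm == arm2 & !y))
}

#' Subgroup efficacy table
#'
#' Per biomarker subgroup and arm: patient count, ACR20/50/70 response
#' rates (%), mean change in DAS28 with its standard error, and the ACR50
#' odds ratio in both directions (ADA vs TCZ and its reciprocal view) with
#' confidence interval.
#'
#' @param records Trial cohort with `subgroup` (see [assign_subgroups()]),
#'   `arm`, ACR endpoint columns, and `das28_change`.
#' @param ci_method CI method for [odds_ratio_ci()].
#' @return Data frame of class `subgroup_analysis`, one row per
#'   subgroup x arm; OR columns (`or_ada_vs_tcz`, `or_tcz_vs_ada` with CIs)
#'   repeat within subgroup. Cells with an empty arm yield `NA` rates and a
#'   `degenerate` flag.
#' @export
subgroup_efficacy <- function(records, ci_method = "profile") {
  if (is.null(records$subgroup)) records <- assign_subgroups(records)
  need <- c("arm", "acr20", "acr50", "acr70", "das28_change")
  for (col in need) if (is.null(records[[col]])) stopf("records lack column '%s'", col)
  rows <- list()
  for (sg in levels(records$subgroup)) {
    sub <- records[records$subgroup == sg, , drop = FALSE]
    cells <- or_cells(sub, "acr50", "ADA", "TCZ")
    both_arms <- (cells["a"] + cells["b"]) > 0 && (cells["c"] + cells["d"]) > 0
    if (both_arms) {
      or_at <- odds_ratio_ci(cells["a"], cells["b"], cells["c"], cells["d"],
                             method = ci_method)
      or_ta <- odds_ratio_ci(cells["c"], cells["d"], cells["a"], cells["b"],
                             method = ci_method)
    } else or_at <- or_ta <- list(or = NA_real_, ci_low = NA_real_,
                                  ci_high = NA_real_, corrected = NA)
    for (arm in levels(records$arm)) {
      aa <- sub[sub$arm == arm, , drop = FALSE]
      n <- nrow(aa)
      rate <- function(ep) if (n) 100 * mean(aa[[ep]]) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        subgroup = sg, arm = arm, n = n,
        acr20 = rate("acr20"), acr50 = rate("acr50"), acr70 = rate("acr70"),
        das28_mean = if (n) mean(aa$das28_change) else NA_real_,
        das28_se = if (n > 1) stats::sd(aa$das28_change) / sqrt(n) else NA_real_,
        or_ada_vs_tcz = or_at$or, or_at_low = or_at$ci_low, or_at_high = or_at$ci_high,
        or_tcz_vs_ada = or_ta$or, or_ta_low = or_ta$ci_low, or_ta_high = or_ta$ci_high,
        degenerate = !both_arms || n == 0,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("subgroup_analysis", "data.frame")
  out
}

#' @export
print.subgroup_analysis <- function(x, digits = 2, ...) {
  cat("Biomarker-defined subgroup efficacy\n")
  df <- as.data.frame(x)
  df$acr20 <- round(df$acr20); df$acr50 <- round(df$acr50)
  df$acr70 <- round(df$acr70)
  df$das28 <- sprintf("%.1f (+/-%.2f)", df$das28_mean, df$das28_se)
  df$or_ada_vs_tcz <- sprintf("%.2f (%.2f-%.1f)", df$or_ada_vs_tcz,
                              df$or_at_low, df$or_at_high)
  print(df[, c("subgroup", "arm", "n", "acr20", "acr50", "acr70",
               "das28", "or_ada_vs_tcz")], row.names = FALSE)
  invisible(x)
}

biomarker_percentiles <- function(values) 100 * rank(values) / length(values)

window_or <- function(records, endpoint, ci, arm1 = "ADA", arm2 = "TCZ") {
  cells <- or_cells(records, endpoint, arm1, arm2)
  n1 <- cells["a"] + cells["b"]; n2 <- cells["c"] + cells["d"]
  if (n1 == 0 || n2 == 0)
    return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                n_arm1 = unname(n1), n_arm2 = unname(n2), empty_arm = TRUE))
  est <- if (ci == "none") {
    cl <- if (any(cells == 0)) cells + 0.5 else cells
    list(or = (cl["a"] * cl["d"]) / (cl["b"] * cl["c"]),
         ci_low = NA_real_, ci_high = NA_real_)
  } else odds_ratio_ci(cells["a"], cells["b"], cells["c"], cells["d"],
                       method = ci)
  list(or = unname(est$or), ci_low = est$ci_low, ci_high = est$ci_high,
       n_arm1 = unname(n1), n_arm2 = unname(n2), empty_arm = FALSE)
}

#' One-dimensional STEPP analysis
#'
#' Subpopulation treatment effect pattern plot: for each window center p
#' (a percentile), the subpopulation of patients whose biomarker percentile
#' lies within `halfwidth_pct` below and above p is formed (percentiles by
#' empirical CDF with midrank ties, bounds inclusive) and the endpoint odds
#' ratio of arm ADA versus arm TCZ is estimated within it.
#'
#' @param records Trial cohort data frame.
#' @param biomarker Column name of the biomarker (censored values at their
#'   LLOQ placeholder).
#' @param halfwidth_pct Window half-width in percentile points.
#' @param centers Window-center percentiles; must lie within
#'   `[halfwidth_pct, 100 - halfwidth_pct]`.
#' @param endpoint Binary endpoint column (default `"acr50"`).
#' @param ci `"wald"`, `"profile"`, or `"none"` (point estimates only).
#' @return Data frame of class `stepp`: center percentile, center
#'   concentration (median biomarker value inside the window), per-arm n,
#'   OR and CI; windows with an empty arm carry `NA` and `empty_arm = TRUE`.
#' @export
stepp_1d <- function(records, biomarker, halfwidth_pct = 20,
                     centers = seq(20, 80, by = 5), endpoint = "acr50",
                     ci = c("wald", "profile", "none")) {
  ci <- match.arg(ci)
  if (is.null(records[[biomarker]])) stopf("records lack column '%s'", biomarker)
  if (any(centers < halfwidth_pct | centers > 100 - halfwidth_pct))
    stopf("centers must lie within [halfwidth, 100 - halfwidth]")
  if (is.unsorted(centers)) stopf("centers must be increasing")
  pct <- biomarker_percentiles(records[[biomarker]])
  rows <- lapply(centers, function(p) {
    inside <- pct >= p - halfwidth_pct & pct <= p + halfwidth_pct
    w <- window_or(records[inside, , drop = FALSE], endpoint, ci)
    data.frame(center_pct = p,
               center_value = stats::median(records[[biomarker]][inside]),
               n_ada = w$n_arm1, n_tcz = w$n_arm2,
               or = w$or, ci_low = w$ci_low, ci_high = w$ci_high,
               empty_arm = w$empty_arm)
  })
  out <- do.call(rbind, rows)
  attr(out, "biomarker") <- biomarker
  attr(out, "direction") <- "ADA_vs_TCZ"
  class(out) <- c("stepp", "data.frame")
  out
}

#' @export
plot.stepp <- function(x, log = "y", ...) {
  ok <- !x$empty_arm & is.finite(x$or)
  plot(x$center_pct[ok], x$or[ok], type = "b", log = log,
       xlab = sprintf("%s percentile window center", attr(x, "biomarker")),
       ylab = "ACR50 odds ratio (ADA vs TCZ)", ...)
  if (any(is.finite(x$ci_low[ok])))
    graphics::segments(x$center_pct[ok], x$ci_low[ok],
                       x$center_pct[ok], x$ci_high[ok])
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' Two-dimensional STEPP analysis
#'
#' Sliding-window treatment-effect estimates over both biomarkers jointly:
#' each grid cell is the intersection of a sICAM1 percentile window and a
#' CXCL13 percentile window (half-width `halfwidth_pct` per axis), and the
#' endpoint odds ratio of ADA versus TCZ is estimated within the cell.
#'
#' @param records Trial cohort data frame with `sicam1` and `cxcl13`.
#' @param halfwidth_pct Half-width per axis, percentile points.
#' @param centers_sicam1,centers_cxcl13 Window-center percentiles per axis.
#' @param endpoint Binary endpoint column.
#' @param ci CI method as in [stepp_1d()].
#' @return Data frame of class `stepp2d`, one row per grid cell:
#'   `sicam1_pct`, `cxcl13_pct`, per-arm n, `or`, CI, `empty_arm`.
#' @export
stepp_2d <- function(records, halfwidth_pct = 25,
                     centers_sicam1 = c(25, 50, 75),
                     centers_cxcl13 = c(25, 50, 75),
                     endpoint = "acr50", ci = c("wald", "profile", "none")) {
  ci <- match.arg(ci)
  for (col in c("sicam1", "cxcl13"))
    if (is.null(records[[col]])) stopf("records lack column '%s'", col)
  for (cc in list(centers_sicam1, centers_cxcl13))
    if (any(cc < halfwidth_pct | cc > 100 - halfwidth_pct))
      stopf("centers must lie within [halfwidth, 100 - halfwidth]")
  p1 <- biomarker_percentiles(records$sicam1)
  p2 <- biomarker_percentiles(records$cxcl13)
  grid <- expand.grid(sicam1_pct = centers_sicam1, cxcl13_pct = centers_cxcl13)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    inside <- p1 >= grid$sicam1_pct[i] - halfwidth_pct &
      p1 <= grid$sicam1_pct[i] + halfwidth_pct &
      p2 >= grid$cxcl13_pct[i] - halfwidth_pct &
      p2 <= grid$cxcl13_pct[i] + halfwidth_pct
    w <- window_or(records[inside, , drop = FALSE], endpoint, ci)
    data.frame(sicam1_pct = grid$sicam1_pct[i], cxcl13_pct = grid$cxcl13_pct[i],
               n_ada = w$n_arm1, n_tcz = w$n_arm2,
               or = w$or, ci_low = w$ci_low, ci_high = w$ci_high,
               empty_arm = w$empty_arm)
  })
  out <- do.call(rbind, rows)
  attr(out, "direction") <- "ADA_vs_TCZ"
  class(out) <- c("stepp2d", "data.frame")
  out
}

#' @export
plot.stepp2d <- function(x, ...) {
  xs <- sort(unique(x$sicam1_pct)); ys <- sort(unique(x$cxcl13_pct))
  z <- matrix(NA_real_, length(xs), length(ys))
  for (i in seq_len(nrow(x)))
    z[match(x$sicam1_pct[i], xs), match(x$cxcl13_pct[i], ys)] <- log2(x$or[i])
  graphics::image(xs, ys, z, xlab = "sICAM1 percentile",
                  ylab = "CXCL13 percentile",
                  main = "log2 ACR50 OR (ADA vs TCZ)", ...)
  invisible(x)
}

#' Per-arm biomarker ROC against an ACR endpoint
#'
#' ROC/AUC of a continuous baseline biomarker against achievement of a
#' binary endpoint within one treatment arm. Censored values enter at
#' their LLOQ placeholder; ties are handled by midranks.
#'
#' @param records Trial cohort data frame.
#' @param biomarker Biomarker column name.
#' @param arm Arm to analyse ("ADA" or "TCZ").
#' @param endpoint Binary endpoint column (default `"acr50"`).
#' @return A [roc_auc()] `roc_curve` object.
#' @export
biomarker_roc <- function(records, biomarker, arm, endpoint = "acr50") {
  sub <- records[records$arm == arm, , drop = FALSE]
  if (!nrow(sub)) stopf("arm '%s' is empty", arm)
  roc_auc(sub[[biomarker]], sub[[endpoint]])
}
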