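# Diversity statistics for the phenotyped panel: factorial ANOVA on SD,
# one-way ANOVA on leaf area, SD-LA correlation, Tukey(-Kramer) multiple
# comparison across origin groups, and the origin-stacked histogram.

signif_stars <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "n.s."))
}

#' Two-way ANOVA for accession x position effects on SD
#'
#' Factorial analysis of variance with interaction on replicate-level
#' density records. With unbalanced replication (the protocol has 3--4
#' leaflets per accession) Type II sums of squares are used by default;
#' on balanced data Type II coincides with the sequential decomposition.
#' Significance is flagged at p < 0.01 (`**`), p < 0.05 (`*`), else
#' `n.s.`, as in the panel summary tables.
#'
#' @param df data frame of replicate-level records.
#' @param response,factor_a,factor_b column names (defaults `sd`,
#'   `accession`, `position`).
#' @param type sums-of-squares type, 2 (default) or 1.
#' @return an `anova_result` data frame: one row per term (`factor_a`,
#'   `factor_b`, interaction, residuals) with `ss`, `df`, `F`, `p`,
#'   `signif`.
#' @export
two_way_anova <- function(df, response = "sd", factor_a = "accession",
                          factor_b = "position", type = 2) {
  a <- factor(df[[factor_a]])
  b <- factor(df[[factor_b]])
  y <- df[[response]]
  if (nlevels(a) < 2L || nlevels(b) < 2L) {
    stopf("both factors need at least two levels")
  }
  if (any(table(a, b) == 0L)) {
    stopf("empty accession x position cell; interaction not estimable")
  }
  dat <- data.frame(y = y, a = a, b = b)
  fit <- lm(y ~ a * b, data = dat)
  df_res <- fit$df.residual
  ss_res <- sum(fit$residuals^2)
  if (ss_res < 1e-10 * max(sum((y - mean(y))^2), 1)) {
    # a saturated/constant response carries no residual variance: report
    # the decomposition without F tests rather than failing
    tab1 <- as.data.frame(stats::anova(fit))
    tab <- data.frame(ss = tab1[["Sum Sq"]], df = tab1[["Df"]],
                      F = NA_real_, p = NA_real_)
  } else {
    tab <- if (type == 2) {
      as.data.frame(car::Anova(fit, type = 2))
    } else {
      as.data.frame(stats::anova(fit))[, c(2, 1, 4, 5)]
    }
    names(tab) <- c("ss", "df", "F", "p")
  }
  out <- data.frame(term = c(factor_a, factor_b,
                             paste0(factor_a, ":", factor_b), "residuals"),
                    ss = tab$ss, df = tab$df, F = tab$F, p = tab$p)
  out$signif <- ifelse(is.na(out$p), "", signif_stars(out$p))
  class(out) <- c("anova_result", "data.frame")
  out
}

#' One-way ANOVA
#'
#' Standard one-way decomposition, used for leaf-area variation among
#' accessions.
#'
#' @param values numeric response.
#' @param group grouping factor (>= 2 levels).
#' @return an `anova_result` data frame (group term + residuals).
#' @export
one_way_anova <- function(values, group) {
  g <- factor(group)
  if (nlevels(g) < 2L) stopf("one-way ANOVA needs at least two groups")
  fit <- aov(values ~ g)
  tab <- summary(fit)[[1]]
  out <- data.frame(term = c("group", "residuals"),
                    ss = tab[["Sum Sq"]], df = tab[["Df"]],
                    F = tab[["F value"]], p = tab[["Pr(>F)"]])
  out$signif <- ifelse(is.na(out$p), "", signif_stars(out$p))
  class(out) <- c("anova_result", "data.frame")
  out
}

#' Pearson correlation between SD and leaf area
#'
#' Pearson product-moment correlation with the exact t test:
#' `t = R * sqrt((n - 2) / (1 - R^2))`, two-sided p.
#'
#' @param sd_all,la paired numeric vectors (n >= 3).
#' @return list with `R`, `n`, `t`, `p`, `signif`.
#' @export
correlation_sd_la <- function(sd_all, la) {
  ok <- stats::complete.cases(sd_all, la)
  x <- sd_all[ok]; y <- la[ok]
  n <- length(x)
  if (n < 3L) stopf("correlation needs at least three complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stopf("zero variance; correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  list(R = unname(ct$estimate), n = n, t = unname(ct$statistic),
       p = ct$p.value, signif = signif_stars(ct$p.value))
}

#' Tukey(-Kramer) all-pairs comparison of group means
#'
#' All pairwise mean comparisons using the studentized range
#' distribution; with unequal group sizes the Kramer standard error
#' `sqrt(MSE/2 * (1/n_i + 1/n_j))` is used. Groups with fewer than two
#' members carry no variance information and are excluded with a warning.
#'
#' @param values numeric response (e.g. accession-level `sd_all`).
#' @param groups group labels (e.g. origin).
#' @param alpha family-wise significance level (default 0.05).
#' @return a `group_comparison`: list with `pairs` (difference, q
#'   statistic, adjusted p, significance per pair), `groups` (per-group n
#'   and mean), `mse`, `df`.
#' @export
tukey_groups <- function(values, groups, alpha = 0.05) {
  g <- factor(groups)
  sizes <- table(g)
  drop <- names(sizes)[sizes < 2L]
  if (length(drop)) {
    warning(sprintf("excluding group(s) with a single member: %s",
                    paste(drop, collapse = ", ")))
    keep <- !(g %in% drop)
    values <- values[keep]
    g <- droplevels(g[keep])
  }
  k <- nlevels(g)
  if (k < 2L) stopf("Tukey comparison needs at least two groups")
  means <- tapply(values, g, mean)
  ns <- tapply(values, g, length)
  df_resid <- length(values) - k
  mse <- sum(tapply(values, g, function(v) sum((v - mean(v))^2))) / df_resid
  combs <- utils::combn(levels(g), 2)
  pairs <- data.frame(group_1 = combs[1, ], group_2 = combs[2, ])
  pairs$diff <- as.numeric(means[pairs$group_1] - means[pairs$group_2])
  se <- as.numeric(sqrt(mse / 2 *
                          (1 / ns[pairs$group_1] + 1 / ns[pairs$group_2])))
  # degenerate case: zero within-group variance; equal means are then not
  # different (q = 0), unequal means are infinitely separated
  pairs$q <- ifelse(se > 0, abs(pairs$diff) / se,
                    ifelse(abs(pairs$diff) < 1e-12, 0, Inf))
  pairs$p_adj <- ptukey(pairs$q, k, df_resid, lower.tail = FALSE)
  pairs$significant <- pairs$p_adj < alpha
  rownames(pairs) <- NULL
  out <- list(pairs = pairs,
              groups = data.frame(group = levels(g), n = as.integer(ns),
                                  mean = as.numeric(means)),
              mse = mse, df = df_resid, alpha = alpha)
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "Tukey-Kramer comparison: %d groups, %d pairs, %d significant at %.2f\n",
    nrow(x$groups), nrow(x$pairs), sum(x$pairs$significant), x$alpha))
  print(head(x$pairs[order(x$pairs$p_adj), ], 10), row.names = FALSE)
  invisible(x)
}

#' Origin-stacked histogram of SD
#'
#' Shared bin edges across groups; per-bin per-group counts whose stack
#' equals the overall histogram. The 5 mm-2 default bin width suits the
#' 90-accession panel scale.
#'
#' @param values numeric SD values (accession means).
#' @param groups origin label per value.
#' @param bin_width histogram bin width in mm-2.
#' @return an `origin_histogram`: list with `breaks`, `mids`, `counts`
#'   (bins x groups matrix) and `totals`.
#' @export
origin_histogram <- function(values, groups, bin_width = 5) {
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stopf("bin_width must be positive")
  }
  if (length(values) == 0L) stopf("no values to bin")
  g <- factor(groups)
  lo <- floor(min(values) / bin_width) * bin_width
  hi <- ceiling(max(values) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  bins <- cut(values, breaks, include.lowest = TRUE, right = FALSE)
  counts <- table(bins, g)
  out <- list(breaks = breaks, mids = breaks[-1] - bin_width / 2,
              counts = unclass(counts), totals = as.integer(rowSums(counts)),
              bin_width = bin_width)
  class(out) <- "origin_histogram"
  out
}

#' @export
print.origin_histogram <- function(x, ...) {
  cat(sprintf("Stacked histogram: %d bins of width %g, %d group(s), %d values\n",
              length(x$mids), x$bin_width, ncol(x$counts), sum(x$totals)))
  invisible(x)
}

#' @export
plot.origin_histogram <- function(x, ...) {
  graphics::barplot(t(x$counts), names.arg = sprintf("%g", x$mids),
                    col = grDevices::hcl.colors(ncol(x$counts), "Spectral"),
                    xlab = "SD (mm-2)", ylab = "accessions",
                    legend.text = colnames(x$counts),
                    args.legend = list(cex = 0.6), ...)
  invisible(x)
}
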