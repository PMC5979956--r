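# Group statistics: one-way ANOVA with Scheffe post hoc comparisons,
# demographics tests (Pearson chi-square, Mann-Whitney U with normal
# approximation), and metric-clinical Spearman correlations.

#' One-way ANOVA with Scheffe post hoc pairwise comparisons
#'
#' Classical fixed-effects one-way ANOVA, F = MS_between / MS_within, plus
#' Scheffe-protected pairwise p values: for groups A, B the contrast
#' statistic F_AB = (mean_A - mean_B)^2 / (MSW (1/n_A + 1/n_B)) is referred
#' to (k - 1) * F(k - 1, N - k), i.e. p = P(F >= F_AB / (k - 1)).
#' For k = 2 the Scheffe p equals the ANOVA p.
#'
#' @param values Named list of numeric vectors, one per group (>= 2 groups,
#'   each with >= 2 observations).
#' @param alpha Significance threshold for the flags (default 0.05).
#' @return List of class `anova_scheffe`: `F`, `p_overall`, `df`,
#'   `group_means` (mean, sd, n per group), `pairwise` (data frame with
#'   group pair, difference, Scheffe p, significance flag).
#' @export
oneway_anova_scheffe <- function(values, alpha = 0.05) {
  if (length(values) < 2) stop("need >= 2 groups", call. = FALSE)
  if (is.null(names(values))) names(values) <- paste0("g", seq_along(values))
  ns <- lengths(values)
  if (any(ns < 2)) stop("each group needs >= 2 observations", call. = FALSE)
  k <- length(values)
  N <- sum(ns)
  means <- vapply(values, mean, numeric(1))
  sds <- vapply(values, stats::sd, numeric(1))
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(values, function(v) sum((v - mean(v))^2), numeric(1)))
  df1 <- k - 1
  df2 <- N - k
  msb <- ssb / df1
  msw <- ssw / df2
  if (msw == 0) {
    if (ssb == 0) {
      warning("all observations identical: F undefined", call. = FALSE)
      f <- NaN; p <- NA_real_
    } else {
      warning("zero within-group variance with unequal means: F = Inf",
              call. = FALSE)
      f <- Inf; p <- 0
    }
  } else {
    f <- msb / msw
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  pairs <- utils::combn(names(values), 2)
  pw <- apply(pairs, 2, function(pr) {
    dmean <- means[pr[1]] - means[pr[2]]
    if (msw == 0) {
      p_ab <- if (dmean == 0) NA_real_ else 0
    } else {
      f_ab <- dmean^2 / (msw * (1 / ns[pr[1]] + 1 / ns[pr[2]]))
      p_ab <- stats::pf(f_ab / df1, df1, df2, lower.tail = FALSE)
    }
    data.frame(group_a = pr[1], group_b = pr[2], diff = unname(dmean),
               p_scheffe = unname(p_ab),
               significant = isTRUE(unname(p_ab) < alpha),
               stringsAsFactors = FALSE)
  })
  structure(list(
    F = unname(f), p_overall = unname(p), df = c(df1, df2),
    group_means = data.frame(group = names(values), mean = unname(means),
                             sd = unname(sds), n = unname(ns),
                             stringsAsFactors = FALSE),
    pairwise = do.call(rbind, pw), alpha = alpha
  ), class = "anova_scheffe")
}

#' @export
print.anova_scheffe <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p_overall))
  print(x$group_means, row.names = FALSE)
  cat("Scheffe pairwise:\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Pearson chi-square test of independence for a 2x2 (or r x c) count table
#'
#' Plain Pearson statistic sum (O - E)^2 / E without continuity correction.
#'
#' @param table Matrix of non-negative integer counts with positive margins.
#' @return List with `statistic`, `df`, `p`.
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero margin in the contingency table", call. = FALSE)
  }
  # small expected counts only affect the asymptotic p, which we report as-is
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Mann-Whitney U test, normal approximation with tie correction
#'
#' U for sample `a` with midranks; z = (U - n1 n2 / 2) / sd(U) where the
#' variance uses the standard tie correction
#' n1 n2 / 12 * ((N + 1) - sum(t^3 - t) / (N (N - 1))).
#'
#' @param a,b Numeric samples (non-empty).
#' @return List with `U`, `z`, `p` (two-sided normal approximation).
#' @export
mann_whitney_z <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("samples must be non-empty")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  v <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (v <= 0) {
    warning("all values tied across both samples: z = 0", call. = FALSE)
    return(list(U = U, z = 0, p = 1))
  }
  z <- (U - n1 * n2 / 2) / sqrt(v)
  list(U = U, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Spearman correlations between tract metrics and clinical variables
#'
#' Rank correlation (chosen over Pearson because the myelopathy disability
#' score is ordinal) between each tract x metric combination and each
#' clinical column, with asymptotic p values. Rows with missing clinical
#' values (controls have no mJOA) are dropped per correlation.
#'
#' @param cohort_table A `cohort_table` from [assemble_cohort_table()].
#' @param clinical Clinical column names (default mjoa and n_levels).
#' @return Data frame: tract, metric, clinical, n, rho, p (NaN rho for
#'   constant columns).
#' @export
correlate_clinical <- function(cohort_table,
                               clinical = c("mjoa", "n_levels")) {
  ct <- as.data.frame(cohort_table)
  out <- list()
  for (tract in unique(ct$tract)) for (metric in unique(ct$metric)) {
    sub <- ct[ct$tract == tract & ct$metric == metric, ]
    for (cl in clinical) {
      ok <- is.finite(sub$value) & is.finite(sub[[cl]])
      x <- sub$value[ok]; y <- sub[[cl]][ok]
      if (sum(ok) < 3) {
        rho <- NA_real_; p <- NA_real_
      } else if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        rho <- NaN; p <- NaN
      } else {
        ht <- suppressWarnings(
          stats::cor.test(x, y, method = "spearman", exact = FALSE))
        rho <- unname(ht$estimate); p <- ht$p.value
      }
      out[[length(out) + 1]] <- data.frame(
        tract = tract, metric = metric, clinical = cl, n = sum(ok),
        rho = rho, p = p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Group comparison of all tract metrics
#'
#' Runs [oneway_anova_scheffe()] for every tract x metric combination of a
#' cohort table, comparing the affected, unaffected and control sides. Each
#' combination is tested independently at `alpha` (no multiplicity
#' correction across tracts/metrics, matching common reporting practice for
#' this design).
#'
#' @param cohort_table A `cohort_table`.
#' @param alpha Significance level (default 0.05).
#' @return Data frame with one row per tract x metric x group pair: group
#'   means +/- SD, overall F and p, Scheffe pairwise p and significance.
#' @export
group_stats <- function(cohort_table, alpha = 0.05) {
  ct <- as.data.frame(cohort_table)
  groups_present <- unique(ct$side_group)
  if (length(groups_present) < 2) {
    stop("need >= 2 groups with observations for group statistics",
         call. = FALSE)
  }
  rows <- list()
  for (tract in unique(ct$tract)) for (metric in unique(ct$metric)) {
    sub <- ct[ct$tract == tract & ct$metric == metric, ]
    values <- split(sub$value, sub$side_group)
    res <- oneway_anova_scheffe(values, alpha = alpha)
    gm <- res$group_means
    for (j in seq_len(nrow(res$pairwise))) {
      pr <- res$pairwise[j, ]
      rows[[length(rows) + 1]] <- data.frame(
        tract = tract, metric = metric,
        group_a = pr$group_a, group_b = pr$group_b,
        mean_a = gm$mean[gm$group == pr$group_a],
        sd_a = gm$sd[gm$group == pr$group_a],
        n_a = gm$n[gm$group == pr$group_a],
        mean_b = gm$mean[gm$group == pr$group_b],
        sd_b = gm$sd[gm$group == pr$group_b],
        n_b = gm$n[gm$group == pr$group_b],
        F = res$F, p_overall = res$p_overall,
        p_scheffe = pr$p_scheffe, significant = pr$significant,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
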