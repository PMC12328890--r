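# Descriptive and variability statistics for intergestural timing.

#' Count-weighted pooled mean
#'
#' `sum(counts * means) / sum(counts)`: the "Total" column of a grouped
#' summary, pooling per-speaker cell means by their token counts.
#'
#' @param means numeric vector of cell means.
#' @param counts matching vector of cell counts (> 0).
#' @return the pooled mean.
#' @examples
#' pooled_weighted_mean(c(5.33, 6.81, 3.33), c(40, 41, 42))  # 5.14 at 2 dp
#' @export
pooled_weighted_mean <- function(means, counts) {
  if (length(means) != length(counts)) stopf("means and counts differ in length")
  if (any(counts <= 0)) stopf("counts must be positive")
  sum(counts * means) / sum(counts)
}

#' Grouped summary of a measure table
#'
#' Count, mean, and sample SD of one measure per grouping cell (by default
#' speaker x class), plus a `Total` row per class whose mean is the
#' count-weighted mean of the speaker cells and whose SD is that of the
#' pooled sample. `NA` measurements are excluded cell-wise; an empty cell
#' is reported with count 0 and undefined mean, and a single-observation
#' cell has an undefined SD.
#'
#' @param table a measure table.
#' @param measure measure column name.
#' @param by grouping columns; the first is pooled into the Total rows.
#' @return a `group_summary` data frame: grouping columns, `count`, `mean`,
#'   `sd`.
#' @export
group_summary <- function(table, measure, by = c("speaker", "class")) {
  stopifnot(measure %in% names(table), all(by %in% names(table)))
  x <- table[[measure]]
  cells <- expand.grid(lapply(table[by], function(v) unique(v)),
                       stringsAsFactors = FALSE)
  stat <- function(sel) {
    v <- x[sel]; v <- v[!is.na(v)]
    c(count = length(v),
      mean = if (length(v)) mean(v) else NA_real_,
      sd = if (length(v) > 1) stats::sd(v) else NA_real_)
  }
  res <- t(apply(cells, 1, function(cl) {
    sel <- rep(TRUE, nrow(table))
    for (j in seq_along(by)) sel <- sel & table[[by[j]]] == cl[j]
    stat(sel)
  }))
  out <- cbind(cells, as.data.frame(res))
  if (length(by) > 1) {
    pool_by <- by[-1]
    tot_cells <- unique(cells[, pool_by, drop = FALSE])
    tot <- t(apply(tot_cells, 1, function(cl) {
      sel <- rep(TRUE, nrow(table))
      for (j in seq_along(pool_by)) sel <- sel & table[[pool_by[j]]] == cl[j]
      stat(sel)
    }))
    tot <- cbind(stats::setNames(data.frame(rep("Total", nrow(tot_cells)),
                                            stringsAsFactors = FALSE), by[1]),
                 tot_cells, as.data.frame(tot))
    out <- rbind(out, tot[, names(out)])
  }
  out <- out[do.call(order, out[rev(by)]), ]
  rownames(out) <- NULL
  attr(out, "measure") <- measure
  class(out) <- c("group_summary", "data.frame")
  out
}

#' Brown-Forsythe test for homogeneity of variance
#'
#' The median-based Levene test: a one-way ANOVA on the absolute deviations
#' of the observations from their group medians, with (k - 1, N - k)
#' degrees of freedom. Deviations about the median rather than the mean
#' make the test robust to departures from normality.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2), or a
#'   numeric vector combined with `g`.
#' @param g optional grouping factor when `groups` is a vector.
#' @return a `variance_test` object: list with `statistic` (F), `df1`,
#'   `df2`, `p.value`, `groups`, `method`.
#' @export
brown_forsythe <- function(groups, g = NULL) {
  if (!is.list(groups)) groups <- split(groups, g)
  groups <- lapply(groups, function(v) v[!is.na(v)])
  k <- length(groups)
  if (k < 2) stopf("need at least 2 groups")
  n <- vapply(groups, length, 1L)
  if (any(n < 2)) stopf("every group needs at least 2 observations")
  z <- lapply(groups, function(v) abs(v - stats::median(v)))
  N <- sum(n)
  zbar <- vapply(z, mean, 1)
  zall <- sum(n * zbar) / N
  ssb <- sum(n * (zbar - zall)^2)
  ssw <- sum(vapply(z, function(v) sum((v - mean(v))^2), 1))
  df1 <- k - 1; df2 <- N - k
  if (ssw == 0) {
    stat <- if (ssb == 0) 0 else Inf
  } else stat <- (ssb / df1) / (ssw / df2)
  p <- if (is.infinite(stat)) 0 else stats::pf(stat, df1, df2, lower.tail = FALSE)
  if (stat == 0) p <- 1
  structure(list(statistic = stat, df1 = df1, df2 = df2, p.value = p,
                 groups = names(groups) %||% as.character(seq_len(k)),
                 method = "Brown-Forsythe (median-based Levene) test"),
            class = "variance_test")
}

#' @export
print.variance_test <- function(x, ...) {
  cat(sprintf("%s\nF(%d, %d) = %.4g, p = %.4g\n", x$method, x$df1, x$df2,
              x$statistic, x$p.value))
  invisible(x)
}

# Profile log-likelihood of k normal samples under a common CV tau:
# for fixed tau the group-mean MLE solves n*tau^2*mu^2 + S1*mu - S2 = 0.
cv_profile_negloglik <- function(ltau, n, S1, S2) {
  tau2 <- exp(2 * ltau)
  mu <- (-S1 + sqrt(S1^2 + 4 * n * tau2 * S2)) / (2 * n * tau2)
  sig2 <- tau2 * mu^2
  -sum(-n / 2 * log(sig2) - (S2 - 2 * mu * S1 + n * mu^2) / (2 * sig2))
}

#' Likelihood-ratio test for equality of coefficients of variation
#'
#' Tests H0: all groups share a common coefficient of variation (CV =
#' sd/mean) under normal models, via the profile likelihood-ratio
#' statistic. Under H0 the group means are profiled out in closed form and
#' the common CV by one-dimensional optimisation; the statistic
#' `2 * (logLik_unrestricted - logLik_H0)` is referred to chi-square(k - 1)
#' (`p_method = "chisq"`), or to a parametric-bootstrap null distribution
#' for small samples (`p_method = "simulation"`). For two groups the
#' signed square root of the statistic is also reported (positive when the
#' first group's CV is larger).
#'
#' Groups whose mean is numerically indistinguishable from zero have an
#' undefined CV; they are dropped with a warning. Negative-mean groups are
#' reflected (the CV of the magnitude is tested).
#'
#' @param groups list of numeric vectors.
#' @param p_method `"chisq"` or `"simulation"`.
#' @param B bootstrap replicates when `p_method = "simulation"`.
#' @param seed optional seed for the bootstrap.
#' @return a `cv_test` object: `statistic`, `signed_root` (2 groups),
#'   `df`, `p.value`, `cv` (per-group sample CVs).
#' @export
cv_equality_test <- function(groups, p_method = c("chisq", "simulation"),
                             B = 1000, seed = NULL) {
  p_method <- match.arg(p_method)
  groups <- lapply(groups, function(v) v[!is.na(v)])
  means <- vapply(groups, mean, 1)
  sds <- vapply(groups, stats::sd, 1)
  unstable <- abs(means) < sqrt(.Machine$double.eps) * pmax(sds, 1)
  if (any(unstable)) {
    warning(sprintf("%d group(s) with mean ~ 0 excluded (CV undefined)",
                    sum(unstable)), call. = FALSE)
    groups <- groups[!unstable]
  }
  if (length(groups) < 2) stopf("need at least 2 usable groups")
  groups <- lapply(groups, function(v) if (mean(v) < 0) -v else v)
  k <- length(groups)
  n <- vapply(groups, length, 1L)
  if (any(n < 2)) stopf("every group needs at least 2 observations")
  lrt_stat <- function(groups) {
    n <- vapply(groups, length, 1L)
    S1 <- vapply(groups, sum, 1)
    S2 <- vapply(groups, function(x) sum(x^2), 1)
    v_mle <- S2 / n - (S1 / n)^2
    l_unc <- sum(-n / 2 * log(v_mle) - n / 2)
    tau0 <- sqrt(sum(n * v_mle / (S1 / n)^2) / sum(n))
    opt <- stats::optimize(cv_profile_negloglik, log(tau0) + c(-4, 4),
                           n = n, S1 = S1, S2 = S2)
    max(0, 2 * (l_unc + opt$objective))
  }
  stat <- lrt_stat(groups)
  cvs <- vapply(groups, function(v) stats::sd(v) / mean(v), 1)
  p <- switch(p_method,
    chisq = stats::pchisq(stat, k - 1, lower.tail = FALSE),
    simulation = with_seed(seed, {
      # bootstrap under the fitted common-CV null
      tau_hat <- sqrt(sum(n * cvs^2) / sum(n))
      mu_hat <- vapply(groups, mean, 1)
      null_stats <- replicate(B, lrt_stat(
        lapply(seq_len(k), function(i)
          stats::rnorm(n[i], mu_hat[i], tau_hat * mu_hat[i]))))
      (1 + sum(null_stats >= stat)) / (B + 1)
    }))
  if (stat == 0) p <- 1
  structure(list(statistic = stat,
                 signed_root = if (k == 2)
                   sign(cvs[1] - cvs[2]) * sqrt(stat) else NA_real_,
                 df = k - 1, p.value = p, cv = cvs,
                 method = sprintf(
                   "Likelihood-ratio test for CV equality (%s p-value)",
                   p_method)),
            class = "cv_test")
}

#' @export
print.cv_test <- function(x, ...) {
  cat(sprintf("%s\nLR = %.4g, df = %d, p = %.4g\nCVs: %s\n", x$method,
              x$statistic, x$df, x$p.value,
              paste(sprintf("%.3f", x$cv), collapse = ", ")))
  invisible(x)
}

#' Correlation between an intergestural lag and gesture duration
#'
#' Pearson correlation (with a two-sided test) between a lag measure and
#' LX duration, per consonant. Consonants with fewer than `min_n` complete
#' pairs, or with a constant series, are flagged and get `NA` statistics.
#'
#' @param table a measure table.
#' @param lag_measure lag column name.
#' @param duration_measure duration column name.
#' @param by grouping column (default `"consonant"`).
#' @param min_n minimum complete pairs per group.
#' @return data frame: group, `n`, `r`, `p`, `flagged`.
#' @export
lag_duration_correlation <- function(table, lag_measure = "onset_lag_ms",
                                     duration_measure = "lx_duration_ms",
                                     by = "consonant", min_n = 3) {
  stopifnot(all(c(lag_measure, duration_measure, by) %in% names(table)))
  res <- lapply(split(table, table[[by]]), function(d) {
    ok <- stats::complete.cases(d[[lag_measure]], d[[duration_measure]])
    x <- d[[lag_measure]][ok]; y <- d[[duration_measure]][ok]
    if (length(x) < min_n || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(n = length(x), r = NA_real_, p = NA_real_,
                        flagged = TRUE))
    ct <- stats::cor.test(x, y)
    data.frame(n = length(x), r = unname(ct$estimate), p = ct$p.value,
               flagged = FALSE)
  })
  out <- do.call(rbind, res)
  out <- cbind(stats::setNames(data.frame(names(res),
                                          stringsAsFactors = FALSE), by), out)
  rownames(out) <- NULL
  out
}

#' Mixed-effects model contract for a kinematic measure
#'
#' Fits `measure ~ fixed + (1 | r)` for each random grouping factor via
#' lmerTest and reports the fixed-effect F test. The contract covers the
#' interface (F statistic, denominator df by Kenward-Roger or
#' Satterthwaite, singular-fit flag); estimation is delegated entirely to
#' lme4/lmerTest.
#'
#' @param table a measure table.
#' @param measure response column.
#' @param fixed fixed-effect column.
#' @param random random-intercept grouping columns.
#' @param ddf denominator-df method: `"Kenward-Roger"` or
#'   `"Satterthwaite"`.
#' @return list: `F`, `df1`, `df2`, `p.value`, `singular`, `model`.
#' @export
mixed_model_contract <- function(table, measure, fixed = "class",
                                 random = c("speaker", "consonant",
                                            "condition"),
                                 ddf = c("Satterthwaite", "Kenward-Roger")) {
  ddf <- match.arg(ddf)
  stopifnot(all(c(measure, fixed, random) %in% names(table)))
  d <- table[stats::complete.cases(table[c(measure, fixed, random)]), ]
  fml <- stats::as.formula(paste(
    measure, "~", fixed, "+",
    paste(sprintf("(1 | %s)", random), collapse = " + ")))
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(fml, data = d,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))))
  an <- suppressMessages(suppressWarnings(stats::anova(fit, ddf = ddf)))
  list(F = an[fixed, "F value"], df1 = an[fixed, "NumDF"],
       df2 = an[fixed, "DenDF"], p.value = an[fixed, "Pr(>F)"],
       singular = lme4::isSingular(fit), model = fit)
}
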