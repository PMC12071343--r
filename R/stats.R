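#' @name stat-results
#' @title Statistical result rows
#' @description All tests in the battery return a one-row tibble with
#'   `test`, `statistic`, `p_value`, `q_value` (filled after FDR correction
#'   where applicable), sample sizes, and the effect `direction`.
NULL

stat_result <- function(test, statistic, p_value, n1, n2 = NA_integer_,
                        direction = NA_character_) {
  tibble::tibble(test = test,
                 statistic = unname(statistic),
                 p_value = unname(p_value),
                 q_value = NA_real_,
                 n1 = as.integer(n1), n2 = as.integer(n2),
                 direction = direction)
}

#' Wilcoxon signed-rank test against zero
#'
#' Two-sided one-sample signed-rank test of the hypothesis that the values
#' are symmetric about zero (used for AUC-versus-zero comparisons). Exact
#' null distribution for n <= 25 after zero removal (when the absolute
#' values are tie-free); tie-corrected normal approximation otherwise.
#'
#' @param values numeric vector; zeros are removed first.
#' @return a one-row stats tibble (see [stat-results]).
#' @export
wilcoxon_signed_rank_vs_zero <- function(values) {
  v <- values[values != 0]
  if (length(v) == 0) stop_fc("all values are zero; signed-rank test undefined")
  n <- length(v)
  exact <- n <= 25 && !any(duplicated(abs(v)))
  wt <- suppressWarnings(stats::wilcox.test(v, mu = 0, exact = exact,
                                            correct = FALSE))
  stat_result("wilcoxon_signed_rank", wt$statistic, wt$p.value, n,
              direction = if (median(v) > 0) "positive" else "negative")
}

#' Mann-Whitney rank-sum test
#'
#' Two-sided two-sample rank test (used for AUC and time-of-peak comparisons
#' between independent groups). Exact null distribution when the smaller
#' group has 8 or fewer observations and there are no cross-group ties;
#' tie-corrected normal approximation otherwise.
#'
#' @param x,y numeric vectors.
#' @return a one-row stats tibble.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop_fc("both groups must be non-empty")
  exact <- min(length(x), length(y)) <= 8 && !any(duplicated(c(x, y)))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = FALSE))
  stat_result("mann_whitney", wt$statistic, wt$p.value, length(x), length(y),
              direction = if (median(x) > median(y)) "x>y" else "x<y")
}

#' F test for equality of variances
#'
#' Ratio of the larger to the smaller sample variance, with degrees of
#' freedom taken from the respective samples and a two-sided p-value
#' obtained by doubling the upper tail (capped at 1) - the convention of
#' common graphing/statistics software. Used to compare time-of-peak spread
#' between conditions.
#'
#' @param x,y numeric vectors (n >= 2 each).
#' @return a one-row stats tibble; `statistic` is F, with attributes `dfn`,
#'   `dfd` recorded in the `direction` field as "x" or "y" for which sample
#'   had the larger variance.
#' @export
variance_f_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop_fc("need at least 2 values per group")
  vx <- stats::var(x); vy <- stats::var(y)
  if (min(vx, vy) == 0) stop_fc("zero variance in one group; F undefined")
  if (vx >= vy) {
    f <- vx / vy; dfn <- length(x) - 1L; dfd <- length(y) - 1L; dir <- "x"
  } else {
    f <- vy / vx; dfn <- length(y) - 1L; dfd <- length(x) - 1L; dir <- "y"
  }
  p <- min(1, 2 * stats::pf(f, dfn, dfd, lower.tail = FALSE))
  out <- stat_result("variance_f", f, p, length(x), length(y), direction = dir)
  out$dfn <- dfn; out$dfd <- dfd
  out
}

#' One-way repeated-measures ANOVA over epochs
#'
#' Within-trial comparison of the baseline, full-expansion (5--8 s) and
#' poststimulus (8--15 s) epoch means, with trials as the repeated unit.
#' Pairwise post hoc paired t contrasts are corrected with the two-stage
#' step-up FDR ([bky_fdr()]); trials with a missing epoch are dropped with a
#' message.
#'
#' @param epoch_matrix numeric matrix or data frame, one row per trial, one
#'   column per epoch (column names are kept as epoch labels).
#' @param alpha FDR level for the post hoc contrasts.
#' @return list with `omnibus` (one-row stats tibble; F with `dfn`, `dfd`)
#'   and `posthoc` (tibble of pairwise contrasts with `q_value`).
#' @export
rm_anova_epochs <- function(epoch_matrix, alpha = 0.05) {
  m <- as.matrix(epoch_matrix)
  if (is.null(colnames(m))) colnames(m) <- paste0("epoch", seq_len(ncol(m)))
  complete <- stats::complete.cases(m)
  if (!all(complete)) {
    rlang::inform(sprintf("dropping %d trial(s) with missing epoch values",
                          sum(!complete)))
    m <- m[complete, , drop = FALSE]
  }
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop_fc("need at least 2 trials and 2 epochs")

  df <- data.frame(y = as.vector(m),
                   epoch = factor(rep(colnames(m), each = n),
                                  levels = colnames(m)),
                   trial = factor(rep(seq_len(n), times = k)))
  fit <- stats::aov(y ~ epoch + Error(trial / epoch), data = df)
  tab <- summary(fit)[["Error: trial:epoch"]][[1]]
  f <- tab["epoch", "F value"]
  p <- tab["epoch", "Pr(>F)"]
  ss_total <- sum((m - mean(m))^2)
  if (!is.finite(f) || tab["epoch", "Sum Sq"] <= 1e-12 * max(ss_total, 1e-300)) {
    f <- 0; p <- 1   # identical epochs: no effect (avoid 0/0 noise ratios)
  }
  omnibus <- stat_result("rm_anova", f, p, n)
  omnibus$dfn <- tab["epoch", "Df"]
  omnibus$dfd <- tab["Residuals", "Df"]

  pairs <- utils::combn(colnames(m), 2)
  posthoc <- dplyr::bind_rows(lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    d <- m[, a] - m[, b]
    tt <- tryCatch(stats::t.test(m[, a], m[, b], paired = TRUE),
                   error = function(e) NULL)
    if (is.null(tt)) {
      # (near-)constant difference: no contrast at all, or a noiseless shift
      stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      pv <- if (mean(d) == 0) 1 else 0
    } else {
      stat <- unname(tt$statistic); pv <- tt$p.value
    }
    tibble::tibble(contrast = paste(a, "vs", b),
                   statistic = stat, p_value = pv)
  }))
  adj <- bky_fdr(posthoc$p_value, alpha)
  posthoc$q_value <- adj$q_value
  posthoc$rejected <- adj$rejected
  list(omnibus = omnibus, posthoc = posthoc)
}

#' Two-stage linear step-up FDR (Benjamini-Krieger-Yekutieli)
#'
#' Adaptive false-discovery-rate control. Stage 1 runs the linear step-up
#' procedure at level `alpha' = alpha / (1 + alpha)`; the number of
#' non-rejected hypotheses estimates the number of true nulls `m0`. Stage 2
#' reruns the step-up at level `alpha' * m / m0`. If the first stage rejects
#' nothing, nothing is rejected; if it rejects everything, everything is.
#' The reported `q_value` for each test is the smallest `alpha` at which it
#' would be rejected by stage 2 given the stage-1 estimate, i.e.
#' `min over j >= i of p_(j) * m0 * (1 + alpha) / j`, capped at 1.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param alpha target FDR level (default 0.05).
#' @return tibble with `p_value`, `q_value`, `rejected` in the input order;
#'   attribute `m0` carries the estimated number of true nulls.
#' @export
bky_fdr <- function(p_values, alpha = 0.05) {
  p <- p_values
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_fc("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) {
    return(structure(tibble::tibble(p_value = numeric(), q_value = numeric(),
                                    rejected = logical()), m0 = 0L))
  }
  ord <- order(p)
  ps <- p[ord]
  step_up <- function(ps, level) {
    ok <- which(ps <= seq_along(ps) * level / m)
    if (length(ok) == 0) 0L else max(ok)
  }
  alpha1 <- alpha / (1 + alpha)
  r1 <- step_up(ps, alpha1)
  if (r1 == 0L) {
    m0 <- m
    rejected_sorted <- rep(FALSE, m)
  } else if (r1 == m) {
    m0 <- 0L
    rejected_sorted <- rep(TRUE, m)
  } else {
    m0 <- m - r1
    r2 <- step_up(ps, alpha1 * m / m0)
    rejected_sorted <- seq_len(m) <= r2
  }
  m0_q <- max(m0, 1L)
  q_sorted <- rev(cummin(rev(pmin(1, ps * m0_q * (1 + alpha) / seq_len(m)))))
  out <- tibble::tibble(p_value = p,
                        q_value = q_sorted[order(ord)],
                        rejected = rejected_sorted[order(ord)])
  attr(out, "m0") <- m0
  out
}

#' Robust outlier removal for a univariate sample
#'
#' FDR-based outlier identification specialized to a mean-only model
#' (the use case: univariate behavioral summaries). The robust center is the
#' sample median; the robust scale (RSDR) is the 68.27th percentile of the
#' absolute residuals inflated by `sqrt(n / (n - 1))` for the one estimated
#' parameter. Each point's two-tailed p-value comes from the t distribution
#' (df = n - 1) of its standardized residual, and the linear step-up
#' procedure at rate `Q` over these p-values flags the outliers, so that for
#' a clean sample the chance of removing anything is about `Q`.
#'
#' @param values numeric vector (n >= 3; smaller samples are returned
#'   untouched with a warning).
#' @param Q false-removal rate (default 0.01, i.e. 1%).
#' @return list with `kept`, `removed`, and `is_outlier` (logical in input
#'   order).
#' @export
rout_outliers <- function(values, Q = 0.01) {
  n <- length(values)
  if (n < 3) {
    rlang::warn("fewer than 3 values: outlier scan skipped")
    return(list(kept = values, removed = numeric(0),
                is_outlier = rep(FALSE, n)))
  }
  resid <- values - stats::median(values)
  rsdr <- stats::quantile(abs(resid), 0.6827, names = FALSE, type = 7) *
    sqrt(n / (n - 1))
  if (rsdr == 0) {
    return(list(kept = values, removed = numeric(0),
                is_outlier = rep(FALSE, n)))
  }
  pvals <- 2 * stats::pt(abs(resid) / rsdr, df = n - 1, lower.tail = FALSE)
  ord <- order(pvals)
  ps <- pvals[ord]
  ok <- which(ps <= seq_len(n) * Q / n)
  out_sorted <- if (length(ok) == 0) rep(FALSE, n) else seq_len(n) <= max(ok)
  is_outlier <- out_sorted[order(ord)]
  list(kept = values[!is_outlier], removed = values[is_outlier],
       is_outlier = is_outlier)
}

#' Two-way ANOVA with sex and familiarity factors
#'
#' Between-subjects two-way ANOVA (main effects and interaction) using
#' type-II sums of squares so that unbalanced cells are handled sensibly.
#' Post hoc pairwise Welch t comparisons between the four cells are
#' FDR-corrected with [bky_fdr()].
#'
#' @param values numeric response.
#' @param factor_a,factor_b factors (e.g. sex and familiarity), recycled
#'   against `values`.
#' @param alpha FDR level for the post hoc contrasts.
#' @return list with `effects` (tibble: term, sum_sq, df, statistic,
#'   p_value) and `posthoc`.
#' @export
two_way_anova <- function(values, factor_a, factor_b, alpha = 0.05) {
  fa <- factor(factor_a); fb <- factor(factor_b)
  d <- data.frame(y = values, a = fa, b = fb)
  cells <- table(fa, fb)
  if (any(cells == 0)) stop_fc("empty factor cell; two-way ANOVA undefined")
  fit <- stats::lm(y ~ a * b, data = d)
  an <- car::Anova(fit, type = 2)
  terms <- rownames(an)[rownames(an) != "Residuals"]
  effects <- tibble::tibble(
    term = c("a", "b", "a:b")[match(terms, c("a", "b", "a:b"))],
    sum_sq = an[terms, "Sum Sq"],
    df = an[terms, "Df"],
    statistic = an[terms, "F value"],
    p_value = an[terms, "Pr(>F)"]
  )
  cell <- interaction(fa, fb, sep = ":")
  pairs <- utils::combn(levels(cell), 2)
  posthoc <- dplyr::bind_rows(lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- values[cell == pairs[1, j]]; g2 <- values[cell == pairs[2, j]]
    tt <- stats::t.test(g1, g2)
    tibble::tibble(contrast = paste(pairs[1, j], "vs", pairs[2, j]),
                   statistic = unname(tt$statistic), p_value = tt$p.value)
  }))
  adj <- bky_fdr(posthoc$p_value, alpha)
  posthoc$q_value <- adj$q_value
  posthoc$rejected <- adj$rejected
  list(effects = effects, posthoc = posthoc)
}

#' Chi-square test on a count table
#'
#' Pearson chi-square test of independence without continuity correction,
#' df = (rows - 1)(columns - 1). Used for the sex-by-response-category
#' table of looming trials.
#'
#' @param count_table matrix of nonnegative counts.
#' @return a one-row stats tibble (statistic is X-squared).
#' @export
chi_square_counts <- function(count_table) {
  m <- as.matrix(count_table)
  if (any(m < 0) || any(m != round(m))) stop_fc("counts must be nonnegative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop_fc("zero marginal in count table")
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  stat_result("chi_square", ct$statistic, ct$p.value, sum(m))
}

#' Normality-gated group comparison
#'
#' Reproduces the test-selection path used for the behavioral and photometry
#' comparisons: when `auto_normality` is on, a Shapiro-Wilk test (alpha =
#' 0.05) on each group (or on the paired differences) decides between the t
#' test and the rank-based alternative (signed-rank when paired or y is
#' absent, rank-sum otherwise). The decision is recorded in the result's
#' `direction`-adjacent columns.
#'
#' @param x,y numeric vectors (`y = NULL` for a one-sample test against 0).
#' @param paired logical.
#' @param auto_normality apply the Shapiro-Wilk gate (default `TRUE`); when
#'   `FALSE`, the t test is used.
#' @return a one-row stats tibble with extra columns `selected` and
#'   `normality_p`.
#' @export
compare_groups <- function(x, y = NULL, paired = FALSE, auto_normality = TRUE) {
  vals <- if (is.null(y)) list(x) else if (paired) list(x - y) else list(x, y)
  shap_p <- vapply(vals, function(v) {
    if (length(unique(v)) < 3) return(0)
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  normal <- all(shap_p > 0.05)
  use_t <- !auto_normality || normal
  if (use_t) {
    tt <- if (is.null(y)) stats::t.test(x, mu = 0) else stats::t.test(x, y, paired = paired)
    out <- stat_result(if (paired) "paired_t" else "t", tt$statistic, tt$p.value,
                       length(x), if (is.null(y)) NA else length(y))
    out$selected <- "t"
  } else if (is.null(y) || paired) {
    d <- if (is.null(y)) x else x - y
    out <- wilcoxon_signed_rank_vs_zero(d)
    out$selected <- "wilcoxon"
  } else {
    out <- mann_whitney(x, y)
    out$selected <- "mann_whitney"
  }
  out$normality_p <- min(shap_p)
  out
}

#' Write a stats table as CSV
#' @param results a tibble of stacked one-row results.
#' @param path CSV path.
#' @export
write_stats <- function(results, path) {
  readr::write_csv(results, path)
  invisible(path)
}
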