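# exact enumeration oracles for the rank tests ------------------------------

enum_signed_rank_p <- function(v) {
  n <- length(v)
  r <- rank(abs(v))
  v_obs <- sum(r[v > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  dist <- as.vector(signs %*% r)
  p_le <- mean(dist <= v_obs)
  p_ge <- mean(dist >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

enum_rank_sum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  dist <- apply(combos, 2, function(i) sum(r[i])) - nx * (nx + 1) / 2
  min(1, 2 * min(mean(dist <= w_obs), mean(dist >= w_obs)))
}

test_that("the signed-rank test against zero is exact for small samples", {
  v <- c(0.3, 0.5, 1.1, 0.2, 0.9, 0.7)
  res <- wilcoxon_signed_rank_vs_zero(v)
  expect_equal(res$p_value, 0.03125)
  expect_equal(res$p_value, enum_signed_rank_p(v))

  sym <- c(-2, 2, -0.5, 0.5)
  expect_equal(wilcoxon_signed_rank_vs_zero(sym)$p_value, 1)

  expect_error(wilcoxon_signed_rank_vs_zero(c(0, 0)), "zero")

  set.seed(14)
  for (i in 1:5) {
    v <- round(rnorm(15), 3)
    v <- v[v != 0]
    if (any(duplicated(abs(v)))) next
    expect_equal(wilcoxon_signed_rank_vs_zero(v)$p_value, enum_signed_rank_p(v),
                 tolerance = 1e-12)
  }
})

test_that("the rank-sum test is exact for small samples and near 1 for identical groups", {
  x <- c(1, 2, 3, 4); y <- c(10, 11, 12, 13)
  res <- mann_whitney(x, y)
  expect_equal(res$p_value, 2 / choose(8, 4), tolerance = 1e-10)
  expect_equal(res$p_value, enum_rank_sum_p(x, y))

  same <- c(1.2, 3.4, 2.2, 5.1)
  expect_gt(mann_whitney(same, same)$p_value, 0.95)

  set.seed(15)
  for (i in 1:5) {
    x <- round(rnorm(6), 3); y <- round(rnorm(6, 0.5), 3)
    if (any(duplicated(c(x, y)))) next
    expect_equal(mann_whitney(x, y)$p_value, enum_rank_sum_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("the variance F test doubles the upper tail with per-sample df", {
  x <- rnorm(10); y <- x
  expect_equal(variance_f_test(x, y)$statistic, 1)

  set.seed(6)
  x <- scale(rnorm(20))[, 1] * 2   # variance exactly 4
  y <- scale(rnorm(19))[, 1]       # variance exactly 1
  res <- variance_f_test(x, y)
  expect_equal(res$statistic, 4)
  expect_equal(res$dfn, 19L)
  expect_equal(res$dfd, 18L)
  expect_equal(res$p_value, 2 * pf(4, 19, 18, lower.tail = FALSE))

  # published convention check: F = 2.879 with dfn 19, dfd 18 gives p ~ 0.029
  expect_equal(round(2 * pf(2.879, 19, 18, lower.tail = FALSE), 3), 0.029)
})

test_that("repeated-measures ANOVA matches a hand sum-of-squares decomposition", {
  m <- rbind(c(0.1, 0.5, 0.2),
             c(0.0, 0.4, 0.1),
             c(0.2, 0.7, 0.3),
             c(-0.1, 0.3, 0.0),
             c(0.1, 0.6, 0.2))
  colnames(m) <- c("baseline", "loom", "post")
  res <- rm_anova_epochs(m)

  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_epoch <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_epoch - ss_subj
  f_hand <- (ss_epoch / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
  expect_equal(res$omnibus$statistic, f_hand, tolerance = 1e-10)
  expect_equal(res$omnibus$p_value,
               pf(f_hand, k - 1, (n - 1) * (k - 1), lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(nrow(res$posthoc), 3)

  # epochs identical within trials: no epoch effect
  flat <- matrix(rep(c(1, 2, 3, 4), 3), ncol = 3)
  res_flat <- rm_anova_epochs(flat)
  expect_equal(res_flat$omnibus$statistic, 0)
  expect_equal(res_flat$omnibus$p_value, 1)
})

test_that("a large epoch shift is detected decisively", {
  set.seed(20)
  n <- 15
  base <- rnorm(n, 0, 0.1)
  m <- cbind(baseline = base, loom = base + 1 + rnorm(n, 0, 0.1),
             post = base + rnorm(n, 0, 0.1))
  res <- rm_anova_epochs(m)
  expect_lt(res$omnibus$p_value, 1e-6)
  expect_true(res$posthoc$rejected[res$posthoc$contrast == "baseline vs loom"])
})

# literal, independently coded two-stage step-up reference
bky_oracle <- function(p, alpha = 0.05) {
  m <- length(p)
  bh_reject <- function(p, q) {
    o <- order(p); k <- 0
    for (i in seq_len(m)) if (p[o][i] <= i * q / m) k <- i
    if (k == 0) integer(0) else o[seq_len(k)]
  }
  q1 <- alpha / (1 + alpha)
  r1 <- length(bh_reject(p, q1))
  if (r1 == 0) return(integer(0))
  if (r1 == m) return(seq_len(m))
  sort(bh_reject(p, q1 * m / (m - r1)))
}

test_that("two-stage FDR matches an independent implementation", {
  expect_true(bky_fdr(0.01, 0.05)$rejected)
  allnull <- bky_fdr(rep(1, 6), 0.05)
  expect_false(any(allnull$rejected))
  expect_equal(attr(allnull, "m0"), 6L)

  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  res <- bky_fdr(p, 0.05)
  expect_equal(which(res$rejected), bky_oracle(p, 0.05))

  set.seed(30)
  for (i in 1:25) {
    p <- runif(sample(3:12, 1))^sample(1:3, 1)
    res <- bky_fdr(p, 0.05)
    expect_equal(sort(which(res$rejected)), bky_oracle(p, 0.05))
    expect_equal(res$rejected, res$q_value <= 0.05 + 1e-12, ignore_attr = TRUE)
  }
})

test_that("lowering a p-value never shrinks the two-stage rejection set", {
  set.seed(31)
  for (i in 1:20) {
    p <- runif(8)
    base_rej <- which(bky_fdr(p, 0.05)$rejected)
    j <- sample(8, 1)
    p2 <- p; p2[j] <- p[j] * runif(1)
    new_rej <- which(bky_fdr(p2, 0.05)$rejected)
    expect_true(all(setdiff(base_rej, j) %in% union(new_rej, j)))
    expect_gte(length(new_rej), length(base_rej) - 1)
  }
})

test_that("robust outlier removal flags gross outliers and spares clean data", {
  res <- rout_outliers(c(1, 1.1, 0.9, 50), Q = 0.01)
  expect_equal(res$removed, 50)
  expect_equal(sort(res$kept), c(0.9, 1, 1.1))

  res3 <- rout_outliers(rep(2, 3))
  expect_equal(length(res3$removed), 0)

  expect_warning(rout_outliers(c(1, 2)), "fewer than 3")
})

test_that("two-way ANOVA matches hand-computed sums of squares on a balanced toy", {
  # balanced 2x2, n = 3 per cell
  a <- rep(c("f", "m"), each = 6)
  b <- rep(rep(c("fam", "unf"), each = 3), 2)
  y <- c(1, 2, 3, 4, 5, 6, 2, 3, 4, 8, 9, 10)
  res <- two_way_anova(y, a, b)

  cell_means <- tapply(y, list(a, b), mean)
  ga <- tapply(y, a, mean); gb <- tapply(y, b, mean); g <- mean(y)
  ss_a <- 6 * sum((ga - g)^2)
  ss_b <- 6 * sum((gb - g)^2)
  ss_ab <- 3 * sum((cell_means - outer(ga, gb, `+`) + g)^2)
  ss_err <- sum((y - cell_means[cbind(a, b)])^2)
  eff <- res$effects
  expect_equal(eff$sum_sq[eff$term == "a"], ss_a, tolerance = 1e-10)
  expect_equal(eff$sum_sq[eff$term == "b"], ss_b, tolerance = 1e-10)
  expect_equal(eff$sum_sq[eff$term == "a:b"], ss_ab, tolerance = 1e-10)
  f_a <- (ss_a / 1) / (ss_err / 8)
  expect_equal(eff$statistic[eff$term == "a"], f_a, tolerance = 1e-10)

  # exactly additive data: interaction sum of squares vanishes
  y_add <- outer(c(0, 1), c(0, 2), `+`)[cbind(match(a, c("f", "m")),
                                              match(b, c("fam", "unf")))] +
    rep(c(-0.1, 0, 0.1), 4)
  res_add <- two_way_anova(y_add, a, b)
  expect_lt(res_add$effects$sum_sq[res_add$effects$term == "a:b"], 1e-20)

  expect_error(two_way_anova(y[1:9], a[1:9], b[1:9]), "empty")
})

test_that("chi-square on count tables is Pearson without correction", {
  same <- rbind(c(10, 5, 5), c(10, 5, 5))
  res <- chi_square_counts(same)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  looming <- rbind(c(29, 9, 10), c(19, 11, 6))
  p <- chi_square_counts(looming)$p_value
  expect_gt(p, 0.4); expect_lt(p, 0.5)

  tw <- rbind(c(12, 5), c(7, 9))
  res2 <- chi_square_counts(tw)
  n <- sum(tw)
  chi_closed <- n * (tw[1, 1] * tw[2, 2] - tw[1, 2] * tw[2, 1])^2 /
    (sum(tw[1, ]) * sum(tw[2, ]) * sum(tw[, 1]) * sum(tw[, 2]))
  expect_equal(res2$statistic, chi_closed, tolerance = 1e-12)

  expect_error(chi_square_counts(rbind(c(0, 0), c(1, 2))), "marginal")
})

test_that("the normality gate picks the right test", {
  set.seed(40)
  xn <- rnorm(20); yn <- rnorm(20)
  expect_equal(compare_groups(xn, yn)$selected, "t")
  xs <- rexp(20)^3
  ys <- rexp(20)^3
  expect_equal(compare_groups(xs, ys)$selected, "mann_whitney")
  expect_equal(compare_groups(xs, ys, paired = TRUE)$selected, "wilcoxon")
  expect_equal(compare_groups(xs, ys, auto_normality = FALSE)$selected, "t")
})
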