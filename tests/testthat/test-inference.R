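simulateCell <- function(n_per_cell = 18, means = NULL, seed = 1) {
  set.seed(seed)
  A <- rep(c("SAL", "VPA"), each = 3 * n_per_cell)
  B <- rep(rep(c("ST", "UE", "PE"), each = n_per_cell), 2)
  mu <- if (is.null(means)) 0 else means[paste(A, B)]
  list(y = rnorm(length(A)) + mu, A = A, B = B)
}

test_that("two-way ANOVA is invariant to translation and has null structure", {
  d <- simulateCell(seed = 2)
  t1 <- twoWayAnova(d$y, d$A, d$B)
  t2 <- twoWayAnova(d$y + 100, d$A, d$B)
  expect_equal(t1$F, t2$F)
  expect_equal(t1$p, t2$p)
  expect_equal(sum(t1$df), length(d$y) - 1)
  # equal cell means, shrinking noise: effect SS vanish
  means <- setNames(rep(5, 6), c(outer(c("SAL", "VPA"), c("ST", "UE", "PE"), paste)))
  for (noise in c(1, 0.01)) {
    set.seed(3)
    y <- 5 + rnorm(108) * noise
    tt <- twoWayAnova(y, d$A, d$B)
    expect_lt(sum(tt$ss[1:3]), 3 * noise^2 * 30)
  }
})

test_that("type III sums of squares match the least-squares projection oracle", {
  set.seed(5)
  for (i in 1:10) {
    n_cell <- sample(3:9, 6, replace = TRUE)
    A <- rep(rep(c("SAL", "VPA"), each = 3), n_cell)
    B <- rep(rep(c("ST", "UE", "PE"), 2), n_cell)
    y <- rnorm(length(A), mean = as.numeric(factor(paste(A, B))))
    got <- twoWayAnova(y, A, B)
    ref <- type3Oracle(y, A, B)
    expect_equal(got$ss[1:3], ref$ss, tolerance = 1e-8)
    expect_equal(got$ss[4], ref$residual, tolerance = 1e-8)
    expect_equal(got$df, c(ref$df, ref$df_res))
    F_ref <- (ref$ss / ref$df) / (ref$residual / ref$df_res)
    expect_equal(got$F[1:3], F_ref, tolerance = 1e-8)
  }
})

test_that("empty or tiny cells are rejected", {
  d <- simulateCell(seed = 7)
  drop <- !(d$A == "VPA" & d$B == "PE")
  expect_error(twoWayAnova(d$y[drop], d$A[drop], d$B[drop]), "empty")
  one <- c(which(d$A == "VPA" & d$B == "PE")[1], which(!(d$A == "VPA" & d$B == "PE")))
  expect_error(twoWayAnova(d$y[one], d$A[one], d$B[one]), "at least 2")
})

test_that("one-way ANOVA reduces to the squared pooled t with two groups", {
  set.seed(11)
  y <- rnorm(30); g <- rep(c("a", "b"), 15)
  ow <- oneWayAnova(y, g)
  tt <- t.test(y[g == "a"], y[g == "b"], var.equal = TRUE)
  expect_equal(ow$F[1], unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(ow$p[1], tt$p.value, tolerance = 1e-10)
  # SS projection oracle with 3 groups
  g3 <- rep(c("ST", "UE", "PE"), each = 10)
  y3 <- rnorm(30, as.numeric(factor(g3)))
  ow3 <- oneWayAnova(y3, g3)
  fit <- lm(y3 ~ factor(g3))
  expect_equal(ow3$ss[2], sum(resid(fit)^2))
  expect_equal(ow3$ss[1], sum((y3 - mean(y3))^2) - sum(resid(fit)^2))
})

test_that("Welch's t matches the hand-computed formula and is antisymmetric", {
  x <- c(5.1, 4.8, 6.0, 5.5, 4.9)
  y <- c(3.2, 7.8, 1.1, 9.0, 4.4, 6.6)
  got <- welchT(x, y)
  ref <- welchOracle(x, y)
  expect_equal(got$statistic, ref$t, tolerance = 1e-12)
  expect_equal(got$df, ref$df, tolerance = 1e-12)
  expect_equal(got$p_raw, ref$p, tolerance = 1e-12)

  swapped <- welchT(y, x)
  expect_equal(swapped$statistic, -got$statistic)
  expect_equal(swapped$p_raw, got$p_raw)

  same <- welchT(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_raw, 1)
  expect_error(welchT(c(1, 1), c(1, 1)), "zero variance")
})

test_that("variance F-test doubles the smaller tail in the argument order", {
  x <- c(1, 2, 3, 4); y <- c(11, 12, 13, 14)  # equal variances
  got <- varianceFTest(x, y)
  expect_equal(got$F, 1)
  expect_equal(got$p, 1)
  set.seed(13)
  x <- rnorm(18, sd = 3); y <- rnorm(21)
  got <- varianceFTest(x, y)
  expect_equal(got$F, var(x) / var(y))
  expect_equal(got$df1, 17)
  expect_equal(got$df2, 20)
  # numerically integrated F-density oracle for the two-sided p
  dens_tail <- integrate(df, got$F, Inf, df1 = 17, df2 = 20)$value
  dens_low <- integrate(df, 0, got$F, df1 = 17, df2 = 20)$value
  expect_equal(got$p, min(1, 2 * min(dens_tail, dens_low)), tolerance = 1e-4)
})

test_that("the printed variance ratio yields its published two-sided p", {
  # F(17, 17) = 5.57 -> p = 0.0009 to one significant figure
  p <- 2 * min(pf(5.57, 17, 17), pf(5.57, 17, 17, lower.tail = FALSE))
  expect_equal(signif(p, 1), 9e-4)
})

test_that("pairwise comparisons apply Welch only where variances differ", {
  set.seed(17)
  n <- 18
  pre <- rep(rep(c("SAL", "VPA"), each = n), 3)
  env <- rep(c("ST", "UE", "PE"), each = 2 * n)
  y <- rnorm(length(pre))
  # 5-fold variance ratio (sd ratio sqrt(5) gives F = 5) only in PE
  y[pre == "VPA" & env == "PE"] <- rnorm(n, sd = sqrt(8))
  res <- bonferroniPairwise(y, pre, env)
  expect_equal(nrow(res), 3)
  expect_true(res$welch_applied[res$environment == "PE"])
  expect_false(any(res$welch_applied[res$environment != "PE"]))
  expect_equal(res$p_adjusted, pmin(1, 3 * res$p_raw))
  expect_true(all(res$p_adjusted >= res$p_raw))
  expect_true(all(res$p_adjusted <= 1))
})

test_that("identical groups produce t = 0 and adjusted p = 1 everywhere", {
  base <- rnorm(18, 5)
  pre <- rep(rep(c("SAL", "VPA"), each = 18), 3)
  env <- rep(c("ST", "UE", "PE"), each = 36)
  y <- rep(base, 6)
  res <- bonferroniPairwise(y, pre, env)
  expect_equal(res$statistic, rep(0, 3))
  expect_equal(res$p_adjusted, rep(1, 3))
})

test_that("groups below n = 2 are skipped with a warning", {
  pre <- c("SAL", "SAL", "VPA", rep(c("SAL", "VPA"), each = 4))
  env <- c(rep("ST", 3), rep("UE", 8))
  y <- rnorm(11)
  expect_warning(res <- bonferroniPairwise(y, pre, env), "ST")
  expect_equal(res$environment, "UE")
})

test_that("Spearman's rho is the Pearson correlation of mean ranks", {
  expect_equal(spearmanRho(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearmanRho(1:10, -(1:10))$rho, -1)
  # tied data against an explicit rank-then-Pearson oracle
  x <- c(1, 2, 2, 3, 4, 4, 4, 5)
  y <- c(2, 1, 3, 3, 5, 4, 6, 7)
  got <- spearmanRho(x, y)
  expect_equal(got$rho, cor(rank(x), rank(y)))
  expect_error(spearmanRho(rep(1, 6), 1:6), "constant")
  expect_error(spearmanRho(1:3, 3:1), "4 complete pairs")
})
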