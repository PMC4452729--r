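#' Two-way factorial ANOVA (type III, sum-to-zero coding)
#'
#' Fits \code{values ~ A * B} with sum-to-zero factor contrasts and
#' returns type III sums of squares, the partitioning appropriate for
#' the unbalanced 2x3 design (one cell has n = 17) when main effects
#' are reported in the presence of an interaction. F for each term is
#' its mean square over the residual mean square.
#'
#' @param values numeric response.
#' @param factorA,factorB factors (e.g. prenatal group and rearing
#'   environment); coerced to factor.
#' @return data.frame with one row per term (\code{factorA},
#'   \code{factorB}, \code{interaction}, \code{residual}): \code{ss},
#'   \code{df}, \code{F}, \code{p}.
#' @examples
#' cohort <- simulateCohort(defaultCohortConfig(seed = 2))
#' m <- measureData(cohort)
#' twoWayAnova(m[, "freezing_training_pct"], prenatalGroup(cohort),
#'             rearingEnv(cohort))
#' @export
twoWayAnova <- function(values, factorA, factorB) {
  A <- droplevels(factor(factorA)); B <- droplevels(factor(factorB))
  ok <- !is.na(values) & !is.na(A) & !is.na(B)
  values <- values[ok]; A <- droplevels(A[ok]); B <- droplevels(B[ok])
  cell_n <- table(A, B)
  if (any(cell_n == 0)) stop("empty design cell(s): ",
                             paste(which(cell_n == 0), collapse = ", "))
  if (any(cell_n < 2)) stop("every cell needs at least 2 observations")
  fit <- stats::lm(values ~ A * B,
                   contrasts = list(A = "contr.sum", B = "contr.sum"))
  aov3 <- car::Anova(fit, type = 3)
  rn <- rownames(aov3)
  pick <- function(term) which(rn == term)
  out <- data.frame(
    term = c("factorA", "factorB", "interaction", "residual"),
    ss = aov3[c(pick("A"), pick("B"), pick("A:B"), pick("Residuals")), "Sum Sq"],
    df = aov3[c(pick("A"), pick("B"), pick("A:B"), pick("Residuals")), "Df"],
    F = c(aov3[c(pick("A"), pick("B"), pick("A:B")), "F value"], NA),
    p = c(aov3[c(pick("A"), pick("B"), pick("A:B")), "Pr(>F)"], NA),
    row.names = NULL)
  stopifnot(sum(out$df) == length(values) - 1)
  out
}

#' One-way ANOVA
#'
#' Standard single-factor decomposition (e.g. environment effects on
#' protein levels within a prenatal group).
#'
#' @param values numeric response.
#' @param group factor.
#' @return data.frame with rows \code{group} and \code{residual}:
#'   \code{ss}, \code{df}, \code{F}, \code{p}.
#' @export
oneWayAnova <- function(values, group) {
  g <- droplevels(factor(group))
  ok <- !is.na(values) & !is.na(g)
  values <- values[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs at least 2 observations")
  tab <- stats::anova(stats::lm(values ~ g))
  data.frame(term = c("group", "residual"),
             ss = tab[, "Sum Sq"], df = tab[, "Df"],
             F = c(tab[1, "F value"], NA), p = c(tab[1, "Pr(>F)"], NA),
             row.names = NULL)
}

#' Welch's unequal-variance t-test
#'
#' Two-sided two-sample t-test with the Welch-Satterthwaite degrees of
#' freedom.
#'
#' @param x,y numeric samples (each n >= 2).
#' @param groups labels for the two samples (reporting only).
#' @return one-row data.frame: \code{group1}, \code{group2},
#'   \code{statistic}, \code{df}, \code{p_raw}, \code{p_adjusted},
#'   \code{correction}, \code{welch_applied}.
#' @export
welchT <- function(x, y, groups = c("x", "y")) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) stop("both samples need n >= 2")
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("zero variance in both samples")
  ht <- stats::t.test(x, y, var.equal = FALSE)
  data.frame(group1 = groups[1], group2 = groups[2],
             statistic = unname(ht$statistic), df = unname(ht$parameter),
             p_raw = ht$p.value, p_adjusted = ht$p.value,
             correction = "none", welch_applied = TRUE)
}

#' Two-sided F-test for equality of variances
#'
#' \eqn{F = s_x^2 / s_y^2} in the order given, with degrees of freedom
#' \eqn{(n_x - 1, n_y - 1)}; the two-sided p doubles the smaller tail,
#' capped at 1.
#'
#' @param x,y numeric samples (each n >= 2, positive variance).
#' @return one-row data.frame: \code{F}, \code{df1}, \code{df2},
#'   \code{p}.
#' @examples
#' # at F(17, 17) = 5.57 the two-sided p is about 0.0009
#' @export
varianceFTest <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) stop("both samples need n >= 2")
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("zero variance sample")
  ht <- stats::var.test(x, y)
  data.frame(F = unname(ht$statistic), df1 = unname(ht$parameter[1]),
             df2 = unname(ht$parameter[2]), p = ht$p.value)
}

#' Bonferroni-corrected within-environment pairwise comparisons
#'
#' The post-hoc scheme for the 2x3 design: for each environment, an
#' independent two-sample t-test of SAL vs VPA (not a pooled-error
#' contrast). Welch's correction is applied automatically for a
#' comparison whose variance F-test has p < 0.05; otherwise the pooled
#' (equal-variance) t is used. Raw p-values are Bonferroni-adjusted by
#' the number of comparisons performed (\eqn{p_{adj} = \min(1, m p)}).
#'
#' @param values numeric response.
#' @param prenatal SAL/VPA labels.
#' @param environment ST/UE/PE labels.
#' @param alpha significance level of the variance-test trigger for
#'   Welch's correction (default 0.05).
#' @return data.frame, one row per environment, with the
#'   \code{\link{welchT}} columns plus \code{environment},
#'   \code{var_F_p} and \code{correction = "bonferroni"}. Environments
#'   where either group has n < 2 are skipped with a warning.
#' @export
bonferroniPairwise <- function(values, prenatal, environment, alpha = 0.05) {
  env <- droplevels(factor(environment, levels = ENVIRONMENT_LEVELS))
  pre <- factor(prenatal, levels = PRENATAL_LEVELS)
  rows <- list()
  for (e in levels(env)) {
    x <- values[pre == "SAL" & env == e & !is.na(values)]
    y <- values[pre == "VPA" & env == e & !is.na(values)]
    if (length(x) < 2 || length(y) < 2) {
      warning("environment ", e, ": group with n < 2, comparison skipped")
      next
    }
    vt <- varianceFTest(x, y)
    welch <- vt$p < alpha
    ht <- stats::t.test(x, y, var.equal = !welch)
    rows[[e]] <- data.frame(
      environment = e, group1 = "SAL", group2 = "VPA",
      statistic = unname(ht$statistic), df = unname(ht$parameter),
      p_raw = ht$p.value, var_F_p = vt$p, welch_applied = welch)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no comparable environments")
  m <- nrow(out)
  out$p_adjusted <- pmin(1, m * out$p_raw)
  out$correction <- "bonferroni"
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties receive mean
#' ranks), with a two-sided p from the t approximation — the form used
#' to relate the emotionality score to protein expression.
#'
#' @param x,y numeric vectors; pairwise-complete cases are used
#'   (n >= 4 required).
#' @return list with \code{rho} and \code{p}.
#' @export
spearmanRho <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: rank correlation undefined")
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ht$estimate), p = ht$p.value)
}
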