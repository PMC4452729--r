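#' Fisher's exact test for a 2x2 table
#'
#' Conditional hypergeometric test; the two-sided p-value sums the
#' probabilities of all tables with the observed margins whose point
#' probability does not exceed that of the observed table (the
#' minimum-likelihood rule). Rows are groups: \code{cbind(events,
#' non-events)}.
#'
#' @param table 2x2 matrix of nonnegative integers.
#' @return data.frame: \code{method}, \code{p_two_sided},
#'   \code{statistic} (NA for Fisher), \code{pi_sup} (NA for Fisher).
#' @examples
#' # pooled Y-maze perseveration, 10/53 exposed vs 2/54 control
#' fisherExact(matrix(c(10, 43, 2, 52), 2, byrow = TRUE))
#' @export
fisherExact <- function(table) {
  table <- checkTable(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("a margin is zero; p = 1 by convention")
    return(data.frame(method = "fisher", p_two_sided = 1,
                      statistic = NA_real_, pi_sup = NA_real_))
  }
  p <- stats::fisher.test(table)$p.value
  data.frame(method = "fisher", p_two_sided = min(1, p),
             statistic = NA_real_, pi_sup = NA_real_)
}

checkTable <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2) || any(table < 0) || any(table != round(table)))
    stop("need a 2x2 table of nonnegative integers")
  storage.mode(table) <- "integer"
  table
}

barnardT <- function(x1, x2, n1, n2) {
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  t <- (p1 - p2) / se
  t[!is.finite(t)] <- 0   # pooled proportion 0 or 1: no evidence either way
  t
}

#' Barnard's unconditional exact test for a 2x2 table
#'
#' Unconditional test treating the two group sizes as fixed and the
#' common success probability \eqn{\pi} as a nuisance parameter. The
#' statistic is the pooled-proportion Wald score
#' \deqn{T = (\hat p_1 - \hat p_2) / \sqrt{\hat p (1-\hat p)(1/n_1 + 1/n_2)}}
#' and the two-sided p-value is the supremum over \eqn{\pi} on a
#' uniform grid of the probability, under independent binomials, of all
#' tables at the same group sizes with \eqn{|T| \ge |T_{obs}|}. The
#' maximizing \eqn{\pi} is reported.
#'
#' @param table 2x2 matrix of nonnegative integers, rows = groups
#'   (events, non-events); group sizes are the row sums.
#' @param grid_step spacing of the nuisance grid on (0, 1)
#'   (default 0.001).
#' @return data.frame: \code{method}, \code{p_two_sided},
#'   \code{statistic} (the observed T), \code{pi_sup} (the nuisance
#'   value attaining the supremum).
#' @examples
#' barnardExact(matrix(c(3, 15, 0, 18), 2, byrow = TRUE))
#' @export
barnardExact <- function(table, grid_step = 0.001) {
  table <- checkTable(table)
  n1 <- sum(table[1, ]); n2 <- sum(table[2, ])
  if (n1 == 0 || n2 == 0) stop("both group sizes must be positive")
  x1 <- table[1, 1]; x2 <- table[2, 1]
  t_obs <- barnardT(x1, x2, n1, n2)
  if (x1 + x2 == 0 || x1 + x2 == n1 + n2)
    return(data.frame(method = "barnard", p_two_sided = 1,
                      statistic = 0, pi_sup = NA_real_))
  grid <- seq(grid_step, 1 - grid_step, by = grid_step)
  allT <- abs(outer(0:n1, 0:n2, barnardT, n1 = n1, n2 = n2))
  extreme <- which(allT >= abs(t_obs) - 1e-12, arr.ind = TRUE)
  k1 <- extreme[, 1] - 1L; k2 <- extreme[, 2] - 1L
  # P(table) = dbinom(k1; n1, pi) * dbinom(k2; n2, pi), summed over the
  # extreme region, evaluated on the whole grid at once
  d1 <- matrix(vapply(grid, function(p) stats::dbinom(k1, n1, p),
                      numeric(length(k1))), nrow = length(k1))
  d2 <- matrix(vapply(grid, function(p) stats::dbinom(k2, n2, p),
                      numeric(length(k2))), nrow = length(k2))
  pvals <- colSums(d1 * d2)
  i <- which.max(pvals)
  data.frame(method = "barnard", p_two_sided = min(1, pvals[i]),
             statistic = t_obs, pi_sup = grid[i])
}
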