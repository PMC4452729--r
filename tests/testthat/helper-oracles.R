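# Independent brute-force oracles. These re-derive each quantity from first
# principles (coordinates, enumeration, dense grids, explicit least squares)
# and deliberately share no code with the package implementation.

# Greedy Ward agglomeration recomputing within-cluster SS from coordinates
# at every step; returns the merge heights (SS increases) in order.
wardGreedyOracle <- function(X) {
  ss <- function(idx) {
    M <- X[idx, , drop = FALSE]
    sum(sweep(M, 2, colMeans(M))^2)
  }
  groups <- as.list(seq_len(nrow(X)))
  heights <- numeric(0)
  while (length(groups) > 1) {
    best <- NULL
    for (i in 1:(length(groups) - 1)) for (j in (i + 1):length(groups)) {
      d <- ss(c(groups[[i]], groups[[j]])) - ss(groups[[i]]) - ss(groups[[j]])
      if (is.null(best) || d < best$d) best <- list(i = i, j = j, d = d)
    }
    heights <- c(heights, best$d)
    groups[[best$i]] <- c(groups[[best$i]], groups[[best$j]])
    groups[[best$j]] <- NULL
  }
  heights
}

# Two-sided Fisher p by explicit enumeration of all tables with the observed
# margins, summing point probabilities <= that of the observed table
# (minimum-likelihood rule, with the conventional relative tolerance).
fisherEnumOracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  xs <- max(0, c1 - r2):min(r1, c1)
  prob <- function(x) exp(lchoose(r1, x) + lchoose(r2, c1 - x) -
                            lchoose(r1 + r2, c1))
  p_obs <- prob(a)
  sum(vapply(xs, prob, 0)[vapply(xs, prob, 0) <= p_obs * (1 + 1e-7)])
}

# Barnard p via a dense nuisance grid, recomputed with an explicit double
# loop over all tables at the observed group sizes.
barnardGridOracle <- function(tab, step = 1e-4) {
  n1 <- sum(tab[1, ]); n2 <- sum(tab[2, ])
  wald <- function(x1, x2) {
    pp <- (x1 + x2) / (n1 + n2)
    se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    t <- (x1 / n1 - x2 / n2) / se
    if (!is.finite(t)) 0 else t
  }
  t_obs <- abs(wald(tab[1, 1], tab[2, 1]))
  ext <- NULL
  for (x1 in 0:n1) for (x2 in 0:n2)
    if (abs(wald(x1, x2)) >= t_obs - 1e-12) ext <- rbind(ext, c(x1, x2))
  best <- 0
  for (p in seq(step, 1 - step, by = step)) {
    tot <- sum(dbinom(ext[, 1], n1, p) * dbinom(ext[, 2], n2, p))
    if (tot > best) best <- tot
  }
  min(1, best)
}

# Type III sums of squares by explicit least-squares model comparison:
# for each term, RSS of the full sum-to-zero-coded model vs the model
# with that term's columns removed (all other columns retained).
type3Oracle <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  mm <- model.matrix(~ A * B,
                     contrasts.arg = list(A = "contr.sum", B = "contr.sum"))
  asg <- attr(mm, "assign")  # 0 intercept, 1 A, 2 B, 3 A:B
  rss <- function(Xm) {
    fit <- lm.fit(Xm, y)
    sum(fit$residuals^2)
  }
  full <- rss(mm)
  ss <- vapply(1:3, function(term) rss(mm[, asg != term, drop = FALSE]) - full,
               numeric(1))
  list(ss = ss, residual = full,
       df = c(nlevels(A) - 1, nlevels(B) - 1,
              (nlevels(A) - 1) * (nlevels(B) - 1)),
       df_res = length(y) - ncol(mm))
}

# Welch statistic, df and p from the textbook formulas.
welchOracle <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
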