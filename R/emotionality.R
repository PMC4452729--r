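#' Pooled-cohort z-transformation with scale orientation
#'
#' Standardizes every measure over the pooled cohort (all animals, both
#' prenatal groups and all environments): subtract the column mean and
#' divide by the sample standard deviation (denominator n - 1), then
#' negate columns whose catalog orientation is inverted, so that larger
#' z always means higher emotionality. Missing cells stay missing.
#'
#' @param x a \linkS4class{BehaviorCohort}, or an animals x measures
#'   numeric matrix.
#' @param inverted for the matrix method, logical per column (or column
#'   names to invert).
#' @param ... unused.
#' @return for a cohort, the cohort with an added \code{"z"} assay; for
#'   a matrix, the standardized oriented matrix.
#' @examples
#' zScore(matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "m")))
#' @rdname zScore
#' @export
setMethod("zScore", "matrix", function(x, inverted = NULL, ...) {
  if (is.character(inverted)) inverted <- colnames(x) %in% inverted
  if (is.null(inverted)) inverted <- rep(FALSE, ncol(x))
  z <- x
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    ok <- !is.na(v)
    if (sum(ok) < 2) stop("measure '", colnames(x)[j], "' has fewer than 2 values")
    s <- stats::sd(v[ok])
    if (!is.finite(s) || s == 0)
      stop("measure '", colnames(x)[j], "' has zero variance")
    z[, j] <- (v - mean(v[ok])) / s
    if (inverted[j]) z[, j] <- -z[, j]
  }
  z
})

#' @rdname zScore
#' @export
setMethod("zScore", "BehaviorCohort", function(x, ...) {
  cat <- measureCatalog(x)
  z <- zScore(measureData(x), inverted = cat$name[cat$inverted])
  SummarizedExperiment::assay(x, "z") <- t(z)
  x
})

#' Extract the standardized oriented matrix
#'
#' @param x a \linkS4class{BehaviorCohort} (after \code{\link{zScore}};
#'   computed on the fly otherwise).
#' @param ... unused.
#' @return animals x measures matrix of oriented z-values.
#' @rdname zMatrix
#' @export
setMethod("zMatrix", "BehaviorCohort", function(x, ...) {
  if (!"z" %in% SummarizedExperiment::assayNames(x)) x <- zScore(x)
  t(SummarizedExperiment::assay(x, "z"))
})

#' Standardized Cronbach's alpha from the mean inter-item correlation
#'
#' \deqn{\alpha = k \bar r / (1 + (k - 1) \bar r)}
#' the internal-consistency coefficient of a k-item scale whose items
#' have mean pairwise Pearson correlation \eqn{\bar r}. This is the
#' standardized form, the natural one for unit-variance z-scored items.
#'
#' @param r_bar mean inter-item correlation, in \eqn{(-1/(k-1), 1]}.
#' @param k number of items, >= 2.
#' @return alpha.
#' @examples
#' cronbachAlpha(0.335, 5)  # 0.716 to 3 decimals
#' @export
cronbachAlpha <- function(r_bar, k) {
  if (k < 2) stop("alpha needs at least 2 items")
  if (any(r_bar <= -1 / (k - 1)))
    stop("r_bar at or below -1/(k-1): alpha undefined")
  k * r_bar / (1 + (k - 1) * r_bar)
}

pairwiseCor <- function(Z) {
  R <- stats::cor(Z, use = "pairwise.complete.obs")
  bad <- which(is.na(R) & upper.tri(R), arr.ind = TRUE)
  if (nrow(bad))
    stop("undefined correlation for pair(s): ",
         paste(apply(bad, 1, function(ij)
           paste(colnames(Z)[ij], collapse = "~")), collapse = ", "))
  R
}

itemRestCor <- function(Z) {
  vapply(seq_len(ncol(Z)), function(j) {
    rest <- rowMeans(Z[, -j, drop = FALSE], na.rm = TRUE)
    stats::cor(Z[, j], rest, use = "pairwise.complete.obs")
  }, numeric(1))
}

#' Internal consistency of an item set
#'
#' Computes pairwise-complete Pearson correlations among the selected
#' (oriented z-scored) items, their mean off-diagonal correlation
#' \eqn{\bar r}, standardized Cronbach's alpha, and the minimum
#' item-rest correlation. A flag is raised when any pairwise correlation
#' falls below 0.28, the reporting floor used when judging that all
#' items cohere.
#'
#' @param x animals x measures z-matrix, or a
#'   \linkS4class{BehaviorCohort}.
#' @param items character, measure names (>= 2) to evaluate.
#' @param orientation optional named vector of +1/-1 applied to the
#'   items before evaluation (defaults to +1).
#' @param ... unused.
#' @return a \linkS4class{ConsistencyResult}.
#' @examples
#' Z <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, letters[1:4]))
#' consistency(Z, c("a", "b", "c"))
#' @rdname consistency
#' @export
setMethod("consistency", "matrix", function(x, items, orientation = NULL, ...) {
  stopifnot(length(items) >= 2, all(items %in% colnames(x)))
  Z <- x[, items, drop = FALSE]
  if (is.null(orientation)) orientation <- stats::setNames(rep(1, length(items)), items)
  Z <- sweep(Z, 2, orientation[items], "*")
  npair <- crossprod(!is.na(Z))
  bad <- which(npair < 3 & upper.tri(npair), arr.ind = TRUE)
  if (nrow(bad))
    stop("fewer than 3 pairwise-complete observations for pair(s): ",
         paste(apply(bad, 1, function(ij)
           paste(colnames(Z)[ij], collapse = "~")), collapse = ", "))
  R <- pairwiseCor(Z)
  r_bar <- mean(R[upper.tri(R)])
  methods::new("ConsistencyResult", items = items, rMatrix = R, rBar = r_bar,
               alpha = cronbachAlpha(r_bar, length(items)),
               minItemTotalR = min(itemRestCor(Z)),
               orientation = orientation[items],
               lowPairFlag = any(R[upper.tri(R)] < 0.28))
})

#' @rdname consistency
#' @export
setMethod("consistency", "BehaviorCohort", function(x, items, ...) {
  consistency(zMatrix(x), items, ...)
})

# Orientation making all item-rest correlations positive, when one exists:
# start from the sign of the leading eigenvector of the correlation matrix,
# then greedily flip items with negative item-rest correlation.
orientItems <- function(R) {
  k <- ncol(R)
  s <- sign(eigen(R, symmetric = TRUE)$vectors[, 1])
  s[s == 0] <- 1
  if (sum(s) < 0) s <- -s
  for (iter in seq_len(2 * k)) {
    Rs <- R * tcrossprod(s)
    item_rest <- rowSums(Rs) - 1
    if (all(item_rest > 0)) break
    worst <- which.min(item_rest)
    s[worst] <- -s[worst]
  }
  stats::setNames(s, colnames(R))
}

#' Exhaustive internal-consistency item selection
#'
#' Enumerates every subset of the candidate measures of size >=
#' \code{min_size}, chooses for each subset an orientation making all
#' item-rest correlations positive when such an orientation exists (on
#' top of the a priori catalog orientation), and returns the subset with
#' maximal standardized Cronbach's alpha. Ties are broken in favor of
#' the larger subset, then lexicographic item names. A warning is issued
#' when no subset achieves alpha > 0.
#'
#' @param x animals x measures z-matrix (already catalog-oriented), or a
#'   \linkS4class{BehaviorCohort} (candidates then default to the
#'   catalog's \code{emotionality_candidate} measures).
#' @param candidates character, candidate measure names (at most 20; the
#'   search is exhaustive).
#' @param min_size smallest subset size considered (default 3).
#' @param ... unused.
#' @return a \linkS4class{ConsistencyResult} for the winning subset; its
#'   \code{orientation} slot records any data-driven sign flips.
#' @rdname selectItems
#' @export
setMethod("selectItems", "matrix", function(x, candidates, min_size = 3, ...) {
  stopifnot(all(candidates %in% colnames(x)))
  if (length(candidates) > 20) stop("exhaustive search limited to 20 candidates")
  if (length(candidates) < min_size) stop("fewer candidates than min_size")
  candidates <- sort(candidates)
  R_all <- pairwiseCor(x[, candidates, drop = FALSE])
  best <- NULL
  for (k in length(candidates):min_size) {
    sets <- utils::combn(candidates, k, simplify = FALSE)
    for (items in sets) {
      R <- R_all[items, items]
      s <- orientItems(R)
      Rs <- R * tcrossprod(s)
      r_bar <- mean(Rs[upper.tri(Rs)])
      if (r_bar <= -1 / (k - 1)) next
      a <- cronbachAlpha(r_bar, k)
      if (is.null(best) || a > best$alpha + 1e-12 ||
          (abs(a - best$alpha) <= 1e-12 && k > length(best$items)))
        best <- list(items = items, alpha = a, orientation = s)
    }
  }
  if (is.null(best)) stop("no admissible subset found")
  if (best$alpha <= 0)
    warning("no item subset reaches alpha > 0; returning the best found")
  consistency(x, best$items, orientation = best$orientation)
})

#' @rdname selectItems
#' @export
setMethod("selectItems", "BehaviorCohort", function(x, candidates = NULL,
                                                    min_size = 3, ...) {
  if (is.null(candidates)) {
    cat <- measureCatalog(x)
    candidates <- cat$name[cat$role == "emotionality_candidate"]
  }
  selectItems(zMatrix(x), candidates, min_size = min_size)
})

#' Composite emotionality score
#'
#' Per animal, the mean of the non-missing oriented z-values over the
#' selected items. The score is defined only when at least
#' \code{ceiling(k/2)} of the k item values are present; otherwise it is
#' missing.
#'
#' @param x animals x measures z-matrix, or a
#'   \linkS4class{BehaviorCohort}.
#' @param items character, the selected measures (or a
#'   \linkS4class{ConsistencyResult}, whose orientation is then applied).
#' @param ... unused.
#' @return named numeric vector of scores (one per animal).
#' @examples
#' cohort <- simulateCohort(defaultCohortConfig(seed = 3))
#' sel <- selectItems(cohort)
#' head(compositeScore(cohort, sel))
#' @rdname compositeScore
#' @export
setMethod("compositeScore", "matrix", function(x, items, ...) {
  orientation <- NULL
  if (methods::is(items, "ConsistencyResult")) {
    orientation <- items@orientation
    items <- items@items
  }
  stopifnot(all(items %in% colnames(x)))
  Z <- x[, items, drop = FALSE]
  if (!is.null(orientation)) Z <- sweep(Z, 2, orientation[items], "*")
  k <- length(items)
  n_ok <- rowSums(!is.na(Z))
  score <- rowMeans(Z, na.rm = TRUE)
  score[n_ok < ceiling(k / 2)] <- NA_real_
  score[n_ok == 0] <- NA_real_
  stats::setNames(score, rownames(x))
})

#' @rdname compositeScore
#' @export
setMethod("compositeScore", "BehaviorCohort", function(x, items, ...) {
  compositeScore(zMatrix(x), items)
})
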