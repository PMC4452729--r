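#' Squared Euclidean distance matrix over selected measures
#'
#' @param Z animals x measures matrix (typically oriented z-scores).
#' @param items measure names to use (default: all columns).
#' @return symmetric matrix of squared Euclidean distances, zero
#'   diagonal. Missing values among the selected columns are an error
#'   (exclude such animals first; \code{\link{clusterAnimals}} does so
#'   with a warning).
#' @export
distanceMatrix <- function(Z, items = NULL) {
  X <- if (is.null(items)) Z else {
    stopifnot(all(items %in% colnames(Z)))
    Z[, items, drop = FALSE]
  }
  if (nrow(X) < 3) stop("need at least 3 animals to cluster")
  if (anyNA(X)) stop("missing values among clustering measures")
  as.matrix(stats::dist(X))^2
}

#' Ward agglomerative linkage on squared Euclidean distances
#'
#' Iteratively merges the pair of clusters whose fusion minimally
#' increases the total within-cluster sum of squares, with dissimilarity
#' updates by the Lance-Williams recurrence for Ward's method applied to
#' squared Euclidean distances. Merge heights are the Ward objective
#' increases themselves (no square-root transform), so the heights sum
#' to the total sum of squares of the clustered data.
#'
#' @param D symmetric matrix of squared Euclidean distances (from
#'   \code{\link{distanceMatrix}}).
#' @return an \code{\link[stats]{hclust}} object; \code{$height} holds
#'   the (non-decreasing) Ward SS increases, and
#'   \code{$method = "ward-squared-euclidean"} records the convention.
#' @export
wardLinkage <- function(D) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(D < -1e-12)) stop("negative distances")
  # hclust ward.D on squared distances realizes the Lance-Williams Ward
  # recurrence; its heights equal twice the within-SS increase per merge
  hc <- stats::hclust(stats::as.dist(D), method = "ward.D")
  hc$height <- hc$height / 2
  if (any(diff(hc$height) < -1e-8)) stop("non-monotone merge heights")
  hc$height <- cummax(hc$height)  # absorb fp jitter only
  hc$method <- "ward-squared-euclidean"
  hc
}

romanLabels <- function(k) as.character(utils::as.roman(seq_len(k)))

#' Cut a Ward tree into k clusters ordered by emotionality
#'
#' Undoes the last k - 1 merges and relabels the resulting clusters
#' I..k by ascending cluster-mean composite emotionality score (ties
#' broken by larger cluster size).
#'
#' @param tree an \code{\link[stats]{hclust}} from
#'   \code{\link{wardLinkage}}.
#' @param k number of clusters.
#' @param scores named numeric composite scores covering all leaves.
#' @param Z optional animals x measures matrix (the clustering input) to
#'   compute within-cluster sums of squares.
#' @param group label stored with the solution (e.g. "SAL").
#' @return a \linkS4class{ClusterSolution}.
#' @export
cutClusters <- function(tree, k, scores, Z = NULL, group = "all") {
  stopifnot(inherits(tree, "hclust"), k >= 1, k <= length(tree$labels))
  raw <- stats::cutree(tree, k = k)
  ids <- names(raw)
  if (!all(ids %in% names(scores)))
    stop("every clustered animal needs a composite score")
  mean_score <- tapply(scores[ids], raw, mean, na.rm = TRUE)
  size <- table(raw)
  ord <- order(mean_score, -as.numeric(size))
  relabel <- stats::setNames(romanLabels(k), names(mean_score)[ord])
  labels <- factor(unname(relabel[as.character(raw)]), levels = romanLabels(k))
  names(labels) <- ids
  wss <- numeric(0)
  if (!is.null(Z)) {
    wss <- vapply(romanLabels(k), function(cl) {
      X <- Z[ids[labels == cl], , drop = FALSE]
      sum(sweep(X, 2, colMeans(X))^2)
    }, numeric(1))
  }
  methods::new("ClusterSolution", k = as.integer(k), labels = labels,
               scores = scores[ids], withinClusterSS = wss,
               tree = tree, group = group)
}

#' @rdname clusterLabels
#' @param x a \linkS4class{ClusterSolution}
#' @return factor of cluster labels named by animal id.
#' @export
setMethod("clusterLabels", "ClusterSolution", function(x) x@labels)

#' Merge-height diagnostics for choosing the number of clusters
#'
#' For each candidate solution size k, reports the height of the merge
#' that would fuse k clusters into k - 1 and the gap between that merge
#' and the previous one. A dominant gap at some k marks a parsimonious
#' solution: large, homogeneous clusters separated by long fusion
#' distances. A gap is flagged dominant when it exceeds the sum of all
#' other positive gaps in the reported range.
#'
#' @param tree an \code{\link[stats]{hclust}} from
#'   \code{\link{wardLinkage}}.
#' @param k_max largest k to report (default 10; limited by n).
#' @return data.frame with \code{k}, \code{merge_height} (fusing k into
#'   k - 1 clusters), \code{gap}, \code{dominant}.
#' @export
homogeneityDiagnostics <- function(tree, k_max = 10) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$labels)
  h <- c(0, tree$height)                   # h[m + 1] = height of merge m
  ks <- 2:min(k_max, n)
  merge_height <- h[n - ks + 2]            # merge n - k + 1 fuses k clusters
  gap <- merge_height - h[n - ks + 1]
  dominant <- vapply(seq_along(gap), function(i)
    gap[i] > 0 & gap[i] > sum(pmax(gap[-i], 0)), logical(1))
  data.frame(k = ks, merge_height = merge_height, gap = gap, dominant = dominant)
}

#' Cluster one prenatal group of a cohort
#'
#' Convenience wrapper running the per-group individual-differences
#' analysis: restricts the cohort to one prenatal group, drops animals
#' with missing values on the clustering items (with a warning), builds
#' squared Euclidean distances over the pooled-cohort z-scores (the
#' cohort is NOT re-standardized within group, so emotionality
#' magnitudes stay comparable across groups), applies Ward linkage and
#' cuts at k clusters ordered by composite score.
#'
#' @param cohort a \linkS4class{BehaviorCohort}.
#' @param items the clustering measures, as a character vector or a
#'   \linkS4class{ConsistencyResult} (default: the selected emotionality
#'   items).
#' @param group "SAL" or "VPA".
#' @param k number of clusters (default 4).
#' @return a \linkS4class{ClusterSolution}.
#' @examples
#' cohort <- simulateCohort(defaultCohortConfig(seed = 11))
#' sel <- selectItems(cohort)
#' clusterAnimals(cohort, sel, group = "VPA", k = 4)
#' @export
clusterAnimals <- function(cohort, items = NULL, group = c("SAL", "VPA"), k = 4) {
  group <- match.arg(group)
  if (is.null(items)) items <- selectItems(cohort)
  cons <- NULL
  if (methods::is(items, "ConsistencyResult")) { cons <- items; items <- cons@items }
  Z <- zMatrix(cohort)
  if (!is.null(cons)) Z <- sweep(Z, 2, ifelse(colnames(Z) %in%
      names(cons@orientation)[cons@orientation < 0], -1, 1), "*")
  keep <- prenatalGroup(cohort) == group
  Zg <- Z[keep, items, drop = FALSE]
  complete <- stats::complete.cases(Zg)
  if (any(!complete))
    warning(sum(!complete), " ", group,
            " animal(s) excluded for missing clustering measures")
  Zg <- Zg[complete, , drop = FALSE]
  scores <- compositeScore(Z, items)
  tree <- wardLinkage(distanceMatrix(Zg, items))
  cutClusters(tree, k, scores, Z = Zg, group = group)
}

#' Core and predicted cluster profiles
#'
#' Summarizes each cluster of a solution: size and percent of the group
#' (nearest integer), mean and s.e.m. of each clustering input measure
#' (oriented z-scale) and of the composite score ("core"), mean and
#' s.e.m. of held-out variables with pairwise deletion ("predicted"),
#' and the rearing-environment composition (proportions summing to 1).
#'
#' @param solution a \linkS4class{ClusterSolution}.
#' @param cohort the \linkS4class{BehaviorCohort} the solution came from.
#' @param predicted_vars measure names profiled without having entered
#'   the clustering (default: the catalog's predicted-only measures).
#' @param core_items clustering input measures (default: columns of the
#'   solution's input, inferred from the tree labels' measures is not
#'   possible, so pass what was clustered; defaults to the catalog's
#'   emotionality candidates).
#' @return tidy data.frame with columns \code{cluster}, \code{n},
#'   \code{percent}, \code{variable}, \code{type} (core / composite /
#'   predicted / environment), \code{mean}, \code{sem}. Percents use
#'   nearest-integer rounding; a \code{"rounding"} attribute records
#'   this convention.
#' @export
profileClusters <- function(solution, cohort, predicted_vars = NULL,
                            core_items = NULL) {
  cat <- measureCatalog(cohort)
  if (is.null(predicted_vars))
    predicted_vars <- cat$name[cat$role == "predicted_only"]
  if (is.null(core_items))
    core_items <- intersect(cat$name[cat$role == "emotionality_candidate"],
                            colnames(zMatrix(cohort)))
  labels <- clusterLabels(solution)
  ids <- names(labels)
  Z <- zMatrix(cohort)[ids, , drop = FALSE]
  raw <- measureData(cohort)[ids, , drop = FALSE]
  env <- stats::setNames(as.character(rearingEnv(cohort)), animalIds(cohort))[ids]
  n_group <- length(ids)
  rows <- list()
  for (cl in levels(labels)) {
    in_cl <- labels == cl
    n <- sum(in_cl)
    pct <- round(100 * n / n_group)
    add <- function(variable, type, m, s)
      data.frame(cluster = cl, n = n, percent = pct, variable = variable,
                 type = type, mean = m, sem = s)
    rows[[length(rows) + 1L]] <- do.call(rbind, c(
      lapply(core_items, function(v)
        add(v, "core", mean(Z[in_cl, v], na.rm = TRUE), sem(Z[in_cl, v]))),
      list(add("composite_score", "composite",
               mean(solution@scores[ids][in_cl], na.rm = TRUE),
               sem(solution@scores[ids][in_cl]))),
      lapply(predicted_vars, function(v)
        add(v, "predicted", mean(raw[in_cl, v], na.rm = TRUE), sem(raw[in_cl, v]))),
      lapply(ENVIRONMENT_LEVELS, function(e)
        add(e, "environment", mean(env[in_cl] == e), NA_real_))))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "rounding") <-
    "percent of group uses nearest-integer rounding of 100 * n / n_group"
  out
}

#' Export a Ward tree as Newick
#'
#' Writes the merge schedule as a Newick tree with the Ward merge
#' heights as node depths (branch lengths derived by \pkg{ape}).
#'
#' @param tree an \code{\link[stats]{hclust}} (or a
#'   \linkS4class{ClusterSolution}, whose tree is used).
#' @param path output file.
#' @return the \code{\link[ape]{phylo}} object, invisibly.
#' @export
exportNewick <- function(tree, path) {
  if (methods::is(tree, "ClusterSolution")) tree <- tree@tree
  stopifnot(inherits(tree, "hclust"))
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(phy)
}
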