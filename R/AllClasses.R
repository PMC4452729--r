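#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

PRENATAL_LEVELS <- c("SAL", "VPA")
ENVIRONMENT_LEVELS <- c("ST", "UE", "PE")
MEASURE_ROLES <- c("emotionality_candidate", "predicted_only")

#' BehaviorCohort: animals x behavioral measures with design metadata
#'
#' A \linkS4class{SummarizedExperiment} subclass holding one behavioral
#' cohort. The \code{"measures"} assay is a measures x animals numeric
#' matrix (missing values allowed); \code{colData} carries the design
#' factors (\code{animal_id}, \code{litter_id}, \code{prenatal} in
#' \{SAL, VPA\}, \code{environment} in \{ST, UE, PE\}), the binary
#' perseveration flag, and the biochemistry assay batch; \code{rowData}
#' is the measure catalog (\code{unit}, \code{inverted}, \code{role}).
#' After \code{\link{zScore}} a second assay \code{"z"} holds the
#' pooled-cohort standardized, orientation-aligned values.
#'
#' @slot .. inherited from SummarizedExperiment; no additional slots.
#' @seealso \code{\link{BehaviorCohort}}, \code{\link{readCohort}},
#'   \code{\link{simulateCohort}}
#' @export
setClass("BehaviorCohort", contains = "SummarizedExperiment")

setValidity("BehaviorCohort", function(object) {
  msgs <- character()
  if (!"measures" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'measures' is required")
  cd <- SummarizedExperiment::colData(object)
  for (col in c("animal_id", "litter_id", "prenatal", "environment"))
    if (!col %in% colnames(cd)) msgs <- c(msgs, sprintf("colData lacks '%s'", col))
  if ("animal_id" %in% colnames(cd) && anyDuplicated(cd$animal_id))
    msgs <- c(msgs, "duplicated animal_id")
  if ("prenatal" %in% colnames(cd) &&
      !all(as.character(cd$prenatal) %in% PRENATAL_LEVELS))
    msgs <- c(msgs, "prenatal labels must be SAL or VPA")
  if ("environment" %in% colnames(cd) &&
      !all(as.character(cd$environment) %in% ENVIRONMENT_LEVELS))
    msgs <- c(msgs, "environment labels must be ST, UE or PE")
  rd <- SummarizedExperiment::rowData(object)
  for (col in c("unit", "inverted", "role"))
    if (!col %in% colnames(rd)) msgs <- c(msgs, sprintf("rowData lacks '%s'", col))
  if ("role" %in% colnames(rd) && !all(rd$role %in% MEASURE_ROLES))
    msgs <- c(msgs, "rowData$role has labels outside the allowed roles")
  if (length(msgs)) msgs else TRUE
})

#' ConsistencyResult: an item set with its internal-consistency summary
#'
#' Produced by \code{\link{consistency}} and \code{\link{selectItems}}.
#' Holds the pairwise Pearson correlation matrix of the (oriented)
#' z-scored items, the mean off-diagonal correlation \code{rBar}, the
#' standardized Cronbach's alpha, the smallest item-rest correlation,
#' and the orientation (+1/-1) applied per item.
#'
#' @slot items character, measure names in the set.
#' @slot rMatrix numeric matrix of pairwise Pearson correlations.
#' @slot rBar numeric(1), mean off-diagonal correlation.
#' @slot alpha numeric(1), standardized Cronbach's alpha
#'   \eqn{k \bar r / (1 + (k-1)\bar r)}.
#' @slot minItemTotalR numeric(1), smallest correlation between one item
#'   and the mean of the remaining items.
#' @slot orientation named numeric of +1/-1 per item (as applied on top
#'   of the catalog orientation).
#' @slot lowPairFlag logical(1), TRUE when some pairwise correlation
#'   falls below the reporting floor (0.28).
#' @export
setClass("ConsistencyResult",
  representation(items = "character", rMatrix = "matrix", rBar = "numeric",
                 alpha = "numeric", minItemTotalR = "numeric",
                 orientation = "numeric", lowPairFlag = "logical"))

setValidity("ConsistencyResult", function(object) {
  msgs <- character()
  k <- length(object@items)
  R <- object@rMatrix
  if (!all(dim(R) == c(k, k))) msgs <- c(msgs, "rMatrix dimensions must match items")
  else {
    if (max(abs(R - t(R))) > 1e-8) msgs <- c(msgs, "rMatrix must be symmetric")
    if (max(abs(diag(R) - 1)) > 1e-8) msgs <- c(msgs, "rMatrix diagonal must be 1")
    expected <- k * object@rBar / (1 + (k - 1) * object@rBar)
    if (abs(object@alpha - expected) > 1e-8)
      msgs <- c(msgs, "alpha inconsistent with rBar and k")
  }
  if (length(msgs)) msgs else TRUE
})

#' ClusterSolution: a k-cluster labeling of one prenatal group
#'
#' Produced by \code{\link{cutClusters}}. Clusters are labeled with
#' roman numerals I..k ordered by ascending cluster-mean composite
#' emotionality score (ties broken by larger cluster size).
#'
#' @slot k integer(1), number of clusters.
#' @slot labels factor of cluster labels (levels I..k), named by animal id.
#' @slot scores named numeric, composite emotionality score per animal.
#' @slot withinClusterSS named numeric, within-cluster sum of squares over
#'   the clustering input columns.
#' @slot tree the \code{\link[stats]{hclust}} merge schedule the solution
#'   was cut from (heights are Ward objective increases).
#' @slot group character(1), prenatal group the solution belongs to
#'   (or "all").
#' @export
setClass("ClusterSolution",
  representation(k = "integer", labels = "factor", scores = "numeric",
                 withinClusterSS = "numeric", tree = "ANY", group = "character"))

setValidity("ClusterSolution", function(object) {
  msgs <- character()
  if (length(object@k) != 1L || object@k < 1L) msgs <- c(msgs, "k must be a positive integer")
  if (nlevels(object@labels) != object@k)
    msgs <- c(msgs, "labels must use exactly k levels")
  if (is.null(names(object@labels)) || anyDuplicated(names(object@labels)))
    msgs <- c(msgs, "labels must be uniquely named by animal id")
  if (!all(names(object@labels) %in% names(object@scores)))
    msgs <- c(msgs, "every clustered animal needs a composite score")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn ConsistencyResult-class compact display
#' @param object a ConsistencyResult
#' @export
setMethod("show", "ConsistencyResult", function(object) {
  cat(sprintf("ConsistencyResult: %d items, rBar = %.3f, alpha = %.3f\n",
              length(object@items), object@rBar, object@alpha))
  cat("  items:", paste(ifelse(object@orientation[object@items] < 0,
                               paste0(object@items, " [-]"), object@items),
                        collapse = ", "), "\n")
  cat(sprintf("  min item-rest r = %.3f%s\n", object@minItemTotalR,
              if (object@lowPairFlag) "  (pairwise r < 0.28 present)" else ""))
})

#' @describeIn ClusterSolution-class compact display
#' @param object a ClusterSolution
#' @export
setMethod("show", "ClusterSolution", function(object) {
  cat(sprintf("ClusterSolution (%s): %d animals in %d clusters\n",
              object@group, length(object@labels), object@k))
  print(table(object@labels))
})
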