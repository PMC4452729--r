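#' Default behavioral measure catalog
#'
#' The catalog drives which columns are read from a cohort table, the
#' orientation applied before composite scoring (inverted = TRUE means a
#' higher raw value indicates LOWER emotionality, so the z-score is
#' negated), and which measures are candidates for the internal
#' consistency item search versus held-out "predicted" variables used
#' only for cluster characterization.
#'
#' The default lists the five fear/anxiety readouts that form the
#' emotionality construct — elevated-plus-maze open-arm time (inverted)
#' and four fear-conditioning freezing percentages (training, long-term
#' context memory, long-term context generalization, long-term tone
#' memory) — plus the autism-relevant predicted-only behaviors (social
#' preference index, hot-plate withdrawal latency) and, when present,
#' normalized protein immunoreactivity and corticosterone variables.
#'
#' @param proteins logical, include the default protein/corticosterone
#'   predicted-only variables.
#' @return data.frame with columns \code{name}, \code{unit},
#'   \code{inverted}, \code{role}.
#' @examples
#' defaultCatalog()
#' @export
defaultCatalog <- function(proteins = TRUE) {
  core <- data.frame(
    name = c("epm_open_arm_s", "freezing_training_pct", "freezing_context_d23_pct",
             "freezing_pretone_d24_pct", "freezing_tone_d24_pct",
             "social_preference", "hot_plate_latency_s"),
    unit = c("s", "percent", "percent", "percent", "percent", "index", "s"),
    inverted = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    role = c(rep("emotionality_candidate", 5), "predicted_only", "predicted_only"),
    stringsAsFactors = FALSE)
  if (proteins) {
    bio <- data.frame(
      name = c("s1_glun2b_ir", "dhip_camkii_ir", "vhip_glun1_ir",
               "amy_glun2b_ir", "cort_plasma"),
      unit = c(rep("percent", 4), "ng/ml"),
      inverted = FALSE,
      role = "predicted_only",
      stringsAsFactors = FALSE)
    core <- rbind(core, bio)
  }
  core
}

validateCatalog <- function(catalog) {
  stopifnot(is.data.frame(catalog),
            all(c("name", "unit", "inverted", "role") %in% colnames(catalog)))
  if (anyDuplicated(catalog$name))
    stop("duplicated measure names in catalog: ",
         paste(unique(catalog$name[duplicated(catalog$name)]), collapse = ", "))
  if (!all(catalog$role %in% MEASURE_ROLES))
    stop("unknown catalog role(s): ",
         paste(setdiff(catalog$role, MEASURE_ROLES), collapse = ", "))
  invisible(catalog)
}

#' Construct a BehaviorCohort
#'
#' @param measures numeric matrix, animals x measures (rownames = animal
#'   ids, colnames = catalog measure names). Transposed internally to the
#'   measures x animals assay orientation.
#' @param colData data.frame with one row per animal: \code{animal_id},
#'   \code{litter_id}, \code{prenatal} (SAL/VPA), \code{environment}
#'   (ST/UE/PE), and optionally \code{perseveration} (logical) and
#'   \code{batch} (assay batch for biochemistry).
#' @param catalog measure catalog as from \code{\link{defaultCatalog}};
#'   only catalog measures present in \code{measures} are kept, in
#'   catalog order.
#' @return a \linkS4class{BehaviorCohort}
#' @examples
#' cohort <- simulateCohort(defaultCohortConfig(seed = 1))
#' cohort
#' @export
BehaviorCohort <- function(measures, colData, catalog = defaultCatalog()) {
  validateCatalog(catalog)
  measures <- as.matrix(measures)
  keep <- intersect(catalog$name, colnames(measures))
  if (!length(keep)) stop("no catalog measures found in 'measures'")
  measures <- measures[, keep, drop = FALSE]
  catalog <- catalog[match(keep, catalog$name), , drop = FALSE]
  colData <- as.data.frame(colData)
  colData$prenatal <- factor(as.character(colData$prenatal), levels = PRENATAL_LEVELS)
  colData$environment <- factor(as.character(colData$environment),
                                levels = ENVIRONMENT_LEVELS)
  if (is.null(colData$perseveration)) colData$perseveration <- NA
  if (is.null(colData$batch)) colData$batch <- NA_integer_
  assay <- t(measures)
  rownames(assay) <- catalog$name
  colnames(assay) <- colData$animal_id
  rd <- S4Vectors::DataFrame(unit = catalog$unit, inverted = catalog$inverted,
                             role = catalog$role, row.names = catalog$name)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(measures = assay), rowData = rd,
    colData = S4Vectors::DataFrame(colData, row.names = colData$animal_id))
  methods::new("BehaviorCohort", se)
}

#' Accessors for BehaviorCohort
#'
#' \code{measureCatalog} returns the measure catalog (data.frame);
#' \code{animalIds}, \code{prenatalGroup}, \code{rearingEnv} and
#' \code{perseveration} return the per-animal design columns;
#' \code{measureData} returns the animals x measures raw matrix.
#'
#' @param x a \linkS4class{BehaviorCohort}
#' @return see individual descriptions.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
setMethod("measureCatalog", "BehaviorCohort", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  data.frame(name = rownames(rd), unit = rd$unit, inverted = rd$inverted,
             role = rd$role, row.names = NULL, stringsAsFactors = FALSE)
})

#' @rdname cohort-accessors
#' @export
setMethod("animalIds", "BehaviorCohort", function(x)
  as.character(SummarizedExperiment::colData(x)$animal_id))

#' @rdname cohort-accessors
#' @export
setMethod("prenatalGroup", "BehaviorCohort", function(x)
  SummarizedExperiment::colData(x)$prenatal)

#' @rdname cohort-accessors
#' @export
setMethod("rearingEnv", "BehaviorCohort", function(x)
  SummarizedExperiment::colData(x)$environment)

#' @rdname cohort-accessors
#' @export
setMethod("perseveration", "BehaviorCohort", function(x)
  SummarizedExperiment::colData(x)$perseveration)

#' @rdname cohort-accessors
#' @export
measureData <- function(x) t(SummarizedExperiment::assay(x, "measures"))

#' Read a cohort table from CSV
#'
#' Expects a header row with the design columns \code{animal_id},
#' \code{litter_id}, \code{prenatal}, \code{environment}, optional
#' \code{perseveration} and \code{batch}, and one column per catalog
#' measure present in the file. Empty cells are read as missing values
#' (never zero). Unknown prenatal/environment labels and duplicated
#' animal ids are hard errors naming the offending row.
#'
#' @param path CSV file path.
#' @param catalog measure catalog; see \code{\link{defaultCatalog}}.
#' @return a \linkS4class{BehaviorCohort}
#' @seealso \code{\link{writeCohort}}
#' @export
readCohort <- function(path, catalog = defaultCatalog()) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  validateCatalog(catalog)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), comment.char = "#")
  for (col in c("animal_id", "litter_id", "prenatal", "environment"))
    if (!col %in% colnames(tab)) stop("cohort file lacks design column '", col, "'")
  bad <- which(!tab$prenatal %in% PRENATAL_LEVELS)
  if (length(bad))
    stop(sprintf("row %d: unknown prenatal label '%s'", bad[1], tab$prenatal[bad[1]]))
  bad <- which(!tab$environment %in% ENVIRONMENT_LEVELS)
  if (length(bad))
    stop(sprintf("row %d: unknown environment label '%s'", bad[1], tab$environment[bad[1]]))
  dup <- which(duplicated(tab$animal_id))
  if (length(dup))
    stop(sprintf("row %d: duplicated animal_id '%s'", dup[1], tab$animal_id[dup[1]]))
  present <- intersect(catalog$name, colnames(tab))
  if (!length(present)) stop("no catalog measure columns found in ", path)
  m <- as.matrix(tab[, present, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tab$animal_id
  cd <- tab[, c("animal_id", "litter_id", "prenatal", "environment"), drop = FALSE]
  cd$perseveration <- if ("perseveration" %in% colnames(tab))
    as.logical(tab$perseveration) else NA
  cd$batch <- if ("batch" %in% colnames(tab)) as.integer(tab$batch) else NA_integer_
  BehaviorCohort(m, cd, catalog)
}

#' Write a cohort table to CSV
#'
#' Inverse of \code{\link{readCohort}}: writes design columns followed by
#' the measure columns, missing values as empty cells.
#'
#' @param cohort a \linkS4class{BehaviorCohort}
#' @param path output CSV path.
#' @return invisibly, the written data.frame.
#' @export
writeCohort <- function(cohort, path) {
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  out <- cbind(cd[, c("animal_id", "litter_id", "prenatal", "environment",
                      "perseveration", "batch")],
               as.data.frame(measureData(cohort)))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(out)
}

#' Social preference index
#'
#' Time sniffing the social stimulus over total sniffing time,
#' \eqn{social / (social + object)}, in [0, 1]. When the total is zero
#' the index is undefined and returned as NA with a warning.
#'
#' @param social_sniff_s,object_sniff_s nonnegative sniffing times (s);
#'   vectors are recycled element-wise.
#' @return numeric preference index in [0, 1] (NA where undefined).
#' @examples
#' preferenceIndex(30, 30)   # 0.5
#' preferenceIndex(12.5, 37.5)
#' @export
preferenceIndex <- function(social_sniff_s, object_sniff_s) {
  if (any(social_sniff_s < 0, na.rm = TRUE) || any(object_sniff_s < 0, na.rm = TRUE))
    stop("sniffing times must be nonnegative")
  total <- social_sniff_s + object_sniff_s
  undef <- !is.na(total) & total == 0
  if (any(undef))
    warning(sum(undef), " animal(s) with zero total sniffing time; index undefined")
  out <- social_sniff_s / total
  out[undef] <- NA_real_
  out
}

#' Freezing time as percent of session
#'
#' @param freeze_s time frozen (s), within [0, period_s].
#' @param period_s session length (s), > 0.
#' @return \code{100 * freeze_s / period_s}, in [0, 100].
#' @examples
#' freezingPercent(45, 180)  # 25
#' @export
freezingPercent <- function(freeze_s, period_s) {
  if (any(period_s <= 0)) stop("period_s must be positive")
  if (any(freeze_s < 0, na.rm = TRUE)) stop("freeze_s must be nonnegative")
  if (any(freeze_s > period_s, na.rm = TRUE))
    stop("freeze_s exceeds session length")
  100 * freeze_s / period_s
}

#' Normalize immunoreactivity within assay batch
#'
#' Expresses each value as a percent of the mean reference-group
#' (SAL-ST) value of its own assay batch; normalization is strictly
#' within batch, never pooled across batches. Batches with no reference
#' animals yield NA for all their values, with a warning.
#'
#' @param values numeric immunoreactivity values.
#' @param batch batch identifier per value.
#' @param reference logical per value, TRUE for reference (SAL-ST) animals.
#' @return numeric, \code{100 * value / mean(reference values of its batch)}.
#' @export
normalizeIR <- function(values, batch, reference) {
  stopifnot(length(values) == length(batch), length(values) == length(reference))
  out <- rep(NA_real_, length(values))
  for (b in unique(batch[!is.na(batch)])) {
    in_b <- !is.na(batch) & batch == b
    ref <- values[in_b & reference]
    ref_mean <- mean(ref, na.rm = TRUE)
    if (!length(ref) || !is.finite(ref_mean) || ref_mean <= 0) {
      warning("batch ", b, " has no usable reference values; flagged missing")
      next
    }
    out[in_b] <- 100 * values[in_b] / ref_mean
  }
  out
}

sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 1L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}
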