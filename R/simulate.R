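CELLS <- c("SAL.ST", "SAL.UE", "SAL.PE", "VPA.ST", "VPA.UE", "VPA.PE")
EMO_MEASURES <- c("epm_open_arm_s", "freezing_training_pct",
                  "freezing_context_d23_pct", "freezing_pretone_d24_pct",
                  "freezing_tone_d24_pct")

#' Cohort simulation settings
#'
#' Builds a validated configuration for \code{\link{simulateCohort}}.
#' Defaults emulate the 2x3 prenatal-exposure (SAL/VPA) by rearing
#' environment (ST/UE/PE) design: 18 animals per cell (17 in VPA-PE);
#' five inter-correlated emotionality measures whose programmed cell
#' means place VPA-ST highest and VPA-PE lowest in emotionality, with
#' SAL-UE/PE above SAL-ST; inflated VPA-PE variance (variance ratio 4 vs
#' SAL-PE) on open-arm time and social preference; rare Y-maze
#' perseveration enriched in VPA (rates 2/54 SAL, 10/53 VPA); and
#' protein/corticosterone variables coupled to each animal's latent
#' emotionality deviation with opposite signs in SAL and VPA.
#'
#' \code{inter_measure_r} is the target mean pairwise Pearson
#' correlation of the five pooled-cohort z-scored measures (default
#' 0.335). Because programmed cell-mean differences already induce
#' between-cell correlation, the generator solves for the within-cell
#' compound-symmetry correlation that delivers the configured pooled
#' value under the configured means, sds and cell sizes.
#'
#' @param n_per_cell named integer vector of cell sizes over
#'   \code{SAL.ST, SAL.UE, SAL.PE, VPA.ST, VPA.UE, VPA.PE}.
#' @param cell_means,cell_sds numeric matrices (cell x emotionality
#'   measure) on the raw measure scale.
#' @param inter_measure_r target pooled mean pairwise correlation, in
#'   [0, 1).
#' @param perseveration_rate named rates per prenatal group.
#' @param pred_means,pred_sds cell x predicted-behavior matrices
#'   (social preference, hot-plate latency).
#' @param protein_effect list with elements \code{SAL} and \code{VPA}:
#'   named coupling coefficients (units of the protein scale per latent
#'   emotionality s.d.) for the protein variables.
#' @param cort_effect same for plasma corticosterone.
#' @param n_batches number of biochemistry assay batches (counterbalanced
#'   across groups; immunoreactivity is normalized within batch).
#' @param seed integer RNG seed; the cohort is fully deterministic given
#'   the seed.
#' @return object of class \code{CohortConfig} (a validated list).
#' @seealso \code{\link{simulateCohort}}
#' @examples
#' cfg <- defaultCohortConfig(seed = 7)
#' cfg$inter_measure_r
#' @export
defaultCohortConfig <- function(n_per_cell = c(SAL.ST = 18, SAL.UE = 18, SAL.PE = 18,
                                               VPA.ST = 18, VPA.UE = 18, VPA.PE = 17),
                                cell_means = NULL, cell_sds = NULL,
                                inter_measure_r = 0.335,
                                perseveration_rate = c(SAL = 2 / 54, VPA = 10 / 53),
                                pred_means = NULL, pred_sds = NULL,
                                protein_effect = NULL, cort_effect = NULL,
                                n_batches = 3L, seed = 1L) {
  # emotionality shift per cell, in units of the baseline measure sd
  shift <- c(SAL.ST = -0.3, SAL.UE = 0.2, SAL.PE = 0.2,
             VPA.ST = 0.7, VPA.UE = 0.6, VPA.PE = -0.9)
  if (is.null(cell_means)) {
    base <- c(epm_open_arm_s = 40, freezing_training_pct = 45,
              freezing_context_d23_pct = 45, freezing_pretone_d24_pct = 45,
              freezing_tone_d24_pct = 45)
    bsd <- c(epm_open_arm_s = 12, freezing_training_pct = 10,
             freezing_context_d23_pct = 10, freezing_pretone_d24_pct = 10,
             freezing_tone_d24_pct = 10)
    orient <- ifelse(EMO_MEASURES == "epm_open_arm_s", -1, 1)  # inverted scale
    cell_means <- outer(shift, orient * bsd, "*") + rep(base, each = 6)
    dimnames(cell_means) <- list(CELLS, EMO_MEASURES)
    # predictable enrichment relaxes open-arm avoidance in VPA only
    cell_means["VPA.PE", "epm_open_arm_s"] <- 60
  }
  if (is.null(cell_sds)) {
    cell_sds <- matrix(rep(c(12, 10, 10, 10, 10), each = 6), nrow = 6,
                       dimnames = list(CELLS, EMO_MEASURES))
    cell_sds["VPA.PE", "epm_open_arm_s"] <- 24  # variance ratio 4 vs SAL-PE
  }
  if (is.null(pred_means)) {
    pred_means <- cbind(
      social_preference = c(0.62, 0.60, 0.55, 0.50, 0.55, 0.68),
      hot_plate_latency_s = rep(10, 6))
    rownames(pred_means) <- CELLS
  }
  if (is.null(pred_sds)) {
    pred_sds <- cbind(social_preference = rep(0.05, 6),
                      hot_plate_latency_s = rep(2, 6))
    rownames(pred_sds) <- CELLS
    pred_sds["VPA.PE", "social_preference"] <- 0.10  # variance ratio 4 vs SAL-PE
  }
  if (is.null(protein_effect)) {
    # IR percent change per latent emotionality s.d.; signs per group follow
    # the opposite behavior-protein coupling seen in exposed vs control animals
    vpa <- c(s1_glun2b_ir = -10, dhip_camkii_ir = -10,
             vhip_glun1_ir = 10, amy_glun2b_ir = -10)
    protein_effect <- list(SAL = -vpa, VPA = vpa)
  }
  if (is.null(cort_effect))
    cort_effect <- list(SAL = c(cort_plasma = -15), VPA = c(cort_plasma = 15))
  cfg <- structure(list(
    n_per_cell = n_per_cell, cell_means = cell_means, cell_sds = cell_sds,
    inter_measure_r = inter_measure_r, perseveration_rate = perseveration_rate,
    pred_means = pred_means, pred_sds = pred_sds,
    protein_effect = protein_effect, cort_effect = cort_effect,
    protein_base = 100, protein_noise_sd = 15,
    cort_base = 120, cort_noise_sd = 30,
    batch_scale = c(0.8, 1.0, 1.25)[seq_len(n_batches)],
    n_batches = as.integer(n_batches), seed = as.integer(seed)),
    class = "CohortConfig")
  validateCohortConfig(cfg)
  cfg
}

#' @rdname defaultCohortConfig
#' @param config a CohortConfig to validate.
#' @export
validateCohortConfig <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  with(config, {
    if (any(n_per_cell < 1)) stop("cell sizes must be positive")
    if (!setequal(names(n_per_cell), CELLS)) stop("n_per_cell must cover all 6 cells")
    if (any(cell_sds <= 0) || any(pred_sds <= 0)) stop("all sds must be positive")
    if (any(perseveration_rate < 0 | perseveration_rate > 1))
      stop("perseveration rates must be in [0, 1]")
    if (inter_measure_r < 0 || inter_measure_r >= 1)
      stop("inter_measure_r must be in [0, 1)")
  })
  rw <- withinCellR(config)
  k <- ncol(config$cell_means)
  if (rw <= -1 / (k - 1) || rw >= 1)
    stop(sprintf(paste0("implied within-cell correlation %.3f gives a ",
                        "non-positive-definite covariance"), rw))
  invisible(TRUE)
}

#' @export
print.CohortConfig <- function(x, ...) {
  cat("CohortConfig:", sum(x$n_per_cell), "animals over", length(CELLS), "cells\n")
  cat("  pooled target mean inter-measure r:", x$inter_measure_r,
      "(within-cell r:", round(withinCellR(x), 3), ")\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# Solve for the within-cell compound-symmetry correlation that delivers the
# configured POOLED mean pairwise correlation, given the between-cell
# mean/sd structure (orientation-aligned so all pairwise signs agree).
withinCellR <- function(config) {
  mu <- config$cell_means
  sg <- config$cell_sds
  orient <- ifelse(colnames(mu) == "epm_open_arm_s", -1, 1)
  mu <- sweep(mu, 2, orient, "*")
  w <- config$n_per_cell[rownames(mu)] / sum(config$n_per_cell)
  mbar <- colSums(w * mu)
  dev <- sweep(mu, 2, mbar)                      # cell deviations, oriented
  V <- colSums(w * sg^2) + colSums(w * dev^2)    # pooled variance per measure
  k <- ncol(mu)
  A <- B <- 0; P <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    s <- sqrt(V[i] * V[j])
    A <- A + sum(w * sg[, i] * sg[, j]) / s
    B <- B + sum(w * dev[, i] * dev[, j]) / s
    P <- P + 1
  }
  (config$inter_measure_r - B / P) / (A / P)
}

#' Simulate a behavioral cohort
#'
#' Draws, per design cell, the five emotionality measures from a
#' multivariate normal with compound-symmetry correlation built from a
#' shared latent emotionality factor, clamps draws to their valid ranges
#' (freezing to [0, 100], times and the preference index to their
#' bounds), draws the rare perseveration flag Bernoulli per prenatal
#' group, and generates protein immunoreactivity (with batch effects,
#' normalized within batch via \code{\link{normalizeIR}}) and plasma
#' corticosterone as linear functions of the animal's latent
#' emotionality deviation plus noise, with group-specific coupling
#' signs. Fully deterministic given \code{config$seed}.
#'
#' @param config a \code{CohortConfig}, see \code{\link{defaultCohortConfig}}.
#' @return a \linkS4class{BehaviorCohort}. The fraction of draws altered
#'   by range clamping is recorded in
#'   \code{metadata(cohort)$truncation_fraction} and a message is issued
#'   if it exceeds 1\%.
#' @examples
#' cohort <- simulateCohort(defaultCohortConfig(seed = 42))
#' table(prenatalGroup(cohort), rearingEnv(cohort))
#' @export
simulateCohort <- function(config = defaultCohortConfig()) {
  validateCohortConfig(config)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  rw <- withinCellR(config)
  emo <- colnames(config$cell_means)
  pred <- colnames(config$pred_means)
  prots <- names(config$protein_effect$SAL)
  corts <- names(config$cort_effect$SAL)
  rows <- list(); clamped <- 0L; total_draws <- 0L
  for (cell in CELLS) {
    n <- config$n_per_cell[[cell]]
    pre <- sub("\\..*", "", cell); env <- sub(".*\\.", "", cell)
    u <- stats::rnorm(n)                                   # latent emotionality
    e <- matrix(stats::rnorm(n * length(emo)), n)
    # the latent factor loads with the measure's orientation, so that inverted
    # scales (open-arm time) anti-correlate with the freezing measures in raw
    # units and the ORIENTED z-scores show compound-symmetry correlation rw
    orient <- ifelse(emo == "epm_open_arm_s", -1, 1)
    raw <- sqrt(max(rw, 0)) * outer(u, orient) +
      sqrt(1 - max(rw, 0)) * e                             # compound symmetry
    if (rw < 0) {  # negative within-cell r: exact mvn factorization
      C <- (matrix(rw, length(emo), length(emo)) + diag(1 - rw, length(emo))) *
        tcrossprod(orient)
      raw <- e %*% chol(C)
    }
    m <- sweep(sweep(raw, 2, config$cell_sds[cell, emo], "*"), 2,
               config$cell_means[cell, emo], "+")
    colnames(m) <- emo
    # clamp to valid scales: freezing in [0,100], times >= 0
    lo <- ifelse(grepl("_pct$", emo), 0, 0)
    hi <- ifelse(grepl("_pct$", emo), 100, Inf)
    before <- m
    m <- pmin(pmax(m, rep(lo, each = n)), rep(hi, each = n))
    clamped <- clamped + sum(m != before)
    total_draws <- total_draws + length(m)
    pb <- sweep(sweep(matrix(stats::rnorm(n * length(pred)), n), 2,
                      config$pred_sds[cell, pred], "*"), 2,
                config$pred_means[cell, pred], "+")
    colnames(pb) <- pred
    before <- pb
    pb[, "social_preference"] <- pmin(pmax(pb[, "social_preference"], 0), 1)
    pb[, "hot_plate_latency_s"] <- pmax(pb[, "hot_plate_latency_s"], 0)
    clamped <- clamped + sum(pb != before)
    total_draws <- total_draws + length(pb)
    eff_p <- config$protein_effect[[pre]]
    eff_c <- config$cort_effect[[pre]]
    batch <- rep_len(seq_len(config$n_batches), n)         # counterbalanced
    raw_ir <- sapply(prots, function(p)
      (config$protein_base + eff_p[[p]] * u +
         stats::rnorm(n, 0, config$protein_noise_sd)) *
        config$batch_scale[batch])
    cort <- sapply(corts, function(p)
      config$cort_base + eff_c[[p]] * u + stats::rnorm(n, 0, config$cort_noise_sd))
    persev <- stats::runif(n) < config$perseveration_rate[[pre]]
    ids <- sprintf("%s_%s_%02d", pre, env, seq_len(n))
    rows[[cell]] <- list(
      cd = data.frame(animal_id = ids,
                      litter_id = sprintf("%s_L%d", cell, ceiling(seq_len(n) / 3)),
                      prenatal = pre, environment = env,
                      perseveration = persev, batch = batch,
                      latent = u, stringsAsFactors = FALSE),
      m = cbind(m, pb), raw_ir = matrix(raw_ir, n, dimnames = list(NULL, prots)),
      cort = matrix(cort, n, dimnames = list(NULL, corts)))
  }
  cd <- do.call(rbind, lapply(rows, `[[`, "cd"))
  m <- do.call(rbind, lapply(rows, `[[`, "m"))
  raw_ir <- do.call(rbind, lapply(rows, `[[`, "raw_ir"))
  cort <- do.call(rbind, lapply(rows, `[[`, "cort"))
  is_ref <- cd$prenatal == "SAL" & cd$environment == "ST"
  ir <- sapply(colnames(raw_ir), function(p)
    normalizeIR(raw_ir[, p], cd$batch, is_ref))
  m <- cbind(m, ir, cort)
  rownames(m) <- cd$animal_id
  frac <- clamped / total_draws
  if (frac > 0.01)
    message(sprintf("range clamping altered %.2f%% of draws (> 1%%)", 100 * frac))
  latent <- cd$latent
  cd$latent <- NULL
  cohort <- BehaviorCohort(m, cd, defaultCatalog(proteins = TRUE))
  S4Vectors::metadata(cohort)$truncation_fraction <- frac
  S4Vectors::metadata(cohort)$within_cell_r <- rw
  S4Vectors::metadata(cohort)$latent <- stats::setNames(latent, cd$animal_id)
  S4Vectors::metadata(cohort)$seed <- config$seed
  cohort
}
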