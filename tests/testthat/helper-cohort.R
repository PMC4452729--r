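# Small fixtures built in code.

CELL_NAMES <- c("SAL.ST", "SAL.UE", "SAL.PE", "VPA.ST", "VPA.UE", "VPA.PE")

tinyCohortDF <- function() {
  data.frame(
    animal_id = paste0("r", 1:6),
    litter_id = paste0("L", c(1, 1, 2, 2, 3, 3)),
    prenatal = rep(c("SAL", "VPA"), each = 3),
    environment = rep(c("ST", "UE", "PE"), 2),
    perseveration = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    batch = c(1L, 2L, 3L, 1L, 2L, 3L),
    epm_open_arm_s = c(30, 42, 55, 12, 20, 70),
    freezing_training_pct = c(40, 35, 30, 60, 55, 25),
    freezing_context_d23_pct = c(45, 38, 32, 65, 58, 28),
    freezing_pretone_d24_pct = c(42, 36, 30, 62, 57, 26),
    freezing_tone_d24_pct = c(48, 40, 34, 70, 60, 30),
    social_preference = c(0.62, 0.60, 0.55, 0.48, 0.55, 0.70),
    hot_plate_latency_s = c(10, 11, 9, 12, 10, 11),
    stringsAsFactors = FALSE)
}

writeTinyCohort <- function(df = tinyCohortDF()) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  write.csv(df, path, row.names = FALSE, na = "")
  path
}

# n x k columns with exact compound-symmetry population correlation r,
# built from a shared latent factor.
csColumns <- function(n, k, r, seed = 1) {
  set.seed(seed)
  u <- rnorm(n)
  Z <- sqrt(r) * u + sqrt(1 - r) * matrix(rnorm(n * k), n)
  colnames(Z) <- paste0("m", seq_len(k))
  Z
}

cellSizes <- function(n) setNames(rep(n, 6), CELL_NAMES)
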