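blobs <- function(centers, n_each, sd = 0.3, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    cbind(rnorm(n_each, centers[i, 1], sd), rnorm(n_each, centers[i, 2], sd))))
  rownames(X) <- sprintf("a%02d", seq_len(nrow(X)))
  X
}

test_that("squared Euclidean distances match the double-loop oracle", {
  X <- rbind(a = c(0, 0), b = c(0, 0), c = c(1, 0), d = c(3, 4))
  D <- distanceMatrix(X)
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], 1)       # squared metric, not 1 after sqrt
  expect_equal(D["a", "d"], 25)
  set.seed(2)
  M <- matrix(rnorm(40), 8, 5, dimnames = list(letters[1:8], NULL))
  D <- distanceMatrix(M)
  for (i in 1:8) for (j in 1:8)
    expect_equal(D[i, j], sum((M[i, ] - M[j, ])^2), tolerance = 1e-12)
  expect_error(distanceMatrix(M[1:2, ]), "at least 3")
  M[1, 1] <- NA
  expect_error(distanceMatrix(M), "missing")
})

test_that("Ward merges follow the coordinate-based greedy SS oracle", {
  set.seed(4)
  X <- matrix(rnorm(10), 5, 2, dimnames = list(letters[1:5], NULL))
  hc <- wardLinkage(distanceMatrix(X))
  expect_equal(hc$height, wardGreedyOracle(X), tolerance = 1e-10)
  # coincident points merge first at height zero
  X2 <- rbind(X, f = X[2, ])
  hc2 <- wardLinkage(distanceMatrix(X2))
  expect_equal(hc2$height[1], 0)
  expect_error(wardLinkage(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("merge heights are non-decreasing and conserve total SS", {
  set.seed(6)
  for (i in 1:20) {
    X <- matrix(rnorm(2 * sample(5:10, 1)), ncol = 2)
    rownames(X) <- sprintf("r%02d", seq_len(nrow(X)))
    hc <- wardLinkage(distanceMatrix(X))
    expect_true(all(diff(hc$height) >= -1e-10))
    total_ss <- sum(sweep(X, 2, colMeans(X))^2)
    expect_equal(sum(hc$height), total_ss, tolerance = 1e-8)
    # Ward conservation at an intermediate cut
    k <- 3
    scores <- setNames(rnorm(nrow(X)), rownames(X))
    sol <- cutClusters(hc, k, scores, Z = X)
    heights_above <- sum(rev(hc$height)[seq_len(k - 1)])
    expect_equal(sum(sol@withinClusterSS) + heights_above, total_ss,
                 tolerance = 1e-8)
  }
})

test_that("cutting recovers boundary cases and planted partitions", {
  X <- blobs(matrix(c(0, 0, 10, 0, 0, 10, 10, 10), 4, 2, byrow = TRUE),
             n_each = 6, sd = 0.3, seed = 8)  # centers ~ 20+ sd apart
  truth <- rep(1:4, each = 6)
  hc <- wardLinkage(distanceMatrix(X))
  scores <- setNames(rowMeans(X), rownames(X))
  expect_equal(cutClusters(hc, 1, scores)@k, 1L)
  expect_equal(nlevels(cutClusters(hc, 1, scores)@labels), 1)
  expect_equal(cutClusters(hc, nrow(X), scores)@k, nrow(X))
  sol <- cutClusters(hc, 4, scores, Z = X)
  # exact agreement with the generating blobs (up to label names)
  agree <- table(clusterLabels(sol), truth)
  expect_true(all(rowSums(agree > 0) == 1))
  expect_true(all(colSums(agree > 0) == 1))
  # labels ordered by ascending mean composite score
  mean_by_cluster <- tapply(scores, clusterLabels(sol), mean)
  expect_true(all(diff(mean_by_cluster) > 0))
})

test_that("cluster labels are invariant to animal input order", {
  X <- blobs(matrix(c(0, 0, 6, 0, 0, 6), 3, 2, byrow = TRUE),
             n_each = 7, sd = 0.4, seed = 10)
  scores <- setNames(rowMeans(X), rownames(X))
  ref <- cutClusters(wardLinkage(distanceMatrix(X)), 3, scores, Z = X)
  ref_labels <- clusterLabels(ref)[sort(names(clusterLabels(ref)))]
  set.seed(12)
  for (i in 1:20) {
    perm <- sample(nrow(X))
    sol <- cutClusters(wardLinkage(distanceMatrix(X[perm, ])), 3, scores,
                       Z = X[perm, ])
    expect_identical(clusterLabels(sol)[sort(names(clusterLabels(sol)))],
                     ref_labels)
  }
})

test_that("height-gap diagnostics point at planted structure and stay quiet on noise", {
  X <- blobs(matrix(c(0, 0, 12, 0), 2, 2, byrow = TRUE), n_each = 10,
             sd = 0.5, seed = 14)
  d <- homogeneityDiagnostics(wardLinkage(distanceMatrix(X)))
  expect_equal(d$k[which.max(d$gap)], 2)
  expect_true(d$dominant[d$k == 2])

  set.seed(16)
  U <- matrix(runif(60), 30, 2)
  rownames(U) <- sprintf("u%02d", 1:30)
  du <- homogeneityDiagnostics(wardLinkage(distanceMatrix(U)))
  expect_false(any(du$dominant[du$k >= 3]))

  X3 <- matrix(rnorm(6), 3, 2, dimnames = list(c("a", "b", "c"), NULL))
  d3 <- homogeneityDiagnostics(wardLinkage(distanceMatrix(X3)))
  expect_equal(d3$k, 2:3)
})

test_that("profiles report sizes, rounded percents, sems and environment mix", {
  # constructed solution with the published cluster sizes 4/28/10/11 of 53
  sizes <- c(4, 28, 10, 11)
  ids <- sprintf("v%02d", 1:53)
  labels <- factor(rep(c("I", "II", "III", "IV"), sizes),
                   levels = c("I", "II", "III", "IV"))
  names(labels) <- ids
  scores <- setNames(rep(c(-2, 0, 1, 2), sizes), ids)
  sol <- methods::new("ClusterSolution", k = 4L, labels = labels,
                      scores = scores, withinClusterSS = numeric(0),
                      tree = NULL, group = "VPA")
  m <- matrix(rnorm(53 * 2), 53,
              dimnames = list(ids, c("freezing_training_pct", "epm_open_arm_s")))
  cd <- data.frame(animal_id = ids, litter_id = "L", prenatal = "VPA",
                   environment = rep(c("ST", "UE", "PE"), length.out = 53))
  cohort <- BehaviorCohort(m, cd, defaultCatalog(proteins = FALSE))
  prof <- profileClusters(sol, cohort, predicted_vars = character(0))
  pct <- unique(prof[, c("cluster", "percent")])
  expect_equal(pct$percent, c(8, 53, 19, 21))   # nearest-integer rounding
  expect_lte(abs(sum(pct$percent) - 100), 1)
  env_rows <- prof[prof$type == "environment", ]
  for (cl in c("I", "II", "III", "IV"))
    expect_equal(sum(env_rows$mean[env_rows$cluster == cl]), 1)
})

test_that("clusters of identical animals have zero sems everywhere", {
  ids <- sprintf("s%02d", 1:9)
  m <- cbind(freezing_training_pct = rep(c(10, 20, 30), each = 3),
             epm_open_arm_s = rep(c(50, 40, 30), each = 3),
             social_preference = rep(c(0.5, 0.6, 0.7), each = 3))
  rownames(m) <- ids
  cd <- data.frame(animal_id = ids, litter_id = "L", prenatal = "SAL",
                   environment = "ST")
  cohort <- BehaviorCohort(m, cd, defaultCatalog(proteins = FALSE))
  labels <- factor(rep(c("I", "II", "III"), each = 3))
  names(labels) <- ids
  scores <- setNames(rep(c(-1, 0, 1), each = 3), ids)
  sol <- methods::new("ClusterSolution", k = 3L, labels = labels,
                      scores = scores, withinClusterSS = numeric(0),
                      tree = NULL, group = "SAL")
  prof <- profileClusters(sol, cohort, predicted_vars = "social_preference",
                          core_items = c("freezing_training_pct", "epm_open_arm_s"))
  expect_equal(prof$sem[prof$type %in% c("core", "composite", "predicted")],
               rep(0, 12))
})

test_that("combined high-emotionality clusters cover 40% of the exposed group", {
  expect_equal(round(100 * (10 + 11) / 53), 40)
  expect_equal(round(100 * 7 / 54), 13)
})

test_that("Newick export round-trips through ape", {
  X <- blobs(matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE), n_each = 4, seed = 18)
  hc <- wardLinkage(distanceMatrix(X))
  path <- withr::local_tempfile(fileext = ".nwk")
  exportNewick(hc, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, rownames(X))
})
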