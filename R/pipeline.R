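#' Pipeline run configuration
#'
#' Assembles and validates the settings for \code{\link{runPipeline}}.
#' Settings may also be read from a YAML file with
#' \code{readRunConfig}; flags given there use the same names.
#'
#' @param output_dir directory for all outputs (created if needed).
#' @param cohort_csv existing cohort table; ignored when
#'   \code{simulate = TRUE}.
#' @param simulate generate the cohort with
#'   \code{\link{simulateCohort}} instead of reading one.
#' @param seed integer seed for all randomness in the run.
#' @param alpha significance level (Welch trigger and summaries).
#' @param k clusters per prenatal group.
#' @param min_size smallest item subset for \code{\link{selectItems}}.
#' @param barnard_grid_step nuisance grid step for
#'   \code{\link{barnardExact}}.
#' @return list of class \code{RunConfig}.
#' @export
runConfig <- function(output_dir, cohort_csv = NULL, simulate = is.null(cohort_csv),
                      seed = 1L, alpha = 0.05, k = 4L, min_size = 3L,
                      barnard_grid_step = 0.001) {
  cfg <- structure(list(output_dir = output_dir, cohort_csv = cohort_csv,
                        simulate = isTRUE(simulate), seed = as.integer(seed),
                        alpha = alpha, k = as.integer(k),
                        min_size = as.integer(min_size),
                        barnard_grid_step = barnard_grid_step),
                   class = "RunConfig")
  if (!cfg$simulate && (is.null(cfg$cohort_csv) || !file.exists(cfg$cohort_csv)))
    stop("cohort file not found: ",
         if (is.null(cfg$cohort_csv)) "<unset>" else cfg$cohort_csv)
  cfg
}

#' @rdname runConfig
#' @param path YAML file with the fields above.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  do.call(runConfig, vals)
}

configHash <- function(cfg) {
  s <- utf8ToInt(paste(deparse(unclass(cfg)), collapse = ""))
  sprintf("%08x", sum(s * (seq_along(s) %% 97)) %% .Machine$integer.max)
}

metaHeader <- function(cfg) {
  sprintf("# emoprofiler %s | seed %d | config %s",
          as.character(utils::packageVersion("emoprofiler")), cfg$seed,
          configHash(cfg))
}

writeTable <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(metaHeader(cfg), con)
  utils::write.csv(df, con, row.names = FALSE, na = "")
}

#' Run the full phenotyping pipeline
#'
#' Executes simulate (optional) -> score -> stats -> cluster and writes
#' all artifacts under \code{config$output_dir}: the cohort table,
#' per-animal composite scores, the consistency report, a tidy
#' statistics table, cluster labels and profiles, per-group Newick
#' dendrograms, and one aggregated JSON report. Every CSV carries a
#' metadata header line (tool version, seed, config hash); the run is
#' byte-identical across repetitions at the same seed.
#'
#' @param config a \code{RunConfig} (see \code{\link{runConfig}}).
#' @return invisibly, the aggregated report list.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)

  cohort <- if (config$simulate) {
    co <- simulateCohort(defaultCohortConfig(seed = config$seed))
    writeCohort(co, out("cohort.csv"))
    writeLines(c(metaHeader(config), readLines(out("cohort.csv"))),
               out("cohort.csv"))
    co
  } else readCohort(config$cohort_csv)

  # -- score ---------------------------------------------------------------
  cohort <- zScore(cohort)
  sel <- selectItems(cohort, min_size = config$min_size)
  scores <- compositeScore(cohort, sel)
  writeTable(data.frame(animal_id = names(scores), score = unname(scores)),
             out("scores.csv"), config)
  consistency_report <- list(
    items = sel@items, orientation = as.list(sel@orientation),
    r_matrix = sel@rMatrix, r_bar = sel@rBar, alpha = sel@alpha,
    min_item_total_r = sel@minItemTotalR, low_pair_flag = sel@lowPairFlag)
  jsonlite::write_json(consistency_report, out("consistency.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)

  # -- stats ---------------------------------------------------------------
  pre <- prenatalGroup(cohort); env <- rearingEnv(cohort)
  m <- measureData(cohort)
  cat <- measureCatalog(cohort)
  stat_rows <- list()
  addRow <- function(...) stat_rows[[length(stat_rows) + 1L]] <<- data.frame(...)
  responses <- c(stats::setNames(asplit(m[, cat$name[cat$role ==
    "emotionality_candidate"], drop = FALSE], 2),
    cat$name[cat$role == "emotionality_candidate"]),
    list(composite_score = scores))
  for (nm in names(responses)) {
    v <- as.numeric(responses[[nm]])
    at <- twoWayAnova(v, pre, env)
    for (i in which(at$term != "residual"))
      addRow(test = "two_way_anova", measure = nm, groups = at$term[i],
             statistic = at$F[i], df = paste(at$df[i], at$df[nrow(at)], sep = ","),
             p_raw = at$p[i], p_adjusted = at$p[i])
    ph <- bonferroniPairwise(v, pre, env, alpha = config$alpha)
    for (i in seq_len(nrow(ph)))
      addRow(test = ifelse(ph$welch_applied[i], "welch_t", "pooled_t"),
             measure = nm, groups = paste0("SAL-VPA@", ph$environment[i]),
             statistic = ph$statistic[i], df = sprintf("%.1f", ph$df[i]),
             p_raw = ph$p_raw[i], p_adjusted = ph$p_adjusted[i])
  }
  persev <- perseveration(cohort)
  if (!all(is.na(persev))) {
    tab <- rbind(VPA = c(sum(persev[pre == "VPA"], na.rm = TRUE),
                         sum(!persev[pre == "VPA"], na.rm = TRUE)),
                 SAL = c(sum(persev[pre == "SAL"], na.rm = TRUE),
                         sum(!persev[pre == "SAL"], na.rm = TRUE)))
    fe <- fisherExact(tab)
    addRow(test = "fisher_exact", measure = "perseveration", groups = "VPA-SAL",
           statistic = NA_real_, df = "", p_raw = fe$p_two_sided,
           p_adjusted = fe$p_two_sided)
    for (e in levels(env)) {
      te <- rbind(c(sum(persev[pre == "VPA" & env == e], na.rm = TRUE),
                    sum(!persev[pre == "VPA" & env == e], na.rm = TRUE)),
                  c(sum(persev[pre == "SAL" & env == e], na.rm = TRUE),
                    sum(!persev[pre == "SAL" & env == e], na.rm = TRUE)))
      be <- barnardExact(te, grid_step = config$barnard_grid_step)
      addRow(test = "barnard_exact", measure = "perseveration",
             groups = paste0("VPA-SAL@", e), statistic = be$statistic,
             df = sprintf("pi=%.3f", ifelse(is.na(be$pi_sup), NA, be$pi_sup)),
             p_raw = be$p_two_sided, p_adjusted = be$p_two_sided)
    }
  }
  bio <- intersect(cat$name[cat$role == "predicted_only"], colnames(m))
  bio <- setdiff(bio, c("social_preference", "hot_plate_latency_s"))
  for (nm in bio) for (g in levels(pre)) {
    in_g <- pre == g
    ok <- sum(!is.na(m[in_g, nm]) & !is.na(scores[in_g]))
    if (ok >= 4) {
      sr <- spearmanRho(scores[in_g], m[in_g, nm])
      addRow(test = "spearman_rho", measure = nm, groups = g,
             statistic = sr$rho, df = as.character(ok), p_raw = sr$p,
             p_adjusted = sr$p)
      ow <- oneWayAnova(m[in_g, nm], env[in_g])
      addRow(test = "one_way_anova", measure = nm, groups = paste0("env@", g),
             statistic = ow$F[1], df = paste(ow$df, collapse = ","),
             p_raw = ow$p[1], p_adjusted = ow$p[1])
    }
  }
  stats_tab <- do.call(rbind, stat_rows)
  writeTable(stats_tab, out("stats.csv"), config)

  # -- cluster -------------------------------------------------------------
  profiles <- list(); label_rows <- list()
  for (g in c("SAL", "VPA")) {
    sol <- clusterAnimals(cohort, sel, group = g, k = config$k)
    exportNewick(sol, out(sprintf("dendrogram_%s.nwk", g)))
    prof <- profileClusters(sol, cohort)
    prof$group <- g
    profiles[[g]] <- prof
    label_rows[[g]] <- data.frame(animal_id = names(clusterLabels(sol)),
                                  group = g,
                                  cluster = as.character(clusterLabels(sol)))
  }
  profiles_tab <- do.call(rbind, profiles)
  rownames(profiles_tab) <- NULL
  writeTable(do.call(rbind, label_rows), out("cluster_labels.csv"), config)
  writeTable(profiles_tab, out("cluster_profiles.csv"), config)

  report <- list(
    meta = list(tool = "emoprofiler",
                version = as.character(utils::packageVersion("emoprofiler")),
                seed = config$seed, config_hash = configHash(config),
                distance = "squared-euclidean", linkage = "ward"),
    consistency = consistency_report,
    statistics = stats_tab,
    cluster_profiles = profiles_tab)
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE, dataframe = "rows")
  invisible(report)
}
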