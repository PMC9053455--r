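#' Assemble a run configuration
#'
#' Collects every tunable parameter of the pipeline with its default. For a
#' simulation run leave the paths `NULL` and supply (or accept) the
#' `simulation` block; for a data run give both input paths.
#'
#' @param microdata_path,covariates_path Optional input CSV paths.
#' @param output_dir Optional directory for intermediate CSV artifacts.
#' @param thresholds Guideline thresholds, minutes/week.
#' @param age_range Inclusive working-age bracket.
#' @param k Number of clusters (labeling requires 4).
#' @param robustness_threshold Mean-ARI threshold for [choose_k()].
#' @param alpha Significance level of the profiling battery.
#' @param baseline,exclude Multinomial-logit baseline category and reference
#'   variables.
#' @param ci_level Confidence level for Wald intervals.
#' @param simulation Optional [simulation_config()].
#' @param rng_seed Seed overriding the simulation block's seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(microdata_path = NULL, covariates_path = NULL,
                       output_dir = NULL,
                       thresholds = c(150, 300), age_range = c(18, 64),
                       k = 4L, robustness_threshold = 0.8, alpha = 0.05,
                       baseline = "unhealthy",
                       exclude = c("agriculture", "pop_gt64"),
                       ci_level = 0.95,
                       simulation = simulation_config(),
                       rng_seed = NULL) {
  if (!is.null(rng_seed)) simulation$rng_seed <- as.integer(rng_seed)
  if (is.null(simulation) &&
      (is.null(microdata_path) || is.null(covariates_path))) {
    stop("either a simulation block or both input paths are required")
  }
  structure(
    list(microdata_path = microdata_path, covariates_path = covariates_path,
         output_dir = output_dir, thresholds = thresholds,
         age_range = age_range, k = as.integer(k),
         robustness_threshold = robustness_threshold, alpha = alpha,
         baseline = baseline, exclude = exclude, ci_level = ci_level,
         simulation = simulation),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Every field of [run_config()] is addressable; the `simulation` block maps
#' onto [simulation_config()] (including nested `minute_distributions`).
#' Omitted fields take their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$simulation
  sim <- if (is.null(sim_args)) simulation_config() else {
    defaults <- default_minute_distributions()
    if (!is.null(sim_args$minute_distributions)) {
      for (cls in names(sim_args$minute_distributions)) {
        defaults[[cls]] <- utils::modifyList(defaults[[cls]],
                                             sim_args$minute_distributions[[cls]])
      }
    }
    sim_args$minute_distributions <- defaults
    if (!is.null(sim_args$age_range)) sim_args$age_range <- unlist(sim_args$age_range)
    do.call(simulation_config, sim_args)
  }
  raw$simulation <- sim
  known <- intersect(names(raw), names(formals(run_config)))
  scalars <- c("thresholds", "age_range", "exclude")
  for (f in intersect(known, scalars)) raw[[f]] <- unlist(raw[[f]])
  do.call(run_config, raw[known])
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes, in order: (optional) simulation of microdata and covariates,
#' working-age filtering, individual classification and regional
#' aggregation, the two-stage Ward + K-means taxonomy with labeling, the
#' ANOVA profiling battery, and the multinomial logistic regression with its
#' diagnostic battery. Any stage failure aborts with the stage name. When
#' `config$output_dir` is set, every intermediate table is written as CSV.
#'
#' @param config A [run_config()].
#' @return An object of class `run_report` collecting every stage's output
#'   plus provenance (seed, package version, sample-size audit trail).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  simulated <- is.null(config$microdata_path)
  audit <- list()

  micro <- run_stage("input", {
    if (simulated) generate_microdata(config$simulation,
                                      thresholds = config$thresholds)
    else read_microdata(config$microdata_path)
  })
  covars <- run_stage("input", {
    if (simulated) generate_covariates(config$simulation)
    else read_covariates(config$covariates_path)
  })
  audit$n_respondents <- nrow(micro)

  eligible <- run_stage("classify", {
    suppressMessages(filter_working_age(micro, config$age_range))
  })
  audit$n_eligible <- nrow(eligible)

  profiles <- run_stage("aggregate", {
    regionalize(eligible, config$thresholds,
                all_regions = unique(micro$region_id))
  })
  audit$n_regions <- nrow(profiles)
  audit$n_regions_dropped <- length(unique(micro$region_id)) - nrow(profiles)

  exploration <- run_stage("cluster", explore_linkages(profiles))
  k_choice <- run_stage("cluster", suppressWarnings(
    choose_k(exploration, config$robustness_threshold)))
  k <- config$k
  solution <- run_stage("cluster", {
    sol <- build_taxonomy(profiles, k)
    if (k != 4L) warning("k != 4: cluster labeling skipped")
    sol
  })

  profiling <- run_stage("profile", {
    suppressWarnings(anova_profile(covars, solution, alpha = config$alpha))
  })

  mlr <- run_stage("mlr", {
    at <- assignment_table(solution)
    if (anyNA(at$cluster_label)) {
      # unlabeled (k != 4): contrast cluster indices against the cluster
      # with the largest non-active rate
      at$cluster_label <- paste0("C", at$cluster_index)
      base <- paste0("C", which.max(solution$centroids[, "rate_non_active"]))
    } else {
      base <- config$baseline
    }
    design <- mlr_design(covars, at, baseline = base,
                         exclude = config$exclude)
    fit <- fit_mlr(design)
    list(design = design, fit = fit,
         table = wald_inference(fit, config$ci_level),
         diagnostics = mlr_diagnostics(design, fit))
  })

  report <- structure(
    list(
      descriptives = descriptive_stats(
        cbind(profiles[, c(rate_cols())],
              covars[match(profiles$region_id, covars$region_id),
                     covariate_names()])),
      profiles = profiles,
      exploration = exploration$agreement,
      k_recommendation = k_choice$k,
      solution = solution,
      cluster_sizes = table(assignment_table(solution)$cluster_label,
                            useNA = "ifany"),
      cluster_means = cluster_means_table(covars, solution),
      profiling = profiling,
      mlr = mlr,
      audit = audit,
      provenance = list(
        seed = config$simulation$rng_seed, simulated = simulated,
        package_version = as.character(utils::packageVersion("hepaclust")),
        config = config)
    ),
    class = "run_report"
  )

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$output_dir, f)
    write_microdata(micro, out("microdata.csv"))
    write_covariates(covars, out("covariates.csv"))
    write_profiles(profiles, out("regional_profiles.csv"))
    utils::write.csv(assignment_table(solution), out("assignments.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(report$descriptives, out("descriptives.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(mlr$table, out("mlr_coefficients.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("=== Regional physical-activity taxonomy run ===\n")
  cat("Respondents:", x$audit$n_respondents, "->", x$audit$n_eligible,
      "after age filter;", x$audit$n_regions, "regions\n")
  cat("Recommended k:", x$k_recommendation, "\n\n")
  print(x$solution)
  cat("\nCluster sizes:\n")
  print(x$cluster_sizes)
  cat("\n")
  print(x$profiling)
  cat("\n")
  print(x$mlr$diagnostics)
  invisible(x)
}
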