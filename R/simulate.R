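# Region ids are assigned globally across archetypes so microdata and
# covariates generated from the same (config, archetypes) pair line up.
region_table <- function(config, archetypes) {
  n_arch <- length(archetypes)
  n_reg <- config$n_regions_per_archetype
  data.frame(
    region_id = sprintf("REG%03d", seq_len(n_arch * n_reg)),
    archetype = rep(vapply(archetypes, `[[`, "", "name"), each = n_reg),
    stringsAsFactors = FALSE
  )
}

draw_zil_minutes <- function(n, par) {
  zero <- stats::runif(n) < par$p_zero
  x <- ifelse(zero, 0, stats::rlnorm(n, par$meanlog, par$sdlog))
  round(x)
}

draw_class_minutes <- function(n, dist) {
  cbind(
    vigorous_min = draw_zil_minutes(n, dist$vigorous),
    moderate_min = draw_zil_minutes(n, dist$moderate),
    walking_min = draw_zil_minutes(n, dist$walking)
  )
}

# Rejection-sample minutes for n individuals of one target class: redraw until
# the scoring rule assigns exactly that class, so the generative class mix is
# realized by construction.
sample_minutes_for_class <- function(n, target, dist, thresholds, cap) {
  out <- matrix(0, n, 3,
                dimnames = list(NULL, c("vigorous_min", "moderate_min",
                                        "walking_min")))
  pending <- seq_len(n)
  for (attempt in seq_len(cap)) {
    if (length(pending) == 0L) break
    draw <- draw_class_minutes(length(pending), dist)
    got <- classify_activity(as.data.frame(draw), thresholds)
    ok <- got == target
    if (any(ok)) {
      out[pending[ok], ] <- draw[ok, , drop = FALSE]
      pending <- pending[!ok]
    }
  }
  if (length(pending) > 0L) {
    stop("minute distribution for class '", target,
         "' cannot realize that class within ", cap, " attempts per individual")
  }
  out
}

#' Generate synthetic survey microdata
#'
#' Draws, for every region of every archetype, respondents whose activity
#' class is first sampled from the archetype's class mix and whose weekly
#' minutes are then rejection-sampled from the class-conditional
#' zero-inflated log-normal distributions until the scoring rule reproduces
#' the target class. Ages are uniform on `config$age_range`, which extends
#' beyond 18-64 so the working-age filter is exercised downstream.
#'
#' @param config A [simulation_config()].
#' @param archetypes List of [archetype_spec()] objects (at least one).
#' @param thresholds Guideline thresholds passed to the scoring rule.
#' @return A data frame with columns `respondent_id`, `region_id`, `age`,
#'   `vigorous_min`, `moderate_min`, `walking_min` plus the generating
#'   `archetype` and `true_class` tags.
#' @export
generate_microdata <- function(config, archetypes = default_archetypes(),
                               thresholds = c(150, 300)) {
  stopifnot(inherits(config, "simulation_config"), length(archetypes) >= 1)
  regions <- region_table(config, archetypes)
  arch_by_name <- stats::setNames(archetypes,
                                  vapply(archetypes, `[[`, "", "name"))
  n_ind <- config$n_individuals_per_region
  classes <- activity_classes()

  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(config$rng_seed)

  pieces <- vector("list", nrow(regions))
  for (r in seq_len(nrow(regions))) {
    arch <- arch_by_name[[regions$archetype[r]]]
    cls <- sample(classes, n_ind, replace = TRUE, prob = arch$class_mix)
    minutes <- matrix(0, n_ind, 3,
                      dimnames = list(NULL, c("vigorous_min", "moderate_min",
                                              "walking_min")))
    for (target in classes) {
      idx <- which(cls == target)
      if (length(idx) == 0L) next
      minutes[idx, ] <- sample_minutes_for_class(
        length(idx), target, config$minute_distributions[[target]],
        thresholds, config$resample_cap
      )
    }
    age <- sample(seq(config$age_range[1], config$age_range[2]), n_ind,
                  replace = TRUE)
    pieces[[r]] <- data.frame(
      respondent_id = sprintf("%s_I%04d", regions$region_id[r], seq_len(n_ind)),
      region_id = regions$region_id[r],
      age = age,
      vigorous_min = minutes[, 1],
      moderate_min = minutes[, 2],
      walking_min = minutes[, 3],
      archetype = regions$archetype[r],
      true_class = cls,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate synthetic regional covariates
#'
#' Draws the 14 socioeconomic indicators for every region independently from
#' archetype-specific normal distributions, then closes the two compositional
#' groups (sector employment shares; population age shares) by renormalizing
#' each to sum exactly to 100. Shares are truncated to [0, 100] and strictly
#' positive indicators to a small positive floor before closure.
#'
#' The covariate stream is decoupled from the microdata stream by deriving a
#' fixed offset sub-seed from the single global seed, so microdata and
#' covariates can be regenerated independently yet reproducibly.
#'
#' @inheritParams generate_microdata
#' @return A data frame with `region_id`, `archetype` and the 14 indicator
#'   columns of [covariate_names()].
#' @export
generate_covariates <- function(config, archetypes = default_archetypes()) {
  stopifnot(inherits(config, "simulation_config"), length(archetypes) >= 1)
  regions <- region_table(config, archetypes)
  arch_by_name <- stats::setNames(archetypes,
                                  vapply(archetypes, `[[`, "", "name"))

  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed((config$rng_seed + 77003L) %% .Machine$integer.max)

  vars <- covariate_names()
  mat <- matrix(NA_real_, nrow(regions), length(vars),
                dimnames = list(NULL, vars))
  for (r in seq_len(nrow(regions))) {
    arch <- arch_by_name[[regions$archetype[r]]]
    x <- stats::rnorm(length(vars), arch$covariate_means[vars],
                      arch$covariate_sds[vars])
    names(x) <- vars
    x[share_cols()] <- pmin(pmax(x[share_cols()], 0), 100)
    x[c("gdp_pc", "density")] <- pmax(x[c("gdp_pc", "density")], 1e-6)
    x[sector_cols()] <- 100 * x[sector_cols()] / sum(x[sector_cols()])
    x[pop_cols()] <- 100 * x[pop_cols()] / sum(x[pop_cols()])
    mat[r, ] <- x
  }
  cbind(regions, as.data.frame(mat))
}
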