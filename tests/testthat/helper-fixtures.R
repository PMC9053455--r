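# Shared fixture builders and brute-force oracles.

microdata_row <- function(vig = 0, mod = 0, walk = 0, age = 30,
                          region = "R1", id = "p1") {
  data.frame(respondent_id = id, region_id = region, age = age,
             vigorous_min = vig, moderate_min = mod, walking_min = walk,
             stringsAsFactors = FALSE)
}

# pa_profile data frame from a matrix of rate rows (must sum to 100)
make_profiles <- function(rates, region_ids = NULL, n_eligible = 100L) {
  rates <- as.matrix(rates)
  if (is.null(region_ids)) {
    region_ids <- sprintf("R%02d", seq_len(nrow(rates)))
  }
  out <- data.frame(region_id = region_ids,
                    rate_non_active = rates[, 1],
                    rate_below_healthy = rates[, 2],
                    rate_healthy = rates[, 3],
                    rate_extra_healthy = rates[, 4],
                    n_eligible = n_eligible,
                    stringsAsFactors = FALSE)
  class(out) <- c("pa_profile", "data.frame")
  out
}

# embed 1-D points x as profiles (x, 100 - x, 0, 0); squared distances double
profiles_1d <- function(x) {
  make_profiles(cbind(x, 100 - x, 0, 0))
}

# all partitions of n points into exactly k non-empty clusters
all_partitions <- function(n, k) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  keep <- apply(grid, 1, function(a) length(unique(a)) == k)
  grid <- grid[keep, , drop = FALSE]
  # canonical labeling so each set partition appears once
  canon <- apply(grid, 1, function(a) paste(match(a, unique(a)), collapse = "."))
  grid[!duplicated(canon), , drop = FALSE]
}

# brute-force global K-means optimum: minimal within-cluster SSE over all
# partitions into k non-empty clusters
global_kmeans_optimum <- function(x, k) {
  x <- as.matrix(x)
  parts <- all_partitions(nrow(x), k)
  best <- Inf
  best_assign <- NULL
  for (i in seq_len(nrow(parts))) {
    a <- parts[i, ]
    sse <- 0
    for (j in unique(a)) {
      xi <- x[a == j, , drop = FALSE]
      sse <- sse + sum(sweep(xi, 2, colMeans(xi))^2)
    }
    if (sse < best) {
      best <- sse
      best_assign <- a
    }
  }
  list(inertia = best, assignment = best_assign)
}

# tiny archetype set with simple covariates, for fast simulation tests
tiny_archetypes <- function(sds = NULL) {
  arcs <- default_archetypes()
  if (!is.null(sds)) {
    for (nm in names(arcs)) {
      arcs[[nm]]$covariate_sds[] <- sds
    }
  }
  arcs
}

quiet_profiles <- function(micro, ...) {
  regionalize(suppressMessages(filter_working_age(micro)), ...)
}
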