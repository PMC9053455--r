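# minimal cluster_solution for profiling tests
fake_solution <- function(assign, region_ids, k = max(assign)) {
  structure(list(assignments = stats::setNames(as.integer(assign), region_ids),
                 centroids = matrix(0, k, 4,
                                    dimnames = list(NULL, c(
                                      "rate_non_active", "rate_below_healthy",
                                      "rate_healthy", "rate_extra_healthy"))),
                 k = k, labels = NULL, inertia = 0,
                 seed_centroids = NULL, iterations = 1L, converged = TRUE),
            class = "cluster_solution")
}

fake_covariates <- function(region_ids, values) {
  cv <- as.data.frame(matrix(50, length(region_ids),
                             length(covariate_names()),
                             dimnames = list(NULL, covariate_names())))
  cv$region_id <- region_ids
  for (nm in names(values)) cv[[nm]] <- values[[nm]]
  cv
}

test_that("cluster means table matches hand arithmetic and flags extremes", {
  ids <- c("A", "B", "C", "D")
  cv <- fake_covariates(ids, list(gdp_pc = c(10, 20, 100, 200),
                                  tertiary = c(40, 44, 10, 14)))
  sol <- fake_solution(c(1, 1, 2, 2), ids, k = 2)
  tab <- cluster_means_table(cv, sol, indicators = c("gdp_pc", "tertiary"))
  gdp <- tab[tab$indicator == "gdp_pc", ]
  expect_equal(gdp$cluster_1, 15)
  expect_equal(gdp$cluster_2, 150)
  expect_equal(gdp$largest_in, 2L)
  expect_equal(gdp$smallest_in, 1L)
  ter <- tab[tab$indicator == "tertiary", ]
  expect_equal(ter$cluster_1, 42)
  expect_equal(ter$cluster_2, 12)
  expect_equal(ter$largest_in, 1L)

  # one region per cluster: means equal the region values
  sol1 <- fake_solution(1:4, ids, k = 4)
  tab1 <- cluster_means_table(cv, sol1, indicators = "gdp_pc")
  expect_equal(unlist(tab1[, paste0("cluster_", 1:4)], use.names = FALSE),
               c(10, 20, 100, 200))
})

test_that("missing covariates for assigned regions fail loudly", {
  cv <- fake_covariates(c("A", "B"), list())
  sol <- fake_solution(c(1, 2, 1), c("A", "B", "MISSING"))
  expect_error(cluster_means_table(cv, sol, indicators = "gdp_pc"), "MISSING")
})

test_that("normality screen calibrates to the per-cluster Shapiro tests", {
  # normal data: inclusion rate should track (1 - alpha)^4 ~ 0.815 under the
  # any-cluster-rejects rule with four clusters of 50
  ids <- sprintf("R%03d", 1:200)
  sol <- fake_solution(rep(1:4, each = 50), ids)
  incl <- vapply(1:100, function(s) {
    set.seed(s)
    cv <- fake_covariates(ids, list(gdp_pc = rnorm(200)))
    normality_screen(cv, sol, indicators = "gdp_pc")$included
  }, logical(1))
  expect_gte(mean(incl), 0.70)
  expect_lte(mean(incl), 0.92)

  # strongly skewed data: excluded in at least 90% of seeds
  incl_ln <- vapply(1:100, function(s) {
    set.seed(s)
    cv <- fake_covariates(ids, list(gdp_pc = rlnorm(200, 0, 1)))
    normality_screen(cv, sol, indicators = "gdp_pc")$included
  }, logical(1))
  expect_lte(mean(incl_ln), 0.10)
})

test_that("untestable indicators are retained with a warning", {
  ids <- c("A", "B", "C", "D", "E")
  cv <- fake_covariates(ids, list(gdp_pc = rep(7, 5)))
  sol <- fake_solution(c(1, 1, 1, 2, 2), ids, k = 2)
  expect_warning(scr <- normality_screen(cv, sol, indicators = "gdp_pc"),
                 "untestable")
  expect_true(scr$included)
  expect_true(scr$untestable)
})

test_that("Levene statistic vanishes for symmetric equal-spread groups", {
  out <- levene_test(list(c(-1, 1), c(-1, 1)))
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
  expect_error(levene_test(list(c(1, 2), 3)), "at least 2")
})

test_that("Levene detects a ninefold variance ratio", {
  rej <- vapply(1:100, function(s) {
    set.seed(s)
    levene_test(list(rnorm(100, 0, 1), rnorm(100, 0, 3)))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.9)
})

test_that("one-way ANOVA matches hand computation and the stats oracle", {
  # hand-worked 3x3: groups (1,2,3), (2,3,4), (6,7,8)
  # means 2,3,7; grand 4; SSB = 3(4+1+9) = 42; SSW = 6; F = 21/1 = 21
  res <- oneway_anova(list(c(1, 2, 3), c(2, 3, 4), c(6, 7, 8)))
  expect_equal(res$statistic, 21)
  expect_equal(res$df, c(2L, 6L))
  expect_equal(res$p_value, pf(21, 2, 6, lower.tail = FALSE))

  # agreement with stats::oneway.test on irregular random groups
  set.seed(10)
  g <- list(rnorm(7), rnorm(12, 0.5), rnorm(9, 1), rnorm(5))
  res2 <- oneway_anova(g)
  ref <- stats::oneway.test(
    y ~ grp, data = data.frame(y = unlist(g),
                               grp = rep(seq_along(g), lengths(g))),
    var.equal = TRUE)
  expect_equal(res2$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res2$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("degenerate ANOVA inputs follow the documented limits", {
  expect_equal(oneway_anova(list(c(0, 2), c(0, 2), c(0, 2)))$statistic, 0)
  res <- oneway_anova(list(c(0, 0, 0), c(1, 1, 1)))
  expect_equal(res$statistic, Inf)
  expect_equal(res$p_value, 0)
  jit <- oneway_anova(list(c(0, 1e-9, 0), c(1, 1, 1 + 1e-9)))
  expect_gt(jit$statistic, 1e6)
  expect_lt(jit$p_value, 1e-12)
})

test_that("Brown-Forsythe with two groups equals Welch's t test", {
  set.seed(11)
  a <- rnorm(10, 0, 1)
  b <- rnorm(25, 1, 4)
  bf <- brown_forsythe_robust(list(a, b))
  tt <- t.test(a, b)
  expect_equal(bf$statistic, unname(tt$statistic)^2, tolerance = 1e-6)
  expect_equal(bf$df[2], unname(tt$parameter), tolerance = 1e-6)
  expect_equal(bf$p_value, tt$p.value, tolerance = 1e-6)
})

test_that("Brown-Forsythe approaches classical F under homoscedasticity", {
  set.seed(12)
  g <- lapply(1:3, function(i) rnorm(200, i * 0.1, 1))
  f <- oneway_anova(g)$statistic
  fstar <- brown_forsythe_robust(g)$statistic
  expect_lt(abs(f - fstar) / f, 0.05)
})

test_that("post hoc adjustments follow their defining formulas", {
  set.seed(13)
  g <- lapply(1:4, function(i) rnorm(12, i * 0.3))
  m <- 6
  bon <- posthoc_pairwise(g, homoscedastic = TRUE)
  expect_equal(bon$p_adj, pmin(1, m * bon$p_raw))
  tam <- posthoc_pairwise(g, homoscedastic = FALSE)
  expect_equal(tam$p_adj, pmin(1, 1 - (1 - tam$p_raw)^m))
  # adjusted >= raw, within [0, 1]; Sidak-type never exceeds Bonferroni
  for (tab in list(bon, tam)) {
    expect_true(all(tab$p_adj >= tab$p_raw - 1e-12))
    expect_true(all(tab$p_adj >= 0 & tab$p_adj <= 1))
  }
  expect_true(all(pmin(1, 1 - (1 - bon$p_raw)^m) <= pmin(1, m * bon$p_raw) + 1e-12))
})

test_that("identical groups yield no significant pairs", {
  g <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  out <- posthoc_pairwise(g, homoscedastic = TRUE)
  expect_true(all(!out$significant))
  expect_true(all(out$p_adj == 1))
})

test_that("a single outlying group accounts for all significant pairs", {
  set.seed(14)
  base <- rnorm(20)
  # groups 1-3 identical by construction, group 4 shifted by ten SDs
  g <- c(lapply(1:3, function(i) base), list(base + 10))
  names(g) <- as.character(1:4)
  out <- posthoc_pairwise(g, homoscedastic = TRUE)
  sig <- out[out$significant, ]
  expect_equal(nrow(sig), 3L)
  expect_true(all(sig$group_i == "4" | sig$group_j == "4"))
})

test_that("the full battery flags the unhealthy cluster as the dominant
          contrast on archetype data", {
  micro <- generate_microdata(simulation_config(rng_seed = 17))
  prof <- quiet_profiles(micro)
  sol <- build_taxonomy(prof)
  cv <- generate_covariates(simulation_config(rng_seed = 17))
  ap <- suppressWarnings(anova_profile(cv, sol))
  unhealthy_idx <- names(sol$labels)[sol$labels == "unhealthy"]
  counts <- stats::setNames(numeric(4), as.character(1:4))
  for (res in ap$results) {
    if (!isTRUE(res$included)) next
    sig <- res$pairwise[res$pairwise$significant, ]
    for (cl in as.character(1:4)) {
      counts[cl] <- counts[cl] + sum(sig$group_i == cl | sig$group_j == cl)
    }
  }
  expect_equal(names(which.max(counts)), unhealthy_idx)
})
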