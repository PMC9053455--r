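# simulate data from the baseline-category logit itself
simulate_mnl <- function(n, B, seed) {
  # B: (p+1) x (J-1), first row intercepts
  set.seed(seed)
  p <- nrow(B) - 1L
  x <- cbind(1, matrix(rnorm(n * p), n, p))
  eta <- x %*% B
  probs <- cbind(exp(eta), 1) / (1 + rowSums(exp(eta)))
  J <- ncol(probs)
  y <- apply(probs, 1, function(pr) sample.int(J, 1, prob = pr))
  lev <- c(paste0("cat", seq_len(J - 1)), "base")
  colnames(x) <- c("(Intercept)", paste0("x", seq_len(p)))
  list(x = x, y = factor(lev[y], levels = lev), baseline = "base",
       probs = probs)
}

test_that("the intercept-only fit reproduces the observed frequencies", {
  set.seed(20)
  y <- factor(sample(c("a", "b", "base"), 120, replace = TRUE,
                     prob = c(0.5, 0.3, 0.2)), levels = c("a", "b", "base"))
  fit <- fit_mlr(list(x = cbind(`(Intercept)` = rep(1, 120)), y = y,
                      baseline = "base"))
  freq <- as.vector(table(y)) / 120
  expect_equal(unname(fit$fitted[1, ]), freq, tolerance = 1e-8)
  expect_equal(fit$log_likelihood, fit$null_log_likelihood, tolerance = 1e-8)
})

test_that("with two categories the fit matches binary logistic regression", {
  sim <- simulate_mnl(300, cbind(c(-0.3, 0.8, -0.5)), seed = 21)
  fit <- fit_mlr(sim)
  ref <- glm(I(y == "cat1") ~ x1 + x2,
             data = data.frame(y = sim$y, x1 = sim$x[, 2], x2 = sim$x[, 3]),
             family = binomial(), control = glm.control(epsilon = 1e-12))
  expect_equal(unname(fit$coefficients[, 1]), unname(coef(ref)),
               tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(fit$vcov))),
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
  expect_equal(fit$log_likelihood, as.numeric(logLik(ref)), tolerance = 1e-8)
})

test_that("the fit agrees with the nnet reference implementation", {
  skip_if_not_installed("nnet")
  sim <- simulate_mnl(400, cbind(c(0.2, 0.7, -0.4), c(-0.5, -0.6, 0.9)),
                      seed = 22)
  fit <- fit_mlr(sim)
  df <- data.frame(y = relevel(sim$y, ref = "base"),
                   x1 = sim$x[, 2], x2 = sim$x[, 3])
  ref <- nnet::multinom(y ~ x1 + x2, data = df, trace = FALSE,
                        reltol = 1e-14, maxit = 500)
  refcoef <- t(coef(ref))[, c("cat1", "cat2")]
  expect_equal(unname(fit$coefficients), unname(refcoef), tolerance = 1e-4)
  # the Newton optimum is at least as good as the reference's
  expect_gte(fit$log_likelihood, as.numeric(logLik(ref)) - 1e-6)
})

test_that("fitted probabilities obey the model identities", {
  sim <- simulate_mnl(200, cbind(c(0.1, 0.5, -0.2), c(-0.3, 0.2, 0.4)),
                      seed = 23)
  fit <- fit_mlr(sim)
  expect_equal(rowSums(fit$fitted), rep(1, 200), tolerance = 1e-9)
  # baseline probability 1 / (1 + sum exp) and the log-odds identity
  eta <- sim$x %*% fit$coefficients
  expect_equal(unname(fit$fitted[, "base"]),
               unname(1 / (1 + rowSums(exp(eta)))), tolerance = 1e-9)
  for (j in 1:2) {
    expect_equal(unname(log(fit$fitted[, j] / fit$fitted[, "base"])),
                 unname(eta[, j]), tolerance = 1e-9)
  }
  expect_lt(fit$score_max, 1e-6)
})

test_that("slopes are invariant to location shifts of a predictor", {
  sim <- simulate_mnl(250, cbind(c(0.1, 0.5, -0.2), c(-0.3, 0.2, 0.4)),
                      seed = 24)
  fit <- fit_mlr(sim)
  shifted <- sim
  shifted$x[, "x1"] <- shifted$x[, "x1"] + 10
  fit2 <- fit_mlr(shifted)
  expect_equal(fit$coefficients[-1, ], fit2$coefficients[-1, ],
               tolerance = 1e-6)
  expect_equal(unname(fit2$coefficients[1, ]),
               unname(fit$coefficients[1, ] - 10 * fit$coefficients["x1", ]),
               tolerance = 1e-6)
})

test_that("coefficients are recovered from model-generated data", {
  B <- cbind(c(0.3, 0.8, -0.6, 0.4), c(-0.2, -0.5, 0.7, 0.3))
  hits <- 0L
  total <- 0L
  for (s in 1:50) {
    sim <- simulate_mnl(5000, B, seed = 400 + s)
    fit <- fit_mlr(sim)
    se <- matrix(sqrt(diag(fit$vcov)), nrow(B), ncol(B))
    within <- abs(fit$coefficients - B) <= 3 * se
    hits <- hits + sum(within)
    total <- total + length(within)
  }
  expect_gte(hits / total, 0.95)
})

test_that("rank-deficient designs fail naming the collinear set", {
  set.seed(25)
  x <- cbind(`(Intercept)` = 1, a = rnorm(50), b = rnorm(50))
  x <- cbind(x, c = x[, "a"] + x[, "b"])
  y <- factor(sample(c("p", "base"), 50, TRUE), levels = c("p", "base"))
  expect_error(fit_mlr(list(x = x, y = y, baseline = "base")), "collinear")
})

test_that("odds-ratio transformation and Wald intervals round-trip", {
  or <- or_ci(0.341, 0.139)
  expect_equal(or$odds_ratio, exp(0.341))
  expect_equal(round(or$odds_ratio, 3), 1.406)
  or0 <- or_ci(0, 0.1)
  expect_equal(or0$odds_ratio, 1)
  # CI symmetric around 1 on the log scale
  expect_equal(log(or0$ci_upper), -log(or0$ci_lower), tolerance = 1e-12)
  # z multiplier is the exact two-sided 95% quantile
  expect_equal(or_ci(1, 1)$ci_upper, exp(1 + qnorm(0.975)), tolerance = 1e-9)
})

test_that("the Wald table lines up with the coefficient matrix", {
  sim <- simulate_mnl(300, cbind(c(0.1, 0.6, 0), c(-0.4, 0, 0.5)), seed = 26)
  fit <- fit_mlr(sim)
  tab <- wald_inference(fit)
  expect_equal(nrow(tab), 6L)
  row <- tab[tab$category == "cat1" & tab$term == "x1", ]
  expect_equal(row$estimate, fit$coefficients["x1", "cat1"])
  expect_equal(row$odds_ratio, exp(row$estimate))
  expect_equal(row$ci_lower, exp(row$estimate - qnorm(0.975) * row$se))
  expect_true(all(tab$stars %in% c("", "*", "**", "***")))
})

test_that("likelihood-ratio test has the model's degrees of freedom", {
  sim <- simulate_mnl(300, cbind(c(0.2, 0.9, -0.7), c(-0.1, -0.4, 0.6)),
                      seed = 27)
  fit <- fit_mlr(sim)
  lr <- likelihood_ratio_test(fit)
  expect_equal(lr$df, 4L) # (J-1) * p = 2 * 2
  expect_gte(lr$chi2, 0)
  expect_equal(lr$p_value, pchisq(lr$chi2, 4, lower.tail = FALSE))

  # adding a pure-noise predictor increases chi2 and df by J-1
  sim2 <- sim
  set.seed(28)
  sim2$x <- cbind(sim$x, noise = rnorm(300))
  fit2 <- fit_mlr(sim2)
  lr2 <- likelihood_ratio_test(fit2)
  expect_equal(lr2$df, 6L)
  expect_gte(lr2$chi2, lr$chi2 - 1e-8)
})

test_that("pseudo-R2 follows the defining formulas", {
  fake <- structure(list(log_likelihood = -80, null_log_likelihood = -120,
                         y = factor(rep(c("a", "base"), 50))),
                    class = "mlr_fit")
  r2 <- pseudo_r2(fake)
  expect_equal(r2$cox_snell, 1 - exp(-0.8))
  expect_equal(r2$nagelkerke, (1 - exp(-0.8)) / (1 - exp(-2.4)))

  fake$log_likelihood <- fake$null_log_likelihood
  r0 <- pseudo_r2(fake)
  expect_equal(r0$cox_snell, 0)
  expect_equal(r0$nagelkerke, 0)

  # Nagelkerke >= Cox-Snell on a real fit
  sim <- simulate_mnl(200, cbind(c(0.2, 1.2, 0.5)), seed = 29)
  r <- pseudo_r2(fit_mlr(sim))
  expect_gte(r$nagelkerke, r$cox_snell)
})

test_that("maximum chance criterion and hit ratio behave as documented", {
  expect_equal(max_chance_criterion(c(73, 31, 57, 35)), (73 / 196) * 1.25)
  expect_equal(max_chance_criterion(rep(25, 4)), 0.3125)

  # perfectly separated data: hit ratio 1
  x <- cbind(`(Intercept)` = 1, z = c(rnorm(60, -4), rnorm(60, 4)))
  y <- factor(rep(c("lo", "base"), each = 60), levels = c("lo", "base"))
  fit <- suppressWarnings(fit_mlr(list(x = x, y = y, baseline = "base")))
  acc <- classification_accuracy(fit)
  expect_equal(acc$hit_ratio, 1)
  expect_true(acc$practical_significance)
})

test_that("collinearity screen matches the auxiliary-regression oracle", {
  # orthogonal predictors: VIF exactly 1
  x <- cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1), c = c(1, -1, -1, 1))
  x <- rbind(x, -x) # n > p
  scr <- collinearity_screen(x)
  expect_equal(scr$vif, rep(1, 3), tolerance = 1e-12)
  expect_equal(scr$tolerance, 1 / scr$vif, tolerance = 1e-12)

  # near-collinear pair: VIF explodes; exact dependence flags infinity
  set.seed(30)
  a <- rnorm(100)
  x2 <- cbind(a = a, b = 2 * a + rnorm(100, 0, 1e-6), c = rnorm(100))
  scr2 <- collinearity_screen(x2)
  expect_gt(scr2$vif[1], 1e6)
  x3 <- cbind(a = a, b = 2 * a, c = rnorm(100))
  scr3 <- collinearity_screen(x3)
  expect_true(scr3$perfect_collinearity[1])
  expect_equal(scr3$vif[1], Inf)

  # independent oracle: car::vif on a random design
  skip_if_not_installed("car")
  set.seed(31)
  z <- matrix(rnorm(300), 100, 3)
  z[, 2] <- z[, 2] + 0.5 * z[, 1]
  colnames(z) <- c("u", "v", "w")
  y <- rnorm(100)
  ref <- car::vif(lm(y ~ u + v + w, data = as.data.frame(z)))
  scr4 <- collinearity_screen(z)
  expect_equal(scr4$vif, unname(ref), tolerance = 1e-8)
})

test_that("design construction applies reference coding and baseline order", {
  cfg <- simulation_config(n_regions_per_archetype = 25L,
                           n_individuals_per_region = 60L, rng_seed = 33)
  micro <- generate_microdata(cfg)
  cv <- generate_covariates(cfg)
  sol <- build_taxonomy(quiet_profiles(micro))
  des <- mlr_design(cv, sol)
  expect_false("agriculture" %in% colnames(des$x))
  expect_false("pop_gt64" %in% colnames(des$x))
  expect_equal(ncol(des$x), 13L) # intercept + 12 predictors
  expect_equal(levels(des$y)[4], "unhealthy")

  fit <- fit_mlr(des)
  expect_true(fit$converged)
  lr <- likelihood_ratio_test(fit)
  expect_equal(lr$df, 36L) # 3 contrasts x 12 predictors
})

test_that("the IIA test degrades gracefully and reports its validity", {
  B <- cbind(c(0.2, 0.6, -0.4), c(-0.3, 0.1, 0.5))
  sim <- simulate_mnl(800, B, seed = 34)
  design <- list(x = sim$x, y = sim$y, baseline = "base")
  fit <- fit_mlr(design)
  out <- hausman_mcfadden_iia(design, "cat1", full_fit = fit)
  expect_equal(out$df, 3L) # one remaining contrast x 3 coefficients
  expect_true(out$validity %in% c("valid", "inconclusive"))
  expect_true(out$p_value >= 0 && out$p_value <= 1)
  expect_error(hausman_mcfadden_iia(design, "base", full_fit = fit),
               "baseline")

  # tiny sample: the non-PD path must not crash
  simsmall <- simulate_mnl(40, B, seed = 35)
  dsmall <- list(x = simsmall$x, y = simsmall$y, baseline = "base")
  fsmall <- suppressWarnings(fit_mlr(dsmall))
  osmall <- suppressWarnings(hausman_mcfadden_iia(dsmall, "cat2",
                                                  full_fit = fsmall))
  expect_true(osmall$validity %in% c("valid", "inconclusive"))
})
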