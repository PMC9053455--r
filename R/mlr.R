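#' Build a multinomial regression design from covariates and cluster labels
#'
#' Assembles the response factor (cluster membership, baseline category
#' last) and the predictor matrix. Because the four sector employment shares
#' and the three population age shares each sum to 100, one variable of each
#' compositional set is excluded and acts as the reference (defaults:
#' agriculture and the >64 population share), leaving 12 predictors.
#'
#' @param covariates Regional covariates data frame.
#' @param solution A labeled `cluster_solution` (or a data frame with
#'   `region_id` and `cluster_label`).
#' @param baseline Baseline response category (default `"unhealthy"`).
#' @param exclude Reference variables dropped from the predictor set.
#' @return List of class `mlr_design`: `y` (factor, baseline level last),
#'   `x` (model matrix with intercept), `predictors`, `baseline`.
#' @export
mlr_design <- function(covariates, solution, baseline = "unhealthy",
                       exclude = c("agriculture", "pop_gt64")) {
  at <- if (inherits(solution, "cluster_solution")) assignment_table(solution)
        else solution
  if (anyNA(at$cluster_label)) stop("cluster labels are required (k = 4)")
  m <- match(at$region_id, covariates$region_id)
  if (anyNA(m)) {
    stop("regions without covariates: ",
         paste(at$region_id[is.na(m)], collapse = ", "))
  }
  predictors <- setdiff(covariate_names(), exclude)
  x <- as.matrix(covariates[m, predictors, drop = FALSE])
  cats <- unique(at$cluster_label)
  if (!baseline %in% cats) stop("baseline '", baseline, "' not a response category")
  lev <- c(sort(setdiff(cats, baseline)), baseline)
  y <- factor(at$cluster_label, levels = lev)
  const <- apply(x, 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    stop("constant predictor(s): ", paste(predictors[const], collapse = ", "))
  }
  structure(list(y = y, x = cbind(`(Intercept)` = 1, x),
                 predictors = predictors, baseline = baseline,
                 region_id = at$region_id),
            class = "mlr_design")
}

# Multinomial log-likelihood, score and observed information for the
# baseline-category logit: eta = X B, with the last level of y the baseline
# (linear predictor identically 0). B is (p+1) x (J-1).
mlr_loglik <- function(B, x, yidx, J) {
  eta <- x %*% B
  denom <- 1 + rowSums(exp(eta))
  ll <- -sum(log(denom))
  nb <- yidx < J
  ll + sum(eta[cbind(which(nb), yidx[nb])])
}

mlr_probs <- function(B, x) {
  eta <- x %*% B
  expeta <- exp(eta)
  denom <- 1 + rowSums(expeta)
  cbind(expeta / denom, 1 / denom)
}

mlr_score_info <- function(B, x, yidx, J) {
  P <- mlr_probs(B, x)[, seq_len(J - 1), drop = FALSE]
  Y <- matrix(0, nrow(x), J - 1)
  nb <- yidx < J
  Y[cbind(which(nb), yidx[nb])] <- 1
  score <- as.vector(crossprod(x, Y - P))
  p1 <- ncol(x)
  info <- matrix(0, p1 * (J - 1), p1 * (J - 1))
  for (j in seq_len(J - 1)) {
    for (k in j:(J - 1)) {
      w <- if (j == k) P[, j] * (1 - P[, j]) else -P[, j] * P[, k]
      blk <- crossprod(x, x * w)
      ri <- (j - 1) * p1 + seq_len(p1)
      ci <- (k - 1) * p1 + seq_len(p1)
      info[ri, ci] <- blk
      info[ci, ri] <- t(blk)
    }
  }
  list(score = score, info = info)
}

#' Fit a baseline-category multinomial logit by maximum likelihood
#'
#' Newton-Raphson on the multinomial log-likelihood with the baseline
#' category's coefficients fixed at zero, with step-halving whenever a full
#' Newton step would decrease the likelihood. The observed information at
#' the optimum provides the Wald covariance. Convergence requires the
#' largest absolute score component below 1e-8 or a relative log-likelihood
#' change below 1e-10; apparent separation (diverging coefficients) is
#' flagged, not silently returned.
#'
#' @param design An `mlr_design`, or a list with `x` (model matrix including
#'   intercept column) and `y` (factor with the baseline level last).
#' @param max_iter Newton iteration cap (default 100).
#' @return Object of class `mlr_fit`: `coefficients` ((p+1) x (J-1) matrix,
#'   columns named by non-baseline category), `vcov`, `log_likelihood`,
#'   `null_log_likelihood`, `fitted` (n x J probabilities, baseline last),
#'   `converged`, `separation`, `iterations`, `categories`, `baseline`,
#'   plus the design data.
#' @export
fit_mlr <- function(design, max_iter = 100L) {
  x <- design$x
  y <- design$y
  stopifnot(is.factor(y), nrow(x) == length(y))
  J <- nlevels(y)
  stopifnot(J >= 2)
  yidx <- as.integer(y)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop("predictor matrix is rank deficient; collinear set includes: ",
         paste(bad, collapse = ", "))
  }
  if (nrow(x) <= (J - 1) * ncol(x)) {
    stop("too few observations for ", (J - 1) * ncol(x), " free coefficients")
  }
  p1 <- ncol(x)
  B <- matrix(0, p1, J - 1)
  ll <- mlr_loglik(B, x, yidx, J)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    si <- mlr_score_info(B, x, yidx, J)
    if (max(abs(si$score)) < 1e-8) {
      converged <- TRUE
      break
    }
    step <- tryCatch(solve(si$info, si$score),
                     error = function(e) MASS::ginv(si$info) %*% si$score)
    lambda <- 1
    repeat {
      Bnew <- B + lambda * matrix(step, p1, J - 1)
      llnew <- mlr_loglik(Bnew, x, yidx, J)
      if (is.finite(llnew) && llnew >= ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) {
        llnew <- ll
        Bnew <- B
        break
      }
    }
    rel_change <- abs(llnew - ll) / (abs(ll) + 1e-10)
    B <- Bnew
    ll <- llnew
    if (rel_change < 1e-10) {
      si <- mlr_score_info(B, x, yidx, J)
      converged <- max(abs(si$score)) < 1e-6
      break
    }
    if (iter >= max_iter) break
  }
  si <- mlr_score_info(B, x, yidx, J)
  separation <- max(abs(B)) > 1e3 || !converged
  vcov <- tryCatch(solve(si$info), error = function(e) MASS::ginv(si$info))
  nonbase <- levels(y)[seq_len(J - 1)]
  dimnames(B) <- list(colnames(x), nonbase)
  cn <- as.vector(outer(colnames(x), nonbase, function(a, b) paste(b, a, sep = ":")))
  dimnames(vcov) <- list(cn, cn)
  # intercept-only fit for the null log-likelihood (analytic multinomial MLE)
  freq <- as.vector(table(y)) / length(y)
  ll0 <- sum(table(y) * log(freq))
  fitted <- mlr_probs(B, x)
  colnames(fitted) <- levels(y)
  structure(
    list(coefficients = B, vcov = vcov, log_likelihood = ll,
         null_log_likelihood = ll0, fitted = fitted,
         converged = converged, separation = separation, iterations = iter,
         score_max = max(abs(si$score)),
         categories = levels(y), baseline = levels(y)[J],
         y = y, x = x,
         predictors = setdiff(colnames(x), "(Intercept)")),
    class = "mlr_fit"
  )
}

#' @export
print.mlr_fit <- function(x, ...) {
  cat("Multinomial logit fit: n =", length(x$y), ", categories =",
      paste(x$categories, collapse = "/"), "(baseline:", x$baseline, ")\n")
  cat("  logLik =", format(x$log_likelihood, digits = 8),
      "| null logLik =", format(x$null_log_likelihood, digits = 8),
      "| iterations =", x$iterations,
      if (!x$converged) "| NOT CONVERGED" else "", "\n")
  invisible(x)
}

#' Odds ratio and Wald confidence interval for a logit coefficient
#'
#' `exp(b)` and `exp(b +/- z se)` with the two-sided normal quantile
#' (1.959964 at the default 95% level).
#'
#' @param estimate Coefficient(s) on the log-odds scale.
#' @param se Standard error(s).
#' @param level Confidence level (default 0.95).
#' @return Data frame `odds_ratio`, `ci_lower`, `ci_upper`.
#' @export
or_ci <- function(estimate, se, level = 0.95) {
  stopifnot(all(se >= 0), level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(odds_ratio = exp(estimate),
             ci_lower = exp(estimate - z * se),
             ci_upper = exp(estimate + z * se))
}

#' Wald inference table: coefficients, odds ratios and confidence intervals
#'
#' Standard errors from the inverse observed information; odds ratio
#' `exp(b)`; Wald interval `exp(b +/- z se)` with `z = 1.959964` at the 95%
#' level. Stars mark two-sided significance at 1% (`***`), 5% (`**`) and
#' 10% (`*`).
#'
#' @param fit An `mlr_fit`.
#' @param level Confidence level (default 0.95).
#' @return Data frame with `category`, `term`, `estimate`, `se`, `z`,
#'   `p_value`, `odds_ratio`, `ci_lower`, `ci_upper`, `stars`.
#' @export
wald_inference <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "mlr_fit"))
  if (fit$separation) warning("fit flagged for separation/non-convergence")
  se_all <- sqrt(pmax(diag(fit$vcov), 0))
  rows <- list()
  for (cat_j in colnames(fit$coefficients)) {
    for (term in rownames(fit$coefficients)) {
      b <- fit$coefficients[term, cat_j]
      se <- se_all[paste(cat_j, term, sep = ":")]
      z <- b / se
      p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
      or <- or_ci(b, se, level)
      rows[[length(rows) + 1L]] <- data.frame(
        category = cat_j, term = term, estimate = b, se = se, z = z,
        p_value = p, odds_ratio = or$odds_ratio,
        ci_lower = or$ci_lower, ci_upper = or$ci_upper,
        stars = if (p < 0.01) "***" else if (p < 0.05) "**"
                else if (p < 0.10) "*" else "",
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Likelihood-ratio test of the fitted model against intercept-only
#'
#' `chi2 = 2 (logL_full - logL_null)` on `(J-1) p` degrees of freedom, where
#' p counts the non-intercept predictors.
#'
#' @param fit An `mlr_fit`.
#' @return List `chi2`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(fit) {
  stopifnot(inherits(fit, "mlr_fit"))
  chi2 <- 2 * (fit$log_likelihood - fit$null_log_likelihood)
  if (chi2 < -1e-6) {
    stop("full-model log-likelihood below the null; optimization failure")
  }
  chi2 <- max(chi2, 0)
  df <- (length(fit$categories) - 1L) * length(fit$predictors)
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Cox-Snell and Nagelkerke pseudo-R-squared
#'
#' `cox_snell = 1 - exp((2/n)(logL_null - logL_full))`; Nagelkerke rescales
#' it by its maximum `1 - exp((2/n) logL_null)` so a saturated fit reaches 1.
#'
#' @param fit An `mlr_fit`.
#' @return List `cox_snell`, `nagelkerke`.
#' @export
pseudo_r2 <- function(fit) {
  stopifnot(inherits(fit, "mlr_fit"))
  n <- length(fit$y)
  cs <- 1 - exp((2 / n) * (fit$null_log_likelihood - fit$log_likelihood))
  max_cs <- 1 - exp((2 / n) * fit$null_log_likelihood)
  list(cox_snell = cs, nagelkerke = cs / max_cs)
}

#' Maximum chance criterion
#'
#' 1.25 times the share of the largest observed category: the hit-ratio
#' benchmark a classifier should exceed to claim practical significance.
#'
#' @param counts Integer vector of category counts.
#' @return Proportion in [0, 1.25].
#' @export
max_chance_criterion <- function(counts) {
  stopifnot(all(counts >= 0), sum(counts) > 0)
  1.25 * max(counts) / sum(counts)
}

#' Classification accuracy of the fitted model
#'
#' Predicts the highest-probability category per region and reports the hit
#' ratio, the maximum chance criterion and the practical-significance flag
#' (hit ratio at or above the criterion).
#'
#' @param fit An `mlr_fit`.
#' @return List `hit_ratio`, `max_chance`, `practical_significance`,
#'   `predicted` (factor), `confusion` (table).
#' @export
classification_accuracy <- function(fit) {
  stopifnot(inherits(fit, "mlr_fit"))
  pred_idx <- max.col(fit$fitted, ties.method = "first")
  predicted <- factor(fit$categories[pred_idx], levels = fit$categories)
  hit <- mean(predicted == fit$y)
  mc <- max_chance_criterion(as.vector(table(fit$y)))
  list(hit_ratio = hit, max_chance = mc,
       practical_significance = hit >= mc,
       predicted = predicted, confusion = table(observed = fit$y,
                                                predicted = predicted))
}

#' Tolerance and variance inflation factors
#'
#' For each predictor, an auxiliary least-squares regression on the
#' remaining predictors gives `R2_aux`; `tolerance = 1 - R2_aux` and
#' `vif = 1 / tolerance`. Perfect collinearity is reported as an infinite
#' VIF with a flag rather than an overflow.
#'
#' @param x Numeric predictor matrix (no intercept column), >= 2 columns.
#' @return Data frame `predictor`, `tolerance`, `vif`, `perfect_collinearity`.
#' @export
collinearity_screen <- function(x) {
  x <- as.matrix(x)
  stopifnot(ncol(x) >= 2, nrow(x) > ncol(x))
  rows <- lapply(seq_len(ncol(x)), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((x[, j] - mean(x[, j]))^2)
    tol <- 1 - r2
    perfect <- tol < 1e-12
    data.frame(predictor = colnames(x)[j],
               tolerance = tol,
               vif = if (perfect) Inf else 1 / tol,
               perfect_collinearity = perfect,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hausman-McFadden test of the independence of irrelevant alternatives
#'
#' Refits the model after removing all observations in one non-baseline
#' category and compares the common coefficients with the full-sample fit:
#' `H = (b_r - b_f)' (V_r - V_f)^- (b_r - b_f)` on df = number of common
#' coefficients. When the covariance difference is not positive definite the
#' statistic is computed with a Moore-Penrose generalized inverse and the
#' result is flagged inconclusive.
#'
#' @param design An `mlr_design` (the full design).
#' @param omit_category Non-baseline category whose observations are dropped.
#' @param full_fit Optional pre-computed full fit (recomputed otherwise).
#' @return List `H`, `df`, `p_value`, `validity` (`"valid"` or
#'   `"inconclusive"`), `omitted`.
#' @export
hausman_mcfadden_iia <- function(design, omit_category, full_fit = NULL) {
  stopifnot(inherits(design, "mlr_design") || is.list(design))
  if (omit_category == design$baseline) {
    stop("omit_category must differ from the baseline")
  }
  if (is.null(full_fit)) full_fit <- fit_mlr(design)
  keep_cat <- setdiff(colnames(full_fit$coefficients), omit_category)
  keep_rows <- design$y != omit_category
  if (sum(keep_rows) <= length(keep_cat) * ncol(design$x)) {
    stop("restricted model is not estimable after omitting '",
         omit_category, "'")
  }
  sub <- list(
    x = design$x[keep_rows, , drop = FALSE],
    y = factor(design$y[keep_rows],
               levels = c(keep_cat, design$baseline)),
    baseline = design$baseline
  )
  fit_r <- fit_mlr(sub)
  nm <- as.vector(outer(colnames(design$x), keep_cat,
                        function(a, b) paste(b, a, sep = ":")))
  b_f <- as.vector(full_fit$coefficients[, keep_cat, drop = FALSE])
  b_r <- as.vector(fit_r$coefficients[, keep_cat, drop = FALSE])
  V_f <- full_fit$vcov[nm, nm]
  V_r <- fit_r$vcov[nm, nm]
  D <- V_r - V_f
  d <- b_r - b_f
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  pd <- all(ev > 1e-10 * max(abs(ev), 1e-12))
  Dinv <- if (pd) solve(D) else MASS::ginv(D)
  H <- drop(t(d) %*% Dinv %*% d)
  df <- length(d)
  p <- if (H < 0) 1 else stats::pchisq(H, df, lower.tail = FALSE)
  list(H = H, df = df, p_value = p,
       validity = if (pd && H >= 0) "valid" else "inconclusive",
       omitted = omit_category)
}

#' Full diagnostic battery for a multinomial logit fit
#'
#' @param design The `mlr_design` used for the fit.
#' @param fit The corresponding `mlr_fit`.
#' @return List of class `mlr_diagnostics`: likelihood-ratio test,
#'   pseudo-R2, classification accuracy, collinearity screen and one
#'   Hausman-McFadden test per non-baseline category.
#' @export
mlr_diagnostics <- function(design, fit) {
  iia <- lapply(setdiff(fit$categories, fit$baseline), function(cat_j) {
    tryCatch(hausman_mcfadden_iia(design, cat_j, full_fit = fit),
             error = function(e) list(H = NA_real_, df = NA_integer_,
                                      p_value = NA_real_,
                                      validity = "not estimable",
                                      omitted = cat_j))
  })
  structure(
    list(lr = likelihood_ratio_test(fit),
         pseudo_r2 = pseudo_r2(fit),
         accuracy = classification_accuracy(fit),
         collinearity = collinearity_screen(
           fit$x[, fit$predictors, drop = FALSE]),
         iia = iia),
    class = "mlr_diagnostics"
  )
}

#' @export
print.mlr_diagnostics <- function(x, ...) {
  cat(sprintf("LR test: chi2(%d) = %.3f, p = %.3g\n", x$lr$df, x$lr$chi2,
              x$lr$p_value))
  cat(sprintf("Pseudo-R2: Cox-Snell %.3f, Nagelkerke %.3f\n",
              x$pseudo_r2$cox_snell, x$pseudo_r2$nagelkerke))
  cat(sprintf("Hit ratio %.1f%% vs maximum chance %.1f%% (%spractically significant)\n",
              100 * x$accuracy$hit_ratio, 100 * x$accuracy$max_chance,
              if (x$accuracy$practical_significance) "" else "not "))
  cat(sprintf("Max VIF %.2f\n", max(x$collinearity$vif)))
  for (t in x$iia) {
    cat(sprintf("IIA (omit %s): H = %.3f, df = %s, p = %.3g [%s]\n",
                t$omitted, t$H, t$df, t$p_value, t$validity))
  }
  invisible(x)
}
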