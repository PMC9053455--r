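covariates_by_cluster <- function(covariates, solution, indicator) {
  at <- assignment_table(solution)
  m <- match(at$region_id, covariates$region_id)
  if (anyNA(m)) {
    stop("regions without covariates: ",
         paste(at$region_id[is.na(m)], collapse = ", "))
  }
  split(covariates[[indicator]][m], at$cluster_index)
}

#' Per-cluster indicator means with extreme-value flags
#'
#' Arithmetic mean of every socioeconomic indicator within every cluster,
#' with the max- and min-holding cluster flagged per indicator (the
#' bold/italics convention of a cluster characterization table).
#'
#' @param covariates Regional covariates data frame (columns
#'   [covariate_names()] plus `region_id`).
#' @param solution A `cluster_solution`.
#' @param indicators Indicator columns to tabulate.
#' @return Data frame: `indicator`, one `cluster_<j>` column per cluster,
#'   `largest_in` and `smallest_in` (cluster indices).
#' @export
cluster_means_table <- function(covariates, solution,
                                indicators = covariate_names()) {
  rows <- lapply(indicators, function(ind) {
    g <- covariates_by_cluster(covariates, solution, ind)
    mns <- vapply(g, mean, numeric(1))
    out <- as.data.frame(as.list(mns))
    names(out) <- paste0("cluster_", names(g))
    out$indicator <- ind
    out$largest_in <- as.integer(names(g)[which.max(mns)])
    out$smallest_in <- as.integer(names(g)[which.min(mns)])
    out
  })
  out <- do.call(rbind, rows)
  out[, c("indicator", setdiff(names(out), "indicator"))]
}

#' Univariate normality screening per indicator
#'
#' Shapiro-Wilk test of each indicator within each cluster; an indicator is
#' excluded from the ANOVA battery if normality is rejected at `alpha` in any
#' cluster. Clusters too small to test (n < 3) or with zero variance make the
#' indicator untestable: it is retained with a warning flag rather than
#' silently dropped.
#'
#' @inheritParams cluster_means_table
#' @param alpha Significance level of the screen (default 0.05).
#' @return Data frame `indicator`, `included`, `untestable`, `min_p`,
#'   `reason`.
#' @export
normality_screen <- function(covariates, solution,
                             indicators = covariate_names(), alpha = 0.05) {
  rows <- lapply(indicators, function(ind) {
    g <- covariates_by_cluster(covariates, solution, ind)
    small <- vapply(g, function(v) length(v) < 3 || stats::sd(v) == 0,
                    logical(1))
    if (any(small)) {
      warning("indicator '", ind, "' untestable for normality in cluster(s) ",
              paste(names(g)[small], collapse = ", "), "; included untested")
      return(data.frame(indicator = ind, included = TRUE, untestable = TRUE,
                        min_p = NA_real_, reason = "untestable"))
    }
    p <- vapply(g, function(v) stats::shapiro.test(v)$p.value, numeric(1))
    rejected <- any(p < alpha)
    data.frame(
      indicator = ind, included = !rejected, untestable = FALSE,
      min_p = min(p),
      reason = if (rejected) {
        paste0("normality rejected in cluster(s) ",
               paste(names(g)[p < alpha], collapse = ", "))
      } else "passed"
    )
  })
  do.call(rbind, rows)
}

check_groups <- function(groups, min_size = 2L) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  sizes <- lengths(groups)
  if (any(sizes < min_size)) {
    stop("every group needs at least ", min_size, " observations")
  }
  invisible(sizes)
}

#' Levene's test of variance homogeneity (group-mean centering)
#'
#' Classical Levene statistic: a one-way F test on the absolute deviations of
#' each observation from its group mean. (Mean centering, not the
#' median-centered Brown-Forsythe variant of the variance test.)
#'
#' @param groups List of >= 2 numeric vectors, each of length >= 2.
#' @return List with `statistic`, `df` (numerator, denominator), `p_value`.
#' @export
levene_test <- function(groups) {
  check_groups(groups)
  z <- lapply(groups, function(v) abs(v - mean(v)))
  res <- oneway_anova(z)
  list(statistic = res$statistic, df = res$df, p_value = res$p_value)
}

#' Classical one-way ANOVA
#'
#' Between/within mean-square F ratio with k-1 and N-k degrees of freedom.
#' The degenerate case of zero within-group variance with unequal means is
#' reported explicitly as infinite F with p = 0.
#'
#' @inheritParams levene_test
#' @return List `statistic`, `df`, `p_value`, plus the sums of squares.
#' @export
oneway_anova <- function(groups) {
  check_groups(groups)
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  if (N <= k) stop("total sample size must exceed the number of groups")
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(n * means) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  df <- c(k - 1L, N - k)
  if (ssw == 0) {
    if (ssb == 0) {
      return(list(statistic = 0, df = df, p_value = 1, ssb = 0, ssw = 0))
    }
    return(list(statistic = Inf, df = df, p_value = 0, ssb = ssb, ssw = 0))
  }
  f <- (ssb / df[1]) / (ssw / df[2])
  list(statistic = f, df = df,
       p_value = stats::pf(f, df[1], df[2], lower.tail = FALSE),
       ssb = ssb, ssw = ssw)
}

#' Brown-Forsythe robust test of equal means
#'
#' The F* statistic for equality of group means under heteroscedasticity:
#' the between-group sum of squares is referenced against
#' sum (1 - n_j/N) s_j^2, with a Satterthwaite-type approximation for the
#' denominator degrees of freedom. With two groups it coincides with Welch's
#' t test (F* = t^2). Used in place of classical ANOVA when Levene's test
#' rejects homoscedasticity.
#'
#' @inheritParams levene_test
#' @return List `statistic`, `df` (df1 = k-1, fractional df2), `p_value`.
#' @export
brown_forsythe_robust <- function(groups) {
  check_groups(groups)
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  means <- vapply(groups, mean, numeric(1))
  vars <- vapply(groups, stats::var, numeric(1))
  grand <- sum(n * means) / N
  num <- sum(n * (means - grand)^2)
  w <- (1 - n / N) * vars
  den <- sum(w)
  if (den == 0) {
    p <- if (num == 0) 1 else 0
    return(list(statistic = if (num == 0) 0 else Inf, df = c(k - 1, NA), p_value = p))
  }
  fstar <- num / den
  cj <- w / den
  df2 <- 1 / sum(cj^2 / (n - 1))
  list(statistic = fstar, df = c(k - 1L, df2),
       p_value = stats::pf(fstar, k - 1, df2, lower.tail = FALSE))
}

#' Pairwise post hoc comparisons (Bonferroni or Tamhane's T2)
#'
#' Under homoscedasticity: pairwise t tests on the pooled within-group
#' variance (df = N - k) with Bonferroni adjustment, p_adj = min(1, m p).
#' Otherwise Tamhane's T2: pairwise Welch t tests with the Sidak-type
#' conservative adjustment p_adj = 1 - (1 - p)^m, capped at 1, where m is the
#' number of pairs.
#'
#' @inheritParams levene_test
#' @param homoscedastic Logical; selects Bonferroni (TRUE) vs Tamhane T2.
#' @param alpha Significance level used for the `significant` flag.
#' @return Data frame with one row per group pair: `group_i`, `group_j`,
#'   `mean_diff`, `p_raw`, `p_adj`, `significant`, `procedure`.
#' @export
posthoc_pairwise <- function(groups, homoscedastic = TRUE, alpha = 0.05) {
  check_groups(groups)
  k <- length(groups)
  nm <- names(groups)
  if (is.null(nm)) nm <- as.character(seq_len(k))
  n <- lengths(groups)
  N <- sum(n)
  means <- vapply(groups, mean, numeric(1))
  vars <- vapply(groups, stats::var, numeric(1))
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  mse <- sum((n - 1) * vars) / (N - k)
  rows <- lapply(seq_len(m), function(q) {
    i <- pairs[1, q]; j <- pairs[2, q]
    diff <- means[i] - means[j]
    if (homoscedastic) {
      se <- sqrt(mse * (1 / n[i] + 1 / n[j]))
      df <- N - k
      procedure <- "bonferroni"
    } else {
      se <- sqrt(vars[i] / n[i] + vars[j] / n[j])
      df <- se^4 / ((vars[i] / n[i])^2 / (n[i] - 1) +
                    (vars[j] / n[j])^2 / (n[j] - 1))
      procedure <- "tamhane_t2"
    }
    p_raw <- if (se == 0) {
      if (diff == 0) 1 else 0
    } else {
      2 * stats::pt(abs(diff) / se, df, lower.tail = FALSE)
    }
    p_adj <- if (homoscedastic) min(1, m * p_raw) else
      min(1, 1 - (1 - p_raw)^m)
    data.frame(group_i = nm[i], group_j = nm[j], mean_diff = diff,
               p_raw = p_raw, p_adj = p_adj, significant = p_adj < alpha,
               procedure = procedure, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full cluster-characterization ANOVA battery
#'
#' For every indicator passing (or untestable under) the normality screen:
#' Levene's test chooses between classical one-way ANOVA (homoscedastic) and
#' the Brown-Forsythe robust means test, and between Bonferroni and Tamhane
#' T2 pairwise post hoc comparisons.
#'
#' @inheritParams cluster_means_table
#' @param alpha Significance level for every test in the battery.
#' @return An object of class `anova_profile`: a list with the normality
#'   `screen`, and per-indicator `results` (statistic, df, p, robust flag,
#'   Levene p, post hoc table and a summary string such as
#'   `"C1 != {C2, C3, C4}"`).
#' @export
anova_profile <- function(covariates, solution,
                          indicators = covariate_names(), alpha = 0.05) {
  screen <- normality_screen(covariates, solution, indicators, alpha)
  results <- lapply(indicators, function(ind) {
    row <- screen[screen$indicator == ind, ]
    if (!row$included) {
      return(list(indicator = ind, included = FALSE, reason = row$reason))
    }
    g <- covariates_by_cluster(covariates, solution, ind)
    lev <- levene_test(g)
    homo <- lev$p_value >= alpha
    test <- if (homo) oneway_anova(g) else brown_forsythe_robust(g)
    ph <- posthoc_pairwise(g, homoscedastic = homo, alpha = alpha)
    list(indicator = ind, included = TRUE, reason = row$reason,
         f_stat = test$statistic, df = test$df, p_value = test$p_value,
         robust_used = !homo, levene_p = lev$p_value, pairwise = ph,
         summary = summarize_pairs(ph))
  })
  names(results) <- indicators
  structure(list(screen = screen, results = results, alpha = alpha),
            class = "anova_profile")
}

# "C1 != {C2, C3}"-style summary of the significant pairs
summarize_pairs <- function(ph) {
  sig <- ph[ph$significant, , drop = FALSE]
  if (nrow(sig) == 0L) return("-")
  paste(sprintf("C%s != C%s", sig$group_i, sig$group_j), collapse = "; ")
}

#' @export
print.anova_profile <- function(x, ...) {
  cat("Cluster characterization ANOVA battery (alpha =", x$alpha, ")\n")
  for (res in x$results) {
    if (!res$included) {
      cat(sprintf("  %-20s excluded (%s)\n", res$indicator, res$reason))
    } else {
      cat(sprintf("  %-20s F%s = %.3f, p = %.4f%s | %s\n", res$indicator,
                  if (res$robust_used) "*" else "", res$f_stat, res$p_value,
                  if (res$robust_used) " [Brown-Forsythe, Tamhane T2]"
                  else " [ANOVA, Bonferroni]",
                  res$summary))
    }
  }
  invisible(x)
}
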