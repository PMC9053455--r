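rate_cols <- function() {
  c("rate_non_active", "rate_below_healthy", "rate_healthy",
    "rate_extra_healthy")
}

profile_matrix <- function(profiles) {
  stopifnot(all(rate_cols() %in% names(profiles)))
  if (nrow(profiles) < 2L) stop("need at least 2 regional profiles")
  # sort by region_id so the whole stage is invariant to input row order
  profiles <- profiles[order(profiles$region_id), , drop = FALSE]
  x <- as.matrix(profiles[, rate_cols()])
  rownames(x) <- profiles$region_id
  x
}

#' Hierarchical clustering of regional activity profiles
#'
#' Agglomerates regions on their four raw percentage rates. Ward's method is
#' only defined on squared Euclidean dissimilarities and is rejected with any
#' other measure. Heights follow the `stats::hclust` `ward.D` convention on
#' squared distances: a merge of two singletons occurs at their squared
#' Euclidean distance, i.e. twice the increase in within-cluster error sum of
#' squares.
#'
#' @param profiles A `pa_profile` data frame (see [regionalize()]).
#' @param linkage One of `"ward"`, `"complete"`, `"average"`, `"single"`.
#' @param distance One of `"squared_euclidean"`, `"euclidean"`,
#'   `"manhattan"`; `"ward"` requires `"squared_euclidean"`.
#' @param k_range Candidate numbers of clusters to cut the tree at.
#' @return A list of class `hier_run` with the `hclust` tree, the cut
#'   partitions (one named integer vector per k) and the run metadata.
#' @export
hierarchical_cluster <- function(profiles, linkage = "ward",
                                 distance = "squared_euclidean",
                                 k_range = 2:6) {
  linkage <- match.arg(linkage, c("ward", "complete", "average", "single"))
  distance <- match.arg(distance,
                        c("squared_euclidean", "euclidean", "manhattan"))
  if (linkage == "ward" && distance != "squared_euclidean") {
    stop("Ward linkage requires the squared Euclidean distance")
  }
  x <- profile_matrix(profiles)
  k_range <- k_range[k_range >= 1 & k_range <= nrow(x)]
  d <- switch(distance,
    squared_euclidean = stats::dist(x)^2,
    euclidean = stats::dist(x),
    manhattan = stats::dist(x, method = "manhattan")
  )
  method <- if (linkage == "ward") "ward.D" else linkage
  tree <- stats::hclust(d, method = method)
  partitions <- lapply(k_range, function(k) stats::cutree(tree, k = k))
  names(partitions) <- as.character(k_range)
  structure(
    list(tree = tree, partitions = partitions, linkage = linkage,
         distance = distance, heights = tree$height, region_ids = rownames(x)),
    class = "hier_run"
  )
}

#' Explore cluster-count robustness across linkage rules and distances
#'
#' Runs hierarchical clustering under every admissible (linkage, distance)
#' combination supplied and records, per candidate k, the agreement between
#' the cut partitions as the mean pairwise adjusted Rand index.
#'
#' @inheritParams hierarchical_cluster
#' @param linkages Character vector of linkage rules to try.
#' @param distances Character vector of distance measures to try (Ward is
#'   automatically paired with squared Euclidean only).
#' @return A list of class `linkage_exploration` with the individual runs and
#'   an `agreement` data frame (k, mean pairwise ARI, number of run pairs).
#' @export
explore_linkages <- function(profiles,
                             linkages = c("ward", "complete", "average"),
                             distances = c("squared_euclidean", "euclidean"),
                             k_range = 2:6) {
  combos <- expand.grid(linkage = linkages, distance = distances,
                        stringsAsFactors = FALSE)
  keep <- !(combos$linkage == "ward" & combos$distance != "squared_euclidean")
  # complete and single linkage depend only on the distance ranking, so the
  # squared-Euclidean run duplicates the Euclidean one; keep a single copy
  dup <- combos$linkage %in% c("complete", "single") &
    combos$distance == "squared_euclidean" &
    "euclidean" %in% distances
  combos <- combos[keep & !dup, , drop = FALSE]
  if (nrow(combos) < 2L) stop("need at least 2 (linkage, distance) runs")
  runs <- lapply(seq_len(nrow(combos)), function(i) {
    hierarchical_cluster(profiles, combos$linkage[i], combos$distance[i],
                         k_range)
  })
  ks <- Reduce(intersect, lapply(runs, function(r) names(r$partitions)))
  agreement <- do.call(rbind, lapply(ks, function(k) {
    parts <- lapply(runs, function(r) r$partitions[[k]])
    pairs <- utils::combn(length(parts), 2)
    aris <- apply(pairs, 2, function(p) {
      mclust::adjustedRandIndex(parts[[p[1]]], parts[[p[2]]])
    })
    data.frame(k = as.integer(k), mean_ari = mean(aris),
               n_pairs = ncol(pairs))
  }))
  structure(list(runs = runs, combos = combos, agreement = agreement),
            class = "linkage_exploration")
}

#' Recommend the number of clusters from a linkage exploration
#'
#' Recommends the smallest k >= 2 whose mean pairwise adjusted Rand index
#' across runs exceeds the robustness threshold. If none qualifies, no
#' recommendation is returned and the caller must fix k explicitly.
#'
#' @param exploration A `linkage_exploration` from [explore_linkages()].
#' @param threshold Mean-ARI robustness threshold (default 0.8).
#' @return List with `k` (integer or `NA` when no candidate qualifies) and
#'   the per-k `report` data frame.
#' @export
choose_k <- function(exploration, threshold = 0.8) {
  stopifnot(inherits(exploration, "linkage_exploration"))
  rep <- exploration$agreement
  ok <- rep$k >= 2 & rep$mean_ari > threshold
  k <- if (any(ok)) min(rep$k[ok]) else NA_integer_
  if (is.na(k)) {
    warning("no candidate k reaches mean ARI > ", threshold,
            "; choose k explicitly")
  }
  list(k = k, report = rep, threshold = threshold)
}

#' Centroids of a hierarchical partition
#'
#' @param profiles A `pa_profile` data frame.
#' @param partition Named integer vector (region_id -> cluster) as returned
#'   in `hier_run$partitions`.
#' @return Numeric matrix, one row per cluster, of mean rate vectors; used as
#'   K-means seeds.
#' @export
partition_centroids <- function(profiles, partition) {
  x <- profile_matrix(profiles)
  partition <- partition[rownames(x)]
  if (anyNA(partition)) stop("partition does not cover all regions")
  ks <- sort(unique(partition))
  cent <- t(vapply(ks, function(k) colMeans(x[partition == k, , drop = FALSE]),
                   numeric(ncol(x))))
  rownames(cent) <- ks
  cent
}

kmeans_inertia <- function(x, centroids, assign) {
  sum((x - centroids[assign, , drop = FALSE])^2)
}

#' K-means refinement from fixed seed centroids
#'
#' Deterministic Lloyd iteration started from the supplied centroids (no
#' random restarts): regions are assigned to their nearest centroid (ties to
#' the lowest cluster index), centroids are recomputed as cluster means, and
#' iteration stops when assignments no longer change or `max_iter` is
#' reached. An emptied cluster is re-seeded with the point farthest from its
#' current centroid, with a message.
#'
#' @param profiles A `pa_profile` data frame.
#' @param seeds k x 4 matrix of distinct starting centroids (rows), e.g. the
#'   Ward-solution centroids from [partition_centroids()].
#' @param max_iter Iteration cap (default 300).
#' @return An object of class `cluster_solution` with `assignments` (named
#'   integer vector), `centroids`, `inertia`, `seed_centroids`, `k`,
#'   `iterations`, `converged` and (after [label_clusters()]) `labels`.
#' @export
kmeans_from_seeds <- function(profiles, seeds, max_iter = 300L) {
  x <- profile_matrix(profiles)
  seeds <- as.matrix(seeds)
  k <- nrow(seeds)
  stopifnot(k >= 1, k <= nrow(x), ncol(seeds) == ncol(x))
  if (anyDuplicated(seeds)) stop("seed centroids must be distinct")
  centroids <- unname(seeds)
  assign_prev <- rep(0L, nrow(x))
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    d2 <- outer(rowSums(x^2), rep(1, k)) - 2 * x %*% t(centroids) +
      outer(rep(1, nrow(x)), rowSums(centroids^2))
    assign <- max.col(-d2, ties.method = "first")
    for (j in seq_len(k)) {
      if (!any(assign == j)) {
        far <- which.max(d2[cbind(seq_len(nrow(x)), assign)])
        message("cluster ", j, " emptied; re-seeded at region ",
                rownames(x)[far])
        assign[far] <- j
      }
    }
    if (identical(assign, assign_prev)) {
      converged <- TRUE
      break
    }
    centroids <- t(vapply(seq_len(k), function(j) {
      colMeans(x[assign == j, , drop = FALSE])
    }, numeric(ncol(x))))
    assign_prev <- assign
    if (iter >= max_iter) break
  }
  colnames(centroids) <- colnames(x)
  structure(
    list(assignments = stats::setNames(assign, rownames(x)),
         centroids = centroids,
         inertia = kmeans_inertia(x, centroids, assign),
         seed_centroids = seeds, k = k, iterations = iter,
         converged = converged, labels = NULL),
    class = "cluster_solution"
  )
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("K-means cluster solution: k =", x$k, ", n =", length(x$assignments),
      "regions, inertia =", format(x$inertia, digits = 6), "\n")
  sizes <- table(x$assignments)
  for (j in seq_len(x$k)) {
    lab <- if (!is.null(x$labels)) paste0(" (", x$labels[[as.character(j)]], ")")
           else ""
    cat(sprintf("  cluster %d%s: %d regions; centroid [%s]\n", j, lab,
                sizes[as.character(j)],
                paste(sprintf("%.1f", x$centroids[j, ]), collapse = ", ")))
  }
  invisible(x)
}

#' Label the four clusters by their dominant rate
#'
#' Assigns the names extra-healthy / healthy / below-healthy / unhealthy to
#' the clusters whose centroids stand out in the extra-healthy, healthy,
#' below-healthy and non-active rates respectively. The labeling is the
#' one-to-one assignment maximizing the sum of the four selected centroid
#' components, so it remains a bijection even under ties.
#'
#' @param solution A `cluster_solution` with k = 4 (otherwise labeling is
#'   skipped with a warning).
#' @return The solution with `labels` filled (cluster index -> label).
#' @export
label_clusters <- function(solution) {
  stopifnot(inherits(solution, "cluster_solution"))
  if (solution$k != 4L) {
    warning("cluster labeling requires k = 4; skipped")
    return(solution)
  }
  label_rate <- c(extra_healthy = "rate_extra_healthy",
                  healthy = "rate_healthy",
                  below_healthy = "rate_below_healthy",
                  unhealthy = "rate_non_active")
  score <- solution$centroids[, label_rate, drop = FALSE] # cluster x label
  perms <- perm4()
  best <- perms[[which.max(vapply(perms, function(p) {
    sum(score[cbind(p, seq_len(4))])
  }, numeric(1)))]]
  labels <- character(4)
  labels[best] <- names(label_rate)
  solution$labels <- stats::setNames(labels, as.character(seq_len(4)))
  solution
}

perm4 <- function() {
  out <- list()
  for (a in 1:4) for (b in 1:4) for (c in 1:4) for (d in 1:4) {
    p <- c(a, b, c, d)
    if (length(unique(p)) == 4L) out[[length(out) + 1L]] <- p
  }
  out
}

#' End-to-end taxonomy: Ward seeding, K-means refinement, labeling
#'
#' Convenience wrapper reproducing the two-stage procedure: Ward hierarchical
#' clustering on squared Euclidean distances supplies the k-cluster
#' centroids, which seed a deterministic K-means refinement; with k = 4 the
#' clusters are then labeled by their dominant rates.
#'
#' @inheritParams hierarchical_cluster
#' @param k Number of clusters (default 4).
#' @return A labeled `cluster_solution`.
#' @export
build_taxonomy <- function(profiles, k = 4L) {
  run <- hierarchical_cluster(profiles, "ward", "squared_euclidean",
                              k_range = k)
  seeds <- partition_centroids(profiles, run$partitions[[as.character(k)]])
  sol <- kmeans_from_seeds(profiles, seeds)
  if (k == 4L) sol <- label_clusters(sol)
  sol
}

#' Cluster assignments as a data frame
#'
#' @param solution A `cluster_solution`.
#' @return Data frame `region_id`, `cluster_index`, `cluster_label`.
#' @export
assignment_table <- function(solution) {
  stopifnot(inherits(solution, "cluster_solution"))
  idx <- as.integer(solution$assignments)
  lab <- if (is.null(solution$labels)) NA_character_
         else unname(solution$labels[as.character(idx)])
  data.frame(region_id = names(solution$assignments),
             cluster_index = idx, cluster_label = lab,
             stringsAsFactors = FALSE)
}
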