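# Behavioral-state discovery: k-means on the z-scored feature matrix,
# a seed-fixed 2-D embedding for plotting, and the enrichment /
# distribution statistics computed on cluster assignments.

# k-means++ seeding: first center uniform, subsequent centers sampled
# proportional to squared distance from the nearest chosen center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  if (k > 1) {
    d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
    for (j in 2:k) {
      probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx <- sample.int(n, 1, prob = probs)
      centers[j, ] <- x[idx, ]
      d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
    }
  }
  centers
}

#' Discover behavioral states by k-means
#'
#' Runs k-means with k-means++ initialization and multiple restarts on the
#' z-scored feature matrix, keeping the lowest-inertia solution. The result
#' is deterministic for a fixed seed. Cluster label order carries no
#' meaning; cross-run comparisons should use label-invariant scores.
#'
#' @param features a `feature_matrix` from [pool_zscore_subsample()], or a
#'   plain numeric matrix.
#' @param k number of states (default 8).
#' @param seed RNG seed.
#' @param nstart number of k-means++ restarts (default 10).
#' @param iter_max Lloyd iteration cap per restart.
#' @return An object of class `state_model`: list with `centroids`
#'   (`k x 7`), `labels` (per-row cluster in `0..k-1`), `inertia` (total
#'   within-cluster sum of squares), `k`, `seed`, and the row `provenance`
#'   when available.
#' @export
fit_states <- function(features, k = 8, seed = 1, nstart = 10,
                       iter_max = 100) {
  x <- if (inherits(features, "feature_matrix")) features$x else as.matrix(features)
  prov <- if (inherits(features, "feature_matrix")) features$provenance else NULL
  if (k < 1) stop_validation("k must be >= 1")
  if (nrow(x) < k) stop_validation("k exceeds the number of rows")
  fit <- with_seed(seed, {
    best <- NULL
    for (r in seq_len(nstart)) {
      init <- kmeanspp_centers(x, k)
      km <- suppressWarnings(
        kmeans(x, centers = init, iter.max = iter_max, algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    best
  })
  structure(list(centroids = unname(fit$centers),
                 labels = unname(fit$cluster) - 1L,
                 inertia = fit$tot.withinss,
                 k = k, seed = seed, provenance = prov),
            class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat("Behavioral state model: k =", x$k, ", inertia =",
      format(x$inertia, digits = 6), ", seed =", x$seed, "\n")
  cat("cluster sizes:", paste(tabulate(x$labels + 1L, x$k), collapse = " "), "\n")
  invisible(x)
}

#' Assign new frames to the nearest learned state
#'
#' @param object a `state_model`.
#' @param newdata a `feature_matrix` or numeric matrix in the same z-scored
#'   feature space the model was fit in.
#' @param ... unused.
#' @return Integer cluster labels in `0..k-1`.
#' @export
predict.state_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_matrix")) newdata$x else as.matrix(newdata)
  d <- apply(object$centroids, 1, function(ct) rowSums(sweep(x, 2, ct)^2))
  max.col(-matrix(d, nrow = nrow(x))) - 1L
}

#' 2-D embedding of the feature matrix for plotting
#'
#' UMAP projection of the pooled feature rows, with the random state fixed
#' so plots are reproducible. The embedding is for visualization only:
#' cluster assignments come from [fit_states()] on the full feature space
#' and never depend on this projection.
#'
#' @param features a `feature_matrix` or numeric matrix.
#' @param seed RNG seed (default 42).
#' @param n_neighbors UMAP neighborhood size; capped at `rows - 1`.
#' @return A two-column matrix of (x, y) coordinates, one row per input row.
#' @export
embed_2d <- function(features, seed = 42, n_neighbors = 15) {
  x <- if (inherits(features, "feature_matrix")) features$x else as.matrix(features)
  if (nrow(x) < 3) stop_validation("at least 3 rows required for embedding")
  n_neighbors <- min(n_neighbors, nrow(x) - 1)
  emb <- with_seed(seed,
    uwot::umap(x, n_neighbors = n_neighbors, n_threads = 1,
               n_sgd_threads = 0, verbose = FALSE))
  colnames(emb) <- c("x", "y")
  emb
}

#' Attach cluster labels to frame provenance and rank metadata
#'
#' @param model a `state_model` fit on a `feature_matrix` (so provenance is
#'   available), or pass `provenance` explicitly.
#' @param ranks a data frame with columns `recording, rank_a, rank_b`
#'   giving each recording animal's 1-4 rank from the reward-competition
#'   Elo ordering; the rank difference `|rank_a - rank_b|` stratifies the
#'   enrichment analysis. Recordings absent from `ranks` get `NA` and are
#'   excluded from enrichment.
#' @param provenance optional data frame `recording, frame` overriding the
#'   model's stored provenance.
#' @return A data frame of class `state_assignment` with columns
#'   `recording, frame, cluster, rank_diff`.
#' @export
state_assignment <- function(model, ranks = NULL, provenance = NULL) {
  prov <- provenance %||% model$provenance
  if (is.null(prov)) stop_validation("no provenance available; pass provenance =")
  if (nrow(prov) != length(model$labels)) {
    stop_validation("provenance rows must match model labels")
  }
  out <- data.frame(recording = prov$recording, frame = prov$frame,
                    cluster = model$labels, rank_diff = NA_integer_,
                    stringsAsFactors = FALSE)
  if (!is.null(ranks)) {
    rd <- abs(ranks$rank_a - ranks$rank_b)
    out$rank_diff <- rd[match(out$recording, ranks$recording)]
  }
  class(out) <- c("state_assignment", "data.frame")
  out
}

#' Percent enrichment of clusters by rank difference
#'
#' For rank-difference stratum i and cluster j, enrichment is
#' `n_ij / n_i. - n_.j / N`: the stratum's share of its frames in the
#' cluster, minus the cluster's share of all frames. Positive values mean
#' the state is over-represented in that stratum. Each stratum's row sums
#' to zero. Frames without rank metadata are excluded.
#'
#' @param assign a `state_assignment` with `rank_diff` set.
#' @param strata optional vector of rank-difference strata to tabulate
#'   (defaults to those observed); a requested stratum with zero frames
#'   yields an `NA` row and a warning, never a silent zero.
#' @return An object of class `enrichment_table`: list with `enrichment`
#'   (strata x clusters matrix), `n_ij`, `n_i`, `n_j`, `N`.
#' @export
percent_enriched <- function(assign, strata = NULL) {
  df <- as.data.frame(assign)
  df <- df[!is.na(df$rank_diff), , drop = FALSE]
  if (nrow(df) == 0) stop_validation("no frames carry rank metadata")
  strata <- strata %||% sort(unique(df$rank_diff))
  clusters <- sort(unique(df$cluster))
  n_ij <- table(factor(df$rank_diff, levels = strata),
                factor(df$cluster, levels = clusters))
  n_ij <- unclass(n_ij)
  n_i <- rowSums(n_ij)
  n_j <- colSums(n_ij)
  N <- sum(n_ij)
  enr <- sweep(n_ij / ifelse(n_i > 0, n_i, NA), 2, n_j / N)
  if (any(n_i == 0)) {
    warning("rank-difference stratum with zero frames: ",
            paste(strata[n_i == 0], collapse = ", "))
  }
  dimnames(enr) <- list(rank_diff = strata, cluster = clusters)
  structure(list(enrichment = enr, n_ij = n_ij, n_i = n_i, n_j = n_j, N = N),
            class = "enrichment_table")
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat("Percent enrichment (rank-difference strata x clusters), N =", x$N, "\n")
  print(round(x$enrichment, 4), ...)
  invisible(x)
}

#' Per-recording cluster distributions
#'
#' Fraction of each recording's frames assigned to each cluster
#' (`frames in cluster / total frames in the recording`); rows sum to 1.
#' These per-recording fractions are the unit of analysis for group
#' comparisons of state usage.
#'
#' @param assign a `state_assignment`.
#' @return A recordings x clusters matrix of fractions.
#' @export
cluster_distribution <- function(assign) {
  df <- as.data.frame(assign)
  if (nrow(df) == 0) stop_validation("empty assignment")
  clusters <- sort(unique(df$cluster))
  tab <- table(df$recording, factor(df$cluster, levels = clusters))
  tab <- unclass(tab)
  empty <- rowSums(tab) == 0
  if (any(empty)) {
    warning("recording(s) with no labeled frames excluded: ",
            paste(rownames(tab)[empty], collapse = ", "))
    tab <- tab[!empty, , drop = FALSE]
  }
  sweep(tab, 1, rowSums(tab), "/")
}

#' Sample frames from each cluster for human review
#'
#' Draws up to `n` frames uniformly without replacement from each cluster
#' (all frames when a cluster is smaller than `n`), reproducibly for a
#' fixed seed. The sampled `(recording, frame)` lists are the ingredients
#' of the cluster-review videos used to decide whether a clustering is
#' interpretable.
#'
#' @param assign a `state_assignment`.
#' @param n frames per cluster (default 600).
#' @param seed RNG seed.
#' @return Named list (one element per cluster) of data frames with
#'   columns `recording, frame`.
#' @export
sample_cluster_frames <- function(assign, n = 600, seed = 1) {
  if (n < 1) stop_validation("n must be >= 1")
  df <- as.data.frame(assign)
  clusters <- sort(unique(df$cluster))
  with_seed(seed, {
    out <- lapply(clusters, function(cl) {
      rows <- df[df$cluster == cl, c("recording", "frame"), drop = FALSE]
      if (nrow(rows) == 0) {
        warning("empty cluster: ", cl)
        return(rows)
      }
      take <- min(n, nrow(rows))
      rows[sample.int(nrow(rows), take), , drop = FALSE]
    })
    names(out) <- as.character(clusters)
    out
  })
}
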