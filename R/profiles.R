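# Group response profiles: 27-dim pattern-frequency features, PCA to >95%
# variance, a 2-D embedding for inspection, and spectral clustering with
# silhouette-based model selection.

#' Per-group pattern-frequency feature matrix
#'
#' Aggregates each group's individual-trials into a 27-dimensional vector of
#' relative transition-pattern frequencies (rows sum to 1). All groups must
#' share the same trial x individual design.
#'
#' @param states data.frame with `group`, `before`, `during`, `after` (and
#'   optionally `condition`) columns.
#' @return Numeric matrix groups x 27 with rownames = group ids, colnames =
#'   pattern labels, and a `condition` attribute (one label per row).
#' @export
build_group_features <- function(states) {
  check_triples(states)
  if (!"group" %in% names(states)) stop("`states` needs a group column", call. = FALSE)
  groups <- sort(unique(states$group))
  sizes <- table(states$group)
  if (length(unique(as.integer(sizes))) != 1L) {
    stop("groups differ in number of individual-trials: unequal designs", call. = FALSE)
  }
  idx <- pattern_index(states$before, states$during, states$after)
  pat <- enumerate_patterns()
  feat <- t(vapply(groups, function(g) {
    tabulate(idx[states$group == g] + 1L, nbins = 27L)
  }, numeric(27)))
  feat <- feat / rowSums(feat)
  dimnames(feat) <- list(groups, pat$pattern)
  if ("condition" %in% names(states)) {
    cond <- vapply(groups, function(g) {
      as.character(states$condition[states$group == g][1])
    }, "")
    attr(feat, "condition") <- unname(cond)
  }
  feat
}

#' PCA reduction to >95% cumulative explained variance
#'
#' Centred (unscaled) principal component analysis; keeps the smallest number
#' of leading components whose cumulative explained variance exceeds the
#' threshold.
#'
#' @param features Numeric matrix (e.g. from [build_group_features()]),
#'   at least 2 rows.
#' @param threshold Cumulative explained-variance threshold.
#' @return List with `scores` (rows x d95 projection), `d95`, `var_ratio`
#'   (per-component explained-variance ratios) and the `prcomp` fit.
#' @export
reduce_pca_95 <- function(features, threshold = 0.95) {
  if (nrow(features) < 2L) stop("need at least 2 rows for PCA", call. = FALSE)
  if (all(apply(features, 2, stats::sd) == 0)) {
    stop("zero variance: features are constant", call. = FALSE)
  }
  fit <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  var_ratio <- fit$sdev^2 / sum(fit$sdev^2)
  d95 <- which(cumsum(var_ratio) > threshold)[1]
  list(scores = fit$x[, seq_len(d95), drop = FALSE], d95 = d95,
       var_ratio = var_ratio, fit = fit)
}

#' Two-dimensional embedding of the reduced profiles
#'
#' Projects the PCA scores to two dimensions for visual inspection of the
#' cluster structure, via classical (metric) multidimensional scaling on the
#' Euclidean distances. The embedding is fully deterministic; the seed is
#' accepted (and set) so the call site's reproducibility contract is uniform
#' across stages. Clustering never uses this embedding.
#'
#' @param scores Numeric matrix with at least 4 rows.
#' @param seed Integer seed.
#' @return Numeric matrix rows x 2.
#' @export
embed_2d <- function(scores, seed = 1) {
  if (nrow(scores) < 4L) stop("need at least 4 rows to embed", call. = FALSE)
  with_seed(seed, {
    emb <- stats::cmdscale(stats::dist(scores), k = 2)
    if (ncol(emb) < 2L) emb <- cbind(emb, 0)[, 1:2, drop = FALSE]
    colnames(emb) <- c("dim1", "dim2")
    rownames(emb) <- rownames(scores)
    emb
  })
}

# number of connected components of a 0/1 adjacency matrix (BFS)
n_components <- function(A) {
  n <- nrow(A)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] == 0L) {
      cur <- cur + 1L
      queue <- s
      comp[s] <- cur
      while (length(queue) > 0L) {
        v <- queue[1]; queue <- queue[-1]
        nb <- which(A[v, ] > 0 & comp == 0L)
        comp[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  cur
}

# Spectral clustering on a symmetrised k-nearest-neighbour connectivity
# graph: symmetric normalised Laplacian, k smallest eigenvectors,
# row-normalised, k-means. The neighbourhood starts small (so compact
# clusters of a few groups are not bridged away) and grows until the graph
# has at most k connected components (more components than clusters would
# make the bottom eigenspace ambiguous).
spectral_cluster <- function(x, k, n_neighbors = NULL) {
  n <- nrow(x)
  if (k < 2L || k > n - 1L) stop("`k` must be in [2, n-1]", call. = FALSE)
  if (is.null(n_neighbors)) n_neighbors <- max(2L, min(n - 1L, floor(log(n))))
  d <- as.matrix(stats::dist(x))
  nn_order <- apply(d, 1L, order)
  build_A <- function(nn) {
    A <- matrix(0, n, n)
    for (i in seq_len(n)) A[i, nn_order[2:(nn + 1L), i]] <- 1
    pmax(A, t(A)) # connectivity-symmetrised
  }
  A <- build_A(n_neighbors)
  while (n_components(A) > k && n_neighbors < n - 1L) {
    n_neighbors <- n_neighbors + 1L
    A <- build_A(n_neighbors)
  }
  deg <- rowSums(A)
  dhalf <- 1 / sqrt(pmax(deg, .Machine$double.eps))
  L <- diag(n) - (dhalf * A) %*% diag(dhalf) # I - D^{-1/2} A D^{-1/2}
  ev <- eigen((L + t(L)) / 2, symmetric = TRUE)
  U <- ev$vectors[, n - seq_len(k) + 1L, drop = FALSE] # k smallest eigenvalues
  U <- U / pmax(sqrt(rowSums(U^2)), .Machine$double.eps)
  # rows of U can be duplicates (tight clusters), which stalls Hartigan-Wong;
  # quality is governed by nstart, so the non-convergence warning is noise
  km <- suppressWarnings(stats::kmeans(U, centers = k, nstart = 50, iter.max = 200))
  km$cluster
}

#' Spectral clustering with silhouette-based selection of k
#'
#' Runs spectral clustering on the PCA scores for each candidate number of
#' clusters, scores each partition by the mean silhouette width computed in
#' the same space, and keeps the k with the highest silhouette. Deterministic
#' given the seed.
#'
#' @param scores PCA score matrix (rows = groups).
#' @param k_grid Candidate cluster counts (all within \[2, n-1\]).
#' @param seed Integer seed for the k-means step.
#' @param n_neighbors Neighbourhood size of the affinity graph (default
#'   `floor(log(n))`, at least 2 - kept small so clusters of a few groups are
#'   not bridged away).
#' @return List with `cluster` (named integer vector, 0-based cluster ids),
#'   `k`, `silhouette` (data.frame k, score) and `n_neighbors`.
#' @export
cluster_with_silhouette <- function(scores, k_grid = 2:6, seed = 1,
                                    n_neighbors = NULL) {
  n <- nrow(scores)
  if (any(k_grid < 2L) || any(k_grid > n - 1L)) {
    stop(sprintf("`k_grid` must lie within [2, %d]", n - 1L), call. = FALSE)
  }
  if (n < max(k_grid) + 1L) stop("too few rows for the requested k_grid", call. = FALSE)
  dmat <- stats::dist(scores)
  res <- with_seed(seed, {
    lapply(k_grid, function(k) {
      cl <- spectral_cluster(scores, k, n_neighbors)
      sil <- mean(cluster::silhouette(cl, dmat)[, "sil_width"])
      list(k = k, cluster = cl, sil = sil)
    })
  })
  sils <- vapply(res, `[[`, 0, "sil")
  best <- res[[which.max(sils)]]
  cl <- best$cluster - 1L # 0-based ids, matching the published cluster labels
  names(cl) <- rownames(scores)
  list(cluster = cl, k = best$k,
       silhouette = data.frame(k = k_grid, score = sils),
       n_neighbors = n_neighbors)
}

#' Full group-profile clustering stage
#'
#' Convenience wrapper chaining [build_group_features()], [reduce_pca_95()],
#' [embed_2d()] and [cluster_with_silhouette()] into one cluster result.
#'
#' @param states data.frame of classified state triples with group ids.
#' @param k_grid Candidate cluster counts.
#' @param seed Seed for clustering and the embedding.
#' @return List with `assignments` (data.frame: group, condition, cluster,
#'   dim1, dim2), `k`, `silhouette`, `d95`, `scores`.
#' @export
cluster_profiles <- function(states, k_grid = 2:6, seed = 1) {
  feat <- build_group_features(states)
  red <- reduce_pca_95(feat)
  emb <- embed_2d(red$scores, seed = seed)
  cl <- cluster_with_silhouette(red$scores, k_grid = k_grid, seed = seed)
  cond <- attr(feat, "condition") %||% rep(NA_character_, nrow(feat))
  list(
    assignments = data.frame(
      group = rownames(feat), condition = cond,
      cluster = as.integer(cl$cluster),
      dim1 = emb[, 1], dim2 = emb[, 2],
      row.names = NULL, stringsAsFactors = FALSE
    ),
    k = cl$k, silhouette = cl$silhouette, d95 = red$d95, scores = red$scores
  )
}
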