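# Multicellular neighbourhood clustering: exact-hop neighbour feature
# aggregation, Gaussian-mixture spatial clusters, Fowlkes-Mallows stability
# selection, and connected-component community characterization.

#' Aggregate features over exact-hop neighbour shells
#'
#' For every cell, concatenates its own feature vector with the mean feature
#' vector of its exact hop-1, hop-2 and hop-3 neighbour sets (output width
#' `(n_steps + 1) * F`). Cells with an empty shell get a zero block for that
#' shell; fully isolated cells are flagged in attribute `"isolated"`.
#'
#' @param graph A `spatial_graph` (typically the 99th-centile-pruned
#'   Delaunay graph).
#' @param features Cells x markers matrix; rownames must cover all graph
#'   nodes (cell ids).
#' @param n_steps Number of hop shells (default 3).
#' @return Numeric matrix, rows aligned to `graph$nodes$cell_id`.
#' @export
aggregate_neighbors <- function(graph, features, n_steps = 3) {
  stopifnot(inherits(graph, "spatial_graph"), n_steps >= 1)
  ids <- as.character(graph$nodes$cell_id)
  if (!all(ids %in% rownames(features))) {
    stop("features is missing rows for some graph nodes")
  }
  f <- features[ids, , drop = FALSE]
  n <- length(ids)
  adj <- Matrix::sparseMatrix(
    i = match(as.character(graph$edges$from), ids),
    j = match(as.character(graph$edges$to), ids),
    x = 1, dims = c(n, n), symmetric = FALSE)
  adj <- ((adj + Matrix::t(adj)) > 0) * 1
  Matrix::diag(adj) <- 0

  shells <- vector("list", n_steps)
  reached <- Matrix::Diagonal(n)           # hop <= 0
  frontier <- adj
  for (s in seq_len(n_steps)) {
    shell <- ((frontier > 0) - (reached > 0) > 0) * 1
    shells[[s]] <- shell
    reached <- ((reached + shell) > 0) * 1
    if (s < n_steps) frontier <- reached %*% adj
  }

  blocks <- lapply(shells, function(S) {
    deg <- Matrix::rowSums(S)
    out <- as.matrix(S %*% f)
    nz <- deg > 0
    out[nz, ] <- out[nz, , drop = FALSE] / deg[nz]
    out
  })
  out <- do.call(cbind, c(list(as.matrix(f)), blocks))
  colnames(out) <- c(colnames(f),
                     unlist(lapply(seq_len(n_steps), function(s)
                       paste0(colnames(f), "_hop", s))))
  rownames(out) <- ids
  attr(out, "isolated") <- ids[Matrix::rowSums(adj) == 0]
  out
}

# Full-covariance Gaussian-mixture EM with k-means initialization and a
# fixed covariance ridge, fully deterministic given `seed`.
.gmm_em <- function(x, k, seed = 0L, reg = 1e-6, max_iter = 200,
                    tol = 1e-8) {
  n <- nrow(x); d <- ncol(x)
  km <- with_seed(seed, kmeans(x, centers = k, nstart = 1, iter.max = 50))
  z <- matrix(0, n, k)
  z[cbind(seq_len(n), km$cluster)] <- 1

  loglik_old <- -Inf
  w <- mu <- sig <- NULL
  for (iter in seq_len(max_iter)) {
    nk <- colSums(z) + 1e-10
    w <- nk / n
    mu <- crossprod(z, x) / nk
    sig <- lapply(seq_len(k), function(j) {
      xc <- sweep(x, 2, mu[j, ])
      s <- crossprod(xc * z[, j], xc) / nk[j]
      s + diag(reg, d)
    })
    logd <- vapply(seq_len(k), function(j) {
      ch <- tryCatch(chol(sig[[j]]), error = function(e) {
        chol(sig[[j]] + diag(1e-4, d))
      })
      xc <- sweep(x, 2, mu[j, ])
      q <- backsolve(ch, t(xc), transpose = TRUE)
      -0.5 * colSums(q^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi) +
        log(w[j])
    }, numeric(n))
    m <- apply(logd, 1, max)
    lse <- m + log(rowSums(exp(logd - m)))
    z <- exp(logd - lse)
    loglik <- sum(lse)
    if (is.finite(loglik_old) && abs(loglik - loglik_old) < tol * abs(loglik)) break
    loglik_old <- loglik
  }
  list(weights = w, means = mu, covariances = sig,
       posterior = z, cluster = max.col(z), loglik = loglik_old)
}

#' Fit Gaussian-mixture spatial clusters
#'
#' Fits a full-covariance Gaussian mixture (EM, k-means initialization,
#' covariance ridge 1e-6, deterministic under `seed`) to the
#' neighbour-aggregated feature matrix and returns hard assignments by
#' maximum posterior.
#'
#' @param augmented Matrix from [aggregate_neighbors()].
#' @param n_clusters Number of mixture components (default 10).
#' @param seed Seed for the initialization.
#' @return Integer cluster labels named by row names, with the fitted model
#'   in attribute `"model"`.
#' @export
fit_spatial_clusters <- function(augmented, n_clusters = 10, seed = 0L) {
  stopifnot(is.matrix(augmented), nrow(augmented) >= n_clusters,
            n_clusters >= 1)
  if (n_clusters == 1) {
    labs <- setNames(rep(1L, nrow(augmented)), rownames(augmented))
    return(labs)
  }
  fit <- .gmm_em(augmented, n_clusters, seed = seed)
  labs <- setNames(fit$cluster, rownames(augmented))
  attr(labs, "model") <- fit[c("weights", "means", "covariances", "loglik")]
  labs
}

#' Predict spatial-cluster assignments from a fitted mixture
#'
#' Assigns new cells to the components of a Gaussian mixture fitted by
#' [fit_spatial_clusters()] by maximum posterior — the fit-on-subsample,
#' predict-on-everything pattern used for large cohorts.
#'
#' @param model The `"model"` attribute of a [fit_spatial_clusters()] result.
#' @param x New feature matrix (same columns as the training data).
#' @return Integer component labels named by row names of `x`.
#' @export
gmm_predict <- function(model, x) {
  stopifnot(is.matrix(x), !is.null(model$means))
  k <- length(model$weights)
  d <- ncol(x)
  logd <- vapply(seq_len(k), function(j) {
    ch <- chol(model$covariances[[j]])
    xc <- sweep(x, 2, model$means[j, ])
    q <- backsolve(ch, t(xc), transpose = TRUE)
    -0.5 * colSums(q^2) - sum(log(diag(ch))) + log(model$weights[j])
  }, numeric(nrow(x)))
  logd <- matrix(logd, nrow = nrow(x))
  setNames(max.col(logd), rownames(x))
}

#' Fowlkes-Mallows index between two labelings
#'
#' `FMI = TP / sqrt((TP + FP)(TP + FN))` over co-assignment pairs; 1 for
#' identical partitions (up to label renaming).
#'
#' @param a,b Two label vectors of equal length.
#' @return FMI in `[0, 1]`.
#' @export
fowlkes_mallows <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  ct <- table(a, b)
  tp <- (sum(ct^2) - n) / 2
  tpfp <- (sum(rowSums(ct)^2) - n) / 2
  tpfn <- (sum(colSums(ct)^2) - n) / 2
  if (tpfp == 0 || tpfn == 0) return(NA_real_)
  tp / sqrt(tpfp * tpfn)
}

#' Cluster-count stability by repeated GMM fits
#'
#' For each candidate cluster number, fits `reps` Gaussian mixtures with
#' different seeds (seed = rep index) and reports the mean Fowlkes-Mallows
#' index over all rep pairs — the stability curve used to choose the number
#' of spatial clusters.
#'
#' @param augmented Matrix from [aggregate_neighbors()].
#' @param n_range Candidate cluster numbers (default 4:15).
#' @param reps Repetitions per candidate (>= 2).
#' @return data.frame with `n_clusters` and `mean_fmi`.
#' @export
cluster_stability <- function(augmented, n_range = 4:15, reps = 5) {
  stopifnot(reps >= 2)
  res <- vapply(n_range, function(k) {
    labs <- lapply(seq_len(reps), function(r) {
      fit_spatial_clusters(augmented, k, seed = r)
    })
    pairs <- utils::combn(reps, 2)
    mean(vapply(seq_len(ncol(pairs)), function(p) {
      fowlkes_mallows(labs[[pairs[1, p]]], labs[[pairs[2, p]]])
    }, numeric(1)))
  }, numeric(1))
  data.frame(n_clusters = n_range, mean_fmi = res)
}

#' Identify same-label communities as connected components
#'
#' For each spatial-cluster label, takes the subgraph of the full Delaunay
#' graph induced by cells carrying that label and returns its connected
#' components of at least `min_size` cells as communities.
#'
#' @param graph A `spatial_graph` (full Delaunay).
#' @param labels Named vector (cell_id -> spatial cluster) covering all
#'   nodes.
#' @param min_size Minimum community size (default 10).
#' @return data.frame: `community_id`, `spatial_cluster`, `n_cells`, plus a
#'   list-column-free membership map in attribute `"members"` (list of
#'   cell-id character vectors).
#' @export
find_communities <- function(graph, labels, min_size = 10) {
  stopifnot(inherits(graph, "spatial_graph"))
  ids <- as.character(graph$nodes$cell_id)
  if (!all(ids %in% names(labels))) stop("labels must cover all graph nodes")
  g <- as_igraph(graph)
  lab <- labels[ids]
  rows <- list(); members <- list()
  cid <- 0L
  for (lv in sort(unique(lab))) {
    sub <- igraph::induced_subgraph(g, which(lab == lv))
    comp <- igraph::components(sub)
    for (ci in seq_len(comp$no)) {
      mem <- igraph::V(sub)$name[comp$membership == ci]
      if (length(mem) < min_size) next
      cid <- cid + 1L
      rows[[cid]] <- data.frame(community_id = cid, spatial_cluster = lv,
                                n_cells = length(mem))
      members[[cid]] <- mem
    }
  }
  out <- if (cid > 0) do.call(rbind, rows) else
    data.frame(community_id = integer(0), spatial_cluster = character(0),
               n_cells = integer(0))
  attr(out, "members") <- members
  out
}

#' Community composition and connectivity statistics
#'
#' Shannon diversity (nats) of member phenotypes and mean vertex degree of
#' the community's induced subgraph.
#'
#' @param members Character vector of member cell ids.
#' @param phenotypes Named vector (cell_id -> phenotype).
#' @param graph The full-Delaunay `spatial_graph`.
#' @return List: `n_cells`, `shannon`, `mean_degree`.
#' @export
community_stats <- function(members, phenotypes, graph) {
  stopifnot(length(members) > 0)
  g <- as_igraph(graph)
  sub <- igraph::induced_subgraph(g, members)
  list(n_cells = length(members),
       shannon = shannon_entropy(phenotypes[members]),
       mean_degree = mean(igraph::degree(sub)))
}

#' Community density per spatial-cluster label
#'
#' Number of (filtered) communities per mm^2 of tissue, by label.
#'
#' @param communities data.frame from [find_communities()].
#' @param tissue_area_mm2 Tissue area in mm^2 (> 0).
#' @return Named numeric vector (label -> communities per mm^2).
#' @export
community_density <- function(communities, tissue_area_mm2) {
  if (tissue_area_mm2 <= 0) stop("tissue_area_mm2 must be > 0")
  counts <- table(communities$spatial_cluster)
  setNames(as.numeric(counts) / tissue_area_mm2, names(counts))
}
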