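# Expression preprocessing, graph-based clustering of a subsample,
# classifier propagation to the full dataset, and QC filters.

#' Preprocess an expression matrix
#'
#' Per marker: values above the 99th percentile (inverse-ECDF quantile, so
#' the cap is an observed value and the transform is exactly idempotent)
#' are clipped to it, then the column is min-max scaled to `[0, 1]`. A
#' constant column becomes all zero (with a warning).
#'
#' @param matrix Numeric cells x markers matrix (rownames = cell ids).
#' @return Matrix of the same shape with values in `[0, 1]`.
#' @export
preprocess_expression <- function(matrix) {
  stopifnot(is.matrix(matrix), nrow(matrix) >= 2, all(is.finite(matrix)))
  out <- matrix
  flat <- character(0)
  for (j in seq_len(ncol(out))) {
    v <- out[, j]
    q <- quantile(v, 0.99, names = FALSE, type = 1)
    v <- pmin(v, q)
    rng <- range(v)
    if (rng[1] == rng[2]) {
      out[, j] <- 0
      flat <- c(flat, colnames(out)[j] %||% as.character(j))
    } else {
      out[, j] <- (v - rng[1]) / (rng[2] - rng[1])
    }
  }
  if (length(flat)) {
    warning("constant marker column(s) scaled to zero: ",
            paste(flat, collapse = ", "))
  }
  out
}

#' Default neighbourhood size for graph clustering
#'
#' Scales the reference neighbourhood (k = 590 at 200,000 sampled cells)
#' down with the subsample, never below 15.
#'
#' @param n_sample Subsample size.
#' @return Integer k.
#' @export
default_k_neighbors <- function(n_sample) {
  max(15L, as.integer(round(590 * n_sample / 200000)))
}

#' Cluster a subsample of cells on a shared-nearest-neighbour graph
#'
#' PhenoGraph-style procedure: a k-nearest-neighbour graph on Euclidean
#' distance in marker space, edges reweighted by the Jaccard overlap of the
#' endpoint neighbourhoods, then modularity-based (Louvain) community
#' detection under a fixed seed.
#'
#' @param matrix Preprocessed cells x markers matrix.
#' @param n_sample Number of cells to sample (<= rows); rows are sampled
#'   without replacement under `seed`.
#' @param k_neighbors Neighbourhood size (< `n_sample`); default scales with
#'   the subsample via [default_k_neighbors()].
#' @param resolution Modularity resolution for the community detection
#'   (default 1). Values below 1 favour larger communities and counteract
#'   the tendency of modularity optimization to subdivide a single dense
#'   population; in practice this plays the role of the manual
#'   similar-cluster merging step.
#' @param seed Seed for sampling and community detection.
#' @return Integer cluster labels named by sampled row names.
#' @export
cluster_subsample <- function(matrix, n_sample = nrow(matrix),
                              k_neighbors = default_k_neighbors(n_sample),
                              resolution = 1, seed = 0L) {
  stopifnot(is.matrix(matrix), n_sample <= nrow(matrix), n_sample >= 2)
  if (k_neighbors >= n_sample) {
    stop("k_neighbors (", k_neighbors, ") must be < n_sample (", n_sample, ")")
  }
  if (is.null(rownames(matrix))) rownames(matrix) <- as.character(seq_len(nrow(matrix)))
  with_seed(seed, {
    idx <- sort(sample.int(nrow(matrix), n_sample))
    x <- matrix[idx, , drop = FALSE]
    k <- as.integer(k_neighbors)
    nn <- RANN::nn2(x, x, k = k + 1L)$nn.idx[, -1, drop = FALSE]
    # Jaccard shared-neighbour weights on the kNN edge set
    nb_sets <- lapply(seq_len(n_sample), function(i) c(i, nn[i, ]))
    from <- rep(seq_len(n_sample), each = k)
    to <- as.integer(t(nn))
    lo <- pmin(from, to); hi <- pmax(from, to)
    eid <- !duplicated(lo * (n_sample + 1) + hi)
    lo <- lo[eid]; hi <- hi[eid]
    w <- vapply(seq_along(lo), function(e) {
      a <- nb_sets[[lo[e]]]; b <- nb_sets[[hi[e]]]
      ov <- length(intersect(a, b))
      ov / (2 * (k + 1) - ov)
    }, numeric(1))
    g <- igraph::graph_from_edgelist(cbind(lo, hi), directed = FALSE)
    igraph::E(g)$weight <- w
    comm <- igraph::cluster_louvain(g, resolution = resolution)
    labels <- igraph::membership(comm)
    setNames(as.integer(labels), rownames(x))
  })
}

#' Propagate cluster labels to unlabelled cells
#'
#' Trains a random-forest classifier on the labelled subsample and predicts
#' labels for the remaining cells; deterministic given `seed`. Per-class
#' accuracy on a held-out third of the training data is attached as
#' attribute `"holdout_accuracy"`.
#'
#' @param train Labelled cells x markers matrix.
#' @param labels Vector of training labels (length `nrow(train)`, every
#'   class with >= 2 members).
#' @param rest Matrix of cells to label (same columns).
#' @param seed Seed for the forest and the holdout split.
#' @param ntree Number of trees.
#' @return Factor of predicted labels for `rest` (named by rownames), with
#'   attribute `holdout_accuracy`.
#' @export
propagate_labels <- function(train, labels, rest, seed = 0L, ntree = 200) {
  stopifnot(is.matrix(train), nrow(train) == length(labels),
            ncol(rest) == ncol(train))
  labels <- factor(labels)
  if (any(table(labels) < 2)) stop("every training class needs >= 2 members")
  with_seed(seed, {
    hold <- sample.int(nrow(train), max(1L, floor(nrow(train) / 3)))
    fit_idx <- setdiff(seq_len(nrow(train)), hold)
    if (length(unique(labels[fit_idx])) == nlevels(labels)) {
      fit_h <- randomForest::randomForest(train[fit_idx, , drop = FALSE],
                                          droplevels(labels[fit_idx]),
                                          ntree = ntree)
      acc <- mean(as.character(predict(fit_h, train[hold, , drop = FALSE])) ==
                    as.character(labels[hold]))
    } else {
      acc <- NA_real_
    }
    fit <- randomForest::randomForest(train, labels, ntree = ntree)
    pred <- predict(fit, rest)
    attr(pred, "holdout_accuracy") <- acc
    pred
  })
}

#' Quality-control filter on segmented cells
#'
#' Drops cells with area strictly below 10 or strictly above 250 um^2
#' (bounds inclusive: 10 and 250 survive), then removes every image left
#' with fewer than 100 cells — in that order.
#'
#' @param cells Cell table with `area` and `image_id`.
#' @param min_area,max_area Area bounds in um^2.
#' @param min_cells_per_image Minimum surviving cells per image.
#' @return Filtered cell table; may be empty.
#' @export
qc_filter <- function(cells, min_area = 10, max_area = 250,
                      min_cells_per_image = 100) {
  stopifnot_cols(cells, c("area", "image_id"))
  out <- cells[cells$area >= min_area & cells$area <= max_area, , drop = FALSE]
  counts <- table(out$image_id)
  keep_imgs <- names(counts)[counts >= min_cells_per_image]
  out <- out[out$image_id %in% keep_imgs, , drop = FALSE]
  if (nrow(out) == 0) message("qc_filter: no cells survived")
  rownames(out) <- NULL
  out
}

#' Expression matrix from a generator cell table
#'
#' Collects the `int_<marker>` columns into a numeric matrix with cell ids
#' as row names.
#'
#' @param cells Cell table.
#' @return Cells x markers matrix.
#' @export
expression_matrix <- function(cells) {
  cols <- grep("^int_", names(cells), value = TRUE)
  if (!length(cols)) stop("no int_<marker> columns in cell table")
  m <- as.matrix(cells[, cols])
  colnames(m) <- sub("^int_", "", cols)
  rownames(m) <- as.character(cells$cell_id)
  m
}

#' Two-component intensity split for a single marker
#'
#' Calls cells positive for one marker by 2-means clustering of
#' log1p-transformed per-cell mean intensities (same logic as pixel-level
#' positivity, applied to the cell table). Used e.g. to call Ki67+ cells at
#' cohort scale without rendering pixels.
#'
#' @param values Non-negative per-cell intensities.
#' @param seed Seed for k-means.
#' @return Logical vector: member of the higher-mean cluster.
#' @export
intensity_positive <- function(values, seed = 0L) {
  stopifnot(all(values >= 0))
  v <- log1p(values)
  if (diff(range(v)) == 0) return(rep(FALSE, length(values)))
  # centres at (median, max): the positive component may hold well under 1%
  # of cells (e.g. Ki67 in stroma), but it is far from the bulk mode, so
  # anchoring one centre at the maximum lets k-means find it
  ctr <- c(median(v), max(v))
  if (ctr[1] == ctr[2]) ctr <- range(v)
  km <- with_seed(seed, kmeans(v, centers = matrix(ctr), iter.max = 50))
  km$cluster == which.max(km$centers)
}
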