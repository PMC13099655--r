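# Delaunay graph construction, interaction counting, nearest-epithelium
# distances and bivariate Ripley's K with Monte-Carlo CSR envelopes.

#' Build a Delaunay spatial graph of cells
#'
#' Delaunay triangulation of cell centroids, with optional edge pruning:
#' `"delaunay_full"` keeps all edges, `"delaunay_pruned_20um"` drops edges
#' longer than 20 um (the interaction graph), `"delaunay_pruned_99pct"`
#' drops the longest 1 percent of edges in the image (the neighbourhood
#' variant). Duplicate coordinates are jittered by 1e-6 um under a fixed
#' seed; fewer than 3 (or collinear) points fall back to a nearest-neighbour
#' chain.
#'
#' @param cells Cell table with `cell_id`, `x`, `y` (um).
#' @param prune One of `"delaunay_full"`, `"delaunay_pruned_20um"`,
#'   `"delaunay_pruned_99pct"`.
#' @param max_edge Pruning length in um for the 20-um variant.
#' @return Object of class `spatial_graph`: `nodes` (cell_id, x, y),
#'   `edges` (from, to as cell_ids, length um), `provenance`.
#' @export
build_graph <- function(cells, prune = c("delaunay_full",
                                         "delaunay_pruned_20um",
                                         "delaunay_pruned_99pct"),
                        max_edge = 20) {
  prune <- match.arg(prune)
  stopifnot_cols(cells, c("cell_id", "x", "y"))
  n <- nrow(cells)
  x <- cells$x; y <- cells$y
  edges <- NULL

  if (n >= 3) {
    dup <- duplicated(cbind(x, y))
    if (any(dup)) {
      jit <- with_seed(99L, matrix(runif(2 * sum(dup), -1e-6, 1e-6), ncol = 2))
      x[dup] <- x[dup] + jit[, 1]
      y[dup] <- y[dup] + jit[, 2]
      message("build_graph: jittered ", sum(dup), " duplicate coordinate(s)")
    }
    tri <- tryCatch(deldir::deldir(x, y, suppressMsge = TRUE),
                    error = function(e) NULL)
    if (!is.null(tri) && nrow(tri$delsgs) > 0) {
      d <- tri$delsgs
      len <- sqrt((d$x1 - d$x2)^2 + (d$y1 - d$y2)^2)
      edges <- data.frame(from = cells$cell_id[d$ind1],
                          to = cells$cell_id[d$ind2], length = len)
    }
  }
  if (is.null(edges)) {
    # degenerate (collinear or < 3 points): nearest-neighbour chain along
    # the dominant axis, so images are not lost wholesale
    if (n >= 2) {
      ord <- if (diff(range(x)) >= diff(range(y))) order(x, y) else order(y, x)
      a <- ord[-n]; b <- ord[-1]
      edges <- data.frame(
        from = cells$cell_id[a], to = cells$cell_id[b],
        length = sqrt((x[a] - x[b])^2 + (y[a] - y[b])^2))
      if (n >= 3) warning("build_graph: degenerate point set, using chain fallback")
    } else {
      edges <- data.frame(from = integer(0), to = integer(0),
                          length = numeric(0))
      warning("build_graph: fewer than 2 points, empty edge set")
    }
  }

  if (prune == "delaunay_pruned_20um") {
    edges <- edges[edges$length <= max_edge, , drop = FALSE]
  } else if (prune == "delaunay_pruned_99pct" && nrow(edges) > 0) {
    edges <- edges[edges$length <= quantile(edges$length, 0.99), , drop = FALSE]
  }
  rownames(edges) <- NULL
  structure(list(nodes = data.frame(cell_id = cells$cell_id, x = cells$x,
                                    y = cells$y),
                 edges = edges, provenance = prune),
            class = "spatial_graph")
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf("spatial_graph (%s): %d nodes, %d edges\n", x$provenance,
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Convert a spatial graph to an igraph object
#' @param graph A `spatial_graph`.
#' @return An undirected igraph with vertex attribute `cell_id` and edge
#'   attribute `length`.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "spatial_graph"))
  ids <- as.character(graph$nodes$cell_id)
  g <- igraph::make_empty_graph(n = nrow(graph$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(graph$edges) > 0) {
    g <- igraph::add_edges(g, rbind(match(as.character(graph$edges$from), ids),
                                    match(as.character(graph$edges$to), ids)))
    g <- igraph::set_edge_attr(g, "length", value = graph$edges$length)
  }
  g
}

#' Normalized cell-cell interaction rates
#'
#' Counts graph edges by compartment pair and normalizes: epithelial-
#' epithelial by the number of epithelial cells, TME-TME by the number of
#' TME cells, and epithelial-TME by the total of both. An absent compartment
#' makes the affected rates `NA`.
#'
#' @param graph A `spatial_graph` (typically 20-um pruned).
#' @param compartment Named vector mapping cell_id to `"epithelial"` or
#'   `"TME"` (anything not epithelial counts as TME).
#' @return Named numeric vector `c(epi_epi, epi_tme, tme_tme)`.
#' @export
count_interactions <- function(graph, compartment) {
  stopifnot(inherits(graph, "spatial_graph"))
  ids <- as.character(graph$nodes$cell_id)
  cmp <- compartment[ids]
  is_epi <- cmp == "epithelial"
  n_epi <- sum(is_epi, na.rm = TRUE)
  n_tme <- sum(!is_epi, na.rm = TRUE)
  fe <- is_epi[match(as.character(graph$edges$from), ids)]
  te <- is_epi[match(as.character(graph$edges$to), ids)]
  ee <- sum(fe & te); tt <- sum(!fe & !te); et <- sum(xor(fe, te))
  c(epi_epi = if (n_epi > 0) ee / n_epi else NA_real_,
    epi_tme = if (n_epi > 0 && n_tme > 0) et / (n_epi + n_tme) else NA_real_,
    tme_tme = if (n_tme > 0) tt / n_tme else NA_real_)
}

#' Nearest-epithelial-cell distance for every TME cell
#'
#' @param cells Cell table with `x`, `y` and `compartment` (epithelial vs
#'   anything else).
#' @return Numeric vector, one entry per non-epithelial cell (named by
#'   cell_id when present); all-`NA` with a warning if the image has no
#'   epithelium.
#' @export
nearest_epithelial_distance <- function(cells) {
  stopifnot_cols(cells, c("x", "y", "compartment"))
  epi <- cells$compartment == "epithelial"
  tme <- !epi
  ids <- if ("cell_id" %in% names(cells)) as.character(cells$cell_id[tme])
    else NULL
  if (!any(epi)) {
    warning("no epithelial cells: distances missing")
    return(setNames(rep(NA_real_, sum(tme)), ids))
  }
  if (!any(tme)) return(setNames(numeric(0), character(0)))
  nn <- RANN::nn2(cbind(cells$x[epi], cells$y[epi]),
                  cbind(cells$x[tme], cells$y[tme]), k = 1)
  setNames(nn$nn.dists[, 1], ids)
}

#' Bivariate Ripley's K with Monte-Carlo CSR envelopes
#'
#' Computes the raw (uncorrected) cross-K between pattern A and pattern B,
#' `K(r) = area / (n_A n_B) * sum_i sum_j 1[d(a_i, b_j) <= r]`, and
#' pointwise min/max envelopes from `n_sim` resimulations of pattern B under
#' complete spatial randomness in the same window. No edge correction is
#' applied: observed and simulated curves share the same border bias, so the
#' envelope comparison is unaffected. With the default `n_sim = 199` the
#' pointwise band corresponds to a two-tailed test at P = 0.01. The image is
#' flagged `"above"`/`"below"` if the observed curve exits the envelope at
#' any radius (a pointwise, not global, rule).
#'
#' @param points_a,points_b Two-column matrices (x, y in um).
#' @param window `c(xmin, xmax, ymin, ymax)` in um.
#' @param radii Radii grid in um.
#' @param n_sim Number of CSR simulations (default 199).
#' @param seed Seed for the simulations.
#' @return Object of class `kcross_result`: data.frame `curve` (r, obs,
#'   lower, upper, call), flags `above`, `below`, and `low_power` when
#'   `n_B < 5`.
#' @export
kcross_envelope <- function(points_a, points_b, window, radii,
                            n_sim = 199, seed = 0L) {
  points_a <- as.matrix(points_a); points_b <- as.matrix(points_b)
  stopifnot(nrow(points_a) > 0, nrow(points_b) > 0, length(window) == 4)
  area <- (window[2] - window[1]) * (window[4] - window[3])
  stopifnot(area > 0)
  low_power <- nrow(points_b) < 5
  if (low_power) warning("kcross_envelope: n_B < 5, low power")

  kfun <- function(b) {
    d <- cross_dist(points_a, b)
    area / (nrow(points_a) * nrow(b)) *
      vapply(radii, function(r) sum(d <= r), numeric(1))
  }
  obs <- kfun(points_b)
  if (n_sim < 1) {
    curve <- data.frame(r = radii, obs = obs, lower = -Inf, upper = Inf,
                        call = "within")
    return(structure(list(curve = curve, above = FALSE, below = FALSE,
                          low_power = low_power, n_a = nrow(points_a),
                          n_b = nrow(points_b), n_sim = 0L),
                     class = "kcross_result"))
  }
  sims <- with_seed(seed, {
    vapply(seq_len(n_sim), function(s) {
      b <- cbind(runif(nrow(points_b), window[1], window[2]),
                 runif(nrow(points_b), window[3], window[4]))
      kfun(b)
    }, numeric(length(radii)))
  })
  sims <- matrix(sims, nrow = length(radii))
  lower <- apply(sims, 1, min)
  upper <- apply(sims, 1, max)
  call <- ifelse(obs > upper, "above", ifelse(obs < lower, "below", "within"))
  structure(list(
    curve = data.frame(r = radii, obs = obs, lower = lower, upper = upper,
                       call = call),
    above = any(call == "above"), below = any(call == "below"),
    low_power = low_power, n_a = nrow(points_a), n_b = nrow(points_b),
    n_sim = n_sim), class = "kcross_result")
}

#' @export
print.kcross_result <- function(x, ...) {
  cat(sprintf("kcross_result: n_A = %d, n_B = %d, %d CSR simulations\n",
              x$n_a, x$n_b, x$n_sim))
  cat(sprintf("  exits envelope: above = %s, below = %s\n", x$above, x$below))
  invisible(x)
}

#' @export
plot.kcross_result <- function(x, ...) {
  cv <- x$curve
  plot(cv$r, cv$obs, type = "l", lwd = 2, xlab = "r (um)", ylab = "Kcross(r)",
       ylim = range(c(cv$obs, cv$lower, cv$upper)), ...)
  graphics::polygon(c(cv$r, rev(cv$r)), c(cv$lower, rev(cv$upper)),
                    col = grDevices::adjustcolor("red", 0.2), border = NA)
  graphics::lines(cv$r, pi * cv$r^2, lty = 2, col = "red")
  invisible(x)
}
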