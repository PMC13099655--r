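# Pixel-level operations: hot-pixel filtering, k-means marker positivity,
# adipocyte detection, myoepithelial thickness and mask-derived metrics.

#' Filter isolated hot pixels
#'
#' Replaces any pixel that exceeds the maximum of its 3x3 neighbourhood
#' (centre excluded) by more than `threshold` with that neighbourhood
#' maximum. Only *single* hot pixels are touched: two adjacent saturated
#' pixels protect each other, since each is the other's neighbourhood
#' maximum. The operation is idempotent.
#'
#' @param image An `image_stack` or a single numeric matrix.
#' @param threshold Non-negative intensity margin (counts). Default 50.
#' @return Same type as the input, filtered.
#' @export
filter_hot_pixels <- function(image, threshold = 50) {
  stopifnot(threshold >= 0)
  if (inherits(image, "image_stack")) {
    out <- image
    for (i in seq_along(image$channel_names)) {
      out$pixels[, , i] <- .hot_filter_plane(image$pixels[, , i], threshold)
    }
    return(out)
  }
  .hot_filter_plane(image, threshold)
}

.hot_filter_plane <- function(m, threshold) {
  h <- nrow(m); w <- ncol(m)
  if (h < 2 || w < 2) return(m)
  pad <- matrix(-Inf, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  nb_max <- matrix(-Inf, h, w)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb_max <- pmax(nb_max, pad[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)])
  }
  hot <- m > nb_max + threshold
  m[hot] <- nb_max[hot]
  m
}

#' Pixel-level marker positivity via k-means
#'
#' Clusters pixel intensities of one channel with k-means and returns the
#' positive-pixel mask. Clustering is done on a `log1p` scale by default —
#' ion counts are lognormal-like, and the compressive transform keeps dim
#' but genuinely positive pixels from being swallowed by a zero-heavy
#' background cluster. With the default `k = 2`, positive pixels are the
#' higher-mean cluster; for `k > 2`, cluster means are sorted and the
#' positive set is every cluster above the largest gap between consecutive
#' means. A constant channel yields an all-negative mask with a warning.
#'
#' @param channel Non-negative numeric matrix (one marker plane).
#' @param k Number of intensity clusters (>= 2).
#' @param um_per_pixel Pixel size, stored on the returned mask.
#' @param seed Seed for the k-means initialization.
#' @param transform `"log1p"` (default) or `"none"`: scale on which pixel
#'   intensities are clustered.
#' @return A `binary_mask` object (logical matrix + metadata).
#' @export
pixel_positivity <- function(channel, k = 2, um_per_pixel = 1, seed = 0L,
                             transform = c("log1p", "none")) {
  stopifnot(is.matrix(channel), all(channel >= 0), k >= 2)
  transform <- match.arg(transform)
  v <- as.numeric(channel)
  if (transform == "log1p") v <- log1p(v)
  if (diff(range(v)) == 0) {
    warning("constant channel: no positive cluster, returning empty mask")
    return(binary_mask(matrix(FALSE, nrow(channel), ncol(channel)),
                       um_per_pixel, "positive_marker"))
  }
  km <- with_seed(seed, {
    uq <- unique(quantile(v, seq(0, 1, length.out = k + 2)[2:(k + 1)]))
    centers <- if (length(uq) >= k) uq[seq_len(k)] else
      seq(min(v), max(v), length.out = k)
    kmeans(v, centers = matrix(centers, ncol = 1), iter.max = 50)
  })
  mu <- as.numeric(km$centers)
  ord <- order(mu)
  pos_clusters <- if (k == 2) ord[2] else {
    gaps <- diff(mu[ord])
    cut_at <- which.max(gaps)
    ord[(cut_at + 1):k]
  }
  mask <- matrix(km$cluster %in% pos_clusters, nrow(channel), ncol(channel))
  binary_mask(mask, um_per_pixel, "positive_marker")
}

#' Binary mask container
#' @param pixels Logical matrix.
#' @param um_per_pixel Pixel size in micrometres.
#' @param class_name One of `positive_marker`, `myoepithelial`, `adipocyte`,
#'   `vessel_blood`, `vessel_lymphatic`, `panCK_object`.
#' @return Object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, um_per_pixel = 1,
                        class_name = "positive_marker") {
  stopifnot(is.matrix(pixels), is.logical(pixels), um_per_pixel > 0)
  class_name <- match.arg(class_name,
                          c("positive_marker", "myoepithelial", "adipocyte",
                            "vessel_blood", "vessel_lymphatic", "panCK_object"))
  structure(list(pixels = pixels, um_per_pixel = um_per_pixel,
                 class_name = class_name), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask (%s): %d x %d px, %.1f%% positive\n", x$class_name,
              nrow(x$pixels), ncol(x$pixels), 100 * mean(x$pixels)))
  invisible(x)
}

.mask_pixels <- function(mask) {
  if (inherits(mask, "binary_mask")) mask$pixels else mask
}

#' Per-cell positive-pixel fraction and positivity call
#'
#' `cell_positive_fraction` returns, for each cell, the number of its pixels
#' inside the positive mask divided by its pixel count. `call_positive`
#' thresholds those fractions (default 0.1 of cell area).
#'
#' @param mask A `binary_mask` (or logical matrix).
#' @param cell_pixels Named list: cell id -> integer matrix of pixel
#'   coordinates (columns `row`, `col`, 1-based).
#' @return Named numeric vector of fractions in `[0, 1]`.
#' @export
cell_positive_fraction <- function(mask, cell_pixels) {
  m <- .mask_pixels(mask)
  vapply(seq_along(cell_pixels), function(i) {
    px <- cell_pixels[[i]]
    if (is.null(px) || nrow(px) == 0) {
      stop("cell '", names(cell_pixels)[i] %||% i, "' has zero pixels")
    }
    mean(m[px])
  }, numeric(1), USE.NAMES = FALSE) |>
    setNames(names(cell_pixels))
}

#' @rdname cell_positive_fraction
#' @param fractions Output of `cell_positive_fraction`.
#' @param threshold Positivity threshold on the fraction (default 0.1).
#' @return Named logical vector: `fraction >= threshold`.
#' @export
call_positive <- function(fractions, threshold = 0.1) {
  stopifnot(threshold >= 0, threshold <= 1)
  fractions >= threshold
}

#' Pixel footprints of cells as discs around their centroids
#'
#' Utility producing the `cell_pixels` list consumed by
#' [cell_positive_fraction()] when no segmentation masks are on hand: each
#' cell's footprint is the digitized disc of its recorded area centred on its
#' centroid (the same convention the synthetic renderer paints with).
#'
#' @param cells Cell table with `x`, `y` (um) and `area` (um^2).
#' @param dim Image dimensions `c(height, width)` in pixels.
#' @param um_per_pixel Pixel size.
#' @param radius_scale Multiplier on the equivalent-disc radius (use < 1 to
#'   probe the nuclear region only).
#' @return Named list of `cbind(row, col)` matrices, one per cell.
#' @export
cell_pixel_discs <- function(cells, dim, um_per_pixel = 1, radius_scale = 1) {
  stopifnot_cols(cells, c("x", "y", "area"))
  h <- dim[1]; w <- dim[2]
  out <- vector("list", nrow(cells))
  r_px <- pmax(1.2, radius_scale * sqrt(cells$area / pi) / um_per_pixel)
  cx <- cells$x / um_per_pixel + 0.5
  cy <- cells$y / um_per_pixel + 0.5
  for (i in seq_len(nrow(cells))) {
    r <- r_px[i]
    xs <- max(1L, floor(cx[i] - r)):min(w, ceiling(cx[i] + r))
    ys <- max(1L, floor(cy[i] - r)):min(h, ceiling(cy[i] + r))
    sel <- which(outer((ys - cy[i])^2, (xs - cx[i])^2, "+") <= r^2,
                 arr.ind = TRUE)
    out[[i]] <- cbind(row = ys[sel[, 1]], col = xs[sel[, 2]])
  }
  names(out) <- if ("cell_id" %in% names(cells)) as.character(cells$cell_id)
    else as.character(seq_len(nrow(cells)))
  out
}

# 3x3 median filter via the classic 19-exchange median-of-9 sorting
# network, vectorized over the whole plane (replicate-padded borders).
.median3x3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(0, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  pad[1, ] <- pad[2, ]; pad[h + 2, ] <- pad[h + 1, ]
  pad[, 1] <- pad[, 2]; pad[, w + 2] <- pad[, w + 1]
  p <- vector("list", 9)
  k <- 0
  for (dx in -1:1) for (dy in -1:1) {
    k <- k + 1
    p[[k]] <- pad[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)]
  }
  op <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]]); hi <- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo; p[[j]] <<- hi
  }
  op(2, 3); op(5, 6); op(8, 9); op(1, 2); op(4, 5); op(7, 8)
  op(2, 3); op(5, 6); op(8, 9); op(1, 4); op(6, 9); op(5, 8)
  op(4, 7); op(2, 5); op(3, 6); op(5, 8); op(5, 3); op(7, 5)
  op(5, 3)
  p[[5]]
}

# ---- object geometry -----------------------------------------------------

# Perimeter of a labelled object by ordered-boundary walk with corrected
# step weights (0.980 per axial step, 1.406 per diagonal step), which is
# accurate to ~1% for smooth digitized shapes. `obj` is a logical matrix.
.object_perimeter <- function(obj) {
  oc <- EBImage::ocontour(EBImage::Image(obj * 1))
  if (length(oc) == 0) return(0)
  per <- 0
  for (ct in oc) {
    n <- nrow(ct)
    if (n < 2) { per <- per + 4 * 0.980; next }
    nxt <- rbind(ct[-1, , drop = FALSE], ct[1, , drop = FALSE])
    step <- abs(nxt - ct)
    diag <- step[, 1] == 1 & step[, 2] == 1
    axial <- xor(step[, 1] > 0, step[, 2] > 0) & pmax(step[, 1], step[, 2]) == 1
    jump <- !(diag | axial)  # non-unit steps along a thin contour
    per <- per + sum(axial) * 0.980 + sum(diag) * 1.406 +
      sum(sqrt(rowSums((nxt[jump, , drop = FALSE] - ct[jump, , drop = FALSE])^2)))
  }
  per
}

# Circularity 4*pi*area/perimeter^2 of a logical object matrix (pixel units).
.object_circularity <- function(obj) {
  a <- sum(obj)
  p <- .object_perimeter(obj)
  if (p <= 0) return(NA_real_)
  4 * pi * a / p^2
}

# Connected components of a logical mask as index lists (row, col), with
# per-component bounding boxes so later geometry runs on small sub-images.
.component_index <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- as.matrix(EBImage::imageData(lab))
  pos <- which(lab > 0)
  if (!length(pos)) return(list())
  h <- nrow(lab)
  by_lab <- split(pos, lab[pos])
  lapply(by_lab, function(ii) {
    cbind(row = ((ii - 1L) %% h) + 1L, col = ((ii - 1L) %/% h) + 1L)
  })
}

# Logical sub-image of one component, padded by one background pixel.
.component_subimage <- function(idx) {
  r0 <- min(idx[, 1]); c0 <- min(idx[, 2])
  sub <- matrix(FALSE, max(idx[, 1]) - r0 + 3L, max(idx[, 2]) - c0 + 3L)
  sub[cbind(idx[, 1] - r0 + 2L, idx[, 2] - c0 + 2L)] <- TRUE
  sub
}

#' Detect adipocytes from a caveolin channel
#'
#' Adipocytes appear as bright membrane (caveolin) rims around dark, hollow
#' interiors. Pipeline: clip at the 99th centile, 3x3 median filter, Otsu
#' binarization, inversion, 8-connected components, removal of components
#' overlapping panCK (epithelial) objects and of the border-touching
#' background component, then size (>= `min_area` um^2) and circularity
#' (>= `min_circularity`) filters.
#'
#' @param caveolin Numeric matrix (caveolin channel).
#' @param panck_objects `binary_mask` (or logical matrix) of epithelial
#'   panCK objects, or `NULL`.
#' @param um_per_pixel Pixel size.
#' @param min_area Minimum object area in um^2 (default 300).
#' @param min_circularity Minimum circularity `4*pi*area/perimeter^2`
#'   (default 0.7).
#' @return data.frame of detected objects: `object_id`, `area` (um^2),
#'   `perimeter` (um), `circularity`, `centroid_x`, `centroid_y` (um), with
#'   the object pixel masks in attribute `"objects"`.
#' @export
detect_adipocytes <- function(caveolin, panck_objects = NULL,
                              um_per_pixel = 1, min_area = 300,
                              min_circularity = 0.7) {
  stopifnot(is.matrix(caveolin))
  empty <- data.frame(object_id = integer(0), area = numeric(0),
                      perimeter = numeric(0), circularity = numeric(0),
                      centroid_x = numeric(0), centroid_y = numeric(0))
  if (all(caveolin == 0)) return(empty)
  q99 <- quantile(caveolin, 0.99)
  clipped <- pmin(caveolin, q99)
  med <- .median3x3(clipped / max(clipped))
  thr <- EBImage::otsu(EBImage::Image(med), range = c(0, 1))
  inv <- med < thr
  comps <- .component_index(inv)
  if (length(comps) == 0) return(empty)

  panck <- if (is.null(panck_objects)) NULL else .mask_pixels(panck_objects)
  h <- nrow(caveolin); w <- ncol(caveolin)
  keep <- list()
  for (idx in comps) {
    touches_border <- any(idx[, 1] == 1 | idx[, 1] == h |
                            idx[, 2] == 1 | idx[, 2] == w)
    if (touches_border) next
    if (!is.null(panck) && any(panck[idx])) next
    area_um2 <- nrow(idx) * um_per_pixel^2
    if (area_um2 < min_area) next
    sub <- .component_subimage(idx)
    per <- .object_perimeter(sub)
    circ <- 4 * pi * nrow(idx) / per^2
    if (is.na(circ) || circ < min_circularity) next
    keep[[length(keep) + 1L]] <- list(
      idx = idx, area = area_um2,
      perimeter = per * um_per_pixel, circularity = circ,
      cx = (mean(idx[, 2]) - 0.5) * um_per_pixel,
      cy = (mean(idx[, 1]) - 0.5) * um_per_pixel)
  }
  if (length(keep) == 0) return(empty)
  out <- data.frame(
    object_id = seq_along(keep),
    area = vapply(keep, `[[`, numeric(1), "area"),
    perimeter = vapply(keep, `[[`, numeric(1), "perimeter"),
    circularity = vapply(keep, `[[`, numeric(1), "circularity"),
    centroid_x = vapply(keep, `[[`, numeric(1), "cx"),
    centroid_y = vapply(keep, `[[`, numeric(1), "cy"))
  attr(out, "objects") <- lapply(keep, `[[`, "idx")
  out
}

#' Myoepithelial layer thickness by distance transform
#'
#' Thickness proxy at each myoepithelial pixel = 2 x Euclidean distance to
#' the nearest non-myoepithelial pixel; means are reported separately for
#' duct-proximal and lobule-proximal pixels.
#'
#' @param myoep `binary_mask` (or logical matrix) of the myoepithelial layer.
#' @param structure_assignment Character matrix of the same shape assigning
#'   each pixel `"duct"`, `"lobule"` or `NA`.
#' @param um_per_pixel Pixel size.
#' @return Named numeric vector `c(duct = ..., lobule = ...)` in um; a class
#'   with no pixels is `NA` (missing, not zero).
#' @export
myoepithelial_thickness <- function(myoep, structure_assignment,
                                    um_per_pixel = 1) {
  m <- .mask_pixels(myoep)
  stopifnot(all(dim(m) == dim(structure_assignment)))
  dm <- as.matrix(EBImage::imageData(EBImage::distmap(EBImage::Image(m * 1))))
  proxy <- 2 * dm * um_per_pixel
  out <- c(duct = NA_real_, lobule = NA_real_)
  for (k in c("duct", "lobule")) {
    sel <- m & !is.na(structure_assignment) & structure_assignment == k
    if (any(sel)) out[k] <- mean(proxy[sel])
  }
  out
}

#' Assign mask pixels to the nearest duct or lobule cell
#'
#' Builds the `structure_assignment` matrix for
#' [myoepithelial_thickness()]: each pixel takes the duct/lobule label of the
#' nearest epithelial cell carrying a structure label.
#'
#' @param cells Cell table with `x`, `y`, `structure_label`.
#' @param dim Image dimensions `c(height, width)` in pixels.
#' @param um_per_pixel Pixel size.
#' @return Character matrix (`"duct"`/`"lobule"`/`NA`).
#' @export
structure_assignment_map <- function(cells, dim, um_per_pixel = 1) {
  stopifnot_cols(cells, c("x", "y", "structure_label"))
  lab <- cells$structure_label
  keep <- lab %in% c("duct", "lobule")
  out <- matrix(NA_character_, dim[1], dim[2])
  if (!any(keep)) return(out)
  px <- cbind((cells$x[keep]) / um_per_pixel + 0.5,
              (cells$y[keep]) / um_per_pixel + 0.5)
  grid <- cbind(rep(seq_len(dim[2]), each = dim[1]),
                rep(seq_len(dim[1]), times = dim[2]))
  nn <- RANN::nn2(px, grid, k = 1)
  out[] <- lab[keep][nn$nn.idx[, 1]]
  out
}

#' Mask-level metrics: area fraction, object count, per-cell distances
#'
#' Holes are filled and components smaller than `min_object_area` removed
#' before counting. `area_fraction` is the mask area over the supplied
#' tissue area; each cell's distance is the Euclidean distance from its
#' centroid to the nearest mask pixel (0 inside the mask). An empty mask
#' yields count 0, fraction 0 and missing distances.
#'
#' @param mask `binary_mask` or logical matrix.
#' @param cells Cell table with `x`, `y` (um), or `NULL`.
#' @param tissue_area_mm2 Tissue area in mm^2 (> 0).
#' @param um_per_pixel Pixel size.
#' @param min_object_area Minimum component area in um^2 (default 10).
#' @return List: `area_fraction`, `object_count`, `distances` (per-cell um,
#'   `NA` when the mask is empty).
#' @export
mask_metrics <- function(mask, cells = NULL, tissue_area_mm2,
                         um_per_pixel = 1, min_object_area = 10) {
  stopifnot(tissue_area_mm2 > 0)
  m <- .mask_pixels(mask)
  if (any(m)) {
    filled <- as.matrix(EBImage::imageData(
      EBImage::fillHull(EBImage::Image(m * 1)))) > 0.5
    lab <- as.matrix(EBImage::imageData(
      EBImage::bwlabel(EBImage::Image(filled * 1))))
    sizes <- tabulate(lab[lab > 0])
    small <- which(sizes * um_per_pixel^2 < min_object_area)
    filled[lab %in% small] <- FALSE
    m <- filled
  }
  count <- if (any(m)) {
    max(EBImage::bwlabel(EBImage::Image(m * 1)))
  } else 0L
  area_um2 <- sum(m) * um_per_pixel^2
  dists <- NULL
  if (!is.null(cells)) {
    stopifnot_cols(cells, c("x", "y"))
    if (!any(m)) {
      dists <- rep(NA_real_, nrow(cells))
    } else {
      idx <- which(m, arr.ind = TRUE)
      # pixel centres in um under the floor() convention
      mask_xy <- cbind((idx[, 2] - 0.5) * um_per_pixel,
                       (idx[, 1] - 0.5) * um_per_pixel)
      nn <- RANN::nn2(mask_xy, cbind(cells$x, cells$y), k = 1)
      d <- nn$nn.dists[, 1]
      inside <- m[cbind(pmin(nrow(m), floor(cells$y / um_per_pixel) + 1L),
                        pmin(ncol(m), floor(cells$x / um_per_pixel) + 1L))]
      d[inside] <- 0
      dists <- d
    }
  }
  list(area_fraction = area_um2 / (tissue_area_mm2 * 1e6),
       object_count = as.integer(count), distances = dists)
}
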