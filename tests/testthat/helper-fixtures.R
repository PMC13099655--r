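# Shared fixture builders. All randomness is seeded at the call site.

# Two well-separated Gaussian blobs in `d` dimensions.
make_blobs <- function(n_per = 30, d = 2, sep = 10, sd = 1, seed = 1) {
  spatialbreast:::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per * d, 0, sd), ncol = d),
               matrix(rnorm(n_per * d, sep, sd), ncol = d))
    rownames(x) <- as.character(seq_len(2 * n_per))
    list(x = x, labels = rep(1:2, each = n_per))
  })
}

# Minimal cell table from coordinate vectors.
toy_cells <- function(x, y, compartment = "epithelial", phenotype = "a",
                      structure_label = "none", patient_id = "P1",
                      image_id = "img1", area = 50) {
  n <- length(x)
  data.frame(cell_id = seq_len(n), image_id = image_id,
             patient_id = patient_id, x = x, y = y, area = area,
             major_axis = 10, minor_axis = 8,
             compartment = rep_len(compartment, n),
             phenotype = rep_len(phenotype, n),
             structure_label = rep_len(structure_label, n))
}

# A small rendered image fixture, cached per test run.
fixture_rendered <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- cohort_config(n_patients = 1, image_width = 500, seed = 11)
      cache <<- generate_image(40, cfg, seed = 11, render = TRUE)
    }
    cache
  }
})

# Independent Moore-neighbour boundary trace: ordered boundary pixels of a
# single 4/8-connected object in a logical matrix. Used as the
# perimeter/circularity oracle (independent of EBImage::ocontour).
trace_boundary <- function(obj) {
  idx <- which(obj, arr.ind = TRUE)
  start <- idx[order(idx[, 2], idx[, 1])[1], ]  # leftmost-topmost
  moves <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                 c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  inside <- function(p) p[1] >= 1 && p[1] <= nrow(obj) &&
    p[2] >= 1 && p[2] <= ncol(obj) && obj[p[1], p[2]]
  path <- list(start)
  dir <- 1L  # last move direction index
  cur <- start
  repeat {
    found <- FALSE
    for (k in 0:7) {
      d <- ((dir + 5 + k) %% 8) + 1  # backtrack-then-clockwise scan
      nxt <- cur + moves[d, ]
      if (inside(nxt)) {
        cur <- nxt; dir <- d; found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel
    if (all(cur == start) && length(path) > 1) break
    path[[length(path) + 1L]] <- cur
    if (length(path) > 4 * sum(obj) + 8) break
  }
  do.call(rbind, path)
}

# Oracle circularity: area by pixel count, perimeter by the traced boundary
# with Vossepoel-Smeulders step weights.
oracle_circularity <- function(obj) {
  bd <- trace_boundary(obj)
  n <- nrow(bd)
  if (n < 2) return(4 * pi * sum(obj) / (4 * 0.980)^2)
  nxt <- rbind(bd[-1, , drop = FALSE], bd[1, , drop = FALSE])
  st <- abs(nxt - bd)
  per <- sum(ifelse(st[, 1] + st[, 2] == 2, 1.406, 0.980))
  4 * pi * sum(obj) / per^2
}
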