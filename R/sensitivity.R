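# Sampling-sensitivity analyses: density-peak-centred cropping, KL
# divergence of composition, permutation co-occurrence enrichment with
# cosine similarity, the quadratic-spline-vs-linear age test, and the
# width x sample-size sweep.

#' Crop an image's cells around its cell-density peak
#'
#' A 2D Gaussian kernel density estimate (Scott's bandwidth, evaluated on a
#' ~10-um grid) locates the densest position; a square crop of side `width`
#' is centred there, shifted minimally to stay inside the image, and cells
#' with centroids inside are retained. A crop as wide as the image returns
#' all cells.
#'
#' @param cells Cell table with `x`, `y` (one image, >= 2 cells).
#' @param width Crop side length in um.
#' @param image_width Parent image side length in um.
#' @param grid_um KDE evaluation grid spacing (default 10 um).
#' @return List: `cells` (subset), `spec` (width, center_x, center_y,
#'   x0/y0 crop origin).
#' @export
crop_at_density_peak <- function(cells, width, image_width, grid_um = 10) {
  stopifnot_cols(cells, c("x", "y"))
  stopifnot(nrow(cells) >= 2, width > 0)
  if (width >= image_width) {
    if (width > image_width) message("crop width exceeds image; returning full image")
    return(list(cells = cells,
                spec = data.frame(width = image_width,
                                  center_x = image_width / 2,
                                  center_y = image_width / 2, x0 = 0, y0 = 0)))
  }
  n <- nrow(cells)
  scott <- function(v) max(1e-6, sd(v)) * n^(-1 / 6)
  ngrid <- max(16L, as.integer(round(image_width / grid_um)) + 1L)
  kd <- MASS::kde2d(cells$x, cells$y,
                    h = c(4 * scott(cells$x), 4 * scott(cells$y)),
                    n = ngrid, lims = c(0, image_width, 0, image_width))
  peak <- which(kd$z == max(kd$z), arr.ind = TRUE)[1, ]
  cx <- kd$x[peak[1]]; cy <- kd$y[peak[2]]
  x0 <- min(max(0, cx - width / 2), image_width - width)
  y0 <- min(max(0, cy - width / 2), image_width - width)
  keep <- cells$x >= x0 & cells$x <= x0 + width &
    cells$y >= y0 & cells$y <= y0 + width
  list(cells = cells[keep, , drop = FALSE],
       spec = data.frame(width = width, center_x = cx, center_y = cy,
                         x0 = x0, y0 = y0))
}

#' Forward Kullback-Leibler divergence between composition vectors
#'
#' `D(p || q) = sum p_k log(p_k / q_k)` in nats, after adding a pseudocount
#' to both vectors and renormalizing (so zero categories are defined).
#'
#' @param p,q Non-negative vectors on the same category index (counts or
#'   proportions).
#' @param pseudocount Added to every category before normalization
#'   (default 1e-6).
#' @return Divergence in nats (>= 0).
#' @export
kl_divergence <- function(p, q, pseudocount = 1e-6) {
  stopifnot(length(p) == length(q), pseudocount > 0, all(p >= 0), all(q >= 0))
  p <- p + pseudocount; q <- q + pseudocount
  p <- p / sum(p); q <- q / sum(q)
  sum(p * log(p / q))
}

#' Phenotype co-occurrence enrichment by permutation
#'
#' Observed adjacency counts between phenotype pairs on the 20-um graph,
#' symmetrized, divided by the expected counts from `n_perm` random
#' relabelings of the cells (fixed seed). Entries for pairs never expected
#' are `NA`.
#'
#' @param graph 20-um pruned `spatial_graph`.
#' @param phenotypes Named vector cell_id -> phenotype covering the nodes.
#' @param n_perm Number of label permutations (default 100).
#' @param seed Permutation seed.
#' @return Phenotype x phenotype enrichment matrix.
#' @export
cooccurrence_enrichment <- function(graph, phenotypes, n_perm = 100,
                                    seed = 0L) {
  stopifnot(inherits(graph, "spatial_graph"))
  ids <- as.character(graph$nodes$cell_id)
  lab <- as.character(phenotypes[ids])
  if (length(unique(lab)) < 2) stop("need at least 2 phenotypes present")
  lev <- sort(unique(lab))
  fi <- match(as.character(graph$edges$from), ids)
  ti <- match(as.character(graph$edges$to), ids)
  count_mat <- function(l) {
    a <- factor(l[fi], levels = lev); b <- factor(l[ti], levels = lev)
    m <- table(a, b)
    m <- unclass(m) + t(unclass(m))
    m
  }
  obs <- count_mat(lab)
  expd <- with_seed(seed, {
    acc <- matrix(0, length(lev), length(lev))
    for (i in seq_len(n_perm)) acc <- acc + count_mat(sample(lab))
    acc / n_perm
  })
  out <- obs / expd
  out[expd == 0] <- NA_real_
  dimnames(out) <- list(lev, lev)
  out
}

#' Cosine similarity between two co-occurrence enrichment matrices
#'
#' Flattens the upper triangles (including the diagonal), drops entries
#' missing in either matrix pairwise, and returns the cosine.
#'
#' @param m1,m2 Square matrices with matching dimnames.
#' @return Cosine similarity in `[-1, 1]`, or `NA` if nothing overlaps.
#' @export
cooccurrence_similarity <- function(m1, m2) {
  common <- intersect(rownames(m1), rownames(m2))
  if (length(common) == 0) return(NA_real_)
  a <- m1[common, common]; b <- m2[common, common]
  ut <- upper.tri(a, diag = TRUE)
  cosine_similarity(a[ut], b[ut])
}

#' Quadratic-spline-versus-linear likelihood-ratio test
#'
#' Fits a linear model `{1, age}` and a quadratic spline with a single knot
#' `{1, age, age^2, max(age - knot, 0)^2}` by least squares, and tests the
#' two extra spline terms with a Gaussian likelihood-ratio statistic
#' `LRT = n log(RSS0 / RSS1)` against chi-square with 2 degrees of freedom.
#' A nonlinearity concentrated at the knot (e.g. a menopause step at 50)
#' loads on the spline terms.
#'
#' @param values Response (e.g. per-patient lobule density or ductal
#'   proportion).
#' @param ages Patient ages (> 6 distinct observations required).
#' @param knot Knot location in years (default 50).
#' @return List: `statistic`, `df` (2), `p`, `rss_linear`, `rss_spline`.
#' @export
spline_vs_linear_lrt <- function(values, ages, knot = 50) {
  keep <- is.finite(values) & is.finite(ages)
  values <- values[keep]; ages <- ages[keep]
  n <- length(values)
  if (n <= 6) stop("need more than 6 observations")
  if (length(unique(ages)) < 4) stop("singular design: too few distinct ages")
  a2 <- ages^2
  hinge <- pmax(ages - knot, 0)^2
  fit0 <- lm(values ~ ages)
  fit1 <- lm(values ~ ages + a2 + hinge)
  rss0 <- sum(resid(fit0)^2)
  rss1 <- sum(resid(fit1)^2)
  stat <- n * log(rss0 / max(rss1, .Machine$double.eps))
  list(statistic = stat, df = 2,
       p = pchisq(stat, df = 2, lower.tail = FALSE),
       rss_linear = rss0, rss_spline = rss1)
}

#' Width x sample-size sensitivity sweep
#'
#' For every combination of crop width and image sample size: images are
#' subsampled (with replacement when more are requested than exist, with a
#' message), each is cropped at its density peak, and three metrics are
#' computed — the KL divergence of each crop's phenotype composition from
#' the same image's reference-width composition, the cosine similarity of
#' its co-occurrence enrichment to the reference's, and the
#' spline-versus-linear p-value for the ductal proportion of epithelial
#' cells against age across the sampled images. A linear trend of each
#' metric across widths summarizes the sensitivity as a rate of change.
#'
#' @param cohort A `tissue_cohort` whose `image_width` is at least
#'   `max(widths)`.
#' @param widths Crop widths in um (default 400-1200 by 200; the largest is
#'   the reference).
#' @param sample_sizes Numbers of images per combination.
#' @param n_perm Permutations for co-occurrence enrichment.
#' @param seed Subsampling seed.
#' @return List: `results` (tidy per width x size x image metrics),
#'   `age_effect` (width x size spline-test p), `rates` (per-metric linear
#'   rate of change across widths).
#' @export
sensitivity_sweep <- function(cohort,
                              widths = c(400, 600, 800, 1000, 1200),
                              sample_sizes = c(50, 100, 400, 700, 1400),
                              n_perm = 20, seed = 0L) {
  stopifnot(inherits(cohort, "tissue_cohort"))
  W <- cohort$config$image_width
  widths <- sort(widths)
  ref_w <- max(widths)
  stopifnot(ref_w <= W)
  imgs <- unique(cohort$cells$image_id)
  phenos <- sort(unique(cohort$cells$phenotype))

  # per-image reference composition and enrichment at the largest width
  ref <- list()
  for (im in imgs) {
    cl <- cohort$cells[cohort$cells$image_id == im, ]
    if (nrow(cl) < 20) next
    crop <- crop_at_density_peak(cl, ref_w, W)$cells
    if (nrow(crop) < 20) next
    comp <- table(factor(crop$phenotype, levels = phenos))
    g <- build_graph(crop, "delaunay_pruned_20um")
    enr <- tryCatch(
      cooccurrence_enrichment(g, setNames(crop$phenotype,
                                          as.character(crop$cell_id)),
                              n_perm = n_perm, seed = child_seed(seed, 1)),
      error = function(e) NULL)
    ref[[im]] <- list(comp = comp, enr = enr, cells = cl)
  }
  usable <- names(ref)
  if (!length(usable)) stop("no image has enough cells for the sweep")

  rows <- list(); age_rows <- list()
  combo <- 0L
  for (wd in widths) {
    for (ns in sample_sizes) {
      combo <- combo + 1L
      pick <- with_seed(child_seed(seed, 100 + combo), {
        if (ns > length(usable)) {
          message("requested ", ns, " images but only ", length(usable),
                  " available: sampling with replacement")
          sample(usable, ns, replace = TRUE)
        } else sample(usable, ns)
      })
      duct_prop <- numeric(0); duct_age <- numeric(0)
      for (im in pick) {
        cl <- ref[[im]]$cells
        crop <- crop_at_density_peak(cl, wd, W)$cells
        if (nrow(crop) < 10) next
        comp <- table(factor(crop$phenotype, levels = phenos))
        klv <- kl_divergence(as.numeric(comp), as.numeric(ref[[im]]$comp))
        cosv <- NA_real_
        if (!is.null(ref[[im]]$enr)) {
          if (wd == ref_w) {
            # the reference compared to itself: 1 by construction
            cosv <- cooccurrence_similarity(ref[[im]]$enr, ref[[im]]$enr)
          } else if (length(unique(crop$phenotype)) >= 2) {
            g <- build_graph(crop, "delaunay_pruned_20um")
            enr <- tryCatch(
              cooccurrence_enrichment(g, setNames(crop$phenotype,
                                                  as.character(crop$cell_id)),
                                      n_perm = n_perm,
                                      seed = child_seed(seed, 2)),
              error = function(e) NULL)
            if (!is.null(enr)) cosv <- cooccurrence_similarity(enr, ref[[im]]$enr)
          }
        }
        epi <- crop$compartment == "epithelial"
        if (any(epi)) {
          duct_prop <- c(duct_prop,
                         mean(crop$structure_label[epi] == "duct"))
          duct_age <- c(duct_age, cl$age[1])
        }
        rows[[length(rows) + 1L]] <- data.frame(
          width = wd, n_images = ns, image_id = im, kl = klv, cosine = cosv)
      }
      p_age <- tryCatch(spline_vs_linear_lrt(duct_prop, duct_age)$p,
                        error = function(e) NA_real_)
      age_rows[[length(age_rows) + 1L]] <- data.frame(
        width = wd, n_images = ns, spline_p = p_age)
    }
  }
  results <- do.call(rbind, rows)
  age_effect <- do.call(rbind, age_rows)
  med <- aggregate(cbind(kl, cosine) ~ width, data = results, FUN = median,
                   na.rm = TRUE, na.action = NULL)
  rate <- function(y) {
    ok <- is.finite(y)
    if (sum(ok) < 2) return(NA_real_)
    unname(coef(lm(y[ok] ~ med$width[ok]))[2])
  }
  list(results = results, age_effect = age_effect,
       rates = c(kl_per_um = rate(med$kl), cosine_per_um = rate(med$cosine)))
}
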