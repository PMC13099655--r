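# Synthetic multiplexed-tissue generator with known ground truth.
#
# Emulates the statistical structure of an aging breast-tissue cohort imaged
# by multiplexed (IMC-style) tissue imaging: ducts and lobules built from
# epithelial cells with a myoepithelial rim, scattered stromal/immune cells
# whose density declines exponentially with age, an age-declining Ki67+
# (proliferating) fraction, a step drop in lobule density at age 50
# (menopause surrogate), and an adipocyte area fraction that grows with age.

#' Marker panel and per-phenotype intensity programs
#'
#' Defines which markers each synthetic phenotype expresses. Positive cells
#' draw marker intensity from lognormal(`mu_pos`, `sdlog`), negative cells
#' from lognormal(`mu_neg`, `sdlog`) with `mu_pos > mu_neg`, giving the
#' bimodal intensity distributions that pixel- and cell-level positivity
#' calling relies on.
#'
#' @param mu_pos,mu_neg Lognormal location (log mean ion count) for positive
#'   and negative cells.
#' @param sdlog Lognormal scale, shared by both components.
#' @return A list with `markers`, `programs` (phenotype -> positive markers),
#'   `compartments` (phenotype -> compartment) and the lognormal parameters.
#' @export
default_intensity_model <- function(mu_pos = log(20), mu_neg = log(1),
                                    sdlog = 0.4) {
  stopifnot(mu_pos > mu_neg, sdlog > 0)
  programs <- list(
    luminal_hr_pos = c("panCK", "ER"),
    luminal_hr_neg = c("panCK"),
    basal          = c("panCK", "CK5", "SMA"),
    fibroblast     = c("vimentin"),
    myofibroblast  = c("vimentin", "SMA"),
    endothelial    = c("CD31", "vimentin"),
    b_cell         = c("CD45", "CD20"),
    t_cell_cd4     = c("CD45", "CD4"),
    t_cell_cd8     = c("CD45", "CD8"),
    macrophage     = c("CD45", "CD68")
  )
  compartments <- c(
    luminal_hr_pos = "epithelial", luminal_hr_neg = "epithelial",
    basal = "epithelial",
    fibroblast = "stromal", myofibroblast = "stromal",
    endothelial = "stromal",
    b_cell = "immune", t_cell_cd4 = "immune", t_cell_cd8 = "immune",
    macrophage = "immune"
  )
  markers <- c("panCK", "CK5", "SMA", "Ki67", "CD45", "CD4", "CD8", "CD20",
               "CD68", "ER", "caveolin", "CD31", "vimentin", "podoplanin")
  list(markers = markers, programs = programs, compartments = compartments,
       mu_pos = mu_pos, mu_neg = mu_neg, sdlog = sdlog)
}

#' Cohort generating parameters
#'
#' Bundles every parameter of the synthetic cohort. Defaults encode the study
#' conditions the pipeline is exercised under: a stromal-majority tissue
#' (~51/38/11 percent stromal/epithelial/immune at young ages, ~2000 cells
#' per mm^2 total), comparable exponential density declines in all three
#' compartments, a low and age-declining proliferative (Ki67+) fraction that
#' is highest in epithelium, a lobule-density step at age 50 and an adipocyte
#' area fraction increasing with age.
#'
#' @param n_patients Number of patients.
#' @param age_range Inclusive age range in years.
#' @param images_per_patient Maximum images (cores) per patient; each patient
#'   receives between 1 and this many, drawn uniformly.
#' @param image_width Image side length in micrometres (square images).
#' @param um_per_pixel Pixel size in micrometres.
#' @param base_density Named vector: scattered-cell density (cells/mm^2) per
#'   compartment at the reference age of 15 years. The epithelial entry is
#'   the *scattered* (non-duct/lobule) epithelium; structure cells add mass
#'   on top of it.
#' @param density_decline_rate Named per-compartment exponential decline rate
#'   beta (per year): d_c(age) = d0_c * exp(-beta_c * (age - 15)). Applies to
#'   scattered cells and thins structure cells equally.
#' @param ki67_base Ki67+ probability for an epithelial cell at age 15.
#' @param ki67_decline Exponential decline rate (per year) of the Ki67+
#'   probability.
#' @param ki67_compartment_mult Multipliers scaling the Ki67+ probability per
#'   compartment (epithelial most proliferative, stromal least).
#' @param lobule_rate_pre50,lobule_rate_post50 Expected lobules per mm^2
#'   before and from age 50 (the programmed menopause step;
#'   `post50 < pre50`).
#' @param duct_rate Expected ducts per mm^2 (age-constant).
#' @param basal_frac_duct,basal_frac_lobule Probability that a duct/lobule
#'   epithelial cell is basal (ducts are basal-enriched).
#' @param adipocyte_fraction_base,adipocyte_fraction_slope Adipocyte area
#'   fraction at age 15 and its per-year linear increase.
#' @param vessel_rate Expected vessels per mm^2.
#' @param intensity_model See [default_intensity_model()].
#' @param seed Integer; fully determines the cohort.
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_patients = 50,
                          age_range = c(15, 86),
                          images_per_patient = 2,
                          image_width = 600,
                          um_per_pixel = 1,
                          base_density = c(epithelial = 150, stromal = 1000,
                                           immune = 220),
                          density_decline_rate = c(epithelial = 0.012,
                                                   stromal = 0.012,
                                                   immune = 0.012),
                          ki67_base = 0.04,
                          ki67_decline = 0.025,
                          ki67_compartment_mult = c(epithelial = 1,
                                                    immune = 0.35,
                                                    stromal = 0.12),
                          lobule_rate_pre50 = 3,
                          lobule_rate_post50 = 0.5,
                          duct_rate = 1.5,
                          basal_frac_duct = 0.35,
                          basal_frac_lobule = 0.10,
                          adipocyte_fraction_base = 0.05,
                          adipocyte_fraction_slope = 0.004,
                          vessel_rate = 3,
                          intensity_model = default_intensity_model(),
                          seed = 1L) {
  cmp <- c("epithelial", "stromal", "immune")
  stopifnot(
    n_patients >= 1,
    length(age_range) == 2, age_range[1] < age_range[2],
    images_per_patient >= 1, images_per_patient <= 5,
    image_width > 0, um_per_pixel > 0,
    all(cmp %in% names(base_density)),
    all(cmp %in% names(density_decline_rate)),
    all(is.finite(base_density)), all(is.finite(density_decline_rate)),
    is.finite(lobule_rate_pre50), is.finite(lobule_rate_post50),
    lobule_rate_post50 >= 0, lobule_rate_post50 <= lobule_rate_pre50,
    ki67_base >= 0, ki67_base <= 1
  )
  cfg <- list(
    n_patients = as.integer(n_patients), age_range = age_range,
    images_per_patient = as.integer(images_per_patient),
    image_width = image_width, um_per_pixel = um_per_pixel,
    base_density = base_density[cmp],
    density_decline_rate = density_decline_rate[cmp],
    ki67_base = ki67_base, ki67_decline = ki67_decline,
    ki67_compartment_mult = ki67_compartment_mult,
    lobule_rate_pre50 = lobule_rate_pre50,
    lobule_rate_post50 = lobule_rate_post50,
    duct_rate = duct_rate,
    basal_frac_duct = basal_frac_duct,
    basal_frac_lobule = basal_frac_lobule,
    adipocyte_fraction_base = adipocyte_fraction_base,
    adipocyte_fraction_slope = adipocyte_fraction_slope,
    vessel_rate = vessel_rate,
    intensity_model = intensity_model,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d patients, ages %g-%g, up to %d images/patient, %g um images\n",
              x$n_patients, x$age_range[1], x$age_range[2],
              x$images_per_patient, x$image_width))
  cat(sprintf("  scattered density at 15y (cells/mm^2): epi %g, stromal %g, immune %g\n",
              x$base_density["epithelial"], x$base_density["stromal"],
              x$base_density["immune"]))
  cat(sprintf("  lobule rate %g -> %g per mm^2 at age 50; duct rate %g\n",
              x$lobule_rate_pre50, x$lobule_rate_post50, x$duct_rate))
  invisible(x)
}

#' Programmed scattered-cell densities at a given age
#'
#' The per-compartment density (cells/mm^2) of *scattered* cells the
#' generator aims for at `age`: `d0_c * exp(-beta_c * (age - 15))`. Duct and
#' lobule cells add further (quantized) epithelial mass on top of the
#' epithelial entry.
#'
#' @param config A [cohort_config()].
#' @param age Age in years.
#' @return Named numeric vector over compartments.
#' @export
expected_scatter_density <- function(config, age) {
  config$base_density * exp(-config$density_decline_rate * (age - 15))
}

#' Programmed Ki67-positive probability
#'
#' @param config A [cohort_config()].
#' @param age Age in years.
#' @param compartment One of `"epithelial"`, `"stromal"`, `"immune"`.
#' @return Probability that a cell of that compartment is Ki67+ at that age.
#' @export
expected_ki67_fraction <- function(config, age, compartment = "epithelial") {
  unname(config$ki67_base * exp(-config$ki67_decline * (age - 15)) *
           config$ki67_compartment_mult[compartment])
}

#' Programmed lobule density (step model)
#'
#' @inheritParams expected_ki67_fraction
#' @return Expected lobules per mm^2: `lobule_rate_pre50` below age 50,
#'   `lobule_rate_post50` at and above it.
#' @export
expected_lobule_rate <- function(config, age) {
  ifelse(age < 50, config$lobule_rate_pre50, config$lobule_rate_post50)
}

# ---- internal geometry helpers ------------------------------------------

# Cells on a jittered hexagonal grid inside a disc (cx, cy, r), spacing s um.
.disc_cell_grid <- function(cx, cy, r, s) {
  xs <- seq(-r, r, by = s)
  ys <- seq(-r, r, by = s * sqrt(3) / 2)
  g <- expand.grid(x = xs, y = ys)
  odd <- (round((g$y + r) / (s * sqrt(3) / 2)) %% 2) == 1
  g$x[odd] <- g$x[odd] + s / 2
  keep <- g$x^2 + g$y^2 <= r^2
  g <- g[keep, , drop = FALSE]
  if (nrow(g) == 0) return(g)
  g$x <- cx + g$x + runif(nrow(g), -s / 4, s / 4)
  g$y <- cy + g$y + runif(nrow(g), -s / 4, s / 4)
  g
}

# Cells on a ring of radius r around (cx, cy), spacing s um along the arc.
.ring_cells <- function(cx, cy, r, s) {
  n <- max(3L, round(2 * pi * r / s))
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)] + runif(1, 0, 2 * pi / n)
  rr <- r * (1 + runif(n, -0.05, 0.05))
  data.frame(x = cx + rr * cos(th), y = cy + rr * sin(th))
}

# Morphology draws: area (um^2) and major/minor axes (um) with
# pi/4 * major * minor = area and major/minor = ratio.
.draw_morphology <- function(n, compartment) {
  mean_area <- c(epithelial = 80, stromal = 70, immune = 45)[compartment]
  area <- pmin(240, pmax(12, rlnorm(n, log(mean_area), 0.3)))
  ratio <- 1 + stats::rexp(n, rate = 2)
  minor <- sqrt(4 * area / (pi * ratio))
  data.frame(area = area, major_axis = minor * ratio, minor_axis = minor)
}

# Draw marker intensities for cells given their positive-marker programs.
# Returns a cells x markers matrix plus the logical positivity truth.
.draw_intensities <- function(phenotype, ki67_pos, im) {
  n <- length(phenotype)
  markers <- im$markers
  pos <- matrix(FALSE, n, length(markers), dimnames = list(NULL, markers))
  for (ph in unique(phenotype)) {
    rows <- phenotype == ph
    pos[rows, im$programs[[ph]]] <- TRUE
  }
  pos[, "Ki67"] <- ki67_pos
  mu <- ifelse(pos, im$mu_pos, im$mu_neg)
  ints <- matrix(rlnorm(n * length(markers), meanlog = mu, sdlog = im$sdlog),
                 n, length(markers), dimnames = list(NULL, markers))
  list(intensities = ints, positive = pos)
}

# Linear indices of the pixels of a filled disc / annulus inside an h x w
# matrix (pixel units). Painting is done by the caller with
# `plane[idx] <- pmax(plane[idx], value)` so the big matrix is modified in
# place instead of being copied across function calls.
.disc_idx <- function(cx, cy, r, h, w, r_in = -1) {
  x0 <- max(1L, floor(cx - r)); x1 <- min(w, ceiling(cx + r))
  y0 <- max(1L, floor(cy - r)); y1 <- min(h, ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(integer(0))
  xs <- x0:x1; ys <- y0:y1
  d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
  sel <- which(d2 <= r^2 & d2 > r_in^2)
  ny <- length(ys)
  ri <- ((sel - 1L) %% ny) + 1L
  ci <- ((sel - 1L) %/% ny) + 1L
  (xs[ci] - 1L) * h + ys[ri]
}

# Rasterize a convex polygon (vertices in um -> pixel grid): logical fill
# mask over the whole image. Ray-casting, vectorized over bounding box.
.polygon_fill <- function(h, w, vx, vy) {
  mask <- matrix(FALSE, h, w)
  x0 <- max(1L, floor(min(vx))); x1 <- min(w, ceiling(max(vx)))
  y0 <- max(1L, floor(min(vy))); y1 <- min(h, ceiling(max(vy)))
  if (x0 > x1 || y0 > y1) return(mask)
  xs <- x0:x1; ys <- y0:y1
  px <- rep(xs, each = length(ys)); py <- rep(ys, times = length(xs))
  inside <- rep(FALSE, length(px))
  k <- length(vx)
  j <- k
  for (i in seq_len(k)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  mask[cbind(py, px)] <- inside
  mask
}

# Random convex polygon around (cx, cy) with nominal radius r: jittered
# regular vertices, so the shape stays plump (circularity well above the
# 0.7 detection cut even after digitization and rim erosion).
.random_convex_polygon <- function(cx, cy, r, n_vertices = 12) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)] +
    runif(n_vertices, -0.12, 0.12) + runif(1, 0, 2 * pi)
  rr <- r * runif(n_vertices, 0.9, 1.1)
  pts <- cbind(cx + rr * cos(th), cy + rr * sin(th))
  hull <- chull(pts)
  pts[hull, , drop = FALSE]
}

# ---- generate_image ------------------------------------------------------

#' Generate one synthetic tissue image
#'
#' Builds the cell table, ground truth and (optionally) the rendered
#' multichannel pixel data for a single image of a patient of the given age.
#' Ducts are rendered as luminal/basal cell rings around a lumen, lobules as
#' acinar cell clusters, both wrapped in a myoepithelial rim mask; stromal
#' and immune cells are scattered as Poisson processes with age-declining
#' densities; adipocytes are convex polygonal caveolin rims with hollow
#' interiors; vessels are small filled objects on their own mask.
#'
#' @param patient_age Age in years (within `config$age_range`).
#' @param config A [cohort_config()].
#' @param seed Integer seed; fixes the image bit-for-bit.
#' @param image_id,patient_id Identifier strings stored in the cell table.
#' @param render If `TRUE`, paint pixel channels and masks; if `FALSE`, only
#'   the cell table and geometric ground truth are produced (much faster,
#'   sufficient for cohort-level statistics).
#' @return A list with `cells` (data.frame of cell records), `truth`
#'   (structure inventory, masks, generating parameters) and `image` (an
#'   `image_stack`, or `NULL` when `render = FALSE`).
#' @export
generate_image <- function(patient_age, config, seed = config$seed,
                           image_id = "img1", patient_id = "p1",
                           render = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  if (patient_age < config$age_range[1] || patient_age > config$age_range[2]) {
    stop("patient_age outside config$age_range")
  }
  W <- config$image_width
  any_structures <- config$lobule_rate_pre50 > 0 || config$duct_rate > 0
  if (any_structures && W < 200) {
    stop("image_width ", W, " um is too small to place duct/lobule structures (need >= 200 um)")
  }
  with_seed(seed, .generate_image_impl(patient_age, config, image_id,
                                       patient_id, render))
}

.generate_image_impl <- function(age, config, image_id, patient_id, render) {
  W <- config$image_width
  area_mm2 <- (W / 1000)^2
  thin <- exp(-config$density_decline_rate[["epithelial"]] * (age - 15))
  im <- config$intensity_model

  cells <- list()
  structures <- list()
  placed <- data.frame(x = numeric(0), y = numeric(0), r = numeric(0))

  place_center <- function(r) {
    # keep structures fully inside and strictly non-overlapping; a crowded
    # image skips the structure rather than accepting a collision
    lo <- r + 5; hi <- W - r - 5
    if (lo >= hi) return(NULL)
    for (try in 1:60) {
      cx <- runif(1, lo, hi); cy <- runif(1, lo, hi)
      if (nrow(placed) == 0 ||
          all(sqrt((placed$x - cx)^2 + (placed$y - cy)^2) > placed$r + r + 8)) {
        return(c(cx, cy))
      }
    }
    NULL
  }

  sid <- 0L
  add_structure <- function(kind, cx, cy, r_outer, rim_in, rim_out, df) {
    sid <<- sid + 1L
    structures[[sid]] <<- data.frame(
      structure_id = sid, kind = kind, x = cx, y = cy, r = r_outer,
      rim_in = rim_in, rim_out = rim_out, n_cells = nrow(df))
    placed[nrow(placed) + 1L, ] <<- c(cx, cy, r_outer)
    if (nrow(df)) cells[[length(cells) + 1L]] <<- df
  }

  epi_phenos <- function(n, p_basal) {
    ph <- ifelse(runif(n) < p_basal, "basal",
                 ifelse(runif(n) < 0.4, "luminal_hr_pos", "luminal_hr_neg"))
    ph
  }

  # Lobules: acinar discs of epithelial cells, myoepithelial rim outside.
  lob_rate <- expected_lobule_rate(config, age)
  n_lob <- rpois(1, lob_rate * area_mm2)
  for (i in seq_len(n_lob)) {
    r <- runif(1, 40, 75)
    ctr <- place_center(r + 6)
    if (is.null(ctr)) next
    g <- .disc_cell_grid(ctr[1], ctr[2], r, s = 12)
    if (nrow(g) == 0) next
    g <- g[runif(nrow(g)) < thin, , drop = FALSE]
    if (nrow(g) == 0) next
    df <- data.frame(x = g$x, y = g$y, compartment = "epithelial",
                     phenotype = epi_phenos(nrow(g), config$basal_frac_lobule),
                     structure_label = "lobule")
    add_structure("lobule", ctr[1], ctr[2], r + 4, r, r + 2, df)
  }

  # Ducts: two concentric epithelial rings around a lumen, thicker rim.
  n_duct <- rpois(1, config$duct_rate * area_mm2)
  for (i in seq_len(n_duct)) {
    rl <- runif(1, 20, 40)
    ctr <- place_center(rl + 24)
    if (is.null(ctr)) next
    ring1 <- .ring_cells(ctr[1], ctr[2], rl + 5, s = 9)
    ring2 <- .ring_cells(ctr[1], ctr[2], rl + 14, s = 9)
    g <- rbind(ring1, ring2)
    g <- g[runif(nrow(g)) < thin, , drop = FALSE]
    if (nrow(g) == 0) next
    df <- data.frame(x = g$x, y = g$y, compartment = "epithelial",
                     phenotype = epi_phenos(nrow(g), config$basal_frac_duct),
                     structure_label = "duct")
    add_structure("duct", ctr[1], ctr[2], rl + 22, rl + 18, rl + 22, df)
  }

  # Adipocytes: convex polygon rims, count set by the target area fraction.
  # Generated before the scattered cells so epithelium can be kept out of
  # their hollow interiors.
  frac <- max(0, config$adipocyte_fraction_base +
                config$adipocyte_fraction_slope * (age - 15))
  mean_adipo_area <- pi * mean(c(18, 30))^2
  n_adipo <- rpois(1, frac * area_mm2 * 1e6 / mean_adipo_area)
  adipos <- list()
  for (i in seq_len(n_adipo)) {
    r <- runif(1, 18, 30)
    ctr <- place_center(r * 1.2)
    if (is.null(ctr)) next
    poly <- .random_convex_polygon(ctr[1], ctr[2], r)
    adipos[[length(adipos) + 1L]] <- list(
      x = ctr[1], y = ctr[2], r = r, rim = sample(2:4, 1),
      vx = poly[, 1], vy = poly[, 2],
      area = shoelace_area(poly[, 1], poly[, 2]))
    placed[nrow(placed) + 1L, ] <- c(ctr[1], ctr[2], r * 1.15)
  }
  in_adipocyte <- function(x, y) {
    if (!length(adipos)) return(rep(FALSE, length(x)))
    hit <- rep(FALSE, length(x))
    for (a in adipos) {
      hit <- hit | ((x - a$x)^2 + (y - a$y)^2 <= (1.15 * a$r)^2)
    }
    hit
  }

  # Scattered cells per compartment (homogeneous Poisson).
  dens <- expected_scatter_density(config, age)
  scatter_pheno <- list(
    epithelial = c(luminal_hr_pos = 0.3, luminal_hr_neg = 0.5, basal = 0.2),
    stromal = c(fibroblast = 0.55, myofibroblast = 0.25, endothelial = 0.20),
    immune = c(t_cell_cd4 = 0.30, t_cell_cd8 = 0.25, b_cell = 0.20,
               macrophage = 0.25)
  )
  for (cmp in names(dens)) {
    n <- rpois(1, dens[[cmp]] * area_mm2)
    if (n == 0) next
    p <- scatter_pheno[[cmp]]
    sx <- runif(n, 0, W); sy <- runif(n, 0, W)
    if (cmp == "epithelial") {
      # keep panCK+ cells out of hollow adipocyte interiors
      keep <- !in_adipocyte(sx, sy)
      sx <- sx[keep]; sy <- sy[keep]
      n <- length(sx)
      if (n == 0) next
    }
    cells[[length(cells) + 1L]] <- data.frame(
      x = sx, y = sy, compartment = cmp,
      phenotype = sample(names(p), n, replace = TRUE, prob = p),
      structure_label = "none")
  }

  cells <- if (length(cells)) do.call(rbind, cells) else
    data.frame(x = numeric(0), y = numeric(0), compartment = character(0),
               phenotype = character(0), structure_label = character(0))
  structures <- if (sid > 0) do.call(rbind, structures) else
    data.frame(structure_id = integer(0), kind = character(0), x = numeric(0),
               y = numeric(0), r = numeric(0), rim_in = numeric(0),
               rim_out = numeric(0), n_cells = integer(0))

  n <- nrow(cells)
  if (n > 0) {
    morph <- .draw_morphology(n, cells$compartment)
    p_ki <- config$ki67_base * exp(-config$ki67_decline * (age - 15)) *
      config$ki67_compartment_mult[cells$compartment]
    ki67_pos <- runif(n) < p_ki
    drawn <- .draw_intensities(cells$phenotype, ki67_pos, im)
    ints <- drawn$intensities
    colnames(ints) <- paste0("int_", colnames(ints))
    cells <- cbind(
      data.frame(cell_id = seq_len(n), image_id = image_id,
                 patient_id = patient_id, age = age),
      cells[, c("x", "y")], morph,
      cells[, c("compartment", "phenotype", "structure_label")],
      data.frame(ki67_pos = ki67_pos), as.data.frame(ints))
    rownames(cells) <- NULL
    positive_truth <- drawn$positive
  } else {
    positive_truth <- matrix(FALSE, 0, length(im$markers),
                             dimnames = list(NULL, im$markers))
  }

  # Vessels: small filled objects; ~20% deliberately below 10 um^2 to
  # exercise the minimum-size filter downstream.
  n_ves <- rpois(1, config$vessel_rate * area_mm2)
  vessels <- if (n_ves > 0) {
    small <- runif(n_ves) < 0.2
    data.frame(x = runif(n_ves, 10, W - 10), y = runif(n_ves, 10, W - 10),
               r = ifelse(small, runif(n_ves, 1.0, 1.6),
                          runif(n_ves, 3, 8)))
  } else {
    data.frame(x = numeric(0), y = numeric(0), r = numeric(0))
  }
  vessels$area <- pi * vessels$r^2

  truth <- list(
    age = age, image_id = image_id, patient_id = patient_id,
    structures = structures,
    n_lobules = sum(structures$kind == "lobule"),
    n_ducts = sum(structures$kind == "duct"),
    adipocytes = adipos, vessels = vessels,
    positive = positive_truth,
    expected_scatter_density = dens,
    expected_ki67 = vapply(c("epithelial", "stromal", "immune"),
                           function(cm) expected_ki67_fraction(config, age, cm),
                           numeric(1)))

  image <- NULL
  if (render) {
    image <- .render_image(cells, truth, config)
    truth$masks <- image$masks
    image <- image$stack
  }
  list(cells = cells, truth = truth, image = image)
}

# Paint channels and masks. Coordinate convention: continuous um, origin
# top-left, x rightward, y downward; cell (x, y) falls in pixel
# (floor(x / um_per_pixel), floor(y / um_per_pixel)) 0-based, i.e. R matrix
# element [floor(y)+1, floor(x)+1].
.render_image <- function(cells, truth, config) {
  mpp <- config$um_per_pixel
  hw <- as.integer(round(config$image_width / mpp))
  im <- config$intensity_model
  markers <- im$markers
  ch <- lapply(markers, function(m) matrix(0, hw, hw))
  names(ch) <- markers

  to_px <- function(v) v / mpp + 0.5  # continuous pixel-center coordinates

  # per-cell discs: only markers bright enough to rise above background are
  # painted (whole-cell disc; nucleus-sized disc for Ki67)
  if (nrow(cells) > 0) {
    cr <- pmax(1.5, sqrt(cells$area / pi) / mpp)
    nr <- pmax(1.2, 0.55 * cr)
    cx <- to_px(cells$x); cy <- to_px(cells$y)
    bright <- exp(im$mu_neg + 2 * im$sdlog)
    for (m in markers) {
      v <- cells[[paste0("int_", m)]]
      rad <- if (m == "Ki67") nr else cr
      sel <- which(v > bright | (m == "Ki67" & cells$ki67_pos))
      plane <- matrix(0, hw, hw)
      for (i in sel) {
        li <- .disc_idx(cx[i], cy[i], rad[i], hw, hw)
        plane[li] <- pmax(plane[li], v[i])
      }
      ch[[m]] <- plane
    }
  }

  myoep <- matrix(FALSE, hw, hw)
  adipo_mask <- matrix(FALSE, hw, hw)
  vessel_mask <- matrix(FALSE, hw, hw)

  # myoepithelial rims: ducts get a thicker rim than lobules
  st <- truth$structures
  for (i in seq_len(nrow(st))) {
    li <- .disc_idx(to_px(st$x[i]), to_px(st$y[i]), st$rim_out[i] / mpp,
                    hw, hw, r_in = st$rim_in[i] / mpp)
    myoep[li] <- TRUE
    ch$SMA[li] <- pmax(ch$SMA[li], exp(im$mu_pos))
    ch$caveolin[li] <- pmax(ch$caveolin[li], exp(im$mu_pos) * 0.8)
  }

  # adipocyte rims on caveolin; interiors stay dark. Erosion to carve the
  # rim is done on the polygon's bounding box only.
  for (a in truth$adipocytes) {
    vx <- to_px(a$vx); vy <- to_px(a$vy)
    t_px <- max(1L, as.integer(round(a$rim / mpp)))
    x0 <- max(1L, floor(min(vx)) - 1L); x1 <- min(hw, ceiling(max(vx)) + 1L)
    y0 <- max(1L, floor(min(vy)) - 1L); y1 <- min(hw, ceiling(max(vy)) + 1L)
    if (x0 > x1 || y0 > y1) next
    sub_h <- y1 - y0 + 1L; sub_w <- x1 - x0 + 1L
    fill_sub <- .polygon_fill(sub_h, sub_w, vx - x0 + 1, vy - y0 + 1)
    er <- EBImage::erode(EBImage::Image(fill_sub * 1),
                         EBImage::makeBrush(2L * t_px + 1L, "disc"))
    rim_sub <- fill_sub & !(as.matrix(er) > 0.5)
    am <- adipo_mask[y0:y1, x0:x1]
    adipo_mask[y0:y1, x0:x1] <- am | fill_sub
    cav <- ch$caveolin[y0:y1, x0:x1]
    cav[rim_sub] <- pmax(cav[rim_sub], exp(im$mu_pos))
    ch$caveolin[y0:y1, x0:x1] <- cav
  }

  # vessels: filled discs on CD31 + mask
  vs <- truth$vessels
  for (i in seq_len(nrow(vs))) {
    li <- .disc_idx(to_px(vs$x[i]), to_px(vs$y[i]), vs$r[i] / mpp, hw, hw)
    vessel_mask[li] <- TRUE
    ch$CD31[li] <- pmax(ch$CD31[li], exp(im$mu_pos))
  }

  # mask classes must be pixel-disjoint: myoepithelial > adipocyte > vessel
  adipo_mask <- adipo_mask & !myoep
  vessel_mask <- vessel_mask & !myoep & !adipo_mask

  # channels are non-negative by construction; skip the public validator
  stack <- structure(
    list(pixels = array(unlist(ch, use.names = FALSE),
                        dim = c(hw, hw, length(markers)),
                        dimnames = list(NULL, NULL, markers)),
         channel_names = markers, um_per_pixel = mpp),
    class = "image_stack")
  list(stack = stack,
       masks = list(myoepithelial = myoep, adipocyte = adipo_mask,
                    vessel = vessel_mask))
}

#' Multichannel image container
#'
#' @param pixels Numeric array `height x width x channels`, finite and
#'   non-negative.
#' @param channel_names Character vector naming the third dimension.
#' @param um_per_pixel Pixel size in micrometres.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(pixels, channel_names, um_per_pixel = 1) {
  stopifnot(length(dim(pixels)) == 3,
            dim(pixels)[3] == length(channel_names),
            all(is.finite(pixels)), all(pixels >= 0), um_per_pixel > 0)
  structure(list(pixels = pixels, channel_names = channel_names,
                 um_per_pixel = um_per_pixel),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("image_stack: %d x %d px, %d channels (%s um/px)\n",
              d[1], d[2], d[3], format(x$um_per_pixel)))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Extract one channel of an image stack as a matrix
#' @param image An `image_stack`.
#' @param channel Channel name.
#' @return Numeric `height x width` matrix.
#' @export
get_channel <- function(image, channel) {
  stopifnot(inherits(image, "image_stack"))
  i <- match(channel, image$channel_names)
  if (is.na(i)) stop("no channel named '", channel, "'")
  image$pixels[, , i]
}

# ---- generate_cohort -----------------------------------------------------

#' Generate a synthetic patient cohort
#'
#' Draws patient ages from a right-skewed (shifted lognormal) distribution
#' with median near 38 years, gives each patient 1 to
#' `config$images_per_patient` images, and generates every image with
#' [generate_image()]. The whole cohort is a deterministic function of
#' `config$seed`.
#'
#' @param config A [cohort_config()].
#' @param render Render pixel data for every image (slow); cohort-level
#'   statistics only need the cell tables, so the default is `FALSE`.
#' @param ages Optional numeric vector of length `n_patients` overriding the
#'   age draw (used to program exact age designs).
#' @return An object of class `tissue_cohort`: list with `cells` (one row
#'   per cell across all images), `patients` (patient_id, age, n_images),
#'   `truth` (per-image ground truth, keyed by image_id), `images` (named
#'   list of `image_stack` or `NULL`s) and `config`.
#' @export
generate_cohort <- function(config, render = FALSE, ages = NULL) {
  stopifnot(inherits(config, "cohort_config"), config$n_patients >= 1)
  with_seed(config$seed, {
    n <- config$n_patients
    if (is.null(ages)) {
      ages <- config$age_range[1] + rlnorm(n, meanlog = log(23), sdlog = 0.55)
      ages <- pmin(config$age_range[2], pmax(config$age_range[1], ages))
    } else {
      stopifnot(length(ages) == n)
    }
    n_img <- if (config$images_per_patient == 1) rep(1L, n) else
      sample.int(config$images_per_patient, n, replace = TRUE)
    pid <- sprintf("P%03d", seq_len(n))
    patients <- data.frame(patient_id = pid, age = ages, n_images = n_img)

    all_cells <- list(); truth <- list(); images <- list()
    k <- 0L
    for (i in seq_len(n)) {
      for (j in seq_len(n_img[i])) {
        k <- k + 1L
        iid <- sprintf("%s_img%d", pid[i], j)
        res <- generate_image(ages[i], config,
                              seed = child_seed(config$seed, k),
                              image_id = iid, patient_id = pid[i],
                              render = render)
        all_cells[[k]] <- res$cells
        truth[[iid]] <- res$truth
        images[[iid]] <- res$image
      }
    }
    cells <- do.call(rbind, all_cells)
    rownames(cells) <- NULL
    cells$cell_id <- seq_len(nrow(cells))
    structure(list(cells = cells, patients = patients, truth = truth,
                   images = images, config = config),
              class = "tissue_cohort")
  })
}

#' @export
print.tissue_cohort <- function(x, ...) {
  cat(sprintf("tissue_cohort: %d patients, %d images, %d cells\n",
              nrow(x$patients), length(x$truth), nrow(x$cells)))
  cat(sprintf("  ages %.0f-%.0f (median %.0f)\n", min(x$patients$age),
              max(x$patients$age), median(x$patients$age)))
  invisible(x)
}

# ---- IO ------------------------------------------------------------------

#' Write an image stack as a multi-page TIFF
#'
#' One page per channel, 32-bit float; channel names and pixel size go to a
#' JSON sidecar at `<path>.json`.
#'
#' @param image An `image_stack`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(image, path) {
  stopifnot(inherits(image, "image_stack"))
  scale <- max(image$pixels, 1)  # TIFF samples must lie in [0, 1]
  pages <- lapply(seq_along(image$channel_names),
                  function(i) image$pixels[, , i] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(channel_names = image$channel_names,
                            um_per_pixel = image$um_per_pixel,
                            intensity_scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a multi-page TIFF written by [write_image_stack()]
#' @param path TIFF path.
#' @return An `image_stack`.
#' @export
read_image_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- if (file.exists(paste0(path, ".json"))) {
    jsonlite::fromJSON(paste0(path, ".json"))
  } else NULL
  chn <- meta$channel_names %||% paste0("ch", seq_along(pages))
  mpp <- meta$um_per_pixel %||% 1
  scale <- meta$intensity_scale %||% 1
  arr <- array(unlist(pages, use.names = FALSE) * scale,
               dim = c(dim(pages[[1]])[1], dim(pages[[1]])[2], length(pages)),
               dimnames = list(NULL, NULL, chn))
  image_stack(arr, chn, mpp)
}

#' Write the cell table as CSV (stable column order)
#' @param cells Cell data.frame as produced by the generator.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cells_csv <- function(cells, path) {
  lead <- c("cell_id", "image_id", "patient_id", "age", "x", "y", "area",
            "major_axis", "minor_axis", "compartment", "phenotype",
            "structure_label", "ki67_pos")
  lead <- intersect(lead, names(cells))
  rest <- setdiff(names(cells), lead)
  write.csv(cells[, c(lead, rest)], path, row.names = FALSE)
  invisible(path)
}
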