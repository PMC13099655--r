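# Pixel-level operations: hot pixels, positivity, adipocyte detection,
# myoepithelial thickness, mask metrics.

test_that("hot-pixel filter replaces single spikes and nothing else", {
  u <- matrix(5, 10, 10)
  expect_identical(filter_hot_pixels(u, 50), u)

  one <- matrix(1, 9, 9); one[5, 5] <- 100
  out <- filter_hot_pixels(one, 50)
  expect_equal(out[5, 5], 1)              # replaced by neighbourhood max
  expect_equal(out[-5, ], one[-5, ])      # everything else untouched

  two <- matrix(1, 9, 9); two[5, 5] <- 100; two[5, 6] <- 100
  out2 <- filter_hot_pixels(two, 50)
  expect_equal(out2, two)                 # adjacent pair protects itself

  # margin semantics: spike of exactly threshold above max is kept
  m <- matrix(1, 5, 5); m[3, 3] <- 51
  expect_equal(filter_hot_pixels(m, 50)[3, 3], 51)
  expect_equal(filter_hot_pixels(m, 49.9)[3, 3], 1)
})

test_that("hot-pixel filter is idempotent and handles tiny images", {
  set.seed(3)
  m <- matrix(rpois(400, 3), 20, 20)
  m[sample(400, 5)] <- 200
  once <- filter_hot_pixels(m, 50)
  expect_identical(filter_hot_pixels(once, 50), once)
  expect_identical(filter_hot_pixels(matrix(7, 1, 1), 10), matrix(7, 1, 1))
})

test_that("pixel positivity separates two intensity modes exactly", {
  set.seed(8)
  truth <- matrix(runif(2500) < 0.3, 50, 50)
  ch <- matrix(1, 50, 50); ch[truth] <- 100
  mask <- pixel_positivity(ch)
  expect_identical(mask$pixels, truth)    # threshold-at-midpoint oracle

  expect_warning(z <- pixel_positivity(matrix(0, 10, 10)), "constant")
  expect_false(any(z$pixels))
})

test_that("pixel positivity is invariant to monotone affine rescaling", {
  set.seed(9)
  truth <- matrix(runif(900) < 0.25, 30, 30)
  ch <- matrix(rlnorm(900, 0, 0.3), 30, 30); ch[truth] <- rlnorm(sum(truth), 3, 0.3)
  m1 <- pixel_positivity(ch)
  m2 <- pixel_positivity(2.5 * ch + 7)
  expect_identical(m1$pixels, m2$pixels)
})

test_that("positivity mask recovers painted Ki67 nuclei", {
  # a young patient, where the programmed proliferative fraction is highest
  cfg <- cohort_config(n_patients = 1, image_width = 500, seed = 13)
  res <- generate_image(16, cfg, seed = 13, render = TRUE)
  ki <- get_channel(res$image, "Ki67")
  painted <- ki > 5                        # pos intensities ~ lognormal(log 20)
  expect_gt(sum(painted), 50)
  mask <- pixel_positivity(ki)
  expect_gte(sum(mask$pixels & painted) / sum(painted), 0.95)
})

test_that("cell positive fractions are exact ratios and calls threshold them", {
  mask <- matrix(FALSE, 10, 10); mask[1:5, 1:10] <- TRUE
  cells <- list(a = cbind(row = rep(1:2, 2), col = c(1, 1, 2, 2)),   # fully in
                b = cbind(row = c(1, 2, 3, 6, 7, 8, 9, 10, 6, 7),
                          col = rep(1, 10)))                          # 3 of 10
  fr <- cell_positive_fraction(mask, cells)
  expect_equal(unname(fr), c(1.0, 0.3))
  expect_identical(unname(call_positive(fr, 0.5)), c(TRUE, FALSE))
  expect_error(cell_positive_fraction(mask, list(bad = cbind(row = integer(0), col = integer(0)))),
               "bad")
})

test_that("Ki67 cell calls from the rendered image match programmed truth", {
  res <- fixture_rendered()
  ki <- get_channel(res$image, "Ki67")
  mask <- pixel_positivity(ki)
  px <- cell_pixel_discs(res$cells, dim(ki), um_per_pixel = 1,
                         radius_scale = 0.55)
  fr <- cell_positive_fraction(mask, px)
  calls <- call_positive(fr, 0.1)
  expect_gte(mean(calls == res$cells$ki67_pos), 0.95)
})

test_that("circularity agrees with an independent boundary-walk oracle", {
  # digitized discs and rectangles up to 50x50
  shapes <- list()
  for (r in c(5, 8, 14, 20)) {
    d <- matrix(FALSE, 2 * r + 5, 2 * r + 5)
    cc <- r + 3
    d[which(outer((1:nrow(d) - cc)^2, (1:ncol(d) - cc)^2, "+") <= r^2)] <- TRUE
    shapes[[length(shapes) + 1]] <- d
  }
  sq <- matrix(FALSE, 46, 46); sq[4:43, 4:43] <- TRUE
  shapes[[length(shapes) + 1]] <- sq
  rect <- matrix(FALSE, 30, 50); rect[6:25, 6:45] <- TRUE
  shapes[[length(shapes) + 1]] <- rect
  for (s in shapes) {
    expect_equal(spatialbreast:::.object_circularity(s),
                 oracle_circularity(s), tolerance = 1e-3)
  }
  # a digitized disc is near-circular; a square sits near pi/4
  expect_gte(spatialbreast:::.object_circularity(shapes[[4]]), 0.9)
  expect_lt(spatialbreast:::.object_circularity(sq), 0.9)
})

test_that("adipocyte detector finds planted rims and applies both filters", {
  # build a clean caveolin plane: 3 large round adipocytes, 2 small, plus a
  # panCK-overlapped impostor that must be subtracted
  set.seed(21)
  cav <- matrix(rlnorm(400 * 400, 0, 0.3), 400, 400)
  panck <- matrix(FALSE, 400, 400)
  plant_ring <- function(m, cx, cy, r, val = 25) {
    idx <- spatialbreast:::.disc_idx(cx, cy, r, nrow(m), ncol(m), r_in = r - 3)
    m[idx] <- val
    m
  }
  centers <- list(c(60, 60, 25), c(160, 300, 30), c(320, 100, 22))
  for (p in centers) cav <- plant_ring(cav, p[1], p[2], p[3])
  cav <- plant_ring(cav, 250, 250, 5)   # too small (< 300 um^2 interior)
  cav <- plant_ring(cav, 40, 350, 4)    # too small
  cav <- plant_ring(cav, 330, 330, 28)  # impostor: epithelial ring
  panck[spatialbreast:::.disc_idx(330, 330, 26, 400, 400)] <- TRUE

  det <- detect_adipocytes(cav, panck, um_per_pixel = 1)
  expect_identical(nrow(det), 3L)
  expect_true(all(det$area >= 300))
  expect_true(all(det$circularity >= 0.7))
  found <- apply(cbind(det$centroid_x, det$centroid_y), 1, function(cc) {
    any(vapply(centers, function(p)
      sqrt((cc[1] - (p[1] - 0.5))^2 + (cc[2] - (p[2] - 0.5))^2) < 6, logical(1)))
  })
  expect_true(all(found))
  expect_identical(nrow(detect_adipocytes(matrix(0, 50, 50))), 0L)
})

test_that("adipocyte detector recovers generator ground truth counts", {
  res <- fixture_rendered()
  cav <- get_channel(res$image, "caveolin")
  panck <- pixel_positivity(get_channel(res$image, "panCK"))
  det <- detect_adipocytes(cav, panck)
  big <- sum(vapply(res$truth$adipocytes, function(a) {
    interior <- a$area - 2 * pi * a$r * a$rim  # rim carved off the fill
    interior >= 300
  }, logical(1)))
  expect_equal(nrow(det), big, tolerance = 0.15)
})

test_that("myoepithelial thickness proxy matches the strip oracle", {
  # analytic oracle: mean over depths d=1..w of 2*min(d, w+1-d) = (w+2)/2
  w <- 40
  strip <- matrix(FALSE, 1000, w + 20)
  strip[, 11:(10 + w)] <- TRUE
  assign_all <- matrix("duct", 1000, w + 20)
  th <- myoepithelial_thickness(strip, assign_all)
  expect_equal(unname(th["duct"]), w / 2, tolerance = 0.1)
  expect_true(is.na(th["lobule"]))

  # single-pixel line: proxy bounded by 2 px
  line <- matrix(FALSE, 50, 50); line[25, 5:45] <- TRUE
  th1 <- myoepithelial_thickness(line, matrix("lobule", 50, 50))
  expect_lte(unname(th1["lobule"]), 2)

  # width ordering: 4 px (duct) vs 8 px (lobule)
  m <- matrix(FALSE, 200, 40)
  m[, 5:8] <- TRUE; m[, 20:27] <- TRUE
  asg <- matrix(NA_character_, 200, 40)
  asg[, 1:14] <- "duct"; asg[, 15:40] <- "lobule"
  th2 <- myoepithelial_thickness(m, asg)
  expect_lt(th2["duct"], th2["lobule"])
})

test_that("mask metrics: fraction, count, and 3-4-5 distances", {
  m <- matrix(FALSE, 100, 100)
  m[1:50, ] <- TRUE
  mm <- mask_metrics(m, cells = NULL, tissue_area_mm2 = 0.01)
  expect_equal(mm$area_fraction, 0.5)

  # distance: mask pixel at row 5, col 4 has centre (3.5, 4.5) um; a cell
  # at (0.5, 0.5) is offset (3, 4) -> distance 5
  m2 <- matrix(FALSE, 20, 20); m2[5, 4] <- TRUE
  cells <- data.frame(x = 0.5, y = 0.5, area = 10)
  mm2 <- mask_metrics(m2, cells, tissue_area_mm2 = 4e-4, min_object_area = 0.5)
  expect_equal(mm2$distances, 5)

  # empty mask
  mm3 <- mask_metrics(matrix(FALSE, 10, 10), cells, tissue_area_mm2 = 1e-4)
  expect_identical(mm3$object_count, 0L)
  expect_equal(mm3$area_fraction, 0)
  expect_true(is.na(mm3$distances))
})

test_that("mask metrics fill holes and apply the minimum object size", {
  res <- fixture_rendered()
  vm <- res$truth$masks$vessel
  planted <- res$truth$vessels
  big <- sum(planted$area >= 10)
  mm <- mask_metrics(vm, cells = NULL,
                     tissue_area_mm2 = (res$image$um_per_pixel *
                                          nrow(vm) / 1000)^2)
  expect_identical(mm$object_count, as.integer(big))

  # a ring is filled before counting: one object, full disc area
  ring <- matrix(FALSE, 60, 60)
  ring[spatialbreast:::.disc_idx(30, 30, 15, 60, 60, r_in = 12)] <- TRUE
  mr <- mask_metrics(ring, cells = NULL, tissue_area_mm2 = 0.0036)
  expect_identical(mr$object_count, 1L)
  expect_gt(mr$area_fraction * 0.0036 * 1e6, pi * 13^2)  # interior included
})
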