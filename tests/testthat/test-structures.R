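# Duct/lobule structures, 3-hop TME association, paired composition tests,
# enrichment ratios.

test_that("contiguous lobules form single structures; separated ones split", {
  set.seed(41)
  lob1 <- cbind(runif(40, 0, 60), runif(40, 0, 60))
  cells <- toy_cells(lob1[, 1], lob1[, 2], compartment = "epithelial",
                     structure_label = "lobule")
  g <- build_graph(cells, "delaunay_full")
  st <- label_structures(cells, g)
  expect_identical(nrow(st), 1L)
  expect_identical(st$n_cells, 40L)
  expect_identical(st$kind, "lobule")

  # second lobule far away; surrounding stromal scatter breaks any direct
  # Delaunay adjacency between the two
  lob2 <- cbind(runif(20, 300, 340), runif(20, 300, 340))
  mid <- cbind(runif(120, 0, 400), runif(120, 0, 400))
  keep <- !(mid[, 1] < 70 & mid[, 2] < 70) &
    !(mid[, 1] > 290 & mid[, 2] > 290)
  mid <- mid[keep, , drop = FALSE]
  nm <- nrow(mid)
  cells2 <- toy_cells(c(lob1[, 1], lob2[, 1], mid[, 1]),
                      c(lob1[, 2], lob2[, 2], mid[, 2]),
                      compartment = rep(c("epithelial", "epithelial", "stromal"),
                                        c(40, 20, nm)),
                      structure_label = rep(c("lobule", "lobule", "none"),
                                            c(40, 20, nm)))
  g2 <- build_graph(cells2, "delaunay_full")
  st2 <- label_structures(cells2, g2)
  expect_identical(nrow(st2), 2L)
  expect_setequal(st2$n_cells, c(40L, 20L))

  # densities and per-structure means
  expect_equal(unname(structure_density(st2, 0.5)["lobule"]), 4)
  expect_equal(unname(structure_density(st2, 0.5)["duct"]), 0)
  cps <- cells_per_structure(st2)
  expect_equal(unname(cps["lobule"]), 30)
  expect_true(is.na(cps["duct"]))
})

test_that("structure components are disjoint and cover labelled cells", {
  cfg <- cohort_config(n_patients = 1, image_width = 600, seed = 43,
                       lobule_rate_pre50 = 6, duct_rate = 4)
  res <- generate_image(30, cfg, seed = 43, render = FALSE)
  g <- build_graph(res$cells, "delaunay_full")
  st <- label_structures(res$cells, g)
  mem <- unlist(attr(st, "members"))
  expect_identical(anyDuplicated(mem), 0L)
  labelled <- res$cells$cell_id[res$cells$structure_label %in%
                                  c("duct", "lobule") &
                                  res$cells$compartment == "epithelial"]
  expect_setequal(as.integer(mem), labelled)
  # densities scale inversely with area (exact)
  d1 <- structure_density(st, 0.36)
  d2 <- structure_density(st, 0.72)
  expect_equal(d1, 2 * d2)
})

test_that("TME association walks at most three hops, nearest kind wins", {
  # chain: epi - t1 - t2 - t3 - t4, spaced 10 um
  cells <- toy_cells(seq(0, 40, by = 10), rep(0, 5),
                     compartment = c("epithelial", rep("stromal", 4)),
                     structure_label = c("duct", rep("none", 4)))
  suppressWarnings(g <- build_graph(cells, "delaunay_pruned_20um"))
  assoc <- associate_tme(g, cells)
  expect_setequal(assoc$cell_id, 2:4)       # t1..t3 in, t4 out
  expect_equal(assoc$hops[order(assoc$cell_id)], 1:3)
  expect_true(all(assoc$kind == "duct"))

  # direct edge: 1 hop
  pair <- toy_cells(c(0, 8), c(0, 0),
                    compartment = c("epithelial", "immune"),
                    structure_label = c("lobule", "none"))
  suppressWarnings(gp <- build_graph(pair, "delaunay_pruned_20um"))
  ap <- associate_tme(gp, pair)
  expect_identical(ap$kind, "lobule")
  expect_equal(ap$hops, 1)
})

test_that("association matches a shortest-path oracle on random graphs", {
  set.seed(44)
  for (rep in 1:5) {
    n <- 80
    cells <- toy_cells(runif(n, 0, 160), runif(n, 0, 160),
                       compartment = sample(c("epithelial", "stromal"), n,
                                            replace = TRUE, prob = c(.4, .6)))
    cells$structure_label <- ifelse(
      cells$compartment == "epithelial",
      sample(c("duct", "lobule"), n, replace = TRUE), "none")
    g <- build_graph(cells, "delaunay_pruned_20um")
    assoc <- associate_tme(g, cells)
    ig <- spatialbreast::as_igraph(g)
    d <- igraph::distances(ig, weights = NA)
    rownames(d) <- colnames(d) <- igraph::V(ig)$name
    for (i in which(cells$compartment != "epithelial")) {
      hops_by_kind <- vapply(c("duct", "lobule"), function(k) {
        src <- as.character(cells$cell_id[cells$structure_label == k])
        if (!length(src)) return(Inf)
        min(d[as.character(cells$cell_id[i]), src])
      }, numeric(1))
      best <- min(hops_by_kind)
      row <- assoc[assoc$cell_id == cells$cell_id[i], ]
      if (best <= 3) {
        expect_identical(nrow(row), 1L)
        expect_equal(row$hops, best)
        # on a strict hop win the kind is determined; ties go to either
        if (hops_by_kind[1] != hops_by_kind[2]) {
          expect_identical(row$kind,
                           names(hops_by_kind)[which.min(hops_by_kind)])
        }
      } else {
        expect_identical(nrow(row), 0L)
      }
    }
  }
})

test_that("identical duct and lobule compositions give p = 1 and zero diffs", {
  set.seed(45)
  props <- matrix(runif(40), 10, 4,
                  dimnames = list(paste0("P", 1:10), paste0("ph", 1:4)))
  props <- props / rowSums(props)
  res <- paired_composition_test(props, props)
  expect_true(all(res$median_diff == 0))
  expect_true(all(res$p == 1))
})

test_that("signed-rank p matches exhaustive enumeration for n = 8 pairs", {
  set.seed(46)
  d <- c(0.12, -0.05, 0.2, 0.07, -0.01, 0.15, 0.09, 0.03)
  duct <- matrix(0.5 + d, 8, 1, dimnames = list(paste0("P", 1:8), "ph"))
  lob <- matrix(0.5, 8, 1, dimnames = list(paste0("P", 1:8), "ph"))
  res <- paired_composition_test(duct, lob)
  # oracle: exact signed-rank distribution by enumerating all 2^8 sign
  # configurations of the ranked |d|
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 8))
  vs <- as.matrix(signs) %*% r
  p_oracle <- mean(vs >= v_obs)
  p_two <- 2 * min(p_oracle, mean(vs <= v_obs))
  expect_equal(res$p, p_two, tolerance = 1e-10)
  expect_equal(res$median_diff, median(d))
  expect_true(res$ci_lower <= res$median_diff &
                res$median_diff <= res$ci_upper)
})

test_that("power floor and BH adjustment behave as documented", {
  set.seed(47)
  duct <- matrix(runif(8), 4, 2, dimnames = list(paste0("P", 1:4), c("a", "b")))
  lob <- matrix(runif(8), 4, 2, dimnames = list(paste0("P", 1:4), c("a", "b")))
  res <- paired_composition_test(duct, lob, min_pairs = 6)
  expect_true(all(is.na(res$p)))            # below the power floor
  # q never smaller than p
  duct2 <- matrix(runif(60), 10, 6,
                  dimnames = list(paste0("P", 1:10), paste0("f", 1:6)))
  lob2 <- matrix(runif(60), 10, 6, dimnames = dimnames(duct2))
  res2 <- paired_composition_test(duct2, lob2)
  expect_true(all(res2$q >= res2$p - 1e-12))
})

test_that("enrichment ratio equals observed over margin-derived expected", {
  obs <- matrix(c(30, 70, 10, 90), 2, 2, byrow = TRUE,
                dimnames = list(c("g1", "g2"), c("phA", "phB")))
  # phenotype at 10% globally, 30 of 100 cells in a group -> 3.0
  er <- enrichment_ratio(obs, c(phA = 0.1, phB = 0.9))
  expect_equal(er["g1", "phA"], 3.0)
  expect_equal(er["g2", "phA"], 1.0)

  # observed equal to expected -> 1 everywhere
  glob <- c(phA = 0.2, phB = 0.8)
  obs_eq <- rbind(g1 = 100 * glob, g2 = 50 * glob)
  expect_true(all(abs(enrichment_ratio(obs_eq, glob) - 1) < 1e-12))

  # 3x3 toy against hand-computed margins (defaults derive global props)
  toy <- matrix(c(5, 10, 5, 2, 8, 10, 3, 2, 5), 3, 3, byrow = TRUE,
                dimnames = list(c("r1", "r2", "r3"), c("c1", "c2", "c3")))
  er3 <- enrichment_ratio(toy)
  gp <- colSums(toy) / sum(toy)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(er3[i, j], toy[i, j] / (sum(toy[i, ]) * gp[[j]]))
  }
  # zero expected -> missing
  obs0 <- matrix(c(0, 10, 0, 5), 2, 2)
  expect_true(all(is.na(enrichment_ratio(obs0,
                                         c(0, 1))[, 1])))
})
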