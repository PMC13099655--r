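# Duct/lobule structure graphs, 3-hop microenvironment association, paired
# duct-vs-lobule composition testing and observed/expected enrichment.

#' Identify duct and lobule structures as connected components
#'
#' For each structure kind (duct, lobule), epithelial cells carrying that
#' annotation induce a subgraph of the full Delaunay graph whose connected
#' components are the structures.
#'
#' @param cells Cell table with `cell_id`, `compartment`, `structure_label`
#'   (`"duct"`, `"lobule"` or `"none"`).
#' @param graph Full-Delaunay `spatial_graph` on the same cells.
#' @return data.frame: `structure_id`, `kind`, `n_cells`; member cell ids in
#'   attribute `"members"`.
#' @export
label_structures <- function(cells, graph) {
  stopifnot_cols(cells, c("cell_id", "compartment", "structure_label"))
  stopifnot(inherits(graph, "spatial_graph"))
  g <- as_igraph(graph)
  ids <- as.character(cells$cell_id)
  rows <- list(); members <- list()
  sid <- 0L
  for (kind in c("duct", "lobule")) {
    sel <- ids[cells$compartment == "epithelial" &
                 cells$structure_label == kind]
    sel <- intersect(sel, igraph::V(g)$name)
    if (!length(sel)) next
    sub <- igraph::induced_subgraph(g, sel)
    comp <- igraph::components(sub)
    for (ci in seq_len(comp$no)) {
      mem <- igraph::V(sub)$name[comp$membership == ci]
      sid <- sid + 1L
      rows[[sid]] <- data.frame(structure_id = sid, kind = kind,
                                n_cells = length(mem))
      members[[sid]] <- mem
    }
  }
  out <- if (sid > 0) do.call(rbind, rows) else
    data.frame(structure_id = integer(0), kind = character(0),
               n_cells = integer(0))
  attr(out, "members") <- members
  out
}

#' Structure density per kind
#' @param structures data.frame from [label_structures()].
#' @param tissue_area_mm2 Tissue area in mm^2 (> 0).
#' @return Named vector `c(duct = ..., lobule = ...)` in structures per
#'   mm^2 (0 when absent).
#' @export
structure_density <- function(structures, tissue_area_mm2) {
  if (tissue_area_mm2 <= 0) stop("tissue_area_mm2 must be > 0")
  vapply(c(duct = "duct", lobule = "lobule"), function(k)
    sum(structures$kind == k) / tissue_area_mm2, numeric(1))
}

#' Mean cells per structure by kind
#'
#' Averages only over structures of the given kind; `NA` when a kind is
#' absent (patients without that kind contribute nothing).
#'
#' @param structures data.frame from [label_structures()].
#' @return Named vector `c(duct = ..., lobule = ...)`.
#' @export
cells_per_structure <- function(structures) {
  vapply(c(duct = "duct", lobule = "lobule"), function(k) {
    v <- structures$n_cells[structures$kind == k]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
}

#' Associate microenvironment cells with duct/lobule regions by graph hops
#'
#' Breadth-first search from all annotated epithelial cells simultaneously
#' on the 20-um pruned Delaunay graph: a TME cell is associated iff its
#' graph distance to some annotated epithelial cell is at most `hops`; its
#' kind is taken from the fewest-hops epithelial cell, ties broken by
#' smallest Euclidean distance (unique assignment).
#'
#' @param graph 20-um pruned `spatial_graph`.
#' @param cells Cell table with `cell_id`, `compartment`, `structure_label`,
#'   `x`, `y`.
#' @param hops Maximum graph distance (default 3).
#' @return data.frame: `cell_id`, `kind`, `hops` — one row per associated
#'   TME cell.
#' @export
associate_tme <- function(graph, cells, hops = 3) {
  stopifnot(inherits(graph, "spatial_graph"))
  stopifnot_cols(cells, c("cell_id", "compartment", "structure_label", "x", "y"))
  g <- as_igraph(graph)
  ids <- igraph::V(g)$name
  cl <- cells[match(ids, as.character(cells$cell_id)), ]
  is_tme <- cl$compartment != "epithelial"
  out <- list()
  for (kind in c("duct", "lobule")) {
    src <- which(cl$compartment == "epithelial" & cl$structure_label == kind)
    if (!length(src)) next
    d <- igraph::distances(g, v = src, weights = NA)  # hop counts
    mind <- apply(d, 2, min)
    nearest_src <- src[apply(d, 2, which.min)]
    reach <- is_tme & is.finite(mind) & mind <= hops
    if (!any(reach)) next
    # Euclidean distance to the nearest (fewest-hops) source cell, used
    # only to break ties between kinds at equal hop count
    ri <- which(reach)
    ns <- nearest_src[ri]
    eu <- sqrt((cl$x[ri] - cl$x[ns])^2 + (cl$y[ri] - cl$y[ns])^2)
    out[[kind]] <- data.frame(cell_id = cl$cell_id[ri], kind = kind,
                              hops = mind[ri], euclid = eu)
  }
  if (!length(out)) {
    return(data.frame(cell_id = integer(0), kind = character(0),
                      hops = numeric(0)))
  }
  all <- do.call(rbind, out)
  all <- all[order(all$cell_id, all$hops, all$euclid), ]
  all <- all[!duplicated(all$cell_id), c("cell_id", "kind", "hops")]
  rownames(all) <- NULL
  all
}

#' Paired duct-vs-lobule composition test
#'
#' For each phenotype, the per-patient proportion among duct-associated
#' cells is compared with the proportion among lobule-associated cells by a
#' paired Wilcoxon signed-rank test; p-values are Benjamini-Hochberg
#' corrected across phenotypes, and the median paired difference gets a
#' bootstrap confidence interval. Only patients with both compartments are
#' used; fewer than `min_pairs` paired patients makes the p-value missing.
#'
#' @param duct_props,lobule_props Patient x phenotype matrices of
#'   proportions (same dimnames).
#' @param n_boot Bootstrap resamples for the CI (default 2000).
#' @param conf_level CI level (default 0.95).
#' @param min_pairs Power floor (default 6).
#' @param seed Bootstrap seed.
#' @return data.frame: `phenotype`, `n_pairs`, `median_diff` (duct minus
#'   lobule), `ci_lower`, `ci_upper`, `p`, `q`.
#' @export
paired_composition_test <- function(duct_props, lobule_props, n_boot = 2000,
                                    conf_level = 0.95, min_pairs = 6,
                                    seed = 0L) {
  stopifnot(identical(dim(duct_props), dim(lobule_props)),
            identical(colnames(duct_props), colnames(lobule_props)))
  common <- intersect(rownames(duct_props), rownames(lobule_props))
  paired <- common[stats::complete.cases(duct_props[common, , drop = FALSE]) &
                     stats::complete.cases(lobule_props[common, , drop = FALSE])]
  res <- with_seed(seed, {
    lapply(colnames(duct_props), function(ph) {
      d <- duct_props[paired, ph] - lobule_props[paired, ph]
      n <- length(d)
      md <- median(d)
      if (n >= 2) {
        bs <- vapply(seq_len(n_boot), function(b)
          median(d[sample.int(n, n, replace = TRUE)]), numeric(1))
        ci <- quantile(bs, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                       names = FALSE)
      } else {
        ci <- c(NA_real_, NA_real_)
      }
      p <- if (n >= min_pairs && any(d != 0)) {
        suppressWarnings(wilcox.test(duct_props[paired, ph],
                                     lobule_props[paired, ph],
                                     paired = TRUE)$p.value)
      } else if (n >= min_pairs) 1 else NA_real_
      data.frame(phenotype = ph, n_pairs = n, median_diff = md,
                 ci_lower = ci[1], ci_upper = ci[2], p = p)
    })
  })
  out <- do.call(rbind, res)
  out$q <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Per-patient phenotype proportions among associated cells
#'
#' Helper assembling the inputs of [paired_composition_test()]: proportions
#' of each phenotype among cells associated with ducts (resp. lobules),
#' per patient.
#'
#' @param cells Cell table (`cell_id`, `patient_id`, `phenotype`).
#' @param association data.frame from [associate_tme()] or any
#'   (`cell_id`, `kind`) table; epithelial structure members can be included
#'   by the caller.
#' @param phenotypes Character vector fixing the column set.
#' @return List of two patient x phenotype matrices: `duct`, `lobule`; rows
#'   are patients observed in both, `NA` where a patient lacks a kind.
#' @export
composition_by_kind <- function(cells, association, phenotypes = NULL) {
  stopifnot_cols(cells, c("cell_id", "patient_id", "phenotype"))
  m <- merge(association, cells[, c("cell_id", "patient_id", "phenotype")],
             by = "cell_id")
  if (is.null(phenotypes)) phenotypes <- sort(unique(m$phenotype))
  pats <- sort(unique(m$patient_id))
  mk <- function(kind) {
    sub <- m[m$kind == kind, ]
    out <- matrix(NA_real_, length(pats), length(phenotypes),
                  dimnames = list(pats, phenotypes))
    for (p in unique(sub$patient_id)) {
      tab <- table(factor(sub$phenotype[sub$patient_id == p],
                          levels = phenotypes))
      out[p, ] <- as.numeric(tab) / sum(tab)
    }
    out
  }
  list(duct = mk("duct"), lobule = mk("lobule"))
}

#' Observed/expected phenotype enrichment
#'
#' Expected counts come from the global phenotype proportions applied to
#' each group's total: `expected[g, k] = total_g * global_prop_k`;
#' enrichment is `observed / expected`, `NA` where expected is zero.
#'
#' @param observed Group x phenotype count matrix.
#' @param global_proportions Named phenotype proportions summing to 1; by
#'   default the column sums of `observed` normalized.
#' @return Matrix of enrichment ratios with the same dimnames.
#' @export
enrichment_ratio <- function(observed, global_proportions = NULL) {
  stopifnot(is.matrix(observed), all(observed >= 0))
  if (is.null(global_proportions)) {
    global_proportions <- colSums(observed) / sum(observed)
  }
  stopifnot(length(global_proportions) == ncol(observed))
  expected <- outer(rowSums(observed), global_proportions)
  out <- observed / expected
  out[expected == 0] <- NA_real_
  dimnames(out) <- dimnames(observed)
  out
}
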