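# Patient x feature matrix assembly: the multiscale tissue phenotype table
# consumed by the aging-wave and sensitivity analyses.

#' Build the patient-level feature matrix from a cohort
#'
#' Runs the cell-level pipeline over every image and aggregates to one row
#' per patient: compartment and phenotype densities (convex-hull based),
#' phenotype proportions within compartments, Ki67+ fractions per
#' compartment (called by two-component intensity clustering of the Ki67
#' channel means), morphology means, duct/lobule structure density and
#' cells-per-structure, and mean nearest-epithelium distances for the
#' microenvironment compartments.
#'
#' @param cohort A `tissue_cohort`.
#' @param qc Apply [qc_filter()] first (default TRUE).
#' @param min_cells_per_image QC threshold passed through.
#' @return List of class `feature_matrix`: `features` (patients x features),
#'   `ages` (named), `meta` (data.frame describing each feature and its
#'   units).
#' @export
build_feature_matrix <- function(cohort, qc = TRUE,
                                 min_cells_per_image = 100) {
  stopifnot(inherits(cohort, "tissue_cohort"))
  cells <- cohort$cells
  if (qc) {
    cells <- qc_filter(cells, min_cells_per_image = min_cells_per_image)
  }
  if (nrow(cells) == 0) stop("no cells after QC")

  # cohort-wide Ki67 positivity call from the intensity mixture
  cells$ki67_call <- intensity_positive(cells$int_Ki67)

  imgs <- unique(cells$image_id)
  areas <- vapply(imgs, function(im)
    tissue_area(cells[cells$image_id == im, ]), numeric(1))
  names(areas) <- imgs

  pats <- sort(unique(cells$patient_id))
  ages <- setNames(cohort$patients$age[match(pats, cohort$patients$patient_id)],
                   pats)

  feat <- list()
  add <- function(name, values, unit, desc) {
    v <- rep(NA_real_, length(pats)); names(v) <- pats
    v[names(values)] <- values
    feat[[name]] <<- v
    meta_rows[[length(meta_rows) + 1L]] <<-
      data.frame(feature = name, unit = unit, description = desc)
  }
  meta_rows <- list()

  # total + per-compartment densities
  dtot <- density_by_patient(cells, areas)
  add("density_total", setNames(dtot$density, dtot$patient_id),
      "cells/mm^2", "total cell density (pooled cores)")
  dcmp <- density_by_patient(cells, areas, "compartment")
  for (cm in unique(dcmp$group)) {
    sub <- dcmp[dcmp$group == cm, ]
    add(paste0("density_", cm), setNames(sub$density, sub$patient_id),
        "cells/mm^2", paste(cm, "cell density"))
  }
  # per-phenotype densities
  dph <- density_by_patient(cells, areas, "phenotype")
  for (ph in unique(dph$group)) {
    sub <- dph[dph$group == ph, ]
    add(paste0("density_", ph), setNames(sub$density, sub$patient_id),
        "cells/mm^2", paste(ph, "density"))
  }
  # phenotype proportions within compartment
  for (cm in unique(cells$compartment)) {
    sub <- cells[cells$compartment == cm, ]
    tab <- table(sub$patient_id, sub$phenotype)
    props <- sweep(tab, 1, rowSums(tab), "/")
    for (ph in colnames(props)) {
      add(paste0("prop_", ph), setNames(as.numeric(props[, ph]),
                                        rownames(props)),
          "fraction", paste(ph, "proportion of", cm, "compartment"))
    }
  }
  # Ki67+ fraction per compartment
  for (cm in unique(cells$compartment)) {
    sub <- cells[cells$compartment == cm, ]
    fr <- tapply(sub$ki67_call, sub$patient_id, mean)
    add(paste0("ki67_", cm), fr, "fraction",
        paste("Ki67+ fraction of", cm, "cells"))
  }
  # morphology means
  cells$axis_ratio <- cells$major_axis / cells$minor_axis
  for (cm in unique(cells$compartment)) {
    sub <- cells[cells$compartment == cm, ]
    add(paste0("area_", cm), tapply(sub$area, sub$patient_id, mean), "um^2",
        paste("mean", cm, "cell area"))
    add(paste0("axis_ratio_", cm),
        tapply(sub$axis_ratio, sub$patient_id, mean), "ratio",
        paste("mean", cm, "major:minor axis ratio"))
  }
  # structures: per-image Delaunay graphs -> duct/lobule inventory
  sd_rows <- lapply(imgs, function(im) {
    cl <- cells[cells$image_id == im, ]
    if (nrow(cl) < 3 || is.na(areas[im])) return(NULL)
    g <- build_graph(cl, "delaunay_full")
    st <- label_structures(cl, g)
    data.frame(patient_id = cl$patient_id[1], area = areas[[im]],
               n_duct = sum(st$kind == "duct"),
               n_lob = sum(st$kind == "lobule"),
               cells_duct = sum(st$n_cells[st$kind == "duct"]),
               cells_lob = sum(st$n_cells[st$kind == "lobule"]))
  })
  sd <- do.call(rbind, sd_rows)
  agg <- aggregate(cbind(area, n_duct, n_lob, cells_duct, cells_lob) ~
                     patient_id, data = sd, FUN = sum)
  add("duct_density", setNames(agg$n_duct / agg$area, agg$patient_id),
      "per mm^2", "duct structures per mm^2")
  add("lobule_density", setNames(agg$n_lob / agg$area, agg$patient_id),
      "per mm^2", "lobule structures per mm^2")
  add("cells_per_duct",
      setNames(ifelse(agg$n_duct > 0, agg$cells_duct / agg$n_duct, NA),
               agg$patient_id), "cells", "mean cells per duct structure")
  add("cells_per_lobule",
      setNames(ifelse(agg$n_lob > 0, agg$cells_lob / agg$n_lob, NA),
               agg$patient_id), "cells", "mean cells per lobule structure")
  # nearest-epithelium distances per TME compartment
  nd_rows <- lapply(imgs, function(im) {
    cl <- cells[cells$image_id == im, ]
    if (!any(cl$compartment == "epithelial")) return(NULL)
    d <- suppressWarnings(nearest_epithelial_distance(cl))
    tme <- cl[cl$compartment != "epithelial", ]
    data.frame(patient_id = tme$patient_id, compartment = tme$compartment,
               dist = as.numeric(d))
  })
  nd <- do.call(rbind, nd_rows)
  if (!is.null(nd)) {
    for (cm in unique(nd$compartment)) {
      sub <- nd[nd$compartment == cm, ]
      add(paste0("dist_epi_", cm), tapply(sub$dist, sub$patient_id, mean),
          "um", paste("mean nearest-epithelium distance,", cm, "cells"))
    }
  }

  features <- do.call(cbind, feat)
  rownames(features) <- pats
  structure(list(features = features, ages = ages,
                 meta = do.call(rbind, meta_rows)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d patients x %d features\n",
              nrow(x$features), ncol(x$features)))
  invisible(x)
}

#' Write a feature matrix as CSV plus a JSON metadata sidecar
#' @param fm A `feature_matrix`.
#' @param path CSV path; metadata goes to `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(patient_id = rownames(fm$features), age = fm$ages,
                   fm$features, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(fm$meta, paste0(path, ".meta.json"), dataframe = "rows")
  invisible(path)
}
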