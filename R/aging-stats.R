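# Cohort-level statistics: convex-hull tissue area, patient densities,
# Spearman age associations, age-group comparisons with Cliff's delta,
# core-to-core variability, and the sliding-window aging-wave analysis.

#' Tissue area from the convex hull of segmented cells
#'
#' Convex hull of cell centroids, in mm^2. Fewer than 3 cells, or a
#' collinear point set, yields `NA` (the image is then excluded from
#' density calculations).
#'
#' @param cells Cell table with `x`, `y` in um (one image).
#' @return Area in mm^2, or `NA`.
#' @export
tissue_area <- function(cells) {
  stopifnot_cols(cells, c("x", "y"))
  if (nrow(cells) < 3) return(NA_real_)
  h <- chull(cells$x, cells$y)
  a <- shoelace_area(cells$x[h], cells$y[h])
  if (a <= 0) return(NA_real_)
  a / 1e6
}

#' Per-patient cell densities
#'
#' Pools each patient's images: density = sum of counts over the patient's
#' images divided by the sum of their hull areas (cores are thereby weighted
#' by tissue amount). Grouping is by any cell-table column (compartment,
#' phenotype, ...).
#'
#' @param cells Cell table (`patient_id`, `image_id`, plus the grouping
#'   column).
#' @param areas Named vector image_id -> area (mm^2), e.g. from
#'   [tissue_area()] per image; `NA` areas exclude the image.
#' @param grouping Column name to stratify by, or `NULL` for total density.
#' @return data.frame: `patient_id`, optional `group`, `density`
#'   (cells/mm^2). Patients with zero usable area are dropped.
#' @export
density_by_patient <- function(cells, areas, grouping = NULL) {
  stopifnot_cols(cells, c("patient_id", "image_id"))
  ok_imgs <- names(areas)[!is.na(areas)]
  cl <- cells[cells$image_id %in% ok_imgs, , drop = FALSE]
  img_pat <- unique(cl[, c("image_id", "patient_id")])
  pat_area <- tapply(areas[img_pat$image_id], img_pat$patient_id, sum)
  pat_area <- pat_area[pat_area > 0]
  if (is.null(grouping)) {
    counts <- table(cl$patient_id)
    pats <- names(pat_area)
    return(data.frame(patient_id = pats,
                      density = as.numeric(counts[pats]) / as.numeric(pat_area),
                      row.names = NULL))
  }
  stopifnot_cols(cl, grouping)
  tab <- table(cl$patient_id, cl[[grouping]])
  pats <- intersect(rownames(tab), names(pat_area))
  out <- expand.grid(patient_id = pats, group = colnames(tab),
                     stringsAsFactors = FALSE)
  out$density <- as.numeric(tab[cbind(out$patient_id, out$group)]) /
    as.numeric(pat_area[out$patient_id])
  out
}

#' Spearman rank correlation of a feature with age
#'
#' Midrank-tied Spearman correlation with a two-sided p-value; a constant
#' feature gives `NA` (undefined), reported missing.
#'
#' @param values Feature values (one per patient).
#' @param ages Matching ages.
#' @return List with `rho` and `p`.
#' @export
spearman_age <- function(values, ages) {
  keep <- is.finite(values) & is.finite(ages)
  values <- values[keep]; ages <- ages[keep]
  if (length(values) < 4) stop("need at least 4 paired observations")
  if (sd(values) == 0 || sd(ages) == 0) return(list(rho = NA_real_, p = NA_real_))
  ct <- suppressWarnings(cor.test(values, ages, method = "spearman",
                                  exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Cliff's delta with a consistent-variance normal confidence interval
#'
#' `delta = (#\{x > y\} - #\{x < y\}) / (n1 n2)`; the CI uses Cliff's
#' consistent variance estimator and a normal approximation, truncated to
#' `[-1, 1]`.
#'
#' @param x,y Two numeric samples.
#' @param conf_level CI level (default 0.95).
#' @return List: `delta`, `ci_lower`, `ci_upper`, `variance`.
#' @export
cliffs_delta <- function(x, y, conf_level = 0.95) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 > 0, n2 > 0)
  dij <- sign(outer(x, y, "-"))
  d <- mean(dij)
  di. <- rowMeans(dij); d.j <- colMeans(dij)
  if (n1 > 1 && n2 > 1) {
    s2 <- (n2^2 * sum((di. - d)^2) + n1^2 * sum((d.j - d)^2) -
             sum((dij - d)^2)) / (n1 * n2 * (n1 - 1) * (n2 - 1))
    s2 <- max(s2, 0)
  } else {
    s2 <- NA_real_
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- if (is.na(s2)) c(NA_real_, NA_real_) else
    pmax(-1, pmin(1, d + c(-1, 1) * z * sqrt(s2)))
  list(delta = d, ci_lower = ci[1], ci_upper = ci[2], variance = s2)
}

#' Young-versus-old comparison for a family of features
#'
#' Splits patients at the age cutoff (default 50, the menopause surrogate),
#' runs a two-sided Mann-Whitney U test per feature, computes Cliff's delta
#' with its CI, and Benjamini-Hochberg-adjusts the p-values across the
#' feature family passed in this one call.
#'
#' @param features Patient x feature matrix (or data.frame of numerics).
#' @param ages Patient ages aligned to rows.
#' @param cutoff Age cutoff in years (default 50); groups are `< cutoff`
#'   and `>= cutoff`.
#' @param conf_level CI level for Cliff's delta.
#' @return data.frame: `feature`, `n_young`, `n_old`, `p`, `q`, `delta`,
#'   `ci_lower`, `ci_upper`, `low_power` (a group smaller than 3).
#' @export
age_group_compare <- function(features, ages, cutoff = 50,
                              conf_level = 0.95) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(ages))
  young <- ages < cutoff
  if (!any(young) || all(young)) stop("both age groups must be non-empty")
  res <- lapply(colnames(features) %||% as.character(seq_len(ncol(features))),
                function(f) {
    xo <- features[!young, f]; xy <- features[young, f]
    xo <- xo[is.finite(xo)]; xy <- xy[is.finite(xy)]
    if (length(xo) == 0 || length(xy) == 0) {
      return(data.frame(feature = f, n_young = length(xy), n_old = length(xo),
                        p = NA_real_, delta = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, low_power = TRUE))
    }
    p <- suppressWarnings(wilcox.test(xy, xo)$p.value)
    cd <- cliffs_delta(xy, xo, conf_level)
    data.frame(feature = f, n_young = length(xy), n_old = length(xo), p = p,
               delta = cd$delta, ci_lower = cd$ci_lower,
               ci_upper = cd$ci_upper,
               low_power = min(length(xy), length(xo)) < 3)
  })
  out <- do.call(rbind, res)
  out$q <- p.adjust(out$p, method = "BH")
  out <- out[, c("feature", "n_young", "n_old", "p", "q", "delta",
                 "ci_lower", "ci_upper", "low_power")]
  rownames(out) <- NULL
  out
}

#' Core-to-core compositional variability within patients
#'
#' Per patient: all pairwise Pearson correlations between the phenotype
#' proportion vectors of the patient's cores, and the per-phenotype variance
#' of those proportions. Single-core patients contribute variance (zero
#' degrees of freedom -> `NA`) but no correlation.
#'
#' @param cells Cell table (`patient_id`, `image_id`, `phenotype`).
#' @return List of two data.frames: `correlations` (`patient_id`, `core_a`,
#'   `core_b`, `r`) and `variances` (`patient_id`, `phenotype`, `variance`).
#' @export
core_variability <- function(cells) {
  stopifnot_cols(cells, c("patient_id", "image_id", "phenotype"))
  phenos <- sort(unique(cells$phenotype))
  cors <- list(); vars <- list()
  for (p in unique(cells$patient_id)) {
    sub <- cells[cells$patient_id == p, ]
    tab <- table(sub$image_id, factor(sub$phenotype, levels = phenos))
    props <- sweep(tab, 1, rowSums(tab), "/")
    vars[[p]] <- data.frame(patient_id = p, phenotype = phenos,
                            variance = apply(props, 2, var))
    if (nrow(props) >= 2) {
      cmb <- utils::combn(rownames(props), 2)
      for (i in seq_len(ncol(cmb))) {
        a <- props[cmb[1, i], ]; b <- props[cmb[2, i], ]
        r <- if (sd(a) == 0 || sd(b) == 0) {
          message("core_variability: constant proportions for patient ", p,
                  ", correlation skipped")
          NA_real_
        } else cor(a, b)
        cors[[length(cors) + 1L]] <- data.frame(
          patient_id = p, core_a = cmb[1, i], core_b = cmb[2, i], r = r)
      }
    }
  }
  list(correlations = if (length(cors)) do.call(rbind, cors) else
         data.frame(patient_id = character(0), core_a = character(0),
                    core_b = character(0), r = numeric(0)),
       variances = do.call(rbind, vars))
}

#' Sliding-window count of age-significant features
#'
#' For each central age t, patients within `[t - window/2, t + window/2]`
#' are split at t and each feature is tested with a linear model on the
#' binary above-centre regressor (`feature ~ 1[age > t]`, two-sided p on the
#' group coefficient). P-values are Benjamini-Hochberg corrected across
#' features within each centre, and the number of features with q below
#' each cutoff is reported per centre. Centres with fewer than
#' `min_per_side` patients on either side are skipped. An optional
#' permutation control reruns the analysis with ages shuffled.
#'
#' @param features Patient x feature matrix.
#' @param ages Patient ages.
#' @param centers Grid of central ages (default 20:70).
#' @param window Window width in years (default 10, i.e. +/- 5).
#' @param q_cutoffs Significance cutoffs on q (default 0.05, 0.01, 0.005).
#' @param min_per_side Minimum patients on each side of the centre
#'   (default 10).
#' @param permute If `TRUE`, shuffle ages (under `seed`) before testing —
#'   the negative control.
#' @param seed Seed for the permutation.
#' @param detail If `TRUE`, attach the per-centre feature p- and q-value
#'   matrices as attributes `"p"` and `"q"` (centres x features).
#' @return data.frame: `center`, `n_window`, one `n_sig_q<cutoff>` column
#'   per cutoff; skipped centres are absent.
#' @export
sliding_window_waves <- function(features, ages, centers = 20:70,
                                 window = 10, q_cutoffs = c(0.05, 0.01, 0.005),
                                 min_per_side = 10, permute = FALSE,
                                 seed = 0L, detail = FALSE) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(ages))
  if (permute) ages <- with_seed(seed, sample(ages))
  half <- window / 2
  rows <- list()
  p_rows <- list(); q_rows <- list()
  for (t in centers) {
    sel <- ages >= t - half & ages <= t + half
    grp <- ages[sel] > t
    if (sum(grp) < min_per_side || sum(!grp) < min_per_side) next
    x <- features[sel, , drop = FALSE]
    ps <- vapply(seq_len(ncol(x)), function(j) {
      v <- x[, j]
      ok <- is.finite(v)
      if (length(unique(grp[ok])) < 2 || sd(v[ok]) == 0) return(NA_real_)
      fit <- lm(v[ok] ~ grp[ok])
      summary(fit)$coefficients[2, 4]
    }, numeric(1))
    qs <- p.adjust(ps, method = "BH")
    counts <- vapply(q_cutoffs, function(qc) sum(qs < qc, na.rm = TRUE),
                     numeric(1))
    rows[[length(rows) + 1L]] <- as.data.frame(
      c(list(center = t, n_window = sum(sel)),
        setNames(as.list(counts), paste0("n_sig_q", q_cutoffs))))
    if (detail) {
      p_rows[[length(p_rows) + 1L]] <- ps
      q_rows[[length(q_rows) + 1L]] <- qs
    }
  }
  if (!length(rows)) {
    return(data.frame(center = numeric(0), n_window = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (detail) {
    cn <- colnames(features) %||% as.character(seq_len(ncol(features)))
    attr(out, "p") <- matrix(unlist(p_rows), nrow = nrow(out), byrow = TRUE,
                             dimnames = list(out$center, cn))
    attr(out, "q") <- matrix(unlist(q_rows), nrow = nrow(out), byrow = TRUE,
                             dimnames = list(out$center, cn))
  }
  out
}
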