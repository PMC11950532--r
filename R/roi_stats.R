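#' Parcellate a volume into region means
#'
#' Averages the voxel values of `volume` within each atlas region
#' (background label 0 is excluded). This is the ROI reduction applied both
#' to morphometric maps (the images themselves) and to sensitivity maps.
#'
#' @param volume 3D numeric array on the same grid as the atlas.
#' @param atlas a [build_atlas()] result (or any list with an integer
#'   `labels` array and a `region_table`).
#' @return named numeric vector of region means, one per region label.
#' @export
parcellate <- function(volume, atlas) {
  lab <- atlas$labels
  if (!all(dim(volume) == dim(lab))) {
    stop(sprintf("grid mismatch: volume %s vs atlas %s",
                 paste(dim(volume), collapse = "x"),
                 paste(dim(lab), collapse = "x")), call. = FALSE)
  }
  K <- max(atlas$region_table$label)
  fg <- lab > 0L
  sums <- rowsum(as.vector(volume)[fg], group = as.integer(lab)[fg])
  counts <- tabulate(as.integer(lab)[fg], nbins = K)
  if (any(counts == 0L)) {
    stop("empty region(s) in atlas: ",
         paste(which(counts == 0L), collapse = ", "), call. = FALSE)
  }
  means <- numeric(K)
  means[as.integer(rownames(sums))] <- sums[, 1]
  means <- means / counts
  names(means) <- atlas$region_table$name[order(atlas$region_table$label)]
  means
}

#' Build a subjects-by-regions ROI matrix
#'
#' @param volumes named list of 3D arrays (names = subject ids).
#' @param atlas a [build_atlas()] result.
#' @param map_type `"morphometric"` or `"sensitivity"`.
#' @param modality free-form modality/channel tag.
#' @return a matrix (subjects x regions) with subject ids as rownames and
#'   attributes `map_type` and `modality`.
#' @export
roi_matrix <- function(volumes, atlas, map_type = c("morphometric", "sensitivity"),
                       modality = "chan1") {
  map_type <- match.arg(map_type)
  m <- t(vapply(volumes, parcellate, numeric(nrow(atlas$region_table)),
                atlas = atlas))
  rownames(m) <- names(volumes)
  attr(m, "map_type") <- map_type
  attr(m, "modality") <- modality
  m
}

#' Benjamini--Hochberg false discovery rate correction
#'
#' Step-up adjusted p-values with enforced monotonicity; a region is
#' significant when its adjusted value falls below `alpha`.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return a list with `q` (adjusted p-values, `q >= p` elementwise) and
#'   `significant` (logical).
#' @export
fdr_correct <- function(p, alpha = 0.05) {
  if (length(p) == 0L) stop("`p` must be non-empty", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, significant = q < alpha)
}

#' Per-region ANCOVA with FDR correction (stage 1)
#'
#' For every atlas region, fits an analysis of covariance with the ROI
#' value as the dependent variable, the clinical condition as the group
#' factor and age as a covariate (sex optionally added). P-values are then
#' corrected across regions, separately per factor, with the
#' Benjamini--Hochberg false discovery rate; the FDR family is all regions
#' of one map type x modality x factor combination.
#'
#' @param matrix a [roi_matrix()] (subjects x regions).
#' @param cohort cohort data.frame aligned with the matrix rows
#'   (matched by `participant_id` against rownames).
#' @param covariates covariates besides the condition factor; default
#'   `"age"`.
#' @param alpha FDR significance level.
#' @return a data.frame of class `roi_stat_table`, one row per region x
#'   factor: `region`, `factor`, `SS`, `F`, `p`, `np2`, `q`,
#'   `significant`; carries `map_type` and `modality` columns.
#' @export
roi_ancova <- function(matrix, cohort, covariates = "age", alpha = 0.05) {
  ids <- rownames(matrix)
  if (is.null(ids) || !identical(sort(ids), sort(cohort$participant_id))) {
    stop("subject ids of the ROI matrix and the cohort do not match", call. = FALSE)
  }
  cohort <- cohort[match(ids, cohort$participant_id), ]
  covariates <- match.arg(covariates, c("age", "sex"), several.ok = TRUE)
  dat <- data.frame(group = factor(cohort$group), age = cohort$age,
                    sex = factor(cohort$sex))
  if (nlevels(dat$group) < 2L) {
    stop("need two groups for the condition factor", call. = FALSE)
  }
  regions <- colnames(matrix)
  if (is.null(regions)) regions <- sprintf("region_%03d", seq_len(ncol(matrix)))
  rows <- vector("list", ncol(matrix))
  factor_names <- c(group = "condition", age = "age", sex = "sex")
  terms <- c("group", covariates)
  for (r in seq_len(ncol(matrix))) {
    dat$.y <- matrix[, r]
    rng <- diff(range(dat$.y))
    if (rng <= 1e-10 * (abs(mean(dat$.y)) + 1e-12)) {
      # a (numerically) constant ROI response carries no evidence of any
      # effect: report a null result instead of a degenerate fit
      tab <- data.frame(factor = factor_names[terms], SS = 0, F = 0, p = 1,
                        np2 = 0, stringsAsFactors = FALSE)
    } else {
      tab <- ancova_table(dat, ".y", terms)
      tab$factor <- factor_names[tab$factor]
    }
    rows[[r]] <- cbind(region = regions[r], tab)
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  out$significant <- NA
  for (f in unique(out$factor)) {
    sel <- out$factor == f
    fc <- fdr_correct(out$p[sel], alpha)
    out$q[sel] <- fc$q
    out$significant[sel] <- fc$significant
  }
  out$map_type <- attr(matrix, "map_type") %||% NA_character_
  out$modality <- attr(matrix, "modality") %||% NA_character_
  rownames(out) <- NULL
  class(out) <- c("roi_stat_table", "data.frame")
  out
}

#' Percentage of significant regions
#'
#' @param significant logical vector of per-region significance flags.
#' @return percentage in `[0, 100]`, rounded to 2 decimals.
#' @export
percent_significant <- function(significant) {
  if (length(significant) == 0L) stop("empty input", call. = FALSE)
  round(100 * mean(as.logical(significant)), 2)
}
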