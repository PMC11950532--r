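#' Significance set
#'
#' The set of atlas regions flagged significant by one analysis, together
#' with the universe of all regions and its provenance.
#'
#' @param regions labels/names of significant regions (subset of
#'   `universe`).
#' @param universe all region labels/names of the atlas.
#' @param map_type,modality,factor provenance tags.
#' @return an object of class `significance_set`.
#' @export
significance_set <- function(regions, universe, map_type = NA, modality = NA,
                             factor = NA) {
  regions <- unique(regions)
  universe <- unique(universe)
  if (length(setdiff(regions, universe))) {
    stop("significant regions must be a subset of the universe", call. = FALSE)
  }
  structure(list(regions = regions, universe = universe,
                 map_type = map_type, modality = modality, factor = factor),
            class = "significance_set")
}

check_universes <- function(a, b) {
  if (!setequal(a$universe, b$universe)) {
    stop("the two significance sets have different region universes", call. = FALSE)
  }
}

#' Jaccard index between two significance sets
#'
#' `|A intersect B| / |A union B|`. When both sets are empty the index is
#' reported as 0 -- the convention of the ratio itself -- but the result
#' carries `both_empty = TRUE`, because two analyses that each find no
#' significant region are in perfect agreement even though the ratio is
#' degenerate. Use [status_agreement()] for a measure that treats that
#' case as full agreement.
#'
#' @param a,b [significance_set()] objects over the same universe.
#' @return a list with `jaccard` (in `[0, 1]`) and `both_empty` (logical).
#' @export
jaccard_index <- function(a, b) {
  check_universes(a, b)
  na <- length(a$regions)
  nb <- length(b$regions)
  if (na == 0L && nb == 0L) {
    return(list(jaccard = 0, both_empty = TRUE))
  }
  u <- length(union(a$regions, b$regions))
  list(jaccard = length(intersect(a$regions, b$regions)) / u,
       both_empty = FALSE)
}

#' Fraction of regions with matching significance status
#'
#' The fraction of universe regions that are either significant in both
#' analyses or in neither. Two empty sets give 1 (perfect agreement).
#'
#' @param a,b [significance_set()] objects over the same universe.
#' @return a fraction in `[0, 1]`.
#' @export
status_agreement <- function(a, b) {
  check_universes(a, b)
  u <- a$universe
  ina <- u %in% a$regions
  inb <- u %in% b$regions
  mean(ina == inb)
}

#' Stage-2 concordance between morphometric and sensitivity significance
#'
#' For each modality and requested factor, extracts the significant-region
#' sets from the two stage-1 statistics tables and reports their Jaccard
#' index, the both-empty flag, the status agreement, and the two set sizes.
#'
#' @param morph,sens [roi_ancova()] tables for the morphometric and
#'   sensitivity maps (must cover the same regions and modalities).
#' @param factors factors to compare (default `c("age", "condition")`).
#' @return a data.frame with columns `modality`, `factor`, `jaccard`,
#'   `both_empty`, `agreement`, `n_sig_morph`, `n_sig_sens`.
#' @export
concordance_report <- function(morph, sens, factors = c("age", "condition")) {
  mods <- sort(unique(morph$modality))
  if (!setequal(mods, unique(sens$modality))) {
    stop("modalities of the two tables differ: ",
         paste(setdiff(union(morph$modality, sens$modality),
                       intersect(morph$modality, sens$modality)),
               collapse = ", "), call. = FALSE)
  }
  rows <- list()
  for (mod in mods) {
    for (f in factors) {
      mrows <- morph[morph$modality == mod & morph$factor == f, ]
      srows <- sens[sens$modality == mod & sens$factor == f, ]
      if (nrow(mrows) == 0L || nrow(srows) == 0L) {
        stop(sprintf("factor `%s` missing for modality `%s`", f, mod),
             call. = FALSE)
      }
      if (!setequal(mrows$region, srows$region)) {
        stop(sprintf("region sets differ for modality `%s`", mod), call. = FALSE)
      }
      a <- significance_set(mrows$region[mrows$significant], mrows$region,
                            "morphometric", mod, f)
      b <- significance_set(srows$region[srows$significant], srows$region,
                            "sensitivity", mod, f)
      j <- jaccard_index(a, b)
      rows[[length(rows) + 1L]] <- data.frame(
        modality = mod, factor = f,
        jaccard = j$jaccard, both_empty = j$both_empty,
        agreement = status_agreement(a, b),
        n_sig_morph = length(a$regions), n_sig_sens = length(b$regions),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
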