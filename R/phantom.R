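#' Atlas specification
#'
#' Describes the synthetic parcellation: a 3D grid partitioned into `n_regions`
#' disjoint ellipsoidal regions on a background of label 0. The synthetic atlas
#' plays the role a whole-brain anatomical labelling (such as the
#' neuromorphometrics parcellation) plays for real scans: it defines the
#' regions over which maps are averaged.
#'
#' @param grid_shape integer triple, voxels per axis.
#' @param n_regions number of regions `K >= 1`.
#' @param seed integer seed controlling centre jitter and semi-axes.
#' @return an object of class `atlas_spec`.
#' @export
atlas_spec <- function(grid_shape = c(32L, 32L, 32L), n_regions = 24L, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L))
  n_regions <- as.integer(n_regions)
  if (n_regions < 1L) stop("`n_regions` must be >= 1", call. = FALSE)
  structure(list(grid_shape = grid_shape, n_regions = n_regions,
                 seed = as.integer(seed)),
            class = "atlas_spec")
}

#' Build a synthetic atlas of disjoint ellipsoidal regions
#'
#' Region centres are seated on a jittered cubic lattice (one region per
#' lattice cell, cells taken in label order) and each region is an axis-aligned
#' ellipsoid around its centre. A voxel inside several ellipsoids is assigned
#' to the nearest centre (Euclidean distance); remaining ties go to the lowest
#' label. Every region is guaranteed at least its centre voxel, and regions
#' are disjoint by construction since each voxel carries exactly one label.
#'
#' @param spec an [atlas_spec()].
#' @return an object of class `atlas`: a list with `labels` (integer 3D
#'   array, 0 = background), `region_table` (data.frame with `label`, `name`,
#'   `n_voxels`), `spec` and `pixdim` (mm, fixed isotropic 1 mm).
#' @export
build_atlas <- function(spec) {
  stopifnot(inherits(spec, "atlas_spec"))
  dims <- spec$grid_shape
  K <- spec$n_regions
  m <- ceiling(K^(1 / 3))
  cell <- floor(dims / m)
  if (any(cell < 4L)) {
    stop(sprintf(
      "grid %s is too small to seat %d disjoint regions (lattice cell < 4 voxels)",
      paste(dims, collapse = "x"), K), call. = FALSE)
  }

  with_seed(derive_seed(spec$seed, "atlas"), {
    # lattice cell index per region, in label order
    cells <- as.matrix(expand.grid(i = seq_len(m), j = seq_len(m), k = seq_len(m)))[seq_len(K), , drop = FALSE]
    centres <- matrix(0, K, 3)
    semi <- matrix(0, K, 3)
    for (r in seq_len(K)) {
      for (a in 1:3) {
        lo <- (cells[r, a] - 1) * cell[a]
        centres[r, a] <- lo + cell[a] / 2 + stats::runif(1, -cell[a] / 6, cell[a] / 6)
        semi[r, a] <- stats::runif(1, 0.30, 0.46) * cell[a]
      }
    }

    co <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]), z = seq_len(dims[3])))
    lab <- integer(nrow(co))
    best <- rep(Inf, nrow(co))
    for (r in seq_len(K)) {
      dx <- co[, 1] - centres[r, 1]
      dy <- co[, 2] - centres[r, 2]
      dz <- co[, 3] - centres[r, 3]
      inside <- (dx / semi[r, 1])^2 + (dy / semi[r, 2])^2 + (dz / semi[r, 3])^2 <= 1
      d2 <- dx^2 + dy^2 + dz^2
      take <- inside & (d2 < best - 1e-12)  # ties keep the earlier (lower) label
      lab[take] <- r
      best[take] <- d2[take]
      # the voxel nearest the centre always belongs to the region
      cv <- which.min(d2)
      if (lab[cv] != r && d2[cv] <= best[cv]) {
        lab[cv] <- r
        best[cv] <- d2[cv]
      }
    }

    labels <- array(lab, dim = dims)
    counts <- tabulate(lab, nbins = K)
    if (any(counts == 0L)) {
      stop("internal error: empty region in generated atlas", call. = FALSE)
    }
    structure(list(
      labels = labels,
      region_table = data.frame(
        label = seq_len(K),
        name = sprintf("region_%03d", seq_len(K)),
        n_voxels = counts
      ),
      spec = spec,
      pixdim = c(1, 1, 1)
    ), class = "atlas")
  })
}

#' Region-wise effect model for the phantom
#'
#' Defines the latent intensity field the phantom renders: each region has a
#' baseline intensity (arbitrary units) that declines linearly with age, and
#' a designated subset of "disease" regions receives an additional additive
#' offset in patients only, emulating pathology-accelerated atrophy on top of
#' healthy ageing. Subjects carry a random intercept (between-subject
#' variability) and voxels carry i.i.d. Gaussian noise. Multiple
#' modality-like channels are produced by scalar mixing of the one latent
#' field.
#'
#' Defaults: baselines are drawn uniformly in 80--120 units, age slopes
#' uniformly in -0.8 to -0.3 units/year on every region (global atrophy with
#' regional variation), and the disease offset is -15 units (roughly 25-50
#' years of extra ageing at the default slopes).
#'
#' @param n_regions number of atlas regions K.
#' @param age_ref reference age (years); slopes act on `age - age_ref`.
#' @param age_sensitive_set region labels with nonzero age slope
#'   (default all).
#' @param disease_set region labels carrying the patient offset.
#' @param disease_offset additive intensity change (units) applied to
#'   `disease_set` regions in patients.
#' @param subject_sd SD (units) of the per-subject random intercept.
#' @param voxel_sd SD (units) of i.i.d. voxel noise.
#' @param sex_offset additive intensity change (units) applied to male
#'   subjects across all regions; 0 by default so the sex covariate is
#'   exercised under the null.
#' @param n_channels number of modality-like channels.
#' @param channel_mixing per-channel scalar weight on the latent field.
#' @param seed seed for the per-region baselines and slopes.
#' @return an object of class `effect_model`.
#' @export
effect_model <- function(n_regions,
                         age_ref = 18,
                         age_sensitive_set = seq_len(n_regions),
                         disease_set = integer(0),
                         disease_offset = -15,
                         subject_sd = 2,
                         voxel_sd = 2,
                         sex_offset = 0,
                         n_channels = 2L,
                         channel_mixing = NULL,
                         seed = 1L) {
  n_regions <- as.integer(n_regions)
  stopifnot(n_regions >= 1L)
  if (subject_sd < 0 || voxel_sd < 0) {
    stop("`subject_sd` and `voxel_sd` must be >= 0", call. = FALSE)
  }
  if (length(disease_set) && (any(disease_set < 1L) || any(disease_set > n_regions))) {
    stop("`disease_set` must be a subset of 1..n_regions", call. = FALSE)
  }
  if (length(age_sensitive_set) && (any(age_sensitive_set < 1L) || any(age_sensitive_set > n_regions))) {
    stop("`age_sensitive_set` must be a subset of 1..n_regions", call. = FALSE)
  }
  if (is.null(channel_mixing)) {
    channel_mixing <- seq(1, 0.6, length.out = n_channels)
  }
  stopifnot(length(channel_mixing) == n_channels)

  with_seed(derive_seed(seed, "effects"), {
    baseline <- stats::runif(n_regions, 80, 120)
    slope <- stats::runif(n_regions, -0.8, -0.3)
  })
  age_slope <- numeric(n_regions)
  age_slope[as.integer(age_sensitive_set)] <- slope[as.integer(age_sensitive_set)]
  offset <- numeric(n_regions)
  offset[as.integer(disease_set)] <- disease_offset

  structure(list(
    n_regions = n_regions,
    baseline = baseline,
    age_slope = age_slope,
    age_sensitive_set = sort(as.integer(age_sensitive_set)),
    disease_offset = offset,
    disease_set = sort(as.integer(disease_set)),
    subject_sd = subject_sd,
    voxel_sd = voxel_sd,
    sex_offset = sex_offset,
    n_channels = as.integer(n_channels),
    channel_mixing = channel_mixing,
    age_ref = age_ref,
    seed = as.integer(seed)
  ), class = "effect_model")
}

#' Sample a synthetic cohort
#'
#' Ages are i.i.d. uniform on `[age_min, age_max]`, sex is balanced
#' Bernoulli(0.5), and `round(n * group_fraction)` randomly chosen subjects
#' are labelled `patient` (the rest `control`).
#'
#' @param n number of subjects (> 0).
#' @param group_fraction fraction of patients in `[0, 1]`.
#' @param age_min,age_max age range in years, `age_min < age_max`.
#' @param seed integer seed.
#' @param id_prefix prefix for subject ids (role prefixes keep cohorts with
#'   different roles disjoint by id).
#' @return a data.frame with columns `participant_id`, `age`, `sex`
#'   (`F`/`M`), `group` (`control`/`patient`).
#' @export
sample_cohort <- function(n, group_fraction = 0, age_min = 18, age_max = 88,
                          seed = 1L, id_prefix = "sub") {
  if (n <= 0) stop("`n` must be a positive integer", call. = FALSE)
  if (group_fraction < 0 || group_fraction > 1) {
    stop("`group_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (age_min >= age_max) stop("`age_min` must be < `age_max`", call. = FALSE)
  n <- as.integer(n)
  with_seed(derive_seed(seed, "cohort", id_prefix), {
    age <- stats::runif(n, age_min, age_max)
    sex <- ifelse(stats::rbinom(n, 1L, 0.5) == 1L, "M", "F")
    n_pat <- round(n * group_fraction)
    group <- rep("control", n)
    if (n_pat > 0) group[sample.int(n, n_pat)] <- "patient"
    data.frame(
      participant_id = format_subject_id(id_prefix, seq_len(n)),
      age = age,
      sex = sex,
      group = group,
      stringsAsFactors = FALSE
    )
  })
}

#' Render one subject's multi-channel volume stack
#'
#' Voxel values follow the additive model: within region `r` and channel `c`,
#' `value = mixing[c] * (baseline[r] + age_slope[r] * (age - age_ref) +
#' disease_offset[r] * is_patient + sex_offset * is_male + subject_intercept)
#' + N(0, voxel_sd)`; background voxels are pure noise. Rendering is
#' deterministic for a fixed `(participant_id, seed)` pair.
#'
#' @param record one-row data.frame (or list) with `participant_id`, `age`,
#'   `sex`, `group`.
#' @param atlas an [build_atlas()] result.
#' @param effects an [effect_model()].
#' @param seed master seed; the subject's own stream is derived from it and
#'   the participant id.
#' @return a list of class `subject_volumes`: `channels` (list of 3D arrays),
#'   `intercept` (the realized subject intercept), `participant_id`.
#' @export
render_subject <- function(record, atlas, effects, seed = 1L) {
  stopifnot(inherits(atlas, "atlas"), inherits(effects, "effect_model"))
  K <- max(atlas$labels)
  if (K > effects$n_regions) {
    stop(sprintf("atlas has region label %d but the effect model covers only %d regions",
                 K, effects$n_regions), call. = FALSE)
  }
  if (length(effects$disease_set) && any(!effects$disease_set %in% atlas$region_table$label)) {
    stop("`disease_set` references regions absent from the atlas", call. = FALSE)
  }
  age <- as.numeric(record$age)
  is_pat <- identical(as.character(record$group), "patient")
  is_male <- identical(as.character(record$sex), "M")
  lab <- as.integer(atlas$labels)

  region_mean <- effects$baseline +
    effects$age_slope * (age - effects$age_ref) +
    if (is_pat) effects$disease_offset else 0
  region_mean <- region_mean + if (is_male) effects$sex_offset else 0

  with_seed(derive_seed(seed, "render", as.character(record$participant_id)), {
    intercept <- if (effects$subject_sd > 0) stats::rnorm(1, 0, effects$subject_sd) else 0
    latent <- numeric(length(lab))
    fg <- lab > 0L
    latent[fg] <- region_mean[lab[fg]] + intercept
    channels <- vector("list", effects$n_channels)
    for (c in seq_len(effects$n_channels)) {
      v <- effects$channel_mixing[c] * latent
      if (effects$voxel_sd > 0) v <- v + stats::rnorm(length(v), 0, effects$voxel_sd)
      channels[[c]] <- array(v, dim = dim(atlas$labels))
    }
    structure(list(channels = channels, intercept = intercept,
                   participant_id = as.character(record$participant_id)),
              class = "subject_volumes")
  })
}

#' Render every subject of a cohort
#'
#' @inheritParams render_subject
#' @param cohort a [sample_cohort()] data.frame.
#' @return a named list of [render_subject()] results, one per cohort row.
#' @export
render_cohort <- function(cohort, atlas, effects, seed = 1L) {
  out <- lapply(seq_len(nrow(cohort)), function(i) {
    render_subject(cohort[i, ], atlas, effects, seed = seed)
  })
  names(out) <- cohort$participant_id
  out
}

#' Ground-truth manifest for a rendered dataset
#'
#' Collects everything needed to re-render any subject bit-exactly: the
#' effect model, the realized per-subject intercepts, and the seeds.
#'
#' @param effects the [effect_model()] used.
#' @param volumes a [render_cohort()] result.
#' @param atlas_spec the [atlas_spec()] used.
#' @param seed the master rendering seed.
#' @return a list of class `ground_truth_manifest`.
#' @export
ground_truth_manifest <- function(effects, volumes, atlas_spec, seed) {
  intercepts <- vapply(volumes, function(v) v$intercept, numeric(1))
  structure(list(
    effects = unclass(effects),
    intercepts = as.list(intercepts),
    atlas_spec = unclass(atlas_spec),
    seed = as.integer(seed)
  ), class = "ground_truth_manifest")
}
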