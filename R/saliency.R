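#' Saliency configuration
#'
#' @param noise_level Gaussian noise SD as a fraction of the input volume's
#'   dynamic range (`max - min`), in `[0, 0.5]`.
#' @param n_samples number of noisy gradient samples averaged (>= 1);
#'   default 25.
#' @param seed integer seed for the noise draws.
#' @param reduce `"signed"` (average raw gradients, default) or
#'   `"absolute"` (average `|gradient|` per sample).
#' @return an object of class `saliency_config`.
#' @export
saliency_config <- function(noise_level = 0.1, n_samples = 25L, seed = 1L,
                            reduce = c("signed", "absolute")) {
  if (noise_level < 0 || noise_level > 0.5) {
    stop("`noise_level` must be in [0, 0.5]", call. = FALSE)
  }
  n_samples <- as.integer(n_samples)
  if (n_samples < 1L) stop("`n_samples` must be >= 1", call. = FALSE)
  structure(list(noise_level = noise_level, n_samples = n_samples,
                 seed = as.integer(seed), reduce = match.arg(reduce)),
            class = "saliency_config")
}

#' Vanilla gradient sensitivity map
#'
#' The gradient of the model's predicted age with respect to every input
#' voxel, revealing the influence each voxel exerts on the prediction.
#' Gradients are taken on the raw (un-normalized) input scale and always
#' from the uncorrected prediction: the linear BrainAGE bias correction
#' happens downstream of the network and never touches the gradient path.
#'
#' @param model a finalized `age_model`.
#' @param volume 3D array (or voxel-by-channel matrix) matching the model
#'   input.
#' @return a sensitivity map with the same shape as the input.
#' @export
vanilla_gradient <- function(model, volume) {
  stopifnot(inherits(model, "age_model"))
  x <- as_volume_matrices(list(volume), model$spec)[[1]]
  norm <- model$norm
  f <- net_forward(model$layers, (x - norm["mu"]) / norm["sd"], want_caches = TRUE)
  if (length(f$out) != 1L) {
    stop("model output is not scalar: cannot form a sensitivity map", call. = FALSE)
  }
  g <- net_backward(model$layers, f$caches, 1)$dinput / norm["sd"]
  if (is.array(volume) && length(dim(volume)) == 3L) {
    array(g[, 1], dim = dim(volume))
  } else {
    g
  }
}

#' SmoothGrad sensitivity map
#'
#' Vanilla gradient maps are noisy; SmoothGrad perturbs the input with
#' i.i.d. Gaussian voxel noise and averages the gradient maps over
#' `n_samples` draws. The noise SD is `noise_level * (max(volume) -
#' min(volume))`, the standard per-input dynamic-range scaling. With
#' `noise_level = 0` and `n_samples = 1` the result equals the vanilla
#' gradient.
#'
#' @param model a finalized `age_model`.
#' @param volume 3D array (or voxel-by-channel matrix).
#' @param cfg a [saliency_config()].
#' @return a sensitivity map with the same shape as the input.
#' @export
smoothgrad <- function(model, volume, cfg) {
  stopifnot(inherits(model, "age_model"), inherits(cfg, "saliency_config"))
  x <- as_volume_matrices(list(volume), model$spec)[[1]]
  rng <- max(x) - min(x)
  sigma <- cfg$noise_level * rng
  if (cfg$noise_level > 0 && sigma == 0) {
    warning("constant input volume: SmoothGrad noise SD is 0")
  }
  acc <- NULL
  with_seed(derive_seed(cfg$seed, "smoothgrad"), {
    for (s in seq_len(cfg$n_samples)) {
      xs <- if (sigma > 0) x + stats::rnorm(length(x), 0, sigma) else x
      g <- vanilla_gradient(model, xs)
      g <- as_volume_matrices(list(g), model$spec)[[1]]
      if (cfg$reduce == "absolute") g <- abs(g)
      acc <- if (is.null(acc)) g else acc + g
    }
  })
  g <- acc / cfg$n_samples
  if (is.array(volume) && length(dim(volume)) == 3L) {
    array(g[, 1], dim = dim(volume))
  } else {
    g
  }
}

#' Calibrate the SmoothGrad noise level by the age-correlation criterion
#'
#' For each noise level on the grid, computes SmoothGrad maps for every
#' calibration subject, parcellates them to region means, and computes the
#' Pearson correlation between age and the region sensitivity for each
#' region. The aggregate score of a level is the mean over regions of
#' `|r|`; the chosen level maximizes the score (ties go to the smallest
#' level). The default grid runs from 0% to 50% of the dynamic range in
#' steps of 2% (26 levels).
#'
#' @param model a finalized `age_model`.
#' @param volumes list of calibration volumes (>= 3 subjects).
#' @param ages their chronological ages (variance > 0).
#' @param atlas a [build_atlas()] result on the same grid.
#' @param grid increasing vector of noise levels in `[0, 0.5]`.
#' @param n_samples SmoothGrad samples per map during calibration.
#' @param seed master seed (per-level, per-subject streams are derived).
#' @param reduce gradient reduction mode, as in [saliency_config()].
#' @return an object of class `noise_calibration`: `table` (level, roi, r),
#'   `summary` (level, score), `chosen_level`, `chosen_score`.
#' @export
calibrate_noise <- function(model, volumes, ages, atlas,
                            grid = seq(0, 0.5, by = 0.02),
                            n_samples = 25L, seed = 1L,
                            reduce = "signed") {
  if (length(volumes) < 3L) stop("need at least 3 calibration subjects", call. = FALSE)
  if (length(volumes) != length(ages)) stop("length mismatch", call. = FALSE)
  if (stats::var(ages) <= 0) stop("age variance is zero", call. = FALSE)
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("`grid` must be strictly increasing", call. = FALSE)
  }
  K <- nrow(atlas$region_table)
  roi_names <- atlas$region_table$name
  tab <- list()
  summ <- data.frame(level = numeric(0), score = numeric(0))
  for (li in seq_along(grid)) {
    lev <- grid[li]
    rois <- matrix(NA_real_, length(volumes), K)
    for (s in seq_along(volumes)) {
      cfg <- saliency_config(noise_level = lev, n_samples = n_samples,
                             seed = derive_seed(seed, "calib", li, s),
                             reduce = reduce)
      m <- smoothgrad(model, volumes[[s]], cfg)
      rois[s, ] <- parcellate(array(as_volume_matrices(list(m), model$spec)[[1]][, 1],
                                    dim = dim(atlas$labels)), atlas)
    }
    r <- vapply(seq_len(K), function(k) {
      v <- rois[, k]
      if (stats::sd(v) == 0) 0 else stats::cor(ages, v)
    }, numeric(1))
    tab[[li]] <- data.frame(level = lev, roi = roi_names, r = r,
                            stringsAsFactors = FALSE)
    summ <- rbind(summ, data.frame(level = lev, score = mean(abs(r))))
  }
  best <- which.max(summ$score)  # first maximum: smallest level on ties
  structure(list(table = do.call(rbind, tab), summary = summ,
                 chosen_level = summ$level[best],
                 chosen_score = summ$score[best]),
            class = "noise_calibration")
}
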