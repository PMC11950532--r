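#' Default experiment configuration
#'
#' One nested list drives the whole experiment. The `desk` scale is the
#' package's reference study: a 32^3 grid with 24 regions of which 6 carry
#' the patient offset, 300 subjects split across five disjoint cohort roles
#' (autoencoder pretraining, regressor training, checkpoint selection, bias
#' correction -- also the noise-calibration set -- and the clinical
#' evaluation cohort), and two modality-like channels, each with its own
#' model. The `tiny` scale is a smoke-test configuration.
#'
#' @param scale `"desk"` or `"tiny"`.
#' @param seed master seed recorded in the config.
#' @return a nested configuration list.
#' @export
default_experiment_config <- function(scale = c("desk", "tiny"), seed = 1L) {
  scale <- match.arg(scale)
  if (scale == "desk") {
    list(
      seed = as.integer(seed),
      phantom = list(
        grid = c(32L, 32L, 32L), n_regions = 24L,
        disease_set = c(3L, 7L, 11L, 14L, 18L, 22L),
        disease_offset = -15, subject_sd = 2, voxel_sd = 2,
        n_channels = 2L, channel_mixing = c(1, 0.7),
        age_min = 18, age_max = 88,
        cohorts = list(pretrain = 80L, train = 110L, select = 30L,
                       correct = 20L, clinical = 60L),
        clinical_fraction = 0.5
      ),
      model = list(
        encoder_widths = c(8L, 16L, 32L), latent_dim = 64L, head_widths = 32L,
        cae = list(epochs = 30L, batch_size = 16L, learning_rate = 1e-3,
                   selection_window = 20L),
        regressor = list(epochs = 60L, batch_size = 16L, learning_rate = 3e-3,
                         selection_window = 30L)
      ),
      saliency = list(grid = seq(0, 0.5, by = 0.02), n_samples = 25L,
                      calib_n_samples = 25L, reduce = "signed"),
      stats = list(alpha = 0.05, brainage_covariates = c("age", "sex"),
                   roi_covariates = "age")
    )
  } else {
    list(
      seed = as.integer(seed),
      phantom = list(
        grid = c(16L, 16L, 16L), n_regions = 6L,
        disease_set = c(2L, 5L),
        disease_offset = -15, subject_sd = 2, voxel_sd = 2,
        n_channels = 1L, channel_mixing = 1,
        age_min = 18, age_max = 88,
        cohorts = list(pretrain = 12L, train = 14L, select = 6L,
                       correct = 6L, clinical = 12L),
        clinical_fraction = 0.5
      ),
      model = list(
        encoder_widths = c(4L, 8L), latent_dim = 16L, head_widths = 8L,
        cae = list(epochs = 4L, batch_size = 8L, learning_rate = 1e-3,
                   selection_window = 3L),
        regressor = list(epochs = 12L, batch_size = 8L, learning_rate = 3e-3,
                         selection_window = 8L)
      ),
      saliency = list(grid = c(0, 0.1), n_samples = 3L,
                      calib_n_samples = 2L, reduce = "signed"),
      stats = list(alpha = 0.05, brainage_covariates = c("age", "sex"),
                   roi_covariates = "age")
    )
  }
}

#' Reference single-modality experiment configuration
#'
#' The desk-scale study restricted to one modality channel (mixing weight
#' 1). This is the configuration whose end-to-end behaviour the package
#' treats as its reference experiment: one significance set per map type
#' and factor, no cross-modality aggregation.
#'
#' @param seed master seed.
#' @return a configuration list.
#' @export
reference_experiment_config <- function(seed = 1L) {
  cfg <- default_experiment_config("desk", seed = seed)
  cfg$phantom$n_channels <- 1L
  cfg$phantom$channel_mixing <- 1
  cfg
}

#' Validate an experiment configuration
#'
#' Returns violations as data (a character vector), not exceptions, so a
#' config can be checked wholesale.
#'
#' @param config a configuration list shaped like
#'   [default_experiment_config()].
#' @return character vector of violations; empty if the config is valid.
#' @export
validate_config <- function(config) {
  v <- character(0)
  need <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  ph <- config$phantom
  need(!is.null(ph), "missing `phantom` section")
  if (!is.null(ph)) {
    need(length(ph$grid) == 3 && all(ph$grid >= 8),
         "phantom$grid must be an integer triple >= 8")
    need(ph$n_regions >= 1, "phantom$n_regions must be >= 1")
    need(all(ph$disease_set >= 1 & ph$disease_set <= ph$n_regions),
         "phantom$disease_set must be a subset of 1..n_regions")
    need(length(ph$channel_mixing) == ph$n_channels,
         "phantom$channel_mixing length must equal n_channels")
    need(ph$age_min < ph$age_max, "phantom age range is empty")
    roles <- c("pretrain", "train", "select", "correct", "clinical")
    need(all(roles %in% names(ph$cohorts)),
         "phantom$cohorts must name pretrain/train/select/correct/clinical")
    need(!anyDuplicated(names(ph$cohorts)),
         "cohort roles must be unique (role-prefixed ids keep them disjoint)")
    f <- 2^length(config$model$encoder_widths)
    need(all(ph$grid %% f == 0),
         sprintf("phantom$grid must be divisible by %d for %d encoder blocks",
                 f, length(config$model$encoder_widths)))
  }
  for (part in c("cae", "regressor")) {
    tc <- config$model[[part]]
    if (!is.null(tc)) {
      need(tc$selection_window <= tc$epochs,
           sprintf("model$%s: selection_window (%d) exceeds epochs (%d)",
                   part, tc$selection_window, tc$epochs))
    }
  }
  sal <- config$saliency
  if (!is.null(sal)) {
    need(all(sal$grid >= 0 & sal$grid <= 0.5),
         "saliency$grid levels must lie in [0, 0.5]")
    need(!is.unsorted(sal$grid, strictly = TRUE),
         "saliency$grid must be strictly increasing")
  }
  v
}

write_csv_file <- function(x, path) {
  utils::write.csv(format(x, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

run_stage <- function(name, verbose, code) {
  if (verbose) message(sprintf("[agemap] stage: %s", name))
  tryCatch(code, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full phantom experiment
#'
#' Executes the whole analysis from one configuration: simulate the phantom
#' dataset; per channel, train the autoencoder on the pretraining cohort,
#' transfer and freeze its encoder, train the regression head on the
#' training cohort with checkpoint selection on the selection cohort, fit
#' the BrainAGE bias correction on the correction cohort, and predict the
#' clinical cohort; run the BrainAGE ANCOVA on corrected and uncorrected
#' gaps; calibrate the SmoothGrad noise level on the correction cohort;
#' compute sensitivity maps of the clinical cohort (from the uncorrected
#' prediction path); run the stage-1 per-region ANCOVAs on morphometric and
#' sensitivity ROI matrices; and compute the stage-2 concordance. All
#' tables are written as CSV, volumes as NIfTI-1, plus a JSON run manifest.
#'
#' @param config a configuration list (see [default_experiment_config()]);
#'   validated before anything runs.
#' @param out_dir output directory.
#' @param seed master seed (defaults to `config$seed`).
#' @param verbose print stage progress.
#' @return invisibly, a list with all in-memory results (`predictions`,
#'   `brainage_ancova`, `calibration`, `roi_stats`, `concordance`,
#'   `manifest`, ...).
#' @export
run_full_experiment <- function(config, out_dir, seed = config$seed,
                                verbose = TRUE) {
  viol <- validate_config(config)
  if (length(viol)) {
    stop("invalid config:\n  - ", paste(viol, collapse = "\n  - "), call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ph <- config$phantom
  md <- config$model
  sal <- config$saliency
  st <- config$stats

  # --- simulate ------------------------------------------------------------
  sim <- run_stage("simulate", verbose, {
    atl_spec <- atlas_spec(ph$grid, ph$n_regions, seed = derive_seed(seed, "atlas"))
    atlas <- build_atlas(atl_spec)
    effects <- effect_model(
      n_regions = ph$n_regions, age_ref = ph$age_min,
      disease_set = ph$disease_set, disease_offset = ph$disease_offset,
      subject_sd = ph$subject_sd, voxel_sd = ph$voxel_sd,
      n_channels = ph$n_channels, channel_mixing = ph$channel_mixing,
      seed = derive_seed(seed, "effects"))
    cohorts <- list()
    volumes <- list()
    for (role in names(ph$cohorts)) {
      frac <- if (role == "clinical") ph$clinical_fraction else 0
      co <- sample_cohort(ph$cohorts[[role]], frac, ph$age_min, ph$age_max,
                          seed = derive_seed(seed, "cohort", role),
                          id_prefix = role)
      cohorts[[role]] <- co
      volumes[[role]] <- render_cohort(co, atlas, effects,
                                       seed = derive_seed(seed, "render"))
    }
    manifest_gt <- ground_truth_manifest(effects, do.call(c, unname(volumes)),
                                         atl_spec, seed)
    all_cohort <- do.call(rbind, unname(cohorts))
    write_dataset(all_cohort, do.call(c, unname(volumes)), atlas, manifest_gt,
                  file.path(out_dir, "dataset"))
    list(atlas = atlas, effects = effects, cohorts = cohorts,
         volumes = volumes, manifest_gt = manifest_gt)
  })
  atlas <- sim$atlas
  cohorts <- sim$cohorts

  chan_vols <- function(role, chan) {
    out <- lapply(sim$volumes[[role]], function(v) v$channels[[chan]])
    names(out) <- names(sim$volumes[[role]])
    out
  }

  spec <- net_spec(ph$grid, 1L, md$encoder_widths, md$latent_dim, md$head_widths)
  n_chan <- ph$n_channels
  predictions <- list()
  brain_ancova <- list()
  calib_rows <- list()
  roi_tabs <- list(morph = list(), sens = list())
  chosen_epochs <- list()
  noise_levels <- numeric(n_chan)

  for (chan in seq_len(n_chan)) {
    tag <- sprintf("chan%d", chan)

    cae <- run_stage(paste0("train-cae/", tag), verbose, {
      vols <- chan_vols("pretrain", chan)
      n_val <- max(1L, round(0.1 * length(vols)))
      val_idx <- seq_len(n_val)   # pretraining cohort is i.i.d.; head rows as val
      cfg <- train_config(md$cae$epochs, md$cae$batch_size,
                          md$cae$learning_rate,
                          selection_window = md$cae$selection_window,
                          seed = derive_seed(seed, "cae", chan))
      train_cae(vols[-val_idx], vols[val_idx], spec, cfg)
    })

    fit <- run_stage(paste0("train-regressor/", tag), verbose, {
      model <- transfer_encoder(cae, spec,
                                seed = derive_seed(seed, "transfer", chan))
      cfg <- train_config(md$regressor$epochs, md$regressor$batch_size,
                          md$regressor$learning_rate,
                          selection_window = md$regressor$selection_window,
                          seed = derive_seed(seed, "regressor", chan))
      train_regressor(model,
                      chan_vols("train", chan), cohorts$train$age,
                      chan_vols("select", chan), cohorts$select$age, cfg)
    })
    model <- fit$model
    chosen_epochs[[tag]] <- list(cae = select_best_checkpoint(cae$store)$epoch,
                                 regressor = fit$selected$epoch)

    bias <- run_stage(paste0("bias-correction/", tag), verbose, {
      pred_c <- predict_age(model, chan_vols("correct", chan))
      fit_bias_correction(compute_brainage(pred_c, cohorts$correct$age),
                          cohorts$correct$age, fit_set_id = "correct")
    })

    ptab <- run_stage(paste0("predict-clinical/", tag), verbose, {
      pred <- predict_age(model, chan_vols("clinical", chan))
      tab <- prediction_table(cohorts$clinical$participant_id,
                              cohorts$clinical$age, pred,
                              cohorts$clinical$group, cohorts$clinical$sex)
      tab <- apply_bias_correction(tab, bias)
      tab$modality <- tag
      tab
    })
    predictions[[tag]] <- ptab

    brain_ancova[[tag]] <- run_stage(paste0("brainage-ancova/", tag), verbose, {
      do.call(rbind, lapply(c("corrected", "raw"), function(g) {
        a <- ancova_brainage(ptab, gap = g, covariates = st$brainage_covariates)
        cbind(modality = tag, correction = g, a)
      }))
    })

    calib <- run_stage(paste0("calibrate-noise/", tag), verbose, {
      calibrate_noise(model, chan_vols("correct", chan), cohorts$correct$age,
                      atlas, grid = sal$grid, n_samples = sal$calib_n_samples,
                      seed = derive_seed(seed, "calib", chan),
                      reduce = sal$reduce)
    })
    noise_levels[chan] <- calib$chosen_level
    calib_rows[[tag]] <- cbind(modality = tag, calib$summary,
                               chosen = calib$summary$level == calib$chosen_level)

    sens_vols <- run_stage(paste0("sensitivity-maps/", tag), verbose, {
      vols <- chan_vols("clinical", chan)
      maps <- lapply(seq_along(vols), function(i) {
        cfg <- saliency_config(calib$chosen_level, sal$n_samples,
                               seed = derive_seed(seed, "maps", chan, i),
                               reduce = sal$reduce)
        m <- smoothgrad(model, vols[[i]], cfg)
        write_volume(m, file.path(out_dir, sprintf("%s_%s_saliency.nii.gz",
                                                   names(vols)[i], tag)))
        m
      })
      names(maps) <- names(vols)
      maps
    })

    rt <- run_stage(paste0("roi-ancova/", tag), verbose, {
      morph_m <- roi_matrix(chan_vols("clinical", chan), atlas,
                            "morphometric", tag)
      sens_m <- roi_matrix(sens_vols, atlas, "sensitivity", tag)
      list(morph = roi_ancova(morph_m, cohorts$clinical,
                              covariates = st$roi_covariates,
                              alpha = st$alpha),
           sens = roi_ancova(sens_m, cohorts$clinical,
                             covariates = st$roi_covariates,
                             alpha = st$alpha),
           morph_m = morph_m, sens_m = sens_m)
    })
    roi_tabs$morph[[tag]] <- rt$morph
    roi_tabs$sens[[tag]] <- rt$sens
    roi_tabs$morph_m[[tag]] <- rt$morph_m
    roi_tabs$sens_m[[tag]] <- rt$sens_m
  }

  morph_all <- do.call(rbind, roi_tabs$morph)
  sens_all <- do.call(rbind, roi_tabs$sens)
  conc <- run_stage("concordance", verbose, {
    concordance_report(morph_all, sens_all, factors = c("age", "condition"))
  })

  # --- outputs -------------------------------------------------------------
  run_stage("write-outputs", verbose, {
    write_csv_file(do.call(rbind, predictions),
                   file.path(out_dir, "predictions.csv"))
    write_csv_file(do.call(rbind, brain_ancova),
                   file.path(out_dir, "brainage_ancova.csv"))
    write_csv_file(do.call(rbind, calib_rows),
                   file.path(out_dir, "noise_calibration.csv"))
    for (f in c("age", "condition")) {
      write_csv_file(morph_all[morph_all$factor == f, ],
                     file.path(out_dir, sprintf("roi_stats_morph_%s.csv", f)))
      write_csv_file(sens_all[sens_all$factor == f, ],
                     file.path(out_dir, sprintf("roi_stats_sens_%s.csv", f)))
    }
    write_csv_file(conc, file.path(out_dir, "concordance.csv"))
  })

  manifest <- list(
    seed = as.integer(seed),
    config = config,
    chosen_epochs = chosen_epochs,
    noise_levels = as.list(stats::setNames(noise_levels,
                                           sprintf("chan%d", seq_len(n_chan)))),
    outputs = c("dataset/participants.tsv", "dataset/atlas.nii.gz",
                "predictions.csv", "brainage_ancova.csv",
                "noise_calibration.csv", "concordance.csv"),
    package_version = as.character(utils::packageVersion("agemap"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(
    atlas = atlas, effects = sim$effects, cohorts = cohorts,
    predictions = do.call(rbind, predictions),
    brainage_ancova = do.call(rbind, brain_ancova),
    calibration = do.call(rbind, calib_rows),
    noise_levels = noise_levels,
    roi_stats = list(morph = morph_all, sens = sens_all),
    roi_matrices = list(morph = roi_tabs$morph_m, sens = roi_tabs$sens_m),
    concordance = conc,
    manifest = manifest,
    out_dir = out_dir
  ))
}
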