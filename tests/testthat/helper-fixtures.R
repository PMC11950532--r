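# Shared fixtures, built in code. The trained small model is expensive
# enough to cache once per test run.

.fixture_env <- new.env(parent = emptyenv())

# A 16^3 single-channel phantom with a trained age model: used by the
# saliency, model-contract and gradient-oracle tests.
small_setup <- function() {
  if (!is.null(.fixture_env$small)) return(.fixture_env$small)
  seed <- 42L
  atlas <- build_atlas(atlas_spec(c(16L, 16L, 16L), 6L, seed = 11L))
  effects <- effect_model(6L, age_ref = 20, disease_set = c(2L, 5L),
                          subject_sd = 1, voxel_sd = 1,
                          n_channels = 1L, channel_mixing = 1, seed = 5L)
  train_co <- sample_cohort(40, 0, 20, 80, seed = seed, id_prefix = "train")
  val_co <- sample_cohort(10, 0, 20, 80, seed = seed, id_prefix = "val")
  chan1 <- function(co) {
    vols <- render_cohort(co, atlas, effects, seed = seed)
    lapply(vols, function(v) v$channels[[1]])
  }
  train_v <- chan1(train_co)
  val_v <- chan1(val_co)
  spec <- net_spec(c(16L, 16L, 16L), 1L, c(4L, 8L), latent_dim = 16L,
                   head_widths = 8L)
  cae <- train_cae(train_v[1:12], val_v[1:3], spec,
                   train_config(3, batch_size = 8, selection_window = 2,
                                seed = seed))
  model <- transfer_encoder(cae, spec, seed = seed)
  fit <- train_regressor(model, train_v, train_co$age, val_v, val_co$age,
                         train_config(40, batch_size = 8,
                                      learning_rate = 3e-3,
                                      selection_window = 20, seed = seed))
  .fixture_env$small <- list(
    atlas = atlas, effects = effects, spec = spec, cae = cae,
    model = fit$model, fit = fit,
    train_co = train_co, val_co = val_co,
    train_v = train_v, val_v = val_v
  )
  .fixture_env$small
}

# A hand-built linear scalar model w . x + b wrapped as an age model, for
# closed-form saliency checks.
make_linear_model <- function(w, dims, bias = 0) {
  spec <- structure(list(input_dim = as.integer(dims), n_channels = 1L),
                    class = "net_spec")
  dense <- agemap:::layer_dense(length(w), 1L)
  dense$W <- matrix(w, ncol = 1)
  dense$b <- bias
  structure(list(
    layers = list(agemap:::layer_flatten(), dense),
    n_encoder = 0L, trainable = c(TRUE, TRUE),
    norm = c(mu = 0, sd = 1), spec = spec,
    age_center = 0, finalized = TRUE
  ), class = "age_model")
}

# Random significance-set pair over a common universe, for concordance fuzz.
random_set_pair <- function(universe_size = 30L) {
  u <- sprintf("r%02d", seq_len(universe_size))
  a <- u[stats::runif(universe_size) < stats::runif(1)]
  b <- u[stats::runif(universe_size) < stats::runif(1)]
  list(a = significance_set(a, u), b = significance_set(b, u), u = u)
}
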