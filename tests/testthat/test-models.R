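test_that("checkpoint selection obeys the window, the minimum and the tie rule", {
  mk_store <- function(scores, window) {
    st <- agemap:::new_checkpoint_store(window)
    for (e in seq_along(scores)) {
      st <- agemap:::store_push(st, e, scores[e], list(epoch_tag = e))
    }
    st
  }
  # monotone decrease: last epoch wins
  expect_equal(select_best_checkpoint(mk_store(c(5, 4, 3, 2, 1), 3))$epoch, 5)
  # the global minimum outside the window is ignored
  expect_equal(select_best_checkpoint(mk_store(c(1, 9, 9, 9, 9), 3))$epoch, 3)
  # ties go to the earliest epoch in the window
  expect_equal(select_best_checkpoint(mk_store(c(4, 2, 2, 5), 4))$epoch, 2)
  # the selected parameters are the matching snapshot
  sel <- select_best_checkpoint(mk_store(c(4, 2, 2, 5), 4))
  expect_equal(sel$params$epoch_tag, 2)
  expect_error(select_best_checkpoint(agemap:::new_checkpoint_store(3)),
               "non-empty")
})

test_that("window invariant holds over fuzzed score sequences", {
  for (i in 1:50) {
    scores <- with_seed(i, round(runif(sample(3:40, 1)), 3))
    w <- sample(seq_along(scores), 1)
    st <- agemap:::new_checkpoint_store(w)
    for (e in seq_along(scores)) st <- agemap:::store_push(st, e, scores[e], list())
    sel <- select_best_checkpoint(st)
    expect_gte(sel$epoch, length(scores) - w + 1)
    expect_lte(sel$epoch, length(scores))
    expect_equal(sel$score, min(scores[(length(scores) - w + 1):length(scores)]))
  }
})

test_that("autoencoder training reduces validation MSE and is deterministic", {
  spec <- net_spec(c(16, 16, 16), 1, c(4, 8), latent_dim = 8, head_widths = 4)
  # constant-zero volumes: a trivially learnable reconstruction target
  zeros <- lapply(1:10, function(i) array(0, dim = c(16, 16, 16)))
  fitz <- train_cae(zeros[1:8], zeros[9:10], spec,
                    train_config(5, batch_size = 4, selection_window = 3, seed = 2))
  expect_lte(fitz$log$val_score[5], fitz$log$val_score[1])

  vols <- with_seed(1, lapply(1:10, function(i) array(rnorm(4096, 0, 0.1), dim = c(16, 16, 16))))
  cfg <- train_config(5, batch_size = 4, selection_window = 3, seed = 2)
  fit <- train_cae(vols[1:8], vols[9:10], spec, cfg)
  expect_equal(nrow(fit$log), 5)

  fit2 <- train_cae(vols[1:8], vols[9:10], spec, cfg)
  expect_identical(fit$log, fit2$log)

  # a validation set of one volume still yields one score per epoch
  fit3 <- train_cae(vols[1:4], vols[5], spec,
                    train_config(2, batch_size = 4, selection_window = 2, seed = 2))
  expect_equal(nrow(fit3$log), 2)
})

test_that("a shape-mismatched volume is rejected with its name", {
  spec <- net_spec(c(16, 16, 16), 1, c(4, 8), latent_dim = 8, head_widths = 4)
  vols <- list(ok = array(0, c(16, 16, 16)), bad = array(0, c(8, 8, 8)))
  expect_error(
    train_cae(vols, vols[1], spec, train_config(1, selection_window = 1)),
    "bad")
})

test_that("the transferred encoder is frozen through head training", {
  s <- small_setup()
  enc_before <- agemap:::encoder_params(
    transfer_encoder(s$cae, s$spec, seed = 42L))
  enc_after <- agemap:::encoder_params(s$model)
  expect_identical(enc_before, enc_after)

  # encoder comes from the selected autoencoder checkpoint
  sel <- select_best_checkpoint(s$cae$store)
  expect_identical(enc_after[[1]]$W, sel$params[[1]]$W)

  # two head seeds: identical encoder, different head initialization
  m1 <- transfer_encoder(s$cae, s$spec, seed = 1)
  m2 <- transfer_encoder(s$cae, s$spec, seed = 2)
  expect_identical(agemap:::encoder_params(m1), agemap:::encoder_params(m2))
  h1 <- m1$layers[[length(m1$layers)]]$W
  h2 <- m2$layers[[length(m2$layers)]]$W
  expect_false(identical(h1, h2))

  # only head layers are trainable
  expect_identical(which(!m1$trainable), seq_len(m1$n_encoder))
})

test_that("the regressor learns age where there is signal and not where there is none", {
  s <- small_setup()
  baseline <- mean(abs(s$val_co$age - mean(s$train_co$age)))
  expect_lt(s$fit$selected$score, baseline)

  # negative control: shuffled ages destroy the signal
  shuf <- with_seed(99, sample(s$train_co$age))
  m0 <- transfer_encoder(s$cae, s$spec, seed = 42L)
  fit0 <- train_regressor(m0, s$train_v, shuf, s$val_v, s$val_co$age,
                          train_config(15, batch_size = 8, learning_rate = 3e-3,
                                       selection_window = 10, seed = 42L))
  expect_gt(fit0$selected$score, 0.6 * baseline)

  # determinism: identical config and seed select the identical checkpoint
  m1 <- transfer_encoder(s$cae, s$spec, seed = 42L)
  cfg <- train_config(6, batch_size = 8, learning_rate = 3e-3,
                      selection_window = 4, seed = 7)
  f1 <- train_regressor(m1, s$train_v[1:10], s$train_co$age[1:10],
                        s$val_v[1:3], s$val_co$age[1:3], cfg)
  m2 <- transfer_encoder(s$cae, s$spec, seed = 42L)
  f2 <- train_regressor(m2, s$train_v[1:10], s$train_co$age[1:10],
                        s$val_v[1:3], s$val_co$age[1:3], cfg)
  expect_identical(f1$selected, f2$selected)
  expect_identical(predict_age(f1$model, s$val_v[1:2]),
                   predict_age(f2$model, s$val_v[1:2]))
})

test_that("prediction is a pure per-volume function with finite output", {
  s <- small_setup()
  v <- s$val_v[[1]]
  batch <- list(v, s$val_v[[2]], v, array(0, dim = dim(v)))
  p <- predict_age(s$model, batch)
  expect_true(all(is.finite(p)))
  expect_identical(p[1], p[3])                      # duplicates agree
  expect_equal(predict_age(s$model, list(v))[1], p[1], tolerance = 1e-5)
  expect_error(predict_age(s$model, list(array(0, c(4, 4, 4)))), "shape")
})
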