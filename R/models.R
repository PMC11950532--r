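#' Network specification
#'
#' Parametric architecture for the autoencoder and the age regressor: an
#' encoder of stride-2 3x3x3 convolution blocks with ReLU activations
#' (`encoder_widths` feature maps per block) followed by a dense projection
#' to `latent_dim`; a mirrored transposed-convolution decoder for the
#' autoencoder; and a dense regression head (`head_widths`, then one scalar
#' output in years) for the age model.
#'
#' @param input_dim integer triple, voxels per axis (each must be divisible
#'   by `2^length(encoder_widths)`).
#' @param n_channels input channels per volume (one per modality model).
#' @param encoder_widths feature maps per encoder block.
#' @param latent_dim latent dimension.
#' @param head_widths hidden layer sizes of the regression head.
#' @return an object of class `net_spec`.
#' @export
net_spec <- function(input_dim = c(32L, 32L, 32L), n_channels = 1L,
                     encoder_widths = c(8L, 16L, 32L), latent_dim = 64L,
                     head_widths = 32L) {
  input_dim <- as.integer(input_dim)
  encoder_widths <- as.integer(encoder_widths)
  stopifnot(length(input_dim) == 3L, length(encoder_widths) >= 1L,
            all(encoder_widths >= 1L), latent_dim >= 1L,
            all(as.integer(head_widths) >= 1L))
  f <- 2L^length(encoder_widths)
  if (any(input_dim %% f != 0L)) {
    stop(sprintf("`input_dim` must be divisible by %d for %d encoder blocks",
                 f, length(encoder_widths)), call. = FALSE)
  }
  structure(list(input_dim = input_dim, n_channels = as.integer(n_channels),
                 encoder_widths = encoder_widths,
                 latent_dim = as.integer(latent_dim),
                 head_widths = as.integer(head_widths)),
            class = "net_spec")
}

#' Training configuration
#'
#' @param epochs number of training epochs (>= 1).
#' @param batch_size minibatch size.
#' @param learning_rate Adam learning rate.
#' @param loss loss function; only `"mse"` is supported.
#' @param selection_window number of final epochs eligible for checkpoint
#'   selection (must be `<= epochs`); default 30.
#' @param seed integer seed controlling initialization and data order.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs, batch_size = 16L, learning_rate = 1e-3,
                         loss = "mse", selection_window = 30L, seed = 1L) {
  epochs <- as.integer(epochs)
  selection_window <- as.integer(selection_window)
  if (epochs < 1L) stop("`epochs` must be >= 1", call. = FALSE)
  if (selection_window > epochs) {
    stop("`selection_window` must be <= `epochs`", call. = FALSE)
  }
  loss <- match.arg(loss, "mse")
  structure(list(epochs = epochs, batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, loss = loss,
                 selection_window = selection_window, seed = as.integer(seed)),
            class = "train_config")
}

# Convert a list of 3D arrays (or matrices) to (nvox x n_channels) matrices,
# validating shapes against the spec. Names are kept for error messages.
as_volume_matrices <- function(volumes, spec) {
  nvox <- prod(spec$input_dim)
  nm <- names(volumes)
  lapply(seq_along(volumes), function(i) {
    v <- volumes[[i]]
    if (is.array(v) && length(dim(v)) == 3L) {
      if (!all(dim(v) == spec$input_dim)) {
        stop(sprintf("volume %s has shape %s, expected %s",
                     if (!is.null(nm) && nzchar(nm[i])) nm[i] else i,
                     paste(dim(v), collapse = "x"),
                     paste(spec$input_dim, collapse = "x")), call. = FALSE)
      }
      matrix(as.vector(v), nvox, 1L)
    } else {
      v <- as.matrix(v)
      if (nrow(v) != nvox || ncol(v) != spec$n_channels) {
        stop(sprintf("volume %s has %d voxels x %d channels, expected %d x %d",
                     if (!is.null(nm) && nzchar(nm[i])) nm[i] else i,
                     nrow(v), ncol(v), nvox, spec$n_channels), call. = FALSE)
      }
      v
    }
  })
}

# Encoder layer stack shared by the autoencoder and the regressor.
build_encoder_layers <- function(spec) {
  dims <- spec$input_dim
  cin <- spec$n_channels
  layers <- list()
  for (w in spec$encoder_widths) {
    layers <- c(layers, list(layer_conv(cin, w, dims, 2L), layer_relu()))
    dims <- (dims - 1L) %/% 2L + 1L
    cin <- w
  }
  feat <- prod(dims) * cin
  layers <- c(layers, list(layer_flatten(),
                           layer_dense(feat, spec$latent_dim),
                           layer_relu()))
  attr(layers, "bottleneck_dims") <- dims
  attr(layers, "bottleneck_ch") <- cin
  layers
}

build_cae_layers <- function(spec) {
  enc <- build_encoder_layers(spec)
  dims <- attr(enc, "bottleneck_dims")
  ch <- attr(enc, "bottleneck_ch")
  n_enc <- length(enc)
  widths <- rev(spec$encoder_widths)
  dec <- list(layer_dense(spec$latent_dim, prod(dims) * ch), layer_relu(),
              layer_unflatten(prod(dims), ch))
  cur <- dims
  for (i in seq_along(widths)) {
    cout <- if (i < length(widths)) widths[i + 1L] else spec$n_channels
    cur <- cur * 2L
    dec <- c(dec, list(layer_convT(widths[i], cout, cur)))
    if (i < length(widths)) dec <- c(dec, list(layer_relu()))
  }
  layers <- c(enc, dec)
  attr(layers, "n_encoder") <- n_enc
  layers
}

build_regressor_layers <- function(spec, encoder_layers = NULL) {
  enc <- if (is.null(encoder_layers)) build_encoder_layers(spec) else encoder_layers
  n_enc <- length(enc)
  # fixed latent standardization (identity until train_regressor sets it
  # from the training-set latent statistics), then the dense head
  head <- list(layer_affine(numeric(spec$latent_dim),
                            rep(1, spec$latent_dim)))
  nin <- spec$latent_dim
  for (w in spec$head_widths) {
    head <- c(head, list(layer_dense(nin, w), layer_relu()))
    nin <- w
  }
  head <- c(head, list(layer_dense(nin, 1L)))
  layers <- c(enc, head)
  attr(layers, "n_encoder") <- n_enc
  layers
}

new_checkpoint_store <- function(window) {
  structure(list(epochs = integer(0), scores = numeric(0),
                 snapshots = list(), snapshot_epochs = integer(0),
                 window = as.integer(window)),
            class = "checkpoint_store")
}

# Ring buffer: only the last `window` snapshots are retained, but scores for
# every epoch are kept for the log.
store_push <- function(store, epoch, score, params) {
  store$epochs <- c(store$epochs, as.integer(epoch))
  store$scores <- c(store$scores, score)
  store$snapshots <- c(store$snapshots, list(params))
  store$snapshot_epochs <- c(store$snapshot_epochs, as.integer(epoch))
  if (length(store$snapshots) > store$window) {
    keep <- (length(store$snapshots) - store$window + 1L):length(store$snapshots)
    store$snapshots <- store$snapshots[keep]
    store$snapshot_epochs <- store$snapshot_epochs[keep]
  }
  store
}

#' Select the best checkpoint within the final training window
#'
#' Among the last `window` epochs, picks the snapshot with the lowest
#' validation score (reconstruction MSE for the autoencoder, MAE for the
#' regressor); ties go to the earliest epoch in the window.
#'
#' @param store a `checkpoint_store` produced by [train_cae()] or
#'   [train_regressor()].
#' @param window number of final epochs considered (default: the window the
#'   store was built with).
#' @param criterion selection criterion; only `"min_val_score"`.
#' @return a list with `params`, `epoch` and `score`.
#' @export
select_best_checkpoint <- function(store, window = store$window,
                                   criterion = "min_val_score") {
  if (!inherits(store, "checkpoint_store") || length(store$epochs) == 0L) {
    stop("`store` must be a non-empty checkpoint store", call. = FALSE)
  }
  criterion <- match.arg(criterion, "min_val_score")
  window <- min(as.integer(window), length(store$epochs))
  last <- store$epochs[length(store$epochs)]
  eligible <- store$snapshot_epochs >= last - window + 1L
  if (!any(eligible)) stop("no snapshots inside the selection window", call. = FALSE)
  idx <- which(eligible)
  sc <- store$scores[match(store$snapshot_epochs[idx], store$epochs)]
  best <- idx[which.min(sc)]   # which.min takes the first minimum: earliest epoch
  list(params = store$snapshots[[best]],
       epoch = store$snapshot_epochs[best],
       score = min(sc))
}

# Shared minibatch Adam loop. `loss_grad(out, target)` returns
# list(loss, dout); validation is scored by `val_score(out, target)`.
run_training <- function(layers, train_x, train_t, val_x, val_t, cfg,
                         trainable, loss_grad, val_score_fun,
                         forward_fun = NULL) {
  n <- length(train_x)
  if (n == 0L) stop("training set is empty", call. = FALSE)
  if (length(val_x) == 0L) stop("validation set is empty", call. = FALSE)
  state <- adam_init(net_params(layers))
  store <- new_checkpoint_store(cfg$selection_window)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_score = numeric(0))
  step <- 0L
  fwd <- if (is.null(forward_fun)) {
    function(l, x, caches) net_forward(l, x, want_caches = caches)
  } else {
    forward_fun
  }
  for (epoch in seq_len(cfg$epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, "order", epoch), sample.int(n))
    ep_loss <- 0
    for (start in seq(1L, n, by = cfg$batch_size)) {
      batch <- ord[start:min(start + cfg$batch_size - 1L, n)]
      acc <- NULL
      bloss <- 0
      for (i in batch) {
        f <- fwd(layers, train_x[[i]], TRUE)
        lg <- loss_grad(f$out, train_t[[i]])
        bloss <- bloss + lg$loss
        bk <- net_backward(layers, f$caches, lg$dout)
        if (is.null(acc)) {
          acc <- bk$grads
        } else {
          for (j in seq_along(acc)) {
            if (!is.null(acc[[j]])) {
              acc[[j]]$dW <- acc[[j]]$dW + bk$grads[[j]]$dW
              acc[[j]]$db <- acc[[j]]$db + bk$grads[[j]]$db
            }
          }
        }
      }
      nb <- length(batch)
      for (j in seq_along(acc)) {
        if (!is.null(acc[[j]])) {
          acc[[j]]$dW <- acc[[j]]$dW / nb
          acc[[j]]$db <- acc[[j]]$db / nb
        }
      }
      step <- step + 1L
      up <- adam_step(layers, acc, state, step, cfg$learning_rate,
                      trainable = trainable)
      layers <- up$layers
      state <- up$state
      ep_loss <- ep_loss + bloss
    }
    val <- mean(vapply(seq_along(val_x), function(i) {
      f <- fwd(layers, val_x[[i]], FALSE)
      val_score_fun(f$out, val_t[[i]])
    }, numeric(1)))
    store <- store_push(store, epoch, val, net_params(layers))
    log <- rbind(log, data.frame(epoch = epoch, train_loss = ep_loss / n,
                                 val_score = val))
  }
  list(layers = layers, store = store, log = log)
}

#' Train the 3D convolutional autoencoder
#'
#' Trains the encoder--decoder stack to reconstruct its input under MSE
#' loss with minibatch Adam. Inputs are standardized internally (one global
#' mean/SD pair computed from the training set, stored with the model).
#' One parameter snapshot and validation reconstruction MSE are recorded
#' per epoch; snapshots are retained for the final `selection_window`
#' epochs only.
#'
#' @param train_volumes,val_volumes lists of 3D arrays (or voxel-by-channel
#'   matrices) matching `spec$input_dim`.
#' @param spec a [net_spec()].
#' @param cfg a [train_config()].
#' @return a list of class `cae_fit`: `layers`, `store`
#'   (a `checkpoint_store`), `log`, `norm` (mean/sd), `spec`, `cfg`.
#' @export
train_cae <- function(train_volumes, val_volumes, spec, cfg) {
  stopifnot(inherits(spec, "net_spec"), inherits(cfg, "train_config"))
  tr <- as_volume_matrices(train_volumes, spec)
  va <- as_volume_matrices(val_volumes, spec)
  mu <- mean(vapply(tr, mean, numeric(1)))
  sd0 <- stats::sd(unlist(lapply(tr, as.vector)))
  if (!is.finite(sd0) || sd0 == 0) sd0 <- 1
  tr <- lapply(tr, function(x) (x - mu) / sd0)
  va <- lapply(va, function(x) (x - mu) / sd0)

  layers <- with_seed(derive_seed(cfg$seed, "cae-init"), build_cae_layers(spec))
  n_enc <- attr(layers, "n_encoder")
  nvox <- prod(spec$input_dim) * spec$n_channels

  res <- run_training(
    layers, tr, tr, va, va, cfg,
    trainable = rep(TRUE, length(layers)),
    loss_grad = function(out, target) {
      d <- out - target
      list(loss = mean(d^2), dout = 2 * d / nvox)
    },
    val_score_fun = function(out, target) mean((out - target)^2)
  )
  structure(list(layers = res$layers, store = res$store, log = res$log,
                 n_encoder = n_enc, norm = c(mu = mu, sd = sd0),
                 spec = spec, cfg = cfg),
            class = "cae_fit")
}

#' Transfer the autoencoder encoder into an age-regression network
#'
#' Copies the encoder parameters of a trained (and checkpoint-selected)
#' autoencoder into a fresh regression network and freezes them: during
#' [train_regressor()] only the randomly initialized dense head is updated.
#' The input normalization constants travel with the encoder so the frozen
#' features see the same input distribution they were trained on.
#'
#' @param cae a `cae_fit` from [train_cae()], or a list with elements
#'   `params` (a checkpoint snapshot), `n_encoder`, `norm`.
#' @param spec a [net_spec()]; the encoder geometry must match the
#'   autoencoder's.
#' @param seed seed for the head initialization (encoder weights are copied,
#'   not re-drawn).
#' @return a list of class `age_model` with frozen encoder, untrained head.
#' @export
transfer_encoder <- function(cae, spec, seed = 1L) {
  stopifnot(inherits(spec, "net_spec"))
  if (inherits(cae, "cae_fit")) {
    sel <- select_best_checkpoint(cae$store)
    src_params <- sel$params
    n_enc <- cae$n_encoder
    norm <- cae$norm
    src_epoch <- sel$epoch
  } else {
    src_params <- cae$params
    n_enc <- cae$n_encoder
    norm <- cae$norm
    src_epoch <- cae$epoch %||% NA_integer_
  }
  layers <- with_seed(derive_seed(seed, "head-init"),
                      build_regressor_layers(spec))
  if (attr(layers, "n_encoder") != n_enc) {
    stop("encoder layout mismatch: autoencoder encoder has a different depth",
         call. = FALSE)
  }
  for (i in seq_len(n_enc)) {
    if (is.null(src_params[[i]]) != is.null(layers[[i]]$W)) {
      stop(sprintf("encoder layout mismatch at layer %d", i), call. = FALSE)
    }
    if (!is.null(src_params[[i]])) {
      if (!all(dim(src_params[[i]]$W) == dim(layers[[i]]$W))) {
        stop(sprintf("encoder layout mismatch at layer %d: %s vs %s", i,
                     paste(dim(src_params[[i]]$W), collapse = "x"),
                     paste(dim(layers[[i]]$W), collapse = "x")), call. = FALSE)
      }
      layers[[i]]$W <- src_params[[i]]$W
      layers[[i]]$b <- src_params[[i]]$b
    }
  }
  trainable <- rep(TRUE, length(layers))
  trainable[seq_len(n_enc)] <- FALSE
  structure(list(layers = layers, n_encoder = n_enc, trainable = trainable,
                 norm = norm, spec = spec, age_center = 0,
                 source_epoch = src_epoch, finalized = FALSE),
            class = "age_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Encoder-only forward (frozen), producing latent vectors. Used to cache
# features once per training run.
encode_volume <- function(model, x) {
  net_forward(model$layers[seq_len(model$n_encoder)], x, want_caches = FALSE)$out
}

#' Train the age-regression head on frozen encoder features
#'
#' The encoder is frozen, so latent features are computed once per volume
#' and the dense head is trained on them with minibatch Adam under MSE loss
#' on age (internally centred at the training-set mean age). The features
#' are standardized by a fixed affine layer set from the training-set
#' latent statistics, so head optimization is invariant to the encoder's
#' output scale. Validation MAE (years) is recorded per epoch with windowed
#' snapshots of the head parameters.
#'
#' @param model an `age_model` from [transfer_encoder()].
#' @param train_volumes,train_ages training volumes and ages (years).
#' @param val_volumes,val_ages validation volumes and ages.
#' @param cfg a [train_config()].
#' @return a list of class `age_fit`: the updated `model` (best checkpoint
#'   loaded), `store`, `log`, `selected` (epoch/score).
#' @export
train_regressor <- function(model, train_volumes, train_ages,
                            val_volumes, val_ages, cfg) {
  stopifnot(inherits(model, "age_model"), inherits(cfg, "train_config"))
  if (length(train_volumes) == 0L) stop("training set is empty", call. = FALSE)
  if (!all(is.finite(train_ages)) || !all(is.finite(val_ages))) {
    stop("ages must be finite", call. = FALSE)
  }
  stopifnot(length(train_volumes) == length(train_ages),
            length(val_volumes) == length(val_ages))
  tr <- as_volume_matrices(train_volumes, model$spec)
  va <- as_volume_matrices(val_volumes, model$spec)
  norm <- model$norm
  tr_z <- lapply(tr, function(x) encode_volume(model, (x - norm["mu"]) / norm["sd"]))
  va_z <- lapply(va, function(x) encode_volume(model, (x - norm["mu"]) / norm["sd"]))

  center <- mean(train_ages)
  head_idx <- (model$n_encoder + 1L):length(model$layers)
  head_layers <- model$layers[head_idx]

  # standardize the frozen features so head optimization is scale-free;
  # the affine layer stays fixed (it has no trainable parameters) and is
  # part of the model, so prediction and input gradients include it
  zm <- do.call(rbind, tr_z)
  head_layers[[1]] <- layer_affine(colMeans(zm), apply(zm, 2, stats::sd))

  res <- run_training(
    head_layers, tr_z, as.list(train_ages - center),
    va_z, as.list(val_ages - center), cfg,
    trainable = rep(TRUE, length(head_layers)),
    loss_grad = function(out, target) {
      d <- out - target
      list(loss = d^2, dout = 2 * d)
    },
    val_score_fun = function(out, target) abs(out - target)
  )
  sel <- select_best_checkpoint(res$store)
  head_final <- net_set_params(head_layers, sel$params)
  model$layers[head_idx] <- head_final
  model$age_center <- center
  model$finalized <- TRUE
  structure(list(model = model, store = res$store, log = res$log,
                 selected = list(epoch = sel$epoch, score = sel$score)),
            class = "age_fit")
}

#' Predict ages for a set of volumes
#'
#' @param model a finalized `age_model` (best checkpoint loaded by
#'   [train_regressor()]).
#' @param volumes list of 3D arrays or voxel-by-channel matrices.
#' @return numeric vector of predicted ages (years), one per volume.
#' @export
predict_age <- function(model, volumes) {
  stopifnot(inherits(model, "age_model"))
  if (!isTRUE(model$finalized)) {
    stop("model is not finalized: train the head first", call. = FALSE)
  }
  xs <- as_volume_matrices(volumes, model$spec)
  norm <- model$norm
  vapply(xs, function(x) {
    out <- net_forward(model$layers, (x - norm["mu"]) / norm["sd"],
                       want_caches = FALSE)$out
    as.numeric(out) + model$age_center
  }, numeric(1))
}

# Extract the encoder parameter snapshot of an age model (used by the
# freeze-invariant tests and the run manifest).
encoder_params <- function(model) {
  net_params(model$layers[seq_len(model$n_encoder)])
}
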