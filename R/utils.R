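#' Derive a reproducible sub-seed
#'
#' All stochastic stages of the pipeline draw their random numbers from seeds
#' derived deterministically from one master seed plus a stage/subject label,
#' so that any stage can be re-run in isolation with identical results.
#' The derivation is a simple multiplicative-congruential hash kept strictly
#' below 2^31 - 1 so the result is always a valid R integer seed.
#'
#' @param seed master integer seed.
#' @param ... additional integer or character components (e.g. a subject id,
#'   an epoch index) mixed into the hash in order.
#' @return a single integer in `[0, 2147483628]`.
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483629
  h <- as.numeric(seed) %% m
  for (p in list(...)) {
    if (is.character(p)) {
      stopifnot(length(p) == 1L)
      cp <- utf8ToInt(p)
      p <- sum(cp * seq_along(cp)) %% m
    }
    for (pi in as.numeric(p)) {
      h <- (h * 48271 + (pi %% m) + 1) %% m
    }
  }
  as.integer(h)
}

#' Evaluate code under a fixed RNG seed
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so seeded helpers never perturb the global stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

# Format a subject id used by the cohort sampler: <prefix>-NNNN
format_subject_id <- function(prefix, i) sprintf("%s-%04d", prefix, i)
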