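#' Shuffled-surrogate baseline profile
#'
#' Destroys the temporal structure of the infant series by random
#' permutation while preserving its marginal category frequencies, then
#' recomputes the lag profile against the original parent series. The
#' resulting profile estimates the recurrence expected if one partner's
#' movement followed the other only by chance. With independent series of
#' category probabilities p and q the expected RR is
#' 100 * sum_c p_c q_c at every lag, so fewer categories imply a higher
#' chance level.
#'
#' @param parent,infant [categorical_series()] of equal length.
#' @param n_shuffles number of random permutations to average (default 1:
#'   a single shuffled surrogate; increase for variance reduction).
#' @param seed integer seed; the result is reproducible bit-for-bit.
#' @param max_lag_s lag window half-width in seconds.
#' @param keep_shuffles if TRUE, attach the individual per-shuffle
#'   profiles as attribute `"shuffles"`.
#' @return A `lag_profile` (mean over shuffles).
#' @export
shuffled_baseline <- function(parent, infant, n_shuffles = 1, seed = 1,
                              max_lag_s = 4, keep_shuffles = FALSE) {
  check_pair(parent, infant)
  stopifnot(n_shuffles >= 1)
  rng <- local_rng(seed)
  profiles <- vector("list", n_shuffles)
  for (s in seq_len(n_shuffles)) {
    surr <- infant
    surr$codes <- sample(infant$codes)
    profiles[[s]] <- lag_profile(parent, surr, max_lag_s = max_lag_s)
  }
  out <- average_profiles(profiles)
  if (keep_shuffles) attr(out, "shuffles") <- profiles
  out
}

#' Random-pairing baseline profile
#'
#' Controls for task-driven recurrence by pairing the parent with infants
#' from other dyads engaged in the same task: k infants are sampled
#' without replacement from the pool (which must exclude the parent's own
#' infant), each pairing is trimmed to the shorter series' length
#' ([trim_pair()]), its lag profile computed, and the k profiles
#' averaged.
#'
#' @param parent a [categorical_series()].
#' @param pool list of [categorical_series()] from other dyads.
#' @param k number of random pairings (default 5).
#' @param seed integer seed.
#' @param max_lag_s lag window half-width in seconds.
#' @return A `lag_profile` (mean over the k pairings).
#' @export
random_pair_baseline <- function(parent, pool, k = 5, seed = 1,
                                 max_lag_s = 4) {
  stopifnot(is.list(pool), length(pool) >= 1)
  if (k > length(pool)) {
    stop("k (", k, ") exceeds pool size (", length(pool), ")")
  }
  own <- vapply(pool, function(s) identical(s$dyad_id, parent$dyad_id) &&
                  !is.na(s$dyad_id), logical(1))
  if (any(own)) {
    stop("pool contains a series from the parent's own dyad (",
         parent$dyad_id, "); exclude it first")
  }
  rng <- local_rng(seed)
  picks <- sample(length(pool), k)
  profiles <- lapply(pool[picks], function(inf) {
    tp <- trim_pair(parent, inf)
    lag_profile(tp$a, tp$b, max_lag_s = max_lag_s)
  })
  average_profiles(profiles)
}

# Scoped RNG: seeds the session RNG for the calling frame and restores
# the previous state on exit, so library functions never leak RNG state.
local_rng <- function(seed, env = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  withr::defer({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, envir = env)
  set.seed(as.integer(seed %% .Machine$integer.max))
  invisible(seed)
}

#' Derive per-dyad sub-seeds from a master seed
#'
#' A single pipeline-level seed fans out deterministically to one sub-seed
#' per dyad (by counter), so cohort runs are reproducible regardless of
#' the order in which dyads are processed.
#'
#' @param master_seed integer.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(master_seed, n) {
  rng <- local_rng(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}
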