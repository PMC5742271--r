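# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles are deliberately naive (double loops, full-matrix
# enumeration) and share no code with the production paths they check.

# Brute-force diagonal-wise recurrence profile: build the full N x N
# match matrix with two explicit loops and sum each diagonal.
brute_lag_profile <- function(pcodes, icodes, L) {
  n <- length(pcodes)
  m <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (icodes[i] == pcodes[j]) m[i, j] <- 1L
    }
  }
  vapply((-L):L, function(tau) {
    # diagonal j - i = tau
    tot <- 0L
    cnt <- 0L
    for (i in seq_len(n)) {
      j <- i + tau
      if (j >= 1 && j <= n) {
        tot <- tot + m[i, j]
        cnt <- cnt + 1L
      }
    }
    100 * tot / cnt
  }, numeric(1))
}

# Exhaustive run-length enumeration for one orientation of a binary
# matrix: walk each column (or row) cell by cell.
brute_lines <- function(m, orientation, lmin) {
  if (orientation == "horizontal") m <- t(m)
  out <- integer(0)
  for (j in seq_len(ncol(m))) {
    run <- 0L
    for (i in seq_len(nrow(m))) {
      if (m[i, j] == 1L) {
        run <- run + 1L
      } else {
        if (run >= lmin) out <- c(out, run)
        run <- 0L
      }
    }
    if (run >= lmin) out <- c(out, run)
  }
  out
}

# Random categorical series on n codes drawn from the given system.
rand_series <- function(n, system = "simple", fps = 25, seed = NULL,
                        dyad_id = NA_character_, role = NA_character_) {
  if (!is.null(seed)) set.seed(seed)
  sys <- coordinate_system(system)
  categorical_series(sample(sys$codes, n, replace = TRUE), fps = fps,
                     system = sys, dyad_id = dyad_id, role = role)
}

# Minimal hand-built trajectory from a matrix of centers (constant box).
traj_from_centers <- function(cx, cy, fps = 25, box = 10, valid = NULL) {
  n <- length(cx)
  if (is.null(valid)) valid <- rep(TRUE, n)
  box_trajectory(data.frame(frame = 0:(n - 1), x = cx - box / 2,
                            y = cy - box / 2, w = box, h = box,
                            valid = valid), fps = fps)
}

# Simulated per-dyad profile pair under a shared generative process
# (used by the statistical-layer null calibrations): dyad-level random
# intercept plus iid noise, identical for both conditions.
sim_null_profiles <- function(n_dyads, lags_s, sd_dyad = 1.5, sd_noise = 2,
                              mu = 30) {
  b <- rnorm(n_dyads, 0, sd_dyad)
  fps <- 25
  mk <- function(i) {
    lag_frames <- as.integer(round(lags_s * fps))
    structure(data.frame(lag_frames = lag_frames,
                         lag_ms = 1000 * lag_frames / fps,
                         rr = mu + b[i] + rnorm(length(lags_s), 0, sd_noise),
                         n_overlap = NA_integer_),
              fps = fps, class = c("lag_profile", "data.frame"))
  }
  list(real = lapply(seq_len(n_dyads), mk),
       baseline = lapply(seq_len(n_dyads), mk))
}
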