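#' Simulation parameters for one synthetic dyad
#'
#' Defines a coupled leader-follower pair emulating a free-play episode:
#' a "parent/object" leader sweeping smoothly left-right with small
#' vertical jitter, and an "infant" follower whose movement direction
#' reproduces the leader's direction a fixed number of frames later.
#' Coupling lives in direction space (the follower copies the leader's
#' movement category, rescaled in magnitude), which is exactly the space
#' the recurrence pipeline measures.
#'
#' @param n_frames episode length in frames (default 600, i.e. 24 s at
#'   25 fps, in the middle of a typical 15-41 s free-play episode).
#' @param fps frames per second (default 25).
#' @param lag_frames leader lead in frames (default 6, i.e. 240 ms at
#'   25 fps).
#' @param amplitude_px half-width of the leader's horizontal sweep
#'   (default 150 px on a 752 x 582 image).
#' @param period_s period of the sweep in seconds (default 2).
#' @param jitter_p per-transition probability that the leader makes a
#'   +-1 px vertical step (default 0.15; keeps most structure horizontal
#'   so the simple coordinate system captures it).
#' @param follower_step_px follower step magnitude per axis (default 3).
#' @param noise_p probability that a follower transition's direction is
#'   replaced by a uniformly random detailed-system category
#'   (default 0.1).
#' @param dropout_p per-frame probability that a box is marked invalid,
#'   independently for each trajectory (default 0.05).
#' @param box_px bounding-box side length (default 40).
#' @param seed integer seed; generation is fully deterministic given it.
#' @return list of class `dyad_sim_params`.
#' @export
dyad_sim_params <- function(n_frames = 600, fps = 25, lag_frames = 6,
                            amplitude_px = 150, period_s = 2,
                            jitter_p = 0.15, follower_step_px = 3,
                            noise_p = 0.1, dropout_p = 0.05,
                            box_px = 40, seed = 1) {
  stopifnot(noise_p >= 0, noise_p < 1, dropout_p >= 0, dropout_p < 1,
            lag_frames >= 0, n_frames > lag_frames + 2, fps > 0)
  structure(as.list(environment()), class = "dyad_sim_params")
}

# detailed code -> unit step signs (sx, sy), image convention
code_signs <- function(code) {
  sx <- c(0L, -1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)[code + 1L]
  sy <- c(0L, 0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)[code + 1L]
  cbind(sx = sx, sy = sy)
}

#' Generate one synthetic coupled dyad
#'
#' The leader's box center follows a sinusoidal horizontal sweep with
#' occasional one-pixel vertical jitter. The follower's displacement
#' direction at transition t reproduces the leader's direction category
#' at transition t - lag_frames (stationary before the lag is defined),
#' with magnitude `follower_step_px`; with probability `noise_p` a
#' transition's direction is replaced by a uniformly random category.
#' Both trajectories then receive independent frame dropout. With
#' `noise_p = 0` and `dropout_p = 0` the follower's detailed-system
#' series equals the leader's shifted by the lag, exactly, on the
#' overlapping range.
#'
#' @param params a [dyad_sim_params()].
#' @param dyad_id label stored in the truth record (default "sim").
#' @return list with `parent` and `infant` ([box_trajectory()] objects)
#'   and `truth` (lag, noise, dropout, seed, dyad id).
#' @export
generate_dyad <- function(params = dyad_sim_params(), dyad_id = "sim") {
  stopifnot(inherits(params, "dyad_sim_params"))
  local_rng(params$seed)
  n <- params$n_frames
  fps <- params$fps
  t <- seq_len(n) - 1
  # leader: sinusoidal left-right sweep + sparse vertical jitter
  lx <- 376 + params$amplitude_px * sin(2 * pi * t / (params$period_s * fps))
  jit <- sample(c(-1L, 0L, 1L), n - 1, replace = TRUE,
                prob = c(params$jitter_p / 2, 1 - params$jitter_p,
                         params$jitter_p / 2))
  ly <- 200 + cumsum(c(0L, jit))
  # leader direction categories per transition (detailed system, eps = 0)
  lead_codes <- classify_step(diff(lx), diff(ly), "detailed")
  # follower: copies the leader's direction lag_frames transitions back
  lag <- params$lag_frames
  fol_codes <- integer(n - 1)
  if (lag > 0) fol_codes[seq_len(min(lag, n - 1))] <- 0L
  idx <- (lag + 1):(n - 1)
  fol_codes[idx] <- lead_codes[idx - lag]
  # directional noise: replace a transition's category uniformly at random
  noisy <- stats::runif(n - 1) < params$noise_p
  fol_codes[noisy] <- sample(0:8, sum(noisy), replace = TRUE)
  steps <- code_signs(fol_codes) * params$follower_step_px
  fx <- 376 + cumsum(c(0, steps[, "sx"]))
  fy <- 350 + cumsum(c(0, steps[, "sy"]))
  mk <- function(x, y, label, drop_seed) {
    local_rng(drop_seed)
    valid <- stats::runif(n) >= params$dropout_p
    b <- data.frame(frame = t, x = x - params$box_px / 2,
                    y = y - params$box_px / 2,
                    w = params$box_px, h = params$box_px, valid = valid)
    b$x[!valid] <- NA; b$y[!valid] <- NA; b$w[!valid] <- NA; b$h[!valid] <- NA
    box_trajectory(b, fps = fps, feature_label = label)
  }
  sub <- derive_seeds(params$seed, 2)
  parent <- mk(lx, ly, "object", sub[1])
  infant <- mk(fx, fy, "infant_face", sub[2])
  list(parent = parent, infant = infant,
       truth = list(dyad_id = dyad_id, lag_frames = lag,
                    noise_p = params$noise_p, dropout_p = params$dropout_p,
                    seed = params$seed, n_frames = n, fps = fps))
}

#' Generate a synthetic cohort of dyads
#'
#' Replicates the study design at cohort level: `n_dyads` dyads whose
#' episode lengths are drawn uniformly from `len_range_s` (default
#' 15-41.08 s, i.e. 375-1027 frames at 25 fps) and whose leader lag can
#' be jittered per dyad. Per-dyad seeds are derived deterministically
#' from `master_seed`, so the cohort is reproducible bit-for-bit.
#'
#' @param n_dyads number of dyads (default 21).
#' @param params base [dyad_sim_params()]; per-dyad `n_frames` and
#'   `seed` are overridden.
#' @param len_range_s episode length range in seconds; set to NULL to
#'   keep `params$n_frames` for every dyad.
#' @param lag_jitter_frames max absolute per-dyad jitter added to
#'   `params$lag_frames` (integer, uniform; default 0).
#' @param master_seed integer cohort seed.
#' @return list of dyads as returned by [generate_dyad()], named by dyad
#'   id.
#' @export
generate_cohort <- function(n_dyads = 21, params = dyad_sim_params(),
                            len_range_s = c(15, 41.08),
                            lag_jitter_frames = 0, master_seed = 1) {
  stopifnot(n_dyads >= 2)
  local_rng(master_seed)
  lens <- if (is.null(len_range_s)) rep(params$n_frames, n_dyads) else {
    round(stats::runif(n_dyads, len_range_s[1], len_range_s[2]) * params$fps)
  }
  lags <- params$lag_frames +
    if (lag_jitter_frames > 0) {
      sample(seq(-lag_jitter_frames, lag_jitter_frames), n_dyads, replace = TRUE)
    } else rep(0L, n_dyads)
  seeds <- derive_seeds(master_seed, n_dyads)
  out <- lapply(seq_len(n_dyads), function(i) {
    p <- params
    p$n_frames <- lens[i]
    p$lag_frames <- max(0L, lags[i])
    p$seed <- seeds[i]
    generate_dyad(p, dyad_id = sprintf("dyad%02d", i))
  })
  names(out) <- vapply(out, function(d) d$truth$dyad_id, character(1))
  out
}

#' Write a simulated dyad to disk
#'
#' Writes the parent and infant trajectory CSVs (schema
#' `frame,x,y,w,h,valid`) plus a `truth.json` recording the ground-truth
#' lag, noise, dropout, and seed.
#'
#' @param dyad result of [generate_dyad()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dyad <- function(dyad, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_trajectory(dyad$parent, file.path(dir, "parent.csv"))
  write_trajectory(dyad$infant, file.path(dir, "infant.csv"))
  jsonlite::write_json(dyad$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
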