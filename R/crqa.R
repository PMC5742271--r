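#' Categorical cross-recurrence matrix
#'
#' Builds the binary N x N cross-recurrence plot between a parent (leader)
#' and infant (follower) series: entry (i, j) is 1 iff the infant's code
#' at time i equals the parent's code at time j. By convention the parent
#' series runs along the horizontal axis (columns, index j) and the infant
#' series along the vertical axis (rows, index i).
#'
#' @param parent,infant [categorical_series()] of equal length, same fps,
#'   same coordinate system. Trim with [trim_pair()] first if needed.
#' @return An integer 0/1 matrix of class `recurrence_plot` with
#'   attribute `fps`.
#' @export
cross_recurrence_matrix <- function(parent, infant) {
  check_pair(parent, infant)
  m <- outer(infant$codes, parent$codes, "==") + 0L
  structure(m, fps = parent$fps, class = c("recurrence_plot", class(m)))
}

check_pair <- function(parent, infant) {
  stopifnot(inherits(parent, "categorical_series"),
            inherits(infant, "categorical_series"))
  if (length(parent$codes) != length(infant$codes)) {
    stop("series lengths differ (", length(parent$codes), " vs ",
         length(infant$codes), "); use trim_pair() first")
  }
  if (!isTRUE(all.equal(parent$fps, infant$fps))) stop("fps mismatch")
  if (parent$system$name != infant$system$name) {
    stop("coordinate systems differ (", parent$system$name, " vs ",
         infant$system$name, ")")
  }
  invisible(TRUE)
}

#' Diagonal-wise cross-recurrence lag profile
#'
#' Computes the recurrence rate (RR, percent) on each diagonal of the
#' cross-recurrence plot within a symmetric lag window. For lag tau
#' (frames),
#' \deqn{RR(\tau) = \frac{100}{N - |\tau|}
#'   \sum_t \mathbf{1}[\,parent(t) = infant(t - \tau)\,],}
#' i.e., each diagonal is normalized by its own number of aligned pairs.
#' With this convention a parent lead of D frames (the infant echoes the
#' parent's movement D frames later) produces a peak at tau = -D:
#' negative lags indicate a parent-leading, positive lags an
#' infant-leading coupling.
#'
#' The computation is a direct shifted comparison, O(N * L); the full
#' recurrence matrix is never materialized (use
#' [cross_recurrence_matrix()] when the plot itself is needed, e.g. for
#' anisotropic measures).
#'
#' @param parent,infant [categorical_series()] of equal length.
#' @param max_lag_s half-width of the lag window in seconds (default 4,
#'   giving 201 lag bins at 25 fps).
#' @return A data.frame of class `lag_profile` with columns `lag_frames`,
#'   `lag_ms`, `rr` (percent), and `n_overlap`, plus attribute `fps`.
#' @export
lag_profile <- function(parent, infant, max_lag_s = 4) {
  check_pair(parent, infant)
  fps <- parent$fps
  L <- max_lag_s * fps
  if (abs(L - round(L)) > 1e-9) {
    stop("max_lag_s * fps must be an integer number of frames")
  }
  L <- as.integer(round(L))
  n <- length(parent$codes)
  if (n <= L) {
    stop("series length (", n, ") must exceed the lag window (", L, " frames)")
  }
  p <- parent$codes
  f <- infant$codes
  lags <- (-L):L
  rr <- vapply(lags, function(tau) {
    if (tau >= 0) {
      # parent(t) vs infant(t - tau), t = tau+1 .. n
      mean(p[(tau + 1):n] == f[1:(n - tau)])
    } else {
      mean(p[1:(n + tau)] == f[(1 - tau):n])
    }
  }, numeric(1)) * 100
  new_lag_profile(lags, rr, n - abs(lags), fps)
}

new_lag_profile <- function(lag_frames, rr, n_overlap, fps) {
  structure(data.frame(lag_frames = as.integer(lag_frames),
                       lag_ms = 1000 * lag_frames / fps,
                       rr = rr,
                       n_overlap = n_overlap),
            fps = fps, class = c("lag_profile", "data.frame"))
}

#' Subsample a lag profile to a coarser grid
#'
#' Keeps every (fps / target_rate_hz)-th lag, always including lag 0 and
#' both endpoints. A 201-bin profile at 25 fps subsampled to 6.25 Hz
#' yields 51 bins.
#'
#' @param p a `lag_profile`.
#' @param target_rate_hz target sampling rate; `fps` must be an integer
#'   multiple of it.
#' @return A `lag_profile` on the coarser grid.
#' @export
subsample_profile <- function(p, target_rate_hz) {
  stopifnot(inherits(p, "lag_profile"))
  fps <- attr(p, "fps")
  stride <- fps / target_rate_hz
  if (abs(stride - round(stride)) > 1e-9) {
    stop("fps (", fps, ") is not an integer multiple of target rate (",
         target_rate_hz, ")")
  }
  stride <- as.integer(round(stride))
  keep <- p$lag_frames %% stride == 0L
  out <- p[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, fps = fps, class = c("lag_profile", "data.frame"))
}

#' Peak of a lag profile
#'
#' Location of the maximum recurrence rate and the implied leader. A
#' negative peak lag means the parent leads (the infant's movement echoes
#' the parent's earlier movement); positive means the infant leads; zero
#' means synchronous. Ties are resolved toward lag 0, then toward the
#' negative lag, with a warning.
#'
#' @param p a `lag_profile`.
#' @return list with `lag_ms`, `lag_frames`, `rr` (peak value), and
#'   `leader` in `{"parent-leading", "infant-leading", "synchronous"}`.
#' @export
peak_lag <- function(p) {
  stopifnot(inherits(p, "lag_profile"), nrow(p) > 0)
  mx <- max(p$rr)
  cand <- which(p$rr == mx)
  if (length(cand) > 1) {
    warning("tie at the profile peak (", length(cand),
            " lags); choosing the lag closest to 0, negative side first")
    d <- abs(p$lag_frames[cand])
    cand <- cand[d == min(d)]
    if (length(cand) > 1) cand <- cand[p$lag_frames[cand] < 0]
  }
  i <- cand[1]
  lag_f <- p$lag_frames[i]
  leader <- if (lag_f < 0) "parent-leading"
            else if (lag_f > 0) "infant-leading" else "synchronous"
  list(lag_ms = p$lag_ms[i], lag_frames = lag_f, rr = p$rr[i], leader = leader)
}

#' Average lag profiles across dyads
#'
#' Per-lag arithmetic mean and standard deviation over a list of profiles
#' sharing the same lag grid.
#'
#' @param profiles list of `lag_profile` objects.
#' @return A `lag_profile` whose `rr` is the per-lag mean, with an extra
#'   column `rr_sd` (SD across profiles; 0 for a single profile).
#' @export
average_profiles <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 1)
  grid <- profiles[[1]]$lag_frames
  for (p in profiles) {
    stopifnot(inherits(p, "lag_profile"))
    if (!identical(p$lag_frames, grid)) stop("profiles have mismatched lag grids")
  }
  rrs <- vapply(profiles, function(p) p$rr, numeric(length(grid)))
  rrs <- matrix(rrs, nrow = length(grid))
  out <- profiles[[1]]
  out$rr <- rowMeans(rrs)
  out$rr_sd <- if (ncol(rrs) > 1) apply(rrs, 1, stats::sd) else rep(0, length(grid))
  out$n_overlap <- NULL
  structure(out, fps = attr(profiles[[1]], "fps"),
            class = c("lag_profile", "data.frame"))
}

#' Write a lag profile to CSV
#'
#' Columns: `lag_frames,lag_ms,rr_percent,n_overlap` and, when present,
#' `rr_sd` and a `condition` label.
#'
#' @param p a `lag_profile`.
#' @param path output path.
#' @param condition optional condition label
#'   (`"real"`, `"shuffled"`, `"random_paired"`).
#' @return `path`, invisibly.
#' @export
write_profile <- function(p, path, condition = NULL) {
  df <- as.data.frame(p)
  names(df)[names(df) == "rr"] <- "rr_percent"
  if (!is.null(condition)) df$condition <- condition
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot a lag profile
#'
#' Base-graphics rendering of a profile (optionally with an SD band and a
#' baseline overlay), with negative lags labeled as parent-leading.
#'
#' @param x a `lag_profile`.
#' @param baseline optional second `lag_profile` drawn for comparison.
#' @param shade_s optional length-2 numeric: lag interval (seconds) to
#'   shade, e.g. a significance window.
#' @param ... passed to [graphics::plot()].
#' @export
plot.lag_profile <- function(x, baseline = NULL, shade_s = NULL, ...) {
  sec <- x$lag_ms / 1000
  ylim <- range(x$rr, if (!is.null(baseline)) baseline$rr,
                if (!is.null(x$rr_sd)) c(x$rr - x$rr_sd, x$rr + x$rr_sd))
  graphics::plot(sec, x$rr, type = "n", xlab = "lag (s)  [negative = parent leads]",
                 ylab = "recurrence rate (%)", ylim = ylim, ...)
  if (!is.null(shade_s)) {
    graphics::rect(shade_s[1], ylim[1], shade_s[2], ylim[2],
                   col = grDevices::adjustcolor("red", 0.15), border = NA)
  }
  if (!is.null(x$rr_sd)) {
    graphics::polygon(c(sec, rev(sec)), c(x$rr - x$rr_sd, rev(x$rr + x$rr_sd)),
                      col = grDevices::adjustcolor("blue", 0.15), border = NA)
  }
  graphics::lines(sec, x$rr, col = "blue", lwd = 2)
  if (!is.null(baseline)) {
    graphics::lines(baseline$lag_ms / 1000, baseline$rr, col = "red", lwd = 2)
  }
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}
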