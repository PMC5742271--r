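#' Line-length distribution of a recurrence plot
#'
#' Lengths of the maximal runs of recurrent points along one orientation
#' of the plot: vertical lines run along columns (uninterrupted episodes
#' of the infant/follower staying in a state matching the parent),
#' horizontal lines along rows (the parent staying in a state matching
#' the infant). Only runs of length at least `lmin` are kept. Runs are
#' maximal (not extendable) and are not wrapped at matrix borders.
#'
#' @param plot a `recurrence_plot` (binary matrix).
#' @param orientation `"vertical"` or `"horizontal"`.
#' @param lmin minimum counted line length (>= 2).
#' @return integer vector of qualifying line lengths (possibly empty).
#' @export
line_length_distribution <- function(plot,
                                     orientation = c("vertical", "horizontal"),
                                     lmin = 2) {
  orientation <- match.arg(orientation)
  stopifnot(is.matrix(plot), lmin >= 2)
  m <- if (orientation == "vertical") plot else t(plot)
  # runs of 1s down each column; a 0-row separator between columns keeps
  # runs from bridging column boundaries
  v <- rbind(m, 0L)
  r <- rle(as.integer(v))
  lens <- r$lengths[r$values == 1L]
  as.integer(lens[lens >= lmin])
}

#' Anisotropic cross-recurrence measures
#'
#' Quantifies the vertical vs horizontal line structures of a
#' cross-recurrence plot. For each orientation:
#'
#' * laminarity `lam` — proportion of recurrent points that belong to
#'   lines of length >= `lmin`;
#' * trapping time `tt` — mean length of those lines (recurrence
#'   points);
#' * maximum line `maxl` — length of the longest such line.
#'
#' With the parent on the horizontal axis, vertical lines measure how
#' long the infant dwells in a state matching the parent, and horizontal
#' lines how long the parent dwells in a state matching the infant;
#' systematically higher horizontal values indicate that the parent's
#' movement is the more regular, sustained one. Unlike auto-recurrence,
#' the main diagonal carries no trivial self-match and is not excluded.
#'
#' @param plot a `recurrence_plot`.
#' @param lmin minimum counted line length (default 2).
#' @return list of class `acrqa_measures`: `lam_v`, `lam_h`, `tt_v`,
#'   `tt_h`, `maxl_v`, `maxl_h`, `lmin`, `n_recurrent_points`, and
#'   `defined` (FALSE when the plot has no recurrent points; all
#'   measures then 0). When an orientation has recurrent points but no
#'   qualifying line, its `lam` and `maxl` are 0 and its `tt` is 0 with
#'   `defined_v`/`defined_h` FALSE.
#' @export
acrqa_measures <- function(plot, lmin = 2) {
  stopifnot(is.matrix(plot))
  npts <- sum(plot == 1L)
  orient <- function(o) {
    lens <- line_length_distribution(plot, o, lmin = lmin)
    if (length(lens) == 0) {
      list(lam = 0, tt = 0, maxl = 0, defined = FALSE)
    } else {
      list(lam = sum(lens) / npts, tt = mean(lens), maxl = max(lens),
           defined = TRUE)
    }
  }
  if (npts == 0) {
    v <- h <- list(lam = 0, tt = 0, maxl = 0, defined = FALSE)
  } else {
    v <- orient("vertical")
    h <- orient("horizontal")
  }
  structure(list(lam_v = v$lam, lam_h = h$lam,
                 tt_v = v$tt, tt_h = h$tt,
                 maxl_v = v$maxl, maxl_h = h$maxl,
                 lmin = as.integer(lmin),
                 n_recurrent_points = npts,
                 defined = npts > 0,
                 defined_v = v$defined, defined_h = h$defined),
            class = "acrqa_measures")
}

#' Convert recurrence points to milliseconds
#'
#' One recurrence point spans one frame, i.e. 1000/fps ms (40 ms at
#' 25 fps). Line lengths (trapping time, maximum line) are reported in
#' points; this converts them to durations.
#'
#' @param points line length in recurrence points.
#' @param fps frames per second.
#' @return duration in milliseconds.
#' @export
ms_from_points <- function(points, fps) {
  stopifnot(fps > 0)
  1000 * points / fps
}

#' Cohort table of anisotropic measures
#'
#' @param measures named list of `acrqa_measures`, one per dyad (names =
#'   dyad ids).
#' @return data.frame, one row per dyad, columns
#'   `dyad_id, lam_v, lam_h, tt_v, tt_h, maxl_v, maxl_h, lmin,
#'   n_recurrent_points`.
#' @export
acrqa_table <- function(measures) {
  stopifnot(is.list(measures), length(measures) >= 1)
  ids <- names(measures)
  if (is.null(ids)) ids <- as.character(seq_along(measures))
  rows <- lapply(seq_along(measures), function(i) {
    m <- measures[[i]]
    data.frame(dyad_id = ids[i], lam_v = m$lam_v, lam_h = m$lam_h,
               tt_v = m$tt_v, tt_h = m$tt_h, maxl_v = m$maxl_v,
               maxl_h = m$maxl_h, lmin = m$lmin,
               n_recurrent_points = m$n_recurrent_points)
  })
  do.call(rbind, rows)
}

#' Paired asymmetry test on anisotropic measures
#'
#' Tests, across dyads, whether vertical and horizontal line measures
#' differ, with one paired t-test per measure (LAM, TT, MaxL) on the
#' per-dyad differences vertical minus horizontal. A negative t
#' indicates horizontal values exceed vertical ones, i.e. the partner on
#' the horizontal axis (parent) sustains matching movement states longer
#' than the one on the vertical axis (infant). Cohen's d for paired data
#' is mean(diff)/SD(diff).
#'
#' @param tab a cohort table from [acrqa_table()] (>= 2 dyads).
#' @return data.frame with one row per measure: `measure, t, df, p, d,
#'   defined` (`defined` FALSE when the differences have zero variance,
#'   leaving t undefined).
#' @export
asymmetry_test <- function(tab) {
  stopifnot(is.data.frame(tab), nrow(tab) >= 2)
  one <- function(measure, v, h) {
    diffs <- v - h
    if (stats::sd(diffs) == 0) {
      # all differences identical: t is 0/0 unless the common value is 0
      zero <- all(diffs == 0)
      data.frame(measure = measure, t = if (zero) 0 else NA_real_,
                 df = length(diffs) - 1L,
                 p = if (zero) 1 else NA_real_,
                 d = if (zero) 0 else NA_real_,
                 defined = zero)
    } else {
      tt <- stats::t.test(v, h, paired = TRUE)
      data.frame(measure = measure, t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 d = mean(diffs) / stats::sd(diffs), defined = TRUE)
    }
  }
  rbind(one("lam", tab$lam_v, tab$lam_h),
        one("tt", tab$tt_v, tab$tt_h),
        one("maxl", tab$maxl_v, tab$maxl_h))
}
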