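#' Bounding-box trajectories
#'
#' A box trajectory holds the per-frame output of an object tracker for one
#' tracked feature: a bounding box (top-left corner, width, height, in image
#' pixel coordinates where y grows downward) and a validity flag indicating
#' whether the tracker reported a detection on that frame. Frames are
#' 0-based and contiguous.
#'
#' @param boxes data.frame with columns `frame`, `x`, `y`, `w`, `h`,
#'   `valid` (logical), ordered by frame.
#' @param fps sampling rate in frames per second (video standard here: 25).
#' @param feature_label free-text label for the tracked feature, e.g.
#'   `"infant_face"` or `"object"`.
#' @return An object of class `box_trajectory`: the data.frame with `fps`
#'   and `feature_label` attributes.
#' @export
box_trajectory <- function(boxes, fps, feature_label = "feature") {
  stopifnot(is.data.frame(boxes))
  req <- c("frame", "x", "y", "w", "h", "valid")
  missing_cols <- setdiff(req, names(boxes))
  if (length(missing_cols) > 0) {
    stop("trajectory is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!is.numeric(fps) || length(fps) != 1 || fps <= 0) {
    stop("fps must be a single positive number")
  }
  boxes <- boxes[order(boxes$frame), req, drop = FALSE]
  if (anyDuplicated(boxes$frame)) {
    dup <- boxes$frame[duplicated(boxes$frame)][1]
    stop("duplicate frame index: ", dup)
  }
  if (nrow(boxes) < 2) stop("trajectory must contain at least 2 frames")
  boxes$frame <- as.integer(boxes$frame)
  boxes$valid <- as.logical(boxes$valid)
  # insert placeholders so frame indices run 0..N-1 without holes
  full <- seq(min(boxes$frame), max(boxes$frame))
  if (min(boxes$frame) != 0L) {
    stop("frame indices must start at 0 (got ", min(boxes$frame), ")")
  }
  if (length(full) != nrow(boxes)) {
    filled <- data.frame(frame = full, x = NA_real_, y = NA_real_,
                         w = NA_real_, h = NA_real_, valid = FALSE)
    idx <- match(boxes$frame, full)
    filled[idx, ] <- boxes
    boxes <- filled
  }
  v <- boxes$valid
  if (any(v & (!is.finite(boxes$x) | !is.finite(boxes$y)))) {
    stop("valid frames must have finite coordinates")
  }
  if (any(v & (boxes$w <= 0 | boxes$h <= 0), na.rm = TRUE)) {
    stop("valid frames must have positive width and height")
  }
  rownames(boxes) <- NULL
  structure(boxes, fps = fps, feature_label = feature_label,
            class = c("box_trajectory", "data.frame"))
}

#' Read a tracker trajectory from CSV
#'
#' Expects a comma-separated file with header `frame,x,y,w,h,valid`
#' (`valid` coded 0/1), one file per tracked feature. Frames missing from
#' the file are inserted as invalid placeholders so the result is always
#' contiguous.
#'
#' @param path path to the CSV file.
#' @param fps sampling rate of the recording, frames per second.
#' @param feature_label optional label; defaults to the file name.
#' @return A [box_trajectory()].
#' @export
load_trajectory <- function(path, fps, feature_label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e))
  )
  if (nrow(df) == 0) stop("empty trajectory file: ", path)
  for (col in c("frame", "x", "y", "w", "h", "valid")) {
    if (!col %in% names(df)) stop(path, ": missing column '", col, "'")
    suppressWarnings(num <- as.numeric(df[[col]]))
    bad <- which(is.na(num) & !is.na(df[[col]]) & df[[col]] != "NA")
    if (length(bad) > 0) {
      stop(path, ": malformed value in column '", col, "', row ", bad[1])
    }
    df[[col]] <- num
  }
  df$valid <- df$valid != 0
  if (is.null(feature_label)) feature_label <- sub("\\.csv$", "", basename(path))
  box_trajectory(df, fps = fps, feature_label = feature_label)
}

#' Write a trajectory to CSV
#'
#' Inverse of [load_trajectory()]; writes the schema
#' `frame,x,y,w,h,valid` with `valid` as 0/1.
#'
#' @param traj a [box_trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  df$valid <- as.integer(df$valid)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Tracker accuracy
#'
#' Percentage of successfully tracked frames out of the total number of
#' frames, computed on the raw tracker output (i.e., before any gap
#' interpolation).
#'
#' @param traj a [box_trajectory()].
#' @return percentage in \[0, 100\].
#' @export
tracking_accuracy <- function(traj) {
  100 * sum(traj$valid) / nrow(traj)
}

#' Fill tracker gaps by linear interpolation
#'
#' Frames where the tracker lost its target are repaired by linear
#' interpolation of the box center and size between the last known frame
#' and the first one available again. Gaps touching the first or last
#' frame have no bracketing observation on one side and are filled by
#' nearest-valid constant extrapolation, with a warning.
#'
#' @param traj a [box_trajectory()].
#' @return The repaired trajectory (all frames valid), with attributes
#'   `n_interpolated` (number of repaired frames) and
#'   `accuracy_percent` (pre-repair [tracking_accuracy()]).
#' @export
interpolate_gaps <- function(traj) {
  v <- traj$valid
  n <- nrow(traj)
  acc <- tracking_accuracy(traj)
  if (!any(v)) stop("trajectory has no valid frames; cannot interpolate")
  n_interp <- sum(!v)
  if (n_interp > 0) {
    if (!v[1] || !v[n]) {
      warning("gap touches trajectory boundary; filled by nearest-valid constant extrapolation")
    }
    idx <- seq_len(n)
    known <- idx[v]
    for (col in c("x", "y", "w", "h")) {
      traj[[col]] <- stats::approx(known, traj[[col]][v], xout = idx,
                                   method = "linear", rule = 2)$y
    }
    traj$valid <- TRUE
  }
  attr(traj, "n_interpolated") <- n_interp
  attr(traj, "accuracy_percent") <- acc
  traj
}

#' Repair a trajectory file and write the result with a QC sidecar
#'
#' Reads a trajectory CSV, interpolates gaps, writes the repaired CSV in
#' the same schema and a JSON sidecar
#' `{accuracy_percent, n_interpolated, n_frames}`.
#'
#' @param in_path input trajectory CSV.
#' @param out_path output CSV path.
#' @param fps frames per second.
#' @return the repaired trajectory, invisibly.
#' @export
repair_trajectory_file <- function(in_path, out_path, fps) {
  traj <- load_trajectory(in_path, fps = fps)
  rep <- interpolate_gaps(traj)
  write_trajectory(rep, out_path)
  sidecar <- list(accuracy_percent = attr(rep, "accuracy_percent"),
                  n_interpolated = attr(rep, "n_interpolated"),
                  n_frames = nrow(rep))
  jsonlite::write_json(sidecar, paste0(out_path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(rep)
}

#' Trim two categorical series to a common length
#'
#' When series from different recordings are paired (random-pairing
#' baseline), the trailing part of the longer series is trimmed so both
#' match the length of the shorter one.
#'
#' @param a,b [categorical_series()] objects with equal fps.
#' @return list with elements `a` and `b`, both of length
#'   `min(length(a), length(b))`.
#' @export
trim_pair <- function(a, b) {
  stopifnot(inherits(a, "categorical_series"), inherits(b, "categorical_series"))
  if (!isTRUE(all.equal(a$fps, b$fps))) {
    stop("cannot pair series with different fps (", a$fps, " vs ", b$fps, ")")
  }
  if (length(a$codes) == 0 || length(b$codes) == 0) stop("empty series")
  n <- min(length(a$codes), length(b$codes))
  a$codes <- a$codes[seq_len(n)]
  b$codes <- b$codes[seq_len(n)]
  list(a = a, b = b)
}
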