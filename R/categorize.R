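#' Movement-direction coordinate systems
#'
#' Two categorical coding schemes for frame-to-frame displacement of a
#' tracked feature:
#'
#' * `"simple"` (3 categories): 0 no left/right movement, 1 right, 2 left.
#'   Only the horizontal displacement component is used.
#' * `"detailed"` (9 categories): 0 no movement, 1 left, 2 up-left, 3 up,
#'   4 up-right, 5 right, 6 down-right, 7 down, 8 down-left.
#'
#' "Up" means decreasing y: pixel coordinates follow the image convention
#' (origin top-left, y grows downward). Category boundaries are sign-based
#' per axis (a dead-zone of half-width `eps` around zero on each axis),
#' not angular sectors.
#'
#' @param name `"simple"` or `"detailed"`.
#' @return An object of class `coordinate_system` with fields `name`,
#'   `n_categories`, and `codes` (the valid integer codes).
#' @export
coordinate_system <- function(name = c("simple", "detailed")) {
  name <- match.arg(name)
  n <- if (name == "simple") 3L else 9L
  structure(list(name = name, n_categories = n, codes = 0:(n - 1L)),
            class = "coordinate_system")
}

#' Categorical movement-direction series
#'
#' One integer code per frame transition: a trajectory of N frames yields
#' a series of N - 1 codes.
#'
#' @param codes integer vector of direction codes, all valid for `system`.
#' @param fps frames per second.
#' @param system a [coordinate_system()] (or its name).
#' @param dyad_id,role optional labels; `role` is typically `"parent"` or
#'   `"infant"`.
#' @return An object of class `categorical_series`.
#' @export
categorical_series <- function(codes, fps, system, dyad_id = NA_character_,
                               role = NA_character_) {
  if (is.character(system)) system <- coordinate_system(system)
  stopifnot(inherits(system, "coordinate_system"))
  codes <- as.integer(codes)
  if (length(codes) > 0 && !all(codes %in% system$codes)) {
    stop("codes outside the ", system$name, " system's range 0..",
         system$n_categories - 1L)
  }
  if (!is.numeric(fps) || fps <= 0) stop("fps must be positive")
  structure(list(codes = codes, fps = fps, system = system,
                 dyad_id = dyad_id, role = role),
            class = "categorical_series")
}

#' @export
length.categorical_series <- function(x) length(x$codes)

#' @export
print.categorical_series <- function(x, ...) {
  cat(sprintf("<categorical_series> %s system, %d codes at %g fps (%s/%s)\n",
              x$system$name, length(x$codes), x$fps,
              x$dyad_id, x$role))
  invisible(x)
}

#' Center of a bounding box
#'
#' @param x,y top-left corner (pixels, image coordinates).
#' @param w,h box width and height (pixels).
#' @return numeric vector `c(cx, cy)` = `(x + w/2, y + h/2)`.
#' @export
box_center <- function(x, y, w, h) {
  c(x + w / 2, y + h / 2)
}

#' Classify one displacement step
#'
#' Maps a frame-to-frame displacement `(dx, dy)` to a direction code.
#' Components with magnitude at most `eps` count as zero. The simple
#' system ignores `dy` entirely; the detailed system maps the sign pair to
#' the eight compass directions, with 0 when both components are within
#' the dead-zone. `dy` is in image coordinates: negative `dy` is upward
#' on screen.
#'
#' @param dx,dy displacement in pixels (vectorized).
#' @param system a [coordinate_system()] or its name.
#' @param eps dead-zone half-width in pixels (default 0: exact ties only).
#' @return integer code(s).
#' @export
classify_step <- function(dx, dy, system = coordinate_system("detailed"),
                          eps = 0) {
  if (is.character(system)) system <- coordinate_system(system)
  stopifnot(inherits(system, "coordinate_system"), eps >= 0)
  if (any(!is.finite(dx)) || any(!is.finite(dy))) {
    stop("dx and dy must be finite")
  }
  sx <- ifelse(abs(dx) <= eps, 0L, ifelse(dx > 0, 1L, -1L))
  if (system$name == "simple") {
    return(ifelse(sx == 0L, 0L, ifelse(sx > 0L, 1L, 2L)))
  }
  sy <- ifelse(abs(dy) <= eps, 0L, ifelse(dy > 0, 1L, -1L))
  # detailed codes keyed by (sx, sy); sy = -1 is upward (image convention)
  # 1 left, 2 up-left, 3 up, 4 up-right, 5 right, 6 down-right, 7 down,
  # 8 down-left, 0 none
  lut <- matrix(c(
    # sy = -1 (up): sx = -1, 0, +1
    2L, 3L, 4L,
    # sy = 0:       sx = -1, 0, +1
    1L, 0L, 5L,
    # sy = +1 (down)
    8L, 7L, 6L), nrow = 3, byrow = TRUE)
  lut[cbind(sy + 2L, sx + 2L)]
}

#' Categorize a trajectory into a movement-direction series
#'
#' Extracts the box center for each frame and classifies the displacement
#' to the next frame's center, yielding one code per transition (series
#' length = number of frames - 1). The trajectory must be fully valid;
#' interpolate tracker gaps first with [interpolate_gaps()].
#'
#' @param traj a [box_trajectory()], all frames valid.
#' @param system a [coordinate_system()] or its name.
#' @param eps dead-zone half-width in pixels, see [classify_step()].
#' @param mirror_x if TRUE, flip the horizontal axis (negate dx) before
#'   classification. Useful when the two partners are filmed by cameras
#'   facing each other, so that the same physical direction appears
#'   mirrored in one of the image planes.
#' @param dyad_id,role labels propagated to the series.
#' @return A [categorical_series()] of length `nrow(traj) - 1`.
#' @export
categorize <- function(traj, system = coordinate_system("detailed"), eps = 0,
                       mirror_x = FALSE, dyad_id = NA_character_,
                       role = NA_character_) {
  stopifnot(inherits(traj, "box_trajectory"))
  if (!all(traj$valid)) {
    stop("trajectory contains invalid frames; run interpolate_gaps() first")
  }
  if (nrow(traj) < 2) stop("need at least 2 frames to categorize")
  cx <- traj$x + traj$w / 2
  cy <- traj$y + traj$h / 2
  dx <- diff(cx)
  if (mirror_x) dx <- -dx
  dy <- diff(cy)
  codes <- classify_step(dx, dy, system = system, eps = eps)
  categorical_series(codes, fps = attr(traj, "fps"), system = system,
                     dyad_id = dyad_id, role = role)
}

#' Collapse detailed codes to the simple system
#'
#' Deterministic surjection: detailed codes 4/5/6 (any rightward
#' component) map to simple 1, codes 2/1/8 (leftward) to simple 2, and
#' codes 0/3/7 (no horizontal component) to simple 0.
#'
#' @param codes integer vector of detailed-system codes.
#' @return integer vector of simple-system codes.
#' @export
simple_from_detailed <- function(codes) {
  stopifnot(all(codes %in% 0:8))
  map <- c(0L, 2L, 2L, 0L, 1L, 1L, 1L, 0L, 2L)  # indexed by detailed code + 1
  map[codes + 1L]
}

#' Write a categorical series to CSV with JSON metadata
#'
#' Writes `frame,code` rows (frame = transition index, 0-based) plus a
#' `.json` sidecar recording system, eps, fps, role, and dyad id.
#'
#' @param series a [categorical_series()].
#' @param path output CSV path.
#' @param eps the dead-zone used during categorization (metadata only).
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, eps = 0) {
  df <- data.frame(frame = seq_along(series$codes) - 1L, code = series$codes)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(system = series$system$name, eps = eps, fps = series$fps,
               role = series$role, dyad_id = series$dyad_id)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
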