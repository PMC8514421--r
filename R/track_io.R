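#' A digitized point track for one chelicera in one strike
#'
#' Container for the raw digitized series: one planar pixel coordinate per
#' digitized frame for the distal cheliceral edge, plus the calibration
#' metadata needed downstream (frame rate, mm-per-pixel scale, cheliceral
#' length). Times are re-zeroed so the first digitized frame of the strike
#' is t = 0; the time of digitized frame k is (k - k0)/fps.
#'
#' @param specimen_id,strike_id Identifiers.
#' @param side `"L"`, `"R"`, or `"body"` (the latter for body reference
#'   series used in drift removal).
#' @param frame_index Integer 0-based frame indices, strictly increasing.
#' @param times Times in seconds, strictly increasing and consistent with
#'   `frame_index / fps` to within 1e-9 s. If `NULL`, computed from
#'   `frame_index` and `fps`.
#' @param x_px,y_px Pixel coordinates of the tracked point.
#' @param fps Frame rate, frames per second.
#' @param scale_mm_per_px Spatial calibration, mm per pixel.
#' @param cheliceral_length_mm Cheliceral length L, mm.
#' @param sex Optional specimen sex.
#' @return An object of class `tracked_strike`.
#' @export
tracked_strike <- function(specimen_id, strike_id, side, frame_index,
                           times = NULL, x_px, y_px, fps, scale_mm_per_px,
                           cheliceral_length_mm, sex = NA_character_) {
  side <- as.character(side)
  if (!side %in% c("L", "R", "body")) {
    stop("unknown side code '", side, "' (expected L, R, or body)")
  }
  frame_index <- as.integer(frame_index)
  n <- length(frame_index)
  if (n < 6L) stop("a tracked strike needs at least 6 digitized points, got ", n)
  if (any(diff(frame_index) <= 0)) {
    bad <- which(diff(frame_index) <= 0)[1] + 1L
    stop("frame_index must be strictly increasing; violation at row ", bad)
  }
  if (!(is.numeric(fps) && fps > 0)) stop("`fps` must be positive")
  if (!(is.numeric(scale_mm_per_px) && scale_mm_per_px > 0)) {
    stop("`scale_mm_per_px` must be positive")
  }
  if (!(is.numeric(cheliceral_length_mm) && cheliceral_length_mm > 0)) {
    stop("`cheliceral_length_mm` must be positive")
  }
  expected <- (frame_index - frame_index[1]) / fps
  if (is.null(times)) {
    times <- expected
  } else {
    times <- as.numeric(times)
    if (length(times) != n) stop("`times` and `frame_index` lengths differ")
    if (any(abs((times - times[1]) - expected) > 1e-9)) {
      bad <- which(abs((times - times[1]) - expected) > 1e-9)[1]
      stop("times inconsistent with frame_index/fps at row ", bad,
           " (tolerance 1e-9 s)")
    }
    times <- times - times[1]
  }
  if (length(x_px) != n || length(y_px) != n) {
    stop("coordinate vectors must match frame_index length")
  }
  structure(
    list(
      specimen_id = as.character(specimen_id),
      strike_id = as.character(strike_id), side = side,
      frame_index = frame_index, times = times,
      x_px = as.numeric(x_px), y_px = as.numeric(y_px),
      fps = fps, scale_mm_per_px = scale_mm_per_px,
      cheliceral_length_mm = cheliceral_length_mm, sex = sex
    ),
    class = "tracked_strike"
  )
}

#' @export
print.tracked_strike <- function(x, ...) {
  cat(sprintf(
    "<tracked_strike> %s / %s / side %s: %d points, %.4g s at %g fps (L = %g mm)\n",
    x$specimen_id, x$strike_id, x$side, length(x$times),
    max(x$times), x$fps, x$cheliceral_length_mm
  ))
  invisible(x)
}

#' Read digitized tracks from CSV
#'
#' Reads a track table with columns `specimen_id, strike_id, side,
#' frame_index, time_s, x_px, y_px` and splits it into one
#' [tracked_strike()] per (specimen, strike, side) group. Validation is
#' total: missing columns, unknown side codes, non-monotone or duplicated
#' frames, and groups with fewer than 6 points all raise errors naming the
#' offending row or group.
#'
#' @param path CSV file path.
#' @param config Either a list with elements `fps`, `scale_mm_per_px`,
#'   `cheliceral_length_mm` (and optionally `sex`), or the path to a YAML
#'   file holding them (as written by [write_strike_fixture()]).
#' @param sides Allowed side codes; defaults to `c("L", "R")`. Use
#'   `"body"` when reading a drift-reference series.
#' @return A named list of `tracked_strike` objects, keyed
#'   `"specimen/strike/side"`.
#' @export
read_tracks <- function(path, config, sides = c("L", "R")) {
  if (!file.exists(path)) stop("track file not found: ", path)
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  needed_cfg <- c("fps", "scale_mm_per_px", "cheliceral_length_mm")
  miss <- setdiff(needed_cfg, names(config))
  if (length(miss)) stop("config is missing: ", paste(miss, collapse = ", "))

  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("specimen_id", "strike_id", "side", "frame_index",
              "time_s", "x_px", "y_px")
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    stop("track CSV is missing column(s): ", paste(miss, collapse = ", "))
  }
  bad_side <- which(!df$side %in% sides)
  if (length(bad_side)) {
    stop("unknown side code '", df$side[bad_side[1]], "' at row ",
         bad_side[1], " of ", path)
  }
  key <- interaction(df$specimen_id, df$strike_id, df$side,
                     sep = "/", drop = TRUE)
  out <- lapply(split(df, key), function(g) {
    g <- g[order(g$frame_index), , drop = FALSE]
    if (anyDuplicated(g$frame_index)) {
      dup <- g$frame_index[duplicated(g$frame_index)][1]
      stop("duplicated frame_index ", dup, " in group ",
           g$specimen_id[1], "/", g$strike_id[1], "/", g$side[1])
    }
    tracked_strike(
      specimen_id = g$specimen_id[1], strike_id = g$strike_id[1],
      side = g$side[1], frame_index = g$frame_index, times = g$time_s,
      x_px = g$x_px, y_px = g$y_px, fps = config$fps,
      scale_mm_per_px = config$scale_mm_per_px,
      cheliceral_length_mm = config$cheliceral_length_mm,
      sex = if (!is.null(config$sex)) config$sex else NA_character_
    )
  })
  out[order(names(out))]
}

#' Convert a pixel track to millimetres
#'
#' Multiplies pixel coordinates by the mm-per-pixel scale, yielding the
#' calibrated planar trajectory of the tracked point. Calibrating an
#' already-calibrated trajectory is an error (the operation is not
#' idempotent in units).
#'
#' @param track A [tracked_strike()].
#' @return An object of class `calibrated_trajectory`: list with `times`
#'   (s), `x_mm`, `y_mm`, `cheliceral_length_mm`, identifiers, and a
#'   `drift_corrected` provenance flag inherited from the track.
#' @export
calibrate <- function(track) {
  if (inherits(track, "calibrated_trajectory")) {
    stop("trajectory is already calibrated to mm; refusing to rescale")
  }
  stopifnot(inherits(track, "tracked_strike"))
  s <- track$scale_mm_per_px
  if (!(is.numeric(s) && s > 0)) stop("non-positive mm-per-pixel scale")
  structure(
    list(
      specimen_id = track$specimen_id, strike_id = track$strike_id,
      side = track$side, times = track$times,
      x_mm = track$x_px * s, y_mm = track$y_px * s,
      cheliceral_length_mm = track$cheliceral_length_mm,
      drift_corrected = isTRUE(attr(track, "drift_corrected")),
      sex = track$sex
    ),
    class = "calibrated_trajectory"
  )
}

#' Subtract a body reference series from a track
#'
#' Point-series equivalent of image stabilization: removes whole-body
#' translation (the lunge) by subtracting a tracked body reference point
#' frame-wise, isolating cheliceral rotation about the pivot. The
#' reference must be digitized at the same times as the track.
#'
#' @param track A [tracked_strike()].
#' @param reference A `tracked_strike` (any side code, typically
#'   `"body"`) sampled at the same times.
#' @return A `tracked_strike` with coordinates expressed relative to the
#'   reference point, flagged with attribute `drift_corrected = TRUE`.
#' @export
remove_drift <- function(track, reference) {
  stopifnot(inherits(track, "tracked_strike"),
            inherits(reference, "tracked_strike"))
  if (length(track$times) != length(reference$times) ||
      any(abs(track$times - reference$times) > 1e-9)) {
    stop("reference series times do not match the track times")
  }
  out <- tracked_strike(
    specimen_id = track$specimen_id, strike_id = track$strike_id,
    side = track$side, frame_index = track$frame_index, times = track$times,
    x_px = track$x_px - reference$x_px,
    y_px = track$y_px - reference$y_px,
    fps = track$fps, scale_mm_per_px = track$scale_mm_per_px,
    cheliceral_length_mm = track$cheliceral_length_mm, sex = track$sex
  )
  attr(out, "drift_corrected") <- TRUE
  out
}

#' Infer the mm-per-pixel scale from the tracked arc radius
#'
#' Optional helper for footage without a calibration target: assumes pure
#' rotation, fits a circle to the pixel track by linear least squares
#' (Kasa fit) and equates the fitted radius with the known cheliceral
#' length. Off the main path by design — it is invalid if body translation
#' was not removed first.
#'
#' @param track A [tracked_strike()].
#' @return The inferred scale, mm per pixel.
#' @export
infer_scale <- function(track) {
  stopifnot(inherits(track, "tracked_strike"))
  x <- track$x_px
  y <- track$y_px
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- stats::lm.fit(A, b)$coefficients
  r_px <- sqrt(sol[3] + sol[1]^2 + sol[2]^2)
  if (!is.finite(r_px) || r_px <= 0) stop("circle fit failed; cannot infer scale")
  unname(track$cheliceral_length_mm / r_px)
}

#' Write per-strike results or species summaries as annotated CSV
#'
#' Writes a data frame to CSV preceded by `#`-prefixed comment lines
#' naming the units of each column. Read back with
#' `read.csv(path, comment.char = "#")`.
#'
#' @param df A data frame.
#' @param path Output file.
#' @param units Optional named character vector mapping column names to
#'   unit strings.
#' @return Invisibly, `path`.
#' @export
write_results_csv <- function(df, path, units = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(units)) {
    for (nm in names(units)) {
      writeLines(sprintf("# %s: %s", nm, units[[nm]]), con)
    }
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
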