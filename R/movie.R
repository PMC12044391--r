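#' Labeled movie container
#'
#' A `labeled_movie` is an ordered list of per-frame integer label images
#' (0 = background, k > 0 = cell k) together with the physical calibration:
#' pixel size in micrometres per pixel and the frame interval in minutes.
#' Pixel coordinates are 0-based (row, col); the physical frame is
#' x = col * pixel_size, y = row * pixel_size with y increasing downward.
#'
#' @param frames List of integer matrices, all the same dimensions.
#' @param pixel_size Micrometres per pixel, > 0.
#' @param dt Frame interval in minutes, > 0.
#' @return An object of class `labeled_movie`.
#' @export
labeled_movie <- function(frames, pixel_size, dt) {
  stopifnot(is.list(frames), length(frames) >= 1,
            pixel_size > 0, dt > 0)
  dims <- lapply(frames, dim)
  if (length(unique(dims)) != 1) stop("all frames must have the same shape")
  frames <- lapply(frames, function(f) {
    if (any(f < 0)) stop("labels must be non-negative")
    storage.mode(f) <- "integer"
    f
  })
  structure(list(frames = frames, pixel_size = pixel_size, dt = dt),
            class = "labeled_movie")
}

#' @export
print.labeled_movie <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<labeled_movie> %d frames of %dx%d px, %.3g um/px, dt = %g min\n",
    length(x$frames), d[1], d[2], x$pixel_size, x$dt))
  invisible(x)
}

#' @export
length.labeled_movie <- function(x) length(x$frames)

#' Electric-field schedule
#'
#' Describes when a direct-current field is applied and in which direction,
#' as a set of ordered, non-overlapping `[t_on, t_off)` intervals in minutes
#' with a unit direction each. The default mirrors a classic reversal
#' protocol: field off for the first hour, rightward (+x) from 1 h to 3 h,
#' leftward from 3 h to 5 h.
#'
#' @param t_on,t_off Numeric vectors of interval starts/ends, minutes.
#' @param ex,ey Components of the field direction per interval; normalized
#'   to unit length.
#' @return A tibble of class `field_schedule` with columns
#'   `t_on, t_off, ex, ey`.
#' @export
field_schedule <- function(t_on = c(60, 180), t_off = c(180, 300),
                           ex = c(1, -1), ey = c(0, 0)) {
  stopifnot(length(t_on) == length(t_off),
            length(ex) == length(t_on), length(ey) == length(t_on))
  if (length(t_on)) {
    stopifnot(all(t_off > t_on))
    o <- order(t_on)
    t_on <- t_on[o]; t_off <- t_off[o]; ex <- ex[o]; ey <- ey[o]
    if (length(t_on) > 1 && any(t_on[-1] < t_off[-length(t_off)]))
      stop("field intervals must not overlap")
    nrm <- sqrt(ex^2 + ey^2)
    if (any(nrm == 0)) stop("field direction must be nonzero")
    ex <- ex / nrm; ey <- ey / nrm
  }
  structure(
    tibble::tibble(t_on = t_on, t_off = t_off, ex = ex, ey = ey),
    class = c("field_schedule", "tbl_df", "tbl", "data.frame")
  )
}

#' Field direction at given times
#'
#' @param schedule A [field_schedule()].
#' @param t_min Numeric vector of times, minutes.
#' @return Tibble with columns `on` (logical), `ex`, `ey` (`NA` when off),
#'   one row per time.
#' @export
field_at <- function(schedule, t_min) {
  on <- rep(FALSE, length(t_min))
  ex <- rep(NA_real_, length(t_min))
  ey <- rep(NA_real_, length(t_min))
  for (k in seq_len(nrow(schedule))) {
    hit <- t_min >= schedule$t_on[k] & t_min < schedule$t_off[k]
    on[hit] <- TRUE
    ex[hit] <- schedule$ex[k]
    ey[hit] <- schedule$ey[k]
  }
  tibble::tibble(on = on, ex = ex, ey = ey)
}

#' Time of field reversal
#'
#' The first boundary between two consecutive "on" intervals whose
#' directions differ (dot product < 1), i.e. where the field flips.
#'
#' @param schedule A [field_schedule()].
#' @return Time in minutes, or `NA` if the schedule contains no reversal.
#' @export
reversal_time <- function(schedule) {
  n <- nrow(schedule)
  if (n < 2) return(NA_real_)
  for (k in seq_len(n - 1)) {
    contiguous <- isTRUE(all.equal(schedule$t_off[k], schedule$t_on[k + 1]))
    d <- schedule$ex[k] * schedule$ex[k + 1] + schedule$ey[k] * schedule$ey[k + 1]
    if (contiguous && d < 1 - 1e-9) return(schedule$t_on[k + 1])
  }
  NA_real_
}

#' Read / write labeled movies as multi-page TIFF
#'
#' Labels are stored as 16-bit grayscale pages, one frame per page. Since
#' the TIFF container carries no calibration, `pixel_size` and `dt` must be
#' supplied on read.
#'
#' @param movie A [labeled_movie()].
#' @param path File path.
#' @param pixel_size,dt Calibration for the movie being read.
#' @return `read_label_movie` returns a [labeled_movie()];
#'   `write_label_movie` returns `path` invisibly.
#' @export
write_label_movie <- function(movie, path) {
  pages <- lapply(movie$frames, function(f) {
    if (max(f) > 65535L) stop("labels exceed 16-bit range")
    f / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_label_movie
#' @export
read_label_movie <- function(path, pixel_size, dt) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  labeled_movie(pages, pixel_size = pixel_size, dt = dt)
}
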