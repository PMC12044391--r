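#' Per-cell shape and position states from a labeled movie
#'
#' Extracts, for every (cell, frame), the centroid, area, and
#' moment-equivalent ellipse fit. Frames are numbered from 0; time in
#' minutes is `frame * dt`.
#'
#' @param movie A [labeled_movie()].
#' @return A tibble (one row per cell per frame) with columns `cell_id`,
#'   `frame`, `x_um`, `y_um`, `area_um2`, `ellipse_a_um`, `ellipse_b_um`,
#'   `ellipse_theta_rad`, `aspect_ratio` (b/a, in (0, 1]) and `degenerate`.
#' @export
cell_states <- function(movie) {
  ps <- movie$pixel_size
  per_frame <- purrr::imap(movie$frames, function(lab, idx) {
    idxs <- which(lab > 0L)
    if (!length(idxs)) return(NULL)
    nr <- nrow(lab)
    rows <- (idxs - 1L) %% nr          # 0-based row
    cols <- (idxs - 1L) %/% nr         # 0-based col
    labs <- lab[idxs]
    purrr::map_dfr(split(seq_along(labs), labs), function(ii) {
      px <- cbind(rows[ii], cols[ii])
      e <- suppressWarnings(fit_ellipse(px, ps))
      tibble::tibble(
        cell_id = labs[ii[1]],
        frame = idx - 1L,
        x_um = e$cx, y_um = e$cy,
        area_um2 = length(ii) * ps^2,
        ellipse_a_um = e$a, ellipse_b_um = e$b,
        ellipse_theta_rad = e$theta,
        aspect_ratio = e$b / e$a,
        degenerate = e$degenerate
      )
    })
  })
  out <- dplyr::bind_rows(per_frame)
  if (nrow(out) == 0) {
    return(tibble::tibble(
      cell_id = integer(), frame = integer(), x_um = double(),
      y_um = double(), area_um2 = double(), ellipse_a_um = double(),
      ellipse_b_um = double(), ellipse_theta_rad = double(),
      aspect_ratio = double(), degenerate = logical()))
  }
  dplyr::arrange(out, .data$frame, .data$cell_id)
}

#' Attach forward-difference velocities to a track table
#'
#' The velocity at frame t is the forward difference
#' `(x(t + dt) - x(t)) / dt`, converted to micrometres per hour, so the
#' velocity is defined at every frame except a track's last observed one.
#' By default a gap in a track (missing frames) leaves the velocity
#' undefined on its near side; with `allow_gaps = TRUE` the difference is
#' taken across the gap and divided by the true elapsed time.
#'
#' @param tracks Track table with `cell_id`, `frame`, `x_um`, `y_um`.
#' @param dt Frame interval, minutes.
#' @param allow_gaps Span gaps longer than one frame (default `FALSE`).
#' @return The track table with `vx_umh`, `vy_umh`, `speed_umh` columns
#'   (`NA` where undefined).
#' @export
compute_velocities <- function(tracks, dt, allow_gaps = FALSE) {
  stopifnot(dt > 0)
  tracks |>
    dplyr::arrange(.data$cell_id, .data$frame) |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::mutate(
      .gap = dplyr::lead(.data$frame) - .data$frame,
      .ok = !is.na(.data$.gap) & (if (allow_gaps) TRUE else .data$.gap == 1L),
      vx_umh = ifelse(.data$.ok,
                      (dplyr::lead(.data$x_um) - .data$x_um) /
                        (.data$.gap * dt) * 60, NA_real_),
      vy_umh = ifelse(.data$.ok,
                      (dplyr::lead(.data$y_um) - .data$y_um) /
                        (.data$.gap * dt) * 60, NA_real_),
      speed_umh = sqrt(.data$vx_umh^2 + .data$vy_umh^2)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".gap", -".ok")
}

#' Directionality of migration with respect to the field
#'
#' The directionality is the population mean of cos(theta_i), where theta_i
#' is the angle between cell i's velocity and the field direction:
#' 1 when every cell moves with the field, 0 for isotropic motion. Cells
#' with zero or undefined velocity are excluded (the cosine is undefined).
#'
#' @param tracks Track table with velocities (see [compute_velocities()]).
#' @param schedule A [field_schedule()].
#' @param dt Frame interval, minutes.
#' @param frames Frames to evaluate; default all frames present.
#' @return A tibble per frame: `frame`, `t_min`, `n` (cells contributing),
#'   `phi` (directionality, `NA` when the field is off or no cell
#'   qualifies), `mean_vx`, `mean_vy`, `mean_speed` (over the same cells).
#' @export
directionality <- function(tracks, schedule, dt, frames = NULL) {
  if (is.null(frames)) frames <- sort(unique(tracks$frame))
  fld <- field_at(schedule, frames * dt)
  eligible <- tracks |>
    dplyr::filter(!is.na(.data$vx_umh), .data$speed_umh > 0,
                  .data$frame %in% frames)
  stats <- eligible |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_vx = mean(.data$vx_umh),
      mean_vy = mean(.data$vy_umh),
      mean_speed = mean(.data$speed_umh),
      .sum_cos_x = sum(.data$vx_umh / .data$speed_umh),
      .sum_cos_y = sum(.data$vy_umh / .data$speed_umh),
      .groups = "drop"
    )
  out <- tibble::tibble(frame = frames, t_min = frames * dt,
                        on = fld$on, ex = fld$ex, ey = fld$ey) |>
    dplyr::left_join(stats, by = "frame") |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      phi = ifelse(.data$on & .data$n > 0,
                   (.data$ex * .data$.sum_cos_x +
                      .data$ey * .data$.sum_cos_y) / .data$n,
                   NA_real_)
    ) |>
    dplyr::select("frame", "t_min", "n", "phi",
                  "mean_vx", "mean_vy", "mean_speed")
  out
}

#' Compare perpendicular velocities before and after field reversal
#'
#' Collects per-cell per-frame velocity components perpendicular to the
#' field (vy for a field along x) in symmetric windows before and after the
#' scheduled field reversal, and tests the two distributions with a
#' two-sided Mann-Whitney U test. An unchanged vy distribution across the
#' reversal indicates near-instantaneous repolarization rather than slow
#' U-turning.
#'
#' @param tracks Track table with velocities.
#' @param schedule A [field_schedule()] containing a reversal.
#' @param dt Frame interval, minutes.
#' @param window Half-window length in minutes; default `NULL` uses the two
#'   full field-on half-experiments.
#' @return An object of class `reversal_comparison`: a list with `samples`
#'   (tibble of `t_min`, `vy_umh`, `period` pre/post), `t_reversal`, and the
#'   Mann-Whitney `statistic` and `p_value`.
#' @export
reversal_comparison <- function(tracks, schedule, dt, window = NULL) {
  t_rev <- reversal_time(schedule)
  if (is.na(t_rev)) stop("schedule contains no field reversal")
  if (is.null(window)) {
    k <- which(abs(schedule$t_on - t_rev) < 1e-9)
    lo <- schedule$t_on[k - 1]
    hi <- schedule$t_off[k]
  } else {
    lo <- t_rev - window
    hi <- t_rev + window
  }
  smp <- tracks |>
    dplyr::filter(!is.na(.data$vy_umh)) |>
    dplyr::mutate(t_min = .data$frame * dt) |>
    dplyr::filter(.data$t_min >= lo, .data$t_min < hi) |>
    dplyr::mutate(period = ifelse(.data$t_min < t_rev, "pre", "post")) |>
    dplyr::select("cell_id", "frame", "t_min", "vy_umh", "period")
  if (!any(smp$period == "pre") || !any(smp$period == "post"))
    stop("empty window on one side of the reversal")
  tst <- two_sample_test(smp$vy_umh[smp$period == "pre"],
                         smp$vy_umh[smp$period == "post"])
  structure(
    list(samples = smp, t_reversal = t_rev,
         statistic = tst$statistic, p_value = tst$p_value),
    class = "reversal_comparison"
  )
}

#' @export
print.reversal_comparison <- function(x, ...) {
  n <- table(x$samples$period)
  cat(sprintf(
    "<reversal_comparison> reversal at %g min; n_pre = %d, n_post = %d\n  Mann-Whitney U = %g, two-sided p = %.3g\n",
    x$t_reversal, n[["pre"]], n[["post"]], x$statistic, x$p_value))
  invisible(x)
}

#' Binned mean speed against cell morphology
#'
#' Bins cells by aspect ratio (short/long axis) and by area, reporting the
#' mean, standard deviation, and count of speeds per bin. Empty bins are
#' omitted.
#'
#' @param tracks Track table with speeds and ellipse fits.
#' @param ar_bins,area_bins Bin edges (strictly increasing). Defaults: 10
#'   equal bins on (0, 1] for aspect ratio; 10 equal-width bins over the
#'   observed area range.
#' @return A tibble with columns `variable` ("aspect_ratio" or "area_um2"),
#'   `bin_lo`, `bin_hi`, `bin_mid`, `n`, `mean_speed`, `sd_speed`.
#' @export
morphology_speed_curves <- function(tracks, ar_bins = seq(0, 1, by = 0.1),
                                    area_bins = NULL) {
  ok <- dplyr::filter(tracks, !is.na(.data$speed_umh))
  if (is.null(area_bins)) {
    rng <- range(ok$area_um2)
    area_bins <- seq(rng[1], rng[2] + 1e-9, length.out = 11)
  }
  for (edges in list(ar_bins, area_bins)) {
    if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  }
  bin_one <- function(x, speed, edges, name) {
    idx <- findInterval(x, edges, rightmost.closed = TRUE)
    keep <- idx >= 1 & idx <= length(edges) - 1
    tibble::tibble(idx = idx[keep], speed = speed[keep]) |>
      dplyr::group_by(.data$idx) |>
      dplyr::summarise(n = dplyr::n(), mean_speed = mean(.data$speed),
                       sd_speed = stats::sd(.data$speed), .groups = "drop") |>
      dplyr::mutate(variable = name,
                    bin_lo = edges[.data$idx], bin_hi = edges[.data$idx + 1],
                    bin_mid = (.data$bin_lo + .data$bin_hi) / 2) |>
      dplyr::select("variable", "bin_lo", "bin_hi", "bin_mid",
                    "n", "mean_speed", "sd_speed")
  }
  dplyr::bind_rows(
    bin_one(ok$aspect_ratio, ok$speed_umh, ar_bins, "aspect_ratio"),
    bin_one(ok$area_um2, ok$speed_umh, area_bins, "area_um2")
  )
}
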