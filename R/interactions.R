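#' Contact inhibition of locomotion metric
#'
#' The CIL of cell i with respect to cell j at time t is the cosine between
#' the direction of cell i's velocity change over one frame and the
#' direction pointing from j's centroid to i's centroid:
#'
#'   CIL_ij(t) = unit(v_i(t + dt) - v_i(t)) . unit(x_i(t) - x_j(t))
#'
#' A value of 1 means cell i accelerated directly away from its neighbour
#' (classic contact inhibition of locomotion); -1 means directly toward it.
#'
#' @param v_i_t,v_i_next Focal-cell velocity at t and t + dt (length-2).
#' @param x_i,x_j Centroids of the focal and neighbour cells at t.
#' @return Value in `[-1, 1]`, or `NA` (with a warning suppressed by
#'   callers) when the velocity change is zero or the centroids coincide —
#'   the metric normalizes by both magnitudes and is undefined there.
#' @export
cil <- function(v_i_t, v_i_next, x_i, x_j) {
  dv <- v_i_next - v_i_t
  dx <- x_i - x_j
  ndv <- sqrt(sum(dv^2))
  ndx <- sqrt(sum(dx^2))
  if (ndv == 0 || ndx == 0) return(NA_real_)
  sum(dv * dx) / (ndv * ndx)
}

#' Velocity alignment metric
#'
#' The change in cosine similarity of two cells' velocities across one
#' frame of contact:
#'
#'   alignment_ij(t) = ( cos angle(v_i(t+dt), v_j(t+dt))
#'                     - cos angle(v_i(t),   v_j(t)) ) / 2
#'
#' 1 indicates a pair that went from perfectly anti-aligned to perfectly
#' aligned over the contact; -1 the reverse. Symmetric in (i, j).
#'
#' @param v_i_t,v_i_next,v_j_t,v_j_next The two cells' velocities at t and
#'   t + dt (length-2 each); all four must be nonzero.
#' @return Value in `[-1, 1]`, or `NA` when any velocity is zero.
#' @export
alignment <- function(v_i_t, v_i_next, v_j_t, v_j_next) {
  n1 <- sqrt(sum(v_i_t^2)); n2 <- sqrt(sum(v_i_next^2))
  n3 <- sqrt(sum(v_j_t^2)); n4 <- sqrt(sum(v_j_next^2))
  if (n1 == 0 || n2 == 0 || n3 == 0 || n4 == 0) return(NA_real_)
  (sum(v_i_next * v_j_next) / (n2 * n4) -
      sum(v_i_t * v_j_t) / (n1 * n3)) / 2
}

#' Build per-contact interaction samples
#'
#' For every oriented contact (focal, neighbour) at frame t where both
#' cells have defined velocities at t and t + dt, computes one sample with
#' the CIL and alignment metrics, the contact angle phi on the focal cell,
#' both speeds, and the field condition. Because interactions need not be
#' reciprocal, each physical contact contributes two samples, one per role
#' assignment.
#'
#' By default samples are restricted to pairwise contacts — frames where
#' each of the two cells touches no other cell — since the metrics are
#' defined for a pair; larger clusters contribute to cluster statistics
#' only.
#'
#' @param tracks Track table with velocities.
#' @param contacts Localized contacts (see [localize_contacts()]).
#' @param schedule A [field_schedule()].
#' @param dt Frame interval, minutes.
#' @param pairwise_only Restrict to two-cell clusters (default `TRUE`).
#' @return A tibble of samples: `frame`, `focal_id`, `neighbor_id`,
#'   `is_onset` (`TRUE` on the first frame of the pair's contact run —
#'   event-level summaries use these rows, since the response to a
#'   collision is expressed across the onset frame),
#'   `phi_rad`, `cil`, `alignment`, `cil_valid`, `alignment_valid`,
#'   `focal_speed_umh`, `neighbor_speed_umh`, `condition`
#'   ("control"/"field_on"). Attribute `drop_counts` reconciles the
#'   oriented contacts that produced no sample, by reason.
#' @export
build_interaction_samples <- function(tracks, contacts, schedule, dt,
                                      pairwise_only = TRUE) {
  n0 <- nrow(contacts)
  dropped <- c(nonpairwise = 0L, missing_kinematics = 0L)
  ct <- contacts
  if (n0) {
    # onset = first frame of the pair's contact run (no contact at frame - 1)
    pa <- pmin(ct$focal_id, ct$neighbor_id)
    pb <- pmax(ct$focal_id, ct$neighbor_id)
    keys <- paste(pa, pb, ct$frame)
    ct$is_onset <- !(paste(pa, pb, ct$frame - 1L) %in% keys)
  }
  if (pairwise_only && n0) {
    deg <- ct |>
      dplyr::count(.data$frame, .data$focal_id, name = "degree")
    ct <- ct |>
      dplyr::left_join(deg, by = c("frame", "focal_id")) |>
      dplyr::left_join(deg, by = c("frame", neighbor_id = "focal_id"),
                       suffix = c("", "_nb"))
    keep <- ct$degree == 1L & ct$degree_nb == 1L
    dropped["nonpairwise"] <- sum(!keep)
    ct <- ct[keep, setdiff(names(ct), c("degree", "degree_nb"))]
  }
  kin <- dplyr::select(tracks, "cell_id", "frame", "x_um", "y_um",
                       "vx_umh", "vy_umh", "speed_umh")
  kin_next <- dplyr::transmute(kin, .data$cell_id, frame = .data$frame - 1L,
                               vx1 = .data$vx_umh, vy1 = .data$vy_umh)
  smp <- ct |>
    dplyr::left_join(kin, by = c(focal_id = "cell_id", "frame")) |>
    dplyr::left_join(kin_next, by = c(focal_id = "cell_id", "frame")) |>
    dplyr::left_join(kin, by = c(neighbor_id = "cell_id", "frame"),
                     suffix = c("", "_j")) |>
    dplyr::left_join(
      dplyr::rename(kin_next, vx1_j = "vx1", vy1_j = "vy1"),
      by = c(neighbor_id = "cell_id", "frame"))
  have_kin <- !(is.na(smp$vx_umh) | is.na(smp$vx1) |
                  is.na(smp$vx_umh_j) | is.na(smp$vx1_j))
  dropped["missing_kinematics"] <- sum(!have_kin)
  smp <- smp[have_kin, , drop = FALSE]

  dvx <- smp$vx1 - smp$vx_umh
  dvy <- smp$vy1 - smp$vy_umh
  dxx <- smp$x_um - smp$x_um_j
  dxy <- smp$y_um - smp$y_um_j
  ndv <- sqrt(dvx^2 + dvy^2)
  ndx <- sqrt(dxx^2 + dxy^2)
  cil_valid <- ndv > 0 & ndx > 0
  cil_val <- ifelse(cil_valid, (dvx * dxx + dvy * dxy) / (ndv * ndx), NA_real_)

  n_i0 <- smp$speed_umh
  n_i1 <- sqrt(smp$vx1^2 + smp$vy1^2)
  n_j0 <- smp$speed_umh_j
  n_j1 <- sqrt(smp$vx1_j^2 + smp$vy1_j^2)
  al_valid <- n_i0 > 0 & n_i1 > 0 & n_j0 > 0 & n_j1 > 0
  al_val <- ifelse(
    al_valid,
    ((smp$vx1 * smp$vx1_j + smp$vy1 * smp$vy1_j) / (n_i1 * n_j1) -
       (smp$vx_umh * smp$vx_umh_j + smp$vy_umh * smp$vy_umh_j) /
         (n_i0 * n_j0)) / 2,
    NA_real_)

  cond <- ifelse(field_at(schedule, smp$frame * dt)$on, "field_on", "control")
  out <- tibble::tibble(
    frame = smp$frame,
    focal_id = smp$focal_id,
    neighbor_id = smp$neighbor_id,
    is_onset = smp$is_onset,
    phi_rad = smp$phi_rad,
    cil = cil_val,
    alignment = al_val,
    cil_valid = cil_valid,
    alignment_valid = al_valid,
    focal_speed_umh = n_i0,
    neighbor_speed_umh = n_j0,
    condition = cond
  )
  attr(out, "drop_counts") <- dropped
  attr(out, "n_oriented_contacts") <- n0
  out
}

#' Four-way behaviour classification from mean CIL and alignment
#'
#' Labels a (mean CIL, mean alignment) pair by sign with a dead zone tau:
#' both metrics within the dead zone is "neutral"; otherwise positive CIL
#' reads "repel" (the cell accelerates away from the contact) versus
#' "stick", and positive alignment reads "align" versus "scatter". The
#' label wording is configuration, not code: pass `mapping` to rename the
#' four quadrants.
#'
#' @param mean_cil,mean_alignment Numeric vectors of grid-cell means.
#' @param tau Dead-zone half-width (default 0.1).
#' @param mapping Named character vector with names `repel.align`,
#'   `repel.scatter`, `stick.align`, `stick.scatter`.
#' @return Character vector of labels.
#' @export
classify_behavior <- function(mean_cil, mean_alignment, tau = 0.1,
                              mapping = c(
                                repel.align = "repel and align",
                                repel.scatter = "repel and scatter",
                                stick.align = "stick and align",
                                stick.scatter = "stick and scatter")) {
  stopifnot(all(c("repel.align", "repel.scatter", "stick.align",
                  "stick.scatter") %in% names(mapping)))
  w1 <- ifelse(mean_cil > tau, "repel", "stick")
  # alignment dead zone: small values fall to the sign side
  w2 <- ifelse(mean_alignment > tau, "align",
               ifelse(mean_alignment < -tau, "scatter",
                      ifelse(mean_alignment >= 0, "align", "scatter")))
  lab <- unname(mapping[paste(w1, w2, sep = ".")])
  lab[abs(mean_cil) <= tau & abs(mean_alignment) <= tau] <- "neutral"
  lab[is.na(mean_cil) | is.na(mean_alignment)] <- NA_character_
  lab
}

#' Contact-position by neighbour-speed response map
#'
#' Aggregates interaction samples on a grid of contact angle phi (default 8
#' equal bins on `[0, pi]`) by neighbour-speed class. The default classes
#' follow the two-speed analysis: "slow" below `slow_max` (50 um/h) and
#' "fast" above `fast_min` (100 um/h), with intermediate speeds discarded;
#' pass numeric `speed_breaks` for continuous binning instead. Grid cells
#' with fewer than `n_min` valid samples carry no behaviour label.
#'
#' @param samples Interaction samples from [build_interaction_samples()].
#' @param phi_bins Number of equal phi bins on `[0, pi]`.
#' @param slow_max,fast_min Speed-class thresholds, um/h.
#' @param speed_breaks Optional numeric break points for continuous
#'   neighbour-speed bins (overrides the two-class scheme).
#' @param n_min Minimum valid samples for a behaviour label (default 5).
#' @param tau Dead zone passed to [classify_behavior()].
#' @param mapping Label mapping passed to [classify_behavior()].
#' @return An object of class `response_map`: list with `cells` (tibble of
#'   `phi_bin`, `phi_lo`, `phi_hi`, `speed_class`, `n`, `n_cil`, `n_alignment`,
#'   `mean_cil`, `mean_alignment`, `label`) and the binning configuration.
#' @export
response_map <- function(samples, phi_bins = 8, slow_max = 50, fast_min = 100,
                         speed_breaks = NULL, n_min = 5, tau = 0.1,
                         mapping = NULL) {
  edges <- seq(0, pi, length.out = phi_bins + 1)
  s <- dplyr::filter(samples, !is.na(.data$phi_rad))
  if (is.null(speed_breaks)) {
    s <- s |>
      dplyr::mutate(speed_class = dplyr::case_when(
        .data$neighbor_speed_umh < slow_max ~ "slow",
        .data$neighbor_speed_umh > fast_min ~ "fast",
        TRUE ~ NA_character_)) |>
      dplyr::filter(!is.na(.data$speed_class))
    classes <- c("slow", "fast")
  } else {
    idx <- findInterval(s$neighbor_speed_umh, speed_breaks,
                        rightmost.closed = TRUE)
    keep <- idx >= 1 & idx <= length(speed_breaks) - 1
    s <- s[keep, , drop = FALSE]
    s$speed_class <- sprintf("[%g,%g)", speed_breaks[idx[keep]],
                             speed_breaks[idx[keep] + 1])
    classes <- sprintf("[%g,%g)", speed_breaks[-length(speed_breaks)],
                       speed_breaks[-1])
  }
  s$phi_bin <- pmin(findInterval(s$phi_rad, edges, rightmost.closed = TRUE),
                    phi_bins)
  grid <- tidyr::expand_grid(phi_bin = seq_len(phi_bins),
                             speed_class = classes)
  agg <- s |>
    dplyr::group_by(.data$phi_bin, .data$speed_class) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_cil = sum(.data$cil_valid),
      n_alignment = sum(.data$alignment_valid),
      mean_cil = if (any(.data$cil_valid))
        mean(.data$cil[.data$cil_valid]) else NA_real_,
      mean_alignment = if (any(.data$alignment_valid))
        mean(.data$alignment[.data$alignment_valid]) else NA_real_,
      .groups = "drop")
  cells <- grid |>
    dplyr::left_join(agg, by = c("phi_bin", "speed_class")) |>
    dplyr::mutate(
      dplyr::across(c("n", "n_cil", "n_alignment"),
                    ~ dplyr::coalesce(.x, 0L)),
      phi_lo = edges[.data$phi_bin],
      phi_hi = edges[.data$phi_bin + 1],
      label = ifelse(
        pmin(.data$n_cil, .data$n_alignment) >= n_min,
        if (is.null(mapping)) classify_behavior(.data$mean_cil,
                                                .data$mean_alignment, tau)
        else classify_behavior(.data$mean_cil, .data$mean_alignment, tau,
                               mapping),
        NA_character_)) |>
    dplyr::relocate("phi_bin", "phi_lo", "phi_hi", "speed_class")
  structure(
    list(cells = cells, phi_edges = edges,
         speed_classes = classes,
         config = list(phi_bins = phi_bins, slow_max = slow_max,
                       fast_min = fast_min, speed_breaks = speed_breaks,
                       n_min = n_min, tau = tau)),
    class = "response_map")
}

#' @export
print.response_map <- function(x, ...) {
  cat(sprintf("<response_map> %d phi bins x %d speed classes, %d samples\n",
              x$config$phi_bins, length(x$speed_classes), sum(x$cells$n)))
  print(x$cells)
  invisible(x)
}
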