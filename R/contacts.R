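#' Detect cell-cell contacts from label adjacency
#'
#' Two cells are in contact wherever their masks have directly adjacent
#' pixels. With the default 8-connectivity a diagonal touch establishes a
#' contact, but the interface length counts only 4-adjacent pixel pairs
#' (times the pixel size), so the length of a straight shared edge of k
#' pixels is k * pixel_size. Every contact is reported in both orientations
#' (focal, neighbor) and (neighbor, focal).
#'
#' @param x An integer label matrix, or a [labeled_movie()] (in which case
#'   every frame is processed and a `frame` column added).
#' @param pixel_size Micrometres per pixel (taken from the movie when `x`
#'   is a [labeled_movie()]).
#' @param connectivity 8 (default) or 4; the adjacency that establishes
#'   contact existence.
#' @return A tibble with columns `focal_id`, `neighbor_id`, `n_pairs4`
#'   (4-adjacent pixel pairs), `interface_length_um`, `bx_um`, `by_um`
#'   (centroid of the focal-side boundary pixels, not yet projected onto
#'   the fitted ellipse; see [localize_contacts()]).
#' @export
detect_contacts <- function(x, pixel_size = NULL, connectivity = 8) {
  if (inherits(x, "labeled_movie")) {
    per <- purrr::imap(x$frames, function(lab, i) {
      ct <- detect_contacts(lab, x$pixel_size, connectivity)
      ct$frame <- rep(i - 1L, nrow(ct))
      ct
    })
    return(dplyr::relocate(dplyr::bind_rows(per), "frame"))
  }
  stopifnot(connectivity %in% c(4, 8), pixel_size > 0)
  lab <- x
  nr <- nrow(lab); nc <- ncol(lab)

  # adjacent pixel pairs via shifted comparisons; coords 0-based (row, col)
  shift_pairs <- function(dr, dc) {
    r1 <- seq_len(nr - abs(dr)) + max(0, -dr)
    c1 <- seq_len(nc - abs(dc)) + max(0, -dc)
    a <- lab[r1, c1, drop = FALSE]
    b <- lab[r1 + dr, c1 + dc, drop = FALSE]
    hit <- which(a > 0L & b > 0L & a != b)
    if (!length(hit)) return(NULL)
    hr <- (hit - 1L) %% nrow(a)
    hc <- (hit - 1L) %/% nrow(a)
    tibble::tibble(
      la = a[hit], lb = b[hit],
      ra = hr + max(0, -dr), ca = hc + max(0, -dc),
      rb = hr + max(0, -dr) + dr, cb = hc + max(0, -dc) + dc,
      four = (abs(dr) + abs(dc)) == 1L
    )
  }
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  pairs <- dplyr::bind_rows(purrr::map(offs, function(o) shift_pairs(o[1], o[2])))
  if (is.null(pairs) || nrow(pairs) == 0) {
    return(tibble::tibble(focal_id = integer(), neighbor_id = integer(),
                          n_pairs4 = integer(), interface_length_um = double(),
                          bx_um = double(), by_um = double()))
  }
  # both orientations
  both <- dplyr::bind_rows(
    pairs,
    dplyr::rename(pairs, la = "lb", lb = "la", ra = "rb", ca = "cb",
                  rb = "ra", cb = "ca")
  )
  both |>
    dplyr::group_by(focal_id = .data$la, neighbor_id = .data$lb) |>
    dplyr::summarise(
      n_pairs4 = sum(.data$four),
      interface_length_um = sum(.data$four) * pixel_size,
      bx_um = mean(.data$ca[!duplicated(cbind(.data$ra, .data$ca))]) * pixel_size,
      by_um = mean(.data$ra[!duplicated(cbind(.data$ra, .data$ca))]) * pixel_size,
      .groups = "drop"
    )
}

#' Localize contacts on the cell surface
#'
#' Projects each contact's focal-side boundary centroid onto the focal
#' cell's fitted ellipse and computes the contact angle phi between the
#' front of the cell (short axis signed by velocity) and the projected
#' site: 0 = front, pi/2 = side, pi = rear. phi is `NA` where the focal
#' velocity is undefined or zero.
#'
#' @param contacts Output of [detect_contacts()] on a movie (with `frame`).
#' @param tracks Track table with ellipse fits and velocities, keyed by
#'   (`cell_id`, `frame`).
#' @return `contacts` with added `contact_x_um`, `contact_y_um` (projected
#'   site) and `phi_rad`.
#' @export
localize_contacts <- function(contacts, tracks) {
  joined <- dplyr::left_join(
    contacts,
    dplyr::select(tracks, "cell_id", "frame", "x_um", "y_um",
                  "ellipse_a_um", "ellipse_b_um", "ellipse_theta_rad",
                  "vx_umh", "vy_umh"),
    by = c(focal_id = "cell_id", "frame")
  )
  res <- purrr::pmap(
    list(joined$bx_um, joined$by_um, joined$x_um, joined$y_um,
         joined$ellipse_a_um, joined$ellipse_b_um, joined$ellipse_theta_rad,
         joined$vx_umh, joined$vy_umh),
    function(bx, by, cx, cy, a, b, th, vx, vy) {
      if (is.na(cx) || is.na(a)) return(c(NA_real_, NA_real_, NA_real_))
      e <- ellipse_fit(cx, cy, a, b, th)
      q <- closest_point_on_ellipse(c(bx, by), e)
      phi <- if (is.na(vx) || (vx == 0 && vy == 0)) NA_real_
             else contact_angle(e, c(vx, vy), q)
      c(q[1], q[2], phi)
    }
  )
  m <- do.call(rbind, res)
  contacts$contact_x_um <- m[, 1]
  contacts$contact_y_um <- m[, 2]
  contacts$phi_rad <- m[, 3]
  contacts
}

#' Build contact events from per-frame contacts
#'
#' A contact event is a maximal run of consecutive frames during which an
#' unordered cell pair is in contact. Runs separated by at most
#' `gap_tolerance` missing frames are merged (default 0: a pair that
#' separates and re-touches starts a new event). The duration of an event
#' spanning frames `[s, e]` is `(e - s + 1) * dt`.
#'
#' @param contacts Per-frame contact tibble with `frame`, `focal_id`,
#'   `neighbor_id`.
#' @param dt Frame interval, minutes.
#' @param gap_tolerance Merge runs separated by up to this many missing
#'   frames.
#' @return A tibble: `cell_a`, `cell_b` (`cell_a < cell_b`), `start_frame`,
#'   `end_frame`, `duration_min`.
#' @export
build_events <- function(contacts, dt, gap_tolerance = 0) {
  if (nrow(contacts) == 0) {
    return(tibble::tibble(cell_a = integer(), cell_b = integer(),
                          start_frame = integer(), end_frame = integer(),
                          duration_min = double()))
  }
  contacts |>
    dplyr::transmute(
      cell_a = pmin(.data$focal_id, .data$neighbor_id),
      cell_b = pmax(.data$focal_id, .data$neighbor_id),
      frame = .data$frame
    ) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$cell_a, .data$cell_b, .data$frame) |>
    dplyr::group_by(.data$cell_a, .data$cell_b) |>
    dplyr::mutate(
      .new_run = c(TRUE, diff(.data$frame) > gap_tolerance + 1L),
      .run = cumsum(.data$.new_run)
    ) |>
    dplyr::group_by(.data$cell_a, .data$cell_b, .data$.run) |>
    dplyr::summarise(start_frame = min(.data$frame),
                     end_frame = max(.data$frame), .groups = "drop") |>
    dplyr::mutate(duration_min = (.data$end_frame - .data$start_frame + 1) * dt) |>
    dplyr::select(-".run") |>
    dplyr::arrange(.data$cell_a, .data$cell_b, .data$start_frame)
}

#' Find clusters of touching cells per frame
#'
#' Clusters are the connected components of the per-frame contact graph;
#' cells without contacts are size-1 clusters. The cluster speed is the
#' mean of the member speeds (members without a defined velocity are
#' excluded; if none has one the speed is `NA`).
#'
#' @param contacts Per-frame contacts (with `frame`).
#' @param tracks Track table giving the cells present per frame (and their
#'   speeds, if available).
#' @return A tibble: `frame`, `cluster_id` (within frame), `size`,
#'   `speed_umh`, `member_ids` (list-column of cell ids).
#' @export
find_clusters <- function(contacts, tracks) {
  has_speed <- "speed_umh" %in% names(tracks)
  frames <- sort(unique(tracks$frame))
  purrr::map_dfr(frames, function(f) {
    cells <- sort(unique(tracks$cell_id[tracks$frame == f]))
    if (!length(cells)) return(NULL)
    ed <- contacts[contacts$frame == f &
                     contacts$focal_id < contacts$neighbor_id, , drop = FALSE]
    g <- igraph::graph_from_data_frame(
      d = data.frame(from = as.character(ed$focal_id),
                     to = as.character(ed$neighbor_id)),
      directed = FALSE,
      vertices = data.frame(name = as.character(cells))
    )
    comp <- igraph::components(g)
    membership <- comp$membership[as.character(cells)]
    spd <- if (has_speed) {
      tracks$speed_umh[match(paste(cells, f), paste(tracks$cell_id, tracks$frame))]
    } else rep(NA_real_, length(cells))
    tibble::tibble(cell_id = cells, cluster_id = as.integer(membership),
                   speed = spd) |>
      dplyr::group_by(.data$cluster_id) |>
      dplyr::summarise(
        size = dplyr::n(),
        speed_umh = if (all(is.na(.data$speed))) NA_real_
                    else mean(.data$speed, na.rm = TRUE),
        member_ids = list(.data$cell_id),
        .groups = "drop"
      ) |>
      dplyr::mutate(frame = f) |>
      dplyr::relocate("frame")
  })
}

#' Compare cluster speeds between two conditions, per cluster size
#'
#' For each cluster size present in both conditions, reports the mean
#' cluster speed per condition, the percent difference of the means, and a
#' two-sided Mann-Whitney p value. Sizes present in only one condition are
#' omitted.
#'
#' @param clusters_a,clusters_b Cluster tables from [find_clusters()] for
#'   the two conditions.
#' @param sizes Cluster sizes to compare; default all sizes present in both.
#' @return A tibble: `size`, `n_a`, `n_b`, `mean_a`, `mean_b`,
#'   `pct_diff` (100 * (mean_b - mean_a) / mean_a), `p_value`.
#' @export
cluster_speed_comparison <- function(clusters_a, clusters_b, sizes = NULL) {
  a <- dplyr::filter(clusters_a, !is.na(.data$speed_umh))
  b <- dplyr::filter(clusters_b, !is.na(.data$speed_umh))
  if (is.null(sizes)) sizes <- sort(intersect(a$size, b$size))
  purrr::map_dfr(sizes, function(s) {
    sa <- a$speed_umh[a$size == s]
    sb <- b$speed_umh[b$size == s]
    if (!length(sa) || !length(sb)) return(NULL)
    tst <- two_sample_test(sa, sb)
    tibble::tibble(size = s, n_a = length(sa), n_b = length(sb),
                   mean_a = mean(sa), mean_b = mean(sb),
                   pct_diff = 100 * (mean(sb) - mean(sa)) / mean(sa),
                   p_value = tst$p_value)
  })
}
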