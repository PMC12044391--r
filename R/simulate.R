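#' Simulation configuration
#'
#' Parameters of the agent-based generator: persistent random walkers with
#' optional electrotactic bias, elliptical bodies (major axis perpendicular
#' to the polarity, as these cells move along their short axis), hard-core
#' exclusion, and tunable collision responses.
#'
#' Polarity update per step: the new polarity angle is drawn from the
#' von Mises density proportional to
#' `exp(kappa_p * cos(th - th_old) + kappa_e * cos(th - th_field))`
#' when the field is on (a von Mises product, itself von Mises), so
#' `kappa_e = 0` recovers an unbiased persistent walk and large `kappa_e`
#' slaves the polarity to the field.
#'
#' Two cells are interacting when their elliptical bodies come within one
#' pixel of each other (so their rasterized masks are adjacent), or when
#' their centre distance is below `interaction_radius_um` if that is set.
#' On contact
#' onset, with probability `p_cil` a cell repolarizes directly away from
#' its neighbour's centroid, and with probability `p_align` it starts
#' relaxing its polarity toward the neighbour's at rate `align_rate` per
#' frame while the contact lasts. A response triggered by a contact first
#' visible at frame s is expressed in the step from frame s + 1 to s + 2:
#' the cell completes its current stride before repolarizing, which is the
#' timing that the per-frame response metrics, evaluated at the onset
#' frame s, measure as the velocity change between v(s) and v(s + 1).
#'
#' @param n_cells Number of cells.
#' @param arena_um Side of the square arena, micrometres.
#' @param pixel_size_um Micrometres per pixel for rasterization.
#' @param dt_min Frame interval, minutes (default 5).
#' @param n_frames Number of frames (default 60, i.e. 5 h at 5 min).
#' @param mean_speed_umh Median step speed, um/h. Default 60 with
#'   `speed_sdlog = 0.5` populates both the slow (<50 um/h) and fast
#'   (>100 um/h) neighbour-speed classes.
#' @param speed_sdlog Log-normal sd of the per-step speed.
#' @param kappa_p Angular persistence (von Mises concentration per step).
#' @param kappa_e Electrotactic bias strength; 0 = no bias.
#' @param schedule A [field_schedule()].
#' @param cell_a_um,cell_b_um Ellipse semi-major/semi-minor axes, um.
#' @param interaction_radius_um Optional fixed centre distance that counts
#'   as an interaction; `NULL` (default) uses the anisotropic body-touch
#'   criterion.
#' @param hardcore_um Minimum allowed centre distance; overlaps are pushed
#'   apart. Default `2 * cell_b_um`.
#' @param p_cil,p_align Per-cell probabilities of the repolarize-away and
#'   align responses at contact onset.
#' @param align_rate Fraction of the angular difference to the neighbour's
#'   polarity closed per frame while aligned.
#' @param boundary "reflect" (default; cells bounce off the arena walls,
#'   required for rasterization) or "periodic" (positions wrap; polarity
#'   untouched — preferred for trajectory-level statistics free of wall
#'   artifacts).
#' @param seed RNG seed; a fixed seed gives bit-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 12, arena_um = 400, pixel_size_um = 2,
                       dt_min = 5, n_frames = 60, mean_speed_umh = 60,
                       speed_sdlog = 0.5, kappa_p = 4, kappa_e = 0,
                       schedule = field_schedule(),
                       cell_a_um = 18, cell_b_um = 10,
                       interaction_radius_um = NULL,
                       hardcore_um = 2 * cell_b_um,
                       p_cil = 0, p_align = 0, align_rate = 0.5,
                       boundary = c("reflect", "periodic"),
                       seed = 1) {
  boundary <- match.arg(boundary)
  stopifnot(n_cells >= 0, arena_um > 0, pixel_size_um > 0, dt_min > 0,
            n_frames >= 1, mean_speed_umh >= 0, speed_sdlog >= 0,
            kappa_p >= 0, kappa_e >= 0, cell_a_um >= cell_b_um,
            cell_b_um > 0, p_cil >= 0, p_cil <= 1,
            p_align >= 0, p_align <= 1,
            align_rate >= 0, align_rate <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# von Mises sampler, Best & Fisher (1979) rejection scheme
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(pmin(1, pmax(-1, f)))
        break
      }
    }
  }
  out + mu
}

wrap_angle <- function(x) atan2(sin(x), cos(x))

# do two ellipses (semi-axes a,b; centres p1,p2; major-axis angles al1,al2)
# come within `margin` of each other? Tested by sampling one boundary and
# checking insideness in the other, inflated by the margin; symmetric.
ellipses_touch <- function(p1, al1, p2, al2, a, b, margin,
                           tpts = seq(0, 2 * pi, length.out = 33)[-33]) {
  d <- sqrt(sum((p2 - p1)^2))
  if (d > 2 * a + margin) return(FALSE)
  if (d <= 2 * b + margin) return(TRUE)
  one_way <- function(pa, ala, pb, alb) {
    bx <- pa[1] + cos(ala) * a * cos(tpts) - sin(ala) * b * sin(tpts)
    by <- pa[2] + sin(ala) * a * cos(tpts) + cos(ala) * b * sin(tpts)
    dx <- bx - pb[1]; dy <- by - pb[2]
    ex <- cos(alb) * dx + sin(alb) * dy
    ey <- -sin(alb) * dx + cos(alb) * dy
    any((ex / (a + margin))^2 + (ey / (b + margin))^2 <= 1)
  }
  one_way(p1, al1, p2, al2) || one_way(p2, al2, p1, al1)
}

# n x n logical matrix of interacting pairs (body touch or fixed radius)
touch_matrix <- function(pos, theta, config) {
  n <- nrow(pos)
  out <- matrix(FALSE, n, n)
  if (n < 2) return(out)
  d <- as.matrix(stats::dist(pos))
  if (!is.null(config$interaction_radius_um)) {
    out <- d < config$interaction_radius_um
  } else {
    a <- config$cell_a_um; b <- config$cell_b_um
    margin <- config$pixel_size_um   # mask adjacency spans about one pixel
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (d[i, j] > 2 * a + margin) next
        out[i, j] <- out[j, i] <- ellipses_touch(
          pos[i, ], theta[i] + pi / 2, pos[j, ], theta[j] + pi / 2,
          a, b, margin)
      }
    }
  }
  diag(out) <- FALSE
  out
}

#' Simulate persistent random walkers with collision responses
#'
#' Runs the agent model described in [sim_config()] and returns true
#' trajectories plus ground truth about contacts and applied responses.
#' All randomness is driven by `config$seed`; the caller's RNG state is
#' left untouched.
#'
#' @param config A [sim_config()].
#' @return A list of class `cell_sim`: `tracks` (tibble `cell_id`, `frame`,
#'   `x_um`, `y_um`, `polarity_rad`, `step_speed_umh`), `contact_pairs`
#'   (tibble `frame`, `cell_a`, `cell_b` of body-touch interactions),
#'   `responses` (tibble `onset_frame`, `cell_id`, `partner_id`,
#'   `response`), and the `config`.
#' @export
simulate_cells <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)

  n <- config$n_cells
  margin <- config$cell_a_um
  lo <- margin; hi <- config$arena_um - margin
  if (hi <= lo) stop("arena too small for the cell size")

  # initial non-overlapping placement
  pos <- matrix(NA_real_, n, 2)
  placed <- 0
  tries <- 0
  while (placed < n) {
    cand <- stats::runif(2, lo, hi)
    ok <- placed == 0 ||
      all(sqrt(rowSums((pos[seq_len(placed), , drop = FALSE] -
                          matrix(cand, placed, 2, byrow = TRUE))^2)) >=
            2 * config$cell_a_um)
    if (ok) {
      placed <- placed + 1
      pos[placed, ] <- cand
    }
    tries <- tries + 1
    if (tries > 1000 * max(1, n)) stop("could not place cells without overlap")
  }
  theta <- stats::runif(n, -pi, pi)

  dt_h <- config$dt_min / 60
  nf <- config$n_frames
  res_tracks <- vector("list", nf)
  res_pairs <- vector("list", nf)
  res_resp <- list()
  align_to <- rep(NA_integer_, n)          # partner a cell is aligning to
  # responses scheduled by onset detection, applied two steps later:
  # pending[[k]] holds rows to apply in the step computing frame k
  pending <- vector("list", nf + 2L)

  touching <- touch_matrix(pos, theta, config)
  record_frame <- function(f, speeds) {
    res_tracks[[f + 1L]] <<- tibble::tibble(
      cell_id = seq_len(n), frame = f,
      x_um = pos[, 1], y_um = pos[, 2],
      polarity_rad = theta, step_speed_umh = speeds)
    if (n >= 2) {
      tn <- which(touching & upper.tri(touching))
      if (length(tn)) {
        res_pairs[[f + 1L]] <<- tibble::tibble(
          frame = f,
          cell_a = (tn - 1) %% n + 1,
          cell_b = (tn - 1) %/% n + 1)
      }
    }
  }
  schedule_responses <- function(f, onset_idx) {
    # onset_idx: upper-triangle indices of pairs first touching at frame f
    for (idx in onset_idx) {
      i <- (idx - 1) %% n + 1
      j <- (idx - 1) %/% n + 1
      for (cellpair in list(c(i, j), c(j, i))) {
        ci <- cellpair[1]; cj <- cellpair[2]
        did_cil <- stats::runif(1) < config$p_cil
        did_align <- stats::runif(1) < config$p_align
        if (did_cil || did_align) {
          row <- tibble::tibble(cell_id = ci, partner_id = cj,
                                cil = did_cil, align = did_align)
          k <- f + 2L   # expressed in the step into frame f + 2
          if (k <= nf - 1L) {
            pending[[k + 1L]] <<- dplyr::bind_rows(pending[[k + 1L]], row)
          }
          res_resp[[length(res_resp) + 1L]] <<- tibble::tibble(
            onset_frame = f, cell_id = ci, partner_id = cj,
            response = if (did_cil && did_align) "both"
                       else if (did_cil) "cil" else "align")
        }
      }
    }
  }

  speeds <- config$mean_speed_umh * exp(stats::rnorm(n, 0, config$speed_sdlog))
  record_frame(0L, speeds)
  if (n >= 2) schedule_responses(0L, which(touching & upper.tri(touching)))

  for (f in seq_len(nf - 1L)) {
    fld <- field_at(config$schedule, (f - 1) * config$dt_min)
    # polarity update: von Mises product of persistence and field bias
    for (i in seq_len(n)) {
      rx <- config$kappa_p * cos(theta[i])
      ry <- config$kappa_p * sin(theta[i])
      if (fld$on) {
        rx <- rx + config$kappa_e * fld$ex
        ry <- ry + config$kappa_e * fld$ey
      }
      theta[i] <- rvonmises(1, atan2(ry, rx), sqrt(rx^2 + ry^2))
    }

    # scheduled collision responses override the stochastic update; a
    # committed response is expressed at least once even if the touch
    # flickered off in the intervening frame
    fresh <- rep(FALSE, n)
    pend <- pending[[f + 1L]]
    if (!is.null(pend)) {
      for (r in seq_len(nrow(pend))) {
        ci <- pend$cell_id[r]; cj <- pend$partner_id[r]
        if (pend$cil[r]) {
          theta[ci] <- atan2(pos[ci, 2] - pos[cj, 2],
                             pos[ci, 1] - pos[cj, 1])
        }
        if (pend$align[r]) {
          align_to[ci] <- cj
          fresh[ci] <- TRUE
        }
      }
    }
    # alignment relaxation while the contact lasts
    new_theta <- theta
    for (i in seq_len(n)) {
      j <- align_to[i]
      if (!is.na(j)) {
        if (fresh[i] || touching[i, j]) {
          new_theta[i] <- theta[i] +
            config$align_rate * wrap_angle(theta[j] - theta[i])
        } else {
          align_to[i] <- NA_integer_
        }
      }
    }
    theta <- new_theta

    # move
    speeds <- config$mean_speed_umh * exp(stats::rnorm(n, 0, config$speed_sdlog))
    pos <- pos + speeds * dt_h * cbind(cos(theta), sin(theta))

    # hard-core separation, a few relaxation sweeps
    for (sweep in 1:5) {
      d2 <- as.matrix(stats::dist(pos))
      bad <- which(d2 < config$hardcore_um & upper.tri(d2))
      if (!length(bad)) break
      for (idx in bad) {
        i <- (idx - 1) %% n + 1
        j <- (idx - 1) %/% n + 1
        dvec <- pos[i, ] - pos[j, ]
        dd <- sqrt(sum(dvec^2))
        if (dd < 1e-9) dvec <- c(1, 0) else dvec <- dvec / dd
        push <- (config$hardcore_um - dd) / 2
        pos[i, ] <- pos[i, ] + push * dvec
        pos[j, ] <- pos[j, ] - push * dvec
      }
    }

    if (config$boundary == "periodic") {
      for (k in 1:2) pos[, k] <- lo + (pos[, k] - lo) %% (hi - lo)
    } else {
      # reflective boundary (flip polarity component on reflection)
      for (k in 1:2) {
        below <- pos[, k] < lo
        above <- pos[, k] > hi
        pos[below, k] <- 2 * lo - pos[below, k]
        pos[above, k] <- 2 * hi - pos[above, k]
        refl <- below | above
        if (any(refl)) {
          if (k == 1) theta[refl] <- wrap_angle(pi - theta[refl])
          else theta[refl] <- -theta[refl]
        }
      }
    }

    was_touching <- touching
    touching <- touch_matrix(pos, theta, config)
    record_frame(f, speeds)
    if (n >= 2) {
      onset <- touching & !was_touching & upper.tri(touching)
      schedule_responses(f, which(onset))
    }
  }

  structure(
    list(tracks = dplyr::bind_rows(res_tracks),
         contact_pairs = dplyr::bind_rows(res_pairs),
         responses = dplyr::bind_rows(res_resp),
         config = config),
    class = "cell_sim")
}

#' @export
print.cell_sim <- function(x, ...) {
  cat(sprintf("<cell_sim> %d cells, %d frames, seed %d; %d interaction pair-frames\n",
              x$config$n_cells, x$config$n_frames, x$config$seed,
              nrow(x$contact_pairs)))
  invisible(x)
}

#' Rasterize simulated trajectories into a labeled movie
#'
#' Each cell is drawn as a filled ellipse with its major axis perpendicular
#' to the polarity (the cells move along their short axis). Pixels claimed
#' by more than one cell go to the nearer centre, which is deterministic
#' and independent of label order. Labels are the cell ids and persist
#' across frames.
#'
#' @param sim A `cell_sim` from [simulate_cells()], or any track tibble
#'   with `cell_id`, `frame`, `x_um`, `y_um`, `polarity_rad`.
#' @param config A [sim_config()] (taken from `sim` when omitted).
#' @return A [labeled_movie()].
#' @export
rasterize_movie <- function(sim, config = NULL) {
  if (inherits(sim, "cell_sim")) {
    if (is.null(config)) config <- sim$config
    tracks <- sim$tracks
  } else {
    tracks <- sim
    if (is.null(config)) stop("config required for a bare track table")
  }
  ps <- config$pixel_size_um
  npx <- ceiling(config$arena_um / ps)
  a <- config$cell_a_um; b <- config$cell_b_um
  frames_idx <- sort(unique(tracks$frame))
  frames <- lapply(frames_idx, function(f) {
    lab <- matrix(0L, npx, npx)
    best <- matrix(Inf, npx, npx)
    sub <- tracks[tracks$frame == f, ]
    for (r in seq_len(nrow(sub))) {
      cx <- sub$x_um[r]; cy <- sub$y_um[r]
      alpha <- sub$polarity_rad[r] + pi / 2   # major axis perp. to polarity
      # bounding box in 0-based pixel indices (x = col*ps, y = row*ps)
      c0 <- max(0L, floor((cx - a) / ps)); c1 <- min(npx - 1L, ceiling((cx + a) / ps))
      r0 <- max(0L, floor((cy - a) / ps)); r1 <- min(npx - 1L, ceiling((cy + a) / ps))
      if (c1 < c0 || r1 < r0) stop("cell fully outside the raster")
      cols <- c0:c1; rows <- r0:r1
      px <- outer(rep(1, length(rows)), cols) * ps - cx
      py <- outer(rows, rep(1, length(cols))) * ps - cy
      ca <- cos(alpha); sa <- sin(alpha)
      ex <- ca * px + sa * py
      ey <- -sa * px + ca * py
      inside <- (ex / a)^2 + (ey / b)^2 <= 1
      if (!any(inside)) stop("cell fully outside the raster")
      d2 <- px^2 + py^2
      sel_rows <- rows + 1L
      sel_cols <- cols + 1L
      cur_lab <- lab[sel_rows, sel_cols, drop = FALSE]
      cur_best <- best[sel_rows, sel_cols, drop = FALSE]
      claim <- inside & d2 < cur_best
      cur_lab[claim] <- sub$cell_id[r]
      cur_best[claim] <- d2[claim]
      lab[sel_rows, sel_cols] <- cur_lab
      best[sel_rows, sel_cols] <- cur_best
    }
    lab
  })
  labeled_movie(frames, pixel_size = ps, dt = config$dt_min)
}
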