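#' Deterministic test fixtures
#'
#' Small, seeded scenes exercising the full pipeline. Stochastic presets
#' run the agent model of [simulate_cells()]; scripted presets move cells
#' on exact prescribed paths, bypassing the stochastic model, so geometric
#' and metric expectations are known in advance.
#'
#' Presets:
#' \describe{
#'   \item{null_control}{Unbiased persistent walkers, no field, no
#'     programmed collision response.}
#'   \item{electrotaxis_basic}{Strong field bias with the classic schedule:
#'     off 0-1 h, +x 1-3 h, -x 3-5 h.}
#'   \item{cil_strong}{Unbiased walkers with `p_cil = 1`: every contact
#'     onset triggers repolarization away from the neighbour. Seeding is
#'     kept sparse, matching the study system, so collisions are mostly
#'     fresh encounters rather than re-contacts within a saturated
#'     population.}
#'   \item{align_strong}{As above with `p_align = 1` instead.}
#'   \item{scripted_reversal_collision}{Two cells collide head-on and both
#'     reverse on the frame after first touch; the CIL metric at the onset
#'     frame is exactly 1 in trajectory terms.}
#'   \item{two_cell_headon}{Two-cell scripted collision; `approach` selects
#'     where the contact lands on the focal (first) cell: "front" (phi ~ 0),
#'     "rear" (phi ~ pi), or "side" (phi ~ pi/2).}
#' }
#'
#' @param name Preset name (see above).
#' @param seed RNG seed for the stochastic presets.
#' @param approach For `two_cell_headon`: "front", "rear", or "side".
#' @return A list with `movie` (a [labeled_movie()]), `tracks` (true
#'   positions and polarities), `truth` (ground-truth contact pairs and
#'   applied responses, where applicable), `config`, and `manifest` (a
#'   plain list echoing preset, seed, and key parameters).
#' @export
make_fixture <- function(name, seed = 1, approach = "front") {
  presets <- c("null_control", "electrotaxis_basic", "cil_strong",
               "align_strong", "scripted_reversal_collision",
               "two_cell_headon")
  if (!name %in% presets) {
    stop("unknown preset '", name, "'; available: ",
         paste(presets, collapse = ", "))
  }
  no_field <- field_schedule(t_on = numeric(0), t_off = numeric(0),
                             ex = numeric(0), ey = numeric(0))
  if (name %in% c("null_control", "electrotaxis_basic",
                  "cil_strong", "align_strong")) {
    cfg <- switch(
      name,
      null_control = sim_config(n_cells = 12, schedule = no_field, seed = seed),
      electrotaxis_basic = sim_config(n_cells = 12, kappa_e = 8, seed = seed),
      cil_strong = sim_config(n_cells = 12, p_cil = 1,
                              schedule = no_field, seed = seed),
      align_strong = sim_config(n_cells = 12, p_align = 1,
                                schedule = no_field, seed = seed)
    )
    sim <- simulate_cells(cfg)
    movie <- rasterize_movie(sim)
    return(list(
      movie = movie, tracks = sim$tracks,
      truth = list(contact_pairs = sim$contact_pairs,
                   responses = sim$responses),
      config = cfg,
      manifest = list(preset = name, seed = seed,
                      n_cells = cfg$n_cells, n_frames = cfg$n_frames,
                      dt_min = cfg$dt_min, pixel_size_um = cfg$pixel_size_um,
                      p_cil = cfg$p_cil, p_align = cfg$p_align,
                      kappa_e = cfg$kappa_e)))
  }
  # scripted presets
  cfg <- sim_config(n_cells = 2, arena_um = 200, pixel_size_um = 1,
                    dt_min = 5, n_frames = 15, schedule = no_field,
                    seed = seed)
  nf <- cfg$n_frames
  f <- seq_len(nf) - 1
  if (name == "scripted_reversal_collision" ||
      (name == "two_cell_headon" && approach == "front")) {
    # approach until frame 11, retreat after; first touch at frame 10
    xa <- ifelse(f <= 11, 40 + 5 * f, 95 - 5 * (f - 11))
    xb <- 200 - xa
    tracks <- tibble::tibble(
      cell_id = rep(1:2, each = nf), frame = rep(f, 2),
      x_um = c(xa, xb), y_um = rep(100, 2 * nf))
    first_touch <- 10L
  } else if (name == "two_cell_headon" && approach == "rear") {
    # cell 2 catches up with cell 1 from behind, then matches its speed
    xa <- 100 + 2 * f
    xb <- ifelse(f <= 11, 30 + 7 * f, 107 + 2 * (f - 11))
    tracks <- tibble::tibble(
      cell_id = rep(1:2, each = nf), frame = rep(f, 2),
      x_um = c(xa, xb), y_um = rep(100, 2 * nf))
    first_touch <- 10L
  } else if (name == "two_cell_headon" && approach == "side") {
    # cell 2 descends onto the top flank of rightward-moving cell 1
    xa <- 60 + 5 * f
    ya <- rep(120, nf)
    xb <- 60 + 5 * f
    yb <- pmin(40 + 5.6 * f, 96)    # stops 24 um above cell 1
    tracks <- tibble::tibble(
      cell_id = rep(1:2, each = nf), frame = rep(f, 2),
      x_um = c(xa, xb), y_um = c(ya, yb))
    first_touch <- 10L
  } else {
    stop("approach must be one of front, rear, side")
  }
  tracks <- tracks |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::mutate(
      .dx = dplyr::lead(.data$x_um) - .data$x_um,
      .dy = dplyr::lead(.data$y_um) - .data$y_um,
      polarity_rad = atan2(.data$.dy, .data$.dx)
    ) |>
    tidyr::fill("polarity_rad", .direction = "down") |>
    dplyr::ungroup() |>
    dplyr::select(-".dx", -".dy")
  movie <- rasterize_movie(tracks, cfg)
  list(movie = movie, tracks = tracks,
       truth = list(first_touch_frame = first_touch),
       config = cfg,
       manifest = list(preset = name, seed = seed, approach = approach,
                       n_frames = nf, dt_min = cfg$dt_min,
                       pixel_size_um = cfg$pixel_size_um,
                       first_touch_frame = first_touch))
}
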