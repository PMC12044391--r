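test_that("fixed seeds give bit-identical simulations and movies", {
  a <- make_fixture("electrotaxis_basic", seed = 5)
  b <- make_fixture("electrotaxis_basic", seed = 5)
  expect_identical(a$tracks, b$tracks)
  expect_identical(a$movie$frames, b$movie$frames)
  expect_identical(a$truth, b$truth)
  c_ <- make_fixture("electrotaxis_basic", seed = 6)
  expect_false(identical(a$tracks, c_$tracks))
  # the caller's RNG stream is not consumed
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulate_cells(sim_config(n_cells = 3, n_frames = 3)))
  expect_identical(rnorm(1), before)
})

test_that("rasterization round-trips ellipse geometry and positions", {
  cfg <- sim_config(n_cells = 1, arena_um = 120, pixel_size_um = 1,
                    n_frames = 1, seed = 2)
  tr <- tibble::tibble(cell_id = 1L, frame = 0L, x_um = 60, y_um = 55,
                       polarity_rad = 0.4)
  mv <- rasterize_movie(tr, cfg)
  st <- cell_states(mv)
  expect_equal(st$x_um, 60, tolerance = 0.5)
  expect_equal(st$y_um, 55, tolerance = 0.5)
  expect_equal(st$ellipse_a_um, cfg$cell_a_um, tolerance = 0.05 * cfg$cell_a_um)
  expect_equal(st$ellipse_b_um, cfg$cell_b_um, tolerance = 0.05 * cfg$cell_b_um)
  # major axis perpendicular to the polarity
  expect_equal(st$ellipse_theta_rad, (0.4 + pi / 2) %% pi, tolerance = 0.05)

  # centroids track true positions within a pixel across a simulation
  sim <- simulate_cells(sim_config(n_cells = 4, n_frames = 5, seed = 3))
  stm <- cell_states(rasterize_movie(sim))
  j <- dplyr::inner_join(sim$tracks, stm, by = c("cell_id", "frame"))
  expect_true(all(abs(j$x_um.x - j$x_um.y) <= 2 * sim$config$pixel_size_um))
  expect_true(all(abs(j$y_um.x - j$y_um.y) <= 2 * sim$config$pixel_size_um))
})

test_that("planted touching cells are detected; empty scenes rasterize empty", {
  cfg <- sim_config(n_cells = 2, arena_um = 100, pixel_size_um = 1,
                    n_frames = 1)
  tr <- tibble::tibble(cell_id = 1:2, frame = 0L,
                       x_um = c(40, 59), y_um = 50,
                       polarity_rad = c(0, pi))   # minor axes along x, touching
  ct <- detect_contacts(rasterize_movie(tr, cfg))
  expect_setequal(unique(ct$focal_id), 1:2)

  cfg0 <- sim_config(n_cells = 0, arena_um = 50, n_frames = 2)
  tr0 <- tibble::tibble(cell_id = integer(), frame = c(0L, 1L)[0],
                        x_um = double(), y_um = double(),
                        polarity_rad = double())
  # an all-background frame comes from a movie with no cells drawn
  mv0 <- labeled_movie(list(matrix(0L, 10, 10)), 1, 5)
  expect_equal(nrow(cell_states(mv0)), 0)
  expect_equal(nrow(detect_contacts(mv0)), 0)
})

test_that("unknown presets fail with the list of available presets", {
  expect_error(make_fixture("nope"), "null_control")
  expect_error(make_fixture("two_cell_headon", approach = "sideways"),
               "front, rear, side")
})

test_that("unbiased walkers drift nowhere; strong bias drives directionality", {
  # steps within a persistent track are autocorrelated, so the standard
  # error is taken over independent per-cell mean velocities
  sim <- simulate_cells(sim_config(n_cells = 30, arena_um = 2000,
                                   n_frames = 40, boundary = "periodic",
                                   schedule = no_field, seed = 4))
  tr <- compute_velocities(sim$tracks, dt = 5)
  per_cell <- tr |> dplyr::filter(!is.na(vx_umh)) |>
    dplyr::group_by(cell_id) |> dplyr::summarise(mvx = mean(vx_umh))
  expect_lt(abs(mean(per_cell$mvx)),
            3 * stats::sd(per_cell$mvx) / sqrt(nrow(per_cell)))

  on_all <- field_schedule(t_on = 0, t_off = 1e6, ex = 1, ey = 0)
  simb <- simulate_cells(sim_config(n_cells = 50, arena_um = 2000,
                                    n_frames = 40, kappa_e = 10,
                                    boundary = "periodic",
                                    schedule = on_all, seed = 4))
  trb <- compute_velocities(simb$tracks, dt = 5)
  db <- directionality(trb, on_all, dt = 5)
  expect_gt(mean(db$phi, na.rm = TRUE), 0.9)

  # directionality rises monotonically with the bias strength
  phi_of <- function(ke) {
    s <- simulate_cells(sim_config(n_cells = 50, arena_um = 2000,
                                   n_frames = 30, kappa_e = ke,
                                   boundary = "periodic",
                                   schedule = on_all, seed = 11))
    d <- directionality(compute_velocities(s$tracks, 5), on_all, 5)
    mean(d$phi, na.rm = TRUE)
  }
  phis <- vapply(c(0, 2, 10), phi_of, numeric(1))
  expect_true(all(diff(phis) > 0))
  expect_lt(abs(phis[1]), 0.2)
})

test_that("hard cores never overlap beyond tolerance and cells stay in bounds", {
  sim <- simulate_cells(sim_config(n_cells = 10, arena_um = 300,
                                   n_frames = 30, p_cil = 0.5, p_align = 0.5,
                                   seed = 6))
  cfg <- sim$config
  for (f in unique(sim$tracks$frame)) {
    sub <- sim$tracks[sim$tracks$frame == f, ]
    d <- stats::dist(cbind(sub$x_um, sub$y_um))
    expect_gte(min(d), cfg$hardcore_um - 1e-6)
  }
  expect_true(all(sim$tracks$x_um >= cfg$cell_a_um - 1e-9))
  expect_true(all(sim$tracks$x_um <= cfg$arena_um - cfg$cell_a_um + 1e-9))
})

test_that("ground-truth contacts agree with rasterized mask contacts at onset", {
  fx <- make_fixture("cil_strong", seed = 2)
  ct <- detect_contacts(fx$movie)
  mask_keys <- paste(pmin(ct$focal_id, ct$neighbor_id),
                     pmax(ct$focal_id, ct$neighbor_id), ct$frame)
  truth <- fx$truth$contact_pairs
  truth_keys <- paste(pmin(truth$cell_a, truth$cell_b),
                      pmax(truth$cell_a, truth$cell_b), truth$frame)
  # the overwhelming majority of simulator-level touches appear in the masks
  expect_gt(mean(truth_keys %in% mask_keys), 0.9)
})
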