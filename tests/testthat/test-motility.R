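mk_track <- function(cell_id, frames, x, y, ...) {
  tibble::tibble(cell_id = cell_id, frame = frames, x_um = x, y_um = y, ...)
}

test_that("forward-difference velocities convert to um/h and respect gaps", {
  tr <- mk_track(1L, 0:1, c(0, 5), c(0, 0))
  v <- compute_velocities(tr, dt = 5)
  expect_equal(v$vx_umh, c(60, NA))
  expect_equal(v$speed_umh, c(60, NA))

  # single-frame track: no velocity
  v1 <- compute_velocities(mk_track(2L, 3L, 1, 1), dt = 5)
  expect_true(is.na(v1$vx_umh))

  # gapped track {0, 1, 3}: velocity at 1 only when spanning is enabled
  tr3 <- mk_track(1L, c(0L, 1L, 3L), c(0, 5, 15), c(0, 0, 0))
  v_strict <- compute_velocities(tr3, dt = 5)
  expect_equal(v_strict$vx_umh, c(60, NA, NA))
  v_gap <- compute_velocities(tr3, dt = 5, allow_gaps = TRUE)
  expect_equal(v_gap$vx_umh, c(60, 60, NA))   # 10 um over 10 min

  # telescoping: integrating velocities recovers the end position
  set.seed(1)
  tw <- mk_track(1L, 0:20, cumsum(rnorm(21)), cumsum(rnorm(21)))
  vv <- compute_velocities(tw, dt = 5)
  expect_equal(tw$x_um[1] + sum(vv$vx_umh, na.rm = TRUE) * 5 / 60,
               tw$x_um[21])
})

test_that("directionality is the mean cosine against the field", {
  sched <- field_schedule(t_on = 0, t_off = 1000, ex = 1, ey = 0)
  base <- dplyr::bind_rows(
    mk_track(1L, 0:1, c(0, 1), c(0, 0)),
    mk_track(2L, 0:1, c(0, cos(pi / 3)), c(0, sin(pi / 3))))
  tr <- compute_velocities(base, dt = 60)
  d <- directionality(tr, sched, dt = 60)
  expect_equal(d$phi[1], (1 + 0.5) / 2)
  expect_equal(d$n, c(2L, 0L))
  expect_true(is.na(d$phi[2]))

  # four symmetric velocities cancel
  sym <- dplyr::bind_rows(lapply(1:4, function(k) {
    dir <- c(1, 0, -1, 0)[k]; diry <- c(0, 1, 0, -1)[k]
    mk_track(as.integer(k), 0:1, c(0, dir), c(0, diry))
  }))
  d2 <- directionality(compute_velocities(sym, 60), sched, 60)
  expect_equal(d2$phi[1], 0)

  # reversing the field reverses phi; phi off the schedule is NA
  sched_neg <- field_schedule(t_on = 0, t_off = 1000, ex = -1, ey = 0)
  d3 <- directionality(tr, sched_neg, dt = 60)
  expect_equal(d3$phi[1], -d$phi[1])
  d_off <- directionality(tr, no_field, dt = 60)
  expect_true(all(is.na(d_off$phi)))
})

test_that("reversal comparison windows vy around the flip and tests it", {
  sched <- field_schedule()   # +x 60-180 min, -x 180-300 min
  set.seed(5)
  nfr <- 60
  tr <- dplyr::bind_rows(lapply(1:8, function(k) {
    mk_track(as.integer(k), 0:(nfr - 1),
             cumsum(rnorm(nfr, 2)), cumsum(rnorm(nfr, 0, 1)))
  }))
  trv <- compute_velocities(tr, dt = 5)
  rc <- reversal_comparison(trv, sched, dt = 5)
  expect_equal(rc$t_reversal, 180)
  expect_gt(rc$p_value, 0.05)   # symmetric noise, no shift
  expect_setequal(unique(rc$samples$period), c("pre", "post"))
  # windows: pre in [60,180), post in [180,300)
  expect_true(all(rc$samples$t_min[rc$samples$period == "pre"] >= 60))
  expect_true(all(rc$samples$t_min[rc$samples$period == "post"] < 300))

  # planted shift in post-reversal vy is detected
  tr_shift <- dplyr::bind_rows(lapply(1:8, function(k) {
    y <- cumsum(c(rnorm(36, 0, 1), rnorm(nfr - 36, 20 * 5 / 60, 1)))
    mk_track(as.integer(k), 0:(nfr - 1), cumsum(rnorm(nfr, 2)), y)
  }))
  rc2 <- reversal_comparison(compute_velocities(tr_shift, 5), sched, dt = 5)
  expect_lt(rc2$p_value, 0.01)

  expect_error(reversal_comparison(trv, no_field, dt = 5), "no field reversal")
  expect_error(
    reversal_comparison(trv[trv$frame < 30, ], sched, dt = 5),
    "empty window")

  td <- tidy(rc)
  expect_equal(nrow(td), 2)
  expect_equal(glance(rc)$p_value, rc$p_value)
})

test_that("morphology-speed curves bin means and flag bad edges", {
  tr <- tibble::tibble(
    cell_id = 1:4, frame = 0L,
    x_um = 0, y_um = 0,
    speed_umh = c(10, 10, 50, 50),
    aspect_ratio = c(0.25, 0.25, 0.75, 0.75),
    area_um2 = c(100, 100, 300, 300))
  mc <- morphology_speed_curves(tr, ar_bins = c(0, 0.5, 1),
                                area_bins = c(0, 200, 400))
  ar <- mc[mc$variable == "aspect_ratio", ]
  expect_equal(ar$mean_speed, c(10, 50))
  expect_equal(ar$n, c(2L, 2L))
  expect_equal(mc$mean_speed[mc$variable == "area_um2"], c(10, 50))
  expect_error(morphology_speed_curves(tr, ar_bins = c(0.5, 0.2, 1)),
               "strictly increasing")

  # planted speed optimum at a known aspect-ratio bin is recovered
  set.seed(3)
  n <- 400
  arv <- runif(n)
  tr2 <- tibble::tibble(
    cell_id = seq_len(n), frame = 0L, x_um = 0, y_um = 0,
    speed_umh = 60 * exp(-((arv - 0.8) / 0.15)^2) + rnorm(n, 0, 2),
    aspect_ratio = arv, area_um2 = 200)
  mc2 <- morphology_speed_curves(tr2, ar_bins = seq(0, 1, 0.1))
  ar2 <- mc2[mc2$variable == "aspect_ratio", ]
  expect_equal(ar2$bin_mid[which.max(ar2$mean_speed)], 0.75, tolerance = 0.11)
})
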