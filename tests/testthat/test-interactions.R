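test_that("CIL metric reproduces its worked examples", {
  # full reversal directly away from the neighbour
  expect_equal(cil(c(1, 0), c(-1, 0), c(0, 0), c(5, 0)), 1)
  # velocity change orthogonal to the separation axis
  expect_equal(cil(c(1, 0), c(1, 1), c(0, 0), c(5, 0)), 0)
  # hand-evaluated oblique case
  expect_equal(cil(c(1, 0), c(0, 1), c(1, 1), c(0, 0)), 0)
  # undefined cases are NA, never silently zero
  expect_true(is.na(cil(c(1, 0), c(1, 0), c(0, 0), c(5, 0))))
  expect_true(is.na(cil(c(1, 0), c(0, 1), c(2, 2), c(2, 2))))
})

test_that("alignment metric reproduces its worked examples", {
  # antiparallel before, parallel after
  expect_equal(alignment(c(1, 0), c(1, 0), c(-1, 0), c(1, 0)), 1)
  # no directional change
  expect_equal(alignment(c(1, 0), c(2, 0), c(1, 0), c(3, 0)), 0)
  # perpendicular before, parallel after
  expect_equal(alignment(c(0, 1), c(1, 0), c(1, 0), c(1, 0)), 0.5)
  expect_true(is.na(alignment(c(0, 0), c(1, 0), c(1, 0), c(1, 0))))
})

test_that("metrics are invariant under global rotation and translation", {
  set.seed(21)
  rot <- function(v, a) c(cos(a) * v[1] - sin(a) * v[2],
                          sin(a) * v[1] + cos(a) * v[2])
  for (k in 1:50) {
    v1 <- rnorm(2); v2 <- rnorm(2); v3 <- rnorm(2); v4 <- rnorm(2)
    x1 <- rnorm(2); x2 <- rnorm(2)
    a <- runif(1, 0, 2 * pi); tr <- rnorm(2, sd = 10)
    expect_equal(cil(rot(v1, a), rot(v2, a), rot(x1, a) + tr, rot(x2, a) + tr),
                 cil(v1, v2, x1, x2), tolerance = 1e-9)
    expect_equal(alignment(rot(v1, a), rot(v2, a), rot(v3, a), rot(v4, a)),
                 alignment(v1, v2, v3, v4), tolerance = 1e-9)
    # alignment is symmetric in the two cells
    expect_equal(alignment(v3, v4, v1, v2), alignment(v1, v2, v3, v4))
  }
  # cil is not symmetric: only the turning cell scores
  v_i <- list(t0 = c(1, 0), t1 = c(-1, 0))   # i reverses
  v_j <- list(t0 = c(-1, 0), t1 = c(-1, 0))  # j keeps going
  x_i <- c(0, 0); x_j <- c(2, 0)
  expect_equal(cil(v_i$t0, v_i$t1, x_i, x_j), 1)
  expect_true(is.na(cil(v_j$t0, v_j$t1, x_j, x_i)))
})

test_that("scripted head-on reversal yields mean CIL of 1 through the pipeline", {
  fx <- make_fixture("scripted_reversal_collision")
  an <- analyze_fixture(fx)
  s <- an$samples
  expect_gt(sum(s$cil_valid), 0)
  expect_equal(mean(s$cil[s$cil_valid]), 1, tolerance = 1e-6)
  # the onset frame is the scripted first-touch frame, both orientations
  expect_true(all(c(1, 2) %in% s$focal_id[s$is_onset]))
  expect_equal(unique(s$frame[s$is_onset]), fx$truth$first_touch_frame)
})

test_that("interaction samples carry both roles and conserve drop counts", {
  fx <- make_fixture("two_cell_headon")
  an <- analyze_fixture(fx)
  s <- an$samples
  # two isolated colliding tracks: both orientations at every sampled frame
  per_frame <- table(s$frame)
  expect_true(all(per_frame == 2))
  drops <- attr(s, "drop_counts")
  expect_equal(nrow(s) + sum(drops), attr(s, "n_oriented_contacts"))
  # all kept rows have both velocities defined
  expect_true(all(!is.na(s$focal_speed_umh)))
  expect_true(all(s$cil[s$cil_valid] >= -1 & s$cil[s$cil_valid] <= 1))
  ok_al <- s$alignment_valid
  expect_true(all(s$alignment[ok_al] >= -1 & s$alignment[ok_al] <= 1))
})

test_that("drop accounting reconciles on a stochastic fixture", {
  fx <- make_fixture("cil_strong", seed = 3)
  an <- analyze_fixture(fx)
  s <- an$samples
  drops <- attr(s, "drop_counts")
  expect_equal(nrow(s) + sum(drops), nrow(an$contacts))
  # non-pairwise contacts are excluded under the default configuration
  deg <- an$contacts |> dplyr::count(frame, focal_id, name = "deg")
  smp_deg <- dplyr::left_join(s, deg, by = c("frame", "focal_id"))
  expect_true(all(smp_deg$deg == 1))
})

test_that("behaviour classification follows signs with a dead zone", {
  expect_equal(classify_behavior(0.8, 0.6), "repel and align")
  expect_equal(classify_behavior(-0.4, -0.5), "stick and scatter")
  expect_equal(classify_behavior(0.05, 0.02), "neutral")
  expect_equal(classify_behavior(0.5, -0.5), "repel and scatter")
  expect_equal(classify_behavior(-0.5, 0.5), "stick and align")
  # custom mapping is honoured
  mp <- c(repel.align = "RA", repel.scatter = "RS",
          stick.align = "SA", stick.scatter = "SS")
  expect_equal(classify_behavior(0.8, 0.6, mapping = mp), "RA")
  expect_true(is.na(classify_behavior(NA_real_, 0.5)))
})

test_that("response map bins by phi and neighbour-speed class", {
  mk_sample <- function(phi, cilv, alv, nspeed) tibble::tibble(
    frame = 0L, focal_id = 1L, neighbor_id = 2L, is_onset = TRUE,
    phi_rad = phi, cil = cilv, alignment = alv,
    cil_valid = TRUE, alignment_valid = TRUE,
    focal_speed_umh = 60, neighbor_speed_umh = nspeed,
    condition = "control")

  # concentration: all samples in one cell of the grid
  s1 <- dplyr::bind_rows(lapply(1:8, function(i) mk_sample(pi / 2, 0.2, 0.1, 30)))
  rm1 <- response_map(s1, n_min = 5)
  occ <- rm1$cells[rm1$cells$n > 0, ]
  expect_equal(nrow(occ), 1)
  expect_equal(occ$speed_class, "slow")
  expect_equal(occ$n, 8L)
  # intermediate speeds are discarded in the two-class scheme
  s_mid <- mk_sample(pi / 2, 0.2, 0.1, 75)
  rm_mid <- response_map(s_mid)
  expect_equal(sum(rm_mid$cells$n), 0L)

  # below n_min: no label
  s2 <- dplyr::bind_rows(lapply(1:4, function(i) mk_sample(0.1, 0.9, 0.9, 150)))
  rm2 <- response_map(s2, n_min = 5)
  expect_true(all(is.na(rm2$cells$label)))

  # planted front/rear populations recover their behaviour labels
  s3 <- dplyr::bind_rows(
    dplyr::bind_rows(lapply(1:10, function(i) mk_sample(0.1, -0.5, -0.5, 150))),
    dplyr::bind_rows(lapply(1:10, function(i) mk_sample(3.0, 0.5, 0.5, 150))))
  rm3 <- response_map(s3, n_min = 5)
  front <- rm3$cells[rm3$cells$phi_lo == 0 & rm3$cells$speed_class == "fast", ]
  rear <- rm3$cells[rm3$cells$phi_hi == pi & rm3$cells$speed_class == "fast", ]
  expect_equal(front$label, "stick and scatter")
  expect_equal(rear$label, "repel and align")

  # empty input: empty map, not an error
  rm0 <- response_map(s1[0, ])
  expect_equal(sum(rm0$cells$n), 0L)

  td <- tidy(rm3)
  expect_equal(sum(td$n), 20L)
  gl <- glance(rm3)
  expect_equal(gl$n_samples, 20L)
  expect_equal(gl$mean_cil, 0)
})
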