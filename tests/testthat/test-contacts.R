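test_that("label adjacency defines contacts and interface length", {
  lab <- matrix(0L, 12, 12)
  lab[4:8, 2:6] <- 1L
  lab[4:8, 7:11] <- 2L
  ct <- detect_contacts(lab, pixel_size = 1)
  expect_equal(nrow(ct), 2)            # both orientations
  expect_equal(sort(ct$focal_id), c(1L, 2L))
  expect_equal(unique(ct$interface_length_um), 5)

  # one-pixel background column separates the cells: no contact
  lab2 <- lab
  lab2[, 7] <- 0L
  lab2[4:8, 8:12] <- 2L
  expect_equal(nrow(detect_contacts(lab2, 1)), 0)

  # pure diagonal touch: contact exists under 8- but not 4-connectivity,
  # and contributes no 4-adjacent interface length
  lab3 <- matrix(0L, 6, 6)
  lab3[2:3, 2:3] <- 1L
  lab3[4:5, 4:5] <- 2L
  ct8 <- detect_contacts(lab3, 1, connectivity = 8)
  expect_equal(nrow(ct8), 2)
  expect_equal(unique(ct8$interface_length_um), 0)
  expect_equal(nrow(detect_contacts(lab3, 1, connectivity = 4)), 0)

  expect_equal(nrow(detect_contacts(matrix(0L, 5, 5), 1)), 0)
})

test_that("contact detection matches the all-pixel-pairs oracle", {
  for (seed in 1:20) {
    lab <- random_label_image(40, 4, seed)
    for (conn in c(4, 8)) {
      ct <- detect_contacts(lab, 1, connectivity = conn)
      got <- sort(unique(paste(pmin(ct$focal_id, ct$neighbor_id),
                               pmax(ct$focal_id, ct$neighbor_id))))
      expect_identical(got, brute_contact_pairs(lab, conn))
    }
  }
})

test_that("contact records are symmetric with equal interface lengths", {
  fx <- make_fixture("cil_strong", seed = 2)
  ct <- detect_contacts(fx$movie)
  key <- paste(ct$frame, ct$focal_id, ct$neighbor_id)
  mirror <- paste(ct$frame, ct$neighbor_id, ct$focal_id)
  expect_true(all(mirror %in% key))
  m <- match(mirror, key)
  expect_equal(ct$interface_length_um, ct$interface_length_um[m])
  expect_true(all(ct$focal_id != ct$neighbor_id))
})

test_that("contact events are maximal runs with configurable gap merging", {
  mk <- function(frames) tibble::tibble(frame = frames, focal_id = 1L,
                                        neighbor_id = 2L)
  ev <- build_events(mk(3:7), dt = 5)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_min, 25)

  ev2 <- build_events(mk(c(2L, 4L)), dt = 5, gap_tolerance = 0)
  expect_equal(nrow(ev2), 2)
  expect_equal(ev2$duration_min, c(5, 5))

  ev3 <- build_events(mk(c(2L, 4L)), dt = 5, gap_tolerance = 1)
  expect_equal(nrow(ev3), 1)
  expect_equal(ev3$start_frame, 2L)
  expect_equal(ev3$end_frame, 4L)
  expect_equal(ev3$duration_min, 15)

  expect_equal(nrow(build_events(mk(integer(0)), 5)), 0)
})

test_that("event durations account for every contact frame at zero gap tolerance", {
  fx <- make_fixture("cil_strong", seed = 1)
  ct <- detect_contacts(fx$movie)
  ev <- build_events(ct, dt = fx$movie$dt, gap_tolerance = 0)
  per_pair_frames <- ct |>
    dplyr::filter(.data$focal_id < .data$neighbor_id) |>
    dplyr::count(.data$focal_id, .data$neighbor_id, name = "n_frames")
  per_pair_events <- ev |>
    dplyr::group_by(cell_a, cell_b) |>
    dplyr::summarise(total = sum(duration_min) / fx$movie$dt, .groups = "drop")
  j <- dplyr::inner_join(per_pair_frames, per_pair_events,
                         by = c(focal_id = "cell_a", neighbor_id = "cell_b"))
  expect_equal(nrow(j), nrow(per_pair_frames))
  expect_equal(j$total, as.numeric(j$n_frames))
})

test_that("clusters are the connected components of the contact graph", {
  tracks <- tibble::tibble(cell_id = 1:5, frame = 0L, x_um = 0, y_um = 0,
                           speed_umh = c(10, 20, 30, 40, NA))
  ct <- tibble::tibble(frame = 0L, focal_id = c(1L, 2L, 2L, 3L),
                       neighbor_id = c(2L, 1L, 3L, 2L))
  cl <- find_clusters(ct, tracks)
  expect_equal(sort(cl$size), c(1L, 1L, 3L))
  big <- cl[cl$size == 3, ]
  expect_setequal(big$member_ids[[1]], 1:3)
  expect_equal(big$speed_umh, 20)
  # member 5 has no speed: singleton with NA speed
  expect_true(is.na(cl$speed_umh[sapply(cl$member_ids, identical, 5L)]))
  # no contacts: all singletons
  cl0 <- find_clusters(ct[0, ], tracks)
  expect_equal(cl0$size, rep(1L, 5))
  # partition property
  expect_equal(sum(cl$size), 5L)
})

test_that("cluster finding matches brute-force reachability on random graphs", {
  set.seed(11)
  for (k in 1:20) {
    n <- sample(4:9, 1)
    tracks <- tibble::tibble(cell_id = seq_len(n), frame = 0L,
                             x_um = 0, y_um = 0, speed_umh = 1)
    n_edges <- sample(0:(n + 2), 1)
    ea <- sample(n, n_edges, replace = TRUE)
    eb <- sample(n, n_edges, replace = TRUE)
    keep <- ea != eb
    ea <- ea[keep]; eb <- eb[keep]
    ct <- tibble::tibble(frame = 0L,
                         focal_id = as.integer(c(ea, eb)),
                         neighbor_id = as.integer(c(eb, ea)))
    cl <- find_clusters(ct, tracks)
    expect_equal(sum(cl$size), n)
    comp <- brute_components(seq_len(n), ea, eb)
    expected_sizes <- sort(as.integer(table(comp)))
    expect_equal(sort(cl$size), expected_sizes)
    # two cells share a cluster iff connected in the oracle
    memb <- integer(n)
    for (r in seq_len(nrow(cl))) memb[cl$member_ids[[r]]] <- r
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      expect_equal(memb[i] == memb[j], unname(comp[i] == comp[j]))
    }
  }
})

test_that("cluster speed comparison reports per-size shifts", {
  mk <- function(speeds, sizes) tibble::tibble(
    frame = 0L, cluster_id = seq_along(speeds), size = sizes,
    speed_umh = speeds, member_ids = list(1L))
  a <- mk(c(10, 11, 12, 13, 14), rep(2L, 5))
  expect_equal(cluster_speed_comparison(a, a)$pct_diff, 0)
  expect_equal(cluster_speed_comparison(a, a)$p_value, 1)

  set.seed(8)
  sp <- rlnorm(500, log(50), 0.3)
  b1 <- mk(sp, rep(2L, 500))
  b2 <- mk(sp * 1.10, rep(2L, 500))
  cmp <- cluster_speed_comparison(b1, b2)
  expect_equal(cmp$pct_diff, 10, tolerance = 1e-6)

  # size present in only one condition is absent from the table
  c1 <- mk(c(10, 20), c(2L, 3L))
  c2 <- mk(c(10, 20), c(2L, 4L))
  expect_equal(cluster_speed_comparison(c1, c2)$size, 2L)
})
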