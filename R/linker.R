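# Jonker-Volgenant style shortest-augmenting-path solver for the square
# linear assignment problem. Costs must be finite. Returns, for each row,
# the assigned column. O(n^3); plenty for per-frame cell counts.
solve_lap <- function(cost) {
  n <- nrow(cost)
  stopifnot(n == ncol(cost), all(is.finite(cost)))
  if (n == 0) return(integer(0))
  u <- numeric(n)        # row potentials
  v <- numeric(n + 1)    # column potentials, v[1] = virtual column 0
  p <- integer(n + 1)    # p[j+1]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf
      j1 <- 0
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1]] <- u[p[j + 1]] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) assignment[p[j + 1]] <- j
  assignment
}

# Gated bipartite matching between two point sets: minimizes total matched
# distance with an explicit "no match" alternative costing alt_factor *
# gate per unmatched point, via the standard padded square construction.
# Returns an integer vector over rows of `from`: the matched row of `to`,
# or NA.
gated_match <- function(from, to, gate, alt_factor = 1.05) {
  nf <- nrow(from); nt <- nrow(to)
  if (nf == 0 || nt == 0) return(rep(NA_integer_, nf))
  d <- sqrt(outer(from[, 1], to[, 1], "-")^2 +
              outer(from[, 2], to[, 2], "-")^2)
  alt <- alt_factor * gate
  big <- 2 * alt + max(gate, 1)   # worse than any pair of alternatives
  top_left <- ifelse(d <= gate, d, big)
  top_right <- matrix(big, nf, nf); diag(top_right) <- alt
  bot_left <- matrix(big, nt, nt); diag(bot_left) <- alt
  bot_right <- matrix(0, nt, nf)
  cost <- rbind(cbind(top_left, top_right), cbind(bot_left, bot_right))
  asg <- solve_lap(cost)
  out <- rep(NA_integer_, nf)
  hit <- asg[seq_len(nf)] <= nt & d[cbind(seq_len(nf), pmin(asg[seq_len(nf)], nt))] <= gate
  out[hit] <- asg[seq_len(nf)][hit]
  out
}

#' Link per-frame detections into tracks
#'
#' A gated frame-to-frame linker with gap closing, for label movies whose
#' labels are not persistent across frames. Consecutive frames are linked
#' by an optimal assignment minimizing total centroid distance, with links
#' beyond `max_link_um` forbidden; track ends then attempt gap closing to
#' later track starts within `max_gap` frames and `max_gap_um`. This is a
#' convenience linker for sparse scenes, not a full LAP tracker with
#' merging and splitting.
#'
#' @param states Per-frame detections: a tibble with `frame`, `x_um`,
#'   `y_um`, and a per-frame `cell_id` (not trusted across frames); e.g.
#'   the output of [cell_states()] on a movie with per-frame labels.
#' @param max_link_um Frame-to-frame gate, micrometres (default 100).
#' @param max_gap Maximum frames bridged by gap closing (default 3:
#'   `start_frame - end_frame <= 3`).
#' @param max_gap_um Distance gate for gap closing (default 150).
#' @return `states` with `cell_id` replaced by persistent track ids (the
#'   original per-frame label is kept as `detection_id`).
#' @export
link_tracks <- function(states, max_link_um = 100, max_gap = 3,
                        max_gap_um = 150) {
  states <- dplyr::arrange(states, .data$frame, .data$cell_id)
  states$detection_id <- states$cell_id
  states$.row <- seq_len(nrow(states))
  frames <- sort(unique(states$frame))
  track_of <- rep(NA_integer_, nrow(states))
  next_track <- 1L

  prev_rows <- integer(0)
  for (f in frames) {
    rows <- states$.row[states$frame == f]
    if (length(prev_rows) && length(rows) &&
        f - states$frame[prev_rows[1]] == 1L) {
      from <- cbind(states$x_um[prev_rows], states$y_um[prev_rows])
      to <- cbind(states$x_um[rows], states$y_um[rows])
      m <- gated_match(from, to, max_link_um)
      for (k in seq_along(prev_rows)) {
        if (!is.na(m[k])) track_of[rows[m[k]]] <- track_of[prev_rows[k]]
      }
    }
    for (r in rows) {
      if (is.na(track_of[r])) {
        track_of[r] <- next_track
        next_track <- next_track + 1L
      }
    }
    prev_rows <- rows
  }

  # gap closing between track ends and later track starts
  info <- tibble::tibble(track = track_of, frame = states$frame,
                         x = states$x_um, y = states$y_um) |>
    dplyr::group_by(.data$track) |>
    dplyr::summarise(
      first = min(.data$frame), last = max(.data$frame),
      x_first = .data$x[which.min(.data$frame)],
      y_first = .data$y[which.min(.data$frame)],
      x_last = .data$x[which.max(.data$frame)],
      y_last = .data$y[which.max(.data$frame)],
      .groups = "drop")
  ends <- info
  starts <- info
  ne <- nrow(ends); ns <- nrow(starts)
  gap_ok <- outer(starts$first, ends$last, "-")
  d <- sqrt(outer(starts$x_first, ends$x_last, "-")^2 +
              outer(starts$y_first, ends$y_last, "-")^2)
  eligible <- gap_ok >= 2 & gap_ok <= max_gap & d <= max_gap_um
  if (any(eligible)) {
    alt <- 1.05 * max_gap_um
    big <- 2 * alt + max_gap_um
    top_left <- ifelse(t(eligible), d |> t(), big)  # rows = ends, cols = starts
    top_right <- matrix(big, ne, ne); diag(top_right) <- alt
    bot_left <- matrix(big, ns, ns); diag(bot_left) <- alt
    cost <- rbind(cbind(top_left, top_right),
                  cbind(bot_left, matrix(0, ns, ne)))
    asg <- solve_lap(cost)
    merge_into <- rep(NA_integer_, ns)   # start track s continues end track e
    for (e in seq_len(ne)) {
      s <- asg[e]
      if (s <= ns && eligible[s, e]) merge_into[s] <- e
    }
    # resolve chains: follow merges to the root track
    root <- seq_len(nrow(info))
    ord <- order(info$first)
    for (s in ord) {
      if (!is.na(merge_into[s])) root[s] <- root[merge_into[s]]
    }
    track_of <- info$track[root][match(track_of, info$track)]
  }

  states$cell_id <- match(track_of, sort(unique(track_of)))
  dplyr::select(states, -".row")
}
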