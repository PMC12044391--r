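# Shared fixtures and independent oracles used across the suite.

no_field <- field_schedule(t_on = numeric(0), t_off = numeric(0),
                           ex = numeric(0), ey = numeric(0))

# pixel set of a filled ellipse rasterized on an n x n grid (0-based coords)
raster_ellipse_pixels <- function(a, b, theta = 0, cx, cy, n) {
  g <- expand.grid(r = 0:(n - 1), c = 0:(n - 1))
  dx <- g$c - cx; dy <- g$r - cy
  ex <- cos(theta) * dx + sin(theta) * dy
  ey <- -sin(theta) * dx + cos(theta) * dy
  inside <- (ex / a)^2 + (ey / b)^2 <= 1
  cbind(g$r[inside], g$c[inside])
}

# random label image with a few blobs (possibly touching)
random_label_image <- function(n, n_blobs, seed) {
  set.seed(seed)
  lab <- matrix(0L, n, n)
  best <- matrix(Inf, n, n)
  for (k in seq_len(n_blobs)) {
    cx <- runif(1, 4, n - 5); cy <- runif(1, 4, n - 5)
    a <- runif(1, 3, n / 4); b <- runif(1, 2, a); th <- runif(1, 0, pi)
    g <- expand.grid(r = 0:(n - 1), c = 0:(n - 1))
    dx <- g$c - cx; dy <- g$r - cy
    ex <- cos(th) * dx + sin(th) * dy
    ey <- -sin(th) * dx + cos(th) * dy
    inside <- (ex / a)^2 + (ey / b)^2 <= 1
    d2 <- dx^2 + dy^2
    claim <- inside & d2 < as.vector(best)
    lab[claim] <- k
    best[claim] <- d2[claim]
  }
  lab
}

# all-pixel-pairs adjacency scan: which unordered label pairs touch?
brute_contact_pairs <- function(lab, connectivity) {
  idx <- which(lab > 0L)
  if (length(idx) < 2) return(character(0))
  nr <- nrow(lab)
  r <- (idx - 1L) %% nr
  c <- (idx - 1L) %/% nr
  l <- lab[idx]
  dr <- abs(outer(r, r, "-"))
  dc <- abs(outer(c, c, "-"))
  adj <- if (connectivity == 8) dr <= 1 & dc <= 1 else dr + dc == 1
  diff_lab <- outer(l, l, "!=")
  hit <- which(adj & diff_lab & upper.tri(adj))
  if (!length(hit)) return(character(0))
  i <- (hit - 1) %% length(idx) + 1
  j <- (hit - 1) %/% length(idx) + 1
  sort(unique(paste(pmin(l[i], l[j]), pmax(l[i], l[j]))))
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
enum_mw <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  combos <- utils::combn(length(pooled), na)
  u_of <- function(av, bv) sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  u_obs <- u_of(a, b)
  us <- apply(combos, 2, function(ii) u_of(pooled[ii], pooled[-ii]))
  p <- min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
  list(U = u_obs, p = p)
}

# brute-force gated matching: minimize matched distance + alt cost per
# unmatched point over all injective partial assignments
brute_gated_match <- function(from, to, gate, alt_factor = 1.05) {
  nf <- nrow(from); nt <- nrow(to)
  d <- sqrt(outer(from[, 1], to[, 1], "-")^2 + outer(from[, 2], to[, 2], "-")^2)
  alt <- alt_factor * gate
  best <- list(cost = Inf, m = rep(NA_integer_, nf))
  recur <- function(i, used, m, cost) {
    if (cost >= best$cost) return()
    if (i > nf) {
      n_unmatched_to <- nt - sum(!is.na(m))
      total <- cost + alt * n_unmatched_to
      if (total < best$cost) best <<- list(cost = total, m = m)
      return()
    }
    recur(i + 1, used, m, cost + alt)   # leave i unmatched
    for (j in seq_len(nt)) {
      if (!used[j] && d[i, j] <= gate) {
        used[j] <- TRUE; m[i] <- j
        recur(i + 1, used, m, cost + d[i, j])
        used[j] <- FALSE; m[i] <- NA_integer_
      }
    }
  }
  recur(1, rep(FALSE, nt), rep(NA_integer_, nf), 0)
  best$m
}

# connected components by reachability closure (repeated edge relaxation)
brute_components <- function(nodes, edges_a, edges_b) {
  comp <- stats::setNames(seq_along(nodes), nodes)
  repeat {
    changed <- FALSE
    for (k in seq_along(edges_a)) {
      ca <- comp[[as.character(edges_a[k])]]
      cb <- comp[[as.character(edges_b[k])]]
      if (ca != cb) {
        comp[comp == max(ca, cb)] <- min(ca, cb)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

analyze_fixture <- function(fx, config = run_config(window_min = c(0, Inf))) {
  analyze_movie(fx$movie, no_field, config)
}
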