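#' Analyze one labeled movie end to end
#'
#' Runs the full measurement chain on a movie whose labels are persistent
#' track ids (use [link_tracks()] first if they are not): shape states and
#' velocities, contact detection and localization, contact events,
#' clusters, interaction samples, the contact-position by neighbour-speed
#' response map (within the analysis window), and the directionality time
#' series.
#'
#' @param movie A [labeled_movie()].
#' @param schedule A [field_schedule()].
#' @param config A [run_config()].
#' @param tracks Optional precomputed track table (with `cell_id`, `frame`,
#'   `x_um`, `y_um` and ellipse columns); computed from the movie when
#'   omitted.
#' @return A list of class `movie_analysis` with elements `tracks`,
#'   `contacts`, `events`, `clusters`, `samples`, `map` (a
#'   [response_map()]), `direction` (the [directionality()] series),
#'   `morphology` (the [morphology_speed_curves()]), plus `schedule`,
#'   `config`, `dt`, and `config_hash`.
#' @export
analyze_movie <- function(movie, schedule, config = run_config(),
                          tracks = NULL) {
  dt <- movie$dt
  if (is.null(tracks)) tracks <- cell_states(movie)
  tracks <- compute_velocities(tracks, dt, allow_gaps = config$allow_gaps)
  contacts <- detect_contacts(movie, connectivity = config$connectivity)
  contacts <- localize_contacts(contacts, tracks)
  events <- build_events(contacts, dt, gap_tolerance = config$gap_tolerance)
  clusters <- find_clusters(contacts, tracks)
  samples <- build_interaction_samples(tracks, contacts, schedule, dt,
                                       pairwise_only = config$pairwise_only)
  win <- config$window_min
  in_win <- samples$frame * dt >= win[1] & samples$frame * dt < win[2]
  map <- response_map(samples[in_win, , drop = FALSE],
                      phi_bins = config$phi_bins,
                      slow_max = config$slow_max, fast_min = config$fast_min,
                      n_min = config$n_min, tau = config$tau)
  direction <- directionality(tracks, schedule, dt)
  morphology <- morphology_speed_curves(tracks)
  structure(
    list(tracks = tracks, contacts = contacts, events = events,
         clusters = clusters, samples = samples, map = map,
         direction = direction, morphology = morphology,
         schedule = schedule, config = config, dt = dt,
         config_hash = config_hash(config)),
    class = "movie_analysis")
}

#' @export
print.movie_analysis <- function(x, ...) {
  cat(sprintf(
    "<movie_analysis> %d track rows, %d oriented contacts, %d events, %d samples (config %s)\n",
    nrow(x$tracks), nrow(x$contacts), nrow(x$events), nrow(x$samples),
    x$config_hash))
  invisible(x)
}

window_filter <- function(df, dt, window_min) {
  t <- df$frame * dt
  df[t >= window_min[1] & t < window_min[2], , drop = FALSE]
}

#' Compare two analyzed conditions
#'
#' Condition-level comparisons of contact statistics inside the analysis
#' window, each with a two-sided Mann-Whitney p value: interface length,
#' event duration, cluster size, and cluster speed per cluster size. The
#' p values are reported uncorrected, as pointwise tests.
#'
#' @param x,y `movie_analysis` objects (e.g. control and electrotaxis).
#' @param labels Length-2 character naming the conditions.
#' @return A list with `summary` (tibble: `comparison`, `n_a`, `n_b`,
#'   `mean_a`, `mean_b`, `p_value`) and `cluster_speed` (the per-size
#'   table of [cluster_speed_comparison()]).
#' @export
compare_conditions <- function(x, y, labels = c("control", "field")) {
  win <- x$config$window_min
  pull_stats <- function(an) {
    ev <- an$events
    t_start <- ev$start_frame * an$dt
    list(
      interface = window_filter(
        an$contacts[an$contacts$focal_id < an$contacts$neighbor_id, ],
        an$dt, win)$interface_length_um,
      duration = ev$duration_min[t_start >= win[1] & t_start < win[2]],
      cluster_size = window_filter(an$clusters, an$dt, win)$size)
  }
  sa <- pull_stats(x); sb <- pull_stats(y)
  one <- function(name, a, b) {
    if (!length(a) || !length(b)) return(NULL)
    tst <- two_sample_test(a, b)
    tibble::tibble(comparison = name, n_a = length(a), n_b = length(b),
                   mean_a = mean(a), mean_b = mean(b),
                   p_value = tst$p_value)
  }
  summary <- dplyr::bind_rows(
    one("interface_length_um", sa$interface, sb$interface),
    one("event_duration_min", sa$duration, sb$duration),
    one("cluster_size", sa$cluster_size, sb$cluster_size))
  cl <- cluster_speed_comparison(window_filter(x$clusters, x$dt, win),
                                 window_filter(y$clusters, y$dt, win))
  list(labels = labels, summary = summary, cluster_speed = cl)
}

#' Run the pipeline and write a report bundle
#'
#' Orchestrates [analyze_movie()] on an experiment movie (and optionally a
#' control movie), runs the condition comparisons and, when the schedule
#' contains a field reversal, the perpendicular-velocity reversal test,
#' and writes all artifacts to `output_dir`: track, contact, event,
#' cluster and interaction-sample CSVs, the response map as JSON, and a
#' markdown summary in which every p value is labeled with its comparison.
#' Outputs are deterministic given inputs and configuration; every
#' artifact embeds the configuration hash.
#'
#' @param movie A [labeled_movie()] (the experiment condition).
#' @param schedule A [field_schedule()] for `movie`.
#' @param output_dir Directory for artifacts (created if needed); `NULL`
#'   writes nothing.
#' @param control Optional control [labeled_movie()].
#' @param control_schedule Schedule for the control movie (default: field
#'   never on).
#' @param config A [run_config()].
#' @param tracks,control_tracks Optional precomputed track tables.
#' @return A list of class `pipeline_result`: `experiment` and (optionally)
#'   `control` analyses, `comparisons`, `reversal` (a
#'   [reversal_comparison()] or `NULL`), and `config`.
#' @export
run_pipeline <- function(movie, schedule, output_dir = NULL,
                         control = NULL,
                         control_schedule = field_schedule(
                           t_on = numeric(0), t_off = numeric(0),
                           ex = numeric(0), ey = numeric(0)),
                         config = run_config(),
                         tracks = NULL, control_tracks = NULL) {
  exp_an <- analyze_movie(movie, schedule, config, tracks = tracks)
  ctl_an <- if (!is.null(control)) {
    analyze_movie(control, control_schedule, config, tracks = control_tracks)
  }
  comparisons <- if (!is.null(ctl_an)) {
    compare_conditions(ctl_an, exp_an, labels = c("control", "experiment"))
  }
  reversal <- if (!is.na(reversal_time(schedule))) {
    reversal_comparison(exp_an$tracks, schedule, exp_an$dt)
  }
  res <- structure(
    list(experiment = exp_an, control = ctl_an, comparisons = comparisons,
         reversal = reversal, config = config,
         config_hash = exp_an$config_hash),
    class = "pipeline_result")
  if (!is.null(output_dir)) write_bundle(res, output_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> config %s\n", x$config_hash))
  print(x$experiment)
  if (!is.null(x$comparisons)) print(x$comparisons$summary)
  invisible(x)
}

stamp <- function(df, hash) dplyr::mutate(df, config_hash = hash)

write_bundle <- function(res, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  h <- res$config_hash
  an <- res$experiment
  out <- function(name) file.path(output_dir, name)
  readr::write_csv(stamp(write_ready_tracks(an$tracks), h), out("tracks.csv"),
                   progress = FALSE)
  readr::write_csv(
    stamp(dplyr::select(
      an$contacts, "frame", "focal_id", "neighbor_id",
      interface_length_um = "interface_length_um",
      contact_x_um = "contact_x_um", contact_y_um = "contact_y_um",
      phi_rad = "phi_rad"), h),
    out("contacts.csv"), progress = FALSE)
  readr::write_csv(stamp(an$events, h), out("events.csv"), progress = FALSE)
  readr::write_csv(
    stamp(dplyr::mutate(
      an$clusters,
      member_ids = purrr::map_chr(.data$member_ids,
                                  ~ paste(.x, collapse = ";"))), h),
    out("clusters.csv"), progress = FALSE)
  readr::write_csv(stamp(an$samples, h), out("interactions.csv"),
                   progress = FALSE)
  readr::write_csv(stamp(an$direction, h), out("directionality.csv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(config = unclass(res$config), config_hash = h,
         phi_edges = an$map$phi_edges, speed_classes = an$map$speed_classes,
         cells = an$map$cells),
    out("response_map.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(render_summary(res), out("summary.md"))
  invisible(output_dir)
}

write_ready_tracks <- function(tracks) {
  dplyr::select(tracks, "cell_id", "frame", "x_um", "y_um",
                dplyr::any_of(c("vx_umh", "vy_umh", "speed_umh", "area_um2",
                                "aspect_ratio", "ellipse_a_um",
                                "ellipse_b_um", "ellipse_theta_rad")))
}

render_summary <- function(res) {
  an <- res$experiment
  drops <- attr(an$samples, "drop_counts")
  lines <- c(
    "# Pipeline summary",
    "",
    sprintf("- config hash: `%s`", res$config_hash),
    sprintf("- track rows: %d; oriented contacts: %d; events: %d; clusters: %d",
            nrow(an$tracks), nrow(an$contacts), nrow(an$events),
            nrow(an$clusters)),
    sprintf("- interaction samples kept: %d; dropped: %s (kept + dropped = %d oriented contacts)",
            nrow(an$samples),
            paste(sprintf("%s = %d", names(drops), drops), collapse = ", "),
            attr(an$samples, "n_oriented_contacts")),
    "",
    "## Response map (analysis window)",
    "")
  labeled <- an$map$cells[!is.na(an$map$cells$label), , drop = FALSE]
  lines <- c(lines, if (nrow(labeled)) {
    sprintf("- phi [%.2f, %.2f) x %s: n = %d, mean CIL = %.3f, mean alignment = %.3f -> %s",
            labeled$phi_lo, labeled$phi_hi, labeled$speed_class, labeled$n,
            labeled$mean_cil, labeled$mean_alignment, labeled$label)
  } else "- no grid cell reached the n_min sample threshold")
  if (!is.null(res$comparisons)) {
    s <- res$comparisons$summary
    lines <- c(lines, "", "## Condition comparisons (Mann-Whitney, two-sided, uncorrected)", "")
    if (!is.null(s) && nrow(s)) {
      lines <- c(lines, sprintf(
        "- %s: mean %s = %.3g vs mean %s = %.3g, p = %.3g",
        s$comparison, res$comparisons$labels[1], s$mean_a,
        res$comparisons$labels[2], s$mean_b, s$p_value))
    }
    cl <- res$comparisons$cluster_speed
    if (!is.null(cl) && nrow(cl)) {
      lines <- c(lines, sprintf(
        "- cluster speed, size %d: mean %.3g vs %.3g (%.1f%% apart), p = %.3g",
        cl$size, cl$mean_a, cl$mean_b, cl$pct_diff, cl$p_value))
    }
  }
  if (!is.null(res$reversal)) {
    lines <- c(lines, "", "## Field reversal", "", sprintf(
      "- vy pre vs post reversal (t = %g min): Mann-Whitney U = %g, two-sided p = %.3g",
      res$reversal$t_reversal, res$reversal$statistic, res$reversal$p_value))
  }
  c(lines, "",
    "p values are pointwise and uncorrected for multiple comparisons.")
}

#' Read and write track tables as CSV
#'
#' The on-disk schema is `cell_id, frame, x_um, y_um, vx_umh, vy_umh,
#' speed_umh, area_um2, aspect_ratio, ellipse_a_um, ellipse_b_um,
#' ellipse_theta_rad`; missing velocities are empty fields.
#'
#' @param tracks A track table.
#' @param path CSV path.
#' @return `read_tracks` returns a tibble; `write_tracks` returns `path`
#'   invisibly.
#' @export
write_tracks <- function(tracks, path) {
  readr::write_csv(write_ready_tracks(tracks), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
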