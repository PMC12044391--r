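#' Unpaired two-sided Mann-Whitney U test
#'
#' Thin wrapper over the rank-sum test with the policy used throughout the
#' package: an exact p value when the combined sample size is at most 20
#' and there are no ties, otherwise the normal approximation with tie and
#' continuity correction. The U statistic is reported for the first sample.
#'
#' @param a,b Numeric samples; both must be non-empty.
#' @return A one-row tibble: `statistic` (U for `a`), `p_value`, `n_a`,
#'   `n_b`, `method` ("exact" or "normal_approx").
#' @export
two_sample_test <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  has_ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 20) && !has_ties
  res <- stats::wilcox.test(a, b, alternative = "two.sided",
                            exact = exact, correct = TRUE)
  tibble::tibble(
    statistic = unname(res$statistic),
    p_value = res$p.value,
    n_a = length(a), n_b = length(b),
    method = if (exact) "exact" else "normal_approx")
}

# FNV-1a over a string; tiny stable checksum for provenance stamping.
# 32-bit arithmetic carried in doubles, multiplication split into 16-bit
# halves to stay within exact double precision.
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    h <- h - (h %% 256) + bitwXor(as.integer(h %% 256), as.integer(b))
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * p) %% 65536) * 65536 + h0 * p) %% 4294967296
  }
  sprintf("%08x", h)
}

#' Pipeline configuration
#'
#' Collects the analysis parameters shared across the pipeline stages;
#' every written artifact embeds this configuration (and its hash) for
#' provenance.
#'
#' @param connectivity Pixel adjacency establishing contact (8 or 4).
#' @param gap_tolerance Missing frames merged inside a contact event.
#' @param slow_max,fast_min Neighbour-speed class thresholds, um/h.
#' @param phi_bins Number of contact-angle bins on `[0, pi]`.
#' @param n_min Minimum valid samples for a behaviour label.
#' @param tau Dead zone of the behaviour classification.
#' @param pairwise_only Restrict interaction samples to two-cell clusters.
#' @param allow_gaps Span track gaps when differentiating positions.
#' @param max_link_um,max_gap,max_gap_um Linker settings (used only when
#'   tracks are linked here rather than supplied).
#' @param window_min Analysis window in minutes for condition statistics
#'   and response maps; default `c(60, 180)`, the first field-on period.
#' @param seed Seed recorded for provenance.
#' @return A list of class `run_config`.
#' @export
run_config <- function(connectivity = 8, gap_tolerance = 0,
                       slow_max = 50, fast_min = 100,
                       phi_bins = 8, n_min = 5, tau = 0.1,
                       pairwise_only = TRUE, allow_gaps = FALSE,
                       max_link_um = 100, max_gap = 3, max_gap_um = 150,
                       window_min = c(60, 180), seed = 1) {
  structure(as.list(environment()), class = "run_config")
}

config_hash <- function(config) {
  fnv1a(as.character(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                      digits = NA)))
}
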