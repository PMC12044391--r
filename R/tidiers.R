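#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a response map
#'
#' @param x A [response_map()].
#' @param ... Unused.
#' @return The per-grid-cell tibble (`phi_bin`, `phi_lo`, `phi_hi`,
#'   `speed_class`, `n`, `n_cil`, `n_alignment`, `mean_cil`,
#'   `mean_alignment`, `label`).
#' @export
tidy.response_map <- function(x, ...) x$cells

#' @rdname tidy.response_map
#' @return For `glance`: a one-row tibble with the total sample count, the
#'   number of labeled grid cells, and the overall mean CIL and alignment
#'   (weighted by valid samples).
#' @export
glance.response_map <- function(x, ...) {
  cells <- x$cells
  wmean <- function(m, w) {
    ok <- !is.na(m) & w > 0
    if (!any(ok)) return(NA_real_)
    sum(m[ok] * w[ok]) / sum(w[ok])
  }
  tibble::tibble(
    n_samples = sum(cells$n),
    n_cells_labeled = sum(!is.na(cells$label)),
    mean_cil = wmean(cells$mean_cil, cells$n_cil),
    mean_alignment = wmean(cells$mean_alignment, cells$n_alignment))
}

#' Tidy a reversal comparison
#'
#' @param x A [reversal_comparison()].
#' @param ... Unused.
#' @return For `tidy`: one row per period (pre/post) with sample size,
#'   mean and sd of the perpendicular velocity. For `glance`: a one-row
#'   tibble with the reversal time, U statistic and p value.
#' @export
tidy.reversal_comparison <- function(x, ...) {
  x$samples |>
    dplyr::group_by(period = factor(.data$period, c("pre", "post"))) |>
    dplyr::summarise(n = dplyr::n(), mean_vy = mean(.data$vy_umh),
                     sd_vy = stats::sd(.data$vy_umh), .groups = "drop")
}

#' @rdname tidy.reversal_comparison
#' @export
glance.reversal_comparison <- function(x, ...) {
  tibble::tibble(t_reversal_min = x$t_reversal, statistic = x$statistic,
                 p_value = x$p_value)
}
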