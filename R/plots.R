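#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_hline labs facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Plot force traces
#'
#' Force versus time, one facet per measurement.
#'
#' @param object A `tf_traces` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tf_traces <- function(object, ...) {
  long <- object |>
    dplyr::mutate(.id = paste(.data$subject_id, .data$session_id,
                              .data$hand, .data$finger)) |>
    tidyr::unnest_longer("force", values_to = "force_gf") |>
    dplyr::group_by(.data$.id) |>
    dplyr::mutate(t_s = (dplyr::row_number() - 1) / .data$rate_hz) |>
    dplyr::ungroup()
  ggplot(long, aes(x = .data$t_s, y = .data$force_gf)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~.id) +
    labs(x = "time (s)", y = "force (gf)") +
    theme_minimal()
}

#' Plot a spectrum
#'
#' @param object A `tf_spectrum`.
#' @param band Optional band to highlight, Hz.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tf_spectrum <- function(object, band = c(3.5, 7.5), ...) {
  kind <- attr(object, "kind") %||% "value"
  ggplot(as_tibble(object), aes(x = .data$freq_hz, y = .data$value)) +
    geom_line() +
    geom_point(size = 0.6) +
    labs(x = "frequency (Hz)",
         y = if (identical(kind, "psd")) "power (gf²)" else "amplitude (gf)") +
    theme_minimal()
}

#' Plot a repeatability sweep
#'
#' Valid-measurement fraction against the validity threshold, per hand.
#'
#' @param object A `repeatability_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.repeatability_report <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$threshold, y = .data$valid_rel,
             colour = .data$hand)) +
    geom_line() +
    geom_point() +
    labs(x = "peak power proportion threshold",
         y = "fraction of valid measurements", colour = "hand") +
    theme_minimal()
}
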