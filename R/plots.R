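#' Probe-ratio profile plot
#'
#' Relative peak area per probe along the panel, faceted by sample, with
#' the calling band (1 - delta, 1 + delta) drawn as dashed lines.  The
#' standard way to eyeball a deletion (points dropping below the band) or
#' duplication (points rising above it).
#'
#' @param calls An `azf_calls` tibble from [call_samples()].
#' @param samples Optional sample ids to restrict to.
#' @param delta Calling threshold drawn as the band (defaults to the value
#'   the calls were made with).
#' @return A ggplot object.
#' @export
plot_probe_ratios <- function(calls, samples = NULL,
                              delta = attr(calls, "delta") %||% 0.3) {
  d <- as_tibble(calls) |> filter(!.data$is_reference)
  if (!is.null(samples)) d <- d |> filter(.data$sample_id %in% samples)
  d$probe_id <- factor(d$probe_id, levels = unique(calls$probe_id))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$probe_id, y = .data$ratio,
                                  colour = .data$region)) +
    ggplot2::geom_hline(yintercept = c(1 - delta, 1 + delta),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = 1, colour = "grey70") +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$sample_id)) +
    ggplot2::labs(x = NULL, y = "relative peak area", colour = "region") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' @rdname plot_probe_ratios
#' @param object An `azf_calls` tibble.
#' @param ... Passed to [plot_probe_ratios()].
#' @export
autoplot.azf_calls <- function(object, ...) plot_probe_ratios(object, ...)

#' Forest plot of association odds ratios
#'
#' Odds ratios with Wald 95 percent intervals on a log scale, one panel per
#' case group; rows with undefined ORs (zero cells) are omitted.
#'
#' @param object An `azf_association` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.azf_association <- function(object, ...) {
  d <- tidy(object) |> filter(!is.na(.data$or))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lo,
                                         xmax = .data$ci_hi), height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$case_group)) +
    ggplot2::labs(x = "odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal(base_size = 9)
}

#' Marker-presence map of the virtual STS comparison
#'
#' Tile map of the predicted presence/absence of each EAA/EMQN marker per
#' catalogue class, annotated with the STS-PCR outcome.
#'
#' @param object An `azf_sts_comparison` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.azf_sts_comparison <- function(object, ...) {
  d <- object$by_class |>
    tidyr::pivot_longer(cols = dplyr::all_of(sts_markers()$marker),
                        names_to = "marker", values_to = "band")
  d$marker <- factor(d$marker, levels = sts_markers()$marker)
  d$class_id <- factor(d$class_id, levels = rev(object$by_class$class_id))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$marker, y = .data$class_id,
                                  fill = .data$band)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(`+` = "grey75", `-` = "firebrick"),
                               name = "fragment") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 9)
}
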