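#' Plot per-day deviation scores with flagged days highlighted
#'
#' Line-and-point time series of the score with the threshold drawn and
#' flagged days emphasized, the conventional presentation for daily
#' deviation indices.
#'
#' @param object a `drift_scores` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot drift_scores
#' @export
autoplot.drift_scores <- function(object, ...) {
  lab <- switch(attr(object, "index") %||% "score",
                wadi = "Activity deviation index",
                sdp = "Sleep deviation score",
                "Deviation score")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$day, y = .data$score)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$threshold),
                       linetype = "dashed", colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$flagged), size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "red"),
                                 name = "Flagged") +
    ggplot2::labs(x = "Day", y = lab) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.drift_scores
#' @param x a `drift_scores` tibble.
#' @param y ignored.
#' @export
plot.drift_scores <- function(x, y, ...) print(autoplot.drift_scores(x, ...))

#' Plot the overlap of activity- and sleep-flagged days
#'
#' @param object an [overlap_days()] report.
#' @param ... unused.
#' @return a ggplot showing, per flagged day, which index flagged it.
#' @method autoplot overlap_report
#' @export
autoplot.overlap_report <- function(object, ...) {
  d <- tidy.overlap_report(object)
  long <- tidyr::pivot_longer(d, c("wadi_flagged", "sdp_flagged"),
                              names_to = "index", values_to = "flagged")
  long$index <- ifelse(long$index == "wadi_flagged", "WADI", "SDP")
  ggplot2::ggplot(long[long$flagged, , drop = FALSE],
                  ggplot2::aes(x = .data$day, y = .data$index)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$overlap), size = 3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red"),
                                 name = "Both indices") +
    ggplot2::labs(x = "Day", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
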