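# ggplot2 displays for the analytics result objects

#' Elbow plot of a WSS curve
#'
#' Total within-cluster sum of squares against the number of clusters, with
#' the elbow chosen by [choose_k()] marked.
#'
#' @param object A [wss_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wss_curve
#' @export
autoplot.wss_curve <- function(object, ...) {
  k_star <- choose_k(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$wss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = k_star, linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = object$k) +
    ggplot2::labs(x = "Number of clusters k",
                  y = "Total within-cluster sum of squares",
                  title = paste0("Elbow at k = ", k_star)) +
    ggplot2::theme_minimal()
}

#' Count distribution of a trait grouping
#'
#' Histogram of per-accession post-composed trait counts coloured by group
#' letter, with the centroid-derived boundaries marked.
#'
#' @param object A [group_accessions()] result.
#' @param binwidth Histogram bin width (default 1 count).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trait_grouping
#' @export
autoplot.trait_grouping <- function(object, binwidth = 1, ...) {
  ggplot2::ggplot(object$labels,
                  ggplot2::aes(x = .data$count, fill = .data$group)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0) +
    ggplot2::geom_vline(xintercept = object$boundaries, linetype = "dashed") +
    ggplot2::labs(x = "Unique post-composed traits per accession",
                  y = "Accessions", fill = "Group") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
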