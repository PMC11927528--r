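# broom-style tidiers for the analytics result objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a WSS curve
#'
#' @param x A [wss_curve()].
#' @param ... Unused.
#' @return A tibble with columns `k`, `wss`, and `curvature` (the second
#'   difference `wss[k-1] - 2 wss[k] + wss[k+1]`, `NA` at the endpoints);
#'   [choose_k()] maximises this scaled by `wss[k]`.
#' @method tidy wss_curve
#' @export
tidy.wss_curve <- function(x, ...) {
  w <- x$wss
  n <- length(w)
  curvature <- rep(NA_real_, n)
  if (n >= 3) {
    idx <- 2:(n - 1)
    curvature[idx] <- w[idx - 1] - 2 * w[idx] + w[idx + 1]
  }
  tibble::tibble(k = x$k, wss = w, curvature = curvature)
}

#' Glance at a WSS curve
#'
#' @param x A [wss_curve()].
#' @param ... Unused.
#' @return A one-row tibble with `k_max`, `chosen_k` (the elbow) and
#'   `wss_at_chosen`.
#' @method glance wss_curve
#' @export
glance.wss_curve <- function(x, ...) {
  k <- choose_k(x)
  tibble::tibble(k_max = max(x$k), chosen_k = k,
                 wss_at_chosen = x$wss[x$k == k])
}

#' Tidy a trait grouping
#'
#' @param x A [group_accessions()] result.
#' @param ... Unused.
#' @return Per-accession labels: a tibble with `accession_id`, `count`,
#'   `group`.
#' @method tidy trait_grouping
#' @export
tidy.trait_grouping <- function(x, ...) {
  x$labels
}

#' Glance at a trait grouping
#'
#' @param x A [group_accessions()] result.
#' @param ... Unused.
#' @return A one-row tibble with `k`, `tot_withinss`, `n_accessions`, and
#'   the boundary list packed as a comma-separated string in `boundaries`.
#' @method glance trait_grouping
#' @export
glance.trait_grouping <- function(x, ...) {
  tibble::tibble(k = x$k, tot_withinss = x$tot_withinss,
                 n_accessions = nrow(x$labels),
                 boundaries = paste(x$boundaries, collapse = ","))
}
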