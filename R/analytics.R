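# Usage analytics over accession x trait observation tables: per-accession
# post-composed trait counts, elbow-method cluster-number selection, k-means
# grouping into lettered strata with centroid-derived count boundaries,
# trait-root frequencies and post/pre ratios.

# is a trait post-composed? substring match on the display name (the store
# appends the COMP identifier to post-composed names), or strict CURIE-prefix
# match on trait_id
.is_post_composed <- function(usage, strict = FALSE) {
  if (strict) {
    startsWith(usage$trait_id, "COMP:")
  } else {
    stringr::str_detect(usage$trait_name, stringr::fixed("COMP"))
  }
}

.check_usage <- function(usage) {
  need <- c("accession_id", "trait_id", "trait_name")
  miss <- setdiff(need, names(usage))
  if (length(miss) > 0) {
    rlang::abort(paste0("usage table is missing column(s): ",
                        paste(miss, collapse = ", ")))
  }
  if (anyNA(usage$accession_id) || anyNA(usage$trait_id)) {
    rlang::abort("usage table has missing accession_id or trait_id values")
  }
  invisible(usage)
}

#' Per-accession post-composed trait counts
#'
#' One row per accession having at least one observation of a post-composed
#' trait: the number of distinct post-composed traits with data and the total
#' number of such observations, sorted descending by total.
#'
#' @param usage Usage table: one row per phenotypic observation with columns
#'   `accession_id`, `accession_name` (optional), `trait_id`, `trait_name`.
#' @param strict If `FALSE` (default) a trait is post-composed when its name
#'   contains the substring `"COMP"`; if `TRUE`, when its `trait_id` has the
#'   `COMP:` prefix.
#'
#' @return A tibble with columns `accession_id`, `accession_name`,
#'   `n_unique_post_traits`, `total_observations`.
#' @export
count_post_per_accession <- function(usage, strict = FALSE) {
  .check_usage(usage)
  if (!"accession_name" %in% names(usage)) {
    usage$accession_name <- as.character(usage$accession_id)
  }
  usage |>
    dplyr::filter(.is_post_composed(usage, strict)) |>
    dplyr::group_by(.data$accession_id, .data$accession_name) |>
    dplyr::summarise(
      n_unique_post_traits = dplyr::n_distinct(.data$trait_id),
      total_observations = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$total_observations), .data$accession_id)
}

#' Within-cluster sum-of-squares curve for the elbow method
#'
#' Standardises the counts (zero mean, unit variance) and, for each k from 1
#' to `k_max`, runs seeded k-means (Lloyd's algorithm, `n_restarts` random
#' initialisations, best solution kept) recording the total within-cluster
#' sum of squares. At k = 1 the WSS equals the total sum of squares of the
#' standardised values, n - 1.
#'
#' @param counts Numeric vector of per-accession counts, or a tibble from
#'   [count_post_per_accession()] (its `n_unique_post_traits` column is used).
#' @param k_max Largest cluster count scanned (default 6). Must not exceed
#'   the number of distinct count values.
#' @param n_restarts Random restarts per k (default 50).
#' @param max_iter Iteration cap per run (default 15).
#' @param seed RNG seed (default 1234).
#'
#' @return A tibble of class `wss_curve` with columns `k` and `wss`.
#' @export
#'
#' @examples
#' wss_curve(c(4, 5, 6, 29, 30, 31, 79, 80, 81), k_max = 4)
wss_curve <- function(counts, k_max = 6, n_restarts = 50, max_iter = 15,
                      seed = 1234) {
  counts <- .as_counts(counts)
  n_distinct <- length(unique(counts))
  if (k_max > n_distinct) {
    rlang::abort(paste0("k_max = ", k_max, " exceeds the number of distinct ",
                        "count values (", n_distinct, ")"))
  }
  x <- scale(counts)
  set.seed(seed)
  wss <- vapply(seq_len(k_max), function(k) {
    stats::kmeans(x, k, nstart = n_restarts, iter.max = max_iter,
                  algorithm = "Lloyd")$tot.withinss
  }, numeric(1))
  out <- tibble::tibble(k = seq_len(k_max), wss = wss)
  class(out) <- c("wss_curve", class(out))
  out
}

.as_counts <- function(counts) {
  if (is.data.frame(counts)) {
    if (!"n_unique_post_traits" %in% names(counts)) {
      rlang::abort("count table must have a n_unique_post_traits column")
    }
    counts <- counts$n_unique_post_traits
  }
  stopifnot(is.numeric(counts), length(counts) >= 1)
  counts
}

#' Choose the cluster count at the elbow of a WSS curve
#'
#' Automates the visual elbow rule: returns the k in `2..k_max - 1` that
#' maximises the relative curvature of the curve, the second difference
#' `WSS(k - 1) - 2 WSS(k) + WSS(k + 1)` scaled by `WSS(k)`. Scaling by the
#' local level makes the rule pick the last k at which the curve still drops
#' by a large factor — the bend a reader identifies on the log-like decay of
#' a WSS plot — rather than the first big absolute drop. Ties break toward
#' smaller k.
#'
#' @param curve A [wss_curve()] (or tibble with columns `k`, `wss` covering
#'   k = 1..k_max with `k_max >= 3`).
#'
#' @return The chosen k, an integer.
#' @export
choose_k <- function(curve) {
  stopifnot(all(c("k", "wss") %in% names(curve)))
  curve <- dplyr::arrange(curve, .data$k)
  k_max <- max(curve$k)
  if (k_max < 3 || !identical(as.integer(curve$k), seq_len(k_max))) {
    rlang::abort("WSS curve must cover k = 1..k_max with k_max >= 3")
  }
  w <- curve$wss
  eligible <- 2:(k_max - 1)
  eps <- 1e-12 * max(w[1], 1)  # guards perfectly separated solutions
  curvature <- (w[eligible - 1] - 2 * w[eligible] + w[eligible + 1]) /
    (w[eligible] + eps)
  eligible[which.max(curvature)]
}

# round half up to an integer (0.5 always moves away from zero upward),
# unlike round()'s round-half-even
.round_half_up <- function(x) floor(x + 0.5)

#' Group accessions by k-means on raw trait counts
#'
#' Runs k-means (Lloyd, seeded restarts) on the raw per-accession counts of
#' distinct post-composed traits, derives k - 1 count boundaries as the
#' midpoints between adjacent sorted centroids (rounded half-up to integers),
#' and labels each accession by thresholding its count against the
#' boundaries — not by raw cluster membership — so the groups read as
#' "A (>= x)", "B (>= y, < x)", "C (< y)". Group A has the highest centroid.
#'
#' @param counts As in [wss_curve()]: a numeric vector or a
#'   [count_post_per_accession()] tibble.
#' @param k Number of groups (default 3); must be at least 2 and no larger
#'   than the number of distinct count values.
#' @param n_restarts,max_iter,seed k-means settings as in [wss_curve()].
#'
#' @return An object of class `trait_grouping`: a list with `k`, `centroids`
#'   (raw-scale, named by group letter, descending), `boundaries`
#'   (increasing integer thresholds), `group_defs` (tibble of group letter
#'   and count band) and `labels` (tibble of `accession_id`, `count`,
#'   `group`; `accession_id` is the input row order index when a bare numeric
#'   vector was supplied).
#' @export
#'
#' @examples
#' g <- group_accessions(c(4, 5, 6, 29, 30, 31, 79, 80, 81), k = 3)
#' g$boundaries
group_accessions <- function(counts, k = 3, n_restarts = 50, max_iter = 15,
                             seed = 1234) {
  tbl <- if (is.data.frame(counts)) counts else NULL
  counts <- .as_counts(counts)
  if (k < 2) rlang::abort("k must be at least 2")
  if (k > length(unique(counts))) {
    rlang::abort(paste0("k = ", k, " exceeds the number of distinct count values"))
  }
  set.seed(seed)
  km <- stats::kmeans(counts, centers = k, nstart = n_restarts,
                      iter.max = max_iter, algorithm = "Lloyd")
  centers <- sort(as.numeric(km$centers))            # ascending
  boundaries <- .round_half_up((centers[-k] + centers[-1]) / 2)
  if (any(diff(boundaries) <= 0)) {
    rlang::abort("degenerate clustering: boundaries are not strictly increasing")
  }
  letters_desc <- LETTERS[seq_len(k)]                # A = highest centroid
  centroids <- stats::setNames(rev(centers), letters_desc)
  labels <- .assign_groups(counts, boundaries, k)
  ids <- if (!is.null(tbl) && "accession_id" %in% names(tbl)) {
    tbl$accession_id
  } else {
    seq_along(counts)
  }
  group_defs <- tibble::tibble(
    group = letters_desc,
    min_count = c(rev(boundaries), NA),
    max_count_excl = c(NA, rev(boundaries))
  )
  structure(
    list(k = k, centroids = centroids, boundaries = as.numeric(boundaries),
         group_defs = group_defs, tot_withinss = km$tot.withinss,
         labels = tibble::tibble(accession_id = ids, count = counts,
                                 group = labels)),
    class = "trait_grouping"
  )
}

# threshold counts against increasing boundaries; highest band -> "A"
.assign_groups <- function(counts, boundaries, k) {
  band <- findInterval(counts, boundaries)  # 0..k-1, k-1 = top band
  LETTERS[k - band]
}

#' @export
print.trait_grouping <- function(x, ...) {
  cat("<trait_grouping> k = ", x$k, "\n", sep = "")
  defs <- vapply(seq_len(x$k), function(i) {
    lo <- x$group_defs$min_count[i]
    hi <- x$group_defs$max_count_excl[i]
    paste0(x$group_defs$group[i], " (",
           if (!is.na(lo)) paste0(">=", lo) else "",
           if (!is.na(lo) && !is.na(hi)) ", " else "",
           if (!is.na(hi)) paste0("<", hi) else "", ")")
  }, character(1))
  cat("groups:", paste(defs, collapse = "  "), "\n")
  cat("centroids:", paste(sprintf("%s=%.2f", names(x$centroids), x$centroids),
                          collapse = "  "), "\n")
  invisible(x)
}

#' Trait-root frequencies
#'
#' Extracts the trait root (first pipe-delimited segment) of every trait
#' name, sums appearance counts per root and ranks them descending. The
#' appearance count of a trait is its number of observation rows, optionally
#' within an accession subset.
#'
#' @param usage Usage table as in [count_post_per_accession()].
#' @param accession_subset Optional vector of `accession_id`s to restrict to
#'   (e.g. the members of one group).
#' @param post_only Keep only post-composed traits (default `TRUE`,
#'   mirroring group-level trait-root summaries).
#' @param strict Passed to the post-composed test; see
#'   [count_post_per_accession()].
#' @param top Optional head size, e.g. `10` for a top-10 slice.
#'
#' @return A tibble with columns `root` and `frequency`, sorted descending
#'   by frequency then by root.
#' @export
trait_root_frequency <- function(usage, accession_subset = NULL,
                                 post_only = TRUE, strict = FALSE, top = NULL) {
  .check_usage(usage)
  if (!is.null(accession_subset)) {
    usage <- dplyr::filter(usage, .data$accession_id %in% accession_subset)
  }
  if (post_only) usage <- dplyr::filter(usage, .is_post_composed(usage, strict))
  out <- usage |>
    dplyr::count(.data$trait_id, .data$trait_name, name = "appearance_count") |>
    dplyr::mutate(root = trait_root(.data$trait_name)) |>
    dplyr::group_by(.data$root) |>
    dplyr::summarise(frequency = sum(.data$appearance_count), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$root)
  if (!is.null(top)) out <- utils::head(out, top)
  out
}

#' Post-composed to pre-composed usage ratio
#'
#' The ratio of post-composed to pre-composed counts, reported at full
#' precision and rounded to 3 decimals. When `n_pre` is zero the ratio is
#' undefined and reported as `NA` alongside the bare counts.
#'
#' @param n_post,n_pre Non-negative counts (vectorised).
#'
#' @return A tibble with columns `n_post`, `n_pre`, `ratio` (full precision,
#'   `NA` when `n_pre == 0`) and `ratio_3dp`.
#' @export
#'
#' @examples
#' post_pre_ratio(c(370, 2303, 35), c(579, 359, 231))
post_pre_ratio <- function(n_post, n_pre) {
  stopifnot(length(n_post) == length(n_pre),
            all(n_post >= 0), all(n_pre >= 0))
  ratio <- ifelse(n_pre > 0, n_post / n_pre, NA_real_)
  tibble::tibble(n_post = n_post, n_pre = n_pre, ratio = ratio,
                 ratio_3dp = round(ratio, 3))
}

#' Per-group usage summary
#'
#' Summarises trait usage per group band in the structure of the
#' comparative-analysis tables: number of accessions without post-composed
#' traits falling in the band, number with, and the number of unique
#' post-composed and pre-composed traits observed by the band's accessions.
#' Accessions with no post-composed observations are placed in a band by
#' their pre-composed trait count (their post-composed count, zero, carries
#' no grouping signal).
#'
#' @param usage Usage table as in [count_post_per_accession()].
#' @param grouping A [group_accessions()] result computed on the same table.
#' @param strict Passed to the post-composed test.
#'
#' @return A tibble with columns `group`, `n_without`, `n_with`,
#'   `n_unique_post`, `n_unique_pre`, one row per group letter. An empty
#'   usage table yields a single all-zero group.
#' @export
group_summary <- function(usage, grouping, strict = FALSE) {
  .check_usage(usage)
  if (nrow(usage) == 0) {
    return(tibble::tibble(group = "A", n_without = 0L, n_with = 0L,
                          n_unique_post = 0L, n_unique_pre = 0L))
  }
  stopifnot(inherits(grouping, "trait_grouping"))
  is_post <- .is_post_composed(usage, strict)
  per_acc <- usage |>
    dplyr::mutate(post = is_post) |>
    dplyr::group_by(.data$accession_id) |>
    dplyr::summarise(
      n_post = dplyr::n_distinct(.data$trait_id[.data$post]),
      n_pre = dplyr::n_distinct(.data$trait_id[!.data$post]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      has_post = .data$n_post > 0,
      band_count = ifelse(.data$has_post, .data$n_post, .data$n_pre),
      group = .assign_groups(.data$band_count, grouping$boundaries, grouping$k)
    )
  traits_by_group <- usage |>
    dplyr::mutate(post = is_post) |>
    dplyr::left_join(dplyr::select(per_acc, "accession_id", "group"),
                     by = "accession_id") |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_unique_post = dplyr::n_distinct(.data$trait_id[.data$post]),
      n_unique_pre = dplyr::n_distinct(.data$trait_id[!.data$post]),
      .groups = "drop"
    )
  per_acc |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_without = sum(!.data$has_post),
                     n_with = sum(.data$has_post), .groups = "drop") |>
    dplyr::left_join(traits_by_group, by = "group") |>
    tidyr::complete(group = LETTERS[seq_len(grouping$k)],
                    fill = list(n_without = 0L, n_with = 0L,
                                n_unique_post = 0L, n_unique_pre = 0L)) |>
    dplyr::arrange(.data$group)
}

#' Read a usage table from a delimited text file
#'
#' @param path Path to a file with a header row and columns `accession_id`,
#'   `accession_name`, `trait_id`, `trait_name`, `observation_unit_id`.
#' @param delim Field delimiter (default tab; use `","` for CSV).
#'
#' @return A usage tibble.
#' @export
read_usage_table <- function(path, delim = "\t") {
  df <- utils::read.delim(path, sep = delim, header = TRUE,
                          colClasses = "character",
                          check.names = FALSE, quote = "\"")
  .check_usage(tibble::as_tibble(df))
}

#' Write a usage table to a delimited text file
#' @param usage A usage tibble.
#' @param path Output path.
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_usage_table <- function(usage, path, delim = "\t") {
  utils::write.table(usage, path, sep = delim, quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
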