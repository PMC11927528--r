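# Deterministic generators for toy ontologies and synthetic usage tables
# with planted cluster structure, so every other module is testable without
# any external download. All names and identifiers here are synthetic.

#' Specify a synthetic fixture suite
#'
#' One spec object drives both generators. A fixed seed makes every output
#' byte-identical across runs.
#'
#' @param seed RNG seed fixing all generated content (default 1234).
#' @param n_trait_terms Number of trait-ontology terms (>= 1).
#' @param n_object,n_attribute,n_time,n_event Per-category orthogonal
#'   ontology sizes (any may be 0; a category of size 0 emits no ontology).
#' @param centroids Strictly increasing planted cluster centres of
#'   per-accession unique post-composed trait counts (default `c(5, 30, 80)`).
#' @param sd Within-cluster standard deviation of the planted counts.
#' @param n_per_cluster Accessions per planted cluster (default 100).
#' @param pre_fraction Target fraction of pre-composed observation rows in
#'   the usage table (default 0.5).
#' @param n_post_pool,n_pre_pool Sizes of the synthetic post-composed and
#'   pre-composed trait pools accessions draw from.
#'
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1234, n_trait_terms = 5, n_object = 3,
                         n_attribute = 3, n_time = 4, n_event = 1,
                         centroids = c(5, 30, 80), sd = 2,
                         n_per_cluster = 100, pre_fraction = 0.5,
                         n_post_pool = 120, n_pre_pool = 60) {
  stopifnot(n_trait_terms >= 1, all(diff(centroids) > 0), sd >= 0,
            n_per_cluster >= 1, pre_fraction >= 0, pre_fraction < 1,
            n_post_pool >= 1, n_pre_pool >= 0)
  structure(
    list(seed = seed, n_trait_terms = n_trait_terms, n_object = n_object,
         n_attribute = n_attribute, n_time = n_time, n_event = n_event,
         centroids = centroids, sd = sd, n_per_cluster = n_per_cluster,
         pre_fraction = pre_fraction, n_post_pool = n_post_pool,
         n_pre_pool = n_pre_pool),
    class = "fixture_spec"
  )
}

# synthetic per-category term name stems; names are mutually disjoint across
# categories by construction, so orthogonality holds for any sizes
.fixture_name <- function(category, i) {
  switch(category,
    trait = paste0("trait ", i),
    object = paste0("plant section ", i),
    attribute = paste0("treatment ", i),
    time = paste0("month ", i),
    event = if (i == 1) "after harvest" else paste0("breeding event ", i)
  )
}

.fixture_prefix <- c(trait = "CO_331", object = "OBJ", attribute = "ATTR",
                     time = "TIME", event = "EVENT")

#' Generate toy trait and orthogonal ontologies
#'
#' Emits a trait ontology plus one ontology per requested orthogonal
#' category, with human-readable synthetic names ("month 1".."month N",
#' "after harvest", "plant section i", "treatment i"). The first trait term
#' is `CO_331:0000294`, named "storage root weight" (a synthetic label), so
#' the worked example of a trait composed with time and event terms can be
#' reproduced exactly. Names are disjoint across categories, so the
#' generated set is orthogonal by construction.
#'
#' @param spec A [fixture_spec()].
#'
#' @return A named list of [obo_document()]s (names `trait`, `object`,
#'   `attribute`, `time`, `event`; absent when the size is 0), with a
#'   `categories` attribute mapping document name to category.
#' @export
#'
#' @examples
#' docs <- make_toy_ontologies(fixture_spec(n_time = 4, n_event = 1))
#' obo_ids(docs$time)
make_toy_ontologies <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  sizes <- c(trait = spec$n_trait_terms, object = spec$n_object,
             attribute = spec$n_attribute, time = spec$n_time,
             event = spec$n_event)
  docs <- list()
  for (cat in names(sizes)) {
    if (sizes[[cat]] == 0) next
    terms <- lapply(seq_len(sizes[[cat]]), function(i) {
      if (cat == "trait" && i == 1) {
        obo_term("CO_331:0000294", "storage root weight",
                 def = "\"Synthetic trait term for worked examples.\" []")
      } else {
        obo_term(sprintf("%s:%07d", .fixture_prefix[[cat]], i),
                 .fixture_name(cat, i))
      }
    })
    docs[[cat]] <- obo_document(
      terms,
      header = list("format-version" = "1.2",
                    "ontology" = paste0("toy_", cat, "_ontology"))
    )
  }
  attr(docs, "categories") <- stats::setNames(names(docs), names(docs))
  docs
}

#' Build a store pre-loaded with the worked-example scenario
#'
#' A store holding the toy trait ontology, four time terms ("month 1" to
#' "month 4") and one breeding event ("after harvest"), with exactly one
#' post-composed term already present: `COMP:0000093` containing
#' `CO_331:0000294`, "month 1" and "after harvest". Composing the trait with
#' all four months and the event then yields four candidates of which one is
#' existing and three are novel, and the next minted identifiers are
#' `COMP:0000094` onwards.
#'
#' @param existing_month Which month (1..4) the pre-stored term uses
#'   (default 1; any single choice gives the same 1/3 split).
#'
#' @return A [vocab_store()].
#' @export
fig2_store <- function(existing_month = 1) {
  spec <- fixture_spec(n_trait_terms = 5, n_object = 0, n_attribute = 0,
                       n_time = 4, n_event = 1)
  docs <- make_toy_ontologies(spec)
  store <- vocab_store()
  load_ontology(store, docs$trait, "toy_trait_ontology", "trait")
  load_ontology(store, docs$time, "toy_time_ontology", "time")
  load_ontology(store, docs$event, "toy_event_ontology", "event")
  cand <- tibble::tibble(trait = "CO_331:0000294", object = NA_character_,
                         attribute = NA_character_,
                         time = sprintf("TIME:%07d", existing_month),
                         event = "EVENT:0000001")
  comp_cv <- .store_composed_cv_id(store)
  .store_add_term(store, comp_cv, "COMP:0000093", render_name(store, cand))
  for (cu in c(cand$trait, cand$time, cand$event)) {
    .store_add_relationship(store, "COMP:0000093", cu, "contains")
  }
  store
}

#' Generate a synthetic usage table with planted cluster structure
#'
#' Per planted cluster, each accession's count of unique post-composed
#' traits is drawn from a normal around the cluster centroid (rounded,
#' truncated at 0 and at the post-trait pool size); that many distinct
#' post-composed traits are sampled from a pool whose names carry a trailing
#' COMP identifier segment ("trait root|month m|after harvest|COMP:NNNNNNN"),
#' as stored display names do. Pre-composed observations are added per
#' accession at a rate targeting `pre_fraction` of all rows. One row is one
#' observation with its own `observation_unit_id`.
#'
#' @param spec A [fixture_spec()].
#'
#' @return A list with `usage` (tibble with columns `accession_id`,
#'   `accession_name`, `trait_id`, `trait_name`, `observation_unit_id`) and
#'   `truth` (tibble with `accession_id`, `planted_cluster` (1 = lowest
#'   centroid), `planted_group` (letter, "A" = highest centroid),
#'   `planted_count`).
#' @export
#'
#' @examples
#' fx <- make_usage_data(fixture_spec(n_per_cluster = 10))
#' dplyr::count(fx$truth, planted_group)
make_usage_data <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  k <- length(spec$centroids)
  set.seed(spec$seed)

  post_pool <- tibble::tibble(
    trait_id = sprintf("COMP:%07d", seq_len(spec$n_post_pool)),
    trait_name = paste0(
      "trait ", 1 + (seq_len(spec$n_post_pool) - 1) %% spec$n_trait_terms,
      "|month ", 1 + (seq_len(spec$n_post_pool) - 1) %/% spec$n_trait_terms %% 12,
      "|after harvest",
      "|", sprintf("COMP:%07d", seq_len(spec$n_post_pool))
    )
  )
  pre_pool <- tibble::tibble(
    trait_id = sprintf("CO_331:%07d", 1000 + seq_len(spec$n_pre_pool)),
    trait_name = paste0("trait ", 1000 + seq_len(spec$n_pre_pool),
                        "|", sprintf("CO_331:%07d", 1000 + seq_len(spec$n_pre_pool)))
  )

  n_acc <- k * spec$n_per_cluster
  cluster <- rep(seq_len(k), each = spec$n_per_cluster)
  planted_count <- pmin(
    pmax(round(stats::rnorm(n_acc, spec$centroids[cluster], spec$sd)), 0),
    spec$n_post_pool
  )
  acc_id <- sprintf("ACC%05d", seq_len(n_acc))

  # pre-composed observations per accession: rate chosen so the expected
  # share of pre rows across the table is pre_fraction
  pre_rate <- if (spec$pre_fraction > 0 && spec$n_pre_pool > 0) {
    spec$pre_fraction / (1 - spec$pre_fraction) * mean(spec$centroids)
  } else {
    0
  }
  n_pre <- if (pre_rate > 0) {
    pmin(stats::rpois(n_acc, pre_rate), spec$n_pre_pool)
  } else {
    rep(0L, n_acc)
  }

  rows <- vector("list", n_acc)
  for (i in seq_len(n_acc)) {
    post_idx <- if (planted_count[i] > 0) {
      sample.int(spec$n_post_pool, planted_count[i])
    } else {
      integer()
    }
    pre_idx <- if (n_pre[i] > 0) sample.int(spec$n_pre_pool, n_pre[i]) else integer()
    rows[[i]] <- tibble::tibble(
      accession_id = acc_id[i],
      accession_name = paste0("accession ", i),
      trait_id = c(post_pool$trait_id[post_idx], pre_pool$trait_id[pre_idx]),
      trait_name = c(post_pool$trait_name[post_idx], pre_pool$trait_name[pre_idx])
    )
  }
  usage <- dplyr::bind_rows(rows)
  usage$observation_unit_id <- sprintf("OU%07d", seq_len(nrow(usage)))

  truth <- tibble::tibble(
    accession_id = acc_id,
    planted_cluster = cluster,
    planted_group = LETTERS[k + 1 - cluster],
    planted_count = planted_count
  )
  list(usage = usage, truth = truth)
}

#' Write a full fixture suite to a directory
#'
#' Writes the toy ontologies as OBO files, the synthetic usage table and
#' ground-truth labels as TSV, and a JSON manifest recording the spec (seed
#' included), so a suite regenerates byte-identically from its manifest.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if missing).
#'
#' @return `dir`, invisibly.
#' @export
write_fixture_suite <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  docs <- make_toy_ontologies(spec)
  for (cat in names(docs)) {
    write_obo(docs[[cat]], file.path(dir, paste0(cat, "_ontology.obo")))
  }
  fx <- make_usage_data(spec)
  write_usage_table(fx$usage, file.path(dir, "usage.tsv"))
  write_usage_table(fx$truth, file.path(dir, "truth.tsv"))
  jsonlite::write_json(unclass(spec), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
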