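# Chado-cvterm-style vocabulary store. The four tables of the cvterm module
# (cv, cvprop, cvterm, cvterm_relationship) are kept as tibbles inside an
# environment, so every operation sees and mutates one consistent state, and
# the whole store serialises to a single JSON file.

.store_categories <- c("trait", "object", "attribute", "time", "event", "composed")
.orthogonal_categories <- c("object", "attribute", "time", "event")

#' Create an empty vocabulary store
#'
#' The store mirrors the Chado cvterm module: `cv` (vocabularies), `cvprop`
#' (one `category` property per vocabulary: trait, object, attribute, time,
#' event or composed), `cvterm` (terms with CURIE, name, definition,
#' obsolescence flag) and `cvterm_relationship` (typed object-subject edges;
#' a post-composed term is the object of one `contains` edge per component).
#'
#' @param composed_vocabulary Name of the vocabulary that will hold minted
#'   post-composed terms; created up front with category `"composed"`.
#'
#' @return An object of class `vocab_store` (an environment holding the four
#'   tables).
#' @export
#'
#' @examples
#' store <- vocab_store()
#' store_vocabularies(store)
vocab_store <- function(composed_vocabulary = "composed_trait_ontology") {
  store <- new.env(parent = emptyenv())
  store$cv <- tibble::tibble(cv_id = integer(), name = character())
  store$cvprop <- tibble::tibble(cv_id = integer(), type = character(),
                                 value = character())
  store$cvterm <- tibble::tibble(cvterm_id = integer(), cv_id = integer(),
                                 curie = character(), name = character(),
                                 definition = character(),
                                 is_obsolete = logical())
  store$cvterm_relationship <- tibble::tibble(object_id = integer(),
                                              subject_id = integer(),
                                              type = character())
  class(store) <- "vocab_store"
  .store_add_cv(store, composed_vocabulary, "composed")
  store
}

#' @export
print.vocab_store <- function(x, ...) {
  cat("<vocab_store> ", nrow(x$cv), " vocabularies, ", nrow(x$cvterm),
      " terms, ", nrow(x$cvterm_relationship), " relationships\n", sep = "")
  invisible(x)
}

.store_add_cv <- function(store, name, category) {
  if (!category %in% .store_categories) {
    rlang::abort(paste0("unknown category '", category, "'; must be one of ",
                        paste(.store_categories, collapse = ", ")))
  }
  existing <- dplyr::filter(store$cv, .data$name == !!name)
  if (nrow(existing) > 0) {
    bound <- store_category(store, name)
    if (!identical(bound, category)) {
      rlang::abort(paste0("vocabulary '", name, "' is already bound to category '",
                          bound, "', cannot rebind to '", category, "'"))
    }
    return(existing$cv_id)
  }
  cv_id <- nrow(store$cv) + 1L
  store$cv <- dplyr::bind_rows(store$cv, tibble::tibble(cv_id = cv_id, name = name))
  store$cvprop <- dplyr::bind_rows(
    store$cvprop,
    tibble::tibble(cv_id = cv_id, type = "category", value = category)
  )
  cv_id
}

#' Vocabularies in a store
#' @param store A [vocab_store()].
#' @return Tibble with columns `vocabulary`, `category`, `n_terms`.
#' @export
store_vocabularies <- function(store) {
  store$cv |>
    dplyr::left_join(store$cvprop, by = "cv_id") |>
    dplyr::left_join(
      dplyr::count(store$cvterm, .data$cv_id, name = "n_terms"),
      by = "cv_id"
    ) |>
    dplyr::transmute(vocabulary = .data$name, category = .data$value,
                     n_terms = dplyr::coalesce(.data$n_terms, 0L))
}

#' Category bound to a vocabulary
#' @param store A [vocab_store()].
#' @param vocabulary_name Vocabulary (cv) name.
#' @return A single category string.
#' @export
store_category <- function(store, vocabulary_name) {
  cv <- dplyr::filter(store$cv, .data$name == vocabulary_name)
  if (nrow(cv) == 0) rlang::abort(paste0("unknown vocabulary '", vocabulary_name, "'"))
  dplyr::filter(store$cvprop, .data$cv_id == cv$cv_id,
                .data$type == "category")$value
}

.store_composed_cv_id <- function(store) {
  dplyr::filter(store$cvprop, .data$type == "category",
                .data$value == "composed")$cv_id[1]
}

# low-level term insert; errors on curie collision across vocabularies,
# no-op when the identical curie already sits in the same vocabulary
.store_add_term <- function(store, cv_id, curie, name,
                            definition = NA_character_, is_obsolete = FALSE) {
  hit <- dplyr::filter(store$cvterm, .data$curie == !!curie)
  if (nrow(hit) > 0) {
    if (hit$cv_id != cv_id) {
      here <- store$cv$name[match(cv_id, store$cv$cv_id)]
      there <- store$cv$name[match(hit$cv_id, store$cv$cv_id)]
      rlang::abort(paste0("curie '", curie, "' already belongs to vocabulary '",
                          there, "'; cannot load it into '", here, "'"))
    }
    return(invisible(FALSE))
  }
  dup_name <- dplyr::filter(store$cvterm, .data$cv_id == !!cv_id,
                            .data$name == !!name)
  if (nrow(dup_name) > 0) {
    rlang::abort(paste0("term name '", name, "' already exists in vocabulary; ",
                        "(name, vocabulary) must be unique"))
  }
  store$cvterm <- dplyr::bind_rows(
    store$cvterm,
    tibble::tibble(cvterm_id = nrow(store$cvterm) + 1L, cv_id = cv_id,
                   curie = curie, name = name, definition = definition,
                   is_obsolete = is_obsolete)
  )
  invisible(TRUE)
}

.store_term_id <- function(store, curie) {
  id <- store$cvterm$cvterm_id[match(curie, store$cvterm$curie)]
  if (anyNA(id)) {
    rlang::abort(paste0("unknown curie: ",
                        paste(curie[is.na(id)], collapse = ", ")))
  }
  id
}

.store_add_relationship <- function(store, object_curie, subject_curie, type) {
  oid <- .store_term_id(store, object_curie)
  sid <- .store_term_id(store, subject_curie)
  dup <- dplyr::filter(store$cvterm_relationship, .data$object_id == oid,
                       .data$subject_id == sid, .data$type == !!type)
  if (nrow(dup) > 0) return(invisible(FALSE))
  store$cvterm_relationship <- dplyr::bind_rows(
    store$cvterm_relationship,
    tibble::tibble(object_id = oid, subject_id = sid, type = type)
  )
  invisible(TRUE)
}

#' Load an ontology document into the store
#'
#' Inserts the document's terms into the named vocabulary under the given
#' category, together with their `is_a` and `part_of` edges (edges whose
#' target is absent from the store are skipped). Loading the same document
#' twice is idempotent.
#'
#' @param store A [vocab_store()].
#' @param doc An [obo_document()].
#' @param vocabulary_name Vocabulary (cv) name to load into.
#' @param category One of `"trait"`, `"object"`, `"attribute"`, `"time"`,
#'   `"event"` (or `"composed"` when importing a composed vocabulary).
#'
#' @return Number of terms newly inserted, invisibly a count.
#' @export
load_ontology <- function(store, doc, vocabulary_name, category) {
  stopifnot(inherits(store, "vocab_store"), inherits(doc, "obo_document"))
  cv_id <- .store_add_cv(store, vocabulary_name, category)
  n <- 0L
  for (term in doc$terms) {
    inserted <- .store_add_term(store, cv_id, term$id,
                                term$name %||% term$id,
                                term$def %||% NA_character_,
                                term$is_obsolete)
    n <- n + as.integer(inserted)
  }
  ids <- obo_ids(doc)
  for (term in doc$terms) {
    for (target in .obo_ref_target(term$is_a)) {
      if (target %in% store$cvterm$curie) {
        .store_add_relationship(store, target, term$id, "is_a")
      }
    }
    for (rel in term$relationship) {
      parts <- stringr::str_split_1(stringr::str_trim(.obo_ref_target(rel)), "\\s+")
      if (length(parts) >= 2 && parts[1] %in% c("part_of", "contains") &&
          parts[2] %in% store$cvterm$curie) {
        if (parts[1] == "contains") {
          # the stanza's term contains the target: term is object,
          # component is subject
          .store_add_relationship(store, term$id, parts[2], "contains")
        } else {
          .store_add_relationship(store, parts[2], term$id, "part_of")
        }
      }
    }
  }
  invisible(ids)
  n
}

#' Look up stored terms by CURIE or name
#'
#' @param store A [vocab_store()].
#' @param curie Optional character vector of CURIEs.
#' @param name Optional exact term name (case-sensitive).
#'
#' @return A tibble of stored terms with columns `curie`, `name`,
#'   `vocabulary`, `category`, `definition`, `is_obsolete`.
#' @export
store_terms <- function(store, curie = NULL, name = NULL) {
  out <- store$cvterm |>
    dplyr::left_join(store$cv, by = "cv_id", suffix = c("", ".cv")) |>
    dplyr::left_join(dplyr::filter(store$cvprop, .data$type == "category"),
                     by = "cv_id") |>
    dplyr::transmute(curie = .data$curie, name = .data$name,
                     vocabulary = .data$name.cv, category = .data$value,
                     definition = .data$definition,
                     is_obsolete = .data$is_obsolete)
  if (!is.null(curie)) out <- dplyr::filter(out, .data$curie %in% !!curie)
  if (!is.null(name)) out <- dplyr::filter(out, .data$name %in% !!name)
  out
}

#' Components of a post-composed term
#'
#' Returns the subjects of all `contains` edges whose object is the given
#' composed term — the unordered component set (one trait term plus one term
#' per orthogonal category used).
#'
#' @param store A [vocab_store()].
#' @param comp_curie CURIE of a stored term (typically `COMP:...`).
#'
#' @return A tibble of component terms (columns as [store_terms()]), ordered
#'   by CURIE for determinism; zero rows when the term has no components.
#' @export
#'
#' @examples
#' store <- fig2_store()
#' components_of(store, "COMP:0000093")
components_of <- function(store, comp_curie) {
  oid <- .store_term_id(store, comp_curie)
  subj <- dplyr::filter(store$cvterm_relationship, .data$object_id == oid,
                        .data$type == "contains")$subject_id
  curies <- store$cvterm$curie[match(subj, store$cvterm$cvterm_id)]
  store_terms(store, curie = curies) |> dplyr::arrange(.data$curie)
}

#' Next COMP identifier to mint
#'
#' `COMP:NNNNNNN` with the numeric suffix zero-padded to 7 digits, equal to
#' one plus the largest suffix among stored COMP terms (1 for a store with
#' none). The sequence is strictly increasing across interleaved commits and
#' never reuses a suffix.
#'
#' @param store A [vocab_store()].
#' @return A single CURIE string.
#' @export
#'
#' @examples
#' next_comp_curie(vocab_store())  # "COMP:0000001"
next_comp_curie <- function(store) {
  comp <- store$cvterm$curie[startsWith(store$cvterm$curie, "COMP:")]
  suffix <- suppressWarnings(as.integer(sub("^COMP:", "", comp)))
  suffix <- suffix[!is.na(suffix)]
  nxt <- if (length(suffix) == 0) 1L else max(suffix) + 1L
  sprintf("COMP:%07d", nxt)
}

#' Check that loaded vocabularies are orthogonal
#'
#' Orthogonal ontologies must be non-overlapping: no two non-composed
#' vocabularies may share a term name (case-insensitive) or a CURIE.
#'
#' @param store A [vocab_store()].
#' @return A tibble of violations with columns `vocabulary_a`,
#'   `vocabulary_b`, `kind` (`"name"` or `"curie"`), `value`; zero rows means
#'   the vocabularies are orthogonal.
#' @export
validate_orthogonality <- function(store) {
  terms <- store_terms(store) |>
    dplyr::filter(.data$category != "composed") |>
    dplyr::mutate(name_lc = tolower(.data$name))
  vocabs <- sort(unique(terms$vocabulary))
  out <- list()
  if (length(vocabs) >= 2) {
    pairs <- utils::combn(vocabs, 2, simplify = FALSE)
    for (p in pairs) {
      a <- dplyr::filter(terms, .data$vocabulary == p[1])
      b <- dplyr::filter(terms, .data$vocabulary == p[2])
      shared_names <- intersect(a$name_lc, b$name_lc)
      shared_curies <- intersect(a$curie, b$curie)
      if (length(shared_names) || length(shared_curies)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          vocabulary_a = p[1], vocabulary_b = p[2],
          kind = c(rep("name", length(shared_names)),
                   rep("curie", length(shared_curies))),
          value = c(shared_names, shared_curies)
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(vocabulary_a = character(), vocabulary_b = character(),
                          kind = character(), value = character()))
  }
  dplyr::bind_rows(out)
}

#' Persist a store to a single JSON file
#'
#' The four tables are written as one JSON object, so a store is a single
#' portable file on disk.
#'
#' @param store A [vocab_store()].
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_store <- function(store, path) {
  jsonlite::write_json(
    list(cv = store$cv, cvprop = store$cvprop, cvterm = store$cvterm,
         cvterm_relationship = store$cvterm_relationship),
    path, dataframe = "columns", na = "null", auto_unbox = FALSE, digits = NA
  )
  invisible(path)
}

#' Read a store back from its JSON file
#' @param path File written by [write_store()].
#' @return A [vocab_store()].
#' @export
read_store <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  store <- new.env(parent = emptyenv())
  as_tbl <- function(x, proto) {
    if (length(x) == 0 || (is.data.frame(x) && nrow(x) == 0)) return(proto)
    tibble::as_tibble(lapply(stats::setNames(names(proto), names(proto)),
                             function(col) {
                               v <- x[[col]]
                               storage.mode(v) <- storage.mode(proto[[col]])
                               v
                             }))
  }
  empty <- vocab_store()
  store$cv <- as_tbl(raw$cv, empty$cv[0, ])
  store$cvprop <- as_tbl(raw$cvprop, empty$cvprop[0, ])
  store$cvterm <- as_tbl(raw$cvterm, empty$cvterm[0, ])
  store$cvterm_relationship <- as_tbl(raw$cvterm_relationship,
                                      empty$cvterm_relationship[0, ])
  class(store) <- "vocab_store"
  store
}

#' Export a stored vocabulary as an OBO document
#'
#' Emits one `[Term]` stanza per term of the vocabulary. `is_a` and `part_of`
#' edges are written in OBO syntax; for a composed vocabulary each term
#' carries one `relationship: contains <curie>` line per component.
#'
#' @param store A [vocab_store()].
#' @param vocabulary_name Vocabulary to export.
#' @return An [obo_document()].
#' @export
export_vocabulary <- function(store, vocabulary_name) {
  cv <- dplyr::filter(store$cv, .data$name == vocabulary_name)
  if (nrow(cv) == 0) rlang::abort(paste0("unknown vocabulary '", vocabulary_name, "'"))
  terms <- dplyr::filter(store$cvterm, .data$cv_id == cv$cv_id) |>
    dplyr::arrange(.data$cvterm_id)
  rel <- store$cvterm_relationship
  stanzas <- lapply(seq_len(nrow(terms)), function(i) {
    row <- terms[i, ]
    mine <- dplyr::filter(rel, .data$subject_id == row$cvterm_id,
                          .data$type == "is_a")
    is_a <- store$cvterm$curie[match(mine$object_id, store$cvterm$cvterm_id)]
    as_object <- dplyr::filter(rel, .data$object_id == row$cvterm_id,
                               .data$type == "contains")
    contains <- store$cvterm$curie[match(as_object$subject_id,
                                         store$cvterm$cvterm_id)]
    part_of <- dplyr::filter(rel, .data$subject_id == row$cvterm_id,
                             .data$type == "part_of")
    part_of <- store$cvterm$curie[match(part_of$object_id, store$cvterm$cvterm_id)]
    obo_term(
      id = row$curie, name = row$name,
      def = if (is.na(row$definition)) NULL else row$definition,
      is_a = sort(is_a),
      relationship = c(paste0("part_of ", sort(part_of)),
                       paste0("contains ", sort(contains))),
      is_obsolete = row$is_obsolete
    )
  })
  obo_document(stanzas, header = list("format-version" = "1.2",
                                      "ontology" = vocabulary_name))
}
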