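# Post-composition engine: expand a user selection into candidate component
# sets (cartesian product), split them into existing vs novel against the
# store, render canonical pipe-delimited display names, and commit novel
# terms under freshly minted COMP identifiers.

#' Build a composition selection
#'
#' A selection names one or more trait terms plus, per orthogonal category,
#' the terms the user picked. Each resulting candidate uses exactly one trait
#' term and at most one term per category; listing several terms in a
#' category expands the cartesian product (e.g. four time points give four
#' candidates).
#'
#' @param trait Character vector of trait-vocabulary CURIEs (non-empty).
#' @param object,attribute,time,event Character vectors of CURIEs from the
#'   corresponding orthogonal vocabularies (any may be empty, not all).
#'
#' @return An object of class `composition_selection`.
#' @export
#'
#' @examples
#' selection(trait = "CO_331:0000294",
#'           time = paste0("TIME:000000", 1:4),
#'           event = "EVENT:0000001")
selection <- function(trait, object = character(), attribute = character(),
                      time = character(), event = character()) {
  stopifnot(is.character(trait), length(trait) >= 1)
  structure(
    list(trait = trait, object = object, attribute = attribute,
         time = time, event = event),
    class = "composition_selection"
  )
}

# check every curie in the selection belongs to a vocabulary of the claimed
# category; abort naming the offender otherwise
.check_selection <- function(store, sel, allowed_categories = .orthogonal_categories) {
  stopifnot(inherits(sel, "composition_selection"))
  orth <- .orthogonal_categories
  if (all(lengths(sel[orth]) == 0)) {
    rlang::abort("nothing to compose: select at least one orthogonal term")
  }
  for (cat in setdiff(orth, allowed_categories)) {
    if (length(sel[[cat]]) > 0) {
      rlang::abort(paste0("category '", cat, "' is not permitted by the configuration"))
    }
  }
  for (cat in c("trait", orth)) {
    for (cu in sel[[cat]]) {
      hit <- store_terms(store, curie = cu)
      if (nrow(hit) == 0) rlang::abort(paste0("unknown curie: ", cu))
      if (hit$category != cat) {
        rlang::abort(paste0("curie ", cu, " belongs to category '", hit$category,
                            "', not '", cat, "'"))
      }
    }
  }
  invisible(sel)
}

#' Enumerate candidate component sets for a selection
#'
#' Expands the cartesian product trait x object x attribute x time x event
#' over the non-empty category lists. Output order is deterministic: trait
#' input order outermost, then object, attribute, time, event, each in input
#' order (the innermost category varies fastest).
#'
#' @param store A [vocab_store()] (used to validate categories).
#' @param sel A [selection()].
#' @param allowed_categories Orthogonal categories the configuration permits;
#'   defaults to all four.
#'
#' @return A tibble with one row per candidate and columns `trait`, `object`,
#'   `attribute`, `time`, `event` (CURIEs, `NA` for unused categories).
#' @export
enumerate_combinations <- function(store, sel,
                                   allowed_categories = .orthogonal_categories) {
  .check_selection(store, sel, allowed_categories)
  cats <- c("trait", .orthogonal_categories)
  lists <- lapply(cats, function(cat) {
    v <- sel[[cat]]
    if (length(v) == 0) NA_character_ else v
  })
  names(lists) <- cats
  # expand with the last list varying fastest (odometer order)
  grid <- rev(expand.grid(rev(lists), KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE))
  tibble::as_tibble(grid)
}

# the set of component curies of one candidate row, as a sorted key
.candidate_key <- function(candidate) {
  curies <- unlist(candidate[c("trait", .orthogonal_categories)], use.names = FALSE)
  paste(sort(curies[!is.na(curies)]), collapse = "\r")
}

# sorted-component-key -> COMP curie for every stored composed term;
# errors when two composed terms share a component set (corrupted store)
.composed_index <- function(store) {
  comp_id <- .store_composed_cv_id(store)
  comp <- dplyr::filter(store$cvterm, .data$cv_id == comp_id)
  if (nrow(comp) == 0) return(stats::setNames(character(), character()))
  edges <- dplyr::filter(store$cvterm_relationship, .data$type == "contains",
                         .data$object_id %in% comp$cvterm_id)
  keys <- edges |>
    dplyr::mutate(subject = store$cvterm$curie[match(.data$subject_id,
                                                     store$cvterm$cvterm_id)]) |>
    dplyr::group_by(.data$object_id) |>
    dplyr::summarise(key = paste(sort(.data$subject), collapse = "\r"))
  if (anyDuplicated(keys$key)) {
    dup <- keys$key[duplicated(keys$key)][1]
    curies <- comp$curie[match(keys$object_id[keys$key == dup], comp$cvterm_id)]
    rlang::abort(paste0("store integrity violation: composed terms ",
                        paste(curies, collapse = ", "),
                        " share an identical component set"))
  }
  stats::setNames(comp$curie[match(keys$object_id, comp$cvterm_id)], keys$key)
}

#' Find the stored composed term matching a candidate component set
#'
#' Matching is on the component CURIE set, insensitive to the order in which
#' components are supplied or in which `contains` edges were inserted.
#'
#' @param store A [vocab_store()].
#' @param candidate A one-row tibble as produced by
#'   [enumerate_combinations()], or a character vector of component CURIEs.
#'
#' @return The matching `COMP:` CURIE, or `NA_character_` when the set is not
#'   stored.
#' @export
find_existing <- function(store, candidate) {
  key <- if (is.character(candidate)) {
    paste(sort(candidate), collapse = "\r")
  } else {
    .candidate_key(candidate)
  }
  idx <- .composed_index(store)
  if (key %in% names(idx)) unname(idx[[key]]) else NA_character_
}

#' Render the canonical display name of a component set
#'
#' Component names joined by `"|"`, trait name first, then object, attribute,
#' time, event. The first pipe-delimited segment of every rendered name is
#' therefore the trait root.
#'
#' @param store A [vocab_store()].
#' @param candidate One-row tibble with columns `trait`, `object`,
#'   `attribute`, `time`, `event` (CURIEs, `NA` for unused categories).
#'
#' @return A single display-name string with no whitespace padding around
#'   segments.
#' @export
#'
#' @examples
#' store <- fig2_store()
#' cand <- tibble::tibble(trait = "CO_331:0000294", object = NA, attribute = NA,
#'                        time = "TIME:0000002", event = "EVENT:0000001")
#' render_name(store, cand)
render_name <- function(store, candidate) {
  curies <- unlist(candidate[c("trait", .orthogonal_categories)], use.names = FALSE)
  curies <- curies[!is.na(curies)]
  if (length(curies) < 2) {
    rlang::abort("a component set needs one trait term and at least one orthogonal term")
  }
  found <- store_terms(store, curie = curies)
  nm <- found$name[match(curies, found$curie)]
  if (anyNA(nm)) {
    rlang::abort(paste0("unknown curie: ",
                        paste(curies[is.na(nm)], collapse = ", ")))
  }
  paste(stringr::str_trim(nm), collapse = "|")
}

#' Extract the trait root of a display name
#'
#' The substring before the first `"|"` (the whole name when it contains
#' none) — the underlying trait variable of a post-composed trait name.
#'
#' @param trait_name Character vector of display names.
#' @return Character vector of trait roots.
#' @export
#'
#' @examples
#' trait_root("storage root weight|month 1|after harvest")
trait_root <- function(trait_name) {
  stringr::str_extract(trait_name, "[^|]+")
}

#' Partition a selection into existing and novel composed terms
#'
#' Expands the selection's candidates and looks each up in the store. The
#' result mirrors the two panes of a post-composing interface: combinations
#' already stored (with their COMP identifier) and never-before-created
#' combinations (with the name they would be stored under). The store is not
#' mutated; use [commit_composed()] to store the novel ones.
#'
#' @inheritParams enumerate_combinations
#'
#' @return A tibble of class `composition_result`: one row per candidate with
#'   the component CURIE columns, `name` (rendered display name), `status`
#'   (`"existing"` or `"novel"`) and `curie` (the COMP identifier, `NA` for
#'   novel rows).
#' @export
#'
#' @examples
#' store <- fig2_store()
#' sel <- selection(trait = "CO_331:0000294",
#'                  time = paste0("TIME:000000", 1:4),
#'                  event = "EVENT:0000001")
#' compose(store, sel)
compose <- function(store, sel, allowed_categories = .orthogonal_categories) {
  candidates <- enumerate_combinations(store, sel, allowed_categories)
  idx <- .composed_index(store)
  keys <- vapply(seq_len(nrow(candidates)),
                 function(i) .candidate_key(candidates[i, ]), character(1))
  curie <- unname(ifelse(keys %in% names(idx), idx[keys], NA_character_))
  out <- candidates |>
    dplyr::mutate(
      name = vapply(seq_len(nrow(candidates)),
                    function(i) render_name(store, candidates[i, ]), character(1)),
      status = ifelse(is.na(curie), "novel", "existing"),
      curie = curie
    )
  class(out) <- c("composition_result", class(out))
  out
}

#' Commit novel composed terms to the store
#'
#' For each novel candidate a COMP identifier is minted ([next_comp_curie()]),
#' a term with the rendered display name is inserted into the composed
#' vocabulary, and one `contains` edge is added per component. The batch is
#' transactional: if any candidate turns out to already exist (or fails
#' validation) the whole batch is rolled back and nothing is minted.
#'
#' @param store A [vocab_store()].
#' @param novel A tibble of candidates (columns `trait`, `object`,
#'   `attribute`, `time`, `event`), e.g. the novel rows of a [compose()]
#'   result. Zero rows is a no-op.
#'
#' @return A tibble with one row per committed term: `curie`, `name`, and a
#'   `components` list-column of component CURIEs.
#' @export
commit_composed <- function(store, novel) {
  cols <- c("trait", .orthogonal_categories)
  stopifnot(all(cols %in% names(novel)))
  if (nrow(novel) == 0) {
    return(tibble::tibble(curie = character(), name = character(),
                          components = list()))
  }
  # snapshot for all-or-nothing semantics
  snapshot <- list(cvterm = store$cvterm,
                   cvterm_relationship = store$cvterm_relationship)
  comp_cv <- .store_composed_cv_id(store)
  out <- vector("list", nrow(novel))
  tryCatch({
    for (i in seq_len(nrow(novel))) {
      cand <- novel[i, cols]
      if (!is.na(find_existing(store, cand))) {
        rlang::abort(paste0("component set already stored as ",
                            find_existing(store, cand),
                            "; commit aborted, batch rolled back"))
      }
      components <- unlist(cand, use.names = FALSE)
      components <- components[!is.na(components)]
      comp_cats <- store_terms(store, curie = components)$category
      if (sum(comp_cats == "trait") != 1) {
        rlang::abort("a component set must contain exactly one trait term")
      }
      curie <- next_comp_curie(store)
      nm <- render_name(store, cand)
      .store_add_term(store, comp_cv, curie, nm)
      for (cu in components) .store_add_relationship(store, curie, cu, "contains")
      out[[i]] <- tibble::tibble(curie = curie, name = nm,
                                 components = list(sort(components)))
    }
  }, error = function(e) {
    store$cvterm <- snapshot$cvterm
    store$cvterm_relationship <- snapshot$cvterm_relationship
    rlang::abort(conditionMessage(e))
  })
  dplyr::bind_rows(out)
}

#' Search stored composed terms by text
#'
#' Case-insensitive substring match against the composed display name, the
#' COMP identifier, or any component's name — a post-composed trait is
#' findable by text from any of its components.
#'
#' @param store A [vocab_store()].
#' @param query Query string; an empty query returns no rows.
#'
#' @return A tibble ordered by `curie` with columns `curie`, `name`, and a
#'   `components` list-column of component CURIEs.
#' @export
#'
#' @examples
#' store <- fig2_store()
#' search_composed(store, "after harvest")
search_composed <- function(store, query) {
  empty <- tibble::tibble(curie = character(), name = character(),
                          components = list())
  if (is.null(query) || !nzchar(query)) return(empty)
  comp_id <- .store_composed_cv_id(store)
  comp <- dplyr::filter(store$cvterm, .data$cv_id == comp_id)
  if (nrow(comp) == 0) return(empty)
  q <- stringr::fixed(query, ignore_case = TRUE)
  rows <- lapply(seq_len(nrow(comp)), function(i) {
    parts <- components_of(store, comp$curie[i])
    hit <- stringr::str_detect(comp$name[i], q) ||
      stringr::str_detect(comp$curie[i], q) ||
      any(stringr::str_detect(parts$name, q))
    if (!hit) return(NULL)
    tibble::tibble(curie = comp$curie[i], name = comp$name[i],
                   components = list(sort(parts$curie)))
  })
  res <- dplyr::bind_rows(rows)
  if (nrow(res) == 0) empty else dplyr::arrange(res, .data$curie)
}
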