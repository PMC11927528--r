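# OBO flat-file reader/writer for the 1.2 tag subset used to exchange trait
# and orthogonal ontologies: {id, name, def, synonym, is_a, relationship,
# is_obsolete, namespace}. Every other tag is carried as an opaque
# "tag: value" line so documents round-trip byte-identically.

#' Tags modelled as structured fields; anything else is pass-through.
#' @noRd
.obo_known_tags <- c("id", "name", "def", "synonym", "is_a",
                     "relationship", "is_obsolete", "namespace")

#' Construct an OBO term stanza
#'
#' @param id Term CURIE, e.g. `"CO_331:0000294"`.
#' @param name Display name, or `NULL`.
#' @param def Definition string (raw, quotes and xrefs included), or `NULL`.
#' @param synonym Character vector of raw synonym strings (scope qualifiers
#'   such as EXACT are kept verbatim, not parsed).
#' @param is_a Character vector of raw `is_a` values (target CURIE, possibly
#'   followed by a `! name` comment).
#' @param relationship Character vector of raw relationship values, e.g.
#'   `"contains COMP:0000093"` or `"part_of CO_331:0000001"`.
#' @param is_obsolete Logical flag.
#' @param namespace Namespace string, or `NULL`.
#' @param other Character vector of verbatim unknown lines (`"tag: value"`).
#'
#' @return An object of class `obo_term`.
#' @export
obo_term <- function(id, name = NULL, def = NULL, synonym = character(),
                     is_a = character(), relationship = character(),
                     is_obsolete = FALSE, namespace = NULL,
                     other = character()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  structure(
    list(id = id, name = name, def = def, synonym = synonym,
         is_a = is_a, relationship = relationship,
         is_obsolete = isTRUE(is_obsolete), namespace = namespace,
         other = other),
    class = "obo_term"
  )
}

#' Construct an OBO document
#'
#' An `obo_document` holds the header (ordered key -> value-list mapping) and
#' an ordered list of `[Term]` stanzas. Term ids must be unique.
#'
#' @param terms List of [obo_term()] objects.
#' @param header Named list; each element a character vector of values for
#'   that header tag, in file order (e.g. `list("format-version" = "1.2")`).
#'
#' @return An object of class `obo_document`.
#' @export
obo_document <- function(terms = list(), header = list("format-version" = "1.2")) {
  ids <- vapply(terms, function(t) t$id, character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    rlang::abort(paste0("duplicate term id in document: ",
                        paste(unique(dup), collapse = ", ")))
  }
  structure(list(header = header, terms = terms), class = "obo_document")
}

#' @export
print.obo_document <- function(x, ...) {
  cat("<obo_document> ", length(x$terms), " term(s)\n", sep = "")
  invisible(x)
}

#' @export
length.obo_document <- function(x) length(x$terms)

#' Term ids of an OBO document
#' @param doc An `obo_document`.
#' @return Character vector of stanza ids in document order.
#' @export
obo_ids <- function(doc) {
  vapply(doc$terms, function(t) t$id, character(1))
}

#' `is_a` references that do not resolve within the document
#' @param doc An `obo_document`.
#' @return Character vector of dangling target ids (possibly empty).
#' @export
obo_dangling_is_a <- function(doc) {
  ids <- obo_ids(doc)
  targets <- unlist(lapply(doc$terms, function(t) .obo_ref_target(t$is_a)))
  unique(setdiff(targets, ids))
}

# "CURIE ! comment" -> "CURIE"
.obo_ref_target <- function(x) {
  stringr::str_trim(stringr::str_extract(x, "^[^!]+"))
}

# split "tag: value" keeping the value verbatim (incl. trailing comments)
.obo_split_tag <- function(line) {
  m <- stringr::str_match(line, "^([A-Za-z0-9_-]+):\\s?(.*)$")
  if (is.na(m[1, 1])) return(NULL)
  list(tag = m[1, 2], value = m[1, 3])
}

#' Parse OBO flat-file text
#'
#' Reads the header and every `[Term]` stanza. The modelled tag subset is
#' `id`, `name`, `def`, `synonym`, `is_a`, `relationship`, `is_obsolete`,
#' `namespace`; all other tags are retained verbatim for round-tripping.
#' Stanza types other than `[Term]` (e.g. `[Typedef]`) are preserved as raw
#' text blocks. Line endings are normalised to `"\n"`.
#'
#' @param text A single string, or a character vector of lines.
#'
#' @return An [obo_document()].
#' @export
#'
#' @examples
#' doc <- parse_obo(c("format-version: 1.2", "", "[Term]",
#'                    "id: CO_331:0000294", "name: storage root weight"))
#' obo_ids(doc)
parse_obo <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(gsub("\r\n?", "\n", text), "\n", fixed = TRUE)[[1]]
  } else {
    text <- gsub("\r$", "", text)
  }

  stanza_starts <- which(stringr::str_trim(text) == "[Term]")
  other_starts <- which(grepl("^\\[[A-Za-z]+\\]$", stringr::str_trim(text)) &
                          stringr::str_trim(text) != "[Term]")
  all_starts <- sort(c(stanza_starts, other_starts))

  header_end <- if (length(all_starts) > 0) all_starts[1] - 1L else length(text)
  header <- list()
  for (line in text[seq_len(header_end)]) {
    if (!nzchar(stringr::str_trim(line))) next
    kv <- .obo_split_tag(line)
    if (is.null(kv)) next
    header[[kv$tag]] <- c(header[[kv$tag]], kv$value)
  }

  # block boundaries: each start runs to the line before the next start
  block_of <- function(start) {
    nxt <- all_starts[all_starts > start]
    end <- if (length(nxt) > 0) nxt[1] - 1L else length(text)
    text[seq(start, end)]
  }

  terms <- list()
  seen_ids <- character()
  for (i in seq_along(stanza_starts)) {
    block <- block_of(stanza_starts[i])[-1]  # drop the [Term] marker
    term <- list(id = NULL, name = NULL, def = NULL, synonym = character(),
                 is_a = character(), relationship = character(),
                 is_obsolete = FALSE, namespace = NULL, other = character())
    for (line in block) {
      if (!nzchar(stringr::str_trim(line))) next
      kv <- .obo_split_tag(line)
      if (is.null(kv)) next
      switch(kv$tag,
        id = { term$id <- c(term$id, kv$value) },
        name = { term$name <- kv$value },
        def = { term$def <- kv$value },
        synonym = { term$synonym <- c(term$synonym, kv$value) },
        is_a = { term$is_a <- c(term$is_a, kv$value) },
        relationship = { term$relationship <- c(term$relationship, kv$value) },
        is_obsolete = { term$is_obsolete <- tolower(kv$value) == "true" },
        namespace = { term$namespace <- kv$value },
        { term$other <- c(term$other, paste0(kv$tag, ": ", kv$value)) }
      )
    }
    if (is.null(term$id) || length(term$id) != 1L) {
      rlang::abort(paste0("[Term] stanza ", i, " must have exactly one id line"))
    }
    if (term$id %in% seen_ids) {
      rlang::abort(paste0("duplicate term id in document: ", term$id))
    }
    seen_ids <- c(seen_ids, term$id)
    terms[[i]] <- obo_term(term$id, term$name, term$def, term$synonym,
                           term$is_a, term$relationship, term$is_obsolete,
                           term$namespace, term$other)
  }

  raw_stanzas <- vapply(other_starts, function(s) {
    paste(sub("\\s+$", "", block_of(s)), collapse = "\n")
  }, character(1))

  doc <- obo_document(terms, header)
  doc$raw_stanzas <- as.character(raw_stanzas)
  doc
}

#' Serialise an OBO document to text
#'
#' Serialisation is deterministic: the header first (tags in stored order),
#' then term stanzas in document order, tags within a stanza in canonical
#' order (`id`, `name`, `namespace`, `def`, `synonym`, `is_a`,
#' `relationship`, `is_obsolete`, then retained unknown lines). Two writes of
#' the same document are byte-identical.
#'
#' @param doc An [obo_document()].
#' @param path Optional file path; when given, the text is written there
#'   (UTF-8, `"\n"` line endings) and returned invisibly.
#'
#' @return A single string of OBO text.
#' @export
write_obo <- function(doc, path = NULL) {
  stopifnot(inherits(doc, "obo_document"))
  lines <- character()
  for (tag in names(doc$header)) {
    lines <- c(lines, paste0(tag, ": ", doc$header[[tag]]))
  }
  for (term in doc$terms) {
    lines <- c(lines, "", "[Term]", paste0("id: ", term$id))
    if (!is.null(term$name)) lines <- c(lines, paste0("name: ", term$name))
    if (!is.null(term$namespace)) lines <- c(lines, paste0("namespace: ", term$namespace))
    if (!is.null(term$def)) lines <- c(lines, paste0("def: ", term$def))
    lines <- c(lines,
               if (length(term$synonym)) paste0("synonym: ", term$synonym),
               if (length(term$is_a)) paste0("is_a: ", term$is_a),
               if (length(term$relationship)) paste0("relationship: ", term$relationship))
    if (isTRUE(term$is_obsolete)) lines <- c(lines, "is_obsolete: true")
    lines <- c(lines, term$other)
  }
  if (length(doc$raw_stanzas)) lines <- c(lines, "", doc$raw_stanzas)
  out <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(out, con, sep = "", useBytes = TRUE)
    return(invisible(out))
  }
  out
}

#' Read an OBO file from disk
#' @param path Path to an OBO flat file.
#' @return An [obo_document()].
#' @export
read_obo <- function(path) {
  parse_obo(readLines(path, warn = FALSE, encoding = "UTF-8"))
}

#' Term stanzas of a document as a tibble
#'
#' One row per term with list-columns for the multi-valued tags; convenient
#' for dplyr-style inspection of an ontology.
#'
#' @param doc An [obo_document()].
#' @return A tibble with columns `id`, `name`, `def`, `namespace`,
#'   `is_obsolete`, `synonym`, `is_a`, `relationship`.
#' @export
obo_tibble <- function(doc) {
  tibble::tibble(
    id = obo_ids(doc),
    name = vapply(doc$terms, function(t) t$name %||% NA_character_, character(1)),
    def = vapply(doc$terms, function(t) t$def %||% NA_character_, character(1)),
    namespace = vapply(doc$terms, function(t) t$namespace %||% NA_character_, character(1)),
    is_obsolete = vapply(doc$terms, function(t) t$is_obsolete, logical(1)),
    synonym = lapply(doc$terms, function(t) t$synonym),
    is_a = lapply(doc$terms, function(t) t$is_a),
    relationship = lapply(doc$terms, function(t) t$relationship)
  )
}
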