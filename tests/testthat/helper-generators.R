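# Random-content generators used by the round-trip and property tests.
# Everything is seeded by the caller.

# a random OBO term with a mix of modelled and unknown tags
random_obo_term <- function(id) {
  maybe <- function(x, p = 0.5) if (stats::runif(1) < p) x else NULL
  n_syn <- stats::rpois(1, 0.7)
  n_isa <- stats::rpois(1, 0.5)
  obo_term(
    id = id,
    name = maybe(paste0("term ", id), 0.9),
    def = maybe(paste0("\"definition of ", id, "\" []"), 0.6),
    synonym = if (n_syn > 0) paste0("\"syn ", seq_len(n_syn), " of ", id,
                                    "\" EXACT []") else character(),
    is_a = if (n_isa > 0) paste0("X:", sprintf("%07d", sample.int(50, n_isa))) else character(),
    relationship = if (stats::runif(1) < 0.3) paste0("part_of X:", sprintf("%07d", sample.int(50, 1))) else character(),
    is_obsolete = stats::runif(1) < 0.1,
    namespace = maybe("toy_namespace", 0.3),
    other = if (stats::runif(1) < 0.4) paste0("comment: free text for ", id) else character()
  )
}

random_obo_document <- function(n_terms = NULL) {
  if (is.null(n_terms)) n_terms <- sample.int(8, 1)
  ids <- paste0("X:", sprintf("%07d", sample.int(1000, n_terms)))
  obo_document(
    lapply(ids, random_obo_term),
    header = list("format-version" = "1.2", "ontology" = "random_toy")
  )
}

# store loaded with the worked-example ontologies but no composed term yet
empty_fig2_store <- function() {
  docs <- make_toy_ontologies(fixture_spec(n_trait_terms = 5, n_object = 2,
                                           n_attribute = 2, n_time = 4,
                                           n_event = 2))
  store <- vocab_store()
  load_ontology(store, docs$trait, "toy_trait_ontology", "trait")
  load_ontology(store, docs$object, "toy_object_ontology", "object")
  load_ontology(store, docs$attribute, "toy_attribute_ontology", "attribute")
  load_ontology(store, docs$time, "toy_time_ontology", "time")
  load_ontology(store, docs$event, "toy_event_ontology", "event")
  store
}

# brute-force minimum WSS over all 2-cluster partitions of standardized x
exhaustive_wss_k2 <- function(x) {
  z <- as.numeric(scale(x))
  n <- length(z)
  best <- Inf
  for (mask in 1:(2^n - 2)) {
    in_a <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    a <- z[in_a]; b <- z[!in_a]
    wss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (wss < best) best <- wss
  }
  best
}

expect_same_document <- function(got, want) {
  expect_equal(length(got$terms), length(want$terms))
  expect_equal(got$header, want$header)
  for (i in seq_along(want$terms)) {
    g <- got$terms[[i]]; w <- want$terms[[i]]
    for (f in c("id", "name", "def", "synonym", "is_a", "relationship",
                "is_obsolete", "namespace", "other")) {
      expect_equal(g[[f]], w[[f]],
                   info = paste0("term ", w$id, " field ", f))
    }
  }
}
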