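---
title: "Post-composing trait ontology terms and analysing their usage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-composing trait ontology terms and analysing their usage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(postcompose)
library(dplyr)
```

## The problem

Crop breeding databases annotate phenotype observations with controlled
vocabulary terms. The curated ("pre-composed") trait ontologies of a crop can
never anticipate every variable a breeder measures: the same underlying trait
may be scored on a specific plant part, after a treatment, at a given month,
or following a breeding event such as harvest. Rather than requesting a new
curated term for every such combination, a database can *post-compose* terms
on the fly: combine exactly one trait term with at most one term from each of
several *orthogonal* ontologies — vocabularies for independent facets of the
observation, here the categories **object** (plant part), **attribute**
(treatment or cycle), **time**, and **event**. Orthogonal means
non-overlapping: no two of these vocabularies may share a term name or
identifier, so a component is attributable to exactly one facet.

`postcompose` implements this machinery end to end:

* an OBO flat-file reader/writer for exchanging the ontologies,
* a vocabulary store mirroring the Chado cvterm relational model,
* the composition engine (candidate expansion, existing-vs-novel detection,
  `COMP` identifier minting, canonical display names, text search), and
* usage analytics that stratify accessions by how many distinct post-composed
  traits they carry data for (k-means with an elbow rule), plus trait-root
  frequencies and post/pre usage ratios.

## The store: a Chado cvterm mirror

Post-composed terms live in four tables named after the Chado cvterm module:
`cv` (one row per vocabulary), `cvprop` (exactly one `category` property per
vocabulary), `cvterm` (terms: CURIE, display name, definition, obsolescence
flag) and `cvterm_relationship` (typed object–subject edges). A post-composed
term is the *object* of one `contains` edge per component; components carry
no rank, so a stored term is identified by its component *set*. The tables
are held as tibbles inside an environment and persist as one JSON file
(`write_store()`/`read_store()`), which keeps the schema's names and
referential discipline without requiring a database server.

Two store-level invariants are enforced at every write: a CURIE is unique
store-wide (loading the same CURIE into a second vocabulary is an error
naming both vocabularies), and no relationship row may reference a missing
term.

## Composition semantics

A *selection* lists one or more trait terms and, per orthogonal category, the
terms the user picked. `enumerate_combinations()` expands the cartesian
product — each candidate keeps exactly one trait term and at most one term
per category — in a deterministic order (trait outermost, then object,
attribute, time, event, each in input order). `compose()` partitions the
candidates into *existing* (a stored composed term has exactly this component
set, order-insensitive) and *novel*. `commit_composed()` then mints
identifiers for the novel sets.

Decisions that were genuinely open, and how this package resolves them:

* **Identifier minting.** Composed terms get `COMP:NNNNNNN` with the suffix
  zero-padded to seven digits and equal to one plus the largest stored
  suffix. Sequential minting from the observed maximum is the simplest rule
  consistent with the printed identifiers of such systems; the sequence never
  reuses a suffix, even across rolled-back batches.
* **Display names.** Component names joined by `"|"`, trait name first, then
  object, attribute, time, event. A pipe-delimited name with the trait first
  is what makes the *trait root* — the first segment — recoverable by the
  regular expression `[^|]+` used in downstream frequency analyses;
  `trait_root(render_name(s))` is the trait term's name by construction. The
  ordering of the remaining segments is this package's convention.
* **Identity is the component set, not the name.** Novel-term detection
  compares CURIE sets, so renaming a component never duplicates a composed
  term, and any permutation of a component set maps to the same stored term.
* **Transactional commits.** A commit batch is all-or-nothing: a conflict
  (e.g. a set concurrently committed) rolls the whole batch back, avoiding
  half-minted identifier runs.
* **Configurable category combinations.** Which orthogonal categories may be
  combined is configuration (`enabled_categories`), defaulting to all four.
  Composed terms are not re-curated; they are local to the store that minted
  them.

## Usage analytics

The analytics operate on a flat usage table: one row per phenotype
observation with `accession_id`, `trait_id`, `trait_name`. A trait counts as
post-composed when its display name contains the substring `"COMP"` —
matching how stored display names carry the minted identifier — with a
`strict` flag to key on the `COMP:` CURIE prefix instead (the substring test
can in principle catch a pre-composed name containing "COMP" as text).

`count_post_per_accession()` tallies, per accession, the distinct
post-composed traits with data and the total such observations. Grouping
then proceeds in two steps that deliberately use *different scalings*:

1. **Elbow scan** (`wss_curve()`): counts are standardised (zero mean, unit
   variance) and k-means is run for k = 1..`k_max` (default 6) with 50
   seeded random restarts of Lloyd's algorithm and an iteration cap of 15,
   recording the total within-cluster sum of squares (WSS). At k = 1 the WSS
   of standardised data is n − 1, a useful self-check.
2. **Grouping** (`group_accessions()`): k-means is re-run on the *raw*
   counts, because the group boundaries must be expressible in count units.

This standardised-scan/raw-grouping split mirrors the analysis convention in
the field's published workflow for these data; centroid *order* is unaffected
by the affine rescaling, so the choice of k transfers between the scales.

**Choosing k.** A reader picks the elbow of a WSS plot visually; a package
needs a rule. The raw second difference `WSS(k−1) − 2·WSS(k) + WSS(k+1)` is
the obvious discretisation of curvature, but on data whose one-cluster WSS
dwarfs everything (any well-separated data) it *always* selects k = 2,
because the first absolute drop dominates no matter how sharp later bends
are. `choose_k()` therefore maximises the *relative* curvature — the second
difference scaled by `WSS(k)` — which selects the last k at which the curve
still falls by a large factor: the bend the eye identifies on these decaying
curves. On three planted, well-separated clusters this recovers k = 3; on a
curve with a single early cliff (e.g. WSS 100, 30, 28, 27, …) it still
returns 2. Ties break toward smaller k. A tiny epsilon (10⁻¹² of the total
sum of squares) guards division when some k separates the data perfectly.

**Boundaries and letters.** The k − 1 group boundaries are the midpoints
between adjacent sorted centroids of the raw-count clustering, rounded half
up to integers; accessions are labelled by *thresholding their count against
the boundaries*, not by raw cluster membership, so the groups are exactly
describable as "A (≥ x)", "B (≥ y, < x)", "C (< y)" with A the
highest-centroid group. Midpoints are this package's reading of
"centroid-derived boundaries"; rounding half-up gives integer thresholds in
count units.

**Group summaries.** `group_summary()` reports, per group: accessions with
and without post-composed data, and the number of unique post- and
pre-composed traits observed by the group's accessions. An accession with no
post-composed observations has count 0 and carries no grouping signal, so it
is placed in a band by its *pre-composed* trait count — an interpretive
choice, flagged here, for reproducing summary tables whose bands are defined
by post-composed counts yet list such accessions.

`post_pre_ratio()` is deliberately small: the post/pre count ratio at full
precision and rounded to three decimals, with the ratio undefined (`NA`,
counts still reported) when the pre-composed count is zero.

## The synthetic generator

`make_toy_ontologies()` emits a trait ontology and per-category orthogonal
ontologies with human-readable synthetic names ("month 1…N", "after
harvest", "plant section i", "treatment i"); names are disjoint across
categories, so orthogonality holds by construction. The first trait term is
`CO_331:0000294` with the synthetic label "storage root weight", so the
worked example of one trait × four months × one event reads naturally.
`fig2_store()` packages that scenario with one composed term
(`COMP:0000093`) pre-stored.

`make_usage_data()` plants cluster structure: per cluster, each accession's
count of distinct post-composed traits is drawn from a rounded normal around
the cluster centroid, truncated at zero and at the trait-pool size, and that
many distinct traits are sampled from a synthetic pool whose display names
carry a trailing `COMP:NNNNNNN` segment, as stored names do. Pre-composed
observations are added per accession at a Poisson rate targeting a given
fraction of all rows. Defaults — centroids 5/30/80, standard deviation 2,
100 accessions per cluster, seed 1234, elbow scan to k\_max = 6 with 50
restarts — are the study conditions under which the grouping pipeline is
expected to recover the planted structure; the truncated rounded normal is
the minimal distributional assumption under which k-means grouping of counts
is meaningful. All generation is seed-deterministic, byte-identically so.

What the generator does *not* emulate: real usage tables are skewed and
zero-inflated rather than a clean mixture of normals, trait pools are shared
unevenly across breeding programmes, and observation counts per accession
correlate with trial design. Passing recovery tests therefore demonstrates
the pipeline's correctness on separable count structure, not that real
accession data separate into three groups.

## Numerical choices and problem sizes

* k-means: `stats::kmeans` with Lloyd's algorithm, `nstart` seeded random
  restarts (default 50), `iter.max` 15; the best-WSS solution is kept. The
  WSS curve is non-increasing in k given this restart budget; for n ≤ 8 the
  k = 2 solution matches the exhaustive optimum over all two-set partitions
  (verified in the tests).
* `wss_curve()` refuses `k_max` larger than the number of distinct values;
  `group_accessions()` likewise for k, and rejects k < 2 (a single group has
  no boundary).
* Degenerate clusterings whose midpoint boundaries are not strictly
  increasing are an error rather than a silent mislabelling.
* Round half up (`floor(x + 0.5)`) is used for boundaries, not banker's
  rounding, so x.5 midpoints resolve upward consistently.
* Test and example problem sizes — 300 accessions (100 per planted cluster),
  20 replicate seeds for recovery, 100 random documents for round-trip
  checks — are the package's chosen balance between statistical force and a
  test suite that runs in well under a minute per file.

## Known limitations

* The OBO dialect is the 1.2 tag subset `{id, name, def, synonym, is_a,
  relationship, is_obsolete, namespace}`; other tags and non-`[Term]`
  stanzas round-trip verbatim but are not modelled. No OWL semantics, no
  reasoning, no obsolete-term replacement chains.
* The store is single-user and in-process; no concurrency, permissions or
  audit history.
* Trait variables are treated as atomic terms; their decomposition into
  trait/method/scale is out of scope.
* Group summaries on real production databases are not reproducible from
  this package alone — they require those databases' usage tables as input;
  the package reproduces the *computations*, given a table.
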