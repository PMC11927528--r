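toy_usage <- function() {
  tibble::tibble(
    accession_id = c("A1", "A1", "A1", "A2", "A2"),
    accession_name = c("acc one", "acc one", "acc one", "acc two", "acc two"),
    trait_id = c("COMP:0000001", "COMP:0000002", "CO_331:0000010",
                 "COMP:0000001", "CO_331:0000010"),
    trait_name = c("trait 1|month 1|COMP:0000001",
                   "trait 1|month 2|COMP:0000002",
                   "trait 10|CO_331:0000010",
                   "trait 1|month 1|COMP:0000001",
                   "trait 10|CO_331:0000010"),
    observation_unit_id = sprintf("OU%03d", 1:5)
  )
}

test_that("per-accession post-composed counts match manual enumeration", {
  counts <- count_post_per_accession(toy_usage())
  expect_equal(counts$accession_id, c("A1", "A2"))
  expect_equal(counts$n_unique_post_traits, c(2L, 1L))
  expect_equal(counts$total_observations, c(2L, 1L))

  no_post <- dplyr::filter(toy_usage(), !grepl("COMP", trait_name))
  expect_equal(nrow(count_post_per_accession(no_post)), 0L)
})

test_that("counts match a brute-force group-by on generated usage data", {
  fx <- make_usage_data(fixture_spec(n_per_cluster = 15, seed = 77))
  counts <- count_post_per_accession(fx$usage)
  brute <- fx$usage[grepl("COMP", fx$usage$trait_name, fixed = TRUE), ]
  brute_tab <- tapply(brute$trait_id, brute$accession_id,
                      function(x) c(unique = length(unique(x)), total = length(x)))
  for (i in seq_len(nrow(counts))) {
    b <- brute_tab[[counts$accession_id[i]]]
    expect_equal(counts$n_unique_post_traits[i], unname(b["unique"]))
    expect_equal(counts$total_observations[i], unname(b["total"]))
  }
  expect_equal(nrow(counts), length(brute_tab))
})

test_that("strict detection keys on the COMP: curie prefix, not the name", {
  usage <- toy_usage()
  # a pre-composed trait whose name happens to contain COMP as text
  usage$trait_name[3] <- "COMPact growth habit|CO_331:0000010"
  loose <- count_post_per_accession(usage)
  strict <- count_post_per_accession(usage, strict = TRUE)
  expect_equal(loose$n_unique_post_traits[loose$accession_id == "A1"], 3L)
  expect_equal(strict$n_unique_post_traits[strict$accession_id == "A1"], 2L)
})

test_that("WSS curve has the closed-form endpoints: n - 1 at k = 1, 0 at k = n", {
  x <- c(3, 9, 17, 25, 40)
  curve <- wss_curve(x, k_max = 5)
  expect_equal(curve$wss[1], length(x) - 1)
  expect_equal(curve$wss[5], 0)
  expect_true(all(diff(curve$wss) <= 1e-8))  # non-increasing in k
  expect_error(wss_curve(c(1, 1, 2), k_max = 3), "distinct")
})

test_that("k = 2 WSS equals the exhaustive-partition optimum for n <= 8", {
  set.seed(11)
  for (rep in 1:8) {
    n <- sample(4:8, 1)
    x <- sample.int(100, n)
    curve <- wss_curve(x, k_max = 3, seed = rep)
    expect_equal(curve$wss[2], exhaustive_wss_k2(x), tolerance = 1e-8)
  }
})

test_that("choose_k maximises the second difference with ties toward smaller k", {
  curve <- tibble::tibble(k = 1:6, wss = c(100, 30, 28, 27, 26.5, 26))
  expect_equal(choose_k(curve), 2L)
  linear <- tibble::tibble(k = 1:6, wss = seq(60, 10, by = -10))
  expect_equal(choose_k(linear), 2L)
  expect_error(choose_k(tibble::tibble(k = 1:2, wss = c(2, 1))), "k_max")
})

test_that("elbow selection recovers the planted cluster count", {
  fx <- make_usage_data(fixture_spec(centroids = c(5, 30, 80), sd = 2,
                                     n_per_cluster = 100, seed = 1234))
  counts <- count_post_per_accession(fx$usage)
  curve <- wss_curve(counts, k_max = 6, seed = 1234)
  expect_equal(choose_k(curve), 3L)
})

test_that("boundaries are centroid midpoints rounded half-up and label by threshold", {
  # three tight clumps at 5 / 30 / 80 so the centroids land on those values
  x <- rep(c(5, 30, 80), each = 20)
  g <- group_accessions(x, k = 3)
  expect_equal(unname(g$centroids), c(80, 30, 5))
  expect_equal(g$boundaries, c(18, 55))
  # thresholding, not raw membership: 56 >= 55 -> A; 54 -> B; 17 -> C
  lab <- postcompose:::.assign_groups(c(56, 54, 17, 55, 18), g$boundaries, 3)
  expect_equal(lab, c("A", "B", "C", "A", "B"))
  expect_error(group_accessions(x, k = 1), "at least 2")
  expect_error(group_accessions(rep(1, 5), k = 2), "distinct")
})

test_that("every count maps to exactly one group and letters follow centroids", {
  fx <- make_usage_data(fixture_spec(seed = 42))
  counts <- count_post_per_accession(fx$usage)
  g <- group_accessions(counts, k = 3)
  expect_equal(nrow(g$labels), nrow(counts))
  expect_true(all(g$labels$group %in% c("A", "B", "C")))
  expect_true(all(g$labels$count[g$labels$group == "A"] >= g$boundaries[2]))
  expect_true(all(g$labels$count[g$labels$group == "C"] < g$boundaries[1]))
  expect_true(all(diff(g$boundaries) > 0))
  expect_equal(sum(table(g$labels$group)), nrow(counts))
})

test_that("grouping recovers at least 99% of planted labels on separated data", {
  fx <- make_usage_data(fixture_spec(centroids = c(5, 30, 80), sd = 2,
                                     n_per_cluster = 100, seed = 1234))
  counts <- count_post_per_accession(fx$usage)
  g <- group_accessions(counts, k = 3)
  merged <- dplyr::inner_join(g$labels, fx$truth, by = "accession_id")
  expect_gte(mean(merged$group == merged$planted_group), 0.99)
})

test_that("trait-root frequencies sum appearance counts per root, ranked", {
  usage <- tibble::tibble(
    accession_id = rep("A1", 9),
    trait_id = rep(c("T:1", "T:2", "T:3"), times = c(2, 3, 4)),
    trait_name = rep(c("A|t1", "A|t2", "B|t1"), times = c(2, 3, 4))
  )
  freq <- trait_root_frequency(usage, post_only = FALSE)
  expect_equal(freq$root, c("A", "B"))
  expect_equal(freq$frequency, c(5L, 4L))
  # a name without a pipe is its own root; top slice respected
  usage2 <- dplyr::bind_rows(usage, tibble::tibble(
    accession_id = "A2", trait_id = "T:4", trait_name = "plainroot"))
  freq2 <- trait_root_frequency(usage2, post_only = FALSE)
  expect_true("plainroot" %in% freq2$root)
  expect_equal(nrow(trait_root_frequency(usage2, post_only = FALSE, top = 1)), 1L)
  # accession subset restricts the tally
  freq_a2 <- trait_root_frequency(usage2, accession_subset = "A2",
                                  post_only = FALSE)
  expect_equal(freq_a2$root, "plainroot")
})

test_that("root extraction of composer-rendered names returns the trait name", {
  store <- empty_fig2_store()
  res <- compose(store, selection(trait = "CO_331:0000294",
                                  time = sprintf("TIME:%07d", 1:4),
                                  event = "EVENT:0000001"))
  expect_true(all(trait_root(res$name) == "storage root weight"))
})

test_that("post/pre ratios reproduce the published per-crop arithmetic", {
  r <- post_pre_ratio(c(2303, 370, 35, 107), c(359, 579, 231, 327))
  expect_equal(r$ratio_3dp, c(6.415, 0.639, 0.152, 0.327))
  expect_equal(post_pre_ratio(0, 100)$ratio, 0)
  # zero pre-composed count: counts reported, ratio undefined
  undef <- post_pre_ratio(4579, 0)
  expect_equal(undef$n_post, 4579)
  expect_true(is.na(undef$ratio))
  expect_error(post_pre_ratio(c(1, 2), 1))
})

test_that("group summary matches a brute-force recount on a known fixture", {
  fx <- make_usage_data(fixture_spec(n_per_cluster = 30, seed = 8))
  usage <- fx$usage
  counts <- count_post_per_accession(usage)
  g <- group_accessions(counts, k = 3)
  summ <- group_summary(usage, g)
  expect_equal(names(summ), c("group", "n_without", "n_with",
                              "n_unique_post", "n_unique_pre"))

  # brute-force recount
  is_post <- grepl("COMP", usage$trait_name, fixed = TRUE)
  accs <- unique(usage$accession_id)
  band_of <- function(cnt) postcompose:::.assign_groups(cnt, g$boundaries, g$k)
  brute <- list()
  for (a in accs) {
    mine <- usage[usage$accession_id == a, ]
    np <- length(unique(mine$trait_id[grepl("COMP", mine$trait_name, fixed = TRUE)]))
    nq <- length(unique(mine$trait_id[!grepl("COMP", mine$trait_name, fixed = TRUE)]))
    brute[[a]] <- list(post = np, pre = nq,
                       group = band_of(if (np > 0) np else nq),
                       has_post = np > 0)
  }
  for (grp in summ$group) {
    members <- names(brute)[vapply(brute, function(b) b$group == grp, logical(1))]
    with_post <- members[vapply(brute[members], function(b) b$has_post, logical(1))]
    expect_equal(summ$n_with[summ$group == grp], length(with_post))
    expect_equal(summ$n_without[summ$group == grp],
                 length(members) - length(with_post))
    rows <- usage[usage$accession_id %in% members, ]
    post_rows <- grepl("COMP", rows$trait_name, fixed = TRUE)
    expect_equal(summ$n_unique_post[summ$group == grp],
                 length(unique(rows$trait_id[post_rows])))
    expect_equal(summ$n_unique_pre[summ$group == grp],
                 length(unique(rows$trait_id[!post_rows])))
  }
  # group populations with post data sum to the accession-count table
  expect_equal(sum(summ$n_with), nrow(counts))
})

test_that("an empty usage table summarises to a single all-zero group", {
  empty <- toy_usage()[0, ]
  summ <- group_summary(empty, grouping = NULL)
  expect_equal(summ$group, "A")
  expect_equal(summ$n_with, 0L)
  expect_equal(summ$n_unique_post, 0L)
})

test_that("usage tables round trip through delimited files", {
  fx <- make_usage_data(fixture_spec(n_per_cluster = 3, seed = 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_usage_table(fx$usage, path)
  back <- read_usage_table(path)
  expect_equal(as.data.frame(back), as.data.frame(fx$usage))
})
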