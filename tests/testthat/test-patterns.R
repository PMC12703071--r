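test_that("cleavage sites are inferred from the mature-arm geometry", {
  fx <- fixture_two_site_hairpin()
  sites <- infer_cleavage_sites(fx$hairpin, fx$annotation)
  expect_equal(sites$interval, c(27L, 49L))
  expect_equal(sites$arm, c("5p", "3p"))
})

test_that("degenerate mature annotations are rejected", {
  hp <- tibble::tibble(id = "h", sequence = strrep("A", 60))
  # 5p mature running to the hairpin end puts the site at interval L
  ann <- tibble::tibble(premirna_id = "h", arm = c("5p", "3p"),
                        start = c(39L, 50L), end = c(60L, 59L))
  expect_error(infer_cleavage_sites(hp, ann), "outside")
  # adjacent matures give coincident sites
  ann2 <- tibble::tibble(premirna_id = "h", arm = c("5p", "3p"),
                         start = c(1L, 23L), end = c(22L, 44L))
  expect_error(infer_cleavage_sites(hp, ann2), "overlapping|upstream")
})

test_that("the 80-nt two-site hairpin yields the worked pattern counts", {
  fx <- fixture_two_site_hairpin()
  pats <- generate_patterns(fx$hairpin, fx$sites, pattern_config(14))
  expect_equal(nrow(pats), 67L)
  expect_equal(sum(pats$label > 0L), 26L)
  expect_equal(sum(pats$label == 7L), 2L)   # central interval of 13
  # label reconstruction recovers the annotated site
  pos <- pats[pats$label > 0L, ]
  g <- pos$window_start + pos$label - 1L
  expect_true(all(g %in% fx$sites$interval))
})

test_that("windows spanning both sites are removed", {
  hp <- tibble::tibble(id = "h", sequence = strrep("ACGU", 8))  # L = 32
  sites <- tibble::tibble(interval = c(14L, 16L), arm = c("5p", "3p"))
  pats <- generate_patterns(hp, sites, pattern_config(14))
  # brute-force enumeration of the 19 windows against both sites
  oracle <- oracle_windows(32L, 14L, c(14L, 16L))
  expect_equal(pats$window_start, oracle$window_start)
  expect_equal(pats$label, oracle$label)
  expect_lt(nrow(pats), 32L - 14L + 1L)
})

test_that("pattern generation agrees with brute-force enumeration on random instances", {
  set.seed(42)
  for (rep in 1:25) {
    s <- sample(c(10L, 12L, 14L, 16L, 18L), 1)
    L <- sample(40:120, 1)
    sites <- sort(sample(seq_len(L - 1L), 2))
    hp <- tibble::tibble(id = "r", sequence = paste0(
      sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = ""
    ))
    pats <- generate_patterns(hp, tibble::tibble(interval = sites), pattern_config(s))
    oracle <- oracle_windows(L, s, sites)
    expect_equal(pats$window_start, oracle$window_start)
    expect_equal(pats$label, oracle$label)
    # windows before two-site filtering always number L - s + 1
    dropped <- sum(vapply(seq_len(L - s + 1L), function(a) {
      sum(sites >= a & sites <= a + s - 2L) > 1L
    }, logical(1)))
    expect_equal(nrow(pats) + dropped, L - s + 1L)
    expect_true(all(pats$label %in% 0:(s - 1L)))
  }
})

test_that("well-separated interior sites each yield s - 1 positive patterns", {
  set.seed(7)
  for (s in c(10L, 14L, 18L)) {
    L <- 90L
    sites <- c(s + 3L, L - s - 3L)
    hp <- tibble::tibble(id = "p", sequence = strrep("A", L))
    pats <- generate_patterns(hp, tibble::tibble(interval = sites), pattern_config(s))
    for (g in sites) {
      expect_equal(sum(pats$window_start + pats$label - 1L == g & pats$label > 0L),
                   s - 1L)
    }
  }
})

test_that("dataset-1 keeps positives and samples negatives reproducibly", {
  corpus <- simulate_corpus(sim_params(n_hairpins = 4L, seed = 5L))
  pats <- generate_corpus_patterns(corpus$hairpins[, c("id", "sequence")],
                                   corpus$structures, corpus$annotations,
                                   pattern_config(14))
  n_pos <- sum(pats$label > 0L)
  d1 <- build_dataset1(pats, n_neg = 10L, seed = 7L)
  expect_equal(nrow(d1), n_pos + 10L)
  expect_equal(sum(d1$label == 0L), 10L)
  # same seed, same sample; different seed, different sample
  d1b <- build_dataset1(pats, n_neg = 10L, seed = 7L)
  expect_identical(d1$pattern_id, d1b$pattern_id)
  d1c <- build_dataset1(pats, n_neg = 10L, seed = 8L)
  expect_false(setequal(d1$pattern_id[d1$label == 0],
                        d1c$pattern_id[d1c$label == 0]))
  # n_neg = 0 keeps positives only; shortage keeps all with a warning
  expect_equal(sum(build_dataset1(pats, n_neg = 0L, seed = 1L)$label == 0L), 0L)
  expect_warning(build_dataset1(pats, n_neg = 1e6, seed = 1L), "keeping all")
})

test_that("dataset-2 samples a fixed number of negatives per hairpin", {
  corpus <- simulate_corpus(sim_params(n_hairpins = 3L, seed = 9L))
  pats <- generate_corpus_patterns(corpus$hairpins[, c("id", "sequence")],
                                   corpus$structures, corpus$annotations,
                                   pattern_config(14))
  d2 <- build_dataset2(pats, neg_per_premirna = 2L, seed = 3L)
  expect_equal(sum(d2$label == 0L), 2L * 3L)
  counts <- table(d2$premirna_id[d2$label == 0L])
  expect_true(all(counts == 2L))
  expect_equal(attr(d2, "variant"), "dataset2")
})

test_that("a hairpin with no negative windows triggers a warning, not an error", {
  # two sites close to the window size leave every window positive or dropped
  hp <- tibble::tibble(id = "tight", sequence = strrep("A", 27),
                       structure = strrep(".", 27))
  pats <- generate_patterns(hp, tibble::tibble(interval = c(13L, 15L)),
                            pattern_config(14)) |>
    dplyr::mutate(pattern_id = paste0("t", dplyr::row_number()),
                  premirna_id = "tight",
                  premirna_seq = hp$sequence, premirna_struct = hp$structure)
  expect_true(all(pats$label > 0L))
  expect_warning(build_dataset2(pats, seed = 1L), "no negative patterns")
})

test_that("fold assignment is balanced, seeded and pattern-level by default", {
  ds <- fixture_small_dataset(n_hairpins = 5L, seed = 2L)
  tab <- table(ds$fold)
  expect_equal(length(tab), 5L)
  expect_lte(max(tab) - min(tab), 1L)
  ds2 <- split_folds(ds, k = 5L, seed = 2L)
  expect_identical(ds$fold, ds2$fold)
  # 11 samples over 5 folds -> sizes {3,2,2,2,2}
  eleven <- split_folds(ds[1:11, ], k = 5L, seed = 1L)
  expect_equal(sort(as.integer(table(eleven$fold))), c(2L, 2L, 2L, 2L, 3L))
  expect_error(split_folds(ds, k = 1L), "k must be")
})

test_that("grouped fold assignment keeps each hairpin in one fold", {
  ds <- fixture_small_dataset(n_hairpins = 10L, seed = 3L)
  g <- split_folds(ds, k = 5L, seed = 4L, group_by_premirna = TRUE)
  per_hairpin <- tapply(g$fold, g$premirna_id, function(x) length(unique(x)))
  expect_true(all(per_hairpin == 1L))
})

test_that("redundancy clustering collapses near-identical sequences", {
  set.seed(1)
  base <- paste0(sample(c("A", "C", "G", "U"), 80, replace = TRUE), collapse = "")
  other <- paste0(sample(c("A", "C", "G", "U"), 80, replace = TRUE), collapse = "")
  recs <- tibble::tibble(
    id = c("a", "a_copy", "b"),
    sequence = c(base, base, other)
  )
  reps <- cluster_redundancy(recs, threshold = 0.80)
  expect_equal(nrow(reps), 2L)
  expect_true("b" %in% reps$id)
  # sequences sharing no 8-mers stay separate
  two <- tibble::tibble(id = c("x", "y"),
                        sequence = c(strrep("AC", 20), strrep("GU", 20)))
  expect_equal(nrow(cluster_redundancy(two, 0.8)), 2L)
  expect_error(cluster_redundancy(two, 0.3), "threshold")
})
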