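# Shared fixtures, built in code at test time.

# The 80-nt two-site hairpin mirroring the hsa-let-7a-1 geometry used in
# the worked example: 5p mature (6, 27), 3p mature (50, 71) so the Dicer
# cleavage sites sit at intervals 27 and 49.
fixture_two_site_hairpin <- function() {
  list(
    hairpin = tibble::tibble(
      id = "fx80",
      sequence = strrep("ACGU", 20),
      structure = paste0(strrep("(", 34), strrep(".", 12), strrep(")", 34))
    ),
    annotation = tibble::tibble(
      premirna_id = "fx80",
      arm = c("5p", "3p"),
      start = c(6L, 50L),
      end = c(27L, 71L)
    ),
    sites = tibble::tibble(interval = c(27L, 49L), arm = c("5p", "3p"))
  )
}

# tiny dataset tibble with hand-set pattern/hairpin strings
fixture_tiny_dataset <- function(s = 6L) {
  stopifnot(s == 6L)
  tab <- tibble::tibble(
    pattern_id = paste0("p", 1:4),
    premirna_id = c("h1", "h2", "h1", "h2"),
    window_start = c(1L, 2L, 3L, 4L),
    pattern_seq = c("ACGUAC", "GGCAUU", "CAGUCA", "AAGGUU"),
    pattern_struct = c("((..))", "(....)", "......", "(.())."),
    premirna_seq = c("ACGUACGUAGGC", "GGCAUUCCAGG", "ACGUACGUAGGC", "GGCAUUCCAGG"),
    premirna_struct = c("(((....)))..", "(((....))).", "(((....)))..", "(((....)))."),
    label = c(0L, 3L, 5L, 1L),
    fold = NA_integer_
  )
  dicersite:::new_pattern_dataset(tab, s = s, variant = "custom")
}

# small model config for fast exact tests
tiny_model_config <- function(s = 6L, fusion = "aff", dropout = 0) {
  dicer_model_config(
    s = s, embed_dim = 4L, n_layers = 2L, n_heads = 2L, ff_dim = 10L,
    out_dim = 8L, fc_hidden = 7L, dropout = dropout, fusion = fusion
  )
}

# simulated corpus -> balanced dataset with folds, small enough for trainer
# mechanism tests
fixture_small_dataset <- function(n_hairpins = 6L, s = 14L, seed = 5L,
                                  noise = 0) {
  corpus <- simulate_corpus(sim_params(n_hairpins = n_hairpins, noise = noise,
                                       seed = seed))
  pats <- generate_corpus_patterns(
    corpus$hairpins[, c("id", "sequence")], corpus$structures,
    corpus$annotations, pattern_config(s)
  )
  split_folds(build_dataset2(pats, seed = seed), k = 5L, seed = seed)
}

# independent brute-force window labeler used as the oracle for
# generate_patterns: enumerate every window and scan both sites literally
oracle_windows <- function(L, s, sites) {
  out <- list()
  for (a in seq_len(L - s + 1L)) {
    inside <- sites[sites >= a & sites <= a + s - 2L]
    if (length(inside) >= 2L) next
    label <- if (length(inside) == 1L) inside - a + 1L else 0L
    out[[length(out) + 1L]] <- data.frame(window_start = a, label = label)
  }
  do.call(rbind, out)
}
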