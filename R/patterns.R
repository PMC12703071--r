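# Cleavage-site inference and cleavage-pattern generation.
#
# Conventions (1-based):
#   * A cleavage site lives on the inter-nucleotide interval g, the gap
#     between nucleotides g and g+1 (1 <= g <= L-1).
#   * The 5p-arm site is the gap just 3' of the 5p mature's last nucleotide
#     (g = end_5p); the 3p-arm site is the gap just 5' of the 3p mature's
#     first nucleotide (g = start_3p - 1). Dicer's two cuts release the
#     mature duplex ends.
#   * A window starting at a covers nucleotides a..a+s-1 and intervals
#     a..a+s-2; a site at global interval g inside the window gets local
#     label k = g - a + 1 in 1..s-1. Label 0 = no site in the window.

#' Pattern-generation configuration
#'
#' @param s Pattern (window) size in nucleotides. The study grid is
#'   10/12/14/16/18, but any `s >= 4` is accepted. A window of `s`
#'   nucleotides has `s - 1` intervals, so there are `s` classes
#'   (0 = negative, 1..s-1 = site at that interval).
#' @param max_seq_len Fixed length full hairpins are padded to for the
#'   sequence input stream.
#' @return A list of class `pattern_config`.
#' @export
pattern_config <- function(s = 14L, max_seq_len = 200L) {
  s <- as.integer(s)
  if (is.na(s) || s < 4L) abort("pattern size s must be >= 4")
  structure(
    list(s = s, n_classes = s, max_seq_len = as.integer(max_seq_len)),
    class = "pattern_config"
  )
}

#' Infer Dicer cleavage sites from mature-arm annotations
#'
#' The 5p site is the interval just 3' of the 5p mature arm
#' (`g = end(5p)`); the 3p site is the interval just 5' of the 3p mature arm
#' (`g = start(3p) - 1`).
#'
#' @param premirna A one-row tibble (or list) with `id` and `sequence`.
#' @param annotations Annotation tibble from [read_mature_annotation()]
#'   (may contain other hairpins; rows are matched by `premirna_id`).
#' @return A tibble with columns `interval`, `arm`, sorted by interval.
#' @export
#' @examples
#' hp <- tibble::tibble(id = "h1", sequence = strrep("ACGU", 20))
#' ann <- tibble::tibble(
#'   premirna_id = "h1", arm = c("5p", "3p"),
#'   start = c(6L, 50L), end = c(27L, 71L)
#' )
#' infer_cleavage_sites(hp, ann)
infer_cleavage_sites <- function(premirna, annotations) {
  id <- premirna$id[[1]]
  L <- nchar(premirna$sequence[[1]])
  ann <- annotations[annotations$premirna_id == id, , drop = FALSE]
  if (sum(ann$arm == "5p") != 1L || sum(ann$arm == "3p") != 1L) {
    abort(paste0("incomplete annotation: ", id))
  }
  g5 <- ann$end[ann$arm == "5p"]
  g3 <- ann$start[ann$arm == "3p"] - 1L
  for (g in c(g5, g3)) {
    if (g < 1L || g > L - 1L) {
      abort(sprintf("inferred cleavage interval %d outside [1, %d] for '%s'",
                    g, L - 1L, id))
    }
  }
  if (g5 >= g3) {
    abort(sprintf("5p site (%d) not upstream of 3p site (%d) for '%s': overlapping matures",
                  g5, g3, id))
  }
  tibble::tibble(interval = c(g5, g3), arm = c("5p", "3p"))
}

#' Generate labeled cleavage patterns for one hairpin
#'
#' Slides a window of `s` nucleotides over the hairpin: positions
#' `a = 1..L-s+1`, each fully contained in the sequence. A window holding
#' exactly one cleavage site at global interval `g` is labeled
#' `k = g - a + 1`; a window with no site is labeled 0; windows spanning
#' both sites (possible when the two cuts are close) are removed so every
#' pattern carries at most one site.
#'
#' @param premirna One-row tibble/list with `id`, `sequence` and optionally
#'   `structure`.
#' @param sites Tibble from [infer_cleavage_sites()] (column `interval`).
#' @param config A [pattern_config()].
#' @return Tibble with columns `premirna_id`, `window_start`, `pattern_seq`,
#'   `pattern_struct`, `label`.
#' @export
generate_patterns <- function(premirna, sites, config = pattern_config()) {
  s <- config$s
  seq <- premirna$sequence[[1]]
  struct <- if ("structure" %in% names(premirna)) premirna$structure[[1]] else NULL
  L <- nchar(seq)
  if (!is.null(struct) && nchar(struct) != L) {
    abort(paste0("sequence/structure length mismatch for '", premirna$id[[1]], "'"))
  }
  if (L < s) abort(sprintf("hairpin '%s' shorter (%d) than pattern size %d",
                           premirna$id[[1]], L, s))
  g <- sort(as.integer(sites$interval))
  a <- seq_len(L - s + 1L)
  # site g falls in window a iff a <= g <= a + s - 2
  inside <- vapply(a, function(ai) sum(g >= ai & g <= ai + s - 2L), integer(1))
  keep <- inside <= 1L
  a <- a[keep]
  label <- integer(length(a))
  hit <- inside[keep] == 1L
  if (any(hit)) {
    gi <- vapply(a[hit], function(ai) g[g >= ai & g <= ai + s - 2L][[1]], integer(1))
    label[hit] <- gi - a[hit] + 1L
  }
  tibble::tibble(
    premirna_id = premirna$id[[1]],
    window_start = a,
    pattern_seq = substring(seq, a, a + s - 1L),
    pattern_struct = if (is.null(struct)) NA_character_ else substring(struct, a, a + s - 1L),
    label = label
  )
}

#' Generate patterns for a whole corpus
#'
#' Convenience wrapper: infers both cleavage sites per hairpin and binds the
#' per-hairpin patterns, attaching the parent sequence and structure columns
#' required by the model's full-sequence input stream.
#'
#' @param hairpins Tibble from [read_fasta()].
#' @param structures Tibble from [read_structures()].
#' @param annotations Tibble from [read_mature_annotation()].
#' @inheritParams generate_patterns
#' @return Tibble of patterns with parent context columns `premirna_seq`,
#'   `premirna_struct` and a `pattern_id`.
#' @export
generate_corpus_patterns <- function(hairpins, structures, annotations,
                                     config = pattern_config()) {
  joined <- dplyr::inner_join(hairpins, structures, by = "id")
  if (nrow(joined) < nrow(hairpins)) {
    abort("some hairpins lack a secondary structure record")
  }
  bad <- nchar(joined$sequence) != nchar(joined$structure)
  if (any(bad)) {
    abort(paste0("sequence/structure length mismatch for: ",
                 paste(joined$id[bad], collapse = ", ")))
  }
  pats <- purrr::map(seq_len(nrow(joined)), function(i) {
    hp <- joined[i, ]
    sites <- infer_cleavage_sites(hp, annotations)
    generate_patterns(hp, sites, config)
  })
  out <- dplyr::bind_rows(pats) |>
    dplyr::left_join(
      dplyr::rename(joined, premirna_id = "id", premirna_seq = "sequence",
                    premirna_struct = "structure"),
      by = "premirna_id"
    ) |>
    dplyr::mutate(pattern_id = paste0(.data$premirna_id, "_w", .data$window_start),
                  .before = 1)
  out
}

finalize_dataset <- function(samples, s, variant) {
  samples <- samples[order(samples$premirna_id, samples$window_start), ]
  if (!"fold" %in% names(samples)) samples$fold <- NA_integer_
  new_pattern_dataset(samples[, dataset_columns], s = s, variant = variant)
}

#' Build a realistic (negatives-majority) pattern dataset
#'
#' Keeps every positive pattern and samples `n_neg` negative patterns
#' uniformly without replacement across the whole corpus.
#'
#' @param patterns Pattern tibble from [generate_corpus_patterns()].
#' @param n_neg Number of negative patterns to sample (default 20000).
#' @param seed Integer seed; the same seed reproduces the same sample.
#' @return A `dicer_dataset` tibble.
#' @export
build_dataset1 <- function(patterns, n_neg = 20000L, seed = 1L) {
  s <- unique(nchar(patterns$pattern_seq))
  stopifnot(length(s) == 1L)
  pos <- patterns[patterns$label > 0L, ]
  neg <- patterns[patterns$label == 0L, ]
  if (nrow(neg) < n_neg) {
    warn(sprintf("only %d negative patterns available (requested %d); keeping all",
                 nrow(neg), n_neg))
    pick <- neg
  } else {
    idx <- with_seed(derive_seed(seed, "dataset"),
                     sample.int(nrow(neg), n_neg, replace = FALSE))
    pick <- neg[idx, ]
  }
  finalize_dataset(dplyr::bind_rows(pos, pick), s = s, variant = "dataset1")
}

#' Build a class-balanced pattern dataset
#'
#' Keeps every positive pattern and samples `neg_per_premirna` negatives
#' from each hairpin, so negatives number twice the hairpin count by
#' default.
#'
#' @inheritParams build_dataset1
#' @param neg_per_premirna Negatives sampled per hairpin (default 2).
#' @return A `dicer_dataset` tibble.
#' @export
build_dataset2 <- function(patterns, neg_per_premirna = 2L, seed = 1L) {
  s <- unique(nchar(patterns$pattern_seq))
  stopifnot(length(s) == 1L)
  pos <- patterns[patterns$label > 0L, ]
  neg <- patterns[patterns$label == 0L, ]
  picks <- with_seed(derive_seed(seed, "dataset"), {
    split(neg, neg$premirna_id) |>
      purrr::imap(function(df, id) {
        if (nrow(df) < neg_per_premirna) {
          warn(sprintf("hairpin '%s' has only %d negative pattern(s) (requested %d); keeping all",
                       id, nrow(df), neg_per_premirna))
          df
        } else {
          df[sample.int(nrow(df), neg_per_premirna), ]
        }
      }) |>
      dplyr::bind_rows()
  })
  short <- setdiff(unique(pos$premirna_id), unique(neg$premirna_id))
  if (length(short) > 0) {
    warn(paste0("no negative patterns available for: ",
                paste(short, collapse = ", ")))
  }
  finalize_dataset(dplyr::bind_rows(pos, picks), s = s, variant = "dataset2")
}

#' Assign cross-validation folds
#'
#' Random partition into `k` near-equal folds at the pattern level, matching
#' the evaluation protocol (each cleavage pattern is an independent unit).
#' Pattern-level assignment lets shifted windows of one hairpin land in
#' different folds; set `group_by_premirna = TRUE` to keep all patterns of a
#' hairpin in one fold for leakage-free evaluation.
#'
#' @param dataset A `dicer_dataset`.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @param group_by_premirna Assign folds per hairpin instead of per pattern.
#' @return The dataset with its `fold` column filled with values in
#'   `0..k-1`; fold sizes differ by at most one (per hairpin when grouped).
#' @export
split_folds <- function(dataset, k = 5L, seed = 1L, group_by_premirna = FALSE) {
  k <- as.integer(k)
  if (k < 2L) abort("k must be >= 2")
  n <- nrow(dataset)
  assign_balanced <- function(m) {
    # 0-based fold ids, sizes differing by <= 1
    sample(rep(seq_len(k) - 1L, length.out = m))
  }
  folds <- with_seed(derive_seed(seed, "folds"), {
    if (group_by_premirna) {
      ids <- unique(dataset$premirna_id)
      per_id <- setNames(assign_balanced(length(ids)), ids)
      unname(per_id[dataset$premirna_id])
    } else {
      assign_balanced(n)
    }
  })
  dataset$fold <- as.integer(folds)
  dataset
}

#' Remove redundant hairpins by sequence similarity
#'
#' When `cdhit_path` names a CD-HIT-EST executable it is invoked with the
#' given identity threshold and its representatives are returned. Otherwise
#' a built-in greedy clusterer is used: sequences are visited in order of
#' decreasing length and joined to the first cluster whose representative
#' has estimated global identity at or above the threshold; identity is
#' estimated from shared 8-mer containment `c` as `c^(1/8)` (inverting the
#' expected k-mer survival of a sequence at identity `t`, roughly `t^k`).
#'
#' @param records Tibble with `id`, `sequence`.
#' @param threshold Identity threshold in (0.5, 1].
#' @param cdhit_path Optional path to a `cd-hit-est` binary.
#' @return Tibble of cluster representatives (subset of `records`).
#' @export
cluster_redundancy <- function(records, threshold = 0.80, cdhit_path = NULL) {
  if (threshold <= 0.5 || threshold > 1) abort("threshold must be in (0.5, 1]")
  if (!is.null(cdhit_path)) {
    return(cluster_redundancy_external(records, threshold, cdhit_path))
  }
  k <- 8L
  kmers <- function(x) {
    n <- nchar(x)
    if (n < k) return(x)
    unique(substring(x, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
  }
  ord <- order(-nchar(records$sequence))
  reps <- integer(0)
  rep_kmers <- list()
  for (i in ord) {
    km <- kmers(records$sequence[[i]])
    placed <- FALSE
    for (j in seq_along(reps)) {
      shared <- sum(km %in% rep_kmers[[j]])
      containment <- shared / length(km)
      if (containment^(1 / k) >= threshold) {
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      rep_kmers[[length(reps)]] <- km
    }
  }
  records[sort(reps), ]
}

cluster_redundancy_external <- function(records, threshold, cdhit_path) {
  dir <- tempfile("cdhit")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  fa <- file.path(dir, "in.fa")
  out <- file.path(dir, "out.fa")
  write_fasta(records, fa)
  res <- suppressWarnings(system2(
    cdhit_path, c("-i", fa, "-o", out, "-c", format(threshold), "-n", "5"),
    stdout = TRUE, stderr = TRUE
  ))
  status <- attr(res, "status") %||% 0L
  if (status != 0L) {
    abort(paste0("cd-hit-est failed (exit ", status, "):\n",
                 paste(res, collapse = "\n")))
  }
  reps <- read_fasta(out)
  records[records$id %in% reps$id, ]
}
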