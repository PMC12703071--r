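# Synthetic pre-miRNA hairpins with planted, learnable cleavage
# determinants. The simulator emulates the geometry real annotated
# hairpins present to the pipeline — a paired stem with a terminal loop,
# two interior cleavage sites at mature-arm-like offsets from the ends,
# and a short sequence motif immediately 5' of each site — without any
# claim of thermodynamic realism.

#' Simulation parameters
#'
#' @param n_hairpins Number of hairpins to draw.
#' @param length_range Hairpin length range (nt), default 60–120.
#' @param pairing_frac Fraction of stem positions that are base-paired;
#'   the remainder become unpaired bulges (default 0.85).
#' @param loop_range Terminal loop length range (default 8–15 nt).
#' @param motif IUPAC motif planted immediately 5' of each cleavage site,
#'   occupying the `nchar(motif)` nucleotides ending at the site interval
#'   (default `"GYUC"`; Y = C or U).
#' @param site_offset_range Distance range of each cleavage site from its
#'   end of the hairpin (5p site from the 5' end, 3p site from the 3' end),
#'   default 20–30 nt, emulating mature-arm geometry. The 3p draw is
#'   additionally constrained so the two sites stay more than
#'   `max_pattern_size - 2` intervals apart and at least
#'   `max_pattern_size - 1` intervals from both ends.
#' @param noise Per-position probability that a planted motif position is
#'   replaced by a random nucleotide. `noise = 1` ablates the motif
#'   entirely.
#' @param max_pattern_size Largest pattern size the corpus must support
#'   (default 18).
#' @param structure_bulge Optionally plant a fixed two-nucleotide bulge
#'   (`".."`) in the structure string starting 6 nt 5' of each site, as a
#'   structural determinant for stress tests.
#' @param seed Integer seed.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_hairpins = 100L,
                       length_range = c(60L, 120L),
                       pairing_frac = 0.85,
                       loop_range = c(8L, 15L),
                       motif = "GYUC",
                       site_offset_range = c(20L, 30L),
                       noise = 0,
                       max_pattern_size = 18L,
                       structure_bulge = FALSE,
                       seed = 1L) {
  stopifnot(length_range[1] <= length_range[2], loop_range[1] <= loop_range[2],
            site_offset_range[1] <= site_offset_range[2],
            noise >= 0, noise <= 1, pairing_frac > 0, pairing_frac <= 1)
  min_needed <- 2L * site_offset_range[1] + max_pattern_size - 1L
  if (length_range[2] < min_needed) {
    abort(sprintf("length range too short for the site offsets: need L >= %d", min_needed))
  }
  structure(
    list(
      n_hairpins = as.integer(n_hairpins),
      length_range = as.integer(length_range),
      pairing_frac = pairing_frac,
      loop_range = as.integer(loop_range),
      motif = motif,
      site_offset_range = as.integer(site_offset_range),
      noise = noise,
      max_pattern_size = as.integer(max_pattern_size),
      structure_bulge = isTRUE(structure_bulge),
      seed = as.integer(seed)
    ),
    class = "sim_params"
  )
}

IUPAC <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U")
)

sample_motif_instance <- function(motif) {
  chars <- strsplit(motif, "", fixed = TRUE)[[1]]
  paste0(vapply(chars, function(ch) {
    opts <- IUPAC[[ch]]
    if (is.null(opts)) abort(paste0("invalid IUPAC code in motif: ", ch))
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

#' Does a sequence window match an IUPAC motif?
#'
#' @param x Sequence fragment (same length as `motif`).
#' @param motif IUPAC motif string.
#' @return Logical.
#' @export
motif_matches <- function(x, motif) {
  if (nchar(x) != nchar(motif)) return(FALSE)
  xs <- strsplit(x, "", fixed = TRUE)[[1]]
  ms <- strsplit(motif, "", fixed = TRUE)[[1]]
  all(vapply(seq_along(xs), function(i) xs[i] %in% IUPAC[[ms[i]]], logical(1)))
}

RC <- c(A = "U", C = "G", G = "C", U = "A")

# sample one integer uniformly from a..b (safe for a == b, unlike sample())
runif_int <- function(a, b) {
  if (a > b) abort("infeasible constraint: empty integer range")
  a + sample.int(b - a + 1L, 1L) - 1L
}

# One hairpin draw. Assumes the caller has set the RNG state.
simulate_hairpin_impl <- function(params, id) {
  p <- params
  s_max <- p$max_pattern_size
  L <- runif_int(p$length_range[1], p$length_range[2])
  # site placement: d5 from the 5' end, d3 from the 3' end, constrained so
  # g3 - g5 = L - d5 - d3 >= s_max - 1 (> s_max - 2 intervals apart)
  d5_max <- min(p$site_offset_range[2], L - p$site_offset_range[1] - (s_max - 1L))
  d5 <- runif_int(p$site_offset_range[1], d5_max)
  d3_max <- min(p$site_offset_range[2], L - d5 - (s_max - 1L))
  d3 <- runif_int(p$site_offset_range[1], d3_max)
  g5 <- d5
  g3 <- L - d3

  # stem/loop scaffold: 5' arm, terminal loop, 3' arm
  loop_len <- runif_int(p$loop_range[1], p$loop_range[2])
  n5 <- ceiling((L - loop_len) / 2)
  n3 <- L - loop_len - n5

  arm5 <- sample(RNA_ALPHABET, n5, replace = TRUE)
  loop <- sample(RNA_ALPHABET, loop_len, replace = TRUE)
  # 3' arm biased toward the reverse complement of the 5' arm
  pair_src <- rev(arm5[seq_len(n3)])
  arm3 <- ifelse(runif(n3) < p$pairing_frac, RC[pair_src],
                 sample(RNA_ALPHABET, n3, replace = TRUE))
  seq_chars <- c(arm5, loop, unname(arm3))

  # plant the motif just 5' of each site (ending at nucleotide g), with
  # per-position mutation noise
  mlen <- nchar(p$motif)
  for (g in c(g5, g3)) {
    inst <- strsplit(sample_motif_instance(p$motif), "", fixed = TRUE)[[1]]
    mut <- runif(mlen) < p$noise
    inst[mut] <- sample(RNA_ALPHABET, sum(mut), replace = TRUE)
    seq_chars[(g - mlen + 1L):g] <- inst
  }

  # dot-bracket: paired stem positions with unpaired bulges at rate
  # 1 - pairing_frac; arms are bracket-balanced by construction
  n_pair <- max(1L, round(p$pairing_frac * min(n5, n3)))
  open_pos <- sort(sample(n5, n_pair))
  close_pos <- sort(sample(n3, n_pair))
  st <- rep(".", L)
  st[open_pos] <- "("
  st[n5 + loop_len + close_pos] <- ")"
  if (p$structure_bulge) {
    for (g in c(g5, g3)) st[(g - 6L):(g - 5L)] <- "."
    # re-balance: trim the now-unequal bracket counts from the stem ends
    n_open <- sum(st == "(")
    n_close <- sum(st == ")")
    if (n_open > n_close) {
      drop <- utils::tail(which(st == "("), n_open - n_close)
      st[drop] <- "."
    } else if (n_close > n_open) {
      drop <- which(st == ")")[seq_len(n_close - n_open)]
      st[drop] <- "."
    }
  }

  mature_len <- 22L
  ann <- tibble::tibble(
    premirna_id = id,
    arm = c("5p", "3p"),
    start = c(max(1L, g5 - mature_len + 1L), g3 + 1L),
    end = c(g5, min(L, g3 + mature_len))
  )
  list(
    hairpin = tibble::tibble(id = id, sequence = paste0(seq_chars, collapse = ""),
                             structure = paste0(st, collapse = "")),
    annotation = ann,
    sites = tibble::tibble(interval = c(g5, g3), arm = c("5p", "3p"))
  )
}

#' Simulate one hairpin
#'
#' @param params A [sim_params()] object.
#' @param id Record id.
#' @param seed Seed for this draw (defaults to the seed in `params`).
#' @return A list with `hairpin` (id, sequence, structure), `annotation`
#'   (two mature-arm rows consistent with [infer_cleavage_sites()]) and
#'   `sites`.
#' @export
simulate_hairpin <- function(params = sim_params(), id = "sim_1",
                             seed = params$seed) {
  with_seed(derive_seed(seed, "sim"), simulate_hairpin_impl(params, id))
}

#' Simulate a hairpin corpus
#'
#' Draws `params$n_hairpins` independent hairpins and optionally writes the
#' three artifact files (FASTA, structure TSV, annotation TSV) that real
#' data would occupy.
#'
#' @param params A [sim_params()] object.
#' @param dir Optional output directory; files `hairpins.fa`,
#'   `structures.tsv`, `matures.tsv` are written when given.
#' @return A list with tibbles `hairpins` (id, sequence, structure),
#'   `structures`, `annotations`, plus the true `sites`.
#' @export
simulate_corpus <- function(params = sim_params(), dir = NULL) {
  draws <- with_seed(derive_seed(params$seed, "sim"), {
    purrr::map(seq_len(params$n_hairpins), function(i) {
      simulate_hairpin_impl(params, sprintf("sim_%04d", i))
    })
  })
  hairpins <- purrr::map_dfr(draws, "hairpin")
  annotations <- purrr::map_dfr(draws, "annotation")
  sites <- purrr::map_dfr(draws, function(d) {
    dplyr::mutate(d$sites, premirna_id = d$hairpin$id[[1]], .before = 1)
  })
  structures <- hairpins[, c("id", "structure")]
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_fasta(hairpins[, c("id", "sequence")], file.path(dir, "hairpins.fa"))
    write_structures(structures, file.path(dir, "structures.tsv"))
    write_mature_annotation(annotations, file.path(dir, "matures.tsv"))
  }
  list(hairpins = hairpins, structures = structures,
       annotations = annotations, sites = sites)
}
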