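# Readers and writers for the on-disk artifacts: hairpin FASTA, Vienna
# dot-bracket structure files, mature-arm annotation TSVs and pattern
# dataset CSVs. Coordinates are 1-based inclusive throughout (miRBase
# convention). DNA input (T) is silently normalised to RNA (U) because
# miRBase distributes some files in the DNA alphabet.

#' Read hairpin sequences from a FASTA file
#'
#' Sequences are uppercased and T is converted to U; the record order of the
#' file is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      abort(paste0("failed to parse FASTA '", path, "': ", conditionMessage(e)))
    }
  )
  ids <- sub("\\s.*$", "", names(set))
  seqs <- normalize_rna(as.character(set))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    abort(paste0("empty sequence for record(s): ",
                 paste(ids[empty], collapse = ", ")))
  }
  for (i in seq_along(seqs)) assert_rna(seqs[[i]], paste0("record '", ids[[i]], "'"))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicated FASTA ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  tibble::tibble(id = ids, sequence = unname(seqs))
}

#' Read dot-bracket secondary structures
#'
#' Accepts either the Vienna three-line format (`>id`, sequence line,
#' structure line — as emitted by RNAfold) or a two-column TSV with columns
#' `id` and `structure`. Structures are validated for bracket balance; when
#' the Vienna form carries a sequence line, the structure length is checked
#' against it.
#'
#' @param path Path to a structure file.
#' @return A tibble with columns `id`, `structure`.
#' @export
read_structures <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(paste0("empty structure file: ", path))

  if (startsWith(lines[[1]], ">")) {
    heads <- which(startsWith(lines, ">"))
    ids <- sub("\\s.*$", "", sub("^>", "", lines[heads]))
    recs <- purrr::map2(heads, c(heads[-1] - 1L, length(lines)), function(h, e) {
      body <- lines[seq(h + 1L, length.out = max(0L, e - h))]
      if (length(body) < 1L) {
        abort(paste0("no structure line for record '", sub("^>", "", lines[[h]]), "'"))
      }
      # RNAfold output: sequence line then "structure (mfe)"; accept a bare
      # structure line too.
      struct_line <- body[[length(body)]]
      struct <- sub("\\s.*$", "", struct_line)
      seq_line <- if (length(body) >= 2L) body[[1L]] else NULL
      list(struct = struct, seq = seq_line)
    })
    structs <- purrr::map_chr(recs, "struct")
    seqs <- purrr::map(recs, "seq")
    for (i in seq_along(ids)) {
      validate_structure(structs[[i]], ids[[i]])
      if (!is.null(seqs[[i]]) && nchar(seqs[[i]]) != nchar(structs[[i]])) {
        abort(sprintf(
          "structure length (%d) differs from sequence length (%d) for '%s'",
          nchar(structs[[i]]), nchar(seqs[[i]]), ids[[i]]
        ))
      }
    }
    out <- tibble::tibble(id = ids, structure = structs)
  } else {
    tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
    if (!all(c("id", "structure") %in% names(tab))) {
      abort("structure TSV must have columns 'id' and 'structure'")
    }
    purrr::walk2(tab$structure, tab$id, validate_structure)
    out <- tibble::tibble(id = tab$id, structure = tab$structure)
  }
  if (anyDuplicated(out$id)) {
    abort("duplicated structure ids")
  }
  out
}

#' Read mature-arm annotations
#'
#' The TSV must have header `premirna_id`, `arm`, `start`, `end` with
#' 1-based inclusive coordinates, one `5p` and one `3p` row per hairpin.
#'
#' @param path Path to the annotation TSV.
#' @param hairpins Optional tibble from [read_fasta()]; when given, every
#'   annotated hairpin must exist and coordinates must fit its length.
#' @return A tibble with columns `premirna_id`, `arm`, `start`, `end`.
#' @export
read_mature_annotation <- function(path, hairpins = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tab <- readr::read_tsv(path, col_types = readr::cols(
    premirna_id = readr::col_character(),
    arm = readr::col_character(),
    start = readr::col_integer(),
    end = readr::col_integer()
  ))
  required <- c("premirna_id", "arm", "start", "end")
  if (!all(required %in% names(tab))) {
    abort(paste0("annotation TSV must have columns: ",
                 paste(required, collapse = ", ")))
  }
  if (!all(tab$arm %in% c("5p", "3p"))) {
    abort("annotation 'arm' must be '5p' or '3p'")
  }
  bad <- tab$start < 1L | tab$start > tab$end
  if (any(bad)) {
    abort(paste0("invalid coordinates (need 1 <= start <= end) for: ",
                 paste(tab$premirna_id[bad], collapse = ", ")))
  }
  counts <- tab |>
    dplyr::count(.data$premirna_id, .data$arm) |>
    tidyr::pivot_wider(names_from = "arm", values_from = "n", values_fill = 0L)
  for (arm in c("5p", "3p")) if (!arm %in% names(counts)) counts[[arm]] <- 0L
  incomplete <- counts$premirna_id[counts[["5p"]] != 1L | counts[["3p"]] != 1L]
  if (length(incomplete) > 0) {
    abort(paste0("incomplete annotation: ", paste(incomplete, collapse = ", ")))
  }
  if (!is.null(hairpins)) {
    missing <- setdiff(tab$premirna_id, hairpins$id)
    if (length(missing) > 0) {
      abort(paste0("annotated hairpins absent from FASTA: ",
                   paste(missing, collapse = ", ")))
    }
    lens <- setNames(nchar(hairpins$sequence), hairpins$id)
    over <- tab$end > lens[tab$premirna_id]
    if (any(over)) {
      abort(paste0("annotation end beyond hairpin length for: ",
                   paste(tab$premirna_id[over], collapse = ", ")))
    }
  }
  tab[, required]
}

#' Write hairpin records to FASTA / structures / annotations
#'
#' Companions to the readers, used by the simulator and the CLI.
#'
#' @param hairpins Tibble with `id`, `sequence`.
#' @param structures Tibble with `id`, `structure`.
#' @param annotations Tibble with `premirna_id`, `arm`, `start`, `end`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(hairpins, path) {
  writeLines(paste0(">", hairpins$id, "\n", hairpins$sequence), path)
  invisible(path)
}

#' @rdname write_fasta
#' @param sequences Optional named character of sequences to interleave in
#'   Vienna style; if omitted a two-column TSV is written.
#' @export
write_structures <- function(structures, path, sequences = NULL) {
  if (is.null(sequences)) {
    readr::write_tsv(structures, path)
  } else {
    writeLines(paste0(">", structures$id, "\n",
                      sequences[structures$id], "\n", structures$structure),
               path)
  }
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_mature_annotation <- function(annotations, path) {
  readr::write_tsv(annotations, path)
  invisible(path)
}

dataset_columns <- c(
  "pattern_id", "premirna_id", "window_start", "pattern_seq",
  "pattern_struct", "premirna_seq", "premirna_struct", "label", "fold"
)

#' Write / read a pattern dataset CSV
#'
#' The CSV schema is fixed: `pattern_id, premirna_id, window_start,
#' pattern_seq, pattern_struct, premirna_seq, premirna_struct, label, fold`.
#' A dataset round-trips losslessly: `read_pattern_dataset(write_pattern_dataset(d))`
#' equals `d`.
#'
#' @param dataset A pattern dataset tibble (see [build_dataset1()]).
#' @param path Output CSV path.
#' @return `write_pattern_dataset()` returns the path invisibly;
#'   `read_pattern_dataset()` returns the dataset tibble.
#' @export
write_pattern_dataset <- function(dataset, path) {
  stopifnot(all(setdiff(dataset_columns, "fold") %in% names(dataset)))
  out <- dataset
  if (!"fold" %in% names(out)) out$fold <- NA_integer_
  meta <- dataset_meta(dataset)
  readr::write_csv(out[, dataset_columns], path)
  meta_path <- paste0(path, ".meta.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pattern_dataset
#' @export
read_pattern_dataset <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  spec <- list(
    pattern_id = readr::col_character(),
    premirna_id = readr::col_character(),
    window_start = readr::col_integer(),
    pattern_seq = readr::col_character(),
    pattern_struct = readr::col_character(),
    premirna_seq = readr::col_character(),
    premirna_struct = readr::col_character(),
    label = readr::col_integer(),
    fold = readr::col_integer()
  )
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  tab <- readr::read_csv(path, col_types = do.call(readr::cols, spec[intersect(names(spec), header)]))
  unknown <- setdiff(names(tab), dataset_columns)
  if (length(unknown) > 0) {
    abort(paste0("unknown dataset column(s): ", paste(unknown, collapse = ", ")))
  }
  if (!all(setdiff(dataset_columns, "fold") %in% names(tab))) {
    abort("dataset CSV is missing required columns")
  }
  if (!"fold" %in% names(tab)) tab$fold <- NA_integer_
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list(s = unique(nchar(tab$pattern_seq)), variant = "custom")
  }
  s <- as.integer(meta$s[[1]])
  bad <- tab$label < 0L | tab$label > s - 1L
  if (any(bad)) {
    abort(sprintf("label outside 0..%d for pattern(s): %s", s - 1L,
                  paste(tab$pattern_id[bad], collapse = ", ")))
  }
  new_pattern_dataset(tab, s = s, variant = meta$variant %||% "custom")
}

dataset_meta <- function(dataset) {
  list(
    s = attr(dataset, "s") %||% unique(nchar(dataset$pattern_seq))[[1]],
    variant = attr(dataset, "variant") %||% "custom"
  )
}

new_pattern_dataset <- function(tab, s, variant = "custom") {
  tab <- tibble::as_tibble(tab)
  structure(tab,
    s = as.integer(s), variant = variant,
    class = c("dicer_dataset", class(tab))
  )
}

#' @export
print.dicer_dataset <- function(x, ...) {
  s <- attr(x, "s")
  cat(sprintf(
    "<dicer_dataset> %d patterns | pattern size %d (%d classes) | variant: %s\n",
    nrow(x), s, s, attr(x, "variant")
  ))
  counts <- table(factor(x$label, levels = 0:(s - 1)))
  cat("class counts: ", paste(sprintf("%s:%d", names(counts), counts), collapse = " "), "\n")
  NextMethod()
}
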