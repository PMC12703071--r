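# Internal helpers: seed management and validation.

RNA_ALPHABET <- c("A", "C", "G", "U")
STRUCT_ALPHABET <- c("(", ")", ".")

# All stochastic steps draw from a named stream derived from one top-level
# seed, so dataset sampling, fold assignment, parameter init and shuffling
# are independently reproducible.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(
    dataset = 1000003L, folds = 2000029L, init = 3000017L,
    shuffle = 4000037L, sim = 5000011L, split = 6000007L,
    dropout = 7000003L
  )
  if (!stream %in% names(offsets)) {
    abort(paste0("unknown seed stream: ", stream))
  }
  as.integer((as.numeric(seed) + offsets[[stream]]) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_rna <- function(x, what = "sequence") {
  bad <- regmatches(x, regexpr("[^ACGU]", x))
  if (length(bad) > 0 && any(nzchar(bad))) {
    pos <- regexpr("[^ACGU]", x)
    abort(sprintf(
      "invalid character '%s' at position %d of %s (alphabet A/C/G/U)",
      substr(x, pos, pos), pos, what
    ))
  }
  invisible(x)
}

assert_structure_chars <- function(x, what = "structure") {
  pos <- regexpr("[^().]", x)
  if (pos > 0) {
    abort(sprintf(
      "invalid character '%s' at position %d of %s (alphabet ( / ) / .)",
      substr(x, pos, pos), pos, what
    ))
  }
  invisible(x)
}

#' Validate a dot-bracket structure string
#'
#' Checks the alphabet and that brackets are balanced and properly nested
#' (every `(` has a matching `)`).
#'
#' @param structure A dot-bracket string over `(`, `)`, `.`.
#' @param id Optional record id used in error messages.
#' @return Invisibly `TRUE`; errors on invalid input.
#' @export
#' @examples
#' validate_structure("(((...)))")
validate_structure <- function(structure, id = NULL) {
  label <- if (is.null(id)) "structure" else paste0("structure '", id, "'")
  assert_structure_chars(structure, label)
  chars <- strsplit(structure, "", fixed = TRUE)[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0) || (length(depth) > 0 && depth[length(depth)] != 0)) {
    abort(paste0("unbalanced brackets in ", label))
  }
  invisible(TRUE)
}

normalize_rna <- function(x) {
  chartr("Tt", "Uu", toupper(x))
}
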