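# Dual sequence/structure 3-mer token encoding.
#
# Every position i of a string yields the overlapping 3-mer starting at i;
# the last two positions cannot form a full 3-mer and are completed with
# "<PH>" placeholders, so the token count always equals the string length.
# Over {A,C,G,U} this gives 4^3 + 4^2 + 4 = 84 distinct tokens; over
# {(,),.} it gives 3^3 + 3^2 + 3 = 39.

PH <- "<PH>"

#' Build a 3-mer token vocabulary
#'
#' Enumerates every token the placeholder-completed overlapping-3-mer
#' scheme can produce: all full 3-mers, all two-character tokens ending in
#' one placeholder and all single-character tokens ending in two, in
#' deterministic lexicographic order. Token ids start at 1; id 0 is
#' reserved for padding and not counted in the vocabulary size.
#'
#' @param kind `"sequence"` (alphabet A/C/G/U, 84 tokens) or `"structure"`
#'   (alphabet `(`/`)`/`.`, 39 tokens).
#' @return A list of class `dicer_vocab` with `kind`, `tokens`, `ids`
#'   (named integer map) and `size`.
#' @export
#' @examples
#' build_vocab("sequence")$size    # 84
#' build_vocab("structure")$size   # 39
build_vocab <- function(kind = c("sequence", "structure")) {
  kind <- match.arg(kind)
  ab <- if (kind == "sequence") RNA_ALPHABET else STRUCT_ALPHABET
  full <- apply(expand.grid(ab, ab, ab, stringsAsFactors = FALSE)[, 3:1], 1, paste0, collapse = "")
  two <- apply(expand.grid(ab, ab, stringsAsFactors = FALSE)[, 2:1], 1, paste0, collapse = "")
  tokens <- c(sort(full), paste0(sort(two), PH), paste0(ab, PH, PH))
  structure(
    list(
      kind = kind,
      tokens = tokens,
      ids = setNames(seq_along(tokens), tokens),
      size = length(tokens),
      pad_id = 0L
    ),
    class = "dicer_vocab"
  )
}

#' Tokenise a string into overlapping 3-mers
#'
#' @param text A sequence (A/C/G/U) or dot-bracket string.
#' @param kind Which alphabet `text` uses.
#' @return Character vector of tokens, one per input position.
#' @export
#' @examples
#' tokenize_3mer("ACGU", "sequence")
#' # "ACG" "CGU" "GU<PH>" "U<PH><PH>"
tokenize_3mer <- function(text, kind = c("sequence", "structure")) {
  kind <- match.arg(kind)
  if (kind == "sequence") assert_rna(text) else assert_structure_chars(text)
  n <- nchar(text)
  if (n == 0L) abort("cannot tokenize an empty string")
  start <- seq_len(n)
  toks <- substring(text, start, pmin(start + 2L, n))
  pad <- n - start + 1L            # characters actually available
  toks <- ifelse(pad >= 3L, toks,
                 paste0(toks, strrep(PH, pmax(0L, 3L - pad))))
  toks
}

#' Map tokens to integer ids
#'
#' @param tokens Character vector from [tokenize_3mer()].
#' @param vocab A [build_vocab()] vocabulary of the matching kind.
#' @return Integer vector of ids in `1..vocab$size`.
#' @export
tokens_to_ids <- function(tokens, vocab) {
  ids <- vocab$ids[tokens]
  if (anyNA(ids)) {
    abort(paste0("token(s) outside vocabulary: ",
                 paste(unique(tokens[is.na(ids)]), collapse = ", ")))
  }
  unname(ids)
}

encode_ids <- function(text, kind, vocab) {
  tokens_to_ids(tokenize_3mer(text, kind), vocab)
}

#' Sinusoidal positional encoding
#'
#' `PE[pos, 2i] = sin(pos / 10000^(2i/dim))`,
#' `PE[pos, 2i+1] = cos(pos / 10000^(2i/dim))`, with `pos` starting at 0.
#'
#' @param length Number of positions.
#' @param dim Encoding dimension (must be even).
#' @return A `length x dim` matrix with entries in `[-1, 1]`.
#' @export
sinusoidal_pe <- function(length, dim) {
  if (dim %% 2L != 0L) abort("positional-encoding dim must be even")
  pos <- seq_len(length) - 1
  i <- seq_len(dim / 2L) - 1
  angle <- outer(pos, 1 / 10000^(2 * i / dim))
  pe <- matrix(0, nrow = length, ncol = dim)
  pe[, 2 * i + 1] <- sin(angle)
  pe[, 2 * i + 2] <- cos(angle)
  pe
}

#' Assemble one model input stream
#'
#' Looks up the 32-dimensional sequence and structure embeddings for each
#' position, concatenates them along the feature axis (giving the model
#' dimension `d_model = 64`), adds the sinusoidal positional encoding over
#' the joint vector, and pads with zero rows to `pad_to` positions. Padded
#' positions carry a `FALSE` mask flag and are excluded from attention and
#' pooling, so results do not depend on the pad length.
#'
#' @param seq_ids,struct_ids Integer token ids (equal length).
#' @param seq_embed,struct_embed Embedding matrices (`vocab_size x
#'   embed_dim`).
#' @param pad_to Total positions after padding, or `NULL` for no padding
#'   (used for fixed-length patterns).
#' @return A list with `values` (`positions x d_model` matrix) and `mask`
#'   (logical vector of valid positions).
#' @export
assemble_stream <- function(seq_ids, struct_ids, seq_embed, struct_embed,
                            pad_to = NULL) {
  n <- length(seq_ids)
  if (length(struct_ids) != n) {
    abort("sequence and structure token counts differ")
  }
  total <- if (is.null(pad_to)) n else as.integer(pad_to)
  if (n > total) abort(sprintf("input length %d exceeds pad length %d", n, total))
  d <- ncol(seq_embed) + ncol(struct_embed)
  values <- matrix(0, nrow = total, ncol = d)
  values[seq_len(n), ] <- cbind(seq_embed[seq_ids, , drop = FALSE],
                                struct_embed[struct_ids, , drop = FALSE]) +
    sinusoidal_pe(n, d)
  list(values = values, mask = seq_len(total) <= n)
}
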