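#' Construct a vocabulary
#'
#' A vocabulary maps token strings to integer ids. Three special tokens are
#' reserved at fixed positions: `[PAD]` (1), `[UNK]` (2), `[MASK]` (3).
#' All other tokens follow in the order given.
#'
#' @param tokens Character vector of unique, non-special token strings.
#' @return An object of class `msp_vocabulary`.
#' @export
vocabulary <- function(tokens) {
  tokens <- as.character(tokens)
  specials <- c("[PAD]", "[UNK]", "[MASK]")
  tokens <- setdiff(tokens, specials)
  if (anyDuplicated(tokens)) stop("vocabulary tokens must be unique")
  all_tokens <- c(specials, tokens)
  v <- structure(
    list(
      tokens = all_tokens,
      index = stats::setNames(seq_along(all_tokens), all_tokens),
      pad_id = 1L, unk_id = 2L, mask_id = 3L
    ),
    class = "msp_vocabulary"
  )
  v
}

#' @export
print.msp_vocabulary <- function(x, ...) {
  cat("<msp_vocabulary> ", length(x$tokens), " tokens ",
      "(specials: [PAD]=1 [UNK]=2 [MASK]=3)\n", sep = "")
  invisible(x)
}

#' @export
length.msp_vocabulary <- function(x) length(x$tokens)

#' Token ids for token strings
#'
#' Unknown tokens map to the `[UNK]` id.
#'
#' @param vocab An `msp_vocabulary`.
#' @param tokens Character vector.
#' @return Integer vector of ids.
#' @export
vocab_ids <- function(vocab, tokens) {
  ids <- unname(vocab$index[tokens])
  ids[is.na(ids)] <- vocab$unk_id
  as.integer(ids)
}

#' Token strings for ids
#' @param vocab An `msp_vocabulary`.
#' @param ids Integer vector of valid ids.
#' @return Character vector.
#' @export
vocab_tokens <- function(vocab, ids) {
  if (any(ids < 1L | ids > length(vocab$tokens)))
    stop("token id out of range for vocabulary")
  vocab$tokens[ids]
}

special_ids <- function(vocab) c(vocab$pad_id, vocab$unk_id, vocab$mask_id)

#' Normalize and split text into tokens
#'
#' Lowercases and splits on whitespace. The tokenizer is deliberately
#' simple; the backbone contract is tokenizer-agnostic.
#'
#' @param text A length-1 character string.
#' @return Character vector of surface tokens.
#' @export
normalize_tokens <- function(text) {
  text <- tolower(trimws(text))
  if (!nzchar(text)) stop("cannot tokenize empty or whitespace-only text")
  strsplit(text, "\\s+")[[1L]]
}

#' Tokenize text against a vocabulary
#'
#' @param text A length-1 character string; must contain at least one token
#'   after normalization.
#' @param vocab An `msp_vocabulary`.
#' @return An object of class `msp_tokens` with fields `ids` and `text`.
#' @export
tokenize <- function(text, vocab) {
  toks <- normalize_tokens(text)
  structure(
    list(ids = vocab_ids(vocab, toks), text = text),
    class = "msp_tokens"
  )
}

#' @export
print.msp_tokens <- function(x, ...) {
  cat("<msp_tokens> ", length(x$ids), " ids: ",
      paste(x$ids, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Write a vocabulary file
#'
#' One token per line, UTF-8; the first three lines are the reserved
#' `[PAD]`, `[UNK]`, `[MASK]` tokens.
#'
#' @param vocab An `msp_vocabulary`.
#' @param path File path.
#' @export
write_vocabulary <- function(vocab, path) {
  writeLines(vocab$tokens, path, useBytes = TRUE)
  invisible(path)
}

#' Read a vocabulary file
#' @param path File path written by [write_vocabulary()].
#' @return An `msp_vocabulary`.
#' @export
read_vocabulary <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 3L || !identical(lines[1:3], c("[PAD]", "[UNK]", "[MASK]")))
    stop("vocabulary file must start with [PAD], [UNK], [MASK]")
  vocabulary(lines[-(1:3)])
}
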