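#' Build a SMILES token vocabulary
#'
#' Collects all distinct tokens (under [smiles_tokenize()] rules) appearing
#' in a training corpus and assigns contiguous integer indices. Index 0 is
#' reserved for padding and never collides with a chemical token; chemical
#' tokens are sorted lexicographically (C locale) so the mapping is
#' reproducible regardless of corpus order.
#'
#' @param corpus Character vector of canonical SMILES strings.
#' @return An object of class `token_vocabulary`: list with `tokens`
#'   (character vector, position = index) and `index` (named integer map),
#'   plus `pad_index = 0`.
#' @export
build_token_vocabulary <- function(corpus) {
  stopifnot(is.character(corpus), length(corpus) > 0L)
  toks <- unique(unlist(lapply(corpus, smiles_tokenize)))
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  toks <- sort(toks)
  idx <- seq_along(toks)
  names(idx) <- toks
  structure(list(tokens = toks, index = idx, pad_index = 0L),
            class = "token_vocabulary")
}

#' @method print token_vocabulary
#' @export
print.token_vocabulary <- function(x, ...) {
  cat("token_vocabulary:", length(x$tokens), "tokens + pad\n")
  invisible(x)
}

#' @export
length.token_vocabulary <- function(x) length(x$tokens)

#' Encode a SMILES string as a fixed-length token-id sequence
#'
#' Tokenizes the SMILES and maps tokens to vocabulary indices, right-padding
#' with the pad index 0 to `max_len`. In lenient mode (default) tokens
#' absent from the vocabulary map to the pad index with a warning; strict
#' mode raises an error. Sequences longer than `max_len` raise an
#' overlength error (callers typically drop such molecules with a logged
#' count) — truncation would silently corrupt the chemistry.
#'
#' @param smiles A canonical SMILES string.
#' @param vocab A [build_token_vocabulary()] object.
#' @param max_len Output length (default 97).
#' @param strict Error on unknown tokens instead of mapping to pad.
#' @return Integer vector of length `max_len`.
#' @export
encode_smiles_tokens <- function(smiles, vocab, max_len = 97L, strict = FALSE) {
  stopifnot(inherits(vocab, "token_vocabulary"))
  toks <- smiles_tokenize(smiles)
  if (length(toks) > max_len)
    stop("SMILES has ", length(toks), " tokens, exceeding max_len ",
         max_len, ": ", smiles, call. = FALSE)
  ids <- unname(vocab$index[toks])
  unknown <- is.na(ids)
  if (any(unknown)) {
    if (strict)
      stop("unknown token(s) ", paste(unique(toks[unknown]), collapse = " "),
           " in: ", smiles, call. = FALSE)
    warning("mapping ", sum(unknown), " unknown token(s) to pad in: ",
            smiles, call. = FALSE)
    ids[unknown] <- vocab$pad_index
  }
  c(as.integer(ids), rep(vocab$pad_index, max_len - length(ids)))
}

#' Decode a token-id sequence back to its token string
#'
#' Inverse of [encode_smiles_tokens()] up to the padding region: pad ids
#' are dropped and the remaining ids are mapped back to their tokens and
#' concatenated.
#'
#' @param ids Integer vector of token ids.
#' @param vocab A [build_token_vocabulary()] object.
#' @return A single string.
#' @export
decode_token_ids <- function(ids, vocab) {
  stopifnot(inherits(vocab, "token_vocabulary"))
  ids <- ids[ids != vocab$pad_index]
  paste(vocab$tokens[ids], collapse = "")
}

#' Serialize / restore a token vocabulary as JSON
#'
#' @param vocab A [build_token_vocabulary()] object.
#' @param path JSON file path.
#' @return `path` (write) or a `token_vocabulary` (read).
#' @export
write_token_vocabulary <- function(vocab, path) {
  jsonlite::write_json(as.list(vocab$index), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_token_vocabulary
#' @export
read_token_vocabulary <- function(path) {
  idx <- unlist(jsonlite::read_json(path))
  idx <- idx[order(idx)]
  structure(list(tokens = names(idx), index = stats::setNames(as.integer(idx), names(idx)),
                 pad_index = 0L),
            class = "token_vocabulary")
}
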