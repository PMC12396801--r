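#' Segment raw text into sentences
#'
#' Rule-based segmenter: splits after sentence-final punctuation
#' (\code{. ! ? ;}) followed by whitespace and an uppercase letter or
#' digit, and at newlines.  A guard list of common French clinical
#' abbreviations (\code{Dr.}, \code{M.}, \code{Mme.}, \code{env.}, ...)
#' prevents splitting after them.  Sentences shorter than
#' \code{min_chars} characters (whitespace included, threshold
#' inclusive: length >= min_chars is kept) are discarded as noise.
#'
#' @param raw_text a single character string.
#' @param min_chars minimum retained sentence length (default 3).
#' @param abbreviations abbreviation tokens (without the dot) after which a
#'   period never ends a sentence.
#' @return character vector of sentences, in original order.
#' @export
segment_text <- function(raw_text, min_chars = 3L,
                         abbreviations = c("Dr", "Prof", "M", "Mme", "Mlle",
                                           "St", "env", "etc", "cf", "resp")) {
  stopifnot(min_chars >= 1L)
  if (is.null(raw_text) || !nzchar(trimws(raw_text))) return(character(0))
  # newline is always a boundary
  chunks <- unlist(stringi::stri_split_regex(raw_text, "\\r?\\n"))
  pieces <- unlist(lapply(chunks, function(ch) {
    parts <- stringi::stri_split_regex(
      ch, "(?<=[.!?;])\\s+(?=[\\p{Lu}0-9])")[[1]]
    # re-merge splits caused by guarded abbreviations ("Dr. Martin")
    if (length(parts) > 1L) {
      merged <- parts[1]
      abbr_re <- paste0("\\b(", paste(abbreviations, collapse = "|"),
                        ")\\.$")
      for (p in parts[-1]) {
        last <- merged[length(merged)]
        if (stringi::stri_detect_regex(trimws(last), abbr_re)) {
          merged[length(merged)] <- paste(last, p)
        } else {
          merged <- c(merged, p)
        }
      }
      parts <- merged
    }
    parts
  }))
  pieces <- trimws(pieces)
  pieces[nchar(pieces) >= min_chars]
}

#' Segment a document into annotated sentences
#'
#' @param raw_text a single character string.
#' @param doc_id document id used to derive sentence ids.
#' @param min_chars minimum retained sentence length.
#' @return list of \code{\link{annotated_sentence}} objects.
#' @export
segment <- function(raw_text, doc_id = "doc", min_chars = 3L) {
  texts <- segment_text(raw_text, min_chars = min_chars)
  lapply(seq_along(texts), function(i) {
    annotated_sentence(text = texts[[i]],
                       sentence_id = paste0(doc_id, "#", i))
  })
}

#' Tokenize text
#'
#' Lowercased runs of Unicode letters or digits; diacritics preserved; no
#' stemming or stop-word removal.  Deterministic.
#'
#' @param text character vector.
#' @return for a single string, a character vector of tokens; for longer
#'   input, a list of token vectors.
#' @export
tokenize <- function(text) {
  toks <- stringi::stri_extract_all_regex(
    stringi::stri_trans_tolower(text), "[\\p{L}\\p{N}]+", omit_no_match = TRUE)
  if (length(text) == 1L) toks[[1]] else toks
}

#' Build a bag-of-words vocabulary from training sentences
#'
#' Contains exactly the tokens whose sentence frequency (number of distinct
#' sentences containing the token) is at least \code{min_df}; indices are
#' assigned in lexicographic token order, starting at 1.  Always build on
#' the training split only: encoding test sentences never alters the
#' vocabulary.
#'
#' @param texts character vector of training sentence texts (or a list of
#'   \code{bleedr_sentence} objects).
#' @param min_df document-frequency floor (default 1).
#' @return object of class \code{bleedr_vocabulary} with fields
#'   \code{tokens} (sorted) and \code{min_df}.
#' @export
build_vocabulary <- function(texts, min_df = 1L) {
  if (is.list(texts) && length(texts) > 0L &&
      inherits(texts[[1]], "bleedr_sentence")) {
    texts <- vapply(texts, function(s) s$text, character(1))
  }
  if (length(texts) == 0L) stop("empty training set", call. = FALSE)
  tok_lists <- stringi::stri_extract_all_regex(
    stringi::stri_trans_tolower(texts), "[\\p{L}\\p{N}]+",
    omit_no_match = TRUE)
  df <- table(unlist(lapply(tok_lists, unique)))
  keep <- sort(names(df)[df >= min_df], method = "radix")
  structure(list(tokens = keep, min_df = as.integer(min_df)),
            class = "bleedr_vocabulary")
}

#' @export
print.bleedr_vocabulary <- function(x, ...) {
  cat(sprintf("<bleedr_vocabulary: %d tokens, min_df=%d>\n",
              length(x$tokens), x$min_df))
  invisible(x)
}

#' Encode sentences as a sparse bag-of-words matrix
#'
#' Counts of in-vocabulary tokens; out-of-vocabulary tokens contribute
#' nothing.  Rows follow the input order, columns the vocabulary index
#' order.
#'
#' @param texts character vector of sentence texts.
#' @param vocab a \code{\link{build_vocabulary}} result.
#' @return a \code{dgCMatrix} of dimension \code{length(texts)} by
#'   \code{length(vocab$tokens)}.
#' @export
bow_encode <- function(texts, vocab) {
  stopifnot(inherits(vocab, "bleedr_vocabulary"))
  n <- length(texts)
  v <- length(vocab$tokens)
  if (n == 0L) return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                           x = numeric(0), dims = c(0L, v),
                                           dimnames = list(NULL, vocab$tokens)))
  tok_lists <- stringi::stri_extract_all_regex(
    stringi::stri_trans_tolower(texts), "[\\p{L}\\p{N}]+",
    omit_no_match = TRUE)
  lens <- lengths(tok_lists)
  rows <- rep.int(seq_len(n), lens)
  cols <- match(unlist(tok_lists), vocab$tokens)
  keep <- !is.na(cols)
  Matrix::sparseMatrix(i = rows[keep], j = cols[keep],
                       x = rep.int(1, sum(keep)), dims = c(n, v),
                       dimnames = list(NULL, vocab$tokens))
}

#' Encode a single sentence
#'
#' @param sentence an \code{\link{annotated_sentence}} or character string.
#' @param vocab a \code{\link{build_vocabulary}} result.
#' @return named numeric count vector of length \code{|vocabulary|}.
#' @export
encode <- function(sentence, vocab) {
  text <- if (inherits(sentence, "bleedr_sentence")) sentence$text
          else as.character(sentence)
  as.numeric(bow_encode(text, vocab)[1L, ])
}

#' Persist / load a vocabulary as two-column CSV
#'
#' @param vocab a \code{bleedr_vocabulary}.
#' @param path CSV path (columns \code{token,index}).
#' @return \code{write_vocabulary}: the path invisibly;
#'   \code{read_vocabulary}: the vocabulary.
#' @export
write_vocabulary <- function(vocab, path) {
  df <- data.frame(token = vocab$tokens, index = seq_along(vocab$tokens))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_vocabulary
#' @param min_df document-frequency floor recorded on the reloaded object.
#' @export
read_vocabulary <- function(path, min_df = 1L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  df <- df[order(df$index), , drop = FALSE]
  structure(list(tokens = as.character(df$token), min_df = as.integer(min_df)),
            class = "bleedr_vocabulary")
}
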