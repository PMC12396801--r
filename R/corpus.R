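#' Normalize ICD-10-GM codes
#'
#' Uppercases and strips dots and whitespace so that dialectal variants of
#' the same code (\code{"k92.2"}, \code{"K92.2 "}, \code{"K922"}) compare
#' equal.  Idempotent.
#'
#' @param codes character vector of raw code strings.
#' @return character vector of normalized codes.
#' @examples
#' normalize_icd(c("k92.2", "R57.1"))  # "K922" "R571"
#' @export
normalize_icd <- function(codes) {
  if (length(codes) == 0L) return(character(0))
  out <- toupper(gsub("[.[:space:]]", "", as.character(codes)))
  out[nzchar(out)]
}

#' Construct an annotated sentence
#'
#' @param text sentence text.
#' @param sentence_id opaque identifier; assigned on corpus construction
#'   when missing.
#' @param gold optional gold sentence label (one of
#'   \code{\link{SENTENCE_LABELS}}).
#' @return a list of class \code{bleedr_sentence}.
#' @export
annotated_sentence <- function(text, sentence_id = NULL, gold = NULL) {
  if (!is.null(gold)) assert_sentence_labels(gold, "sentence gold label")
  structure(list(sentence_id = sentence_id, text = as.character(text),
                 gold = gold),
            class = "bleedr_sentence")
}

#' Construct an annotated document
#'
#' A discharge summary: ordered sentences, the stay's ICD-10-GM codes
#' (normalized on construction) and optional gold labels at sentence and
#' document level.  Sentence ids are auto-assigned as
#' \code{doc_id#index} when absent so predictions can be joined back to
#' gold.
#'
#' @param doc_id unique document identifier.
#' @param sentences list of \code{\link{annotated_sentence}} objects.
#' @param raw_text optional unsegmented text.
#' @param icd_codes character vector of stay-level ICD codes.
#' @param gold_doc optional character vector of document labels, a subset
#'   of \code{\link{POSITIVE_LABELS}}; \code{character(0)} denotes an
#'   irrelevant document, \code{NULL} an unlabeled one.
#' @return a list of class \code{bleedr_document}.
#' @export
annotated_document <- function(doc_id, sentences = list(), raw_text = NULL,
                               icd_codes = character(0), gold_doc = NULL) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L, nzchar(doc_id))
  if (!is.null(gold_doc)) {
    gold_doc <- as.character(gold_doc)
    assert_document_labels(gold_doc)
  }
  sentences <- lapply(seq_along(sentences), function(i) {
    s <- sentences[[i]]
    if (!inherits(s, "bleedr_sentence")) s <- do.call(annotated_sentence, s)
    if (is.null(s$sentence_id)) s$sentence_id <- paste0(doc_id, "#", i)
    s
  })
  structure(list(doc_id = doc_id, raw_text = raw_text, sentences = sentences,
                 icd_codes = sort(unique(normalize_icd(icd_codes))),
                 gold_doc = gold_doc),
            class = "bleedr_document")
}

#' Construct a corpus of annotated documents
#'
#' @param documents list of \code{\link{annotated_document}} objects.
#' @param split_tag one of \code{"TRAIN"}, \code{"TEST"}, \code{"UNSPLIT"}.
#' @return a list of class \code{bleedr_corpus}.
#' @export
bleedr_corpus <- function(documents = list(),
                          split_tag = c("UNSPLIT", "TRAIN", "TEST")) {
  split_tag <- match.arg(split_tag)
  ids <- vapply(documents, function(d) d$doc_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate doc_id in corpus: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(list(documents = documents, split_tag = split_tag),
            class = "bleedr_corpus")
}

#' @export
length.bleedr_corpus <- function(x) length(x$documents)

#' @export
print.bleedr_corpus <- function(x, ...) {
  ns <- sum(vapply(x$documents, function(d) length(d$sentences), integer(1)))
  cat(sprintf("<bleedr_corpus: %d documents, %d sentences, split=%s>\n",
              length(x$documents), ns, x$split_tag))
  invisible(x)
}

#' Flatten a corpus to a sentence table
#'
#' @param corpus a \code{bleedr_corpus}.
#' @return data.frame with columns \code{doc_id}, \code{sentence_id},
#'   \code{text} and \code{gold} (\code{NA} when unlabeled).
#' @export
corpus_sentences <- function(corpus) {
  stopifnot(inherits(corpus, "bleedr_corpus"))
  per_doc <- lapply(corpus$documents, function(d) {
    n <- length(d$sentences)
    if (n == 0L) return(NULL)
    data.frame(
      doc_id = rep(d$doc_id, n),
      sentence_id = vapply(d$sentences, function(s) s$sentence_id, character(1)),
      text = vapply(d$sentences, function(s) s$text, character(1)),
      gold = vapply(d$sentences, function(s)
        if (is.null(s$gold)) NA_character_ else s$gold, character(1)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_doc)
  if (is.null(out)) {
    out <- data.frame(doc_id = character(0), sentence_id = character(0),
                      text = character(0), gold = character(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

doc_from_json <- function(obj, line_no, expect_gold) {
  if (is.null(obj$doc_id)) {
    stop(sprintf("line %d: missing doc_id", line_no), call. = FALSE)
  }
  sentences <- list()
  if (!is.null(obj$sentences)) {
    sentences <- lapply(obj$sentences, function(s) {
      annotated_sentence(text = s$text,
                         sentence_id = s$sentence_id,
                         gold = s$gold)
    })
  } else if (is.null(obj$raw_text)) {
    stop(sprintf("line %d: document %s has neither raw_text nor sentences",
                 line_no, obj$doc_id), call. = FALSE)
  }
  gold_doc <- if (is.null(obj$gold_doc)) NULL else
    as.character(unlist(obj$gold_doc))
  doc <- annotated_document(
    doc_id = as.character(obj$doc_id),
    sentences = sentences,
    raw_text = if (is.null(obj$raw_text)) NULL else as.character(obj$raw_text),
    icd_codes = as.character(unlist(obj$icd_codes)),
    gold_doc = gold_doc)
  if (expect_gold) {
    has_sent_gold <- all(vapply(doc$sentences,
                                function(s) !is.null(s$gold), logical(1)))
    if (length(doc$sentences) > 0L && !has_sent_gold) {
      stop(sprintf("line %d: document %s lacks gold sentence labels",
                   line_no, doc$doc_id), call. = FALSE)
    }
    if (is.null(doc$gold_doc) && length(doc$sentences) == 0L) {
      stop(sprintf("line %d: document %s lacks gold labels",
                   line_no, doc$doc_id), call. = FALSE)
    }
  }
  doc
}

#' Read a corpus from JSONL
#'
#' One JSON object per line with keys \code{doc_id}, \code{raw_text} or
#' \code{sentences} (list of \code{{sentence_id, text, gold}}),
#' \code{icd_codes} and \code{gold_doc}.  ICD codes are normalized
#' (uppercase, dot and whitespace stripped) on load.  Files ending in
#' \code{.gz} are decompressed transparently.
#'
#' @param path path to a JSONL (optionally gzipped) corpus file.
#' @param expect_gold require gold labels on every document.
#' @param split_tag split tag to attach to the corpus.
#' @return a \code{\link{bleedr_corpus}}.
#' @export
read_corpus <- function(path, expect_gold = FALSE, split_tag = "UNSPLIT") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt", encoding = "UTF-8")
         else file(path, "rt", encoding = "UTF-8")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  docs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
      error = function(e) stop(sprintf("parse error at line %d: %s",
                                       i, conditionMessage(e)), call. = FALSE))
    docs[[i]] <- doc_from_json(obj, i, expect_gold)
  }
  corpus <- bleedr_corpus(docs, split_tag = split_tag)
  message(sprintf("read %d documents (%d sentences) from %s",
                  length(docs),
                  nrow(corpus_sentences(corpus)), path))
  corpus
}

doc_to_json <- function(doc) {
  obj <- list(doc_id = doc$doc_id)
  if (!is.null(doc$raw_text)) obj$raw_text <- doc$raw_text
  if (length(doc$sentences) > 0L) {
    obj$sentences <- lapply(doc$sentences, function(s) {
      o <- list(sentence_id = s$sentence_id, text = s$text)
      if (!is.null(s$gold)) o$gold <- s$gold
      o
    })
  }
  if (length(doc$icd_codes) > 0L) obj$icd_codes <- as.list(doc$icd_codes)
  if (!is.null(doc$gold_doc)) obj$gold_doc <- as.list(doc$gold_doc)
  obj
}

#' Write a corpus to JSONL
#'
#' Inverse of \code{\link{read_corpus}}: \code{read_corpus(write_corpus(c))}
#' reproduces \code{c} field for field (codes are already normalized).
#' Optional fields (raw text, gold labels) are omitted from lines where they
#' are absent.
#'
#' @param corpus a \code{\link{bleedr_corpus}}.
#' @param path output path; \code{.gz} suffix triggers gzip compression.
#' @return the path, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "bleedr_corpus"))
  lines <- vapply(corpus$documents, function(d) {
    as.character(jsonlite::toJSON(doc_to_json(d), auto_unbox = TRUE,
                                  digits = NA))
  }, character(1))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Split a corpus into train and test sets
#'
#' Document-level (never sentence-level) random partition, deterministic for
#' a fixed seed.  The training fraction is honored to the nearest document.
#'
#' @param corpus a \code{\link{bleedr_corpus}} with at least two documents.
#' @param train_fraction proportion of documents assigned to training,
#'   strictly between 0 and 1 (default 0.7).
#' @param seed integer seed governing the random assignment.
#' @return list with elements \code{train} and \code{test}, both
#'   \code{bleedr_corpus} objects tagged accordingly.
#' @export
split_corpus <- function(corpus, train_fraction = 0.7, seed) {
  stopifnot(inherits(corpus, "bleedr_corpus"))
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  n <- length(corpus$documents)
  if (n < 2L) stop("need at least 2 documents to split", call. = FALSE)
  n_train <- round(n * train_fraction)
  n_train <- max(1L, min(n - 1L, n_train))
  idx <- with_local_seed(seed, sample.int(n, n_train))
  list(
    train = bleedr_corpus(corpus$documents[sort(idx)], split_tag = "TRAIN"),
    test = bleedr_corpus(corpus$documents[sort(setdiff(seq_len(n), idx))],
                         split_tag = "TEST"))
}

# Run code under a temporary RNG state so package functions never disturb
# the caller's random stream.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
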