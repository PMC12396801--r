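#' Sentence and document label sets
#'
#' The annotation scheme distinguishes four mutually exclusive sentence
#' labels: \code{IRRELEVANT} (no bleeding information), \code{ANTECEDENT}
#' (bleeding in the patient's history, before admission), \code{CLIN_SIG}
#' (clinically significant bleeding not meeting ISTH major-bleeding
#' criteria) and \code{SEVERE} (severe bleeding per ISTH: fatal bleeding,
#' bleeding at a critical site, haemoglobin drop of 20 g/L or more, or
#' transfusion of two or more units).  At the document level a discharge
#' summary carries the set of positive labels present in its sentences;
#' the empty set denotes an irrelevant document.
#'
#' @format \code{SENTENCE_LABELS} is a character vector of the four
#'   sentence labels; \code{POSITIVE_LABELS} the three positive
#'   (document-assignable) labels.
#' @export
SENTENCE_LABELS <- c("IRRELEVANT", "ANTECEDENT", "CLIN_SIG", "SEVERE")

#' @rdname SENTENCE_LABELS
#' @export
POSITIVE_LABELS <- c("ANTECEDENT", "CLIN_SIG", "SEVERE")

assert_sentence_labels <- function(x, what = "labels") {
  bad <- setdiff(unique(x), SENTENCE_LABELS)
  if (length(bad) > 0L) {
    stop(sprintf("invalid %s: %s", what, paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

assert_document_labels <- function(x) {
  bad <- setdiff(unique(x), POSITIVE_LABELS)
  if (length(bad) > 0L) {
    stop(sprintf("invalid document labels: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(x)) stop("duplicate document labels", call. = FALSE)
  invisible(x)
}
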