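#' Reference evaluation tables from the original study corpus
#'
#' Per-class document-level metric values reported for the NLP cascade and
#' the ICD rule arm on the confidential study corpus, and the class
#' distribution of that corpus (counts and percentages per label, at
#' sentence and document level, by split).  Bundled as plain inputs so the
#' package's averaging and bookkeeping arithmetic can be checked against
#' the published columns; they are not recomputable from data shipped
#' here.
#'
#' @param arm \code{"nlp"} or \code{"rule"}.
#' @return \code{reference_metrics}: data.frame with one row per metric
#'   and one column per class plus the reported macro (and micro for the
#'   NLP arm).  \code{reference_class_distribution}: data.frame with
#'   columns \code{label}, \code{level}, \code{split}, \code{count},
#'   \code{pct}.
#' @export
reference_metrics <- function(arm = c("nlp", "rule")) {
  arm <- match.arg(arm)
  utils::read.csv(system.file("extdata",
                              paste0("reference_metrics_", arm, ".csv"),
                              package = "bleedr", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' @rdname reference_metrics
#' @export
reference_class_distribution <- function() {
  utils::read.csv(system.file("extdata", "reference_class_distribution.csv",
                              package = "bleedr", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
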