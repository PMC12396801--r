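#' Load an ICD-10 bleeding code table
#'
#' Reads a CSV with columns \code{code}, \code{group} (one of
#' \code{clin_sig}, \code{severe}) and \code{description}, normalizes the
#' codes and validates that the two severity groups are mutually
#' exclusive, following the ISTH-based partition into clinically
#' significant and severe bleeding.
#'
#' The bundled default table (see \code{\link{default_code_table}})
#' contains the handful of codes named in the original study report
#' (K92.2, R31, K26.4 as clinically significant; R57.1, I85.3 as severe)
#' extended with standard ICD-10 bleeding codes grouped by ISTH site
#' logic (intracranial and intraspinal sites severe).  It is a partial
#' stand-in for a complete institutional list, which users can supply via
#' this loader.
#'
#' @param path CSV path.
#' @return object of class \code{bleedr_code_table} with fields
#'   \code{clin_sig_codes}, \code{severe_codes}, \code{descriptions}.
#' @export
load_code_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("code", "group", "description")
  if (!all(need %in% names(df))) {
    stop("code table must have columns code, group, description",
         call. = FALSE)
  }
  bad <- setdiff(unique(df$group), c("clin_sig", "severe"))
  if (length(bad) > 0L) {
    stop("unknown severity group: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  df$code <- normalize_icd(df$code)
  clin <- unique(df$code[df$group == "clin_sig"])
  sev <- unique(df$code[df$group == "severe"])
  both <- intersect(clin, sev)
  if (length(both) > 0L) {
    stop("codes listed in both severity groups: ",
         paste(both, collapse = ", "), call. = FALSE)
  }
  descr <- stats::setNames(df$description, df$code)
  structure(list(clin_sig_codes = sort(clin), severe_codes = sort(sev),
                 descriptions = descr),
            class = "bleedr_code_table")
}

#' @rdname load_code_table
#' @export
default_code_table <- function() {
  load_code_table(system.file("extdata", "icd_bleeding_codes.csv",
                              package = "bleedr", mustWork = TRUE))
}

#' @export
print.bleedr_code_table <- function(x, ...) {
  cat(sprintf("<bleedr_code_table: %d clin_sig, %d severe codes>\n",
              length(x$clin_sig_codes), length(x$severe_codes)))
  invisible(x)
}

match_codes <- function(stay_codes, table_codes, match_mode) {
  if (length(stay_codes) == 0L || length(table_codes) == 0L) {
    return(character(0))
  }
  if (match_mode == "exact") {
    intersect(table_codes, stay_codes)
  } else {
    fired <- vapply(table_codes, function(tc) {
      any(startsWith(stay_codes, tc))
    }, logical(1))
    table_codes[fired]
  }
}

#' Classify a hospital stay from its ICD codes
#'
#' A stay is labeled CLIN_SIG when any of its codes matches the
#' clinically-significant group, SEVERE likewise; both labels can fire on
#' one stay, and an empty verdict means no bleeding detected.  ANTECEDENT
#' is structurally never emitted: ICD-10 has no codes for a history of
#' bleeding.  In \code{prefix} mode (the default) a stay code matches a
#' table entry when it starts with the normalized entry, so a
#' category-level entry such as R31 captures its subcodes.
#'
#' @param icd_codes character vector of stay codes (normalized internally).
#' @param table a \code{\link{load_code_table}} result.
#' @param match_mode \code{"prefix"} (default) or \code{"exact"}.
#' @return object of class \code{bleedr_verdict}: \code{labels}
#'   (character subset of CLIN_SIG/SEVERE) and \code{matched_codes}
#'   (named list of fired table codes per label).
#' @export
classify_stay <- function(icd_codes, table = default_code_table(),
                          match_mode = c("prefix", "exact")) {
  match_mode <- match.arg(match_mode)
  codes <- normalize_icd(icd_codes)
  matched <- list(
    CLIN_SIG = match_codes(codes, table$clin_sig_codes, match_mode),
    SEVERE = match_codes(codes, table$severe_codes, match_mode))
  labels <- names(matched)[lengths(matched) > 0L]
  structure(list(labels = labels,
                 matched_codes = matched[lengths(matched) > 0L]),
            class = "bleedr_verdict")
}

#' @export
print.bleedr_verdict <- function(x, ...) {
  if (length(x$labels) == 0L) {
    cat("<verdict: no bleeding detected>\n")
  } else {
    cat("<verdict:", paste(x$labels, collapse = "+"), ">\n")
  }
  invisible(x)
}

#' Rule-arm verdicts for every document in a corpus
#'
#' @param corpus a \code{bleedr_corpus} with stay ICD codes.
#' @param table code table.
#' @param match_mode see \code{\link{classify_stay}}.
#' @return list of character label sets, one per document, in corpus
#'   order.
#' @export
rule_verdicts <- function(corpus, table = default_code_table(),
                          match_mode = "prefix") {
  lapply(corpus$documents, function(d) {
    classify_stay(d$icd_codes, table, match_mode)$labels
  })
}

#' Evaluate the rule-based classifier against gold document labels
#'
#' Document-level per-class metrics for IRRELEVANT, CLIN_SIG and SEVERE;
#' ANTECEDENT is reported as excluded (the rule arm cannot emit it).  No
#' sentence-level metrics exist for this arm, since verdicts attach to
#' whole stays.
#'
#' @param corpus corpus with gold document labels and stay codes.
#' @param table code table.
#' @param match_mode see \code{\link{classify_stay}}.
#' @return a document-level \code{\link{metrics_report}}.
#' @export
evaluate_rule_classifier <- function(corpus, table = default_code_table(),
                                     match_mode = "prefix") {
  gold <- lapply(corpus$documents, function(d) d$gold_doc)
  if (any(vapply(gold, is.null, logical(1)))) {
    stop("corpus lacks gold document labels", call. = FALSE)
  }
  pred <- rule_verdicts(corpus, table, match_mode)
  # strip ANTECEDENT from gold sets: the rule arm is scored on the label
  # space it can express
  gold <- lapply(gold, function(s) setdiff(s, "ANTECEDENT"))
  metrics_report(pred, gold, classes = SENTENCE_LABELS,
                 granularity = "DOCUMENT",
                 excluded_classes = "ANTECEDENT")
}
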