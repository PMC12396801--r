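#' Round half away from zero
#'
#' Reporting helper matching conventional table rounding (R's
#' \code{round()} rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 2L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Class-membership indicator matrix: units x classes.  `labels` is either a
# character vector (one mutually exclusive label per unit, sentence
# granularity) or a list of character sets (document granularity, where the
# empty set means the document is IRRELEVANT).
label_membership <- function(labels, classes) {
  if (is.list(labels)) {
    m <- vapply(classes, function(cl) {
      if (cl == "IRRELEVANT") {
        vapply(labels, function(s) length(s) == 0L, logical(1))
      } else {
        vapply(labels, function(s) cl %in% s, logical(1))
      }
    }, logical(length(labels)))
  } else {
    m <- vapply(classes, function(cl) labels == cl,
                logical(length(labels)))
  }
  matrix(m, nrow = if (is.list(labels)) length(labels) else length(labels),
         dimnames = list(NULL, classes))
}

#' Per-class one-vs-rest confusion counts
#'
#' At sentence granularity \code{pred} and \code{gold} are character
#' vectors of mutually exclusive labels; at document granularity they are
#' lists of label sets (the empty set denoting an irrelevant document).
#' Counts are one-vs-rest per class, so TP+FP+FN+TN equals the number of
#' evaluation units for every class.
#'
#' @param pred predicted labels.
#' @param gold gold labels, aligned with \code{pred}.
#' @param classes character vector of classes to count.
#' @return data.frame with columns \code{class, tp, fp, fn, tn}.
#' @export
confusion <- function(pred, gold, classes = SENTENCE_LABELS) {
  if (length(pred) != length(gold)) {
    stop("pred and gold have different lengths", call. = FALSE)
  }
  pm <- label_membership(pred, classes)
  gm <- label_membership(gold, classes)
  counts <- lapply(classes, function(cl) {
    p <- pm[, cl]; g <- gm[, cl]
    data.frame(class = cl,
               tp = sum(p & g), fp = sum(p & !g),
               fn = sum(!p & g), tn = sum(!p & !g),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, counts)
}

safe_ratio <- function(num, den) {
  flagged <- den == 0
  val <- ifelse(flagged, 0, num / pmax(den, 1e-300))
  list(value = val, flagged = flagged)
}

#' Metrics from confusion counts
#'
#' precision = TP/(TP+FP), recall = TP/(TP+FN), specificity = TN/(TN+FP),
#' accuracy = (TP+TN)/total, F1 = 2PR/(P+R).  Undefined 0/0 ratios are
#' reported as 0 with the corresponding \code{*_flagged} column set, so
#' arithmetic stays defined at near-zero counts.
#'
#' @param counts a data.frame from \code{\link{confusion}} (columns
#'   \code{class, tp, fp, fn, tn}).
#' @return data.frame of per-class metrics with flag columns.
#' @export
metrics_from_confusion <- function(counts) {
  stopifnot(all(c("tp", "fp", "fn", "tn") %in% names(counts)))
  total <- counts$tp + counts$fp + counts$fn + counts$tn
  p <- safe_ratio(counts$tp, counts$tp + counts$fp)
  r <- safe_ratio(counts$tp, counts$tp + counts$fn)
  s <- safe_ratio(counts$tn, counts$tn + counts$fp)
  f <- safe_ratio(2 * p$value * r$value, p$value + r$value)
  data.frame(
    class = if (!is.null(counts$class)) counts$class else NA_character_,
    accuracy = (counts$tp + counts$tn) / total,
    precision = p$value, recall = r$value, specificity = s$value,
    f1 = f$value,
    precision_flagged = p$flagged, recall_flagged = r$flagged,
    specificity_flagged = s$flagged, f1_flagged = f$flagged,
    stringsAsFactors = FALSE)
}

#' Unweighted macro average
#'
#' Arithmetic mean of per-class metric values with equal class weight.
#'
#' @param per_class_values nonempty numeric vector.
#' @return the mean, unrounded (use \code{\link{round_half_away}} for
#'   display at table precision).
#' @export
macro_average <- function(per_class_values) {
  if (length(per_class_values) == 0L) {
    stop("macro_average of empty list", call. = FALSE)
  }
  mean(as.numeric(per_class_values))
}

#' Full metrics report at one granularity
#'
#' Per-class one-vs-rest metrics, their unweighted macro average over the
#' included classes, and micro (pooled-count) metrics computed from the
#' summed confusion matrices.
#'
#' @param pred predicted labels (vector or list of sets, see
#'   \code{\link{confusion}}).
#' @param gold gold labels.
#' @param classes classes to include.
#' @param granularity \code{"SENTENCE"} or \code{"DOCUMENT"}.
#' @param excluded_classes classes structurally unavailable to the
#'   classifier (reported as excluded, e.g. ANTECEDENT for the ICD rule
#'   arm).
#' @return object of class \code{bleedr_metrics} with fields
#'   \code{granularity}, \code{per_class}, \code{macro}, \code{micro},
#'   \code{counts}, \code{excluded_classes}.
#' @export
metrics_report <- function(pred, gold, classes = SENTENCE_LABELS,
                           granularity = c("SENTENCE", "DOCUMENT"),
                           excluded_classes = character(0)) {
  granularity <- match.arg(granularity)
  classes <- setdiff(classes, excluded_classes)
  counts <- confusion(pred, gold, classes)
  per_class <- metrics_from_confusion(counts)
  metric_cols <- c("accuracy", "precision", "recall", "specificity", "f1")
  macro <- vapply(metric_cols, function(m) macro_average(per_class[[m]]),
                  numeric(1))
  pooled <- data.frame(class = "pooled",
                       tp = sum(counts$tp), fp = sum(counts$fp),
                       fn = sum(counts$fn), tn = sum(counts$tn))
  micro <- metrics_from_confusion(pooled)
  structure(list(granularity = granularity, per_class = per_class,
                 macro = macro,
                 micro = unlist(micro[1, metric_cols]),
                 counts = counts,
                 excluded_classes = excluded_classes),
            class = "bleedr_metrics")
}

#' @export
print.bleedr_metrics <- function(x, ...) {
  cat(sprintf("Metrics (%s level)\n", tolower(x$granularity)))
  tab <- x$per_class
  tab[2:6] <- lapply(tab[2:6], round_half_away)
  print(tab[, 1:6], row.names = FALSE)
  cat("macro:", paste(sprintf("%s=%.2f", names(x$macro),
                              round_half_away(x$macro)), collapse = " "), "\n")
  cat("micro:", paste(sprintf("%s=%.2f", names(x$micro),
                              round_half_away(x$micro)), collapse = " "), "\n")
  if (length(x$excluded_classes)) {
    cat("excluded:", paste(x$excluded_classes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' ROC curve and AUC for a binary score
#'
#' Threshold sweep over the unique scores (each threshold classifies
#' units with score >= threshold as positive), yielding a monotone curve
#' from (0,0) to (1,1); AUC by the trapezoidal rule, which equals the
#' Mann-Whitney pairwise concordance probability with ties counted one
#' half.
#'
#' @param scores numeric decision scores (larger = more positive).
#' @param binary_gold 0/1 (or logical) gold labels; both classes must be
#'   present.
#' @param stage_id optional identifier of the cascade decision being
#'   scored.
#' @return object of class \code{bleedr_roc} with fields \code{points}
#'   (data.frame threshold, fpr, tpr), \code{auc}, \code{stage_id}.
#' @export
roc_and_auc <- function(scores, binary_gold, stage_id = NULL) {
  gold <- as.integer(binary_gold)
  if (length(scores) != length(gold)) {
    stop("scores and gold have different lengths", call. = FALSE)
  }
  if (length(unique(gold)) < 2L) {
    stop("both classes must be present in binary_gold", call. = FALSE)
  }
  n_pos <- sum(gold == 1L)
  n_neg <- sum(gold == 0L)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & gold == 1L) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & gold == 0L) / n_neg,
                numeric(1))
  points <- data.frame(threshold = c(Inf, thr, -Inf),
                       fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) +
                                 utils::tail(points$tpr, -1)) / 2)
  structure(list(points = points, auc = auc, stage_id = stage_id),
            class = "bleedr_roc")
}

#' @export
print.bleedr_roc <- function(x, ...) {
  cat(sprintf("<ROC%s: AUC = %.4f, %d points>\n",
              if (is.null(x$stage_id)) "" else paste0(" ", x$stage_id),
              x$auc, nrow(x$points)))
  invisible(x)
}

#' Cohen's kappa between two labelings
#'
#' Chance-corrected agreement kappa = (po - pe)/(1 - pe), with the expected
#' agreement pe from the product of the two raters' marginals.  Returns 1
#' when pe = 1 and the labelings are identical.
#'
#' @param labels_a,labels_b aligned label vectors over the same alphabet.
#' @return kappa in [-1, 1].
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("labelings have different lengths", call. = FALSE)
  }
  lev <- sort(unique(c(as.character(labels_a), as.character(labels_b))))
  a <- factor(as.character(labels_a), levels = lev)
  b <- factor(as.character(labels_b), levels = lev)
  n <- length(a)
  po <- mean(a == b)
  pe <- sum((table(a) / n) * (table(b) / n))
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    return(if (po == 1) 1 else 0)
  }
  (po - pe) / (1 - pe)
}

#' Fleiss' kappa for multiple raters
#'
#' Standard formulation for n units each rated by the same number of
#' raters into k categories.
#'
#' @param ratings either an n x r matrix of labels (one column per rater)
#'   or an n x k matrix of category counts per unit.
#' @param is_counts set to \code{TRUE} when \code{ratings} already holds
#'   category counts.
#' @return kappa; 1.0 for unanimous ratings when at least two categories
#'   are realized across units.
#' @export
fleiss_kappa <- function(ratings, is_counts = FALSE) {
  if (is_counts) {
    counts <- as.matrix(ratings)
  } else {
    ratings <- as.matrix(ratings)
    if (ncol(ratings) < 2L) stop("need at least 2 raters", call. = FALSE)
    if (anyNA(ratings)) stop("incomplete rating matrix", call. = FALSE)
    lev <- sort(unique(as.character(ratings)))
    counts <- t(apply(ratings, 1, function(row) {
      tabulate(factor(as.character(row), levels = lev), nbins = length(lev))
    }))
  }
  r <- rowSums(counts)
  if (length(unique(r)) != 1L) {
    stop("all units must have the same number of ratings", call. = FALSE)
  }
  r <- r[1]
  if (r < 2L) stop("need at least 2 raters", call. = FALSE)
  n <- nrow(counts)
  p_j <- colSums(counts) / (n * r)
  P_i <- (rowSums(counts^2) - r) / (r * (r - 1))
  Pbar <- mean(P_i)
  Pe <- sum(p_j^2)
  if (abs(1 - Pe) < .Machine$double.eps^0.5) {
    return(if (Pbar == 1) 1 else 0)
  }
  (Pbar - Pe) / (1 - Pe)
}

#' Compare the NLP and rule-based classifiers on one corpus
#'
#' Produces a side-by-side document-level per-class metric table, paired
#' Cohen kappa between the two methods' CLIN_SIG and SEVERE verdicts, and
#' per-class confusion counts for both arms.
#'
#' @param report_nlp document-level \code{\link{metrics_report}} of the
#'   cascade.
#' @param report_rule document-level \code{\link{metrics_report}} of the
#'   ICD rule arm.
#' @param verdicts list with aligned elements \code{doc_id}, \code{nlp}
#'   and \code{rule}, the latter two lists of document label sets.
#' @return object of class \code{bleedr_comparison}: \code{table}
#'   (long-format per-class metrics per method), \code{kappa} (named
#'   vector for CLIN_SIG and SEVERE), \code{confusions}.
#' @export
compare_classifiers <- function(report_nlp, report_rule, verdicts) {
  stopifnot(inherits(report_nlp, "bleedr_metrics"),
            inherits(report_rule, "bleedr_metrics"))
  if (report_nlp$granularity != "DOCUMENT" ||
      report_rule$granularity != "DOCUMENT") {
    stop("comparison requires document-level reports", call. = FALSE)
  }
  if (length(verdicts$nlp) != length(verdicts$rule)) {
    stop("verdict lists are not aligned", call. = FALSE)
  }
  kappa <- vapply(c(CLIN_SIG = "CLIN_SIG", SEVERE = "SEVERE"), function(cl) {
    a <- vapply(verdicts$nlp, function(s) cl %in% s, logical(1))
    b <- vapply(verdicts$rule, function(s) cl %in% s, logical(1))
    cohen_kappa(a, b)
  }, numeric(1))
  tab <- rbind(
    cbind(method = "nlp", report_nlp$per_class[, 1:6]),
    cbind(method = "rule", report_rule$per_class[, 1:6]))
  structure(list(table = tab, kappa = kappa,
                 confusions = list(nlp = report_nlp$counts,
                                   rule = report_rule$counts),
                 excluded = list(nlp = report_nlp$excluded_classes,
                                 rule = report_rule$excluded_classes)),
            class = "bleedr_comparison")
}

#' @export
print.bleedr_comparison <- function(x, ...) {
  tab <- x$table
  tab[3:7] <- lapply(tab[3:7], round_half_away)
  print(tab, row.names = FALSE)
  cat("method agreement (Cohen kappa):",
      paste(sprintf("%s=%.2f", names(x$kappa),
                    round_half_away(x$kappa)), collapse = " "), "\n")
  invisible(x)
}

#' Write a metrics report to CSV
#'
#' Per-class rows plus macro and micro rows, raw (unrounded) values.
#'
#' @param report a \code{bleedr_metrics}.
#' @param path output CSV path.
#' @return the path invisibly.
#' @export
write_metrics_csv <- function(report, path) {
  metric_cols <- c("accuracy", "precision", "recall", "specificity", "f1")
  per <- report$per_class[, c("class", metric_cols)]
  extra <- data.frame(class = c("macro", "micro"),
                      rbind(report$macro, report$micro))
  names(extra) <- c("class", metric_cols)
  utils::write.csv(rbind(per, extra), path, row.names = FALSE)
  invisible(path)
}
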