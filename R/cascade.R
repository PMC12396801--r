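#' Hyperparameter settings for the cascade
#'
#' Each stage's regularization is selected by grid search under stratified
#' k-fold cross-validation, maximizing the mean CV F1 of the stage's
#' positive/minority class.  The grid value is interpreted as the inverse
#' regularization strength C: for the logistic stages it maps to the ridge
#' penalty lambda = 1/(n C); for the SVM stage it is the soft-margin cost.
#'
#' @param grid candidate C values, all positive (default
#'   \code{c(0.01, 0.1, 1, 10, 100)}).
#' @param cv_folds number of cross-validation folds (>= 2, default 5).
#' @param class_weighting apply balanced inverse-frequency class weights in
#'   every stage (default TRUE); switchable off for ablation.
#' @param min_df vocabulary document-frequency floor.
#' @return list of class \code{bleedr_hyperparams}.
#' @export
cascade_hyperparams <- function(grid = c(0.01, 0.1, 1, 10, 100),
                                cv_folds = 5L, class_weighting = TRUE,
                                min_df = 1L) {
  if (any(grid <= 0)) stop("grid candidates must be > 0", call. = FALSE)
  if (cv_folds < 2L) stop("cv_folds must be >= 2", call. = FALSE)
  structure(list(grid = as.numeric(grid), cv_folds = as.integer(cv_folds),
                 class_weighting = isTRUE(class_weighting),
                 min_df = as.integer(min_df)),
            class = "bleedr_hyperparams")
}

#' Balanced inverse-frequency class weights
#'
#' weight(c) = N / (k * count(c)) with N the total sample count and k the
#' number of classes, so rarer classes receive heavier weight and balanced
#' classes receive unit weight.  Used to counter the extreme sentence-level
#' class imbalance (about 97\% irrelevant sentences).
#'
#' @param label_counts named vector of per-class counts, all > 0.
#' @return named numeric vector of weights.
#' @examples
#' compute_class_weights(c(maj = 900, min = 100))  # 0.556, 5
#' @export
compute_class_weights <- function(label_counts) {
  label_counts <- unlist(label_counts)
  if (any(label_counts <= 0)) {
    stop("every class must have a positive count", call. = FALSE)
  }
  n <- sum(label_counts)
  k <- length(label_counts)
  n / (k * label_counts)
}

# Stratified fold assignment: shuffle within each stratum, deal folds
# round-robin.  Deterministic under with_local_seed at the call site.
stratified_folds <- function(strata, k) {
  folds <- integer(length(strata))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

f1_binary <- function(pred, gold) {
  tp <- sum(pred & gold); fp <- sum(pred & !gold); fn <- sum(!pred & gold)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

# Ridge logistic regression at a grid of C values; returns coefficient
# matrix (V+1 rows: intercept first) per lambda.
fit_logistic_path <- function(x, y, c_grid, weights) {
  n <- nrow(x)
  lams <- 1 / (n * c_grid)
  ord <- order(lams, decreasing = TRUE)
  fit <- glmnet::glmnet(x, factor(y, levels = c(FALSE, TRUE)),
                        family = "binomial", alpha = 0,
                        lambda = lams[ord], weights = weights,
                        standardize = FALSE, thresh = 1e-9, maxit = 1e6)
  coefs <- lapply(seq_along(c_grid), function(i) {
    as.numeric(glmnet::coef.glmnet(fit, s = lams[i]))
  })
  coefs  # each: c(intercept, per-token coefficients)
}

logistic_scores <- function(x, coef_vec) {
  as.numeric(x %*% coef_vec[-1]) + coef_vec[1]
}

obs_weights <- function(y, class_weighting) {
  if (!class_weighting) return(rep(1, length(y)))
  cw <- compute_class_weights(table(y))
  as.numeric(cw[as.character(y)])
}

# Grid-searched binary ridge logistic stage.  Returns the fitted
# coefficient vector at the selected C, the CV table, and out-of-fold
# binary predictions at the selected C (used to build the stage-2 pool).
train_logistic_stage <- function(x, y, strata, hp, stage_name) {
  if (length(unique(y)) < 2L) {
    stop(stage_name, ": single-class training pool", call. = FALSE)
  }
  k <- hp$cv_folds
  folds <- stratified_folds(strata, k)
  cv_f1 <- matrix(0, nrow = k, ncol = length(hp$grid))
  oof_scores <- matrix(NA_real_, nrow = length(y), ncol = length(hp$grid))
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    if (length(unique(y[tr])) < 2L) next
    coefs <- fit_logistic_path(x[tr, , drop = FALSE], y[tr], hp$grid,
                               obs_weights(y[tr], hp$class_weighting))
    for (i in seq_along(hp$grid)) {
      s <- logistic_scores(x[te, , drop = FALSE], coefs[[i]])
      oof_scores[te, i] <- s
      cv_f1[f, i] <- f1_binary(s > 0, y[te])
    }
  }
  mean_f1 <- colMeans(cv_f1)
  best <- which.max(mean_f1)
  final <- fit_logistic_path(x, y, hp$grid[best],
                             obs_weights(y, hp$class_weighting))[[1]]
  list(coef = final, C = hp$grid[best],
       cv = data.frame(candidate = hp$grid, mean_cv_f1 = mean_f1,
                       selected = seq_along(hp$grid) == best),
       oof_positive = oof_scores[, best] > 0)
}

# Linear SVM with class weights; weights and intercept extracted so the
# decision score is the plain linear form x.w + b, > 0 for the positive
# class.
fit_linear_svm <- function(x, y, cost, class_weighting) {
  yf <- factor(y, levels = c(FALSE, TRUE))
  cw <- if (class_weighting) compute_class_weights(table(yf)) else
    c("FALSE" = 1, "TRUE" = 1)
  m <- e1071::svm(x = as.matrix(x), y = yf, kernel = "linear", cost = cost,
                  class.weights = cw, scale = FALSE)
  w <- as.numeric(Matrix::crossprod(m$SV, m$coefs))
  b <- -m$rho
  # libsvm's positive decision side is its first internal label; align so
  # that score > 0 means y == TRUE
  first_level <- m$levels[m$labels[1]]
  if (first_level != "TRUE") {
    w <- -w; b <- -b
  }
  list(w = w, b = b)
}

svm_scores <- function(x, fit) {
  as.numeric(x %*% fit$w) + fit$b
}

STAGE2_CLASSES <- c("IRRELEVANT", "ANTECEDENT", "BLEEDING")

# One-vs-rest multi-class linear SVM stage with grid search; model
# selection metric is the mean CV F1 of the pool's minority class.
train_svm_stage <- function(x, labels, hp, stage_name) {
  labels <- factor(labels, levels = STAGE2_CLASSES)
  present <- levels(droplevels(labels))
  if (length(present) < 2L) {
    stop(stage_name, ": single-class training pool", call. = FALSE)
  }
  minority <- names(which.min(table(droplevels(labels))))
  k <- hp$cv_folds
  folds <- stratified_folds(as.character(labels), k)
  cv_f1 <- matrix(0, nrow = k, ncol = length(hp$grid))
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    if (length(unique(labels[tr])) < 2L) next
    for (i in seq_along(hp$grid)) {
      fits <- fit_ovr(x[tr, , drop = FALSE], labels[tr], hp$grid[i],
                      hp$class_weighting, STAGE2_CLASSES)
      pred <- predict_ovr(x[te, , drop = FALSE], fits)$label
      cv_f1[f, i] <- f1_binary(pred == minority, labels[te] == minority)
    }
  }
  mean_f1 <- colMeans(cv_f1)
  best <- which.max(mean_f1)
  # all three one-vs-rest classifiers are always present; a class absent
  # from the pool gets a constant negative score
  fits <- fit_ovr(x, labels, hp$grid[best], hp$class_weighting,
                  STAGE2_CLASSES)
  list(fits = fits, classes = STAGE2_CLASSES, C = hp$grid[best],
       cv = data.frame(candidate = hp$grid, mean_cv_f1 = mean_f1,
                       selected = seq_along(hp$grid) == best))
}

fit_ovr <- function(x, labels, cost, class_weighting, classes) {
  fits <- lapply(classes, function(cl) {
    y <- labels == cl
    if (length(unique(y)) < 2L) {
      # class absent from this fold: constant negative score
      return(list(w = rep(0, ncol(x)), b = -1))
    }
    fit_linear_svm(x, y, cost, class_weighting)
  })
  names(fits) <- classes
  fits
}

# One-vs-rest decision: argmax of the per-class scores, exact ties broken
# by the fixed priority IRRELEVANT < ANTECEDENT < BLEEDING (ties go to the
# clinically critical branch).
predict_ovr <- function(x, fits) {
  scores <- vapply(fits, function(f) svm_scores(x, f), numeric(nrow(x)))
  if (nrow(x) == 1L) scores <- matrix(scores, nrow = 1L,
                                      dimnames = list(NULL, names(fits)))
  priority <- match(colnames(scores), STAGE2_CLASSES)
  label <- apply(scores, 1L, function(s) {
    best <- which(s == max(s))
    colnames(scores)[best[which.max(priority[best])]]
  })
  list(label = label, scores = scores)
}

#' Train the three-stage bleeding-detection cascade
#'
#' Stage 1 is a class-weighted ridge logistic regression separating
#' relevant (any bleeding-related gold label) from irrelevant sentences.
#' Stage 2 is a one-vs-rest linear SVM over \{IRRELEVANT, ANTECEDENT,
#' BLEEDING\}, trained on the gold-positive sentences plus the stage-1
#' false positives found via out-of-fold stage-1 predictions on the
#' training set (so stage 2 can learn to reject material that will reach
#' it in deployment).  Stage 3 is a second ridge logistic regression
#' separating severe from clinically significant bleeding, trained on the
#' gold bleeding sentences.  Every stage's C is chosen by grid search
#' maximizing mean cross-validated F1 of its positive/minority class; all
#' stages share one vocabulary built from the training sentences.
#' Deterministic for a fixed seed.
#'
#' @param train training \code{bleedr_corpus} with gold sentence labels
#'   covering all four classes.
#' @param hyperparams a \code{\link{cascade_hyperparams}}.
#' @param seed integer seed governing fold assignment.
#' @return object of class \code{bleedr_cascade}.
#' @export
train_cascade <- function(train, hyperparams = cascade_hyperparams(),
                          seed = 1L) {
  stopifnot(inherits(train, "bleedr_corpus"),
            inherits(hyperparams, "bleedr_hyperparams"))
  sent <- corpus_sentences(train)
  if (nrow(sent) == 0L || anyNA(sent$gold)) {
    stop("training corpus lacks gold sentence labels", call. = FALSE)
  }
  missing <- setdiff(SENTENCE_LABELS, unique(sent$gold))
  if (length(missing) > 0L) {
    stage <- if (all(missing %in% c("CLIN_SIG", "SEVERE"))) "stage 3"
             else if (identical(missing, "ANTECEDENT")) "stage 2"
             else "stage 1"
    stop(stage, ": single-class training pool (missing labels: ",
         paste(missing, collapse = ", "), ")", call. = FALSE)
  }
  vocab <- build_vocabulary(sent$text, min_df = hyperparams$min_df)
  x <- bow_encode(sent$text, vocab)
  with_local_seed(seed, {
    # stage 1: relevant vs irrelevant, all sentences
    y1 <- sent$gold != "IRRELEVANT"
    s1 <- train_logistic_stage(x, y1, sent$gold, hyperparams, "stage 1")
    # stage 2 pool: gold positives plus stage-1 out-of-fold false positives
    pool2 <- which(y1 | (s1$oof_positive & !y1))
    lab2 <- ifelse(sent$gold[pool2] %in% c("CLIN_SIG", "SEVERE"), "BLEEDING",
                   sent$gold[pool2])
    s2 <- train_svm_stage(x[pool2, , drop = FALSE], lab2, hyperparams,
                          "stage 2")
    # stage 3: severe vs clinically significant, gold bleeding sentences
    pool3 <- which(sent$gold %in% c("CLIN_SIG", "SEVERE"))
    y3 <- sent$gold[pool3] == "SEVERE"
    s3 <- train_logistic_stage(x[pool3, , drop = FALSE], y3,
                               sent$gold[pool3], hyperparams, "stage 3")
    report <- rbind(cbind(stage = "stage1", s1$cv),
                    cbind(stage = "stage2", s2$cv),
                    cbind(stage = "stage3", s3$cv))
    structure(list(vocab = vocab,
                   stage1 = list(coef = s1$coef, C = s1$C),
                   stage2 = list(fits = s2$fits, classes = s2$classes,
                                 C = s2$C),
                   stage3 = list(coef = s3$coef, C = s3$C),
                   hyperparams = hyperparams, seed = as.integer(seed),
                   train_report = report),
              class = "bleedr_cascade")
  })
}

#' @export
print.bleedr_cascade <- function(x, ...) {
  cat(sprintf(paste0("<bleedr_cascade: |V|=%d, C1=%g, C2=%g, C3=%g,",
                     " weighting=%s>\n"),
              length(x$vocab$tokens), x$stage1$C, x$stage2$C, x$stage3$C,
              x$hyperparams$class_weighting))
  invisible(x)
}

# Vectorized cascade routing over an encoded sentence matrix.
cascade_route <- function(model, x) {
  n <- nrow(x)
  pred <- rep("IRRELEVANT", n)
  s1 <- logistic_scores(x, model$stage1$coef)
  s2 <- matrix(NA_real_, n, length(model$stage2$classes),
               dimnames = list(NULL, model$stage2$classes))
  s3 <- rep(NA_real_, n)
  to2 <- which(s1 > 0)
  if (length(to2) > 0L) {
    ovr <- predict_ovr(x[to2, , drop = FALSE], model$stage2$fits)
    s2[to2, ] <- ovr$scores
    pred[to2] <- ovr$label
    to3 <- to2[ovr$label == "BLEEDING"]
    if (length(to3) > 0L) {
      s3[to3] <- logistic_scores(x[to3, , drop = FALSE], model$stage3$coef)
      pred[to3] <- ifelse(s3[to3] > 0, "SEVERE", "CLIN_SIG")
    }
  }
  list(pred = pred, stage1 = s1, stage2 = s2, stage3 = s3)
}

#' Predict a single sentence through the cascade
#'
#' Routing: a sentence scoring non-positive at stage 1 is IRRELEVANT and
#' carries only the stage-1 score; otherwise stage 2 assigns IRRELEVANT,
#' ANTECEDENT or BLEEDING; BLEEDING sentences get a stage-3 severity
#' decision (positive score = SEVERE, else CLIN_SIG).  Exactly one label
#' is returned; \code{stage_scores} carries each visited stage's decision
#' score for ROC construction.
#'
#' @param model fitted \code{bleedr_cascade}.
#' @param sentence an \code{\link{annotated_sentence}} or character
#'   string.
#' @return list with \code{label} and \code{stage_scores}.
#' @export
predict_sentence <- function(model, sentence) {
  stopifnot(inherits(model, "bleedr_cascade"))
  text <- if (inherits(sentence, "bleedr_sentence")) sentence$text
          else as.character(sentence)
  r <- cascade_route(model, bow_encode(text, model$vocab))
  scores <- list(stage1 = r$stage1[1])
  if (r$stage1[1] > 0) scores$stage2 <- r$stage2[1, ]
  if (!is.na(r$stage3[1])) scores$stage3 <- r$stage3[1]
  list(label = r$pred[1], stage_scores = scores)
}

#' Predict all sentences of a corpus and aggregate per document
#'
#' @param model fitted \code{bleedr_cascade}.
#' @param corpus a \code{bleedr_corpus}.
#' @return list with \code{sentences} (data.frame of per-sentence
#'   predictions and visited-stage scores) and \code{documents} (named
#'   list of predicted document label sets, in corpus order).
#' @export
predict_corpus <- function(model, corpus) {
  stopifnot(inherits(model, "bleedr_cascade"),
            inherits(corpus, "bleedr_corpus"))
  sent <- corpus_sentences(corpus)
  x <- bow_encode(sent$text, model$vocab)
  r <- cascade_route(model, x)
  sentences <- data.frame(sent[c("doc_id", "sentence_id")],
                          pred = r$pred, score_stage1 = r$stage1,
                          score_stage3 = r$stage3,
                          stringsAsFactors = FALSE)
  sentences <- cbind(sentences,
                     stats::setNames(as.data.frame(r$stage2),
                                     paste0("score_stage2_",
                                            colnames(r$stage2))))
  docs <- lapply(corpus$documents, function(d) {
    labs <- sentences$pred[sentences$doc_id == d$doc_id]
    if (length(labs) == 0L) character(0) else aggregate_document(labs)
  })
  names(docs) <- vapply(corpus$documents, function(d) d$doc_id, character(1))
  list(sentences = sentences, documents = docs)
}

#' Aggregate sentence labels to a document label set
#'
#' Union-like aggregation: the document receives every non-IRRELEVANT
#' label present among its sentences; a document whose sentences are all
#' IRRELEVANT is classified the same (empty label set).  Order-invariant,
#' idempotent under duplication and monotone (adding a sentence never
#' removes a document label).
#'
#' @param sentence_labels nonempty character vector of sentence labels.
#' @return character vector: subset of \code{\link{POSITIVE_LABELS}}.
#' @export
aggregate_document <- function(sentence_labels) {
  if (length(sentence_labels) == 0L) {
    stop("cannot aggregate an empty sentence list", call. = FALSE)
  }
  assert_sentence_labels(sentence_labels)
  intersect(POSITIVE_LABELS, unique(sentence_labels))
}

#' Evaluate the cascade on a labeled corpus
#'
#' Sentence-level metrics over the four sentence classes (the micro
#' granularity) and document-level metrics over the four document classes
#' (the macro granularity; IRRELEVANT = empty label set).
#'
#' @param model fitted \code{bleedr_cascade}.
#' @param corpus gold-labeled corpus.
#' @return list with \code{sentence} and \code{document}
#'   \code{\link{metrics_report}}s and the raw \code{predictions}.
#' @export
evaluate_cascade <- function(model, corpus) {
  pred <- predict_corpus(model, corpus)
  sent <- corpus_sentences(corpus)
  if (anyNA(sent$gold)) stop("corpus lacks gold sentence labels",
                             call. = FALSE)
  gold_docs <- lapply(corpus$documents, function(d) d$gold_doc)
  if (any(vapply(gold_docs, is.null, logical(1)))) {
    stop("corpus lacks gold document labels", call. = FALSE)
  }
  list(sentence = metrics_report(pred$sentences$pred, sent$gold,
                                 classes = SENTENCE_LABELS,
                                 granularity = "SENTENCE"),
       document = metrics_report(unname(pred$documents), gold_docs,
                                 classes = SENTENCE_LABELS,
                                 granularity = "DOCUMENT"),
       predictions = pred)
}

#' Stage-wise ROC curves
#'
#' Stage 1 is scored on all sentences (gold: any bleeding-related label).
#' Stage 2 is scored one-vs-rest for a chosen class on the sentences the
#' model routes to it (stage-1 score > 0).  Stage 3 is scored on routed
#' sentences whose gold is CLIN_SIG or SEVERE (gold: SEVERE).
#'
#' @param model fitted cascade.
#' @param corpus gold-labeled corpus.
#' @param stage 1, 2 or 3.
#' @param positive_class for stage 2, which one-vs-rest class to score
#'   (default \code{"IRRELEVANT"}).
#' @return a \code{\link{roc_and_auc}} result.
#' @export
stage_roc <- function(model, corpus, stage,
                      positive_class = "IRRELEVANT") {
  sent <- corpus_sentences(corpus)
  x <- bow_encode(sent$text, model$vocab)
  r <- cascade_route(model, x)
  if (stage == 1) {
    return(roc_and_auc(r$stage1, sent$gold != "IRRELEVANT", "stage1"))
  }
  routed <- which(r$stage1 > 0)
  if (stage == 2) {
    gold2 <- ifelse(sent$gold[routed] %in% c("CLIN_SIG", "SEVERE"),
                    "BLEEDING", sent$gold[routed])
    return(roc_and_auc(r$stage2[routed, positive_class],
                       gold2 == positive_class,
                       paste0("stage2_", positive_class)))
  }
  pool <- routed[sent$gold[routed] %in% c("CLIN_SIG", "SEVERE") &
                 !is.na(r$stage3[routed])]
  roc_and_auc(r$stage3[pool], sent$gold[pool] == "SEVERE", "stage3")
}
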