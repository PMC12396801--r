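# Independent brute-force oracles ---------------------------------------

# per-unit one-vs-rest counting, no pooling tricks
brute_confusion <- function(pred, gold, classes) {
  has <- function(labels, i, cl) {
    if (is.list(labels)) {
      if (cl == "IRRELEVANT") length(labels[[i]]) == 0L
      else cl %in% labels[[i]]
    } else labels[[i]] == cl
  }
  do.call(rbind, lapply(classes, function(cl) {
    tp <- fp <- fn <- tn <- 0L
    for (i in seq_along(pred)) {
      p <- has(pred, i, cl); g <- has(gold, i, cl)
      if (p && g) tp <- tp + 1L else if (p) fp <- fp + 1L
      else if (g) fn <- fn + 1L else tn <- tn + 1L
    }
    data.frame(class = cl, tp = tp, fp = fp, fn = fn, tn = tn,
               stringsAsFactors = FALSE)
  }))
}

# Mann-Whitney pairwise concordance with ties counted one half
brute_auc <- function(scores, gold) {
  pos <- scores[gold == 1]; neg <- scores[gold == 0]
  conc <- 0
  for (p in pos) for (n in neg) {
    conc <- conc + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  conc / (length(pos) * length(neg))
}

test_that("confusion counts match the brute-force oracle", {
  # perfect prediction
  gold <- rep(c("CLIN_SIG", "IRRELEVANT"), c(4, 6))
  cc <- confusion(gold, gold, c("CLIN_SIG", "IRRELEVANT"))
  expect_equal(cc$tp, c(4, 6))
  expect_equal(cc$fp + cc$fn, c(0, 0))
  expect_equal(cc$tp + cc$tn, c(10, 10))

  # degenerate all-negative predictor
  gold <- rep(c("SEVERE", "IRRELEVANT"), c(3, 7))
  cc <- confusion(rep("IRRELEVANT", 10), gold, "SEVERE")
  expect_equal(cc[, c("tp", "fp", "fn", "tn")],
               data.frame(tp = 0L, fp = 0L, fn = 3L, tn = 7L))

  # random sentence-level and document-level instances vs oracle
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(3:15, 1)
    pred <- sample(SENTENCE_LABELS, n, replace = TRUE)
    gold <- sample(SENTENCE_LABELS, n, replace = TRUE)
    expect_equal(confusion(pred, gold, SENTENCE_LABELS),
                 brute_confusion(pred, gold, SENTENCE_LABELS))
    rnd_sets <- function(n) lapply(seq_len(n), function(i) {
      s <- POSITIVE_LABELS[runif(3) < 0.4]
      s
    })
    ps <- rnd_sets(n); gs <- rnd_sets(n)
    expect_equal(confusion(ps, gs, SENTENCE_LABELS),
                 brute_confusion(ps, gs, SENTENCE_LABELS))
  }
})

test_that("per-class metrics follow the confusion formulas with flagged 0/0", {
  m <- metrics_from_confusion(
    data.frame(class = "x", tp = 3, fp = 1, fn = 2, tn = 4))
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / 1.35)

  all_good <- metrics_from_confusion(
    data.frame(class = "x", tp = 5, fp = 0, fn = 0, tn = 5))
  expect_true(all(unlist(all_good[2:6]) == 1))

  undef <- metrics_from_confusion(
    data.frame(class = "x", tp = 0, fp = 0, fn = 2, tn = 8))
  expect_equal(undef$precision, 0)
  expect_true(undef$precision_flagged)
  expect_false(undef$recall_flagged)
})

test_that("macro average is the unweighted mean at table precision", {
  expect_equal(round_half_away(macro_average(c(0.81, 0.72, 0.87, 0.92))),
               0.83)
  expect_equal(round_half_away(macro_average(c(0.95, 0.77, 0.03))), 0.58)
  for (x in c(0, 0.5, 0.77)) {
    expect_equal(macro_average(rep(x, 3)), x)
  }
  v <- c(0.1, 0.4, 0.9)
  expect_equal(macro_average(v), macro_average(rev(v)))
  expect_error(macro_average(numeric(0)), "empty")
  # reporting helper rounds half away from zero
  expect_equal(round_half_away(0.815), 0.82)
  expect_equal(round_half_away(-0.815), -0.82)
})

test_that("micro metrics over pooled counts equal summed-confusion metrics", {
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    pred <- sample(SENTENCE_LABELS, n, replace = TRUE)
    gold <- sample(SENTENCE_LABELS, n, replace = TRUE)
    rep_ <- metrics_report(pred, gold, granularity = "SENTENCE")
    cc <- brute_confusion(pred, gold, SENTENCE_LABELS)
    pooled <- metrics_from_confusion(
      data.frame(class = "pooled", tp = sum(cc$tp), fp = sum(cc$fp),
                 fn = sum(cc$fn), tn = sum(cc$tn)))
    for (m in c("accuracy", "precision", "recall", "specificity", "f1")) {
      expect_equal(unname(rep_$micro[[m]]), pooled[[m]])
    }
    expect_equal(unname(rep_$macro[["f1"]]),
                 mean(metrics_from_confusion(cc)$f1))
  }
})

test_that("ROC curve is monotone (0,0)->(1,1) and AUC equals concordance", {
  r <- roc_and_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 1))
  expect_equal(r$auc, 2 / 3)

  expect_equal(roc_and_auc(c(5, 4, 1, 0), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_and_auc(rep(0.3, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)

  set.seed(23)
  for (rep in 1:15) {
    n <- sample(5:50, 1)
    scores <- round(rnorm(n), 1)  # rounding forces ties
    gold <- sample(0:1, n, replace = TRUE)
    if (length(unique(gold)) < 2) next
    r <- roc_and_auc(scores, gold)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
    expect_equal(r$points$fpr[1], 0)
    expect_equal(r$points$tpr[nrow(r$points)], 1)
    expect_equal(r$auc, brute_auc(scores, gold), tolerance = 1e-9)
    if (requireNamespace("pROC", quietly = TRUE)) {
      expect_equal(r$auc,
                   as.numeric(pROC::auc(pROC::roc(gold, scores,
                                                  quiet = TRUE,
                                                  direction = "<"))),
                   tolerance = 1e-9)
    }
  }
  expect_error(roc_and_auc(c(1, 2), c(1, 1)), "both classes")
})

test_that("Cohen kappa matches hand values, is symmetric, near 0 under independence", {
  expect_equal(cohen_kappa(c("a", "b", "a"), c("a", "b", "a")), 1.0)

  # 100 units, po = 0.8, symmetric 50/50 marginals => pe = 0.5, kappa = 0.6
  a <- rep(c("A", "A", "B", "B"), c(40, 10, 40, 10))
  b <- rep(c("A", "B", "B", "A"), c(40, 10, 40, 10))
  expect_equal(cohen_kappa(a, b), 0.6)
  expect_equal(cohen_kappa(a, b), cohen_kappa(b, a))

  tab <- table(a, b)
  expect_equal(cohen_kappa(a, b), e1071::classAgreement(tab)$kappa)

  set.seed(99)
  x <- sample(c("A", "B"), 10000, replace = TRUE)
  y <- sample(c("A", "B"), 10000, replace = TRUE)
  expect_lt(abs(cohen_kappa(x, y)), 0.05)

  expect_error(cohen_kappa(c("a"), c("a", "b")), "length")
})

test_that("Fleiss kappa matches the published formulation", {
  # unanimous raters over two realized categories
  m <- matrix(c("a", "a", "a",
                "b", "b", "b"), nrow = 2, byrow = TRUE)
  expect_equal(fleiss_kappa(m), 1.0)

  # 4 units x 3 raters worked example: kappa = 1/3
  m <- matrix(c("a", "a", "a",
                "a", "b", "b",
                "b", "b", "b",
                "a", "a", "b"), nrow = 4, byrow = TRUE)
  expect_equal(fleiss_kappa(m), 1 / 3)

  # uniformly random raters: kappa ~ 0
  set.seed(7)
  big <- matrix(sample(letters[1:4], 3000 * 3, replace = TRUE), ncol = 3)
  expect_lt(abs(fleiss_kappa(big)), 0.05)

  expect_error(fleiss_kappa(matrix("a", 2, 1)), "2 raters")
  expect_error(fleiss_kappa(matrix(c("a", NA, "b", "a"), 2, 2)),
               "incomplete")
})

test_that("classifier comparison pairs reports and method-agreement kappa", {
  gold <- list(c("CLIN_SIG"), character(0), c("SEVERE", "CLIN_SIG"),
               c("ANTECEDENT"))
  nlp <- gold
  rule <- list(c("CLIN_SIG"), character(0), c("CLIN_SIG"), character(0))
  rep_nlp <- metrics_report(nlp, gold, granularity = "DOCUMENT")
  rep_rule <- metrics_report(rule, lapply(gold, setdiff, "ANTECEDENT"),
                             granularity = "DOCUMENT",
                             excluded_classes = "ANTECEDENT")
  cmp <- compare_classifiers(rep_nlp, rep_rule,
                             list(nlp = nlp, rule = rule))
  expect_equal(unname(cmp$kappa[["CLIN_SIG"]]), 1.0)
  # rule arm missed the only SEVERE document: kappa 0 and recall 0
  expect_equal(unname(cmp$kappa[["SEVERE"]]), 0)
  rr <- cmp$table[cmp$table$method == "rule" & cmp$table$class == "SEVERE", ]
  expect_equal(rr$recall, 0)
  # identical sets give identical columns and kappa 1
  cmp2 <- compare_classifiers(rep_nlp, rep_nlp,
                              list(nlp = nlp, rule = nlp))
  expect_true(all(cmp2$kappa == 1))
  expect_error(compare_classifiers(rep_nlp, rep_rule,
                                   list(nlp = nlp, rule = rule[1:2])),
               "aligned")
})
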