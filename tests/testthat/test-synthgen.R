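test_that("template banks are complete and carry ISTH severity cues", {
  for (sig in c("realistic", "separable")) {
    for (lang in c("fr", "en")) {
      bank <- template_bank(sig, lang)
      counts <- table(bank$label)
      expect_true(all(counts[SENTENCE_LABELS] >= 5))
      sev <- bank$template[bank$label == "SEVERE"]
      # every severe template realizes an ISTH criterion: transfusion
      # units, haemoglobin drop, or a critical bleeding site
      expect_true(all(grepl(
        "<units>|<hb>|<site>|intracr|intraspinal|Intracranial", sev)))
    }
  }
  # realistic irrelevant bank includes negated bleeding mentions
  irr <- template_bank("realistic")
  expect_true(any(irr$negation))
  neg <- irr$template[irr$negation]
  expect_true(all(grepl("saignement|hémorrag|sang", neg, ignore.case = TRUE)))
})

test_that("generation is deterministic down to bytes", {
  cfg <- small_cfg(n_documents = 20L, seed = 123)
  f1 <- withr::local_tempfile(fileext = ".jsonl")
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(generate_corpus(cfg), f1)
  write_corpus(generate_corpus(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("document gold labels equal the union of sentence gold labels", {
  co <- generate_corpus(small_cfg(n_documents = 60L, seed = 5))
  for (d in co$documents) {
    sent_labels <- vapply(d$sentences, `[[`, "", "gold")
    rederived <- setdiff(unique(sent_labels), "IRRELEVANT")
    expect_setequal(d$gold_doc, rederived)
    # and the aggregation operator agrees
    expect_setequal(d$gold_doc, aggregate_document(sent_labels))
  }
})

test_that("realized sentence prevalences match the configured ones", {
  cfg <- synth_config(n_documents = 150L, sentences_per_doc = c(60L, 100L),
                      seed = 9)
  co <- generate_corpus(cfg)
  sent <- corpus_sentences(co)
  n <- nrow(sent)
  expect_gt(n, 5000)
  for (lab in SENTENCE_LABELS) {
    p <- cfg$sentence_prevalence[[lab]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(sent$gold == lab) - p), 3 * se + 1e-12)
  }
})

test_that("severe-code emission at zero silences the rule arm for SEVERE", {
  cfg <- small_cfg(n_documents = 200L, sentences = c(15L, 30L), seed = 21,
                   icd_sensitivity = c(CLIN_SIG = 0.77, SEVERE = 0),
                   icd_false_positive_rate = 0)
  co <- generate_corpus(cfg)
  tab <- default_code_table()
  sev_docs <- Filter(function(d) "SEVERE" %in% d$gold_doc, co$documents)
  expect_gt(length(sev_docs), 5)
  for (d in sev_docs) {
    expect_length(classify_stay(d$icd_codes, tab)$matched_codes$SEVERE, 0L)
  }
  rep_ <- evaluate_rule_classifier(co)
  expect_equal(rep_$per_class$recall[rep_$per_class$class == "SEVERE"], 0)
})

test_that("corpus summary reproduces hand counts and validates gold", {
  co <- tiny_corpus()
  s <- corpus_summary(co)
  expect_identical(s$label, SENTENCE_LABELS)
  expect_equal(s$sentence_n, c(3L, 1L, 1L, 1L))
  expect_equal(s$document_n, c(1L, 1L, 1L, 1L))
  expect_equal(s$sentence_pct[1], 50)
  expect_equal(s$document_pct, rep(33.33, 4))

  unlabeled <- bleedr_corpus(list(annotated_document(
    "u", sentences = list(annotated_sentence("Texte.")))))
  expect_error(corpus_summary(unlabeled), "gold")
})

test_that("infeasible configurations are rejected", {
  expect_error(synth_config(sentence_prevalence = c(IRRELEVANT = 0.5,
                                                    ANTECEDENT = 0.1,
                                                    CLIN_SIG = 0.1,
                                                    SEVERE = 0.1)),
               "sum to 1")
  expect_error(synth_config(negation_rate = 1.5), "probabilities")
  # positive prevalence but an empty template pool for that label
  bank <- template_bank("realistic")
  bank <- bank[bank$label != "SEVERE", ]
  expect_error(generate_corpus(small_cfg(n_documents = 5L), bank),
               "no templates")
  # sentence prevalence unreachable given rare document labels
  expect_error(
    generate_corpus(small_cfg(
      sentence_prevalence = c(IRRELEVANT = 0.5, ANTECEDENT = 0.3,
                              CLIN_SIG = 0.1, SEVERE = 0.1))),
    "infeasible")
})
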