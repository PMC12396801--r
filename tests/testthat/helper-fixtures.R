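# Hand-built three-document corpus covering all labels, used across tests.
tiny_corpus <- function() {
  bleedr_corpus(list(
    annotated_document(
      doc_id = "A",
      sentences = list(
        annotated_sentence("Pas de saignement actif.", gold = "IRRELEVANT"),
        annotated_sentence("Méléna objectivé à l'entrée.", gold = "CLIN_SIG"),
        annotated_sentence("Choc hémorragique, 3 culots transfusés.",
                           gold = "SEVERE")),
      icd_codes = c("K92.2", "R57.1"),
      gold_doc = c("CLIN_SIG", "SEVERE")),
    annotated_document(
      doc_id = "B",
      sentences = list(
        annotated_sentence("Antécédent d'hémorragie digestive en 2010.",
                           gold = "ANTECEDENT"),
        annotated_sentence("Retour à domicile organisé.",
                           gold = "IRRELEVANT")),
      icd_codes = character(0),
      gold_doc = "ANTECEDENT"),
    annotated_document(
      doc_id = "C",
      sentences = list(
        annotated_sentence("Mobilisation avec physiothérapie.",
                           gold = "IRRELEVANT")),
      icd_codes = "I10",
      gold_doc = character(0))))
}

# Small fast generator config for unit tests.
small_cfg <- function(n_documents = 80L, sentences = c(10L, 25L), seed = 1L,
                      ...) {
  synth_config(n_documents = n_documents, sentences_per_doc = sentences,
               seed = seed, ...)
}

# Reduced hyperparameter search for unit-test-sized corpora.
fast_hp <- function(...) {
  cascade_hyperparams(grid = c(0.1, 1, 10), cv_folds = 3L, ...)
}
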