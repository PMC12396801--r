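#' Synthetic corpus configuration
#'
#' Defaults emulate the statistical structure of the study corpus: 400
#' discharge summaries of 120-210 sentences (about 65,000 sentences in
#' total), sentence-label prevalences from the training-set class
#' distribution (97.45\% irrelevant, 0.33\% history, 1.91\% clinically
#' significant, 0.32\% severe), document-level label marginals (36.79\%
#' of documents irrelevant; history 23.93\%, clinically significant
#' 50.36\%, severe 27.50\%), and ICD code emission with sensitivity 0.77
#' for the clinically-significant group and 0.03 for the severe group --
#' severe-bleeding codes being rare in administrative data is the
#' mechanism behind the rule arm's near-zero severe recall.
#'
#' The generator is hierarchical: a latent document label set is drawn
#' first (so document-level class balance is realistic), then sentence
#' labels within each document at rates calibrated so the unconditional
#' sentence-label proportions match the configured prevalences exactly in
#' expectation.  Gold document labels are derived as the union of the
#' realized sentence labels.
#'
#' @param n_documents number of documents.
#' @param sentences_per_doc integer range (min, max), sampled uniformly.
#' @param sentence_prevalence named proportions over the four sentence
#'   labels; must sum to 1 (up to rounding slack, renormalized).
#' @param doc_irrelevant_rate probability a document's latent label set is
#'   empty.
#' @param doc_label_rates named marginal probabilities of the three
#'   positive labels at document level.
#' @param negation_rate proportion of irrelevant sentences phrased as a
#'   negated bleeding mention ("pas de saignement actif").
#' @param icd_sensitivity named probabilities that a gold-positive
#'   document emits a matching severity-group code.
#' @param icd_false_positive_rate probability a gold-negative document
#'   emits a code from a group anyway.
#' @param seed integer seed; the corpus is fully deterministic given it.
#' @return list of class \code{bleedr_synth_config}.
#' @export
synth_config <- function(n_documents = 400L,
                         sentences_per_doc = c(120L, 210L),
                         sentence_prevalence = c(IRRELEVANT = 0.9745,
                                                 ANTECEDENT = 0.0033,
                                                 CLIN_SIG = 0.0191,
                                                 SEVERE = 0.0032),
                         doc_irrelevant_rate = 0.3679,
                         doc_label_rates = c(ANTECEDENT = 0.2393,
                                             CLIN_SIG = 0.5036,
                                             SEVERE = 0.2750),
                         negation_rate = 0.05,
                         icd_sensitivity = c(CLIN_SIG = 0.77, SEVERE = 0.03),
                         icd_false_positive_rate = 0.05,
                         seed = 1L) {
  stopifnot(n_documents >= 1L, length(sentences_per_doc) == 2L,
            sentences_per_doc[1] >= 1L,
            sentences_per_doc[2] >= sentences_per_doc[1])
  if (!setequal(names(sentence_prevalence), SENTENCE_LABELS)) {
    stop("sentence_prevalence must name all four sentence labels",
         call. = FALSE)
  }
  if (any(sentence_prevalence < 0) || any(sentence_prevalence > 1)) {
    stop("prevalences must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(sentence_prevalence) - 1) > 0.005) {
    stop("sentence prevalences must sum to 1", call. = FALSE)
  }
  sentence_prevalence <- sentence_prevalence / sum(sentence_prevalence)
  probs <- c(doc_irrelevant_rate, doc_label_rates, negation_rate,
             icd_sensitivity, icd_false_positive_rate)
  if (any(probs < 0) || any(probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_documents = as.integer(n_documents),
                 sentences_per_doc = as.integer(sentences_per_doc),
                 sentence_prevalence = sentence_prevalence[SENTENCE_LABELS],
                 doc_irrelevant_rate = doc_irrelevant_rate,
                 doc_label_rates = doc_label_rates[POSITIVE_LABELS],
                 negation_rate = negation_rate,
                 icd_sensitivity = icd_sensitivity,
                 icd_false_positive_rate = icd_false_positive_rate,
                 seed = as.integer(seed)),
            class = "bleedr_synth_config")
}

#' Built-in sentence template banks
#'
#' French-styled clinical fragments per sentence label, with slot fillers
#' for years, haemoglobin drops, transfusion unit counts and bleeding
#' sites.  Severe templates realize ISTH major-bleeding cues (critical
#' site, haemoglobin drop of at least 20 g/L, at least two units
#' transfused); a fraction of irrelevant sentences are negated bleeding
#' mentions.  Three signal regimes exist:
#' \describe{
#'   \item{realistic}{naturalistic fragments with the lexical overlap real
#'     notes show (negations share bleeding terms with positive classes).}
#'   \item{separable}{each label's content words are disjoint from every
#'     other label's, so a linear bag-of-words cascade can recover the
#'     labels nearly perfectly -- the parameter-recovery fixture.}
#'   \item{none}{all labels share one generic template pool; a negative
#'     control carrying no lexical signal.}
#' }
#' An English bank (\code{language = "en"}) is included for portability
#' testing.
#'
#' @param signal one of \code{"realistic"}, \code{"separable"},
#'   \code{"none"}.
#' @param language \code{"fr"} (default) or \code{"en"}.
#' @return data.frame of class \code{bleedr_template_bank} with columns
#'   \code{label}, \code{template}, \code{negation}.
#' @export
template_bank <- function(signal = c("realistic", "separable", "none"),
                          language = c("fr", "en")) {
  signal <- match.arg(signal)
  language <- match.arg(language)
  bank <- if (language == "fr") fr_bank(signal) else en_bank(signal)
  structure(bank, class = c("bleedr_template_bank", "data.frame"))
}

bank_df <- function(label, templates, negation = FALSE) {
  data.frame(label = label, template = templates, negation = negation,
             stringsAsFactors = FALSE)
}

fr_bank <- function(signal) {
  if (signal == "none") {
    generic <- c("Evolution clinique durant le sejour hospitalier.",
                 "Suivi ambulatoire organise apres la sortie.",
                 "Parametres vitaux controles regulierement.",
                 "Discussion avec la famille au sujet du projet de soins.",
                 "Examens complementaires realises selon le protocole.")
    return(do.call(rbind, lapply(SENTENCE_LABELS, bank_df,
                                 templates = generic)))
  }
  if (signal == "separable") {
    return(rbind(
      bank_df("IRRELEVANT", c(
        "Contrôle biologique stable.",
        "Mobilisation avec physiothérapie.",
        "Traitement habituel poursuivi.",
        "Retour domicile organisé.",
        "Alimentation orale tolérée.")),
      bank_df("ANTECEDENT", c(
        "Antécédent de saignement en <year>.",
        "Ancien épisode de saignement en <year>.",
        "Notion de saignement en <year>.",
        "Saignement mentionné aux antécédents en <year>.",
        "Antécédent ancien, épisode de saignement en <year>.")),
      bank_df("CLIN_SIG", c(
        "Hématurie macroscopique constatée.",
        "Méléna objectivé.",
        "Épistaxis récidivante.",
        "Rectorragies intermittentes.",
        "Hématome sous anticoagulation.")),
      bank_df("SEVERE", c(
        "Choc hémorragique, transfusion de <units> culots.",
        "Chute hémoglobine <hb> g/L.",
        "Hémorragie intracrânienne massive.",
        "Transfusion de <units> culots pour déglobulisation.",
        "Choc avec hémoglobine effondrée, <units> culots."))))
  }
  rbind(
    bank_df("IRRELEVANT", c(
      "Poursuite du traitement habituel à domicile.",
      "Le patient reste stable sur le plan cardiovasculaire.",
      "Contrôle biologique prévu chez le médecin traitant.",
      "Mobilisation progressive avec l'équipe de physiothérapie.",
      "Adaptation du traitement antihypertenseur durant le séjour.",
      "Le status neurologique est dans la norme.",
      "Alimentation orale bien tolérée.",
      "Retour à domicile organisé avec les soins à domicile.")),
    bank_df("IRRELEVANT", c(
      "Pas de saignement actif objectivé.",
      "Aucun signe d'hémorragie à l'anamnèse.",
      "Pas d'extériorisation de sang durant le séjour.",
      "Absence de saignement visible au status.",
      "Pas de récidive hémorragique durant l'hospitalisation."),
      negation = TRUE),
    bank_df("ANTECEDENT", c(
      "Antécédent d'hémorragie digestive en <year>.",
      "Status post saignement gastro-intestinal en <year>.",
      "Ancien épisode d'épistaxis récidivante en <year>.",
      "Notion d'hémorragie cérébrale en <year> dans les antécédents.",
      "Connu pour un ulcère hémorragique en <year>.")),
    bank_df("CLIN_SIG", c(
      "Hématurie macroscopique constatée durant le séjour.",
      "Méléna objectivé à l'entrée.",
      "Épistaxis nécessitant un méchage.",
      "Saignement digestif de faible abondance à la gastroscopie.",
      "Hématome du membre inférieur sous anticoagulation.",
      "Rectorragies intermittentes durant l'hospitalisation.")),
    bank_df("SEVERE", c(
      "Choc hémorragique avec transfusion de <units> culots érythrocytaires.",
      "Chute d'hémoglobine de <hb> g/L sur hémorragie digestive.",
      "Hémorragie intracrânienne objectivée au CT cérébral.",
      "Hémorragie sévère au niveau <site>, prise en charge aux soins intensifs.",
      "Transfusion de <units> concentrés érythrocytaires pour déglobulisation majeure.")))
}

en_bank <- function(signal) {
  if (signal != "realistic") return(fr_bank(signal))
  rbind(
    bank_df("IRRELEVANT", c(
      "Usual home medication continued.",
      "The patient remained hemodynamically stable.",
      "Laboratory follow-up planned with the family physician.",
      "Progressive mobilisation with physiotherapy.",
      "Neurological status within normal limits.")),
    bank_df("IRRELEVANT", c(
      "No visible bleeding at the anamnesis.",
      "No evidence of active bleeding.",
      "No source of bleeding identified.",
      "No recurrence of hemorrhage during the stay.",
      "Absence of overt bleeding on examination."), negation = TRUE),
    bank_df("ANTECEDENT", c(
      "History of gastrointestinal hemorrhage in <year>.",
      "Prior episode of recurrent epistaxis in <year>.",
      "Known previous bleeding ulcer in <year>.",
      "Past intracerebral hemorrhage in <year>.",
      "Bleeding episode documented in <year> in the history.")),
    bank_df("CLIN_SIG", c(
      "Macroscopic hematuria noted during the stay.",
      "Melena observed on admission.",
      "Epistaxis requiring nasal packing.",
      "Minor digestive bleeding seen at gastroscopy.",
      "Lower-limb hematoma under anticoagulation.")),
    bank_df("SEVERE", c(
      "Hemorrhagic shock, transfusion of <units> packed red cells.",
      "Hemoglobin drop of <hb> g/L from digestive hemorrhage.",
      "Intracranial hemorrhage on CT.",
      "Severe <site> bleeding requiring intensive care.",
      "Transfusion of <units> units for major blood loss.")))
}

fill_template <- function(template) {
  out <- template
  if (grepl("<year>", out, fixed = TRUE)) {
    out <- sub("<year>", sample(2005:2014, 1L), out, fixed = TRUE)
  }
  while (grepl("<units>", out, fixed = TRUE)) {
    out <- sub("<units>", sample(2:4, 1L), out, fixed = TRUE)
  }
  if (grepl("<hb>", out, fixed = TRUE)) {
    out <- sub("<hb>", sample(20:45, 1L), out, fixed = TRUE)
  }
  if (grepl("<site>", out, fixed = TRUE)) {
    out <- sub("<site>", sample(c("intracrânien", "intraspinal",
                                  "rétropéritonéal",
                                  "péricardique"), 1L), out, fixed = TRUE)
  }
  out
}

# Within-document sentence-label rates from a config: the latent document
# marginal for label l after rejection of empty positive sets is
# d_l = (1 - p_irr) * q_l / P(nonempty); the within-document rate
# r_l = prevalence_l / d_l then makes the unconditional sentence-label
# share equal prevalence_l exactly in expectation.
synth_rates <- function(config) {
  p_irr <- config$doc_irrelevant_rate
  d <- config$doc_label_rates
  if (p_irr >= 1) stop("doc_irrelevant_rate must be < 1", call. = FALSE)
  q <- pmin(d / (1 - p_irr), 1)
  p_nonempty <- 1 - prod(1 - q)
  d_actual <- (1 - p_irr) * q / p_nonempty
  prev <- config$sentence_prevalence[POSITIVE_LABELS]
  r <- ifelse(d_actual > 0, prev / d_actual, 0)
  if (any(r > 1) || sum(r) > 1) {
    stop("infeasible config: sentence prevalences too high for the ",
         "document label rates", call. = FALSE)
  }
  list(q = q, r = stats::setNames(r, POSITIVE_LABELS))
}

sample_doc_labels <- function(q) {
  repeat {
    l <- POSITIVE_LABELS[stats::runif(3) < q]
    if (length(l) > 0L) return(l)
  }
}

noise_icd_codes <- c("I10", "E119", "N179", "J449", "F051", "Z921",
                     "M810", "E785")

sample_icd <- function(gold_doc, config, code_table) {
  groups <- list(CLIN_SIG = code_table$clin_sig_codes,
                 SEVERE = code_table$severe_codes)
  codes <- character(0)
  for (lab in names(groups)) {
    p <- if (lab %in% gold_doc) config$icd_sensitivity[[lab]]
         else config$icd_false_positive_rate
    if (stats::runif(1) < p) {
      codes <- c(codes, sample(groups[[lab]], 1L))
    }
  }
  n_noise <- sample(0:3, 1L)
  c(codes, sample(noise_icd_codes, n_noise))
}

#' Generate a synthetic annotated corpus
#'
#' Fully deterministic given the config seed: regenerating with the same
#' config yields byte-identical JSONL after \code{\link{write_corpus}}.
#' Gold document labels are the union of the realized gold sentence
#' labels; stay ICD codes are emitted per document by Bernoulli draws
#' conditioned on the gold document labels (sensitivity per severity
#' group, a false-positive rate for gold-negative documents) plus a few
#' non-bleeding administrative codes.
#'
#' @param config a \code{\link{synth_config}}.
#' @param templates a \code{\link{template_bank}}.
#' @param code_table ICD table supplying the severity code groups.
#' @return a \code{\link{bleedr_corpus}}.
#' @export
generate_corpus <- function(config = synth_config(),
                            templates = template_bank("realistic"),
                            code_table = default_code_table()) {
  stopifnot(inherits(config, "bleedr_synth_config"))
  for (lab in SENTENCE_LABELS) {
    if (config$sentence_prevalence[[lab]] > 0 &&
        sum(templates$label == lab) == 0L) {
      stop("no templates for label with positive prevalence: ", lab,
           call. = FALSE)
    }
  }
  rates <- synth_rates(config)
  with_local_seed(config$seed, {
    docs <- lapply(seq_len(config$n_documents), function(i) {
      doc_id <- sprintf("synth-%04d", i)
      n_sent <- sample(config$sentences_per_doc[1]:config$sentences_per_doc[2],
                       1L)
      latent <- if (stats::runif(1) < config$doc_irrelevant_rate) character(0)
                else sample_doc_labels(rates$q)
      probs <- c(rates$r[latent], 1 - sum(rates$r[latent]))
      labels <- sample(c(latent, "IRRELEVANT"), n_sent, replace = TRUE,
                       prob = probs)
      sentences <- lapply(seq_len(n_sent), function(j) {
        lab <- labels[[j]]
        pool <- templates[templates$label == lab, , drop = FALSE]
        if (lab == "IRRELEVANT" && any(pool$negation)) {
          use_neg <- stats::runif(1) < config$negation_rate
          pool <- pool[pool$negation == use_neg, , drop = FALSE]
        }
        annotated_sentence(
          text = fill_template(sample(pool$template, 1L)),
          sentence_id = paste0(doc_id, "#", j), gold = lab)
      })
      gold_doc <- intersect(POSITIVE_LABELS, unique(labels))
      annotated_document(doc_id = doc_id, sentences = sentences,
                         icd_codes = sample_icd(gold_doc, config, code_table),
                         gold_doc = gold_doc)
    })
    bleedr_corpus(docs)
  })
}

#' Generate the separable parameter-recovery corpus
#'
#' Same document and prevalence structure as \code{\link{generate_corpus}}
#' but each label's templates carry disjoint high-signal content words, so
#' a linear bag-of-words cascade can reach near-perfect held-out
#' performance.  The fixture for cascade recovery tests.
#'
#' @param config a \code{\link{synth_config}}.
#' @param code_table ICD table supplying the severity code groups.
#' @return a \code{\link{bleedr_corpus}}.
#' @export
generate_separable_corpus <- function(config = synth_config(),
                                      code_table = default_code_table()) {
  generate_corpus(config, template_bank("separable"), code_table)
}

#' Class distribution of a labeled corpus
#'
#' Counts and percentages per label at sentence level (share of all
#' sentences) and document level (share of documents containing at least
#' one instance of the label; an irrelevant document is one with an empty
#' gold label set).
#'
#' @param corpus corpus with gold labels.
#' @return data.frame with columns \code{label}, \code{sentence_n},
#'   \code{sentence_pct}, \code{document_n}, \code{document_pct}
#'   (percentages rounded half-away to 2 decimals).
#' @export
corpus_summary <- function(corpus) {
  sent <- corpus_sentences(corpus)
  if (nrow(sent) == 0L || anyNA(sent$gold)) {
    stop("corpus lacks gold sentence labels", call. = FALSE)
  }
  gold_docs <- lapply(corpus$documents, function(d) d$gold_doc)
  if (any(vapply(gold_docs, is.null, logical(1)))) {
    stop("corpus lacks gold document labels", call. = FALSE)
  }
  n_sent <- nrow(sent)
  n_doc <- length(gold_docs)
  rows <- lapply(SENTENCE_LABELS, function(lab) {
    sn <- sum(sent$gold == lab)
    dn <- if (lab == "IRRELEVANT") {
      sum(vapply(gold_docs, function(s) length(s) == 0L, logical(1)))
    } else {
      sum(vapply(gold_docs, function(s) lab %in% s, logical(1)))
    }
    data.frame(label = lab, sentence_n = sn,
               sentence_pct = round_half_away(100 * sn / n_sent),
               document_n = dn,
               document_pct = round_half_away(100 * dn / n_doc),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
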