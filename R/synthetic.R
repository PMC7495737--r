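#' Specification of a synthetic triage corpus
#'
#' Describes a labeled title+abstract corpus with a planted, tunable class
#' signal: background tokens are drawn from a Zipf distribution over a
#' synthetic vocabulary, and signal keywords (stand-ins for strong
#' relevance cues such as "mutation" or "interaction") are inserted
#' per sentence with class-conditional rates. With
#' `signal_rate_pos > signal_rate_neg` the corpus is learnable; with equal
#' rates it is a null corpus carrying no signal.
#'
#' @param n_docs Number of documents.
#' @param positive_fraction Fraction labeled positive (exact before noise).
#' @param vocab_size Background vocabulary size.
#' @param signal_tokens Character vector of signal keywords.
#' @param signal_rate_pos,signal_rate_neg Per-sentence probability of
#'   planting a signal token in positive / negative documents.
#' @param sentences_per_doc,words_per_sentence Integer ranges
#'   (`c(min, max)`) sampled uniformly per document / sentence.
#' @param label_noise Probability of flipping each label, in `[0, 0.5)`.
#' @param seed Integer seed; the single source of randomness.
#' @return List of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_docs = 400L, positive_fraction = 0.5,
                           vocab_size = 100L,
                           signal_tokens = c("mutationx", "interactx",
                                             "bindx"),
                           signal_rate_pos = 0.8, signal_rate_neg = 0.05,
                           sentences_per_doc = c(4L, 8L),
                           words_per_sentence = c(4L, 10L),
                           label_noise = 0, seed = 1L) {
  spec <- list(n_docs = as.integer(n_docs),
               positive_fraction = positive_fraction,
               vocab_size = as.integer(vocab_size),
               signal_tokens = as.character(signal_tokens),
               signal_rate_pos = signal_rate_pos,
               signal_rate_neg = signal_rate_neg,
               sentences_per_doc = as.integer(sentences_per_doc),
               words_per_sentence = as.integer(words_per_sentence),
               label_noise = label_noise, seed = as.integer(seed))
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(spec$n_docs >= 1L, "n_docs must be >= 1")
  chk(spec$positive_fraction > 0 && spec$positive_fraction < 1,
      "positive_fraction must lie in (0, 1)")
  chk(spec$vocab_size >= 2L, "vocab_size must be >= 2")
  chk(length(spec$signal_tokens) >= 1L, "signal_tokens must be non-empty")
  chk(spec$signal_rate_pos >= 0 && spec$signal_rate_pos <= 1,
      "signal_rate_pos must lie in [0, 1]")
  chk(spec$signal_rate_neg >= 0 && spec$signal_rate_neg <= 1,
      "signal_rate_neg must lie in [0, 1]")
  chk(length(spec$sentences_per_doc) == 2L &&
        all(spec$sentences_per_doc >= 1L) &&
        spec$sentences_per_doc[1L] <= spec$sentences_per_doc[2L],
      "sentences_per_doc must be a positive c(min, max) range")
  chk(length(spec$words_per_sentence) == 2L &&
        all(spec$words_per_sentence >= 1L) &&
        spec$words_per_sentence[1L] <= spec$words_per_sentence[2L],
      "words_per_sentence must be a positive c(min, max) range")
  chk(spec$label_noise >= 0 && spec$label_noise < 0.5,
      "label_noise must lie in [0, 0.5)")
  if (length(problems))
    stop("invalid synthetic spec:\n  - ", paste(problems, collapse = "\n  - "))
  structure(spec, class = "synthetic_spec")
}

# Zipf(1) background distribution over w001..wNNN
zipf_probs <- function(vocab_size) {
  p <- 1 / seq_len(vocab_size)
  p / sum(p)
}

synth_sentence <- function(spec, plant_prob, background, probs,
                           extra_token = NULL, extra_prob = 0) {
  len <- sample(spec$words_per_sentence[1L]:spec$words_per_sentence[2L], 1L)
  toks <- sample(background, len, replace = TRUE, prob = probs)
  if (stats::runif(1L) < plant_prob) {
    sig <- sample(spec$signal_tokens, 1L)
    toks[sample.int(len, 1L)] <- sig
  }
  if (!is.null(extra_token) && stats::runif(1L) < extra_prob)
    toks[sample.int(len, 1L)] <- extra_token
  toks
}

synth_document <- function(spec, pmid, label, plant_prob, background, probs,
                           extra_token = NULL, extra_prob = 0) {
  n_sent <- sample(spec$sentences_per_doc[1L]:spec$sentences_per_doc[2L], 1L)
  sents <- vapply(seq_len(n_sent), function(s) {
    toks <- synth_sentence(spec, plant_prob, background, probs,
                           extra_token, extra_prob)
    # capitalize so the rule-based splitter recovers the boundary
    paste0(toupper(substr(toks[1L], 1L, 1L)),
           substr(toks[1L], 2L, nchar(toks[1L])),
           if (length(toks) > 1L) paste0(" ", paste(toks[-1L], collapse = " "))
           else "", ".")
  }, character(1))
  triage_document(pmid = pmid, title = sents[1L],
                  abstract = paste(utils::tail(sents, -1L), collapse = " "),
                  label = label)
}

#' Generate a labeled synthetic corpus
#'
#' Draws documents token-by-token from a Zipf background distribution,
#' plants signal keywords at the class-conditional per-sentence rates,
#' optionally flips labels with probability `label_noise`, and (when `dir`
#' is given) writes the same corpus in both corpus dialects plus a
#' ground-truth TSV, so both parsers are exercised on identical content.
#' Deterministic given `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Optional output directory; receives `corpus.json` (PM
#'   dialect), `corpus.xml` (BioCreative XML-like dialect) and `truth.tsv`.
#' @return List of [triage_document()] objects; label allocation is exact
#'   (`round(n_docs * positive_fraction)` positives before noise).
#' @export
generate_corpus <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  background <- sprintf("w%03d", seq_len(spec$vocab_size))
  probs <- zipf_probs(spec$vocab_size)
  n_pos <- round(spec$n_docs * spec$positive_fraction)
  labels <- sample(c(rep("positive", n_pos),
                     rep("negative", spec$n_docs - n_pos)))
  docs <- vector("list", spec$n_docs)
  for (i in seq_len(spec$n_docs)) {
    lab <- labels[i]
    rate <- if (lab == "positive") spec$signal_rate_pos else spec$signal_rate_neg
    if (spec$label_noise > 0 && stats::runif(1L) < spec$label_noise)
      lab <- if (lab == "positive") "negative" else "positive"
    docs[[i]] <- synth_document(spec, sprintf("SYN%05d", i), lab, rate,
                                background, probs)
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_pm_json(docs, file.path(dir, "corpus.json"))
    write_bc_xml(docs, file.path(dir, "corpus.xml"))
    write_corpus_tsv(docs, file.path(dir, "truth.tsv"))
  }
  docs
}

#' Generate hard negative documents
#'
#' Negatives that mimic the positive class — signal keywords planted at the
#' positive rate — while carrying a subtler distinguishing cue: a
#' suppressor token (`"noeffectx"`) planted in most sentences. A classifier
#' that only detects signal-keyword presence mistakes these for positives,
#' mirroring the characteristic false-positive errors on documents that
#' mention strong relevance keywords without describing the relevant
#' relation.
#'
#' @param spec A [synthetic_spec()].
#' @param n Number of hard negatives (default `spec$n_docs`).
#' @param suppressor_token The distinguishing token.
#' @param suppressor_rate Per-sentence planting probability.
#' @return List of [triage_document()], all labeled negative and each
#'   containing at least one signal token.
#' @export
generate_hard_negatives <- function(spec, n = spec$n_docs,
                                    suppressor_token = "noeffectx",
                                    suppressor_rate = 0.9) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1L)
  background <- sprintf("w%03d", seq_len(spec$vocab_size))
  probs <- zipf_probs(spec$vocab_size)
  docs <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      d <- synth_document(spec, sprintf("HRD%05d", i), "negative",
                          spec$signal_rate_pos, background, probs,
                          extra_token = suppressor_token,
                          extra_prob = suppressor_rate)
      has_signal <- any(vapply(spec$signal_tokens, grepl, logical(1),
                               x = doc_text(d), fixed = TRUE))
      if (has_signal) break
    }
    docs[[i]] <- d
  }
  docs
}
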