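#' Construct a triage document
#'
#' A document is one labeled title+abstract record identified by its PMID
#' (PubMed unique identifier). Records whose title and abstract are both
#' empty after cleaning are rejected: there is nothing to classify.
#'
#' @param pmid Non-empty character scalar, the PubMed identifier.
#' @param title Character scalar, may be empty.
#' @param abstract Character scalar, may be empty.
#' @param label One of `"positive"`, `"negative"`, `"unlabeled"`.
#' @return An object of class `"triage_document"`.
#' @export
triage_document <- function(pmid, title = "", abstract = "",
                            label = c("unlabeled", "positive", "negative")) {
  label <- match.arg(label)
  if (!is.character(pmid) || length(pmid) != 1L || is.na(pmid) || !nzchar(pmid))
    stop("pmid must be a non-empty character scalar")
  title <- if (is.null(title) || length(title) == 0L || is.na(title[1L])) "" else as.character(title[1L])
  abstract <- if (is.null(abstract) || length(abstract) == 0L || is.na(abstract[1L])) "" else as.character(abstract[1L])
  if (!nzchar(clean_text(title)) && !nzchar(clean_text(abstract)))
    stop("document ", pmid, " has no text after cleaning")
  structure(list(pmid = pmid, title = title, abstract = abstract, label = label),
            class = "triage_document")
}

#' @export
print.triage_document <- function(x, ...) {
  cat(sprintf("<triage_document %s [%s]> %s\n", x$pmid, x$label,
              substr(doc_text(x), 1L, 60L)))
  invisible(x)
}

#' Full text of a document
#'
#' Title and abstract concatenated in corpus order, separated by a single
#' space; empty parts contribute nothing.
#'
#' @param doc A `triage_document`.
#' @return Character scalar.
#' @export
doc_text <- function(doc) {
  parts <- c(doc$title, doc$abstract)
  paste(parts[nzchar(parts)], collapse = " ")
}

# numeric class encoding used throughout: negative = 0, positive = 1
label_to_int <- function(label) {
  v <- c(negative = 0L, positive = 1L, unlabeled = NA_integer_)[label]
  unname(v)
}

#' Parse a PM-dialect JSON corpus file
#'
#' Reads the BioCreative VI Precision Medicine JSON dialect: an array of
#' article records (or an object with a `documents` array), each carrying an
#' `id` (the PMID), a relevance marker `relevant` with value `"yes"` or
#' `"no"` (either at top level or inside the record's `infons`), and a list
#' of `passages` whose `infons$type` distinguishes title from abstract text.
#'
#' @param path Path to the JSON file.
#' @return A list of [triage_document()] objects. Records without an `id`,
#'   or with no text after cleaning, are skipped with a warning.
#' @export
parse_pm_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  parsed <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed JSON in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  records <- if (!is.null(parsed$documents)) parsed$documents else parsed
  if (length(records) == 0L) return(list())
  out <- vector("list", length(records))
  kept <- 0L
  for (rec in records) {
    pmid <- rec$id
    if (is.null(pmid) || !nzchar(as.character(pmid)[1L])) {
      warning("skipping record with missing 'id' in ", path, call. = FALSE)
      next
    }
    pmid <- as.character(pmid)[1L]
    relevant <- rec$relevant
    if (is.null(relevant) && !is.null(rec$infons)) relevant <- rec$infons$relevant
    label <- if (is.null(relevant)) "unlabeled"
             else if (identical(tolower(as.character(relevant)), "yes")) "positive"
             else if (identical(tolower(as.character(relevant)), "no")) "negative"
             else "unlabeled"
    title <- character(0)
    abstract <- character(0)
    for (p in rec$passages) {
      type <- tolower(as.character(p$infons$type %||% ""))
      txt <- as.character(p$text %||% "")
      if (identical(type, "title")) title <- c(title, txt)
      else abstract <- c(abstract, txt)
    }
    doc <- tryCatch(
      triage_document(pmid,
                      paste(title, collapse = " "),
                      paste(abstract, collapse = " "),
                      label),
      error = function(e) {
        warning("skipping record ", pmid, ": ", conditionMessage(e), call. = FALSE)
        NULL
      })
    if (!is.null(doc)) { kept <- kept + 1L; out[[kept]] <- doc }
  }
  out[seq_len(kept)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse a BioCreative XML-like corpus file (IAS/ACT dialect)
#'
#' Each record element carries PMID, title and abstract in their labeled
#' child elements, and the class under `CURATIONRELEVANCE` (values such as
#' POSITIVE/NEGATIVE, RELEVANT/NOT-RELEVANT, yes/no are recognized
#' case-insensitively).
#'
#' @param path Path to the XML file.
#' @return A list of [triage_document()] objects. A record whose relevance
#'   value is unrecognized is kept as unlabeled, with a warning listing the
#'   offending value.
#' @export
parse_bc_xml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  xml <- tryCatch(
    xml2::read_xml(path),
    error = function(e) stop("malformed XML in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  recs <- xml2::xml_find_all(xml, ".//document | .//DOCUMENT | .//record")
  out <- list()
  for (rec in recs) {
    grab <- function(tag) {
      node <- xml2::xml_find_first(rec, paste0("./", tag, " | ./",
                                               tolower(tag), " | ./", toupper(tag)))
      if (inherits(node, "xml_missing")) "" else trimws(xml2::xml_text(node))
    }
    pmid <- grab("PMID")
    if (!nzchar(pmid)) pmid <- grab("ID")
    if (!nzchar(pmid)) {
      warning("skipping record with missing PMID in ", path, call. = FALSE)
      next
    }
    relev <- grab("CURATIONRELEVANCE")
    label <-
      if (!nzchar(relev)) "unlabeled"
      else if (grepl("^(positive|relevant|curatable|yes|true)$", relev, ignore.case = TRUE)) "positive"
      else if (grepl("^(negative|not[- _]?relevant|no|false)$", relev, ignore.case = TRUE)) "negative"
      else {
        warning("record ", pmid, ": unknown CURATIONRELEVANCE value '", relev,
                "'; kept as unlabeled", call. = FALSE)
        "unlabeled"
      }
    doc <- tryCatch(
      triage_document(pmid, grab("TITLE"), grab("ABSTRACT"), label),
      error = function(e) {
        warning("skipping record ", pmid, ": ", conditionMessage(e), call. = FALSE)
        NULL
      })
    if (!is.null(doc)) out[[length(out) + 1L]] <- doc
  }
  out
}

#' Clean text down to the alphanumeric alphabet
#'
#' Every character other than letters, digits and spaces is replaced by a
#' space; runs of spaces are collapsed and the result trimmed. Sentence
#' splitting, when wanted, must happen before this (see
#' [split_and_tokenize()]), because the boundary punctuation is removed.
#'
#' @param raw Character vector.
#' @return Character vector of the same length; elements may become `""`.
#' @export
clean_text <- function(raw) {
  x <- gsub("[^A-Za-z0-9 ]", " ", raw)
  x <- gsub(" +", " ", x)
  trimws(x)
}

#' Split a document into sentences and tokens
#'
#' Sentence boundaries are found on the raw text (a `.`, `?` or `!` followed
#' by whitespace and a capital letter or digit) before punctuation removal.
#' Each sentence is then cleaned with [clean_text()], lowercased and split
#' on whitespace. Sentences with fewer than `min_tokens` tokens are dropped
#' as noise; sentences beyond `max_sentences` and tokens beyond `max_words`
#' are truncated from the end.
#'
#' @param doc A [triage_document()].
#' @param max_sentences,max_words Truncation limits (defaults 30 and 50).
#' @param min_tokens Minimum tokens for a sentence to survive (default 2).
#' @return A list of class `"tokenized_document"` with fields `pmid`,
#'   `sentences` (list of character vectors) and `label`. Errors if no
#'   sentence survives; callers drop such records.
#' @export
split_and_tokenize <- function(doc, max_sentences = 30L, max_words = 50L,
                               min_tokens = 2L) {
  text <- doc_text(doc)
  pieces <- strsplit(text, "(?<=[.?!])\\s+(?=[A-Z0-9])", perl = TRUE)[[1L]]
  sentences <- list()
  for (s in pieces) {
    toks <- strsplit(tolower(clean_text(s)), " ", fixed = TRUE)[[1L]]
    toks <- toks[nzchar(toks)]
    if (length(toks) >= min_tokens)
      sentences[[length(sentences) + 1L]] <- utils::head(toks, max_words)
  }
  if (length(sentences) == 0L)
    stop("document ", doc$pmid, " has no sentence with >= ", min_tokens,
         " tokens after cleaning")
  sentences <- utils::head(sentences, max_sentences)
  structure(list(pmid = doc$pmid, sentences = sentences, label = doc$label),
            class = "tokenized_document")
}

#' Tokenize a corpus, dropping empty records
#'
#' Applies [split_and_tokenize()] to each document; records with no
#' surviving sentence are dropped with a warning, mirroring the removal of
#' empty-text data points during preprocessing.
#'
#' @inheritParams split_and_tokenize
#' @param docs List of [triage_document()].
#' @return List of `tokenized_document`.
#' @export
tokenize_corpus <- function(docs, max_sentences = 30L, max_words = 50L,
                            min_tokens = 2L) {
  out <- list()
  for (doc in docs) {
    td <- tryCatch(split_and_tokenize(doc, max_sentences, max_words, min_tokens),
                   error = function(e) {
                     warning(conditionMessage(e), call. = FALSE)
                     NULL
                   })
    if (!is.null(td)) out[[length(out) + 1L]] <- td
  }
  out
}

PAD_TOKEN <- "<PAD/>"
OOV_TOKEN <- "<UNK/>"

#' Build a vocabulary from a tokenized corpus
#'
#' Index 0 is reserved for the pad token `<PAD/>`, index 1 for
#' out-of-vocabulary. Remaining tokens with frequency at least `min_count`
#' are indexed from 2 in deterministic order: frequency descending, ties
#' broken lexicographically.
#'
#' @param corpus Non-empty list of `tokenized_document`.
#' @param min_count Minimum corpus frequency (default 1).
#' @return Named integer vector of class `"triage_vocabulary"` mapping token
#'   to 0-based index.
#' @export
build_vocabulary <- function(corpus, min_count = 1L) {
  if (length(corpus) == 0L) stop("cannot build a vocabulary from an empty corpus")
  tokens <- unlist(lapply(corpus, function(d) unlist(d$sentences, use.names = FALSE)),
                   use.names = FALSE)
  tab <- table(tokens)
  tab <- tab[tab >= min_count]
  ord <- order(-as.integer(tab), names(tab), method = "radix")
  keep <- names(tab)[ord]
  idx <- c(0L, 1L, seq_along(keep) + 1L)
  names(idx) <- c(PAD_TOKEN, OOV_TOKEN, keep)
  structure(idx, class = "triage_vocabulary")
}

#' @export
print.triage_vocabulary <- function(x, ...) {
  cat(sprintf("<triage_vocabulary> %d tokens (incl. %s=0, %s=1)\n",
              length(x), PAD_TOKEN, OOV_TOKEN))
  invisible(x)
}

vocab_lookup <- function(vocab, tokens) {
  idx <- unname(vocab[tokens])
  idx[is.na(idx)] <- 1L  # out-of-vocabulary
  as.integer(idx)
}

#' Index a tokenized corpus into a padded grid
#'
#' Produces the `[n_docs x max_sentences x max_words]` integer grid consumed
#' by the model: token indices left-aligned, pad id 0 elsewhere, with a
#' logical mask marking the real-token positions and an integer label vector
#' (negative = 0, positive = 1, `NA` for unlabeled).
#'
#' @param docs List of `tokenized_document`, pre-truncated to the limits.
#' @param vocab A `triage_vocabulary`.
#' @param max_sentences,max_words Grid dimensions.
#' @return A list of class `"indexed_batch"` with fields `ids`, `mask`
#'   (arrays `[n, S, W]`), `labels`, `pmids`.
#' @export
index_batch <- function(docs, vocab, max_sentences = 30L, max_words = 50L) {
  n <- length(docs)
  ids <- array(0L, dim = c(n, max_sentences, max_words))
  mask <- array(FALSE, dim = c(n, max_sentences, max_words))
  labels <- integer(n)
  pmids <- character(n)
  for (i in seq_len(n)) {
    d <- docs[[i]]
    if (length(d$sentences) > max_sentences)
      stop("document ", d$pmid, " exceeds max_sentences; truncate first")
    for (s in seq_along(d$sentences)) {
      toks <- d$sentences[[s]]
      if (length(toks) > max_words)
        stop("document ", d$pmid, " exceeds max_words; truncate first")
      ids[i, s, seq_along(toks)] <- vocab_lookup(vocab, toks)
      mask[i, s, seq_along(toks)] <- TRUE
    }
    labels[i] <- label_to_int(d$label)
    pmids[i] <- d$pmid
  }
  structure(list(ids = ids, mask = mask, labels = labels, pmids = pmids),
            class = "indexed_batch")
}

#' Recover token lists from an indexed batch
#'
#' Inverse of [index_batch()] up to the out-of-vocabulary collapse: every
#' unmasked position is dropped, and each surviving id is mapped back
#' through the vocabulary.
#'
#' @param batch An `indexed_batch`.
#' @param vocab The `triage_vocabulary` used to build it.
#' @return List (per document) of lists of character vectors.
#' @export
deindex_batch <- function(batch, vocab) {
  rev_map <- names(vocab)[order(unname(vocab))]
  lapply(seq_len(dim(batch$ids)[1L]), function(i) {
    sents <- list()
    for (s in seq_len(dim(batch$ids)[2L])) {
      m <- batch$mask[i, s, ]
      if (!any(m)) next
      sents[[length(sents) + 1L]] <- rev_map[batch$ids[i, s, m] + 1L]
    }
    sents
  })
}

#' Load word vectors in word2vec text format
#'
#' The file starts with a `"<vocab> <dim>"` header followed by one
#' whitespace-separated `token v1 ... v<dim>` line per word. Rows for
#' vocabulary tokens present in the file are copied; the pad row is all
#' zeros; out-of-vocabulary and missing tokens are drawn uniformly from
#' `[-0.05, 0.05]` under `seed`.
#'
#' @param path Path to the embedding file.
#' @param vocab A `triage_vocabulary`.
#' @param dim Expected vector dimension; must match the file header.
#' @param seed Integer seed for the random rows.
#' @return Numeric matrix `[V x dim]`, rows ordered by vocabulary index.
#' @export
load_pretrained_embeddings <- function(path, vocab, dim, seed = 1L) {
  if (!file.exists(path))
    stop("embedding file not found: ", path,
         "; use random initialization (captriage() with embeddings = NULL)")
  con <- file(path, "r")
  on.exit(close(con))
  header <- scan(con, what = integer(), n = 2L, quiet = TRUE)
  if (length(header) != 2L || header[2L] != dim)
    stop("embedding header dimension ", header[2L], " does not match dim = ", dim)
  V <- length(vocab)
  set.seed(seed)
  E <- matrix(stats::runif(V * dim, -0.05, 0.05), nrow = V)
  E[1L, ] <- 0  # pad row
  filled <- logical(V)
  for (i in seq_len(header[1L])) {
    fields <- scan(con, what = character(), n = dim + 1L, quiet = TRUE)
    if (length(fields) < dim + 1L) break
    tok <- fields[1L]
    j <- unname(vocab[tok])
    if (!is.na(j) && j >= 2L) {
      E[j + 1L, ] <- as.numeric(fields[-1L])
      filled[j + 1L] <- TRUE
    }
  }
  rownames(E) <- names(vocab)[order(unname(vocab))]
  E
}

#' Write a corpus as canonical TSV
#'
#' Three columns — pmid, label, text (title and abstract joined) — for
#' inspection and as the ground-truth file of the synthetic generator.
#'
#' @param docs List of [triage_document()].
#' @param path Output path.
#' @export
write_corpus_tsv <- function(docs, path) {
  df <- data.frame(pmid = vapply(docs, `[[`, "", "pmid"),
                   label = vapply(docs, `[[`, "", "label"),
                   text = vapply(docs, doc_text, ""),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write documents in the PM JSON dialect
#'
#' @param docs List of [triage_document()].
#' @param path Output path.
#' @export
write_pm_json <- function(docs, path) {
  records <- lapply(docs, function(d) {
    rec <- list(id = d$pmid,
                passages = list(
                  list(infons = list(type = "title"), text = d$title),
                  list(infons = list(type = "abstract"), text = d$abstract)))
    if (d$label != "unlabeled")
      rec$relevant <- if (d$label == "positive") "yes" else "no"
    rec
  })
  jsonlite::write_json(list(documents = records), path,
                       auto_unbox = TRUE, pretty = FALSE)
  invisible(path)
}

#' Write documents in the BioCreative XML-like dialect
#'
#' @param docs List of [triage_document()].
#' @param path Output path.
#' @export
write_bc_xml <- function(docs, path) {
  root <- xml2::xml_new_root("documents")
  for (d in docs) {
    node <- xml2::xml_add_child(root, "document")
    xml2::xml_add_child(node, "PMID", d$pmid)
    if (d$label != "unlabeled")
      xml2::xml_add_child(node, "CURATIONRELEVANCE",
                          if (d$label == "positive") "POSITIVE" else "NEGATIVE")
    xml2::xml_add_child(node, "TITLE", d$title)
    xml2::xml_add_child(node, "ABSTRACT", d$abstract)
  }
  xml2::write_xml(root, path)
  invisible(path)
}
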