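test_that("clean_text keeps only letters, digits and single spaces", {
  expect_equal(clean_text("p53-mediated (PPI)!"), "p53 mediated PPI")
  expect_equal(clean_text(""), "")
  expect_equal(clean_text("ABC123"), "ABC123")
  # idempotence on assorted inputs
  raw <- c("a,b;c", "  spaced   out  ", "MeCP2/FOXG1 (OMIM #613454)?!", "")
  expect_equal(clean_text(clean_text(raw)), clean_text(raw))
})

test_that("PM JSON parsing maps labels, pmids and passages", {
  path <- write_pm_fixture(tempfile(fileext = ".json"))
  docs <- parse_pm_json(path)
  expect_length(docs, 3L)
  expect_equal(docs[[1]]$pmid, "9685346")
  expect_equal(docs[[1]]$label, "negative")
  expect_equal(docs[[2]]$label, "positive")
  expect_equal(docs[[3]]$label, "unlabeled")
  expect_match(docs[[1]]$title, "^Protein X")
  expect_match(docs[[1]]$abstract, "mutation")

  empty <- tempfile(fileext = ".json")
  writeLines("[]", empty)
  expect_equal(parse_pm_json(empty), list())

  bad <- tempfile(fileext = ".json")
  writeLines('{"documents": [ {"id": ', bad)
  expect_error(parse_pm_json(bad), "malformed JSON")

  noid <- tempfile(fileext = ".json")
  writeLines('[{"relevant":"no","passages":[{"infons":{"type":"title"},"text":"T."}]}]',
             noid)
  expect_warning(d <- parse_pm_json(noid), "missing 'id'")
  expect_length(d, 0L)
})

test_that("BioCreative XML parsing reads CURATIONRELEVANCE and keeps partial text", {
  path <- write_bc_fixture(tempfile(fileext = ".xml"))
  docs <- parse_bc_xml(path)
  expect_length(docs, 2L)
  expect_equal(docs[[1]]$label, "positive")
  expect_equal(docs[[1]]$pmid, "111")
  # empty abstract with non-empty title is retained
  expect_equal(docs[[2]]$label, "negative")
  expect_equal(docs[[2]]$abstract, "")

  bad <- tempfile(fileext = ".xml")
  writeLines("<documents><document></documents>", bad)
  expect_error(parse_bc_xml(bad), "malformed XML")

  odd <- tempfile(fileext = ".xml")
  writeLines("<documents><document><PMID>9</PMID>
    <CURATIONRELEVANCE>MAYBE</CURATIONRELEVANCE>
    <TITLE>Some title text.</TITLE><ABSTRACT>More text.</ABSTRACT>
    </document></documents>", odd)
  expect_warning(d <- parse_bc_xml(odd), "MAYBE")
  expect_equal(d[[1]]$label, "unlabeled")
})

test_that("sentence splitting happens before cleaning, with truncation", {
  doc <- triage_document("1", "A binds B.", "C mutates.", "positive")
  tok <- split_and_tokenize(doc, min_tokens = 1L)
  expect_equal(tok$sentences, list(c("a", "binds", "b"), c("c", "mutates")))

  single <- triage_document("2", "Hello", "", "negative")
  tok1 <- split_and_tokenize(single, min_tokens = 1L)
  expect_equal(tok1$sentences, list("hello"))
  # the default noise filter drops sub-minimal sentences
  expect_error(split_and_tokenize(single), "no sentence")

  three <- triage_document("3", "One two. Three four. Five six.", "", "positive")
  expect_length(split_and_tokenize(three, max_sentences = 1L)$sentences, 1L)
  expect_equal(split_and_tokenize(three, max_words = 1L,
                                  min_tokens = 1L)$sentences[[1]], "one")
})

test_that("vocabulary ordering is frequency-desc then lexicographic, reserved ids fixed", {
  tok <- structure(list(pmid = "1", sentences = list(c("a", "b", "a")),
                        label = "positive"), class = "tokenized_document")
  v <- build_vocabulary(list(tok))
  expect_equal(unname(v[c("<PAD/>", "<UNK/>", "a", "b")]), 0:3)
  # determinism and injectivity
  v2 <- build_vocabulary(list(tok))
  expect_identical(v, v2)
  expect_equal(anyDuplicated(unname(v)), 0L)
  # min_count above all frequencies leaves only the reserved tokens
  expect_length(build_vocabulary(list(tok), min_count = 10L), 2L)
  expect_error(build_vocabulary(list()), "empty corpus")
})

test_that("index_batch pads, masks and round-trips", {
  tok <- structure(list(pmid = "1", sentences = list("a"), label = "positive"),
                   class = "tokenized_document")
  v <- build_vocabulary(list(structure(list(
    pmid = "0", sentences = list(c("a", "b", "a")), label = "positive"),
    class = "tokenized_document")))
  b <- index_batch(list(tok), v, max_sentences = 2L, max_words = 3L)
  expect_equal(b$ids[1, , ], matrix(c(2L, 0L, 0L, 0L, 0L, 0L), 2L, byrow = TRUE))
  expect_equal(b$mask[1, 2, ], rep(FALSE, 3L))
  expect_equal(b$labels, 1L)

  # mask count equals token count; de-indexing recovers the token lists
  corpus <- tokenize_corpus(toy_docs(), min_tokens = 1L)
  vb <- build_vocabulary(corpus)
  bb <- index_batch(corpus, vb, 10L, 12L)
  for (i in seq_along(corpus)) {
    expect_equal(sum(bb$mask[i, , ]),
                 length(unlist(corpus[[i]]$sentences)))
  }
  expect_equal(deindex_batch(bb, vb),
               lapply(corpus, `[[`, "sentences"))

  # unknown tokens map to the reserved OOV index
  tok_oov <- structure(list(pmid = "9", sentences = list(c("zzz", "a")),
                            label = "negative"), class = "tokenized_document")
  b2 <- index_batch(list(tok_oov), v, 1L, 2L)
  expect_equal(b2$ids[1, 1, ], c(1L, 2L))

  too_long <- structure(list(pmid = "8", sentences = list(letters[1:5]),
                             label = "negative"), class = "tokenized_document")
  expect_error(index_batch(list(too_long), v, 1L, 3L), "max_words")
})

test_that("word2vec text embeddings load with pad/OOV conventions", {
  v <- toy_vocab()
  path <- tempfile()
  writeLines(c("2 4", "a 1 2 3 4", "c -1 0 0.5 2"), path)
  E <- load_pretrained_embeddings(path, v, 4L, seed = 9L)
  expect_equal(dim(E), c(length(v), 4L))
  expect_equal(E["a", ], c(1, 2, 3, 4))
  expect_equal(E["c", ], c(-1, 0, 0.5, 2))
  expect_equal(E["<PAD/>", ], rep(0, 4L))
  # missing tokens drawn uniformly in [-0.05, 0.05], reproducibly
  expect_true(all(abs(E["b", ]) <= 0.05))
  E2 <- load_pretrained_embeddings(path, v, 4L, seed = 9L)
  expect_identical(E, E2)
  expect_error(load_pretrained_embeddings(path, v, 5L), "dimension")
  expect_error(load_pretrained_embeddings(tempfile(), v, 4L),
               "random initialization")
})

test_that("serialize-then-parse is the identity on documents, twice over", {
  docs <- toy_docs()
  jp <- tempfile(fileext = ".json")
  xp <- tempfile(fileext = ".xml")
  write_pm_json(docs, jp)
  write_bc_xml(docs, xp)
  back_j <- parse_pm_json(jp)
  back_x <- parse_bc_xml(xp)
  strip <- function(ds) lapply(ds, function(d) d[c("pmid", "title", "abstract", "label")])
  expect_equal(strip(back_j), strip(docs))
  expect_equal(strip(back_x), strip(docs))
  # idempotence: a second serialize-parse cycle changes nothing
  write_pm_json(back_j, jp)
  expect_equal(strip(parse_pm_json(jp)), strip(docs))
})
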