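# shared fixtures, all built in code at test time

toy_vocab <- function(tokens = letters[1:6]) {
  idx <- c(stats::setNames(0:1, c("<PAD/>", "<UNK/>")),
           stats::setNames(seq_along(tokens) + 1L, tokens))
  structure(idx, class = "triage_vocabulary")
}

toy_docs <- function() {
  list(
    triage_document("1001", "Kinase A binds partner B strongly.",
                    "A missense mutation disrupts the interaction. The complex fails to form.",
                    "positive"),
    triage_document("1002", "Survey of plant genomes.",
                    "We sequenced several genomes. No interactions were assayed.",
                    "negative"))
}

# deterministic micro model used by gradient and forward tests
micro_config <- function(...) {
  defaults <- list(embed_dim = 3L, hidden = 3L, batch_size = 2L, epochs = 1L,
                   dropout_input = 0, dropout_output = 0,
                   conv_windows = 2L, conv_maps = 4L,
                   word_heads = 1L, word_dim = 2L, sent_heads = 1L,
                   sent_dim = 2L, caps_dim = 2L, parent_caps = 2L,
                   parent_dim = 2L, routing_iters = 1L, max_sentences = 4L,
                   max_words = 4L, seed = 5L)
  do.call(triage_config, utils::modifyList(defaults, list(...)))
}

micro_fixture <- function(cfg = micro_config()) {
  vocab <- toy_vocab()
  set.seed(11)
  params <- captriage:::init_params(cfg, vocab)
  # keep every ReLU away from its kink so central differences are valid
  params$b1 <- params$b1 + 0.2
  for (k in seq_along(params$conv$kernels))
    params$conv$kernels[[k]]$b <- params$conv$kernels[[k]]$b + 0.1
  list(cfg = cfg, vocab = vocab, params = params,
       doc_ids = list(list(c(3L, 4L, 5L), c(6L, 7L)),
                      list(c(8L, 3L), c(4L, 6L, 8L))),
       labels = c(1L, 0L))
}

write_pm_fixture <- function(path) {
  writeLines('{"documents":[
    {"id":"9685346","relevant":"no","passages":[
      {"infons":{"type":"title"},"text":"Protein X interacts with Y."},
      {"infons":{"type":"abstract"},"text":"A mutation was found. No effect on the interaction was seen."}]},
    {"id":"1234","relevant":"yes","passages":[
      {"infons":{"type":"title"},"text":"Mutation disrupts binding."},
      {"infons":{"type":"abstract"},"text":"The variant abolished complex formation."}]},
    {"id":"5678","passages":[
      {"infons":{"type":"title"},"text":"An unlabeled record."},
      {"infons":{"type":"abstract"},"text":"It has no relevance marker."}]}
  ]}', path)
  path
}

write_bc_fixture <- function(path) {
  writeLines('<documents>
  <document>
    <PMID>111</PMID>
    <CURATIONRELEVANCE>POSITIVE</CURATIONRELEVANCE>
    <TITLE>Complex formation is mutation sensitive.</TITLE>
    <ABSTRACT>Binding assays show loss of interaction.</ABSTRACT>
  </document>
  <document>
    <PMID>222</PMID>
    <CURATIONRELEVANCE>NEGATIVE</CURATIONRELEVANCE>
    <TITLE>A title without an abstract.</TITLE>
    <ABSTRACT></ABSTRACT>
  </document>
</documents>', path)
  path
}
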