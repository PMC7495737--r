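test_that("config validation enforces geometry and ranges", {
  expect_error(triage_config(conv_windows = 3L, conv_maps = 10L,
                             caps_dim = 32L), "divisible")
  expect_error(triage_config(dropout_input = 1.2))
  expect_s3_class(triage_config_small(), "triage_config")
  expect_equal(triage_config()$conv_windows, c(3L, 4L, 5L))
  expect_equal(triage_config()$epochs, 50L)
  expect_equal(triage_config()$batch_size, 128L)
  expect_equal(triage_config()$learning_rate, 0.01)
})

test_that("ablation harness builds all five architectures from one schema", {
  archs <- c("cnn", "capsule", "selfatt", "hieratt", "full")
  cfgs <- lapply(archs, ablation_config, base = triage_config_small())
  names(cfgs) <- archs
  expect_equal(cfgs$cnn$attention, "none")
  expect_equal(cfgs$cnn$head, "maxpool")
  expect_equal(cfgs$cnn$conv_windows, c(3L, 8L))
  expect_equal(cfgs$capsule$head, "capsule")
  expect_equal(cfgs$selfatt$attention, "word")
  expect_equal(cfgs$hieratt$attention, "hierarchical")
  expect_equal(cfgs$hieratt$head, "maxpool")
  expect_equal(cfgs$full$attention, "hierarchical")
  expect_equal(cfgs$full$head, "capsule")
  for (cfg in cfgs) expect_s3_class(cfg, "triage_config")
  # every variant can be fitted and produces valid probabilities
  docs <- toy_docs()
  for (arch in c("cnn", "selfatt")) {
    cfg <- ablation_config(arch, triage_config_small(epochs = 1L,
                                                     conv_windows = c(2L, 3L)))
    m <- captriage(docs, cfg)
    P <- predict(m, docs, type = "prob")
    expect_equal(unname(rowSums(P)), rep(1, 2), tolerance = 1e-12)
  }
})

test_that("forward probabilities are rows of a stochastic matrix, stable across batching", {
  docs <- toy_docs()
  cfg <- micro_config()
  m <- captriage(docs, cfg)
  toks <- tokenize_corpus(docs, cfg$max_sentences, cfg$max_words, 1L)
  batch <- index_batch(toks, m$state$vocab, cfg$max_sentences, cfg$max_words)
  P <- triage_forward(batch, m)
  expect_equal(unname(rowSums(P)), rep(1, 2), tolerance = 1e-12)
  expect_true(all(is.finite(P)))
  # eval-mode determinism
  expect_identical(P, triage_forward(batch, m))
  # partition invariance: one-document batches give identical rows
  for (i in 1:2) {
    bi <- index_batch(toks[i], m$state$vocab, cfg$max_sentences, cfg$max_words)
    expect_equal(unname(triage_forward(bi, m)), unname(P[i, , drop = FALSE]),
                 tolerance = 1e-14)
  }
  # a one-token document still yields finite probabilities
  one <- structure(list(pmid = "z", sentences = list("kinase"),
                        label = "unlabeled"), class = "tokenized_document")
  b1 <- index_batch(list(one), m$state$vocab, cfg$max_sentences, cfg$max_words)
  expect_true(all(is.finite(triage_forward(b1, m))))
})

test_that("training is reproducible and rejects unusable corpora", {
  docs <- toy_docs()
  cfg <- micro_config(epochs = 3L, dropout_input = 0.2, dropout_output = 0.2)
  m1 <- captriage(docs, cfg)
  m2 <- captriage(docs, cfg)
  expect_identical(m1$history$train_loss, m2$history$train_loss)
  expect_identical(m1$state$params, m2$state$params)

  unl <- c(docs, list(triage_document("77", "Some unlabeled title here.",
                                      "", "unlabeled")))
  expect_error(captriage(unl, cfg), "unlabeled")
  expect_error(captriage(list(), cfg), "no usable documents")
})

test_that("zero learning rate leaves every parameter unchanged", {
  docs <- toy_docs()
  cfg <- micro_config(epochs = 2L, learning_rate = 0)
  m <- captriage(docs, cfg)
  set.seed(cfg$seed)
  toks <- tokenize_corpus(docs, cfg$max_sentences, cfg$max_words, cfg$min_tokens)
  vocab <- build_vocabulary(toks, cfg$min_count)
  init <- captriage:::init_params(cfg, vocab)
  expect_equal(m$state$params$E, init$E, tolerance = 1e-14)
  expect_equal(m$state$params$W1, init$W1, tolerance = 1e-14)
  expect_equal(m$state$params$caps$W, init$caps$W, tolerance = 1e-14)
})

test_that("checkpoints round-trip bit-identically in eval mode", {
  docs <- toy_docs()
  m <- captriage(docs, micro_config())
  path <- tempfile(fileext = ".ckpt")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(m$state, m2$state)
  P1 <- predict(m, docs, type = "prob")
  P2 <- predict(m2, docs, type = "prob")
  expect_identical(P1, P2)
  saveRDS(list(format = "other"), path)
  expect_error(load_checkpoint(path), "not a captriage checkpoint")
  # training log round-trips as one JSON record per epoch
  lg <- tempfile(fileext = ".jsonl")
  write_training_log(m, lg)
  lines <- readLines(lg)
  expect_length(lines, nrow(m$history))
  expect_equal(jsonlite::fromJSON(lines[1])$epoch, 1L)
})

test_that("prediction reports argmax labels with exact ties going negative", {
  docs <- toy_docs()
  m <- captriage(docs, micro_config())
  pred <- predict(m, docs)
  expect_named(pred, c("pmid", "label", "prob", "prob_positive"))
  expect_true(all(pred$prob >= 0.5))
  # force an exact tie through a zeroed output layer
  m0 <- m
  m0$state$params$W2[] <- 0
  m0$state$params$b2[] <- 0
  tied <- predict(m0, docs)
  expect_equal(unique(tied$label), "negative")
  expect_equal(tied$prob, rep(0.5, 2))
})

test_that("analytic gradients match central differences on the micro model", {
  fx <- micro_fixture()
  lg <- captriage:::batch_loss_grads(fx$params, fx$cfg, fx$doc_ids, fx$labels,
                                     train = FALSE)
  ga <- captriage:::flatten_nested(lg$grads)
  gn <- captriage:::numeric_gradient(fx$params, fx$cfg, fx$doc_ids, fx$labels)
  rel <- sqrt(sum((ga - gn)^2)) / sqrt(sum(gn^2))
  expect_lt(rel, 1e-4)
  # and per parameter block, none hides a large error
  expect_lt(max(abs(ga - gn)), 1e-6)
})

test_that("maxpool-head gradients are also exact", {
  cfg <- micro_config(head = "maxpool", attention = "word")
  fx <- micro_fixture(cfg)
  lg <- captriage:::batch_loss_grads(fx$params, fx$cfg, fx$doc_ids, fx$labels,
                                     train = FALSE)
  ga <- captriage:::flatten_nested(lg$grads)
  gn <- captriage:::numeric_gradient(fx$params, fx$cfg, fx$doc_ids, fx$labels)
  expect_lt(sqrt(sum((ga - gn)^2)) / sqrt(sum(gn^2)), 1e-4)
})

test_that("epoch selection modes expose final or best-dev parameters", {
  spec <- synthetic_spec(n_docs = 60L, seed = 31L)
  docs <- generate_corpus(spec)
  cfg_f <- triage_config_small(epochs = 3L, seed = 32L)
  cfg_b <- triage_config_small(epochs = 3L, seed = 32L, select = "best_dev")
  mf <- captriage(docs, cfg_f)
  mb <- captriage(docs, cfg_b)
  expect_equal(mf$selected_epoch, 3L)
  expect_equal(mb$selected_epoch, mb$best_epoch)
  expect_identical(mf$history$train_loss, mb$history$train_loss)
})
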