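test_that("scaled dot-product attention matches hand-derived cases", {
  # singleton softmax
  r <- scaled_dot_attention(matrix(2.3), matrix(-1), matrix(7))
  expect_equal(r$weights, matrix(1))
  expect_equal(r$output, matrix(7))
  # identical keys give uniform weights and the column mean of V
  K <- matrix(1, 3, 2)
  V <- matrix(c(1, 2, 6, 0, 0, 3), 3, 2)
  r2 <- scaled_dot_attention(matrix(c(5, -2), 1), K, V)
  expect_equal(r2$weights, matrix(1 / 3, 1, 3))
  expect_equal(r2$output, matrix(colMeans(V), 1))
  # two keys, hand softmax of logits (1/sqrt(2), 0)
  r3 <- scaled_dot_attention(matrix(c(1, 0), 1), rbind(c(1, 0), c(0, 1)),
                             matrix(c(1, 0), 2))
  sig <- exp(1 / sqrt(2)) / (exp(1 / sqrt(2)) + 1)
  expect_equal(r3$weights, matrix(c(sig, 1 - sig), 1), tolerance = 1e-12)
  expect_equal(r3$output, matrix(sig), tolerance = 1e-12)
})

test_that("attention errors on degenerate input", {
  expect_error(scaled_dot_attention(matrix(1), matrix(1), matrix(1),
                                    mask = FALSE), "masked")
  expect_error(scaled_dot_attention(matrix(NaN), matrix(1), matrix(1)),
               "non-finite")
})

test_that("attention agrees with the brute-force oracle and is row-stochastic", {
  set.seed(71)
  for (rep in 1:25) {
    n <- sample(1:4, 1); m <- sample(1:4, 1)
    dk <- sample(1:3, 1); dv <- sample(1:3, 1)
    Q <- matrix(rnorm(n * dk), n); K <- matrix(rnorm(m * dk), m)
    V <- matrix(rnorm(m * dv), m)
    got <- scaled_dot_attention(Q, K, V)
    want <- brute_attention(Q, K, V)
    expect_equal(got$output, want$output, tolerance = 1e-6)
    expect_equal(got$weights, want$weights, tolerance = 1e-6)
    expect_equal(rowSums(got$weights), rep(1, n), tolerance = 1e-6)
    expect_true(all(got$weights >= 0))
  }
})

test_that("masked key positions get zero weight and do not affect output", {
  set.seed(72)
  Q <- matrix(rnorm(6), 2)
  K <- matrix(rnorm(12), 4)
  V <- matrix(rnorm(8), 4)
  mask <- c(TRUE, FALSE, TRUE, FALSE)
  r <- scaled_dot_attention(Q, K, V, mask)
  expect_equal(unname(r$weights[, !mask]), matrix(0, 2, 2), tolerance = 1e-9)
  expect_equal(rowSums(r$weights), c(1, 1), tolerance = 1e-6)
  # perturbing masked rows of K and V changes nothing
  K2 <- K; V2 <- V
  K2[!mask, ] <- 99; V2[!mask, ] <- -99
  r2 <- scaled_dot_attention(Q, K2, V2, mask)
  expect_equal(r$output, r2$output, tolerance = 1e-9)
})

test_that("multi-head attention with one identity head reduces to scaled dot attention", {
  set.seed(73)
  X <- matrix(rnorm(12), 4, 3)
  p <- attention_params(3L, 1L, 3L, 3L, init = "identity")
  got <- multi_head_attention(X, p)
  want <- scaled_dot_attention(X, X, X)$output
  expect_equal(unclass(got), want, ignore_attr = TRUE)
  # contract: output is [n x d_model] for any head count
  p8 <- attention_params(3L, 8L, 2L, 2L)
  expect_equal(dim(multi_head_attention(X, p8)), c(4L, 3L))
  # zero output projection annihilates everything
  p0 <- attention_params(3L, 2L, 2L, 2L)
  p0$W_O[] <- 0
  expect_equal(unclass(multi_head_attention(X, p0)),
               matrix(0, 4, 3), ignore_attr = TRUE)
})

test_that("word encoder pools attended tokens; sentence encoder attends across rows", {
  set.seed(74)
  p <- attention_params(3L, 1L, 3L, 3L, init = "identity")
  # single token: attention of a singleton is the identity
  x <- matrix(rnorm(3), 1)
  expect_equal(encode_words(x, p), as.vector(x))
  # all-pad sentence yields the zero vector
  expect_equal(encode_words(matrix(rnorm(6), 2), p, mask = c(FALSE, FALSE)),
               rep(0, 3))
  # pad positions do not influence the sentence vector
  X <- matrix(rnorm(12), 4, 3)
  mask <- c(TRUE, TRUE, FALSE, TRUE)
  X2 <- X; X2[!mask, ] <- 5
  expect_equal(encode_words(X, p, mask), encode_words(X2, p, mask))
  # two-token hand computation under identity projections:
  # masked mean of softmax(XX'/sqrt(3)) X
  X3 <- rbind(c(1, 0, 1), c(0, 2, 0))
  want <- colMeans(brute_attention(X3, X3, X3)$output)
  expect_equal(encode_words(X3, p), want, tolerance = 1e-9)

  # sentence level: singleton document reduces to the identity
  s <- matrix(rnorm(3), 1)
  expect_equal(unclass(encode_sentences(s, p)), s, ignore_attr = TRUE)
  out <- encode_sentences(X, p)
  for (W in attr(out, "weights"))
    expect_equal(rowSums(W), rep(1, nrow(W)), tolerance = 1e-6)
})

test_that("two-level encoding matches a brute-force straight-line computation", {
  set.seed(75)
  pw <- attention_params(2L, 1L, 2L, 2L, init = "identity")
  ps <- attention_params(2L, 1L, 2L, 2L, init = "identity")
  sents <- list(matrix(rnorm(6), 3, 2), matrix(rnorm(4), 2, 2),
                matrix(rnorm(2), 1, 2))
  svec <- t(vapply(sents, function(X)
    colMeans(brute_attention(X, X, X)$output), numeric(2)))
  want <- brute_attention(svec, svec, svec)$output
  got_svec <- t(vapply(sents, encode_words, numeric(2), params = pw))
  expect_equal(got_svec, svec, tolerance = 1e-9)
  expect_equal(unclass(encode_sentences(got_svec, ps)), want,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("exported attention records are row-stochastic with h matrices per level", {
  docs <- toy_docs()
  cfg <- micro_config(word_heads = 2L, sent_heads = 2L)
  set.seed(6)
  m <- captriage(docs, cfg)
  tok <- split_and_tokenize(docs[[1]], cfg$max_sentences, cfg$max_words,
                            min_tokens = 1L)
  rec <- export_attention_weights(tok, m)
  word_rec <- Filter(function(r) r$level == "word", rec)
  sent_rec <- Filter(function(r) r$level == "sentence", rec)
  expect_length(word_rec, 2L * length(tok$sentences))
  expect_length(sent_rec, 2L)
  for (r in rec)
    expect_equal(rowSums(r$weights), rep(1, nrow(r$weights)), tolerance = 1e-6)
  # zeroed projections give zero logits, hence uniform weights
  m0 <- m
  m0$state$params$word_att$W_Q <- lapply(m0$state$params$word_att$W_Q,
                                         function(W) W * 0)
  rec0 <- export_attention_weights(tok, m0)
  w <- Filter(function(r) r$level == "word", rec0)[[1]]$weights
  expect_equal(w, matrix(1 / ncol(w), nrow(w), ncol(w)), tolerance = 1e-9)
  # JSON-lines writer emits one parseable record per line
  path <- tempfile(fileext = ".jsonl")
  write_attention_jsonl(rec, path)
  lines <- readLines(path)
  expect_length(lines, length(rec))
  first <- jsonlite::fromJSON(lines[1])
  expect_named(first, c("pmid", "level", "sentence", "head", "tokens", "weights"),
               ignore.order = TRUE)
})
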