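#' Scaled dot-product attention
#'
#' Computes `softmax(Q K' / sqrt(d_k)) V` row-wise. Masked (pad) key
#' positions receive weight 0: their logits are shifted by -1e9 before the
#' softmax, so every weight row sums to 1 over the unmasked columns.
#'
#' @param Q Query matrix `[n x d_k]`.
#' @param K Key matrix `[m x d_k]`.
#' @param V Value matrix `[m x d_v]`.
#' @param mask Logical vector of length `m`, `TRUE` at real positions;
#'   `NULL` means all real. At least one entry must be `TRUE`.
#' @return List with `output` (`[n x d_v]`) and `weights` (`[n x m]`).
#' @export
scaled_dot_attention <- function(Q, K, V, mask = NULL) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (!all(is.finite(Q), is.finite(K), is.finite(V)))
    stop("non-finite attention inputs")
  if (ncol(Q) != ncol(K)) stop("Q and K must share d_k")
  if (nrow(K) != nrow(V)) stop("K and V must share the key axis")
  if (is.null(mask)) mask <- rep(TRUE, nrow(K))
  if (!any(mask)) stop("all key positions are masked")
  logits <- Q %*% t(K) / sqrt(ncol(Q))
  logits[, !mask] <- logits[, !mask, drop = FALSE] - 1e9
  W <- softmax_rows(logits)
  list(output = W %*% V, weights = W)
}

softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  ex <- exp(x)
  ex / rowSums(ex)
}

#' Multi-head self-attention parameters
#'
#' Per head `i`, the projections `W_Q[i]`, `W_K[i]` (`d_model x d_k`) and
#' `W_V[i]` (`d_model x d_v`); the output matrix `W_O` maps the
#' `h * d_v`-wide head concatenation back to `d_model`, so the layer can be
#' stacked regardless of the head geometry (e.g. 8 heads of dimension 32
#' over 200-dimensional embeddings concatenate to 256 and are reprojected
#' to 200).
#'
#' @param d_model Input/output width.
#' @param h Number of heads.
#' @param d_k,d_v Per-head key and value dimensions (default `d_model / h`
#'   rounded up).
#' @param init `"glorot"` (random, uses the current RNG state),
#'   `"identity"` (requires `h = 1`, `d_k = d_v = d_model`) or `"zero"`.
#' @return List of class `"attention_params"`.
#' @export
attention_params <- function(d_model, h, d_k = NULL, d_v = NULL,
                             init = c("glorot", "identity", "zero")) {
  init <- match.arg(init)
  if (is.null(d_k)) d_k <- ceiling(d_model / h)
  if (is.null(d_v)) d_v <- d_k
  mk <- function(nr, nc) {
    switch(init,
           glorot = matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc),
           identity = {
             if (nr != nc) stop("identity init needs square matrices (h = 1, d_k = d_v = d_model)")
             diag(nr)
           },
           zero = matrix(0, nr, nc))
  }
  structure(list(
    h = h, d_k = d_k, d_v = d_v, d_model = d_model,
    W_Q = lapply(seq_len(h), function(i) mk(d_model, d_k)),
    W_K = lapply(seq_len(h), function(i) mk(d_model, d_k)),
    W_V = lapply(seq_len(h), function(i) mk(d_model, d_v)),
    W_O = mk(h * d_v, d_model)
  ), class = "attention_params")
}

# forward with cache for backprop; X [n x d_model], mask length n (keys ==
# queries: self-attention). Returns out [n x d_model].
mha_forward <- function(X, params, mask = NULL) {
  h <- params$h
  heads <- vector("list", h)
  caches <- vector("list", h)
  for (i in seq_len(h)) {
    Q <- X %*% params$W_Q[[i]]
    K <- X %*% params$W_K[[i]]
    V <- X %*% params$W_V[[i]]
    att <- scaled_dot_attention(Q, K, V, mask)
    heads[[i]] <- att$output
    caches[[i]] <- list(Q = Q, K = K, V = V, A = att$weights)
  }
  concat <- do.call(cbind, heads)
  list(out = concat %*% params$W_O,
       cache = list(X = X, mask = mask, heads = caches, concat = concat))
}

# backward pass; returns dX and gradients for every projection matrix
mha_backward <- function(dOut, params, cache) {
  X <- cache$X
  mask <- cache$mask
  h <- params$h
  d_v <- params$d_v
  dW_O <- crossprod(cache$concat, dOut)
  dConcat <- dOut %*% t(params$W_O)
  dX <- matrix(0, nrow(X), ncol(X))
  dW_Q <- vector("list", h); dW_K <- vector("list", h); dW_V <- vector("list", h)
  for (i in seq_len(h)) {
    cc <- cache$heads[[i]]
    dH <- dConcat[, ((i - 1L) * d_v + 1L):(i * d_v), drop = FALSE]
    dA <- dH %*% t(cc$V)
    dV <- crossprod(cc$A, dH)
    # softmax jacobian row-wise; masked columns carry zero weight already
    A <- cc$A
    dLogit <- (dA - rowSums(dA * A)) * A
    scale <- 1 / sqrt(params$d_k)
    dQ <- dLogit %*% cc$K * scale
    dK <- crossprod(dLogit, cc$Q) * scale
    dW_Q[[i]] <- crossprod(X, dQ)
    dW_K[[i]] <- crossprod(X, dK)
    dW_V[[i]] <- crossprod(X, dV)
    dX <- dX + dQ %*% t(params$W_Q[[i]]) + dK %*% t(params$W_K[[i]]) +
      dV %*% t(params$W_V[[i]])
  }
  list(dX = dX, W_Q = dW_Q, W_K = dW_K, W_V = dW_V, W_O = dW_O)
}

#' Multi-head self-attention
#'
#' Each head applies [scaled_dot_attention()] to its own linear projections
#' of `X` (queries, keys and values are all `X`: self-attention); head
#' outputs are concatenated and reprojected by `W_O`.
#'
#' @param X Input matrix `[n x d_model]`.
#' @param params An [attention_params()] object.
#' @param mask Logical length-`n` vector, `TRUE` at real positions.
#' @return Matrix `[n x d_model]`; the per-head weight matrices are attached
#'   as attribute `"weights"` (list of `[n x n]` matrices).
#' @export
multi_head_attention <- function(X, params, mask = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 1L) stop("X must have at least one row")
  fw <- mha_forward(X, params, mask)
  structure(fw$out, weights = lapply(fw$cache$heads, `[[`, "A"))
}

#' Encode one sentence into a vector
#'
#' Word-level multi-head self-attention over the token embeddings, followed
#' by a masked mean over the real positions. An all-pad sentence yields the
#' zero vector (flagged by the sentence mask downstream).
#'
#' @param X Embedded sentence `[n_words x d_model]`.
#' @param params Word-level [attention_params()].
#' @param mask Logical length-`n_words` vector; `NULL` means all real.
#' @return Numeric vector of length `d_model`.
#' @export
encode_words <- function(X, params, mask = NULL) {
  X <- as.matrix(X)
  if (is.null(mask)) mask <- rep(TRUE, nrow(X))
  if (!any(mask)) return(numeric(params$d_model))
  att <- mha_forward(X[mask, , drop = FALSE], params, NULL)
  colMeans(att$out)
}

#' Relate the sentences of a document
#'
#' Sentence-level multi-head self-attention over the sentence vectors; the
#' full attended sequence is returned (the convolution stage consumes it),
#' with pad sentences zeroed.
#'
#' @param S Sentence-vector matrix `[n_sentences x d_model]`.
#' @param params Sentence-level [attention_params()].
#' @param mask Logical length-`n_sentences` vector.
#' @return Matrix `[n_sentences x d_model]` with attribute `"weights"`.
#' @export
encode_sentences <- function(S, params, mask = NULL) {
  S <- as.matrix(S)
  if (is.null(mask)) mask <- rep(TRUE, nrow(S))
  if (!any(mask)) stop("document has no real sentence")
  out <- matrix(0, nrow(S), ncol(S))
  att <- mha_forward(S[mask, , drop = FALSE], params, NULL)
  out[mask, ] <- att$out
  structure(out, weights = lapply(att$cache$heads, `[[`, "A"))
}

# learned-query attention pooling: one trainable query scores each token,
# the sentence vector is the softmax-weighted token sum
query_pool_forward <- function(H, q) {
  l <- as.vector(H %*% q) / sqrt(length(q))
  a <- exp(l - max(l))
  a <- a / sum(a)
  list(out = as.vector(crossprod(H, a)), a = a, H = H)
}

query_pool_backward <- function(dOut, q, cache) {
  H <- cache$H
  a <- cache$a
  da <- as.vector(H %*% dOut)
  dl <- (da - sum(da * a)) * a
  scale <- 1 / sqrt(length(q))
  list(dH = tcrossprod(a, dOut) + tcrossprod(dl, q) * scale,
       dq = as.vector(crossprod(H, dl)) * scale)
}

# sinusoidal positional encoding, added to token embeddings when enabled
positional_encoding <- function(n, d) {
  pos <- seq_len(n) - 1L
  pe <- matrix(0, n, d)
  for (j in seq_len(d)) {
    rate <- 1 / 10000^((2 * ((j - 1L) %/% 2L)) / d)
    pe[, j] <- if (j %% 2L == 1L) sin(pos * rate) else cos(pos * rate)
  }
  pe
}

#' Export attention weights for a document
#'
#' Runs the fitted model's attention layers over one tokenized document and
#' returns the per-head word-word matrices (one set per sentence) and the
#' sentence-sentence matrices, with the token strings they connect —
#' the raw material for dependency-line visualizations.
#'
#' @param doc A `tokenized_document`.
#' @param model A fitted [captriage()] object (or a raw model state).
#' @return List of records, each `list(pmid, level, sentence, head, tokens,
#'   weights)`; every weight row sums to 1.
#' @export
export_attention_weights <- function(doc, model) {
  state <- if (inherits(model, "captriage")) model$state else model
  cfg <- state$config
  E <- state$params$E
  vocab <- state$vocab
  records <- list()
  svecs <- NULL
  use_word <- cfg$attention %in% c("word", "hierarchical")
  for (s in seq_along(doc$sentences)) {
    toks <- utils::head(doc$sentences[[s]], cfg$max_words)
    ids <- vocab_lookup(vocab, toks)
    X <- E[ids + 1L, , drop = FALSE]
    if (cfg$positional) X <- X + positional_encoding(nrow(X), ncol(X))
    if (use_word) {
      att <- mha_forward(X, state$params$word_att, NULL)
      for (h in seq_along(attr_weights(att))) {
        records[[length(records) + 1L]] <- list(
          pmid = doc$pmid, level = "word", sentence = s, head = h,
          tokens = toks, weights = attr_weights(att)[[h]])
      }
      H <- att$out
    } else H <- X
    svec <- if (identical(cfg$pool, "query"))
      query_pool_forward(H, state$params$q_word)$out else colMeans(H)
    svecs <- rbind(svecs, svec)
  }
  rownames(svecs) <- NULL
  if (cfg$attention == "hierarchical" && nrow(svecs) >= 1L) {
    att <- mha_forward(svecs, state$params$sent_att, NULL)
    labels <- paste0("s", seq_len(nrow(svecs)))
    for (h in seq_along(attr_weights(att))) {
      records[[length(records) + 1L]] <- list(
        pmid = doc$pmid, level = "sentence", sentence = NA_integer_, head = h,
        tokens = labels, weights = attr_weights(att)[[h]])
    }
  }
  records
}

attr_weights <- function(fw) lapply(fw$cache$heads, `[[`, "A")

#' Write attention records as JSON lines
#'
#' One record per line: `{pmid, level, sentence, head, tokens, weights}`.
#'
#' @param records Output of [export_attention_weights()].
#' @param path Output path.
#' @export
write_attention_jsonl <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    r$weights <- apply(r$weights, 1L, function(x) x, simplify = FALSE)
    writeLines(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
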