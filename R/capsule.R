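#' Capsule squashing nonlinearity
#'
#' Maps a vector into the open unit ball while preserving its direction:
#' `v = (||s||^2 / (1 + ||s||^2)) * s / ||s||`. Short vectors shrink to
#' near-zero length, long ones approach (but never reach) length 1. The
#' zero-norm singularity is regularized by an `eps` inside the norm.
#'
#' @param s Numeric vector (or a matrix, squashed row-wise).
#' @param eps Norm regularizer (default 1e-8).
#' @return Object of the same shape as `s`.
#' @export
squash <- function(s, eps = 1e-8) {
  if (is.matrix(s)) return(t(apply(s, 1L, squash, eps = eps)))
  if (!all(is.finite(s))) stop("non-finite capsule input")
  n2 <- sum(s^2)
  s * (n2 / ((1 + n2) * sqrt(n2 + eps)))
}

# row-wise squash with cache for backprop; the eps sits only inside the
# norm divisor, so v = s * n2 / ((1+n2) * sqrt(n2+eps))
squash_rows <- function(S, eps = 1e-8) {
  n2 <- rowSums(S^2)
  m <- sqrt(n2 + eps)
  g <- n2 / ((1 + n2) * m)
  list(out = S * g, n2 = n2, m = m, g = g)
}

# dL/dS given dL/dV: v = g(n2) s with g = n2/((1+n2) m), m = sqrt(n2+eps);
# dv/ds = g I + 2 (dg/dn2) s s'
squash_rows_backward <- function(dV, S, cache) {
  n2 <- cache$n2
  m <- cache$m
  h <- (1 + n2) * m
  dh <- m + (1 + n2) / (2 * m)
  dgdn2 <- (h - n2 * dh) / h^2
  dot <- rowSums(S * dV)
  dV * cache$g + S * (2 * dgdn2 * dot)
}

#' Prediction vectors of a capsule layer
#'
#' Each child capsule `i` predicts each parent capsule `j` through the
#' transform `u_hat[j|i] = W[i,j] u_i`. Transforms are shared across spatial
#' positions per (child type, parent) pair, so `W` is indexed by the child's
#' type (its feature group), not its position.
#'
#' @param u Child outputs, matrix `[n_child x dim_child]`.
#' @param params A [capsule_params()] object; `child_type` of length
#'   `n_child` defaults to recycling `1..n_types` across positions.
#' @return Array `[n_child x n_parent x dim_parent]`.
#' @export
prediction_vectors <- function(u, params) {
  u <- as.matrix(u)
  if (ncol(u) != params$dim_child)
    stop("child dimension ", ncol(u), " does not match params dim_child ",
         params$dim_child)
  N <- nrow(u)
  types <- rep_len(seq_len(params$n_types), N)
  uh <- array(0, dim = c(N, params$n_parent, params$dim_parent))
  for (i in seq_len(N)) {
    for (j in seq_len(params$n_parent)) {
      uh[i, j, ] <- params$W[, , types[i], j] %*% u[i, ]
    }
  }
  uh
}

#' Routing softmax
#'
#' Coupling coefficients of one child over all parents:
#' `c_ij = exp(z_ij) / sum_k exp(z_ik)`; non-negative and summing to 1.
#'
#' @param z Numeric vector of routing logits.
#' @return Numeric vector of the same length.
#' @export
routing_softmax <- function(z) {
  if (!all(is.finite(z))) stop("non-finite routing logits")
  ez <- exp(z - max(z))
  ez / sum(ez)
}

#' Dynamic routing by agreement
#'
#' Iteratively couples children to the parents whose emerging outputs agree
#' with their prediction vectors. Logits start at 0 (uniform couplings);
#' each round computes couplings `c = softmax(z)` per child, parent inputs
#' `s_j = sum_i c_ij u_hat[j|i]`, outputs `v_j = squash(s_j)`, and then
#' raises `z_ij` by the agreement `u_hat[j|i] . v_j` (the logit update is
#' skipped after the final round).
#'
#' @param u_hat Prediction-vector array `[n_child x n_parent x dim_parent]`.
#' @param r Number of routing iterations, `>= 1` (default 3).
#' @return List with `v` (`[n_parent x dim_parent]`) and `c`
#'   (`[n_child x n_parent]`, rows summing to 1).
#' @export
dynamic_routing <- function(u_hat, r = 3L) {
  if (r < 1L) stop("routing needs r >= 1")
  if (!all(is.finite(u_hat))) stop("non-finite prediction vectors")
  rt <- routing_forward(u_hat, r)
  list(v = rt$v, c = rt$c)
}

routing_forward <- function(u_hat, r) {
  dd <- dim(u_hat)
  N <- dd[1L]; J <- dd[2L]; dp <- dd[3L]
  z <- matrix(0, N, J)
  cmat <- NULL; sq <- NULL; S <- NULL
  for (t in seq_len(r)) {
    cmat <- t(apply(z, 1L, routing_softmax))
    if (J == 1L) cmat <- matrix(cmat, N, 1L)
    S <- matrix(0, J, dp)
    for (d in seq_len(dp)) {
      ud <- matrix(u_hat[, , d], N, J)
      S[, d] <- colSums(cmat * ud)
    }
    sq <- squash_rows(S)
    if (t < r) {
      for (d in seq_len(dp)) {
        ud <- matrix(u_hat[, , d], N, J)
        z <- z + ud * matrix(sq$out[, d], N, J, byrow = TRUE)
      }
    }
  }
  list(v = sq$out, c = cmat, S = S, sq = sq)
}

# backward through the final routing round with couplings treated as
# routing state (no gradient through c): dL/du_hat[i,j,] = c_ij dL/ds_j
routing_backward <- function(dV, u_hat, rt) {
  dd <- dim(u_hat)
  N <- dd[1L]; J <- dd[2L]; dp <- dd[3L]
  dS <- squash_rows_backward(dV, rt$S, rt$sq)
  dU <- array(0, dim = dd)
  for (d in seq_len(dp)) {
    dU[, , d] <- rt$c * matrix(dS[, d], N, J, byrow = TRUE)
  }
  dU
}

#' Capsule layer parameters
#'
#' Child-to-parent transforms shared across positions per (child type,
#' parent) pair, plus the routing geometry. Defaults follow the main model:
#' capsule dimension 32 for both layers and 3 routing iterations.
#'
#' @param n_types Number of child capsule types (feature groups per
#'   position).
#' @param n_parent Number of parent capsules.
#' @param dim_child,dim_parent Capsule dimensions (default 32).
#' @param r Routing iterations (default 3).
#' @param init `"glorot"` (uses the current RNG state) or `"identity"`
#'   (requires `dim_child == dim_parent`).
#' @return List of class `"capsule_params"` with transform array `W`
#'   `[dim_parent x dim_child x n_types x n_parent]`.
#' @export
capsule_params <- function(n_types, n_parent, dim_child = 32L,
                           dim_parent = 32L, r = 3L,
                           init = c("glorot", "identity")) {
  init <- match.arg(init)
  if (r < 1L) stop("routing needs r >= 1")
  W <- array(0, dim = c(dim_parent, dim_child, n_types, n_parent))
  for (g in seq_len(n_types)) for (j in seq_len(n_parent)) {
    W[, , g, j] <- if (init == "glorot")
      matrix(stats::rnorm(dim_parent * dim_child,
                          sd = sqrt(2 / (dim_parent + dim_child))),
             dim_parent, dim_child)
    else {
      if (dim_child != dim_parent) stop("identity init needs equal capsule dims")
      diag(dim_parent)
    }
  }
  structure(list(n_types = as.integer(n_types), n_parent = as.integer(n_parent),
                 dim_child = as.integer(dim_child),
                 dim_parent = as.integer(dim_parent), r = as.integer(r), W = W),
            class = "capsule_params")
}

#' Primary capsules from convolution features
#'
#' Converts the scalar convolution output into vector capsules: each
#' position's feature vector is cut into consecutive groups of `dim_child`
#' features, and each group is squashed. With the main-model defaults
#' (384 features, dimension 32) this yields 12 capsule types per position.
#'
#' @param F Convolution output `[n_positions x n_features]`;
#'   `n_features` must be divisible by `dim_child`.
#' @param dim_child Capsule dimension.
#' @return Matrix `[n_positions * (n_features / dim_child) x dim_child]`;
#'   row `(s-1)*G + g` is group `g` at position `s`. Every row norm is `< 1`.
#' @export
primary_capsules <- function(F, dim_child) {
  F <- as.matrix(F)
  if (ncol(F) %% dim_child != 0L)
    stop("feature count ", ncol(F), " is not divisible by dim_child ",
         dim_child, "; adjust conv maps or the capsule dimension")
  G <- ncol(F) %/% dim_child
  n <- nrow(F)
  U <- matrix(0, n * G, dim_child)
  for (s in seq_len(n)) for (g in seq_len(G)) {
    U[(s - 1L) * G + g, ] <- F[s, ((g - 1L) * dim_child + 1L):(g * dim_child)]
  }
  sq <- squash_rows(U)
  structure(sq$out, groups = G)
}

# cached version for the model path
primary_capsules_forward <- function(F, dim_child) {
  G <- ncol(F) %/% dim_child
  n <- nrow(F)
  U <- matrix(0, n * G, dim_child)
  for (s in seq_len(n)) for (g in seq_len(G)) {
    U[(s - 1L) * G + g, ] <- F[s, ((g - 1L) * dim_child + 1L):(g * dim_child)]
  }
  sq <- squash_rows(U)
  list(out = sq$out, cache = list(U = U, sq = sq, G = G, n = n,
                                  dim_child = dim_child))
}

primary_capsules_backward <- function(dOut, cache) {
  dU <- squash_rows_backward(dOut, cache$U, cache$sq)
  dF <- matrix(0, cache$n, cache$G * cache$dim_child)
  for (s in seq_len(cache$n)) for (g in seq_len(cache$G)) {
    dF[s, ((g - 1L) * cache$dim_child + 1L):(g * cache$dim_child)] <-
      dU[(s - 1L) * cache$G + g, ]
  }
  dF
}
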