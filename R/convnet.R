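#' Parallel convolution parameters
#'
#' One kernel bank per window width, all applied in parallel to the same
#' input sequence; their feature maps are spliced together along the
#' feature axis. Defaults follow the main model: windows 3, 4 and 5 with
#' 128 feature maps each (384 features total).
#'
#' @param d_in Input feature width (the attended sentence-vector dimension).
#' @param windows Integer vector of window widths.
#' @param maps Feature maps per window.
#' @param init `"glorot"` (uses the current RNG state) or `"zero"`.
#' @return List of class `"conv_params"`; element `kernels` holds, per
#'   window, `W` (`[maps x (w * d_in)]`, the flattened-window kernel) and
#'   `b` (length `maps`).
#' @export
conv_params <- function(d_in, windows = c(3L, 4L, 5L), maps = 128L,
                        init = c("glorot", "zero")) {
  init <- match.arg(init)
  kernels <- lapply(windows, function(w) {
    nin <- w * d_in
    W <- if (init == "glorot")
      matrix(stats::rnorm(maps * nin, sd = sqrt(2 / (nin + maps))), maps, nin)
    else matrix(0, maps, nin)
    list(w = as.integer(w), W = W, b = numeric(maps))
  })
  structure(list(d_in = d_in, windows = as.integer(windows),
                 maps = as.integer(maps), kernels = kernels),
            class = "conv_params")
}

# build the [n x (w*d)] unrolled-window matrix under 'same' zero padding
conv_unroll <- function(X, w) {
  n <- nrow(X); d <- ncol(X)
  left <- (w - 1L) %/% 2L
  Xp <- rbind(matrix(0, left, d), X, matrix(0, w - 1L - left, d))
  do.call(cbind, lapply(0:(w - 1L), function(o) Xp[(1L + o):(n + o), , drop = FALSE]))
}

conv_forward <- function(X, params) {
  n <- nrow(X)
  outs <- vector("list", length(params$kernels))
  caches <- vector("list", length(params$kernels))
  for (k in seq_along(params$kernels)) {
    kr <- params$kernels[[k]]
    U <- conv_unroll(X, kr$w)
    Z <- U %*% t(kr$W) + matrix(kr$b, n, length(kr$b), byrow = TRUE)
    outs[[k]] <- pmax(Z, 0)
    caches[[k]] <- list(U = U, active = Z > 0)
  }
  list(out = do.call(cbind, outs), cache = list(n = n, d = ncol(X), caches = caches))
}

conv_backward <- function(dOut, params, cache) {
  n <- cache$n; d <- cache$d
  dX <- matrix(0, n, d)
  grads <- vector("list", length(params$kernels))
  col0 <- 0L
  for (k in seq_along(params$kernels)) {
    kr <- params$kernels[[k]]
    m <- length(kr$b)
    dF <- dOut[, (col0 + 1L):(col0 + m), drop = FALSE]
    col0 <- col0 + m
    dZ <- dF * cache$caches[[k]]$active
    grads[[k]] <- list(W = crossprod(dZ, cache$caches[[k]]$U), b = colSums(dZ))
    dU <- dZ %*% kr$W
    # fold the unrolled-window gradient back onto the padded input rows
    left <- (kr$w - 1L) %/% 2L
    for (o in 0:(kr$w - 1L)) {
      rows <- (1L + o):(n + o) - left  # position in X of offset-o slice
      valid <- rows >= 1L & rows <= n
      dX[rows[valid], ] <- dX[rows[valid], ] +
        dU[valid, (o * d + 1L):((o + 1L) * d), drop = FALSE]
    }
    dX
  }
  list(dX = dX, kernels = grads)
}

#' Parallel multi-width convolution with ReLU
#'
#' For each window width `w`, computes `S_t = ReLU(W x_{t:t+w-1} + b)` at
#' every position under same-length zero padding, and splices the
#' per-window feature maps together along the feature axis. The position
#' count is preserved so the capsule stage sees one feature vector per
#' sentence position.
#'
#' @param X Input matrix `[n x d_in]`, `n >= 1`.
#' @param params A [conv_params()] object.
#' @return Matrix `[n x sum(maps)]`, entrywise non-negative.
#' @export
parallel_convolution <- function(X, params) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("empty input sequence")
  if (ncol(X) != params$d_in) stop("input width ", ncol(X),
                                   " does not match conv d_in ", params$d_in)
  conv_forward(X, params)$out
}
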