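#' @title A compact 1-D convolutional network for parameter regression
#' @description
#' The regression model that maps a binned 5-s MEA window to the three
#' data-dependent MaxInterval parameters is a small 1-D CNN: a stack of
#' valid (no padding) convolution blocks, each followed by ReLU and
#' non-overlapping max-pooling, a dense ReLU layer, and a linear head of
#' exactly three outputs (max-start, max-end, min-between, in
#' milliseconds).  Convolutions are computed as sums of shifted matrix
#' products so all heavy lifting runs through BLAS; training is plain
#' mini-batch Adam on the mean-squared error of the parameter targets.
#' Everything is seeded and deterministic.
#' @name cnn_engine
NULL

#' Default architecture specification
#'
#' @param conv list of conv blocks, each `list(filters, kernel, pool)`.
#' @param dense width of the dense ReLU head.
#' @param output number of linear outputs; must be 3 for parameter
#'   regression.
#' @export
cnn_architecture <- function(conv = list(list(filters = 16, kernel = 7, pool = 4),
                                         list(filters = 32, kernel = 7, pool = 4)),
                             dense = 64, output = 3L) {
  structure(list(conv = conv, dense = as.integer(dense),
                 output = as.integer(output)),
            class = "cnn_architecture")
}

variant_length <- function(variant) {
  switch(variant, spikes30 = 1667L, signal30 = 1667L, signal100 = 500L,
         stop("unknown variant: ", variant))
}

#' Build (initialize) a parameter-regression CNN
#'
#' @param config a [train_config()].
#' @param variant input variant: `"spikes30"`, `"signal30"` or
#'   `"signal100"`.
#' @return A model handle (class `mea_cnn`) holding the architecture,
#'   seeded initial weights and the parameter count.
#' @export
build_model <- function(config = train_config(), variant = config$variant) {
  arch <- config$architecture
  stopifnot(inherits(arch, "cnn_architecture"))
  if (arch$output != 3L)
    stop("configuration error: the parameter head must have exactly 3 outputs")
  len <- variant_length(variant)
  set.seed(config$seed)
  weights <- list()
  cin <- 1L
  L <- len
  for (i in seq_along(arch$conv)) {
    blk <- arch$conv[[i]]
    if (L < blk$kernel)
      stop("configuration error: conv block ", i,
           " kernel exceeds its input length (", L, ")")
    fan_in <- blk$kernel * cin
    weights[[paste0("Wc", i)]] <-
      array(stats::rnorm(blk$kernel * cin * blk$filters,
                         sd = sqrt(2 / fan_in)),
            dim = c(blk$kernel, cin, blk$filters))
    weights[[paste0("bc", i)]] <- numeric(blk$filters)
    L <- (L - blk$kernel + 1L) %/% blk$pool
    if (L < 1L)
      stop("configuration error: pooling in block ", i,
           " leaves no temporal positions")
    cin <- blk$filters
  }
  flat <- L * cin
  weights$Wd <- matrix(stats::rnorm(flat * arch$dense, sd = sqrt(2 / flat)),
                       flat, arch$dense)
  weights$bd <- numeric(arch$dense)
  weights$Wo <- matrix(stats::rnorm(arch$dense * 3L, sd = sqrt(1 / arch$dense)),
                       arch$dense, 3L)
  weights$bo <- numeric(3L)
  structure(list(architecture = arch, variant = variant, input_len = len,
                 weights = weights,
                 n_parameters = sum(vapply(weights, length, 0L)),
                 config = config),
            class = "mea_cnn")
}

#' @export
print.mea_cnn <- function(x, ...) {
  cat(sprintf("1-D CNN (%s, input %d): %d conv blocks, dense %d -> 3; %d parameters\n",
              x$variant, x$input_len, length(x$architecture$conv),
              x$architecture$dense, x$n_parameters))
  invisible(x)
}

# ---- forward / backward -------------------------------------------------

w_slice <- function(W, j) matrix(W[j, , ], nrow = dim(W)[2L], ncol = dim(W)[3L])

conv_fwd <- function(X, W, b) {
  d <- dim(X)  # (batch, L, Cin)
  k <- dim(W)[1L]; f <- dim(W)[3L]
  Lout <- d[2L] - k + 1L
  acc <- matrix(rep(b, each = d[1L] * Lout), d[1L] * Lout, f)
  for (j in seq_len(k)) {
    Xj <- X[, j:(j + Lout - 1L), , drop = FALSE]
    dim(Xj) <- c(d[1L] * Lout, d[3L])
    acc <- acc + Xj %*% w_slice(W, j)
  }
  dim(acc) <- c(d[1L], Lout, f)
  acc
}

conv_bwd <- function(X, W, dOut) {
  d <- dim(X); k <- dim(W)[1L]
  Lout <- dim(dOut)[2L]; f <- dim(dOut)[3L]
  dmat <- dOut; dim(dmat) <- c(d[1L] * Lout, f)
  dW <- array(0, dim = dim(W))
  dX <- array(0, dim = d)
  for (j in seq_len(k)) {
    Xj <- X[, j:(j + Lout - 1L), , drop = FALSE]
    dim(Xj) <- c(d[1L] * Lout, d[3L])
    dW[j, , ] <- crossprod(Xj, dmat)
    dXj <- dmat %*% t(w_slice(W, j))
    dim(dXj) <- c(d[1L], Lout, d[3L])
    dX[, j:(j + Lout - 1L), ] <- dX[, j:(j + Lout - 1L), , drop = FALSE] + dXj
  }
  list(dW = dW, db = colSums(dmat), dX = dX)
}

pool_fwd <- function(A, p) {
  d <- dim(A)
  Lp <- d[2L] %/% p
  A <- A[, seq_len(Lp * p), , drop = FALSE]
  dim(A) <- c(d[1L], p, Lp, d[3L])
  ap <- aperm(A, c(2L, 1L, 3L, 4L))
  dim(ap) <- c(p, d[1L] * Lp * d[3L])
  amax <- max.col(t(ap), ties.method = "first")
  vals <- ap[cbind(amax, seq_len(ncol(ap)))]
  dim(vals) <- c(d[1L], Lp, d[3L])
  list(out = vals, amax = amax, p = p, in_dim = d)
}

pool_bwd <- function(cache, dOut) {
  d <- cache$in_dim; p <- cache$p
  Lp <- d[2L] %/% p
  n <- d[1L] * Lp * d[3L]
  grad <- matrix(0, p, n)
  grad[cbind(cache$amax, seq_len(n))] <- as.numeric(dOut)
  dim(grad) <- c(p, d[1L], Lp, d[3L])
  grad <- aperm(grad, c(2L, 1L, 3L, 4L))
  dim(grad) <- c(d[1L], Lp * p, d[3L])
  if (Lp * p < d[2L]) {  # positions dropped by pooling receive zero grad
    full <- array(0, dim = d)
    full[, seq_len(Lp * p), ] <- grad
    grad <- full
  }
  grad
}

cnn_forward <- function(model, X, keep_cache = FALSE) {
  w <- model$weights
  arch <- model$architecture
  A <- X
  dim(A) <- c(nrow(X), ncol(X), 1L)
  cache <- list(inputs = list(), pre = list(), pools = list())
  for (i in seq_along(arch$conv)) {
    cache$inputs[[i]] <- A
    Z <- conv_fwd(A, w[[paste0("Wc", i)]], w[[paste0("bc", i)]])
    cache$pre[[i]] <- Z
    A <- pmax(Z, 0)
    pl <- pool_fwd(A, arch$conv[[i]]$pool)
    cache$pools[[i]] <- pl
    A <- pl$out
  }
  d <- dim(A)
  flat <- A
  dim(flat) <- c(d[1L], d[2L] * d[3L])
  cache$flat <- flat
  zd <- sweep(flat %*% w$Wd, 2L, w$bd, "+")
  cache$zd <- zd
  hd <- pmax(zd, 0)
  cache$hd <- hd
  out <- sweep(hd %*% w$Wo, 2L, w$bo, "+")
  if (keep_cache) list(out = out, cache = cache) else out
}

cnn_backward <- function(model, cache, dOut) {
  w <- model$weights
  arch <- model$architecture
  g <- list()
  g$Wo <- crossprod(cache$hd, dOut)
  g$bo <- colSums(dOut)
  dh <- dOut %*% t(w$Wo)
  dh <- dh * (cache$zd > 0)
  g$Wd <- crossprod(cache$flat, dh)
  g$bd <- colSums(dh)
  dflat <- dh %*% t(w$Wd)
  last <- length(arch$conv)
  dA <- dflat
  dim(dA) <- dim(cache$pools[[last]]$out)
  for (i in rev(seq_along(arch$conv))) {
    dA <- pool_bwd(cache$pools[[i]], dA)
    dA <- dA * (cache$pre[[i]] > 0)
    cb <- conv_bwd(cache$inputs[[i]], w[[paste0("Wc", i)]], dA)
    g[[paste0("Wc", i)]] <- cb$dW
    g[[paste0("bc", i)]] <- cb$db
    dA <- cb$dX
  }
  g
}

adam_init <- function(weights) {
  list(m = lapply(weights, function(w) array(0, dim = dim(w) %||% length(w))),
       v = lapply(weights, function(w) array(0, dim = dim(w) %||% length(w))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(weights, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  for (nm in names(weights)) {
    gr <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * gr
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * gr^2
    mh <- opt$m[[nm]] / (1 - beta1^opt$t)
    vh <- opt$v[[nm]] / (1 - beta2^opt$t)
    weights[[nm]] <- weights[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(weights = weights, opt = opt)
}
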