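# Minimal CNN primitives (im2col convolutions, pooling, manual backprop)
# used by the heat-map producer and the frozen feature constructor. All
# arrays follow the EBImage layout (x, y, channel); everything is plain
# double arithmetic, so runs are bitwise reproducible given the seed.

convMatForward <- function(x, Wm, b) {
  d <- dim(x); wd <- d[1L]; ht <- d[2L]; cin <- d[3L]
  cout <- ncol(Wm)
  pad <- array(0, c(wd + 2L, ht + 2L, cin))
  pad[2:(wd + 1L), 2:(ht + 1L), ] <- x
  X <- matrix(0, wd * ht, 9L * cin)
  k <- 0L
  for (dy in -1:1) for (dx in -1:1) {
    X[, k * cin + seq_len(cin)] <-
      matrix(pad[(1:wd) + dx + 1L, (1:ht) + dy + 1L, , drop = FALSE],
             wd * ht, cin)
    k <- k + 1L
  }
  y <- sweep(X %*% Wm, 2L, b, "+")
  list(out = array(y, c(wd, ht, cout)), X = X, dims = d)
}

convMatBackward <- function(cache, dout, Wm, needInput = TRUE) {
  d <- cache$dims; wd <- d[1L]; ht <- d[2L]; cin <- d[3L]
  dY <- matrix(dout, wd * ht, ncol(Wm))
  dW <- crossprod(cache$X, dY)
  db <- colSums(dY)
  dx <- NULL
  if (needInput) {
    dX <- dY %*% t(Wm)
    dpad <- array(0, c(wd + 2L, ht + 2L, cin))
    k <- 0L
    for (dy in -1:1) for (dx_ in -1:1) {
      dpad[(1:wd) + dx_ + 1L, (1:ht) + dy + 1L, ] <-
        dpad[(1:wd) + dx_ + 1L, (1:ht) + dy + 1L, , drop = FALSE] +
        array(dX[, k * cin + seq_len(cin)], c(wd, ht, cin))
      k <- k + 1L
    }
    dx <- dpad[2:(wd + 1L), 2:(ht + 1L), , drop = FALSE]
  }
  list(dW = dW, db = db, dx = dx)
}

avgPool <- function(x, s) {
  d <- dim(x)
  a <- colMeans(array(x, c(s, d[1L] / s, d[2L] * d[3L])), dims = 1L)
  a <- array(a, c(d[1L] / s, d[2L], d[3L]))
  a <- aperm(a, c(2L, 1L, 3L))
  a <- colMeans(array(a, c(s, d[2L] / s, d[1L] / s * d[3L])), dims = 1L)
  aperm(array(a, c(d[2L] / s, d[1L] / s, d[3L])), c(2L, 1L, 3L))
}

avgPoolBackward <- function(dout, s) {
  d <- dim(dout)
  up <- dout[rep(seq_len(d[1L]), each = s),
             rep(seq_len(d[2L]), each = s), , drop = FALSE]
  up / (s * s)
}

upsampleNearest <- function(x, s) {
  d <- dim(x)
  x[rep(seq_len(d[1L]), each = s), rep(seq_len(d[2L]), each = s), ,
    drop = FALSE]
}

upsampleNearestBackward <- function(dout, s) {
  d <- dim(dout)
  a <- colSums(array(dout, c(s, d[1L] / s, d[2L] * d[3L])), dims = 1L)
  a <- aperm(array(a, c(d[1L] / s, d[2L], d[3L])), c(2L, 1L, 3L))
  a <- colSums(array(a, c(s, d[2L] / s, d[1L] / s * d[3L])), dims = 1L)
  aperm(array(a, c(d[2L] / s, d[1L] / s, d[3L])), c(2L, 1L, 3L))
}

heInit <- function(nr, nc, fanin) matrix(rnorm(nr * nc, 0, sqrt(2 / fanin)),
                                         nr, nc)

#' Initialise the coattention heat-map network
#'
#' A compact fully convolutional encoder--decoder: three 3x3 convolution
#' blocks with stride-2 average pooling (total stride 4), a 1x1 scoring
#' convolution, nearest-neighbour upsampling back to the input size, and a
#' per-pixel sigmoid head. A trainable identity-preserving skip connection
#' from the input's channel mean to the logit makes the network emit its
#' input mask at initialisation (the same role bilinear-initialised
#' upsampling plays in classic fully convolutional segmentation nets),
#' so that early, untrained heat maps are already meaningful proposals.
#'
#' @param seed integer seed for weight initialisation
#' @param channels widths of the three convolution blocks
#' @return parameter list (class \code{comp_net})
#' @export
compInit <- function(seed = 1L, channels = c(8L, 16L, 16L)) {
  set.seed(seed)
  p <- list(
    W1 = heInit(27L, channels[1L], 27L), b1 = numeric(channels[1L]),
    W2 = heInit(9L * channels[1L], channels[2L], 9L * channels[1L]),
    b2 = numeric(channels[2L]),
    W3 = heInit(9L * channels[2L], channels[3L], 9L * channels[2L]),
    b3 = numeric(channels[3L]),
    Ws = matrix(rnorm(channels[3L], 0, 0.01), channels[3L], 1L),
    bs = 0,
    gain = 4)
  class(p) <- "comp_net"
  p
}

compForward <- function(p, x) {
  c1 <- convMatForward(x, p$W1, p$b1)
  a1 <- pmax(c1$out, 0)
  p1 <- avgPool(a1, 2L)
  c2 <- convMatForward(p1, p$W2, p$b2)
  a2 <- pmax(c2$out, 0)
  p2 <- avgPool(a2, 2L)
  c3 <- convMatForward(p2, p$W3, p$b3)
  a3 <- pmax(c3$out, 0)
  d <- dim(a3)
  sc <- sweep(matrix(a3, d[1L] * d[2L], d[3L]) %*% p$Ws, 2L, p$bs, "+")
  sc <- array(sc, c(d[1L], d[2L], 1L))
  up <- upsampleNearest(sc, 4L)
  skip <- 2 * (x[, , 1L] + x[, , 2L] + x[, , 3L]) / 3 - 1
  logit <- up[, , 1L] + p$gain * skip
  heat <- 1 / (1 + exp(-logit))
  list(heat = heat,
       cache = list(x = x, c1 = c1, a1 = a1, c2 = c2, a2 = a2, c3 = c3,
                    a3 = a3, sc = sc, skip = skip, heat = heat))
}

compBackward <- function(p, cache, dheat) {
  h <- cache$heat
  dlogit <- dheat * h * (1 - h)
  dgain <- sum(dlogit * cache$skip)
  dup <- array(dlogit, c(dim(dlogit), 1L))
  dsc <- upsampleNearestBackward(dup, 4L)
  d <- dim(cache$a3)
  dscm <- matrix(dsc, d[1L] * d[2L], 1L)
  dWs <- crossprod(matrix(cache$a3, d[1L] * d[2L], d[3L]), dscm)
  dbs <- sum(dscm)
  da3 <- array(dscm %*% t(p$Ws), d)
  da3 <- da3 * (cache$c3$out > 0)
  g3 <- convMatBackward(cache$c3, da3, p$W3, TRUE)
  da2p <- avgPoolBackward(g3$dx, 2L)
  da2 <- da2p * (cache$c2$out > 0)
  g2 <- convMatBackward(cache$c2, da2, p$W2, TRUE)
  da1p <- avgPoolBackward(g2$dx, 2L)
  da1 <- da1p * (cache$c1$out > 0)
  g1 <- convMatBackward(cache$c1, da1, p$W1, FALSE)
  list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db,
       W3 = g3$dW, b3 = g3$db, Ws = dWs, bs = dbs, gain = dgain)
}

#' Initialise the frozen feature constructor
#'
#' A deterministic, seeded random-weight convolutional feature extractor:
#' two 3x3 convolution blocks with pooling, global average pooling and a
#' fixed random linear projection to \code{featureDim}. It stands in for a
#' large pretrained backbone in download-free settings; weights are frozen
#' and only input gradients are propagated (so losses can steer the
#' heat-map network through it).
#'
#' @param seed integer seed
#' @param featureDim output feature dimension
#' @return parameter list (class \code{fc_net})
#' @export
fcInit <- function(seed = 1L, featureDim = 2048L) {
  set.seed(seed + 1000003L)
  p <- list(
    W1 = heInit(27L, 8L, 27L), b1 = numeric(8L),
    W2 = heInit(72L, 16L, 72L), b2 = numeric(16L),
    Wd = matrix(rnorm(16L * featureDim, 0, 1 / sqrt(16)), 16L, featureDim),
    featureDim = as.integer(featureDim))
  class(p) <- "fc_net"
  p
}

fcForward <- function(p, x) {
  c1 <- convMatForward(x, p$W1, p$b1)
  a1 <- pmax(c1$out, 0)
  p1 <- avgPool(a1, 4L)
  c2 <- convMatForward(p1, p$W2, p$b2)
  a2 <- pmax(c2$out, 0)
  g <- apply(a2, 3L, mean)
  f <- as.numeric(crossprod(p$Wd, g))
  list(features = f,
       cache = list(c1 = c1, c2 = c2, a2dim = dim(a2)))
}

fcBackwardInput <- function(p, cache, df) {
  dg <- as.numeric(p$Wd %*% df)
  d2 <- cache$a2dim
  da2 <- array(rep(dg / (d2[1L] * d2[2L]), each = d2[1L] * d2[2L]), d2)
  da2 <- da2 * (cache$c2$out > 0)
  g2 <- convMatBackward(cache$c2, da2, p$W2, TRUE)
  da1p <- avgPoolBackward(g2$dx, 4L)
  da1 <- da1p * (cache$c1$out > 0)
  g1 <- convMatBackward(cache$c1, da1, p$W1, TRUE)
  g1$dx
}

adamInit <- function(params) {
  trainable <- setdiff(names(params), c("featureDim"))
  st <- list(t = 0L, m = list(), v = list())
  for (nm in trainable) {
    st$m[[nm]] <- params[[nm]] * 0
    st$v[[nm]] <- params[[nm]] * 0
  }
  st
}

adamStep <- function(params, grads, state, lr, weightDecay = 0,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(state$m)) {
    g <- grads[[nm]] + weightDecay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}
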