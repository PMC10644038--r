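# Contrastive losses of the refinement stage. All pairwise distances use
# the mean-squared-difference convention: msd(x, y) = mean((x - y)^2),
# i.e. the feature-dimension constant is replaced by the MSE criterion.
# Probabilities are the softmax contrast p = exp(-d+) / (exp(-d+) +
# exp(-d-)) = sigmoid(d- - d+); -log p is evaluated in the numerically
# stable softplus form and clamped at -log(1e-12).

LOG_CLAMP <- -log(1e-12)

msd <- function(x, y) mean((x - y)^2)

nlogSigmoid <- function(z) {
  # -log sigmoid(z), stable for large |z|
  v <- ifelse(z > 0, log1p(exp(-z)), -z + log1p(exp(z)))
  pmin(v, LOG_CLAMP)
}

dNlogSigmoid <- function(z) {
  # d/dz of -log sigmoid(z) = sigmoid(z) - 1, zero where clamped
  ifelse(nlogSigmoid(z) >= LOG_CLAMP, 0, -1 / (1 + exp(z)))
}

#' Training configuration for the refinement stage
#'
#' @param wCa,wCs,wT loss weights (defaults 1, 0.5, 0.5)
#' @param margin hinge cutoff of the cosegmentation loss (default 2)
#' @param epochs,minEpochs training epochs and stabilisation epochs
#' @param lateLosses activate cosegmentation/temporal losses at the final
#'   epoch only
#' @param lr,weightDecay Adam settings; the published configuration keeps
#'   the heat-map network's learning rate fixed at 1e-6 (an alternative
#'   0.01 operating point is reported for Adam and can be set here)
#' @param featureDim feature-constructor output dimension
#' @param compInput "mask", "image" or "masked_image"
#' @param backbone "random"
#' @param seed weight-initialisation seed
#' @return a \code{\link{LossConfig}}
#' @export
lossConfig <- function(wCa = 1, wCs = 0.5, wT = 0.5, margin = 2,
                       epochs = 10L, minEpochs = 2L, lateLosses = TRUE,
                       lr = 1e-6, weightDecay = 5e-4, featureDim = 2048L,
                       compInput = "mask", backbone = "random", seed = 1L) {
  new("LossConfig", wCa = wCa, wCs = wCs, wT = wT, margin = margin,
      epochs = as.integer(epochs), minEpochs = as.integer(minEpochs),
      lateLosses = lateLosses, lr = lr, weightDecay = weightDecay,
      featureDim = as.integer(featureDim), compInput = compInput,
      backbone = backbone, seed = as.integer(seed))
}

#' Cosegmentation loss between two object/background feature pairs
#'
#' \code{L = d+ + d-} where \code{d+} is the mean squared difference
#' between the two object vectors and \code{d-} is the hinge
#' \code{max(0, margin - mean of the two intra-image object-background
#' mean squared differences)}: small when objects agree across images and
#' each object is at least \code{margin}-far from its own background.
#'
#' @param pairA,pairB lists with elements \code{object} and
#'   \code{background} (equal-length numeric vectors)
#' @param cfg a \code{\link{LossConfig}} (margin)
#' @return non-negative scalar
#' @export
cosegmentationLoss <- function(pairA, pairB, cfg = lossConfig()) {
  stopifnot(length(pairA$object) == length(pairB$object),
            length(pairA$object) == length(pairA$background),
            length(pairB$object) == length(pairB$background))
  dplus <- msd(pairA$object, pairB$object)
  intra <- 0.5 * (msd(pairA$object, pairA$background) +
                  msd(pairB$object, pairB$background))
  dminus <- max(0, cfg@margin - intra)
  dplus + dminus
}

cosegmentationLossGrad <- function(pairA, pairB, cfg = lossConfig()) {
  d <- length(pairA$object)
  gAo <- (2 / d) * (pairA$object - pairB$object)
  gBo <- -gAo
  intra <- 0.5 * (msd(pairA$object, pairA$background) +
                  msd(pairB$object, pairB$background))
  gAb <- numeric(d); gBb <- numeric(d)
  if (cfg@margin - intra > 0) {
    gAo <- gAo - (1 / d) * (pairA$object - pairA$background)
    gAb <- (1 / d) * (pairA$object - pairA$background)
    gBo <- gBo - (1 / d) * (pairB$object - pairB$background)
    gBb <- (1 / d) * (pairB$object - pairB$background)
  }
  list(Ao = gAo, Ab = gAb, Bo = gBo, Bb = gBb,
       value = cosegmentationLoss(pairA, pairB, cfg))
}

#' Temporal loss over aligned previous/current object features
#'
#' For every ordered pair of base algorithms (i, j), contrasts the
#' current-frame inter-object distance against the previous-frame one:
#' \code{p_ij = exp(-msd(B_i, B_j)) / (exp(-msd(B_i, B_j)) +
#' exp(-msd(A_i, A_j)))}, and accumulates \code{-log p_ij}. Drives the
#' current heat maps' objects to agree at least as well as the previous
#' ones did.
#'
#' @param prevObjects,currObjects lists of equal-length feature vectors,
#'   aligned by algorithm index (length N)
#' @param cfg a \code{\link{LossConfig}}
#' @return non-negative scalar; 0 (with a message) when N < 2
#' @export
temporalLoss <- function(prevObjects, currObjects, cfg = lossConfig()) {
  N <- length(currObjects)
  stopifnot(length(prevObjects) == N)
  if (N < 2L) {
    message("temporal loss undefined for a single algorithm; returning 0")
    return(0)
  }
  total <- 0
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j) next
    obp <- msd(currObjects[[i]], currObjects[[j]])
    obm <- msd(prevObjects[[i]], prevObjects[[j]])
    total <- total + nlogSigmoid(obm - obp)
  }
  total
}

temporalLossGrad <- function(prevObjects, currObjects, cfg = lossConfig()) {
  N <- length(currObjects)
  d <- length(currObjects[[1L]])
  gPrev <- lapply(prevObjects, function(v) numeric(d))
  gCurr <- lapply(currObjects, function(v) numeric(d))
  total <- 0
  if (N >= 2L) {
    for (i in seq_len(N)) for (j in seq_len(N)) {
      if (i == j) next
      obp <- msd(currObjects[[i]], currObjects[[j]])
      obm <- msd(prevObjects[[i]], prevObjects[[j]])
      z <- obm - obp
      total <- total + nlogSigmoid(z)
      dz <- dNlogSigmoid(z)
      dObp <- -dz; dObm <- dz
      gCurr[[i]] <- gCurr[[i]] +
        dObp * (2 / d) * (currObjects[[i]] - currObjects[[j]])
      gCurr[[j]] <- gCurr[[j]] -
        dObp * (2 / d) * (currObjects[[i]] - currObjects[[j]])
      gPrev[[i]] <- gPrev[[i]] +
        dObm * (2 / d) * (prevObjects[[i]] - prevObjects[[j]])
      gPrev[[j]] <- gPrev[[j]] -
        dObm * (2 / d) * (prevObjects[[i]] - prevObjects[[j]])
    }
  }
  list(prev = gPrev, curr = gCurr, value = total)
}

#' Coattention loss over a set of object/background feature pairs
#'
#' For every ordered pair of images (i, j), contrasts the inter-image
#' object distance \code{msd(o_i, o_j)} against the mean intra-image
#' object-background distance \code{(msd(o_i, b_i) + msd(o_j, b_j)) / 2}
#' through the same softmax form, accumulating \code{-log p_ij}. Minimised
#' when the shared object looks alike across images while each image's
#' figure and ground are far apart.
#'
#' @param pairs list of >= 2 feature pairs (\code{object}/\code{background})
#' @param cfg a \code{\link{LossConfig}}
#' @return non-negative scalar; 0 (with a message) when fewer than 2 pairs
#' @export
coattentionLoss <- function(pairs, cfg = lossConfig()) {
  N <- length(pairs)
  if (N < 2L) {
    message("coattention loss needs >= 2 feature pairs; returning 0")
    return(0)
  }
  total <- 0
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j) next
    dplus <- msd(pairs[[i]]$object, pairs[[j]]$object)
    dminus <- 0.5 * (msd(pairs[[i]]$object, pairs[[i]]$background) +
                     msd(pairs[[j]]$object, pairs[[j]]$background))
    total <- total + nlogSigmoid(dminus - dplus)
  }
  total
}

coattentionLossGrad <- function(pairs, cfg = lossConfig()) {
  N <- length(pairs)
  d <- length(pairs[[1L]]$object)
  gO <- lapply(seq_len(N), function(i) numeric(d))
  gB <- lapply(seq_len(N), function(i) numeric(d))
  total <- 0
  if (N >= 2L) {
    for (i in seq_len(N)) for (j in seq_len(N)) {
      if (i == j) next
      oi <- pairs[[i]]$object; oj <- pairs[[j]]$object
      bi <- pairs[[i]]$background; bj <- pairs[[j]]$background
      dplus <- msd(oi, oj)
      dminus <- 0.5 * (msd(oi, bi) + msd(oj, bj))
      z <- dminus - dplus
      total <- total + nlogSigmoid(z)
      dz <- dNlogSigmoid(z)
      gO[[i]] <- gO[[i]] - dz * (2 / d) * (oi - oj) +
        dz * (1 / d) * (oi - bi)
      gO[[j]] <- gO[[j]] + dz * (2 / d) * (oi - oj) +
        dz * (1 / d) * (oj - bj)
      gB[[i]] <- gB[[i]] - dz * (1 / d) * (oi - bi)
      gB[[j]] <- gB[[j]] - dz * (1 / d) * (oj - bj)
    }
  }
  list(object = gO, background = gB, value = total)
}

#' Scheduled total loss
#'
#' Before the final epoch only the coattention term contributes; at the
#' final epoch the cosegmentation and temporal terms activate with their
#' configured weights (1 / 0.5 / 0.5 by default). Setting
#' \code{lateLosses = FALSE} applies the full combination at every epoch.
#'
#' @param lca,lcs,lt the three loss values
#' @param cfg a \code{\link{LossConfig}}
#' @param epoch current epoch in \code{[1, cfg@epochs]}
#' @return weighted total
#' @export
totalLoss <- function(lca, lcs, lt, cfg = lossConfig(), epoch = 1L) {
  stopifnot(epoch >= 1L, epoch <= cfg@epochs)
  if (cfg@lateLosses && epoch < cfg@epochs) return(cfg@wCa * lca)
  cfg@wCa * lca + cfg@wCs * lcs + cfg@wT * lt
}
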