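#' Object/background feature extraction from a masked image
#'
#' Computes \code{object = F(src * heat)} and
#' \code{background = F(src * (1 - heat))}, where \code{*} is per-pixel
#' multiplication broadcast over channels and \code{F} the frozen feature
#' constructor.
#'
#' @param src W x H x 3 array
#' @param heat matrix in [0,1], same spatial size
#' @param fc feature-constructor parameters from \code{\link{fcInit}}
#' @param withCache keep forward caches (for backpropagation)
#' @return list with \code{object}, \code{background} vectors (and caches
#'   when requested)
#' @export
extractFeatures <- function(src, heat, fc, withCache = FALSE) {
  d <- dim(src)
  if (!identical(d[1:2], dim(heat)))
    stop("image and heat map spatial sizes differ")
  if (min(heat) < 0 || max(heat) > 1) stop("heat map must lie in [0,1]")
  hm3 <- array(heat, d)       # broadcast over channels
  fo <- fcForward(fc, src * hm3)
  fb <- fcForward(fc, src * (1 - hm3))
  out <- list(object = fo$features, background = fb$features)
  if (withCache) {
    out$cacheO <- fo$cache
    out$cacheB <- fb$cache
  }
  out
}

compInputFor <- function(cfg, mask, img) {
  switch(cfg@compInput,
         mask = array(mask, c(dim(mask), 3L)),
         image = img,
         masked_image = img * array(mask, c(dim(mask), 3L)))
}

# One temporal pair (t, t+1) inside a (view, modality) group: run the
# heat-map network on every algorithm candidate of both frames, extract
# features, evaluate the scheduled losses and accumulate parameter
# gradients. Returns the gradient list and loss values.
pairStep <- function(comp, fc, imgs, maskPrev, maskCurr, cfg, epoch) {
  algs <- names(maskPrev)
  blend <- cfg@lateLosses && epoch <= cfg@minEpochs
  finalEpoch <- !cfg@lateLosses || epoch == cfg@epochs

  st <- list()   # per (frame, algorithm) forward state
  pairsAll <- list()
  for (fr in c("prev", "curr")) {
    msk <- if (fr == "prev") maskPrev else maskCurr
    img <- imgs[[fr]]
    for (a in algs) {
      fwd <- compForward(comp, compInputFor(cfg, msk[[a]], img))
      heat <- if (blend) 0.5 * (fwd$heat + msk[[a]]) else fwd$heat
      ft <- extractFeatures(img, heat, fc, withCache = TRUE)
      st[[paste(fr, a)]] <- list(fwd = fwd, heat = heat, img = img,
                                 features = ft, frame = fr, alg = a)
      pairsAll[[paste(fr, a)]] <- list(object = ft$object,
                                       background = ft$background)
    }
  }

  gFeat <- lapply(st, function(s)
    list(object = numeric(length(s$features$object)),
         background = numeric(length(s$features$object))))

  gca <- coattentionLossGrad(pairsAll, cfg)
  lca <- gca$value
  for (i in seq_along(pairsAll)) {
    gFeat[[i]]$object <- gFeat[[i]]$object + cfg@wCa * gca$object[[i]]
    gFeat[[i]]$background <- gFeat[[i]]$background +
      cfg@wCa * gca$background[[i]]
  }

  lcs <- 0; lt <- 0
  if (finalEpoch) {
    # cosegmentation: previous vs current frame of the same algorithm
    for (a in algs) {
      kp <- paste("prev", a); kc <- paste("curr", a)
      g <- cosegmentationLossGrad(pairsAll[[kp]], pairsAll[[kc]], cfg)
      lcs <- lcs + g$value / length(algs)
      w <- cfg@wCs / length(algs)
      gFeat[[kp]]$object <- gFeat[[kp]]$object + w * g$Ao
      gFeat[[kp]]$background <- gFeat[[kp]]$background + w * g$Ab
      gFeat[[kc]]$object <- gFeat[[kc]]$object + w * g$Bo
      gFeat[[kc]]$background <- gFeat[[kc]]$background + w * g$Bb
    }
    # temporal: object features aligned by algorithm
    if (length(algs) >= 2L) {
      prevO <- lapply(algs, function(a) pairsAll[[paste("prev", a)]]$object)
      currO <- lapply(algs, function(a) pairsAll[[paste("curr", a)]]$object)
      g <- temporalLossGrad(prevO, currO, cfg)
      lt <- g$value
      for (ai in seq_along(algs)) {
        kp <- paste("prev", algs[ai]); kc <- paste("curr", algs[ai])
        gFeat[[kp]]$object <- gFeat[[kp]]$object + cfg@wT * g$prev[[ai]]
        gFeat[[kc]]$object <- gFeat[[kc]]$object + cfg@wT * g$curr[[ai]]
      }
    }
  }

  # backpropagate through the feature constructor and heat-map network
  grads <- NULL
  for (k in names(st)) {
    s <- st[[k]]
    dXo <- fcBackwardInput(fc, s$features$cacheO, gFeat[[k]]$object)
    dXb <- fcBackwardInput(fc, s$features$cacheB, gFeat[[k]]$background)
    dheat <- dXo[, , 1L] * s$img[, , 1L] + dXo[, , 2L] * s$img[, , 2L] +
      dXo[, , 3L] * s$img[, , 3L] -
      dXb[, , 1L] * s$img[, , 1L] - dXb[, , 2L] * s$img[, , 2L] -
      dXb[, , 3L] * s$img[, , 3L]
    if (blend) dheat <- 0.5 * dheat
    g <- compBackward(comp, s$fwd$cache, dheat)
    grads <- if (is.null(grads)) g else
      stats::setNames(lapply(names(g), function(n) grads[[n]] + g[[n]]),
                      names(g))
  }
  list(grads = grads, lca = lca, lcs = lcs, lt = lt,
       total = totalLoss(lca, lcs, lt, cfg, epoch))
}

#' Stage 2: train the heat-map network and emit refined heat maps
#'
#' For each (view, modality) group the consecutive time pairs (t, t+1) are
#' visited in order; per pair the batch consists of the available base
#' algorithm candidates of both frames (batch size = number of
#' algorithms). The coattention loss is applied throughout; the
#' cosegmentation and temporal losses activate at the final epoch. During
#' the first \code{minEpochs} epochs the network's heat maps are
#' stabilised by pixel-wise averaging with the Stage-1 masks before
#' feature extraction. Gradients are zeroed at each pair; Adam updates the
#' heat-map network only (the feature constructor is frozen). After the
#' final epoch, heat maps are emitted for every (time, view, modality,
#' algorithm) entry of the mask set.
#'
#' @param maskset Stage-1 \code{\link{MaskSet}}
#' @param dataset the source \code{\link{VstemDataset}}
#' @param cfg a \code{\link{LossConfig}}
#' @param side working resolution (pixels, divisible by 4)
#' @param seed integer seed for weight initialisation (overrides
#'   \code{cfg@seed} when given)
#' @param verbose print per-epoch loss summaries
#' @return a \code{\link{HeatMapSet}}
#' @export
trainRefinement <- function(maskset, dataset, cfg = lossConfig(),
                            side = 96L, seed = NULL, verbose = FALSE) {
  side <- as.integer(side)
  if (side %% 4L != 0L) stop("working resolution must be divisible by 4")
  if (!is.null(seed)) cfg@seed <- as.integer(seed)
  rec <- records(dataset)
  algs <- algorithms(maskset)
  if (length(algs) < 1L) stop("mask set has no algorithm layers")

  # working-resolution caches of images and masks
  imgCache <- list(); mskCache <- list()
  for (r in seq_len(nrow(rec))) {
    row <- as.list(rec[r, ])
    rkey <- maskKey(row$plant, row$time, row$view, row$modality)
    imgCache[[rkey]] <- resizeToWorking(readImageArray(row$path), side,
                                        "bilinear")
    for (a in algs) {
      k <- maskKey(row$plant, row$time, row$view, row$modality, a)
      m <- masks(maskset)[[k]]
      if (!is.null(m)) mskCache[[k]] <- resizeToWorking(m, side, "nearest")
    }
  }

  groups <- unique(rec[, c("plant", "view", "modality")])
  pairsOf <- function(g) {
    tt <- sort(rec$time[rec$plant == g$plant & rec$view == g$view &
                        rec$modality == g$modality])
    tt[which(diff(tt) >= 1L)]  # t with a successor (gaps allowed, ordered)
  }
  havePair <- any(vapply(seq_len(nrow(groups)), function(i) {
    length(pairsOf(as.list(groups[i, ]))) > 0
  }, logical(1)))
  if (!havePair) stop("no valid temporal pair in any (view, modality) group")

  comp <- compInit(cfg@seed)
  fc <- fcInit(cfg@seed, cfg@featureDim)
  adam <- adamInit(comp)

  for (epoch in seq_len(cfg@epochs)) {
    eloss <- c(lca = 0, lcs = 0, lt = 0, n = 0)
    for (gi in seq_len(nrow(groups))) {
      g <- as.list(groups[gi, ])
      tt <- sort(rec$time[rec$plant == g$plant & rec$view == g$view &
                          rec$modality == g$modality])
      if (length(tt) < 2L) next
      for (pi in seq_len(length(tt) - 1L)) {
        tPrev <- tt[pi]; tCurr <- tt[pi + 1L]
        getM <- function(tm) {
          out <- list()
          for (a in algs) {
            k <- maskKey(g$plant, tm, g$view, g$modality, a)
            if (!is.null(mskCache[[k]])) out[[a]] <- mskCache[[k]]
          }
          out
        }
        mPrev <- getM(tPrev); mCurr <- getM(tCurr)
        common <- intersect(names(mPrev), names(mCurr))
        if (length(common) < length(algs) && verbose)
          message("reduced batch at (", g$view, ", ", g$modality, ", t=",
                  tPrev, "): ", length(common), " of ", length(algs),
                  " algorithms present")
        if (length(common) < 1L) next
        imgs <- list(
          prev = imgCache[[maskKey(g$plant, tPrev, g$view, g$modality)]],
          curr = imgCache[[maskKey(g$plant, tCurr, g$view, g$modality)]])
        step <- pairStep(comp, fc, imgs, mPrev[common], mCurr[common],
                         cfg, epoch)
        upd <- adamStep(comp, step$grads, adam, cfg@lr, cfg@weightDecay)
        comp <- upd$params; adam <- upd$state
        class(comp) <- "comp_net"
        eloss <- eloss + c(step$lca, step$lcs, step$lt, 1)
      }
    }
    if (verbose)
      message(sprintf("epoch %d/%d: Lca %.4f Lcs %.4f Lt %.4f (%d pairs)",
                      epoch, cfg@epochs, eloss[1] / max(eloss[4], 1),
                      eloss[2] / max(eloss[4], 1),
                      eloss[3] / max(eloss[4], 1), eloss[4]))
  }

  # emit final heat maps for every available (i, j, k, a)
  maps <- list()
  for (r in seq_len(nrow(rec))) {
    row <- as.list(rec[r, ])
    rkey <- maskKey(row$plant, row$time, row$view, row$modality)
    for (a in algs) {
      k <- maskKey(row$plant, row$time, row$view, row$modality, a)
      if (is.null(mskCache[[k]])) next
      fwd <- compForward(comp, compInputFor(cfg, mskCache[[k]],
                                            imgCache[[rkey]]))
      maps[[k]] <- pmin(pmax(fwd$heat, 0), 1)
    }
  }
  new("HeatMapSet", maps = maps, algorithms = algs, side = side)
}
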