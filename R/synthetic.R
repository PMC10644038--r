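#' Configuration of the synthetic plant-image generator
#'
#' Defaults emulate the structure of turntable phenotyping collections:
#' several time points over which the plant only grows, side views at 72
#' degree increments, and three modalities (visible, fluorescence,
#' infrared) re-rendering the same ground-truth shape with
#' modality-specific colours, contrast and noise.
#'
#' @param nTime time points (>= 2)
#' @param nViews side views (72-degree in-plane rotation steps)
#' @param nModalities 1-3 modalities, ordered visible, fluorescence,
#'   infrared
#' @param side image side in pixels (>= 32; 96 is a practical desk scale,
#'   384 matches full-scale processing)
#' @param growthRate fraction of the skeleton revealed per time step
#'   relative to uniform growth (1 = plant completes at the last time
#'   point)
#' @param branchCount lateral branches
#' @param noiseLevel per-pixel Gaussian sensor noise sd
#' @param dilatePx,erodePx,flipFraction default corruption settings for
#'   \code{\link{corruptMask}}
#' @param seed integer seed; generation is bitwise deterministic given it
#' @return a \code{\link{SyntheticConfig}}
#' @export
syntheticConfig <- function(nTime = 5L, nViews = 4L, nModalities = 3L,
                            side = 96L, growthRate = 1, branchCount = 4L,
                            noiseLevel = 0.04, dilatePx = 2L, erodePx = 2L,
                            flipFraction = 0.02, seed = 1L) {
  new("SyntheticConfig", nTime = as.integer(nTime),
      nViews = as.integer(nViews), nModalities = as.integer(nModalities),
      side = as.integer(side), growthRate = growthRate,
      branchCount = as.integer(branchCount), noiseLevel = noiseLevel,
      dilatePx = as.integer(dilatePx), erodePx = as.integer(erodePx),
      flipFraction = flipFraction, seed = as.integer(seed))
}

MODALITY_PALETTE <- list(
  visible = list(fg = c(0.15, 0.75, 0.20), bg = c(0.13, 0.11, 0.09)),
  fluorescence = list(fg = c(0.80, 0.15, 0.10), bg = c(0.04, 0.02, 0.03)),
  infrared = list(fg = c(0.62, 0.62, 0.62), bg = c(0.45, 0.45, 0.45)))

smoothField <- function(side, coarse = 8L) {
  # low-frequency field: coarse random grid upsampled bilinearly
  f <- matrix(rnorm(coarse * coarse), coarse, coarse)
  up <- EBImage::imageData(EBImage::resize(EBImage::Image(f), w = side,
                                           h = side, filter = "bilinear"))
  matrix(as.numeric(up), side, side)
}

# random branching skeleton; each point carries a growth index in (0, 1]
plantSkeleton <- function(cfg) {
  side <- cfg@side
  nStem <- round(0.72 * side)
  x <- side / 2; y <- 0.92 * side
  pts <- matrix(0, 0, 3)   # x, y, growth index
  stem <- matrix(0, nStem, 2)
  for (s in seq_len(nStem)) {
    x <- x + rnorm(1, 0, 0.35)
    y <- y - 1
    stem[s, ] <- c(x, y)
    pts <- rbind(pts, c(x, y, s / nStem))
  }
  for (b in seq_len(cfg@branchCount)) {
    gAtt <- runif(1, 0.15, 0.65)
    at <- stem[max(1L, round(gAtt * nStem)), ]
    ang <- runif(1, pi / 6, pi / 2.2) * sample(c(-1, 1), 1)
    len <- round(runif(1, 0.18, 0.38) * nStem)
    bx <- at[1L]; by <- at[2L]
    for (s in seq_len(len)) {
      bx <- bx + sin(ang) + rnorm(1, 0, 0.3)
      by <- by - cos(ang) * 0.8
      g <- gAtt + (s / len) * (1 - gAtt) * 0.8
      pts <- rbind(pts, c(bx, by, g))
    }
  }
  pts
}

rasterizeSkeleton <- function(pts, side, frac, radius) {
  m <- matrix(0, side, side)
  keep <- pts[pts[, 3L] <= frac, , drop = FALSE]
  if (nrow(keep)) {
    xi <- pmin(pmax(round(keep[, 1L]), 1L), side)
    yi <- pmin(pmax(round(keep[, 2L]), 1L), side)
    m[cbind(xi, yi)] <- 1
  }
  if (radius > 0)
    m <- EBImage::imageData(EBImage::dilate(
      EBImage::Image(m), EBImage::makeBrush(2L * radius + 1L, "disc")))
  matrix(as.numeric(m), side, side)
}

rotateBinary <- function(m, angle) {
  if (angle %% 360 == 0) return(m)
  side <- nrow(m)
  out <- EBImage::imageData(EBImage::rotate(
    EBImage::Image(m), angle, filter = "none",
    output.dim = c(side, side), bg.col = 0))
  matrix(as.numeric(out > 0.5), side, side)
}

renderModality <- function(mask, modality, texture, noise) {
  pal <- MODALITY_PALETTE[[modality]]
  side <- nrow(mask)
  img <- array(0, c(side, side, 3L))
  shade <- 1 + 0.25 * texture    # gentle illumination field
  for (c in 1:3) {
    bg <- pal$bg[c] * shade
    fg <- pal$fg[c] * (1 + 0.08 * texture)
    img[, , c] <- bg * (1 - mask) + fg * mask + noise[, , c]
  }
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic temporal multi-view multi-modality dataset
#'
#' Renders a randomly branching plant that grows monotonically over time
#' (the mask at t is a subset of the mask at t+1, before view rotation),
#' rotated in-plane per view (a 2-D proxy for turntable side views) and
#' re-rendered per modality over a textured background with sensor noise.
#' Ground-truth masks are exact by construction. The dataset is written in
#' the package's on-disk layout with a manifest and is bitwise
#' deterministic given the seed.
#'
#' @param cfg a \code{\link{SyntheticConfig}}
#' @param dir output directory
#' @param plant plant identifier
#' @param writeTruth also write the ground-truth masks under
#'   \code{<dir>/truth}
#' @return list with \code{dataset} (a \code{\link{VstemDataset}}) and
#'   \code{truth} (a \code{\link{MaskSet}} with the single pseudo-algorithm
#'   "truth")
#' @export
generateVstem <- function(cfg = syntheticConfig(), dir = tempfile("vstem"),
                          plant = "plant1", writeTruth = TRUE) {
  validObject(cfg)
  if (cfg@nModalities > 3L) stop("at most 3 modalities are supported")
  set.seed(cfg@seed)
  side <- cfg@side
  modalities <- names(MODALITY_PALETTE)[seq_len(cfg@nModalities)]
  angles <- if (cfg@nViews <= 5L) 72 * (seq_len(cfg@nViews) - 1L)
            else round(360 * (seq_len(cfg@nViews) - 1L) / cfg@nViews)
  views <- sprintf("v%03d", angles)

  pts <- plantSkeleton(cfg)
  # base (unrotated) truth per time; radius non-decreasing => nested masks
  fracs <- pmin(1, cfg@growthRate * seq_len(cfg@nTime) / cfg@nTime)
  radii <- 1L + as.integer(seq_len(cfg@nTime) > cfg@nTime / 2)
  baseMasks <- lapply(seq_len(cfg@nTime), function(t)
    rasterizeSkeleton(pts, side, fracs[t], radii[t]))

  # per-(view, modality) background texture; per-record sensor noise
  textures <- list()
  for (v in views) for (md in modalities)
    textures[[paste(v, md)]] <- smoothField(side)

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  recs <- list()
  truth <- list()
  for (vi in seq_along(views)) {
    rotMasks <- lapply(baseMasks, rotateBinary, angle = angles[vi])
    for (md in modalities) {
      tex <- textures[[paste(views[vi], md)]]
      for (t in seq_len(cfg@nTime)) {
        noise <- array(rnorm(side * side * 3L, 0, cfg@noiseLevel),
                       c(side, side, 3L))
        img <- renderModality(rotMasks[[t]], md, tex, noise)
        rel <- file.path(plant, md, views[vi], sprintf("t%02d.png", t))
        fp <- file.path(dir, rel)
        dir.create(dirname(fp), recursive = TRUE, showWarnings = FALSE)
        EBImage::writeImage(EBImage::Image(img, colormode = "Color"),
                            fp, bits = 8L)
        recs[[rel]] <- list(plant = plant, time = t, view = views[vi],
                            modality = md, path = rel)
        truth[[maskKey(plant, t, views[vi], md, "truth")]] <- rotMasks[[t]]
      }
    }
  }
  man <- list(type = "vstem", views = views, modalities = modalities,
              records = unname(recs))
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  truthSet <- new("MaskSet", masks = truth, algorithms = "truth")
  if (writeTruth) writeMasks(truthSet, file.path(dir, "truth"))
  list(dataset = loadDataset(dir), truth = truthSet)
}

#' Corrupt a binary mask (imperfect base-segmenter model)
#'
#' Applies morphological dilation and/or erosion followed by independent
#' per-pixel flips with probability \code{flipFraction}.
#'
#' @param truth 0/1 matrix
#' @param dilatePx,erodePx disc radii (0 = skip)
#' @param flipFraction per-pixel flip probability
#' @param seed integer seed for the flips
#' @return 0/1 matrix
#' @export
corruptMask <- function(truth, dilatePx = 0L, erodePx = 0L,
                        flipFraction = 0, seed = 1L) {
  m <- truth
  if (dilatePx > 0)
    m <- EBImage::imageData(EBImage::dilate(
      EBImage::Image(m), EBImage::makeBrush(2L * dilatePx + 1L, "disc")))
  if (erodePx > 0)
    m <- EBImage::imageData(EBImage::erode(
      EBImage::Image(m), EBImage::makeBrush(2L * erodePx + 1L, "disc")))
  m <- matrix(as.numeric(m), nrow(truth), ncol(truth))
  if (flipFraction > 0) {
    set.seed(seed)
    flip <- runif(length(m)) < flipFraction
    m[flip] <- 1 - m[flip]
  }
  m
}
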