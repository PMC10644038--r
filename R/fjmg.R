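#' Dense-CRF hyperparameters
#'
#' @param bilateralWeight,bilateralSpatialSd,rgbSd appearance (bilateral)
#'   kernel: weight 10, spatial sd 80 px, colour sd 13 (8-bit scale)
#' @param spatialWeight,spatialSd smoothness (Gaussian) kernel: weight 3.0,
#'   spatial sd 3 px
#' @param iterations mean-field iterations (5)
#' @return a \code{\link{CrfParams}}
#' @export
crfParams <- function(bilateralWeight = 10, bilateralSpatialSd = 80,
                      rgbSd = 13, spatialWeight = 3, spatialSd = 3,
                      iterations = 5L) {
  new("CrfParams", bilateralWeight = bilateralWeight,
      bilateralSpatialSd = bilateralSpatialSd, rgbSd = rgbSd,
      spatialWeight = spatialWeight, spatialSd = spatialSd,
      iterations = as.integer(iterations))
}

#' Refine a heat map with dense-CRF mean-field inference
#'
#' Two-class fully connected CRF over the image: unary potentials are
#' \code{-log} of the (clamped) heat map and its complement; pairwise
#' potentials combine an appearance kernel (position + colour) and a
#' smoothness kernel (position only) under a Potts compatibility. The
#' output is the per-pixel argmax after the configured number of
#' mean-field iterations; with \code{iterations = 0} it reduces to
#' \code{heat > 0.5}. A pure function of its inputs.
#'
#' @param img W x H x 3 array in [0,1]
#' @param heat matrix in [0,1], same spatial size
#' @param params a \code{\link{CrfParams}}
#' @return 0/1 matrix
#' @export
denseCrfRefine <- function(img, heat, params = crfParams()) {
  d <- dim(img)
  if (!identical(d[1:2], dim(heat)))
    stop("image and heat map spatial sizes differ")
  if (min(heat) < 0 || max(heat) > 1) stop("heat map must lie in [0,1]")
  n <- d[1L] * d[2L]
  rgb <- matrix(img, n, 3L)
  q1 <- crf_meanfield_cpp(rgb, as.numeric(heat), d[1L], d[2L],
                          params@bilateralWeight, params@bilateralSpatialSd,
                          params@rgbSd, params@spatialWeight,
                          params@spatialSd, params@iterations, 1e-8)
  matrix(as.numeric(q1 > 0.5), d[1L], d[2L])
}

#' Jaccard index between two binary masks
#' @param a,b 0/1 matrices of equal shape
#' @return |a intersect b| / |a union b|; 1 when both are empty
#' @export
maskJaccard <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  uni <- sum(a == 1 | b == 1)
  if (uni == 0) return(1)
  sum(a == 1 & b == 1) / uni
}

#' Select the final mask among refined candidates
#'
#' Returns the candidate with the highest Jaccard similarity to the
#' reference mask; ties resolve to the lowest algorithm index (list
#' order).
#'
#' @param candidates named, ordered list of 0/1 matrices (one per
#'   algorithm)
#' @param reference 0/1 matrix
#' @return list with \code{mask}, \code{algorithm}, and the named
#'   \code{scores} vector
#' @export
selectFinalMask <- function(candidates, reference) {
  if (length(candidates) < 1L) stop("no candidates to select from")
  scores <- vapply(candidates, maskJaccard, numeric(1), b = reference)
  best <- which.max(scores)   # first maximum on ties
  list(mask = candidates[[best]], algorithm = names(candidates)[best],
       scores = scores)
}

#' Pixel-wise consensus of a record's Stage-1 masks
#'
#' Mean over algorithm layers thresholded at 0.5 (ties to foreground).
#' Used as the selection reference: the only mask-level information the
#' unsupervised pipeline possesses about a record.
#'
#' @param maskList list of 0/1 matrices
#' @return 0/1 matrix
#' @export
consensusMask <- function(maskList) {
  s <- Reduce(`+`, maskList) / length(maskList)
  (s >= 0.5) * 1
}

#' Stage 3: refine every heat map and select the final mask per record
#'
#' Each candidate heat map is resized back to the record's original
#' resolution, refined by \code{\link{denseCrfRefine}} against the
#' original image, and scored by Jaccard similarity to a reference
#' computed from the record itself: the Stage-1 consensus mask
#' (\code{reference = "consensus"}, default) or an Otsu segmentation of
#' the image (\code{"otsu"}). The best-scoring candidate becomes the final
#' mask; exactly one final mask is produced per (time, view, modality)
#' record that has at least one candidate.
#'
#' @param dataset a \code{\link{VstemDataset}}
#' @param heatmaps a \code{\link{HeatMapSet}}
#' @param maskset the Stage-1 \code{\link{MaskSet}} (for the consensus
#'   reference)
#' @param params a \code{\link{CrfParams}}
#' @param reference "consensus" or "otsu"
#' @return a \code{\link{FinalMaskSet}}
#' @export
runFJMG <- function(dataset, heatmaps, maskset = NULL,
                    params = crfParams(),
                    reference = c("consensus", "otsu")) {
  reference <- match.arg(reference)
  if (reference == "consensus" && is.null(maskset))
    stop("consensus reference needs the Stage-1 mask set")
  rec <- records(dataset)
  algs <- algorithms(heatmaps)
  hm <- heatMaps(heatmaps)
  finals <- list(); chosen <- character(); rows <- list()
  for (r in seq_len(nrow(rec))) {
    row <- as.list(rec[r, ])
    rkey <- maskKey(row$plant, row$time, row$view, row$modality)
    cand <- list()
    img <- NULL
    for (a in algs) {
      k <- maskKey(row$plant, row$time, row$view, row$modality, a)
      if (is.null(hm[[k]])) next
      if (is.null(img)) img <- readImageArray(row$path)
      heat <- hm[[k]]
      if (!identical(dim(heat), dim(img)[1:2])) {
        heat <- EBImage::imageData(EBImage::resize(
          EBImage::Image(heat), w = dim(img)[1L], h = dim(img)[2L],
          filter = "bilinear"))
        heat <- pmin(pmax(heat, 0), 1)
      }
      cand[[a]] <- denseCrfRefine(img, heat, params)
    }
    if (!length(cand)) {
      stop("record without any heat-map candidate: ", rkey)
    }
    ref <- if (reference == "consensus") {
      ml <- list()
      for (a in algorithms(maskset)) {
        k <- maskKey(row$plant, row$time, row$view, row$modality, a)
        m <- masks(maskset)[[k]]
        if (!is.null(m)) {
          if (!identical(dim(m), dim(img)[1:2]))
            m <- resizeToWorking2(m, dim(img)[1:2])
          ml[[a]] <- m
        }
      }
      consensusMask(ml)
    } else {
      otsuThreshold(luminance(img))
    }
    sel <- selectFinalMask(cand, ref)
    finals[[rkey]] <- sel$mask
    chosen[rkey] <- sel$algorithm
    rows[[rkey]] <- data.frame(
      plant = row$plant, time = row$time, view = row$view,
      modality = row$modality, algorithm = names(sel$scores),
      jaccard = as.numeric(sel$scores),
      selected = names(sel$scores) == sel$algorithm,
      stringsAsFactors = FALSE)
  }
  new("FinalMaskSet", masks = finals, chosen = chosen,
      scores = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

# nearest-neighbour resize of a binary mask to an arbitrary target shape
resizeToWorking2 <- function(m, wh) {
  out <- EBImage::imageData(EBImage::resize(EBImage::Image(m),
                                            w = wh[1L], h = wh[2L],
                                            filter = "none"))
  matrix(as.numeric(out), wh[1L], wh[2L])
}
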