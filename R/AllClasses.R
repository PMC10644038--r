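#' @import methods
#' @importFrom stats rnorm runif setNames aggregate
#' @importFrom utils head write.csv read.csv
#' @useDynLib PhenoCoseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' VstemDataset: an indexed temporal multi-view multi-modality image set
#'
#' Container for an image collection of a single plant (or several) indexed
#' by time point \code{i}, side view \code{j} and imaging modality \code{k}.
#' Records are kept sorted by (modality, view, time) and the index triple is
#' unique per plant.
#'
#' @slot records data.frame with columns \code{plant}, \code{time},
#'   \code{view}, \code{modality}, \code{path}, \code{height}, \code{width}.
#' @slot views ordered character vector of view labels.
#' @slot modalities ordered character vector of modality labels.
#'
#' @exportClass VstemDataset
setClass("VstemDataset",
  representation(records = "data.frame",
                 views = "character",
                 modalities = "character"))

setValidity("VstemDataset", function(object) {
  rec <- object@records
  need <- c("plant", "time", "view", "modality", "path", "height", "width")
  if (!all(need %in% names(rec)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (nrow(rec) == 0L) return("dataset has no records")
  key <- paste(rec$plant, rec$time, rec$view, rec$modality)
  if (anyDuplicated(key)) return("duplicate (plant, time, view, modality)")
  if (any(rec$height < 8 | rec$width < 8)) return("images must be >= 8 px")
  if (!all(rec$view %in% object@views)) return("view not in view list")
  if (!all(rec$modality %in% object@modalities))
    return("modality not in modality list")
  ord <- order(match(rec$modality, object@modalities),
               match(rec$view, object@views), rec$time)
  if (!identical(ord, seq_len(nrow(rec))))
    return("records must be sorted by (modality, view, time)")
  TRUE
})

#' MaskSet: binary masks indexed by (plant, time, view, modality, algorithm)
#'
#' Holds the per-algorithm binary masks produced by the mask-generation
#' stage (or ground truth, with a single pseudo-algorithm). Masks are stored
#' in memory as 0/1 matrices; entries may be missing where a base algorithm
#' produced no output.
#'
#' @slot masks named list of 0/1 matrices, keyed by
#'   \code{plant/time/view/modality/algorithm} (see \code{\link{maskKey}}).
#' @slot algorithms ordered character vector of algorithm names.
#' @slot workingRes logical; \code{TRUE} when masks are at the working
#'   resolution rather than the source image resolution.
#'
#' @exportClass MaskSet
setClass("MaskSet",
  representation(masks = "list", algorithms = "character",
                 workingRes = "logical"),
  prototype(workingRes = FALSE))

setValidity("MaskSet", function(object) {
  if (length(object@masks) &&
      (is.null(names(object@masks)) || any(names(object@masks) == "")))
    return("masks must be a named list")
  for (nm in names(object@masks)) {
    m <- object@masks[[nm]]
    if (!is.matrix(m)) return(paste0("mask '", nm, "' is not a matrix"))
    if (!all(m %in% c(0, 1)))
      return(paste0("mask '", nm, "' is not strictly binary"))
  }
  TRUE
})

#' HeatMapSet: per-candidate object-probability maps
#'
#' Output of the refinement stage: one heat map in [0,1] per Stage-1 mask
#' that participated in training, at the working resolution.
#'
#' @slot maps named list of numeric matrices in [0,1], keyed like
#'   \code{\link{MaskSet}}.
#' @slot algorithms character vector of algorithm names.
#' @slot side working resolution (pixels).
#'
#' @exportClass HeatMapSet
setClass("HeatMapSet",
  representation(maps = "list", algorithms = "character", side = "integer"))

setValidity("HeatMapSet", function(object) {
  for (nm in names(object@maps)) {
    m <- object@maps[[nm]]
    if (!is.matrix(m) || any(!is.finite(m)) || min(m) < 0 || max(m) > 1)
      return(paste0("heat map '", nm, "' must be a finite matrix in [0,1]"))
  }
  TRUE
})

#' FinalMaskSet: one selected binary mask per (time, view, modality)
#'
#' @slot masks named list of 0/1 matrices keyed by
#'   \code{plant/time/view/modality}.
#' @slot chosen named character vector: key -> winning algorithm.
#' @slot scores data.frame of per-candidate Jaccard scores against the
#'   selection reference (columns plant, time, view, modality, algorithm,
#'   jaccard, selected).
#'
#' @exportClass FinalMaskSet
setClass("FinalMaskSet",
  representation(masks = "list", chosen = "character", scores = "data.frame"))

#' Segmenter: a pluggable base segmentation algorithm
#'
#' Wraps a function \code{image -> binary mask} (or \code{NULL} to signal
#' "no output", the way external cosegmenters can fail on some records).
#'
#' @slot name algorithm name (used as the algorithm index).
#' @slot fn function taking an H x W x 3 array and an ImageRecord row
#'   (list), returning a 0/1 matrix of the same spatial size or NULL.
#' @slot params free-form parameter list.
#'
#' @exportClass Segmenter
setClass("Segmenter",
  representation(name = "character", fn = "function", params = "list"))

#' LossConfig: training configuration for the heat-map refinement stage
#'
#' Defaults follow the framework's published operating point: loss weights
#' 1 / 0.5 / 0.5 (coattention / cosegmentation / temporal), contrastive
#' margin 2, mean-squared-difference distance convention, 10 epochs with a
#' 2-epoch stabilisation phase, batch size equal to the number of base
#' algorithms, Adam with weight decay 5e-4. The cosegmentation and temporal
#' losses activate at the final epoch only (\code{lateLosses}).
#'
#' @slot wCa,wCs,wT loss weights (coattention, cosegmentation, temporal).
#' @slot margin hinge cutoff of the cosegmentation loss.
#' @slot epochs,minEpochs total epochs and length of the stabilisation
#'   phase during which heat maps are blended with the Stage-1 masks by
#'   pixel-wise averaging.
#' @slot lateLosses if TRUE, cosegmentation + temporal losses only
#'   contribute at the final epoch.
#' @slot lr,weightDecay Adam learning rate and decoupled weight decay.
#' @slot featureDim output dimension of the feature constructor.
#' @slot compInput what the heat-map network consumes: "mask" (Stage-1
#'   binary mask replicated to 3 channels), "image", or "masked_image".
#' @slot backbone "random" (seeded random-init feature constructor).
#' @slot seed integer seed for all weight initialisation.
#'
#' @exportClass LossConfig
setClass("LossConfig",
  representation(wCa = "numeric", wCs = "numeric", wT = "numeric",
                 margin = "numeric", epochs = "integer",
                 minEpochs = "integer", lateLosses = "logical",
                 lr = "numeric", weightDecay = "numeric",
                 featureDim = "integer", compInput = "character",
                 backbone = "character", seed = "integer"))

setValidity("LossConfig", function(object) {
  if (any(c(object@wCa, object@wCs, object@wT) < 0))
    return("loss weights must be >= 0")
  if (object@margin <= 0) return("margin must be > 0")
  if (object@epochs < object@minEpochs || object@minEpochs < 2L)
    return("need epochs >= minEpochs >= 2")
  if (!object@compInput %in% c("mask", "image", "masked_image"))
    return("compInput must be one of mask/image/masked_image")
  TRUE
})

#' CrfParams: dense-CRF hyperparameters
#'
#' Defaults are the published operating point of the fully connected CRF:
#' appearance (bilateral) kernel with weight 10, spatial standard deviation
#' 80 px and colour standard deviation 13 (8-bit scale); smoothness
#' (Gaussian) kernel with weight 3.0 and spatial standard deviation 3 px;
#' 5 mean-field iterations.
#'
#' @slot bilateralWeight,bilateralSpatialSd,rgbSd appearance kernel.
#' @slot spatialWeight,spatialSd smoothness kernel.
#' @slot iterations mean-field iterations (0 reduces to thresholding the
#'   heat map at 0.5).
#'
#' @exportClass CrfParams
setClass("CrfParams",
  representation(bilateralWeight = "numeric", bilateralSpatialSd = "numeric",
                 rgbSd = "numeric", spatialWeight = "numeric",
                 spatialSd = "numeric", iterations = "integer"))

setValidity("CrfParams", function(object) {
  v <- c(object@bilateralWeight, object@bilateralSpatialSd, object@rgbSd,
         object@spatialWeight, object@spatialSd)
  if (any(v <= 0)) return("all CRF parameters must be positive")
  if (object@iterations < 0L) return("iterations must be >= 0")
  TRUE
})

#' SyntheticConfig: parameters of the synthetic plant-image generator
#'
#' @slot nTime,nViews,nModalities index-space sizes.
#' @slot side image side in pixels.
#' @slot growthRate fraction of the full skeleton revealed per time step.
#' @slot branchCount number of lateral branches.
#' @slot noiseLevel standard deviation of per-pixel Gaussian sensor noise.
#' @slot dilatePx,erodePx,flipFraction default mask-corruption settings.
#' @slot seed integer seed.
#'
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  representation(nTime = "integer", nViews = "integer",
                 nModalities = "integer", side = "integer",
                 growthRate = "numeric", branchCount = "integer",
                 noiseLevel = "numeric", dilatePx = "integer",
                 erodePx = "integer", flipFraction = "numeric",
                 seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  if (object@nTime < 2L) return("nTime must be >= 2 (temporal pairs)")
  if (object@side < 32L) return("side must be >= 32")
  if (object@nViews < 1L || object@nModalities < 1L)
    return("need >= 1 view and modality")
  TRUE
})
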