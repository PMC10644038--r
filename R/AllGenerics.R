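#' @describeIn VstemDataset number of records
#' @param x,object a VstemDataset
#' @export
setGeneric("nRecords", function(x) standardGeneric("nRecords"))
setMethod("nRecords", "VstemDataset", function(x) nrow(x@records))

#' @describeIn VstemDataset the record table
#' @export
setGeneric("records", function(x) standardGeneric("records"))
setMethod("records", "VstemDataset", function(x) x@records)

#' @describeIn VstemDataset number of time points (m)
#' @export
setGeneric("nTimePoints", function(x) standardGeneric("nTimePoints"))
setMethod("nTimePoints", "VstemDataset",
          function(x) length(unique(x@records$time)))

#' @describeIn VstemDataset ordered view labels (p views)
#' @export
setGeneric("viewLabels", function(x) standardGeneric("viewLabels"))
setMethod("viewLabels", "VstemDataset", function(x) x@views)

#' @describeIn VstemDataset ordered modality labels (o modalities)
#' @export
setGeneric("modalityLabels", function(x) standardGeneric("modalityLabels"))
setMethod("modalityLabels", "VstemDataset", function(x) x@modalities)

setMethod("show", "VstemDataset", function(object) {
  r <- object@records
  cat("VstemDataset:", nrow(r), "records |",
      length(unique(r$plant)), "plant(s),",
      length(unique(r$time)), "time points,",
      length(object@views), "views,",
      length(object@modalities), "modalities\n")
  cat("  views:", paste(object@views, collapse = ", "), "\n")
  cat("  modalities:", paste(object@modalities, collapse = ", "), "\n")
})

#' @describeIn MaskSet algorithm names
#' @param x,object a MaskSet
#' @export
setGeneric("algorithms", function(x) standardGeneric("algorithms"))
setMethod("algorithms", "MaskSet", function(x) x@algorithms)
setMethod("algorithms", "HeatMapSet", function(x) x@algorithms)

#' @describeIn MaskSet the named list of 0/1 matrices
#' @export
setGeneric("masks", function(x) standardGeneric("masks"))
setMethod("masks", "MaskSet", function(x) x@masks)
setMethod("masks", "FinalMaskSet", function(x) x@masks)

#' @describeIn HeatMapSet the named list of heat-map matrices
#' @export
setGeneric("heatMaps", function(x) standardGeneric("heatMaps"))
setMethod("heatMaps", "HeatMapSet", function(x) x@maps)

#' @describeIn FinalMaskSet per-candidate Jaccard scores table
#' @export
setGeneric("candidateScores", function(x) standardGeneric("candidateScores"))
setMethod("candidateScores", "FinalMaskSet", function(x) x@scores)

#' @describeIn FinalMaskSet winning algorithm per record
#' @export
setGeneric("chosenAlgorithm", function(x) standardGeneric("chosenAlgorithm"))
setMethod("chosenAlgorithm", "FinalMaskSet", function(x) x@chosen)

setMethod("show", "MaskSet", function(object) {
  cat("MaskSet:", length(object@masks), "masks |",
      length(object@algorithms), "algorithm(s):",
      paste(object@algorithms, collapse = ", "), "\n")
})

setMethod("show", "HeatMapSet", function(object) {
  cat("HeatMapSet:", length(object@maps), "heat maps at",
      object@side, "px |", paste(object@algorithms, collapse = ", "), "\n")
})

setMethod("show", "FinalMaskSet", function(object) {
  cat("FinalMaskSet:", length(object@masks), "final masks; selections:\n")
  print(table(object@chosen))
})

setMethod("show", "Segmenter", function(object) {
  cat("Segmenter:", object@name, "\n")
})

#' Index key for mask-like containers
#'
#' Builds the canonical \code{plant/time/view/modality[/algorithm]} key used
#' by \code{\link{MaskSet}}, \code{\link{HeatMapSet}} and
#' \code{\link{FinalMaskSet}}.
#'
#' @param plant plant identifier
#' @param time time index (integer >= 1)
#' @param view view label
#' @param modality modality label
#' @param algorithm optional algorithm name
#' @return character key
#' @export
maskKey <- function(plant, time, view, modality, algorithm = NULL) {
  k <- paste(plant, time, view, modality, sep = "/")
  if (!is.null(algorithm)) k <- paste(k, algorithm, sep = "/")
  k
}
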