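#' Pixel precision of a predicted mask
#'
#' TP / (TP + FP): the fraction of predicted foreground pixels that are
#' truly foreground. An empty prediction (no foreground, hence no false
#' positives) is scored 1 by convention, with a message, so temporal
#' sequences with tiny early plants do not propagate NaN.
#'
#' @param pred,truth 0/1 matrices of equal shape
#' @return scalar in [0,1]
#' @export
maskPrecision <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) stop("mask shapes differ")
  posP <- sum(pred == 1)
  if (posP == 0) {
    message("empty prediction: precision defined as 1")
    return(1)
  }
  sum(pred == 1 & truth == 1) / posP
}

#' Evaluate a mask collection against ground truth
#'
#' Computes per-record precision and Jaccard, then unweighted means per
#' (modality, view), per modality, and overall, mirroring the usual
#' per-view / per-modality reporting layout.
#'
#' @param pred named list of 0/1 matrices keyed by
#'   \code{plant/time/view/modality} (e.g. \code{masks(finalMaskSet)}), or
#'   a \code{\link{FinalMaskSet}}
#' @param truth named list of 0/1 matrices with matching keys, or a
#'   single-algorithm \code{\link{MaskSet}} of ground-truth masks
#' @return list with \code{perRecord}, \code{perView},
#'   \code{perModality} and \code{overall} data frames
#' @export
evaluateDataset <- function(pred, truth) {
  if (is(pred, "FinalMaskSet")) pred <- masks(pred)
  if (is(truth, "MaskSet")) {
    tm <- masks(truth)
    names(tm) <- vapply(strsplit(names(tm), "/", fixed = TRUE),
                        function(p) paste(p[1:4], collapse = "/"), "")
    truth <- tm
  }
  missP <- setdiff(names(truth), names(pred))
  missT <- setdiff(names(pred), names(truth))
  if (length(missP) || length(missT))
    stop("index mismatch; missing predictions: ",
         paste(utils::head(missP, 5), collapse = ", "),
         "; missing truth: ", paste(utils::head(missT, 5), collapse = ", "))
  keys <- names(pred)
  parts <- strsplit(keys, "/", fixed = TRUE)
  per <- data.frame(
    plant = vapply(parts, `[`, "", 1L),
    time = as.integer(vapply(parts, `[`, "", 2L)),
    view = vapply(parts, `[`, "", 3L),
    modality = vapply(parts, `[`, "", 4L),
    precision = vapply(keys, function(k)
      maskPrecision(pred[[k]], truth[[k]]), numeric(1)),
    jaccard = vapply(keys, function(k)
      maskJaccard(pred[[k]], truth[[k]]), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(per) <- NULL
  agg <- function(by) {
    out <- aggregate(per[, c("precision", "jaccard")], by = per[by],
                     FUN = mean)
    out
  }
  list(perRecord = per,
       perView = agg(c("modality", "view")),
       perModality = agg("modality"),
       overall = data.frame(precision = mean(per$precision),
                            jaccard = mean(per$jaccard)))
}

#' Write an evaluation report as CSV files
#'
#' @param report output of \code{\link{evaluateDataset}}
#' @param out directory
#' @return invisibly, the file paths
#' @export
writeEvalReport <- function(report, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  paths <- c(perRecord = file.path(out, "metrics_per_record.csv"),
             perView = file.path(out, "metrics_per_view.csv"),
             perModality = file.path(out, "metrics_per_modality.csv"),
             overall = file.path(out, "metrics_overall.csv"))
  for (nm in names(paths))
    utils::write.csv(report[[nm]], paths[[nm]], row.names = FALSE)
  invisible(paths)
}
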