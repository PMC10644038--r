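#' Default run configuration
#'
#' A plain named list mirroring the YAML config consumed by the command
#' line interface: stage selection, module parameter blocks and the global
#' seed. Every stochastic component derives from \code{seed}.
#'
#' @param input dataset directory
#' @param output run directory
#' @param seed global integer seed
#' @return named list
#' @export
defaultRunConfig <- function(input = NULL, output = NULL, seed = 1L) {
  list(
    input = input,
    output = output,
    seed = as.integer(seed),
    stages = c("omg", "omr", "fjmg", "evaluate"),
    working_side = 96L,
    omg = list(segmenters = c("otsu", "excess_green"),
               excess_green_threshold = 0.05,
               otsu_invert = list(),
               precomputed = list()),
    omr = list(epochs = 10L, min_epochs = 2L, lr = 1e-6,
               weight_decay = 5e-4, margin = 2, weights = c(1, 0.5, 0.5),
               comp_input = "mask", feature_dim = 2048L,
               backbone = "random"),
    fjmg = list(bilateral_weight = 10, bilateral_spatial_sd = 80,
                rgb_sd = 13, spatial_weight = 3, spatial_sd = 3,
                iterations = 5L, reference = "consensus"),
    truth = NULL)
}

validateRunConfig <- function(config) {
  if (is.null(config$input) || !dir.exists(config$input))
    stop("config error: input directory missing or does not exist")
  if (is.null(config$output))
    stop("config error: output directory not set")
  bad <- setdiff(config$stages, c("omg", "omr", "fjmg", "evaluate"))
  if (length(bad))
    stop("config error: unknown stage(s): ", paste(bad, collapse = ", "))
  invisible(config)
}

buildSegmenters <- function(config) {
  segs <- list()
  for (s in config$omg$segmenters) {
    segs[[s]] <- switch(s,
      otsu = segOtsu(invert = unlist(config$omg$otsu_invert)),
      excess_green = segExcessGreen(config$omg$excess_green_threshold),
      stop("unknown segmenter '", s, "'"))
  }
  for (nm in names(config$omg$precomputed))
    segs[[nm]] <- segPrecomputed(nm, config$omg$precomputed[[nm]])
  segs
}

#' Run the full pipeline (or selected stages) into a run directory
#'
#' Executes mask generation, heat-map refinement, CRF refinement with
#' final selection, and (when ground truth is available) evaluation, in
#' that order. All artifacts -- Stage-1 masks, heat maps, refined final
#' masks, per-candidate scores, metric tables and the resolved
#' configuration -- are written under the run directory, which is thereby
#' self-describing.
#'
#' @param config named list as produced by \code{\link{defaultRunConfig}}
#' @param verbose print progress
#' @return invisibly, the run directory path
#' @export
runPipeline <- function(config, verbose = TRUE) {
  validateRunConfig(config)
  out <- config$output
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(out, "config.yaml"))
  dataset <- loadDataset(config$input)

  maskset <- NULL
  if ("omg" %in% config$stages) {
    if (verbose) message("[omg] generating initial masks")
    maskset <- runOMG(dataset, buildSegmenters(config), verbose = verbose)
    writeMasks(maskset, file.path(out, "masks"))
  }
  hm <- NULL
  if ("omr" %in% config$stages) {
    if (is.null(maskset)) maskset <- readMasks(file.path(out, "masks"))
    if (verbose) message("[omr] training heat-map refinement")
    o <- config$omr
    cfg <- lossConfig(wCa = o$weights[1], wCs = o$weights[2],
                      wT = o$weights[3], margin = o$margin,
                      epochs = o$epochs, minEpochs = o$min_epochs,
                      lr = o$lr, weightDecay = o$weight_decay,
                      featureDim = o$feature_dim,
                      compInput = o$comp_input, backbone = o$backbone,
                      seed = config$seed)
    hm <- trainRefinement(maskset, dataset, cfg,
                          side = config$working_side, verbose = verbose)
    writeHeatMaps(hm, file.path(out, "heatmaps"))
  }
  final <- NULL
  if ("fjmg" %in% config$stages) {
    if (is.null(maskset)) maskset <- readMasks(file.path(out, "masks"))
    if (is.null(hm)) hm <- readHeatMaps(file.path(out, "heatmaps"))
    if (verbose) message("[fjmg] dense-CRF refinement and selection")
    f <- config$fjmg
    params <- crfParams(f$bilateral_weight, f$bilateral_spatial_sd,
                        f$rgb_sd, f$spatial_weight, f$spatial_sd,
                        f$iterations)
    final <- runFJMG(dataset, hm, maskset, params,
                     reference = f$reference)
    writeMasks(final, file.path(out, "final"))
    utils::write.csv(candidateScores(final),
                     file.path(out, "candidate_scores.csv"),
                     row.names = FALSE)
  }
  if ("evaluate" %in% config$stages && !is.null(config$truth)) {
    if (verbose) message("[evaluate] scoring against ground truth")
    if (is.null(final)) {
      fm <- readMasks(file.path(out, "final"))
    } else fm <- masks(final)
    truth <- readMasks(config$truth)
    report <- evaluateDataset(fm, truth)
    writeEvalReport(report, file.path(out, "metrics"))
  }
  invisible(out)
}

#' Evaluate a prediction directory against a truth directory
#'
#' Both directories must be mask collections written by
#' \code{\link{writeMasks}} with matching (plant, time, view, modality)
#' index sets.
#'
#' @param predDir,truthDir mask directories
#' @param out optional directory for CSV reports
#' @return the evaluation report (see \code{\link{evaluateDataset}})
#' @export
evaluateRun <- function(predDir, truthDir, out = NULL) {
  pred <- readMasks(predDir)
  if (is(pred, "MaskSet")) {
    pm <- masks(pred)
    names(pm) <- vapply(strsplit(names(pm), "/", fixed = TRUE),
                        function(p) paste(p[1:4], collapse = "/"), "")
    pred <- pm
  }
  truth <- readMasks(truthDir)
  report <- evaluateDataset(pred, truth)
  if (!is.null(out)) writeEvalReport(report, out)
  report
}
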