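#' Read an image file as a 3-channel array in [0,1]
#'
#' Grayscale images are replicated to 3 channels; an alpha channel, if
#' present, is dropped. The first two dimensions follow the EBImage
#' convention (x, y).
#'
#' @param path image file (PNG/TIFF/JPEG)
#' @return numeric array W x H x 3 in [0,1]
#' @export
readImageArray <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  a
}

#' Read a binary mask file (single-channel PNG with values {0,255})
#'
#' @param path mask file
#' @return 0/1 matrix
#' @export
readMaskFile <- function(path) {
  a <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  if (!all(a %in% c(0, 1)))
    stop("mask file is not binary {0,255}: ", path)
  matrix(as.numeric(a), nrow(a), ncol(a))
}

parseLayout <- function(root, exts = c("png", "tif", "tiff", "jpg", "jpeg")) {
  pat <- paste0("\\.(", paste(exts, collapse = "|"), ")$")
  files <- list.files(root, pattern = pat, recursive = TRUE,
                      full.names = FALSE, ignore.case = TRUE)
  files <- files[!grepl("^(masks|heatmaps|final|truth)/", files)]
  if (!length(files)) stop("no records found under ", root)
  parts <- strsplit(files, "/", fixed = TRUE)
  bad <- files[lengths(parts) != 4L]
  if (length(bad))
    stop("unparseable path(s) under plant/modality/view/t<NN> layout: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  tm <- vapply(parts, function(p) {
    m <- regmatches(p[4], regexec("^t([0-9]+)\\.", p[4]))[[1]]
    if (length(m) < 2L) NA_integer_ else as.integer(m[2])
  }, integer(1))
  if (anyNA(tm))
    stop("unparseable time index in: ",
         paste(utils::head(files[is.na(tm)], 5L), collapse = ", "))
  data.frame(plant = vapply(parts, `[`, "", 1L),
             modality = vapply(parts, `[`, "", 2L),
             view = vapply(parts, `[`, "", 3L),
             time = tm,
             path = file.path(root, files),
             stringsAsFactors = FALSE)
}

#' Load a temporal multi-view multi-modality image collection
#'
#' Indexes an on-disk image tree into a \code{\link{VstemDataset}}. A JSON
#' manifest (\code{manifest.json} at the root, as written by
#' \code{\link{generateVstem}}) is authoritative when present; otherwise
#' filenames are parsed under the default
#' \code{<plant>/<modality>/<view>/t<NN>.<ext>} layout. Record order is
#' deterministic: sorted by (modality, view, time) using the ordered view
#' and modality lists.
#'
#' @param root dataset directory
#' @param views,modalities optional ordered label lists; default: manifest
#'   order, else sorted unique labels found on disk
#' @return a \code{\link{VstemDataset}}
#' @export
loadDataset <- function(root, views = NULL, modalities = NULL) {
  if (!dir.exists(root)) stop("dataset root does not exist: ", root)
  mf <- file.path(root, "manifest.json")
  if (file.exists(mf)) {
    man <- jsonlite::read_json(mf, simplifyVector = TRUE)
    rec <- as.data.frame(man$records, stringsAsFactors = FALSE)
    rec$path <- file.path(root, rec$path)
    rec$time <- as.integer(rec$time)
    if (is.null(views)) views <- as.character(man$views)
    if (is.null(modalities)) modalities <- as.character(man$modalities)
  } else {
    rec <- parseLayout(root)
  }
  if (nrow(rec) == 0L) stop("no records")
  if (is.null(views)) views <- sort(unique(rec$view))
  if (is.null(modalities)) modalities <- sort(unique(rec$modality))
  dims <- t(vapply(rec$path, function(p) {
    a <- readImageArray(p)
    c(dim(a)[1L], dim(a)[2L])
  }, numeric(2)))
  rec$width <- as.integer(dims[, 1L])
  rec$height <- as.integer(dims[, 2L])
  rec <- rec[order(match(rec$modality, modalities),
                   match(rec$view, views), rec$time), , drop = FALSE]
  rownames(rec) <- NULL
  new("VstemDataset",
      records = rec[, c("plant", "time", "view", "modality",
                        "path", "height", "width")],
      views = views, modalities = modalities)
}

#' Resize an image or mask to the square working resolution
#'
#' Continuous-valued inputs are interpolated bilinearly; binary masks use
#' nearest-neighbour interpolation and remain strictly binary. An input
#' already at the target size is returned unchanged.
#'
#' @param img matrix (mask or single channel) or W x H x C array
#' @param side target side in pixels (>= 8)
#' @param filter "auto" (nearest for binary input, bilinear otherwise),
#'   "bilinear" or "nearest"
#' @return resized image of the same kind
#' @export
resizeToWorking <- function(img, side, filter = c("auto", "bilinear",
                                                  "nearest")) {
  filter <- match.arg(filter)
  if (!is.numeric(side) || length(side) != 1L || side < 8)
    stop("side must be a single value >= 8")
  side <- as.integer(side)
  d <- dim(img)
  if (d[1L] == side && d[2L] == side) return(img)
  if (filter == "auto")
    filter <- if (all(img %in% c(0, 1))) "nearest" else "bilinear"
  ef <- if (filter == "nearest") "none" else "bilinear"
  out <- EBImage::imageData(
    EBImage::resize(EBImage::Image(img), w = side, h = side, filter = ef))
  if (is.matrix(img)) matrix(as.numeric(out), side, side) else out
}

maskRelPath <- function(plant, time, view, modality, algorithm = NULL,
                        ext = "png") {
  fn <- sprintf("t%02d%s.%s", time,
                if (is.null(algorithm)) "" else paste0("_", algorithm), ext)
  file.path(plant, modality, view, fn)
}

#' Write a mask collection to disk
#'
#' One single-channel PNG per mask with values {0, 255}, plus a JSON
#' manifest mapping each (plant, time, view, modality[, algorithm]) entry to
#' its file. Re-reading with \code{\link{readMasks}} reproduces the masks
#' exactly.
#'
#' @param x a \code{\link{MaskSet}} or \code{\link{FinalMaskSet}}
#' @param out output directory (created if needed)
#' @return invisibly, the manifest path
#' @export
writeMasks <- function(x, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  ms <- masks(x)
  isFinal <- is(x, "FinalMaskSet")
  entries <- vector("list", length(ms))
  for (i in seq_along(ms)) {
    key <- names(ms)[i]
    m <- ms[[i]]
    if (!all(m %in% c(0, 1)))
      stop("mask '", key, "' is not strictly binary; refusing to write")
    p <- strsplit(key, "/", fixed = TRUE)[[1]]
    rel <- maskRelPath(p[1], as.integer(p[2]), p[3], p[4],
                       if (isFinal) NULL else p[5])
    fp <- file.path(out, rel)
    dir.create(dirname(fp), recursive = TRUE, showWarnings = FALSE)
    ok <- tryCatch({
      EBImage::writeImage(EBImage::Image(m), fp, bits = 8L); TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop("failed to write mask ", fp, ": ",
                          conditionMessage(ok))
    entries[[i]] <- c(list(plant = p[1], time = as.integer(p[2]),
                           view = p[3], modality = p[4]),
                      if (!isFinal) list(algorithm = p[5]),
                      list(path = rel))
  }
  man <- list(type = if (isFinal) "final_masks" else "masks",
              algorithms = if (isFinal) unname(unique(x@chosen))
                           else algorithms(x),
              entries = entries)
  mf <- file.path(out, "manifest.json")
  jsonlite::write_json(man, mf, auto_unbox = TRUE, pretty = TRUE)
  invisible(mf)
}

#' Read a mask collection written by \code{\link{writeMasks}}
#'
#' @param dir directory containing \code{manifest.json}
#' @return a \code{\link{MaskSet}} (for per-algorithm masks) or a named
#'   list of 0/1 matrices (for final masks)
#' @export
readMasks <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json under ", dir)
  man <- jsonlite::read_json(mf, simplifyVector = FALSE)
  out <- list()
  for (e in man$entries) {
    m <- readMaskFile(file.path(dir, e$path))
    key <- maskKey(e$plant, e$time, e$view, e$modality, e$algorithm)
    out[[key]] <- m
  }
  if (identical(man$type, "final_masks")) return(out)
  new("MaskSet", masks = out,
      algorithms = as.character(unlist(man$algorithms)))
}

#' Write a heat-map collection as 16-bit single-channel TIFFs plus manifest
#'
#' Probabilities are stored as \code{value / 65535} (TIFF is used because
#' it is the lossless 16-bit single-channel format the imaging stack
#' writes natively).
#'
#' @param hm a \code{\link{HeatMapSet}}
#' @param out output directory
#' @return invisibly, the manifest path
#' @export
writeHeatMaps <- function(hm, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  entries <- vector("list", length(hm@maps))
  for (i in seq_along(hm@maps)) {
    key <- names(hm@maps)[i]
    p <- strsplit(key, "/", fixed = TRUE)[[1]]
    rel <- maskRelPath(p[1], as.integer(p[2]), p[3], p[4], p[5],
                       ext = "tif")
    fp <- file.path(out, rel)
    dir.create(dirname(fp), recursive = TRUE, showWarnings = FALSE)
    EBImage::writeImage(EBImage::Image(hm@maps[[i]]), fp, bits = 16L)
    entries[[i]] <- list(plant = p[1], time = as.integer(p[2]), view = p[3],
                         modality = p[4], algorithm = p[5], path = rel)
  }
  man <- list(type = "heatmaps", side = hm@side,
              algorithms = hm@algorithms, entries = entries)
  mf <- file.path(out, "manifest.json")
  jsonlite::write_json(man, mf, auto_unbox = TRUE, pretty = TRUE)
  invisible(mf)
}

#' Read heat maps written by \code{\link{writeHeatMaps}}
#' @param dir directory containing \code{manifest.json}
#' @return a \code{\link{HeatMapSet}}
#' @export
readHeatMaps <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = FALSE)
  maps <- list()
  for (e in man$entries) {
    a <- EBImage::imageData(EBImage::readImage(file.path(dir, e$path)))
    if (length(dim(a)) == 3L) a <- a[, , 1L]
    maps[[maskKey(e$plant, e$time, e$view, e$modality, e$algorithm)]] <-
      matrix(as.numeric(a), nrow(a), ncol(a))
  }
  new("HeatMapSet", maps = maps,
      algorithms = as.character(unlist(man$algorithms)),
      side = as.integer(man$side))
}
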