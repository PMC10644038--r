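#' Otsu threshold of a single-channel intensity image
#'
#' Exhaustively scans all 256 candidate 8-bit levels and picks the
#' threshold maximising the between-class variance
#' \eqn{\sigma_b^2(t) = w_0 w_1 (\mu_0 - \mu_1)^2}. The brighter class is
#' labelled foreground (\code{intensity > t*}) unless \code{invert}.
#'
#' @param img numeric matrix in [0,1] (or any range; it is rescaled to
#'   8-bit levels internally)
#' @param invert label the darker class as foreground
#' @return 0/1 matrix; a constant image yields an all-background mask with
#'   a warning
#' @export
otsuThreshold <- function(img, invert = FALSE) {
  if (!is.matrix(img)) stop("otsuThreshold expects a single-channel matrix")
  lv <- pmin(pmax(round(img * 255), 0), 255)
  h <- tabulate(as.integer(lv) + 1L, nbins = 256L)
  n <- sum(h)
  if (sum(h > 0) < 2L) {
    warning("constant image: no meaningful Otsu split; all-background mask")
    return(matrix(0, nrow(img), ncol(img)))
  }
  lev <- 0:255
  w0 <- cumsum(h)                      # pixels with level <= t
  s0 <- cumsum(h * lev)
  mu <- s0[256] / n
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0             # both classes non-empty
  mu0 <- s0 / pmax(w0, 1)
  mu1 <- (s0[256] - s0) / pmax(w1, 1)
  sb2 <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
  sb2[!valid] <- -Inf
  tstar <- lev[which.max(sb2)]         # lowest maximiser on ties
  m <- (lv > tstar) * 1
  if (invert) m <- 1 - m
  matrix(as.numeric(m), nrow(img), ncol(img))
}

#' Luminance channel of a 3-channel image
#' @param img W x H x 3 array
#' @return matrix; Rec. 601 luma weights
#' @export
luminance <- function(img) {
  0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
}

#' Excess-green index segmentation
#'
#' Classifies each pixel by the excess-green vegetation index
#' \eqn{ExG = 2g - r - b} computed on channel-normalised chromatic
#' coordinates (\eqn{r = R/(R+G+B)} etc.; a black pixel has ExG 0).
#'
#' @param img W x H x 3 array
#' @param threshold foreground iff ExG > threshold
#' @return 0/1 matrix
#' @export
excessGreenSegment <- function(img, threshold = 0.05) {
  if (length(dim(img)) != 3L || dim(img)[3L] != 3L)
    stop("excessGreenSegment expects a 3-channel image")
  d <- dim(img)
  r <- matrix(img[, , 1L], d[1L], d[2L])
  g <- matrix(img[, , 2L], d[1L], d[2L])
  b <- matrix(img[, , 3L], d[1L], d[2L])
  s <- r + g + b
  s[s == 0] <- 1
  exg <- (2 * g - r - b) / s
  (exg > threshold) * 1
}

#' Frame-difference segmentation against a fixed background image
#'
#' @param img W x H x 3 array (or matrix)
#' @param background image of the same shape (e.g., an empty-chamber shot)
#' @param threshold foreground iff the per-pixel absolute difference,
#'   averaged over channels, exceeds this
#' @return 0/1 matrix
#' @export
frameDifferenceSegment <- function(img, background, threshold = 0.1) {
  if (!identical(dim(img), dim(background)))
    stop("image and background shapes differ")
  d <- abs(img - background)
  if (length(dim(d)) == 3L) d <- apply(d, c(1L, 2L), mean)
  (d > threshold) * 1
}

#' Construct a base segmenter
#'
#' @param name algorithm name (becomes the algorithm index)
#' @param fn function(img, record) -> 0/1 matrix, or NULL for "no output"
#' @param params free-form parameter list
#' @return a \code{\link{Segmenter}}
#' @export
makeSegmenter <- function(name, fn, params = list()) {
  new("Segmenter", name = name, fn = fn, params = params)
}

#' Built-in Otsu segmenter (luminance channel)
#'
#' @param invert named logical vector of per-modality polarity inversion
#'   (e.g. \code{c(infrared = TRUE)} when plants are darker than the
#'   background in that modality), or a single logical
#' @return a \code{\link{Segmenter}}
#' @export
segOtsu <- function(invert = FALSE) {
  makeSegmenter("otsu", function(img, record) {
    inv <- if (length(invert) > 1L || !is.null(names(invert)))
      isTRUE(invert[[record$modality]]) else isTRUE(invert)
    otsuThreshold(luminance(img), invert = inv)
  }, params = list(invert = invert))
}

#' Built-in excess-green segmenter
#' @param threshold ExG threshold
#' @return a \code{\link{Segmenter}}
#' @export
segExcessGreen <- function(threshold = 0.05) {
  makeSegmenter("excess_green",
                function(img, record) excessGreenSegment(img, threshold),
                params = list(threshold = threshold))
}

#' Precomputed-mask segmenter
#'
#' Imports masks produced by an external algorithm from a directory in the
#' package's mask layout (see \code{\link{writeMasks}}); records without a
#' stored mask signal "no output".
#'
#' @param name algorithm name
#' @param dir mask directory with a manifest
#' @return a \code{\link{Segmenter}}
#' @export
segPrecomputed <- function(name, dir) {
  stored <- readMasks(dir)
  if (is(stored, "MaskSet")) stored <- masks(stored)
  lut <- stats::setNames(stored,
    vapply(strsplit(names(stored), "/", fixed = TRUE),
           function(p) paste(p[1:4], collapse = "/"), ""))
  makeSegmenter(name, function(img, record) {
    key <- maskKey(record$plant, record$time, record$view, record$modality)
    lut[[key]]
  }, params = list(dir = dir))
}

#' Stage 1: generate initial binary masks for every record
#'
#' Applies every registered base segmenter to every image. A segmenter may
#' return \code{NULL} (no output) or fail on a record; such entries are
#' skipped with a message, never fatally.
#'
#' @param dataset a \code{\link{VstemDataset}}
#' @param segmenters list of \code{\link{Segmenter}} objects (>= 1)
#' @param verbose print per-record skips
#' @return a \code{\link{MaskSet}}
#' @export
runOMG <- function(dataset, segmenters, verbose = TRUE) {
  if (length(segmenters) < 1L) stop("need at least one segmenter")
  rec <- records(dataset)
  out <- list()
  for (r in seq_len(nrow(rec))) {
    row <- as.list(rec[r, ])
    img <- readImageArray(row$path)
    for (sg in segmenters) {
      m <- tryCatch(sg@fn(img, row), error = function(e) e)
      if (inherits(m, "error")) {
        if (verbose)
          message("segmenter '", sg@name, "' failed on ",
                  row$path, ": ", conditionMessage(m))
        next
      }
      if (is.null(m)) {
        if (verbose)
          message("segmenter '", sg@name, "': no output for ", row$path)
        next
      }
      if (!all(m %in% c(0, 1)))
        stop("segmenter '", sg@name, "' produced a non-binary mask")
      key <- maskKey(row$plant, row$time, row$view, row$modality, sg@name)
      out[[key]] <- m
    }
  }
  new("MaskSet", masks = out,
      algorithms = vapply(segmenters, function(s) s@name, ""))
}
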