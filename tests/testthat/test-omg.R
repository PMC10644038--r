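test_that("Otsu separates a perfectly bimodal image and flags constants", {
  img <- matrix(c(rep(0, 10), rep(1, 10)), 4, 5)
  m <- otsuThreshold(img)
  expect_identical(m, (img > 0) * 1)
  expect_warning(m0 <- otsuThreshold(matrix(0.5, 8, 8)), "constant")
  expect_true(all(m0 == 0))
})

test_that("Otsu matches the exhaustive between-class-variance maximiser", {
  # independent oracle: direct two-class statistics per candidate level
  bruteOtsu <- function(lv) {
    best <- -Inf; tstar <- NA_integer_
    for (t in 0:255) {
      lo <- lv[lv <= t]; hi <- lv[lv > t]
      if (!length(lo) || !length(hi)) next
      sb2 <- (length(lo) / length(lv)) * (length(hi) / length(lv)) *
        (mean(lo) - mean(hi))^2
      if (sb2 > best) { best <- sb2; tstar <- t }
    }
    tstar
  }
  set.seed(19)
  for (rep in 1:20) {
    lv <- sample(0:255, 256, replace = TRUE)
    img <- matrix(lv / 255, 16, 16)
    m <- otsuThreshold(img)
    tstar <- bruteOtsu(lv)
    expect_identical(m, matrix((lv > tstar) * 1, 16, 16))
  }
  # polarity inversion flips the labels
  img <- matrix(sample(0:255, 64, TRUE) / 255, 8, 8)
  expect_identical(otsuThreshold(img, invert = TRUE),
                   1 - otsuThreshold(img))
})

test_that("excess-green index follows per-pixel hand evaluation", {
  px <- function(r, g, b) array(c(r, g, b) / 255, c(1, 1, 3))
  expect_equal(excessGreenSegment(px(0, 255, 0), 0)[1, 1], 1)  # pure green
  expect_equal(excessGreenSegment(px(80, 80, 80), 0)[1, 1], 0) # gray
  # 4-pixel toy image vs direct evaluation of 2g - r - b on chromatic coords
  vals <- rbind(c(10, 200, 30), c(100, 100, 100), c(0, 0, 0),
                c(200, 50, 10)) / 255
  img <- array(0, c(2, 2, 3))
  for (c in 1:3) img[, , c] <- matrix(vals[, c], 2, 2)
  s <- pmax(rowSums(vals), 1e-12)
  exg <- (2 * vals[, 2] - vals[, 1] - vals[, 3]) / s
  expect_equal(as.numeric(excessGreenSegment(img, 0.05)),
               as.numeric(exg > 0.05))
  expect_error(excessGreenSegment(matrix(0, 4, 4)), "3-channel")
})

test_that("frame differencing equals the per-pixel oracle", {
  set.seed(11)
  bg <- array(runif(8 * 8 * 3), c(8, 8, 3))
  expect_true(all(frameDifferenceSegment(bg, bg, 0.05) == 0))
  img <- array(0, c(4, 4, 3)); img[2, 3, ] <- 1
  m <- frameDifferenceSegment(img, array(0, c(4, 4, 3)), 0.5)
  expect_equal(sum(m), 1); expect_equal(m[2, 3], 1)
  img2 <- array(runif(8 * 8 * 3), c(8, 8, 3))
  oracle <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8)
    oracle[i, j] <- as.numeric(mean(abs(img2[i, j, ] - bg[i, j, ])) > 0.1)
  expect_equal(frameDifferenceSegment(img2, bg, 0.1), oracle)
  expect_error(frameDifferenceSegment(img2, array(0, c(4, 4, 3)), 0.1),
               "shapes differ")
})

test_that("mask generation maps all records x segmenters, tolerating failures", {
  g <- synthSmall(seed = 9L, nTime = 3L, nViews = 2L, nModalities = 2L,
                  side = 32L)
  segs <- list(segOtsu(), segExcessGreen())
  ms <- runOMG(g$dataset, segs, verbose = FALSE)
  expect_equal(length(masks(ms)), 24L)
  expect_true(all(vapply(masks(ms), function(m) all(m %in% c(0, 1)),
                         logical(1))))
  # a segmenter that fails on one modality: skips logged, not fatal
  flaky <- makeSegmenter("flaky", function(img, record) {
    if (record$modality == "fluorescence") stop("boom")
    otsuThreshold(luminance(img))
  })
  expect_message(ms2 <- runOMG(g$dataset, list(segOtsu(), flaky)),
                 "failed")
  expect_equal(length(masks(ms2)), 12L + 6L)
  # determinism and zero-segmenter error
  ms3 <- runOMG(g$dataset, segs, verbose = FALSE)
  expect_identical(masks(ms3), masks(ms))
  expect_error(runOMG(g$dataset, list()), "at least one")
  # a pure map: permuting segmenter order never changes mask content
  msR <- runOMG(g$dataset, rev(segs), verbose = FALSE)
  expect_identical(rev(algorithms(msR)), algorithms(ms))
  expect_identical(masks(msR)[names(masks(ms))], masks(ms))
})

test_that("precomputed masks plug in as a segmenter", {
  g <- synthSmall(seed = 9L, nTime = 2L, nViews = 1L, nModalities = 1L,
                  side = 32L)
  root <- dirname(dirname(dirname(dirname(records(g$dataset)$path[1]))))
  sg <- segPrecomputed("truth", file.path(root, "truth"))
  ms <- runOMG(g$dataset, list(sg), verbose = FALSE)
  expect_equal(length(masks(ms)), 2L)
  tr <- truthByRecord(g$truth)
  for (k in names(masks(ms)))
    expect_identical(masks(ms)[[k]], tr[[baseKey(k)]])
})
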