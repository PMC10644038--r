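test_that("CRF preserves unanimous unaries and reduces to thresholding", {
  set.seed(51)
  side <- 32L
  img <- array(runif(side * side * 3), c(side, side, 3))
  allFg <- denseCrfRefine(img, matrix(0.999, side, side), crfParams())
  expect_true(all(allFg == 1))
  allBg <- denseCrfRefine(img, matrix(0.001, side, side), crfParams())
  expect_true(all(allBg == 0))
  heat <- matrix(runif(side * side), side, side)
  zero <- denseCrfRefine(img, heat, crfParams(iterations = 0L))
  expect_identical(zero, (heat > 0.5) * 1)
  expect_error(denseCrfRefine(img, matrix(0.5, 4, 4)), "sizes differ")
})

test_that("CRF cleans salt-and-pepper noise on a colour-separable blob", {
  mkBlob <- function(side) {
    m <- matrix(0, side, side)
    cx <- side / 2
    for (i in 1:side) for (j in 1:side)
      if ((i - cx)^2 + (j - cx)^2 < (side / 4)^2) m[i, j] <- 1
    m
  }
  side <- 48L
  blob <- mkBlob(side)
  improved <- 0L
  for (s in 1:5) {
    set.seed(s)
    img <- array(0, c(side, side, 3))
    for (c in 1:3)
      img[, , c] <- 0.15 + 0.5 * blob * (c == 2) +
        matrix(rnorm(side^2, 0, 0.02), side, side)
    img <- pmin(pmax(img, 0), 1)
    heat <- blob
    flip <- matrix(runif(side^2) < 0.05, side, side)
    heat[flip] <- 1 - heat[flip]
    out <- denseCrfRefine(img, heat, crfParams())
    jBefore <- maskJaccard((heat > 0.5) * 1, blob)
    jAfter <- maskJaccard(out, blob)
    expect_gte(jAfter, jBefore)
    if (jAfter > jBefore) improved <- improved + 1L
  }
  expect_gte(improved, 4L)
})

test_that("final-mask selection is the Jaccard argmax with stable ties", {
  set.seed(53)
  ref <- matrix(as.numeric(runif(64) > 0.5), 8, 8)
  good <- ref; good[1, 1] <- 1 - good[1, 1]
  bad <- 1 - ref
  sel <- selectFinalMask(list(a = bad, b = good), ref)
  expect_equal(sel$algorithm, "b")
  expect_identical(sel$mask, good)
  # ties resolve to the lowest algorithm index
  tie <- selectFinalMask(list(first = ref, second = ref), ref)
  expect_equal(tie$algorithm, "first")
  # random candidates: equals exhaustive comparison
  for (rep in 1:20) {
    cand <- lapply(1:3, function(i) matrix(as.numeric(runif(36) > 0.5), 6, 6))
    names(cand) <- c("a1", "a2", "a3")
    r <- matrix(as.numeric(runif(36) > 0.5), 6, 6)
    js <- vapply(cand, function(m) {
      inter <- sum(m & r); uni <- sum(m | r)
      if (uni == 0) 1 else inter / uni
    }, numeric(1))
    sel <- selectFinalMask(cand, r)
    expect_equal(sel$algorithm, names(cand)[which.max(js)])
  }
  expect_error(selectFinalMask(list(), ref), "no candidates")
})

test_that("stage 3 yields exactly one final mask per record, deterministically", {
  g <- synthSmall(seed = 55L, nTime = 2L, nViews = 2L, nModalities = 1L,
                  side = 48L)
  ms <- corruptedMaskSet(g$truth, seed = 55L)
  cfg <- lossConfig(epochs = 2L, minEpochs = 2L, featureDim = 32L,
                    seed = 1L)
  hm <- trainRefinement(ms, g$dataset, cfg, side = 48L)
  fin <- runFJMG(g$dataset, hm, ms, crfParams())
  expect_length(masks(fin), nRecords(g$dataset))
  expect_equal(nrow(candidateScores(fin)), length(heatMaps(hm)))
  expect_true(all(unlist(masks(fin)) %in% c(0, 1)))
  # final mask equals one of its refined candidates; scores reproducible
  fin2 <- runFJMG(g$dataset, hm, ms, crfParams())
  expect_identical(masks(fin), masks(fin2))
  expect_identical(chosenAlgorithm(fin), chosenAlgorithm(fin2))
  # single-algorithm run: the final mask is the only candidate
  one <- new("MaskSet",
             masks = masks(ms)[grep("/dilated$", names(masks(ms)))],
             algorithms = "dilated")
  hm1 <- new("HeatMapSet",
             maps = heatMaps(hm)[grep("/dilated$", names(heatMaps(hm)))],
             algorithms = "dilated", side = hm@side)
  f1 <- runFJMG(g$dataset, hm1, one, crfParams())
  expect_true(all(chosenAlgorithm(f1) == "dilated"))
})

test_that("the consensus reference is the thresholded mean over algorithms", {
  a <- matrix(c(1, 1, 0, 0), 2, 2)
  b <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_identical(consensusMask(list(a, b)),
                   matrix(c(1, 1, 1, 0), 2, 2))  # ties (0.5) to foreground
  c3 <- matrix(c(1, 0, 0, 0), 2, 2)
  expect_identical(consensusMask(list(a, b, c3)),
                   matrix(c(1, 0, 0, 0), 2, 2))  # 2/3 majority needed
})
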