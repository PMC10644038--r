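test_that("masked feature extraction multiplies image and heat per pixel", {
  set.seed(31)
  fc <- fcInit(seed = 31L, featureDim = 16L)
  src <- array(runif(8 * 8 * 3), c(8, 8, 3))
  heat <- matrix(runif(64), 8, 8)
  fp <- extractFeatures(src, heat, fc)
  # oracle: per-pixel products computed by explicit loops, then the frozen
  # backbone applied to those tensors
  mo <- array(0, dim(src)); mb <- array(0, dim(src))
  for (i in 1:8) for (j in 1:8) for (c in 1:3) {
    mo[i, j, c] <- src[i, j, c] * heat[i, j]
    mb[i, j, c] <- src[i, j, c] * (1 - heat[i, j])
  }
  expect_equal(fp$object, PhenoCoseg:::fcForward(fc, mo)$features,
               tolerance = 1e-12)
  expect_equal(fp$background, PhenoCoseg:::fcForward(fc, mb)$features,
               tolerance = 1e-12)
  # annihilation and symmetry at extreme heat maps
  z <- extractFeatures(src, matrix(0, 8, 8), fc)
  expect_equal(z$object, PhenoCoseg:::fcForward(fc, src * 0)$features)
  expect_equal(z$background, PhenoCoseg:::fcForward(fc, src)$features)
  o <- extractFeatures(src, matrix(1, 8, 8), fc)
  expect_equal(o$object, z$background)
  expect_equal(o$background, z$object)
  expect_error(extractFeatures(src, matrix(0, 4, 4), fc), "sizes differ")
  expect_error(extractFeatures(src, matrix(2, 8, 8), fc), "\\[0,1\\]")
})

test_that("refinement training emits one bounded heat map per candidate", {
  g <- synthSmall(seed = 41L, nTime = 3L, nViews = 1L, nModalities = 1L,
                  side = 64L)
  ms <- corruptedMaskSet(g$truth, seed = 41L)
  cfg <- lossConfig(epochs = 2L, minEpochs = 2L, featureDim = 64L,
                    seed = 41L)
  hm <- trainRefinement(ms, g$dataset, cfg, side = 64L)
  expect_s4_class(hm, "HeatMapSet")
  expect_length(heatMaps(hm), 6L)   # 3 times x 1 view x 1 modality x 2 algs
  rng <- range(unlist(lapply(heatMaps(hm), range)))
  expect_gte(rng[1], 0); expect_lte(rng[2], 1)
})

test_that("training is bitwise deterministic given the seed", {
  g <- synthSmall(seed = 43L, nTime = 3L, nViews = 1L, nModalities = 1L,
                  side = 64L)
  ms <- corruptedMaskSet(g$truth, seed = 43L)
  cfg <- lossConfig(epochs = 2L, minEpochs = 2L, featureDim = 64L,
                    seed = 7L)
  hm1 <- trainRefinement(ms, g$dataset, cfg, side = 64L)
  hm2 <- trainRefinement(ms, g$dataset, cfg, side = 64L)
  expect_identical(heatMaps(hm1), heatMaps(hm2))
})

test_that("training does not destroy already-good proposals", {
  g <- synthSmall(seed = 47L, nTime = 3L, nViews = 1L, nModalities = 1L,
                  side = 64L)
  tr <- masks(g$truth)
  ml <- list()
  for (k in names(tr)) {
    b <- baseKey(k)
    ml[[paste0(b, "/exact")]] <- tr[[k]]
    ml[[paste0(b, "/near")]] <- corruptMask(tr[[k]], flipFraction = 0.01,
                                            seed = 5L)
  }
  ms <- new("MaskSet", masks = ml, algorithms = c("exact", "near"))
  cfg <- lossConfig(epochs = 3L, minEpochs = 2L, featureDim = 64L,
                    seed = 47L)
  hm <- trainRefinement(ms, g$dataset, cfg, side = 64L)
  truthRec <- truthByRecord(g$truth)
  jStage1 <- meanTruthJaccard(ml, truthRec)
  thr <- lapply(heatMaps(hm), function(h) (h > 0.5) * 1)
  jHeat <- meanTruthJaccard(thr, truthRec)
  expect_gte(jHeat, jStage1 - 0.05)
})

test_that("missing temporal pairs and missing algorithms are handled", {
  g <- synthSmall(seed = 49L, nTime = 2L, nViews = 1L, nModalities = 1L,
                  side = 64L)
  ms <- corruptedMaskSet(g$truth, seed = 49L)
  # drop one algorithm at one time point: batch reduces, run continues
  drop <- grep("/2/.*dilated", names(masks(ms)), value = TRUE)[1]
  ms@masks[[drop]] <- NULL
  cfg <- lossConfig(epochs = 2L, minEpochs = 2L, featureDim = 32L,
                    seed = 1L)
  hm <- trainRefinement(ms, g$dataset, cfg, side = 64L)
  expect_length(heatMaps(hm), 3L)
  # a single time point nowhere offers a pair: error
  rec <- records(g$dataset)
  one <- new("VstemDataset", records = rec[rec$time == 1, , drop = FALSE],
             views = g$dataset@views, modalities = g$dataset@modalities)
  expect_error(trainRefinement(ms, one, cfg, side = 64L),
               "no valid temporal pair")
})
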