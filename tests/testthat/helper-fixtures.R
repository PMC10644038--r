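# Shared fixtures: small synthetic datasets and corrupted Stage-1 mask
# sets built in code at test time.

synthSmall <- function(seed = 7L, nTime = 3L, nViews = 2L,
                       nModalities = 2L, side = 64L) {
  generateVstem(
    syntheticConfig(nTime = nTime, nViews = nViews,
                    nModalities = nModalities, side = side, seed = seed),
    dir = file.path(tempdir(), sprintf("vstem_s%d_%d_%d_%d_%d", seed,
                                       nTime, nViews, nModalities, side)))
}

baseKey <- function(k) {
  p <- strsplit(k, "/", fixed = TRUE)[[1]]
  paste(p[1:4], collapse = "/")
}

truthByRecord <- function(truthSet) {
  tm <- masks(truthSet)
  stats::setNames(tm, vapply(names(tm), baseKey, ""))
}

# two imperfect base algorithms derived from ground truth: one dilated and
# noisy, one eroded and noisy
corruptedMaskSet <- function(truthSet, seed = 1L, dilatePx = 2L,
                             erodePx = 1L, flipFraction = 0.02) {
  tm <- masks(truthSet)
  out <- list()
  for (k in names(tm)) {
    b <- baseKey(k)
    out[[paste0(b, "/dilated")]] <-
      corruptMask(tm[[k]], dilatePx = dilatePx,
                  flipFraction = flipFraction, seed = seed * 1000L + 1L)
    out[[paste0(b, "/eroded")]] <-
      corruptMask(tm[[k]], erodePx = erodePx,
                  flipFraction = flipFraction, seed = seed * 1000L + 2L)
  }
  new("MaskSet", masks = out, algorithms = c("dilated", "eroded"))
}

meanTruthJaccard <- function(maskList, truthRec) {
  mean(vapply(names(maskList), function(k)
    maskJaccard(maskList[[k]], truthRec[[baseKey(k)]]), numeric(1)))
}

randomFeaturePair <- function(d) {
  list(object = rnorm(d), background = rnorm(d))
}
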