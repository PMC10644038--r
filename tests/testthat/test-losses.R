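# Independent direct-summation oracles, written from the loss definitions
# without reference to the package internals.

oracleMsd <- function(x, y) sum((x - y)^2) / length(x)

oracleCoseg <- function(A, B, m) {
  dplus <- oracleMsd(A$object, B$object)
  dminus <- max(0, m - 0.5 * (oracleMsd(A$object, A$background) +
                              oracleMsd(B$object, B$background)))
  dplus + dminus
}

oracleTemporal <- function(prevO, currO) {
  N <- length(currO); total <- 0
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j) next
    obp <- oracleMsd(currO[[i]], currO[[j]])
    obm <- oracleMsd(prevO[[i]], prevO[[j]])
    p <- exp(-obp) / (exp(-obp) + exp(-obm))
    total <- total - log(max(p, 1e-12))
  }
  total
}

oracleCoattention <- function(pairs) {
  N <- length(pairs); total <- 0
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j) next
    dp <- oracleMsd(pairs[[i]]$object, pairs[[j]]$object)
    dm <- 0.5 * (oracleMsd(pairs[[i]]$object, pairs[[i]]$background) +
                 oracleMsd(pairs[[j]]$object, pairs[[j]]$background))
    p <- exp(-dp) / (exp(-dp) + exp(-dm))
    total <- total - log(max(p, 1e-12))
  }
  total
}

test_that("losses match direct-summation oracles on random instances", {
  set.seed(101)
  for (rep in 1:60) {
    d <- sample(2:16, 1); N <- sample(2:4, 1)
    A <- randomFeaturePair(d); B <- randomFeaturePair(d)
    expect_equal(cosegmentationLoss(A, B), oracleCoseg(A, B, 2),
                 tolerance = 1e-6)
    prevO <- lapply(seq_len(N), function(i) rnorm(d))
    currO <- lapply(seq_len(N), function(i) rnorm(d))
    expect_equal(temporalLoss(prevO, currO),
                 oracleTemporal(prevO, currO), tolerance = 1e-6)
    pairs <- lapply(seq_len(N), function(i) randomFeaturePair(d))
    expect_equal(coattentionLoss(pairs), oracleCoattention(pairs),
                 tolerance = 1e-6)
  }
})

test_that("analytic loss values hold at symmetric and extreme inputs", {
  # worked cosegmentation case: d+ = 0, intra msd = 1 each, hinge at 2
  A <- list(object = c(1, 0), background = c(0, 1))
  B <- list(object = c(1, 0), background = c(0, 1))
  expect_equal(cosegmentationLoss(A, B), 1)
  # identical object and background everywhere: hinge saturates at margin
  C <- list(object = c(0.3, 0.7), background = c(0.3, 0.7))
  expect_equal(cosegmentationLoss(C, C), 2)
  # hinge cutoff: intra distance beyond the margin leaves only d+
  far <- list(object = rep(0, 4), background = rep(3, 4))  # msd 9 > 2m
  far2 <- list(object = rep(0.1, 4), background = rep(-3, 4))
  expect_equal(cosegmentationLoss(far, far2),
               oracleMsd(far$object, far2$object))
  # temporal symmetry: equal distances give p = 1/2 per ordered pair
  v <- list(c(1, 2), c(3, 5))
  expect_equal(temporalLoss(v, v), 2 * log(2))
  # temporal limit: current objects agree, previous far apart
  expect_lt(temporalLoss(list(c(0, 0), c(10, 10)),
                         list(c(1, 1), c(1, 1))), 1e-8)
  # coattention symmetry: identical objects, object == background
  p0 <- list(object = c(1, 1), background = c(1, 1))
  expect_equal(coattentionLoss(list(p0, p0, p0)), 6 * log(2))
  # coattention limit: identical objects, far backgrounds
  pf <- list(object = c(0, 0), background = c(20, 20))
  expect_lt(coattentionLoss(list(pf, pf)), 1e-8)
})

test_that("mirrored softmax probabilities are complementary", {
  set.seed(5)
  for (rep in 1:50) {
    obp <- rexp(1); obm <- rexp(1)
    p <- exp(-obp) / (exp(-obp) + exp(-obm))
    q <- exp(-obm) / (exp(-obm) + exp(-obp))
    expect_equal(p + q, 1, tolerance = 1e-12)
    # the package's stable form agrees: -log p computed via softplus
    expect_equal(PhenoCoseg:::nlogSigmoid(obm - obp), -log(p),
                 tolerance = 1e-9)
  }
})

test_that("losses are non-negative, finite and symmetric where claimed", {
  set.seed(33)
  for (rep in 1:30) {
    d <- sample(2:12, 1)
    A <- randomFeaturePair(d); B <- randomFeaturePair(d)
    lcs <- cosegmentationLoss(A, B)
    expect_gte(lcs, 0); expect_true(is.finite(lcs))
    expect_equal(lcs, cosegmentationLoss(B, A))
    pairs <- lapply(1:3, function(i) randomFeaturePair(d))
    lca <- coattentionLoss(pairs)
    expect_gte(lca, 0); expect_true(is.finite(lca))
    lt <- temporalLoss(lapply(1:3, function(i) rnorm(d)),
                       lapply(1:3, function(i) rnorm(d)))
    expect_gte(lt, 0); expect_true(is.finite(lt))
  }
  expect_message(l1 <- temporalLoss(list(rnorm(3)), list(rnorm(3))),
                 "single algorithm")
  expect_equal(l1, 0)
  expect_message(l2 <- coattentionLoss(list(randomFeaturePair(3))), ">= 2")
  expect_equal(l2, 0)
})

test_that("the loss schedule gates cosegmentation and temporal terms", {
  cfg <- lossConfig(epochs = 10L)
  expect_equal(totalLoss(1, 1, 1, cfg, epoch = 1L), 1)
  expect_equal(totalLoss(1, 1, 1, cfg, epoch = 9L), 1)
  expect_equal(totalLoss(1, 1, 1, cfg, epoch = 10L), 2)
  expect_equal(totalLoss(0, 0, 0, cfg, epoch = 10L), 0)
  cfgAll <- lossConfig(epochs = 5L, lateLosses = FALSE)
  expect_equal(totalLoss(1, 2, 4, cfgAll, epoch = 1L), 1 + 1 + 2)
  expect_error(totalLoss(1, 1, 1, cfg, epoch = 11L))
})

test_that("analytic loss gradients agree with finite differences", {
  set.seed(77)
  num <- function(f, x, eps = 1e-6)
    vapply(seq_along(x), function(i) {
      xp <- x; xm <- x
      xp[i] <- xp[i] + eps; xm[i] <- xm[i] - eps
      (f(xp) - f(xm)) / (2 * eps)
    }, numeric(1))
  d <- 5
  A <- randomFeaturePair(d); B <- randomFeaturePair(d)
  g <- PhenoCoseg:::cosegmentationLossGrad(A, B)
  expect_equal(g$Ao, num(function(v)
    cosegmentationLoss(list(object = v, background = A$background), B),
    A$object), tolerance = 1e-5)
  expect_equal(g$Bb, num(function(v)
    cosegmentationLoss(A, list(object = B$object, background = v)),
    B$background), tolerance = 1e-5)
  prevO <- lapply(1:3, function(i) rnorm(d))
  currO <- lapply(1:3, function(i) rnorm(d))
  gt <- PhenoCoseg:::temporalLossGrad(prevO, currO)
  expect_equal(gt$curr[[2]], num(function(v) {
    cc <- currO; cc[[2]] <- v; temporalLoss(prevO, cc)
  }, currO[[2]]), tolerance = 1e-5)
  pairs <- lapply(1:3, function(i) randomFeaturePair(d))
  gc <- PhenoCoseg:::coattentionLossGrad(pairs)
  expect_equal(gc$object[[1]], num(function(v) {
    pp <- pairs; pp[[1]]$object <- v; coattentionLoss(pp)
  }, pairs[[1]]$object), tolerance = 1e-5)
  expect_equal(gc$background[[3]], num(function(v) {
    pp <- pairs; pp[[3]]$background <- v; coattentionLoss(pp)
  }, pairs[[3]]$background), tolerance = 1e-5)
})
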