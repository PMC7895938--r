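test_that("BM covariance equals shared root-to-MRCA path lengths", {
  tree <- readNewick(text = "((A:1,B:1):1,C:2);")
  expect_equal(unname(phyloCovariance(tree)),
               matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3, 3))
  star <- readNewick(text = "(A:1,B:1,C:1);")
  Cs <- phyloCovariance(star)
  expect_equal(unname(Cs), diag(3))
  for (seed in 11:13) {
    tr <- randomTestTree(6, seed)
    expect_equal(phyloCovariance(tr), oracleSharedTimes(tr), tolerance = 1e-12)
  }
})

test_that("OU covariance follows the fixed-root Hansen form", {
  cherry <- readNewick(text = "(A:1,B:1);")
  V <- ouCovariance(cherry, alpha = 1, sigma2 = 2)
  expect_equal(unname(diag(V)), rep(1 - exp(-2), 2), tolerance = 1e-9)
  expect_equal(V[1, 2], 0)

  star <- readNewick(text = "(A:1,B:1,C:1);")
  for (a in c(0.01, 1, 50)) {
    Vs <- ouCovariance(star, alpha = a)
    expect_equal(max(abs(Vs[upper.tri(Vs)])), 0)
  }

  tree <- randomTestTree(7, 21)
  Tdepth <- nodeDepths(tree)$T
  C <- phyloCovariance(tree)
  Vsmall <- ouCovariance(tree, alpha = 1e-9 / Tdepth, sigma2 = 1.7)
  expect_lt(max(abs(Vsmall - 1.7 * C)), 1e-6)

  # off-diagonal correlations are non-increasing in alpha
  alphas <- c(0.01, 0.1, 1, 10) / Tdepth
  cors <- sapply(alphas, function(a) {
    V <- ouCovariance(tree, a)
    stats::cov2cor(V)[1, 2]
  })
  expect_true(all(diff(cors) <= 1e-12))

  expect_error(ouCovariance(tree, alpha = 0), "alpha")
  expect_error(ouCovariance(tree, alpha = -1), "alpha")
})

test_that("log-likelihoods match closed forms and the dense oracle", {
  tree <- readNewick(text = "(A:1,B:1,C:1);")
  x <- c(A = 1, B = 2, C = 3)
  expect_equal(traitLogLik("WN", list(mu = 2, sigma2 = 2 / 3), tree, x),
               -1.5 * (log(2 * pi * 2 / 3) + 1), tolerance = 1e-9)

  star2 <- readNewick(text = "(A:1,B:1);")
  x2 <- c(A = 0, B = 2)
  lnl <- traitLogLik("BM", list(z0 = 1, sigma2 = 1), star2, x2)
  expect_equal(lnl, oracleMvnLogLik(x2, c(1, 1), diag(2)), tolerance = 1e-10)
  expect_equal(lnl, -2.8379, tolerance = 1e-4)
})

test_that("pruning and dense BM paths agree on random trees and parameters", {
  set.seed(202)
  maxDiff <- 0
  for (rep in 1:100) {
    tr <- randomTestTree(sample(4:12, 1), seed = 5000 + rep)
    x <- setNames(rnorm(length(tr$tip.label), 10, 4), tr$tip.label)
    z0 <- rnorm(1, 10, 3)
    s2 <- runif(1, 0.1, 5)
    dense <- traitLogLik("BM", list(z0 = z0, sigma2 = s2), tr, x, "dense")
    prune <- traitLogLik("BM", list(z0 = z0, sigma2 = s2), tr, x, "pruning")
    maxDiff <- max(maxDiff, abs(dense - prune))
  }
  expect_lt(maxDiff, 1e-8)
})

test_that("OU likelihood reaches the BM limit as alpha tends to zero", {
  for (seed in 31:33) {
    tr <- randomTestTree(8, seed)
    Tdepth <- nodeDepths(tr)$T
    x <- setNames(rnorm(8, 20, 3), tr$tip.label)
    bm <- traitLogLik("BM", list(z0 = 20, sigma2 = 1.5), tr, x)
    ou <- traitLogLik("OU", list(z0 = 20, sigma2 = 1.5, alpha = 1e-9 / Tdepth),
                      tr, x)
    expect_equal(ou, bm, tolerance = 1e-4)
  }
})

test_that("coincident zero-distance tips give a singularity error", {
  expect_warning(tr <- readNewick(text = "((A:0,B:0):1,C:1);"),
                 "zero-length")
  x <- c(A = 1, B = 2, C = 3)
  expect_error(suppressWarnings(
    traitLogLik("BM", list(z0 = 0, sigma2 = 1), tr, x)
  ), "singular")
})

test_that("WN fit returns the sample mean and MLE variance exactly", {
  tree <- readNewick(text = "(A:1,B:1,C:1);")
  fit <- fitTraitModel("WN", tree, c(A = 1, B = 2, C = 3))
  expect_identical(fit$mu, 2)
  expect_equal(fit$sigma2, 2 / 3, tolerance = 1e-15)
  expect_equal(fit$lnL, -1.5 * (log(2 * pi * 2 / 3) + 1), tolerance = 1e-12)
  expect_equal(fit$k, 2L)
})

test_that("BM fit matches a brute-force grid maximization on a 2-tip star", {
  star2 <- readNewick(text = "(A:1,B:1);")
  fit <- fitTraitModel("BM", star2, c(A = 0, B = 2))
  # independent check: dense-likelihood grid search over (z0, sigma2)
  grid <- expand.grid(z0 = seq(-1, 3, by = 0.05),
                      s2 = seq(0.2, 3, by = 0.05))
  lnls <- mapply(function(z, s) oracleMvnLogLik(c(0, 2), rep(z, 2), s * diag(2)),
                 grid$z0, grid$s2)
  bestGrid <- grid[which.max(lnls), ]
  expect_equal(fit$z0, bestGrid$z0, tolerance = 0.051)
  expect_equal(fit$sigma2, bestGrid$s2, tolerance = 0.051)
  expect_equal(fit$z0, 1)
  expect_equal(fit$sigma2, 1)
})

test_that("BM on a unit star tree equals the WN fit", {
  star <- readNewick(text = "(A:1,B:1,C:1,D:1);")
  x <- c(A = 3, B = 5, C = 2, D = 9)
  bm <- fitTraitModel("BM", star, x)
  wn <- fitTraitModel("WN", star, x)
  expect_equal(bm$z0, wn$mu, tolerance = 1e-10)
  expect_equal(bm$sigma2, wn$sigma2, tolerance = 1e-10)
  expect_equal(bm$lnL, wn$lnL, tolerance = 1e-10)
})

test_that("BM estimates are scale- and shift-equivariant", {
  tr <- randomTestTree(10, 77)
  x <- setNames(rnorm(10, 15, 3), tr$tip.label)
  fit <- fitTraitModel("BM", tr, x)
  for (cc in c(0.5, 3)) {
    scaled <- tr
    scaled$edge.length <- tr$edge.length * cc
    fitS <- fitTraitModel("BM", scaled, x)
    expect_equal(fitS$sigma2, fit$sigma2 / cc, tolerance = 1e-8)
    expect_equal(fitS$z0, fit$z0, tolerance = 1e-8)
  }
  fitShift <- fitTraitModel("BM", tr, x + 7)
  expect_equal(fitShift$z0, fit$z0 + 7, tolerance = 1e-8)
  expect_equal(fitShift$sigma2, fit$sigma2, tolerance = 1e-10)
  expect_equal(fitShift$lnL, fit$lnL, tolerance = 1e-8)
})

test_that("OU shift equivariance and BM nesting hold on fixtures", {
  for (seed in 41:43) {
    tr <- randomTestTree(10, seed)
    x <- setNames(rnorm(10, 25, 2), tr$tip.label)
    bm <- fitTraitModel("BM", tr, x)
    ou <- fitTraitModel("OU", tr, x)
    expect_gte(ou$lnL, bm$lnL - 1e-6)
    ouShift <- fitTraitModel("OU", tr, x + 11)
    expect_equal(ouShift$z0, ou$z0 + 11, tolerance = 1e-5)
    expect_equal(ouShift$alpha, ou$alpha, tolerance = 1e-4)
    expect_equal(ouShift$lnL, ou$lnL, tolerance = 1e-6)
  }
})

test_that("OU fit recovers parameters on an OU-simulated tree", {
  tree <- simulateYuleTree(150, birthRate = 0.05, seed = 91)
  Tdepth <- nodeDepths(tree)$T
  alphaTrue <- 2 / Tdepth
  x <- simulateTraits(tree, list(model = "OU", sigma2 = 1, alpha = alphaTrue,
                                 z0 = 20, theta = 20), seed = 92)
  fit <- fitTraitModel("OU", tree, x)
  expect_equal(fit$lnL, max(fit$diagnostics$multistartLnL), tolerance = 1e-6)
  expect_lt(abs(log(fit$alpha / alphaTrue)), log(4))
  expect_equal(fit$negLogAlpha, -log(fit$alpha))
  expect_equal(fit$theta, fit$z0)
})

test_that("model comparison reports ranks, counts and deltas coherently", {
  tree <- simulateYuleTree(80, birthRate = 0.05, seed = 55)
  x <- simulateTraits(tree, list(model = "BM", sigma2 = 1, z0 = 10), seed = 56)
  cmp <- compareTraitModels(tree, x)
  expect_equal(vapply(cmp$fits, `[[`, integer(1), "k"),
               c(BM = 2L, OU = 3L, WN = 2L))
  expect_gte(cmp$lnL[["OU"]], cmp$lnL[["BM"]] - 1e-6)
  expect_equal(unname(cmp$delta_lnL[cmp$best_by_lnL]), 0)
  expect_equal(unname(cmp$delta_AICc[cmp$best_by_AICc]), 0)
  for (f in cmp$fits) {
    expect_equal(f$AICc,
                 2 * f$k - 2 * f$lnL + 2 * f$k * (f$k + 1) / (f$n - f$k - 1))
  }
})

test_that("tempo averages per-tree Brownian rates over tree variants", {
  tree <- simulateYuleTree(40, birthRate = 0.05, seed = 61)
  x <- simulateTraits(tree, list(model = "BM", sigma2 = 1, z0 = 0), seed = 62)
  single <- tempoSigma2(tree, x)
  expect_equal(single$sigma2, fitTraitModel("BM", tree, x)$sigma2)
  expect_equal(single$nTrees, 1L)

  half <- tree
  half$edge.length <- tree$edge.length / 2 # sigma2 MLE doubles
  both <- tempoSigma2(list(tree, half), x)
  expect_equal(both$perTree, c(single$sigma2, 2 * single$sigma2),
               tolerance = 1e-8)
  expect_equal(both$sigma2, mean(both$perTree))
  expect_equal(mean(c(1.0, 1.4)), 1.2) # the averaging rule itself
})

test_that("multi-tree summaries report mean and sd per parameter", {
  tree <- simulateYuleTree(30, birthRate = 0.05, seed = 71)
  x <- simulateTraits(tree, list(model = "BM", sigma2 = 1, z0 = 0), seed = 72)
  one <- summarizeOverTrees(tree, x, "BM")
  expect_true(all(one$sd == 0))
  expect_equal(attr(one, "nTrees"), 1L)

  scales <- c(1, 0.5, 0.25)
  trees <- lapply(scales, function(s) {
    t2 <- tree
    t2$edge.length <- tree$edge.length * s
    t2
  })
  summ <- summarizeOverTrees(trees, x, "BM")
  per <- fitTraitModel("BM", tree, x)$sigma2 / scales
  row <- summ[summ$parameter == "sigma2", ]
  expect_equal(row$mean, mean(per), tolerance = 1e-8)
  expect_equal(row$sd, sd(per), tolerance = 1e-8)

  mismatch <- ape::drop.tip(tree, tree$tip.label[1])
  expect_error(summarizeOverTrees(list(tree, mismatch), x, "BM"),
               "tip set")
})
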