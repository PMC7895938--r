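test_that("Yule trees are ultrametric binary trees of the requested size", {
  cherry <- simulateYuleTree(2, birthRate = 1, seed = 1)
  expect_equal(length(cherry$tip.label), 2)
  expect_true(checkUltrametric(cherry)$ultrametric)

  tr <- simulateYuleTree(50, birthRate = 0.1, seed = 2)
  expect_equal(length(tr$tip.label), 50)
  expect_equal(tr$Nnode, 49) # fully binary
  expect_true(checkUltrametric(tr)$ultrametric)
  expect_true(all(tr$edge.length >= 0))
})

test_that("generators are bit-reproducible and seed-sensitive", {
  t1 <- simulateYuleTree(20, 0.5, seed = 10)
  t2 <- simulateYuleTree(20, 0.5, seed = 10)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  t3 <- simulateYuleTree(20, 0.5, seed = 11)
  expect_false(identical(ape::write.tree(t1), ape::write.tree(t3)))

  ds1 <- simulateGlobtherm(simulationConfig(seed = 3, nTips = 30, nOrders = 3))
  ds2 <- simulateGlobtherm(simulationConfig(seed = 3, nTips = 30, nOrders = 3))
  expect_identical(ds1$table, ds2$table)
  ds3 <- simulateGlobtherm(simulationConfig(seed = 4, nTips = 30, nOrders = 3))
  expect_false(identical(ds1$table$tolerance, ds3$table$tolerance))
})

test_that("Yule depths match an independent waiting-time simulator", {
  nReps <- 400
  lambda <- 1
  depths <- vapply(seq_len(nReps), function(i) {
    nodeDepths(simulateYuleTree(20, lambda, seed = 20000 + i))$T
  }, numeric(1))
  set.seed(99)
  oracle <- oracleYuleDepths(20000, 20, lambda)
  se <- sqrt(var(depths) / nReps + var(oracle) / length(oracle))
  expect_lt(abs(mean(depths) - mean(oracle)), 3 * se)
})

test_that("trait simulation matches the analytic BM moments", {
  branch <- readNewick(text = "(A:4,B:4);")
  ends <- vapply(seq_len(2000), function(i) {
    simulateTraits(branch, list(model = "BM", sigma2 = 1, z0 = 0),
                   seed = 30000 + i)[["A"]]
  }, numeric(1))
  v <- var(ends)
  expect_gt(v, 3.5)
  expect_lt(v, 4.5)
  expect_lt(abs(mean(ends)), 3 * sqrt(4 / 2000) * 2)
})

test_that("sister-tip covariance under BM matches the phylogenetic covariance", {
  tr <- readNewick(text = "((A:1,B:1):2,C:3);")
  sims <- vapply(seq_len(2000), function(i) {
    simulateTraits(tr, list(model = "BM", sigma2 = 1.5, z0 = 0),
                   seed = 40000 + i)[c("A", "B")]
  }, numeric(2))
  covAB <- cov(sims[1, ], sims[2, ])
  expect_equal(covAB, 1.5 * phyloCovariance(tr)["A", "B"], tolerance = 0.25)
})

test_that("OU simulation reaches its stationary distribution at large alpha*t", {
  branch <- readNewick(text = "(A:10,B:10);")
  spec <- list(model = "OU", sigma2 = 2, alpha = 2, theta = 7, z0 = 0)
  sims <- vapply(seq_len(2000), function(i) {
    simulateTraits(branch, spec, seed = 50000 + i)[["A"]]
  }, numeric(1))
  expect_equal(mean(sims), 7, tolerance = 0.06)       # theta
  expect_equal(var(sims), 2 / (2 * 2), tolerance = 0.08) # sigma2/(2 alpha)
})

test_that("degenerate zero-rate BM puts every tip at the root state", {
  tr <- simulateYuleTree(12, 0.3, seed = 60)
  x <- simulateTraits(tr, list(model = "BM", sigma2 = 0, z0 = 3.3), seed = 61)
  expect_true(all(x == 3.3))
})

test_that("synthetic tables carry ground truth and satisfy the invariants", {
  cfg <- simulationConfig(seed = 8, nTips = 60, nOrders = 5,
                          upperModel = list(model = "BM", sigma2 = 0.5, z0 = 38),
                          lowerModel = list(model = "BM", sigma2 = 2.0, z0 = 2))
  ds <- simulateGlobtherm(cfg)
  expect_equal(ds$truth$upperModel$sigma2, 0.5)
  expect_equal(ds$truth$lowerModel$sigma2, 2.0)
  expect_setequal(unique(ds$table$species), ds$tree$tip.label)
  up <- ds$table[ds$table$limit_side == "upper", ]
  lo <- ds$table[ds$table$limit_side == "lower", ]
  expect_true(all(up$tolerance[match(lo$species, up$species)] > lo$tolerance))
  expect_equal(length(unique(ds$table$order)), 5)
  expect_true(all(ds$table$order_age > 0))
  ages <- tapply(ds$table$order_age, ds$table$order, unique)
  expect_true(all(vapply(ages, length, integer(1)) == 1)) # one age per order
  expect_true(all(ds$truth$eraOf %in%
                    c("full glaciation", "partial glaciation",
                      "partial warm", "warm")))
  expect_error(simulateGlobtherm(simulationConfig(nTips = 5, nOrders = 9)),
               "nOrders")
})

test_that("written datasets round-trip through the package readers", {
  ds <- simulateGlobtherm(simulationConfig(seed = 12, nTips = 30, nOrders = 3))
  dir <- withr::local_tempdir()
  paths <- writeSyntheticDataset(ds, dir)
  tree <- readNewick(paths$tree)
  tab <- readTraitTable(paths$table)
  eras <- readEraTable(paths$eras)
  expect_setequal(tree$tip.label, ds$tree$tip.label)
  expect_equal(nrow(tab), nrow(ds$table))
  expect_equal(tab$tolerance, ds$table$tolerance, tolerance = 1e-12)
  expect_s3_class(eras, "eraTable")
  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_equal(truth$lowerModel$sigma2, 2.0)
})
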