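test_that("readNewick parses, validates and labels a calibrated tree", {
  tree <- readNewick(text = "((A:1,B:1):1,C:2);")
  expect_s3_class(tree, "phylo")
  expect_setequal(tree$tip.label, c("A", "B", "C"))
  nd <- nodeDepths(tree)
  expect_equal(nd$T, 2)
  expect_true(checkUltrametric(tree)$ultrametric)
  expect_true(all(grepl("^nd", tree$node.label)))
})

test_that("readNewick rejects malformed and unlengthed input", {
  expect_error(readNewick(text = "((A:1,B:1):1,C:2"), "character")
  expect_error(readNewick(text = "((A:1,B:1)):1,C:2);"), "unmatched")
  expect_error(readNewick(text = "((A:1,B:1):1,C);"), "branch length")
  expect_error(readNewick(text = "((A:1,B:1):1,A:2);"), "duplicate")
  expect_error(readNewick(text = "((A:1,B:1):1,C:-2);"), "negative")
})

test_that("read/write round-trip preserves topology and branch lengths", {
  for (seed in 1:5) {
    tree <- randomTestTree(9, seed)
    path <- withr::local_tempfile(fileext = ".nwk")
    writeNewick(tree, path)
    back <- readNewick(path)
    expect_setequal(back$tip.label, tree$tip.label)
    d0 <- oracleTipDistances(tree)
    d1 <- oracleTipDistances(back)[rownames(d0), colnames(d0)]
    expect_lt(max(abs(d0 - d1)) / max(d0), 1e-9)
  }
})

test_that("checkUltrametric reports the maximum relative depth deviation", {
  res <- checkUltrametric(readNewick(text = "((A:1,B:2):1,C:2);"))
  expect_false(res$ultrametric)
  expect_equal(res$maxRelDeviation, 1 / 3)
  cherry <- checkUltrametric(readNewick(text = "(A:5,B:5);"))
  expect_true(cherry$ultrametric)
  expect_equal(cherry$maxRelDeviation, 0)
})

writeTraitCsv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  write.csv(df, path, row.names = FALSE)
  path
}

test_that("readTraitTable types records and drops unparseable numerics", {
  df <- makeTraitTable(paste0("sp", 1:5), upper = 30 + 1:5, lower = 1:5)
  tab <- readTraitTable(writeTraitCsv(df))
  expect_equal(nrow(tab), 10)
  expect_equal(attr(tab, "report")$n_dropped, 0)

  df$tolerance[3] <- "NA"
  expect_message(tab2 <- readTraitTable(writeTraitCsv(df)), "dropped 1")
  expect_equal(nrow(tab2), 9)
  expect_equal(attr(tab2, "report")$n_dropped, 1)
})

test_that("readTraitTable enforces schema and invariants", {
  df <- makeTraitTable("sp1", upper = 30, lower = 5)
  expect_error(readTraitTable(writeTraitCsv(df[setdiff(names(df), "order_age")])),
               "order_age")
  dfBad <- makeTraitTable("sp1", upper = 30, lower = 5, lat = 95)
  expect_error(readTraitTable(writeTraitCsv(dfBad)), "latitude")
  dfSwap <- makeTraitTable("sp1", upper = 2, lower = 20)
  expect_error(readTraitTable(writeTraitCsv(dfSwap)), "upper tolerance below")
})

test_that("matchTreeTraits intersects, prunes and reports", {
  tree <- readNewick(text = "((A:1,B:1):1,C:2);")
  tab <- makeTraitTable(c("B", "C", "D"), upper = c(31, 32, 33),
                        lower = c(1, 2, 3))
  m <- matchTreeTraits(tree, tab, "upper", minOverlap = 2)
  expect_setequal(m$tree$tip.label, c("B", "C"))
  expect_equal(m$report$dropped_tips, "A")
  expect_equal(m$report$dropped_records, "d")
  expect_equal(unname(m$x[c("B", "C")]), c(31, 32))
  expect_error(matchTreeTraits(tree, tab, "upper"), "insufficient overlap")
})

test_that("name canonicalization matches underscore and case variants", {
  tree <- readNewick(text = "((Genus_species:1,Other_one:1):1,Third_sp:2);")
  tab <- makeTraitTable(c("genus species", "OTHER ONE", "Third_sp"),
                        upper = c(30, 31, 32), lower = c(1, 2, 3))
  m <- matchTreeTraits(tree, tab, "upper")
  expect_equal(m$report$n, 3)
  expect_length(m$report$dropped_tips, 0)
})

test_that("duplicate species records are averaged before matching", {
  tree <- readNewick(text = "((A:1,B:1):1,C:2);")
  tab <- makeTraitTable(c("A", "A", "B", "C"), upper = c(30, 34, 31, 32),
                        lower = c(1, 1, 2, 3))
  m <- matchTreeTraits(tree, tab, "upper")
  expect_equal(unname(m$x["A"]), 32)
  expect_equal(m$report$duplicates_averaged, "a")
})

test_that("pruning preserves path lengths among retained tips", {
  tree <- readNewick(text = "((A:1,B:1):1,C:2);")
  tab <- makeTraitTable(c("A", "C", "X"), upper = c(30, 32, 33),
                        lower = c(1, 3, 4))
  m <- matchTreeTraits(tree, tab, "upper", minOverlap = 2)
  expect_equal(oracleTipDistances(m$tree)["A", "C"], 4)

  for (seed in 6:8) {
    big <- randomTestTree(10, seed)
    keep <- sort(big$tip.label)[1:6]
    tabR <- makeTraitTable(keep, upper = 30 + seq_along(keep),
                           lower = seq_along(keep))
    mr <- matchTreeTraits(big, tabR, "upper")
    d0 <- oracleTipDistances(big)[keep, keep]
    d1 <- oracleTipDistances(mr$tree)[keep, keep]
    expect_equal(d1, d0, tolerance = 1e-10)
  }
})

test_that("matchTreeTraits is idempotent", {
  tree <- randomTestTree(8, 99)
  keep <- sort(tree$tip.label)[1:5]
  tab <- makeTraitTable(keep, upper = 30 + seq_along(keep),
                        lower = seq_along(keep))
  m1 <- matchTreeTraits(tree, tab, "upper")
  m2 <- matchTreeTraits(m1$tree, tab, "upper")
  expect_equal(m2$tree$tip.label, m1$tree$tip.label)
  expect_equal(m2$x, m1$x)
  expect_length(m2$report$dropped_tips, 0)
})
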