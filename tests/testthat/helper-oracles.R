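# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: plain solve()/determinant() Gaussian
# densities, explicit root-to-tip path walks, and a direct waiting-time
# simulator for Yule depths.

# Gaussian log-density via solve() and determinant() -- no Cholesky reuse.
oracleMvnLogLik <- function(x, mu, V) {
  n <- length(x)
  r <- x - mu
  ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  -0.5 * (n * log(2 * pi) + ld + as.numeric(t(r) %*% solve(V, r)))
}

# Root-to-node path for every node as an ordered vector of node ids.
oraclePaths <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  parent <- integer(n + tree$Nnode)
  elen <- numeric(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  lapply(seq_len(n + tree$Nnode), function(node) {
    path <- node
    while (node != root) {
      node <- parent[node]
      path <- c(node, path)
    }
    path
  })
}

# Brute-force shared root-to-MRCA time for each tip pair (BM covariance),
# by summing edge lengths along the common prefix of root-to-tip paths.
oracleSharedTimes <- function(tree) {
  n <- length(tree$tip.label)
  paths <- oraclePaths(tree)
  elen <- numeric(n + tree$Nnode)
  elen[tree$edge[, 2]] <- tree$edge.length
  depthOf <- function(path) sum(elen[path[-1]])
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in i:n) {
      pi <- paths[[i]]
      pj <- paths[[j]]
      m <- min(length(pi), length(pj))
      common <- pi[seq_len(m)][pi[seq_len(m)] == pj[seq_len(m)]]
      C[i, j] <- C[j, i] <- depthOf(common)
    }
  }
  C
}

# Brute-force tip-to-tip path distance matrix.
oracleTipDistances <- function(tree) {
  C <- oracleSharedTimes(tree)
  d <- diag(C)
  outer(d, d, "+") - 2 * C
}

# Random non-ultrametric test tree with strictly positive branch lengths.
randomTestTree <- function(nTips, seed) {
  set.seed(seed)
  tree <- ape::rtree(nTips)
  tree$edge.length <- runif(nrow(tree$edge), 0.2, 2)
  tree
}

# Independent Yule tree-depth sampler: the depth of an n-tip pure-birth
# tree in this construction is a sum of independent exponential waits at
# rates (2, 3, ..., n-1, n) * lambda.
oracleYuleDepths <- function(nReps, nTips, lambda) {
  rates <- c(seq(2L, max(2L, nTips - 1L)), nTips) * lambda
  replicate(nReps, sum(rexp(length(rates), rate = rates)))
}

# Small trait-table fixture: one row per species and side.
makeTraitTable <- function(species, upper, lower, order = "ordA",
                           order_age = 45, group = "ectotherm",
                           tmax = 30, tmin = 5, lat = 10) {
  k <- length(species)
  rep_len2 <- function(v) rep_len(v, k)
  mk <- function(side, tol) data.frame(
    species = species, group = group, limit_side = side, metric = "critical",
    tolerance = tol, order = rep_len2(order), order_age = rep_len2(order_age),
    current_tmax = rep_len2(tmax), current_tmin = rep_len2(tmin),
    realm = "terrestrial", latitude = rep_len2(lat), longitude = 0,
    stringsAsFactors = FALSE
  )
  rbind(mk("upper", upper), mk("lower", lower))
}

# Era fixture used in most palaeoclimate tests: [60,30)=warm,
# [30,10)=partial glaciation, [10,0)=full glaciation.
testEras <- function() {
  eraTable(older_bound = c(60, 30, 10), younger_bound = c(30, 10, 0),
           category = c("warm", "partial glaciation", "full glaciation"))
}
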