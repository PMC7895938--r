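#' Ancestral state reconstruction under fitted Brownian motion
#'
#' Each internal node's estimate is the conditional expectation of its state
#' given the tip values under the fitted BM model (root state `z0hat`, rate
#' `sigma2hat`); its uncertainty is the analytic conditional variance scaled
#' by `sigma2hat`. By construction the root estimate equals the
#' generalized-least-squares `z0hat` of the BM fit. Node ages are reported
#' in Mya before present (tips of an ultrametric tree at age 0).
#'
#' @param tree A `phylo` object.
#' @param x Named trait vector (degrees C) over the tips.
#' @param fit Optional precomputed BM `evoModelFit`; fitted if missing.
#' @return A `data.frame` with one row per node (internal nodes and, for
#'   completeness, tips with variance 0): `node` (ape id), `label`, `age`
#'   (Mya), `estimate` (degC), `variance` (degC^2); attribute `fit` carries
#'   the BM fit used.
#' @export
reconstructBM <- function(tree, x, fit = NULL) {
  validatePhylogeny(tree, minTips = 2L)
  x <- alignTrait(tree, x)
  if (is.null(fit)) fit <- fitTraitModel("BM", tree, x)
  stopifnot(identical(fit$model, "BM"))
  n <- length(tree$tip.label)
  nNode <- n + tree$Nnode
  nd <- nodeDepths(tree)
  # Full BM covariance over tips AND internal nodes: entry (u, v) is the
  # depth of their most recent common ancestor.
  mr <- ape::mrca(tree, full = TRUE)
  Cfull <- matrix(nd$depths[mr], nNode, nNode)
  tips <- seq_len(n)
  internals <- (n + 1L):nNode
  Ctt <- Cfull[tips, tips, drop = FALSE]
  Cat <- Cfull[internals, tips, drop = FALSE]
  Caa <- Cfull[internals, internals, drop = FALSE]
  R <- chol(Ctt)
  # W = Ctt^-1 t(Cat)
  W <- backsolve(R, backsolve(R, t(Cat), transpose = TRUE))
  est <- fit$z0 + as.numeric(Cat %*% backsolve(R, backsolve(R, x - fit$z0,
                                                            transpose = TRUE)))
  condVar <- diag(Caa) - rowSums(t(W) * Cat)
  condVar[condVar < 0] <- 0 # clip tiny negative round-off
  labels <- c(tree$tip.label,
              tree$node.label %||% paste0("nd", internals))
  out <- data.frame(
    node = seq_len(nNode),
    label = labels,
    age = nd$T - nd$depths,
    estimate = c(as.numeric(x), est),
    variance = c(rep(0, n), fit$sigma2 * condVar),
    isTip = c(rep(TRUE, n), rep(FALSE, tree$Nnode))
  )
  attr(out, "fit") <- fit
  out
}

#' Traitgram segment geometry
#'
#' A traitgram draws the trait value of every lineage against node age. This
#' returns one segment per edge of the tree, from the parent's
#' ancestral-state estimate to the child's estimate (or its observed value
#' when the child is a tip), on a Mya-before-present age axis.
#'
#' @param tree A `phylo` object.
#' @param states Output of [reconstructBM()] on the same tree.
#' @param x Named trait vector over the tips (used for tip endpoints).
#' @return A `data.frame` with one row per edge: `parent`, `child`,
#'   `age_parent`, `age_child` (Mya), `value_parent`, `value_child` (degC),
#'   `variance_parent`, `variance_child` (degC^2).
#' @export
traitgramSegments <- function(tree, states, x) {
  x <- alignTrait(tree, x)
  if (nrow(states) != length(tree$tip.label) + tree$Nnode) {
    stop("states were not computed on this tree")
  }
  edge <- tree$edge
  value <- states$estimate
  value[seq_along(x)] <- as.numeric(x)
  data.frame(
    parent = edge[, 1],
    child = edge[, 2],
    age_parent = states$age[edge[, 1]],
    age_child = states$age[edge[, 2]],
    value_parent = value[edge[, 1]],
    value_child = value[edge[, 2]],
    variance_parent = states$variance[edge[, 1]],
    variance_child = states$variance[edge[, 2]]
  )
}
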