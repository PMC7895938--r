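#' Brownian-motion phylogenetic covariance matrix
#'
#' Under Brownian motion with rate `sigma2`, the covariance between two tips
#' is `sigma2 * t_a(i,j)`, the shared root-to-MRCA path length, and a tip's
#' variance is `sigma2 * d_i`, its depth. This returns the unit-rate matrix
#' `C` with `C[i,j] = t_a(i,j)` (Mya).
#'
#' @param tree A `phylo` object.
#' @return Symmetric positive semi-definite matrix over tips, dimnames set to
#'   tip labels.
#' @export
phyloCovariance <- function(tree) {
  validatePhylogeny(tree)
  C <- ape::vcv.phylo(tree)
  C[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Ornstein-Uhlenbeck covariance matrix (fixed root)
#'
#' The fixed-root (Hansen) form for tips `i`, `j` with depths `d_i`, `d_j`
#' and shared time `t_a`:
#' `V[i,j] = sigma2/(2*alpha) * (1 - exp(-2*alpha*t_a)) *`
#' `exp(-alpha * ((d_i - t_a) + (d_j - t_a)))`.
#' The expression `(1 - exp(-2*alpha*t_a)) / (2*alpha)` is evaluated with
#' `expm1` so the Brownian limit `alpha -> 0` (where it tends to `t_a`) is
#' numerically exact down to extremely small `alpha`.
#'
#' @param tree A `phylo` object.
#' @param alpha Attraction strength towards the optimum (Mya^-1, > 0).
#' @param sigma2 Brownian rate (degrees C^2 Mya^-1, > 0).
#' @return Symmetric positive semi-definite matrix over tips.
#' @export
ouCovariance <- function(tree, alpha, sigma2 = 1) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    stop("alpha must be a single positive number")
  }
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  C <- phyloCovariance(tree)
  d <- diag(C)
  # shared-time factor, stable at small alpha: -expm1(-2*a*t)/(2*a) -> t
  shared <- -expm1(-2 * alpha * C) / (2 * alpha)
  decay <- exp(-alpha * (outer(d, d, "+") - 2 * C))
  V <- sigma2 * shared * decay
  dimnames(V) <- dimnames(C)
  (V + t(V)) / 2
}

# Gaussian log-density of x under mean vector mu and covariance V (dense
# Cholesky path). Errors informatively when V is computationally singular.
denseMvnLogLik <- function(x, mu, V) {
  R <- tryCatch(
    chol(V),
    error = function(e) {
      stop("singular covariance matrix (coincident zero-distance tips?): ",
           conditionMessage(e), call. = FALSE)
    }
  )
  n <- length(x)
  z <- backsolve(R, x - mu, transpose = TRUE)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z^2))
}

# Felsenstein pruning evaluation of the BM log-likelihood with fixed root
# state z0 and rate sigma2. Independent of the dense path: works on the tree
# edges alone, never forms the covariance matrix. Handles multifurcations by
# sequential pairwise merging.
bmLogLikPruning <- function(tree, x, z0, sigma2) {
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  n <- length(tree$tip.label)
  x <- x[tree$tip.label]
  nNode <- n + tree$Nnode
  val <- numeric(nNode)   # partial-mean trait value per node
  extra <- numeric(nNode) # extra variance-length accumulated at each node
  val[seq_len(n)] <- as.numeric(x)
  lnL <- 0
  edge <- tree$edge
  len <- tree$edge.length
  children <- split(seq_len(nrow(edge)), edge[, 1])
  post <- rev(unique(ape::reorder.phylo(tree, "cladewise")$edge[, 1]))
  for (node in post) {
    rows <- children[[as.character(node)]]
    kids <- edge[rows, 2]
    v <- len[rows] + extra[kids]
    cv <- val[kids[1]]
    cl <- v[1]
    if (length(kids) > 1) {
      for (j in 2:length(kids)) {
        s <- cl + v[j]
        contrast <- cv - val[kids[j]]
        lnL <- lnL - 0.5 * (log(2 * pi * sigma2 * s) + contrast^2 / (sigma2 * s))
        cv <- (v[j] * cv + cl * val[kids[j]]) / s
        cl <- cl * v[j] / s
      }
    }
    val[node] <- cv
    extra[node] <- cl
  }
  root <- n + 1L
  if (extra[root] > 0) {
    lnL <- lnL - 0.5 * (log(2 * pi * sigma2 * extra[root]) +
                          (val[root] - z0)^2 / (sigma2 * extra[root]))
  } else if (abs(val[root] - z0) > 1e-8) {
    return(-Inf)
  }
  lnL
}

#' Log-likelihood of a trait vector under BM, OU or WN
#'
#' Brownian motion (BM): multivariate normal with mean `z0` and covariance
#' `sigma2 * C`. Ornstein-Uhlenbeck (OU, single stationary peak with the
#' optimum constrained to the root state): mean `z0`, fixed-root Hansen
#' covariance. White noise (WN): iid Normal(`mu`, `sigma2`), ignoring the
#' tree.
#'
#' @param model `"BM"`, `"OU"` or `"WN"`.
#' @param params Named list: BM needs `z0`, `sigma2`; OU needs `z0`,
#'   `sigma2`, `alpha`; WN needs `mu`, `sigma2`.
#' @param tree A `phylo` object (ignored for WN except for tip matching).
#' @param x Named trait vector aligned to `tree$tip.label`.
#' @param method For BM, `"dense"` (multivariate normal) or `"pruning"`
#'   (Felsenstein contrasts); the two agree to numerical precision and exist
#'   as mutually checking paths.
#' @return The log-likelihood (finite for valid inputs).
#' @export
traitLogLik <- function(model = c("BM", "OU", "WN"), params, tree, x,
                        method = c("dense", "pruning")) {
  model <- match.arg(model)
  method <- match.arg(method)
  x <- alignTrait(tree, x)
  n <- length(x)
  if (model == "WN") {
    mu <- params$mu %||% params$z0
    sigma2 <- params$sigma2
    if (sigma2 <= 0) stop("sigma2 must be > 0")
    return(sum(stats::dnorm(x, mu, sqrt(sigma2), log = TRUE)))
  }
  if (model == "BM") {
    if (method == "pruning") {
      return(bmLogLikPruning(tree, x, params$z0, params$sigma2))
    }
    V <- params$sigma2 * phyloCovariance(tree)
    return(denseMvnLogLik(x, rep(params$z0, n), V))
  }
  # OU with theta = z0: the mean vector is constant at z0 for any alpha
  V <- ouCovariance(tree, alpha = params$alpha, sigma2 = params$sigma2)
  denseMvnLogLik(x, rep(params$z0, n), V)
}

# Ensure x is a named vector covering exactly the tree tips, in tip order.
alignTrait <- function(tree, x) {
  if (is.null(names(x))) {
    if (length(x) != length(tree$tip.label)) {
      stop("unnamed trait vector of length ", length(x), " for a ",
           length(tree$tip.label), "-tip tree")
    }
    names(x) <- tree$tip.label
    return(x)
  }
  missing <- setdiff(tree$tip.label, names(x))
  if (length(missing)) {
    stop("trait values missing for tips: ", paste(head(missing, 5), collapse = ", "))
  }
  x[tree$tip.label]
}
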