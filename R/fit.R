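#' Default fitting options for trait-model maximum likelihood
#'
#' @param alphaBounds OU attraction-strength search bounds in units of
#'   `1/T` (tree depth); the pair is multiplied by `1/T` at fit time.
#'   Default `c(1e-9, 100)`, i.e. alpha in `[1e-9/T, 100/T]`. The lower
#'   bound is small enough that the OU fit always attains the nested
#'   Brownian-motion likelihood.
#' @param nStarts Number of multistart initializations for the OU profile
#'   search over `log(alpha)` (default 5).
#' @param seed Seed controlling multistart jitter (default 1); fits are
#'   deterministic given the seed.
#' @param reltol Convergence tolerance for the optimizer.
#' @return A list of options for [fitTraitModel()].
#' @export
fitOptions <- function(alphaBounds = c(1e-9, 100), nStarts = 5L, seed = 1L,
                       reltol = 1e-10) {
  stopifnot(length(alphaBounds) == 2L, alphaBounds[1] > 0,
            alphaBounds[2] > alphaBounds[1], nStarts >= 1L)
  list(alphaBounds = alphaBounds, nStarts = as.integer(nStarts),
       seed = as.integer(seed), reltol = reltol)
}

# Generalized-least-squares profile of (z0, sigma2) for a unit-rate
# covariance V0: z0hat = (1'V0^-1 x)/(1'V0^-1 1), sigma2hat = r'V0^-1 r / n
# (MLE denominator n), and the profiled log-likelihood.
glsProfile <- function(x, V0) {
  n <- length(x)
  R <- tryCatch(chol(V0), error = function(e) {
    stop("singular covariance matrix (coincident zero-distance tips?)",
         call. = FALSE)
  })
  one <- rep(1, n)
  w1 <- backsolve(R, one, transpose = TRUE)
  wx <- backsolve(R, x, transpose = TRUE)
  z0 <- sum(w1 * wx) / sum(w1 * w1)
  r <- wx - z0 * w1
  sigma2 <- sum(r^2) / n
  logdet <- 2 * sum(log(diag(R)))
  lnL <- -0.5 * (n * (log(2 * pi) + log(sigma2) + 1) + logdet)
  list(z0 = z0, sigma2 = sigma2, lnL = lnL)
}

aiccFromLnL <- function(lnL, k, n) {
  if (n - k - 1 <= 0) return(NA_real_)
  2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1)
}

newModelFit <- function(model, n, lnL, k, sigma2, z0 = NA_real_, mu = NA_real_,
                        alpha = NA_real_, converged = TRUE, diagnostics = list()) {
  fit <- list(
    model = model, n = n, sigma2 = sigma2, z0 = z0, mu = mu,
    theta = if (model == "OU") z0 else NA_real_,
    alpha = alpha,
    negLogAlpha = if (model == "OU") -log(alpha) else NA_real_,
    lnL = lnL, k = k, AICc = aiccFromLnL(lnL, k, n),
    converged = converged,
    logBase = "natural",
    units = c(sigma2 = "degC^2 Mya^-1", alpha = "Mya^-1",
              z0 = "degC", mu = "degC", theta = "degC"),
    diagnostics = diagnostics
  )
  class(fit) <- "evoModelFit"
  fit
}

#' @export
print.evoModelFit <- function(x, ...) {
  cat(sprintf("%s fit (n = %d tips)\n", x$model, x$n))
  cat(sprintf("  lnL = %.4f, k = %d, AICc = %.4f\n", x$lnL, x$k, x$AICc))
  cat(sprintf("  sigma2 = %.6g degC^2/Mya\n", x$sigma2))
  if (x$model == "OU") {
    cat(sprintf("  alpha = %.6g /Mya  (-log alpha = %.4f, natural log)\n",
                x$alpha, x$negLogAlpha))
    cat(sprintf("  z0 = theta = %.4f degC\n", x$z0))
  } else if (x$model == "BM") {
    cat(sprintf("  z0 = %.4f degC\n", x$z0))
  } else {
    cat(sprintf("  mu = %.4f degC\n", x$mu))
  }
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  invisible(x)
}

#' Maximum-likelihood fit of one trait-evolution model
#'
#' White noise (WN) and Brownian motion (BM) have closed-form maximum
#' likelihood estimates via generalized-least-squares profiling with MLE
#' (denominator `n`) variance. The Ornstein-Uhlenbeck (OU) fit profiles
#' `(z0, sigma2)` at each candidate `alpha` and optimizes `log(alpha)` over
#' a bounded interval with multistarts; the interval endpoints are always
#' included as candidates, so the reported optimum is at least as good as
#' every initialization and the Brownian limit.
#'
#' @param model `"BM"`, `"OU"` or `"WN"`.
#' @param tree A `phylo` object.
#' @param x Named trait vector (degrees C) over the tips.
#' @param options See [fitOptions()].
#' @return An `evoModelFit`: parameter estimates (`sigma2` in degC^2/Mya,
#'   `alpha` in 1/Mya, `z0`/`mu`/`theta` in degC), `lnL`, `k`, `AICc` and,
#'   for OU, `negLogAlpha = -log(alpha)` (natural logarithm).
#' @export
fitTraitModel <- function(model = c("BM", "OU", "WN"), tree, x,
                          options = fitOptions()) {
  model <- match.arg(model)
  validatePhylogeny(tree, minTips = 2L)
  x <- alignTrait(tree, x)
  n <- length(x)
  if (model == "WN") {
    mu <- mean(x)
    sigma2 <- sum((x - mu)^2) / n
    if (sigma2 <= 0) stop("trait is constant; WN variance MLE is zero")
    lnL <- -0.5 * n * (log(2 * pi * sigma2) + 1)
    return(newModelFit("WN", n, lnL, k = 2L, sigma2 = sigma2, mu = mu))
  }
  C <- phyloCovariance(tree)
  if (model == "BM") {
    prof <- glsProfile(x, C)
    return(newModelFit("BM", n, prof$lnL, k = 2L,
                       sigma2 = prof$sigma2, z0 = prof$z0))
  }
  # OU: profile likelihood over log(alpha)
  d <- diag(C)
  Tdepth <- max(d)
  lb <- log(options$alphaBounds[1] / Tdepth)
  ub <- log(options$alphaBounds[2] / Tdepth)
  profile <- function(la) {
    a <- exp(la)
    shared <- -expm1(-2 * a * C) / (2 * a)
    V0 <- shared * exp(-a * (outer(d, d, "+") - 2 * C))
    glsProfile(x, (V0 + t(V0)) / 2)
  }
  objective <- function(la) -profile(la)$lnL
  set.seed(deriveSeed(options$seed, "ou-multistart"))
  starts <- seq(lb, ub, length.out = options$nStarts + 2L)[-c(1L, options$nStarts + 2L)]
  starts <- pmin(ub, pmax(lb, starts + runif(length(starts), -0.1, 0.1)))
  candidates <- lapply(starts, function(s) {
    fit <- tryCatch(
      optim(s, objective, method = "L-BFGS-B", lower = lb, upper = ub,
            control = list(factr = options$reltol / .Machine$double.eps)),
      error = function(e) NULL
    )
    if (is.null(fit)) return(NULL)
    list(la = fit$par, nll = fit$value, conv = fit$convergence == 0)
  })
  candidates <- Filter(Negate(is.null), candidates)
  for (endpoint in c(lb, ub)) {
    candidates <- c(candidates,
                    list(list(la = endpoint, nll = objective(endpoint), conv = TRUE)))
  }
  if (!length(candidates)) {
    stop("OU optimizer failed at every multistart; no candidate solution")
  }
  nlls <- vapply(candidates, `[[`, numeric(1), "nll")
  best <- candidates[[which.min(nlls)]]
  anyConv <- any(vapply(candidates, `[[`, logical(1), "conv"))
  prof <- profile(best$la)
  alpha <- exp(best$la)
  newModelFit("OU", n, prof$lnL, k = 3L, sigma2 = prof$sigma2,
              z0 = prof$z0, alpha = alpha, converged = anyConv,
              diagnostics = list(
                alphaBounds = options$alphaBounds / Tdepth,
                treeDepth = Tdepth,
                atLowerBound = isTRUE(abs(best$la - lb) < 1e-8),
                atUpperBound = isTRUE(abs(best$la - ub) < 1e-8),
                nStarts = options$nStarts,
                seed = options$seed,
                multistartLnL = -nlls
              ))
}

#' Fit and compare BM, OU and WN on the same data
#'
#' All three models are fitted to the identical (tree, trait) pair. Because
#' BM is nested in OU as `alpha -> 0` and the OU search interval reaches
#' that limit, `lnL(OU) >= lnL(BM)` up to optimizer tolerance. Models are
#' ranked both by raw log-likelihood (the headline ranking) and by AICc.
#'
#' @inheritParams fitTraitModel
#' @return An `evoModelComparison`: the three `evoModelFit`s plus
#'   `delta_lnL`, `delta_AICc`, `best_by_lnL` and `best_by_AICc`.
#' @export
compareTraitModels <- function(tree, x, options = fitOptions()) {
  fits <- list(
    BM = fitTraitModel("BM", tree, x, options),
    OU = fitTraitModel("OU", tree, x, options),
    WN = fitTraitModel("WN", tree, x, options)
  )
  lnL <- vapply(fits, `[[`, numeric(1), "lnL")
  aicc <- vapply(fits, `[[`, numeric(1), "AICc")
  cmp <- list(
    fits = fits,
    n = fits$BM$n,
    lnL = lnL,
    AICc = aicc,
    delta_lnL = max(lnL) - lnL,
    delta_AICc = aicc - min(aicc),
    best_by_lnL = names(which.max(lnL)),
    best_by_AICc = if (all(is.na(aicc))) NA_character_ else
      names(which.min(aicc))
  )
  class(cmp) <- "evoModelComparison"
  cmp
}

#' @export
print.evoModelComparison <- function(x, ...) {
  cat(sprintf("Model comparison on %d tips\n", x$n))
  tab <- data.frame(
    model = names(x$lnL),
    k = vapply(x$fits, `[[`, integer(1), "k"),
    lnL = round(x$lnL, 4),
    AICc = round(x$AICc, 4),
    dAICc = round(x$delta_AICc, 4)
  )
  print(tab, row.names = FALSE)
  cat(sprintf("best by lnL: %s; best by AICc: %s\n",
              x$best_by_lnL, x$best_by_AICc))
  invisible(x)
}

#' Tempo of evolution: Brownian rate averaged over tree variants
#'
#' The evolutionary tempo is the Brownian rate parameter `sigma2` (degC^2
#' per Mya). When two (or more) tree variants are supplied — typically a
#' smoothed and an unsmoothed chronogram — the reported tempo is the
#' arithmetic mean of the per-tree maximum-likelihood estimates.
#'
#' @param trees A single `phylo`, a `multiPhylo`, or a list of `phylo`.
#' @param x Named trait vector covering the tips of every tree.
#' @param options See [fitOptions()].
#' @return List with `sigma2` (the averaged tempo), `perTree` (per-tree
#'   estimates) and `nTrees`.
#' @export
tempoSigma2 <- function(trees, x, options = fitOptions()) {
  trees <- asTreeList(trees)
  per <- vapply(seq_along(trees), function(i) {
    fit <- tryCatch(
      fitTraitModel("BM", trees[[i]], x, options),
      error = function(e) stop("BM fit failed on tree ", i, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    fit$sigma2
  }, numeric(1))
  list(sigma2 = mean(per), perTree = per, nTrees = length(per))
}

#' Summarize fitted parameters across a set of trees
#'
#' Refits one model on every tree (for example 100 chronograms sampled from
#' a Bayesian posterior) and reports the mean and standard deviation
#' (denominator `nTrees - 1`; 0 for a single tree) of each parameter.
#'
#' @param trees A `multiPhylo` or list of `phylo` sharing the same tip set.
#' @param x Named trait vector over the shared tips.
#' @param model `"BM"`, `"OU"` or `"WN"`.
#' @param options See [fitOptions()].
#' @return A `data.frame` with one row per parameter (`mean`, `sd`) plus
#'   attribute `nTrees`.
#' @export
summarizeOverTrees <- function(trees, x, model = c("BM", "OU", "WN"),
                               options = fitOptions()) {
  model <- match.arg(model)
  trees <- asTreeList(trees)
  tipSets <- lapply(trees, function(t) sort(t$tip.label))
  if (length(trees) > 1L &&
      !all(vapply(tipSets[-1], identical, logical(1), tipSets[[1]]))) {
    stop("trees do not share the same tip set")
  }
  fields <- switch(model,
                   BM = c("sigma2", "z0", "lnL", "AICc"),
                   OU = c("sigma2", "alpha", "negLogAlpha", "z0", "lnL", "AICc"),
                   WN = c("sigma2", "mu", "lnL", "AICc"))
  vals <- t(vapply(trees, function(tr) {
    fit <- fitTraitModel(model, tr, x, options)
    vapply(fields, function(f) fit[[f]], numeric(1))
  }, numeric(length(fields))))
  colnames(vals) <- fields
  out <- data.frame(
    parameter = fields,
    mean = colMeans(vals),
    sd = if (nrow(vals) > 1L) apply(vals, 2, sd) else rep(0, length(fields)),
    row.names = NULL
  )
  attr(out, "nTrees") <- length(trees)
  out
}

asTreeList <- function(trees) {
  if (inherits(trees, "phylo")) return(list(trees))
  if (inherits(trees, "multiPhylo")) return(unclass(trees))
  if (is.list(trees) && all(vapply(trees, inherits, logical(1), "phylo"))) {
    return(trees)
  }
  stop("'trees' must be a phylo, multiPhylo, or list of phylo objects")
}
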