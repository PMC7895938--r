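#' Configuration for the synthetic GlobTherm-like generator
#'
#' Defaults describe the conditions the package's analyses assume: a
#' time-calibrated ultrametric order-level phylogeny some hundreds of Mya
#' deep, species-level upper and lower thermal limits evolving on it with
#' a faster Brownian rate for lower than upper limits, a latitudinal
#' gradient in current climate with additive coupling into the limits, and
#' taxonomic orders whose crown ages map onto palaeoclimate eras.
#'
#' @param seed Master seed; every stage derives its own substream.
#' @param nTips Number of species (default 200).
#' @param birthRate Yule speciation rate, Mya^-1 (default 0.015, giving
#'   tree depths of a few hundred Mya at the default size).
#' @param nOrders Number of taxonomic orders to partition tips into
#'   (default 25, roughly one order per eight species as in order-level
#'   curated thermal-limit compilations).
#' @param upperModel,lowerModel Trait-model specs for the two limit sides:
#'   lists with `model` in BM/OU/WN and the relevant parameters (`sigma2`,
#'   degC^2/Mya; `alpha`, Mya^-1; `z0`/`theta`/`mu`, degC). Defaults:
#'   BM with `sigma2 = 0.5`, `z0 = 40` (upper, a heat-tolerance-like root
#'   state) and BM with `sigma2 = 2.0`, `z0 = -10` (lower, cold-tolerance
#'   like) — lower limits evolving faster than upper.
#' @param climateSlope Additive coupling of the (centred) current climate
#'   into the limit, degC per degC (default 0.3).
#' @param group Group label stamped on all records (default "ectotherm").
#' @param eras Era table used for order-age labelling
#'   (default [defaultEraTable()]).
#' @param latRange Latitude band species are drawn from (default
#'   `c(-60, 60)`).
#' @param maxResample Maximum whole-dataset redraws to enforce
#'   upper > lower (default 50).
#' @return A validated list of class `simulationConfig`.
#' @export
simulationConfig <- function(seed = 1L, nTips = 200L, birthRate = 0.015,
                             nOrders = 25L,
                             upperModel = list(model = "BM", sigma2 = 0.5, z0 = 40),
                             lowerModel = list(model = "BM", sigma2 = 2.0, z0 = -10),
                             climateSlope = 0.3,
                             group = "ectotherm",
                             eras = defaultEraTable(),
                             latRange = c(-60, 60),
                             maxResample = 50L) {
  stopifnot(nTips >= 3L, birthRate > 0, nOrders >= 1L, nOrders <= nTips,
            inherits(eras, "eraTable"), length(latRange) == 2L)
  for (m in list(upperModel, lowerModel)) {
    stopifnot(m$model %in% c("BM", "OU", "WN"))
    if (is.null(m$sigma2) || m$sigma2 < 0) stop("model spec needs sigma2 >= 0")
    if (m$model == "OU" && (is.null(m$alpha) || m$alpha <= 0)) {
      stop("OU model spec needs alpha > 0")
    }
  }
  cfg <- list(seed = as.integer(seed), nTips = as.integer(nTips),
              birthRate = birthRate, nOrders = as.integer(nOrders),
              upperModel = upperModel, lowerModel = lowerModel,
              climateSlope = climateSlope, group = group, eras = eras,
              latRange = latRange, maxResample = as.integer(maxResample))
  class(cfg) <- c("simulationConfig", "list")
  cfg
}

#' Simulate an ultrametric Yule (pure-birth) phylogeny
#'
#' Forward simulation: starting from the root split (two lineages), waiting
#' times between speciation events are exponential with rate
#' `k * birthRate` for `k` extant lineages and the splitting lineage is
#' chosen uniformly; after the `n`-th tip appears one further exponential
#' waiting time is added so tips are contemporaneous at the present.
#' Deterministic given the seed.
#'
#' @param nTips Number of tips (>= 2).
#' @param birthRate Speciation rate (Mya^-1).
#' @param seed Seed.
#' @return An ultrametric `phylo` with tip labels `t1..tn` (branch lengths
#'   in Mya).
#' @export
simulateYuleTree <- function(nTips, birthRate = 0.015, seed = 1L) {
  stopifnot(nTips >= 2L, birthRate > 0)
  set.seed(as.integer(seed))
  # Record the sequence of (lineage slot, time) speciation events; the tree
  # is rebuilt from this log. A split leaves the first daughter in the
  # parent's slot and appends the second daughter as a new slot.
  splitLog <- vector("list", nTips - 2L)
  t <- 0
  k <- 2L
  while (k < nTips) {
    t <- t + rexp(1, rate = k * birthRate)
    i <- sample.int(k, 1L)
    splitLog[[k - 1L]] <- c(lineage = i, time = t)
    k <- k + 1L
  }
  t <- t + rexp(1, rate = k * birthRate)
  buildYule(splitLog, t, nTips)
}

# Reconstruct the phylo object from the ordered split log. Lineage indices
# follow the convention of simulateYuleTree: a split of lineage i leaves the
# first daughter at slot i and appends the second daughter at the end.
buildYule <- function(splitLog, presentTime, nTips) {
  nodeTime <- 0           # root at time 0
  # nodes: list of (time, childA, childB); children are lineage slots until
  # they themselves split, then node references.
  slots <- list(list(node = 1L, side = 1L), list(node = 1L, side = 2L))
  nodes <- list(list(time = 0, children = vector("list", 2L)))
  for (s in splitLog) {
    i <- s[["lineage"]]
    tm <- s[["time"]]
    nodes[[length(nodes) + 1L]] <- list(time = tm, children = vector("list", 2L))
    newNode <- length(nodes)
    parent <- slots[[i]]
    nodes[[parent$node]]$children[[parent$side]] <- list(node = newNode)
    slots[[i]] <- list(node = newNode, side = 1L)
    slots[[length(slots) + 1L]] <- list(node = newNode, side = 2L)
  }
  for (j in seq_along(slots)) {
    p <- slots[[j]]
    nodes[[p$node]]$children[[p$side]] <- list(tip = paste0("t", j))
  }
  emit <- function(child, parentTime) {
    if (!is.null(child$tip)) {
      sprintf("%s:%.10f", child$tip, presentTime - parentTime)
    } else {
      nd <- nodes[[child$node]]
      sprintf("(%s,%s):%.10f",
              emit(nd$children[[1]], nd$time),
              emit(nd$children[[2]], nd$time),
              nd$time - parentTime)
    }
  }
  root <- nodes[[1L]]
  text <- sprintf("(%s,%s);",
                  emit(root$children[[1]], 0),
                  emit(root$children[[2]], 0))
  tree <- ape::read.tree(text = text)
  stopifnot(length(tree$tip.label) == nTips)
  tree
}

#' Simulate a continuous trait on a phylogeny
#'
#' Brownian motion: each branch adds Normal(0, `sigma2 * t`) change from a
#' root state `z0`. Ornstein-Uhlenbeck (Hansen transition): along a branch
#' of length `t`, `child ~ Normal(theta + (parent - theta) * exp(-alpha*t),`
#' `sigma2/(2*alpha) * (1 - exp(-2*alpha*t)))`. White noise: iid
#' Normal(`mu`, `sigma2`) at the tips, ignoring the tree. Deterministic
#' given the seed.
#'
#' @param tree A `phylo` object.
#' @param model List: `model` in BM/OU/WN plus parameters (`sigma2`,
#'   `alpha`, `z0`, `theta`, `mu`).
#' @param seed Seed.
#' @return Named numeric vector over the tips (degrees C).
#' @export
simulateTraits <- function(tree, model, seed = 1L) {
  stopifnot(model$model %in% c("BM", "OU", "WN"))
  set.seed(as.integer(seed))
  n <- length(tree$tip.label)
  if (model$model == "WN") {
    mu <- model$mu %||% model$z0 %||% 0
    x <- rnorm(n, mu, sqrt(model$sigma2))
    names(x) <- tree$tip.label
    return(x)
  }
  z0 <- model$z0 %||% model$theta %||% 0
  tr <- ape::reorder.phylo(tree, "cladewise") # parents before children
  val <- numeric(n + tree$Nnode)
  val[n + 1L] <- z0
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]
    ch <- tr$edge[e, 2]
    len <- tr$edge.length[e]
    if (model$model == "BM") {
      val[ch] <- val[par] + if (model$sigma2 > 0 && len > 0) {
        rnorm(1, 0, sqrt(model$sigma2 * len))
      } else 0
    } else {
      theta <- model$theta %||% z0
      a <- model$alpha
      m <- theta + (val[par] - theta) * exp(-a * len)
      v <- model$sigma2 * (-expm1(-2 * a * len)) / (2 * a)
      val[ch] <- if (v > 0) rnorm(1, m, sqrt(v)) else m
    }
  }
  x <- val[seq_len(n)]
  names(x) <- tree$tip.label
  x
}

#' Simulate a GlobTherm-like species table with known ground truth
#'
#' Generates a Yule phylogeny, partitions its tips into taxonomic orders
#' (contiguous clades in cladewise tip order, dated by their most recent
#' common ancestor), draws a latitudinal gradient in current climate,
#' evolves latent upper and lower thermal limits on the tree under the
#' configured models, adds the climate coupling, and assembles the
#' species-level trait table. The constraint upper > lower is enforced by
#' redrawing the trait stage (new substream) until it holds everywhere.
#'
#' @param config A [simulationConfig()].
#' @return List of class `syntheticDataset`: `tree` (`phylo`), `table`
#'   (trait table, two rows per species), `truth` (true parameters per
#'   limit side, per-species latent climate and order map, seed, config).
#' @export
simulateGlobtherm <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "simulationConfig"))
  tree <- simulateYuleTree(config$nTips, config$birthRate,
                           seed = deriveSeed(config$seed, "yule-tree"))
  nd <- nodeDepths(tree)
  n <- config$nTips
  tipOrder <- tree$tip.label
  span <- c(config$eras$younger_bound[nrow(config$eras)],
            config$eras$older_bound[1])
  # Orders are the monophyletic clades crossing a time slice chosen so that
  # exactly nOrders lineages exist there; each order's origination age is
  # its crown node age (its sole tip's stem age for singleton orders).
  ages <- nd$T - nd$depths
  intAges <- sort(ages[(n + 1L):(n + tree$Nnode)], decreasing = TRUE)
  m <- config$nOrders
  slice <- if (m <= 1L) {
    nd$T + 1
  } else if (m >= n) {
    min(intAges) / 2
  } else {
    (intAges[m - 1L] + intAges[m]) / 2
  }
  parentOf <- integer(n + tree$Nnode)
  parentOf[tree$edge[, 2]] <- tree$edge[, 1]
  crossing <- if (m <= 1L) {
    n + 1L # the root clade is the single order
  } else {
    which(parentOf > 0L & ages < slice & ages[pmax(parentOf, 1L)] >= slice)
  }
  orderOf <- character(0)
  orderAge <- numeric(0)
  for (b in seq_along(crossing)) {
    node <- crossing[b]
    if (node <= n) {
      tipsB <- tree$tip.label[node]
      age <- ages[parentOf[node]] # singleton order: stem age
    } else {
      tipsB <- ape::extract.clade(tree, node)$tip.label
      age <- ages[node] # crown age
    }
    age <- min(max(age, span[1] + 1e-6), span[2]) # keep inside the era span
    orderOf[tipsB] <- sprintf("order_%02d", b)
    orderAge[tipsB] <- age
  }
  set.seed(deriveSeed(config$seed, "climate"))
  lat <- runif(n, config$latRange[1], config$latRange[2])
  lon <- runif(n, -180, 180)
  tmax <- 38 - 0.35 * abs(lat) + rnorm(n, 0, 2)
  tmin <- 22 - 0.70 * abs(lat) + rnorm(n, 0, 3)
  realm <- sample(.traitRealms, n, replace = TRUE,
                  prob = c(0.15, 0.05, 0.10, 0.70))
  names(lat) <- names(lon) <- names(tmax) <- names(tmin) <- names(realm) <- tipOrder
  # trait stage: redraw until upper > lower for every species
  attempt <- 0L
  repeat {
    attempt <- attempt + 1L
    upperLatent <- simulateTraits(tree, config$upperModel,
                                  seed = deriveSeed(config$seed,
                                                    paste0("upper-", attempt)))
    lowerLatent <- simulateTraits(tree, config$lowerModel,
                                  seed = deriveSeed(config$seed,
                                                    paste0("lower-", attempt)))
    upper <- upperLatent + config$climateSlope * (tmax - mean(tmax))
    lower <- lowerLatent + config$climateSlope * (tmin - mean(tmin))
    if (all(upper > lower)) break
    if (attempt >= config$maxResample) {
      stop("could not satisfy upper > lower within ", config$maxResample,
           " redraws; widen the gap between the configured root states")
    }
  }
  mkRows <- function(side, tol) {
    data.frame(
      species = tipOrder, group = config$group, limit_side = side,
      metric = "critical", tolerance = as.numeric(tol),
      order = orderOf[tipOrder], order_age = orderAge[tipOrder],
      current_tmax = as.numeric(tmax), current_tmin = as.numeric(tmin),
      realm = as.character(realm), latitude = as.numeric(lat),
      longitude = as.numeric(lon), stringsAsFactors = FALSE
    )
  }
  table <- rbind(mkRows("upper", upper), mkRows("lower", lower))
  rownames(table) <- NULL
  validateTraitTable(table)
  ds <- list(
    tree = tree,
    table = table,
    truth = list(
      upperModel = config$upperModel, lowerModel = config$lowerModel,
      climateSlope = config$climateSlope,
      latentUpper = upperLatent, latentLower = lowerLatent,
      currentTmax = tmax, currentTmin = tmin,
      orderOf = orderOf, orderAge = orderAge,
      eraOf = assignEra(orderAge[tipOrder], config$eras),
      treeDepth = nd$T, seed = config$seed, attempts = attempt,
      config = config
    )
  )
  class(ds) <- "syntheticDataset"
  ds
}

#' Write a synthetic dataset to disk in the formats the readers accept
#'
#' @param dataset A `syntheticDataset`.
#' @param dir Output directory (created if needed).
#' @return Named list of the written paths (`tree`, `table`, `eras`,
#'   `truth`), invisibly.
#' @export
writeSyntheticDataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "syntheticDataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    tree = file.path(dir, "tree.nwk"),
    table = file.path(dir, "traits.csv"),
    eras = file.path(dir, "eras.csv"),
    truth = file.path(dir, "truth.json")
  )
  writeNewick(dataset$tree, paths$tree)
  write.csv(dataset$table, paths$table, row.names = FALSE)
  eras <- dataset$truth$config$eras
  write.csv(as.data.frame(eras), paths$eras, row.names = FALSE)
  truth <- dataset$truth
  truth$config$eras <- as.data.frame(truth$config$eras)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(paths)
}

#' @export
print.syntheticDataset <- function(x, ...) {
  cat(sprintf("Synthetic thermal-limit dataset: %d species, %d orders, tree depth %.1f Mya\n",
              length(x$tree$tip.label), length(unique(x$truth$orderOf)),
              x$truth$treeDepth))
  cat(sprintf("  upper: %s (sigma2 = %.3g); lower: %s (sigma2 = %.3g); climate slope %.2f\n",
              x$truth$upperModel$model, x$truth$upperModel$sigma2,
              x$truth$lowerModel$model, x$truth$lowerModel$sigma2,
              x$truth$climateSlope))
  invisible(x)
}
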