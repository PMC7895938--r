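#' Assemble the predictor table for importance analysis
#'
#' One row per species: the response is the thermal limit for one side
#' (duplicates averaged), and the predictors are the experienced current
#' climate (current_tmax for upper limits, current_tmin for lower limits),
#' the order age (Mya) and the palaeoclimate category at order origin. The
#' category is encoded ordinally by warmth (full glaciation = 1 ... warm =
#' 4) by default, or one-hot via `encoding = "onehot"`. Rows with missing
#' predictors are dropped and counted.
#'
#' @param table A trait table (see [readTraitTable()]).
#' @param eras An `eraTable`.
#' @param group Group to analyse; `NULL` for all.
#' @param limitSide `"upper"` or `"lower"`.
#' @param encoding `"ordinal"` (default) or `"onehot"` for the
#'   palaeoclimate category.
#' @return A `data.frame` with column `response` (degC) and predictor
#'   columns `current_temperature`, `age`, `palaeo_temperature` (or one-hot
#'   columns); attribute `report` counts dropped rows.
#' @export
buildFeatureTable <- function(table, eras, group = NULL,
                              limitSide = c("upper", "lower"),
                              encoding = c("ordinal", "onehot")) {
  limitSide <- match.arg(limitSide)
  encoding <- match.arg(encoding)
  recs <- table[table$limit_side == limitSide, , drop = FALSE]
  if (!is.null(group)) recs <- recs[recs$group == group, , drop = FALSE]
  if (!nrow(recs)) stop("no records for the requested group/limit side")
  climCol <- if (limitSide == "upper") "current_tmax" else "current_tmin"
  key <- canonicalName(recs$species)
  agg <- function(v) tapply(v, key, function(z) mean(z, na.rm = FALSE))
  df <- data.frame(
    response = as.numeric(agg(recs$tolerance)),
    current_temperature = as.numeric(agg(recs[[climCol]])),
    age = as.numeric(agg(recs$order_age))
  )
  complete <- complete.cases(df)
  nDropped <- sum(!complete)
  if (nDropped) {
    message("buildFeatureTable: dropped ", nDropped,
            " species with missing predictors")
  }
  df <- df[complete, , drop = FALSE]
  if (!nrow(df)) stop("no complete rows after predictor assembly")
  cat4 <- assignEra(df$age, eras)
  if (encoding == "ordinal") {
    df$palaeo_temperature <- match(cat4, .eraCategories) # ordered by warmth
  } else {
    for (lev in .eraCategories) {
      df[[paste0("palaeo_", gsub(" ", "_", lev))]] <- as.numeric(cat4 == lev)
    }
  }
  rownames(df) <- NULL
  attr(df, "report") <- list(n = nrow(df), n_dropped = nDropped)
  df
}

#' Random-forest node-purity importance of thermal-limit predictors
#'
#' Fits a regression random forest (bootstrapped rows, `ceiling(p/3)`
#' candidate predictors per split) and reports each predictor's node-purity
#' importance — the total reduction in residual sum of squares attributed to
#' its splits — normalized to percent of the total. Model accuracy is the
#' out-of-bag R-squared. Deterministic given the seed.
#'
#' @param features Output of [buildFeatureTable()] (column `response` plus
#'   predictors).
#' @param nTrees Number of trees (default 500).
#' @param seed Seed for the forest's bootstrap/split randomness.
#' @return List of class `importanceReport`: `importance` (named percent
#'   vector summing to 100), `r_squared` (out-of-bag), `n`, `nTrees`,
#'   `seed`.
#' @export
fitForestImportance <- function(features, nTrees = 500L, seed = 1L) {
  stopifnot("response" %in% names(features))
  if (nrow(features) < 20L) {
    stop("at least 20 rows are required to fit the forest (got ",
         nrow(features), ")")
  }
  y <- features$response
  Xdf <- features[setdiff(names(features), "response")]
  p <- ncol(Xdf)
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(
    x = Xdf, y = y, ntree = as.integer(nTrees),
    mtry = max(1L, ceiling(p / 3)), importance = FALSE
  )
  purity <- rf$importance[, "IncNodePurity"]
  total <- sum(purity)
  imp <- if (total > 0) 100 * purity / total else
    setNames(rep(100 / p, p), names(purity))
  vy <- mean((y - mean(y))^2)
  r2 <- if (vy > 0) 1 - mean((y - rf$predicted)^2) / vy else 0
  res <- list(importance = imp, r_squared = r2, n = length(y),
              nTrees = as.integer(nTrees), seed = as.integer(seed))
  class(res) <- "importanceReport"
  res
}

#' Importance with confidence intervals from repeated forest fits
#'
#' Refits the forest `nRepeats` times with seeds derived from a master seed
#' and reports, per predictor, the mean normalized importance and its
#' percentile 95% confidence interval (2.5 and 97.5 percentiles across
#' refits); the reported R-squared is the mean across refits.
#'
#' @inheritParams fitForestImportance
#' @param nRepeats Number of refits (>= 30; default 100).
#' @return List of class `importanceReport`: `importance` (mean %),
#'   `ci_lo`, `ci_hi` (95% CI bounds, %), `r_squared` (mean out-of-bag R2),
#'   `n`, `nTrees`, `nRepeats`, `seed`.
#' @export
repeatImportance <- function(features, nTrees = 500L, nRepeats = 100L,
                             seed = 1L) {
  if (nRepeats < 30L) stop("nRepeats must be at least 30")
  runs <- lapply(seq_len(nRepeats), function(i) {
    fitForestImportance(features, nTrees = nTrees,
                        seed = deriveSeed(seed, paste0("forest-repeat-", i)))
  })
  impMat <- do.call(rbind, lapply(runs, `[[`, "importance"))
  res <- list(
    importance = colMeans(impMat),
    ci_lo = apply(impMat, 2, quantile, probs = 0.025, type = 7),
    ci_hi = apply(impMat, 2, quantile, probs = 0.975, type = 7),
    r_squared = mean(vapply(runs, `[[`, numeric(1), "r_squared")),
    n = runs[[1]]$n, nTrees = as.integer(nTrees),
    nRepeats = as.integer(nRepeats), seed = as.integer(seed)
  )
  class(res) <- "importanceReport"
  res
}

#' @export
print.importanceReport <- function(x, ...) {
  cat(sprintf("Random-forest importance (n = %d, %d trees%s)\n", x$n, x$nTrees,
              if (!is.null(x$nRepeats)) paste0(", ", x$nRepeats, " refits") else ""))
  ord <- order(x$importance, decreasing = TRUE)
  for (i in ord) {
    ci <- if (!is.null(x$ci_lo)) {
      sprintf("  [%.1f, %.1f]", x$ci_lo[i], x$ci_hi[i])
    } else ""
    cat(sprintf("  %-22s %6.1f%%%s\n", names(x$importance)[i],
                x$importance[i], ci))
  }
  cat(sprintf("  out-of-bag R^2 = %.3f\n", x$r_squared))
  invisible(x)
}
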