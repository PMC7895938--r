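#' Configuration for a full analysis run
#'
#' @param trees Path(s) to Newick tree file(s) (one or more chronogram
#'   variants, e.g. smoothed and unsmoothed; tempo is averaged over them),
#'   or `phylo`/`multiPhylo` objects.
#' @param traitTable Path to the species-level trait CSV, or a trait
#'   `data.frame`.
#' @param eras Path to an era CSV, or an `eraTable`
#'   (default [defaultEraTable()]).
#' @param groups Groups to analyse; `NULL` (default) runs every group
#'   present in the table.
#' @param limitSides Limit sides to analyse (default both).
#' @param outDir Output directory; `NULL` to skip writing files.
#' @param seed Master seed for permutations and forests.
#' @param fit Model-fit options, see [fitOptions()].
#' @param nPerm Permutations for the origin contrast (default 1000).
#' @param forest List with `nTrees` (default 500) and `nRepeats`
#'   (default 100) for the importance stage.
#' @param stages Stages to run, a subset of
#'   `c("models", "ancestral", "contrast", "importance")`; the match stage
#'   always runs.
#' @param posteriorTrees Optional path(s)/objects for a posterior tree set;
#'   when given, per-parameter multi-tree summaries are added.
#' @return A list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(trees, traitTable, eras = defaultEraTable(),
                           groups = NULL, limitSides = c("upper", "lower"),
                           outDir = NULL, seed = 1L, fit = fitOptions(),
                           nPerm = 1000L,
                           forest = list(nTrees = 500L, nRepeats = 100L),
                           stages = c("models", "ancestral", "contrast",
                                      "importance"),
                           posteriorTrees = NULL) {
  stopifnot(all(limitSides %in% c("upper", "lower")),
            all(stages %in% c("models", "ancestral", "contrast", "importance")))
  cfg <- list(trees = trees, traitTable = traitTable, eras = eras,
              groups = groups, limitSides = limitSides, outDir = outDir,
              seed = as.integer(seed), fit = fit, nPerm = as.integer(nPerm),
              forest = forest, stages = stages,
              posteriorTrees = posteriorTrees)
  class(cfg) <- c("pipelineConfig", "list")
  cfg
}

resolveTrees <- function(spec) {
  if (is.character(spec)) {
    return(lapply(spec, readNewick))
  }
  asTreeList(spec)
}

resolveTraitTable <- function(spec) {
  if (is.character(spec)) return(readTraitTable(spec))
  validateTraitTable(spec)
  spec
}

resolveEras <- function(spec) {
  if (is.character(spec)) return(readEraTable(spec))
  stopifnot(inherits(spec, "eraTable"))
  spec
}

pipelineLog <- function(...) message("[thermevol] ", sprintf(...))

#' Run the full tempo-and-mode analysis
#'
#' For every requested group and limit side: match tree and table, fit and
#' compare BM/OU/WN, compute the tempo (BM sigma2 averaged over the
#' supplied tree variants) and mode (-log alpha from the OU fit on the
#' first tree), reconstruct ancestral states and traitgram segments,
#' contrast cold- versus warm-origin species, and fit the random-forest
#' importance model. Every stage logs its row and tip counts; a stage
#' failure aborts with an error naming the stage. With an `outDir` set, a
#' Table-1-style tempo/mode CSV, per-combination JSON/CSV exports and a run
#' manifest are written; re-running from the manifest reproduces every
#' numeric output bit-identically.
#'
#' @param config A [pipelineConfig()].
#' @return A list of class `resultsBundle`: `tempoMode` (data.frame with
#'   columns taxa, metric, n, tempo_sigma2, mode_neg_log_alpha, lnlik_ou,
#'   lnlik_bm, lnlik_wn), `analyses` (per group x side: comparison,
#'   ancestral states, segments, contrast, importance, multi-tree summary),
#'   `manifest`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  trees <- stage("read-trees", resolveTrees(config$trees))
  table <- stage("read-traits", resolveTraitTable(config$traitTable))
  eras <- stage("read-eras", resolveEras(config$eras))
  posterior <- if (!is.null(config$posteriorTrees)) {
    stage("read-posterior-trees", resolveTrees(config$posteriorTrees))
  }
  groups <- config$groups %||% unique(table$group)
  pipelineLog("%d tree variant(s), %d trait records, groups: %s",
              length(trees), nrow(table), paste(groups, collapse = ", "))
  analyses <- list()
  rows <- list()
  for (g in groups) {
    if (!any(table$group == g)) {
      stop("pipeline stage 'match' failed: group '", g,
           "' has no records in the trait table", call. = FALSE)
    }
    for (side in config$limitSides) {
      key <- paste(g, side, sep = ".")
      matched <- stage(paste0("match:", key),
                       matchTreeTraits(trees[[1]], table, side, group = g))
      pipelineLog("%s: matched %d species (%d tips dropped, %d records dropped)",
                  key, matched$report$n, length(matched$report$dropped_tips),
                  length(matched$report$dropped_records))
      res <- list(match_report = matched$report)
      cmp <- NULL
      if ("models" %in% config$stages) {
        cmp <- stage(paste0("models:", key),
                     compareTraitModels(matched$tree, matched$x, config$fit))
        tempo <- stage(paste0("tempo:", key), {
          perTreeX <- matched$x
          tempoSigma2(lapply(trees, function(tr) {
            matchTreeTraits(tr, table, side, group = g)$tree
          }), perTreeX, config$fit)
        })
        res$comparison <- cmp
        res$tempo <- tempo
        rows[[key]] <- data.frame(
          taxa = g, metric = side, n = cmp$n,
          tempo_sigma2 = tempo$sigma2,
          mode_neg_log_alpha = cmp$fits$OU$negLogAlpha,
          lnlik_ou = cmp$lnL[["OU"]], lnlik_bm = cmp$lnL[["BM"]],
          lnlik_wn = cmp$lnL[["WN"]],
          best_by_lnL = cmp$best_by_lnL, best_by_AICc = cmp$best_by_AICc
        )
        if (!is.null(posterior)) {
          res$posteriorSummary <- stage(paste0("posterior:", key), {
            pm <- lapply(posterior, function(tr) {
              matchTreeTraits(tr, table, side, group = g)$tree
            })
            summarizeOverTrees(pm, matched$x, "OU", config$fit)
          })
        }
      }
      if ("ancestral" %in% config$stages) {
        res$ancestral <- stage(paste0("ancestral:", key), {
          states <- reconstructBM(matched$tree, matched$x,
                                  fit = if (!is.null(cmp)) cmp$fits$BM)
          list(states = states,
               segments = traitgramSegments(matched$tree, states, matched$x))
        })
      }
      if ("contrast" %in% config$stages) {
        res$contrast <- stage(paste0("contrast:", key),
                              originContrast(table, eras, group = g,
                                             limitSide = side,
                                             nPerm = config$nPerm,
                                             seed = deriveSeed(config$seed,
                                                               paste0("contrast-", key))))
      }
      if ("importance" %in% config$stages) {
        res$importance <- stage(paste0("importance:", key), {
          feats <- buildFeatureTable(table, eras, group = g, limitSide = side)
          repeatImportance(feats,
                           nTrees = config$forest$nTrees %||% 500L,
                           nRepeats = config$forest$nRepeats %||% 100L,
                           seed = deriveSeed(config$seed,
                                             paste0("forest-", key)))
        })
      }
      analyses[[key]] <- res
    }
  }
  tempoMode <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  manifest <- list(
    package = "thermevol",
    version = as.character(utils::packageVersion("thermevol")),
    seed = config$seed,
    config = serializableConfig(config),
    created = format(Sys.time(), tz = "UTC")
  )
  bundle <- list(tempoMode = tempoMode, analyses = analyses,
                 manifest = manifest)
  class(bundle) <- "resultsBundle"
  if (!is.null(config$outDir)) writeResultsBundle(bundle, config$outDir)
  bundle
}

# Configuration in a JSON-serializable form; file-backed inputs keep their
# paths so the manifest suffices to re-run, in-memory inputs are flagged.
serializableConfig <- function(config) {
  pathOr <- function(x, what) {
    if (is.character(x)) x else paste0("<in-memory ", what, ">")
  }
  list(
    trees = pathOr(config$trees, "trees"),
    traitTable = pathOr(config$traitTable, "trait table"),
    eras = if (is.character(config$eras)) config$eras else
      as.data.frame(config$eras),
    groups = config$groups, limitSides = config$limitSides,
    outDir = config$outDir, seed = config$seed, fit = config$fit,
    nPerm = config$nPerm, forest = config$forest, stages = config$stages,
    posteriorTrees = if (!is.null(config$posteriorTrees)) {
      pathOr(config$posteriorTrees, "posterior trees")
    }
  )
}

#' Re-run a pipeline from a written manifest
#'
#' @param manifestPath Path to a `manifest.json` written by [runPipeline()].
#' @param outDir Optional new output directory (defaults to the manifest's).
#' @return The recomputed `resultsBundle`.
#' @export
rerunFromManifest <- function(manifestPath, outDir = NULL) {
  m <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
  cfg <- m$config
  # JSON has no NULL scalar: absent/empty optional fields come back as
  # empty lists and must be restored to NULL
  for (field in c("groups", "posteriorTrees", "outDir")) {
    if (!length(cfg[[field]])) cfg[field] <- list(NULL)
  }
  if (any(grepl("^<in-memory", unlist(cfg[c("trees", "traitTable")])))) {
    stop("manifest refers to in-memory inputs; re-run requires file-backed inputs")
  }
  eras <- if (is.character(cfg$eras)) cfg$eras else
    eraTable(cfg$eras$older_bound, cfg$eras$younger_bound, cfg$eras$category)
  fit <- fitOptions(alphaBounds = unlist(cfg$fit$alphaBounds),
                    nStarts = cfg$fit$nStarts, seed = cfg$fit$seed,
                    reltol = cfg$fit$reltol)
  runPipeline(pipelineConfig(
    trees = cfg$trees, traitTable = cfg$traitTable, eras = eras,
    groups = cfg$groups, limitSides = cfg$limitSides,
    outDir = outDir %||% cfg$outDir, seed = cfg$seed, fit = fit,
    nPerm = cfg$nPerm,
    forest = as.list(cfg$forest), stages = cfg$stages,
    posteriorTrees = cfg$posteriorTrees
  ))
}

#' Write a results bundle to disk
#'
#' Writes `tempo_mode.csv` (Table-1-style columns), per-combination model
#' comparison JSON, ancestral-state and traitgram CSVs, origin-contrast
#' JSON, importance CSV and the run manifest.
#'
#' @param bundle A `resultsBundle`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
writeResultsBundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "resultsBundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(bundle$tempoMode)) {
    write.csv(bundle$tempoMode, file.path(dir, "tempo_mode.csv"),
              row.names = FALSE)
  }
  for (key in names(bundle$analyses)) {
    res <- bundle$analyses[[key]]
    safe <- gsub("[^A-Za-z0-9_.-]", "_", key)
    if (!is.null(res$comparison)) {
      cmp <- res$comparison
      jsonlite::write_json(
        list(n = cmp$n, lnL = as.list(cmp$lnL), AICc = as.list(cmp$AICc),
             best_by_lnL = cmp$best_by_lnL, best_by_AICc = cmp$best_by_AICc,
             fits = lapply(cmp$fits, function(f) {
               f[c("model", "n", "sigma2", "z0", "mu", "theta", "alpha",
                   "negLogAlpha", "lnL", "k", "AICc", "converged", "logBase")]
             }),
             tempo = res$tempo),
        file.path(dir, paste0("models_", safe, ".json")),
        auto_unbox = TRUE, digits = NA, force = TRUE)
    }
    if (!is.null(res$ancestral)) {
      write.csv(res$ancestral$states,
                file.path(dir, paste0("ancestral_", safe, ".csv")),
                row.names = FALSE)
      write.csv(res$ancestral$segments,
                file.path(dir, paste0("traitgram_", safe, ".csv")),
                row.names = FALSE)
    }
    if (!is.null(res$contrast)) {
      jsonlite::write_json(unclass(res$contrast),
                           file.path(dir, paste0("contrast_", safe, ".json")),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
    }
    if (!is.null(res$importance)) {
      imp <- res$importance
      write.csv(data.frame(predictor = names(imp$importance),
                           importance_pct = as.numeric(imp$importance),
                           ci_lo = as.numeric(imp$ci_lo),
                           ci_hi = as.numeric(imp$ci_hi),
                           r_squared = imp$r_squared, n = imp$n,
                           n_trees = imp$nTrees, seed = imp$seed),
                file.path(dir, paste0("importance_", safe, ".csv")),
                row.names = FALSE)
    }
  }
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' @export
print.resultsBundle <- function(x, ...) {
  cat("thermevol results bundle\n")
  if (!is.null(x$tempoMode)) {
    print(x$tempoMode, row.names = FALSE)
  }
  invisible(x)
}
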