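#' Read a time-calibrated phylogeny from a Newick file
#'
#' Parses a strict Newick tree and validates it for comparative analysis:
#' branch lengths are mandatory (the models are calibrated in Mya), all
#' branch lengths must be non-negative, tip labels must be unique and the
#' tree must be rooted with at least two tips. Unlabeled internal nodes are
#' assigned stable synthetic ids (`nd<number>` in ape's node numbering).
#'
#' @param path Path to a Newick file (single tree).
#' @param text Newick string; overrides `path` when supplied.
#' @return An object of class `phylo` (ape) that passes [validatePhylogeny()].
#' @seealso [writeNewick()], [checkUltrametric()]
#' @export
readNewick <- function(path, text = NULL) {
  if (is.null(text)) {
    if (!file.exists(path)) stop("tree file not found: ", path)
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  checkNewickSyntax(text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) stop("Newick parse error: no tree could be read", call. = FALSE)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  validatePhylogeny(tree)
  if (is.null(tree$node.label) || all(tree$node.label == "")) {
    tree$node.label <- paste0("nd", seq_len(tree$Nnode) + length(tree$tip.label))
  }
  tree
}

# Light syntactic pre-check so malformed input fails with a character offset
# instead of ape's silent NULL return.
checkNewickSyntax <- function(text) {
  chars <- strsplit(text, "")[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("Newick parse error: unmatched ')' at character ", i, call. = FALSE)
      }
    }
  }
  if (depth != 0L) {
    stop("Newick parse error: ", depth, " unclosed '(' at end of input (character ",
         length(chars), ")", call. = FALSE)
  }
  if (!grepl(";", text, fixed = TRUE)) {
    stop("Newick parse error: missing terminating ';' at character ",
         length(chars), call. = FALSE)
  }
  invisible(TRUE)
}

#' Validate a phylogeny for trait-model analysis
#'
#' @param tree A `phylo` object.
#' @param minTips Minimum number of tips required (default 2).
#' @return The tree, invisibly, if valid; otherwise an error.
#' @export
validatePhylogeny <- function(tree, minTips = 2L) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  n <- length(tree$tip.label)
  if (n < minTips) stop("tree has ", n, " tips; at least ", minTips, " required")
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; branch lengths in Mya are required")
  }
  if (anyNA(tree$edge.length)) stop("tree has missing branch lengths")
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  }
  # exactly one root node (basal polytomies, e.g. star trees, are allowed)
  roots <- setdiff(tree$edge[, 1], tree$edge[, 2])
  if (length(roots) != 1L) stop("tree must have exactly one root")
  zero <- sum(tree$edge.length[tree$edge[, 2] <= n] == 0)
  if (zero > 0) {
    warning(zero, " zero-length terminal branch(es); consider a branch-length floor")
  }
  invisible(tree)
}

#' Write a phylogeny to a Newick file
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Root-to-node path lengths and tree depth
#'
#' @param tree A `phylo` object.
#' @return List with `depths` (named for tips, numeric for all nodes in ape
#'   numbering) and `T` (maximum tip depth, the tree depth in Mya).
#' @export
nodeDepths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  tips <- seq_along(tree$tip.label)
  list(depths = d, T = max(d[tips]))
}

#' Test whether a tree is ultrametric within a relative tolerance
#'
#' A tree is called ultrametric when all root-to-tip path lengths agree with
#' the maximum tip depth `T` to within `relTol` relative deviation.
#'
#' @param tree A `phylo` object.
#' @param relTol Relative tolerance (> 0, default 1e-3).
#' @return List with `ultrametric` (logical) and `maxRelDeviation`.
#' @export
checkUltrametric <- function(tree, relTol = 1e-3) {
  stopifnot(relTol > 0)
  nd <- nodeDepths(tree)
  tipDepths <- nd$depths[seq_along(tree$tip.label)]
  dev <- if (nd$T > 0) max(abs(tipDepths - nd$T)) / nd$T else 0
  list(ultrametric = dev <= relTol, maxRelDeviation = dev)
}

#' Default column schema for species-level thermal-limit tables
#'
#' Maps canonical field names to column names in a delimited file. Override
#' individual entries to adapt to a foreign header.
#'
#' @param ... Named overrides, e.g. `species = "binomial"`.
#' @return Named character vector of column names.
#' @export
traitSchema <- function(...) {
  schema <- c(
    species = "species", group = "group", limit_side = "limit_side",
    metric = "metric", tolerance = "tolerance", order = "order",
    order_age = "order_age", current_tmax = "current_tmax",
    current_tmin = "current_tmin", realm = "realm",
    latitude = "latitude", longitude = "longitude"
  )
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(schema))
    if (length(bad)) stop("unknown schema fields: ", paste(bad, collapse = ", "))
    schema[names(over)] <- over
  }
  schema
}

.traitGroups <- c("ectotherm", "endotherm", "plant", "plant&algae")
.limitSides  <- c("upper", "lower")
.traitMetrics <- c("lethal", "critical", "TNZ-edge")
.traitRealms <- c("marine", "intertidal", "freshwater", "terrestrial")

#' Read a species-level thermal-limit table
#'
#' Reads a delimited text file (comma or tab separated, sniffed from the
#' header line) into a validated trait table with one record per species,
#' limit side and measurement. Rows whose tolerance or order age cannot be
#' parsed as numbers are dropped and counted in the attached report.
#'
#' @param path Path to a CSV/TSV file with a header.
#' @param schema Column mapping from [traitSchema()].
#' @return A `data.frame` with canonical columns `species`, `group`,
#'   `limit_side`, `metric`, `tolerance` (degrees C), `order`, `order_age`
#'   (Mya), `current_tmax`, `current_tmin` (degrees C), `realm`, `latitude`,
#'   `longitude`, and attribute `report` (list with `n_read`, `n_dropped`).
#' @export
readTraitTable <- function(path, schema = traitSchema()) {
  if (!file.exists(path)) stop("trait table not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("species", "group", "limit_side", "tolerance", "order", "order_age")
  for (field in required) {
    if (!schema[[field]] %in% names(raw)) {
      stop("required column '", schema[[field]], "' (field '", field,
           "') absent from ", path)
    }
  }
  pick <- function(field, default = NA) {
    col <- schema[[field]]
    if (col %in% names(raw)) raw[[col]] else rep(default, nrow(raw))
  }
  tab <- data.frame(
    species = as.character(pick("species")),
    group = as.character(pick("group")),
    limit_side = as.character(pick("limit_side")),
    metric = as.character(pick("metric", "critical")),
    tolerance = suppressWarnings(as.numeric(pick("tolerance"))),
    order = as.character(pick("order")),
    order_age = suppressWarnings(as.numeric(pick("order_age"))),
    current_tmax = suppressWarnings(as.numeric(pick("current_tmax"))),
    current_tmin = suppressWarnings(as.numeric(pick("current_tmin"))),
    realm = as.character(pick("realm", NA_character_)),
    latitude = suppressWarnings(as.numeric(pick("latitude"))),
    longitude = suppressWarnings(as.numeric(pick("longitude"))),
    stringsAsFactors = FALSE
  )
  nRead <- nrow(tab)
  keep <- !is.na(tab$tolerance) & !is.na(tab$order_age)
  nDropped <- sum(!keep)
  if (nDropped > 0) {
    message("readTraitTable: dropped ", nDropped, " row(s) with unparseable numerics")
  }
  tab <- tab[keep, , drop = FALSE]
  validateTraitTable(tab)
  attr(tab, "report") <- list(n_read = nRead, n_dropped = nDropped)
  tab
}

#' Validate a trait table against its invariants
#'
#' Checks factor levels, positive order ages, latitude range and the
#' per-species consistency requirement that mean upper tolerance is at least
#' the mean lower tolerance when both sides are present.
#'
#' @param tab A trait table (see [readTraitTable()]).
#' @return The table, invisibly, if valid.
#' @export
validateTraitTable <- function(tab) {
  stopifnot(is.data.frame(tab))
  badSide <- setdiff(unique(tab$limit_side), .limitSides)
  if (length(badSide)) stop("unknown limit_side value(s): ", paste(badSide, collapse = ", "))
  if (any(tab$order_age <= 0, na.rm = TRUE)) stop("order_age must be > 0 Mya")
  lat <- tab$latitude[!is.na(tab$latitude)]
  if (any(lat < -90 | lat > 90)) stop("latitude outside [-90, 90]")
  upper <- tapply(tab$tolerance[tab$limit_side == "upper"],
                  tab$species[tab$limit_side == "upper"], mean)
  lower <- tapply(tab$tolerance[tab$limit_side == "lower"],
                  tab$species[tab$limit_side == "lower"], mean)
  both <- intersect(names(upper), names(lower))
  bad <- both[upper[both] < lower[both]]
  if (length(bad)) {
    stop("upper tolerance below lower tolerance for species: ",
         paste(head(bad, 5), collapse = ", "))
  }
  invisible(tab)
}

#' Match a phylogeny with a trait table
#'
#' Selects records for one limit side (and optionally one group), averages
#' duplicate per-species records, canonicalizes names (case-folding and
#' underscore/space interchange only), prunes the tree to the species shared
#' by tree and table, and returns the aligned trait vector. Pruning with
#' `ape::keep.tip` preserves path lengths between retained tips.
#'
#' @param tree A `phylo` object.
#' @param table A trait table (see [readTraitTable()]).
#' @param limitSide `"upper"` or `"lower"`.
#' @param group Optional group filter (e.g. `"ectotherm"`).
#' @param minOverlap Minimum shared species count (default 3).
#' @return List with `tree` (pruned `phylo`), `x` (named numeric trait
#'   vector, degrees C, ordered as `tree$tip.label`), and `report` (dropped
#'   tips, dropped records, duplicates averaged, n).
#' @export
matchTreeTraits <- function(tree, table, limitSide = c("upper", "lower"),
                            group = NULL, minOverlap = 3L) {
  limitSide <- match.arg(limitSide)
  validatePhylogeny(tree)
  recs <- table[table$limit_side == limitSide, , drop = FALSE]
  if (!is.null(group)) recs <- recs[recs$group == group, , drop = FALSE]
  if (nrow(recs) == 0L) {
    stop("no records for limit_side='", limitSide, "'",
         if (!is.null(group)) paste0(", group='", group, "'"))
  }
  key <- canonicalName(recs$species)
  dupSpecies <- unique(key[duplicated(key)])
  vals <- tapply(recs$tolerance, key, mean)
  tipKey <- canonicalName(tree$tip.label)
  if (anyDuplicated(tipKey)) stop("tip labels collide after canonicalization")
  shared <- intersect(tipKey, names(vals))
  if (length(shared) < minOverlap) {
    stop("insufficient overlap between tree and table: ", length(shared),
         " shared species (minimum ", minOverlap, ")")
  }
  keepTips <- tree$tip.label[tipKey %in% shared]
  droppedTips <- setdiff(tree$tip.label, keepTips)
  droppedRecords <- setdiff(names(vals), shared)
  pruned <- if (length(droppedTips)) ape::keep.tip(tree, keepTips) else tree
  x <- as.numeric(vals[canonicalName(pruned$tip.label)])
  names(x) <- pruned$tip.label
  if (anyNA(x)) stop("internal error: unmatched tip after pruning")
  list(
    tree = pruned,
    x = x,
    report = list(
      n = length(x),
      dropped_tips = droppedTips,
      dropped_records = droppedRecords,
      duplicates_averaged = dupSpecies
    )
  )
}
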