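.eraCategories <- c("full glaciation", "partial glaciation", "partial warm", "warm")

#' Construct and validate an era table
#'
#' An era table maps contiguous age intervals (Mya before present, ordered
#' old to young) to palaeoclimate categories: full glaciation, partial
#' glaciation, partial warm, warm. Intervals are half-open on the young
#' side: an age exactly on a boundary belongs to the older interval.
#'
#' @param older_bound Numeric vector of interval old bounds (Mya),
#'   decreasing.
#' @param younger_bound Numeric vector of interval young bounds (Mya);
#'   `younger_bound[i]` must equal `older_bound[i+1]`, and the last must
#'   be 0 or positive.
#' @param category Character vector of palaeoclimate categories.
#' @return A `data.frame` of class `eraTable`.
#' @export
eraTable <- function(older_bound, younger_bound, category) {
  stopifnot(length(older_bound) == length(younger_bound),
            length(older_bound) == length(category))
  tab <- data.frame(older_bound = as.numeric(older_bound),
                    younger_bound = as.numeric(younger_bound),
                    category = as.character(category),
                    stringsAsFactors = FALSE)
  if (any(tab$older_bound <= tab$younger_bound)) {
    stop("each interval must have older_bound > younger_bound")
  }
  if (any(tab$younger_bound < 0)) stop("bounds must be non-negative Mya")
  if (nrow(tab) > 1L) {
    if (any(diff(tab$older_bound) >= 0)) {
      stop("intervals must be sorted old to young")
    }
    if (any(abs(tab$younger_bound[-nrow(tab)] - tab$older_bound[-1]) > 1e-9)) {
      stop("intervals must be contiguous (younger bound of one = older bound of next)")
    }
  }
  bad <- setdiff(tab$category, .eraCategories)
  if (length(bad)) {
    stop("unknown palaeoclimate category: ", paste(bad, collapse = ", "),
         " (expected: ", paste(.eraCategories, collapse = ", "), ")")
  }
  class(tab) <- c("eraTable", "data.frame")
  tab
}

#' Read an era table from CSV
#'
#' @param path CSV with columns `older_bound`, `younger_bound`, `category`.
#' @return An `eraTable`.
#' @export
readEraTable <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("older_bound", "younger_bound", "category")
  missing <- setdiff(need, names(raw))
  if (length(missing)) stop("era table missing column(s): ",
                            paste(missing, collapse = ", "))
  eraTable(raw$older_bound, raw$younger_bound, raw$category)
}

#' Illustrative default era table
#'
#' A coarse deep-time partition of the last 541 Mya into the four
#' palaeoclimate categories. These boundary dates are illustrative,
#' user-supplied defaults sketching the major alternation of icehouse and
#' greenhouse regimes; they are not a published dating and analyses meant to
#' reflect a specific palaeoclimate reconstruction should supply their own
#' table.
#'
#' @return An `eraTable` spanning 541-0 Mya.
#' @export
defaultEraTable <- function() {
  eraTable(
    older_bound   = c(541, 360, 260, 150,  66,  34, 2.6),
    younger_bound = c(360, 260, 150,  66,  34, 2.6,   0),
    category = c("warm", "partial glaciation", "warm", "partial warm",
                 "warm", "partial glaciation", "full glaciation")
  )
}

#' Assign a palaeoclimate category to an origination age
#'
#' Deterministic lookup in an era table. Intervals are half-open on the
#' young side, so an age exactly on an internal boundary falls in the older
#' interval; the oldest interval includes its old bound.
#'
#' @param order_age Origination age(s) in Mya (vectorized).
#' @param eras An `eraTable`.
#' @return Character vector of categories.
#' @export
assignEra <- function(order_age, eras) {
  stopifnot(inherits(eras, "eraTable"))
  oldest <- eras$older_bound[1]
  youngest <- eras$younger_bound[nrow(eras)]
  vapply(order_age, function(age) {
    if (is.na(age) || age > oldest || age < youngest) {
      stop("order age ", age, " Mya outside the era table span [",
           youngest, ", ", oldest, "] Mya", call. = FALSE)
    }
    i <- which(age < eras$older_bound & age >= eras$younger_bound)
    if (!length(i)) i <- 1L # age equal to the oldest bound
    eras$category[i[1L]]
  }, character(1))
}

#' Collapse palaeoclimate categories to cold versus warm origin
#'
#' Full and partial glaciation collapse to `cold-origin`; partial warm and
#' warm collapse to `warm-origin`.
#'
#' @param category Character vector of palaeoclimate categories.
#' @return Character vector in `{cold-origin, warm-origin}`.
#' @export
collapseOrigin <- function(category) {
  bad <- setdiff(unique(category), .eraCategories)
  if (length(bad)) stop("unknown palaeoclimate category: ",
                        paste(bad, collapse = ", "))
  ifelse(category %in% c("full glaciation", "partial glaciation"),
         "cold-origin", "warm-origin")
}

#' Boxplot statistics for a group of thermal limits
#'
#' Quartiles use linear interpolation (R's default quantile type 7); the
#' whiskers extend to the most extreme observations within 1.5 interquartile
#' ranges of the quartiles (the convention of R's `boxplot`), and points
#' beyond the whiskers are outliers.
#'
#' @param values Numeric vector (degrees C), length >= 1.
#' @return List: `n`, `median`, `q1`, `q3`, `iqr`, `whisker_lo`,
#'   `whisker_hi`, `outliers` (values), `n_outliers`.
#' @export
groupBoxStats <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values supplied")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  loFence <- q[1] - 1.5 * iqr
  hiFence <- q[3] + 1.5 * iqr
  inside <- values[values >= loFence & values <= hiFence]
  out <- values[values < loFence | values > hiFence]
  list(n = length(values), median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
       whisker_lo = min(inside), whisker_hi = max(inside),
       outliers = out, n_outliers = length(out))
}

#' Contrast thermal limits between cold- and warm-origin species
#'
#' Species are assigned a palaeoclimate category from the origination age of
#' their taxonomic order, collapsed to cold versus warm origin, and the two
#' distributions of thermal limits are compared: boxplot statistics per
#' class and a two-sided permutation test of the difference in medians
#' (origin labels shuffled `nPerm` times;
#' `p = (1 + #{|d_perm| >= |d_obs|}) / (nPerm + 1)`).
#'
#' @param table A trait table (see [readTraitTable()]).
#' @param eras An `eraTable`.
#' @param group Group to analyse (e.g. `"ectotherm"`); `NULL` for all.
#' @param limitSide `"upper"` or `"lower"`.
#' @param nPerm Number of permutations (>= 1000; default 10000).
#' @param seed Seed for the permutation stream.
#' @return List of class `originContrast`: per-class `stats` (from
#'   [groupBoxStats()]), `delta_median` (cold minus warm, degC), `p_value`,
#'   `n` per class, `nPerm`, `seed`.
#' @export
originContrast <- function(table, eras, group = NULL,
                           limitSide = c("upper", "lower"),
                           nPerm = 10000L, seed = 1L) {
  limitSide <- match.arg(limitSide)
  if (nPerm < 1000L) stop("nPerm must be at least 1000")
  recs <- table[table$limit_side == limitSide, , drop = FALSE]
  if (!is.null(group)) recs <- recs[recs$group == group, , drop = FALSE]
  if (!nrow(recs)) stop("no records to contrast")
  # one value per species (duplicates averaged), order age carried along
  key <- canonicalName(recs$species)
  vals <- tapply(recs$tolerance, key, mean)
  ages <- tapply(recs$order_age, key, function(a) a[1])
  origin <- collapseOrigin(assignEra(as.numeric(ages), eras))
  v <- as.numeric(vals)
  cold <- v[origin == "cold-origin"]
  warm <- v[origin == "warm-origin"]
  if (!length(cold) || !length(warm)) {
    stop("degenerate contrast: one origin class is empty ",
         "(cold n=", length(cold), ", warm n=", length(warm), ")")
  }
  dObs <- median(cold) - median(warm)
  nc <- length(cold)
  set.seed(deriveSeed(seed, "origin-contrast"))
  exceed <- 0L
  for (b in seq_len(nPerm)) {
    idx <- sample.int(length(v), nc)
    dPerm <- median(v[idx]) - median(v[-idx])
    if (abs(dPerm) >= abs(dObs)) exceed <- exceed + 1L
  }
  res <- list(
    limit_side = limitSide, group = group,
    stats = list(cold_origin = groupBoxStats(cold),
                 warm_origin = groupBoxStats(warm)),
    n = c(cold_origin = length(cold), warm_origin = length(warm)),
    delta_median = dObs,
    p_value = (1 + exceed) / (nPerm + 1),
    nPerm = nPerm, seed = seed
  )
  class(res) <- "originContrast"
  res
}

#' @export
print.originContrast <- function(x, ...) {
  cat(sprintf("Origin contrast (%s limits%s)\n", x$limit_side,
              if (!is.null(x$group)) paste0(", ", x$group) else ""))
  cat(sprintf("  cold-origin: n = %d, median = %.2f degC\n",
              x$n["cold_origin"], x$stats$cold_origin$median))
  cat(sprintf("  warm-origin: n = %d, median = %.2f degC\n",
              x$n["warm_origin"], x$stats$warm_origin$median))
  cat(sprintf("  delta median (cold - warm) = %.3f degC, permutation p = %.4g (%d perms)\n",
              x$delta_median, x$p_value, x$nPerm))
  invisible(x)
}
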