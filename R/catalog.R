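# Direction-specific empirical normative catalog: for each age/disc-size
# group G and angular point j, the raw sample R_{G,j} of normal RNFL values
# at j over all normal eyes in G.  The eCDF of that sample,
#   eCDF_{G,j}(x) = |{r in R_{G,j} : r <= x}| / |R_{G,j}|,
# is the quantile map every downstream decay computation uses.  Samples are
# stored column-sorted so evaluation is a binary search.

#' Empirical CDF of a normative thickness sample
#'
#' @param sample numeric vector of thickness values (micrometres), non-empty.
#' @return object of class `rnfl_ecdf`: list with the ascending-sorted
#'   `sample` and its `size`.
#' @export
rnfl_ecdf <- function(sample) {
  sample <- as.numeric(sample)
  if (length(sample) == 0L || anyNA(sample))
    stop("eCDF sample must be non-empty and free of missing values")
  structure(list(sample = sort(sample), size = length(sample)),
            class = "rnfl_ecdf")
}

#' Evaluate an empirical CDF
#'
#' Right-continuous counting definition: the fraction of stored sample values
#' `<= x`.  Ties count with multiplicity.
#'
#' @param e an [rnfl_ecdf].
#' @param x thickness value(s); any real is valid.
#' @return quantile value(s) in \[0, 1\].
#' @examples
#' ecdf_eval(rnfl_ecdf(c(70, 80, 90, 100)), 80)  # 0.5
#' @export
ecdf_eval <- function(e, x) {
  stopifnot(inherits(e, "rnfl_ecdf"))
  findInterval(x, e$sample) / e$size
}

#' Build the direction-specific normative catalog
#'
#' For each populated group and each angular point j, stores the sample of
#' RNFL values at j over every normal, non-excluded eye of the group.  A fully
#' populated catalog (all 9 age x disc-size groups) at N = 256 therefore
#' holds 9 x 256 = 2304 empirical distributions.
#'
#' @param normals an [rnfl_profiles] collection: all eyes must have status
#'   `"normal"`, pass the 30-micrometre exclusion flag, and carry group
#'   metadata (age and disc area).
#' @param min_group_warn warn when a populated group holds fewer eyes than
#'   this (quantile resolution degrades in small samples).
#' @return object of class `normative_catalog`: list with `n_points`,
#'   `groups` (named list, one thickness matrix per populated group with
#'   every column sorted ascending), and `group_sizes`.
#' @export
build_catalog <- function(normals, min_group_warn = 20L) {
  stopifnot(inherits(normals, "rnfl_profiles"))
  if (nrow(normals$values) == 0L) stop("cannot build a catalog from zero eyes")
  if (anyNA(normals$meta$status) || any(normals$meta$status != "normal"))
    stop("catalog input must contain only eyes with status 'normal'")
  if (any(normals$meta$excluded))
    stop("catalog input contains profiles flagged excluded (thickness < 30 um)")
  if (is.null(normals$meta$group))
    stop("profiles must carry age and disc_area metadata for grouping")
  keys <- as.character(normals$meta$group)
  groups <- lapply(split(seq_along(keys), keys), function(i) {
    # column-wise sorting breaks the eye/row correspondence, so dimnames off
    unname(apply(normals$values[i, , drop = FALSE], 2L, sort))
  })
  groups <- lapply(groups, function(m) {
    if (is.null(dim(m))) matrix(m, nrow = 1L) else m
  })
  sizes <- vapply(groups, nrow, integer(1))
  small <- names(sizes)[sizes < min_group_warn]
  if (length(small))
    warning("group(s) with fewer than ", min_group_warn, " eyes: ",
            paste(small, collapse = ", "))
  structure(list(n_points = normals$n_points, groups = groups,
                 group_sizes = sizes),
            class = "normative_catalog")
}

#' @export
print.normative_catalog <- function(x, ...) {
  cat(sprintf("<normative_catalog> %d group(s) x %d angular points = %d eCDFs\n",
              length(x$groups), x$n_points, n_entries(x)))
  for (g in names(x$groups))
    cat(sprintf("  %-14s %4d eyes\n", g, x$group_sizes[[g]]))
  invisible(x)
}

#' Number of empirical distributions held in a catalog
#' @param catalog a `normative_catalog`.
#' @return integer: populated groups times angular points.
#' @export
n_entries <- function(catalog) {
  stopifnot(inherits(catalog, "normative_catalog"))
  length(catalog$groups) * catalog$n_points
}

#' Extract one direction-specific eCDF from the catalog
#' @param catalog a `normative_catalog`.
#' @param group group label, e.g. `"Age1:Small"`.
#' @param j angular point index in `1..n_points`.
#' @return an [rnfl_ecdf].
#' @export
catalog_ecdf <- function(catalog, group, j) {
  stopifnot(inherits(catalog, "normative_catalog"))
  group <- as.character(group)
  if (!group %in% names(catalog$groups))
    stop("group not populated in catalog: ", group)
  if (j < 1L || j > catalog$n_points) stop("angular point out of range: ", j)
  s <- catalog$groups[[group]][, j]
  structure(list(sample = s, size = length(s)), class = "rnfl_ecdf")
}

# Type-1 (left-continuous inverse) empirical quantile of a sorted sample:
# the smallest order statistic whose eCDF reaches p.  Chosen so that the
# quantile of eCDF(x) returns x for every sample point.
quantile_type1 <- function(sorted, p) sorted[ceiling(p * length(sorted))]

#' Per-angle normative quantile contours
#'
#' Inverse-eCDF thickness quantiles at every angular point of one group --
#' the concentric percentile contours of the normative map (e.g. the 5th,
#' 25th, 50th and 75th percentiles), or a decile table with
#' `probs = seq(0.1, 0.9, by = 0.1)`.
#'
#' @param catalog a `normative_catalog`.
#' @param group group label.
#' @param probs probabilities, each strictly inside (0, 1).
#' @return numeric matrix, `length(probs)` rows (named by probability) by
#'   `n_points` columns of thickness in micrometres; monotone in `probs` at
#'   every column.
#' @export
quantile_contours <- function(catalog, group,
                              probs = c(0.05, 0.25, 0.50, 0.75)) {
  stopifnot(inherits(catalog, "normative_catalog"))
  if (any(probs <= 0 | probs >= 1))
    stop("probs must lie strictly inside (0, 1)")
  group <- as.character(group)
  if (!group %in% names(catalog$groups))
    stop("group not populated in catalog: ", group)
  m <- catalog$groups[[group]]
  out <- vapply(seq_len(ncol(m)),
                function(j) quantile_type1(m[, j], probs),
                numeric(length(probs)))
  out <- matrix(out, nrow = length(probs),
                dimnames = list(format(probs), NULL))
  out
}

#' Save a normative catalog as a long-format CSV
#'
#' One row per stored value: `group`, `j`, `value`.  Plain text, readable by
#' any tool, and losslessly invertible by [load_catalog()].
#'
#' @param catalog a `normative_catalog`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
save_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "normative_catalog"))
  rows <- lapply(names(catalog$groups), function(g) {
    m <- catalog$groups[[g]]
    data.frame(group = g,
               j = rep(seq_len(ncol(m)), each = nrow(m)),
               value = as.vector(m))
  })
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(group = character(), j = integer(), value = numeric())
  attr_line <- sprintf("# n_points=%d", catalog$n_points)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(attr_line, con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a normative catalog written by [save_catalog()]
#' @param path CSV path.
#' @return a `normative_catalog`.
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (!grepl("^# n_points=\\d+$", first))
    stop("corrupt catalog file (missing n_points comment line): ", path)
  n_points <- as.integer(sub("^# n_points=", "", first))
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!identical(names(df), c("group", "j", "value")))
    stop("corrupt catalog file (expected columns group,j,value): ", path)
  if (nrow(df) > 0 && (anyNA(df$value) || anyNA(df$j)))
    stop("corrupt catalog file (non-numeric entries): ", path)
  groups <- lapply(split(df, df$group), function(d) {
    js <- sort(unique(d$j))
    if (!identical(js, seq_len(n_points)))
      stop("corrupt catalog file (incomplete angular coverage): ", path)
    counts <- table(d$j)
    if (length(unique(counts)) != 1L)
      stop("corrupt catalog file (ragged group sample): ", path)
    vapply(seq_len(n_points), function(j) sort(d$value[d$j == j]),
           numeric(counts[[1L]]))
  })
  groups <- lapply(groups, function(m) {
    if (is.null(dim(m))) matrix(m, nrow = 1L) else m
  })
  structure(list(n_points = n_points, groups = groups,
                 group_sizes = vapply(groups, nrow, integer(1))),
            class = "normative_catalog")
}

#' Export decile tables in the supplementary-table layout
#'
#' Writes, for each populated group, a heading line followed by 9 decile rows
#' (10th..90th percentile) by `n_points` columns.
#'
#' @param catalog a `normative_catalog`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_deciles <- function(catalog, path) {
  stopifnot(inherits(catalog, "normative_catalog"))
  probs <- seq(0.1, 0.9, by = 0.1)
  con <- file(path, "w")
  on.exit(close(con))
  for (g in names(catalog$groups)) {
    writeLines(sprintf("# group=%s", g), con)
    q <- quantile_contours(catalog, g, probs)
    df <- data.frame(decile = paste0(probs * 100, "th"), q, check.names = FALSE)
    names(df) <- c("decile", paste0("p", seq_len(catalog$n_points)))
    write.csv(df, con, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
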