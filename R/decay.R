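# Angular Quantile and Angular Decay: an eye's pointwise rank relative to the
# normal population of its own age/disc-size group,
#   AngularQuantile(i, j) = eCDF_{G,j}(RNFL(i, j)),
#   AngularDecay(i, j)    = 1 - AngularQuantile(i, j),
# both circular sequences in [0, 1].  High decay at j means the eye ranks low
# among normal RNFL observations at that direction.  The transform is raw and
# pointwise: no smoothing across angles.

#' Angular Quantile of profiles against a normative catalog
#'
#' @param profiles an [rnfl_profiles] collection carrying group metadata;
#'   every group must be populated in `catalog`.  Glaucomatous eyes are
#'   ranked against the normal-only catalog of their group; normal eyes may
#'   be ranked too (against a catalog that includes themselves).
#' @param catalog a [build_catalog()] result.
#' @return numeric matrix (eyes x angular points) of quantile values in
#'   \[0, 1\], rows named by `eye_id`.
#' @export
angular_quantile <- function(profiles, catalog) {
  stopifnot(inherits(profiles, "rnfl_profiles"),
            inherits(catalog, "normative_catalog"))
  if (profiles$n_points != catalog$n_points)
    stop("profiles and catalog disagree on the number of angular points")
  if (is.null(profiles$meta$group))
    stop("profiles must carry group metadata")
  keys <- as.character(profiles$meta$group)
  missing_g <- setdiff(unique(keys), names(catalog$groups))
  if (length(missing_g))
    stop("group(s) absent from catalog: ", paste(missing_g, collapse = ", "))
  q <- matrix(NA_real_, nrow = nrow(profiles$values), ncol = profiles$n_points,
              dimnames = list(profiles$meta$eye_id, NULL))
  for (g in unique(keys)) {
    rows <- which(keys == g)
    ref <- catalog$groups[[g]]          # columns sorted ascending
    n_ref <- nrow(ref)
    for (j in seq_len(profiles$n_points))
      q[rows, j] <- findInterval(profiles$values[rows, j], ref[, j]) / n_ref
  }
  q
}

#' Angular Decay of profiles against a normative catalog
#'
#' The elementwise complement `1 - AngularQuantile`.
#'
#' @inheritParams angular_quantile
#' @return object of class `decay_set`: list with `quantile` and `decay`
#'   matrices (eyes x angular points), `meta` (the profiles' metadata) and
#'   `n_points`.
#' @export
angular_decay <- function(profiles, catalog) {
  q <- angular_quantile(profiles, catalog)
  structure(list(quantile = q, decay = 1 - q, meta = profiles$meta,
                 n_points = ncol(q)),
            class = "decay_set")
}

#' @export
print.decay_set <- function(x, ...) {
  cat(sprintf("<decay_set> %d eyes x %d angular points\n",
              nrow(x$decay), x$n_points))
  invisible(x)
}

#' Write decay and quantile matrices as row-per-eye CSVs
#'
#' @param x a `decay_set`.
#' @param decay_path output CSV for the decay matrix.
#' @param quantile_path optional output CSV for the quantile matrix
#'   (identical layout).
#' @return `decay_path`, invisibly.
#' @export
write_decay <- function(x, decay_path, quantile_path = NULL) {
  stopifnot(inherits(x, "decay_set"))
  put <- function(m, path) {
    df <- data.frame(eye_id = x$meta$eye_id, m, check.names = FALSE)
    names(df) <- c("eye_id", paste0("p", seq_len(x$n_points)))
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  put(x$decay, decay_path)
  if (!is.null(quantile_path)) put(x$quantile, quantile_path)
  invisible(decay_path)
}

#' Read a decay matrix CSV back into a `decay_set`
#' @param path CSV written by [write_decay()].
#' @return a `decay_set` (quantile reconstructed as `1 - decay`; metadata
#'   limited to `eye_id`).
#' @export
read_decay <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "eye_id") stop("expected an eye_id column in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m) || any(m < 0 | m > 1))
    stop("decay values must lie in [0, 1]: ", path)
  rownames(m) <- df$eye_id
  structure(list(quantile = 1 - m, decay = m,
                 meta = data.frame(eye_id = df$eye_id,
                                   stringsAsFactors = FALSE),
                 n_points = ncol(m)),
            class = "decay_set")
}
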