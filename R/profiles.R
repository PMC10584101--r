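# Angular coordinate convention shared by every module: point j (1..N) sits at
# theta_j = (j - 1) * 360 / N degrees, counterclockwise TSNIT, j = 1 at the
# temporal origin (0 degrees).  Both eyes are assumed already recorded in TSNIT
# index order by the device, so no laterality mirroring is performed.

#' Angular grid of a circular RNFL scan
#'
#' @param n_points number of equally spaced angular points on the circle.
#' @return numeric vector of length `n_points`: the angle (degrees, in
#'   \[0, 360)) of each point, counterclockwise TSNIT with point 1 at the
#'   temporal origin.
#' @examples
#' grid_angles(256)[1:4]   # 0.000 1.406 2.812 4.219
#' @export
grid_angles <- function(n_points = 256L) {
  stopifnot(is.numeric(n_points), length(n_points) == 1L, n_points >= 1)
  (seq_len(n_points) - 1) * 360 / n_points
}

# Thickness floor (micrometres) below which a scan is considered a
# segmentation-floor artifact and flagged for exclusion.
RNFL_FLOOR_UM <- 30

AGE_BANDS <- c("Age1", "Age2", "Age3")
DISC_CLASSES <- c("Small", "Average", "Large")

#' Assign an eye to its age-band / disc-size group
#'
#' Cohort strata: age bands Age1 (40-49 years), Age2 (50-59), Age3 (>= 60);
#' disc classes Small (< 1.6 mm^2), Average (1.6-2.6 mm^2, bounds inclusive),
#' Large (> 2.6 mm^2).  The 3 x 3 = 9 combinations partition the cohort.
#'
#' @param age age in whole years; the cohort inclusion criterion is
#'   `age >= 40`, younger ages raise an error.
#' @param disc_area optic disc area in mm^2, positive.
#' @return data.frame with columns `age_band`, `disc_class` and `group`
#'   (factor with levels `"Age1:Small"` ... `"Age3:Large"`), one row per input.
#' @examples
#' assign_group(45, 1.5)    # Age1:Small
#' assign_group(60, 2.6)    # Age3:Average (both boundaries inclusive)
#' @export
assign_group <- function(age, disc_area) {
  stopifnot(length(age) == length(disc_area))
  if (any(!is.finite(age)) || any(!is.finite(disc_area)))
    stop("age and disc_area must be finite")
  if (any(age < 40))
    stop("age below 40 is outside the cohort (inclusion criterion age >= 40)")
  if (any(disc_area <= 0))
    stop("disc_area must be positive")
  age_band <- ifelse(age >= 60, "Age3", ifelse(age >= 50, "Age2", "Age1"))
  disc_class <- ifelse(disc_area < 1.6, "Small",
                       ifelse(disc_area <= 2.6, "Average", "Large"))
  data.frame(
    age_band   = factor(age_band, levels = AGE_BANDS),
    disc_class = factor(disc_class, levels = DISC_CLASSES),
    group      = group_label(age_band, disc_class)
  )
}

group_label <- function(age_band, disc_class) {
  lv <- as.vector(outer(AGE_BANDS, DISC_CLASSES, paste, sep = ":"))
  factor(paste(age_band, disc_class, sep = ":"), levels = lv)
}

#' Construct a collection of RNFL profiles
#'
#' The container holds the thickness matrix (rows = eyes, columns = angular
#' points) together with per-eye metadata.  Profiles with any thickness below
#' 30 micrometres are retained but flagged `excluded`, so callers can report
#' exclusion counts rather than losing rows silently.
#'
#' @param values numeric matrix, one row per eye, `n_points` columns of RNFL
#'   thickness in micrometres (non-negative).
#' @param eye_id character vector of unique eye identifiers (default
#'   `eye_1 ...`).
#' @param age,disc_area,status optional per-eye metadata; `status` is
#'   `"normal"` or `"glaucoma"`.
#' @return object of class `rnfl_profiles`: a list with elements `values`
#'   (the matrix) and `meta` (data.frame with `eye_id`, `age`, `disc_area`,
#'   `status`, `excluded`, and -- when age and disc area are present --
#'   `age_band`, `disc_class`, `group`).
#' @export
rnfl_profiles <- function(values, eye_id = NULL, age = NULL, disc_area = NULL,
                          status = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  if (anyNA(values) || any(!is.finite(values)))
    stop("thickness values must be finite and non-missing")
  if (any(values < 0))
    stop("negative RNFL thickness is not a valid measurement")
  if (is.null(eye_id)) eye_id <- paste0("eye_", seq_len(n))
  eye_id <- as.character(eye_id)
  if (anyDuplicated(eye_id)) stop("eye_id values must be unique")
  meta <- data.frame(eye_id = eye_id, stringsAsFactors = FALSE)
  meta$age <- if (is.null(age)) NA_real_ else as.numeric(age)
  meta$disc_area <- if (is.null(disc_area)) NA_real_ else as.numeric(disc_area)
  meta$status <- if (is.null(status)) NA_character_ else {
    status <- as.character(status)
    if (!all(status %in% c("normal", "glaucoma")))
      stop("status must be 'normal' or 'glaucoma'")
    status
  }
  meta$excluded <- apply(values, 1L, function(v) any(v < RNFL_FLOOR_UM))
  if (!anyNA(meta$age) && !anyNA(meta$disc_area)) {
    g <- assign_group(meta$age, meta$disc_area)
    meta <- cbind(meta, g)
  }
  rownames(values) <- eye_id
  structure(list(values = values, meta = meta, n_points = ncol(values)),
            class = "rnfl_profiles")
}

#' @export
print.rnfl_profiles <- function(x, ...) {
  cat(sprintf("<rnfl_profiles> %d eyes x %d angular points (%.2f deg apart)\n",
              nrow(x$values), x$n_points, 360 / x$n_points))
  if (!all(is.na(x$meta$status)))
    cat("  status:", paste(names(table(x$meta$status)),
                           table(x$meta$status), collapse = ", "), "\n")
  n_ex <- sum(x$meta$excluded)
  if (n_ex > 0)
    cat(sprintf("  %d profile(s) flagged excluded (thickness < %g um)\n",
                n_ex, RNFL_FLOOR_UM))
  invisible(x)
}

#' @export
length.rnfl_profiles <- function(x) nrow(x$values)

#' Subset an rnfl_profiles collection by eye
#' @param x an `rnfl_profiles` object.
#' @param i eye index, logical mask or eye_id vector.
#' @param ... unused.
#' @export
`[.rnfl_profiles` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$meta$eye_id)
  out <- x
  out$values <- x$values[i, , drop = FALSE]
  out$meta <- x$meta[i, , drop = FALSE]
  rownames(out$meta) <- NULL
  out
}

#' Read circular RNFL profiles from CSV
#'
#' Expects the conventional supplementary-table layout: one row per eye,
#' `n_points` comma-separated thickness columns.  A header row of angular-point
#' labels and a leading non-numeric id column are auto-detected.  A separate
#' metadata CSV (columns `eye_id`, `age`, `disc_area`, `status`) may be joined
#' on `eye_id`; when the data file carries no id column, rows are labelled
#' `eye_1 ... eye_n` in file order.
#'
#' @param path CSV of thickness values.
#' @param metadata optional metadata CSV path.
#' @param n_points expected number of angular points; default infers from the
#'   first row and then enforces it on all others.
#' @return an [rnfl_profiles] object, rows in file order.
#' @export
read_profiles <- function(path, metadata = NULL, n_points = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- count.fields(path, sep = ",", quote = "\"")
  if (length(nf) == 0L) stop("empty profile file: ", path)
  raw <- read.csv(path, header = FALSE, colClasses = "character",
                  check.names = FALSE, strip.white = TRUE)
  is_num <- function(v) !is.na(suppressWarnings(as.numeric(v)))
  has_id <- !all(is_num(raw[-1L, 1L]))
  body_cols <- if (has_id) raw[-1L, -1L, drop = FALSE] else raw[-1L, , drop = FALSE]
  first <- if (has_id) raw[1L, -1L] else raw[1L, ]
  has_header <- nrow(raw) > 1L && !all(is_num(unlist(first)))
  data_rows <- if (has_header) seq.int(2L, nrow(raw)) else seq_len(nrow(raw))
  width <- nf[data_rows[1L]] - has_id
  if (is.null(n_points)) n_points <- width
  bad <- data_rows[nf[data_rows] - has_id != n_points]
  if (length(bad))
    stop(sprintf("malformed input: row %d of %s has %d value column(s), expected %d",
                 bad[1L], path, nf[bad[1L]] - has_id, n_points))
  vals_chr <- as.matrix(raw[data_rows, (1L + has_id):ncol(raw), drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(vals_chr), nrow = length(data_rows)))
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("parse error: non-numeric value '%s' at row %d, column %d of %s",
                 vals_chr[idx[1L], idx[2L]], data_rows[idx[1L]],
                 idx[2L] + has_id, path))
  }
  eye_id <- if (has_id) as.character(raw[data_rows, 1L]) else NULL
  prof <- rnfl_profiles(vals, eye_id = eye_id)
  if (!is.null(metadata)) {
    md <- read.csv(metadata, stringsAsFactors = FALSE)
    need <- c("eye_id", "age", "disc_area", "status")
    if (!all(need %in% names(md)))
      stop("metadata CSV must have columns: ", paste(need, collapse = ", "))
    m <- match(prof$meta$eye_id, as.character(md$eye_id))
    if (anyNA(m))
      stop("metadata is missing eye_id(s): ",
           paste(utils::head(prof$meta$eye_id[is.na(m)], 3L), collapse = ", "))
    prof <- rnfl_profiles(vals, eye_id = prof$meta$eye_id,
                          age = md$age[m], disc_area = md$disc_area[m],
                          status = md$status[m])
  }
  prof
}

#' Write profiles back to the row-per-eye CSV layout
#'
#' @param x an `rnfl_profiles` object.
#' @param path output CSV for the thickness matrix (id column + one column per
#'   angular point).
#' @param metadata_path optional output CSV for `eye_id`, `age`, `disc_area`,
#'   `status`.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(x, path, metadata_path = NULL) {
  stopifnot(inherits(x, "rnfl_profiles"))
  df <- data.frame(eye_id = x$meta$eye_id, x$values, check.names = FALSE)
  names(df) <- c("eye_id", paste0("p", seq_len(x$n_points)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(metadata_path))
    write.csv(x$meta[, c("eye_id", "age", "disc_area", "status")],
              metadata_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
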