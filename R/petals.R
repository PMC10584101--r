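# Petal tracing: a petal is a maximal circular run of angular points whose
# Angular Decay strictly exceeds the quantile threshold tau (default 0.75,
# i.e. the last quartile of normal decay).  Runs are found on the circle, so
# a defect straddling the temporal origin (point N -> point 1) is a single
# petal.  From the petal set come the directional indices:
#   nu       petal count,
#   pi*      the widest petal,
#   mu*      decay-weighted circular mean direction of pi*,
#   lambda*  width(pi*)/N  (local loss),
#   Lambda   sum of petal widths / N  (global loss),
# with 0 <= lambda* <= Lambda <= 1.

#' Trace contiguous supra-threshold decay regions on the circle
#'
#' @param decay numeric vector of decay values in \[0, 1\], one per angular
#'   point.
#' @param tau threshold, strictly inside (0, 1).  Exceedance is strict
#'   (`decay > tau`); points equal to `tau` are outside petals.
#' @return list of petals ordered by start index from the origin; each petal
#'   is a list with `start` and `end` (angular point indices, 1..N, the
#'   counterclockwise circular interval), `width` (member count), `indices`
#'   (member points in counterclockwise order) and `sum_decay` (summed member
#'   decay, used for tie-breaking the widest petal).  A run spanning the
#'   N -> 1 boundary is one petal; decay above `tau` everywhere gives a
#'   single petal of width N.
#' @export
trace_petals <- function(decay, tau = 0.75) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1)
    stop("tau must lie strictly inside (0, 1)")
  n <- length(decay)
  stopifnot(n >= 1L)
  above <- decay > tau
  if (!any(above)) return(list())
  if (all(above)) {
    return(list(list(start = 1L, end = n, width = n, indices = seq_len(n),
                     sum_decay = sum(decay))))
  }
  # rotate so the scan starts at a sub-threshold point; runs then never wrap
  k <- which(!above)[1L]
  rot <- c(seq.int(k, n), if (k > 1L) seq_len(k - 1L))
  r <- rle(above[rot])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  petals <- lapply(which(r$values), function(i) {
    idx <- rot[seq.int(starts[i], ends[i])]
    list(start = idx[1L], end = idx[length(idx)], width = length(idx),
         indices = idx, sum_decay = sum(decay[idx]))
  })
  petals[order(vapply(petals, `[[`, integer(1), "start"))]
}

#' Widest petal
#'
#' Maximal-width petal; ties broken by larger summed decay, then by smaller
#' start index, so the choice is deterministic and decay-respecting.
#'
#' @param petals list returned by [trace_petals()].
#' @return the widest petal, or `NULL` when the list is empty (the eye has no
#'   supra-threshold region; its directional summaries are NA).
#' @export
widest_petal <- function(petals) {
  if (length(petals) == 0L) return(NULL)
  w <- vapply(petals, `[[`, integer(1), "width")
  s <- vapply(petals, `[[`, numeric(1), "sum_decay")
  st <- vapply(petals, `[[`, integer(1), "start")
  petals[[order(-w, -s, st)[1L]]]
}

#' Weighted circular mean direction
#'
#' The quadrant-specific inverse tangent (two-argument form) of the weighted
#' resultant: `atan2(sum w sin(theta), sum w cos(theta))`, normalized to
#' \[0, 360).
#'
#' @param angles angles in degrees.
#' @param weights non-negative weights, same length, at least one positive.
#' @return mean direction in degrees, in \[0, 360).
#' @examples
#' weighted_circular_mean(c(30, 90), c(1, 1))  # 60
#' @export
weighted_circular_mean <- function(angles, weights = rep(1, length(angles))) {
  if (length(angles) != length(weights))
    stop("angles and weights must have equal length")
  if (length(angles) == 0L || all(weights <= 0))
    stop("at least one positive weight is required")
  th <- angles * pi / 180
  s <- sum(weights * sin(th))
  c_ <- sum(weights * cos(th))
  if (sqrt(s^2 + c_^2) < 1e-12)
    stop("undefined direction: weighted resultant length is (numerically) zero")
  (atan2(s, c_) * 180 / pi) %% 360
}

#' Directional decay summary of one eye
#'
#' Traces petals at threshold `tau` and computes the petal count `nu`, the
#' widest petal `pi_star`, its decay-weighted circular mean direction
#' `mu_star` (grid angles of member points weighted by their raw decay
#' values), the local loss `lambda_star = width(pi*)/N`, and the global loss
#' `Lambda = (sum of petal widths)/N`.  With no petal, `mu_star`,
#' `lambda_star`, `theta_s`, `theta_t` are NA and `nu = Lambda = 0`.
#'
#' @param decay numeric decay vector for one eye, or a `decay_set` (then one
#'   summary row per eye is returned).
#' @param tau threshold in (0, 1); default 0.75.
#' @param ... unused.
#' @return for a vector: a list of class `decay_summary` with fields `tau`,
#'   `nu`, `pi_star`, `theta_s`, `theta_t`, `mu_star`, `lambda_star`,
#'   `Lambda`, `petals`.  For a `decay_set`: a data.frame with columns
#'   `eye_id`, `tau`, `nu`, `theta_s`, `theta_t`, `mu_star`, `lambda_star`,
#'   `Lambda`.
#' @export
summarize_decay <- function(decay, tau = 0.75, ...) UseMethod("summarize_decay")

#' @export
summarize_decay.default <- function(decay, tau = 0.75, ...) {
  decay <- as.numeric(decay)
  n <- length(decay)
  petals <- trace_petals(decay, tau)
  nu <- length(petals)
  pi_star <- widest_petal(petals)
  Lambda <- sum(vapply(petals, `[[`, integer(1), "width")) / n
  if (is.null(pi_star)) {
    out <- list(tau = tau, nu = 0L, pi_star = NULL, theta_s = NA_integer_,
                theta_t = NA_integer_, mu_star = NA_real_,
                lambda_star = NA_real_, Lambda = 0, petals = petals)
  } else {
    theta <- grid_angles(n)
    mu_star <- tryCatch(
      weighted_circular_mean(theta[pi_star$indices], decay[pi_star$indices]),
      error = function(e) {
        warning("mu* undefined (degenerate resultant); reported NA")
        NA_real_
      })
    out <- list(tau = tau, nu = nu, pi_star = pi_star,
                theta_s = pi_star$start, theta_t = pi_star$end,
                mu_star = mu_star, lambda_star = pi_star$width / n,
                Lambda = Lambda, petals = petals)
  }
  class(out) <- "decay_summary"
  out
}

#' @export
summarize_decay.decay_set <- function(decay, tau = 0.75, ...) {
  rows <- lapply(seq_len(nrow(decay$decay)), function(i) {
    s <- summarize_decay(decay$decay[i, ], tau)
    data.frame(eye_id = decay$meta$eye_id[i], tau = tau, nu = s$nu,
               theta_s = s$theta_s, theta_t = s$theta_t, mu_star = s$mu_star,
               lambda_star = s$lambda_star, Lambda = s$Lambda,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.decay_summary <- function(x, ...) {
  cat(sprintf("<decay_summary> tau = %.2f: nu = %d, Lambda = %.4f\n",
              x$tau, x$nu, x$Lambda))
  if (!is.null(x$pi_star))
    cat(sprintf("  pi*: points %d..%d (width %d), mu* = %.2f deg, lambda* = %.4f\n",
                x$theta_s, x$theta_t, x$pi_star$width, x$mu_star,
                x$lambda_star))
  else cat("  no petal: mu*, lambda* = NA\n")
  invisible(x)
}
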