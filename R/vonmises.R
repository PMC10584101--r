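# Finite mixtures of univariate von Mises ("circular normal") distributions,
#   f(x | mu, kappa) = exp(kappa * cos(x - mu)) / (2 pi I0(kappa)),
# fitted by EM: the E-step computes posterior responsibilities, the M-step
# updates mixing proportions (mean responsibility), locations (responsibility-
# weighted circular means) and concentrations (inverse of the Bessel ratio
# A(kappa) = I1(kappa)/I0(kappa) at the weighted mean resultant length).
# All interfaces are in degrees; computation is in radians.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) (r * 180 / pi) %% 360

KAPPA_MAX <- 500  # concentration cap: avoids Bessel overflow on degenerate data

#' von Mises probability density
#'
#' @param x angle(s) in degrees.
#' @param mu location angle in degrees.
#' @param kappa concentration, `>= 0`; `kappa = 0` is the circular uniform.
#' @return density value(s); integrates to 1 over any 360-degree interval of
#'   the angle measured in radians.
#' @examples
#' vm_pdf(123, 45, 0)  # 1 / (2*pi)
#' @export
vm_pdf <- function(x, mu, kappa) {
  if (any(kappa < 0)) stop("kappa must be non-negative")
  # scaled Bessel keeps the density finite at large kappa
  exp(kappa * (cos(deg2rad(x - mu)) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher wrapped-Cauchy envelope rejection sampler.
#'
#' @param n sample size.
#' @param mu location (degrees).
#' @param kappa concentration `>= 0`.
#' @return angles in degrees, in \[0, 360).
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) stop("kappa must be non-negative")
  if (kappa == 0) return(runif(n, 0, 360))
  mu_r <- deg2rad(mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    nf <- sum(ok)
    if (nf > 0L) {
      theta <- sign(u3[ok] - 0.5) * acos(f[ok])
      out[got + seq_len(nf)] <- theta + mu_r
      got <- got + nf
    }
  }
  rad2deg(out)
}

# Bessel ratio A(kappa) = I1/I0, computed with scaled Bessels for stability.
bessel_ratio <- function(kappa) {
  ifelse(kappa == 0, 0,
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}

# Inverse of A(kappa) at mean resultant length R: Best-Fisher three-regime
# approximation refined by Newton steps on A(kappa) - R, using
# A'(kappa) = 1 - A/kappa - A^2.  Capped at KAPPA_MAX.
a1_inverse <- function(R, n_newton = 5L) {
  if (R < 0) R <- 0
  if (R >= 1) return(KAPPA_MAX)
  k <- if (R < 0.53) 2 * R + R^3 + 5 * R^5 / 6
       else if (R < 0.85) -0.4 + 1.39 * R + 0.43 / (1 - R)
       else 1 / (R^3 - 4 * R^2 + 3 * R)
  k <- min(max(k, 1e-8), KAPPA_MAX)
  for (i in seq_len(n_newton)) {
    A <- bessel_ratio(k)
    dA <- 1 - A / k - A^2
    if (!is.finite(dA) || dA <= 0) break
    k <- k - (A - R) / dA
    if (!is.finite(k) || k <= 0) { k <- 1e-8; break }
    if (k > KAPPA_MAX) { k <- KAPPA_MAX; break }
  }
  k
}

# log density, vectorized over x for one component
vm_logpdf_rad <- function(x_rad, mu_rad, kappa) {
  kappa * (cos(x_rad - mu_rad) - 1) -
    log(2 * pi) - log(besselI(kappa, 0, expon.scaled = TRUE))
}

#' Fit a K-component von Mises mixture by EM
#'
#' Starts from random responsibility assignments (`n_restarts` independent
#' initializations) and keeps the fit with the best log-likelihood.
#' Components are reported sorted by location so fits are comparable across
#' seeds (label switching resolved).
#'
#' @param angles sample of directions in degrees.
#' @param K number of components, `1 <= K <= length(angles)`.
#' @param n_restarts independent random initializations (default 20).
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter EM iteration cap per restart (default 500); a restart that
#'   hits the cap is kept but flagged via `converged = FALSE`, not an error.
#' @param seed optional RNG seed for reproducible initialization.
#' @return object of class `vm_mixture`: list with `components` (data.frame
#'   `mu`, `kappa`, `alpha`, sorted by `mu`), `loglik`, `bic`
#'   (`-2 loglik + (3K - 1) log n`), `n`, `K`, `assignments`
#'   (max-responsibility labels), `responsibilities` (n x K, rows sum to 1),
#'   `converged`, `loglik_trace` of the winning restart.
#' @export
fit_mixture_em <- function(angles, K, n_restarts = 20L, tol = 1e-8,
                           max_iter = 500L, seed = NULL) {
  angles <- as.numeric(angles)
  if (anyNA(angles) || any(!is.finite(angles)))
    stop("angles must be finite and non-missing")
  n <- length(angles)
  if (K < 1L) stop("K must be at least 1")
  if (K > n) stop("K (", K, ") exceeds the sample size (", n, ")")
  if (!is.null(seed)) set.seed(seed)
  x <- deg2rad(angles)
  # short-run strategy: every restart gets a capped burn-in, then only the
  # best candidate (by log-likelihood) is run to full convergence from its
  # responsibilities
  burn <- min(75L, max_iter)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    # random responsibility init
    resp <- matrix(runif(n * K), n, K)
    resp <- resp / rowSums(resp)
    fit <- em_run(x, resp, tol, burn)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (!best$converged) {
    trace0 <- best$trace
    best <- em_run(x, best$resp, tol, max_iter)
    best$trace <- c(trace0, best$trace)
  }
  ord <- order(rad2deg(best$mu))
  resp <- best$resp[, ord, drop = FALSE]
  comps <- data.frame(mu = rad2deg(best$mu[ord]), kappa = best$kappa[ord],
                      alpha = best$alpha[ord])
  structure(list(
    components = comps, loglik = best$loglik,
    bic = -2 * best$loglik + (3 * K - 1) * log(n),
    n = n, K = K,
    assignments = max.col(resp, ties.method = "first"),
    responsibilities = resp,
    converged = best$converged, loglik_trace = best$trace
  ), class = "vm_mixture")
}

em_run <- function(x, resp, tol, max_iter) {
  n <- length(x); K <- ncol(resp)
  sx <- sin(x); cx <- cos(x)
  mu <- numeric(K); kappa <- numeric(K); alpha <- numeric(K)
  ll <- -Inf; ll_old <- -Inf; trace <- numeric(max_iter); converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # M-step
    wsum <- colSums(resp)
    wsum[wsum < 1e-12] <- 1e-12
    alpha <- wsum / n
    S <- colSums(resp * sx); C <- colSums(resp * cx)
    mu <- atan2(S, C)
    Rbar <- pmin(sqrt(S^2 + C^2) / wsum, 1 - 1e-12)
    kappa <- vapply(Rbar, a1_inverse, numeric(1))
    # E-step + log-likelihood (log-sum-exp); the component log density is
    # kappa*cos(x - mu) - kappa expressed via two outer products
    logd <- cx %o% (kappa * cos(mu)) + sx %o% (kappa * sin(mu))
    logd <- sweep(logd, 2L,
                  log(alpha) - kappa - log(2 * pi) -
                    log(besselI(kappa, 0, expon.scaled = TRUE)),
                  "+")
    m <- logd[cbind(seq_len(n), max.col(logd, ties.method = "first"))]
    lse <- m + log(rowSums(exp(logd - m)))
    resp <- exp(logd - lse)
    ll <- sum(lse)
    trace[iter] <- ll
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(mu = mu, kappa = kappa, alpha = alpha, loglik = ll, resp = resp,
       converged = converged, trace = trace[seq_len(iter)])
}

#' @export
print.vm_mixture <- function(x, ...) {
  cat(sprintf("<vm_mixture> K = %d, n = %d, loglik = %.3f, BIC = %.3f%s\n",
              x$K, x$n, x$loglik, x$bic,
              if (x$converged) "" else " (not converged)"))
  print(round(x$components, 3))
  invisible(x)
}

#' Select the number of mixture components by BIC
#'
#' Fits each K in `K_range` and returns the fit minimizing
#' `BIC = -2 loglik + (3K - 1) log n` (K locations, K concentrations, K - 1
#' free proportions).  The full BIC table is attached for reporting.
#'
#' @param angles sample of directions in degrees.
#' @param K_range candidate component counts (default 1:5).
#' @inheritParams fit_mixture_em
#' @return the BIC-minimizing `vm_mixture`, with attribute `bic_table`
#'   (data.frame `K`, `loglik`, `bic`).
#' @export
select_K <- function(angles, K_range = 1:5, n_restarts = 20L, tol = 1e-8,
                     max_iter = 500L, seed = NULL) {
  if (length(K_range) == 0L) stop("K_range must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  fits <- lapply(K_range, function(K)
    fit_mixture_em(angles, K, n_restarts = n_restarts, tol = tol,
                   max_iter = max_iter, seed = NULL))
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  best <- fits[[which.min(bics)]]
  attr(best, "bic_table") <- data.frame(
    K = K_range, loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    bic = bics)
  best
}

#' Assign angles to mixture components
#'
#' Maximum-responsibility labelling under a fitted mixture; ties go to the
#' lower-index component.  Deterministic given the fit.
#'
#' @param fit a `vm_mixture`.
#' @param angles directions in degrees (defaults to relabelling nothing new:
#'   pass the angles to classify).
#' @return integer labels in `1..K`.
#' @export
assign_clusters <- function(fit, angles) {
  stopifnot(inherits(fit, "vm_mixture"))
  x <- deg2rad(as.numeric(angles))
  logd <- vapply(seq_len(fit$K), function(k)
    log(fit$components$alpha[k]) +
      vm_logpdf_rad(x, deg2rad(fit$components$mu[k]), fit$components$kappa[k]),
    numeric(length(x)))
  logd <- matrix(logd, length(x), fit$K)
  max.col(logd, ties.method = "first")
}

#' Circular mean direction of a sample
#' @param angles directions in degrees.
#' @return mean direction in degrees in \[0, 360).
#' @export
circular_mean <- function(angles) {
  weighted_circular_mean(angles, rep(1, length(angles)))
}

#' Circular correlation coefficient
#'
#' The Jammalamadaka-SenGupta circular analogue of Pearson's correlation:
#' `sum sin(a - a_bar) sin(b - b_bar)` over the root of the product of the
#' summed squared sine deviations, with circular means `a_bar`, `b_bar`.
#'
#' @param a,b paired direction samples in degrees, equal length `>= 2`.
#' @return coefficient in \[-1, 1\].
#' @export
circular_correlation <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    stop("a and b must be paired samples of equal length >= 2")
  abar <- deg2rad(circular_mean(a))
  bbar <- deg2rad(circular_mean(b))
  sa <- sin(deg2rad(a) - abar)
  sb <- sin(deg2rad(b) - bbar)
  den <- sqrt(sum(sa^2) * sum(sb^2))
  if (den < 1e-12)
    stop("undefined: one of the samples has no angular dispersion")
  sum(sa * sb) / den
}

#' Export a fitted mixture as CSV tables
#'
#' @param fit a `vm_mixture`.
#' @param angles the fitted directions (degrees), for the per-observation
#'   table.
#' @param eye_id optional identifiers, one per angle.
#' @param model_path CSV for per-component parameters (`K`, `component`,
#'   `mu`, `kappa`, `alpha`, `loglik`, `bic`).
#' @param cluster_path optional CSV for per-eye assignments (`eye_id`,
#'   `mu_star`, `cluster`, `responsibility`).
#' @return `model_path`, invisibly.
#' @export
export_mixture <- function(fit, angles, eye_id = NULL, model_path,
                           cluster_path = NULL) {
  stopifnot(inherits(fit, "vm_mixture"))
  md <- data.frame(K = fit$K, component = seq_len(fit$K),
                   mu = round(fit$components$mu, 2),
                   kappa = round(fit$components$kappa, 4),
                   alpha = round(fit$components$alpha, 4),
                   loglik = fit$loglik, bic = fit$bic)
  write.csv(md, model_path, row.names = FALSE, quote = FALSE)
  if (!is.null(cluster_path)) {
    lab <- assign_clusters(fit, angles)
    resp <- vapply(seq_along(angles), function(i)
      fit$responsibilities[i, lab[i]], numeric(1))
    if (is.null(eye_id)) eye_id <- paste0("eye_", seq_along(angles))
    cd <- data.frame(eye_id = eye_id, mu_star = round(angles, 2),
                     cluster = lab, responsibility = round(resp, 4))
    write.csv(cd, cluster_path, row.names = FALSE, quote = FALSE)
  }
  invisible(model_path)
}
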