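# Polar visualizations.  Convention for decay plots: a pale blue circle of
# radius tau marks the threshold; the decay curve is drawn in blue where it
# is below tau, petals in pink, the widest petal in red, and the weighted
# circular mean of the widest petal as a dashed red radial line.

polar_xy <- function(r, theta_deg) {
  th <- theta_deg * pi / 180
  list(x = r * cos(th), y = r * sin(th))
}

draw_circle <- function(r, ...) {
  th <- seq(0, 2 * pi, length.out = 361)
  graphics::lines(r * cos(th), r * sin(th), ...)
}

#' Polar plot of one eye's Angular Decay with petals
#'
#' @param decay numeric decay vector for one eye.
#' @param tau threshold in (0, 1).
#' @param file optional PNG path; when given, the plot is written there.
#' @param main plot title.
#' @return the [summarize_decay()] of the eye, invisibly.
#' @export
plot_decay <- function(decay, tau = 0.75, file = NULL, main = "Angular Decay") {
  decay <- as.numeric(decay)
  if (length(decay) == 0L) stop("empty decay sequence")
  n <- length(decay)
  theta <- grid_angles(n)
  s <- summarize_decay(decay, tau)
  if (!is.null(file)) {
    grDevices::png(file, width = 640, height = 640)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = main)
  draw_circle(1, col = "grey80")
  draw_circle(tau, col = "lightblue", lwd = 2)
  in_petal <- rep(FALSE, n)
  in_star <- rep(FALSE, n)
  for (p in s$petals) in_petal[p$indices] <- TRUE
  if (!is.null(s$pi_star)) in_star[s$pi_star$indices] <- TRUE
  xy <- polar_xy(decay, theta)
  col <- ifelse(in_star, "red", ifelse(in_petal, "pink", "blue"))
  # draw as short segments so color changes at petal boundaries
  nxt <- c(seq.int(2L, n), 1L)
  graphics::segments(xy$x, xy$y, xy$x[nxt], xy$y[nxt], col = col, lwd = 2)
  if (!is.null(s$pi_star) && !is.na(s$mu_star)) {
    m <- polar_xy(1, s$mu_star)
    graphics::segments(0, 0, m$x, m$y, col = "red", lty = 2, lwd = 2)
  }
  graphics::mtext(sprintf("tau=%.2f  nu=%d  lambda*=%.4f  Lambda=%.4f  mu*=%s",
                          s$tau, s$nu, s$lambda_star, s$Lambda,
                          if (is.na(s$mu_star)) "NA"
                          else sprintf("%.2f", s$mu_star)),
                  side = 1, line = 1)
  invisible(s)
}

#' Polar plot of a group's normative quantile contours
#'
#' Nested percentile contours (default the 5th, 25th, 50th and 75th) of
#' normal RNFL thickness around the circle.
#'
#' @param catalog a `normative_catalog`.
#' @param group populated group label.
#' @param probs contour probabilities in (0, 1).
#' @param file optional PNG path.
#' @return the contour matrix, invisibly.
#' @export
plot_contours <- function(catalog, group,
                          probs = c(0.05, 0.25, 0.50, 0.75), file = NULL) {
  q <- quantile_contours(catalog, group, probs)
  theta <- grid_angles(catalog$n_points)
  rmax <- max(q) * 1.05
  if (!is.null(file)) {
    grDevices::png(file, width = 640, height = 640)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(NA, xlim = c(-rmax, rmax), ylim = c(-rmax, rmax), asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = sprintf("Normative RNFL contours: %s", group))
  cols <- grDevices::hcl.colors(nrow(q), "Zissou 1")
  for (i in seq_len(nrow(q))) {
    xy <- polar_xy(q[i, ], theta)
    graphics::lines(c(xy$x, xy$x[1L]), c(xy$y, xy$y[1L]), col = cols[i], lwd = 2)
  }
  graphics::legend("topright", legend = rownames(q), col = cols, lwd = 2,
                   bty = "n", title = "quantile")
  invisible(q)
}

#' Rose histogram of decay directions with fitted mixture density
#'
#' Circular histogram of mu* directions with the fitted von Mises mixture
#' density overlaid and the TSNIT sector boundaries annotated.
#'
#' @param angles directions in degrees.
#' @param fit optional `vm_mixture` to overlay.
#' @param file optional PNG path.
#' @param breaks number of histogram sectors.
#' @return invisible `NULL`.
#' @export
plot_rose <- function(angles, fit = NULL, file = NULL, breaks = 36L) {
  if (length(angles) == 0L) stop("empty angle vector")
  if (!is.null(file)) {
    grDevices::png(file, width = 640, height = 640)
    on.exit(grDevices::dev.off())
  }
  h <- graphics::hist(angles %% 360, breaks = seq(0, 360, length.out = breaks + 1),
                      plot = FALSE)
  dens <- h$density * (360 / breaks)       # sector probability mass
  r <- sqrt(dens / max(dens))
  graphics::plot(NA, xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3), asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = "Decay directions (TSNIT)")
  draw_circle(1, col = "grey85")
  for (i in seq_len(breaks)) {
    a0 <- h$breaks[i] * pi / 180; a1 <- h$breaks[i + 1L] * pi / 180
    th <- seq(a0, a1, length.out = 8)
    graphics::polygon(c(0, r[i] * cos(th)), c(0, r[i] * sin(th)),
                      col = "indianred1", border = "white")
  }
  sect <- c(T = 0, S = 90, N = 180, I = 270)
  for (nm in names(sect)) {
    p <- polar_xy(1.18, sect[[nm]])
    graphics::text(p$x, p$y, nm)
  }
  if (!is.null(fit)) {
    th <- seq(0, 360, length.out = 721)
    d <- rowSums(vapply(seq_len(fit$K), function(k)
      fit$components$alpha[k] *
        vm_pdf(th, fit$components$mu[k], fit$components$kappa[k]),
      numeric(length(th))))
    rr <- sqrt(d / max(d))
    xy <- polar_xy(rr, th)
    graphics::lines(xy$x, xy$y, col = "darkred", lwd = 2)
  }
  invisible(NULL)
}
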