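# Static figures: CE plane with confidence ellipse, acceptability curve,
# tornado diagram. Base graphics, suitable for writing to PDF/PNG devices.

#' Plot the cost-effectiveness plane
#'
#' Scatter of PSA draws (delta QALY vs delta cost) with the base-case point
#' and, optionally, the normal-theory confidence ellipse.
#'
#' @param psa A `psa_result`.
#' @param ellipse Draw the 95% confidence ellipse?
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, NULL.
#' @export
plot_ce_plane <- function(psa, ellipse = TRUE, ...) {
  d <- psa$deltas
  graphics::plot(d$delta_qaly, d$delta_cost, pch = 16, cex = 0.4,
                 col = grDevices::grey(0.4, 0.5),
                 xlab = "Incremental QALYs", ylab = "Incremental cost (EUR)", ...)
  graphics::abline(h = 0, v = 0, col = "grey60")
  if (ellipse && nrow(d) >= 3) {
    el <- confidence_ellipse(psa)
    if (!el$degenerate) {
      th <- seq(0, 2 * pi, length.out = 200)
      rot <- matrix(c(cos(el$angle_rad), sin(el$angle_rad),
                      -sin(el$angle_rad), cos(el$angle_rad)), 2, 2)
      xy <- t(rot %*% rbind(el$radii[1] * cos(th), el$radii[2] * sin(th)))
      graphics::lines(el$centre[1] + xy[, 1], el$centre[2] + xy[, 2],
                      col = "firebrick", lwd = 2)
    }
  }
  graphics::points(psa$base$delta_qaly, psa$base$delta_cost,
                   pch = 4, col = "blue", lwd = 2)
  invisible(NULL)
}

#' Plot the cost-effectiveness acceptability curve
#'
#' @param curve A `ckdcea_ceac` data.frame from [ceac()].
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, NULL.
#' @export
plot_ceac <- function(curve, ...) {
  graphics::plot(curve$wtp, curve$prob_cost_effective, type = "l", lwd = 2,
                 ylim = c(0, 1), xlab = "Willingness to pay (EUR/QALY)",
                 ylab = "Probability cost-effective", ...)
  graphics::abline(h = c(0.5, 0.95), lty = 3, col = "grey60")
  invisible(NULL)
}

#' Tornado diagram from a deterministic sensitivity analysis
#'
#' Horizontal bars spanning the low/high incremental outcome per parameter,
#' widest swing on top.
#'
#' @param dsa A `ckdcea_dsa` from [run_dsa()].
#' @param outcome `"cost"` or `"qaly"`.
#' @param top Show at most this many parameters.
#' @return Invisibly, NULL.
#' @export
plot_tornado <- function(dsa, outcome = c("cost", "qaly"), top = 12) {
  outcome <- match.arg(outcome)
  lo <- dsa[[paste0("delta_", outcome, "_low")]]
  hi <- dsa[[paste0("delta_", outcome, "_high")]]
  ord <- order(abs(hi - lo), decreasing = TRUE)[seq_len(min(top, nrow(dsa)))]
  ord <- rev(ord)
  base <- attr(dsa, "base")
  ctr <- if (outcome == "cost") base$delta_cost else base$delta_qaly
  y <- seq_along(ord)
  old <- graphics::par(mar = c(4, 12, 1, 1))
  on.exit(graphics::par(old))
  graphics::plot(NA, xlim = range(c(lo[ord], hi[ord], ctr)),
                 ylim = c(0.5, length(ord) + 0.5), yaxt = "n",
                 xlab = sprintf("Incremental %s", if (outcome == "cost") "cost (EUR)" else "QALYs"),
                 ylab = "")
  graphics::segments(lo[ord], y, hi[ord], y, lwd = 8, col = "steelblue")
  graphics::abline(v = ctr, lty = 2)
  graphics::axis(2, at = y, labels = dsa$parameter[ord], las = 1, cex.axis = 0.8)
  invisible(NULL)
}
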