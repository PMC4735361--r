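#' Heatmap of an activation or asymmetry matrix
#'
#' Base-graphics heatmap with region names on both axes, rows plotted top
#' to bottom in protocol order.
#'
#' @param mat square matrix with dimnames.
#' @param main plot title.
#' @param col colour ramp.
#' @return invisibly `NULL`.
#' @export
plot_matrix_heatmap <- function(mat, main = "",
                                col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)) {
  k <- nrow(mat)
  op <- graphics::par(mar = c(6, 6, 3, 1))
  on.exit(graphics::par(op))
  graphics::image(seq_len(k), seq_len(k), t(mat[k:1, , drop = FALSE]),
                  col = col, axes = FALSE, xlab = "", ylab = "", main = main)
  graphics::axis(1, at = seq_len(k), labels = colnames(mat), las = 2, cex.axis = 0.6)
  graphics::axis(2, at = seq_len(k), labels = rev(rownames(mat)), las = 2, cex.axis = 0.6)
  invisible(NULL)
}

#' Distance-distance plot
#'
#' Classical squared Mahalanobis distance against robust squared distance
#' with the chi-square threshold drawn on both axes; points beyond either
#' line are the respective method's outliers.
#'
#' @param report an `outlier_report`.
#' @return invisibly `NULL`.
#' @export
plot_distance_distance <- function(report) {
  t <- report$table
  graphics::plot(t$md, t$rd, xlab = "Mahalanobis distance (squared)",
                 ylab = "robust distance (squared)",
                 main = sprintf("distance-distance plot (%.1f%% quantile)",
                                100 * report$level))
  graphics::abline(h = report$threshold, v = report$threshold, col = "red")
  flagged <- t$flag_md | t$flag_rd
  if (any(flagged))
    graphics::text(t$md[flagged], t$rd[flagged], t$region[flagged],
                   pos = 3, cex = 0.7)
  invisible(NULL)
}

#' Scatterplot with the robust tolerance ellipse
#'
#' The (area, retention) dataset with the MCD tolerance ellipse at the
#' report's quantile level.
#'
#' @param report an `outlier_report`.
#' @return invisibly `NULL`.
#' @export
plot_tolerance_ellipse <- function(report) {
  t <- report$table
  e <- report$ellipse
  th <- seq(0, 2 * pi, length.out = 200)
  pts <- cbind(e$axes[1] * cos(th), e$axes[2] * sin(th))
  R <- matrix(c(cos(e$angle), sin(e$angle), -sin(e$angle), cos(e$angle)), 2)
  pts <- sweep(pts %*% t(R), 2, e$center, `+`)
  graphics::plot(t$area_mm2, t$retention_s,
                 xlim = range(c(t$area_mm2, pts[, 1])),
                 ylim = range(c(t$retention_s, pts[, 2])),
                 xlab = "region area (mm^2)", ylab = "retention index (s)",
                 main = "retention vs area with robust tolerance ellipse")
  graphics::lines(pts, col = "red")
  if (any(t$flag_rd))
    graphics::text(t$area_mm2[t$flag_rd], t$retention_s[t$flag_rd],
                   t$region[t$flag_rd], pos = 3, cex = 0.7)
  invisible(NULL)
}
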