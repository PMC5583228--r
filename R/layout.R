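#' 2-D scalp coordinates for extended 10-20 electrode labels
#'
#' Returns approximate top-view head coordinates (nose up, unit head radius)
#' for the electrode labels used by the generator. Positions are derived from
#' the standard angular layout of the extended 10-20 system; they are meant
#' for topographic visualization, not for source modelling.
#'
#' @return data frame `label, x, y`.
#' @export
electrode_layout <- function() {
  # rows: anterior-posterior position y0 at the midline, lateral spread at
  # full eccentricity; columns within a row are spaced evenly
  row_spec <- list(
    FP = list(y = 0.80, labels = c("FP1", "FPZ", "FP2")),
    AF = list(y = 0.60, labels = c("AF7", "AF3", "AF4", "AF8")),
    F  = list(y = 0.40, labels = c("F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8")),
    FC = list(y = 0.20, labels = c("FT7", "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6", "FT8")),
    C  = list(y = 0.00, labels = c("T7", "C5", "C3", "C1", "CZ", "C2", "C4", "C6", "T8")),
    CP = list(y = -0.20, labels = c("TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6", "TP8")),
    P  = list(y = -0.40, labels = c("P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8")),
    PO = list(y = -0.60, labels = c("PO7", "PO5", "PO3", "POZ", "PO4", "PO6", "PO8")),
    O  = list(y = -0.80, labels = c("O1", "OZ", "O2")),
    M  = list(y = -0.10, labels = c("M1", "M2"), x = c(-1.05, 1.05))
  )
  out <- lapply(row_spec, function(rw) {
    k <- length(rw$labels)
    x <- if (!is.null(rw$x)) rw$x
         else if (k == 1L) 0
         else {
       # spread across the head width available at this y (circular outline)
       half <- 0.95 * sqrt(max(0, 1 - rw$y^2))
       seq(-half, half, length.out = k)
    }
    data.frame(label = rw$labels, x = x, y = rw$y)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Topographic map of a channel correlation map
#'
#' Renders the per-channel correlations of a [fingerprint()] result as an
#' interpolated scalp image (inverse-distance-weighted interpolation on a
#' regular grid clipped to the head circle) with electrode markers and a
#' colorbar. Channels whose label is not in the layout are skipped with a
#' warning. Rendering is deterministic given identical inputs.
#'
#' @param map a `correlation_map` (or any data frame with `channel` and `r`).
#' @param file output PNG path.
#' @param layout coordinate table, default [electrode_layout()].
#' @param grid_n interpolation grid resolution per axis (default 81).
#' @return `file`, invisibly.
#' @export
topomap <- function(map, file, layout = electrode_layout(), grid_n = 81) {
  idx <- match(map$channel, layout$label)
  if (anyNA(idx)) {
    warning(sprintf("unknown channel label(s) skipped: %s",
                    paste(map$channel[is.na(idx)], collapse = ", ")))
  }
  keep <- !is.na(idx)
  if (!any(keep)) stop("no channel label resolvable to layout coordinates", call. = FALSE)
  px <- layout$x[idx[keep]]; py <- layout$y[idx[keep]]; pr <- map$r[keep]
  field <- .idw_field(px, py, pr, grid_n)
  ax <- seq(-1.1, 1.1, length.out = grid_n)
  zlim <- max(abs(pr), 1e-6) * c(-1, 1)
  pal <- grDevices::hcl.colors(64, "Blue-Red 3")
  grDevices::png(file, width = 640, height = 560, type = "cairo")
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::layout(matrix(1:2, 1), widths = c(5, 1))
  graphics::par(mar = c(1, 1, 2, 1))
  graphics::image(ax, ax, field, asp = 1, axes = FALSE, xlab = "", ylab = "",
                  col = pal, zlim = zlim, main = "entropy-SRT Spearman r")
  th <- seq(0, 2 * pi, length.out = 181)
  graphics::lines(1.05 * cos(th), 1.05 * sin(th))
  graphics::lines(c(-0.1, 0, 0.1), c(1.04, 1.15, 1.04))  # nose
  graphics::points(px, py, pch = 21, bg = "white", cex = 0.8)
  graphics::par(mar = c(3, 1, 3, 3))
  graphics::image(1, seq(zlim[1], zlim[2], length.out = 64),
                  matrix(seq(zlim[1], zlim[2], length.out = 64), 1), col = pal,
                  axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4)
  invisible(file)
}

# inverse-distance-weighted (p = 2) interpolation, NA outside the head circle
.idw_field <- function(px, py, pv, grid_n) {
  ax <- seq(-1.1, 1.1, length.out = grid_n)
  gx <- rep(ax, times = grid_n)
  gy <- rep(ax, each = grid_n)
  d2 <- outer(gx, px, function(a, b) (a - b)^2) +
        outer(gy, py, function(a, b) (a - b)^2)
  d2 <- pmax(d2, 1e-12)
  wts <- 1 / d2
  z <- as.vector((wts %*% pv) / rowSums(wts))
  z[gx^2 + gy^2 > 1.1^2] <- NA
  matrix(z, grid_n, grid_n)
}
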