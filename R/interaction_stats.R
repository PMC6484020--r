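# Statistical layer over interaction-distance series: occupancy,
# median/MAD summaries, Pearson correlation, 2D Gaussian-kernel density
# estimates.
#
# Operational conventions for named interactions (config-exposed in the
# pipeline): a salt bridge is the minimum distance between side-chain N/O
# atoms of the charged groups (default occupancy cutoff 0.4 nm); a
# cation-pi contact is the distance from the cationic-group centroid to
# the aromatic-ring heavy-atom centroid (default cutoff 0.6 nm).

#' Per-frame distance series between two atom groups
#'
#' @param ensemble a non-empty `trajectory_ensemble`.
#' @param group_a,group_b disjoint non-empty atom index sets.
#' @param mode `"min"` (minimum over cross pairs) or `"centroid"`
#'   (centroid-to-centroid).
#' @param label optional series label (e.g. `"d1"`).
#' @return A `distance_series`: list with `values` (nm per frame), `times`,
#'   `label`, `mode` and `summary` (median and unscaled MAD).
#' @export
distance_series <- function(ensemble, group_a, group_b,
                            mode = c("min", "centroid"), label = NULL) {
  mode <- match.arg(mode)
  if (is.null(ensemble) || n_frames(ensemble) == 0L) {
    stop("empty input: distance_series needs at least one frame")
  }
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("selection error: empty atom group")
  }
  if (length(intersect(group_a, group_b)) > 0L) {
    stop("selection error: atom groups overlap")
  }
  values <- if (mode == "min") {
    .min_dist_over_frames(ensemble$frames, group_a, group_b)
  } else {
    vapply(ensemble$frames, function(f) {
      ca <- colMeans(f[group_a, , drop = FALSE])
      cb <- colMeans(f[group_b, , drop = FALSE])
      sqrt(sum((ca - cb)^2))
    }, numeric(1))
  }
  s <- structure(
    list(values = values, times = ensemble$times, label = label, mode = mode),
    class = "distance_series"
  )
  s$summary <- summarize_series(s)
  s
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf("distance_series %s (%s): %d frames, median %.3f [%.3f] nm\n",
              x$label %||% "", x$mode, length(x$values),
              x$summary$median, x$summary$mad))
  invisible(x)
}

.series_values <- function(x) {
  if (inherits(x, "distance_series")) x$values else as.numeric(x)
}

#' Median and unscaled MAD of a distance series
#'
#' The MAD is the raw median absolute deviation from the median (no
#' 1.4826 normal-consistency factor): it is the spread number quoted in
#' brackets next to medians in distribution-plot legends.
#'
#' @param series a `distance_series` or numeric vector.
#' @return List with `median` and `mad`, in the series units.
#' @export
summarize_series <- function(series) {
  v <- .series_values(series)
  if (length(v) == 0L) stop("empty series")
  list(median = median(v), mad = mad(v, constant = 1))
}

#' Fraction of frames at or below a distance cutoff
#'
#' Operationalises interaction persistence ("occupancy"): the fraction of
#' frames in which the contact is formed.
#'
#' @param series a `distance_series` or numeric vector.
#' @param cutoff_nm non-negative cutoff; a frame counts iff value <= cutoff.
#' @return Fraction in \[0, 1\].
#' @export
occupancy <- function(series, cutoff_nm) {
  if (!is.numeric(cutoff_nm) || cutoff_nm < 0) {
    stop("cutoff must be a non-negative distance")
  }
  v <- .series_values(series)
  if (length(v) == 0L) stop("empty series")
  mean(v <= cutoff_nm)
}

#' Sample correlation of two matched series
#'
#' @param series_a,series_b `distance_series` or numeric vectors of equal
#'   length >= 3.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(series_a, series_b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  a <- .series_values(series_a)
  b <- .series_values(series_b)
  if (length(a) != length(b)) stop("series length mismatch")
  if (length(a) < 3L) stop("need at least 3 paired observations")
  if (sd(a) == 0 || sd(b) == 0) {
    stop("undefined correlation: a series has zero variance")
  }
  cor(a, b, method = method)
}

# Scott's rule bandwidth per axis: sigma * n^(-1/6) for a 2D product
# Gaussian kernel.
.scott_bandwidth <- function(x) sd(x) * length(x)^(-1 / 6)

#' 2D Gaussian-kernel density estimate of a distance pair
#'
#' Product-Gaussian KDE on a regular grid spanning the data range plus
#' `span_bw` bandwidths on each side, with the sample Pearson correlation
#' attached. Bandwidths default to Scott's rule per axis.
#'
#' @param series_a,series_b matched `distance_series` or numeric vectors of
#'   equal length >= 10.
#' @param bandwidth `"scott"` or a numeric length-2 vector of kernel
#'   standard deviations (axis units).
#' @param n grid resolution per axis.
#' @param span_bw grid margin in bandwidths beyond the data range (>= 4 so
#'   the grid captures essentially all kernel mass).
#' @return A `density2d`: list with `x`, `y` (grid coordinates), `z`
#'   (density grid), `bandwidth`, `pearson_r`.
#' @export
kde2d_density <- function(series_a, series_b, bandwidth = "scott",
                          n = 128, span_bw = 4) {
  a <- .series_values(series_a)
  b <- .series_values(series_b)
  if (length(a) != length(b)) stop("series length mismatch")
  if (length(a) < 10L) stop("need at least 10 paired observations")
  if (identical(bandwidth, "scott")) {
    bw <- c(.scott_bandwidth(a), .scott_bandwidth(b))
  } else {
    bw <- rep(as.numeric(bandwidth), length.out = 2L)
  }
  if (any(!is.finite(bw)) || any(bw <= 0)) {
    stop("bandwidth error: degenerate sample (zero spread)")
  }
  lims <- c(range(a) + c(-1, 1) * span_bw * bw[1],
            range(b) + c(-1, 1) * span_bw * bw[2])
  # MASS::kde2d divides its h argument by 4 to get the kernel sd
  k <- MASS::kde2d(a, b, h = 4 * bw, n = n, lims = lims)
  structure(
    list(x = k$x, y = k$y, z = k$z, bandwidth = bw,
         pearson_r = pearson_r(a, b)),
    class = "density2d"
  )
}

#' @export
print.density2d <- function(x, ...) {
  cat(sprintf("density2d: %d x %d grid, bandwidth (%.4g, %.4g), r = %.3f\n",
              length(x$x), length(x$y), x$bandwidth[1], x$bandwidth[2],
              x$pearson_r))
  invisible(x)
}

#' Trapezoidal integral of a 2D density grid
#'
#' @param density a `density2d`.
#' @return The integral over the grid (close to 1 when the grid spans the
#'   kernel mass).
#' @export
density2d_integral <- function(density) {
  rowint <- apply(density$z, 1, function(row) pracma::trapz(density$y, row))
  pracma::trapz(density$x, rowint)
}

#' Write a 2D density grid as TSV
#' @param density a `density2d`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_density2d <- function(density, path) {
  df <- as.data.frame(density$z)
  names(df) <- sprintf("y_%.6g", density$y)
  df <- cbind(x = density$x, df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Render a 2D density with its correlation in the legend
#' @param density a `density2d`.
#' @param path output PNG path.
#' @param xlab,ylab axis labels.
#' @return `path`, invisibly.
#' @export
plot_density2d <- function(density, path, xlab = "d (nm)", ylab = "d (nm)") {
  png(path, width = 700, height = 700, res = 110)
  op <- par(mar = c(5, 5, 2, 1))
  on.exit({ par(op); dev.off() })
  image(density$x, density$y, density$z,
        col = rev(hcl.colors(64, "Blues")), xlab = xlab, ylab = ylab)
  legend("topright", bty = "n",
         legend = sprintf("r = %.2f", density$pearson_r))
  box()
  invisible(path)
}

#' Plot a distance distribution with median [MAD] legend
#' @param series a `distance_series`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
plot_distance_distribution <- function(series, path) {
  png(path, width = 700, height = 500, res = 110)
  op <- par(mar = c(5, 5, 2, 1))
  on.exit({ par(op); dev.off() })
  d <- stats::density(series$values)
  plot(d, main = series$label %||% "distance", xlab = "distance (nm)")
  legend("topright", bty = "n",
         legend = sprintf("%.2f [%.2f] nm", series$summary$median,
                          series$summary$mad))
  invisible(path)
}
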