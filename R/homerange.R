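#' Minimum convex polygon (100% MCP) home range
#'
#' Area of the convex hull of all position fixes. Duplicate points are
#' ignored; collinear point sets have zero hull area and are flagged with
#' status \code{"linear"}, matching the convention of reporting such fish as
#' "Linear" rather than as a numeric area.
#'
#' @param x,y fix coordinates (m); \code{x} may be a 2-column matrix or a
#'   data frame with \code{x}, \code{y}.
#' @return A \code{homerange} object with \code{method = "MCP"},
#'   \code{level = 100}, \code{area} (km2), \code{status} (\code{"ok"} or
#'   \code{"linear"}), \code{n_points}, and the hull vertices.
#' @export
#' @examples
#' mcp_area(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))$area  # 1 km2
mcp_area <- function(x, y = NULL) {
  xy <- as_xy(x, y)
  if (nrow(xy) < 1) stop("need at least one point")
  dup <- duplicated(complex(real = xy[, 1], imaginary = xy[, 2]))
  xy <- xy[!dup, , drop = FALSE]
  status <- "ok"; area <- 0; hull <- xy
  if (nrow(xy) >= 3) {
    h <- grDevices::chull(xy[, 1], xy[, 2])
    hull <- xy[h, , drop = FALSE]
    area <- polygon_area(hull[, 1], hull[, 2]) / 1e6
  }
  if (area == 0) status <- "linear"
  structure(list(method = "MCP", level = 100, area = area,
                 status = status, n_points = nrow(xy), hull = hull),
            class = "homerange")
}

as_xy <- function(x, y) {
  if (is.data.frame(x)) {
    stopifnot(all(c("x", "y") %in% names(x)))
    cbind(x = x$x, y = x$y)
  } else if (is.matrix(x)) {
    colnames(x) <- c("x", "y")[seq_len(ncol(x))]
    x[, 1:2, drop = FALSE]
  } else cbind(x = x, y = y)
}

polygon_area <- function(px, py) {
  abs(sum(px * c(py[-1], py[1]) - c(px[-1], px[1]) * py)) / 2
}

#' @export
print.homerange <- function(x, ...) {
  if (x$method == "MCP") {
    cat(sprintf("MCP home range: %s (n = %d)\n",
                if (x$status == "linear") "Linear"
                else sprintf("%.3f km2", x$area), x$n_points))
  } else {
    cat(sprintf("%g%% KD home range: %s (n = %d, cell %g m)\n",
                x$level,
                if (x$status != "ok") x$status
                else sprintf("%.3f km2", x$area),
                x$n_points, x$grid_cell))
    if (!is.null(x$bandwidth))
      cat(sprintf("  bandwidth: h_xx %.0f, h_yy %.0f, h_xy %.0f m2\n",
                  x$bandwidth[1, 1], x$bandwidth[2, 2], x$bandwidth[1, 2]))
  }
  invisible(x)
}

#' @export
plot.homerange <- function(x, add = FALSE, col = "steelblue", ...) {
  if (x$method == "MCP") {
    if (!add) plot(x$hull, type = "n", asp = 1, xlab = "x (m)", ylab = "y (m)", ...)
    graphics::polygon(x$hull[, 1], x$hull[, 2], border = col)
  } else {
    if (is.null(x$density)) stop("density surface was not retained")
    graphics::contour(x$grid_x, x$grid_y, x$density,
                      levels = x$threshold, add = add,
                      drawlabels = FALSE, col = col, asp = 1, ...)
  }
  invisible(x)
}

# --- kernel density machinery ------------------------------------------------

# Bin points (with multiplicity) onto a cell-sized lattice.
bin_points <- function(xy, cell) {
  ix <- floor(xy[, 1] / cell); iy <- floor(xy[, 2] / cell)
  key <- complex(real = ix, imaginary = iy)
  uk <- unique(key)
  w <- tabulate(match(key, uk))
  ux <- Re(uk); uy <- Im(uk)
  list(ix = ux, iy = uy, w = as.numeric(w),
       cx = (ux + 0.5) * cell, cy = (uy + 0.5) * cell)
}

# Autocorrelation of binned weights via FFT: returns data frame of lattice
# offsets (in cells) with summed weight products sum_i sum_j w_i w_j at that
# offset (both signs included; offset 0 includes the i = j terms).
bin_autocorrelation <- function(bins) {
  ix <- bins$ix - min(bins$ix); iy <- bins$iy - min(bins$iy)
  m1 <- max(ix) + 1L; m2 <- max(iy) + 1L
  P1 <- stats::nextn(2L * m1, c(2, 3)); P2 <- stats::nextn(2L * m2, c(2, 3))
  W <- matrix(0, P1, P2)
  W[cbind(ix + 1L, iy + 1L)] <- bins$w
  F <- stats::fft(W)
  A <- Re(stats::fft(F * Conj(F), inverse = TRUE)) / (P1 * P2)
  # fold wrap-around indices to signed offsets
  keep <- which(A > max(A) * 1e-14, arr.ind = TRUE)
  dx <- keep[, 1] - 1L; dy <- keep[, 2] - 1L
  dx <- ifelse(dx > P1 / 2, dx - P1, dx)
  dy <- ifelse(dy > P2 / 2, dy - P2, dy)
  ok <- abs(dx) < m1 & abs(dy) < m2
  data.frame(dx = dx[ok], dy = dy[ok], a = A[keep][ok])
}

# Bivariate normal density with covariance Sigma at offsets (dx, dy).
phi2 <- function(dx, dy, Sigma) {
  det <- Sigma[1, 1] * Sigma[2, 2] - Sigma[1, 2]^2
  if (det <= 0) return(rep(NaN, length(dx)))
  i11 <- Sigma[2, 2] / det; i22 <- Sigma[1, 1] / det; i12 <- -Sigma[1, 2] / det
  q <- i11 * dx^2 + 2 * i12 * dx * dy + i22 * dy^2
  exp(-0.5 * q) / (2 * pi * sqrt(det))
}

# Smoothed-cross-validation criterion for bandwidth matrix H given pilot G:
# SCV(H) = (4 pi)^-1 n^-1 |H|^-1/2
#          + n^-2 sum_ij [phi_{2H+2G} - 2 phi_{H+2G} + phi_{2G}](Xi - Xj)
scv_criterion <- function(H, G, ac, n, cell) {
  detH <- H[1, 1] * H[2, 2] - H[1, 2]^2
  if (!is.finite(detH) || detH <= 0) return(Inf)
  dx <- ac$dx * cell; dy <- ac$dy * cell
  term <- phi2(dx, dy, 2 * H + 2 * G) - 2 * phi2(dx, dy, H + 2 * G) +
    phi2(dx, dy, 2 * G)
  1 / (4 * pi * n * sqrt(detH)) + sum(ac$a * term) / n^2
}

chol_to_H <- function(p) {
  L <- matrix(c(exp(p[1]), p[3], 0, exp(p[2])), 2, 2)
  L %*% t(L)
}

# Select a full bandwidth matrix by smoothed cross-validation on binned data.
select_bandwidth_scv <- function(bins, n, cell) {
  mu <- c(sum(bins$w * bins$cx), sum(bins$w * bins$cy)) / n
  S <- matrix(0, 2, 2)
  S[1, 1] <- sum(bins$w * (bins$cx - mu[1])^2) / n
  S[2, 2] <- sum(bins$w * (bins$cy - mu[2])^2) / n
  S[1, 2] <- S[2, 1] <- sum(bins$w * (bins$cx - mu[1]) * (bins$cy - mu[2])) / n
  detS <- S[1, 1] * S[2, 2] - S[1, 2]^2
  if (!is.finite(detS) || detS <= 0)
    return(list(H = NULL, status = "failed"))
  G <- n^(-1 / 3) * S               # normal-scale pilot, d = 2
  ac <- bin_autocorrelation(bins)
  H0 <- n^(-1 / 3) * S              # normal-scale start
  p0 <- c(log(sqrt(H0[1, 1])), 0, 0) # lower-triangular Cholesky parameters
  p0[3] <- H0[1, 2] / sqrt(H0[1, 1])
  p0[2] <- log(sqrt(H0[2, 2] - p0[3]^2))
  opt <- tryCatch(
    stats::optim(p0, function(p) scv_criterion(chol_to_H(p), G, ac, n, cell),
                 method = "Nelder-Mead",
                 control = list(maxit = 400, reltol = 1e-7)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value))
    return(list(H = NULL, status = "failed"))
  H <- chol_to_H(opt$par)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  # degenerate optimum: bandwidth collapsed to (sub-)cell scale or blown up
  if (min(ev) < (cell / 4)^2 || max(ev) > 100 * max(S[1, 1], S[2, 2]))
    return(list(H = H, status = "failed"))
  list(H = H, status = "ok")
}

# Evaluate the Gaussian-kernel density on the binning lattice by FFT
# convolution of the bin weights with the kernel.
kde_grid <- function(bins, H, n, cell) {
  sd_max <- sqrt(max(eigen(H, symmetric = TRUE, only.values = TRUE)$values))
  pad <- ceiling(4 * sd_max / cell) + 1L
  ix <- bins$ix - min(bins$ix) + pad; iy <- bins$iy - min(bins$iy) + pad
  m1 <- max(ix) + pad + 1L; m2 <- max(iy) + pad + 1L
  P1 <- stats::nextn(m1 + 2L * pad, c(2, 3)); P2 <- stats::nextn(m2 + 2L * pad, c(2, 3))
  W <- matrix(0, P1, P2)
  W[cbind(ix + 1L, iy + 1L)] <- bins$w
  kx <- c(0:(P1 %/% 2), -((P1 - P1 %/% 2 - 1):1)) * cell
  ky <- c(0:(P2 %/% 2), -((P2 - P2 %/% 2 - 1):1)) * cell
  K <- outer(kx, ky, function(a, b) phi2(a, b, H))
  dens <- Re(stats::fft(stats::fft(W) * stats::fft(K), inverse = TRUE)) /
    (P1 * P2) / n
  dens[dens < 0] <- 0
  gx <- (min(bins$ix) - pad + seq_len(P1) - 1 + 0.5) * cell
  gy <- (min(bins$iy) - pad + seq_len(P2) - 1 + 0.5) * cell
  list(x = gx, y = gy, z = dens)
}

# Smallest density threshold whose superlevel set holds `level` fraction of
# the total mass; returns area (km2) and the threshold.
volume_contour_area <- function(dens, cell, level) {
  v <- sort(as.numeric(dens$z), decreasing = TRUE)
  mass <- v * (cell^2)
  cum <- cumsum(mass)
  tot <- cum[length(cum)]
  k <- which(cum >= level * tot)[1]
  list(area = k * cell^2 / 1e6, threshold = v[k])
}

#' Kernel-density home range with volume contours
#'
#' Gaussian-kernel utilization distribution on a square grid, with a full
#' (unconstrained) 2x2 bandwidth matrix selected by smoothed
#' cross-validation (SCV), and home-range areas taken as the smallest set of
#' grid cells containing the requested fraction of the density volume. The
#' SCV objective is evaluated on binned data (bin width = the analysis
#' grid), which keeps the cost flat in the number of fixes even with the
#' massive duplication produced by passive arrays; degenerate optima (all
#' mass at one or two sites) are reported as failures rather than areas.
#'
#' @param x,y fix coordinates (m), as in [mcp_area()].
#' @param levels volume percentages to contour (default 50, 90, 95).
#' @param cell analysis grid size (m).
#' @param bandwidth \code{"scv"} (default), or a fixed 2x2 bandwidth matrix
#'   (m2), or a single number taken as an isotropic standard deviation (m).
#' @param keep_density retain the density surface (for plotting)?
#' @return A list of \code{homerange} objects, one per level, each with
#'   \code{method = "KD"}, \code{area} (km2), \code{bandwidth},
#'   \code{grid_cell} and \code{status} (\code{"ok"} or \code{"failed"}).
#'   Failed fits report \code{NA} area at every level.
#' @export
#' @examples
#' set.seed(1)
#' pts <- matrix(rnorm(4000, sd = 300), ncol = 2)
#' hr <- kd_homerange(pts, bandwidth = 60)
#' hr[["95"]]$area
kd_homerange <- function(x, y = NULL, levels = c(50, 90, 95), cell = 20,
                         bandwidth = "scv", keep_density = FALSE) {
  xy <- as_xy(x, y)
  n <- nrow(xy)
  fail <- function(status) {
    out <- lapply(levels, function(lv)
      structure(list(method = "KD", level = lv, area = NA_real_,
                     status = status, n_points = n, bandwidth = NULL,
                     grid_cell = cell), class = "homerange"))
    names(out) <- as.character(levels)
    out
  }
  if (n < 5 || nrow(unique(xy)) < 5) return(fail("failed"))
  bins <- bin_points(xy, cell)
  if (identical(bandwidth, "scv")) {
    sel <- select_bandwidth_scv(bins, n, cell)
    if (sel$status != "ok") return(fail("failed"))
    H <- sel$H
  } else if (is.matrix(bandwidth)) {
    H <- bandwidth
  } else {
    H <- diag(as.numeric(bandwidth)^2, 2)
  }
  dens <- kde_grid(bins, H, n, cell)
  out <- lapply(levels, function(lv) {
    vc <- volume_contour_area(dens, cell, lv / 100)
    structure(list(method = "KD", level = lv, area = vc$area,
                   status = "ok", n_points = n, bandwidth = H,
                   grid_cell = cell, threshold = vc$threshold,
                   grid_x = if (keep_density) dens$x,
                   grid_y = if (keep_density) dens$y,
                   density = if (keep_density) dens$z),
              class = "homerange")
  })
  names(out) <- as.character(levels)
  out
}

#' Cumulative home-range area over tracking time
#'
#' Applies a home-range estimator to all fixes accumulated up to each step
#' boundary (default: months of 365/12 days), reporting the area and the
#' percentage of the final estimate — the standard asymptote diagnostic.
#'
#' @param fixes data frame with \code{x}, \code{y} and either \code{time}
#'   (s) or \code{interval}.
#' @param method \code{"mcp"} or \code{"kd"} (95% level).
#' @param step step length in seconds, or \code{"month"} (365/12 days).
#' @param interval interval length (s) used when only \code{interval} is
#'   present.
#' @param ... passed to the estimator.
#' @return Data frame with \code{elapsed} (s), \code{area} (km2, \code{NA}
#'   where the estimator failed) and \code{pct_final}.
#' @export
cumulative_area_curve <- function(fixes, method = c("mcp", "kd"),
                                  step = "month", interval = 300, ...) {
  method <- match.arg(method)
  tm <- if ("time" %in% names(fixes)) fixes$time else fixes$interval * interval
  if (identical(step, "month")) step <- 365 * 86400 / 12
  span <- max(tm) - min(tm)
  if (span < step) stop("track spans fewer than two steps")
  bounds <- seq(min(tm) + step, max(tm) + step - 1e-9, by = step)
  est <- function(sub) {
    if (method == "mcp") {
      hr <- mcp_area(sub)
      if (hr$status == "ok") hr$area else NA_real_
    } else {
      hr <- kd_homerange(sub, levels = 95, ...)[["95"]]
      if (hr$status == "ok") hr$area else NA_real_
    }
  }
  area <- vapply(bounds, function(b) est(fixes[tm <= b, , drop = FALSE]),
                 numeric(1))
  final <- area[length(area)]
  data.frame(elapsed = bounds - min(tm), area = area,
             pct_final = if (!is.na(final) && final > 0)
               100 * area / final else NA_real_)
}

#' Classify a cumulative-area curve as asymptotic
#'
#' A curve is called \code{"Yes"} (asymptotic) when the relative area
#' increase over the final step is below \code{tol_yes}, \code{"Maybe"}
#' below \code{tol_maybe}, otherwise \code{"No"}. The thresholds are an
#' explicit contract of this package; the literature offers no standard.
#'
#' @param curve data frame from [cumulative_area_curve()].
#' @param tol_yes,tol_maybe relative-increase thresholds (fractions).
#' @return \code{"Yes"}, \code{"Maybe"} or \code{"No"}.
#' @export
classify_asymptote <- function(curve, tol_yes = 0.05, tol_maybe = 0.15) {
  a <- curve$area[!is.na(curve$area)]
  k <- length(a)
  if (k < 2) return("No")
  prev <- a[k - 1]; last <- a[k]
  rel <- if (prev > 0) (last - prev) / prev else if (last == 0) 0 else Inf
  if (rel < tol_yes) "Yes" else if (rel < tol_maybe) "Maybe" else "No"
}
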