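#' Synthetic staggered receiver grid
#'
#' Deterministic staggered grid of receivers centered on the origin, the
#' package's stand-in for a field array (real array coordinates are not
#' distributed with the package). The default 4 x 8 grid at 600 m spacing
#' gives 32 receivers covering roughly 30 km2 of acoustic footprint.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param spacing receiver spacing (m); odd rows are offset by half a
#'   spacing (staggered).
#' @param depth constant or per-receiver depth (m), metadata only.
#' @return Data frame with \code{receiver_id}, \code{x}, \code{y},
#'   \code{depth}.
#' @export
#' @examples
#' nrow(receiver_grid(4, 8, 600))  # 32
receiver_grid <- function(n_rows = 4, n_cols = 8, spacing = 600, depth = 15) {
  if (spacing <= 0) stop("spacing must be positive")
  stopifnot(n_rows >= 1, n_cols >= 1)
  row <- rep(seq_len(n_rows), each = n_cols)
  col <- rep(seq_len(n_cols), times = n_rows)
  x <- (col - 1) * spacing + ifelse(row %% 2 == 0, spacing / 2, 0)
  y <- (row - 1) * spacing
  data.frame(receiver_id = sprintf("R%02d", seq_along(x)),
             x = x - mean(range(x)), y = y - mean(range(y)),
             depth = rep_len(depth, length(x)),
             stringsAsFactors = FALSE)
}

#' Acoustic detection model
#'
#' Detection probability versus distance and the effective tag ping rate.
#' The probability curve is logistic in distance,
#' \deqn{p(d) = p0 / (1 + \exp((d - d50)/slope)),}
#' monotone non-increasing with \code{p(d) -> 0} as \code{d -> Inf}. The
#' default ping interval of 105 s is the mean of a uniform 30-180 s random
#' tag delay.
#'
#' @param ping_interval mean time between tag transmissions (s).
#' @param p0 detection probability at distance zero (<= 1).
#' @param d50 distance of 50% detection probability (m).
#' @param slope logistic slope scale (m).
#' @return An object of class \code{detection_model}.
#' @export
detection_model <- function(ping_interval = 105, p0 = 1, d50 = 300, slope = 50) {
  stopifnot(ping_interval > 0, p0 > 0, p0 <= 1, d50 > 0, slope > 0)
  structure(list(ping_interval = ping_interval, p0 = p0,
                 d50 = d50, slope = slope),
            class = "detection_model")
}

#' @export
print.detection_model <- function(x, ...) {
  cat(sprintf(
    "Detection model: ping %g s, p(d) = %g / (1 + exp((d - %g)/%g))\n",
    x$ping_interval, x$p0, x$d50, x$slope))
  invisible(x)
}

#' Detection probability at distance
#'
#' @param model a [detection_model].
#' @param distance distance(s) in m.
#' @return Probability in \[0, 1\], non-increasing in distance.
#' @export
detection_prob <- function(model, distance) {
  model$p0 / (1 + exp((distance - model$d50) / model$slope))
}

#' Expected detections in one interval
#'
#' Expected number of detections a receiver registers from a tag held at a
#' fixed distance over one interval: the interval length divided by the ping
#' rate, multiplied by the probability of detection at that distance.
#'
#' @param interval interval length (s).
#' @param model a [detection_model].
#' @param distance tag-receiver distance(s), m.
#' @return Expected (fractional) detection count(s).
#' @export
#' @examples
#' m <- detection_model(ping_interval = 105)
#' expected_detections(300, m, 0)  # 300/105 * p(0)
expected_detections <- function(interval, model, distance) {
  if (interval <= 0) stop("interval must be positive")
  (interval / model$ping_interval) * detection_prob(model, distance)
}

#' Simulated detection log for a track ("Sim-Detect" generation)
#'
#' Computes, for every interval of a simulated track and every receiver, the
#' expected number of detections, keeping records with expected counts above
#' a small threshold. Counts are deterministic expectations (the model's
#' formula); set \code{poisson = TRUE} for a stochastic Poisson draw around
#' them.
#'
#' @param track data frame with \code{interval}, \code{x}, \code{y} (one row
#'   per interval), as produced by [simulate_tracks()].
#' @param array receiver table (\code{receiver_id}, \code{x}, \code{y}).
#' @param model a [detection_model].
#' @param interval interval length (s).
#' @param threshold drop records with expected count below this.
#' @param poisson draw integer counts from Poisson(expected)?
#' @return Data frame with \code{interval}, \code{receiver_id},
#'   \code{expected_count} (plus \code{count} if \code{poisson}).
#' @export
simulate_detections <- function(track, array, model, interval = 300,
                                threshold = 1e-6, poisson = FALSE) {
  # tracks dwell on few distinct cells; compute per distinct position
  key <- complex(real = track$x, imaginary = track$y)
  uk <- unique(key)
  pos_of <- match(key, uk)
  ux <- Re(uk); uy <- Im(uk)
  dmat <- sqrt(outer(ux, array$x, "-")^2 + outer(uy, array$y, "-")^2)
  emat <- expected_detections(interval, model, dmat) # n_pos x n_recv
  emat[emat < threshold] <- 0
  hit <- which(emat > 0, arr.ind = TRUE)
  if (nrow(hit) == 0)
    return(data.frame(interval = integer(), receiver_id = character(),
                      expected_count = numeric(), stringsAsFactors = FALSE))
  per_pos <- split(seq_len(nrow(hit)), hit[, 1])
  rows <- lapply(seq_along(ux), function(p) {
    h <- per_pos[[as.character(p)]]
    if (is.null(h)) return(NULL)
    ints <- track$interval[pos_of == p]
    data.frame(interval = rep(ints, each = length(h)),
               receiver_id = rep(array$receiver_id[hit[h, 2]], length(ints)),
               expected_count = rep(emat[cbind(hit[h, 1], hit[h, 2])],
                                    length(ints)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$interval, out$receiver_id), , drop = FALSE]
  rownames(out) <- NULL
  if (poisson) out$count <- stats::rpois(nrow(out), out$expected_count)
  out
}

#' Classify receivers as core or peripheral
#'
#' A receiver is peripheral when it lies on the convex hull of the array
#' (i.e. it is not completely surrounded by other receivers), including
#' receivers sitting on a hull edge between two vertices. Degenerate arrays
#' (fewer than 3 receivers, or all collinear) are entirely peripheral.
#'
#' @param array receiver table (\code{receiver_id}, \code{x}, \code{y}).
#' @param tol distance tolerance (m) for lying on a hull edge.
#' @return Named character vector, \code{"core"} or \code{"peripheral"} per
#'   receiver id.
#' @export
#' @examples
#' g <- expand.grid(x = 1:3 * 100, y = 1:3 * 100)
#' g$receiver_id <- paste0("r", 1:9)
#' table(classify_peripheral(g))  # 1 core, 8 peripheral
classify_peripheral <- function(array, tol = 1e-6) {
  n <- nrow(array)
  out <- rep("peripheral", n)
  names(out) <- array$receiver_id
  if (n < 3) return(out)
  h <- grDevices::chull(array$x, array$y)
  if (length(h) < 3) return(out) # collinear
  hx <- array$x[h]; hy <- array$y[h]
  on_hull <- vapply(seq_len(n), function(i) {
    px <- array$x[i]; py <- array$y[i]
    for (k in seq_along(h)) {
      k2 <- if (k == length(h)) 1L else k + 1L
      d <- point_segment_distance(px, py, hx[k], hy[k], hx[k2], hy[k2])
      if (d <= tol) return(TRUE)
    }
    FALSE
  }, logical(1))
  out[!on_hull] <- "core"
  out
}

point_segment_distance <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  L2 <- vx^2 + vy^2
  if (L2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
  sqrt((px - ax - t * vx)^2 + (py - ay - t * vy)^2)
}
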