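#' Movement parameters for the three-step home-range movement kernel
#'
#' Bundle the species-level parameters of the individual-based movement model:
#' the probability \eqn{\psi} of making a discernible move in one time step,
#' the mean \eqn{\lambda} of the exponential distribution of move distances,
#' and the von Mises concentration \eqn{\kappa} of movement directions taken
#' relative to the bearing towards the home-range center.
#'
#' @param psi probability of a discernible move per interval, in \[0, 1\].
#' @param lambda_mean mean of the exponential move-distance distribution (m).
#' @param kappa von Mises concentration of turning angles (dimensionless,
#'   >= 0); larger values mean stronger affinity to the home-range center.
#' @param max_move upper bound on a single move (m); draws beyond it are
#'   clamped, not resampled.
#' @param min_move suppression threshold (m); draws below it are treated as
#'   "no move" (beneath the spatial resolution of one grid cell).
#' @param interval time step (s).
#' @param species optional species label carried through reports.
#' @return An object of class \code{movement_params}.
#' @seealso [species_params()] for the packaged defaults.
#' @export
#' @examples
#' movement_params(psi = 0.008, lambda_mean = 561, kappa = 3.67)
movement_params <- function(psi, lambda_mean, kappa, max_move = 6000,
                            min_move = 200, interval = 300, species = NA_character_) {
  stopifnot(is.numeric(psi), length(psi) == 1L, psi >= 0, psi <= 1,
            is.numeric(lambda_mean), lambda_mean > 0,
            is.numeric(kappa), kappa >= 0,
            min_move > 0, min_move < max_move, interval > 0)
  structure(list(psi = psi, lambda_mean = lambda_mean, kappa = kappa,
                 max_move = max_move, min_move = min_move,
                 interval = interval, species = species),
            class = "movement_params")
}

#' @export
print.movement_params <- function(x, ...) {
  cat("Movement parameters",
      if (!is.na(x$species)) paste0("(", x$species, ")"), "\n")
  cat(sprintf("  psi    = %.4f  (move probability per %g-s interval)\n",
              x$psi, x$interval))
  cat(sprintf("  lambda = %.1f m  (mean move distance)\n", x$lambda_mean))
  cat(sprintf("  kappa  = %.2f  (center-bias concentration)\n", x$kappa))
  cat(sprintf("  moves clamped at %g m, suppressed below %g m\n",
              x$max_move, x$min_move))
  invisible(x)
}

#' Packaged species parameter sets
#'
#' Movement parameters for the three exploited Dry Tortugas reef fishes the
#' model was built around. Values are per 5-minute interval; distances in
#' meters.
#'
#' @param species one of \code{"red_grouper"}, \code{"black_grouper"},
#'   \code{"mutton_snapper"}, or \code{"all"} for a named list of all three.
#' @return A \code{movement_params} object (or list of them for
#'   \code{"all"}).
#' @export
#' @examples
#' species_params("red_grouper")
species_params <- function(species = c("red_grouper", "black_grouper",
                                       "mutton_snapper", "all")) {
  species <- match.arg(species)
  tab <- list(
    red_grouper    = c(psi = 0.0080, lambda = 561, kappa = 3.67),
    black_grouper  = c(psi = 0.0056, lambda = 456, kappa = 1.19),
    mutton_snapper = c(psi = 0.0576, lambda = 608, kappa = 3.20)
  )
  mk <- function(nm) {
    p <- tab[[nm]]
    movement_params(psi = p[["psi"]], lambda_mean = p[["lambda"]],
                    kappa = p[["kappa"]], species = nm)
  }
  if (species == "all") {
    out <- lapply(names(tab), mk)
    names(out) <- names(tab)
    out
  } else mk(species)
}

#' Quadrant-aware heading between two points
#'
#' Bearing of \code{target} as seen from \code{origin}, measured
#' counter-clockwise from the positive x axis, in \eqn{(-\pi, \pi]}.
#'
#' @param origin,target numeric length-2 vectors (x, y) in meters.
#' @return Angle in radians.
#' @export
heading <- function(origin, target) {
  dx <- target[1] - origin[1]
  dy <- target[2] - origin[2]
  if (dx == 0 && dy == 0) stop("undefined heading: coincident points")
  atan2(dy, dx)
}

#' Euclidean displacement between two points
#'
#' @param origin,dest numeric length-2 vectors (x, y) in meters.
#' @return Nonnegative distance in meters; zero iff the points coincide.
#' @export
displacement <- function(origin, dest) {
  sqrt((dest[1] - origin[1])^2 + (dest[2] - origin[2])^2)
}

#' Von Mises density of movement directions
#'
#' Density of the direction \code{theta} under a von Mises distribution with
#' mean direction \code{theta_bar} (the bearing towards the home-range
#' center) and concentration \code{kappa}. \code{kappa = 0} is the uniform
#' circular distribution; the density is maximal at \code{theta_bar}, so
#' higher \code{kappa} means stronger home-range affinity.
#'
#' @param theta angle(s), radians.
#' @param theta_bar mean direction, radians.
#' @param kappa concentration, >= 0.
#' @return Density value(s); integrates to 1 over any \eqn{2\pi} interval.
#' @export
#' @examples
#' dvonmises(0, 0, 0)        # 1 / (2 * pi)
#' integrate(dvonmises, -pi, pi, theta_bar = 0.3, kappa = 3.67)
dvonmises <- function(theta, theta_bar, kappa) {
  if (kappa < 0) stop("kappa must be nonnegative")
  # exp(kappa * (cos(.) - 1)) / (2 pi I0(kappa) e^-kappa) is stable for large kappa
  exp(kappa * (cos(theta - theta_bar) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Sample movement directions from a von Mises distribution
#'
#' Draws via the Best-Fisher rejection algorithm; falls back to the uniform
#' circular distribution for vanishing concentration.
#'
#' @param n number of draws.
#' @param theta_bar mean direction (bearing to the home-range center), rad.
#' @param kappa concentration, >= 0.
#' @return Angles in \eqn{(-\pi, \pi]}.
#' @export
sample_turn <- function(n, theta_bar = 0, kappa = 0) {
  if (kappa < 0) stop("kappa must be nonnegative")
  if (kappa < 1e-9) return(stats::runif(n, -pi, pi))
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- max(16L, ceiling((n - got) * 1.4))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    acc <- sign(u3[ok] - 0.5) * acos(pmin(1, pmax(-1, f[ok])))
    take <- min(length(acc), n - got)
    if (take > 0) out[(got + 1):(got + take)] <- acc[seq_len(take)]
    got <- got + take
  }
  wrap_angle(out + theta_bar)
}

#' Wrap angles into (-pi, pi]
#' @param theta angles, radians.
#' @return Wrapped angles.
#' @keywords internal
wrap_angle <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

#' Draw one candidate move of the three-step movement kernel
#'
#' Implements the per-interval movement decision: with probability
#' \code{1 - psi} the fish does not move; otherwise a distance is drawn from
#' the exponential distribution with mean \code{lambda_mean}, clamped at
#' \code{max_move}, and suppressed (treated as "no move") below
#' \code{min_move}. The movement direction is drawn from a von Mises
#' distribution centered on the bearing from \code{current} to \code{center};
#' when the fish sits exactly at its center the bearing is undefined and the
#' direction is uniform.
#'
#' @param params a [movement_params] object.
#' @param current current position, length-2 (m).
#' @param center home-range center, length-2 (m).
#' @return \code{NULL} for "no move", otherwise a list with elements
#'   \code{origin}, \code{dest}, \code{d} (drawn distance after clamping),
#'   \code{theta} (movement direction) and \code{theta_bar} (bearing to
#'   center, \code{NA} when drawn uniformly).
#' @export
sample_move <- function(params, current, center) {
  stopifnot(inherits(params, "movement_params"))
  if (stats::runif(1) >= params$psi) return(NULL)
  d <- min(stats::rexp(1, 1 / params$lambda_mean), params$max_move)
  if (d < params$min_move) return(NULL)
  at_center <- all(current == center)
  theta_bar <- if (at_center) NA_real_ else heading(current, center)
  theta <- if (at_center) stats::runif(1, -pi, pi)
           else sample_turn(1, theta_bar, params$kappa)
  dest <- current + d * c(cos(theta), sin(theta))
  list(origin = current, dest = dest, d = d,
       theta = theta, theta_bar = theta_bar)
}
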