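#' Extract discernible moves from a position-fix series
#'
#' A move is any pair of consecutive fixes separated by at least
#' \code{min_move} meters. For each move the bearing to the home-range
#' center (\code{theta_bar}), the movement direction (\code{theta}), and the
#' wrapped turning angle relative to the center bearing are recorded. The
#' center defaults to the arithmetic centroid of all fixes.
#'
#' @param fixes data frame with columns \code{x} and \code{y}, ordered in
#'   time, one row per interval.
#' @param center length-2 position, or \code{"centroid"} (default) for the
#'   arithmetic mean of the fixes; \code{"trimmed"} uses a 10% trimmed mean.
#' @param min_move suppression threshold (m).
#' @return List with \code{moves} (data frame: \code{d_prev},
#'   \code{d_centroid}, \code{theta}, \code{theta_bar}, \code{turn_rel}),
#'   \code{psi_hat} (moves / intervals), \code{n_intervals} and
#'   \code{center}.
#' @export
extract_moves <- function(fixes, center = "centroid", min_move = 200) {
  empty <- list(moves = data.frame(d_prev = numeric(), d_centroid = numeric(),
                                   theta = numeric(), theta_bar = numeric(),
                                   turn_rel = numeric()),
                psi_hat = NA_real_, n_intervals = nrow(fixes),
                center = c(NA_real_, NA_real_))
  if (nrow(fixes) < 2) return(empty)
  if (identical(center, "centroid")) {
    center <- c(mean(fixes$x), mean(fixes$y))
  } else if (identical(center, "trimmed")) {
    center <- c(mean(fixes$x, trim = 0.1), mean(fixes$y, trim = 0.1))
  }
  dx <- diff(fixes$x); dy <- diff(fixes$y)
  d <- sqrt(dx^2 + dy^2)
  mv <- which(d >= min_move)
  n_int <- nrow(fixes) - 1L
  if (length(mv) == 0) {
    empty$psi_hat <- 0; empty$n_intervals <- n_int; empty$center <- center
    return(empty)
  }
  ox <- fixes$x[mv]; oy <- fixes$y[mv]
  theta <- atan2(dy[mv], dx[mv])
  theta_bar <- atan2(center[2] - oy, center[1] - ox)
  moves <- data.frame(
    d_prev = d[mv],
    d_centroid = sqrt((center[1] - ox)^2 + (center[2] - oy)^2),
    theta = theta, theta_bar = theta_bar,
    turn_rel = wrap_angle(theta - theta_bar))
  list(moves = moves, psi_hat = length(mv) / n_int,
       n_intervals = n_int, center = center)
}

#' Maximum-likelihood exponential fit to move distances
#'
#' The MLE of the exponential mean is the sample mean; with a positive
#' \code{truncation} the distances are treated as left-truncated at that
#' value (memorylessness: mean = truncation + lambda), which matches move
#' records filtered at a minimum displacement.
#'
#' @param distances positive move distances (m).
#' @param truncation left-truncation threshold (m), subtracted before the
#'   mean is taken.
#' @return List with \code{lambda}, \code{se} (= lambda/sqrt(n)) and
#'   \code{n}.
#' @export
#' @examples
#' fit_exponential(c(100, 200, 300))$lambda  # 200
fit_exponential <- function(distances, truncation = 0) {
  if (length(distances) == 0) stop("no distances to fit")
  if (any(distances <= 0)) stop("distances must be positive")
  if (any(distances < truncation))
    stop("distances must be at least the truncation threshold")
  lambda <- mean(distances - truncation)
  list(lambda = lambda, se = lambda / sqrt(length(distances)),
       n = length(distances))
}

# A(kappa) = I1(kappa)/I0(kappa), the mean resultant length of a von Mises
A_vm <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

#' Maximum-likelihood von Mises fit to turning angles
#'
#' Mean direction by vector averaging; concentration by numerically
#' inverting the Bessel-function ratio \eqn{A(\kappa) = I_1/I_0 = \bar R}.
#' Small-sample bias corrections are not applied. A zero resultant length
#' gives \code{kappa = 0}; (near-)identical angles give a capped, flagged
#' estimate.
#'
#' @param angles turning angles (rad).
#' @param cap upper cap on the concentration estimate.
#' @return List with \code{kappa}, \code{se}, \code{mu} (mean direction),
#'   \code{Rbar}, \code{n} and logical \code{capped}.
#' @export
fit_von_mises <- function(angles, cap = 1e3) {
  n <- length(angles)
  if (n < 2) stop("need at least two angles")
  C <- mean(cos(angles)); S <- mean(sin(angles))
  Rbar <- sqrt(C^2 + S^2)
  mu <- atan2(S, C)
  if (Rbar < .Machine$double.eps)
    return(list(kappa = 0, se = NA_real_, mu = mu, Rbar = Rbar, n = n,
                capped = FALSE))
  capped <- FALSE
  if (A_vm(cap) <= Rbar) {
    kappa <- cap; capped <- TRUE
  } else {
    kappa <- stats::uniroot(function(k) A_vm(k) - Rbar,
                            lower = 1e-8, upper = cap, tol = 1e-10)$root
  }
  # asymptotic SE from the Fisher information of kappa:
  # var(kappa_hat) ~ 1 / (n * A'(kappa)), A'(k) = 1 - A/k - A^2
  Ak <- A_vm(kappa)
  Ap <- 1 - Ak^2 - ifelse(kappa > 0, Ak / kappa, 0.5)
  se <- if (Ap > 0) 1 / sqrt(n * Ap) else NA_real_
  list(kappa = kappa, se = se, mu = mu, Rbar = Rbar, n = n, capped = capped)
}

#' Fit the three-step movement model to a position-fix series
#'
#' The central fitting routine: extracts discernible moves from consecutive
#' fixes, then estimates the move probability \eqn{\psi} (moves per
#' interval), the exponential move-distance mean \eqn{\lambda} (with
#' optional left-truncation adjustment at the suppression threshold), and
#' the von Mises concentration \eqn{\kappa} of turning angles relative to
#' the bearing towards the home-range centroid.
#'
#' For simulated (complete) tracks every interval counts in \eqn{\psi}'s
#' denominator; for observation-style data where fixes exist only when a
#' fish was detected, the same convention applies to the supplied rows, so
#' pass one row per interval with detections.
#'
#' @param fixes data frame with \code{x}, \code{y} ordered in time, one row
#'   per interval.
#' @param center home-range center: \code{"centroid"} (default),
#'   \code{"trimmed"}, or a length-2 position.
#' @param min_move suppression threshold (m).
#' @param interval interval length (s).
#' @param truncate_lambda treat move distances as left-truncated at
#'   \code{min_move} when fitting \eqn{\lambda}?
#' @param kappa_min_dist moves starting closer to the center than this are
#'   excluded from the \eqn{\kappa} fit (their bearing to the center is
#'   undefined at the center and dominated by grid-quantisation noise
#'   nearby). Default: one cell diagonal, \code{sqrt(2) * min_move}.
#' @param species optional label.
#' @return An object of class \code{movefit} with components \code{psi},
#'   \code{lambda}, \code{lambda_se}, \code{kappa}, \code{kappa_se},
#'   \code{mu}, \code{n_intervals}, \code{n_moves}, \code{center},
#'   \code{moves}, and the call. Methods: \code{print}, \code{summary},
#'   \code{coef}, \code{simulate}.
#' @export
#' @examples
#' tr <- simulate_tracks(data.frame(fish_id = "f", home_x = 100, home_y = 100),
#'                       species_params("mutton_snapper"),
#'                       duration = 30 * 86400, seed = 2)$f
#' fit <- fit_movement(tr)
#' coef(fit)
fit_movement <- function(fixes, center = "centroid", min_move = 200,
                         interval = 300, truncate_lambda = TRUE,
                         kappa_min_dist = sqrt(2) * min_move,
                         species = NA_character_) {
  ex <- extract_moves(fixes, center = center, min_move = min_move)
  mv <- ex$moves
  if (nrow(mv) < 2) stop("fewer than two discernible moves; cannot fit")
  fe <- fit_exponential(mv$d_prev,
                        truncation = if (truncate_lambda) min_move else 0)
  far <- mv$turn_rel[mv$d_centroid >= kappa_min_dist]
  if (length(far) < 2) far <- mv$turn_rel
  fv <- fit_von_mises(far)
  structure(list(
    species = species,
    psi = ex$psi_hat,
    lambda = fe$lambda, lambda_se = fe$se,
    kappa = fv$kappa, kappa_se = fv$se, mu = fv$mu, Rbar = fv$Rbar,
    kappa_capped = fv$capped,
    n_intervals = ex$n_intervals, n_moves = nrow(mv),
    interval = interval, min_move = min_move,
    truncate_lambda = truncate_lambda,
    center = ex$center, moves = mv,
    call = match.call()), class = "movefit")
}

#' @export
print.movefit <- function(x, ...) {
  cat("Three-step movement model fit",
      if (!is.na(x$species)) paste0("(", x$species, ")"), "\n")
  cat(sprintf("  %d moves over %d intervals\n", x$n_moves, x$n_intervals))
  cat(sprintf("  psi    = %.4f\n", x$psi))
  cat(sprintf("  lambda = %.1f m (SE %.1f)%s\n", x$lambda, x$lambda_se,
              if (x$truncate_lambda)
                sprintf(", left-truncated at %g m", x$min_move) else ""))
  cat(sprintf("  kappa  = %.2f (SE %.2f)%s\n", x$kappa, x$kappa_se,
              if (x$kappa_capped) " [capped]" else ""))
  invisible(x)
}

#' @export
summary.movefit <- function(object, ...) {
  est <- data.frame(
    estimate = c(object$psi, object$lambda, object$kappa),
    se = c(sqrt(object$psi * (1 - object$psi) / object$n_intervals),
           object$lambda_se, object$kappa_se),
    row.names = c("psi", "lambda", "kappa"))
  out <- list(species = object$species, estimates = est,
              n_moves = object$n_moves, n_intervals = object$n_intervals,
              mean_direction = object$mu, Rbar = object$Rbar,
              center = object$center)
  class(out) <- "summary.movefit"
  out
}

#' @export
print.summary.movefit <- function(x, ...) {
  cat("Movement model parameter estimates",
      if (!is.na(x$species)) paste0("(", x$species, ")"), "\n")
  print(round(x$estimates, 4))
  cat(sprintf("n moves %d / intervals %d; mean turn direction %.3f rad, Rbar %.3f\n",
              x$n_moves, x$n_intervals, x$mean_direction, x$Rbar))
  cat(sprintf("home-range center (%.1f, %.1f)\n", x$center[1], x$center[2]))
  invisible(x)
}

#' @export
coef.movefit <- function(object, ...) {
  c(psi = object$psi, lambda = object$lambda, kappa = object$kappa)
}

#' Simulate tracks from a fitted movement model
#'
#' @param object a \code{movefit} object.
#' @param nsim number of fish to simulate.
#' @param seed optional seed.
#' @param duration simulated time (s).
#' @param center home-range center for the simulated fish; defaults to the
#'   fitted centroid.
#' @param ... unused.
#' @return As [simulate_tracks()]: a named list of track data frames.
#' @export
simulate.movefit <- function(object, nsim = 1, seed = NULL,
                             duration = 365 * 86400, center = NULL, ...) {
  if (is.null(center)) center <- object$center
  params <- movement_params(psi = object$psi, lambda_mean = object$lambda,
                            kappa = object$kappa,
                            min_move = object$min_move,
                            interval = object$interval,
                            species = object$species)
  ctr <- snap_to_cell(center)
  cohort <- data.frame(fish_id = sprintf("sim%03d", seq_len(nsim)),
                       home_x = ctr[1], home_y = ctr[2])
  simulate_tracks(cohort, params, duration = duration, seed = seed)
}

#' Bootstrap sensitivity of the exponential fit to sample size
#'
#' Repeatedly subsamples \code{m} move distances without replacement and
#' refits the exponential mean, summarising the spread of the refitted
#' \eqn{\lambda} values.
#'
#' @param distances pooled move distances (m).
#' @param m subsample size.
#' @param B number of bootstrap subsamples.
#' @param truncation passed to [fit_exponential()].
#' @return List with \code{mean}, \code{sd}, \code{range} of the fitted
#'   lambdas and the vector \code{lambdas}.
#' @export
bootstrap_subsample <- function(distances, m = 437, B = 1000, truncation = 0) {
  n <- length(distances)
  if (m > n) stop("subsample size m exceeds the number of observations")
  lam <- vapply(seq_len(B), function(b) {
    fit_exponential(sample(distances, m), truncation = truncation)$lambda
  }, numeric(1))
  list(mean = mean(lam), sd = stats::sd(lam), range = range(lam),
       lambdas = lam)
}

#' Bootstrap sensitivity to the number of individuals
#'
#' Mimics parameterising the model from very few fish: repeatedly picks two
#' individuals at random, pools their move distances, draws \code{B}
#' subsamples of \code{m} from the pool and refits the exponential mean.
#' When a pooled pair holds fewer than \code{m} moves the subsample is drawn
#' with replacement and flagged.
#'
#' @param per_fish_distances named list of per-individual distance vectors.
#' @param n_pairs number of random pairs.
#' @param m subsample size per bootstrap.
#' @param B bootstrap draws per pair.
#' @param truncation passed to [fit_exponential()].
#' @return List with across-pair \code{mean}, \code{sd}, \code{range}, the
#'   per-pair means \code{pair_means}, and \code{replaced} flags.
#' @export
bootstrap_pairs <- function(per_fish_distances, n_pairs = 100, m = 437,
                            B = 500, truncation = 0) {
  if (length(per_fish_distances) < 2) stop("need at least two individuals")
  pm <- numeric(n_pairs); fl <- logical(n_pairs)
  for (i in seq_len(n_pairs)) {
    pick <- sample(length(per_fish_distances), 2)
    pool <- unlist(per_fish_distances[pick], use.names = FALSE)
    repl <- length(pool) < m
    fl[i] <- repl
    lam <- vapply(seq_len(B), function(b) {
      fit_exponential(sample(pool, m, replace = repl),
                      truncation = truncation)$lambda
    }, numeric(1))
    pm[i] <- mean(lam)
  }
  list(mean = mean(pm), sd = stats::sd(pm), range = range(pm),
       pair_means = pm, replaced = fl)
}
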