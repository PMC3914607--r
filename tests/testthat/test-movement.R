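test_that("heading is the quadrant-aware bearing", {
  expect_equal(heading(c(0, 0), c(1, 1)), pi / 4)
  expect_equal(heading(c(0, 0), c(-1, 0)), pi)
  expect_equal(heading(c(2, 3), c(5, 7)), atan2(4, 3))
  expect_error(heading(c(1, 1), c(1, 1)), "undefined heading")
})

test_that("displacement is the Euclidean distance", {
  expect_equal(displacement(c(0, 0), c(3, 4)), 5)
  expect_equal(displacement(c(7, -2), c(7, -2)), 0)
  expect_equal(displacement(c(100, 200), c(400, 600)), 500)
})

test_that("von Mises density is normalised, peaked at the mean, uniform at kappa 0", {
  expect_equal(dvonmises(1.3, -2, 0), 1 / (2 * pi))
  expect_equal(dvonmises(0, 0, 1), exp(1) / (2 * pi * besselI(1, 0)),
               tolerance = 1e-10)
  for (kap in c(0.5, 3.67, 50)) {
    I <- integrate(dvonmises, -pi, pi, theta_bar = 0.7, kappa = kap,
                   rel.tol = 1e-12)$value
    expect_lt(abs(I - 1), 1e-8)
    grid <- seq(-pi, pi, length.out = 1000)
    dens <- dvonmises(grid, 0.7, kap)
    expect_equal(grid[which.max(dens)], 0.7, tolerance = 0.01)
  }
  expect_error(dvonmises(0, 0, -1), "nonnegative")
})

test_that("sample_turn matches the target distribution", {
  set.seed(42)
  # uniform limit: Rayleigh test of uniformity not significant at alpha 0.01
  th <- sample_turn(1e5, 0, 0)
  Z <- length(th) * (mean(cos(th))^2 + mean(sin(th))^2)
  expect_lt(Z, -log(0.01))
  # concentrated case: circular mean near the target direction
  th <- sample_turn(1e5, 0, 3.67)
  expect_lt(abs(atan2(mean(sin(th)), mean(cos(th)))), 0.02)
  # mean resultant length matches A(kappa) = I1/I0
  Rbar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  A <- besselI(3.67, 1) / besselI(3.67, 0)
  expect_equal(Rbar, A, tolerance = 0.01)
  # wrapped-normal limit: sd -> 1/sqrt(kappa)
  th <- sample_turn(1e5, 0, 500)
  expect_equal(sd(th), 1 / sqrt(500), tolerance = 0.02)
  # non-zero mean direction is honoured and wrapped into (-pi, pi]
  th <- sample_turn(1e4, 3, 8)
  expect_true(all(th > -pi & th <= pi))
  m <- atan2(mean(sin(th)), mean(cos(th)))
  expect_equal(m, 3, tolerance = 0.05)
})

test_that("sample_move follows the move/suppress/clamp contract", {
  set.seed(7)
  never <- movement_params(psi = 0, lambda_mean = 500, kappa = 1)
  expect_true(all(vapply(1:50, function(i)
    is.null(sample_move(never, c(0, 0), c(1000, 0))), logical(1))))

  # with a huge mean, draws beyond max_move are clamped, never exceeded
  big <- movement_params(psi = 1, lambda_mean = 1e6, kappa = 2)
  d <- replicate(200, sample_move(big, c(0, 0), c(1000, 0))$d)
  expect_true(all(d <= 6000))
  expect_gt(mean(d == 6000), 0.9) # nearly every draw hits the clamp

  # with a tiny mean, every draw is beneath min_move and suppressed
  small <- movement_params(psi = 1, lambda_mean = 5, kappa = 2)
  expect_true(all(vapply(1:200, function(i)
    is.null(sample_move(small, c(0, 0), c(1000, 0))), logical(1))))

  # at the center the direction is uniform but a step is still taken
  at <- movement_params(psi = 1, lambda_mean = 5000, kappa = 5)
  st <- sample_move(at, c(0, 0), c(0, 0))
  expect_true(is.na(st$theta_bar))
  expect_equal(displacement(st$origin, st$dest), st$d)
})

test_that("realised move frequency and step lengths match closed forms", {
  set.seed(9)
  p <- species_params("red_grouper")
  n_int <- 2e5
  u <- runif(n_int) < p$psi
  d <- pmin(rexp(sum(u), 1 / p$lambda_mean), p$max_move)
  moves <- sum(d >= p$min_move)
  p_keep <- p$psi * exp(-p$min_move / p$lambda_mean) # clamp cannot push below min
  se <- sqrt(p_keep * (1 - p_keep) / n_int)
  expect_lt(abs(moves / n_int - p_keep), 3 * se)
  # truncated (and top-clamped) exponential mean in closed form
  lam <- p$lambda_mean
  dd <- pmin(rexp(2e5, 1 / lam), p$max_move)
  kept <- dd[dd >= p$min_move]
  m_cl <- p$min_move + lam * (1 - exp(-(p$max_move - p$min_move) / lam))
  se_m <- lam / sqrt(length(kept))
  expect_lt(abs(mean(kept) - m_cl), 4 * se_m)
})

test_that("distance to center shrinks with concentration", {
  mean_r <- function(kappa, seed) {
    set.seed(seed)
    pp <- movement_params(psi = 0.02, lambda_mean = 561, kappa = kappa)
    tr <- simulate_tracks(one_fish(), pp, duration = 120 * 86400)$f1
    mean(sqrt((tr$x - 100)^2 + (tr$y - 100)^2))
  }
  for (seed in 1:3) {
    r <- vapply(c(0.5, 1.19, 3.67), mean_r, numeric(1), seed = seed)
    expect_true(all(diff(r) < 0))
  }
})
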