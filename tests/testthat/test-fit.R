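test_that("moves are extracted with the suppression threshold and centroid", {
  # 1001 fixes = 1000 transition intervals, 8 discernible moves
  x <- rep(0, 1001); x[c(100, 300, 500, 700) + 1] <- 400
  y <- rep(0, 1001); y[c(200, 400, 600, 800) + 1] <- -400
  fx <- data.frame(x = x, y = y)
  ex <- extract_moves(fx)
  expect_equal(nrow(ex$moves), 16) # each spike is a move out and back
  still <- data.frame(x = rep(5, 100), y = rep(5, 100))
  ex2 <- extract_moves(still)
  expect_equal(nrow(ex2$moves), 0)
  expect_equal(ex2$psi_hat, 0)
  expect_equal(nrow(extract_moves(fx[1, ])$moves), 0)
  # psi_hat is moves / transition intervals
  expect_equal(ex$psi_hat, 16 / 1000)
  expect_true(all(ex$moves$turn_rel > -pi & ex$moves$turn_rel <= pi))
})

test_that("exponential fit is the (truncation-shifted) sample mean", {
  f <- fit_exponential(c(100, 200, 300))
  expect_equal(f$lambda, 200)
  expect_equal(f$se, 200 / sqrt(3))
  f1 <- fit_exponential(437)
  expect_equal(f1$lambda, 437)
  expect_equal(f1$se, 437)
  expect_equal(fit_exponential(c(300, 500), truncation = 200)$lambda, 200)
  expect_error(fit_exponential(numeric(0)))
  set.seed(4)
  d <- rexp(16821, 1 / 561)
  fr <- fit_exponential(d)
  expect_lt(abs(fr$lambda - 561), 3 * 561 / sqrt(16821))
})

test_that("clamped data biases the exponential mean by the analytic factor", {
  set.seed(8)
  lam <- 561; cap <- 1500
  d <- pmin(rexp(5e4, 1 / lam), cap)
  expected_mean <- lam * (1 - exp(-cap / lam))
  f <- fit_exponential(d)
  expect_equal(f$lambda, expected_mean, tolerance = 0.02)
  expect_lt(f$lambda, lam)
})

test_that("von Mises fit recovers concentration by Bessel-ratio inversion", {
  set.seed(12)
  u <- runif(1e4, -pi, pi)
  expect_lt(fit_von_mises(u)$kappa, 0.05)
  th <- sample_turn(1e5, 0, 3.67)
  fv <- fit_von_mises(th)
  expect_equal(fv$kappa, 3.67, tolerance = 0.05 / 3.67)
  expect_lt(abs(fv$mu), 0.02)
  same <- fit_von_mises(rep(1.2, 50))
  expect_true(same$capped)
  expect_equal(same$kappa, 1e3)
  expect_error(fit_von_mises(0.4), "two")
})

test_that("subsample bootstrap reproduces the population mean", {
  set.seed(5)
  pop <- rexp(16821, 1 / 561.4)
  bs <- bootstrap_subsample(pop, m = 437, B = 200)
  expect_lt(abs(bs$mean - 561.4), 3 * bs$sd)
  one <- bootstrap_subsample(pop, m = 437, B = 1)
  expect_equal(length(one$lambdas), 1)
  full <- bootstrap_subsample(pop, m = length(pop), B = 3)
  expect_true(all(abs(full$lambdas - mean(pop)) < 1e-9))
  expect_error(bootstrap_subsample(pop, m = length(pop) + 1), "exceeds")
})

test_that("pair bootstrap exposes unrepresentative individuals", {
  set.seed(6)
  # homogeneous population: pair bootstrap stays near the common mean
  hom <- lapply(1:10, function(i) rexp(600, 1 / 500))
  bh <- bootstrap_pairs(hom, n_pairs = 20, m = 437, B = 20)
  expect_equal(bh$mean, 500, tolerance = 0.05)
  # two subpopulations: the across-pair range spans both regimes
  mix <- c(lapply(1:5, function(i) rexp(600, 1 / 300)),
           lapply(1:5, function(i) rexp(600, 1 / 800)))
  bm <- bootstrap_pairs(mix, n_pairs = 40, m = 437, B = 20)
  expect_lt(bm$range[1], 450)
  expect_gt(bm$range[2], 650)
  single <- bootstrap_pairs(hom, n_pairs = 1, B = 1)
  expect_equal(length(single$pair_means), 1)
  expect_error(bootstrap_pairs(hom[1]), "two")
  # undersized pools are resampled with replacement and flagged
  tiny <- lapply(1:3, function(i) rexp(50, 1 / 500))
  bt <- bootstrap_pairs(tiny, n_pairs = 5, m = 437, B = 5)
  expect_true(all(bt$replaced))
})

test_that("fit_movement returns a classed fit with methods", {
  set.seed(30)
  p <- species_params("mutton_snapper")
  tr <- simulate_tracks(one_fish(), p, duration = 60 * 86400)$f1
  fit <- fit_movement(tr, species = "mutton_snapper")
  expect_s3_class(fit, "movefit")
  expect_named(coef(fit), c("psi", "lambda", "kappa"))
  expect_output(print(fit), "lambda")
  expect_output(print(summary(fit)), "estimates|psi")
  sim <- simulate(fit, nsim = 2, seed = 1, duration = 86400)
  expect_length(sim, 2)
  expect_equal(nrow(sim[[1]]), 288)
})
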