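test_that("MCP areas match closed-form hulls and flag degeneracy", {
  tri <- mcp_area(c(0, 200, 0), c(0, 0, 200))
  expect_equal(tri$area, 0.02)
  expect_equal(tri$status, "ok")
  sq <- mcp_area(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))
  expect_equal(sq$area, 1)
  line <- mcp_area(c(0, 100, 200, 300), c(0, 0, 0, 0))
  expect_equal(line$status, "linear")
  expect_equal(line$area, 0)
  expect_equal(mcp_area(5, 5)$status, "linear")
  set.seed(2)
  u <- cbind(runif(1e4, 0, 2000), runif(1e4, 0, 1000))
  expect_equal(mcp_area(u)$area, 2, tolerance = 0.005)
})

test_that("MCP is invariant to point order and duplication", {
  set.seed(3)
  pts <- cbind(rnorm(200, sd = 400), rnorm(200, sd = 400))
  a <- mcp_area(pts)$area
  expect_equal(mcp_area(pts[sample(200), ])$area, a)
  expect_equal(mcp_area(pts[rep(1:200, 3), ])$area, a)
})

test_that("KD with a fixed bandwidth matches the Gaussian closed form", {
  set.seed(14)
  sigma <- 500
  pts <- cbind(rnorm(1e5, sd = sigma), rnorm(1e5, sd = sigma))
  hr <- kd_homerange(pts, levels = c(50, 90, 95), bandwidth = 50)
  a95 <- hr[["95"]]$area
  closed <- pi * (sigma^2 + 50^2) * qchisq(0.95, 2) / 1e6
  expect_equal(a95, closed, tolerance = 0.02)
  # nesting of volume contours
  expect_lt(hr[["50"]]$area, hr[["90"]]$area)
  expect_lt(hr[["90"]]$area, hr[["95"]]$area)
})

test_that("KD fails cleanly on degenerate inputs", {
  same <- cbind(rep(100, 50), rep(100, 50))
  out <- kd_homerange(same)
  expect_equal(out[["95"]]$status, "failed")
  expect_true(is.na(out[["95"]]$area))
  two_sites <- rbind(same, cbind(rep(300, 50), rep(100, 50)))
  expect_equal(kd_homerange(two_sites)[["95"]]$status, "failed")
  expect_equal(kd_homerange(cbind(1:3, 1:3))[["95"]]$status, "failed")
})

test_that("SCV-selected KD areas scale as s^2 under coordinate scaling", {
  set.seed(15)
  p <- species_params("red_grouper")
  tr <- simulate_tracks(one_fish(), p, duration = 90 * 86400)$f1
  base <- kd_homerange(tr, levels = 95)[["95"]]
  expect_equal(base$status, "ok")
  s <- 2
  scaled <- kd_homerange(data.frame(x = tr$x * s, y = tr$y * s),
                         levels = 95, cell = 20 * s)[["95"]]
  expect_equal(scaled$area / base$area, s^2, tolerance = 0.02)
  # bandwidth matrix is recorded and positive definite
  expect_true(all(eigen(base$bandwidth)$values > 0))
})

test_that("the 95% area is stable to halving the grid cell", {
  set.seed(16)
  pts <- cbind(rnorm(2e4, sd = 400), rnorm(2e4, sd = 400))
  a20 <- kd_homerange(pts, levels = 95, cell = 20, bandwidth = 80)[["95"]]$area
  a10 <- kd_homerange(pts, levels = 95, cell = 10, bandwidth = 80)[["95"]]$area
  expect_lt(abs(a20 - a10) / a10, 0.03)
})

test_that("cumulative MCP area curves are non-decreasing to the final range", {
  set.seed(17)
  p <- species_params("mutton_snapper")
  tr <- simulate_tracks(one_fish(), p, duration = 365 * 86400)$f1
  cv <- cumulative_area_curve(tr, "mcp")
  expect_equal(nrow(cv), 12)
  expect_true(all(diff(cv$area) >= 0))
  expect_equal(cv$pct_final[12], 100)
  still <- data.frame(interval = 1:200000,
                      x = rep(c(0, 300, 0, 300), 50000),
                      y = rep(c(0, 0, 300, 300), 50000))
  cs <- cumulative_area_curve(still, "mcp")
  expect_true(all(cs$area == cs$area[1]))
  expect_error(cumulative_area_curve(tr[1:10, ], "mcp"), "two steps")
})

test_that("asymptote classification follows the contract thresholds", {
  flat <- data.frame(elapsed = 1:5, area = rep(2, 5))
  expect_equal(classify_asymptote(flat), "Yes")
  dbl <- data.frame(elapsed = 1:3, area = c(1, 2, 4))
  expect_equal(classify_asymptote(dbl), "No")
  mid <- data.frame(elapsed = 1:3, area = c(1, 2, 2.2))
  expect_equal(classify_asymptote(mid), "Maybe")
  expect_equal(classify_asymptote(data.frame(elapsed = 1, area = 3)), "No")
})
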