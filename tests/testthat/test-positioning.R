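test_that("detections are grouped into 5-min batches", {
  log <- data.frame(time = c(10, 290, 310, 3590),
                    receiver_id = "r1", expected_count = 1)
  b <- batch_detections(log, 300)
  expect_equal(b$batch, c(0, 0, 1, 11))
  # an hour of continuous detections spans 12 batches
  hour <- data.frame(time = seq(0, 3599, by = 60), receiver_id = "r1",
                     expected_count = 1)
  expect_equal(length(unique(batch_detections(hour, 300)$batch)), 12)
  bad <- data.frame(time = c("2006-01-01T00:00:10", "not a time"),
                    receiver_id = "r1", expected_count = 1)
  expect_warning(bb <- batch_detections(bad), "unparseable")
  expect_equal(nrow(bb), 1)
})

test_that("position fixes follow the weighted-centroid contract", {
  m <- detection_model()
  arr <- data.frame(receiver_id = c("a", "b", "c"),
                    x = c(0, 1000, 500), y = c(0, 0, 900))
  # single receiver: the fix is the receiver
  log <- data.frame(time = 10, receiver_id = "a", expected_count = 2)
  fx <- estimate_positions(log, arr, m)
  expect_equal(c(fx$x, fx$y), c(0, 0))
  expect_equal(fx$n_receivers, 1)
  # symmetric two-receiver batch: the midpoint
  log2 <- data.frame(time = c(10, 20), receiver_id = c("a", "b"),
                     expected_count = c(1.5, 1.5))
  fx2 <- estimate_positions(log2, arr, m)
  expect_equal(c(fx2$x, fx2$y), c(500, 0))
  # three receivers, counts (2,1,1): strictly inside, nearer the heavy vertex
  log3 <- data.frame(time = c(1, 2, 3), receiver_id = c("a", "b", "c"),
                     expected_count = c(2, 1, 1))
  fx3 <- estimate_positions(log3, arr, m)
  d <- sqrt((arr$x - fx3$x)^2 + (arr$y - fx3$y)^2)
  expect_true(all(d > 0))
  expect_equal(which.min(d), 1L)
  # inside the hull of contributors
  expect_true(fx3$x > 0 && fx3$x < 1000 && fx3$y > 0 && fx3$y < 900)
})

test_that("the estimator is permutation-invariant and translation-equivariant", {
  m <- detection_model()
  arr <- data.frame(receiver_id = c("a", "b", "c"),
                    x = c(0, 800, 300), y = c(0, 100, 700))
  log <- data.frame(time = c(1, 2, 3), receiver_id = c("a", "b", "c"),
                    expected_count = c(1.2, 0.4, 2.5))
  f1 <- estimate_positions(log, arr, m)
  f2 <- estimate_positions(log[3:1, ], arr, m)
  expect_equal(c(f1$x, f1$y), c(f2$x, f2$y))
  shift <- arr; shift$x <- shift$x + 5000; shift$y <- shift$y - 2000
  f3 <- estimate_positions(log, shift, m)
  expect_equal(c(f3$x, f3$y), c(f1$x + 5000, f1$y - 2000))
})

test_that("multi-receiver batches position better than single-receiver ones", {
  set.seed(21)
  p <- species_params("mutton_snapper")
  arr <- receiver_grid(4, 8, 600)
  m <- detection_model()
  coh <- instantiate_cohort(arr, p)
  core <- which(classify_peripheral(arr)[coh$receiver_id] == "core")[1]
  tr <- simulate_tracks(coh[core, ], p, duration = 90 * 86400)[[1]]
  fx <- reefhr:::detect_fixes(tr, arr, m, interval = 300)
  err <- sqrt((fx$x - tr$x[fx$interval])^2 + (fx$y - tr$y[fx$interval])^2)
  rms <- function(v) sqrt(mean(v^2))
  expect_gt(sum(fx$n_receivers >= 2), 50)
  expect_lt(rms(err[fx$n_receivers >= 2]), rms(err[fx$n_receivers == 1]))
})
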