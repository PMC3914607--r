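# shared fixtures: small arrays and cohorts built in code

toy_array_grid <- function(n = 3, spacing = 600) {
  g <- expand.grid(x = (seq_len(n) - (n + 1) / 2) * spacing,
                   y = (seq_len(n) - (n + 1) / 2) * spacing)
  data.frame(receiver_id = sprintf("r%02d", seq_len(nrow(g))),
             x = g$x, y = g$y, depth = 15, stringsAsFactors = FALSE)
}

one_fish <- function(x = 100, y = 100, id = "f1") {
  data.frame(fish_id = id, home_x = x, home_y = y, stringsAsFactors = FALSE)
}

# a short deterministic track stepping along a square
square_track <- function(side = 1000, reps = 1) {
  pts <- rbind(c(0, 0), c(side, 0), c(side, side), c(0, side))
  pts <- pts[rep(1:4, reps), , drop = FALSE]
  data.frame(interval = seq_len(nrow(pts)), x = pts[, 1], y = pts[, 2],
             moved = 1L)
}
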