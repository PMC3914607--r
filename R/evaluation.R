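#' Paired t statistic
#'
#' Standard paired t statistic for equal-length samples.
#'
#' @param a,b paired numeric vectors.
#' @return List with \code{t}, \code{df} (n - 1), \code{mean_diff} and
#'   \code{p} (two-sided).
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  s <- stats::sd(d)
  if (s == 0) stop("zero variance of paired differences")
  n <- length(d)
  t <- mean(d) / (s / sqrt(n))
  list(t = t, df = n - 1, mean_diff = mean(d),
       p = 2 * stats::pt(-abs(t), n - 1))
}

# Sim-Detect position fixes for one track, computed per distinct cell (the
# expected-count and centroid arithmetic is identical for every interval the
# fish spends on the same cell).
detect_fixes <- function(track, array, model, interval = 300,
                         threshold = 1e-6) {
  key <- complex(real = track$x, imaginary = track$y)
  uk <- unique(key)
  pos_of <- match(key, uk)
  ux <- Re(uk); uy <- Im(uk)
  dmat <- sqrt(outer(ux, array$x, "-")^2 + outer(uy, array$y, "-")^2)
  emat <- expected_detections(interval, model, dmat)
  emat[emat < threshold] <- 0
  fx <- rep(NA_real_, length(ux)); fy <- fx; nr <- integer(length(ux))
  for (p in seq_along(ux)) {
    cnt <- emat[p, ]
    if (all(cnt == 0)) next
    est <- estimate_position_one(array$x, array$y, cnt, model)
    fx[p] <- est$x; fy[p] <- est$y; nr[p] <- est$n_receivers
  }
  got <- !is.na(fx[pos_of])
  data.frame(interval = track$interval[got],
             x = fx[pos_of][got], y = fy[pos_of][got],
             n_receivers = nr[pos_of][got])
}

#' Simulate a cohort and compare true-path and detection-derived home ranges
#'
#' Runs the full comparison experiment for one species: one simulated fish
#' per receiver (home range centered on the receiver's cell) for the given
#' duration; per fish, 100% MCP and (optionally) 95% KD home ranges are
#' computed from the true path ("Sim-Actual") and from position fixes
#' estimated out of the simulated detection log ("Sim-Detect").
#'
#' @param params a [movement_params] object.
#' @param array receiver table; default [receiver_grid()].
#' @param model a [detection_model].
#' @param duration simulated time (s), default one year.
#' @param seed optional seed.
#' @param kd compute 95% KD home ranges (SCV bandwidth) as well as MCPs?
#' @param cell_size movement grid cell (m).
#' @return An object of class \code{cohort_experiment}: \code{per_fish}
#'   data frame (areas in km2, \code{NA} for failed KD fits and linear
#'   MCPs, with status columns), \code{summary} group statistics,
#'   \code{paired} paired t results for MCP, and the inputs used. KD
#'   failures are excluded from KD means, with the group \code{n} reporting
#'   the fish actually used.
#' @export
run_cohort_experiment <- function(params, array = receiver_grid(),
                                  model = detection_model(),
                                  duration = 365 * 86400, seed = NULL,
                                  kd = TRUE, cell_size = 200) {
  if (!is.null(seed)) set.seed(seed)
  cohort <- instantiate_cohort(array, params, cell_size)
  periph <- classify_peripheral(array)
  n_int <- as.integer(duration / params$interval)
  res <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    tr <- simulate_track_one(params,
                             center = c(cohort$home_x[i], cohort$home_y[i]),
                             n_intervals = n_int, cell_size = cell_size)
    sa_mcp <- mcp_area(tr)
    fx <- detect_fixes(tr, array, model, interval = params$interval)
    sd_mcp <- if (nrow(fx) >= 1) mcp_area(fx) else NULL
    row <- data.frame(
      fish_id = cohort$fish_id[i],
      receiver_id = cohort$receiver_id[i],
      peripheral = unname(periph[cohort$receiver_id[i]]),
      sa_mcp = if (sa_mcp$status == "ok") sa_mcp$area else NA_real_,
      sa_mcp_status = sa_mcp$status,
      sd_mcp = if (!is.null(sd_mcp) && sd_mcp$status == "ok")
        sd_mcp$area else NA_real_,
      n_fixes = nrow(fx),
      stringsAsFactors = FALSE)
    if (kd) {
      sa_kd <- kd_homerange(tr, levels = 95)[["95"]]
      sd_kd <- if (nrow(fx) >= 5) kd_homerange(fx, levels = 95)[["95"]]
               else NULL
      row$sa_kd <- if (sa_kd$status == "ok") sa_kd$area else NA_real_
      row$sd_kd <- if (!is.null(sd_kd) && sd_kd$status == "ok")
        sd_kd$area else NA_real_
    }
    res[[i]] <- row
  }
  per_fish <- do.call(rbind, res)
  grp <- function(v) {
    v <- v[!is.na(v)]
    c(mean = mean(v), sd = stats::sd(v), n = length(v),
      se = stats::sd(v) / sqrt(length(v)))
  }
  cols <- intersect(c("sa_mcp", "sd_mcp", "sa_kd", "sd_kd"), names(per_fish))
  summary <- t(vapply(cols, function(cn) grp(per_fish[[cn]]), numeric(4)))
  ok <- stats::complete.cases(per_fish[, c("sa_mcp", "sd_mcp")])
  paired <- if (sum(ok) >= 2 &&
                stats::sd(per_fish$sd_mcp[ok] - per_fish$sa_mcp[ok]) > 0)
    paired_t(per_fish$sd_mcp[ok], per_fish$sa_mcp[ok]) else NULL
  structure(list(per_fish = per_fish, summary = summary, paired = paired,
                 species = params$species, params = params,
                 duration = duration, seed = seed),
            class = "cohort_experiment")
}

#' @export
print.cohort_experiment <- function(x, ...) {
  cat("Cohort home-range experiment",
      if (!is.na(x$species)) paste0("(", x$species, ")"), "\n")
  cat(sprintf("  %d fish, %.0f days\n", nrow(x$per_fish),
              x$duration / 86400))
  print(round(x$summary, 3))
  if (!is.null(x$paired))
    cat(sprintf("  paired t (Sim-Detect - Sim-Actual MCP): t = %.2f, df = %d\n",
                x$paired$t, x$paired$df))
  invisible(x)
}

#' Per-receiver home-range bias and the core/peripheral contrast
#'
#' Percentage over/underestimation of the detection-derived MCP relative to
#' the true-path MCP for the fish centered at each receiver, with a
#' one-tailed two-sample t statistic (equal variances) testing whether
#' peripheral-centered fish are underestimated relative to core-centered
#' fish.
#'
#' @param experiment a \code{cohort_experiment}.
#' @param measure \code{"mcp"} (default) or \code{"kd"}.
#' @return List with \code{bias} (data frame: receiver, class, pct_bias),
#'   group means, and \code{t}, \code{df}, \code{p} for the
#'   peripheral-minus-core contrast (negative t = peripheral more
#'   underestimated); test fields are \code{NA} (flagged) under degenerate
#'   variance.
#' @export
peripheral_bias <- function(experiment, measure = c("mcp", "kd")) {
  measure <- match.arg(measure)
  pf <- experiment$per_fish
  a <- if (measure == "mcp") pf$sa_mcp else pf$sa_kd
  b <- if (measure == "mcp") pf$sd_mcp else pf$sd_kd
  ok <- !is.na(a) & !is.na(b) & a > 0
  bias <- data.frame(receiver_id = pf$receiver_id[ok],
                     class = pf$peripheral[ok],
                     pct_bias = 100 * (b[ok] - a[ok]) / a[ok],
                     stringsAsFactors = FALSE)
  bp <- bias$pct_bias[bias$class == "peripheral"]
  bc <- bias$pct_bias[bias$class == "core"]
  out <- list(bias = bias,
              mean_peripheral = mean(bp), mean_core = mean(bc),
              t = NA_real_, df = NA_integer_, p = NA_real_,
              skipped = FALSE)
  n1 <- length(bp); n2 <- length(bc)
  if (n1 >= 2 && n2 >= 2) {
    sp2 <- ((n1 - 1) * stats::var(bp) + (n2 - 1) * stats::var(bc)) /
      (n1 + n2 - 2)
    if (sp2 > 0) {
      out$t <- (mean(bp) - mean(bc)) / sqrt(sp2 * (1 / n1 + 1 / n2))
      out$df <- n1 + n2 - 2L
      out$p <- stats::pt(out$t, out$df)   # one-tailed: peripheral < core
      return(out)
    }
  }
  out$skipped <- TRUE
  out
}

#' Home-range filtering criteria
#'
#' Row-selection rule for per-fish home-range tables: minimum days tracked,
#' minimum detections, admissible asymptote calls and admissible peripheral
#' classes.
#'
#' @param min_days keep fish with days strictly greater than this (0 = all).
#' @param min_detections keep fish with detections strictly greater than
#'   this (0 = all).
#' @param asymptote_in admissible asymptote values (nonempty subset of Yes,
#'   Maybe, No).
#' @param peripheral_in admissible peripheral-effect classes (nonempty).
#' @return A \code{filter_criteria} object.
#' @export
filter_criteria <- function(min_days = 0, min_detections = 0,
                            asymptote_in = c("Yes", "Maybe", "No"),
                            peripheral_in = c("Low", "Moderate", "High",
                                              "Very high")) {
  if (length(asymptote_in) == 0 || length(peripheral_in) == 0)
    stop("criteria subsets must be nonempty")
  structure(list(min_days = min_days, min_detections = min_detections,
                 asymptote_in = asymptote_in, peripheral_in = peripheral_in),
            class = "filter_criteria")
}

#' Apply filtering criteria to a per-fish home-range table
#'
#' Removes rows failing any criterion and summarises the surviving MCP and
#' 95% KD areas. Fish whose estimate is degenerate ("Linear") stay in the
#' reported N but are excluded from the corresponding mean and SE.
#'
#' @param table per-fish table with columns \code{days}, \code{detections},
#'   \code{asymptote}, \code{peripheral}, \code{mcp_km2}, \code{kd_km2}
#'   (numeric, \code{NA} for degenerate) and status columns
#'   \code{mcp_status} / \code{kd_status}; see [load_table3()].
#' @param criteria a [filter_criteria] object.
#' @return List with \code{n} (rows passing), and for each estimator the
#'   \code{mean}, \code{se} and \code{n_used}.
#' @export
#' @examples
#' t3 <- load_table3()
#' rg <- t3[t3$species == "RG", ]
#' apply_filters(rg, filter_criteria(60, 1000, "Yes", "Low"))$n  # 12
apply_filters <- function(table, criteria) {
  stopifnot(inherits(criteria, "filter_criteria"))
  keep <- table$days > criteria$min_days &
    table$detections > criteria$min_detections &
    table$asymptote %in% criteria$asymptote_in &
    table$peripheral %in% criteria$peripheral_in
  sub <- table[keep, , drop = FALSE]
  one <- function(v) {
    u <- v[!is.na(v)]
    if (length(u) == 0)
      return(list(mean = NA_real_, se = NA_real_, n_used = 0L))
    list(mean = mean(u),
         se = if (length(u) > 1) stats::sd(u) / sqrt(length(u)) else NA_real_,
         n_used = length(u))
  }
  list(n = nrow(sub), mcp = one(sub$mcp_km2), kd = one(sub$kd_km2))
}
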