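#' Group detection records into positioning batches
#'
#' Detections are pooled over fixed batching windows (default 5 minutes)
#' before position estimation; empty batches are omitted.
#'
#' @param log detection records with a \code{time} column (seconds, numeric)
#'   or an \code{interval} column (already-batched interval index), a
#'   \code{receiver_id} and an \code{expected_count} (or \code{count}).
#' @param batch batch length (s) applied to \code{time}.
#' @return The log with a \code{batch} index column, unparseable rows
#'   dropped with a warning.
#' @export
batch_detections <- function(log, batch = 300) {
  if (batch <= 0) stop("batch must be positive")
  if ("interval" %in% names(log)) {
    log$batch <- log$interval
    return(log)
  }
  tm <- log$time
  if (is.character(tm)) {
    parsed <- as.POSIXct(tm, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
    alt <- is.na(parsed)
    parsed[alt] <- as.POSIXct(tm[alt], tz = "UTC",
                              format = "%Y-%m-%d %H:%M:%S")
    bad <- is.na(parsed)
    if (any(bad)) {
      warning(sprintf("dropping %d detection(s) with unparseable timestamps",
                      sum(bad)))
      log <- log[!bad, , drop = FALSE]
      parsed <- parsed[!bad]
    }
    tm <- as.numeric(parsed)
  }
  log$batch <- floor(tm / batch)
  log
}

# one batch -> fix: two-pass inverse-detection-probability weighted centroid
estimate_position_one <- function(rx, ry, counts, model) {
  w <- counts
  if (all(w <= 0)) return(NULL)
  cx <- sum(w * rx) / sum(w); cy <- sum(w * ry) / sum(w)
  for (pass in 1:2) {
    r <- sqrt((rx - cx)^2 + (ry - cy)^2)
    w <- counts / pmax(detection_prob(model, r), 1e-3)
    cx <- sum(w * rx) / sum(w); cy <- sum(w * ry) / sum(w)
  }
  list(x = cx, y = cy, n_receivers = sum(counts > 0), total_weight = sum(w))
}

#' Estimate position fixes from a detection log
#'
#' Converts multi-receiver detection batches into one position fix per batch
#' with a model-weighted centroid: an initial centroid from raw counts is
#' refined by re-weighting each receiver's count by the inverse detection
#' probability at its distance from the provisional fix (two refinement
#' passes). A single-receiver batch yields the receiver's position. Fixes
#' always lie within the convex hull of the contributing receivers.
#'
#' @param log detection records (see [batch_detections()]); a \code{fish_id}
#'   column, if present, is carried through and batches are per fish.
#' @param array receiver table (\code{receiver_id}, \code{x}, \code{y}).
#' @param model a [detection_model] used for the inverse-probability
#'   weights; set \code{weighting = "count"} for a plain count-weighted
#'   centroid.
#' @param batch batch length (s).
#' @param weighting \code{"model"} (default) or \code{"count"}.
#' @return Data frame of fixes: \code{batch}, \code{x}, \code{y},
#'   \code{n_receivers}, \code{total_weight} (and \code{fish_id} if given).
#' @export
estimate_positions <- function(log, array, model, batch = 300,
                               weighting = c("model", "count")) {
  weighting <- match.arg(weighting)
  log <- batch_detections(log, batch)
  cnt <- if ("count" %in% names(log)) log$count else log$expected_count
  log$.cnt <- cnt
  ri <- match(log$receiver_id, array$receiver_id)
  if (anyNA(ri)) stop("detection log names receivers absent from the array")
  log$.rx <- array$x[ri]; log$.ry <- array$y[ri]
  keys <- if ("fish_id" %in% names(log))
    interaction(log$fish_id, log$batch, drop = TRUE) else factor(log$batch)
  pieces <- split(log, keys)
  rows <- lapply(pieces, function(b) {
    est <- if (weighting == "model")
      estimate_position_one(b$.rx, b$.ry, b$.cnt, model)
    else {
      w <- b$.cnt
      if (all(w <= 0)) NULL else
        list(x = sum(w * b$.rx) / sum(w), y = sum(w * b$.ry) / sum(w),
             n_receivers = sum(w > 0), total_weight = sum(w))
    }
    if (is.null(est)) return(NULL)
    out <- data.frame(batch = b$batch[1], x = est$x, y = est$y,
                      n_receivers = est$n_receivers,
                      total_weight = est$total_weight,
                      stringsAsFactors = FALSE)
    if ("fish_id" %in% names(b)) out$fish_id <- b$fish_id[1]
    out
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    return(data.frame(batch = integer(), x = numeric(), y = numeric(),
                      n_receivers = integer(), total_weight = numeric()))
  out <- out[order(out$batch), , drop = FALSE]
  rownames(out) <- NULL
  out
}
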