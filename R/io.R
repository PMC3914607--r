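#' Load the packaged per-fish movement and home-range table
#'
#' Per-fish tracking summaries and home-range estimates (MCP and 95% KD,
#' km2) for 44 acoustically tracked red grouper (RG), 2 black grouper (BG)
#' and 2 mutton snapper (MS), as used by the filter analyses. "Linear"
#' entries (degenerate, collinear-fix fish) are parsed to \code{NA} areas
#' with a status marker. The loader checks the transcription against fixed
#' row counts and column totals and refuses to return a corrupted table.
#'
#' @return Data frame with columns \code{species}, \code{id},
#'   \code{total_length_cm}, \code{peripheral}, \code{days},
#'   \code{asymptote}, \code{mcp_km2}, \code{kd_km2} (numeric, \code{NA}
#'   for degenerate), \code{mcp_status}, \code{kd_status},
#'   \code{detections}, \code{detections_pct}, \code{moves},
#'   \code{moves_pct}.
#' @export
#' @examples
#' t3 <- load_table3()
#' table(t3$species)
load_table3 <- function() {
  path <- system.file("extdata", "table3_fish.csv", package = "reefhr",
                      mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(mcp_km2 = "character",
                                      kd_km2 = "character"))
  ok <- nrow(d) == 48 &&
    identical(as.integer(table(d$species)[c("RG", "BG", "MS")]),
              c(44L, 2L, 2L)) &&
    sum(d$detections) == 2181556L && sum(d$moves) == 18525L
  if (!isTRUE(ok)) stop("packaged per-fish table failed its checksum")
  d$mcp_status <- ifelse(d$mcp_km2 == "Linear", "Linear", "ok")
  d$kd_status <- ifelse(d$kd_km2 == "Linear", "Linear", "ok")
  d$mcp_km2 <- suppressWarnings(as.numeric(d$mcp_km2))
  d$kd_km2 <- suppressWarnings(as.numeric(d$kd_km2))
  d
}

iso_time <- function(seconds, origin = "2006-01-01") {
  format(as.POSIXct(seconds, origin = origin, tz = "UTC"),
         "%Y-%m-%dT%H:%M:%S")
}

#' Write a simulated track to CSV
#'
#' Columns: \code{fish_id}, \code{timestamp} (ISO-8601, UTC),
#' \code{x_m}, \code{y_m}, \code{moved}.
#'
#' @param track track data frame from [simulate_tracks()].
#' @param file output path.
#' @param fish_id identifier written to every row.
#' @param interval interval length (s).
#' @param origin track start date.
#' @export
write_track_csv <- function(track, file, fish_id = "fish1", interval = 300,
                            origin = "2006-01-01") {
  out <- data.frame(fish_id = fish_id,
                    timestamp = iso_time((track$interval - 1) * interval,
                                         origin),
                    x_m = track$x, y_m = track$y, moved = track$moved)
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
}

#' Read a track CSV written by [write_track_csv()]
#' @param file path.
#' @param interval interval length (s).
#' @return Track data frame (\code{interval}, \code{x}, \code{y},
#'   \code{moved}, \code{fish_id}).
#' @export
read_track_csv <- function(file, interval = 300) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  t0 <- as.POSIXct(d$timestamp[1], tz = "UTC",
                   tryFormats = "%Y-%m-%dT%H:%M:%S")
  tt <- as.POSIXct(d$timestamp, tz = "UTC", tryFormats = "%Y-%m-%dT%H:%M:%S")
  data.frame(interval = as.integer(round(as.numeric(tt - t0, units = "secs") /
                                           interval)) + 1L,
             x = d$x_m, y = d$y_m, moved = d$moved, fish_id = d$fish_id,
             stringsAsFactors = FALSE)
}

#' Write / read a receiver table
#'
#' CSV columns \code{receiver_id}, \code{x_m}, \code{y_m}, \code{depth_m}.
#' @param array receiver table.
#' @param file path.
#' @export
write_receivers_csv <- function(array, file) {
  utils::write.csv(data.frame(receiver_id = array$receiver_id,
                              x_m = array$x, y_m = array$y,
                              depth_m = array$depth),
                   file, row.names = FALSE, quote = FALSE)
}

#' @rdname write_receivers_csv
#' @export
read_receivers_csv <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  data.frame(receiver_id = d$receiver_id, x = d$x_m, y = d$y_m,
             depth = d$depth_m, stringsAsFactors = FALSE)
}

#' Write / read a detection log
#'
#' CSV columns \code{timestamp}, \code{receiver_id}, \code{tag_id},
#' \code{expected_count}.
#' @param detections detection records from [simulate_detections()].
#' @param file path.
#' @param tag_id tag identifier written to every row.
#' @param interval interval length (s).
#' @param origin start date for timestamps.
#' @export
write_detections_csv <- function(detections, file, tag_id = "tag1",
                                 interval = 300, origin = "2006-01-01") {
  utils::write.csv(
    data.frame(timestamp = iso_time((detections$interval - 1) * interval,
                                    origin),
               receiver_id = detections$receiver_id, tag_id = tag_id,
               expected_count = detections$expected_count),
    file, row.names = FALSE, quote = FALSE)
}

#' @rdname write_detections_csv
#' @export
read_detections_csv <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  tt <- as.POSIXct(d$timestamp, tz = "UTC", tryFormats = "%Y-%m-%dT%H:%M:%S")
  data.frame(time = as.numeric(tt), receiver_id = d$receiver_id,
             fish_id = d$tag_id, expected_count = d$expected_count,
             stringsAsFactors = FALSE)
}

#' Write position fixes to CSV
#'
#' CSV columns \code{fish_id}, \code{timestamp}, \code{x_m}, \code{y_m},
#' \code{n_receivers}.
#' @param fixes fixes from [estimate_positions()].
#' @param file path.
#' @param batch batch length (s).
#' @param origin start date.
#' @export
write_fixes_csv <- function(fixes, file, batch = 300, origin = "2006-01-01") {
  utils::write.csv(
    data.frame(fish_id = if ("fish_id" %in% names(fixes)) fixes$fish_id
               else "fish1",
               timestamp = iso_time(fixes$batch * batch, origin),
               x_m = fixes$x, y_m = fixes$y,
               n_receivers = fixes$n_receivers),
    file, row.names = FALSE, quote = FALSE)
}

#' Export home-range polygons as GeoJSON
#'
#' Writes the MCP hull as a GeoJSON Polygon in the local planar coordinate
#' system (meters; no geodetic projection is implied).
#'
#' @param hr a \code{homerange} object from [mcp_area()].
#' @param file output path.
#' @export
write_homerange_geojson <- function(hr, file) {
  stopifnot(inherits(hr, "homerange"), hr$method == "MCP")
  ring <- rbind(hr$hull, hr$hull[1, , drop = FALSE])
  coords <- paste(sprintf("[%.2f, %.2f]", ring[, 1], ring[, 2]),
                  collapse = ", ")
  txt <- sprintf(paste0(
    '{"type": "Feature", "properties": {"method": "MCP", "level": %g, ',
    '"area_km2": %.6f, "status": "%s"}, ',
    '"geometry": {"type": "Polygon", "coordinates": [[%s]]}}'),
    hr$level, hr$area, hr$status, coords)
  writeLines(txt, file)
  invisible(file)
}

#' Generate a fixture track with its generating truth
#'
#' Convenience fixture generator for fitting tests: simulates one track and
#' writes both the track CSV and a sidecar file of the true generating
#' parameters.
#'
#' @param params a [movement_params] object.
#' @param center home-range center (m).
#' @param duration simulated time (s).
#' @param seed seed (required; fixtures are deterministic).
#' @param file track CSV path; sidecar written to \code{paste0(file,
#'   ".truth")}.
#' @return Invisibly, the track data frame.
#' @export
generate_fixture_track <- function(params, center = c(100, 100),
                                   duration = 365 * 86400, seed,
                                   file) {
  cohort <- data.frame(fish_id = "fix1", home_x = center[1],
                       home_y = center[2])
  tr <- simulate_tracks(cohort, params, duration = duration, seed = seed)$fix1
  write_track_csv(tr, file, fish_id = "fix1", interval = params$interval)
  truth <- c(psi = params$psi, lambda = params$lambda_mean,
             kappa = params$kappa, seed = seed)
  writeLines(paste(names(truth), truth, sep = "="), paste0(file, ".truth"))
  invisible(tr)
}
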