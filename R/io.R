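#' Read a detection log
#'
#' Reads a delimited text file of receiver downloads (one row per received
#' ping) into the canonical detection tibble: columns `tag_id`, `station_id`
#' (character) and `timestamp` (POSIXct, UTC). Rows are sorted by
#' `tag_id`, then `timestamp`, with timestamp ties broken by `station_id`
#' and then input order; exact duplicate rows (same tag, station and
#' timestamp) are collapsed to one, as overlapping receiver downloads can
#' repeat records.
#'
#' @param path Path to a delimited text file with a header row.
#' @param stations Station table (see [read_stations()]); every
#'   `station_id` in the file must appear in it.
#' @param col_map Named character vector mapping canonical names to the
#'   file's column names, e.g. `c(tag_id = "Transmitter", station_id =
#'   "Receiver", timestamp = "DateTime")`.
#' @param delim Field delimiter (default comma).
#' @param tz Time zone the file's timestamps are recorded in; they are
#'   converted to UTC on read. Defaults to `"UTC"`.
#' @return A detection tibble sorted canonically, with attribute
#'   `n_duplicates` giving the number of collapsed rows.
#' @seealso [write_detections()], [filter_to_deployment_windows()]
#' @export
read_detections <- function(path, stations,
                            col_map = c(tag_id = "tag_id",
                                        station_id = "station_id",
                                        timestamp = "timestamp"),
                            delim = ",", tz = "UTC") {
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  missing_cols <- setdiff(unname(col_map), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("detection file lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  det <- tibble::tibble(
    tag_id     = as.character(raw[[col_map[["tag_id"]]]]),
    station_id = as.character(raw[[col_map[["station_id"]]]]),
    timestamp  = parse_timestamps(raw[[col_map[["timestamp"]]]], tz = tz)
  )
  as_detections(det, stations)
}

## Parse character timestamps, hard-erroring with 1-based line numbers
## (header excluded) for anything unparseable.
parse_timestamps <- function(x, tz = "UTC") {
  ts <- suppressWarnings(
    lubridate::parse_date_time(x, orders = c("Ymd HMS", "Ymd HM", "YmdHMS"),
                               tz = tz, quiet = TRUE)
  )
  bad <- which(is.na(ts) | is.na(x))
  if (length(bad) > 0) {
    abort(paste0("unparseable timestamp(s) at data line(s): ",
                 paste(head(bad, 10), collapse = ", "),
                 if (length(bad) > 10) " ..." else ""))
  }
  lubridate::with_tz(ts, "UTC")
}

#' Coerce a data frame to the canonical detection representation
#'
#' Validates referential integrity against the station table, converts
#' timestamps to UTC, collapses exact duplicates and applies the canonical
#' sort (tag, timestamp, station, input order).
#'
#' @param det Data frame with `tag_id`, `station_id`, `timestamp`.
#' @inheritParams read_detections
#' @return Canonical detection tibble.
#' @export
as_detections <- function(det, stations = NULL) {
  det <- tibble::as_tibble(det)[, c("tag_id", "station_id", "timestamp")]
  det$tag_id <- as.character(det$tag_id)
  det$station_id <- as.character(det$station_id)
  if (!lubridate::is.POSIXct(det$timestamp)) {
    det$timestamp <- parse_timestamps(as.character(det$timestamp))
  }
  det$timestamp <- lubridate::with_tz(det$timestamp, "UTC")
  if (!is.null(stations)) {
    unknown <- setdiff(unique(det$station_id), stations$station_id)
    if (length(unknown) > 0) {
      abort(paste0("detections reference unknown station_id(s): ",
                   paste(sort(unknown), collapse = ", ")))
    }
  }
  n0 <- nrow(det)
  det <- dplyr::distinct(det, .data$tag_id, .data$station_id, .data$timestamp,
                         .keep_all = TRUE)
  ## stable total order: tie on timestamp broken by station then input order
  det <- det[order(det$tag_id, det$timestamp, det$station_id), , drop = FALSE]
  out <- tibble::as_tibble(det)
  attr(out, "n_duplicates") <- n0 - nrow(out)
  out
}

#' Write detections to the canonical CSV
#'
#' Writes `tag_id`, `station_id` and an ISO-8601 UTC `timestamp` column so
#' that a read of the written file reproduces the input exactly.
#'
#' @param detections Canonical detection tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path) {
  out <- tibble::tibble(
    tag_id = detections$tag_id,
    station_id = detections$station_id,
    timestamp = format(detections$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read receiver station metadata
#'
#' The station table holds one row per receiver deployment location:
#' `station_id`, `name`, `latitude`, `longitude` (decimal degrees), `depth`
#' (m), `island_id`, and the deployment windows in which the receiver was in
#' the water and recording. Windows are half-open `[start, end)` instants
#' encoded in two list-columns.
#'
#' @param path CSV with columns `station_id,name,latitude,longitude,depth,`
#'   `island_id,window_start,window_end`; a station with several deployment
#'   windows repeats across rows.
#' @return One-row-per-station tibble with list-columns `window_start`,
#'   `window_end` (POSIXct vectors, UTC).
#' @export
read_stations <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  raw$latitude <- as.numeric(raw$latitude)
  raw$longitude <- as.numeric(raw$longitude)
  raw$depth <- as.numeric(raw$depth)
  raw$window_start <- parse_timestamps(raw$window_start)
  raw$window_end <- parse_timestamps(raw$window_end)
  st <- raw |>
    dplyr::arrange(.data$station_id, .data$window_start) |>
    dplyr::group_by(.data$station_id, .data$name, .data$latitude,
                    .data$longitude, .data$depth, .data$island_id) |>
    dplyr::summarise(ws = list(.data$window_start),
                     we = list(.data$window_end),
                     .groups = "drop") |>
    dplyr::rename(window_start = "ws", window_end = "we")
  validate_stations(st)
}

validate_stations <- function(stations) {
  for (i in seq_len(nrow(stations))) {
    s <- stations$window_start[[i]]
    e <- stations$window_end[[i]]
    if (length(s) != length(e) || any(s >= e)) {
      abort(paste0("station ", stations$station_id[i],
                   ": deployment windows must satisfy start < end"))
    }
    if (length(s) > 1 && any(s[-1] < e[-length(e)])) {
      abort(paste0("station ", stations$station_id[i],
                   ": deployment windows overlap"))
    }
  }
  tibble::as_tibble(stations)
}

#' Read tag deployment metadata
#'
#' @param path CSV with columns `tag_id,tag_date,tag_station,sex,island_id`
#'   and optionally `battery_days` (defaults to 1350, the V16 battery life).
#' @return Tibble with `tag_date` as `Date`, `sex` one of `F`, `M`, `ND`.
#' @export
read_tags <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  out <- tibble::tibble(
    tag_id = as.character(raw$tag_id),
    tag_date = as.Date(raw$tag_date),
    tag_station = as.character(raw$tag_station),
    sex = as.character(raw$sex),
    island_id = as.character(raw$island_id),
    battery_days = if ("battery_days" %in% names(raw))
      as.integer(raw$battery_days) else 1350L
  )
  bad_sex <- setdiff(unique(out$sex), c("F", "M", "ND"))
  if (length(bad_sex) > 0) {
    abort(paste0("sex must be one of F, M, ND; found: ",
                 paste(bad_sex, collapse = ", ")))
  }
  if (any(is.na(out$tag_date))) abort("unparseable tag_date")
  out
}

#' Restrict detections to receiver deployment windows
#'
#' A detection can only be genuine while its receiver was deployed; records
#' outside every half-open `[start, end)` deployment window of their station
#' are dropped. The drop is the contract, not an error: the number removed
#' is reported via a message and as an attribute.
#'
#' @param detections Canonical detection tibble.
#' @param stations Station table with `window_start`/`window_end`
#'   list-columns.
#' @param quiet Suppress the message.
#' @return Kept detections, with attribute `n_dropped`.
#' @export
filter_to_deployment_windows <- function(detections, stations, quiet = FALSE) {
  keep <- rep(FALSE, nrow(detections))
  for (j in seq_len(nrow(stations))) {
    idx <- which(detections$station_id == stations$station_id[j])
    if (length(idx) == 0) next
    t <- detections$timestamp[idx]
    s <- stations$window_start[[j]]
    e <- stations$window_end[[j]]
    inside <- rep(FALSE, length(idx))
    for (w in seq_along(s)) inside <- inside | (t >= s[w] & t < e[w])
    keep[idx] <- inside
  }
  out <- detections[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  if (!quiet) {
    inform(paste0("filter_to_deployment_windows: dropped ", sum(!keep),
                  " of ", length(keep), " detections"))
  }
  out
}
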