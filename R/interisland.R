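#' Default inter-island great-circle distances
#'
#' Straight-line distances between the Eastern Tropical Pacific islands
#' used for transfer-speed calculations: Cocos-Galapagos 710 km and
#' Cocos-Malpelo 627 km. Distances are symmetric; the table lists each
#' unordered pair once.
#'
#' @return Tibble `island_a`, `island_b`, `distance_km`.
#' @export
island_distances <- function() {
  tibble::tibble(island_a = c("cocos", "cocos"),
                 island_b = c("galapagos", "malpelo"),
                 distance_km = c(710, 627))
}

#' Haversine distance between two stations, km
#'
#' Fallback for island pairs without a configured distance; uses the
#' great-circle (haversine) distance between representative station
#' coordinates.
#'
#' @param lat1,lon1,lat2,lon2 Decimal degrees.
#' @return Distance in kilometres.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2)) / 1000
}

lookup_distance <- function(from, to, distances) {
  i <- which((distances$island_a == from & distances$island_b == to) |
               (distances$island_a == to & distances$island_b == from))
  if (length(i) == 0) NA_real_ else distances$distance_km[i[1]]
}

#' Detect inter-island transfers
#'
#' Scans each tag's island-labelled detection sequence in time order and
#' emits one transfer per change of island: departure is the last detection
#' at the origin island before the change, arrival the first detection at
#' the destination. Travel time is therefore a lower bound on the true
#' at-sea time. Speed is the configured straight-line distance divided by
#' that travel time.
#'
#' @param detections Canonical detection tibble pooled over islands.
#' @param stations Station table carrying `island_id`.
#' @param distances Distance table as from [island_distances()]; pairs not
#'   listed fall back to the haversine distance between the involved
#'   stations (or `NA` without coordinates).
#' @return Tibble of transfers: `tag_id`, `from_island`, `to_island`,
#'   `departure`, `arrival`, `travel_days`, `distance_km`, `speed_ms`.
#' @export
detect_transfers <- function(detections, stations,
                             distances = island_distances()) {
  det <- detections
  det$island <- stations$island_id[match(det$station_id, stations$station_id)]
  if (any(is.na(det$island))) abort("detections reference stations without island_id")

  out <- det |>
    dplyr::group_by(.data$tag_id) |>
    dplyr::group_modify(function(d, key) {
      isl <- d$island
      chg <- which(isl[-1] != isl[-length(isl)])
      if (length(chg) == 0) {
        return(tibble::tibble(from_island = character(), to_island = character(),
                              departure = as.POSIXct(character(), tz = "UTC"),
                              arrival = as.POSIXct(character(), tz = "UTC"),
                              from_station = character(), to_station = character()))
      }
      tibble::tibble(from_island = isl[chg], to_island = isl[chg + 1],
                     departure = d$timestamp[chg], arrival = d$timestamp[chg + 1],
                     from_station = d$station_id[chg],
                     to_station = d$station_id[chg + 1])
    }) |>
    dplyr::ungroup()
  if (nrow(out) == 0) {
    return(tibble::tibble(tag_id = character(), from_island = character(),
                          to_island = character(),
                          departure = as.POSIXct(character(), tz = "UTC"),
                          arrival = as.POSIXct(character(), tz = "UTC"),
                          travel_days = numeric(), distance_km = numeric(),
                          speed_ms = numeric()))
  }
  out$travel_days <- as.numeric(out$arrival - out$departure, units = "days")
  out$distance_km <- purrr::pmap_dbl(
    list(out$from_island, out$to_island, out$from_station, out$to_station),
    function(fi, ti, fs, ts) {
      d <- lookup_distance(fi, ti, distances)
      if (!is.na(d)) return(d)
      a <- match(fs, stations$station_id); b <- match(ts, stations$station_id)
      if (any(is.na(c(stations$latitude[c(a, b)], stations$longitude[c(a, b)]))))
        return(NA_real_)
      haversine_km(stations$latitude[a], stations$longitude[a],
                   stations$latitude[b], stations$longitude[b])
    })
  out$speed_ms <- route_speed(out$distance_km, out$travel_days)
  out[, c("tag_id", "from_island", "to_island", "departure", "arrival",
          "travel_days", "distance_km", "speed_ms")]
}

#' Straight-line speed of a transfer
#'
#' @param distance_km Great-circle route distance, km (> 0).
#' @param travel_days Travel time, days (> 0).
#' @return Speed in metres per second: `distance_km * 1000 /
#'   (travel_days * 86400)`.
#' @examples
#' route_speed(710, 10)   # 0.82 m/s at 2 decimals
#' @export
route_speed <- function(distance_km, travel_days) {
  if (any(!is.na(distance_km) & distance_km <= 0) ||
      any(!is.na(travel_days) & travel_days <= 0)) {
    abort("distance_km and travel_days must be positive")
  }
  distance_km * 1000 / (travel_days * 86400)
}

#' Summarise transfers per ordered route
#'
#' One row per ordered island pair with trip count, median/min/max travel
#' time and the maximum straight-line speed (attained on the fastest trip).
#' The median of an even number of trips is the midpoint of the central
#' pair.
#'
#' @param transfers Output of [detect_transfers()].
#' @return Tibble: `from_island`, `to_island`, `n_trips`,
#'   `median_travel_days`, `min_travel_days`, `max_travel_days`,
#'   `distance_km`, `max_speed_ms` (2-decimal rounding applied to speed).
#' @export
summarize_routes <- function(transfers) {
  if (nrow(transfers) == 0) {
    return(tibble::tibble(from_island = character(), to_island = character(),
                          n_trips = integer(), median_travel_days = numeric(),
                          min_travel_days = numeric(),
                          max_travel_days = numeric(), distance_km = numeric(),
                          max_speed_ms = numeric()))
  }
  transfers |>
    dplyr::group_by(.data$from_island, .data$to_island) |>
    dplyr::summarise(
      n_trips = dplyr::n(),
      median_travel_days = median(.data$travel_days),
      min_travel_days = min(.data$travel_days),
      max_travel_days = max(.data$travel_days),
      distance_km = .data$distance_km[1],
      max_speed_ms = round(route_speed(.data$distance_km[1],
                                       min(.data$travel_days)), 2),
      .groups = "drop")
}
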