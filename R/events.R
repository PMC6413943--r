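#' Segment a detection stream into residence events
#'
#' Sweeps each tag's time-ordered detections and groups them into residence
#' events at single receivers, following the V-track-style criteria used for
#' VEMCO arrays: an event at station S opens once `min_pings` detections at S
#' accumulate with consecutive same-station gaps no longer than `timeout_s`
#' seconds; while open it is extended by further S detections within the
#' timeout; it closes when (a) a later detection shows the gap since the last
#' S detection exceeded the timeout (`timeout`), (b) `other_station_pings`
#' detections at one single other station S' accumulate after the last S
#' detection (`other_station`; those detections then seed the candidate event
#' at S'), or (c) the stream ends (`stream_end`). The event start/end are the
#' first/last S detections belonging to it.
#'
#' Detections at a station whose own run is interrupted by a
#' longer-than-timeout same-station gap restart that station's run; the
#' terminating detections at another receiver must themselves satisfy the gap
#' rule, since they seed a candidate event under it. When a detection arrives
#' beyond `last-S-detection + timeout_s`, timeout closure takes precedence
#' over other-station closure.
#'
#' @param detections Canonical detection tibble (may contain several tags;
#'   each tag's stream is segmented independently). Must be time-sorted
#'   within tag or an error is raised.
#' @param min_pings Minimum detections at a receiver before an event is
#'   recorded (default 2).
#' @param timeout_s Maximum inter-ping gap, seconds, within an event
#'   (default 900).
#' @param other_station_pings Number of detections at a single other
#'   receiver that terminate an open event (default 2).
#' @return Tibble of events: `tag_id`, `station_id`, `start`, `end`,
#'   `n_detections`, `duration_s`, `termination_reason`.
#' @examples
#' st <- data.frame(station_id = c("A", "B"))
#' det <- as_detections(data.frame(
#'   tag_id = "t1", station_id = c("A", "A", "B", "B"),
#'   timestamp = as.POSIXct("2012-01-01", tz = "UTC") + c(0, 300, 400, 500)))
#' segment_events(det)
#' @export
segment_events <- function(detections, min_pings = 2L, timeout_s = 900,
                           other_station_pings = 2L) {
  if (nrow(detections) == 0) return(empty_events())
  detections |>
    dplyr::group_by(.data$tag_id) |>
    dplyr::group_modify(~ segment_one_tag(.x, .y$tag_id, min_pings, timeout_s,
                                          other_station_pings)) |>
    dplyr::ungroup() |>
    dplyr::relocate("tag_id")
}

empty_events <- function() {
  tibble::tibble(tag_id = character(), station_id = character(),
                 start = as.POSIXct(character(), tz = "UTC"),
                 end = as.POSIXct(character(), tz = "UTC"),
                 n_detections = integer(), duration_s = numeric(),
                 termination_reason = character())
}

## The sweep for a single tag. State:
##  - open event (station, start idx/time, last S time, n)
##  - per-station candidate runs (first time, last time, count), reset by
##    own-station gap violations and, while an event at S is open, by every
##    S detection.
segment_one_tag <- function(det, tag, min_pings, timeout_s, other_station_pings) {
  tt <- as.numeric(det$timestamp)
  if (is.unsorted(tt)) abort("detections must be sorted by timestamp within tag")
  st <- det$station_id
  n <- length(tt)

  runs <- list()       # station -> c(first, last, count)
  open <- NULL         # list(station, start, last, n)
  out <- list()

  close_event <- function(reason) {
    out[[length(out) + 1L]] <<- list(station_id = open$station,
                                     start = open$start, end = open$last,
                                     n_detections = open$n,
                                     termination_reason = reason)
    open <<- NULL
  }

  for (i in seq_len(n)) {
    s <- st[i]; t <- tt[i]

    ## timeout closure first: the gap exceeded the threshold before this
    ## detection arrived, whatever its station
    if (!is.null(open) && (t - open$last) > timeout_s) {
      close_event("timeout")
    }

    if (!is.null(open) && s == open$station) {
      ## extends the open event; other-station accumulators reset
      open$last <- t
      open$n <- open$n + 1L
      runs <- list()
      next
    }

    ## update this station's candidate run (own gap rule)
    r <- runs[[s]]
    if (is.null(r) || (t - r[2]) > timeout_s) {
      r <- c(t, t, 1)
    } else {
      r <- c(r[1], t, r[3] + 1)
    }
    runs[[s]] <- r

    if (!is.null(open)) {
      if (r[3] >= other_station_pings) {
        close_event("other_station")
        ## the accumulated detections seed the candidate at s; open it if
        ## the run already satisfies the opening threshold
        if (r[3] >= min_pings) {
          open <- list(station = s, start = r[1], last = r[2], n = as.integer(r[3]))
          runs <- list()
        }
      }
    } else if (r[3] >= min_pings) {
      open <- list(station = s, start = r[1], last = r[2], n = as.integer(r[3]))
      runs <- list()
    }
  }
  if (!is.null(open)) close_event("stream_end")

  if (length(out) == 0) return(empty_events()[, -1])
  ev <- dplyr::bind_rows(lapply(out, function(e) {
    tibble::tibble(station_id = e$station_id,
                   start = .POSIXct(e$start, tz = "UTC"),
                   end = .POSIXct(e$end, tz = "UTC"),
                   n_detections = e$n_detections,
                   duration_s = e$end - e$start,
                   termination_reason = e$termination_reason)
  }))
  ev
}

#' Classify residence events as visits or transits
#'
#' An event shorter than the time an animal cruising at ~0.5 m/s would need
#' to cross the receiver's detection range (15 min here) is taken as a
#' transit — the animal passing through — rather than residence. The
#' threshold is strict: an event of exactly `transit_min` minutes is a visit.
#'
#' @param events Output of [segment_events()].
#' @param transit_min Transit threshold, minutes (default 15).
#' @return The events tibble with a logical `is_transit` column.
#' @export
classify_visits <- function(events, transit_min = 15) {
  dplyr::mutate(events, is_transit = .data$duration_s < transit_min * 60)
}

#' Count non-transit visits per station
#'
#' @param visits Output of [classify_visits()].
#' @return Tibble `station_id`, `n_visits`, `n_transits`,
#'   `total_duration_h` (visit hours, transits excluded).
#' @export
count_visits <- function(visits) {
  visits |>
    dplyr::group_by(.data$station_id) |>
    dplyr::summarise(
      n_visits = sum(!.data$is_transit),
      n_transits = sum(.data$is_transit),
      total_duration_h = sum(.data$duration_s[!.data$is_transit]) / 3600,
      .groups = "drop")
}
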