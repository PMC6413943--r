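#' Local calendar date of a detection
#'
#' Behavioural "days at the island" are local days; timestamps are stored in
#' UTC and shifted by a fixed offset when converted to dates (no daylight
#' saving at these latitudes).
#'
#' @param timestamp POSIXct, UTC.
#' @param utc_offset_hours Hours to add to UTC to obtain local time
#'   (default -6, Cocos Island).
#' @return `Date` vector.
#' @export
local_date <- function(timestamp, utc_offset_hours = -6) {
  as.Date(timestamp + utc_offset_hours * 3600, tz = "UTC")
}

#' Per-tag monitoring duration and residency index
#'
#' For each tag, the monitoring duration is the count of calendar days from
#' the tagging date through the date of its last detection, both inclusive
#' (a shark tagged and last heard the same day has monitored 1 day). The
#' residency index (RI) is the number of distinct local days with at least
#' one detection anywhere on the focal island, divided by the monitoring
#' duration; RI = 1 means the animal was detected every day from tagging to
#' its last detection.
#'
#' @param detections Canonical detection tibble.
#' @param tags Tag deployment tibble (see [read_tags()]).
#' @param stations Station table; used to restrict detections to
#'   `focal_island`. If `NULL`, all detections count.
#' @param focal_island `island_id` whose array defines "detected at the
#'   island" (default `"cocos"`); ignored when `stations` is `NULL`.
#' @param utc_offset_hours Offset used to convert timestamps to local days.
#' @return Tibble, one row per tag: `tag_id`, `tag_date`,
#'   `last_detection_date`, `monitoring_days`, `detected_days` (count),
#'   `residency_index`. Tags with no detections on the focal island are
#'   returned with `NA` summaries and flagged in `has_detections`.
#' @export
track_summaries <- function(detections, tags, stations = NULL,
                            focal_island = "cocos", utc_offset_hours = -6) {
  det <- detections
  if (!is.null(stations)) {
    focal_stations <- stations$station_id[stations$island_id == focal_island]
    det <- det[det$station_id %in% focal_stations, , drop = FALSE]
  }
  det$date <- local_date(det$timestamp, utc_offset_hours)

  per_tag <- det |>
    dplyr::group_by(.data$tag_id) |>
    dplyr::summarise(last_detection_date = max(.data$date),
                     detected_days = dplyr::n_distinct(.data$date),
                     first_detection_date = min(.data$date),
                     .groups = "drop")

  out <- dplyr::left_join(tags[, c("tag_id", "tag_date")], per_tag, by = "tag_id")
  bad <- !is.na(out$first_detection_date) & out$first_detection_date < out$tag_date
  if (any(bad)) {
    abort(paste0("detections precede tagging date for tag(s): ",
                 paste(out$tag_id[bad], collapse = ", ")))
  }
  out$has_detections <- !is.na(out$last_detection_date)
  out$monitoring_days <- ifelse(out$has_detections,
    as.integer(out$last_detection_date - out$tag_date) + 1L, NA_integer_)
  out$residency_index <- out$detected_days / out$monitoring_days
  out$first_detection_date <- NULL
  tibble::as_tibble(out)
}

#' Monitoring duration of one tag
#'
#' Calendar days from tagging through last detection, inclusive of both.
#'
#' @param tag_date Tagging `Date`.
#' @param last_detection_date `Date` of the final detection.
#' @return Integer day count (same-day tag and detection gives 1).
#' @export
monitoring_duration <- function(tag_date, last_detection_date) {
  if (any(last_detection_date < tag_date)) {
    abort("last_detection_date precedes tag_date")
  }
  as.integer(last_detection_date - tag_date) + 1L
}

#' Residency index from day counts
#'
#' @param detected_days Number of distinct days with a detection.
#' @param monitoring_days Monitoring duration in days (>= 1).
#' @return `detected_days / monitoring_days`, in (0, 1].
#' @export
residency_index <- function(detected_days, monitoring_days) {
  if (any(monitoring_days < 1)) abort("monitoring_days must be >= 1")
  if (any(detected_days < 1 | detected_days > monitoring_days)) {
    abort("detected_days must lie in [1, monitoring_days]")
  }
  detected_days / monitoring_days
}

#' Daily presence matrix
#'
#' Binary tag-by-date presence: 1 iff the tag was detected at least once on
#' that local date. With `season_align = TRUE` columns are re-indexed as
#' days since the most recent July 1st (day-of-season 0-364), so that
#' multi-year tracks align on a common seasonal axis.
#'
#' @inheritParams track_summaries
#' @param season_align Re-index dates to days since July 1st.
#' @param long Return a long tibble (`tag_id`, `date`/`season_day`,
#'   `present`) instead of a wide 0/1 matrix-shaped tibble.
#' @return Wide tibble (one row per tag, one 0/1 column per date) or the
#'   long form.
#' @export
daily_presence_matrix <- function(detections, tags, utc_offset_hours = -6,
                                  season_align = FALSE, long = FALSE) {
  det <- detections
  det$date <- local_date(det$timestamp, utc_offset_hours)
  pres <- dplyr::distinct(det, .data$tag_id, .data$date)
  all_dates <- seq(min(pres$date), max(pres$date), by = "day")
  grid <- tidyr::expand_grid(tag_id = unique(tags$tag_id), date = all_dates)
  grid <- dplyr::left_join(grid,
                           dplyr::mutate(pres, present = 1L),
                           by = c("tag_id", "date"))
  grid$present <- dplyr::coalesce(grid$present, 0L)
  if (season_align) {
    yr <- as.integer(format(grid$date, "%Y"))
    jul1 <- as.Date(paste0(yr, "-07-01"))
    before <- grid$date < jul1
    jul1[before] <- as.Date(paste0(yr[before] - 1L, "-07-01"))
    grid$season_day <- as.integer(grid$date - jul1)
    grid$date <- NULL
    grid <- grid |>
      dplyr::group_by(.data$tag_id, .data$season_day) |>
      dplyr::summarise(present = max(.data$present), .groups = "drop")
    if (long) return(grid)
    return(tidyr::pivot_wider(grid, names_from = "season_day",
                              values_from = "present", values_fill = 0L))
  }
  if (long) return(grid)
  tidyr::pivot_wider(grid, names_from = "date", values_from = "present",
                     values_fill = 0L)
}

#' Tagging-bias track correction
#'
#' Because an animal is necessarily at its tagging site when tagged (and may
#' have been there for an unknown time before), the initial run of visits at
#' the tagging location inflates apparent preference for that site. The
#' corrected track begins at the earlier of: (a) the start of the first
#' visit at any station other than the tagging station, or (b) the start of
#' the first tagging-station visit that follows an absence of at least
#' `absence_h` hours from the tagging station (gap between successive
#' tagging-station visits). Visits starting before that instant are dropped.
#' If neither rule ever fires the whole track is dropped
#' (`rule = "none_applicable"`).
#'
#' The returned tibble carries attributes `analysis_start` and `rule`
#' (`"other_site_first"`, `"absent_24h"` or `"none_applicable"`). Applying
#' the correction to an already-corrected track is the identity.
#'
#' @param visits Time-ordered visit tibble of one tag (from
#'   [classify_visits()] or [segment_events()]).
#' @param tag_station Station at which the tag was attached.
#' @param absence_h Absence threshold, hours (default 24).
#' @return The retained visits, with correction attributes.
#' @export
correct_tagging_bias <- function(visits, tag_station, absence_h = 24) {
  if (!is.null(attr(visits, "analysis_start")) || !is.null(attr(visits, "rule"))) {
    return(visits)  # already corrected: idempotent by construction
  }
  stopifnot(nrow(visits) == 0 || !is.unsorted(as.numeric(visits$start)))

  start_a <- start_b <- as.POSIXct(NA_real_, tz = "UTC")
  other <- visits$station_id != tag_station
  if (any(other)) start_a <- visits$start[which(other)[1]]
  at_tag <- which(!other)
  if (length(at_tag) >= 2) {
    gaps <- as.numeric(visits$start[at_tag[-1]]) -
      as.numeric(visits$end[at_tag[-length(at_tag)]])
    hit <- which(gaps >= absence_h * 3600)
    if (length(hit) > 0) start_b <- visits$start[at_tag[hit[1] + 1L]]
  }

  candidates <- c(start_a, start_b)
  if (all(is.na(candidates))) {
    kept <- visits[0, , drop = FALSE]
    attr(kept, "analysis_start") <- as.POSIXct(NA_real_, tz = "UTC")
    attr(kept, "rule") <- "none_applicable"
    return(kept)
  }
  analysis_start <- min(candidates, na.rm = TRUE)
  rule <- if (!is.na(start_a) && analysis_start == start_a) {
    "other_site_first"
  } else {
    "absent_24h"
  }
  kept <- visits[visits$start >= analysis_start, , drop = FALSE]
  attr(kept, "analysis_start") <- analysis_start
  attr(kept, "rule") <- rule
  kept
}

#' Apply the tagging-bias correction to a cohort
#'
#' @param visits Visit tibble for many tags.
#' @param tags Tag deployment tibble with `tag_station`.
#' @inheritParams correct_tagging_bias
#' @return Tibble of retained visits across tags plus columns
#'   `analysis_start` and `correction_rule`.
#' @export
correct_cohort <- function(visits, tags, absence_h = 24) {
  visits |>
    dplyr::group_by(.data$tag_id) |>
    dplyr::group_modify(function(v, key) {
      st <- tags$tag_station[match(key$tag_id, tags$tag_id)]
      cv <- correct_tagging_bias(v, st, absence_h)
      if (nrow(cv) == 0) return(cv)
      cv$analysis_start <- attr(cv, "analysis_start")
      cv$correction_rule <- attr(cv, "rule")
      cv
    }) |>
    dplyr::ungroup()
}

#' Cohort residency-index summary
#'
#' Mean and sample standard deviation of RI over tags monitored at least
#' `min_monitoring_days`, plus the Pearson correlation between monitoring
#' duration and RI (longer tracks tend to show lower RI).
#'
#' @param summaries Output of [track_summaries()].
#' @param min_monitoring_days Minimum monitoring duration to include
#'   (default 0: all tags with detections).
#' @return One-row tibble: `n`, `mean_ri`, `sd_ri` (0 with `single_tag =
#'   TRUE` when n = 1), `cor_duration_ri`, `cor_df`, `cor_p`. An empty
#'   cohort yields `n = 0` and `NA` statistics.
#' @export
summarize_ri <- function(summaries, min_monitoring_days = 0) {
  x <- summaries[summaries$has_detections &
                   summaries$monitoring_days >= min_monitoring_days, ,
                 drop = FALSE]
  n <- nrow(x)
  if (n == 0) {
    return(tibble::tibble(n = 0L, mean_ri = NA_real_, sd_ri = NA_real_,
                          single_tag = NA, cor_duration_ri = NA_real_,
                          cor_df = NA_integer_, cor_p = NA_real_))
  }
  ct <- if (n >= 3 && sd(x$monitoring_days) > 0 && sd(x$residency_index) > 0) {
    stats::cor.test(x$monitoring_days, x$residency_index)
  } else NULL
  tibble::tibble(
    n = n,
    mean_ri = mean(x$residency_index),
    sd_ri = if (n > 1) sd(x$residency_index) else 0,
    single_tag = n == 1,
    cor_duration_ri = if (!is.null(ct)) unname(ct$estimate) else NA_real_,
    cor_df = if (!is.null(ct)) unname(ct$parameter) else NA_integer_,
    cor_p = if (!is.null(ct)) ct$p.value else NA_real_
  )
}
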