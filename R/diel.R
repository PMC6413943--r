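#' Hourly detection (or shark-presence) counts
#'
#' Bins detections into consecutive local-time hours spanning the record.
#' `by = "detections"` counts pings; `by = "sharks"` counts distinct tags
#' heard within the hour (the series used for the presence periodogram,
#' since one animal parked beside a receiver otherwise dominates the
#' spectrum).
#'
#' @param detections Canonical detection tibble.
#' @param utc_offset_hours Local-time offset applied before binning
#'   (default -6).
#' @param by Count `"detections"` or distinct `"sharks"` per hour.
#' @return Tibble with one row per hour of the contiguous span:
#'   `bin_start` (local wall-clock, encoded UTC), `hour_of_day` (0-23),
#'   `count`.
#' @export
hourly_counts <- function(detections, utc_offset_hours = -6,
                          by = c("detections", "sharks")) {
  by <- match.arg(by)
  local <- detections$timestamp + utc_offset_hours * 3600
  bin <- lubridate::floor_date(local, "hour")
  tab <- if (by == "detections") {
    dplyr::count(tibble::tibble(bin = bin), .data$bin, name = "count")
  } else {
    tibble::tibble(bin = bin, tag_id = detections$tag_id) |>
      dplyr::distinct() |>
      dplyr::count(.data$bin, name = "count")
  }
  span <- seq(min(bin), max(bin), by = 3600)
  out <- tibble::tibble(bin_start = span)
  out <- dplyr::left_join(out, tab, by = c(bin_start = "bin"))
  out$count <- dplyr::coalesce(out$count, 0L)
  out$hour_of_day <- lubridate::hour(out$bin_start)
  out[, c("bin_start", "hour_of_day", "count")]
}

#' Hour-of-day profile
#'
#' Aggregates an hourly series (or detections directly) into the 24
#' hour-of-day bins.
#'
#' @inheritParams hourly_counts
#' @return 24-row tibble `hour_of_day`, `count`.
#' @export
hour_profile <- function(detections, utc_offset_hours = -6,
                         by = c("detections", "sharks")) {
  hourly_counts(detections, utc_offset_hours, by) |>
    dplyr::group_by(.data$hour_of_day) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    tidyr::complete(hour_of_day = 0:23, fill = list(count = 0L))
}

#' Dominant period of an hourly series
#'
#' Removes the series mean and computes the raw periodogram
#' I(f_k) = |sum_t x_t e^{-2 pi i f_k t}|^2 / n at the Fourier frequencies
#' f_k = k/n, k = 1..floor(n/2); the dominant period is the reciprocal of
#' the frequency with maximal power, in hours. A diel presence rhythm shows
#' up as a sharp peak at 24 h.
#'
#' @param counts Numeric vector of hourly counts, or the tibble from
#'   [hourly_counts()] (its `count` column is used). Needs >= 48 hours.
#' @return List: `period_h` (dominant period, hours; `NA` for a constant
#'   series), `spectrum` tibble (`frequency` cycles/hour, `period_h`,
#'   `power`).
#' @export
periodogram_peak <- function(counts) {
  if (is.data.frame(counts)) counts <- counts$count
  x <- as.numeric(counts)
  n <- length(x)
  if (n < 48) abort("need at least 48 hourly bins")
  x <- x - mean(x)
  if (all(x == 0)) {
    return(list(period_h = NA_real_,
                spectrum = tibble::tibble(frequency = numeric(),
                                          period_h = numeric(),
                                          power = numeric())))
  }
  ft <- fft(x)
  k <- seq_len(floor(n / 2))
  spec <- tibble::tibble(frequency = k / n,
                         period_h = n / k,
                         power = Mod(ft[k + 1])^2 / n)
  list(period_h = spec$period_h[which.max(spec$power)], spectrum = spec)
}

#' Map detection times to circle angles
#'
#' Hour-of-day at minute resolution mapped to degrees: angle =
#' (hour + minute/60 + second/3600) * 15, so midnight is 0 degrees and noon
#' 180.
#'
#' @inheritParams hourly_counts
#' @return Numeric vector of angles in \[0, 360).
#' @export
detection_angles <- function(detections, utc_offset_hours = -6) {
  local <- detections$timestamp + utc_offset_hours * 3600
  (lubridate::hour(local) + lubridate::minute(local) / 60 +
     lubridate::second(local) / 3600) * DEG_PER_HOUR
}

#' Circular summary of diel timing
#'
#' Computes the mean resultant length r, mean angle, Rayleigh test of
#' uniformity (Z = n r^2, with the standard large-sample p approximation)
#' and Rao's spacing test U with a seeded Monte-Carlo p-value under
#' circular uniformity.
#'
#' @param angles_deg Angles in degrees.
#' @param rao_reps Monte-Carlo replicates for Rao's p (default 10000).
#' @param rao_seed Optional integer; if given, the Monte-Carlo draw is made
#'   reproducible without disturbing the caller's RNG stream.
#' @return One-row tibble: `n`, `mean_angle` (degrees in \[0,360), `NA`
#'   when r = 0), `mean_hour`, `r`, `rayleigh_Z`, `rayleigh_p`, `rao_U`
#'   (degrees), `rao_p`.
#' @export
circular_stats <- function(angles_deg, rao_reps = 10000, rao_seed = NULL) {
  n <- length(angles_deg)
  if (n == 0) abort("no angles supplied")
  th <- angles_deg * pi / 180
  C <- sum(cos(th)); S <- sum(sin(th))
  r <- sqrt(C^2 + S^2) / n
  mean_angle <- if (r < 1e-12) NA_real_ else (atan2(S, C) * 180 / pi) %% 360
  Z <- n * r^2
  rayleigh_p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - Z * n)) - (1 + 2 * n))
  rayleigh_p <- min(1, rayleigh_p)

  U <- rao_spacing_U(angles_deg)
  rao_p <- NA_real_
  if (n >= 2) {
    draw <- function() {
      null_U <- replicate(rao_reps, rao_spacing_U(stats::runif(n, 0, 360)))
      (1 + sum(null_U >= U)) / (rao_reps + 1)
    }
    rao_p <- if (is.null(rao_seed)) draw() else with_local_seed(rao_seed, draw())
  }
  tibble::tibble(n = n, mean_angle = mean_angle,
                 mean_hour = mean_angle / DEG_PER_HOUR,
                 r = r, rayleigh_Z = Z, rayleigh_p = rayleigh_p,
                 rao_U = U, rao_p = rao_p)
}

#' Rao's spacing statistic
#'
#' U = 1/2 * sum |T_i - 360/n| over the n circular spacings T_i of the
#' sorted angles (including the wrap-around gap). U = 0 iff the angles are
#' perfectly evenly spaced; clustering inflates U.
#'
#' @param angles_deg Angles in degrees.
#' @return U in degrees.
#' @export
rao_spacing_U <- function(angles_deg) {
  n <- length(angles_deg)
  if (n < 2) return(NA_real_)
  a <- sort(angles_deg %% 360)
  gaps <- c(diff(a), 360 - a[n] + a[1])
  0.5 * sum(abs(gaps - 360 / n))
}

## Run code under a temporary seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Full diel report
#'
#' Convenience wrapper: hourly series (sharks per hour) with periodogram
#' peak, plus circular statistics on the detection times.
#'
#' @inheritParams hourly_counts
#' @inheritParams circular_stats
#' @return List: `summary` (one-row tibble with dominant period and the
#'   circular statistics), `hourly`, `spectrum`, `profile`.
#' @export
diel_report <- function(detections, utc_offset_hours = -6, rao_reps = 10000,
                        rao_seed = NULL) {
  hourly <- hourly_counts(detections, utc_offset_hours, by = "sharks")
  pk <- periodogram_peak(hourly)
  circ <- circular_stats(detection_angles(detections, utc_offset_hours),
                         rao_reps = rao_reps, rao_seed = rao_seed)
  list(summary = dplyr::bind_cols(tibble::tibble(period_h = pk$period_h), circ),
       hourly = hourly, spectrum = pk$spectrum,
       profile = hour_profile(detections, utc_offset_hours))
}
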