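test_that("monitoring duration counts both endpoints", {
  expect_equal(monitoring_duration(as.Date("2012-01-01"), as.Date("2012-01-01")), 1L)
  expect_equal(monitoring_duration(as.Date("2012-01-01"), as.Date("2012-01-05")), 5L)
  expect_error(monitoring_duration(as.Date("2012-01-05"), as.Date("2012-01-01")))
})

test_that("residency index follows its definition", {
  expect_equal(residency_index(5, 5), 1)
  expect_equal(residency_index(3, 5), 0.6)   # detections on D0, D1, D4
  expect_error(residency_index(0, 5))
  expect_error(residency_index(6, 5))
})

test_that("track summaries equal a recount from raw dates", {
  set.seed(21)
  sim <- simulate_detections(sim_config(
    n_sharks = 5, study_days = 40, stations = cocos_stations(),
    dist_range_m = 100, night_leak = 0, rng_seed = 77))
  ts <- track_summaries(sim$detections, sim$tags, sim$stations)
  dates <- local_date(sim$detections$timestamp, -6)
  for (k in seq_len(nrow(ts))) {
    d <- dates[sim$detections$tag_id == ts$tag_id[k]]
    expect_equal(ts$detected_days[k], length(unique(d)))
    expect_equal(ts$monitoring_days[k],
                 as.integer(max(d) - ts$tag_date[k]) + 1L)
    expect_equal(ts$residency_index[k],
                 length(unique(d)) / (as.integer(max(d) - ts$tag_date[k]) + 1L))
  }
})

test_that("RI ignores detection multiplicity within a day", {
  st <- cocos_stations()
  t0 <- as.POSIXct("2011-09-01 18:00:00", tz = "UTC")
  det1 <- as_detections(make_det(rep("alcyone", 3), c(0, 86400, 4 * 86400),
                                 t0 = t0), st)
  det2 <- as_detections(make_det(rep("alcyone", 6),
                                 c(0, 10, 86400, 86410, 4 * 86400, 4 * 86400 + 9),
                                 t0 = t0), st)
  tags <- tibble::tibble(tag_id = "t1", tag_date = as.Date("2011-09-01"),
                         tag_station = "alcyone", sex = "ND",
                         island_id = "cocos", battery_days = 1350L)
  r1 <- track_summaries(det1, tags, st)$residency_index
  r2 <- track_summaries(det2, tags, st)$residency_index
  expect_equal(r1, r2)
  expect_equal(r1, 3 / 5)
})

test_that("mean RI at daily presence 0.5 matches a direct Bernoulli oracle", {
  set.seed(14)
  n_days <- 400
  sim <- simulate_detections(sim_config(
    n_sharks = 25, study_days = n_days, stations = cocos_stations(),
    p_res = 0.5, dist_range_m = 100, night_leak = 0,
    site_mu_log_h = vapply(default_site_mu(), function(x) log(0.4),
                           numeric(1)),
    rng_seed = 14))
  ts <- track_summaries(sim$detections, sim$tags, sim$stations)

  # oracle: presence Bernoulli(0.5) with day 0 forced; RI conditioned on
  # the final detected day
  oracle <- replicate(4000, {
    pres <- c(TRUE, runif(n_days - 1) < 0.5)
    last <- max(which(pres))
    sum(pres[1:last]) / last
  })
  expect_lt(abs(mean(ts$residency_index) - mean(oracle)), 0.02)
})

test_that("presence matrix has one cell per tag-day and matches detected days", {
  st <- cocos_stations()
  t0 <- as.POSIXct("2011-09-05 15:00:00", tz = "UTC")
  det <- as_detections(make_det("alcyone", 0, t0 = t0), st)
  tags <- tibble::tibble(tag_id = "t1", tag_date = as.Date("2011-09-05"))
  m <- daily_presence_matrix(det, tags)
  expect_equal(dim(m), c(1L, 2L))          # tag_id + single date column
  expect_equal(sum(m[, -1]), 1)

  set.seed(5)
  sim <- simulate_detections(sim_config(
    n_sharks = 6, study_days = 30, stations = cocos_stations(),
    dist_range_m = 100, rng_seed = 3))
  ts <- track_summaries(sim$detections, sim$tags, sim$stations)
  mm <- daily_presence_matrix(sim$detections, sim$tags)
  rs <- rowSums(mm[, -1])
  expect_equal(unname(rs[match(ts$tag_id, mm$tag_id)]), ts$detected_days)
})

test_that("a March-May presence trough injected by the generator is recovered", {
  mult <- rep(1, 12); mult[3:5] <- 0.1
  sim <- simulate_detections(sim_config(
    n_sharks = 12, study_days = 365, study_start = as.Date("2012-01-01"),
    stations = cocos_stations(as.Date("2012-01-01"), 365),
    p_res = 0.6, month_mult = mult, dist_range_m = 100,
    site_mu_log_h = vapply(default_site_mu(), function(x) log(0.4),
                           numeric(1)),
    rng_seed = 6))
  long <- daily_presence_matrix(sim$detections, sim$tags, long = TRUE)
  long$month <- as.integer(format(long$date, "%m"))
  monthly <- tapply(long$present, long$month, mean)
  trough <- mean(monthly[3:5]); rest <- mean(monthly[-(3:5)])
  expect_lt(trough, 0.35 * rest)
})

test_that("bias correction rule (a): track starts at the first off-site visit", {
  v <- make_visits(c("A", "A", "B", "A"), c(0, 5, 10, 15), rep(1, 4))
  cv <- correct_tagging_bias(v, "A")
  expect_equal(attr(cv, "rule"), "other_site_first")
  expect_equal(nrow(cv), 2)
  expect_equal(cv$station_id, c("B", "A"))
})

test_that("bias correction rule (b) and the none-applicable fallback", {
  # 30 h absence between tagging-site visits triggers rule (b)
  v <- make_visits(c("A", "A", "A"), c(0, 5, 36), rep(1, 3))
  cv <- correct_tagging_bias(v, "A")
  expect_equal(attr(cv, "rule"), "absent_24h")
  expect_equal(nrow(cv), 1)

  # all visits at the tagging site, max gap 12 h: whole track dropped
  v2 <- make_visits(rep("A", 4), c(0, 12, 24, 36), rep(0.5, 4))
  cv2 <- correct_tagging_bias(v2, "A")
  expect_equal(attr(cv2, "rule"), "none_applicable")
  expect_equal(nrow(cv2), 0)
})

test_that("bias correction matches the brute-force oracle and is idempotent", {
  set.seed(99)
  for (rep in 1:150) {
    n <- sample(2:12, 1)
    starts <- cumsum(runif(n, 0.5, 30))
    v <- make_visits(sample(c("A", "B", "C"), n, replace = TRUE,
                            prob = c(0.7, 0.2, 0.1)),
                     starts, runif(n, 0.1, 0.4))
    cv <- correct_tagging_bias(v, "A")
    orc <- oracle_bias_correction(v, "A")
    expect_equal(attr(cv, "rule"), orc$rule)
    expect_equal(nrow(cv), nrow(orc$kept))
    if (nrow(cv) > 0) {
      expect_equal(as.numeric(cv$start), as.numeric(orc$kept$start))
    }
    cv2 <- correct_tagging_bias(cv, "A")
    expect_identical(cv2, cv)
  }
})

test_that("cohort RI summary: closed forms and the empty sentinel", {
  s <- tibble::tibble(tag_id = c("a", "b"), has_detections = TRUE,
                      monitoring_days = c(10L, 20L),
                      residency_index = c(0.2, 0.6))
  out <- summarize_ri(s)
  expect_equal(out$mean_ri, 0.4)
  expect_equal(out$sd_ri, sqrt(0.08), tolerance = 1e-12)

  one <- summarize_ri(s[2, ])
  expect_equal(one$sd_ri, 0)
  expect_true(one$single_tag)

  none <- summarize_ri(s, min_monitoring_days = 100)
  expect_equal(none$n, 0L)
  expect_true(is.na(none$mean_ri))
})
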