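test_that("a single detection never opens an event", {
  det <- make_det("A", 0)
  expect_equal(nrow(segment_events(det)), 0)
})

test_that("gaps at or below the timeout extend one event to stream end", {
  det <- make_det(c("A", "A", "A"), c(0, 600, 1200))
  ev <- segment_events(det)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_s, 1200)
  expect_equal(ev$n_detections, 3L)
  expect_equal(ev$termination_reason, "stream_end")

  # boundary: a gap of exactly 900 s still belongs to the event
  ev2 <- segment_events(make_det(c("A", "A"), c(0, 900)))
  expect_equal(nrow(ev2), 1)
  ev3 <- segment_events(make_det(c("A", "A", "A"), c(0, 901, 1000)))
  expect_equal(nrow(ev3), 1)  # first ping dropped, event from 901
  expect_equal(ev3$n_detections, 2L)
})

test_that("two pings at another receiver terminate the event and seed the next", {
  det <- make_det(c("A", "A", "B", "B", "A"), c(0, 300, 400, 500, 700))
  ev <- segment_events(det)
  expect_equal(ev$station_id, c("A", "B"))
  expect_equal(ev$termination_reason, c("other_station", "stream_end"))
  expect_equal(as.numeric(ev$start - ev$start[1], units = "secs"), c(0, 400))
  expect_equal(ev$duration_s, c(300, 100))
  # the trailing A detection reaches min_pings nowhere: not in any event
  expect_equal(sum(ev$n_detections), 4)

  orc <- oracle_segment(det)
  expect_equal(ev$station_id, orc$station_id)
  expect_equal(as.numeric(ev$start), orc$start)
  expect_equal(as.numeric(ev$end), orc$end)
})

test_that("unsorted input errors; empty input yields an empty result", {
  det <- make_det(c("A", "A"), c(100, 0))
  expect_error(segment_events(det), "sorted")
  expect_equal(nrow(segment_events(make_det(character(), numeric()))), 0)
})

test_that("fuzzed streams segment identically to the brute-force oracle", {
  set.seed(2024)
  for (rep in 1:200) {
    det <- random_stream(n_det = sample(5:60, 1),
                         n_stations = sample(2:4, 1),
                         mean_gap = sample(c(120, 400, 900), 1))
    ev <- segment_events(det)
    orc <- oracle_segment(det)
    expect_equal(nrow(ev), nrow(orc))
    if (nrow(ev) > 0) {
      expect_equal(ev$station_id, orc$station_id)
      expect_equal(as.numeric(ev$start), orc$start)
      expect_equal(as.numeric(ev$end), orc$end)
      expect_equal(ev$n_detections, orc$n_detections)
      expect_equal(ev$termination_reason, orc$termination_reason)
    }
  }
})

test_that("segmentation is invariant to splitting at timeout-exceeding gaps", {
  set.seed(55)
  for (rep in 1:20) {
    det <- random_stream(40, mean_gap = 700)
    ev_whole <- segment_events(det)
    gaps <- diff(as.numeric(det$timestamp))
    cut <- which(gaps > 900)
    if (length(cut) == 0) next
    k <- sample(cut, 1)
    ev_split <- dplyr::bind_rows(segment_events(det[1:k, ]),
                                 segment_events(det[(k + 1):nrow(det), ]))
    # a stream_end at the split corresponds to a timeout in the whole stream
    norm <- function(e) {
      e$termination_reason[e$termination_reason == "stream_end"] <- "timeout"
      e[order(e$start), c("station_id", "start", "end", "n_detections")]
    }
    expect_equal(norm(as.data.frame(ev_split)), norm(as.data.frame(ev_whole)),
                 ignore_attr = TRUE)
  }
})

test_that("every detection joins at most one event", {
  set.seed(9)
  det <- random_stream(200, n_stations = 3, mean_gap = 300)
  ev <- segment_events(det)
  # total event detections cannot exceed the stream length
  expect_lte(sum(ev$n_detections), nrow(det))
  # within a station, events never overlap
  by_st <- split(ev, ev$station_id)
  for (e in by_st) {
    if (nrow(e) < 2) next
    e <- e[order(e$start), ]
    expect_true(all(as.numeric(e$start[-1]) > as.numeric(e$end[-nrow(e)])))
  }
})

test_that("infinite thresholds collapse the stream to a single event", {
  set.seed(31)
  det <- random_stream(80, n_stations = 3, mean_gap = 2000)
  ev <- segment_events(det, timeout_s = Inf, other_station_pings = .Machine$integer.max)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_detections,
               sum(det$station_id == ev$station_id &
                     det$timestamp >= ev$start))
})

test_that("transit classification uses a strict 15-minute threshold", {
  t0 <- as.POSIXct("2012-01-01", tz = "UTC")
  ev <- tibble::tibble(tag_id = "t", station_id = "A",
                       start = t0, end = t0 + c(899, 900, 3000),
                       n_detections = 5L, duration_s = c(899, 900, 3000),
                       termination_reason = "stream_end")
  vis <- classify_visits(ev)
  expect_equal(vis$is_transit, c(TRUE, FALSE, FALSE))

  set.seed(3)
  durs <- sample(c(100, 899, 900, 901, 5000), 50, replace = TRUE)
  ev2 <- tibble::tibble(tag_id = "t", station_id = "A", start = t0,
                        end = t0 + durs, n_detections = 2L,
                        duration_s = durs, termination_reason = "timeout")
  vis2 <- classify_visits(ev2)
  expect_equal(sum(vis2$is_transit), sum(durs < 900))
  counts <- count_visits(vis2)
  expect_equal(counts$n_visits + counts$n_transits, 50L)
})
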