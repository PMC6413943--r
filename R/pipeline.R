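#' Run the full residency-analysis pipeline
#'
#' Orchestrates the stages end to end: deployment-window filtering, event
#' segmentation, visit classification, tagging-bias correction, residency
#' summaries, the site-preference mixed model (with ML likelihood-ratio
#' test and pairwise contrasts), diel statistics, the movement network and
#' inter-island transfers. All stages are deterministic given the inputs,
#' parameters and `rao_seed`.
#'
#' @param detections Canonical detection tibble.
#' @param stations Station table.
#' @param tags Tag deployment tibble.
#' @param utc_offset_hours Local-time offset (default -6).
#' @param min_pings,timeout_s,other_station_pings Event-segmentation
#'   parameters (defaults 2, 900 s, 2).
#' @param transit_min Transit threshold, minutes (default 15).
#' @param absence_h Tagging-bias absence threshold, hours (default 24).
#' @param min_monitoring_days Extra RI summary restricted to tags monitored
#'   at least this long (default 120).
#' @param response Duration transform for the mixed model (default
#'   `"log_hours"`).
#' @param focal_island Island defining residency (default `"cocos"`).
#' @param distances Inter-island distance table.
#' @param rao_reps,rao_seed Rao's-test Monte-Carlo settings.
#' @param out_dir If given, stage outputs are written there as CSV.
#' @return List with elements `events`, `visits`, `corrected_visits`,
#'   `track_summaries`, `ri_summary`, `ri_summary_min_days`, `site_fit`,
#'   `site_lrt`, `site_contrasts`, `diel`, `network`, `transfers`,
#'   `routes`.
#' @export
run_pipeline <- function(detections, stations, tags,
                         utc_offset_hours = -6,
                         min_pings = 2, timeout_s = 900,
                         other_station_pings = 2,
                         transit_min = 15, absence_h = 24,
                         min_monitoring_days = 120,
                         response = "log_hours",
                         focal_island = "cocos",
                         distances = island_distances(),
                         rao_reps = 2000, rao_seed = 17,
                         out_dir = NULL) {
  det <- filter_to_deployment_windows(detections, stations, quiet = TRUE)

  events <- segment_events(det, min_pings, timeout_s, other_station_pings)
  visits <- classify_visits(events, transit_min)
  corrected <- correct_cohort(visits, tags, absence_h)

  tracks <- track_summaries(det, tags, stations, focal_island,
                            utc_offset_hours)
  ri_all <- summarize_ri(tracks)
  ri_min <- summarize_ri(tracks, min_monitoring_days)

  cocos_det <- det[det$station_id %in%
                     stations$station_id[stations$island_id == focal_island], ]

  site_fit <- site_lrt <- site_contrasts <- NULL
  model_rec <- tryCatch(visit_records(corrected, response = response),
                        error = function(e) NULL)
  if (!is.null(model_rec) && nlevels(droplevels(model_rec$site)) >= 2 &&
      dplyr::n_distinct(model_rec$tag_id) >= 2) {
    site_fit <- fit_lmm(model_rec, criterion = "REML")
    full_ml <- fit_lmm(model_rec, criterion = "ML")
    null_ml <- fit_lmm(model_rec[, c("tag_id", "response")], criterion = "ML")
    site_lrt <- lrt_site_effect(null_ml, full_ml)
    site_contrasts <- pairwise_site_contrasts(site_fit)
  }

  diel <- diel_report(cocos_det, utc_offset_hours, rao_reps = rao_reps,
                      rao_seed = rao_seed)
  network <- movement_matrix(events)
  transfers <- detect_transfers(det, stations, distances)
  routes <- summarize_routes(transfers)

  out <- list(events = events, visits = visits,
              corrected_visits = corrected, track_summaries = tracks,
              ri_summary = ri_all, ri_summary_min_days = ri_min,
              site_fit = site_fit, site_lrt = site_lrt,
              site_contrasts = site_contrasts, diel = diel,
              network = network, transfers = transfers, routes = routes)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(x, f) readr::write_csv(x, file.path(out_dir, f),
                                          progress = FALSE)
    wr(events, "events.csv")
    wr(corrected, "corrected_visits.csv")
    wr(tracks, "track_summaries.csv")
    wr(dplyr::bind_rows(ri_all, ri_min), "ri_summary.csv")
    if (!is.null(site_fit)) {
      wr(tidy(site_fit), "site_model.csv")
      wr(site_contrasts, "site_contrasts.csv")
    }
    wr(diel$summary, "diel_summary.csv")
    wr(diel$spectrum, "diel_spectrum.csv")
    export_network(network, file.path(out_dir, "network_edges.csv"),
                   file.path(out_dir, "network.graphml"))
    wr(transfers, "transfers.csv")
    wr(routes, "routes.csv")
  }
  out
}
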