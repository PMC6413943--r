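#' Build a directed movement network from residence events
#'
#' For each tag, every consecutive pair of residence events at distinct
#' stations contributes one movement on the directed edge from the first
#' station to the second. Same-station consecutive pairs are ignored unless
#' `self_loops = TRUE`. Node degree is the number of distinct partner
#' stations (union of in- and out-neighbours); node strength is the total
#' number of movements into plus out of the node.
#'
#' @param events Events tibble from [segment_events()], time-ordered within
#'   tag. Overlapping events within a tag are an error.
#' @param self_loops Count same-station consecutive pairs as self-loops.
#' @param max_gap_h Suppress transitions whose between-event gap (start of
#'   the later minus end of the earlier) exceeds this many hours
#'   (default `Inf`: all consecutive pairs count).
#' @param stations Optional station table; with `island_level = TRUE`
#'   events are mapped to their station's `island_id` so nodes are islands.
#' @param island_level Aggregate stations to islands.
#' @return `movement_network` object: list of tibbles `edges` (`from`,
#'   `to`, `count`) and `nodes` (`node`, `degree`, `strength`).
#' @export
movement_matrix <- function(events, self_loops = FALSE, max_gap_h = Inf,
                            stations = NULL, island_level = FALSE) {
  ev <- events
  if (island_level) {
    if (is.null(stations)) abort("island_level = TRUE requires a station table")
    ev$station_id <- stations$island_id[match(ev$station_id, stations$station_id)]
  }
  trans <- ev |>
    dplyr::group_by(.data$tag_id) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::group_modify(function(e, key) {
      if (nrow(e) >= 2 &&
          any(as.numeric(e$start[-1]) < as.numeric(e$end[-nrow(e)]))) {
        abort(paste0("overlapping events for tag ", key$tag_id))
      }
      if (nrow(e) < 2) return(tibble::tibble(from = character(),
                                             to = character()))
      from <- e$station_id[-nrow(e)]
      to <- e$station_id[-1]
      gap_h <- (as.numeric(e$start[-1]) - as.numeric(e$end[-nrow(e)])) / 3600
      keep <- gap_h <= max_gap_h & (self_loops | from != to)
      tibble::tibble(from = from[keep], to = to[keep])
    }) |>
    dplyr::ungroup()

  edges <- dplyr::count(trans, .data$from, .data$to, name = "count")
  node_ids <- sort(unique(ev$station_id))
  partners <- function(nd) {
    length(unique(c(edges$to[edges$from == nd & edges$to != nd],
                    edges$from[edges$to == nd & edges$from != nd])))
  }
  strength <- function(nd) {
    sum(edges$count[edges$from == nd]) + sum(edges$count[edges$to == nd])
  }
  nodes <- tibble::tibble(
    node = node_ids,
    degree = vapply(node_ids, partners, integer(1), USE.NAMES = FALSE),
    strength = vapply(node_ids, strength, numeric(1), USE.NAMES = FALSE))
  structure(list(edges = edges, nodes = nodes), class = "movement_network")
}

#' @export
print.movement_network <- function(x, ...) {
  cat("Movement network:", nrow(x$nodes), "nodes,",
      nrow(x$edges), "directed edges,",
      sum(x$edges$count), "movements\n")
  print(x$edges, ...)
  invisible(x)
}

#' Export a movement network
#'
#' Writes the directed edge list as CSV and, optionally, as GraphML with a
#' `count` edge attribute (via igraph), so the network opens in standard
#' graph tools.
#'
#' @param network A `movement_network`.
#' @param csv_path Path for the edge-list CSV (`from,to,count`).
#' @param graphml_path Optional path for a GraphML file.
#' @return Invisibly, the paths written.
#' @export
export_network <- function(network, csv_path, graphml_path = NULL) {
  readr::write_csv(network$edges, csv_path, progress = FALSE)
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(
      as.data.frame(network$edges),
      directed = TRUE,
      vertices = as.data.frame(network$nodes))
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(c(csv_path, graphml_path))
}

#' Read a movement network back from its edge-list CSV
#'
#' @param csv_path Edge-list CSV written by [export_network()].
#' @return Edges tibble (`from`, `to`, `count`).
#' @export
read_network_edges <- function(csv_path) {
  readr::read_csv(csv_path, col_types = "cci", progress = FALSE,
                  show_col_types = FALSE)
}
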