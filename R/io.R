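## Plain-text ingestion and output helpers. Networks arrive either as an
## edge-list CSV (edge_id, up_node, down_node, length_m) or as a GeoJSON
## FeatureCollection of LineStrings; sites and barriers as CSV point
## tables in planar metres.

#' Read a network edge table from CSV
#'
#' Lines starting with `#` are treated as comments (output headers carry
#' the simulation seed that way).
#'
#' @param path CSV with columns `edge_id`, `up_node`, `down_node`,
#'   `length_m`.
#' @return data.frame ready for [build_network()].
#' @export
read_edge_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a river network from a GeoJSON FeatureCollection of LineStrings
#'
#' Each LineString becomes one edge; its length is the summed Euclidean
#' length of its segments and its endpoints become nodes. Endpoints closer
#' than `tol` metres are merged into one node, which is how confluences
#' are recovered from the drawing. Coordinates must be planar metres.
#'
#' @param path GeoJSON file.
#' @param outlet optional outlet node id (`"n<k>"` indices assigned in
#'   reading order); when omitted, inferred from the feature orientation
#'   (features drawn upstream to downstream).
#' @param tol endpoint merge tolerance in metres.
#' @return a [build_network()] object.
#' @export
read_network_geojson <- function(path, outlet = NULL, tol = 1) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  if (is.null(feats)) stop("not a GeoJSON FeatureCollection")
  ends <- list()
  node_of <- function(x, y) {
    for (i in seq_along(ends))
      if ((ends[[i]][1] - x)^2 + (ends[[i]][2] - y)^2 <= tol^2)
        return(names(ends)[i])
    id <- sprintf("n%d", length(ends) + 1L)
    ends[[id]] <<- c(x, y)
    id
  }
  rows <- lapply(seq_along(feats), function(k) {
    g <- feats[[k]]$geometry
    if (is.null(g) || g$type != "LineString")
      stop("feature ", k, " is not a LineString")
    cc <- do.call(rbind, lapply(g$coordinates, function(p)
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
    len <- sum(sqrt(diff(cc[, 1])^2 + diff(cc[, 2])^2))
    u <- node_of(cc[1, 1], cc[1, 2])
    d <- node_of(cc[nrow(cc), 1], cc[nrow(cc), 2])
    data.frame(edge_id = sprintf("e%d", k), up_node = u, down_node = d,
               length_m = len, stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, rows)
  nodes <- data.frame(node_id = names(ends),
                      x = vapply(ends, `[`, 0, 1),
                      y = vapply(ends, `[`, 0, 2), stringsAsFactors = FALSE)
  build_network(edges, nodes, outlet = outlet)
}

#' Read site or barrier point tables
#'
#' Site tables need `site_id`, `x`, `y`, `catchment`; barrier tables need
#' `barrier_id`, `x`, `y`, `catchment` and optionally `removed` (0/1 or
#' logical). Removed barriers are filtered out here; every remaining
#' barrier is treated as a barrier for fish, since registry metadata on
#' passability is typically too patchy to act on.
#'
#' @param path CSV path.
#' @return data.frame (barriers: with removed rows dropped).
#' @export
read_sites_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' @rdname read_sites_csv
#' @export
read_barriers_csv <- function(path) {
  b <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if ("removed" %in% names(b)) b <- b[!as.logical(b$removed), , drop = FALSE]
  rownames(b) <- NULL
  b
}

#' Read a long-format density table
#' @param path CSV with columns `site`, `year`, `species`, `density`.
#' @return data.frame.
#' @export
read_density_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

## write a CSV with a seed-bearing comment header
write_output_csv <- function(df, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed: %d", seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
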