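# Connectome input/output: delimited edge lists in (configurable dialects,
# including the hemibrain per-ROI layout), scan reports out (TSV/JSON), and
# GraphML export of flagged nodes for visual inspection.

#' Edge-list dialect
#'
#' Describes how to parse one family of delimited connectome files: the
#' delimiter, the source/target ID columns (names when a header is present,
#' 1-based indices otherwise), and optional region-of-interest and synapse
#' weight columns.
#'
#' @param delimiter field separator (default comma).
#' @param source,target column name or index of the two neuron-ID fields.
#' @param roi,weight optional column name/index of ROI label and synapse
#'   weight.
#' @param header whether the file carries a header row.
#' @return A list of class `edge_dialect`.
#' @export
edge_dialect <- function(delimiter = ",", source = "source", target = "target",
                         roi = NULL, weight = NULL, header = TRUE) {
  if (identical(source, target)) stop("source and target columns must differ")
  structure(list(delimiter = delimiter, source = source, target = target,
                 roi = roi, weight = weight, header = header),
            class = "edge_dialect")
}

#' Hemibrain edge-list dialect preset
#'
#' Headered CSV with columns `bodyId_pre`, `bodyId_post`, `roi`, `weight`,
#' the layout of the hemibrain v1.1 per-ROI connection exports.
#'
#' @return An [edge_dialect()].
#' @export
dialect_hemibrain <- function() {
  edge_dialect(",", "bodyId_pre", "bodyId_post", roi = "roi",
               weight = "weight")
}

pick_column <- function(df, col, path) {
  if (is.numeric(col)) {
    if (col > ncol(df)) stop("no column ", col, " in ", path)
    return(df[[col]])
  }
  if (!col %in% names(df)) {
    stop("no column '", col, "' in ", path,
         " (columns: ", paste(names(df), collapse = ", "), ")")
  }
  df[[col]]
}

#' Read a connectome edge list
#'
#' Parses a delimited text file of connected neuron pairs into an undirected
#' simple graph. Neuron IDs are kept as opaque strings. Directed records are
#' collapsed to undirected edges; duplicate pairs (either orientation) and
#' self-loops are dropped, with counts reported via `message()` and retained
#' as graph attributes. Synapse weights, if present, are ignored for
#' topology.
#'
#' @param path file path.
#' @param dialect an [edge_dialect()].
#' @return An `igraph` graph.
#' @export
read_edge_list <- function(path, dialect = edge_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(
    utils::read.table(path, sep = dialect$delimiter, header = dialect$header,
                      colClasses = "character", quote = "\"",
                      comment.char = "", stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e))
  )
  if (nrow(raw) == 0L) {
    warning("empty edge list: ", path)
    return(neuron_graph(NULL))
  }
  src <- pick_column(raw, dialect$source, path)
  tgt <- pick_column(raw, dialect$target, path)
  bad <- which(is.na(src) | is.na(tgt) | src == "" | tgt == "")
  if (length(bad)) {
    stop("malformed record at line ",
         bad[1L] + if (isTRUE(dialect$header)) 1L else 0L, " of ", path)
  }
  g <- neuron_graph(cbind(src, tgt))
  ds <- igraph::graph_attr(g, "dropped_self_loops")
  dd <- igraph::graph_attr(g, "dropped_duplicates")
  if (ds + dd > 0) {
    message("read_edge_list: dropped ", ds, " self-loop and ", dd,
            " duplicate record(s) from ", path)
  }
  g
}

report_fields <- function() {
  c("input", "component_sizes", "accepted", "accepted_size", "seed",
    "n_windows", "n_flagged", "n_clusters", "n_singletons",
    "gridness_fraction", "gridness_percent", "flagged_nodes")
}

#' Write a scan report
#'
#' JSON preserves the full report structure (summary fields, cluster node
#' unions and the per-window table) and round-trips through
#' [read_report()]. TSV writes the per-window table preceded by
#' `#`-commented summary lines.
#'
#' @param report a `grid_scan_report` from [grid_scan()].
#' @param path output file path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "grid_scan_report"))
  if (format == "json") {
    payload <- report[c(report_fields(), "criteria")]
    payload$clusters <- lapply(report$clusters, function(cl) {
      list(centers = cl$centers, node_union = cl$node_union,
           n_windows = cl$n_windows)
    })
    payload$windows <- report$windows
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (f in c("input", "accepted", "accepted_size", "n_windows",
                "n_flagged", "n_clusters", "gridness_percent")) {
      writeLines(paste0("# ", f, ": ", paste(report[[f]], collapse = ",")), con)
    }
    utils::write.table(report$windows, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a JSON scan report
#'
#' @param path a file written by [write_report()] with `format = "json"`.
#' @return A `grid_scan_report`.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$flagged_nodes <- as.character(x$flagged_nodes)
  x$component_sizes <- as.integer(x$component_sizes)
  if (is.data.frame(x$clusters)) {
    x$clusters <- lapply(seq_len(nrow(x$clusters)), function(i) {
      list(centers = as.character(x$clusters$centers[[i]]),
           node_union = as.character(x$clusters$node_union[[i]]),
           n_windows = as.integer(x$clusters$n_windows[[i]]))
    })
  } else {
    x$clusters <- list()
  }
  if (is.null(x$windows) || !length(x$windows)) x$windows <- empty_window_table()
  structure(x, class = "grid_scan_report")
}

#' Export a graph with grid-membership marks as GraphML
#'
#' Writes standard GraphML with a boolean node attribute `grid_member`
#' marking the flagged nodes, replacing by-eye inspection with a file any
#' graph viewer can load.
#'
#' @param g an `igraph` graph.
#' @param flagged_nodes character vector of flagged node IDs (subset of the
#'   nodes of `g`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(g, flagged_nodes, path) {
  flagged_nodes <- as.character(flagged_nodes)
  check_nodes(g, flagged_nodes)
  igraph::V(g)$grid_member <- igraph::V(g)$name %in% flagged_nodes
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
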