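# Sliding-window square-grid detection: classify every closed 2-hop window of
# a network component against metric bands calibrated on reference models,
# cluster overlapping flagged windows, and score the component by the
# fraction of its nodes covered by clustered windows.

#' Square-grid classification criteria
#'
#' Inclusive `[min, max]` acceptance bands for the window metrics, plus the
#' minimum component and window sizes. The defaults are the calibrated
#' idealized-square-grid bands: transitivity in `[0, 0.20]` (excludes
#' triangular grids), spectral bipartivity in `[0.80, 1.0]` (selects
#' square-grid-like bipartite structure), sigma in `[0, 0.50]` (excludes
#' small-world architecture), components of at least 36 nodes, windows of at
#' least 4 nodes (a window smaller than the C4 motif cannot hold a square).
#'
#' @param transitivity_band,bipartivity_band,sigma_band numeric length-2
#'   vectors `c(lo, hi)` with `lo <= hi`.
#' @param min_component_nodes minimum size of an analyzable component.
#' @param min_window_nodes minimum size of a flaggable window.
#' @return A list of class `grid_criteria`.
#' @export
grid_criteria <- function(transitivity_band = c(0, 0.20),
                          bipartivity_band = c(0.80, 1.0),
                          sigma_band = c(0, 0.50),
                          min_component_nodes = 36,
                          min_window_nodes = 4) {
  bands <- list(transitivity_band = transitivity_band,
                bipartivity_band = bipartivity_band,
                sigma_band = sigma_band)
  for (b in names(bands)) {
    v <- bands[[b]]
    if (length(v) != 2L || any(!is.finite(v)) || v[1L] > v[2L] || v[1L] < 0) {
      stop("`", b, "` must be c(lo, hi) with 0 <= lo <= hi")
    }
  }
  structure(c(bands, list(min_component_nodes = min_component_nodes,
                          min_window_nodes = min_window_nodes)),
            class = "grid_criteria")
}

#' @export
print.grid_criteria <- function(x, ...) {
  cat("Square-grid criteria\n")
  cat(sprintf("  transitivity in [%.2f, %.2f]\n", x$transitivity_band[1], x$transitivity_band[2]))
  cat(sprintf("  bipartivity  in [%.2f, %.2f]\n", x$bipartivity_band[1], x$bipartivity_band[2]))
  cat(sprintf("  sigma        in [%.2f, %.2f]\n", x$sigma_band[1], x$sigma_band[2]))
  cat(sprintf("  component size >= %d, window size >= %d\n",
              x$min_component_nodes, x$min_window_nodes))
  invisible(x)
}

#' Largest-component filter
#'
#' Networks are analyzed per contiguous component; a component below the
#' minimum neuron count is excluded from evaluation as an insufficient
#' sample.
#'
#' @param g an `igraph` graph.
#' @param criteria a [grid_criteria()].
#' @return A list with `accepted` (logical), `graph` (the largest-component
#'   subgraph, or `NULL` when rejected), `size` (largest-component node
#'   count) and `component_sizes` (all component sizes, largest first).
#' @export
component_filter <- function(g, criteria = grid_criteria()) {
  comps <- graph_components(g)
  sizes <- lengths(comps)
  if (!length(comps) || sizes[1L] < criteria$min_component_nodes) {
    return(list(accepted = FALSE, graph = NULL,
                size = if (length(comps)) sizes[1L] else 0L,
                component_sizes = sizes))
  }
  list(accepted = TRUE, graph = subgraph_of(g, comps[[1L]]),
       size = sizes[1L], component_sizes = sizes)
}

#' Score one scan window
#'
#' Computes the metric record of a window subgraph: node and edge counts,
#' transitivity, mean square clustering, spectral bipartivity and sigma.
#' Sigma is computed only for windows of at least 4 nodes (smaller windows
#' cannot be flagged anyway) and is `NA` otherwise.
#'
#' @param g_window a connected `igraph` graph (an induced window subgraph).
#' @param sigma_seed integer seed for sigma's random references.
#' @return A one-row data frame (the metric record).
#' @export
score_window <- function(g_window, sigma_seed = 1L) {
  n <- igraph::vcount(g_window)
  if (n == 0L) stop("cannot score an empty window")
  data.frame(
    n_nodes = n,
    n_edges = igraph::ecount(g_window),
    transitivity = transitivity_global(g_window),
    square_clustering = if (n > 0) square_clustering_mean(g_window) else NA_real_,
    bipartivity = spectral_bipartivity(g_window),
    sigma = if (n >= 4L) small_world_sigma(g_window, seed = sigma_seed) else NA_real_
  )
}

in_band <- function(x, band) is.finite(x) & x >= band[1L] & x <= band[2L]

#' Classify a window metric record against the criteria
#'
#' A window is flagged as square-grid-like when every band check passes
#' (inclusive at both endpoints) and the window reaches the minimum size.
#' Windows whose sigma is `NA` (too small) are never flagged.
#'
#' @param m a metric record as returned by [score_window()].
#' @param criteria a [grid_criteria()].
#' @return `TRUE` or `FALSE`.
#' @export
classify_window <- function(m, criteria = grid_criteria()) {
  isTRUE(m$n_nodes >= criteria$min_window_nodes &&
         in_band(m$transitivity, criteria$transitivity_band) &&
         in_band(m$bipartivity, criteria$bipartivity_band) &&
         in_band(m$sigma, criteria$sigma_band))
}

#' Scan every 2-hop window of a component
#'
#' Slides the closed 2-hop window across all nodes of an accepted component:
#' each node of interest defines a window of itself, its neighbors and their
#' neighbors; the induced subgraph is scored and classified. Per-window sigma
#' seeds are derived from `seed`, so a scan is reproducible end to end.
#'
#' @param g a connected `igraph` graph (an accepted component).
#' @param criteria a [grid_criteria()].
#' @param seed master integer seed.
#' @return A list of windows; each window is a list with `center`, `members`
#'   (sorted node IDs), `metrics` (one-row data frame) and `flagged`.
#' @export
scan_windows <- function(g, criteria = grid_criteria(), seed = 1L) {
  centers <- sort(igraph::V(g)$name)
  out <- vector("list", length(centers))
  for (i in seq_along(centers)) {
    members <- ego_window(g, centers[i], radius = 2)
    sub <- subgraph_of(g, members)
    m <- score_window(sub, sigma_seed = derive_seed(seed, i))
    out[[i]] <- list(center = centers[i], members = members, metrics = m,
                     flagged = classify_window(m, criteria))
  }
  out
}

#' Cluster flagged windows by node overlap
#'
#' Two flagged windows overlap when they share at least one node; clusters
#' are the connected components of the overlap relation. Isolated flagged
#' windows do not form a cluster (non-contiguous windows are weak evidence)
#' and are returned separately.
#'
#' @param windows a list of flagged windows (see [scan_windows()]).
#' @return A list with `clusters` (each a list holding `centers`,
#'   `node_union` and `n_windows`, with `n_windows >= 2`) and `singletons`
#'   (list of the windows left unclustered).
#' @export
overlap_clusters <- function(windows) {
  if (!length(windows)) return(list(clusters = list(), singletons = list()))
  stopifnot(all(vapply(windows, `[[`, TRUE, "flagged")))
  nw <- length(windows)
  # overlap graph on window indices
  pairs <- matrix(integer(0), ncol = 2L)
  if (nw > 1L) {
    memb <- lapply(windows, `[[`, "members")
    idx <- utils::combn(nw, 2L)
    share <- vapply(seq_len(ncol(idx)), function(j) {
      length(intersect(memb[[idx[1L, j]]], memb[[idx[2L, j]]])) > 0L
    }, TRUE)
    pairs <- t(idx[, share, drop = FALSE])
  }
  og <- igraph::graph_from_edgelist(rbind(pairs, cbind(seq_len(nw), seq_len(nw))),
                                    directed = FALSE)
  comp <- igraph::components(og)$membership[seq_len(nw)]
  groups <- split(seq_len(nw), comp)
  clusters <- list()
  singletons <- list()
  for (grp in groups) {
    if (length(grp) >= 2L) {
      clusters[[length(clusters) + 1L]] <- list(
        centers = sort(vapply(windows[grp], `[[`, character(1), "center")),
        node_union = sort(unique(unlist(lapply(windows[grp], `[[`, "members")))),
        n_windows = length(grp)
      )
    } else {
      singletons[[length(singletons) + 1L]] <- windows[[grp]]
    }
  }
  list(clusters = clusters, singletons = singletons)
}

#' Square-grid-ness score of a component
#'
#' Fraction of the component's nodes covered by the union of clustered
#' flagged windows.
#'
#' @param component a nonempty `igraph` graph (the scanned component).
#' @param clusters the `clusters` element of [overlap_clusters()].
#' @return A fraction in `[0, 1]`.
#' @seealso [gridness_percent()] for the whole-percent reporting convention.
#' @export
gridness_score <- function(component, clusters) {
  n <- igraph::vcount(component)
  if (n == 0L) stop("cannot score an empty component")
  covered <- unique(unlist(lapply(clusters, `[[`, "node_union")))
  if (!all(covered %in% igraph::V(component)$name)) {
    stop("cluster node unions must be subsets of the component")
  }
  length(covered) / n
}

#' Whole-percent form of a grid-ness fraction
#'
#' @param fraction a value in `[0, 1]`.
#' @return The percentage rounded to a whole percent.
#' @export
gridness_percent <- function(fraction) {
  stopifnot(fraction >= 0, fraction <= 1)
  round(100 * fraction)
}

#' Full square-grid scan of a network
#'
#' Pipeline: largest-component filter, 2-hop window scan with band
#' classification, overlap clustering of flagged windows, and component
#' grid-ness scoring.
#'
#' @param g an `igraph` graph (a whole network; may be disconnected).
#' @param criteria a [grid_criteria()].
#' @param seed master integer seed (drives all sigma references).
#' @param input_id optional label (e.g. the ROI name) carried in the report.
#' @return An object of class `grid_scan_report`: a list with the input
#'   label, component sizes, acceptance flag and size, the window table
#'   (one row per window), cluster summaries, flagged-node union, and the
#'   grid-ness fraction and whole percent.
#' @export
grid_scan <- function(g, criteria = grid_criteria(), seed = 1L,
                      input_id = "network") {
  filt <- component_filter(g, criteria)
  rep0 <- list(input = input_id,
               component_sizes = as.integer(filt$component_sizes),
               accepted = filt$accepted,
               accepted_size = as.integer(filt$size),
               criteria = unclass(criteria), seed = as.integer(seed))
  if (!filt$accepted) {
    out <- c(rep0, list(
      n_windows = 0L, n_flagged = 0L, n_clusters = 0L, n_singletons = 0L,
      gridness_fraction = 0, gridness_percent = 0L,
      flagged_nodes = character(0), clusters = list(),
      windows = empty_window_table()))
    class(out) <- "grid_scan_report"
    return(out)
  }
  wins <- scan_windows(filt$graph, criteria, seed)
  flagged <- Filter(function(w) w$flagged, wins)
  oc <- overlap_clusters(flagged)
  frac <- gridness_score(filt$graph, oc$clusters)
  cluster_of <- rep(NA_integer_, length(wins))
  centers <- vapply(wins, `[[`, character(1), "center")
  for (ci in seq_along(oc$clusters)) {
    cluster_of[centers %in% oc$clusters[[ci]]$centers] <- ci
  }
  tab <- do.call(rbind, lapply(wins, `[[`, "metrics"))
  tab <- cbind(data.frame(center = centers, stringsAsFactors = FALSE), tab)
  tab$flagged <- vapply(wins, `[[`, TRUE, "flagged")
  tab$cluster <- cluster_of
  rownames(tab) <- NULL
  out <- c(rep0, list(
    n_windows = length(wins),
    n_flagged = length(flagged),
    n_clusters = length(oc$clusters),
    n_singletons = length(oc$singletons),
    gridness_fraction = frac,
    gridness_percent = gridness_percent(frac),
    flagged_nodes = sort(unique(unlist(lapply(oc$clusters, `[[`, "node_union")))),
    clusters = oc$clusters,
    windows = tab))
  class(out) <- "grid_scan_report"
  out
}

empty_window_table <- function() {
  data.frame(center = character(0), n_nodes = integer(0), n_edges = integer(0),
             transitivity = numeric(0), square_clustering = numeric(0),
             bipartivity = numeric(0), sigma = numeric(0),
             flagged = logical(0), cluster = integer(0))
}

#' @export
print.grid_scan_report <- function(x, ...) {
  cat("Square-grid scan of", x$input, "\n")
  cat("  components:", paste(x$component_sizes, collapse = ", "), "\n")
  if (!x$accepted) {
    cat("  rejected: largest component has", x$accepted_size,
        "nodes (minimum", x$criteria$min_component_nodes, ")\n")
    return(invisible(x))
  }
  cat(sprintf("  windows: %d scanned, %d flagged, %d cluster(s), %d singleton(s)\n",
              x$n_windows, x$n_flagged, x$n_clusters, x$n_singletons))
  cat(sprintf("  square-grid-ness: %d%% (%d of %d nodes)\n",
              x$gridness_percent, length(x$flagged_nodes), x$accepted_size))
  invisible(x)
}
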