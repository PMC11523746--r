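# Calibration sweep: generate the six reference models over their parameter
# grids, compute the metric suite on each graph, and summarize per-model
# min/max ranges from which the square-grid criteria bands can be read.

#' Calibration sweep configuration
#'
#' Default grids follow the calibration design: grid-like models span 9 to 81
#' nodes (square lattices 3x3..9x9, triangular lattices at
#' [triangular_sweep_dims()]), non-grid models span 9 to 27 nodes
#' (represented at n = 9, 18, 27), edge probability P in \{0.4, 0.5\} for the
#' random model, attachment count M in 3..6, ring neighbors k in \{4, 6\} and
#' rewiring probability p in \{0.1, 0.5\} for the small-world model. Odd k is
#' invalid for the ring construction, so the "4 to 6" range is realized as
#' \{4, 6\}. Stochastic models are replicated `n_seeds` times per parameter
#' cell.
#'
#' @param complete_n node counts for the complete model.
#' @param square_dims data frame of `rows`, `cols` for square lattices.
#' @param triangular_dims data frame of `m`, `n` for triangular lattices.
#' @param random_n,random_p grids for the random model.
#' @param pa_n,pa_m grids for the preferential-attachment model.
#' @param sw_n,sw_k,sw_p grids for the small-world model.
#' @param n_seeds replicates per stochastic parameter cell.
#' @param seed master seed; all replicate seeds are derived from it.
#' @return A list of class `sweep_config`.
#' @export
sweep_config <- function(complete_n = 9:27,
                         square_dims = data.frame(rows = 3:9, cols = 3:9),
                         triangular_dims = triangular_sweep_dims(),
                         random_n = c(9L, 18L, 27L), random_p = c(0.4, 0.5),
                         pa_n = c(9L, 18L, 27L), pa_m = 3:6,
                         sw_n = c(9L, 18L, 27L), sw_k = c(4L, 6L),
                         sw_p = c(0.1, 0.5),
                         n_seeds = 20L, seed = 1L) {
  structure(list(complete_n = complete_n, square_dims = square_dims,
                 triangular_dims = triangular_dims,
                 random_n = random_n, random_p = random_p,
                 pa_n = pa_n, pa_m = pa_m,
                 sw_n = sw_n, sw_k = sw_k, sw_p = sw_p,
                 n_seeds = n_seeds, seed = seed),
            class = "sweep_config")
}

sweep_specs <- function(config) {
  specs <- list()
  add <- function(model, params) {
    specs[[length(specs) + 1L]] <<- c(list(model = model), params)
  }
  for (n in config$complete_n) add("complete", list(n = n))
  for (i in seq_len(nrow(config$square_dims))) {
    add("square_grid", list(rows = config$square_dims$rows[i],
                            cols = config$square_dims$cols[i]))
  }
  for (i in seq_len(nrow(config$triangular_dims))) {
    add("triangular_grid", list(m = config$triangular_dims$m[i],
                                n_tri = config$triangular_dims$n[i]))
  }
  for (n in config$random_n) for (p in config$random_p) {
    add("random", list(n = n, p = p, stochastic = TRUE))
  }
  for (n in config$pa_n) for (m in config$pa_m) {
    if (m < n) add("preferential", list(n = n, m_attach = m, stochastic = TRUE))
  }
  for (n in config$sw_n) for (k in config$sw_k) for (p in config$sw_p) {
    if (k >= n) stop("infeasible small-world spec: k = ", k, " >= n = ", n)
    add("small_world", list(n = n, k = k, p = p, stochastic = TRUE))
  }
  specs
}

sweep_metrics <- function(g, sigma_seed) {
  comps <- graph_components(g)
  largest <- subgraph_of(g, comps[[1L]])
  data.frame(
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    n_largest = igraph::vcount(largest),
    square_clustering = square_clustering_mean(g),
    transitivity = transitivity_global(g),
    bipartivity = spectral_bipartivity(g),
    sigma = if (igraph::vcount(largest) >= 4L) {
      small_world_sigma(largest, seed = sigma_seed)
    } else NA_real_
  )
}

#' Run the calibration sweep
#'
#' Generates every configured model instance (stochastic cells replicated
#' over derived seeds), computes the metric suite on each graph — path-based
#' quantities on the largest component — and aggregates per-model min/max
#' ranges. Fully reproducible from the config seed.
#'
#' @param config a [sweep_config()].
#' @return A list of class `sweep_result` with `records` (one data-frame row
#'   per generated graph) and `summary` (per-model min/max of each metric).
#' @export
run_sweep <- function(config = sweep_config()) {
  specs <- sweep_specs(config)
  rows <- list()
  cell <- 0L
  for (sp in specs) {
    cell <- cell + 1L
    reps <- if (isTRUE(sp$stochastic)) config$n_seeds else 1L
    for (r in seq_len(reps)) {
      gseed <- derive_seed(config$seed, cell * 1000L + r)
      gspec <- generator_spec(sp$model, n = sp$n, rows = sp$rows,
                              cols = sp$cols, m = sp$m, n_tri = sp$n_tri,
                              p = sp$p, m_attach = sp$m_attach, k = sp$k)
      g <- build_graph(gspec, seed = gseed)
      met <- sweep_metrics(g, sigma_seed = derive_seed(gseed, 7L))
      param <- sp[setdiff(names(sp), c("model", "stochastic"))]
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(model = sp$model,
                   params = paste(names(param), unlist(param), sep = "=",
                                  collapse = ","),
                   replicate = r, stringsAsFactors = FALSE),
        met)
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  metric_cols <- c("square_clustering", "transitivity", "bipartivity", "sigma")
  models <- unique(records$model)
  summary <- do.call(rbind, lapply(models, function(mod) {
    sub <- records[records$model == mod, ]
    out <- data.frame(model = mod, stringsAsFactors = FALSE)
    for (mc in metric_cols) {
      out[[paste0(mc, "_min")]] <- min(sub[[mc]], na.rm = TRUE)
      out[[paste0(mc, "_max")]] <- max(sub[[mc]], na.rm = TRUE)
    }
    out
  }))
  structure(list(records = records, summary = summary, config = config),
            class = "sweep_result")
}

#' Derive (and validate) square-grid criteria from a sweep summary
#'
#' Returns the default idealized-square-grid bands after asserting that they
#' are consistent with the sweep: the square-grid model must pass every band,
#' and the complete and triangular-grid models must each fail at least one
#' band. A violated assertion names the offending band.
#'
#' @param summary the `summary` data frame of a [run_sweep()] result (or the
#'   `sweep_result` itself).
#' @return A [grid_criteria()].
#' @export
derive_criteria <- function(summary) {
  if (inherits(summary, "sweep_result")) summary <- summary$summary
  crit <- grid_criteria()
  need <- c("square_grid")
  if (!all(need %in% summary$model)) {
    stop("summary must contain the square_grid model")
  }
  row_of <- function(mod) summary[summary$model == mod, , drop = FALSE]
  passes <- function(row) {
    c(transitivity = row$transitivity_min >= crit$transitivity_band[1L] &&
        row$transitivity_max <= crit$transitivity_band[2L],
      bipartivity = row$bipartivity_min >= crit$bipartivity_band[1L] &&
        row$bipartivity_max <= crit$bipartivity_band[2L],
      sigma = row$sigma_min >= crit$sigma_band[1L] &&
        row$sigma_max <= crit$sigma_band[2L])
  }
  sq <- passes(row_of("square_grid"))
  if (!all(sq)) {
    stop("square-grid model violates the ", names(sq)[!sq][1L], " band")
  }
  for (mod in intersect(c("complete", "triangular_grid"), summary$model)) {
    if (all(passes(row_of(mod)))) {
      stop("model ", mod, " passes every band; criteria do not discriminate")
    }
  }
  crit
}

#' Write a sweep summary as TSV
#'
#' One row per model with `(min, max)` columns per metric, values printed at
#' 2 decimals to mirror the calibration table layout.
#'
#' @param result a `sweep_result` (or its `summary` data frame).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sweep_summary <- function(result, path) {
  s <- if (inherits(result, "sweep_result")) result$summary else result
  fmt <- s
  num <- vapply(fmt, is.numeric, TRUE)
  fmt[num] <- lapply(fmt[num], function(x) sprintf("%.2f", x))
  utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
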