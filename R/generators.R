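# Reference network models. Six parameterized generators produce the graphs
# used to calibrate the square-grid criteria, plus a hybrid
# "planted lattice + background" fixture for detector-recovery tests.
# All generators are pure functions of their parameters and seed.

#' Complete graph
#'
#' Every pair of nodes shares an edge.
#'
#' @param n node count (at least 2).
#' @return An `igraph` graph with `n` nodes and `n(n-1)/2` edges.
#' @export
gen_complete <- function(n) {
  if (n < 2) stop("complete graph needs n >= 2")
  nm <- paste0("v", seq_len(n))
  pairs <- utils::combn(nm, 2L)
  neuron_graph(t(pairs))
}

lattice_name <- function(r, c) paste0("g", r, "_", c)

#' Square-grid lattice
#'
#' Nodes at integer grid positions, edges between horizontal and vertical
#' neighbors. The 2x2 case is the C4 cycle, the minimal square grid.
#' The result is bipartite and triangle-free, with
#' `rows*(cols-1) + cols*(rows-1)` edges.
#'
#' @param rows,cols lattice dimensions (each at least 2).
#' @return An `igraph` graph with `rows*cols` nodes.
#' @export
gen_square_lattice <- function(rows, cols) {
  if (rows < 2 || cols < 2) stop("square lattice needs rows >= 2 and cols >= 2")
  horiz <- expand.grid(r = seq_len(rows), c = seq_len(cols - 1L))
  vert <- expand.grid(r = seq_len(rows - 1L), c = seq_len(cols))
  edges <- rbind(
    cbind(lattice_name(horiz$r, horiz$c), lattice_name(horiz$r, horiz$c + 1L)),
    cbind(lattice_name(vert$r, vert$c), lattice_name(vert$r + 1L, vert$c))
  )
  neuron_graph(edges)
}

#' Triangular-grid lattice
#'
#' Standard planar row lattice of triangles: `m + 1` rows of nodes on
#' `(n + 1) %/% 2 + 1` columns with horizontal, vertical and alternating
#' diagonal edges (odd `n` trims the dangling last column on alternate rows).
#' Connected and triangle-rich.
#'
#' @param m rows of triangles.
#' @param n columns of triangles (defaults to `m`).
#' @return An `igraph` graph.
#' @export
gen_triangular_lattice <- function(m, n = m) {
  if (m < 1 || n < 1) stop("triangular lattice needs m >= 1 and n >= 1")
  ncol_full <- (n + 1L) %/% 2L          # columns 0..ncol_full
  rows <- 0:m
  cols <- 0:ncol_full
  nm <- function(i, j) paste0("t", i, "_", j)
  e <- list()
  # horizontal
  h <- expand.grid(i = cols[cols < ncol_full], j = rows)
  e[[1]] <- cbind(nm(h$i, h$j), nm(h$i + 1L, h$j))
  # vertical
  v <- expand.grid(i = cols, j = rows[rows < m])
  e[[2]] <- cbind(nm(v$i, v$j), nm(v$i, v$j + 1L))
  # diagonals: up-left from even rows, up-right from odd rows
  jr_even <- rows[rows < m & rows %% 2L == 0L]
  if (length(jr_even)) {
    d <- expand.grid(i = cols[cols < ncol_full], j = jr_even)
    e[[3]] <- cbind(nm(d$i + 1L, d$j), nm(d$i, d$j + 1L))
  }
  jr_odd <- rows[rows < m & rows %% 2L == 1L]
  if (length(jr_odd)) {
    d <- expand.grid(i = cols[cols < ncol_full], j = jr_odd)
    e[[4]] <- cbind(nm(d$i, d$j), nm(d$i + 1L, d$j + 1L))
  }
  edges <- do.call(rbind, e)
  if (n %% 2L == 1L) {
    # odd column count: drop the overhanging last-column nodes on odd rows
    drop <- nm(ncol_full, rows[rows %% 2L == 1L])
    keep <- !(edges[, 1L] %in% drop) & !(edges[, 2L] %in% drop)
    edges <- edges[keep, , drop = FALSE]
  }
  neuron_graph(edges)
}

#' Default triangular-lattice sweep dimensions
#'
#' Square-shaped instances `m = n = 3..11`, whose node counts (10 to 78) span
#' the 9-to-81 calibration range used for grid-like models.
#'
#' @return A data frame with columns `m` and `n`.
#' @export
triangular_sweep_dims <- function() {
  data.frame(m = 3:11, n = 3:11)
}

#' Erdos-Renyi random graph G(n, p)
#'
#' Each of the `n(n-1)/2` possible edges is present independently with
#' probability `p`. May be disconnected at low `p`; callers analyze per
#' component.
#'
#' @param n node count (at least 2).
#' @param p edge probability in `(0, 1]`.
#' @param seed integer seed; the same seed yields the identical edge set.
#' @return An `igraph` graph.
#' @export
gen_random <- function(n, p, seed = 1L) {
  if (n < 2) stop("random graph needs n >= 2")
  if (p <= 0 || p > 1) stop("`p` must be in (0, 1]")
  nm <- paste0("v", seq_len(n))
  pairs <- t(utils::combn(nm, 2L))
  keep <- with_seed(seed, stats::runif(nrow(pairs)) < p)
  neuron_graph(pairs[keep, , drop = FALSE], nodes = nm)
}

#' Preferential-attachment (Barabasi-Albert) graph
#'
#' Growth model: starting from `m_attach` nodes, each new node attaches
#' `m_attach` edges to distinct existing nodes chosen with probability
#' proportional to their current degree (the first arrival connects to all
#' initial nodes). The result is connected with `(n - m_attach) * m_attach`
#' edges.
#'
#' @param n final node count.
#' @param m_attach edges added per new node, `1 <= m_attach < n`.
#' @param seed integer seed.
#' @return An `igraph` graph.
#' @export
gen_preferential <- function(n, m_attach, seed = 1L) {
  if (m_attach < 1 || m_attach >= n) stop("need 1 <= m_attach < n")
  nm <- paste0("v", seq_len(n))
  with_seed(seed, {
    edges <- matrix(character(0), ncol = 2L)
    targets <- nm[seq_len(m_attach)]
    repeated <- character(0)  # one entry per edge endpoint => degree weights
    for (src_i in (m_attach + 1L):n) {
      src <- nm[src_i]
      edges <- rbind(edges, cbind(src, targets))
      repeated <- c(repeated, targets, rep(src, m_attach))
      # next targets: m_attach distinct degree-weighted draws
      picked <- character(0)
      while (length(picked) < m_attach) {
        picked <- unique(c(picked, repeated[sample.int(length(repeated), 1L)]))
      }
      targets <- picked
    }
    neuron_graph(edges, nodes = nm)
  })
}

#' Small-world (Watts-Strogatz) graph
#'
#' Ring of `n` nodes each joined to its `k` nearest neighbors; every edge is
#' then rewired with probability `p` to a uniformly chosen non-adjacent
#' endpoint. Rewiring preserves the edge count `n*k/2`.
#'
#' @param n node count.
#' @param k even number of ring neighbors, `k < n`.
#' @param p rewiring probability in `[0, 1]`.
#' @param seed integer seed.
#' @return An `igraph` graph.
#' @export
gen_small_world <- function(n, k, p, seed = 1L) {
  if (k %% 2 != 0) stop("`k` must be even for the ring construction")
  if (k >= n) stop("need k < n")
  if (p < 0 || p > 1) stop("`p` must be in [0, 1]")
  with_seed(seed, {
    adj <- matrix(FALSE, n, n)
    for (j in seq_len(k %/% 2L)) {
      for (i in seq_len(n)) {
        t <- ((i - 1L + j) %% n) + 1L
        adj[i, t] <- adj[t, i] <- TRUE
      }
    }
    # rewire lap by lap, as in the original construction
    for (j in seq_len(k %/% 2L)) {
      for (i in seq_len(n)) {
        t <- ((i - 1L + j) %% n) + 1L
        if (!adj[i, t]) next  # already rewired away
        if (stats::runif(1L) < p) {
          free <- which(!adj[i, ] & seq_len(n) != i)
          free <- setdiff(free, t)
          if (!length(free)) next  # node saturated, keep the edge
          w <- free[sample.int(length(free), 1L)]
          adj[i, t] <- adj[t, i] <- FALSE
          adj[i, w] <- adj[w, i] <- TRUE
        }
      }
    }
    idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
    nm <- paste0("v", seq_len(n))
    neuron_graph(cbind(nm[idx[, 1L]], nm[idx[, 2L]]), nodes = nm)
  })
}

#' Generator specification
#'
#' Declarative description of one model instance, the unit of the calibration
#' sweep configuration and of hybrid backgrounds.
#'
#' @param model one of `"complete"`, `"square_grid"`, `"triangular_grid"`,
#'   `"random"`, `"preferential"`, `"small_world"`.
#' @param n node count (non-lattice models).
#' @param rows,cols lattice dimensions (`square_grid`).
#' @param m,n_tri triangular-lattice dimensions.
#' @param p edge/rewiring probability (`random`, `small_world`).
#' @param m_attach attachment count (`preferential`).
#' @param k ring neighbors (`small_world`).
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(model, n = NULL, rows = NULL, cols = NULL,
                           m = NULL, n_tri = NULL, p = NULL,
                           m_attach = NULL, k = NULL) {
  model <- match.arg(model, c("complete", "square_grid", "triangular_grid",
                              "random", "preferential", "small_world"))
  structure(list(model = model, n = n, rows = rows, cols = cols, m = m,
                 n_tri = n_tri, p = p, m_attach = m_attach, k = k),
            class = "generator_spec")
}

#' Build a graph from a generator specification
#'
#' @param spec a [generator_spec()].
#' @param seed integer seed for the stochastic models.
#' @return An `igraph` graph.
#' @export
build_graph <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "generator_spec"))
  switch(spec$model,
    complete        = gen_complete(spec$n),
    square_grid     = gen_square_lattice(spec$rows, spec$cols),
    triangular_grid = gen_triangular_lattice(spec$m,
                        if (is.null(spec$n_tri)) spec$m else spec$n_tri),
    random          = gen_random(spec$n, spec$p, seed),
    preferential    = gen_preferential(spec$n, spec$m_attach, seed),
    small_world     = gen_small_world(spec$n, spec$k, spec$p, seed)
  )
}

#' Hybrid planted-lattice graph
#'
#' Disjoint union of a square lattice (the planted pattern) and a background
#' graph, joined by `n_bridges` randomly chosen lattice-to-background edges.
#' Used as ground truth for detector-recovery tests.
#'
#' @param lattice_rows,lattice_cols dimensions of the planted square lattice.
#' @param background a [generator_spec()] for the background graph, or an
#'   `igraph` graph.
#' @param n_bridges number of lattice-to-background bridge edges (at least 1).
#' @param seed integer seed (drives the background model and bridge placement).
#' @return A list with elements `graph` (the hybrid `igraph`) and `planted`
#'   (character vector of lattice node IDs).
#' @export
gen_hybrid <- function(lattice_rows, lattice_cols, background, n_bridges,
                       seed = 1L) {
  if (n_bridges < 1) stop("`n_bridges` must be at least 1")
  lat <- gen_square_lattice(lattice_rows, lattice_cols)
  bg <- if (inherits(background, "generator_spec")) {
    build_graph(background, seed = derive_seed(seed, 1L))
  } else {
    background
  }
  lat_nodes <- paste0("L_", igraph::V(lat)$name)
  bg_nodes <- paste0("B_", igraph::V(bg)$name)
  lat_edges <- igraph::as_edgelist(lat)
  bg_edges <- igraph::as_edgelist(bg)
  edges <- rbind(
    matrix(paste0("L_", lat_edges), ncol = 2L),
    if (nrow(bg_edges)) matrix(paste0("B_", bg_edges), ncol = 2L)
  )
  bridges <- with_seed(derive_seed(seed, 2L), {
    pick <- sample.int(length(lat_nodes) * length(bg_nodes), n_bridges)
    cbind(lat_nodes[(pick - 1L) %% length(lat_nodes) + 1L],
          bg_nodes[(pick - 1L) %/% length(lat_nodes) + 1L])
  })
  g <- neuron_graph(rbind(edges, bridges), nodes = c(lat_nodes, bg_nodes))
  list(graph = g, planted = sort(lat_nodes))
}
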