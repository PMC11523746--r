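# The square-grid metric suite, implemented from first principles on the
# adjacency matrix / adjacency lists. Graphs handled here are single windows
# or network components (up to ~1000 nodes), so dense linear algebra is
# appropriate throughout.

adjacency_of <- function(g) {
  igraph::as_adjacency_matrix(g, sparse = FALSE)
}

#' Global transitivity (triangle clustering)
#'
#' Ratio of three times the number of triangles to the number of triads,
#' where a triad is two edges sharing a vertex. Defined as 0 for triad-free
#' graphs, so perfect square grids score 0.
#'
#' @param g an `igraph` graph.
#' @return A fraction in `[0, 1]`.
#' @export
transitivity_global <- function(g) {
  if (igraph::vcount(g) == 0L) return(0)
  a <- adjacency_of(g)
  k <- rowSums(a)
  triads <- sum(k * (k - 1)) / 2
  if (triads == 0) return(0)
  tri3 <- sum(diag(a %*% a %*% a)) / 2  # 3 * number of triangles
  tri3 / triads
}

#' Square (four-cycle) clustering coefficient of nodes
#'
#' For each node v, the fraction of possible four-cycles through v that are
#' realized (formulation of Lind, Gonzalez and Herrmann): over all pairs
#' `u < w` of neighbors of v, the number of common neighbors of u and w other
#' than v, divided by that count plus the remaining potential closure
#' capacity of u and w. A node with no closable neighbor pair scores 0.
#'
#' @param g an `igraph` graph.
#' @param v node IDs to evaluate (default: all nodes).
#' @return Named numeric vector of values in `[0, 1]`.
#' @export
square_clustering <- function(g, v = igraph::V(g)$name) {
  check_nodes(g, v)
  a <- adjacency_of(g)
  nm <- rownames(a)
  k <- rowSums(a)
  out <- numeric(length(v))
  names(out) <- v
  for (x in v) {
    nb <- which(a[x, ] > 0)
    if (length(nb) < 2L) next
    pairs <- utils::combn(length(nb), 2L)
    num <- 0
    den <- 0
    for (pi in seq_len(ncol(pairs))) {
      u <- nb[pairs[1L, pi]]
      w <- nb[pairs[2L, pi]]
      q <- sum(a[u, ] * a[w, ]) - 1  # common neighbors minus v itself
      eta <- 1 + q + a[u, w]
      num <- num + q
      den <- den + q + (k[u] - eta) + (k[w] - eta)
    }
    if (den > 0) out[x] <- num / den
  }
  out
}

#' Mean square clustering coefficient of a graph
#'
#' Arithmetic mean of [square_clustering()] over all nodes; the graph-level
#' "clustering coefficient" used in the model calibration table.
#'
#' @param g a nonempty `igraph` graph.
#' @return A fraction in `[0, 1]`.
#' @export
square_clustering_mean <- function(g) {
  if (igraph::vcount(g) == 0L) stop("square clustering of an empty graph is undefined")
  mean(square_clustering(g))
}

#' Spectral bipartivity
#'
#' Fraction of closed-walk weight carried by even-length walks,
#' `sum(cosh(lambda)) / sum(exp(lambda))` over the adjacency eigenvalues.
#' Equals 1 exactly for bipartite graphs (square grids included) and
#' approaches 0.5 for highly non-bipartite graphs such as large complete
#' graphs.
#'
#' @param g a nonempty `igraph` graph.
#' @return A value in `(0.5, 1]` for graphs with edges (1 for edgeless).
#' @export
spectral_bipartivity <- function(g) {
  if (igraph::vcount(g) == 0L) stop("bipartivity of an empty graph is undefined")
  ev <- eigen(adjacency_of(g), symmetric = TRUE, only.values = TRUE)$values
  s <- max(ev)  # rescale so exp() cannot overflow for large dense graphs
  b <- sum(exp(ev - s) + exp(-ev - s)) / 2 / sum(exp(ev - s))
  min(b, 1)  # the ratio is <= 1 analytically; clamp rounding noise
}

# All-pairs shortest-path distances of an unweighted graph by logical
# matrix-power layering; Inf marks unreachable pairs.
all_pairs_dist <- function(g) {
  n <- igraph::vcount(g)
  a <- adjacency_of(g) > 0
  d <- matrix(Inf, n, n, dimnames = dimnames(a))
  diag(d) <- 0
  d[a] <- 1
  reach <- a
  step <- 1
  repeat {
    reach <- (reach %*% a) > 0
    new <- reach & !is.finite(d)
    if (!any(new)) break
    step <- step + 1
    d[new] <- step
  }
  d
}

#' Average shortest path length
#'
#' Mean shortest-path distance over all unordered pairs of distinct nodes.
#' Requires a connected graph; callers holding a disconnected network should
#' pass its largest component.
#'
#' @param g a connected `igraph` graph with at least 2 nodes.
#' @return A nonnegative real.
#' @export
avg_path_length <- function(g) {
  if (igraph::vcount(g) < 2L) stop("average path length needs at least 2 nodes")
  d <- all_pairs_dist(g)
  vals <- d[upper.tri(d)]
  if (any(!is.finite(vals))) {
    stop("graph is disconnected; pass a connected component ",
         "(e.g. the largest one from graph_components())")
  }
  mean(vals)
}

#' Mean local triangle clustering coefficient
#'
#' Per-node fraction of closed triads `2 t_v / (k_v (k_v - 1))` (0 for nodes
#' of degree below 2), averaged over all nodes. This is the clustering term C
#' of the small-world coefficient sigma.
#'
#' @param g a nonempty `igraph` graph.
#' @return A fraction in `[0, 1]`.
#' @export
triangle_clustering_mean <- function(g) {
  if (igraph::vcount(g) == 0L) stop("clustering of an empty graph is undefined")
  a <- adjacency_of(g)
  k <- rowSums(a)
  t2 <- rowSums((a %*% a) * a)  # 2 * triangles through each node
  cc <- ifelse(k >= 2, t2 / (k * (k - 1)), 0)
  mean(cc)
}

#' Degree-preserving random reference graph
#'
#' Maslov-Sneppen randomization: repeated double-edge swaps that preserve
#' every node's degree; swaps that would create self-loops or parallel edges
#' are rejected and retried. Complete graphs admit no legal swap and are
#' returned unchanged.
#'
#' @param g an `igraph` graph with at least 2 edges.
#' @param n_swaps_per_edge accepted swaps per edge (default 5).
#' @param seed integer seed; output is deterministic given the seed.
#' @return An `igraph` graph with the identical degree sequence.
#' @export
random_reference <- function(g, n_swaps_per_edge = 5, seed = 1L) {
  m <- igraph::ecount(g)
  if (m < 2L) stop("randomization needs at least 2 edges")
  n <- igraph::vcount(g)
  if (m == n * (n - 1) / 2) return(g)  # complete: no legal swap exists
  nm <- igraph::V(g)$name
  a <- adjacency_of(g) > 0
  el <- igraph::as_edgelist(g, names = FALSE)
  target <- n_swaps_per_edge * m
  max_attempts <- max(1000L, 100L * target)
  with_seed(seed, {
    done <- 0L
    tried <- 0L
    chunk <- 2048L
    while (done < target && tried < max_attempts) {
      e1 <- sample.int(m, chunk, replace = TRUE)
      e2 <- sample.int(m, chunk, replace = TRUE)
      flip <- stats::runif(chunk) < 0.5
      for (i in seq_len(chunk)) {
        if (done >= target || tried >= max_attempts) break
        tried <- tried + 1L
        if (e1[i] == e2[i]) next
        ab <- el[e1[i], ]
        cd <- el[e2[i], ]
        if (flip[i]) cd <- rev(cd)
        # propose (a,d) and (c,b)
        if (ab[1L] == cd[2L] || cd[1L] == ab[2L]) next
        if (a[ab[1L], cd[2L]] || a[cd[1L], ab[2L]]) next
        a[ab[1L], ab[2L]] <- a[ab[2L], ab[1L]] <- FALSE
        a[cd[1L], cd[2L]] <- a[cd[2L], cd[1L]] <- FALSE
        a[ab[1L], cd[2L]] <- a[cd[2L], ab[1L]] <- TRUE
        a[cd[1L], ab[2L]] <- a[ab[2L], cd[1L]] <- TRUE
        el[e1[i], ] <- c(ab[1L], cd[2L])
        el[e2[i], ] <- c(cd[1L], ab[2L])
        done <- done + 1L
      }
    }
  })
  idx <- which(a & upper.tri(a), arr.ind = TRUE)
  neuron_graph(cbind(nm[idx[, 1L]], nm[idx[, 2L]]), nodes = nm)
}

#' Small-world coefficient sigma
#'
#' `sigma = (C / C_rand) / (L / L_rand)`, where C is the mean local triangle
#' clustering and L the average shortest path length of the graph, and
#' C_rand, L_rand are the means of the same quantities over degree-preserving
#' random references. Values above 1 indicate small-world architecture. For
#' triangle-free graphs (C = 0) sigma is defined as 0, so ideal square grids
#' score 0.
#'
#' @param g a connected `igraph` graph with at least 4 nodes.
#' @param n_rand number of random references (default 10).
#' @param n_swaps_per_edge accepted swaps per edge per reference (default 5).
#' @param seed integer seed; reference seeds are derived from it, making the
#'   value fully reproducible.
#' @return A nonnegative real (possibly `Inf` in the degenerate case where
#'   every reference is triangle-free while the graph is not).
#' @export
small_world_sigma <- function(g, n_rand = 10, n_swaps_per_edge = 5, seed = 1L) {
  if (igraph::vcount(g) < 4L) stop("sigma needs at least 4 nodes")
  cc <- triangle_clustering_mean(g)
  if (cc == 0) return(0)
  ll <- avg_path_length(g)
  c_rand <- numeric(n_rand)
  l_rand <- numeric(n_rand)
  for (i in seq_len(n_rand)) {
    ref <- random_reference(g, n_swaps_per_edge, seed = derive_seed(seed, i))
    c_rand[i] <- triangle_clustering_mean(ref)
    comps <- graph_components(ref)
    l_rand[i] <- avg_path_length(subgraph_of(ref, comps[[1L]]))
  }
  cr <- mean(c_rand)
  lr <- mean(l_rand)
  if (cr == 0) return(Inf)
  (cc / cr) / (ll / lr)
}
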