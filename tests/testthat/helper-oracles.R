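# Brute-force oracles, independent of the package's matrix-based routes:
# explicit enumeration and breadth-first search on neighbor sets.

neighbor_set <- function(g, v) {
  sort(igraph::neighbors(g, v)$name)
}

# count triangles by exhaustive triple enumeration
oracle_triangles <- function(g) {
  nm <- sort(igraph::V(g)$name)
  if (length(nm) < 3L) return(0L)
  cnt <- 0L
  trip <- utils::combn(nm, 3L)
  for (i in seq_len(ncol(trip))) {
    a <- trip[1L, i]; b <- trip[2L, i]; d <- trip[3L, i]
    if (igraph::are_adjacent(g, a, b) && igraph::are_adjacent(g, b, d) &&
        igraph::are_adjacent(g, a, d)) {
      cnt <- cnt + 1L
    }
  }
  cnt
}

oracle_transitivity <- function(g) {
  k <- igraph::degree(g)
  triads <- sum(k * (k - 1)) / 2
  if (triads == 0) return(0)
  3 * oracle_triangles(g) / triads
}

# two-colorability by BFS
oracle_bipartite <- function(g) {
  nm <- igraph::V(g)$name
  color <- stats::setNames(rep(NA_integer_, length(nm)), nm)
  for (start in nm) {
    if (!is.na(color[start])) next
    color[start] <- 0L
    queue <- start
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (u in neighbor_set(g, v)) {
        if (is.na(color[u])) {
          color[u] <- 1L - color[v]
          queue <- c(queue, u)
        } else if (color[u] == color[v]) {
          return(FALSE)
        }
      }
    }
  }
  TRUE
}

# ball of radius r around v by plain BFS
oracle_ball <- function(g, v, r) {
  dist <- stats::setNames(rep(Inf, igraph::vcount(g)), igraph::V(g)$name)
  dist[v] <- 0
  queue <- v
  while (length(queue)) {
    x <- queue[1L]; queue <- queue[-1L]
    for (u in neighbor_set(g, x)) {
      if (!is.finite(dist[u])) {
        dist[u] <- dist[x] + 1
        queue <- c(queue, u)
      }
    }
  }
  sort(names(dist)[dist <= r])
}

# square clustering from its definition via neighbor-set enumeration
oracle_square_clustering <- function(g, v) {
  nb <- neighbor_set(g, v)
  if (length(nb) < 2L) return(0)
  k <- igraph::degree(g)
  num <- 0
  den <- 0
  pairs <- utils::combn(nb, 2L)
  for (i in seq_len(ncol(pairs))) {
    u <- pairs[1L, i]; w <- pairs[2L, i]
    common <- setdiff(intersect(neighbor_set(g, u), neighbor_set(g, w)), v)
    q <- length(common)
    eta <- 1 + q + as.integer(igraph::are_adjacent(g, u, w))
    num <- num + q
    den <- den + q + (k[[u]] - eta) + (k[[w]] - eta)
  }
  if (den > 0) num / den else 0
}

# small random graph fixture (guaranteed at least one edge)
rand_fixture <- function(n, p, seed) {
  g <- gen_random(n, p, seed)
  if (igraph::ecount(g) == 0L) {
    g <- igraph::add_edges(g, c("v1", "v2"))
  }
  g
}

# relabel nodes with random fresh names
permute_names <- function(g, seed) {
  nm <- igraph::V(g)$name
  set.seed(seed)
  new <- paste0("x", sample(seq_along(nm) + 1000L))
  igraph::set_vertex_attr(g, "name", value = new)
}

table2_intervals <- list(
  random = list(square_clustering = c(0.07, 0.40), transitivity = c(0.14, 0.60),
                bipartivity = c(0.50, 0.93), sigma = c(0.89, 1.23)),
  preferential = list(square_clustering = c(0.15, 0.56), transitivity = c(0.20, 0.67),
                      bipartivity = c(0.50, 0.65), sigma = c(0.75, 1.08)),
  small_world = list(square_clustering = c(0.05, 0.55), transitivity = c(0.08, 0.72),
                     bipartivity = c(0.54, 0.89), sigma = c(0.60, 4.88))
)
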