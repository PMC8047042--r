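# Brute-force graph-metric oracles, independent of the package's igraph
# route: plain adjacency matrices, all-pairs BFS, triangle counting by
# neighbour-pair enumeration, and exhaustive shortest-path enumeration for
# betweenness. Only usable at small n; that is the point.

oracle_adjacency <- function(net) {
  n <- length(net$nodes)
  a <- matrix(0L, n, n, dimnames = list(net$nodes, net$nodes))
  e <- net$edges
  if (nrow(e) > 0) {
    for (i in seq_len(nrow(e))) {
      a[e[i, 1], e[i, 2]] <- 1L
      a[e[i, 2], e[i, 1]] <- 1L
    }
  }
  a
}

oracle_bfs <- function(a, s) {
  n <- nrow(a)
  d <- rep(Inf, n)
  d[s] <- 0
  frontier <- s
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in which(a[v, ] == 1L)) {
        if (is.infinite(d[w])) {
          d[w] <- d[v] + 1
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  d
}

oracle_distances <- function(net) {
  a <- oracle_adjacency(net)
  t(vapply(seq_len(nrow(a)), function(s) oracle_bfs(a, s), numeric(nrow(a))))
}

oracle_mpl <- function(net) {
  d <- oracle_distances(net)
  v <- d[upper.tri(d)]
  v <- v[is.finite(v)]
  if (length(v) == 0) 0 else mean(v)
}

oracle_gcc_meanlocal <- function(net) {
  a <- oracle_adjacency(net)
  n <- nrow(a)
  if (n == 0) return(0)
  cc <- vapply(seq_len(n), function(v) {
    nb <- which(a[v, ] == 1L)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      tri <- tri + a[nb[i], nb[j]]
    }
    tri / choose(k, 2)
  }, numeric(1))
  mean(cc)
}

oracle_md <- function(net) {
  n <- length(net$nodes)
  if (n == 0) 0 else 2 * nrow(net$edges) / n
}

# all shortest s-t paths by DFS over the BFS distance field
oracle_all_shortest_paths <- function(a, d_s, s, t) {
  paths <- list()
  walk <- function(v, path) {
    if (v == t) {
      paths[[length(paths) + 1]] <<- path
      return()
    }
    for (w in which(a[v, ] == 1L)) {
      if (d_s[w] == d_s[v] + 1 && d_s[w] <= d_s[t]) walk(w, c(path, w))
    }
  }
  if (is.finite(d_s[t])) walk(s, s)
  paths
}

oracle_betweenness <- function(net) {
  a <- oracle_adjacency(net)
  n <- nrow(a)
  if (n == 0) return(numeric(0))
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    d_s <- oracle_bfs(a, s)
    for (t in (s + 1):n) {
      paths <- oracle_all_shortest_paths(a, d_s, s, t)
      if (length(paths) == 0) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        through <- sum(vapply(paths, function(p) v %in% p, logical(1)))
        bc[v] <- bc[v] + through / length(paths)
      }
    }
  }
  bc
}

oracle_mean_bc <- function(net) {
  b <- oracle_betweenness(net)
  if (length(b) == 0) 0 else mean(b)
}

oracle_mean_hc <- function(net) {
  n <- length(net$nodes)
  if (n <= 1) return(0)
  d <- oracle_distances(net)
  hc <- vapply(seq_len(n), function(v) {
    sum(1 / d[v, -v][is.finite(d[v, -v])]) / (n - 1)
  }, numeric(1))
  mean(hc)
}

random_semnet <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("v%02d", seq_len(n))
  pairs <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(pairs)) < p
  semnet(nodes, pairs[keep, , drop = FALSE])
}
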