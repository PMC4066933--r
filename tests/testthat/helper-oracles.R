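# Independent brute-force oracles used across tests. These deliberately use
# naive enumeration, not the algorithms of the package.

# all shortest paths between s and t by exhaustive DFS (paths as node
# sequences); adj is a logical/0-1 symmetric matrix
.enumerate_shortest_paths <- function(adj, s, t) {
  n <- nrow(adj)
  # BFS distance for pruning only (textbook, independent of Brandes)
  dist <- rep(Inf, n); dist[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) for (w in which(adj[v, ] > 0))
      if (dist[w] == Inf) { dist[w] <- dist[v] + 1; nxt <- c(nxt, w) }
    frontier <- nxt
  }
  if (!is.finite(dist[t])) return(list())
  paths <- list()
  dfs <- function(path) {
    v <- path[length(path)]
    if (v == t) { paths[[length(paths) + 1]] <<- path; return() }
    if (length(path) - 1 >= dist[t]) return()
    for (w in which(adj[v, ] > 0))
      if (!(w %in% path) && dist[w] == length(path)) dfs(c(path, w))
  }
  dfs(s)
  paths
}

# raw betweenness by enumerating every shortest path of every unordered pair
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  btw <- rep(0, n)
  for (s in seq_len(n - 1)) for (t in seq(s + 1, n)) {
    paths <- .enumerate_shortest_paths(adj, s, t)
    if (length(paths) == 0) next
    for (p in paths) {
      interior <- setdiff(p, c(s, t))
      btw[interior] <- btw[interior] + 1 / length(paths)
    }
  }
  btw
}

# topological overlap by explicit double loop
brute_tom <- function(a) {
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    shared <- sum(a[i, -c(i, j)] * a[-c(i, j), j])
    tom[i, j] <- (shared + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# hypergeometric upper tail by term-by-term summation
brute_hyper_tail <- function(N, K, n, x) {
  js <- x:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# small aligned synthetic cohort used by several suites
small_cohort <- function(seed = 42, ...) {
  simulate_cohort(sim_params(seed = seed, ...))
}

# random symmetric 0/1 adjacency with given density (no self-loops)
random_graph_adj <- function(n, density = 0.4) {
  a <- matrix(0, n, n)
  up <- upper.tri(a)
  a[up] <- as.numeric(runif(sum(up)) < density)
  a + t(a)
}
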