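## Brute-force graph-metric oracles, independent of the igraph-backed
## implementation: explicit BFS for distances/efficiency, adjacency-cube
## triangle counting for clustering, and a plain Brandes accumulation for
## betweenness.

oracleDegree <- function(adj) colSums(adj != 0)

oracleClustering <- function(adj) {
  A <- (adj != 0) * 1
  tri <- diag(A %*% A %*% A) / 2
  d <- colSums(A)
  cc <- ifelse(d < 2, 0, tri / (d * (d - 1) / 2))
  as.numeric(cc)
}

oracleBfsDistances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer()
      for (v in frontier) {
        nb <- which(adj[v, ] != 0)
        new <- nb[dist[nb] == Inf]
        dist[new] <- dist[v] + 1
        nxt <- c(nxt, new)
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
  }
  D
}

oracleEfficiency <- function(adj) {
  D <- oracleBfsDistances(adj)
  inv <- 1 / D
  diag(inv) <- 0
  inv[is.infinite(D)] <- 0
  rowSums(inv) / (nrow(adj) - 1)
}

## Brandes' accumulation for unweighted undirected geodesic betweenness
## (each unordered pair counted once).
oracleBetweenness <- function(adj) {
  n <- nrow(adj)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    order_visited <- integer()
    queue <- c(s)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      order_visited <- c(order_visited, v)
      for (w in which(adj[v, ] != 0)) {
        if (dist[w] < 0) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in which(adj[w, ] != 0)) {
        if (dist[v] == dist[w] - 1L)
          delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc / 2
}

randomAdjacency <- function(n, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- matrix(0L, n, n)
  up <- which(upper.tri(a))
  a[up] <- rbinom(length(up), 1, p)
  a | t(a)
}

## Small preprocessed synthetic cohort shared across tests (built once).
smallCohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- cohortDesign(nRegions = 64, nVolumes = 140, nModules = 4,
                        hubsPerModule = 2, nSwitch = 4,
                        groupSizes = c(patient = 8, control = 8, holdout = 0),
                        seed = 424242)
      cache <<- generateCohort(d)
    }
    cache
  }
})
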