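#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Pearson correlation matrices over usable volumes
#'
#' Computes the full (signed) N x N Pearson correlation matrix per subject,
#' using non-censored volumes only. Zero-variance regions yield zero
#' correlations with a warning.
#'
#' @param cohort a preprocessed [RoiTimeSeriesSet-class].
#' @return a [ConnectomeSet-class].
#' @export
buildConnectomes <- function(cohort) {
  stopifnot(is(cohort, "RoiTimeSeriesSet"))
  n <- nRegions(cohort)
  S <- nSubjects(cohort)
  r <- array(NA_real_, c(n, n, S))
  usable <- integer(S)
  for (i in seq_len(S)) {
    keep <- cohort@censor[[i]]
    usable[i] <- sum(keep)
    if (usable[i] < 2L)
      stop("subject ", i, ": fewer than 2 usable volumes")
    x <- cohort@signals[[i]][keep, , drop = FALSE]
    sds <- apply(x, 2L, stats::sd)
    if (any(sds == 0)) {
      warning("subject ", i, ": ", sum(sds == 0),
              " zero-variance region(s); correlations set to 0")
      ri <- matrix(0, n, n)
      ok <- sds > 0
      ri[ok, ok] <- stats::cor(x[, ok, drop = FALSE])
      diag(ri) <- 1
    } else {
      ri <- stats::cor(x)
    }
    r[, , i] <- ri
  }
  new("ConnectomeSet", r = r, colData = cohort@colData, usableVolumes = usable)
}

#' Threshold correlation matrices into binary graphs
#'
#' For each subject and each density d, keeps exactly round(d * N(N-1)/2)
#' edges with the largest signed correlations (ties broken by value, then
#' lexicographic node pair; fully deterministic). Self-loops never enter.
#'
#' @param connectomes a [ConnectomeSet-class].
#' @param densities numeric vector of link densities (default the 2-10% ladder
#'   in 1% steps).
#' @return a [BinaryGraphStack-class].
#' @export
thresholdGraphs <- function(connectomes, densities = seq(0.02, 0.10, by = 0.01)) {
  stopifnot(is(connectomes, "ConnectomeSet"))
  n <- nRegions(connectomes)
  S <- nSubjects(connectomes)
  adjacency <- vector("list", length(densities))
  names(adjacency) <- format(densities)
  for (k in seq_along(densities)) {
    a <- array(FALSE, c(n, n, S))
    for (i in seq_len(S)) {
      ri <- connectomes@r[, , i]
      diag(ri) <- -Inf
      a[, , i] <- .selectTopEdges(ri, densities[k])
    }
    adjacency[[k]] <- a
  }
  new("BinaryGraphStack", adjacency = adjacency, densities = densities,
      colData = connectomes@colData)
}

.asIgraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj * 1, mode = "undirected", diag = FALSE)
}

#' Nodal topology of one binary graph
#'
#' Degree, clustering coefficient (0 when degree < 2), nodal efficiency
#' (mean inverse shortest path length to all other nodes, 1/Inf = 0 for
#' unreachable pairs) and unnormalised geodesic betweenness centrality.
#'
#' @param adj N x N logical/0-1 symmetric adjacency (no self-loops).
#' @return data.frame with columns `node`, `degree`, `clustering`,
#'   `efficiency`, `betweenness`.
#' @export
nodalMetrics <- function(adj) {
  g <- .asIgraph(adj)
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  sp <- igraph::distances(g)
  inv <- 1 / sp
  diag(inv) <- 0
  inv[is.infinite(sp)] <- 0
  eff <- rowSums(inv) / (n - 1)
  bc <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  data.frame(node = seq_len(n), degree = as.numeric(deg),
             clustering = as.numeric(cc), efficiency = eff,
             betweenness = as.numeric(bc))
}

#' Long-format metric table for a graph stack
#'
#' Computes nodal metrics for every subject at every density. Degree alone is
#' cheap; clustering/efficiency/betweenness can be disabled for degree-only
#' analyses.
#'
#' @param stack a [BinaryGraphStack-class].
#' @param metrics subset of `c("degree", "clustering", "efficiency",
#'   "betweenness")`.
#' @return data.frame: `subject_id`, `group`, `density`, `node`, one column
#'   per requested metric.
#' @export
graphMetricTable <- function(stack,
                             metrics = c("degree", "clustering",
                                         "efficiency", "betweenness")) {
  stopifnot(is(stack, "BinaryGraphStack"))
  metrics <- match.arg(metrics, several.ok = TRUE)
  ids <- as.character(stack@colData$subject_id)
  groups <- subjectGroups(stack)
  out <- vector("list", length(stack@densities) * length(ids))
  k <- 0L
  for (di in seq_along(stack@densities)) {
    a <- stack@adjacency[[di]]
    for (i in seq_along(ids)) {
      adj <- a[, , i]
      if (identical(metrics, "degree")) {
        mt <- data.frame(node = seq_len(nrow(adj)), degree = colSums(adj))
      } else {
        mt <- nodalMetrics(adj)[, c("node", metrics), drop = FALSE]
      }
      k <- k + 1L
      out[[k]] <- cbind(subject_id = ids[i], group = groups[i],
                        density = stack@densities[di], mt)
    }
  }
  do.call(rbind, out)
}

#' Global means of nodal metrics
#'
#' @param metricTable output of [graphMetricTable()].
#' @return data.frame with per subject x density means across nodes.
#' @export
globalMetrics <- function(metricTable) {
  metricCols <- setdiff(colnames(metricTable),
                        c("subject_id", "group", "density", "node"))
  agg <- stats::aggregate(metricTable[metricCols],
                          metricTable[c("subject_id", "group", "density")], mean)
  agg[order(agg$density, agg$subject_id), , drop = FALSE]
}

#' Louvain modularity averaged over repetitions
#'
#' Runs single-graph Louvain community detection `nReps` times with shuffled
#' node order and returns the mean Newman-Girvan modularity of the obtained
#' partitions. Seeded and deterministic.
#'
#' @param adj binary symmetric adjacency with at least one edge.
#' @param nReps repetitions.
#' @param seed RNG seed.
#' @return mean modularity Q (numeric scalar).
#' @export
modularityQ <- function(adj, nReps = 100L, seed = 1L) {
  g <- .asIgraph(adj)
  if (igraph::ecount(g) == 0L) stop("graph has no edges: modularity undefined")
  set.seed(seed)
  n <- igraph::vcount(g)
  qs <- vapply(seq_len(nReps), function(r) {
    perm <- sample.int(n)
    gp <- igraph::permute(g, perm)
    cl <- igraph::cluster_louvain(gp)
    igraph::modularity(gp, igraph::membership(cl))
  }, numeric(1))
  mean(qs)
}

#' Small-worldness ratio against degree-preserving rewired references
#'
#' sigma = (CC / CC_random) / (E_random / E), where CC and E are the global
#' (node-mean) clustering coefficient and efficiency, and the random reference
#' is the mean over `nRandom` Maslov-Sneppen degree-preserving rewirings
#' (10 * M swap attempts each). A network is conventionally deemed
#' small-world when the ratio exceeds 2.
#'
#' @param adj binary symmetric adjacency.
#' @param nRandom number of rewired reference graphs.
#' @param seed RNG seed.
#' @return list with `sigma`, `smallWorld` (sigma > 2), `cc`, `eff`,
#'   `ccRandom`, `effRandom`.
#' @export
smallWorldness <- function(adj, nRandom = 10L, seed = 1L) {
  g <- .asIgraph(adj)
  if (igraph::ecount(g) == 0L) stop("graph has no edges")
  set.seed(seed)
  globalCCEff <- function(gr) {
    nm <- nodalMetrics(igraph::as_adjacency_matrix(gr, sparse = FALSE))
    c(cc = mean(nm$clustering), eff = mean(nm$efficiency))
  }
  obs <- globalCCEff(g)
  refs <- vapply(seq_len(nRandom), function(i) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * igraph::ecount(g)))
    globalCCEff(gr)
  }, numeric(2))
  ccR <- mean(refs["cc", ])
  effR <- mean(refs["eff", ])
  sigma <- (obs["cc"] / ccR) / (effR / obs["eff"])
  list(sigma = unname(sigma), smallWorld = unname(sigma > 2),
       cc = unname(obs["cc"]), eff = unname(obs["eff"]),
       ccRandom = ccR, effRandom = effR)
}
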