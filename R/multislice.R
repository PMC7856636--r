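#' @include AllClasses.R AllGenerics.R utils.R
#' @useDynLib hubshift, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## adjacency array (N x N x S logical) -> edge table (slice, i, j), i < j
.edgeTable <- function(adjArray) {
  S <- dim(adjArray)[3L]
  parts <- lapply(seq_len(S), function(s) {
    idx <- which(adjArray[, , s] & upper.tri(adjArray[, , s]), arr.ind = TRUE)
    cbind(slice = s, i = idx[, 1L], j = idx[, 2L])
  })
  do.call(rbind, parts)
}

#' Categorical multislice community detection
#'
#' Optimizes the categorical multislice modularity of Mucha-style multilayer
#' networks: each subject's binary graph is one slice; intra-slice quality is
#' Newman-Girvan with resolution `gamma`, and every pair of slices is coupled
#' with strength `omega` at the same node (all-to-all categorical coupling).
#' Optimization is a generalized Louvain (randomized greedy vertex moves plus
#' community aggregation), seeded and deterministic.
#'
#' @param adjArray N x N x S logical/0-1 array of binary undirected graphs
#'   (all slices share the node set; every slice needs at least one edge).
#' @param gamma intra-slice resolution (study default 1.5).
#' @param omega inter-slice coupling strength (study default 0.1).
#' @param seed RNG seed.
#' @return integer matrix N x S of community labels per (node, slice), with
#'   the achieved multilayer quality (unnormalized) in `attr(., "quality")`.
#' @export
multislicePartition <- function(adjArray, gamma = 1.5, omega = 0.1, seed = 1L) {
  if (length(dim(adjArray)) == 2L)
    adjArray <- array(adjArray, c(dim(adjArray), 1L))
  n <- dim(adjArray)[1L]
  S <- dim(adjArray)[3L]
  edges <- .edgeTable(adjArray)
  if (is.null(edges) || nrow(edges) == 0L) stop("no edges in any slice")
  memb <- multisliceLouvainCpp(edges, n, S, gamma, omega, as.integer(seed))
  out <- matrix(memb, n, S)
  attr(out, "quality") <- multisliceQualityCpp(edges, memb, n, S, gamma, omega)
  out
}

#' Multilayer quality of a given partition
#'
#' Unnormalized categorical multislice modularity value of an arbitrary
#' (node, slice) partition; useful for comparing partitions.
#'
#' @param adjArray as in [multislicePartition()].
#' @param membership N x S integer matrix of community labels.
#' @param gamma,omega quality parameters.
#' @return numeric scalar.
#' @export
multisliceQuality <- function(adjArray, membership, gamma = 1.5, omega = 0.1) {
  if (length(dim(adjArray)) == 2L)
    adjArray <- array(adjArray, c(dim(adjArray), 1L))
  n <- dim(adjArray)[1L]
  S <- dim(adjArray)[3L]
  edges <- .edgeTable(adjArray)
  multisliceQualityCpp(edges, as.integer(membership), n, S, gamma, omega)
}

## agreement of one categorical run: fraction of slices where i, j share a
## community
.runAgreement <- function(membership) {
  S <- ncol(membership)
  am <- matrix(0, nrow(membership), nrow(membership))
  for (s in seq_len(S)) {
    lab <- membership[, s]
    am <- am + outer(lab, lab, "==")
  }
  am / S
}

#' Group agreement matrix over subject subsamples
#'
#' For one group of subjects: repeats `nReps` times drawing `nSubsample`
#' subjects without replacement, running the categorical multislice
#' partition, and recording the run-level agreement (fraction of slices in
#' which two nodes share a community); the agreement matrix (AM) is the mean
#' over repetitions. Entries lie in [0, 1] with unit diagonal.
#'
#' @param adjArray N x N x S array of one group's binary graphs (the study
#'   uses 10% density).
#' @param nSubsample subjects drawn per repetition (study value 34; default
#'   the full group, i.e. no subsampling).
#' @param nReps repetitions (study value 1000).
#' @param gamma,omega multislice parameters.
#' @param seed RNG seed.
#' @return N x N numeric agreement matrix.
#' @export
agreementMatrix <- function(adjArray, nSubsample = dim(adjArray)[3L],
                            nReps = 100L, gamma = 1.5, omega = 0.1, seed = 1L) {
  S <- dim(adjArray)[3L]
  if (nReps < 1L) stop("nReps must be at least 1")
  if (nSubsample > S) stop("nSubsample exceeds group size")
  set.seed(seed)
  n <- dim(adjArray)[1L]
  am <- matrix(0, n, n)
  for (r in seq_len(nReps)) {
    pick <- if (nSubsample < S) sort(sample.int(S, nSubsample)) else seq_len(S)
    runSeed <- .deriveSeed(seed, paste0("am", r))
    memb <- multislicePartition(adjArray[, , pick, drop = FALSE],
                                gamma = gamma, omega = omega, seed = runSeed)
    am <- am + .runAgreement(memb)
  }
  am / nReps
}

#' Agreement difference and nodal modular reorganization
#'
#' diff = AM_patient - AM_control (entries in [-1, 1]); the nodal modular
#' reorganization score of node i is sum_j |diff_ij|, reported together with
#' its positive and negative components (gain of shared-module partners vs
#' loss).
#'
#' @param amPatient,amControl N x N agreement matrices on the same node set.
#' @return list: `diff` (N x N), `reorg` data.frame with `node`, `reorg`,
#'   `positive`, `negative`.
#' @export
differenceAndReorg <- function(amPatient, amControl) {
  if (!all(dim(amPatient) == dim(amControl)))
    stop("agreement matrices differ in shape")
  d <- amPatient - amControl
  diag(d) <- 0
  pos <- rowSums(pmax(d, 0))
  neg <- rowSums(pmin(d, 0))
  list(diff = d,
       reorg = data.frame(node = seq_len(nrow(d)),
                          reorg = pos + abs(neg),
                          positive = pos, negative = neg))
}

#' Permutation null for nodal modular reorganization
#'
#' Shuffles subjects between the two groups (sizes preserved), recomputes
#' both agreement matrices and the nodal reorganization scores per
#' permutation, and returns one-sided p-values
#' p_i = (1 + #\{perm reorg_i >= observed_i\}) / (1 + nPerm) with a
#' significance flag at `alpha` (study threshold .01).
#'
#' @param adjPatient,adjControl N x N x S arrays of the two groups' graphs.
#' @param nPerm number of label permutations (>= 99 to resolve p < .01).
#' @param nReps inner agreement repetitions per permutation (reduced
#'   Monte-Carlo by default; the study's full setting is 1000).
#' @param nSubsample subjects per agreement draw (default min group size).
#' @param gamma,omega multislice parameters.
#' @param alpha significance threshold on the one-sided p.
#' @param seed RNG seed.
#' @return list: `observed` (reorg data.frame with `perm_p` and `significant`
#'   columns added), `diff` (observed difference matrix), `nullReorg`
#'   (nPerm x N matrix).
#' @export
reorgPermutationNull <- function(adjPatient, adjControl, nPerm = 1000L,
                                 nReps = 10L,
                                 nSubsample = min(dim(adjPatient)[3L],
                                                  dim(adjControl)[3L]),
                                 gamma = 1.5, omega = 0.1, alpha = 0.01,
                                 seed = 1L) {
  if (nPerm < 99L) stop("nPerm < 99 cannot resolve p < .01")
  nP <- dim(adjPatient)[3L]; nC <- dim(adjControl)[3L]
  if (nP < 1L || nC < 1L) stop("both groups must be non-empty")
  n <- dim(adjPatient)[1L]
  all <- array(c(adjPatient, adjControl), c(n, n, nP + nC))
  computeReorg <- function(idxP, tag) {
    amP <- agreementMatrix(all[, , idxP, drop = FALSE], nSubsample = nSubsample,
                           nReps = nReps, gamma = gamma, omega = omega,
                           seed = .deriveSeed(seed, paste0(tag, "P")))
    amC <- agreementMatrix(all[, , setdiff(seq_len(nP + nC), idxP), drop = FALSE],
                           nSubsample = nSubsample, nReps = nReps,
                           gamma = gamma, omega = omega,
                           seed = .deriveSeed(seed, paste0(tag, "C")))
    differenceAndReorg(amP, amC)
  }
  obs <- computeReorg(seq_len(nP), "obs")
  set.seed(seed)
  nullReorg <- matrix(NA_real_, nPerm, n)
  for (p in seq_len(nPerm)) {
    idxP <- sample.int(nP + nC, nP)
    nullReorg[p, ] <- computeReorg(idxP, paste0("perm", p))$reorg$reorg
  }
  exceed <- colSums(nullReorg >= matrix(obs$reorg$reorg, nPerm, n, byrow = TRUE))
  out <- obs$reorg
  out$perm_p <- (1 + exceed) / (1 + nPerm)
  out$significant <- out$perm_p < alpha
  list(observed = out, diff = obs$diff, nullReorg = nullReorg)
}
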