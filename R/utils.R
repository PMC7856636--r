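#' @include AllClasses.R
NULL

## Deterministic edge selection shared by graph thresholding and by the
## generator's expected-degree computation.
##
## Returns the logical adjacency keeping exactly m = round(d * N(N-1)/2)
## strongest (signed) upper-triangle entries; ties broken by value, then by
## lexicographic (i, j) so the output is reproducible.
.selectTopEdges <- function(r, density) {
  n <- nrow(r)
  idx <- which(upper.tri(r), arr.ind = TRUE)
  v <- r[upper.tri(r)]
  m <- round(density * n * (n - 1) / 2)
  if (m < 1L) stop("density ", density, " yields zero edges for N = ", n)
  if (m > length(v)) stop("density exceeds the complete graph")
  ord <- order(-v, idx[, 1L], idx[, 2L])
  keep <- ord[seq_len(m)]
  adj <- matrix(FALSE, n, n)
  adj[idx[keep, , drop = FALSE]] <- TRUE
  adj | t(adj)
}

## Zero-phase Butterworth band-pass applied column-wise. Columns are demeaned
## and extended by odd reflection at both ends before forward-backward
## filtering, which suppresses the start-up transients filtfilt otherwise
## leaks into short series.
.butterBandpass <- function(x, trSeconds, low = 0.008, high = 0.1, order = 2L) {
  nyq <- 1 / (2 * trSeconds)
  if (high >= nyq)
    stop("band-pass upper edge (", high, " Hz) must be below Nyquist (", nyq, " Hz)")
  if (low <= 0 || low >= high) stop("require 0 < low < high")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  x <- as.matrix(x)
  Tn <- nrow(x)
  pad <- min(Tn - 1L, 60L)
  apply(x, 2L, function(col) {
    c0 <- col - mean(col)
    pre <- 2 * c0[1L] - c0[(pad + 1L):2L]
    post <- 2 * c0[Tn] - c0[(Tn - 1L):(Tn - pad)]
    out <- signal::filtfilt(bf, c(pre, c0, post))
    out[(pad + 1L):(pad + Tn)]
  })
}

## Linear interpolation over censored volumes (used before filtering so spike
## gaps do not leak through the pass band).
.interpolateCensored <- function(x, usable) {
  if (all(usable) || !any(usable)) return(x)
  t_all <- seq_len(nrow(x))
  apply(x, 2L, function(col) {
    stats::approx(t_all[usable], col[usable], xout = t_all, rule = 2)$y
  })
}

.vecUpperTri <- function(m) m[upper.tri(m)]

## Seed stream: derive per-stage/per-draw seeds below 2^31 from a master seed.
.deriveSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
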