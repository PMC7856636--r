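#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame
NULL

#' Cohort design: ground truth for the synthetic generator
#'
#' A `CohortDesign` holds every parameter of the synthetic two-group cohort:
#' the atlas size and scan dimensions, the modular structure and hub set of the
#' latent connectivity model, the planted hub-disruption slope `kTrue`, the set
#' of regions whose module identity switches in patients, the sparse
#' region-to-pain weight map, and the motion-corruption rate. The defaults
#' emulate a two-group osteoarthritis-style cohort: 46 discovery patients,
#' 35 controls and 45 hold-out patients, 300 volumes at TR = 2.5 s, 256
#' regions in 8 modules.
#'
#' @slot nRegions number of atlas regions (nodes).
#' @slot nVolumes number of acquired volumes per subject (before dropping the
#'   initial saturation volumes).
#' @slot trSeconds repetition time in seconds.
#' @slot moduleAssignment integer vector of length `nRegions`; latent module
#'   label per region.
#' @slot hubSet integer indices of regions with elevated cross-module loadings
#'   (the planted hubs).
#' @slot kTrue planted hub-disruption slope (dimensionless); negative values
#'   mean hubs lose degree in patients.
#' @slot switchSet integer indices of regions whose module identity differs in
#'   the patient group.
#' @slot switchTarget integer vector, same length as `switchSet`: module each
#'   switch region joins in patients.
#' @slot betaPain named numeric vector (names = region indices) of nonzero
#'   degree-to-pain weights; sparse relative to `nRegions`.
#' @slot noiseSd standard deviation of the Gaussian noise added to the pain
#'   score (NRS units).
#' @slot motionRate probability in [0, 1) that a volume is motion corrupted.
#' @slot groupSizes named integer vector with elements `patient`, `control`,
#'   `holdout`.
#' @slot subjectLoadingSd per-subject multiplicative jitter SD on region
#'   loadings; the source of between-subject connectivity variation.
#' @slot ageEffect optional slope of an age confound on loadings (0 = off).
#' @slot analysisDensity link density at which expected degree (the pain
#'   predictor and the disruption standardisation) is evaluated.
#' @slot seed RNG seed; the generator is fully deterministic given the design.
#' @export
setClass("CohortDesign",
  representation(
    nRegions = "integer", nVolumes = "integer", trSeconds = "numeric",
    moduleAssignment = "integer", hubSet = "integer",
    kTrue = "numeric", switchSet = "integer", switchTarget = "integer",
    betaPain = "numeric", noiseSd = "numeric", motionRate = "numeric",
    groupSizes = "integer", subjectLoadingSd = "numeric",
    ageEffect = "numeric", analysisDensity = "numeric", seed = "integer"
  )
)

setValidity("CohortDesign", function(object) {
  msg <- character()
  n <- object@nRegions
  if (length(object@moduleAssignment) != n)
    msg <- c(msg, "moduleAssignment must cover all regions")
  if (length(object@hubSet) && (min(object@hubSet) < 1L || max(object@hubSet) > n))
    msg <- c(msg, "hubSet must be a subset of 1..nRegions")
  if (length(object@switchSet) != length(object@switchTarget))
    msg <- c(msg, "switchSet and switchTarget lengths differ")
  if (length(object@switchSet) && (min(object@switchSet) < 1L || max(object@switchSet) > n))
    msg <- c(msg, "switchSet must be a subset of 1..nRegions")
  if (object@motionRate < 0 || object@motionRate >= 1)
    msg <- c(msg, "motionRate must lie in [0, 1)")
  if (length(object@betaPain) > n / 4)
    msg <- c(msg, "betaPain must be sparse (at most nRegions/4 nonzeros)")
  if (length(object@betaPain) && any(is.na(suppressWarnings(as.integer(names(object@betaPain))))))
    msg <- c(msg, "betaPain must be named by region indices")
  if (!all(c("patient", "control", "holdout") %in% names(object@groupSizes)))
    msg <- c(msg, "groupSizes needs patient/control/holdout entries")
  if (object@analysisDensity <= 0 || object@analysisDensity >= 1)
    msg <- c(msg, "analysisDensity must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Per-subject ROI time-series with nuisance regressors and censor masks
#'
#' Container for a cohort of region-of-interest time-series. Each subject
#' carries a T x N signal matrix, a per-volume nuisance table (frame-wise
#' displacement, DVARS and intensity z-scores, six motion parameters, global /
#' white-matter / CSF signals) and a logical censor mask (TRUE = usable).
#' Subject-level metadata (group, age, sex, pain and questionnaire scores)
#' live in a `DataFrame` with one row per subject.
#'
#' @slot signals list of T x N numeric matrices, one per subject.
#' @slot nuisance list of data.frames (rows = volumes) with columns
#'   `fd_mm`, `dvars_z`, `intensity_z`, `mp1`..`mp6`, `gs`, `wm`, `csf`.
#' @slot censor list of logical vectors (TRUE = volume usable).
#' @slot trSeconds repetition time in seconds.
#' @slot colData `S4Vectors::DataFrame` of subject covariates.
#' @slot design the generating `CohortDesign`, or NULL for imported data.
#' @slot log character vector recording the preprocessing steps applied, in
#'   order.
#' @export
setClass("RoiTimeSeriesSet",
  representation(
    signals = "list", nuisance = "list", censor = "list",
    trSeconds = "numeric", colData = "DataFrame",
    design = "ANY", log = "character"
  )
)

setValidity("RoiTimeSeriesSet", function(object) {
  msg <- character()
  s <- length(object@signals)
  if (length(object@nuisance) != s || length(object@censor) != s)
    msg <- c(msg, "signals, nuisance and censor must have one element per subject")
  if (nrow(object@colData) != s)
    msg <- c(msg, "colData must have one row per subject")
  for (i in seq_len(s)) {
    ti <- nrow(object@signals[[i]])
    if (nrow(object@nuisance[[i]]) != ti)
      msg <- c(msg, sprintf("subject %d: nuisance rows != volumes", i))
    if (length(object@censor[[i]]) != ti)
      msg <- c(msg, sprintf("subject %d: censor length != volumes", i))
  }
  ncols <- vapply(object@signals, ncol, 1L)
  if (s && length(unique(ncols)) != 1L)
    msg <- c(msg, "all subjects must share the region set")
  if (length(msg)) head(msg, 3L) else TRUE
})

#' Per-subject Pearson correlation matrices
#'
#' N x N x S array of full (signed) Pearson correlation matrices, one slab per
#' subject, computed over non-censored volumes only, with the subject metadata
#' carried along.
#'
#' @slot r numeric array N x N x S; unit diagonal, symmetric slabs.
#' @slot colData `S4Vectors::DataFrame` of subject covariates.
#' @slot usableVolumes integer vector: volumes entering each correlation.
#' @export
setClass("ConnectomeSet",
  representation(r = "array", colData = "DataFrame", usableVolumes = "integer")
)

setValidity("ConnectomeSet", function(object) {
  d <- dim(object@r)
  msg <- character()
  if (length(d) != 3L || d[1] != d[2])
    msg <- c(msg, "r must be an N x N x S array")
  if (nrow(object@colData) != d[3])
    msg <- c(msg, "colData rows must match subjects")
  rng <- range(object@r, na.rm = TRUE)
  if (rng[1] < -1 - 1e-8 || rng[2] > 1 + 1e-8)
    msg <- c(msg, "correlations must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Binary undirected graphs at a ladder of link densities
#'
#' For each subject and each link density d, the adjacency of the binary
#' undirected graph keeping exactly round(d * N(N-1)/2) strongest edges of the
#' correlation matrix (signed ranking, deterministic tie-break).
#'
#' @slot adjacency list named by density (e.g. "0.05") of N x N x S logical
#'   arrays.
#' @slot densities numeric vector of link densities.
#' @slot colData `S4Vectors::DataFrame` of subject covariates.
#' @export
setClass("BinaryGraphStack",
  representation(adjacency = "list", densities = "numeric", colData = "DataFrame")
)

setValidity("BinaryGraphStack", function(object) {
  if (length(object@adjacency) != length(object@densities))
    return("one adjacency array per density required")
  TRUE
})
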