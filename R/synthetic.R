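#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Construct a synthetic cohort design
#'
#' Builds a [CohortDesign-class] with defaults emulating a two-group chronic
#' pain imaging cohort: 256 regions in 8 latent modules of unequal size with
#' four hub regions per module, 300 volumes at TR = 2.5 s, 46 discovery
#' patients / 35 controls / 45 hold-out patients, a planted hub-disruption
#' slope of -0.2, 8 regions whose module identity switches in patients, and a
#' sparse 4-region degree-to-pain weight map.
#'
#' @param nRegions,nVolumes,trSeconds atlas and scan dimensions.
#' @param nModules number of latent modules (sizes decrease linearly).
#' @param hubsPerModule planted hubs per module (elevated own loadings, low
#'   region noise and cross-module bridges, hence elevated degree).
#' @param kTrue planted hub-disruption slope; 0 disables disruption.
#' @param nSwitch number of module-switching regions planted in patients
#'   (non-hubs, one per module until exhausted); 0 disables.
#' @param betaPain named numeric vector of degree-to-pain weights, or NULL for
#'   the default sparse map (4 non-hub regions, graded weights, mixed signs).
#' @param noiseSd SD of the Gaussian noise on the pain score (NRS units).
#' @param motionRate per-volume probability of motion corruption.
#' @param groupSizes named integer vector (patient, control, holdout).
#' @param subjectLoadingSd per-subject loading jitter SD (baseline
#'   between-subject connectivity variation).
#' @param ageEffect slope of an optional age confound on loadings (0 = off).
#' @param analysisDensity density at which expected degree is evaluated.
#' @param seed RNG seed.
#' @return a validated [CohortDesign-class].
#' @examples
#' d <- cohortDesign(nRegions = 64, groupSizes = c(patient = 8, control = 8, holdout = 0))
#' d
#' @export
cohortDesign <- function(nRegions = 256L, nVolumes = 300L, trSeconds = 2.5,
                         nModules = 8L, hubsPerModule = 4L,
                         kTrue = -0.2, nSwitch = 8L,
                         betaPain = NULL, noiseSd = 0.6, motionRate = 0.03,
                         groupSizes = c(patient = 46L, control = 35L, holdout = 45L),
                         subjectLoadingSd = 0.12, ageEffect = 0,
                         analysisDensity = 0.05, seed = 20201119L) {
  nRegions <- as.integer(nRegions)
  nModules <- as.integer(nModules)
  ## unequal module sizes (large associative modules down to small specialised
  ## ones), as in empirical functional parcellations: linearly decreasing
  ## profile, minimum 4 regions
  w <- seq(2, 0.5, length.out = nModules)
  sizes <- pmax(4L, as.integer(round(nRegions * w / sum(w))))
  while (sum(sizes) != nRegions) {
    k <- if (sum(sizes) > nRegions) which.max(sizes) else which.min(sizes)
    sizes[k] <- sizes[k] + sign(nRegions - sum(sizes))
  }
  moduleAssignment <- rep(seq_len(nModules), sizes)
  moduleStart <- cumsum(c(1L, sizes[-nModules]))
  ## hubs: the first `hubsPerModule` regions of each module (given elevated
  ## own-module loadings and cross-module bridges by the generator)
  hubSet <- as.integer(outer(seq_len(hubsPerModule) - 1L, moduleStart, "+"))
  hubSet <- sort(hubSet[hubSet <= nRegions])
  ## switch regions: one non-hub region per module (last region of the module),
  ## reassigned to the next module cyclically
  nSwitch <- as.integer(nSwitch)
  moduleEnd <- cumsum(sizes)
  if (nSwitch > 0L) {
    switchSet <- as.integer(moduleEnd)[seq_len(min(nSwitch, nModules))]
    if (nSwitch > nModules) {
      extra <- as.integer(moduleEnd - 1L)[seq_len(nSwitch - nModules)]
      switchSet <- c(switchSet, extra)
    }
    switchTarget <- as.integer(moduleAssignment[switchSet] %% nModules + 1L)
  } else {
    switchSet <- integer()
    switchTarget <- integer()
  }
  if (is.null(betaPain)) {
    ## one late non-hub region per module (hub degrees are dominated by the
    ## global-signal regression and track individual variation poorly);
    ## graded weights with signs alternating across modules
    latePick <- as.integer(moduleStart + pmax(sizes - 4L, 2L))
    cand <- setdiff(latePick, switchSet)
    cand <- cand[!is.na(cand) & cand <= nRegions]
    cand <- cand[seq_len(min(4L, length(cand)))]
    w <- c(2, -2, 2, -2)[seq_along(cand)]
    betaPain <- stats::setNames(w, cand)
  }
  gs <- vapply(c("patient", "control", "holdout"),
               function(g) as.integer(groupSizes[[g]]), 1L)
  new("CohortDesign",
      nRegions = nRegions, nVolumes = as.integer(nVolumes), trSeconds = trSeconds,
      moduleAssignment = as.integer(moduleAssignment), hubSet = hubSet,
      kTrue = kTrue, switchSet = switchSet, switchTarget = switchTarget,
      betaPain = betaPain, noiseSd = noiseSd, motionRate = motionRate,
      groupSizes = gs, subjectLoadingSd = subjectLoadingSd,
      ageEffect = ageEffect, analysisDensity = analysisDensity,
      seed = as.integer(seed))
}

## Gain translating the planted slope into loading scale factors. The loading
## perturbation is attenuated between loading space and the degree-difference
## regression (correlations only partially track loading scale; thresholded
## degree only partially tracks correlation scale), so the raw scale factor is
## rescaled by this calibration constant, fixed once against the estimand on
## the default design (see the methods vignette).
.kDisruptionGain <- 1.0

## Region noise SD range in the latent factor model (sources are unit
## variance): per-region noise levels are heterogeneous, which both spreads
## the expected-degree profile (high-SNR regions are high-degree) and smooths
## the correlation distribution around the density threshold; hub regions sit
## at the low-noise (high-SNR) end.
.regionNoiseRange <- c(0.7, 1.3)
## Range of per-region own-module loadings; the spread (together with the hub
## cross-loadings) sets the across-node variance of expected degree.
.ownLoadingRange <- c(0.5, 1.3)
## Every region also loads on the cyclically next module at this fraction of
## its own loading: the inter-module integration that makes the emulated
## networks small-world (connected across modules) at sparse density.
.neighborCrossLoading <- 0.5

## Own-module loading multiplier for hub regions (top of the loading range,
## boosted), and the strength of their bridges into two further modules.
.hubOwnBoost <- 1.35
.hubBridgeLoading <- 0.45
## Pain-weighted regions vary their noise level (not their loadings) across
## patients: a region's noise SD directly scales every one of its
## correlations, so it is the effective per-subject lever on that region's
## degree. Log-normal multiplier SD on the pain nodes' noise, patients only
## (pain-encoding variability is a patient-state phenomenon; controls keep
## the structural noise profile, which keeps the normative degree profile
## clean).
.painNoiseJitterSd <- 1.0

## Long-range pair factors: this many region pairs (roughly one per five
## regions) in distant modules share a private latent source, emulating the
## strong homotopic / long-range functional couplings of real connectomes;
## they provide the shortcut edges that make sparse graphs small-world.
.pairFactorLoading <- 1.2
.nPairFactors <- function(n) n %/% 5L

## Loading mix: module-level factor weight, local ring-window weight (every
## region shares a window factor with the next two regions on its module
## ring, the sparse-graph backbone guaranteeing local clustering and
## connectedness), and the weak coupling onto the cyclically next module.
.moduleLoading <- 1.0
.localLoading <- 0.55
.neighborModuleLoading <- 0.4

## Module geometry helper.
.moduleLayout <- function(design) {
  M <- max(design@moduleAssignment)
  sizes <- tabulate(design@moduleAssignment, M)
  list(M = M, sizes = sizes, start = cumsum(c(1L, sizes[-M])),
       P = .nPairFactors(design@nRegions))
}

## Base (control-group) loading matrix. Columns: M module factors, P
## long-range pair factors, then n local ring-window factors (window i is
## anchored at region i and shared with the next two regions on the module
## ring). Hubs are regions with elevated own loadings plus bridge loadings
## into two other modules.
.designLoadings <- function(design, ownLoading) {
  n <- design@nRegions
  geo <- .moduleLayout(design)
  M <- geo$M; P <- geo$P; sizes <- geo$sizes; start <- geo$start
  own <- ownLoading
  own[design@hubSet] <- .hubOwnBoost * max(.ownLoadingRange)
  L <- matrix(0, n, M + P + n)
  mod <- design@moduleAssignment
  L[cbind(seq_len(n), mod)] <- .moduleLoading * own
  L[cbind(seq_len(n), mod %% M + 1L)] <-
    .neighborModuleLoading * .moduleLoading * own
  for (h in design@hubSet) {
    others <- setdiff(seq_len(M), mod[h])
    pick <- others[(seq_len(2L) + h) %% length(others) + 1L]
    L[h, pick] <- .hubBridgeLoading * own[h]
  }
  for (p in seq_len(P)) {
    mA <- ((p - 1L) %% M) + 1L
    mB <- ((mA + M %/% 2L - 1L) %% M) + 1L
    off <- 3L + (p - 1L) %/% M
    a <- start[mA] + off
    b <- start[mB] + off + 1L
    if (a > n || b > n || off + 1L >= sizes[mA] || off + 2L >= sizes[mB]) next
    L[a, M + p] <- .pairFactorLoading * own[a]
    L[b, M + p] <- .pairFactorLoading * own[b]
  }
  for (i in seq_len(n)) {
    m <- mod[i]
    pos <- i - start[m] + 1L
    nxt <- start[m] + (pos %% sizes[m])
    nx2 <- start[m] + ((pos + 1L) %% sizes[m])
    L[i, M + P + i] <- .localLoading * own[i]
    L[nxt, M + P + i] <- .localLoading * own[nxt]
    L[nx2, M + P + i] <- 0.5 * .localLoading * own[nx2]
  }
  L
}

## Patient-group switch: reassign each switch region's module factor AND its
## local ring ties to the target module, so its community identity genuinely
## moves (module membership in these graphs rides on the ring backbone as
## much as on the module factor).
.applyModuleSwitch <- function(L, design, ownLoading) {
  if (!length(design@switchSet)) return(L)
  n <- design@nRegions
  geo <- .moduleLayout(design)
  M <- geo$M; P <- geo$P; start <- geo$start; sizes <- geo$sizes
  own <- ownLoading
  own[design@hubSet] <- .hubOwnBoost * max(.ownLoadingRange)
  for (s in seq_along(design@switchSet)) {
    i <- design@switchSet[s]
    from <- design@moduleAssignment[i]
    to <- design@switchTarget[s]
    L[i, seq_len(M)] <- 0
    L[i, to] <- .moduleLoading * own[i]
    L[i, to %% M + 1L] <- .neighborModuleLoading * .moduleLoading * own[i]
    ## leave the windows it anchors/joins in the old module
    L[i, M + P + seq_len(n)] <- 0
    ## join the target module ring at a deterministic anchor within the module
    anchorPos <- (3L + 2L * s) %% sizes[to]
    anchor <- start[to] + anchorPos
    anchor2 <- start[to] + ((anchorPos + 1L) %% sizes[to])
    L[i, M + P + anchor] <- .localLoading * own[i]
    L[i, M + P + anchor2] <- 0.5 * .localLoading * own[i]
  }
  L
}

## Expected Pearson correlation implied by loadings (unit-variance sources,
## independent region noise).
.expectedCorrelation <- function(L, noiseSd) {
  cv <- tcrossprod(L)
  diag(cv) <- diag(cv) + noiseSd^2
  stats::cov2cor(cv)
}

.expectedDegree <- function(L, density, noiseSd) {
  r <- .expectedCorrelation(L, noiseSd)
  diag(r) <- 0
  colSums(.selectTopEdges(r, density))
}

## Expected REALIZED degree: finite-scan correlation estimates fluctuate
## around the model correlation (SD about .corNoiseWidth after band-pass),
## so the expected degree of the thresholded realized graph is a smooth
## (probit) count of correlations near the subject's density threshold, not
## a hard count. The pain score is generated from this quantity, since it is
## what thresholded data can actually express.
.corNoiseWidth <- 0.09
## Project the global-signal direction out of the loadings before computing
## expected correlations: nuisance regression removes the across-region mean
## signal, which otherwise dominates high-loading (hub) regions and makes
## the analytic degree wildly overestimate their realized degree.
.gsrLoadings <- function(L) {
  w <- colMeans(L)
  denom <- sum(w * w)
  if (denom < 1e-12) return(L)
  L - (L %*% w) %*% t(w) / denom
}
.smoothExpectedDegree <- function(L, density, noiseSd) {
  r <- .expectedCorrelation(.gsrLoadings(L), noiseSd)
  diag(r) <- 0
  v <- r[upper.tri(r)]
  m <- round(density * length(v))
  thr <- sort(v, decreasing = TRUE)[m]
  p <- stats::pnorm((r - thr) / .corNoiseWidth)
  diag(p) <- 0
  colSums(p)
}

## AR(1) sources band-limited to the resting-state band, unit variance.
.latentSources <- function(T, M, trSeconds, phi = 0.5) {
  src <- matrix(stats::rnorm(T * M), T, M)
  src <- apply(src, 2L, function(e) stats::filter(e, phi, method = "recursive"))
  src <- .butterBandpass(src, trSeconds)
  scale(src)[, , drop = FALSE]
}

#' Generate a synthetic two-group cohort of ROI time-series
#'
#' Draws a full cohort from a [CohortDesign-class]: band-limited modular
#' time-series per subject, per-volume nuisance tables with motion-corrupted
#' volumes, and a clinical covariate table whose pain score is a sparse linear
#' function of expected nodal degree plus noise.
#'
#' The latent model is a factor model over unit-variance AR(1) sources
#' band-limited to 0.008-0.1 Hz: module factors, local ring-window factors
#' (the clustering backbone), and long-range pair factors (the small-world
#' shortcuts), with heterogeneous per-region noise. Patients' loadings are
#' scaled by `1 + g * kTrue * z_i` where `z_i` is the standardised control
#' expected degree and `g` a fixed calibration gain, planting an
#' approximately linear degree-difference-vs-degree relation with slope
#' `kTrue`. Switch-set regions have their module factor and ring ties
#' reassigned to a target module in patients. The pain score is a sparse
#' linear map of expected nodal degree, whose between-subject variation is
#' driven by subject-varying noise levels on the pain-weighted regions
#' (patients only). Motion-corrupted volumes receive a global signal spike
#' and a frame-wise displacement entry drawn from uniform(0.6, 1.5) mm,
#' guaranteeing the FD > 0.5 mm censoring rule fires on them.
#'
#' The generator is fully deterministic given the design (same seed, same
#' bytes).
#'
#' @param design a [CohortDesign-class].
#' @param seed optional override of `design@seed`.
#' @return a [RoiTimeSeriesSet-class] whose `sampleData()` carries the cohort
#'   table and whose `design` slot retains the ground truth.
#' @examples
#' d <- cohortDesign(nRegions = 64, nVolumes = 120,
#'                   groupSizes = c(patient = 6, control = 6, holdout = 0))
#' cohort <- generateCohort(d)
#' cohort
#' @export
generateCohort <- function(design, seed = NULL) {
  stopifnot(is(design, "CohortDesign"))
  validObject(design)
  if (!is.null(seed)) design@seed <- as.integer(seed)
  set.seed(design@seed)
  n <- design@nRegions
  T <- design@nVolumes

  ownLoading <- stats::runif(n, .ownLoadingRange[1], .ownLoadingRange[2])
  regionNoise <- stats::runif(n, .regionNoiseRange[1], .regionNoiseRange[2])
  regionNoise[design@hubSet] <- .regionNoiseRange[1]
  ## pain-weighted regions get fixed mid-high structural parameters so the
  ## degree->pain mapping has comparable strength in every realisation
  painIdx <- as.integer(names(design@betaPain))
  ownLoading[painIdx] <- 1.1
  regionNoise[painIdx] <- 1.0
  Lc <- .designLoadings(design, ownLoading)

  ## control expected degree -> standardised z drives the patient disruption
  degC <- .expectedDegree(Lc, design@analysisDensity, regionNoise)
  z <- as.numeric(scale(degC))

  Lp <- Lc * pmax(0.1, 1 + .kDisruptionGain * design@kTrue * z)
  Lp <- .applyModuleSwitch(Lp, design, ownLoading)

  sizes <- design@groupSizes
  groups <- c(rep("patient", sizes[["patient"]]),
              rep("control", sizes[["control"]]),
              rep("holdout-patient", sizes[["holdout"]]))
  S <- length(groups)
  isPat <- groups != "control"

  age <- ifelse(isPat, stats::rnorm(S, 65.3, 7.4), stats::rnorm(S, 59.5, 7.9))
  age <- round(pmin(pmax(age, 45), 75))
  sex <- ifelse(stats::runif(S) < ifelse(isPat, 0.65, 0.57), "F", "M")

  signals <- vector("list", S)
  nuisance <- vector("list", S)
  censor <- vector("list", S)
  degExp <- matrix(NA_real_, S, n)

  for (s in seq_len(S)) {
    Lbase <- if (isPat[s]) Lp else Lc
    jitter <- 1 + stats::rnorm(n, 0, design@subjectLoadingSd)
    if (design@ageEffect != 0)
      jitter <- jitter * (1 + design@ageEffect * (age[s] - 62) / 10)
    Ls <- Lbase * pmax(0.1, jitter)
    noiseS <- regionNoise
    if (isPat[s]) {
      betaIdx <- as.integer(names(design@betaPain))
      noiseS[betaIdx] <- regionNoise[betaIdx] *
        exp(stats::rnorm(length(betaIdx), 0, .painNoiseJitterSd))
    }
    degExp[s, ] <- .smoothExpectedDegree(Ls, design@analysisDensity, noiseS)

    src <- .latentSources(T, ncol(Ls), design@trSeconds)
    wm <- as.numeric(scale(stats::filter(stats::rnorm(T), 0.6, method = "recursive")))
    csf <- as.numeric(scale(stats::filter(stats::rnorm(T), 0.6, method = "recursive")))
    X <- src %*% t(Ls) +
      matrix(stats::rnorm(T * n), T, n) %*% diag(noiseS) +
      outer(wm, stats::rnorm(n, 0, 0.15)) + outer(csf, stats::rnorm(n, 0, 0.15))

    fd <- pmin(abs(stats::rnorm(T, 0.12, 0.06)), 0.45)
    dvars <- pmin(pmax(stats::rnorm(T, 0, 0.7), -2.2), 2.2)
    intens <- pmin(pmax(stats::rnorm(T, 0, 0.7), -2.2), 2.2)
    bad <- stats::runif(T) < design@motionRate
    if (any(bad)) {
      fd[bad] <- stats::runif(sum(bad), 0.6, 1.5)
      dvars[bad] <- stats::runif(sum(bad), 2.5, 5)
      X[bad, ] <- X[bad, ] +
        outer(sample(c(-1, 1), sum(bad), TRUE) * stats::runif(sum(bad), 5, 9),
              rep(1, n))
    }
    mp <- apply(matrix(stats::rnorm(T * 6, 0, 0.02), T, 6), 2L, cumsum)
    gs <- rowMeans(X)
    nuisance[[s]] <- data.frame(fd_mm = fd, dvars_z = dvars, intensity_z = intens,
                                mp1 = mp[, 1], mp2 = mp[, 2], mp3 = mp[, 3],
                                mp4 = mp[, 4], mp5 = mp[, 5], mp6 = mp[, 6],
                                gs = gs, wm = wm, csf = csf)
    colnames(X) <- sprintf("R%03d", seq_len(n))
    signals[[s]] <- X
    censor[[s]] <- rep(TRUE, T)
  }

  ## pain score: sparse linear map of expected degree + noise, scaled to an
  ## NRS-like range (patients approx 6.5 +/- 1.5)
  betaIdx <- as.integer(names(design@betaPain))
  score <- as.numeric(degExp[, betaIdx, drop = FALSE] %*% design@betaPain)
  nrs <- numeric(S)
  if (any(isPat)) {
    sc <- score[isPat]
    scS <- if (stats::sd(sc) > 0) (sc - mean(sc)) / stats::sd(sc) else sc * 0
    nrs[isPat] <- 6.5 + 1.3 * scS + stats::rnorm(sum(isPat), 0, design@noiseSd)
  }
  nrs[!isPat] <- abs(stats::rnorm(sum(!isPat), 0.4, 0.3))
  nrs <- pmin(pmax(nrs, 0), 10)

  cd <- DataFrame(
    subject_id = sprintf("S%03d", seq_len(S)),
    group = groups, age = age, sex = sex, nrs = round(nrs, 2),
    pcs = round(pmin(pmax(19 + 4 * (nrs - 6.5) / 1.5 + stats::rnorm(S, 0, 10), 0), 52), 1),
    dn4 = round(pmin(pmax(stats::rnorm(S, 2.7, 2.2), 0), 10), 0),
    hads_a = round(pmin(pmax(stats::rnorm(S, 8.6, 4.1), 0), 21), 0),
    hads_d = round(pmin(pmax(stats::rnorm(S, 7.9, 3.9), 0), 21), 0),
    koos_pain = round(pmin(pmax(63.6 - 3 * (nrs - 6.5) + stats::rnorm(S, 0, 15), 0), 100), 1),
    koos_symptoms = round(pmin(pmax(stats::rnorm(S, 60.5, 19.3), 0), 100), 1),
    koos_adl = round(pmin(pmax(stats::rnorm(S, 61.4, 15.8), 0), 100), 1),
    koos_sr = round(pmin(pmax(stats::rnorm(S, 91.5, 17.6), 0), 100), 1),
    koos_ql = round(pmin(pmax(stats::rnorm(S, 78.6, 16.4), 0), 100), 1),
    pain_duration = round(pmin(pmax(stats::rnorm(S, 6.8, 5.4), 0.2), 30), 1),
    tug = round(pmin(pmax(stats::rnorm(S, 13.1, 3.9), 5), 40), 1),
    sixmwt = round(pmin(pmax(stats::rnorm(S, 257.8, 75.5), 50), 700), 0)
  )
  rownames(degExp) <- cd$subject_id

  new("RoiTimeSeriesSet",
      signals = signals, nuisance = nuisance, censor = censor,
      trSeconds = design@trSeconds, colData = cd,
      design = list(design = design,
                    expectedDegree = degExp,
                    controlExpectedDegree = degC,
                    loadingsControl = Lc, loadingsPatient = Lp),
      log = "generated")
}

#' Write a cohort to plain-text fixture files
#'
#' Writes one TSV time-series file and one TSV nuisance table per subject, a
#' cohort CSV, the design as JSON, and a JSON manifest listing all paths.
#' Files round-trip bit-exactly through [readCohortFixture()].
#'
#' @param cohort a [RoiTimeSeriesSet-class].
#' @param dir writable output directory (created if missing).
#' @return invisibly, the manifest as a list (also written to
#'   `manifest.json`).
#' @export
writeCohortFixture <- function(cohort, dir) {
  stopifnot(is(cohort, "RoiTimeSeriesSet"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- cohort@colData$subject_id
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  tsFiles <- character(length(ids)); nuFiles <- character(length(ids))
  for (i in seq_along(ids)) {
    tsFiles[i] <- file.path(dir, paste0(ids[i], "_timeseries.tsv"))
    m <- cohort@signals[[i]]
    df <- as.data.frame(apply(m, 2L, fmt))
    utils::write.table(df, tsFiles[i], sep = "\t", quote = FALSE, row.names = FALSE)
    nuFiles[i] <- file.path(dir, paste0(ids[i], "_nuisance.tsv"))
    nu <- cohort@nuisance[[i]]
    nu[] <- lapply(nu, fmt)
    utils::write.table(nu, nuFiles[i], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cohortFile <- file.path(dir, "cohort.csv")
  utils::write.csv(as.data.frame(cohort@colData), cohortFile, row.names = FALSE)
  designFile <- NA_character_
  if (is.list(cohort@design) && is(cohort@design$design, "CohortDesign")) {
    designFile <- file.path(dir, "design.json")
    d <- cohort@design$design
    jsonlite::write_json(list(
      nRegions = d@nRegions, nVolumes = d@nVolumes, trSeconds = d@trSeconds,
      moduleAssignment = d@moduleAssignment, hubSet = d@hubSet,
      kTrue = d@kTrue, switchSet = d@switchSet, switchTarget = d@switchTarget,
      betaPain = as.list(d@betaPain), noiseSd = d@noiseSd,
      motionRate = d@motionRate, groupSizes = as.list(d@groupSizes),
      subjectLoadingSd = d@subjectLoadingSd, ageEffect = d@ageEffect,
      analysisDensity = d@analysisDensity, seed = d@seed
    ), designFile, auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(n_subjects = length(ids), tr_seconds = cohort@trSeconds,
                   timeseries = basename(tsFiles), nuisance = basename(nuFiles),
                   cohort = basename(cohortFile),
                   design = if (is.na(designFile)) NULL else basename(designFile))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a cohort back from fixture files
#'
#' @param dir directory written by [writeCohortFixture()].
#' @return a [RoiTimeSeriesSet-class] (all-pass censor masks; the design slot
#'   holds the design re-read from JSON when present).
#' @export
readCohortFixture <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  cd <- utils::read.csv(file.path(dir, manifest$cohort), stringsAsFactors = FALSE)
  signals <- lapply(file.path(dir, manifest$timeseries), function(f)
    as.matrix(utils::read.table(f, header = TRUE, sep = "\t", check.names = FALSE)))
  nuisance <- lapply(file.path(dir, manifest$nuisance), function(f)
    utils::read.table(f, header = TRUE, sep = "\t"))
  censor <- lapply(signals, function(m) rep(TRUE, nrow(m)))
  design <- NULL
  if (!is.null(manifest$design) && file.exists(file.path(dir, manifest$design))) {
    j <- jsonlite::read_json(file.path(dir, manifest$design), simplifyVector = TRUE)
    design <- list(design = new("CohortDesign",
      nRegions = as.integer(j$nRegions), nVolumes = as.integer(j$nVolumes),
      trSeconds = j$trSeconds, moduleAssignment = as.integer(j$moduleAssignment),
      hubSet = as.integer(j$hubSet), kTrue = j$kTrue,
      switchSet = as.integer(j$switchSet), switchTarget = as.integer(j$switchTarget),
      betaPain = stats::setNames(as.numeric(unlist(j$betaPain)), names(j$betaPain)),
      noiseSd = j$noiseSd, motionRate = j$motionRate,
      groupSizes = stats::setNames(as.integer(unlist(j$groupSizes)), names(j$groupSizes)),
      subjectLoadingSd = j$subjectLoadingSd, ageEffect = j$ageEffect,
      analysisDensity = j$analysisDensity, seed = as.integer(j$seed)))
  }
  new("RoiTimeSeriesSet", signals = signals, nuisance = nuisance, censor = censor,
      trSeconds = manifest$tr_seconds, colData = DataFrame(cd),
      design = design, log = "read")
}
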