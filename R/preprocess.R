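#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Discard initial saturation volumes
#'
#' Drops the first `nDrop` volumes of every subject (signal, nuisance table
#' and censor mask alike), the usual guard against T1 saturation effects at
#' the start of an acquisition (default 4 volumes = 10 s at TR 2.5 s).
#'
#' @param cohort a [RoiTimeSeriesSet-class].
#' @param nDrop number of leading volumes to discard.
#' @return the truncated [RoiTimeSeriesSet-class].
#' @export
dropInitialVolumes <- function(cohort, nDrop = 4L) {
  stopifnot(is(cohort, "RoiTimeSeriesSet"))
  nDrop <- as.integer(nDrop)
  if (nDrop == 0L) return(cohort)
  for (i in seq_len(nSubjects(cohort))) {
    ti <- nrow(cohort@signals[[i]])
    if (ti <= nDrop)
      stop("subject ", i, ": only ", ti, " volumes, cannot drop ", nDrop)
    keep <- (nDrop + 1L):ti
    cohort@signals[[i]] <- cohort@signals[[i]][keep, , drop = FALSE]
    cohort@nuisance[[i]] <- cohort@nuisance[[i]][keep, , drop = FALSE]
    cohort@censor[[i]] <- cohort@censor[[i]][keep]
  }
  cohort@log <- c(cohort@log, sprintf("drop_initial(%d)", nDrop))
  cohort
}

.nuisanceColumns <- c("mp1", "mp2", "mp3", "mp4", "mp5", "mp6", "gs", "wm", "csf")

#' Regress nuisance signals out of every region's time-series
#'
#' Replaces each region's series by the residuals of an ordinary
#' least-squares fit on an intercept, the six rigid-body motion parameters and
#' the global / white-matter / CSF signals. Collinear columns are dropped
#' (with a warning) via the QR pivoting of the design.
#'
#' @param cohort a [RoiTimeSeriesSet-class] whose nuisance tables carry
#'   `mp1..mp6`, `gs`, `wm`, `csf`.
#' @return the residualised [RoiTimeSeriesSet-class].
#' @export
regressNuisance <- function(cohort) {
  stopifnot(is(cohort, "RoiTimeSeriesSet"))
  for (i in seq_len(nSubjects(cohort))) {
    nu <- cohort@nuisance[[i]]
    miss <- setdiff(.nuisanceColumns, colnames(nu))
    if (length(miss))
      stop("subject ", i, ": missing nuisance columns ", paste(miss, collapse = ", "))
    X <- cbind(1, as.matrix(nu[, .nuisanceColumns]))
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
      warning("subject ", i, ": rank-deficient nuisance design, ",
              ncol(X) - qrX$rank, " collinear column(s) dropped")
    cohort@signals[[i]] <- qr.resid(qrX, cohort@signals[[i]])
  }
  cohort@log <- c(cohort@log, "regress_nuisance")
  cohort
}

#' Composite motion censoring with scrubbing
#'
#' Marks as unusable every volume whose frame-wise displacement exceeds
#' `fdThresh` mm, OR whose z-scored DVARS exceeds `dvarsThresh`, OR whose
#' z-scored volume intensity deviation exceeds `intensityThresh`; each flagged
#' volume is scrubbed together with its two preceding and two following
#' volumes (i-2 .. i+2, clipped at the series ends).
#'
#' Censoring is idempotent: the mask depends only on the nuisance table.
#'
#' @param cohort a [RoiTimeSeriesSet-class].
#' @param fdThresh frame-wise displacement threshold in mm.
#' @param dvarsThresh,intensityThresh z-score thresholds.
#' @return the cohort with updated censor masks; per-subject counts are
#'   retrievable with [qcVolumeCount()].
#' @export
censorMotion <- function(cohort, fdThresh = 0.5, dvarsThresh = 2.3,
                         intensityThresh = 2.3) {
  stopifnot(is(cohort, "RoiTimeSeriesSet"))
  for (i in seq_len(nSubjects(cohort))) {
    nu <- cohort@nuisance[[i]]
    ti <- nrow(nu)
    hit <- which(nu$fd_mm > fdThresh | abs(nu$dvars_z) > dvarsThresh |
                 abs(nu$intensity_z) > intensityThresh)
    mask <- rep(TRUE, ti)
    if (length(hit)) {
      scrub <- unique(pmin(pmax(rep(hit, each = 5L) + (-2L:2L), 1L), ti))
      mask[scrub] <- FALSE
    }
    cohort@censor[[i]] <- mask
  }
  cohort@log <- unique(c(cohort@log, "censor_motion"))
  cohort
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a second-order Butterworth band-pass (default 0.008-0.1 Hz),
#' forward-backward for zero phase, to every region's series. Censored
#' volumes are linearly interpolated before filtering (so spike gaps do not
#' leak across the pass band) and the censor mask is re-applied afterwards;
#' set `interpolateCensored = FALSE` to filter the raw series instead.
#'
#' @param cohort a [RoiTimeSeriesSet-class] (TR must be set).
#' @param low,high pass-band edges in Hz; `high` must be below Nyquist.
#' @param order Butterworth order.
#' @param interpolateCensored interpolate over censored volumes first.
#' @return the filtered [RoiTimeSeriesSet-class].
#' @export
bandpassFilter <- function(cohort, low = 0.008, high = 0.1, order = 2L,
                           interpolateCensored = TRUE) {
  stopifnot(is(cohort, "RoiTimeSeriesSet"))
  for (i in seq_len(nSubjects(cohort))) {
    x <- cohort@signals[[i]]
    if (interpolateCensored) x <- .interpolateCensored(x, cohort@censor[[i]])
    cohort@signals[[i]] <- .butterBandpass(x, cohort@trSeconds, low, high, order)
  }
  cohort@log <- c(cohort@log, sprintf("bandpass(%g-%g)", low, high))
  cohort
}

#' Volume-count quality control
#'
#' A subject passes if at least `minVolumes` usable (non-censored) volumes
#' remain; the boundary is inclusive (exactly `minVolumes` passes, since the
#' exclusion rule is "fewer than").
#'
#' @param cohort a [RoiTimeSeriesSet-class] with censor masks computed.
#' @param minVolumes minimum usable volume count.
#' @return data.frame with one row per subject: `subject_id`, `group`,
#'   `volumes`, `censored`, `usable`, `passed_volume_qc`.
#' @export
qcVolumeCount <- function(cohort, minVolumes = 200L) {
  stopifnot(is(cohort, "RoiTimeSeriesSet"))
  usable <- vapply(cohort@censor, sum, 1L)
  total <- vapply(cohort@censor, length, 1L)
  data.frame(subject_id = as.character(cohort@colData$subject_id),
             group = subjectGroups(cohort),
             volumes = total, censored = total - usable, usable = usable,
             passed_volume_qc = usable >= minVolumes)
}

#' Within-group connectivity outlier detection
#'
#' For each group independently, computes for every subject the mean (over the
#' other subjects of the group) of the Pearson correlation between the two
#' subjects' vectorised upper-triangle connectivity, and flags subjects whose
#' mean lies strictly below the group mean minus `nSd` standard deviations.
#'
#' @param connectomes a [ConnectomeSet-class].
#' @param nSd outlier cut in group SD units.
#' @return data.frame: `subject_id`, `group`, `mean_within_group_r`,
#'   `passed_outlier_qc`.
#' @export
qcConnectivityOutlier <- function(connectomes, nSd = 2) {
  stopifnot(is(connectomes, "ConnectomeSet"))
  groups <- subjectGroups(connectomes)
  S <- nSubjects(connectomes)
  vecs <- vapply(seq_len(S), function(i) .vecUpperTri(connectomes@r[, , i]),
                 numeric(nRegions(connectomes) * (nRegions(connectomes) - 1) / 2))
  meanR <- rep(NA_real_, S)
  pass <- rep(TRUE, S)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 3L) {
      warning("group '", g, "' has fewer than 3 subjects; outlier QC skipped")
      next
    }
    cc <- stats::cor(vecs[, idx, drop = FALSE])
    diag(cc) <- NA
    mi <- rowMeans(cc, na.rm = TRUE)
    meanR[idx] <- mi
    cut <- mean(mi) - nSd * stats::sd(mi)
    pass[idx] <- !(mi < cut)
  }
  data.frame(subject_id = as.character(connectomes@colData$subject_id),
             group = groups, mean_within_group_r = meanR,
             passed_outlier_qc = pass)
}

#' Run the standard preprocessing chain
#'
#' Convenience wrapper applying, in order: [dropInitialVolumes()],
#' [regressNuisance()], [censorMotion()], [bandpassFilter()]. The order is
#' recorded in the object's log.
#'
#' @param cohort a [RoiTimeSeriesSet-class] fresh from the generator or from
#'   [readCohortFixture()].
#' @param nDrop leading volumes to discard.
#' @param fdThresh,dvarsThresh,intensityThresh censoring thresholds.
#' @param low,high band-pass edges in Hz.
#' @return the preprocessed [RoiTimeSeriesSet-class].
#' @export
preprocessCohort <- function(cohort, nDrop = 4L, fdThresh = 0.5,
                             dvarsThresh = 2.3, intensityThresh = 2.3,
                             low = 0.008, high = 0.1) {
  cohort <- dropInitialVolumes(cohort, nDrop)
  cohort <- regressNuisance(cohort)
  cohort <- censorMotion(cohort, fdThresh, dvarsThresh, intensityThresh)
  bandpassFilter(cohort, low, high)
}
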