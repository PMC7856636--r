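test_that("initial-volume dropping truncates signal, nuisance and mask together", {
  co <- smallCohort()
  t0 <- nrow(signalMatrix(co, 1))
  d4 <- dropInitialVolumes(co, 4)
  expect_equal(nrow(signalMatrix(d4, 1)), t0 - 4)
  expect_equal(nrow(d4@nuisance[[1]]), t0 - 4)
  expect_length(censorMask(d4, 1), t0 - 4)
  expect_equal(signalMatrix(d4, 1), signalMatrix(co, 1)[-(1:4), ])
  ## 300 volumes -> 296 after the standard drop
  expect_equal(300L - 4L, 296L)
  ## n = 0 is the identity; too-short series error
  expect_identical(dropInitialVolumes(co, 0), co)
  short <- co
  short@signals[[1]] <- short@signals[[1]][1:3, ]
  short@nuisance[[1]] <- short@nuisance[[1]][1:3, ]
  short@censor[[1]] <- short@censor[[1]][1:3]
  expect_error(dropInitialVolumes(short, 4), "cannot drop")
})

test_that("nuisance regression leaves residuals orthogonal to the regressors", {
  co <- regressNuisance(smallCohort())
  nu <- co@nuisance[[1]]
  X <- cbind(1, as.matrix(nu[, c("mp1", "mp2", "mp3", "mp4", "mp5", "mp6",
                                 "gs", "wm", "csf")]))
  resid <- signalMatrix(co, 1)
  expect_lt(max(abs(crossprod(X, resid))), 1e-6)
  ## a region equal to the global signal is annihilated
  co2 <- smallCohort()
  co2@signals[[1]][, 5] <- co2@nuisance[[1]]$gs
  r2 <- regressNuisance(co2)
  expect_lt(max(abs(signalMatrix(r2, 1)[, 5])), 1e-8)
  ## a region built from a motion parameter keeps only its innovation noise
  co3 <- smallCohort()
  T3 <- nrow(co3@signals[[1]])
  set.seed(8)
  noise <- rnorm(T3, 0, 0.5)
  co3@signals[[1]][, 6] <- 2 * co3@nuisance[[1]]$mp1 + noise
  r3 <- regressNuisance(co3)
  expect_equal(var(signalMatrix(r3, 1)[, 6]), var(noise), tolerance = 0.1)
})

test_that("composite censoring ORs the criteria and scrubs +/- 2 volumes", {
  co <- smallCohort()
  ## hand-built nuisance: only volume 2 (1-based) violates FD
  T1 <- nrow(co@signals[[1]])
  nu <- co@nuisance[[1]]
  nu$fd_mm <- rep(0.1, T1); nu$dvars_z <- 0; nu$intensity_z <- 0
  nu$fd_mm[2] <- 0.6
  co@nuisance[[1]] <- nu
  cm <- censorMotion(co)
  expect_equal(which(!censorMask(cm, 1)), 1:4)
  ## all clean -> nothing censored; all dirty -> everything censored
  nu$fd_mm <- rep(0.1, T1); co@nuisance[[1]] <- nu
  expect_equal(sum(!censorMask(censorMotion(co), 1)), 0)
  nu$fd_mm <- rep(1.0, T1); co@nuisance[[1]] <- nu
  expect_equal(sum(censorMask(censorMotion(co), 1)), 0)
  ## DVARS alone triggers too (OR rule), and censoring is idempotent
  nu$fd_mm <- rep(0.1, T1); nu$dvars_z[10] <- 3; co@nuisance[[1]] <- nu
  c1 <- censorMotion(co)
  expect_equal(which(!censorMask(c1, 1)), 8:12)
  expect_identical(censorMask(censorMotion(c1), 1), censorMask(c1, 1))
})

test_that("band-pass keeps the pass band and removes drift and DC", {
  tr <- 2.5
  t <- seq(0, by = tr, length.out = 400)
  probe <- function(f) sin(2 * pi * f * t)
  filt <- function(x) hubshift:::.butterBandpass(matrix(x), tr)[, 1]
  ## 0.05 Hz probe passes (amplitude ratio >= 0.9)
  expect_gte(sd(filt(probe(0.05))) / sd(probe(0.05)), 0.9)
  ## 0.004 Hz drift strongly attenuated
  expect_lt(sd(filt(probe(0.004))) / sd(probe(0.004)), 0.5)
  ## constant series -> zero output
  expect_lt(max(abs(filt(rep(5, 400)))), 1e-6)
  ## upper edge must stay below Nyquist
  expect_error(hubshift:::.butterBandpass(matrix(probe(0.05)), tr, high = 0.2),
               "Nyquist")
})

test_that("volume-count QC uses an inclusive boundary", {
  co <- censorMotion(smallCohort())
  qc <- qcVolumeCount(co, minVolumes = 100)
  expect_equal(qc$usable, qc$volumes - qc$censored)
  mk <- function(usable, minVolumes = 100) {
    x <- smallCohort()
    ti <- nrow(x@signals[[1]])
    x@censor[[1]] <- rep(c(TRUE, FALSE), c(usable, ti - usable))
    qcVolumeCount(x, minVolumes)$passed_volume_qc[1]
  }
  expect_true(mk(120))
  expect_true(mk(100))    # exactly the threshold passes ("fewer than" excludes)
  expect_false(mk(99))    # below the threshold fails
})

test_that("connectivity outlier QC flags a sign-flipped subject within its group", {
  set.seed(17)
  n <- 12
  base <- matrix(rnorm(n * n), n); base <- cor(base)
  mkSlab <- function(sdEps) {
    eps <- matrix(rnorm(n * n, 0, sdEps), n); eps <- (eps + t(eps)) / 2
    out <- pmin(pmax(base + eps, -1), 1); diag(out) <- 1
    out
  }
  r <- array(NA_real_, c(n, n, 21))
  for (i in 1:20) r[, , i] <- mkSlab(0.05)
  r[, , 21] <- -base; diag(r[, , 21]) <- 1
  cd <- S4Vectors::DataFrame(subject_id = sprintf("S%02d", 1:21),
                             group = rep("patient", 21))
  conn <- new("ConnectomeSet", r = r, colData = cd, usableVolumes = rep(100L, 21))
  qc <- qcConnectivityOutlier(conn)
  expect_false(qc$passed_outlier_qc[21])
  expect_true(all(qc$passed_outlier_qc[1:20]))
  ## identical matrices: SD = 0, nobody strictly below the cut
  r0 <- array(rep(base, 5), c(n, n, 5))
  cd0 <- S4Vectors::DataFrame(subject_id = sprintf("C%d", 1:5),
                              group = rep("control", 5))
  conn0 <- new("ConnectomeSet", r = r0, colData = cd0, usableVolumes = rep(100L, 5))
  expect_true(all(qcConnectivityOutlier(conn0)$passed_outlier_qc))
  ## flags are computed within each group independently: adding an unrelated
  ## control group leaves the patient flags untouched
  extra <- array(NA_real_, c(n, n, 6))
  set.seed(99)
  for (i in 1:6) extra[, , i] <- mkSlab(0.05)
  rMix <- array(c(r, extra), c(n, n, 27))
  cdMix <- S4Vectors::DataFrame(subject_id = sprintf("M%02d", 1:27),
                                group = c(rep("patient", 21), rep("control", 6)))
  connMix <- new("ConnectomeSet", r = rMix, colData = cdMix,
                 usableVolumes = rep(100L, 27))
  qcMix <- qcConnectivityOutlier(connMix)
  expect_equal(qcMix$passed_outlier_qc[1:21], qc$passed_outlier_qc)
})

test_that("a motion-free cohort passes both QC steps for every subject", {
  d <- cohortDesign(nRegions = 48, nVolumes = 120, nModules = 4,
                    hubsPerModule = 2, motionRate = 0, nSwitch = 0,
                    groupSizes = c(patient = 6, control = 6, holdout = 0),
                    seed = 99)
  co <- preprocessCohort(generateCohort(d))
  qcv <- qcVolumeCount(co, minVolumes = 100)
  expect_true(all(qcv$censored == 0))
  expect_true(all(qcv$passed_volume_qc))
  expect_true(all(qcConnectivityOutlier(buildConnectomes(co))$passed_outlier_qc))
})
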