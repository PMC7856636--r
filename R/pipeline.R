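#' @include AllClasses.R AllGenerics.R synthetic.R preprocess.R connectome.R
#' @include hubdisruption.R nodal.R multislice.R cohortstats.R
NULL

#' Kennard-Stone split on standardized covariates
#'
#' Max-min Euclidean distance selection: starting from the two most distant
#' points, repeatedly adds the point farthest from the already-selected set
#' until `nSelect` points are chosen. Used to split patients into discovery
#' and hold-out sets with uniform coverage of the covariate space.
#'
#' @param covariates numeric matrix / data.frame (rows = subjects).
#' @param nSelect number of rows to select (the discovery set).
#' @return integer indices of the selected rows.
#' @export
kennardStoneSplit <- function(covariates, nSelect) {
  X <- scale(as.matrix(covariates))
  X[is.nan(X)] <- 0
  n <- nrow(X)
  stopifnot(nSelect >= 2L, nSelect <= n)
  D <- as.matrix(stats::dist(X))
  sel <- as.integer(arrayInd(which.max(D), dim(D)))
  while (length(sel) < nSelect) {
    rest <- setdiff(seq_len(n), sel)
    dmin <- apply(D[rest, sel, drop = FALSE], 1L, min)
    sel <- c(sel, rest[which.max(dmin)])
  }
  sort(sel)
}

.writeCsv <- function(x, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(x, path, row.names = FALSE)
  path
}

#' Run the full discovery -> hold-out analysis pipeline
#'
#' Executes the stages in order — preprocess, volume/outlier QC, correlation
#' matrices, density thresholding, nodal/global metrics, hub disruption
#' indices with group contrast and clinical correlations, nodal permutation
#' statistics, covariate-adjusted elastic-net pain prediction with hold-out
#' validation, and (optionally) multislice modular reorganization — writing
#' one CSV per result surface plus a JSON manifest with parameters, seeds and
#' file hashes. Two runs from the same config produce identical outputs.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{design}{a [CohortDesign-class] (or `cohort`, a ready
#'       [RoiTimeSeriesSet-class]).}
#'     \item{outDir}{output directory.}
#'     \item{seed}{master seed; every stochastic stage derives its stream
#'       from it.}
#'     \item{densities}{density ladder (default 2-10% by 1%).}
#'     \item{analysisDensity}{density for K contrasts and nodal work (0.05).}
#'     \item{minVolumes}{usable-volume QC threshold (default 200).}
#'     \item{modreorg}{NULL to skip, or list(nPerm, nReps, density).}
#'     \item{clinicalCols}{clinical columns for the K correlation screen.}
#'   }
#' @return the manifest (list), invisibly; all outputs under `outDir`.
#' @export
runPipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$outDir))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  outDir <- config$outDir
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  densities <- if (is.null(config$densities)) seq(0.02, 0.10, 0.01) else config$densities
  ad <- if (is.null(config$analysisDensity)) 0.05 else config$analysisDensity

  cohort <- if (!is.null(config$cohort)) config$cohort
            else generateCohort(config$design, seed = .deriveSeed(seed, "cohort"))
  cohort <- preprocessCohort(cohort)

  minVol <- if (is.null(config$minVolumes)) 200L else as.integer(config$minVolumes)
  qcVol <- qcVolumeCount(cohort, minVolumes = minVol)
  conn <- buildConnectomes(cohort)
  qcOut <- qcConnectivityOutlier(conn)
  qc <- merge(qcVol, qcOut, by = c("subject_id", "group"))
  keep <- which(qc$passed_volume_qc & qc$passed_outlier_qc)
  if (!length(keep))
    stop("QC excluded every subject (volume threshold ", minVol, ")")
  files <- list(qc = .writeCsv(qc, outDir, "qc_report.csv"))
  if (length(keep) < nSubjects(conn)) {
    conn <- new("ConnectomeSet", r = conn@r[, , keep, drop = FALSE],
                colData = conn@colData[keep, , drop = FALSE],
                usableVolumes = conn@usableVolumes[keep])
  }
  cohortTab <- as.data.frame(conn@colData)
  cohortTab$group[cohortTab$group == "holdout-patient"] <- "holdout-patient"
  files$cohort <- .writeCsv(cohortTab, outDir, "cohort.csv")

  stack <- thresholdGraphs(conn, densities)
  ## degree at every density; full metric set at the analysis density
  degTab <- graphMetricTable(stack, metrics = "degree")
  adStack <- new("BinaryGraphStack",
                 adjacency = stack@adjacency[which(abs(densities - ad) < 1e-9)],
                 densities = ad, colData = stack@colData)
  fullTab <- graphMetricTable(adStack)
  files$metrics <- .writeCsv(fullTab, outDir, "metrics_analysis_density.csv")
  files$degree <- .writeCsv(degTab, outDir, "degree_all_densities.csv")

  ## hub disruption: degree K across densities + all metrics at ad
  ktDeg <- kIndexTable(degTab, metrics = "degree")
  ktFull <- kIndexTable(fullTab)
  files$kindex <- .writeCsv(ktFull, outDir, "k_indices.csv")
  files$kindex_degree <- .writeCsv(ktDeg, outDir, "k_degree_all_densities.csv")
  contrast <- groupKContrast(ktFull, cohortTab, density = ad)
  files$k_contrast <- .writeCsv(contrast, outDir, "k_group_contrast.csv")
  clinCols <- config$clinicalCols
  if (is.null(clinCols))
    clinCols <- intersect(c("nrs", "pcs", "dn4", "hads_a", "hads_d", "koos_pain",
                            "koos_symptoms", "koos_adl", "koos_sr", "koos_ql",
                            "pain_duration", "tug"), colnames(cohortTab))
  kc <- kClinicalCorrelations(ktFull, cohortTab, clinCols, density = ad)
  files$k_clinical <- .writeCsv(kc, outDir, "k_clinical_correlations.csv")

  ## nodal statistics at the analysis density
  nodal <- nodalDifferencePermutation(
    degTab, density = ad,
    nPerm = if (is.null(config$nPermNodal)) 10000L else config$nPermNodal,
    seed = .deriveSeed(seed, "nodal"))
  files$nodal <- .writeCsv(nodal, outDir, "nodal_differences.csv")

  ## elastic net: discovery patients -> hold-out patients
  wide <- .degreeWide(degTab, ad)
  groups <- attr(wide, "groups")
  degMat <- t(wide)          # subjects x nodes
  colnames(degMat) <- sprintf("node%03d", seq_len(ncol(degMat)))
  disc <- groups == "patient"
  hold <- groups == "holdout-patient"
  enet <- NULL
  if (sum(disc) >= 10L) {
    covDisc <- cohortTab[match(rownames(degMat)[disc], cohortTab$subject_id), ]
    adjDisc <- adjustAgeSex(degMat[disc, , drop = FALSE], covDisc)
    enet <- elasticNetFit(adjDisc, covDisc$nrs,
                          seed = .deriveSeed(seed, "enet"))
    coefTab <- data.frame(node = seq_len(ncol(degMat)),
                          coefficient = as.numeric(enet$coef))
    files$enet_coef <- .writeCsv(coefTab, outDir, "elasticnet_coefficients.csv")
    predDisc <- data.frame(subject_id = rownames(degMat)[disc],
                           actual = covDisc$nrs,
                           predicted = predict(enet, adjDisc))
    valid <- NULL
    if (sum(hold) >= 4L) {
      covHold <- cohortTab[match(rownames(degMat)[hold], cohortTab$subject_id), ]
      adjHold <- adjustAgeSex(degMat[hold, , drop = FALSE], covHold,
                              transform = attr(adjDisc, "transform"))
      valid <- elasticNetValidate(enet, adjHold, covHold$nrs)
      predHold <- data.frame(subject_id = rownames(degMat)[hold],
                             actual = covHold$nrs, predicted = valid$predicted)
      files$enet_pred <- .writeCsv(rbind(cbind(set = "discovery", predDisc),
                                         cbind(set = "holdout", predHold)),
                                   outDir, "elasticnet_predictions.csv")
    } else {
      files$enet_pred <- .writeCsv(cbind(set = "discovery", predDisc),
                                   outDir, "elasticnet_predictions.csv")
    }
    enetSummary <- data.frame(
      lambda = enet$lambdaMin, alpha = enet$alpha, n_nonzero = enet$nNonzero,
      training_r = enet$trainingR,
      holdout_r = if (is.null(valid)) NA_real_ else valid$r,
      holdout_p = if (is.null(valid)) NA_real_ else valid$p)
    files$enet_summary <- .writeCsv(enetSummary, outDir, "elasticnet_summary.csv")
  }

  ## modular reorganization at 10% density (optional: the expensive stage)
  if (!is.null(config$modreorg)) {
    mr <- config$modreorg
    md <- if (is.null(mr$density)) 0.10 else mr$density
    mdStack <- thresholdGraphs(conn, md)
    a <- mdStack@adjacency[[1L]]
    gAll <- subjectGroups(mdStack)
    reorg <- reorgPermutationNull(
      a[, , gAll == "patient", drop = FALSE],
      a[, , gAll == "control", drop = FALSE],
      nPerm = if (is.null(mr$nPerm)) 1000L else mr$nPerm,
      nReps = if (is.null(mr$nReps)) 10L else mr$nReps,
      gamma = if (is.null(mr$gamma)) 1.5 else mr$gamma,
      omega = if (is.null(mr$omega)) 0.1 else mr$omega,
      seed = .deriveSeed(seed, "modreorg"))
    files$reorg <- .writeCsv(reorg$observed, outDir, "modular_reorganization.csv")
    utils::write.table(round(reorg$diff, 6), file.path(outDir, "agreement_diff.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    files$agreement_diff <- file.path(outDir, "agreement_diff.tsv")
  }

  manifest <- list(
    created = "run", seed = seed, densities = densities,
    analysis_density = ad,
    n_subjects = nrow(cohortTab),
    groups = as.list(table(cohortTab$group)),
    files = lapply(files, basename),
    hashes = as.list(tools::md5sum(unlist(files)))
  )
  names(manifest$hashes) <- basename(names(manifest$hashes))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Human-readable report of a pipeline run
#'
#' Assembles the main result surfaces of a completed run — the hub
#' disruption contrast table, the top-disrupted-node table, the elastic-net
#' coefficients and predicted-vs-actual correlation, and the modular
#' reorganization table — from the CSVs referenced by a run manifest.
#' Regeneration from the same manifest is idempotent.
#'
#' @param outDir directory containing `manifest.json` and the stage outputs.
#' @param file optional path to write the report text.
#' @return character vector of report lines, invisibly.
#' @export
pipelineReport <- function(outDir, file = NULL) {
  manifest <- jsonlite::read_json(file.path(outDir, "manifest.json"),
                                  simplifyVector = TRUE)
  lines <- c("Connectome reorganization analysis report",
             sprintf("subjects: %d; densities: %s; analysis density: %s",
                     manifest$n_subjects,
                     paste(manifest$densities, collapse = ", "),
                     manifest$analysis_density), "")
  rd <- function(nm) {
    f <- file.path(outDir, manifest$files[[nm]])
    if (!is.null(manifest$files[[nm]]) && file.exists(f)) utils::read.csv(f) else NULL
  }
  kc <- rd("k_contrast")
  if (!is.null(kc)) {
    lines <- c(lines, "Hub disruption group contrast (ANCOVA, age + sex adjusted):",
               utils::capture.output(print(kc, row.names = FALSE)), "")
  } else lines <- c(lines, "Hub disruption contrast: not run", "")
  nd <- rd("nodal")
  if (!is.null(nd)) {
    top <- nd[nd$flagged, , drop = FALSE]
    lines <- c(lines, sprintf("Top disrupted nodes (|delta| > 2 SD): %d flagged", nrow(top)),
               utils::capture.output(print(top, row.names = FALSE)), "")
  }
  es <- rd("enet_summary")
  if (!is.null(es)) {
    lines <- c(lines, "Elastic-net degree -> pain model:",
               utils::capture.output(print(es, row.names = FALSE)), "")
  }
  mr <- rd("reorg")
  if (!is.null(mr)) {
    sig <- mr[mr$significant, , drop = FALSE]
    lines <- c(lines, sprintf("Modular reorganization: %d node(s) significant at p < .01", nrow(sig)),
               utils::capture.output(print(sig, row.names = FALSE)), "")
  }
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
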