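#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Hub disruption index of one subject against a normative profile
#'
#' Ordinary least-squares fit of y = K x + b, where x is the normative
#' (control-group mean) nodal metric and y is the subject's nodal metric
#' minus x. A negative K means nodes that are hubs in the normative profile
#' lose the metric while peripheral nodes gain it.
#'
#' @param subjectMetric numeric vector of nodal values for the subject.
#' @param controlMean numeric vector of normative nodal values (same length,
#'   nonzero variance).
#' @return list with `K` (slope), `b` (intercept) and `r2`.
#' @examples
#' kIndex(c(20, 20, 20), c(10, 20, 30)) # K = -1, b = 20
#' @export
kIndex <- function(subjectMetric, controlMean) {
  if (length(subjectMetric) != length(controlMean))
    stop("subject and normative vectors differ in length")
  if (stats::var(controlMean) == 0)
    stop("normative vector has zero variance")
  y <- subjectMetric - controlMean
  x <- controlMean
  K <- stats::cov(x, y) / stats::var(x)
  b <- mean(y) - K * mean(x)
  fitted <- K * x + b
  ssr <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else NA_real_
  list(K = K, b = b, r2 = r2)
}

#' Hub disruption indices for a whole cohort
#'
#' Computes subject-level K per density and per metric, referencing every
#' subject (patients, hold-out patients and, by default, the controls
#' themselves) to the control-group mean nodal profile. With
#' `looControls = TRUE` each control is referenced to the mean of the other
#' controls (leave-one-out), removing the slight negative bias of control K
#' toward 0.
#'
#' Also returns the group-level K (`attr(., "groupK")`): the fit of the
#' patient group-mean difference profile on the control mean, per density and
#' metric, for both the pooled profile and the mean of subject-level slopes.
#'
#' @param metricTable long table from [graphMetricTable()].
#' @param metrics metric columns to use.
#' @param controlGroup label of the normative group.
#' @param looControls leave-one-out normative mean for controls.
#' @return data.frame: `subject_id`, `group`, `density`, `metric`, `K`,
#'   `intercept`, `r2`, with the group-level table attached as attribute
#'   `groupK`.
#' @export
kIndexTable <- function(metricTable,
                        metrics = intersect(c("degree", "clustering",
                                              "efficiency", "betweenness"),
                                            colnames(metricTable)),
                        controlGroup = "control", looControls = FALSE) {
  stopifnot(all(c("subject_id", "group", "density", "node") %in% colnames(metricTable)))
  out <- list(); gout <- list()
  for (d in sort(unique(metricTable$density))) {
    sub <- metricTable[metricTable$density == d, , drop = FALSE]
    ids <- unique(sub$subject_id)
    groups <- sub$group[match(ids, sub$subject_id)]
    ctrlIds <- ids[groups == controlGroup]
    if (!length(ctrlIds)) stop("no subjects in control group '", controlGroup, "'")
    for (m in metrics) {
      ## nodes x subjects matrix of the metric
      wide <- matrix(NA_real_, max(sub$node), length(ids),
                     dimnames = list(NULL, ids))
      wide[cbind(sub$node, match(sub$subject_id, ids))] <- sub[[m]]
      ctrlMean <- rowMeans(wide[, ctrlIds, drop = FALSE])
      for (i in seq_along(ids)) {
        ref <- ctrlMean
        if (looControls && groups[i] == controlGroup && length(ctrlIds) > 1L)
          ref <- rowMeans(wide[, setdiff(ctrlIds, ids[i]), drop = FALSE])
        f <- kIndex(wide[, i], ref)
        out[[length(out) + 1L]] <- data.frame(
          subject_id = ids[i], group = groups[i], density = d, metric = m,
          K = f$K, intercept = f$b, r2 = f$r2)
      }
      for (g in setdiff(unique(groups), controlGroup)) {
        gm <- rowMeans(wide[, ids[groups == g], drop = FALSE])
        fp <- kIndex(gm, ctrlMean)
        ksub <- vapply(which(groups == g),
                       function(i) kIndex(wide[, i], ctrlMean)$K, numeric(1))
        gout[[length(gout) + 1L]] <- data.frame(
          group = g, density = d, metric = m,
          K_pooled = fp$K, intercept_pooled = fp$b, r2_pooled = fp$r2,
          K_mean_of_subjects = mean(ksub))
      }
    }
  }
  res <- do.call(rbind, out)
  attr(res, "groupK") <- do.call(rbind, gout)
  res
}

#' Covariate-adjusted group contrast of hub disruption indices
#'
#' At a single density: ANCOVA `K ~ group + age + sex` per metric, reporting
#' the group effect, its F statistic and p-value. Across all densities
#' (`density = NULL`): one observation per subject x density with the group
#' effect tested by OLS on the long table with cluster-robust (by subject)
#' standard errors, a pragmatic equivalent of a repeated-measures ANCOVA.
#'
#' @param ktable output of [kIndexTable()].
#' @param cohort data.frame or DataFrame with `subject_id`, `age`, `sex`.
#' @param density single density, or NULL for the repeated-measures pooling.
#' @param groups the two group labels to contrast (reference first).
#' @return data.frame per metric: `estimate` (non-reference minus reference,
#'   adjusted), `statistic`, `df`, `p`.
#' @export
groupKContrast <- function(ktable, cohort, density = 0.05,
                           groups = c("control", "patient")) {
  cohort <- as.data.frame(cohort)
  miss <- setdiff(c("subject_id", "age", "sex"), colnames(cohort))
  if (length(miss)) stop("cohort table lacks ", paste(miss, collapse = ", "))
  dat <- ktable[ktable$group %in% groups, , drop = FALSE]
  dat <- merge(dat, cohort[, c("subject_id", "age", "sex")], by = "subject_id")
  if (anyNA(dat$age) || anyNA(dat$sex)) {
    bad <- unique(dat$subject_id[is.na(dat$age) | is.na(dat$sex)])
    stop("missing covariates for: ", paste(bad, collapse = ", "))
  }
  dat$group <- factor(dat$group, levels = groups)
  res <- list()
  for (m in unique(dat$metric)) {
    if (!is.null(density)) {
      dm <- dat[dat$metric == m & abs(dat$density - density) < 1e-9, , drop = FALSE]
      fit <- stats::lm(K ~ group + age + sex, data = dm)
      a <- stats::anova(fit)
      est <- stats::coef(fit)[[paste0("group", groups[2])]]
      res[[m]] <- data.frame(metric = m, density = density, estimate = est,
                             statistic = a["group", "F value"],
                             df = a["group", "Df"],
                             p = a["group", "Pr(>F)"])
    } else {
      dm <- dat[dat$metric == m, , drop = FALSE]
      fit <- stats::lm(K ~ group + age + sex + factor(density), data = dm)
      ct <- lmtest::coeftest(fit, vcov = sandwich::vcovCL(fit, cluster = dm$subject_id))
      rn <- paste0("group", groups[2])
      res[[m]] <- data.frame(metric = m, density = NA_real_,
                             estimate = ct[rn, "Estimate"],
                             statistic = ct[rn, "t value"], df = NA_real_,
                             p = ct[rn, "Pr(>|t|)"])
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Partial correlations of K indices with clinical scores, FDR-corrected
#'
#' For patients only: Pearson partial correlation (both variables residualised
#' on age + sex) between each hub disruption index and each clinical column,
#' two-sided p, and Benjamini-Hochberg q across the full metric x clinical
#' grid.
#'
#' @param ktable output of [kIndexTable()] (one density).
#' @param cohort data.frame with `subject_id`, `age`, `sex` and the clinical
#'   columns.
#' @param clinicalCols character vector of clinical column names.
#' @param density density at which to take K.
#' @param patientGroups group labels treated as patients.
#' @param alpha FDR level for the pass flag.
#' @return data.frame: `metric`, `clinical`, `n`, `r`, `p`, `q`, `pass_fdr`.
#' @export
kClinicalCorrelations <- function(ktable, cohort, clinicalCols,
                                  density = 0.05,
                                  patientGroups = "patient", alpha = 0.05) {
  cohort <- as.data.frame(cohort)
  kt <- ktable[ktable$group %in% patientGroups &
               abs(ktable$density - density) < 1e-9, , drop = FALSE]
  res <- list()
  for (m in unique(kt$metric)) {
    km <- kt[kt$metric == m, c("subject_id", "K")]
    dd <- merge(km, cohort, by = "subject_id")
    rk <- stats::resid(stats::lm(K ~ age + sex, data = dd))
    for (cl in clinicalCols) {
      y <- dd[[cl]]
      if (is.null(y)) stop("clinical column '", cl, "' not in cohort table")
      if (stats::sd(y, na.rm = TRUE) == 0 || all(is.na(y))) {
        warning("clinical column '", cl, "' is constant; NA row emitted")
        res[[length(res) + 1L]] <- data.frame(metric = m, clinical = cl,
                                              n = nrow(dd), r = NA, p = NA)
        next
      }
      ry <- stats::resid(stats::lm(stats::reformulate(c("age", "sex"), cl), data = dd))
      ct <- stats::cor.test(rk, ry)
      res[[length(res) + 1L]] <- data.frame(metric = m, clinical = cl,
                                            n = nrow(dd),
                                            r = unname(ct$estimate), p = ct$p.value)
    }
  }
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$pass_fdr <- !is.na(out$q) & out$q < alpha
  out
}

#' Node-subsampling robustness of the hub disruption index
#'
#' Recomputes every subject's K on random subsets of `fractionKeep` of the
#' nodes (default 20%, i.e. removing 80%), `nDraws` times, and reports the
#' across-subject Pearson correlation between the full-node K and the mean
#' subsampled K per metric. High correlations indicate the disruption
#' permeates the network rather than reflecting a few regions.
#'
#' @param metricTable long table from [graphMetricTable()] at one density.
#' @param density density to analyse.
#' @param metrics metric columns.
#' @param fractionKeep fraction of nodes retained per draw.
#' @param nDraws number of draws.
#' @param seed RNG seed.
#' @param controlGroup normative group label.
#' @return list with `subjects` (data.frame subject x metric: `K`,
#'   `K_sub_mean`) and `correlation` (data.frame metric, r, p).
#' @export
kRobustness <- function(metricTable, density = 0.05,
                        metrics = intersect(c("degree", "clustering",
                                              "efficiency", "betweenness"),
                                            colnames(metricTable)),
                        fractionKeep = 0.2, nDraws = 100L, seed = 1L,
                        controlGroup = "control") {
  sub <- metricTable[abs(metricTable$density - density) < 1e-9, , drop = FALSE]
  ids <- unique(sub$subject_id)
  groups <- sub$group[match(ids, sub$subject_id)]
  n <- max(sub$node)
  keepN <- floor(fractionKeep * n)
  if (keepN < 3L) stop("fractionKeep * N < 3: too few nodes for a slope")
  set.seed(seed)
  draws <- replicate(nDraws, sample.int(n, keepN), simplify = FALSE)
  subjRes <- list(); corRes <- list()
  for (m in metrics) {
    wide <- matrix(NA_real_, n, length(ids), dimnames = list(NULL, ids))
    wide[cbind(sub$node, match(sub$subject_id, ids))] <- sub[[m]]
    ctrlMean <- rowMeans(wide[, groups == controlGroup, drop = FALSE])
    Kfull <- vapply(seq_along(ids), function(i) kIndex(wide[, i], ctrlMean)$K, numeric(1))
    Ksub <- rowMeans(vapply(draws, function(nodes) {
      vapply(seq_along(ids), function(i)
        kIndex(wide[nodes, i], ctrlMean[nodes])$K, numeric(1))
    }, numeric(length(ids))))
    ct <- stats::cor.test(Kfull, Ksub)
    subjRes[[m]] <- data.frame(subject_id = ids, group = groups, metric = m,
                               K = Kfull, K_sub_mean = Ksub)
    corRes[[m]] <- data.frame(metric = m, r = unname(ct$estimate), p = ct$p.value)
  }
  list(subjects = do.call(rbind, subjRes),
       correlation = do.call(rbind, corRes))
}
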