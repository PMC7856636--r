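#' @include AllClasses.R AllGenerics.R utils.R
NULL

## nodes x subjects degree matrix from the long metric table
.degreeWide <- function(metricTable, density) {
  sub <- metricTable[abs(metricTable$density - density) < 1e-9, , drop = FALSE]
  if (!nrow(sub)) stop("no rows at density ", density)
  ids <- unique(sub$subject_id)
  wide <- matrix(NA_real_, max(sub$node), length(ids), dimnames = list(NULL, ids))
  wide[cbind(sub$node, match(sub$subject_id, ids))] <- sub$degree
  attr(wide, "groups") <- sub$group[match(ids, sub$subject_id)]
  wide
}

#' Top disrupted nodes by mean degree difference, with a permutation null
#'
#' Computes the per-node mean degree difference Delta_i = mean(patient) -
#' mean(control), flags nodes whose Delta lies more than `nSd` SDs from the
#' mean Delta (SD taken across the nodes, untrimmed), and attaches a
#' two-sided permutation p-value per node obtained by randomly reassigning
#' subjects to the two groups (group sizes preserved):
#' p = (1 + #\{|Delta_perm| >= |Delta_obs|\}) / (1 + nPerm).
#'
#' @param metricTable long table from [graphMetricTable()] including `degree`.
#' @param density analysis density (default 5%).
#' @param groups the two group labels (reference second: difference is
#'   `groups[1]` minus `groups[2]`).
#' @param nSd flagging threshold in SD units of the Delta distribution.
#' @param nPerm number of permutations.
#' @param seed RNG seed.
#' @return data.frame per node: `node`, `delta`, `flagged`, `perm_p`.
#' @export
nodalDifferencePermutation <- function(metricTable, density = 0.05,
                                       groups = c("patient", "control"),
                                       nSd = 2, nPerm = 10000L, seed = 1L) {
  if (nPerm < 100L) warning("nPerm < 100: permutation p-values are coarse")
  wide <- .degreeWide(metricTable, density)
  gr <- attr(wide, "groups")
  keep <- gr %in% groups
  wide <- wide[, keep, drop = FALSE]
  gr <- gr[keep]
  n1 <- sum(gr == groups[1]); n2 <- sum(gr == groups[2])
  if (min(n1, n2) < 5L) stop("groups must have at least 5 subjects")
  delta <- rowMeans(wide[, gr == groups[1], drop = FALSE]) -
           rowMeans(wide[, gr == groups[2], drop = FALSE])
  flagged <- abs(delta - mean(delta)) > nSd * stats::sd(delta)
  set.seed(seed)
  S <- ncol(wide)
  exceed <- integer(nrow(wide))
  absObs <- abs(delta)
  for (p in seq_len(nPerm)) {
    idx <- sample.int(S, n1)
    dperm <- rowMeans(wide[, idx, drop = FALSE]) -
             rowMeans(wide[, -idx, drop = FALSE])
    exceed <- exceed + (abs(dperm) >= absObs)
  }
  data.frame(node = seq_len(nrow(wide)), delta = delta, flagged = flagged,
             perm_p = (1 + exceed) / (1 + nPerm))
}

#' Stepwise forward/backward linear model of a clinical variable on nodes
#'
#' Iterates forward selection (partial-F p-to-enter < `alphaEnter`) and
#' backward elimination (partial-F p-to-remove > `alphaRemove`) until stable.
#' Among equally significant candidates the first by column order enters
#' (deterministic; exactly one of a collinear pair can ever enter).
#'
#' @param nodeDegrees n x k matrix of degree values for the selected nodes
#'   (columns named).
#' @param clinical numeric response vector of length n.
#' @param alphaEnter,alphaRemove partial-F thresholds.
#' @return list: `terms` (retained column names, possibly empty), `fit` (lm or
#'   NULL), `F`, `df`, `adjR2`, `p`, `stdBeta` (standardised coefficients).
#' @export
stepwiseModel <- function(nodeDegrees, clinical,
                          alphaEnter = 0.05, alphaRemove = 0.10) {
  nodeDegrees <- as.matrix(nodeDegrees)
  if (is.null(colnames(nodeDegrees)))
    colnames(nodeDegrees) <- paste0("node", seq_len(ncol(nodeDegrees)))
  stopifnot(length(clinical) == nrow(nodeDegrees))
  dat <- data.frame(.y = clinical, nodeDegrees, check.names = FALSE)
  candidates <- colnames(nodeDegrees)
  terms <- character()
  repeat {
    changed <- FALSE
    ## forward step
    pool <- setdiff(candidates, terms)
    if (length(pool)) {
      base <- if (length(terms))
        stats::lm(stats::reformulate(sprintf("`%s`", terms), ".y"), data = dat)
      else stats::lm(.y ~ 1, data = dat)
      ps <- vapply(pool, function(v) {
        fit <- stats::update(base, stats::as.formula(sprintf(". ~ . + `%s`", v)))
        if (length(stats::coef(fit)) != length(stats::coef(base)) + 1L ||
            anyNA(stats::coef(fit))) return(NA_real_)
        stats::anova(base, fit)[2, "Pr(>F)"]
      }, numeric(1))
      if (any(!is.na(ps) & ps < alphaEnter)) {
        terms <- c(terms, pool[which.min(replace(ps, is.na(ps), Inf))])
        changed <- TRUE
      }
    }
    ## backward step
    if (length(terms) > 0L) {
      fit <- stats::lm(stats::reformulate(sprintf("`%s`", terms), ".y"), data = dat)
      dr <- stats::drop1(fit, test = "F")
      pr <- dr[-1, "Pr(>F)"]
      names(pr) <- rownames(dr)[-1]
      if (any(pr > alphaRemove)) {
        worst <- names(pr)[which.max(pr)]
        terms <- setdiff(terms, gsub("`", "", worst))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (!length(terms))
    return(list(terms = character(), fit = NULL, F = NA_real_, df = c(NA, NA),
                adjR2 = NA_real_, p = NA_real_, stdBeta = numeric()))
  fit <- stats::lm(stats::reformulate(sprintf("`%s`", terms), ".y"), data = dat)
  sm <- summary(fit)
  beta <- stats::coef(fit)[-1]
  stdBeta <- beta * apply(nodeDegrees[, terms, drop = FALSE], 2, stats::sd) /
    stats::sd(clinical)
  list(terms = terms, fit = fit,
       F = unname(sm$fstatistic[1]), df = unname(sm$fstatistic[2:3]),
       adjR2 = sm$adj.r.squared,
       p = unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                            lower.tail = FALSE)),
       stdBeta = stats::setNames(as.numeric(stdBeta), terms))
}

#' Adjust nodal degree for age and sex
#'
#' Per node, fits degree ~ age + sex on the fitting sample and replaces each
#' observation by the fitted value at the sample-mean covariates plus the
#' residual — removing covariate-driven variance while preserving scale. The
#' learned transform (coefficients and covariate means) is frozen in the
#' result and must be re-applied to hold-out samples via `transform =`.
#'
#' @param degreeMatrix subjects x nodes numeric matrix.
#' @param cohort data.frame with `age` and `sex` aligned to the rows.
#' @param transform a frozen transform from a previous call (for hold-out
#'   data), or NULL to learn one.
#' @return the adjusted matrix, with the frozen transform in
#'   `attr(., "transform")`.
#' @export
adjustAgeSex <- function(degreeMatrix, cohort, transform = NULL) {
  degreeMatrix <- as.matrix(degreeMatrix)
  cohort <- as.data.frame(cohort)
  stopifnot(nrow(cohort) == nrow(degreeMatrix))
  sexNum <- as.numeric(factor(cohort$sex, levels = sort(unique(as.character(cohort$sex)))))
  if (is.null(transform)) {
    X <- cbind(age = cohort$age, sex = sexNum)
    Xc <- cbind(1, X)
    qrX <- qr(Xc)
    coefs <- qr.coef(qrX, degreeMatrix)       # 3 x nodes (may contain NA if collinear)
    coefs[is.na(coefs)] <- 0
    transform <- list(coef = coefs, means = colMeans(X))
  }
  adj <- degreeMatrix -
    outer(cohort$age - transform$means["age"], transform$coef["age", ]) -
    outer(sexNum - transform$means["sex"], transform$coef["sex", ])
  attr(adj, "transform") <- transform
  adj
}

#' Elastic-net prediction of pain intensity from whole-brain nodal degree
#'
#' Fits an elastic net (mixing penalty alpha, default 0.5) of the outcome on
#' all nodal degrees over a log-spaced lambda grid of `nLambda` values running
#' four decades down from lambda_max (the smallest lambda with an all-zero
#' coefficient vector). The lambda minimising the `nFolds`-fold
#' cross-validated mean squared error is selected and the model refit on the
#' full sample. Predictors are standardised internally; coefficients are
#' reported on the original scale.
#'
#' @param degrees n x p matrix of (covariate-adjusted) nodal degrees.
#' @param outcome numeric response of length n (e.g. NRS pain).
#' @param alpha elastic-net mixing parameter in (0, 1].
#' @param nFolds CV folds.
#' @param nLambda grid size.
#' @param seed RNG seed for the fold assignment.
#' @return object of class `elasticNetModel`: list with `alpha`, `lambda`
#'   (grid), `lambdaMin`, `cvMse`, `coef` (named, original scale, sparse in
#'   content), `intercept`, `trainingR`, plus the frozen standardisation.
#' @export
elasticNetFit <- function(degrees, outcome, alpha = 0.5, nFolds = 10L,
                          nLambda = 100L, seed = 1L) {
  X <- as.matrix(degrees)
  y <- as.numeric(outcome)
  stopifnot(nrow(X) == length(y))
  if (stats::sd(y) == 0) stop("outcome is constant")
  if (nrow(X) < nFolds) stop("need at least nFolds observations")
  if (is.null(colnames(X))) colnames(X) <- paste0("node", seq_len(ncol(X)))
  n <- nrow(X)
  ## internal standardisation (1/n variance, glmnet's convention); the
  ## outcome is scaled to unit variance as well so the stated penalty
  ## lambda (alpha ||b||_1 + (1 - alpha)/2 ||b||_2^2) holds exactly for the
  ## problem glmnet solves (its gaussian path works on the y-standardised
  ## scale)
  xm <- colMeans(X)
  xs <- sqrt(colMeans(sweep(X, 2, xm)^2))
  xs[xs == 0] <- 1
  Xs <- sweep(sweep(X, 2, xm), 2, xs, "/")
  sy <- sqrt(mean((y - mean(y))^2))
  ys <- y / sy
  ## lambda_max: smallest lambda zeroing all coefficients
  lambdaMax <- max(abs(crossprod(Xs, ys - mean(ys)))) / (n * alpha)
  lambda <- exp(seq(log(lambdaMax), log(lambdaMax * 1e-4), length.out = nLambda))
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(nFolds), n))
  cv <- glmnet::cv.glmnet(Xs, ys, alpha = alpha, lambda = lambda,
                          foldid = foldid, standardize = FALSE,
                          thresh = 1e-12, type.measure = "mse")
  lambdaMin <- cv$lambda.min
  fit <- glmnet::glmnet(Xs, ys, alpha = alpha, lambda = lambda,
                        standardize = FALSE, thresh = 1e-12)
  betaS <- as.numeric(stats::coef(fit, s = lambdaMin, exact = TRUE,
                                  x = Xs, y = ys))[-1]
  interceptS <- as.numeric(stats::coef(fit, s = lambdaMin, exact = TRUE,
                                       x = Xs, y = ys))[1]
  beta <- betaS * sy / xs
  intercept <- interceptS * sy - sum(beta * xm)
  pred <- as.numeric(X %*% beta + intercept)
  out <- list(alpha = alpha, lambda = lambda, lambdaMin = lambdaMin,
              cvMse = stats::setNames(cv$cvm * sy^2, format(cv$lambda)),
              coef = stats::setNames(beta, colnames(X)), intercept = intercept,
              nNonzero = sum(beta != 0),
              trainingR = stats::cor(pred, y),
              standardization = list(mean = xm, sd = xs, ySd = sy),
              betaStd = betaS, interceptStd = interceptS)
  class(out) <- "elasticNetModel"
  out
}

#' @export
print.elasticNetModel <- function(x, ...) {
  cat("Elastic-net model (alpha =", x$alpha, ")\n")
  cat("  lambda grid:", length(x$lambda), "values; chosen lambda =",
      signif(x$lambdaMin, 4), "\n")
  cat("  nonzero coefficients:", x$nNonzero, "of", length(x$coef), "\n")
  cat("  training r(pred, actual):", round(x$trainingR, 3), "\n")
  invisible(x)
}

#' Predict from a fitted elastic-net model
#' @param object an `elasticNetModel`.
#' @param newdata n x p matrix on the original degree scale.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.elasticNetModel <- function(object, newdata, ...) {
  as.numeric(as.matrix(newdata) %*% object$coef + object$intercept)
}

#' Validate an elastic-net model on a hold-out sample
#'
#' Applies the frozen coefficients to hold-out (already covariate-adjusted
#' with the frozen discovery transform) degrees and reports the Pearson
#' correlation between predicted and actual outcome with its two-sided p.
#'
#' @param model an `elasticNetModel`.
#' @param degrees hold-out n x p degree matrix.
#' @param outcome hold-out outcome vector (n >= 4).
#' @return list: `r`, `p`, `predicted`, `actual`.
#' @export
elasticNetValidate <- function(model, degrees, outcome) {
  if (length(outcome) < 4L) stop("need at least 4 hold-out observations")
  pred <- predict(model, degrees)
  ct <- stats::cor.test(pred, outcome)
  list(r = unname(ct$estimate), p = ct$p.value, predicted = pred,
       actual = as.numeric(outcome))
}

#' Check elastic-net KKT conditions at the chosen lambda
#'
#' For the internally standardised problem (predictors unit variance,
#' outcome unit variance): (1/(2n))||y - b0 - X beta||^2 +
#' lambda (alpha ||beta||_1 + (1-alpha)/2 ||beta||^2). Verifies the
#' subgradient conditions: for active coefficients
#' x_j'r/n = lambda (alpha sign(beta_j) + (1-alpha) beta_j); for inactive,
#' |x_j'r/n| <= lambda alpha (within `tol`).
#'
#' @param model an `elasticNetModel`.
#' @param degrees,outcome the training data the model was fit on.
#' @param tol violation tolerance.
#' @return list: `maxViolation`, `ok`.
#' @export
elasticNetKkt <- function(model, degrees, outcome, tol = 1e-6) {
  X <- as.matrix(degrees)
  y <- as.numeric(outcome)
  st <- model$standardization
  Xs <- sweep(sweep(X, 2, st$mean), 2, st$sd, "/")
  n <- nrow(Xs)
  beta <- model$betaStd
  r <- y / st$ySd - model$interceptStd - as.numeric(Xs %*% beta)
  g <- as.numeric(crossprod(Xs, r)) / n
  lam <- model$lambdaMin; a <- model$alpha
  active <- beta != 0
  viol <- numeric(length(beta))
  viol[active] <- abs(g[active] - lam * (a * sign(beta[active]) +
                                           (1 - a) * beta[active]))
  viol[!active] <- pmax(abs(g[!active]) - lam * a, 0)
  ## intercept optimality: mean residual must be ~0
  v0 <- abs(mean(r))
  list(maxViolation = max(c(viol, v0)), ok = max(c(viol, v0)) <= tol)
}
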