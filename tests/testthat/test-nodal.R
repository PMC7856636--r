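mkDegreeTable <- function(nNodes, nPerGroup, boost = NULL, boostNodes = integer(),
                          seed = 1, sd = 3) {
  set.seed(seed)
  subj <- sprintf("S%03d", seq_len(2 * nPerGroup))
  grp <- rep(c("patient", "control"), each = nPerGroup)
  base <- seq(5, 25, length.out = nNodes)
  rows <- lapply(seq_along(subj), function(i) {
    mu <- base
    if (grp[i] == "patient" && length(boostNodes)) mu[boostNodes] <- mu[boostNodes] + boost
    data.frame(node = seq_len(nNodes), subject_id = subj[i], group = grp[i],
               density = 0.05, degree = rnorm(nNodes, mu, sd))
  })
  do.call(rbind, rows)
}

test_that("nodal permutation statistics flag planted group differences", {
  mt <- mkDegreeTable(60, 20, boost = 8, boostNodes = c(7, 23, 41), seed = 2)
  res <- nodalDifferencePermutation(mt, nPerm = 500, seed = 3)
  expect_equal(nrow(res), 60)
  expect_true(all(res$flagged[c(7, 23, 41)]))
  expect_true(all(res$perm_p[c(7, 23, 41)] <= 0.01))
  ## p-value floor is 1/(1+nPerm)
  expect_gte(min(res$perm_p), 1 / 501)
  ## determinism
  expect_identical(res, nodalDifferencePermutation(mt, nPerm = 500, seed = 3))
})

test_that("nodal permutation p-values are uniform under the null", {
  pvals <- unlist(lapply(1:4, function(s) {
    mt <- mkDegreeTable(50, 15, seed = 100 + s)
    nodalDifferencePermutation(mt, nPerm = 400, seed = s)$perm_p
  }))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  ## and few nodes flagged (the +/-2 SD rule tail)
  mt <- mkDegreeTable(200, 15, seed = 9)
  res <- nodalDifferencePermutation(mt, nPerm = 200, seed = 9)
  expect_lt(mean(res$flagged), 0.15)
})

test_that("stepwise selection keeps informative nodes and drops noise", {
  set.seed(44)
  n <- 60
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("node", 1:6)))
  y <- 0.9 * X[, 2] + rnorm(n, 0, 0.4)
  res <- stepwiseModel(X, y)
  expect_true("node2" %in% res$terms)
  expect_lt(length(res$terms), 4)
  expect_gt(res$adjR2, 0.5)
  ## independent outcome -> usually the empty model
  empties <- sum(vapply(1:10, function(s) {
    set.seed(200 + s)
    length(stepwiseModel(X, rnorm(n))$terms) == 0
  }, logical(1)))
  expect_gte(empties, 8)
  ## perfectly collinear predictors: exactly one of the pair is retained
  X2 <- cbind(X[, 1:2], dup = X[, 2])
  colnames(X2) <- c("a", "b", "dup")
  res2 <- stepwiseModel(X2, y)
  expect_equal(sum(c("b", "dup") %in% res2$terms), 1)
})

test_that("age/sex adjustment removes covariate-driven degree variance", {
  set.seed(10)
  n <- 46
  cohort <- data.frame(age = round(rnorm(n, 63, 7)),
                       sex = sample(c("F", "M"), n, TRUE))
  deg <- matrix(rnorm(n * 20, 15, 3), n, 20)
  deg <- deg + outer(cohort$age - mean(cohort$age), rep(0.4, 20))
  adj <- adjustAgeSex(deg, cohort)
  corAge <- apply(adj, 2, function(col) cor(col, cohort$age))
  expect_lt(max(abs(corAge)), 0.05)
  ## scale preserved: per-node means survive
  expect_equal(colMeans(adj), colMeans(deg), tolerance = 1e-9)
  ## frozen transform reproduces itself on the fitting sample
  adj2 <- adjustAgeSex(deg, cohort, transform = attr(adj, "transform"))
  expect_equal(adj2[, 1], adj[, 1], tolerance = 1e-12)
  ## orthogonal covariates leave the data nearly untouched
  deg0 <- matrix(rnorm(n * 5, 10, 2), n, 5)
  cohort0 <- data.frame(age = rep(60, n) + rep(c(-1, 1), length.out = n),
                        sex = rep(c("F", "M"), length.out = n))
  adj0 <- adjustAgeSex(deg0, cohort0)
  expect_equal(cor(adj0[, 1], deg0[, 1]), 1, tolerance = 0.01)
})

test_that("elastic net solves the penalised problem (KKT) and finds sparse signal", {
  set.seed(77)
  n <- 50; p <- 80
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("n", 1:p)))
  beta <- numeric(p); beta[c(5, 20, 60)] <- c(2, -1.5, 1)
  y <- as.numeric(X %*% beta) + rnorm(n, 0, 0.5)
  fit <- elasticNetFit(X, y, seed = 1)
  expect_true(all(which(abs(beta) > 0) %in% which(fit$coef != 0)))
  kkt <- elasticNetKkt(fit, X, y)
  expect_true(kkt$ok)
  expect_lt(kkt$maxViolation, 1e-6)
  ## the lambda grid has 100 values spanning four decades
  expect_length(fit$lambda, 100)
  expect_equal(max(fit$lambda) / min(fit$lambda), 1e4, tolerance = 1e-8)
  ## grouping property: duplicated informative predictor shares weight
  X2 <- cbind(X, dup5 = X[, 5])
  fit2 <- elasticNetFit(X2, y, seed = 1)
  expect_gt(fit2$coef["n5"], 0)
  expect_gt(fit2$coef["dup5"], 0)
  ## constant outcome refuses to fit
  expect_error(elasticNetFit(X, rep(3, n)), "constant")
})

test_that("elastic net matches ridge closed form as alpha approaches zero", {
  set.seed(88)
  n <- 40; p <- 5
  X <- matrix(rnorm(n * p), n, p)
  y <- X[, 1] - 0.5 * X[, 3] + rnorm(n, 0, 0.3)
  alpha <- 1e-4
  lam <- 0.3
  ## the package convention: predictors and outcome standardised to unit
  ## (1/n) variance, penalty lam * ((1-alpha)/2) ||beta||^2 at alpha -> 0
  xm <- colMeans(X); xs <- sqrt(colMeans(sweep(X, 2, xm)^2))
  Xs <- sweep(sweep(X, 2, xm), 2, xs, "/")
  ys <- y / sqrt(mean((y - mean(y))^2))
  fit <- glmnet::glmnet(Xs, ys, alpha = alpha, lambda = lam,
                        standardize = FALSE, thresh = 1e-14)
  betaHat <- as.numeric(coef(fit))[-1]
  ## ridge closed form for the same objective: (X'X/n + lam I)^-1 X'y/n
  yc <- ys - mean(ys)
  ridge <- solve(crossprod(Xs) / n + diag(lam * (1 - alpha), p),
                 crossprod(Xs, yc) / n)
  expect_lt(max(abs(betaHat - as.numeric(ridge))), 1e-4)
})

test_that("hold-out validation uses frozen coefficients", {
  set.seed(99)
  n <- 60; p <- 30
  X <- matrix(rnorm(n * p), n, p)
  beta <- numeric(p); beta[c(2, 9)] <- c(1.5, -1)
  y <- as.numeric(X %*% beta) + rnorm(n, 0, 0.4)
  fit <- elasticNetFit(X[1:40, ], y[1:40], seed = 2)
  ## validating on the training set reproduces the training correlation
  valSelf <- elasticNetValidate(fit, X[1:40, ], y[1:40])
  expect_equal(valSelf$r, fit$trainingR, tolerance = 1e-9)
  ## true hold-out keeps high r; shuffled outcome destroys it
  val <- elasticNetValidate(fit, X[41:60, ], y[41:60])
  expect_gt(val$r, 0.7)
  set.seed(3)
  valShuf <- elasticNetValidate(fit, X[41:60, ], sample(y[41:60]))
  expect_lt(abs(valShuf$r), 0.6)
  expect_error(elasticNetValidate(fit, X[1:3, ], y[1:3]), "at least 4")
})
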