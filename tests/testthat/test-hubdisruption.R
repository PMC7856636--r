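test_that("kIndex reproduces the closed-form OLS slope on any input", {
  ## hand-enumerated example: x = (10,20,30), subject = (20,20,20)
  f <- kIndex(c(20, 20, 20), c(10, 20, 30))
  expect_equal(f$K, -1)
  expect_equal(f$b, 20)
  ## identity and proportional profiles
  expect_equal(kIndex(c(3, 7, 9), c(3, 7, 9))$K, 0)
  expect_equal(kIndex(2 * c(3, 7, 9), c(3, 7, 9))$K, 1)
  expect_equal(kIndex(2 * c(3, 7, 9), c(3, 7, 9))$b, 0, tolerance = 1e-12)
  ## oracle: covariance/variance ratio on random vectors
  set.seed(12)
  for (i in 1:20) {
    x <- rnorm(50, 10, 4); y <- rnorm(50, 0, 2) + 0.3 * x
    f <- kIndex(y + x, x)
    expect_equal(f$K, cov(x, y) / var(x), tolerance = 1e-12)
    fit <- lm((y + x - x) ~ x)
    expect_equal(f$b, unname(coef(fit)[1]), tolerance = 1e-9)
    expect_equal(f$r2, summary(fit)$r.squared, tolerance = 1e-9)
  }
  expect_error(kIndex(1:3, c(2, 2, 2)), "zero variance")
  expect_error(kIndex(1:3, 1:4), "length")
})

test_that("K is invariant to a common additive shift (only b moves)", {
  set.seed(4)
  x <- rnorm(30, 20, 5); y <- rnorm(30)
  f0 <- kIndex(x + y, x)
  f1 <- kIndex(x + y + 7, x + 7)
  expect_equal(f1$K, f0$K, tolerance = 1e-12)
  expect_equal(f1$b, f0$b - 7 * f0$K, tolerance = 1e-9)
})

test_that("kIndexTable references all groups to the control mean profile", {
  set.seed(21)
  mt <- expand.grid(node = 1:20, subject_id = sprintf("S%02d", 1:12),
                    density = 0.05, stringsAsFactors = FALSE)
  mt$group <- ifelse(as.integer(sub("S", "", mt$subject_id)) <= 6,
                     "patient", "control")
  base <- seq(2, 40, length.out = 20)
  mt$degree <- base[mt$node] + rnorm(nrow(mt))
  kt <- kIndexTable(mt, metrics = "degree")
  expect_equal(nrow(kt), 12)
  ## control-group K values average approximately 0 by construction
  expect_lt(abs(mean(kt$K[kt$group == "control"])), 0.05)
  ## a subject equal to the control mean has K = 0 exactly
  ctrlMean <- tapply(mt$degree[mt$group == "control"],
                     mt$node[mt$group == "control"], mean)
  mt2 <- mt
  mt2$degree[mt2$subject_id == "S01"] <- ctrlMean[mt2$node[mt2$subject_id == "S01"]]
  kt2 <- kIndexTable(mt2, metrics = "degree")
  expect_equal(kt2$K[kt2$subject_id == "S01"], 0, tolerance = 1e-12)
  ## group-level table carries both pooled and mean-of-subjects modes
  gk <- attr(kt, "groupK")
  expect_true(all(c("K_pooled", "K_mean_of_subjects") %in% colnames(gk)))
  expect_equal(gk$K_pooled, gk$K_mean_of_subjects, tolerance = 1e-9)
})

test_that("group contrast detects a planted K shift and respects covariates", {
  set.seed(33)
  mkTable <- function(shift) {
    subj <- sprintf("S%02d", 1:40)
    grp <- rep(c("control", "patient"), each = 20)
    base <- seq(5, 40, length.out = 25)
    rows <- lapply(seq_along(subj), function(i) {
      slope <- 1 + if (grp[i] == "patient") shift else 0
      data.frame(node = 1:25, subject_id = subj[i], group = grp[i],
                 density = 0.05,
                 degree = slope * base + rnorm(25, 0, 1.5))
    })
    do.call(rbind, rows)
  }
  cohort <- data.frame(subject_id = sprintf("S%02d", 1:40),
                       age = round(rnorm(40, 60, 6)),
                       sex = sample(c("F", "M"), 40, TRUE))
  ktShift <- kIndexTable(mkTable(-0.25), metrics = "degree")
  res <- groupKContrast(ktShift, cohort, density = 0.05)
  expect_lt(res$p, 0.001)
  expect_lt(res$estimate, 0)
  ## null: no planted shift, effect small
  ktNull <- kIndexTable(mkTable(0), metrics = "degree")
  resNull <- groupKContrast(ktNull, cohort, density = 0.05)
  expect_lt(abs(resNull$estimate), 0.1)
  ## missing covariates are reported by subject
  cohortNA <- cohort; cohortNA$age[3] <- NA
  expect_error(groupKContrast(ktShift, cohortNA), "S03")
})

test_that("clinical correlation screen finds a planted association and FDR-controls noise", {
  set.seed(55)
  n <- 40
  kt <- data.frame(subject_id = sprintf("P%02d", 1:n), group = "patient",
                   density = 0.05, metric = "degree",
                   K = rnorm(n, -0.1, 0.1), intercept = 0, r2 = 0.5)
  cohort <- data.frame(subject_id = sprintf("P%02d", 1:n),
                       age = round(rnorm(n, 63, 6)),
                       sex = sample(c("F", "M"), n, TRUE))
  cohort$planted <- kt$K * 10 + rnorm(n, 0, 0.05)
  for (j in 1:11) cohort[[paste0("noise", j)]] <- rnorm(n)
  cols <- c("planted", paste0("noise", 1:11))
  res <- kClinicalCorrelations(kt, cohort, cols, density = 0.05)
  expect_equal(nrow(res), 12)      # 1 metric x 12 clinical columns
  planted <- res[res$clinical == "planted", ]
  expect_gt(planted$r, 0.9)
  expect_true(planted$pass_fdr)
  expect_lt(sum(res$pass_fdr[res$clinical != "planted"]), 3)
  ## constant clinical column yields an NA row with a warning
  cohort$flat <- 1
  expect_warning(res2 <- kClinicalCorrelations(kt, cohort, c("flat", "planted")),
                 "constant")
  expect_true(is.na(res2$r[res2$clinical == "flat"]))
})

test_that("node-subsampling robustness reduces to identity at fractionKeep = 1", {
  set.seed(66)
  mt <- expand.grid(node = 1:30, subject_id = sprintf("S%02d", 1:10),
                    density = 0.05, stringsAsFactors = FALSE)
  mt$group <- ifelse(as.integer(sub("S", "", mt$subject_id)) <= 5,
                     "patient", "control")
  mt$degree <- seq(2, 30, length.out = 30)[mt$node] + rnorm(nrow(mt), 0, 2)
  rb <- kRobustness(mt, fractionKeep = 1, nDraws = 3, seed = 2)
  expect_equal(rb$subjects$K, rb$subjects$K_sub_mean, tolerance = 1e-12)
  expect_equal(rb$correlation$r, 1, tolerance = 1e-9)
  ## same seed reproduces; subsampled K tracks full K on structured data
  rb1 <- kRobustness(mt, fractionKeep = 0.3, nDraws = 20, seed = 5)
  rb2 <- kRobustness(mt, fractionKeep = 0.3, nDraws = 20, seed = 5)
  expect_identical(rb1, rb2)
  expect_gt(rb1$correlation$r, 0.5)
  expect_error(kRobustness(mt, fractionKeep = 0.05), "too few")
})
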