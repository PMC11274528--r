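test_that("Lin's CCC: perfect concordance, shift penalty, formula oracle", {
  x <- c(12.1, 15.3, 18.2, 21.4, 24.9, 28.0, 31.3, 35.2, 38.8, 42.5)
  expect_equal(lin_ccc(x, x)$ccc, 1)
  shifted <- lin_ccc(x, x + 5)
  expect_lt(shifted$ccc, 1)
  expect_equal(shifted$pearson_r, 1)
  y <- c(13.0, 14.8, 19.1, 20.2, 26.0, 27.1, 30.0, 36.4, 37.9, 44.0)
  expect_equal(lin_ccc(x, y)$ccc, oracle_ccc(x, y), tolerance = 1e-12)
  # |ccc| <= |r| always
  expect_lte(abs(lin_ccc(x, y)$ccc), abs(lin_ccc(x, y)$pearson_r))
  expect_error(lin_ccc(rep(1, 5), rep(1, 5)), "zero combined variance")
})

test_that("CCC is invariant under a common affine map but penalized by unequal ones", {
  x <- c(3.2, 4.1, 5.9, 7.4, 8.8, 10.1, 12.3)
  y <- c(3.0, 4.4, 5.5, 7.9, 8.6, 10.6, 12.0)
  base <- lin_ccc(x, y)$ccc
  same <- lin_ccc(2 * x + 1, 2 * y + 1)$ccc
  expect_equal(same, base, tolerance = 1e-12)
  expect_lt(lin_ccc(x, 1.5 * y + 4)$ccc, lin_ccc(x, y)$pearson_r)
})

test_that("Bland-Altman reproduces the limits-of-agreement geometry", {
  x <- c(10, 12, 15, 17, 20, 23, 26, 30)
  expect_equal(bland_altman(x, x),
               list(mean_diff = 0, loa_low = 0, loa_high = 0, sd_diff = 0,
                    n = 8L))
  # construct differences with mean 3.7 and sd 12.9 exactly: the limits
  # must come out at 3.7 -/+ 1.96 * 12.9 = -21.58 / +28.98
  set.seed(14)
  z <- rnorm(40)
  z <- (z - mean(z)) / sd(z)
  d <- 3.7 + 12.9 * z
  ba <- bland_altman(d, rep(0, length(d)))
  expect_equal(ba$mean_diff, 3.7, tolerance = 1e-12)
  expect_equal(ba$loa_low, 3.7 - 1.96 * 12.9, tolerance = 1e-9)
  expect_equal(ba$loa_high, 3.7 + 1.96 * 12.9, tolerance = 1e-9)
  # antisymmetry
  y <- d + rnorm(length(d))
  b1 <- bland_altman(d, y); b2 <- bland_altman(y, d)
  expect_equal(b1$mean_diff, -b2$mean_diff, tolerance = 1e-12)
  expect_equal(b1$loa_low, -b2$loa_high, tolerance = 1e-12)
})

test_that("cross-tabulation diagnostics match hand counts and Bayes identity", {
  # 2x2 geometry echoing a 1D-like method at n = 230, prevalence 102
  truth <- rep(c(TRUE, FALSE), c(102, 128))
  pred <- c(rep(TRUE, 73), rep(FALSE, 29), rep(TRUE, 7), rep(FALSE, 121))
  cr <- crosstab_metrics(pred, truth)
  expect_equal(unname(cr$counts), c(73, 7, 121, 29))
  expect_equal(cr$sensitivity, 100 * 73 / 102, tolerance = 1e-12)
  expect_equal(cr$specificity, 100 * 121 / 128, tolerance = 1e-12)
  expect_equal(round(cr$sensitivity, 1), 71.6)
  expect_equal(round(cr$specificity, 1), 94.5)
  expect_equal(cr$lr_pos, (73 / 102) / (1 - 121 / 128), tolerance = 1e-12)
  expect_equal(cr$lr_neg, (1 - 73 / 102) / (121 / 128), tolerance = 1e-12)
  # PPV from sens/spec/prevalence via Bayes
  prev <- 102 / 230
  se <- cr$sensitivity / 100; sp <- cr$specificity / 100
  expect_equal(cr$ppv / 100, se * prev / (se * prev + (1 - sp) * (1 - prev)),
               tolerance = 1e-12)
  expect_equal(cr$npv / 100,
               sp * (1 - prev) / (sp * (1 - prev) + (1 - se) * prev),
               tolerance = 1e-12)
})

test_that("degenerate predictors and absent classes are reported, not NaN", {
  truth <- rep(c(TRUE, FALSE), c(5, 5))
  allneg <- crosstab_metrics(rep(FALSE, 10), truth)
  expect_equal(allneg$sensitivity, 0)
  expect_equal(allneg$specificity, 100)
  expect_true(is.na(allneg$ppv))
  expect_true(any(grepl("PPV undefined", allneg$notes)))
  oneclass <- crosstab_metrics(rep(TRUE, 5), rep(TRUE, 5))
  expect_true(is.na(oneclass$specificity))
  expect_true(any(grepl("no true non-progressions", oneclass$notes)))
})

test_that("identical predictions give perfect diagnostics", {
  truth <- rep(c(TRUE, FALSE), c(7, 9))
  cr <- crosstab_metrics(truth, truth)
  expect_equal(cr$sensitivity, 100)
  expect_equal(cr$specificity, 100)
})

test_that("ROC: separation, null signal, and the Mann-Whitney identity", {
  r <- roc_optimal_threshold(c(1, 2, 3, 10, 11, 12),
                             c(rep(FALSE, 3), rep(TRUE, 3)))
  expect_equal(r$auc, 1)
  expect_gte(r$threshold, 3)
  expect_lt(r$threshold, 10)
  # permuted labels: AUC near 0.5
  set.seed(99)
  ch <- rnorm(400)
  tr <- sample(rep(c(TRUE, FALSE), 200))
  expect_lt(abs(roc_optimal_threshold(ch, tr)$auc - 0.5), 0.08)
  # 20-point fixture with ties: AUC == U / (n1 n0) to 1e-12
  set.seed(7)
  ch20 <- round(c(rnorm(10, 30, 15), rnorm(10, 10, 15)))
  tr20 <- rep(c(TRUE, FALSE), each = 10)
  r20 <- roc_optimal_threshold(ch20, tr20)
  expect_equal(r20$auc, oracle_auc(ch20, tr20), tolerance = 1e-12)
  expect_error(roc_optimal_threshold(1:5, rep(TRUE, 5)), "both truth classes")
})

test_that("ROC AUC agrees with pROC on a mixed fixture", {
  skip_if_not_installed("pROC")
  set.seed(12)
  ch <- c(rnorm(30, 45, 20), rnorm(40, 15, 18))
  tr <- rep(c(TRUE, FALSE), c(30, 40))
  r <- roc_optimal_threshold(ch, tr)
  pr <- pROC::roc(response = tr, predictor = ch, quiet = TRUE,
                  direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  # Youden-optimal operating point matches pROC's "youden" best threshold
  co <- pROC::coords(pr, "best", best.method = "youden",
                     ret = c("sensitivity", "specificity"))
  expect_equal(r$sensitivity / 100, co$sensitivity[1], tolerance = 1e-9)
  expect_equal(r$specificity / 100, co$specificity[1], tolerance = 1e-9)
})

test_that("Youden ties break toward higher specificity", {
  # cutoffs 0 and 2 tie at J = 0.5: (sens, spec) = (1, .5) vs (.5, 1)
  ch <- c(3, 1, 2, 0)
  tr <- c(TRUE, TRUE, FALSE, FALSE)
  r <- roc_optimal_threshold(ch, tr)
  expect_equal(r$specificity, 100)
  expect_equal(r$threshold, 2)
})

test_that("subgroup concordance separates small-tumor noise from large", {
  set.seed(5)
  n <- 120
  mtd <- runif(n, 20, 50)
  vde_v <- runif(n, -2, 8)
  # noise inversely proportional to tumor size: small tumors disagree more
  vde_3d <- vde_v + rnorm(n, 0, 12 / mtd)
  w <- data.frame(mean_mtd_v = mtd, vde_v = vde_v, vde_3d = vde_3d)
  sg <- subgroup_concordance(w, cut = 35)
  expect_equal(sg$subgroup, c("small", "large"))
  expect_lt(sg$lcc[sg$subgroup == "small"], sg$lcc[sg$subgroup == "large"])
  # identical variants: perfect concordance in both subgroups
  w2 <- data.frame(mean_mtd_v = mtd, vde_v = vde_v, vde_3d = vde_v)
  sg2 <- subgroup_concordance(w2, cut = 35)
  expect_equal(sg2$lcc, c(1, 1))
  # cut beyond every MTD: one empty subgroup flagged
  sg3 <- subgroup_concordance(w, cut = 100)
  expect_equal(sg3$n[sg3$subgroup == "large"], 0L)
  expect_true(is.na(sg3$lcc[sg3$subgroup == "large"]))
})

test_that("the minimal-dMTD sweep raises concordance under a fixed-noise model", {
  set.seed(8)
  n <- 500
  # signed true MTD change (growth and regression); over 1-year windows the
  # volume-based VDE is the clean signal, the diameter-based VDE adds fixed
  # measurement noise. Raising the |dMTD| floor trims the low-signal middle
  # of the distribution, so retained signal variance (and concordance) rises.
  delta <- rnorm(n, 0, 5)
  vde_v <- delta
  vde_3d <- vde_v + rnorm(n, 0, 1.5)
  w <- data.frame(delta_mtd_v = delta, vde_v = vde_v, vde_3d = vde_3d)
  sw <- vde_concordance_sweep(w, delta_mtd_grid = seq(0, 10, by = 1))
  expect_equal(sw$fraction_retained[1], 1)
  expect_equal(sw$lcc[1], lin_ccc(w$vde_v, w$vde_3d)$ccc)
  expect_true(all(diff(sw$lcc) > -0.02))
  expect_gt(sw$lcc[nrow(sw)], sw$lcc[1])
  # cutoff beyond every change: nothing retained, LCC undefined
  sw2 <- vde_concordance_sweep(w, delta_mtd_grid = 20)
  expect_equal(sw2$n, 0L)
  expect_true(is.na(sw2$lcc))
})
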