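#' Lin's concordance correlation coefficient
#'
#' Measures agreement with the identity line between two measurement
#' series: `ccc = 2 * s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with
#' population (divide-by-n) moments, the classical form. Unlike Pearson's
#' r it is attenuated by location and scale shift, so `|ccc| <= |r|`.
#' The confidence interval uses the Fisher z-transform of the CCC with
#' Lin's asymptotic variance.
#'
#' @param x,y numeric vectors of equal length `>= 3`
#' @param conf confidence level (default 0.95)
#' @param variance `"population"` (classical) or `"sample"` (n-1 moments)
#' @return list with `ccc`, `ci` (length 2), `pearson_r`, `n`
#' @export
lin_ccc <- function(x, y, conf = 0.95, variance = c("population", "sample")) {
  variance <- match.arg(variance)
  stopifnot(length(x) == length(y), length(x) >= 3L)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  denom_n <- if (variance == "population") n else n - 1L
  mx <- mean(x); my <- mean(y)
  sx2 <- sum((x - mx)^2) / denom_n
  sy2 <- sum((y - my)^2) / denom_n
  sxy <- sum((x - mx) * (y - my)) / denom_n
  if (sx2 + sy2 == 0) {
    stop("zero combined variance: concordance undefined", call. = FALSE)
  }
  ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  r <- if (sx2 > 0 && sy2 > 0) sxy / sqrt(sx2 * sy2) else NA_real_
  ci <- c(NA_real_, NA_real_)
  if (is.finite(r) && abs(ccc) < 1 && abs(r) > 0 && n > 2) {
    u <- (mx - my) / (sx2 * sy2)^(1 / 4)
    C <- ccc / r  # bias-correction factor
    z <- atanh(ccc)
    sz2 <- ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
              4 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
              2 * ccc^4 * u^4 / (r^2 * (1 - ccc^2)^2)) / (n - 2)
    if (is.finite(sz2) && sz2 > 0) {
      q <- qnorm(1 - (1 - conf) / 2)
      ci <- tanh(z + c(-1, 1) * q * sqrt(sz2))
    }
  }
  list(ccc = ccc, ci = ci, pearson_r = r, n = n)
}

#' Bland-Altman limits of agreement
#'
#' Differences `d = x - y`: the mean difference (systematic bias of method
#' x relative to method y) and the 95% limits of agreement
#' `mean(d) +/- 1.96 * sd(d)` (sample standard deviation).
#'
#' @param x,y numeric vectors of equal length `>= 3`
#' @return list with `mean_diff`, `loa_low`, `loa_high`, `sd_diff`, `n`
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  d <- x - y
  d <- d[is.finite(d)]
  m <- mean(d)
  s <- sd(d)
  list(mean_diff = m, loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
       sd_diff = s, n = length(d))
}

#' Full agreement report between two measurement series
#'
#' Pearson correlation (with its Fisher-z CI), Lin's concordance
#' correlation, and Bland-Altman limits of agreement.
#'
#' @inheritParams lin_ccc
#' @return list of class `agreement_report`
#' @export
agreement_report <- function(x, y, conf = 0.95) {
  ct <- cor.test(x, y, conf.level = conf)
  ccc <- lin_ccc(x, y, conf = conf)
  ba <- bland_altman(x, y)
  structure(list(pearson_r = unname(ct$estimate),
                 pearson_ci = as.numeric(ct$conf.int),
                 lin_ccc = ccc$ccc, lin_ccc_ci = ccc$ci,
                 ba_mean_diff = ba$mean_diff,
                 ba_loa_low = ba$loa_low, ba_loa_high = ba$loa_high,
                 n = ba$n),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement (n = %d)\n", x$n))
  cat(sprintf("  Pearson r   %.3f  [%.3f, %.3f]\n", x$pearson_r,
              x$pearson_ci[1], x$pearson_ci[2]))
  cat(sprintf("  Lin's CCC   %.3f  [%.3f, %.3f]\n", x$lin_ccc,
              x$lin_ccc_ci[1], x$lin_ccc_ci[2]))
  cat(sprintf("  Bland-Altman mean %.2f, LoA [%.2f, %.2f]\n",
              x$ba_mean_diff, x$ba_loa_low, x$ba_loa_high))
  invisible(x)
}

#' Cross-tabulation diagnostics against the volume ground truth
#'
#' Builds the 2x2 table of predicted vs true progression labels and derives
#' sensitivity, specificity, PPV, NPV (percent, with Clopper-Pearson exact
#' CIs) and both likelihood ratios. All metrics are computed from the
#' integer counts, so they are exactly recomputable from the stored table.
#' A diagnostic whose defining truth class is absent is reported as `NA`
#' with a note, never silently propagated.
#'
#' @param predicted,truth character vectors (`"progression"` /
#'   `"non_progression"`) or logicals, aligned
#' @param conf confidence level for the exact binomial CIs
#' @return list of class `classification_report`: `counts` (TP, FP, TN,
#'   FN), `sensitivity`, `specificity`, `ppv`, `npv` (percent), `lr_pos`,
#'   `lr_neg`, per-metric CIs, `n`, `notes`
#' @export
crosstab_metrics <- function(predicted, truth, conf = 0.95) {
  to_l <- function(v) if (is.logical(v)) v else v == "progression"
  p <- to_l(predicted); t <- to_l(truth)
  stopifnot(length(p) == length(t))
  ok <- !is.na(p) & !is.na(t)
  p <- p[ok]; t <- t[ok]
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t); tn <- sum(!p & !t)
  notes <- character(0)
  prop_ci <- function(k, n) {
    if (n == 0) return(c(NA_real_, NA_real_))
    as.numeric(binom.test(k, n, conf.level = conf)$conf.int) * 100
  }
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  ppv <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) 100 * tn / (tn + fn) else NA_real_
  if (tp + fn == 0) notes <- c(notes, "no true progressions: sensitivity/LR undefined")
  if (tn + fp == 0) notes <- c(notes, "no true non-progressions: specificity/LR undefined")
  if (tp + fp == 0) notes <- c(notes, "no predicted progressions: PPV undefined")
  if (tn + fn == 0) notes <- c(notes, "no predicted non-progressions: NPV undefined")
  lr_pos <- if (!is.na(sens) && !is.na(spec) && spec < 100) {
    (sens / 100) / (1 - spec / 100)
  } else NA_real_
  lr_neg <- if (!is.na(sens) && !is.na(spec) && spec > 0) {
    (1 - sens / 100) / (spec / 100)
  } else NA_real_
  structure(list(
    counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
    sensitivity = sens, sensitivity_ci = prop_ci(tp, tp + fn),
    specificity = spec, specificity_ci = prop_ci(tn, tn + fp),
    ppv = ppv, ppv_ci = prop_ci(tp, tp + fp),
    npv = npv, npv_ci = prop_ci(tn, tn + fn),
    lr_pos = lr_pos, lr_neg = lr_neg,
    n = tp + fp + tn + fn, notes = notes),
    class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("2x2 classification (n = %d): TP %d FP %d TN %d FN %d\n",
              x$n, x$counts["TP"], x$counts["FP"], x$counts["TN"],
              x$counts["FN"]))
  cat(sprintf("  sensitivity %.1f%%  specificity %.1f%%  PPV %.1f%%  NPV %.1f%%\n",
              x$sensitivity, x$specificity, x$ppv, x$npv))
  cat(sprintf("  LR+ %.1f  LR- %.2f\n", x$lr_pos, x$lr_neg))
  for (nt in x$notes) cat("  note:", nt, "\n")
  invisible(x)
}

#' Empirical ROC curve and optimal progression threshold
#'
#' Sweeps every distinct observed percent change as a candidate cutoff
#' (rule: progression if `change > t`), computes the empirical ROC, its
#' trapezoidal AUC (which equals the normalized Mann-Whitney U statistic),
#' and the optimal threshold. `criterion = "youden"` maximizes
#' sensitivity + specificity - 1 (ties broken toward higher specificity);
#' `"closest01"` minimizes the euclidean distance to the perfect (0, 1)
#' corner.
#'
#' @param changes numeric percent changes, one per follow-up
#' @param truth aligned truth labels (`"progression"` /
#'   `"non_progression"` or logical)
#' @param criterion `"youden"` or `"closest01"`
#' @return list with `auc`, `threshold`, `sensitivity`, `specificity`
#'   (percent, at the optimum) and `curve` (`data.frame` of `threshold`,
#'   `tpr`, `fpr`)
#' @export
roc_optimal_threshold <- function(changes, truth,
                                  criterion = c("youden", "closest01")) {
  criterion <- match.arg(criterion)
  t <- if (is.logical(truth)) truth else truth == "progression"
  ok <- is.finite(changes) & !is.na(t)
  changes <- changes[ok]; t <- t[ok]
  n1 <- sum(t); n0 <- sum(!t)
  if (n1 == 0 || n0 == 0) {
    stop("both truth classes must be present for ROC analysis", call. = FALSE)
  }
  cuts <- c(-Inf, sort(unique(changes)))
  tpr <- vapply(cuts, function(ct) sum(changes[t] > ct) / n1, numeric(1))
  fpr <- vapply(cuts, function(ct) sum(changes[!t] > ct) / n0, numeric(1))
  ord <- order(fpr, tpr)  # ascending fpr for trapezoid integration
  auc <- sum(diff(fpr[ord]) * (head(tpr[ord], -1) + tail(tpr[ord], -1)) / 2)
  finite <- which(is.finite(cuts))
  j <- tpr[finite] - fpr[finite]
  if (criterion == "youden") {
    cand <- which(j == max(j))
    # ties: prefer higher specificity (lower fpr), then lower threshold
    best <- cand[order(fpr[finite][cand], cuts[finite][cand])][1L]
  } else {
    d2 <- (1 - tpr[finite])^2 + fpr[finite]^2
    cand <- which(d2 == min(d2))
    best <- cand[order(fpr[finite][cand], cuts[finite][cand])][1L]
  }
  i <- finite[best]
  list(auc = auc, threshold = cuts[i],
       sensitivity = 100 * tpr[i], specificity = 100 * (1 - fpr[i]),
       curve = data.frame(threshold = cuts, tpr = tpr, fpr = fpr))
}

#' VDE concordance by tumor-size subgroup
#'
#' Splits VDE windows at the MTD cut (default 35 mm, where agreement
#' between the diameter-based and volume-based MTD is best) and reports
#' Lin's concordance between `vde_v` and `vde_3d`, the mean difference and
#' the window count in each subgroup. Small multi-residue tumors are the
#' regime where the diameter-based VDE is known to disagree with the
#' volume-based VDE (the "residue effect").
#'
#' @param windows `data.frame` with columns `mean_mtd_v`, `vde_v`, `vde_3d`
#'   (one row per window), e.g. from [vde_table()]
#' @param cut MTD split point in mm
#' @return `data.frame` with one row per subgroup (`"small"` `< cut`,
#'   `"large"` `>= cut`): `n`, `lcc`, `mean_diff` (vde_3d - vde_v); empty
#'   subgroups carry `NA` and a `note`
#' @export
subgroup_concordance <- function(windows, cut = 35) {
  stopifnot(cut > 0,
            all(c("mean_mtd_v", "vde_v", "vde_3d") %in% names(windows)))
  grp <- ifelse(windows$mean_mtd_v < cut, "small", "large")
  out <- lapply(c("small", "large"), function(g) {
    w <- windows[grp == g, , drop = FALSE]
    if (nrow(w) < 3L) {
      return(data.frame(subgroup = g, n = nrow(w), lcc = NA_real_,
                        mean_diff = if (nrow(w)) mean(w$vde_3d - w$vde_v)
                        else NA_real_,
                        note = "too few windows for concordance"))
    }
    cc <- lin_ccc(w$vde_v, w$vde_3d)
    data.frame(subgroup = g, n = nrow(w), lcc = cc$ccc,
               mean_diff = mean(w$vde_3d - w$vde_v), note = NA_character_)
  })
  do.call(rbind, out)
}

#' VDE concordance as a function of a minimal MTD-change cutoff
#'
#' For each cutoff in `delta_mtd_grid`, retains the windows whose absolute
#' volume-based MTD change is at least the cutoff, recomputes Lin's
#' concordance between `vde_v` and `vde_3d` on the retained windows, and
#' reports the retained fraction. Raising the lower limit discards the
#' windows in which measurement noise dominates the true MTD change, so
#' concordance typically rises as the retained fraction falls.
#'
#' @param windows `data.frame` with columns `delta_mtd_v`, `vde_v`,
#'   `vde_3d`
#' @param delta_mtd_grid non-negative cutoffs in mm (default 0 to 10 by
#'   0.5)
#' @return `data.frame` with `delta_mtd_min`, `lcc` (`NA` when fewer than
#'   3 windows remain), `n`, `fraction_retained`
#' @export
vde_concordance_sweep <- function(windows,
                                  delta_mtd_grid = seq(0, 10, by = 0.5)) {
  stopifnot(all(delta_mtd_grid >= 0),
            all(c("delta_mtd_v", "vde_v", "vde_3d") %in% names(windows)))
  n_all <- nrow(windows)
  out <- lapply(delta_mtd_grid, function(ct) {
    w <- windows[abs(windows$delta_mtd_v) >= ct, , drop = FALSE]
    lcc <- if (nrow(w) >= 3L) lin_ccc(w$vde_v, w$vde_3d)$ccc else NA_real_
    data.frame(delta_mtd_min = ct, lcc = lcc, n = nrow(w),
               fraction_retained = if (n_all) nrow(w) / n_all else 0)
  })
  do.call(rbind, out)
}
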