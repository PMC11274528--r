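#' Measurability and progression thresholds
#'
#' All tunable cutoffs of the response-assessment layer in one place.
#' RANO-derived progression thresholds (inclusive `>=`): 20% for 1D, 25%
#' for 2D, 40% for 3D and for the segmented volume. LGG-optimized
#' thresholds (strict `>`, the ROC-derived alternative set): 16% for 1D,
#' 33% for 2D, 52% for 3D, 15% for the MTD.3D percent change.
#' Measurability minima: 10 mm (1D), 100 mm^2 (2D), 0.5 mL (3D).
#' `vde_alarm` is the 8 mm/year velocity that signals impending anaplastic
#' transformation and `mtd_subgroup_cut` the 35 mm MTD split between small
#' and large tumors in the concordance analysis.
#'
#' @param prog_1d,prog_2d,prog_3d,prog_volume RANO-style progression
#'   thresholds, percent
#' @param lgg_1d,lgg_2d,lgg_3d,lgg_mtd3d LGG-optimized thresholds, percent
#' @param min_1d,min_2d,min_3d measurability minima (mm, mm^2, mL)
#' @param vde_alarm anaplastic-transformation alarm velocity, mm/year
#' @param mtd_subgroup_cut small/large tumor MTD split, mm
#' @return object of class `threshold_config`
#' @export
threshold_config <- function(prog_1d = 20, prog_2d = 25, prog_3d = 40,
                             prog_volume = 40,
                             lgg_1d = 16, lgg_2d = 33, lgg_3d = 52,
                             lgg_mtd3d = 15,
                             min_1d = 10, min_2d = 100, min_3d = 0.5,
                             vde_alarm = 8, mtd_subgroup_cut = 35) {
  vals <- list(prog_1d = prog_1d, prog_2d = prog_2d, prog_3d = prog_3d,
               prog_volume = prog_volume,
               lgg_1d = lgg_1d, lgg_2d = lgg_2d, lgg_3d = lgg_3d,
               lgg_mtd3d = lgg_mtd3d,
               min_1d = min_1d, min_2d = min_2d, min_3d = min_3d,
               vde_alarm = vde_alarm, mtd_subgroup_cut = mtd_subgroup_cut)
  if (!all(vapply(vals, is_scalar_number, logical(1))) ||
      any(unlist(vals) <= 0)) {
    stop("all thresholds must be positive numbers", call. = FALSE)
  }
  structure(vals, class = "threshold_config")
}

#' Select the baseline scan of a follow-up series
#'
#' For progression assessment the baseline is the first MRI between 72
#' hours and 2 years after surgery: scans within 72 hours are unusable
#' (post-surgical enhancement, edema, ischemia), and a patient whose first
#' qualifying scan falls more than 2 years post-surgery is excluded. For
#' chemotherapy-response assessment the baseline is the last scan strictly
#' before chemotherapy onset. Failure returns an exclusion record rather
#' than an error, so cohort accounting can tally the reasons.
#'
#' @param dates sorted `Date` vector of scan dates
#' @param surgery_date `Date` of the (most recent relevant) surgery
#' @param chemo_start optional `Date`; when given together with
#'   `mode = "chemo"`, baseline is the last scan before it
#' @param mode `"progression"` or `"chemo"`
#' @return list with either `index` (into `dates`) and `date`, or
#'   `index = NA` and `reason`
#' @export
select_baseline <- function(dates, surgery_date, chemo_start = NULL,
                            mode = c("progression", "chemo")) {
  mode <- match.arg(mode)
  dates <- as_date_strict(dates, "scan date")
  if (is.unsorted(dates)) stop("scan dates must be sorted", call. = FALSE)
  if (mode == "chemo") {
    if (is.null(chemo_start) || is.na(chemo_start)) {
      return(list(index = NA_integer_, reason = "no chemotherapy start date"))
    }
    chemo_start <- as_date_strict(chemo_start, "chemo start")
    idx <- which(dates < chemo_start)
    if (!length(idx)) {
      return(list(index = NA_integer_, reason = "no scan before chemotherapy"))
    }
    i <- idx[length(idx)]
    return(list(index = i, date = dates[i]))
  }
  surgery_date <- as_date_strict(surgery_date, "surgery date")
  lo <- surgery_date + 3       # 72 hours
  hi <- surgery_date + round(2 * 365.25)
  post <- which(dates >= lo)
  if (!length(post)) {
    return(list(index = NA_integer_,
                reason = "no scan more than 72 hours post-surgery"))
  }
  i <- post[1L]
  if (dates[i] > hi) {
    return(list(index = NA_integer_,
                reason = "first postoperative baseline scan over 2 years post-surgery"))
  }
  list(index = i, date = dates[i])
}

#' Percentage change between baseline and follow-up size
#'
#' @param baseline,followup sizes in the same unit; baseline must be
#'   non-zero
#' @return percent change, `100 * (followup - baseline) / baseline`
#' @export
percent_change <- function(baseline, followup) {
  if (any(baseline == 0)) {
    stop("zero baseline size: percent change undefined", call. = FALSE)
  }
  100 * (followup - baseline) / baseline
}

#' Classify a percent change as progression or non-progression
#'
#' Two threshold sets are supported. `mode = "rano"` applies the
#' high-grade-glioma-derived criteria with inclusive comparison
#' (progression iff change `>=` 20% / 25% / 40% for 1D / 2D / 3D and
#' volume). `mode = "lgg"` applies the LGG-optimized ROC-derived set with
#' strict comparison (change `>` 16% / 33% / 52%, and `>` 15% for the
#' MTD.3D percent change). The segmented volume keeps the 40% inclusive
#' rule in both modes: it is the ground-truth definition, a deliberate,
#' configurable asymmetry. The `mtd3d` method has no published RANO rule;
#' in `rano` mode it borrows the 1D 20% criterion (MTD is a diameter).
#'
#' @param change percent change (scalar or vector)
#' @param method one of `"1d"`, `"2d"`, `"3d"`, `"mtd3d"`, `"volume"`
#' @param thresholds a [threshold_config()]
#' @param mode `"rano"` or `"lgg"`
#' @return character vector, `"progression"` or `"non_progression"`
#' @export
classify_response <- function(change, method, thresholds = threshold_config(),
                              mode = c("rano", "lgg")) {
  mode <- match.arg(mode)
  method <- match.arg(method, c("1d", "2d", "3d", "mtd3d", "volume"))
  if (method == "volume") {
    prog <- change >= thresholds$prog_volume
  } else if (mode == "rano") {
    thr <- switch(method, "1d" = thresholds$prog_1d, "2d" = thresholds$prog_2d,
                  "3d" = thresholds$prog_3d, "mtd3d" = thresholds$prog_1d)
    prog <- change >= thr
  } else {
    thr <- switch(method, "1d" = thresholds$lgg_1d, "2d" = thresholds$lgg_2d,
                  "3d" = thresholds$lgg_3d, "mtd3d" = thresholds$lgg_mtd3d)
    prog <- change > thr
  }
  ifelse(prog, "progression", "non_progression")
}

#' Build the follow-up response table for a measured cohort
#'
#' For every patient: resolve the baseline (see [select_baseline()]), apply
#' the measurability exclusions at baseline, compute the percent change of
#' each linear method and of the segmented volume for every follow-up scan,
#' and classify each against its threshold. The segmented-volume label is
#' the ground truth ("golden standard") the linear methods are judged
#' against. A follow-up that shrinks below measurability still classifies
#' (as non-progression); measurability is a baseline property.
#'
#' @param measurements `data.frame` with columns `patient_id`, `scan_date`,
#'   `size_1d`, `size_2d`, `size_3d`, `volume_seg`, `mtd_3d`
#' @param manifest `data.frame` with columns `patient_id`, `surgery_date`,
#'   and optionally `chemo_start`
#' @param thresholds a [threshold_config()]
#' @param mode `"rano"` or `"lgg"` (see [classify_response()])
#' @param baseline_mode `"progression"` or `"chemo"`
#' @return list with `table` (one row per retained follow-up x method:
#'   `patient_id`, `baseline_date`, `followup_date`, `method`, `pct_change`,
#'   `label`, `truth_pct_change`, `truth_label`) and `exclusions` (named
#'   counts per reason; `n_followups` and per-method retained counts close
#'   the ledger: retained + excluded = total follow-ups for every method)
#' @export
build_response_table <- function(measurements, manifest,
                                 thresholds = threshold_config(),
                                 mode = c("rano", "lgg"),
                                 baseline_mode = "progression") {
  mode <- match.arg(mode)
  need <- c("patient_id", "scan_date", "size_1d", "size_2d", "size_3d",
            "volume_seg", "mtd_3d")
  stopifnot(all(need %in% names(measurements)))
  methods <- c("1d", "2d", "3d", "mtd3d")
  size_col <- c("1d" = "size_1d", "2d" = "size_2d", "3d" = "size_3d",
                "mtd3d" = "mtd_3d")
  excl <- c()
  bump <- function(excl, reason, n = 1L) {
    excl[reason] <- (if (reason %in% names(excl)) excl[[reason]] else 0L) + n
    excl
  }
  rows <- list()
  n_followups <- 0L
  for (pid in unique(measurements$patient_id)) {
    mm <- measurements[measurements$patient_id == pid, , drop = FALSE]
    mm <- mm[order(as.Date(mm$scan_date)), , drop = FALSE]
    man <- manifest[manifest$patient_id == pid, , drop = FALSE][1L, ]
    bl <- select_baseline(as.Date(mm$scan_date),
                          surgery_date = man$surgery_date,
                          chemo_start = if ("chemo_start" %in% names(man))
                            man$chemo_start else NULL,
                          mode = baseline_mode)
    if (is.na(bl$index)) {
      excl <- bump(excl, bl$reason)
      next
    }
    fu <- which(as.Date(mm$scan_date) > as.Date(mm$scan_date)[bl$index])
    if (!length(fu)) {
      excl <- bump(excl, "post-surgery scan without follow-up")
      next
    }
    n_followups <- n_followups + length(fu)
    base <- mm[bl$index, ]
    # measurability at baseline, straight from the sizes
    measurable <- c("1d" = base$size_1d >= thresholds$min_1d,
                    "2d" = base$size_2d >= thresholds$min_2d,
                    "3d" = base$size_3d >= thresholds$min_3d,
                    "mtd3d" = base$size_3d >= thresholds$min_3d)
    truth_chg <- percent_change(base$volume_seg, mm$volume_seg[fu])
    truth_lab <- classify_response(truth_chg, "volume", thresholds, mode)
    for (m in methods) {
      if (!measurable[[m]]) {
        excl <- bump(excl, sprintf("non-measurable at baseline (%s)", m),
                     length(fu))
        next
      }
      chg <- percent_change(base[[size_col[[m]]]], mm[[size_col[[m]]]][fu])
      lab <- classify_response(chg, m, thresholds, mode)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid,
        baseline_date = as.Date(mm$scan_date)[bl$index],
        followup_date = as.Date(mm$scan_date)[fu],
        method = m, pct_change = chg, label = lab,
        truth_pct_change = truth_chg, truth_label = truth_lab)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), baseline_date = as.Date(character()),
               followup_date = as.Date(character()), method = character(),
               pct_change = numeric(), label = character(),
               truth_pct_change = numeric(), truth_label = character())
  retained <- vapply(methods, function(m) sum(tab$method == m), integer(1))
  list(table = tab,
       exclusions = as.list(excl),
       n_followups = n_followups,
       retained = retained)
}
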