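#' Mean tumor diameter from the three diameters
#'
#' `MTD.3D = (D1 * D2 * D3)^(1/3)`, the geometric mean of the three
#' axis-aligned diameters -- the diameter of the sphere with the same
#' half-product volume as the measured ellipsoid.
#'
#' @param d1,d2,d3 diameters in mm, all positive
#' @return MTD in mm
#' @export
mtd_from_diameters <- function(d1, d2, d3) {
  if (any(c(d1, d2, d3) <= 0)) {
    stop("diameters must all be positive", call. = FALSE)
  }
  (d1 * d2 * d3)^(1 / 3)
}

#' Mean tumor diameter from the segmented volume
#'
#' `MTD.V = (2 * V)^(1/3)` with `V` in mm^3 (the argument is in mL and is
#' converted). On a mathematically perfect sphere of diameter `d` this reads
#' `(pi/3)^(1/3) * d ~ 1.0156 * d`: the halving convention carries a small
#' documented upward bias relative to the true diameter.
#'
#' @param v segmented volume in mL, `>= 0`
#' @return MTD in mm
#' @export
mtd_from_volume <- function(v) {
  if (any(v < 0)) stop("volume must be non-negative", call. = FALSE)
  (2 * v * 1000)^(1 / 3)
}

#' Treatment-free assessment windows eligible for VDE estimation
#'
#' The VDE is only interpretable over stretches of follow-up at least 6
#' months long with no interfering therapeutic intervention. This splits a
#' sorted scan series at every treatment event (surgery, chemotherapy or
#' radiotherapy start) into maximal treatment-free segments; a segment is an
#' eligible window when it holds at least 2 scans spanning at least
#' `min_span_days`. A scan falling exactly on an event date belongs to both
#' adjacent segments.
#'
#' @param dates `Date` vector of scan dates, sorted ascending (an unsorted
#'   series is an error, never silently reordered)
#' @param events `Date` vector of treatment event dates (may be empty)
#' @param min_span_days minimal window span in days (default 182, i.e. 6
#'   months)
#' @param pairwise if `TRUE`, additionally enumerate all scan *pairs* at
#'   least `min_span_days` apart within each treatment-free segment
#'   (per-assessment analysis) instead of one window per segment
#' @return `data.frame` with one row per candidate window: `start`, `end`,
#'   `n_scans`, `span_days`, `eligible`, `excluded_reason`, and a
#'   list-column `scan_index` of the indices into `dates`
#' @export
eligible_windows <- function(dates, events = as.Date(character()),
                             min_span_days = 182, pairwise = FALSE) {
  dates <- as_date_strict(dates, "scan date")
  events <- as_date_strict(events, "event date")
  if (is.unsorted(dates, strictly = FALSE)) {
    stop("scan dates must be sorted ascending", call. = FALSE)
  }
  events <- sort(unique(events[!is.na(events)]))
  cuts <- c(as.Date(-Inf, origin = "1970-01-01"), events,
            as.Date(Inf, origin = "1970-01-01"))
  rows <- list()
  for (s in seq_len(length(cuts) - 1L)) {
    # inclusive on both ends: an on-event scan feeds both segments
    idx <- which(dates >= cuts[s] & dates <= cuts[s + 1L])
    if (length(idx) < 2L) {
      if (length(idx) == 1L) {
        rows[[length(rows) + 1L]] <- data.frame(
          start = dates[idx], end = dates[idx], n_scans = 1L, span_days = 0,
          eligible = FALSE, excluded_reason = "fewer than 2 scans")
        rows[[length(rows)]]$scan_index <- list(idx)
      }
      next
    }
    if (pairwise) {
      for (a in seq_along(idx)) {
        for (b in seq_along(idx)) {
          if (b <= a) next
          span <- as.numeric(dates[idx[b]] - dates[idx[a]])
          if (span >= min_span_days) {
            rows[[length(rows) + 1L]] <- data.frame(
              start = dates[idx[a]], end = dates[idx[b]], n_scans = 2L,
              span_days = span, eligible = TRUE,
              excluded_reason = NA_character_)
            rows[[length(rows)]]$scan_index <- list(idx[c(a, b)])
          }
        }
      }
    } else {
      span <- as.numeric(dates[idx[length(idx)]] - dates[idx[1L]])
      ok <- span >= min_span_days
      rows[[length(rows) + 1L]] <- data.frame(
        start = dates[idx[1L]], end = dates[idx[length(idx)]],
        n_scans = length(idx), span_days = span, eligible = ok,
        excluded_reason = if (ok) NA_character_ else
          sprintf("window span %d days < %d", as.integer(span),
                  as.integer(min_span_days)))
      rows[[length(rows)]]$scan_index <- list(idx)
    }
  }
  if (!length(rows)) {
    out <- data.frame(start = as.Date(character()), end = as.Date(character()),
                      n_scans = integer(), span_days = numeric(),
                      eligible = logical(), excluded_reason = character())
    out$scan_index <- list()
    return(out)
  }
  do.call(rbind, rows)
}

#' Velocity of diameter expansion (VDE)
#'
#' The slope, in mm/year, of the ordinary least-squares fit of MTD against
#' time for all scans inside one eligible window. A year is 365.25 days.
#' With exactly two scans this coincides with the endpoint difference
#' divided by the elapsed time.
#'
#' @param dates `Date` vector (>= 2 scans, non-zero time span)
#' @param mtd MTD values in mm, same length
#' @return list with `vde` (mm/year), `intercept` (mm at window start),
#'   `n_scans`, `span_days`
#' @export
vde_slope <- function(dates, mtd) {
  dates <- as_date_strict(dates, "scan date")
  if (length(dates) < 2L) stop("VDE needs at least 2 scans", call. = FALSE)
  if (length(mtd) != length(dates)) {
    stop("dates and mtd must have the same length", call. = FALSE)
  }
  years <- as.numeric(dates - dates[1L]) / 365.25
  if (max(years) == 0) stop("zero time span in VDE window", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, years), mtd)
  list(vde = unname(fit$coefficients[2L]),
       intercept = unname(fit$coefficients[1L]),
       n_scans = length(dates),
       span_days = as.numeric(dates[length(dates)] - dates[1L]))
}

#' Per-window VDE table for a measured cohort
#'
#' For each patient, splits the scan series into treatment-free windows
#' (see [eligible_windows()]) and computes the VDE for both MTD variants:
#' `vde_3d` from the diameter-based `mtd_3d` and `vde_v` from the
#' volume-based `mtd_v`. Also reports the window-mean `mtd_v` (used for the
#' small/large-tumor subgroup split) and the absolute MTD change over the
#' window (used by the concordance sweep).
#'
#' @param measurements `data.frame` with columns `patient_id`, `scan_date`,
#'   `mtd_3d`, `mtd_v` (one row per scan)
#' @param manifest `data.frame` with columns `patient_id`, `scan_date` and
#'   optional event columns `surgery_date`, `chemo_start`, `radio_start`
#' @inheritParams eligible_windows
#' @return `data.frame`, one row per eligible window: `patient_id`, `start`,
#'   `end`, `n_scans`, `vde_3d`, `vde_v`, `mean_mtd_v`, `delta_mtd_v`,
#'   `delta_mtd_3d`
#' @export
vde_table <- function(measurements, manifest, min_span_days = 182,
                      pairwise = FALSE) {
  stopifnot(all(c("patient_id", "scan_date", "mtd_3d", "mtd_v") %in%
                  names(measurements)))
  out <- list()
  for (pid in unique(measurements$patient_id)) {
    mm <- measurements[measurements$patient_id == pid, , drop = FALSE]
    mm <- mm[order(as.Date(mm$scan_date)), , drop = FALSE]
    man <- manifest[manifest$patient_id == pid, , drop = FALSE]
    ev <- character(0)
    for (col in c("surgery_date", "chemo_start", "radio_start")) {
      if (col %in% names(man)) ev <- c(ev, as.character(man[[col]]))
    }
    ev <- unique(ev[!is.na(ev) & nzchar(ev)])
    win <- eligible_windows(as.Date(mm$scan_date), as.Date(ev),
                            min_span_days = min_span_days,
                            pairwise = pairwise)
    win <- win[win$eligible, , drop = FALSE]
    if (!nrow(win)) next
    for (r in seq_len(nrow(win))) {
      idx <- win$scan_index[[r]]
      s3 <- vde_slope(as.Date(mm$scan_date[idx]), mm$mtd_3d[idx])
      sv <- vde_slope(as.Date(mm$scan_date[idx]), mm$mtd_v[idx])
      out[[length(out) + 1L]] <- data.frame(
        patient_id = pid, start = win$start[r], end = win$end[r],
        n_scans = win$n_scans[r],
        vde_3d = s3$vde, vde_v = sv$vde,
        mean_mtd_v = mean(mm$mtd_v[idx]),
        delta_mtd_v = mm$mtd_v[idx[length(idx)]] - mm$mtd_v[idx[1L]],
        delta_mtd_3d = mm$mtd_3d[idx[length(idx)]] - mm$mtd_3d[idx[1L]])
    }
  }
  if (!length(out)) {
    return(data.frame(patient_id = character(), start = as.Date(character()),
                      end = as.Date(character()), n_scans = integer(),
                      vde_3d = numeric(), vde_v = numeric(),
                      mean_mtd_v = numeric(), delta_mtd_v = numeric(),
                      delta_mtd_3d = numeric()))
  }
  do.call(rbind, out)
}
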