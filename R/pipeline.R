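#' Provenance block for a pipeline run
#' @keywords internal
provenance <- function(config, seed = NULL) {
  list(package = "lggrowth",
       version = as.character(utils::packageVersion("lggrowth")),
       config_hash = config_hash(config),
       seed = seed)
}

#' Simulate a synthetic cohort (pipeline step 1)
#'
#' Thin orchestration wrapper around [generate_cohort()]: builds the
#' config, generates the cohort, and writes a provenance block
#' (`provenance.json`: config hash, seed, package version) into the output
#' directory.
#'
#' @param config a [cohort_config()], or a named list of arguments passed
#'   to [cohort_config()]
#' @param out_dir output directory
#' @return invisibly, the [generate_cohort()] result
#' @export
run_simulate <- function(config, out_dir) {
  if (!inherits(config, "cohort_config")) {
    config <- do.call(cohort_config, config)
  }
  res <- generate_cohort(config, out_dir)
  jsonlite::write_json(provenance(unclass(config), seed = config$seed),
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Measure every scan of a cohort (pipeline step 2)
#'
#' Reads each mask listed in the manifest and runs [measure_mask()].
#' Row-level failures (e.g. a missing mask file) do not abort the run;
#' they are collected, reported in a summary warning, and returned in the
#' `failures` attribute.
#'
#' @param manifest a `data.frame` with columns `patient_id`, `scan_date`,
#'   `mask_path` (plus event columns), or the path to such a CSV; relative
#'   mask paths are resolved against the manifest's directory
#' @param out_csv optional path for the measurement CSV
#' @param ... passed on to [measure_mask()] (`thresholds`,
#'   `crossing_tolerance`, `exact`, `slice_gap`)
#' @return `data.frame` with one row per successfully measured scan
#'   (manifest columns + measurement columns); attribute `failures` is a
#'   `data.frame` of failed rows with error messages
#' @export
run_measure <- function(manifest, out_csv = NULL, ...) {
  base_dir <- "."
  if (is.character(manifest)) {
    base_dir <- dirname(manifest)
    manifest <- read.csv(manifest, colClasses = "character")
  }
  stopifnot(all(c("patient_id", "scan_date", "mask_path") %in% names(manifest)))
  if (!nrow(manifest)) {
    warning("empty manifest: returning empty measurement table", call. = FALSE)
  }
  rows <- list(); fails <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, , drop = FALSE]
    path <- row$mask_path
    if (!file.exists(path)) path <- file.path(base_dir, row$mask_path)
    m <- tryCatch({
      if (!file.exists(path)) {
        stop(sprintf("mask file not found: %s", row$mask_path), call. = FALSE)
      }
      mask <- read_lesion_mask(path)
      measure_mask(mask, ...)
    }, error = function(e) e)
    if (inherits(m, "error")) {
      fails[[length(fails) + 1L]] <- data.frame(
        patient_id = row$patient_id, scan_date = row$scan_date,
        mask_path = row$mask_path, error = conditionMessage(m))
    } else {
      rows[[length(rows) + 1L]] <- cbind(row, m, row.names = NULL)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    cbind(manifest[0, , drop = FALSE],
          data.frame(W = numeric(), PW = numeric(), D1 = numeric(),
                     D2 = numeric(), D3 = numeric(), size_1d = numeric(),
                     size_2d = numeric(), size_3d = numeric(),
                     volume_seg = numeric(), measurable_1d = logical(),
                     measurable_2d = logical(), measurable_3d = logical(),
                     mtd_3d = numeric(), mtd_v = numeric(),
                     n_components = integer(), retained_fraction = numeric(),
                     cavity_crossing_fraction = numeric(),
                     flags = character()))
  if (length(fails)) {
    fdf <- do.call(rbind, fails)
    warning(sprintf("%d of %d scans failed to measure (see attr(, 'failures'))",
                    nrow(fdf), nrow(manifest)), call. = FALSE)
    attr(out, "failures") <- fdf
  } else {
    attr(out, "failures") <- NULL
  }
  if (!is.null(out_csv)) write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Assess response and agreement for a measured cohort (pipeline step 3)
#'
#' Runs the full statistical layer on a measurement table: the response
#' table with progression labels ([build_response_table()]), per-method
#' cross-tabulation diagnostics against the segmented-volume truth,
#' ROC-optimal thresholds, per-scan size/MTD agreement, the per-window VDE
#' table with its agreement, subgroup concordance and the minimal-ΔMTD
#' concordance sweep. When `out_dir` is given, tables are written as CSV,
#' reports as JSON, and Bland-Altman / ROC figures as PNG.
#'
#' @param measurements measurement `data.frame` from [run_measure()] (or
#'   the path to its CSV)
#' @param manifest cohort manifest `data.frame` or CSV path
#' @param mode threshold mode, `"rano"` or `"lgg"`
#' @param thresholds a [threshold_config()]
#' @param out_dir optional output directory for CSV/JSON/plots
#' @param pairwise_vde use per-assessment scan pairs instead of maximal
#'   treatment-free windows for the VDE (see [eligible_windows()])
#' @return list with `response` (see [build_response_table()]),
#'   `crosstab` (per-method [crosstab_metrics()]), `roc` (per-method
#'   [roc_optimal_threshold()] or an explanatory `NA` record), `agreement`
#'   (size and MTD [agreement_report()]s), `vde_windows`, `vde_agreement`,
#'   `subgroups`, `sweep`, `provenance`
#' @export
run_assess <- function(measurements, manifest, mode = c("rano", "lgg"),
                       thresholds = threshold_config(), out_dir = NULL,
                       pairwise_vde = FALSE) {
  mode <- match.arg(mode)
  if (is.character(measurements)) measurements <- read.csv(measurements)
  if (is.character(manifest)) {
    manifest <- read.csv(manifest, colClasses = "character")
  }
  resp <- build_response_table(measurements, manifest, thresholds, mode)
  methods <- c("1d", "2d", "3d", "mtd3d")
  crosstab <- list(); roc <- list()
  for (m in methods) {
    tm <- resp$table[resp$table$method == m, , drop = FALSE]
    if (!nrow(tm)) {
      crosstab[[m]] <- NULL
      roc[[m]] <- list(auc = NA_real_, threshold = NA_real_,
                       note = "no retained follow-ups")
      next
    }
    crosstab[[m]] <- crosstab_metrics(tm$label, tm$truth_label)
    roc[[m]] <- tryCatch(
      roc_optimal_threshold(tm$pct_change, tm$truth_label),
      error = function(e) list(auc = NA_real_, threshold = NA_real_,
                               note = conditionMessage(e)))
  }
  safe_agreement <- function(x, y) {
    tryCatch(agreement_report(x, y), error = function(e)
      list(note = paste("agreement unavailable:", conditionMessage(e))))
  }
  agreement <- list(
    size_3d_vs_volume = safe_agreement(measurements$size_3d,
                                       measurements$volume_seg),
    mtd_3d_vs_mtd_v = safe_agreement(measurements$mtd_3d,
                                     measurements$mtd_v))
  vw <- vde_table(measurements, manifest, pairwise = pairwise_vde)
  vde_agreement <- if (nrow(vw) >= 3L) {
    agreement_report(vw$vde_3d, vw$vde_v)
  } else NULL
  subgroups <- if (nrow(vw)) {
    subgroup_concordance(vw, cut = thresholds$mtd_subgroup_cut)
  } else NULL
  sweep <- if (nrow(vw)) vde_concordance_sweep(vw) else NULL
  res <- list(response = resp, crosstab = crosstab, roc = roc,
              agreement = agreement, vde_windows = vw,
              vde_agreement = vde_agreement, subgroups = subgroups,
              sweep = sweep,
              provenance = provenance(list(mode = mode,
                                           thresholds = unclass(thresholds))))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(resp$table, file.path(out_dir, "response_table.csv"),
              row.names = FALSE)
    if (nrow(vw)) {
      write.csv(vw, file.path(out_dir, "vde_windows.csv"), row.names = FALSE)
    }
    report <- list(
      mode = mode,
      exclusions = resp$exclusions, n_followups = resp$n_followups,
      retained = as.list(resp$retained),
      crosstab = lapply(crosstab, unclass),
      roc = lapply(roc, function(r) r[setdiff(names(r), "curve")]),
      agreement = lapply(agreement, unclass),
      vde_agreement = if (!is.null(vde_agreement)) unclass(vde_agreement),
      subgroups = subgroups, sweep = sweep,
      provenance = res$provenance)
    jsonlite::write_json(report, file.path(out_dir, "assessment.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    tryCatch({
      png(file.path(out_dir, "bland_altman_mtd.png"), width = 700,
          height = 550)
      plot_bland_altman(measurements$mtd_3d, measurements$mtd_v,
                        xlab = "mean MTD (mm)",
                        ylab = "MTD.3D - MTD.V (mm)")
      dev.off()
    }, error = function(e) try(dev.off(), silent = TRUE))
    for (m in methods) {
      if (!is.null(roc[[m]]$curve)) {
        png(file.path(out_dir, sprintf("roc_%s.png", m)),
            width = 550, height = 550)
        plot_roc(roc[[m]], main = sprintf("ROC, %s method", m))
        dev.off()
      }
    }
  }
  res
}
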