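#' Configuration for a synthetic longitudinal LGG cohort
#'
#' Describes the study conditions the generator emulates: post-surgical
#' patients followed with imaging every 3 to 6 months over several visits,
#' each lesion an irregular main residue with a resection cavity, up to 3
#' satellite residues, and a patient-specific true velocity of diameter
#' expansion. Defaults reflect a surgically treated LGG population:
#' growth rates mostly in the normal 3-4 mm/year band with occasional
#' post-treatment regression and occasional fast growers approaching the
#' 8 mm/year anaplastic alarm level, every patient with a cavity, and a
#' treated fraction whose chemotherapy/radiotherapy onset splits the VDE
#' windows.
#'
#' @param n_patients number of patients
#' @param scans_per_patient integer range `c(min, max)` of scans per patient
#' @param scan_interval range of days between consecutive scans (90-180
#'   days, i.e. 3 to 6 months)
#' @param voxel_spacing voxel spacing in mm
#' @param image_shape image grid in voxels
#' @param growth_model `"isotropic"` or `"anisotropic"` (growth allocated
#'   to one axis per step, cycling over axes across steps)
#' @param vde_range range of true VDE in mm/year
#' @param vde_values optional explicit true VDE per patient (mm/year,
#'   recycled over patients); overrides `vde_range` when given. Used to
#'   plant known growth-rate distributions in recovery experiments.
#' @param semi_axes_range range (mm) from which each baseline semi-axis is
#'   drawn
#' @param irregularity_range range of the irregularity amplitude
#' @param cavity_prob probability a patient has a visible resection cavity
#' @param max_satellites maximal number of satellite residues (0-3 drawn
#'   uniformly)
#' @param chemo_fraction,radio_fraction fraction of patients with a
#'   chemotherapy / radiotherapy start during follow-up
#' @param start_date first surgery date of the cohort (calendar anchoring
#'   only)
#' @param seed integer RNG seed; the cohort is a pure function of
#'   config + seed
#' @return object of class `cohort_config`
#' @export
cohort_config <- function(n_patients = 10L,
                          scans_per_patient = c(3L, 6L),
                          scan_interval = c(90, 180),
                          voxel_spacing = c(1, 1, 1),
                          image_shape = c(128L, 128L, 128L),
                          growth_model = c("anisotropic", "isotropic"),
                          vde_range = c(-2, 8),
                          vde_values = NULL,
                          semi_axes_range = c(8, 18),
                          irregularity_range = c(0, 0.3),
                          cavity_prob = 1,
                          max_satellites = 3L,
                          chemo_fraction = 0.5,
                          radio_fraction = 0.2,
                          start_date = as.Date("2015-01-01"),
                          seed = 1L) {
  growth_model <- match.arg(growth_model)
  stopifnot(n_patients >= 1, length(scans_per_patient) == 2L,
            scans_per_patient[1] >= 1,
            scans_per_patient[2] >= scans_per_patient[1],
            length(scan_interval) == 2L,
            scan_interval[1] <= scan_interval[2],
            length(voxel_spacing) == 3L, all(voxel_spacing > 0),
            length(image_shape) == 3L, all(image_shape >= 16),
            length(vde_range) == 2L, vde_range[1] <= vde_range[2],
            cavity_prob >= 0, cavity_prob <= 1,
            max_satellites >= 0, max_satellites <= 3,
            chemo_fraction >= 0, chemo_fraction <= 1)
  if (scan_interval[1] < 90 || scan_interval[2] > 180) {
    warning("scan_interval outside the usual 90-180 day follow-up schedule",
            call. = FALSE)
  }
  structure(list(
    n_patients = as.integer(n_patients),
    scans_per_patient = as.integer(scans_per_patient),
    scan_interval = as.numeric(scan_interval),
    voxel_spacing = as.numeric(voxel_spacing),
    image_shape = as.integer(image_shape),
    growth_model = growth_model,
    vde_range = as.numeric(vde_range),
    vde_values = if (!is.null(vde_values)) as.numeric(vde_values),
    semi_axes_range = as.numeric(semi_axes_range),
    irregularity_range = as.numeric(irregularity_range),
    cavity_prob = cavity_prob,
    max_satellites = as.integer(max_satellites),
    chemo_fraction = chemo_fraction,
    radio_fraction = radio_fraction,
    start_date = as_date_strict(start_date, "start_date"),
    seed = as.integer(seed)),
    class = "cohort_config")
}

#' @keywords internal
sample_range <- function(a, b) {
  # uniform integer draw on [a, b]; immune to sample()'s 1:n expansion
  if (a >= b) return(as.integer(a))
  as.integer(a) + sample.int(as.integer(b - a + 1L), 1L) - 1L
}

#' @keywords internal
draw_baseline_spec <- function(config, patient = 1L) {
  shape <- config$image_shape
  sp <- config$voxel_spacing
  extent <- (shape - 1) * sp
  center <- extent / 2 + runif(3, -4, 4)
  axes <- runif(3, config$semi_axes_range[1], config$semi_axes_range[2])
  irr <- runif(1, config$irregularity_range[1], config$irregularity_range[2])
  cavity <- NULL
  if (runif(1) < config$cavity_prob) {
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    off <- runif(1, 0.3, 0.7) * max(axes)
    cav_r <- runif(1, 4, min(10, 0.8 * min(axes)))
    cavity <- list(center = center + dir * off, radius = cav_r)
  }
  sats <- list()
  n_sat <- sample.int(config$max_satellites + 1L, 1L) - 1L
  anchor <- if (is.null(cavity)) center else cavity$center
  anchor_r <- if (is.null(cavity)) max(axes) else cavity$radius
  for (k in seq_len(n_sat)) {
    # satellites sit in a shell around the cavity (or the lesion)
    for (try in 1:8) {
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      sa <- runif(3, 2.5, 6)
      ct <- anchor + dir * (anchor_r + max(sa) + runif(1, 2, 6))
      if (all(ct - max(sa) > 0) && all(ct + max(sa) < extent)) {
        sats[[length(sats) + 1L]] <- list(center = ct, semi_axes = sa)
        break
      }
    }
  }
  lesion_spec(
    center = center, semi_axes = axes,
    orientation = runif(3, 0, pi),
    irregularity_amplitude = irr,
    irregularity_seed = sample.int(.Machine$integer.max, 1L),
    cavity = cavity, satellites = sats,
    true_vde = if (!is.null(config$vde_values)) {
      config$vde_values[(patient - 1L) %% length(config$vde_values) + 1L]
    } else {
      runif(1, config$vde_range[1], config$vde_range[2])
    })
}

#' Generate a synthetic longitudinal lesion cohort on disk
#'
#' Draws per-patient baseline lesions, grows them scan by scan at the
#' patient's true VDE (see [grow_spec()]), voxelizes each timepoint to a
#' NIfTI label mask, and writes the cohort manifest (CSV) and the analytic
#' ground truth (JSON) alongside. A configurable fraction of patients
#' receives a chemotherapy and/or radiotherapy start date placed between
#' two scans, so downstream VDE window exclusion is exercised. The whole
#' cohort is a deterministic function of `config` (including its `seed`).
#'
#' @param config a [cohort_config()]
#' @param out_dir output directory (created if missing); masks go to
#'   `out_dir/masks/`
#' @return invisibly, a list with `manifest` (`data.frame`), `ground_truth`
#'   (nested list, also serialized to `ground_truth.json`), `manifest_path`
#' @export
generate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "cohort_config"))
  mask_dir <- file.path(out_dir, "masks")
  ok <- dir.create(mask_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(mask_dir)) {
    stop(sprintf("cannot create output directory '%s'", out_dir),
         call. = FALSE)
  }
  with_local_seed(config$seed, {
    manifest <- list()
    gt <- list()
    for (p in seq_len(config$n_patients)) {
      pid <- sprintf("P%03d", p)
      surgery <- config$start_date + round(runif(1, 0, 60))
      n_scans <- sample_range(config$scans_per_patient[1],
                              config$scans_per_patient[2])
      scan_dates <- surgery + round(runif(1, 30, 90)) +
        c(0, cumsum(round(runif(max(0L, n_scans - 1L),
                                config$scan_interval[1],
                                config$scan_interval[2]))))
      chemo <- radio <- NA
      if (n_scans >= 3L && runif(1) < config$chemo_fraction) {
        k <- sample_range(2L, n_scans - 1L)
        chemo <- scan_dates[k] +
          round(as.numeric(scan_dates[k + 1L] - scan_dates[k]) / 2)
      }
      if (n_scans >= 3L && runif(1) < config$radio_fraction) {
        k <- sample_range(2L, n_scans - 1L)
        radio <- scan_dates[k] +
          round(as.numeric(scan_dates[k + 1L] - scan_dates[k]) / 3)
      }
      spec <- draw_baseline_spec(config, patient = p)
      scans <- list()
      cur <- spec
      for (s in seq_len(n_scans)) {
        if (s > 1L) {
          dt <- as.numeric(scan_dates[s] - scan_dates[s - 1L]) / 365.25
          cur <- grow_spec(cur, dt, mode = config$growth_model,
                           axis = ((s - 2L) %% 3L) + 1L)
        }
        mask <- generate_lesion_mask(cur, spacing = config$voxel_spacing,
                                     shape = config$image_shape)
        fname <- sprintf("%s_%s.nii.gz", pid, format(scan_dates[s]))
        write_lesion_mask(mask, file.path(mask_dir, fname))
        manifest[[length(manifest) + 1L]] <- data.frame(
          patient_id = pid, scan_date = format(scan_dates[s]),
          mask_path = file.path("masks", fname),
          surgery_date = format(surgery),
          chemo_start = if (is.na(chemo)) "" else format(chemo),
          radio_start = if (is.na(radio)) "" else format(radio))
        scans[[s]] <- list(scan_date = format(scan_dates[s]),
                           true_volume_ml = true_volume(cur),
                           true_diameters_mm = true_diameters(cur),
                           true_mtd_mm = true_mtd(cur))
      }
      v0 <- scans[[1L]]$true_volume_ml
      for (s in seq_along(scans)) {
        scans[[s]]$true_progression <-
          s > 1L && (scans[[s]]$true_volume_ml - v0) / v0 >= 0.40
      }
      gt[[pid]] <- list(patient_id = pid, true_vde = spec$true_vde,
                        surgery_date = format(surgery), scans = scans)
    }
    manifest <- do.call(rbind, manifest)
    manifest_path <- file.path(out_dir, "manifest.csv")
    write.csv(manifest, manifest_path, row.names = FALSE, quote = FALSE)
    jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(list(manifest = manifest, ground_truth = gt,
                   manifest_path = manifest_path))
  })
}
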