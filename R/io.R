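#' Read a PET study from NIfTI files
#'
#' Loads an SUV volume plus tumor and muscle masks, validating that all three
#' share dimensions and affine (within `affine_tol`). Nonzero mask values are
#' coerced to membership; negative SUV values, shape mismatches, affine
#' mismatches and empty masks are distinct hard errors (resampling is out of
#' scope).
#'
#' @param suv_path,tumor_mask_path,muscle_mask_path NIfTI files (.nii or
#'   .nii.gz).
#' @param subject_id,day,injected_activity,body_weight scan metadata.
#' @param affine_tol maximum absolute elementwise affine difference.
#' @return A [pet_study()].
#' @export
read_pet_study <- function(suv_path, tumor_mask_path, muscle_mask_path,
                           subject_id = "subject", day = 0L,
                           injected_activity = NULL, body_weight = NULL,
                           affine_tol = 1e-4) {
  for (p in c(suv_path, tumor_mask_path, muscle_mask_path)) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
  }
  suv_img <- RNifti::readNifti(suv_path)
  tum_img <- RNifti::readNifti(tumor_mask_path)
  mus_img <- RNifti::readNifti(muscle_mask_path)
  ref_affine <- RNifti::xform(suv_img)
  for (nm in c("tumor", "muscle")) {
    img <- if (nm == "tumor") tum_img else mus_img
    if (!identical(dim(img), dim(suv_img))) {
      stop(sprintf("%s mask shape (%s) does not match SUV volume shape (%s)",
                   nm, paste(dim(img), collapse = "x"),
                   paste(dim(suv_img), collapse = "x")), call. = FALSE)
    }
    aff <- RNifti::xform(img)
    if (max(abs(aff - ref_affine)) > affine_tol) {
      stop(sprintf(
        "%s mask affine does not match the SUV affine within %g:\nSUV affine:\n%s\nmask affine:\n%s",
        nm, affine_tol,
        paste(apply(ref_affine, 1, paste, collapse = " "), collapse = "\n"),
        paste(apply(aff, 1, paste, collapse = " "), collapse = "\n")),
        call. = FALSE)
    }
  }
  if (any(suv_img < 0)) {
    stop("SUV volume contains negative values", call. = FALSE)
  }
  vox <- attr(suv_img, "pixdim")[1:3]
  pet_study(array(as.numeric(suv_img), dim(suv_img)),
            as_mask(array(as.numeric(tum_img), dim(tum_img))),
            as_mask(array(as.numeric(mus_img), dim(mus_img))),
            subject_id = subject_id, day = day, voxel_size = vox,
            injected_activity = injected_activity, body_weight = body_weight)
}

#' Write a PET study as NIfTI volumes plus a JSON sidecar
#'
#' Writes the SUV volume and both masks as separate `.nii.gz` files sharing
#' one affine built from the study's voxel size, and echoes the metadata to a
#' JSON sidecar for provenance.
#'
#' @param study a [pet_study()].
#' @param dir output directory (created if needed).
#' @param prefix file stem; defaults to `subject_day<d>`.
#' @return Character vector of the four written paths (suv, tumor mask,
#'   muscle mask, sidecar), invisibly.
#' @export
write_pet_study <- function(study, dir,
                            prefix = sprintf("%s_day%02d", study$subject_id,
                                             study$day)) {
  stopifnot(inherits(study, "pet_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(prefix, c("_suv.nii.gz", "_tumor_mask.nii.gz",
                                           "_muscle_mask.nii.gz", "_meta.json")))
  imgs <- list(study$suv, study$tumor_mask * 1L, study$muscle_mask * 1L)
  for (i in 1:3) {
    img <- RNifti::asNifti(imgs[[i]])
    img <- RNifti::`pixdim<-`(img, study$voxel_size)
    RNifti::writeNifti(img, paths[i])
  }
  meta <- list(subject_id = study$subject_id, day = study$day,
               voxel_size_mm = study$voxel_size,
               injected_activity_bq = study$injected_activity,
               body_weight_g = study$body_weight)
  jsonlite::write_json(meta, paths[4], auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}

#' Write analysis results with a provenance manifest
#'
#' Writes each table as CSV, each histogram set via [histogram_report()],
#' each classification's masks as NIfTI, then a JSON manifest listing every
#' written file exactly once with its MD5 checksum, alongside the seed,
#' package version and a config echo sufficient to re-run bit-identically.
#' File naming is deterministic, so a rerun with the same inputs produces
#' byte-identical output.
#'
#' @param out_dir output directory.
#' @param tables named list of data.frames.
#' @param histograms named list of lists of [fractional_histogram()] objects
#'   (one CSV/plot pair per entry).
#' @param classifications named list of `proliferative_classification`
#'   objects; their masks are written as NIfTI.
#' @param config list echoed into the manifest.
#' @param seed the run seed, echoed into the manifest.
#' @param plots also write PNG plots for histogram sets.
#' @return The manifest list, invisibly.
#' @export
write_results <- function(out_dir, tables = list(), histograms = list(),
                          classifications = list(), config = NULL,
                          seed = NULL, plots = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (nm in names(tables)) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    tryCatch(utils::write.csv(tables[[nm]], f, row.names = FALSE),
             error = function(e) stop(sprintf("failed writing %s: %s", f,
                                              conditionMessage(e)), call. = FALSE))
    written <- c(written, f)
  }
  for (nm in names(histograms)) {
    rep <- histogram_report(histograms[[nm]], out_dir = out_dir,
                            basename = nm, plot = plots)
    written <- c(written, rep$files)
  }
  for (nm in names(classifications)) {
    cls <- classifications[[nm]]
    for (part in c("proliferative", "necrotic")) {
      f <- file.path(out_dir, sprintf("%s_%s_mask.nii.gz", nm, part))
      RNifti::writeNifti(RNifti::asNifti(cls[[paste0(part, "_mask")]] * 1L), f)
      written <- c(written, f)
    }
  }
  manifest <- list(
    package = "pethet",
    version = as.character(utils::packageVersion("pethet")),
    seed = seed,
    config = config,
    files = lapply(written, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    }))
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}

#' Pipeline run configuration
#'
#' Collects the tunable parameters of [run_pipeline()] and validates them.
#'
#' @param seed master RNG seed for the simulated study.
#' @param out_dir output directory.
#' @param bin_width histogram bin width in SUV, > 0.
#' @param threshold_sd_multiplier muscle-SD multiplier for the proliferative
#'   threshold, >= 0 (default 2).
#' @param ks_voxels `"all"` or `"proliferative"`: which tumor voxels enter
#'   the KS comparisons.
#' @param alpha significance level used in reports, in (0, 1).
#' @param n_per_arm simulated animals per imaging arm.
#' @param imaging_days baseline and follow-up day of the simulated PET study.
#' @param arm_suppression named day-10 suppression factor per arm, each in
#'   (0, 1\].
#' @param grid_shape phantom grid passed to [phantom_spec()].
#' @param plots write PNG figures alongside the CSVs.
#' @return A validated `run_config` list.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("pethet_run_"),
                       bin_width = 0.1, threshold_sd_multiplier = 2,
                       ks_voxels = c("all", "proliferative"), alpha = 0.05,
                       n_per_arm = 4L, imaging_days = c(0L, 10L),
                       arm_suppression = c(vehicle = 1, trastuzumab = 0.8,
                                           niraparib = 0.85, combination = 0.7),
                       grid_shape = c(48L, 48L, 48L), plots = TRUE) {
  ks_voxels <- match.arg(ks_voxels)
  assert_scalar_number(bin_width, "bin_width", 0, strict_lower = TRUE)
  assert_scalar_number(threshold_sd_multiplier, "threshold_sd_multiplier", 0)
  assert_scalar_number(alpha, "alpha", 0, 1, strict_lower = TRUE,
                       strict_upper = TRUE)
  if (length(imaging_days) != 2L || diff(imaging_days) <= 0) {
    stop("`imaging_days` must be two strictly increasing days", call. = FALSE)
  }
  if (is.null(names(arm_suppression)) || any(arm_suppression <= 0) ||
      any(arm_suppression > 1)) {
    stop("`arm_suppression` must be a named vector with values in (0, 1]",
         call. = FALSE)
  }
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 bin_width = bin_width,
                 threshold_sd_multiplier = threshold_sd_multiplier,
                 ks_voxels = ks_voxels, alpha = alpha,
                 n_per_arm = as.integer(n_per_arm),
                 imaging_days = as.integer(imaging_days),
                 arm_suppression = arm_suppression,
                 grid_shape = as.integer(grid_shape), plots = plots),
            class = "run_config")
}

#' Run the full analysis pipeline on a simulated study
#'
#' End-to-end orchestration: simulate a multi-arm longitudinal PET study,
#' quantify every scan (ROI summaries, muscle-referenced threshold, voxel
#' classification), build cohort fractional histograms and KS comparisons
#' (baseline vs follow-up within each arm, and each arm vs vehicle at
#' follow-up), simulate and analyze a caliper growth cohort, analyze a
#' synthetic in-vitro assay set (dose response, percent survival, assay
#' percent changes, biomarker-viability regression), and write all artifacts
#' plus a provenance manifest. Identical config and seed yield byte-identical
#' output.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the in-memory results of every stage plus
#'   the manifest.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  arms <- names(config$arm_suppression)
  seeds <- derive_seeds(config$seed, length(arms) * config$n_per_arm + 2L)
  growth_seed <- seeds[length(seeds) - 1L]
  plate_seed <- seeds[length(seeds)]

  message("stage simulate+quantify: ", length(arms), " arms x ",
          config$n_per_arm, " animals x 2 timepoints")
  studies <- list()  # studies[[arm]][[animal]] = list of 2 pet_study
  quant_rows <- list()
  si <- 0L
  for (arm in arms) {
    studies[[arm]] <- vector("list", config$n_per_arm)
    for (i in seq_len(config$n_per_arm)) {
      si <- si + 1L
      spec <- phantom_spec(seed = seeds[si], grid_shape = config$grid_shape)
      tp <- data.frame(day = config$imaging_days,
                       suppression = c(1, config$arm_suppression[[arm]]))
      series <- generate_longitudinal_study(
        spec, tp, subject_id = sprintf("%s_%02d", arm, i))
      studies[[arm]][[i]] <- series
      for (st in series) {
        q <- quantify_study(st, config$threshold_sd_multiplier)
        quant_rows[[length(quant_rows) + 1L]] <- data.frame(
          subject_id = st$subject_id, arm = arm, day = st$day,
          tumor_mean = q$tumor$mean, tumor_sd = q$tumor$sd,
          tumor_max = q$tumor$max, tumor_n = q$tumor$n_voxels,
          muscle_mean = q$muscle$mean, muscle_sd = q$muscle$sd,
          threshold = q$threshold,
          proliferative_fraction = q$classification$proliferative_fraction,
          proliferative_mean = if (q$classification$empty) NA_real_ else
            q$classification$proliferative_summary$mean)
      }
    }
  }
  quant_table <- do.call(rbind, quant_rows)

  message("stage heterogeneity: histograms and KS comparisons")
  d0 <- config$imaging_days[1]; dT <- config$imaging_days[2]
  pick <- function(arm, day) {
    lapply(studies[[arm]], function(series) {
      series[[which(vapply(series, function(s) s$day, 0L) == day)]]
    })
  }
  pooled_voxels <- function(study_list) {
    unlist(lapply(study_list, function(s) {
      if (config$ks_voxels == "all") s$suv[s$tumor_mask]
      else {
        q <- quantify_study(s, config$threshold_sd_multiplier)
        s$suv[q$classification$proliferative_mask]
      }
    }))
  }
  all_vox <- unlist(lapply(arms, function(a) {
    c(pooled_voxels(pick(a, d0)), pooled_voxels(pick(a, dT)))
  }))
  edges <- suv_bin_edges(all_vox, config$bin_width)
  hists <- list()
  for (arm in arms) {
    for (d in c(d0, dT)) {
      hists[[sprintf("%s_day%02d", arm, d)]] <-
        fractional_histogram(pooled_voxels(pick(arm, d)), edges,
                             source_id = sprintf("%s day %d", arm, d))
    }
  }
  ks_rows <- list()
  for (arm in arms) {
    ks <- longitudinal_ks(pick(arm, d0), pick(arm, dT),
                          voxels = config$ks_voxels,
                          sd_multiplier = config$threshold_sd_multiplier)
    ks_rows[[length(ks_rows) + 1L]] <- data.frame(
      comparison = sprintf("%s_day%d_vs_day%d", arm, d0, dT),
      D = ks$distance, p_value = ks$p_value, n1 = ks$n1, n2 = ks$n2,
      method = ks$method)
  }
  vehicle <- arms[1]
  for (arm in setdiff(arms, vehicle)) {
    ks <- longitudinal_ks(pick(arm, dT), pick(vehicle, dT),
                          voxels = config$ks_voxels,
                          sd_multiplier = config$threshold_sd_multiplier)
    ks_rows[[length(ks_rows) + 1L]] <- data.frame(
      comparison = sprintf("%s_vs_%s_day%d", arm, vehicle, dT),
      D = ks$distance, p_value = ks$p_value, n1 = ks$n1, n2 = ks$n2,
      method = ks$method)
  }
  ks_table <- do.call(rbind, ks_rows)

  message("stage growth: caliper cohort analysis")
  cohort <- generate_growth_cohort(seed = growth_seed)
  growth <- growth_report(cohort, alpha = config$alpha)

  message("stage invitro: plate assays and regression")
  invitro <- run_invitro_stage(plate_seed)

  message("stage report: writing artifacts to ", config$out_dir)
  final_day <- max(cohort$day)
  tables <- c(list(
    suv_quantification = quant_table,
    ks_comparisons = ks_table,
    growth_summary = growth$summary,
    growth_comparisons = growth$comparisons,
    growth_vehicle_normalized = normalize_to_vehicle(cohort, day = final_day)),
    invitro$tables)
  cfg_echo <- unclass(config)
  cfg_echo$out_dir <- NULL  # path is machine-local, not part of provenance
  manifest <- write_results(config$out_dir, tables = tables,
                            histograms = list(fractional_histograms = hists),
                            config = cfg_echo, seed = config$seed,
                            plots = config$plots)
  invisible(list(quantification = quant_table, histograms = hists,
                 ks = ks_table, growth = growth, invitro = invitro,
                 cohort = cohort, manifest = manifest))
}

# In-vitro stage: dose-response viability, fixed-dose survival, 2DG/EdU
# percent changes, and the biomarker-vs-endpoint regression, all from seeded
# synthetic plates. Mean fractions mirror a trastuzumab/niraparib combination
# experiment at 48 h (viability 0.60/0.85/0.42 of control; 2DG 0.542/0.767/
# 0.385; EdU 0.325/0.771/0.203). The 2DG channel carries much larger
# well-to-well spread than EdU: glucose-uptake shifts of this size were not
# statistically resolvable at five replicates, so its noise is set high
# enough that rank tests at n = 5 usually stay nonsignificant.
run_invitro_stage <- function(seed) {
  seeds <- derive_seeds(seed, 4L)
  dose_conditions <- data.frame(
    label = c("control", rep("trastuzumab", 4)),
    dose = c(0, 0.1, 1, 10, 100),
    dose_unit = c(NA, rep("ug/mL", 4)),
    mean_signal_fraction = c(1, 0.9, 0.6, 0.5, 0.45),
    sd = c(0.05, 0.06, 0.05, 0.05, 0.05))
  dose_plate <- generate_plate(seeds[1], dose_conditions)
  dose_tab <- dose_response_table(dose_plate, "trastuzumab")

  viab <- generate_plate(seeds[2], channel = "viability_gfp")
  edu <- generate_plate(seeds[3], conditions = local({
    cc <- default_plate_conditions()
    cc$mean_signal_fraction <- c(1, 0.325, 0.771, 0.203)
    cc$sd <- c(0.05, 0.0327, 0.0489, 0.0148)
    cc
  }), channel = "proliferation_edu")
  tdg <- generate_plate(seeds[4], conditions = local({
    cc <- default_plate_conditions()
    cc$mean_signal_fraction <- c(1, 0.542, 0.767, 0.385)
    cc$sd <- c(0.10, 0.25, 0.28, 0.22)
    cc
  }), channel = "glucose_2dg")

  conds <- c("trastuzumab", "niraparib", "combination")
  ctrl <- function(plate) plate$signal[plate$condition == "control"]
  survival_rows <- do.call(rbind, lapply(conds, function(cn) {
    ps <- percent_survival(viab$signal[viab$condition == cn], ctrl(viab))
    data.frame(condition = cn, percent_survival = ps$percent, sd = ps$sd,
               n = ps$n)
  }))
  change_rows <- do.call(rbind, lapply(conds, function(cn) {
    rbind(
      data.frame(condition = cn, channel = "proliferation_edu",
                 percent_change = assay_percent_change(
                   edu$signal[edu$condition == cn], ctrl(edu))$percent_change,
                 sd = assay_percent_change(
                   edu$signal[edu$condition == cn], ctrl(edu))$sd),
      data.frame(condition = cn, channel = "glucose_2dg",
                 percent_change = assay_percent_change(
                   tdg$signal[tdg$condition == cn], ctrl(tdg))$percent_change,
                 sd = assay_percent_change(
                   tdg$signal[tdg$condition == cn], ctrl(tdg))$sd))
  }))

  # per-well pairing (condition x replicate) of the 48 h proliferation
  # biomarker against endpoint viability across all conditions
  key <- function(p) paste(p$condition, p$replicate)
  m <- match(key(edu), key(viab))
  reg <- biomarker_viability_regression(edu$signal, viab$signal[m])
  reg_row <- data.frame(biomarker = "proliferation_edu",
                        slope = reg$slope, intercept = reg$intercept,
                        r_squared = reg$r_squared, p_value = reg$p_value,
                        n = reg$n)
  m2 <- match(key(tdg), key(viab))
  reg2 <- biomarker_viability_regression(tdg$signal, viab$signal[m2])
  reg_row <- rbind(reg_row,
                   data.frame(biomarker = "glucose_2dg", slope = reg2$slope,
                              intercept = reg2$intercept,
                              r_squared = reg2$r_squared,
                              p_value = reg2$p_value, n = reg2$n))
  list(tables = list(invitro_dose_response = dose_tab,
                     invitro_percent_survival = survival_rows,
                     invitro_percent_change = change_rows,
                     invitro_regression = reg_row),
       regression = list(proliferation_edu = reg, glucose_2dg = reg2))
}
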