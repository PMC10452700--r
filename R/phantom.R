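#' Specification for a synthetic FLT-PET tumor phantom
#'
#' Describes the geometry and intensity model of a digital phantom emulating a
#' heterogeneous xenograft tumor: an ellipsoidal tumor with a concentric
#' necrotic core at low SUV (default mean 0.4) occupying `necrotic_fraction`
#' of tumor voxels, a viable high-uptake rim, and a separate cuboid of
#' reference muscle. Voxel intensities are independent Gaussian draws per
#' region, clipped at 0; no spatial autocorrelation is modeled.
#'
#' The default necrotic fraction (0.45) sits mid-range of the 30--60% necrotic
#' cores typical of aggressive patient-derived xenografts. Viable-rim and
#' muscle levels are modeling assumptions chosen so the rim is clearly
#' separable from muscle background (see the package vignette).
#'
#' @param seed integer RNG seed; identical specs produce bit-identical phantoms.
#' @param grid_shape integer length-3, voxel grid dimensions.
#' @param voxel_size numeric length-3, voxel edge lengths in mm.
#' @param necrotic_fraction fraction of tumor voxels in the necrotic core, in
#'   \[0, 1\].
#' @param necrotic_suv_mean,necrotic_suv_sd SUV distribution of necrotic voxels.
#' @param viable_suv_mean,viable_suv_sd SUV distribution of viable-rim voxels
#'   (before suppression).
#' @param muscle_suv_mean,muscle_suv_sd SUV distribution of reference muscle.
#' @param suppression multiplicative factor in (0, 1\] applied to the viable
#'   mean, modeling a treatment-induced downward shift of proliferative
#'   uptake; necrotic SUV is treatment-invariant.
#' @param tumor_axis_frac tumor ellipsoid semi-axes as a fraction of each grid
#'   half-extent. The default (0.72) gives roughly 50,000 tumor voxels on the
#'   default 64^3 grid.
#'
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()], [generate_longitudinal_study()]
#' @export
phantom_spec <- function(seed = 1L,
                         grid_shape = c(64L, 64L, 64L),
                         voxel_size = c(0.5, 0.5, 0.5),
                         necrotic_fraction = 0.45,
                         necrotic_suv_mean = 0.4, necrotic_suv_sd = 0.05,
                         viable_suv_mean = 1.2, viable_suv_sd = 0.2,
                         muscle_suv_mean = 0.5, muscle_suv_sd = 0.05,
                         suppression = 1,
                         tumor_axis_frac = 0.72) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(is.na(grid_shape)) || any(grid_shape < 1L)) {
    stop("`grid_shape` must be three positive integers", call. = FALSE)
  }
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    stop("`voxel_size` must be three positive lengths (mm)", call. = FALSE)
  }
  assert_scalar_number(necrotic_fraction, "necrotic_fraction", 0, 1)
  assert_scalar_number(necrotic_suv_mean, "necrotic_suv_mean", 0, strict_lower = TRUE)
  assert_scalar_number(viable_suv_mean, "viable_suv_mean", 0, strict_lower = TRUE)
  assert_scalar_number(muscle_suv_mean, "muscle_suv_mean", 0, strict_lower = TRUE)
  assert_scalar_number(necrotic_suv_sd, "necrotic_suv_sd", 0)
  assert_scalar_number(viable_suv_sd, "viable_suv_sd", 0)
  assert_scalar_number(muscle_suv_sd, "muscle_suv_sd", 0)
  assert_scalar_number(suppression, "suppression", 0, 1, strict_lower = TRUE)
  assert_scalar_number(tumor_axis_frac, "tumor_axis_frac", 0, 1, strict_lower = TRUE)
  structure(list(seed = as.integer(seed), grid_shape = grid_shape,
                 voxel_size = as.numeric(voxel_size),
                 necrotic_fraction = necrotic_fraction,
                 necrotic_suv_mean = necrotic_suv_mean,
                 necrotic_suv_sd = necrotic_suv_sd,
                 viable_suv_mean = viable_suv_mean,
                 viable_suv_sd = viable_suv_sd,
                 muscle_suv_mean = muscle_suv_mean,
                 muscle_suv_sd = muscle_suv_sd,
                 suppression = suppression,
                 tumor_axis_frac = tumor_axis_frac),
            class = "phantom_spec")
}

# Geometry shared by all phantoms from one spec: tumor/necrotic/viable/muscle
# masks depend only on the grid, not on the RNG, so a longitudinal series
# keeps identical anatomy across timepoints.
phantom_geometry <- function(spec) {
  dims <- spec$grid_shape
  ctr <- (dims + 1) / 2
  semi <- spec$tumor_axis_frac * dims / 2
  if (any(semi < 3)) {
    stop("grid too small: tumor semi-axes fall below 3 voxels", call. = FALSE)
  }
  ax <- ((seq_len(dims[1]) - ctr[1]) / semi[1])^2
  ay <- ((seq_len(dims[2]) - ctr[2]) / semi[2])^2
  az <- ((seq_len(dims[3]) - ctr[3]) / semi[3])^2
  r2 <- outer(outer(ax, ay, "+"), az, "+")  # squared ellipsoidal radius
  tumor <- r2 <= 1

  # Reference muscle: fixed cuboid near the low corner, one-eighth of each
  # grid extent; anatomy is irrelevant to the statistics, disjointness is not.
  msz <- pmax(4L, as.integer(round(dims / 8)))
  m_from <- c(2L, 2L, 2L)
  m_to <- m_from + msz - 1L
  if (any(m_to > dims)) {
    stop("grid too small to place the muscle reference region", call. = FALSE)
  }
  muscle <- array(FALSE, dims)
  muscle[m_from[1]:m_to[1], m_from[2]:m_to[2], m_from[3]:m_to[3]] <- TRUE
  if (any(tumor & muscle)) {
    stop("grid too small: tumor ellipsoid overlaps the muscle region", call. = FALSE)
  }

  # Concentric necrotic core: the necrotic_fraction innermost tumor voxels by
  # ellipsoidal radius, so the realized fraction is exact to within one voxel.
  tumor_idx <- which(tumor)
  n_tumor <- length(tumor_idx)
  k <- as.integer(round(spec$necrotic_fraction * n_tumor))
  necrotic <- array(FALSE, dims)
  if (k > 0L) {
    ord <- order(r2[tumor_idx])
    necrotic[tumor_idx[ord[seq_len(k)]]] <- TRUE
  }
  viable <- tumor & !necrotic
  list(tumor = tumor, necrotic = necrotic, viable = viable, muscle = muscle)
}

#' Generate a synthetic PET phantom with ground truth
#'
#' Builds an SUV volume in which the necrotic core, viable rim, and reference
#' muscle each draw voxel values independently from their region's normal
#' distribution (the viable mean scaled by `spec$suppression`); negative draws
#' are clipped to 0. The same spec always yields bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @param subject_id,day metadata stamped on the returned study.
#'
#' @return A list with components `study` (a [pet_study()]) and `truth`
#'   (class `ground_truth`: `necrotic_mask`, `viable_mask`, and
#'   `true_proliferative_fraction`, the viable fraction of tumor voxels).
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 7, grid_shape = c(24, 24, 24)))
#' ph$truth$true_proliferative_fraction
#' @export
generate_phantom <- function(spec, subject_id = "phantom", day = 0L) {
  stopifnot(inherits(spec, "phantom_spec"))
  geo <- phantom_geometry(spec)
  suv <- array(0, spec$grid_shape)
  with_seed(spec$seed, {
    suv[geo$necrotic] <- stats::rnorm(sum(geo$necrotic),
                                      spec$necrotic_suv_mean, spec$necrotic_suv_sd)
    suv[geo$viable] <- stats::rnorm(sum(geo$viable),
                                    spec$suppression * spec$viable_suv_mean,
                                    spec$viable_suv_sd)
    suv[geo$muscle] <- stats::rnorm(sum(geo$muscle),
                                    spec$muscle_suv_mean, spec$muscle_suv_sd)
  })
  suv[suv < 0] <- 0
  study <- pet_study(suv, geo$tumor, geo$muscle, subject_id = subject_id,
                     day = day, voxel_size = spec$voxel_size)
  truth <- structure(
    list(necrotic_mask = geo$necrotic, viable_mask = geo$viable,
         true_proliferative_fraction = sum(geo$viable) / sum(geo$tumor)),
    class = "ground_truth")
  list(study = study, truth = truth)
}

#' Generate a longitudinal phantom series for one animal
#'
#' One phantom per timepoint, sharing tumor/muscle geometry, with the viable
#' mean scaled by each timepoint's suppression factor. Per-timepoint noise
#' seeds are derived deterministically from `spec$seed`, so the series is
#' reproducible while each scan gets independent noise.
#'
#' @param spec a [phantom_spec()] (its `suppression` field is ignored in favor
#'   of the per-timepoint values).
#' @param timepoints data.frame (or list of pairs) with columns `day`
#'   (strictly increasing integers) and `suppression` (each in (0, 1\]). The
#'   default mirrors a baseline/day-10 imaging design.
#' @param subject_id identifier shared by the series.
#'
#' @return List of [pet_study()] objects, one per timepoint, with the shared
#'   `ground_truth` attached as attribute `"truth"`.
#' @export
generate_longitudinal_study <- function(spec,
                                        timepoints = data.frame(
                                          day = c(0L, 10L),
                                          suppression = c(1, 1)),
                                        subject_id = "subject") {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.list(timepoints) && !is.data.frame(timepoints)) {
    timepoints <- do.call(rbind, lapply(timepoints, function(tp) {
      data.frame(day = tp[[1]], suppression = tp[[2]])
    }))
  }
  if (NROW(timepoints) == 0L) {
    stop("`timepoints` must contain at least one (day, suppression) row",
         call. = FALSE)
  }
  days <- timepoints$day
  supp <- timepoints$suppression
  if (any(diff(days) <= 0)) stop("days must be strictly increasing", call. = FALSE)
  if (any(supp <= 0 | supp > 1)) {
    stop("suppression values must lie in (0, 1]", call. = FALSE)
  }
  sub_seeds <- derive_seeds(spec$seed, NROW(timepoints))
  truth <- NULL
  studies <- vector("list", NROW(timepoints))
  for (i in seq_len(NROW(timepoints))) {
    sp <- spec
    sp$seed <- sub_seeds[i]
    sp$suppression <- supp[i]
    ph <- generate_phantom(sp, subject_id = subject_id, day = days[i])
    studies[[i]] <- ph$study
    if (is.null(truth)) truth <- ph$truth
  }
  attr(studies, "truth") <- truth
  studies
}

#' Generate a synthetic four-arm xenograft growth cohort
#'
#' Simulates longitudinal caliper measurements for a treatment study. Each
#' animal enrolls at a baseline volume drawn uniformly from the 125--300 mm^3
#' window and then grows multiplicatively: at every assessment the volume is
#' scaled by `1 + N(mean_pct_change, sd_pct_change)/100` (floored at 1% of the
#' previous volume so volumes stay positive). Perpendicular lengths L1 = L2
#' are back-computed from the volume via the caliper formula.
#'
#' The default arms emulate a four-arm vehicle / trastuzumab / niraparib /
#' combination design whose per-assessment growth rates compound, over six
#' assessments, to endpoint percent changes of roughly +117 / +43 / +22 /
#' -32% with spreads comparable to an in-vivo cohort.
#'
#' @param seed integer RNG seed.
#' @param arms data.frame with columns `name`, `mean_pct_change` (percent per
#'   assessment) and `sd_pct_change` (percent, >= 0).
#' @param n_per_arm animals per arm (>= 1).
#' @param n_assessments number of post-baseline assessments.
#' @param assessment_interval_days days between assessments.
#' @param baseline_range enrollment volume window in mm^3.
#'
#' @return A `cohort_table`: data.frame with columns `subject_id`, `arm`,
#'   `day`, `L1`, `L2`, `volume` and attribute `arms`.
#' @export
generate_growth_cohort <- function(seed = 1L,
                                   arms = default_growth_arms(),
                                   n_per_arm = 5L,
                                   n_assessments = 6L,
                                   assessment_interval_days = 3L,
                                   baseline_range = c(125, 300)) {
  stopifnot(is.data.frame(arms),
            all(c("name", "mean_pct_change", "sd_pct_change") %in% names(arms)))
  if (n_per_arm < 1L) stop("`n_per_arm` must be >= 1", call. = FALSE)
  if (any(arms$sd_pct_change < 0)) stop("arm sd must be >= 0", call. = FALSE)
  days <- seq(0L, by = as.integer(assessment_interval_days),
              length.out = n_assessments + 1L)
  rows <- with_seed(seed, {
    out <- list()
    for (a in seq_len(nrow(arms))) {
      for (i in seq_len(n_per_arm)) {
        sid <- sprintf("%s_%02d", arms$name[a], i)
        vol <- stats::runif(1, baseline_range[1], baseline_range[2])
        vols <- numeric(length(days))
        vols[1] <- vol
        for (t in seq_len(n_assessments)) {
          g <- 1 + stats::rnorm(1, arms$mean_pct_change[a],
                                arms$sd_pct_change[a]) / 100
          vols[t + 1] <- vols[t] * max(g, 0.01)
        }
        # invert the caliper formula under L1 = L2 = L: V = (pi/6) L^3
        L <- (6 * vols / pi)^(1 / 3)
        out[[length(out) + 1L]] <- data.frame(
          subject_id = sid, arm = arms$name[a], day = days,
          L1 = L, L2 = L, volume = vols)
      }
    }
    do.call(rbind, out)
  })
  rownames(rows) <- NULL
  cohort_table(rows, arms = arms$name)
}

#' Default treatment arms for the synthetic growth cohort
#'
#' Per-assessment growth rates chosen so that six assessments compound to
#' endpoint percent changes typical of a vehicle-controlled trastuzumab /
#' niraparib / combination study (about +117, +43, +22 and -32%).
#'
#' @return data.frame with columns `name`, `mean_pct_change`, `sd_pct_change`.
#' @export
default_growth_arms <- function() {
  data.frame(
    name = c("vehicle", "trastuzumab", "niraparib", "combination"),
    mean_pct_change = c(13.8, 6.1, 3.3, -6.3),
    sd_pct_change = c(11.5, 7.0, 13.0, 16.0))
}

#' Generate a synthetic assay plate
#'
#' Simulates per-well signals for a plate assay. Each condition's wells draw
#' from Normal(mean_signal_fraction x control_signal, sd x control_signal),
#' clipped at 0. A control condition (mean fraction 1) must be present. The
#' default conditions emulate a 48 h combination-therapy viability experiment
#' in which trastuzumab, niraparib, and the combination reduce survival to
#' about 60%, 85%, and 42% of control.
#'
#' @param seed integer RNG seed.
#' @param conditions data.frame with columns `label`, `dose`, `dose_unit`,
#'   `mean_signal_fraction` (>= 0) and `sd` (fraction of control signal, >= 0).
#' @param n_replicates wells per condition (>= 1; default 5, the study-design
#'   minimum replicate count).
#' @param control_label which condition is the control; must appear in
#'   `conditions` with all signals interpretable relative to it.
#' @param control_signal arbitrary-unit signal level of the control mean.
#' @param timepoint_h,channel metadata stamped on every well; `channel` is one
#'   of `"viability_gfp"`, `"glucose_2dg"`, `"proliferation_edu"`.
#'
#' @return An `assay_plate`: data.frame of wells with columns `condition`,
#'   `dose`, `dose_unit`, `timepoint_h`, `channel`, `replicate`, `signal`, and
#'   attribute `control` naming the control condition.
#' @export
generate_plate <- function(seed = 1L,
                           conditions = default_plate_conditions(),
                           n_replicates = 5L,
                           control_label = "control",
                           control_signal = 1000,
                           timepoint_h = 48,
                           channel = c("viability_gfp", "glucose_2dg",
                                       "proliferation_edu")) {
  channel <- match.arg(channel)
  stopifnot(is.data.frame(conditions),
            all(c("label", "mean_signal_fraction", "sd") %in% names(conditions)))
  if (n_replicates < 1L) stop("`n_replicates` must be >= 1", call. = FALSE)
  if (!control_label %in% conditions$label) {
    stop(sprintf("no control condition '%s' present on the plate", control_label),
         call. = FALSE)
  }
  if (any(conditions$mean_signal_fraction < 0)) {
    stop("`mean_signal_fraction` must be >= 0", call. = FALSE)
  }
  if (is.null(conditions$dose)) conditions$dose <- NA_real_
  if (is.null(conditions$dose_unit)) conditions$dose_unit <- NA_character_
  wells <- with_seed(seed, {
    out <- list()
    for (ci in seq_len(nrow(conditions))) {
      sig <- stats::rnorm(n_replicates,
                          conditions$mean_signal_fraction[ci] * control_signal,
                          conditions$sd[ci] * control_signal)
      sig[sig < 0] <- 0
      out[[ci]] <- data.frame(
        condition = conditions$label[ci],
        dose = conditions$dose[ci],
        dose_unit = conditions$dose_unit[ci],
        timepoint_h = timepoint_h,
        channel = channel,
        replicate = seq_len(n_replicates),
        signal = sig)
    }
    do.call(rbind, out)
  })
  rownames(wells) <- NULL
  structure(wells, control = control_label,
            class = c("assay_plate", "data.frame"))
}

#' Default plate conditions for the synthetic viability assay
#'
#' Control plus 1 ug/mL trastuzumab, 1 uM niraparib, and their combination,
#' with survival fractions of 1.00, 0.60, 0.85 and 0.42 of control (the
#' niraparib-alone level is a modeling assumption; at 1 uM its single-agent
#' effect is modest).
#'
#' @return data.frame of condition definitions for [generate_plate()].
#' @export
default_plate_conditions <- function() {
  data.frame(
    label = c("control", "trastuzumab", "niraparib", "combination"),
    dose = c(0, 1, 1, 1),
    dose_unit = c(NA, "ug/mL", "uM", "combo"),
    mean_signal_fraction = c(1, 0.60, 0.85, 0.42),
    sd = c(0.05, 0.0425, 0.08, 0.1041))
}
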