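#' Construct a PET study object
#'
#' Bundles an SUV volume with co-registered binary tumor and reference-muscle
#' masks and scan metadata for a single animal and timepoint. The masks must
#' share the volume's dimensions, be non-empty, and be disjoint; any nonzero
#' mask value is treated as membership.
#'
#' @param suv 3-D numeric array of standardized uptake values (dimensionless,
#'   body-weight normalized assuming 1 g/mL tissue density). All values must
#'   be >= 0. If the scanner output is an activity-concentration volume, convert
#'   it first with [compute_suv()].
#' @param tumor_mask,muscle_mask arrays of the same shape as `suv`; nonzero
#'   values mark region membership.
#' @param subject_id character identifier for the animal.
#' @param day integer study day of the scan.
#' @param voxel_size numeric length-3, voxel edge lengths in mm.
#' @param injected_activity injected tracer activity in Bq (optional; only
#'   needed when converting raw activity volumes).
#' @param body_weight animal body weight in g (optional likewise).
#'
#' @return An object of class `pet_study`.
#' @export
pet_study <- function(suv, tumor_mask, muscle_mask, subject_id = "subject",
                      day = 0L, voxel_size = c(1, 1, 1),
                      injected_activity = NULL, body_weight = NULL) {
  if (!is.array(suv) || length(dim(suv)) != 3L) {
    stop("`suv` must be a 3-D array", call. = FALSE)
  }
  if (any(suv < 0, na.rm = TRUE)) {
    stop("SUV volume contains negative values; SUV must be >= 0", call. = FALSE)
  }
  tumor_mask <- as_mask(tumor_mask)
  muscle_mask <- as_mask(muscle_mask)
  if (!identical(dim(tumor_mask), dim(suv)) ||
      !identical(dim(muscle_mask), dim(suv))) {
    stop("masks must have the same dimensions as the SUV volume", call. = FALSE)
  }
  if (!any(tumor_mask)) stop("tumor mask is empty", call. = FALSE)
  if (!any(muscle_mask)) stop("muscle mask is empty", call. = FALSE)
  if (any(tumor_mask & muscle_mask)) {
    stop("tumor and muscle masks overlap; they must be disjoint", call. = FALSE)
  }
  structure(
    list(suv = suv, tumor_mask = tumor_mask, muscle_mask = muscle_mask,
         subject_id = as.character(subject_id), day = as.integer(day),
         voxel_size = as.numeric(voxel_size),
         injected_activity = injected_activity, body_weight = body_weight),
    class = "pet_study")
}

#' @export
print.pet_study <- function(x, ...) {
  cat("<pet_study>", x$subject_id, "day", x$day, "\n")
  cat("  grid:", paste(dim(x$suv), collapse = " x "),
      " voxel:", paste(signif(x$voxel_size, 3), collapse = " x "), "mm\n")
  cat(sprintf("  tumor: %d voxels   muscle: %d voxels\n",
              sum(x$tumor_mask), sum(x$muscle_mask)))
  invisible(x)
}

#' Convert an activity-concentration volume to SUV
#'
#' Standard body-weight SUV: tissue concentration divided by injected activity
#' per unit body mass, with tissue density taken as 1 g/mL so the result is
#' dimensionless. Decay correction is assumed to have been applied upstream by
#' the scanner.
#'
#' @param activity numeric array (or vector) of activity concentration, Bq/mL;
#'   all values must be >= 0.
#' @param injected_activity injected dose in Bq; must be > 0.
#' @param body_weight body weight in g; must be > 0.
#'
#' @return Array of SUV values, same shape as `activity`.
#' @examples
#' compute_suv(1000, injected_activity = 1e5, body_weight = 20) # 0.2
#' @export
compute_suv <- function(activity, injected_activity, body_weight) {
  assert_scalar_number(injected_activity, "injected_activity", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(body_weight, "body_weight", lower = 0, strict_lower = TRUE)
  if (any(activity < 0, na.rm = TRUE)) {
    stop("activity values must be >= 0", call. = FALSE)
  }
  activity * body_weight / injected_activity
}

#' Summary statistics of SUV over a region of interest
#'
#' Computes mean, sample standard deviation (n - 1 denominator), maximum and
#' voxel count over the voxels of the selected mask. A single-voxel ROI yields
#' sd = 0 with a degenerate-ROI warning.
#'
#' @param study a [pet_study()] object.
#' @param which `"tumor"` or `"muscle"`.
#'
#' @return An object of class `suv_summary` with fields `mean`, `sd`, `max`,
#'   `n_voxels`.
#' @export
roi_summary <- function(study, which = c("tumor", "muscle")) {
  which <- match.arg(which)
  stopifnot(inherits(study, "pet_study"))
  mask <- if (which == "tumor") study$tumor_mask else study$muscle_mask
  vals <- study$suv[mask]
  if (length(vals) == 0L) {
    stop(sprintf("%s ROI is empty: no voxels to summarize", which), call. = FALSE)
  }
  s <- if (length(vals) == 1L) {
    warning(sprintf("degenerate %s ROI: single voxel, sd reported as 0", which),
            call. = FALSE)
    0
  } else {
    stats::sd(vals)
  }
  suv_summary(mean(vals), s, max(vals), length(vals))
}

suv_summary <- function(mean, sd, max, n_voxels) {
  structure(list(mean = mean, sd = sd, max = max, n_voxels = n_voxels),
            class = "suv_summary")
}

#' @export
print.suv_summary <- function(x, ...) {
  cat(sprintf("<suv_summary> mean %.4g  sd %.4g  max %.4g  n %d\n",
              x$mean, x$sd, x$max, x$n_voxels))
  invisible(x)
}

#' Muscle-referenced proliferative SUV threshold
#'
#' The proliferative cutoff is the reference-muscle mean SUV plus
#' `sd_multiplier` standard deviations (default 2). The muscle summary must be
#' based on at least two voxels, since a standard deviation from one voxel is
#' undefined.
#'
#' @param muscle an `suv_summary` for the reference muscle ROI.
#' @param sd_multiplier number of muscle SDs above the muscle mean; >= 0.
#'
#' @return The threshold SUV (scalar).
#' @export
proliferative_threshold <- function(muscle, sd_multiplier = 2) {
  stopifnot(inherits(muscle, "suv_summary"))
  assert_scalar_number(sd_multiplier, "sd_multiplier", lower = 0)
  if (muscle$n_voxels < 2L) {
    stop("muscle ROI has fewer than 2 voxels; sd (and hence the threshold) is undefined",
         call. = FALSE)
  }
  muscle$mean + sd_multiplier * muscle$sd
}

#' Classify tumor voxels as proliferative or necrotic
#'
#' A tumor voxel is proliferative iff its SUV is greater than or equal to the
#' threshold (the boundary is inclusive: ties go to proliferative). Tumor
#' voxels below the threshold are labeled necrotic/non-proliferative. The two
#' label masks partition the tumor mask exactly.
#'
#' @param study a [pet_study()] object.
#' @param threshold SUV cutoff, >= 0; typically from [proliferative_threshold()].
#'
#' @return An object of class `proliferative_classification` with fields
#'   `threshold`, `proliferative_mask`, `necrotic_mask`,
#'   `proliferative_summary` (an `suv_summary`, or `NULL` when no voxel
#'   passes), `empty` (flag for the no-voxel-passes case) and
#'   `proliferative_fraction`.
#' @export
classify_voxels <- function(study, threshold) {
  stopifnot(inherits(study, "pet_study"))
  assert_scalar_number(threshold, "threshold", lower = 0)
  prolif <- study$tumor_mask & (study$suv >= threshold)
  necrotic <- study$tumor_mask & !prolif
  n_tumor <- sum(study$tumor_mask)
  n_prolif <- sum(prolif)
  summary <- NULL
  if (n_prolif > 0L) {
    vals <- study$suv[prolif]
    summary <- suv_summary(mean(vals),
                           if (n_prolif > 1L) stats::sd(vals) else 0,
                           max(vals), n_prolif)
  }
  structure(
    list(threshold = threshold,
         proliferative_mask = prolif,
         necrotic_mask = necrotic,
         proliferative_summary = summary,
         empty = n_prolif == 0L,
         proliferative_fraction = n_prolif / n_tumor),
    class = "proliferative_classification")
}

#' @export
print.proliferative_classification <- function(x, ...) {
  cat(sprintf("<proliferative_classification> threshold %.4g SUV\n", x$threshold))
  cat(sprintf("  proliferative: %d / %d tumor voxels (fraction %.3f)\n",
              sum(x$proliferative_mask),
              sum(x$proliferative_mask) + sum(x$necrotic_mask),
              x$proliferative_fraction))
  if (x$empty) cat("  note: no voxel reached the threshold\n")
  invisible(x)
}

#' Full SUV quantification of one PET study
#'
#' Composes the per-scan quantification chain: tumor and muscle ROI summaries,
#' the muscle-referenced proliferative threshold, and per-voxel classification.
#' Muscle statistics are computed per scan (per animal and timepoint), never
#' pooled across scans.
#'
#' @inheritParams proliferative_threshold
#' @param study a [pet_study()] object.
#'
#' @return An object of class `study_quantification`: list with `tumor`,
#'   `muscle` (both `suv_summary`), `threshold`, and `classification`.
#' @export
quantify_study <- function(study, sd_multiplier = 2) {
  tumor <- roi_summary(study, "tumor")
  muscle <- roi_summary(study, "muscle")
  thr <- proliferative_threshold(muscle, sd_multiplier)
  cls <- classify_voxels(study, thr)
  structure(list(subject_id = study$subject_id, day = study$day,
                 tumor = tumor, muscle = muscle,
                 threshold = thr, classification = cls),
            class = "study_quantification")
}

#' @export
print.study_quantification <- function(x, ...) {
  cat("<study_quantification>", x$subject_id, "day", x$day, "\n")
  cat(sprintf("  tumor  mean %.4g (sd %.3g, max %.3g, n %d)\n",
              x$tumor$mean, x$tumor$sd, x$tumor$max, x$tumor$n_voxels))
  cat(sprintf("  muscle mean %.4g (sd %.3g, n %d)\n",
              x$muscle$mean, x$muscle$sd, x$muscle$n_voxels))
  cat(sprintf("  threshold %.4g SUV -> proliferative fraction %.3f\n",
              x$threshold, x$classification$proliferative_fraction))
  if (!is.null(x$classification$proliferative_summary)) {
    cat(sprintf("  proliferative mean SUV %.4g\n",
                x$classification$proliferative_summary$mean))
  }
  invisible(x)
}
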