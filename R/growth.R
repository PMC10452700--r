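#' Caliper tumor volume from two perpendicular lengths
#'
#' Evaluates the ellipsoid-style caliper formula
#' `V = (4*pi/3) * (L1/2) * (L2/2) * ((L1 + L2)/4)`,
#' where the third semi-axis is taken as the mean of the two measured radii.
#'
#' @param L1,L2 perpendicular tumor lengths in mm, >= 0. Vectorized.
#' @return Tumor volume in mm^3.
#' @examples
#' caliper_volume(2, 2)  # sphere of radius 1: 4*pi/3
#' caliper_volume(6, 4)  # 20*pi
#' @export
caliper_volume <- function(L1, L2) {
  if (any(L1 < 0) || any(L2 < 0)) {
    stop("caliper lengths must be >= 0", call. = FALSE)
  }
  (4 * pi / 3) * (L1 / 2) * (L2 / 2) * ((L1 + L2) / 4)
}

#' Percent change from baseline
#'
#' @param baseline baseline value, > 0.
#' @param current current value. Vectorized over `current`.
#' @return `100 * (current - baseline) / baseline`.
#' @export
percent_change <- function(baseline, current) {
  if (any(baseline <= 0)) {
    stop("baseline must be > 0 for a percent change", call. = FALSE)
  }
  100 * (current - baseline) / baseline
}

#' Construct a cohort table of longitudinal growth records
#'
#' @param records data.frame with columns `subject_id`, `arm`, `day`, `L1`,
#'   `L2` and optionally `volume` (recomputed from the caliper formula if
#'   absent) and `weight`.
#' @param arms arm names; every record's arm must be among them.
#' @return A `cohort_table` (data.frame subclass with attribute `arms`).
#' @export
cohort_table <- function(records, arms = unique(records$arm)) {
  stopifnot(is.data.frame(records),
            all(c("subject_id", "arm", "day", "L1", "L2") %in% names(records)))
  if (!all(records$arm %in% arms)) {
    stop("every record's arm must appear in `arms`", call. = FALSE)
  }
  if (anyDuplicated(records[c("subject_id", "day")])) {
    stop("each subject may appear at most once per day", call. = FALSE)
  }
  if (is.null(records$volume)) {
    records$volume <- caliper_volume(records$L1, records$L2)
  }
  structure(records, arms = as.character(arms),
            class = c("cohort_table", "data.frame"))
}

# Per-subject percent change from its own day-0 baseline, for every
# post-baseline day. Subjects without a baseline row are dropped with a warning.
percent_change_table <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  out <- list()
  for (sid in unique(cohort$subject_id)) {
    rows <- cohort[cohort$subject_id == sid, , drop = FALSE]
    base <- rows$volume[rows$day == 0]
    if (length(base) != 1L) {
      warning(sprintf("subject %s has no day-0 baseline; excluded", sid),
              call. = FALSE)
      next
    }
    post <- rows[rows$day > 0, , drop = FALSE]
    if (nrow(post) == 0L) next
    out[[sid]] <- data.frame(subject_id = sid, arm = post$arm, day = post$day,
                             pct_change = percent_change(base, post$volume))
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(subject_id = character(), arm = character(),
               day = integer(), pct_change = numeric())
  rownames(res) <- NULL
  res
}

#' Normalize treated growth to the vehicle-arm mean
#'
#' Each subject's percent change from its own baseline at the given day is
#' divided by the vehicle-arm mean percent change at that day.
#'
#' @param cohort a [cohort_table()].
#' @param vehicle_arm name of the vehicle/control arm.
#' @param day assessment day at which to normalize.
#' @return data.frame with `subject_id`, `arm`, `pct_change`, `normalized`.
#' @export
normalize_to_vehicle <- function(cohort, vehicle_arm = "vehicle", day) {
  pct <- percent_change_table(cohort)
  pct <- pct[pct$day == day, , drop = FALSE]
  veh <- pct$pct_change[pct$arm == vehicle_arm]
  if (length(veh) == 0L) {
    stop(sprintf("vehicle arm '%s' has no subjects at day %s", vehicle_arm, day),
         call. = FALSE)
  }
  vm <- mean(veh)
  if (abs(vm) < .Machine$double.eps) {
    stop("vehicle mean percent change is exactly 0; normalization is degenerate",
         call. = FALSE)
  }
  pct$normalized <- pct$pct_change / vm
  pct
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact enumeration p-value when the smaller group has at most 8 observations
#' and there are no ties; otherwise the normal approximation with midranks,
#' tie-corrected variance and continuity correction. The branch taken is
#' recorded in the result.
#'
#' @param a,b non-empty numeric groups.
#' @return Object of class `mw_result`: `U` (for group `a`), `p_value`,
#'   `n1`, `n2`, `method`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value # 0.1
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- min(length(a), length(b)) <= 8L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  structure(list(U = unname(wt$statistic), p_value = wt$p.value,
                 n1 = length(a), n2 = length(b),
                 method = if (exact) "exact" else "normal_approx"),
            class = "mw_result")
}

#' @export
print.mw_result <- function(x, ...) {
  cat(sprintf("<mw_result> U = %g, p = %.4g (%s; n = %d/%d)\n",
              x$U, x$p_value, x$method, x$n1, x$n2))
  invisible(x)
}

#' Grubbs extreme studentized deviate outlier test
#'
#' Single-pass two-sided Grubbs test: `G = max|x - mean| / sd` is compared to
#' the critical value
#' `G_crit = ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))`
#' where `t` is the upper `alpha / (2n)` quantile of Student's t with `n - 2`
#' degrees of freedom. The most extreme point is flagged iff `G > G_crit`;
#' the test is not re-applied after removal.
#'
#' @param values numeric vector, length >= 3, with nonzero sample SD.
#' @param alpha two-sided significance level.
#' @return List with `outlier_index` (`NA` if none flagged), `G`,
#'   `critical_value`, `n`, `alpha`.
#' @examples
#' grubbs_outlier(c(1, 1, 1, 1, 10))$outlier_index # 5
#' @export
grubbs_outlier <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3L) stop("Grubbs test requires at least 3 values", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) stop("Grubbs test is undefined for zero sample SD", call. = FALSE)
  dev <- abs(values - mean(values))
  G <- max(dev) / s
  tq <- stats::qt(1 - alpha / (2 * n), df = n - 2)
  gcrit <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
  list(outlier_index = if (G > gcrit) which.max(dev) else NA_integer_,
       G = G, critical_value = gcrit, n = n, alpha = alpha)
}

#' Cohort growth-curve report
#'
#' Per-day, per-arm mean and sample SD of percent change from baseline, plus
#' pairwise two-sided Mann-Whitney comparisons between arms at each day.
#' Optionally pre-screens each arm-day group with a single-pass Grubbs test
#' at `alpha` and drops the flagged value. Raw p-values are reported
#' (`p_adjust = "none"`); Holm adjustment across each day's comparisons is
#' available but off by default.
#'
#' @param cohort a [cohort_table()] with at least one arm.
#' @param screen_outliers apply [grubbs_outlier()] per arm-day before
#'   summarizing.
#' @param alpha significance level for the outlier screen.
#' @param p_adjust `"none"` (default) or `"holm"`.
#' @param out_dir if non-`NULL`, write `growth_summary.csv`,
#'   `growth_comparisons.csv` and a growth-curve plot there.
#'
#' @return Object of class `growth_report`: list with `summary` (day, arm, n,
#'   mean_pct_change, sd_pct_change), `comparisons` (day, arm_a, arm_b, U,
#'   p_value, method), `files`.
#' @export
growth_report <- function(cohort, screen_outliers = FALSE, alpha = 0.05,
                          p_adjust = c("none", "holm"), out_dir = NULL) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(inherits(cohort, "cohort_table"))
  arms <- attr(cohort, "arms")
  pct <- percent_change_table(cohort)
  days <- sort(unique(pct$day))
  summ <- list(); comp <- list()
  for (d in days) {
    groups <- list()
    for (arm in arms) {
      v <- pct$pct_change[pct$day == d & pct$arm == arm]
      if (length(v) == 0L) next
      if (screen_outliers && length(v) >= 3L && stats::sd(v) > 0) {
        g <- grubbs_outlier(v, alpha)
        if (!is.na(g$outlier_index)) v <- v[-g$outlier_index]
      }
      groups[[arm]] <- v
      summ[[length(summ) + 1L]] <- data.frame(
        day = d, arm = arm, n = length(v),
        mean_pct_change = mean(v),
        sd_pct_change = if (length(v) > 1L) stats::sd(v) else 0)
    }
    gn <- names(groups)
    if (length(gn) >= 2L) {
      prs <- utils::combn(gn, 2)
      pvals <- numeric(ncol(prs)); rows <- list()
      for (j in seq_len(ncol(prs))) {
        mw <- mann_whitney(groups[[prs[1, j]]], groups[[prs[2, j]]])
        pvals[j] <- mw$p_value
        rows[[j]] <- data.frame(day = d, arm_a = prs[1, j], arm_b = prs[2, j],
                                U = mw$U, p_value = mw$p_value,
                                method = mw$method)
      }
      if (p_adjust == "holm") {
        adj <- stats::p.adjust(pvals, "holm")
        for (j in seq_along(rows)) rows[[j]]$p_value <- adj[j]
      }
      comp <- c(comp, rows)
    }
  }
  summary_df <- do.call(rbind, summ)
  comparisons <- if (length(comp)) do.call(rbind, comp) else
    data.frame(day = integer(), arm_a = character(), arm_b = character(),
               U = numeric(), p_value = numeric(), method = character())
  rownames(summary_df) <- rownames(comparisons) <- NULL
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    f1 <- file.path(out_dir, "growth_summary.csv")
    f2 <- file.path(out_dir, "growth_comparisons.csv")
    utils::write.csv(summary_df, f1, row.names = FALSE)
    utils::write.csv(comparisons, f2, row.names = FALSE)
    f3 <- file.path(out_dir, "growth_curves.png")
    grDevices::png(f3, width = 800, height = 600)
    plot_growth_summary(summary_df, arms)
    grDevices::dev.off()
    files <- c(f1, f2, f3)
  }
  structure(list(summary = summary_df, comparisons = comparisons,
                 files = files),
            class = "growth_report")
}

plot_growth_summary <- function(summary_df, arms) {
  cols <- grDevices::hcl.colors(length(arms), "Dark 3")
  rng <- range(summary_df$mean_pct_change + summary_df$sd_pct_change,
               summary_df$mean_pct_change - summary_df$sd_pct_change)
  graphics::plot(NULL, xlim = range(summary_df$day), ylim = rng,
                 xlab = "Day", ylab = "Tumor volume change from baseline (%)",
                 main = "Cohort growth curves (mean ± SD)")
  for (i in seq_along(arms)) {
    s <- summary_df[summary_df$arm == arms[i], , drop = FALSE]
    if (nrow(s) == 0L) next
    graphics::lines(s$day, s$mean_pct_change, col = cols[i], lwd = 2)
    graphics::arrows(s$day, s$mean_pct_change - s$sd_pct_change,
                     s$day, s$mean_pct_change + s$sd_pct_change,
                     angle = 90, code = 3, length = 0.03, col = cols[i])
  }
  graphics::legend("topleft", legend = arms, col = cols, lwd = 2, bty = "n")
}

#' @export
print.growth_report <- function(x, ...) {
  cat("<growth_report>\n")
  print(x$summary)
  if (nrow(x$comparisons)) {
    cat("pairwise Mann-Whitney comparisons:\n")
    print(x$comparisons)
  }
  invisible(x)
}
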