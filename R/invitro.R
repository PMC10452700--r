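#' Percent survival of treated wells relative to control
#'
#' `100 * mean(treated) / mean(control)`, with spread propagated from the
#' treated replicate SD: `sd = 100 * sd(treated) / mean(control)`.
#'
#' @param treated,control non-empty numeric replicate signals; the control
#'   mean must be positive.
#' @return List with `percent`, `sd`, `n`.
#' @export
percent_survival <- function(treated, control) {
  if (length(treated) == 0L || length(control) == 0L) {
    stop("treated and control replicate sets must be non-empty", call. = FALSE)
  }
  cm <- mean(control)
  if (cm <= 0) stop("control mean must be positive", call. = FALSE)
  list(percent = 100 * mean(treated) / cm,
       sd = if (length(treated) > 1L) 100 * stats::sd(treated) / cm else 0,
       n = length(treated))
}

#' Percent change of an assay readout relative to control
#'
#' `100 * (mean(treated) - mean(control)) / mean(control)`; negative values
#' are decreases. Consistent with [percent_survival()]:
#' `survival = 100 + percent change` for the same inputs.
#'
#' @inheritParams percent_survival
#' @return List with `percent_change`, `sd`, `n`.
#' @export
assay_percent_change <- function(treated, control) {
  s <- percent_survival(treated, control)
  list(percent_change = s$percent - 100, sd = s$sd, n = s$n)
}

#' Fold change relative to a baseline signal
#'
#' @param signal_t signal at the later timepoint. Vectorized.
#' @param signal_baseline baseline signal, > 0.
#' @return `signal_t / signal_baseline`.
#' @export
normalize_to_baseline <- function(signal_t, signal_baseline) {
  if (any(signal_baseline <= 0)) {
    stop("baseline signal must be > 0", call. = FALSE)
  }
  signal_t / signal_baseline
}

#' Dose-response survival table for one agent
#'
#' Orders the agent's dose levels, computes percent survival (mean over
#' replicate wells relative to the plate's control condition) with replicate
#' SD at each dose, and compares each dose group to control with a two-sided
#' Mann-Whitney test. All doses of one agent must share a unit.
#'
#' @param plate an `assay_plate` (see [generate_plate()]).
#' @param agent condition label prefix or exact label identifying the agent's
#'   dose series; rows are matched by exact `condition == agent` or, when the
#'   plate encodes doses as separate conditions, by `condition` equal to
#'   `agent` (multiple rows distinguished by `dose`).
#' @param channel assay channel to analyze.
#' @return data.frame with one row per dose: `dose`, `dose_unit`,
#'   `percent_survival`, `sd`, `n`, `U`, `p_value`, `method`, sorted by dose.
#' @export
dose_response_table <- function(plate, agent, channel = NULL) {
  stopifnot(inherits(plate, "assay_plate"))
  control_label <- attr(plate, "control")
  df <- as.data.frame(plate)
  if (!is.null(channel)) df <- df[df$channel == channel, , drop = FALSE]
  control <- df$signal[df$condition == control_label]
  if (length(control) == 0L) {
    stop(sprintf("plate has no wells for control condition '%s'", control_label),
         call. = FALSE)
  }
  rows <- df[df$condition == agent, , drop = FALSE]
  doses <- sort(unique(rows$dose))
  if (length(doses) < 2L) {
    stop("dose-response requires at least 2 dose levels plus control",
         call. = FALSE)
  }
  units <- unique(rows$dose_unit)
  if (length(units) != 1L) {
    stop(sprintf("mixed dose units for agent '%s': %s", agent,
                 paste(units, collapse = ", ")), call. = FALSE)
  }
  out <- lapply(doses, function(d) {
    sig <- rows$signal[rows$dose == d]
    ps <- percent_survival(sig, control)
    mw <- mann_whitney(sig, control)
    data.frame(dose = d, dose_unit = units, percent_survival = ps$percent,
               sd = ps$sd, n = ps$n, U = mw$U, p_value = mw$p_value,
               method = mw$method)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Ordinary least-squares regression of a 48 h biomarker on endpoint viability
#'
#' Fits `endpoint ~ biomarker` by OLS and reports slope, intercept,
#' `R^2 = 1 - SS_res / SS_tot`, and the two-tailed slope p-value from the t
#' distribution with n - 2 degrees of freedom. A constant response (zero
#' `SS_tot`) yields `R^2 = 0` with a warning rather than `NaN`.
#'
#' @param biomarker per-well biomarker values (e.g. EdU or 2DG signal at
#'   48 h); must not be constant.
#' @param endpoint matched per-well endpoint viability values.
#' @return Object of class `regression_result`: `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`.
#' @export
biomarker_viability_regression <- function(biomarker, endpoint) {
  x <- as.numeric(biomarker); y <- as.numeric(endpoint)
  if (length(x) != length(y)) stop("inputs must be matched per well", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("regression requires at least 3 matched pairs", call. = FALSE)
  if (stats::var(x) == 0) {
    stop("biomarker values are constant; slope is undefined", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum(stats::residuals(fit)^2)
  slope <- unname(stats::coef(fit)[2])
  if (ss_tot == 0) {
    warning("endpoint values are constant; reporting R^2 = 0", call. = FALSE)
    r2 <- 0
    p <- 1
  } else {
    r2 <- 1 - ss_res / ss_tot
    # two-tailed slope test on n - 2 df, robust to perfect fits
    se <- sqrt(ss_res / (n - 2) / sum((x - mean(x))^2))
    p <- if (se == 0) as.numeric(slope == 0) else 2 * stats::pt(-abs(slope / se), n - 2)
  }
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, p_value = p, n = n),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> y = %.4g + %.4g x; R^2 = %.4f, p = %.4g (n = %d)\n",
              x$intercept, x$slope, x$r_squared, x$p_value, x$n))
  invisible(x)
}
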