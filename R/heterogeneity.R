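#' Default SUV bin edges for fractional-frequency histograms
#'
#' Equal-width bins (default 0.1 SUV) from 0 up to the 99.9th percentile of
#' the supplied values, rounded up to a whole bin. The high-percentile cap
#' keeps a handful of extreme voxels from stretching the axis; when values
#' exceed the cap a single overflow bin up to the maximum is appended, so
#' every voxel is always covered and normalization stays exact.
#'
#' @param values pooled SUV values the edges must cover.
#' @param bin_width bin width in SUV, > 0.
#' @param upper_quantile quantile of `values` the regular bins extend to.
#' @return Numeric vector of strictly increasing bin edges.
#' @export
suv_bin_edges <- function(values, bin_width = 0.1, upper_quantile = 0.999) {
  assert_scalar_number(bin_width, "bin_width", 0, strict_lower = TRUE)
  if (length(values) == 0L) stop("no values supplied", call. = FALSE)
  top <- max(stats::quantile(values, upper_quantile, names = FALSE), bin_width)
  edges <- seq(0, (ceiling(top / bin_width) + 1) * bin_width, by = bin_width)
  mx <- max(values)
  if (mx > edges[length(edges)]) edges <- c(edges, mx)
  edges
}

#' Fractional-frequency histogram of voxel SUV values
#'
#' The fractional frequency of a bin is its voxel count divided by the total
#' number of voxels, so histograms from tumors of different sizes are directly
#' comparable. Bins are left-closed/right-open, with the last bin closed on
#' the right. Values outside the edges are an error (they would silently
#' break normalization).
#'
#' @param values numeric SUV values, at least one.
#' @param bin_edges strictly increasing numeric vector of length B + 1
#'   covering the data range; see [suv_bin_edges()].
#' @param source_id label carried into reports.
#'
#' @return Object of class `fractional_histogram` with fields `bin_edges`,
#'   `fractional_frequency` (length B, sums to 1), `n_voxels`, `source_id`.
#' @examples
#' fractional_histogram(c(1, 1, 2, 2), c(0.5, 1.5, 2.5))$fractional_frequency
#' @export
fractional_histogram <- function(values, bin_edges, source_id = "") {
  if (length(values) == 0L) stop("no values to histogram", call. = FALSE)
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0)) {
    stop("`bin_edges` must be strictly increasing with at least two edges",
         call. = FALSE)
  }
  nb <- length(bin_edges) - 1L
  idx <- findInterval(values, bin_edges, rightmost.closed = TRUE)
  bad <- idx < 1L | idx > nb
  if (any(bad)) {
    stop(sprintf("value %g lies outside the bin edges [%g, %g]",
                 values[which(bad)[1]], bin_edges[1], bin_edges[nb + 1L]),
         call. = FALSE)
  }
  freq <- tabulate(idx, nbins = nb) / length(values)
  structure(list(bin_edges = as.numeric(bin_edges),
                 fractional_frequency = freq,
                 n_voxels = length(values),
                 source_id = as.character(source_id)),
            class = "fractional_histogram")
}

#' @export
print.fractional_histogram <- function(x, ...) {
  cat(sprintf("<fractional_histogram> '%s': %d voxels in %d bins over [%g, %g] SUV\n",
              x$source_id, x$n_voxels, length(x$fractional_frequency),
              x$bin_edges[1], x$bin_edges[length(x$bin_edges)]))
  invisible(x)
}

#' @export
plot.fractional_histogram <- function(x, ..., col = "steelblue") {
  mids <- (utils::head(x$bin_edges, -1) + utils::tail(x$bin_edges, -1)) / 2
  graphics::plot(mids, x$fractional_frequency, type = "s", col = col,
                 xlab = "SUV", ylab = "Fractional frequency",
                 main = x$source_id, ...)
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov comparison of SUV samples
#'
#' Computes the KS distance D, the supremum absolute difference between the
#' two empirical cumulative distribution functions, on the raw samples
#' (lossless; binning is for reporting only). The p-value uses the exact
#' conditional distribution when `n1 * n2 <= exact_limit` and the asymptotic
#' Kolmogorov distribution with effective sample size `n1 n2 / (n1 + n2)`
#' otherwise; the method used is recorded in the result.
#'
#' @param a,b non-empty numeric samples.
#' @param exact_limit product-of-sample-sizes cutoff for the exact method.
#'
#' @return Object of class `ks_result`: `distance`, `p_value`, `n1`, `n2`,
#'   `method` (`"exact"` or `"asymptotic"`).
#' @examples
#' ks_two_sample(c(1, 2, 3), c(1.5, 2.5, 3.5))$distance # 1/3
#' @export
ks_two_sample <- function(a, b, exact_limit = 1e4) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  a <- as.numeric(a); b <- as.numeric(b)
  n1 <- length(a); n2 <- length(b)
  # D = sup_x |ECDF_a(x) - ECDF_b(x)|, evaluated at the pooled order statistics
  w <- sort(unique(c(a, b)))
  fa <- stats::ecdf(a)(w)
  fb <- stats::ecdf(b)(w)
  d <- max(abs(fa - fb))
  if (as.double(n1) * n2 <= exact_limit) {
    method <- "exact"
    p <- 1 - stats::psmirnov(d, sizes = c(n1, n2), z = c(a, b), exact = TRUE)
  } else {
    method <- "asymptotic"
    ne <- as.double(n1) * n2 / (n1 + n2)
    p <- ks_asymptotic_p(sqrt(ne) * d)
  }
  structure(list(distance = d, p_value = min(max(p, 0), 1),
                 n1 = n1, n2 = n2, method = method),
            class = "ks_result")
}

# Complementary CDF of the Kolmogorov distribution,
# Q(t) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 t^2).
ks_asymptotic_p <- function(t) {
  if (t <= 0) return(1)
  k <- seq_len(101)
  terms <- (-1)^(k - 1) * exp(-2 * k^2 * t^2)
  min(1, max(0, 2 * sum(terms)))
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("<ks_result> D = %.4f, p = %.4g (%s; n1 = %d, n2 = %d)\n",
              x$distance, x$p_value, x$method, x$n1, x$n2))
  invisible(x)
}

#' Cohort-level KS comparison across timepoints or arms
#'
#' Pools tumor-voxel SUVs across the animals of each group (one empirical
#' distribution per cohort-timepoint, matching one reported D per cohort
#' pair) and applies [ks_two_sample()]. With `voxels = "proliferative"` only
#' voxels at or above each scan's own muscle-referenced threshold enter the
#' pool. A per-animal alternative (`pool = FALSE`) pairs studies by position
#' and returns one `ks_result` per pair.
#'
#' @param studies_a,studies_b non-empty lists of [pet_study()] objects (e.g.
#'   one cohort at baseline and at a follow-up day, or two cohorts on the
#'   same day).
#' @param voxels `"all"` (default) or `"proliferative"`.
#' @param pool pool voxels across animals within each group (default) or
#'   compare animal-by-animal.
#' @param sd_multiplier threshold multiplier for `voxels = "proliferative"`.
#'
#' @return A `ks_result`, or a list of them when `pool = FALSE`.
#' @export
longitudinal_ks <- function(studies_a, studies_b,
                            voxels = c("all", "proliferative"),
                            pool = TRUE, sd_multiplier = 2) {
  voxels <- match.arg(voxels)
  if (length(studies_a) == 0L || length(studies_b) == 0L) {
    stop("both study lists must be non-empty", call. = FALSE)
  }
  extract <- function(study) {
    stopifnot(inherits(study, "pet_study"))
    if (voxels == "all") {
      study$suv[study$tumor_mask]
    } else {
      q <- quantify_study(study, sd_multiplier)
      study$suv[q$classification$proliferative_mask]
    }
  }
  if (pool) {
    ks_two_sample(unlist(lapply(studies_a, extract)),
                  unlist(lapply(studies_b, extract)))
  } else {
    if (length(studies_a) != length(studies_b)) {
      stop("per-animal comparison requires equal-length study lists", call. = FALSE)
    }
    Map(function(x, y) ks_two_sample(extract(x), extract(y)),
        studies_a, studies_b)
  }
}

#' Tabulate and plot a set of fractional histograms
#'
#' Aligns histograms sharing one set of bin edges into a wide table (one
#' frequency column per source) and optionally writes the table as CSV plus
#' an overlay plot.
#'
#' @param histograms non-empty list of [fractional_histogram()] objects with
#'   identical bin edges.
#' @param out_dir directory to write into, or `NULL` to skip writing.
#' @param basename file stem for the CSV/PNG pair.
#' @param plot also write the overlay plot (PNG).
#'
#' @return Invisibly, a list with the wide `table` (data.frame: `bin_left`,
#'   `bin_right`, one column per source) and the written `files`.
#' @export
histogram_report <- function(histograms, out_dir = NULL,
                             basename = "fractional_histograms", plot = TRUE) {
  if (length(histograms) == 0L) stop("no histograms supplied", call. = FALSE)
  edges <- histograms[[1]]$bin_edges
  for (h in histograms) {
    stopifnot(inherits(h, "fractional_histogram"))
    if (length(h$bin_edges) != length(edges) ||
        any(abs(h$bin_edges - edges) > 1e-12)) {
      stop("histograms have mismatched bin edges and cannot be aligned",
           call. = FALSE)
    }
  }
  tab <- data.frame(bin_left = utils::head(edges, -1),
                    bin_right = utils::tail(edges, -1))
  ids <- vapply(histograms, function(h) h$source_id, character(1))
  ids[ids == ""] <- sprintf("hist_%d", which(ids == ""))
  ids <- make.unique(ids)
  for (i in seq_along(histograms)) {
    tab[[ids[i]]] <- histograms[[i]]$fractional_frequency
  }
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    csv <- file.path(out_dir, paste0(basename, ".csv"))
    utils::write.csv(tab, csv, row.names = FALSE)
    files <- csv
    if (plot) {
      png_path <- file.path(out_dir, paste0(basename, ".png"))
      grDevices::png(png_path, width = 800, height = 600)
      on.exit(grDevices::dev.off(), add = TRUE)
      mids <- (tab$bin_left + tab$bin_right) / 2
      cols <- grDevices::hcl.colors(length(ids), "Dark 3")
      graphics::matplot(mids, as.matrix(tab[ids]), type = "s", lty = 1,
                        col = cols, xlab = "SUV",
                        ylab = "Fractional frequency",
                        main = "Tumor voxel SUV distributions")
      graphics::legend("topright", legend = ids, col = cols, lty = 1, bty = "n")
      files <- c(files, png_path)
    }
  }
  invisible(list(table = tab, files = files))
}
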