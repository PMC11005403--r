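#' Fit a qPCR standard curve
#'
#' Least-squares line of quantification cycle against log10 template
#' copies, Cq = slope * log10(copies) + intercept, fitted to a dilution
#' series (typically 10-fold serial dilutions of a plasmid bearing the
#' assayed locus). The amplification efficiency is
#' \deqn{E = 10^{-1/\mathrm{slope}} - 1,}
#' 1.0 meaning perfect doubling each cycle (slope -1/log10(2) = -3.3219);
#' a slope of -3.5873 corresponds to E = 0.90.
#'
#' @param dilution_copies Template copies per reaction (> 0), length >= 3.
#' @param cq Measured Cq values, same length.
#' @return An object of class `standard_curve` with fields `slope`,
#'   `intercept`, `r_squared`, `efficiency`, `n`.
#' @examples
#' copies <- 10^(3:9)
#' cq <- 38 - 3.3219 * log10(copies)
#' fit_standard_curve(copies, cq)$efficiency # 1.0
#' @export
fit_standard_curve <- function(dilution_copies, cq) {
  if (length(dilution_copies) != length(cq)) {
    stop("`dilution_copies` and `cq` must have equal length", call. = FALSE)
  }
  if (length(cq) < 3L) stop("need at least 3 dilution points", call. = FALSE)
  if (any(!is.finite(dilution_copies)) || any(dilution_copies <= 0)) {
    stop("`dilution_copies` must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(cq))) stop("`cq` must be finite", call. = FALSE)
  lx <- log10(dilution_copies)
  if (stats::var(lx) == 0) stop("degenerate dilution series (constant copies)", call. = FALSE)
  fit <- stats::lm(cq ~ lx)
  slope <- unname(stats::coef(fit)[2L])
  if (slope >= 0) stop("non-negative slope: Cq must decrease with copies", call. = FALSE)
  sst <- sum((cq - mean(cq))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  structure(
    list(slope = slope, intercept = unname(stats::coef(fit)[1L]),
         r_squared = r2, efficiency = 10^(-1 / slope) - 1, n = length(cq)),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> slope %.4f, intercept %.3f, E = %.3f, R^2 = %.4f (n = %d)\n",
              x$slope, x$intercept, x$efficiency, x$r_squared, x$n))
  invisible(x)
}

#' Absolute copies from a Cq value
#'
#' Inverts the standard curve: copies = 10^((cq - intercept) / slope),
#' monotonically decreasing in Cq. Replicate Cq values should be averaged
#' arithmetically *before* inversion (inverting each replicate and then
#' averaging is upward-biased).
#'
#' @param curve A [fit_standard_curve()] result.
#' @param cq Cq value(s).
#' @return Estimated template copies, vectorised over `cq`.
#' @export
copies_from_cq <- function(curve, cq) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope >= 0) stop("invalid standard curve (slope >= 0)", call. = FALSE)
  10^((cq - curve$intercept) / curve$slope)
}

#' Chromosomes per cell from qPCR and cell counts
#'
#' Ploidy as locus copies per mL of culture divided by cells per mL
#' (counted e.g. in a Thoma chamber). Replicate scatter in Cq is propagated
#' to the ploidy estimate to first order: the SD of the mean Cq maps to a
#' relative SD of ln(10)/|slope| per Cq cycle. Cell counts are treated as
#' error-free unless `cells_sd` is given, in which case the two relative
#' variances add. Estimates below one chromosome per cell are allowed
#' (they occur at early time points when cell harvesting is incomplete)
#' but carry a `sub_unity` flag.
#'
#' @param copies_per_ml Locus copies per mL of culture.
#' @param cells_per_ml Cell density (> 0).
#' @param copies_sd Optional SD of `copies_per_ml`.
#' @param cells_sd Optional SD of `cells_per_ml`.
#' @return A list with `ploidy`, `sd` and `sub_unity`.
#' @examples
#' chromosomes_per_cell(1.6e9, 2e8)$ploidy # 8
#' @export
chromosomes_per_cell <- function(copies_per_ml, cells_per_ml,
                                 copies_sd = 0, cells_sd = 0) {
  if (!is.finite(cells_per_ml) || cells_per_ml <= 0) {
    stop("`cells_per_ml` must be > 0", call. = FALSE)
  }
  if (!is.finite(copies_per_ml) || copies_per_ml < 0) {
    stop("`copies_per_ml` must be >= 0", call. = FALSE)
  }
  ploidy <- copies_per_ml / cells_per_ml
  rel2 <- 0
  if (copies_sd > 0 && copies_per_ml > 0) rel2 <- rel2 + (copies_sd / copies_per_ml)^2
  if (cells_sd > 0) rel2 <- rel2 + (cells_sd / cells_per_ml)^2
  list(ploidy = ploidy, sd = ploidy * sqrt(rel2), sub_unity = ploidy < 1)
}

#' Ploidy of qPCR samples against a standard curve
#'
#' Convenience wrapper for a table of samples: averages the replicate Cq
#' values of each sample, inverts the standard curve, scales reaction
#' copies to copies per mL of culture, and divides by the cell density.
#'
#' @param curve A [fit_standard_curve()] result.
#' @param samples Data frame with columns `label`, `cells_per_ml`, and one
#'   or more Cq replicate columns matching `cq_cols`.
#' @param volume_scale Factor converting copies per reaction to copies per
#'   mL of culture (template volume / extraction yield bookkeeping).
#' @param cq_cols Names of the replicate columns; default every column
#'   starting with "cq".
#' @return Data frame (label, mean_cq, sd_cq, copies, ploidy, sd, sub_unity).
#' @export
ploidy_table <- function(curve, samples, volume_scale = 1,
                         cq_cols = grep("^cq", names(samples), value = TRUE)) {
  stopifnot(inherits(curve, "standard_curve"), is.data.frame(samples))
  if (length(cq_cols) == 0L) stop("no Cq replicate columns found", call. = FALSE)
  need <- c("label", "cells_per_ml")
  if (!all(need %in% names(samples))) {
    stop("`samples` needs columns label, cells_per_ml", call. = FALSE)
  }
  cqm <- as.matrix(samples[, cq_cols, drop = FALSE])
  mean_cq <- rowMeans(cqm)
  sd_cq <- apply(cqm, 1L, stats::sd)
  se_cq <- sd_cq / sqrt(ncol(cqm))
  copies <- copies_from_cq(curve, mean_cq) * volume_scale
  copies_sd <- copies * log(10) / abs(curve$slope) * se_cq
  res <- mapply(function(cp, cpsd, cells) {
    out <- chromosomes_per_cell(cp, cells, copies_sd = cpsd)
    c(out$ploidy, out$sd, out$sub_unity)
  }, copies, copies_sd, samples$cells_per_ml)
  data.frame(label = samples$label, mean_cq = mean_cq, sd_cq = sd_cq,
             copies = copies, ploidy = res[1L, ], sd = res[2L, ],
             sub_unity = as.logical(res[3L, ]))
}

#' Simulate a qPCR ploidy experiment
#'
#' Generates a noiseless 10-fold dilution series (10^3 to 10^9 copies) and
#' noisy sample Cq triplicates from known amplification efficiency,
#' intercept and true ploidy, for estimator validation.
#'
#' @param true_ploidy Chromosomes per cell to simulate.
#' @param cells_per_ml Cell density of the simulated sample.
#' @param efficiency Amplification efficiency E (slope = -1/log10(1 + E)).
#' @param intercept Cq at one copy.
#' @param cq_noise_sd SD of Gaussian Cq noise per replicate.
#' @param n_replicates Replicates per sample (triplicates by default).
#' @param volume_scale Copies-per-reaction to copies-per-mL factor.
#' @return List with `standards` (copies, cq), `sample` (1-row data frame
#'   with cq replicate columns and cells_per_ml) and `true_ploidy`.
#' @export
simulate_qpcr <- function(true_ploidy, cells_per_ml = 2e8, efficiency = 0.9,
                          intercept = 38, cq_noise_sd = 0.15,
                          n_replicates = 3, volume_scale = 1) {
  slope <- -1 / log10(1 + efficiency)
  std_copies <- 10^(3:9)
  standards <- data.frame(copies = std_copies,
                          cq = intercept + slope * log10(std_copies))
  true_copies <- true_ploidy * cells_per_ml / volume_scale
  cq <- intercept + slope * log10(true_copies) +
    stats::rnorm(n_replicates, 0, cq_noise_sd)
  sample <- as.data.frame(as.list(stats::setNames(cq, paste0("cq", seq_len(n_replicates)))))
  sample$label <- "sim"
  sample$cells_per_ml <- cells_per_ml
  list(standards = standards, sample = sample, true_ploidy = true_ploidy)
}
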