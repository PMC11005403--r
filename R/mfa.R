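#' Binned coverage over a chromosome
#'
#' Container for per-bin mean sequencing depth on the fixed bin grid of a
#' genome (0-based, half-open bins; the last bin may be partial).
#'
#' @param genome A [genome_def()].
#' @param bin_size Bin width in bp.
#' @param values Non-negative per-bin mean depths, length `ceiling(L / bin_size)`.
#' @return An object of class `coverage_profile`.
#' @export
coverage_profile <- function(genome, bin_size, values) {
  stopifnot(inherits(genome, "genome_def"))
  nb <- n_bins_for(genome, bin_size)
  if (length(values) != nb) {
    stop(sprintf("expected %d bins for bin_size %g, got %d values",
                 nb, bin_size, length(values)), call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("coverage values must be finite and non-negative", call. = FALSE)
  }
  structure(list(genome = genome, bin_size = as.numeric(bin_size),
                 values = as.numeric(values)),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("<coverage_profile> %s: %d bins of %g bp, mean depth %.3g\n",
              x$genome$name, length(x$values), x$bin_size, mean(x$values)))
  invisible(x)
}

#' Bin a depth track
#'
#' Averages a depth track onto the bin grid. The track is a data frame of
#' non-overlapping 0-based half-open intervals (`start`, `end`, `value`),
#' as returned by [read_depth()]; per-position input is the special case of
#' width-1 intervals. Each bin's value is the length-weighted mean depth
#' over all positions of the bin (positions not covered by any interval
#' count as depth 0); a partial last bin is averaged over its actual width.
#'
#' @param track Data frame with columns `start`, `end`, `value`.
#' @param genome A [genome_def()].
#' @param bin_size Bin width in bp (>= 1).
#' @return A [coverage_profile()].
#' @examples
#' g <- genome_def(4, ori_position = 0)
#' track <- data.frame(start = 0:3, end = 1:4, value = c(2, 2, 4, 4))
#' bin_coverage(track, g, bin_size = 2)$values # 2 4
#' @export
bin_coverage <- function(track, genome, bin_size) {
  stopifnot(inherits(genome, "genome_def"))
  if (bin_size < 1) stop("`bin_size` must be >= 1", call. = FALSE)
  need <- c("start", "end", "value")
  if (!is.data.frame(track) || !all(need %in% names(track))) {
    stop("`track` must be a data frame with columns start, end, value",
         call. = FALSE)
  }
  L <- genome$length
  s <- as.numeric(track$start); e <- as.numeric(track$end)
  v <- as.numeric(track$value)
  if (any(!is.finite(s)) || any(!is.finite(e)) || any(!is.finite(v))) {
    stop("track coordinates and values must be finite", call. = FALSE)
  }
  if (any(v < 0)) stop("negative depth values are not allowed", call. = FALSE)
  if (any(s < 0) || any(e > L) || any(e <= s)) {
    stop("track intervals must satisfy 0 <= start < end <= genome length",
         call. = FALSE)
  }
  o <- order(s)
  if (any(e[o][-length(o)] > s[o][-1L])) {
    stop("overlapping depth intervals are self-contradictory; merge upstream",
         call. = FALSE)
  }

  nb <- n_bins_for(genome, bin_size)
  acc <- numeric(nb)
  for (i in seq_along(s)) {
    b0 <- floor(s[i] / bin_size)
    b1 <- floor((e[i] - 1) / bin_size)
    bs <- (b0:b1) * bin_size
    ov <- pmin(e[i], bs + bin_size) - pmax(s[i], bs)
    acc[(b0:b1) + 1L] <- acc[(b0:b1) + 1L] + v[i] * ov
  }
  widths <- pmin(bin_starts(genome, bin_size) + bin_size, L) -
    bin_starts(genome, bin_size)
  coverage_profile(genome, bin_size, acc / widths)
}

#' Normalize coverage to a marker-frequency profile
#'
#' Divides every bin by the genome-wide mean bin depth, yielding relative
#' copy number with arithmetic mean exactly 1. This is the "normalized
#' average reads per position" scale on which oriC peak height and area
#' are quantified.
#'
#' @param cov A [coverage_profile()].
#' @return An object of class `mfa_profile` (fields `genome`, `bin_size`,
#'   `values`, `sigma`; `sigma = 0` means unsmoothed).
#' @export
normalize_profile <- function(cov) {
  stopifnot(inherits(cov, "coverage_profile"))
  m <- mean(cov$values)
  if (m <= 0) stop("all-zero coverage: no signal to normalize", call. = FALSE)
  new_mfa_profile(cov$genome, cov$bin_size, cov$values / m, sigma = 0)
}

new_mfa_profile <- function(genome, bin_size, values, sigma) {
  structure(list(genome = genome, bin_size = as.numeric(bin_size),
                 values = as.numeric(values), sigma = as.numeric(sigma)),
            class = "mfa_profile")
}

#' @export
print.mfa_profile <- function(x, ...) {
  cat(sprintf("<mfa_profile> %s: %d bins of %g bp, sigma=%g bins, range [%.3f, %.3f]\n",
              x$genome$name, length(x$values), x$bin_size, x$sigma,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.mfa_profile <- function(x, ...) {
  data.frame(bin_start = bin_starts(x$genome, x$bin_size), value = x$values)
}

gaussian_kernel <- function(sigma) {
  h <- ceiling(4 * sigma)
  w <- stats::dnorm(-h:h, sd = sigma)
  w / sum(w)
}

#' Gaussian smoothing of an MFA profile
#'
#' Convolves the profile with a discrete Gaussian kernel of bandwidth
#' `sigma` (in bins), truncated at +/- 4 sigma and normalized to sum 1.
#' With `circular = TRUE` (the default, and the correct choice for a
#' circular chromosome -- the *P. furiosus* peak sits at coordinate 0)
#' the convolution wraps around the coordinate origin and preserves the
#' profile mean exactly. Linear smoothing renormalizes the truncated kernel
#' at the edges and is flagged with a warning, since it distorts the ends
#' of the track.
#'
#' @param mfa An `mfa_profile` (see [normalize_profile()]).
#' @param sigma Bandwidth in bins (>= 0); 0 returns the input unchanged.
#' @param circular Wrap around the origin of coordinates? Default `TRUE`.
#' @return A smoothed `mfa_profile` with `sigma` recorded.
#' @export
gaussian_smooth <- function(mfa, sigma = 10, circular = TRUE) {
  stopifnot(inherits(mfa, "mfa_profile"))
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma < 0) {
    stop("`sigma` must be a finite scalar >= 0", call. = FALSE)
  }
  if (sigma == 0) return(mfa)
  x <- mfa$values
  n <- length(x)
  w <- gaussian_kernel(sigma)
  h <- (length(w) - 1L) %/% 2L
  out <- numeric(n)
  if (circular) {
    ## modular indexing handles kernels wider than the profile
    for (j in -h:h) {
      out <- out + w[j + h + 1L] * x[((seq_len(n) - 1L + j) %% n) + 1L]
    }
  } else {
    warning("linear (non-circular) smoothing distorts profile edges",
            call. = FALSE)
    wsum <- numeric(n)
    for (j in -h:h) {
      idx <- seq_len(n) + j
      ok <- idx >= 1L & idx <= n
      out[ok] <- out[ok] + w[j + h + 1L] * x[idx[ok]]
      wsum[ok] <- wsum[ok] + w[j + h + 1L]
    }
    out <- out / wsum
  }
  new_mfa_profile(mfa$genome, mfa$bin_size, out, sigma = sigma)
}
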