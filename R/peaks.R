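#' Detect and quantify the oriC peak of an MFA profile
#'
#' The apex is the maximum bin within `window` bp (circular distance) of the
#' annotated origin; ties are broken toward the bin nearest the origin, then
#' toward the lowest coordinate. The baseline is the median of all bins
#' farther than L/4 from the origin (the far half of the chromosome, robust
#' to peak leakage). Peak height is apex minus baseline, and the peak is
#' called detected when the height reaches `min_height`. The support bounds
#' are the first bins on each side of the apex where the baseline-subtracted
#' profile drops to or below zero, clipped at the antipode.
#'
#' @param mfa An `mfa_profile`, normally smoothed (an unsmoothed profile is
#'   accepted with a warning).
#' @param ori Origin coordinate in bp; defaults to the genome annotation.
#' @param window Search half-width around the origin in bp (<= L/2).
#' @param min_height Detection threshold in relative copy-number units.
#'   The default 0.05 keeps false detections on origin-less (pure RDR)
#'   profiles rare at typical simulated depths.
#' @param baseline Optional fixed baseline level; by default the far-half
#'   median is used.
#' @return An object of class `peak_call` with fields `apex_position`,
#'   `apex_value`, `baseline`, `height`, `area`, `left_bound`,
#'   `right_bound`, `detected`.
#' @export
detect_ori_peak <- function(mfa, ori = mfa$genome$ori_position,
                            window = mfa$genome$length / 10,
                            min_height = 0.05, baseline = NULL) {
  stopifnot(inherits(mfa, "mfa_profile"))
  L <- mfa$genome$length
  if (window > L / 2) stop("`window` must not exceed L/2", call. = FALSE)
  if (ori < 0 || ori >= L) stop("`ori` must lie in [0, L)", call. = FALSE)
  if (mfa$sigma == 0) {
    warning("peak detection on an unsmoothed profile (sigma = 0)", call. = FALSE)
  }
  v <- mfa$values
  n <- length(v)
  pos <- bin_starts(mfa$genome, mfa$bin_size)
  d_ori <- circular_distance(pos, ori, L, mfa$genome$circular)

  near <- which(d_ori <= window)
  vmax <- max(v[near])
  cand <- near[v[near] == vmax]
  cand <- cand[order(d_ori[cand], pos[cand])]
  apex_idx <- cand[1L]

  if (is.null(baseline)) {
    far <- d_ori > L / 4
    if (!any(far)) stop("no bins beyond L/4 from ori; profile too coarse", call. = FALSE)
    baseline <- stats::median(v[far])
  }

  height <- vmax - baseline
  detected <- height >= min_height

  ## walk outward from the apex until the excess profile touches zero,
  ## at most half the chromosome each way
  excess <- v - baseline
  half <- n %/% 2L
  step_bound <- function(dir) {
    k <- 0L
    while (k < half) {
      k <- k + 1L
      i <- ((apex_idx - 1L + dir * k) %% n) + 1L
      if (excess[i] <= 0) break
    }
    ((apex_idx - 1L + dir * k) %% n) + 1L
  }
  li <- step_bound(-1L)
  ri <- step_bound(+1L)

  peak <- structure(
    list(apex_position = pos[apex_idx], apex_value = vmax,
         baseline = baseline, height = height, area = 0,
         left_bound = pos[li], right_bound = pos[ri],
         detected = detected,
         .apex_idx = apex_idx, .left_idx = li, .right_idx = ri),
    class = "peak_call"
  )
  peak$area <- peak_area(mfa, peak)
  peak
}

#' @export
print.peak_call <- function(x, ...) {
  cat(sprintf(paste0("<peak_call> %s: apex %.4f at %s bp, baseline %.4f, ",
                     "height %.4f, area %.4g\n"),
              if (x$detected) "detected" else "not detected",
              x$apex_value, format(x$apex_position, big.mark = ","),
              x$baseline, x$height, x$area))
  invisible(x)
}

#' Integrated area of a called peak
#'
#' Trapezoidal integration of the positive part of the baseline-subtracted
#' profile between the peak bounds (walking circularly through the apex),
#' in relative copy-number units times bp. An undetected peak has area 0.
#'
#' @param mfa The `mfa_profile` the peak was called on.
#' @param peak A `peak_call`.
#' @return Peak area (relative units x bp).
#' @export
peak_area <- function(mfa, peak) {
  stopifnot(inherits(mfa, "mfa_profile"), inherits(peak, "peak_call"))
  if (!peak$detected) return(0)
  n <- length(mfa$values)
  span <- (peak$.right_idx - peak$.left_idx) %% n
  ## both bounds at the antipode: the support is the whole circle
  if (span == 0L && peak$.left_idx != peak$.apex_idx) span <- n
  idx <- ((peak$.left_idx - 1L + 0:span) %% n) + 1L
  y <- pmax(mfa$values[idx] - peak$baseline, 0)
  if (length(y) < 2L) return(0)
  sum((y[-length(y)] + y[-1L]) / 2) * mfa$bin_size
}

#' Estimate the oriC-initiation fraction from peak geometry
#'
#' Inverts the two-mode expected copy-number model. With the peak-to-trough
#' contrast \eqn{k = \mathrm{apex}/\mathrm{trough} - 1} (the trough being
#' the profile minimum near the antipode of the origin), the origin-firing
#' fraction is
#' \deqn{\hat f = \frac{k (1 + r/2)}{r (1 + k/2)}}
#' exact on noiseless profiles. The replicating fraction r must be supplied:
#' f and r are not jointly identifiable from profile shape alone, since
#' profiles with equal contrast k are bin-wise identical after
#' normalization.
#'
#' @param mfa The `mfa_profile` the peak was called on.
#' @param peak A detected `peak_call`.
#' @param r Replicating fraction in (0, 1].
#' @param trough_window Half-width (bp) of the antipodal region searched for
#'   the trough; default L/10.
#' @return Estimated origin-firing fraction, clipped to \[0, 1\].
#' @export
estimate_ori_fraction <- function(mfa, peak, r,
                                  trough_window = mfa$genome$length / 10) {
  stopifnot(inherits(mfa, "mfa_profile"), inherits(peak, "peak_call"))
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0 || r > 1) {
    stop("`r` must lie in (0, 1]: f is unidentifiable at r = 0", call. = FALSE)
  }
  if (!peak$detected && peak$height <= 0) return(0)
  L <- mfa$genome$length
  pos <- bin_starts(mfa$genome, mfa$bin_size)
  anti <- (peak$apex_position + L / 2) %% L
  near_anti <- circular_distance(pos, anti, L, mfa$genome$circular) <= trough_window
  trough <- min(mfa$values[near_anti])
  if (trough <= 0) stop("non-positive trough value; profile degenerate", call. = FALSE)
  k <- peak$apex_value / trough - 1
  if (k <= 0) return(0)
  f_hat <- k * (1 + r / 2) / (r * (1 + k / 2))
  min(max(f_hat, 0), 1)
}

#' Peak height and area along a growth time course
#'
#' Calls the oriC peak in each sample of a time course and assembles the
#' Fig.-5-style summary table: one row per sample with apex position,
#' baseline, height, area and detection flag, sorted by time. Undetected
#' peaks are reported with height and area 0 (not NA) so that time-course
#' plots stay continuous.
#'
#' @param samples A list of samples, each a list with `label` (unique),
#'   `hours` (numeric time) and `mfa` (an `mfa_profile`).
#' @param ori Origin coordinate; default from each sample's genome.
#' @param window Search half-width in bp passed to [detect_ori_peak()].
#' @param min_height Detection threshold passed to [detect_ori_peak()].
#' @return A data frame (label, hours, apex_position, baseline, height,
#'   area, detected) sorted by hours.
#' @export
timecourse_summary <- function(samples, ori = NULL, window = NULL,
                               min_height = 0.05) {
  if (!is.list(samples) || length(samples) == 0L) {
    stop("`samples` must be a non-empty list", call. = FALSE)
  }
  labels <- vapply(samples, function(s) as.character(s$label), "")
  if (anyDuplicated(labels)) {
    stop("duplicate sample labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(samples, function(s) {
    mfa <- s$mfa
    stopifnot(inherits(mfa, "mfa_profile"))
    pk <- detect_ori_peak(
      mfa,
      ori = if (is.null(ori)) mfa$genome$ori_position else ori,
      window = if (is.null(window)) mfa$genome$length / 10 else window,
      min_height = min_height
    )
    data.frame(label = as.character(s$label), hours = as.numeric(s$hours),
               apex_position = pk$apex_position, baseline = pk$baseline,
               height = if (pk$detected) pk$height else 0,
               area = pk$area, detected = pk$detected)
  })
  out <- do.call(rbind, rows)
  out[order(out$hours), , drop = FALSE]
}
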