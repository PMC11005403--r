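#' Loading-normalized band volume of a western-blot lane
#'
#' Normalizes a chemiluminescence band volume to the total protein of the
#' lane (stain-free imaging), using the reference lane's total protein as
#' the anchor: normalization factor = reference total / lane total, and
#' normalized volume = band volume x factor. Scaling a lane's loading
#' (band and total together) leaves the result unchanged.
#'
#' @param band_volume Band intensity volume of the lane (>= 0).
#' @param total_protein Total-protein signal of the lane (> 0).
#' @param reference_total Total-protein signal of the reference lane (> 0).
#' @return Normalized band volume.
#' @examples
#' normalize_lane(100, total_protein = 25, reference_total = 50) # 200
#' @export
normalize_lane <- function(band_volume, total_protein, reference_total) {
  if (any(!is.finite(band_volume)) || any(band_volume < 0)) {
    stop("`band_volume` must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(total_protein)) || any(total_protein <= 0) ||
      any(!is.finite(reference_total)) || any(reference_total <= 0)) {
    stop("total-protein signals must be finite and > 0", call. = FALSE)
  }
  band_volume * reference_total / total_protein
}

#' Expression relative to a reference lane
#'
#' 100 x normalized lane volume / normalized reference volume: the percent
#' of the reference lane's protein level. The reference maps to 100% of
#' itself.
#'
#' @param lane_norm Normalized volume of the lane of interest.
#' @param reference_norm Normalized volume of the reference lane (> 0).
#' @return Percent of reference.
#' @export
relative_expression <- function(lane_norm, reference_norm) {
  if (any(!is.finite(reference_norm)) || any(reference_norm <= 0)) {
    stop("`reference_norm` must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(lane_norm)) || any(lane_norm < 0)) {
    stop("`lane_norm` must be finite and >= 0", call. = FALSE)
  }
  100 * lane_norm / reference_norm
}

#' Summarize replicate blots as percent of a reference lane
#'
#' Applies lane normalization and percent-of-reference scaling within each
#' experiment (replicate blot), then summarizes each lane label across
#' experiments by mean and SD.
#'
#' @param lanes Data frame with columns `lane`, `band_volume`,
#'   `total_protein`, `experiment`.
#' @param reference Lane label used as the 100% reference in every
#'   experiment.
#' @return Data frame (lane, mean_percent, sd_percent, n).
#' @export
blot_summary <- function(lanes, reference) {
  need <- c("lane", "band_volume", "total_protein", "experiment")
  if (!is.data.frame(lanes) || !all(need %in% names(lanes))) {
    stop("`lanes` needs columns lane, band_volume, total_protein, experiment",
         call. = FALSE)
  }
  per_exp <- lapply(split(lanes, lanes$experiment), function(d) {
    ref <- d[d$lane == reference, , drop = FALSE]
    if (nrow(ref) != 1L) {
      stop(sprintf("experiment '%s' needs exactly one reference lane '%s'",
                   d$experiment[1L], reference), call. = FALSE)
    }
    norm <- normalize_lane(d$band_volume, d$total_protein, ref$total_protein)
    ref_norm <- norm[d$lane == reference]
    data.frame(lane = d$lane, percent = relative_expression(norm, ref_norm))
  })
  all <- do.call(rbind, per_exp)
  agg <- lapply(split(all$percent, all$lane), function(p) {
    c(mean = mean(p), sd = if (length(p) > 1L) stats::sd(p) else NA_real_,
      n = length(p))
  })
  out <- data.frame(lane = names(agg),
                    mean_percent = vapply(agg, `[[`, 0, "mean"),
                    sd_percent = vapply(agg, `[[`, 0, "sd"),
                    n = vapply(agg, `[[`, 0, "n"))
  rownames(out) <- NULL
  out
}
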