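#' Define a (circular) chromosome
#'
#' A genome definition carries the minimal geometry MFA needs: the chromosome
#' length, whether it is circular, and the annotated position of the
#' replication origin (oriC). Thermococcales carry a single circular
#' chromosome with one origin; the origins of the three reference species
#' sit at 1,712,000 bp (*T. kodakarensis*), 0 bp (*P. furiosus*) and
#' 1,671,000 bp (*T. barophilus*).
#'
#' All coordinates in this package are 0-based; bins are half-open
#' `[start, start + bin_size)` intervals. Note that genome-browser style
#' 1-based positions must be shifted by one.
#'
#' @param length Chromosome length in bp (positive integer).
#' @param ori_position oriC coordinate in `[0, length)`.
#' @param name Chromosome/strain label.
#' @param circular Is the chromosome circular? Default `TRUE`.
#'
#' @return An object of class `genome_def`.
#' @examples
#' tbar <- genome_def(2010000, ori_position = 1671000, name = "T.barophilus")
#' @export
genome_def <- function(length, ori_position, name = "chr", circular = TRUE) {
  if (!is.numeric(length) || length(length) != 1L || !is.finite(length) ||
      length < 2 || length != floor(length)) {
    stop("`length` must be a single positive integer >= 2", call. = FALSE)
  }
  if (!is.numeric(ori_position) || length(ori_position) != 1L ||
      !is.finite(ori_position) || ori_position < 0 || ori_position >= length) {
    stop("`ori_position` must lie in [0, length)", call. = FALSE)
  }
  structure(
    list(name = as.character(name)[1L], length = as.numeric(length),
         circular = isTRUE(circular), ori_position = as.numeric(ori_position)),
    class = "genome_def"
  )
}

#' @export
print.genome_def <- function(x, ...) {
  cat(sprintf("<genome_def> %s: %s bp, %s, oriC at %s bp\n",
              x$name, format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear",
              format(x$ori_position, big.mark = ",")))
  invisible(x)
}

#' Circular distance between coordinates
#'
#' Shortest distance between positions on a circle of circumference `L`
#' (at most `L/2`). On a linear genome this is plain absolute distance.
#'
#' @param x,y Coordinates (vectors recycle).
#' @param L Circumference in bp.
#' @param circular Wrap around the origin of coordinates? Default `TRUE`.
#' @return Numeric vector of distances.
#' @export
circular_distance <- function(x, y, L, circular = TRUE) {
  d <- abs(x - y)
  if (circular) pmin(d, L - d) else d
}

## Membership of position x in the circular arc [a, a + w) mod L.
## Vectorised over x; a scalar, w scalar in [0, L].
in_circular_arc <- function(x, a, w, L) {
  if (w >= L) return(rep(TRUE, length(x)))
  off <- (x - a) %% L
  off < w
}

n_bins_for <- function(genome, bin_size) as.integer(ceiling(genome$length / bin_size))

## 0-based start coordinates and midpoints of the bin grid
bin_starts <- function(genome, bin_size) (seq_len(n_bins_for(genome, bin_size)) - 1) * bin_size
bin_mids <- function(genome, bin_size) {
  s <- bin_starts(genome, bin_size)
  e <- pmin(s + bin_size, genome$length)
  (s + e) / 2
}
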