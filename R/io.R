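#' Read a depth track (bedGraph or two-column TSV)
#'
#' Reads sequencing depth along a chromosome from either a 4-column
#' bedGraph (`chrom start end value`, 0-based half-open) or a 2-column
#' TSV of per-position depth (`position depth`, 0-based; each row becomes
#' a width-1 interval). `track` and comment (`#`, `browser`) lines are
#' skipped. Input must describe the single chromosome of `genome` --
#' multi-contig files and chromosome-name mismatches are rejected.
#' Intervals running past the chromosome end are an error unless
#' `wrap = TRUE` on a circular genome, in which case they are split at the
#' coordinate origin.
#'
#' @param path Input file.
#' @param genome A [genome_def()].
#' @param wrap Allow intervals crossing the origin of a circular genome?
#' @return Data frame with columns `start`, `end`, `value`, ready for
#'   [bin_coverage()].
#' @export
read_depth <- function(path, genome, wrap = FALSE) {
  stopifnot(inherits(genome, "genome_def"))
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path), call. = FALSE)
  lines <- readLines(path)
  lineno <- seq_along(lines)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]; lineno <- lineno[keep]
  if (length(lines) == 0L) stop(sprintf("'%s': no data lines", path), call. = FALSE)

  fields <- strsplit(lines, "[\t ]+")
  nf <- lengths(fields)
  bad <- which(!(nf %in% c(2L, 4L)))
  if (length(bad)) {
    stop(sprintf("'%s': malformed line %d (expected 2 or 4 fields, got %d)",
                 path, lineno[bad[1L]], nf[bad[1L]]), call. = FALSE)
  }
  if (length(unique(nf)) != 1L) {
    stop(sprintf("'%s': mixed 2- and 4-column records (first at line %d)",
                 path, lineno[which(nf != nf[1L])[1L]]), call. = FALSE)
  }

  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(vapply(fields, `[`, "", col)))
    if (anyNA(v)) {
      stop(sprintf("'%s': non-numeric %s at line %d", path, what,
                   lineno[which(is.na(v))[1L]]), call. = FALSE)
    }
    v
  }

  if (nf[1L] == 4L) {
    chrom <- vapply(fields, `[`, "", 1L)
    if (length(unique(chrom)) > 1L) {
      stop(sprintf("'%s': multiple contigs (%s); single-chromosome input required",
                   path, paste(unique(chrom), collapse = ", ")), call. = FALSE)
    }
    if (chrom[1L] != genome$name) {
      stop(sprintf("'%s': chromosome '%s' does not match genome '%s'",
                   path, chrom[1L], genome$name), call. = FALSE)
    }
    out <- data.frame(start = num(2L, "start"), end = num(3L, "end"),
                      value = num(4L, "value"))
  } else {
    pos <- num(1L, "position")
    out <- data.frame(start = pos, end = pos + 1, value = num(2L, "depth"))
  }

  L <- genome$length
  if (any(out$start < 0)) {
    stop(sprintf("'%s': negative coordinate at line %d", path,
                 lineno[which(out$start < 0)[1L]]), call. = FALSE)
  }
  over <- out$end > L
  if (any(over)) {
    if (!(wrap && genome$circular)) {
      stop(sprintf("'%s': interval end %g exceeds genome length %g at line %d (use wrap = TRUE on a circular genome)",
                   path, out$end[which(over)[1L]], L, lineno[which(over)[1L]]),
           call. = FALSE)
    }
    if (any(out$start >= L)) {
      stop(sprintf("'%s': start coordinate beyond genome length at line %d",
                   path, lineno[which(out$start >= L)[1L]]), call. = FALSE)
    }
    wrapped <- out[over, , drop = FALSE]
    out <- rbind(
      out[!over, , drop = FALSE],
      data.frame(start = wrapped$start, end = L, value = wrapped$value),
      data.frame(start = 0, end = wrapped$end - L, value = wrapped$value)
    )
  }
  out[order(out$start), , drop = FALSE]
}

#' Write a coverage or MFA profile as bedGraph
#'
#' One record per bin (`chrom start end value`, 0-based half-open); the
#' last record is clipped at the chromosome end.
#'
#' @param x A `coverage_profile` or `mfa_profile`.
#' @param path Output path.
#' @param digits Significant digits for values; `NA` writes full precision.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path, digits = NA) {
  stopifnot(inherits(x, "coverage_profile") || inherits(x, "mfa_profile"))
  s <- bin_starts(x$genome, x$bin_size)
  e <- pmin(s + x$bin_size, x$genome$length)
  v <- if (is.na(digits)) format(x$values, digits = 17, trim = TRUE, scientific = FALSE)
       else formatC(x$values, digits = digits, format = "g")
  ok <- try(writeLines(paste(x$genome$name, format(s, scientific = FALSE, trim = TRUE),
                             format(e, scientific = FALSE, trim = TRUE), v,
                             sep = "\t"), path), silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop(sprintf("cannot write '%s'", path), call. = FALSE)
  }
  invisible(path)
}

#' Write an MFA profile as a two-column TSV
#'
#' Columns `bin_start` (0-based) and `mfa_value`, with provenance recorded
#' in `#`-prefixed header lines.
#'
#' @param mfa An `mfa_profile`.
#' @param path Output path.
#' @param provenance Optional named character vector added to the header.
#' @return `path`, invisibly.
#' @export
write_mfa_tsv <- function(mfa, path, provenance = NULL) {
  stopifnot(inherits(mfa, "mfa_profile"))
  hdr <- c(sprintf("# mfakit mfa profile; genome=%s length=%g ori=%g bin_size=%g sigma=%g",
                   mfa$genome$name, mfa$genome$length, mfa$genome$ori_position,
                   mfa$bin_size, mfa$sigma),
           if (!is.null(provenance)) sprintf("# %s=%s", names(provenance), provenance),
           "bin_start\tmfa_value")
  body <- paste(format(bin_starts(mfa$genome, mfa$bin_size),
                       scientific = FALSE, trim = TRUE),
                format(mfa$values, digits = 17, trim = TRUE, scientific = FALSE),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
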