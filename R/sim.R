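#' Simulation parameters for a replicating polyploid population
#'
#' Describes an asynchronous population of `n_chromosomes` chromosome copies
#' (pooled over cells; each cell of a polyploid Thermococcale carries many),
#' of which a fraction `replicating_fraction` (r) are mid-replication. A
#' replicating chromosome fired either at oriC, with probability
#' `ori_fraction` (f), or -- modelling dispersed recombination-dependent
#' replication (RDR) -- at a uniformly random site with probability 1 - f.
#' Replication is bidirectional from the initiation site and replication
#' progress is Uniform(0, 1), the steady-state of an asynchronous culture.
#'
#' @param genome A [genome_def()].
#' @param n_chromosomes Number of chromosomes in the pool (N >= 1).
#' @param replicating_fraction r, fraction of chromosomes mid-replication, in \[0, 1\].
#' @param ori_fraction f, probability a firing occurred at oriC, in \[0, 1\].
#' @param mean_depth_per_copy lambda, expected reads per bin per chromosome copy (> 0).
#' @param bin_size Bin width in bp.
#' @param seed Integer seed; the one source of randomness for a simulation.
#'
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(genome, n_chromosomes, replicating_fraction, ori_fraction,
                       mean_depth_per_copy, bin_size = 1000, seed = 1L) {
  stopifnot(inherits(genome, "genome_def"))
  chk_scalar <- function(x, nm, lo = -Inf, hi = Inf) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
      stop(sprintf("`%s` must be a finite scalar in [%s, %s]", nm, lo, hi),
           call. = FALSE)
    }
  }
  chk_scalar(n_chromosomes, "n_chromosomes", 1)
  chk_scalar(replicating_fraction, "replicating_fraction", 0, 1)
  chk_scalar(ori_fraction, "ori_fraction", 0, 1)
  chk_scalar(mean_depth_per_copy, "mean_depth_per_copy")
  if (mean_depth_per_copy <= 0) stop("`mean_depth_per_copy` must be > 0", call. = FALSE)
  chk_scalar(bin_size, "bin_size", 1)
  chk_scalar(seed, "seed")
  if (genome$length < 2 * bin_size) {
    stop("genome length must be at least twice the bin size", call. = FALSE)
  }
  structure(
    list(genome = genome, n_chromosomes = as.integer(n_chromosomes),
         replicating_fraction = replicating_fraction,
         ori_fraction = ori_fraction,
         mean_depth_per_copy = mean_depth_per_copy,
         bin_size = as.numeric(bin_size), seed = as.integer(seed)),
    class = "sim_params"
  )
}

#' Expected copy number under the two-mode initiation model
#'
#' Closed-form per-chromosome expected copy number at position x for the
#' mixture of oriC-initiated and dispersed (RDR) initiation:
#' \deqn{E[c(x)] = 1 + r\left[\frac{1-f}{2} + f\left(1 - \frac{2d(x)}{L}\right)\right]}
#' where d(x) is the circular distance from x to oriC (<= L/2). The first
#' mixture term is the coverage probability of a uniformly placed arc of
#' Uniform(0,1) relative length (= 1/2); the second is the probability that
#' an ori-centred arc of half-width pL/2 with p ~ Uniform(0,1) reaches x.
#' The profile is maximal at oriC and minimal at the antipode; its
#' genome-wide mean is 1 + r/2.
#'
#' @param params A [sim_params()].
#' @param position Coordinate(s) in `[0, L)`.
#' @return Expected copies per chromosome (>= 1), vectorised over `position`.
#' @export
expected_copy_number <- function(params, position) {
  stopifnot(inherits(params, "sim_params"))
  L <- params$genome$length
  if (any(!is.finite(position)) || any(position < 0) || any(position >= L)) {
    stop("`position` must lie in [0, L)", call. = FALSE)
  }
  d <- circular_distance(position, params$genome$ori_position, L,
                         params$genome$circular)
  r <- params$replicating_fraction
  f <- params$ori_fraction
  1 + r * ((1 - f) / 2 + f * (1 - 2 * d / L))
}

#' Simulate coverage from a replicating population
#'
#' Draws the replication state of every chromosome (replicating or not,
#' initiation site, progress), computes the per-bin total copy number of the
#' pool, and samples per-bin read counts as Poisson with mean
#' `lambda * total copies`. Bin membership of the replicated arc is evaluated
#' at bin midpoints. A chromosome mid-replication contributes copy number 2
#' inside its replicated arc (a circular interval of length `p * L` centred
#' on the initiation site) and 1 outside; a non-replicating chromosome
#' contributes 1 everywhere. Identical seeds give identical output.
#'
#' @param params A [sim_params()].
#' @return An object of class `sim_truth`: a list with `params`, `states`
#'   (data frame of per-chromosome replication states), and `coverage`
#'   (a [coverage_profile()] of simulated per-bin read counts).
#' @examples
#' g <- genome_def(200000, ori_position = 50000)
#' p <- sim_params(g, n_chromosomes = 200, replicating_fraction = 0.6,
#'                 ori_fraction = 0.8, mean_depth_per_copy = 5, seed = 42)
#' sim <- simulate_population(p)
#' mean(sim$coverage$values) # ~ N * lambda * (1 + r/2)
#' @export
simulate_population <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  g <- params$genome
  L <- g$length
  N <- params$n_chromosomes
  nb <- n_bins_for(g, params$bin_size)
  mids <- bin_mids(g, params$bin_size)

  ## one RNG stream for the whole simulation, restored on exit
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(params$seed)

  replicating <- stats::runif(N) < params$replicating_fraction
  at_ori <- stats::runif(N) < params$ori_fraction
  init_site <- ifelse(at_ori, g$ori_position, stats::runif(N, 0, L))
  progress <- stats::runif(N)
  init_site[!replicating] <- NA_real_
  progress[!replicating] <- NA_real_

  ## total copies per bin: N baseline plus one extra inside each replicated arc
  copies <- rep(as.numeric(N), nb)
  idx <- which(replicating)
  for (i in idx) {
    w <- progress[i] * L
    a <- (init_site[i] - w / 2) %% L
    copies <- copies + in_circular_arc(mids, a, w, L)
  }

  counts <- stats::rpois(nb, params$mean_depth_per_copy * copies)

  cov <- coverage_profile(g, params$bin_size, as.numeric(counts))
  structure(
    list(params = params,
         states = data.frame(replicating = replicating,
                             init_site = init_site, progress = progress),
         coverage = cov),
    class = "sim_truth"
  )
}

#' @export
print.sim_truth <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("<sim_truth> N=%d chromosomes, r=%.3g, f=%.3g, ",
                     "lambda=%.3g, %d bins of %g bp (seed %d)\n"),
              p$n_chromosomes, p$replicating_fraction, p$ori_fraction,
              p$mean_depth_per_copy, length(x$coverage$values), p$bin_size,
              p$seed))
  invisible(x)
}

#' Write / read simulated truth
#'
#' `write_truth()` emits the simulated coverage as bedGraph and the
#' generating parameters (including the seed) as a flat `key=value` sidecar
#' (`<path>.params`). `read_truth()` round-trips both, so that re-running
#' [simulate_population()] with the recorded parameters reproduces the
#' coverage bit-for-bit.
#'
#' @param sim A `sim_truth`.
#' @param path Output bedGraph path; the sidecar gets a `.params` suffix.
#' @return `write_truth()` returns `path` invisibly; `read_truth()` returns
#'   a list with `params` and `coverage`.
#' @export
write_truth <- function(sim, path) {
  stopifnot(inherits(sim, "sim_truth"))
  write_bedgraph(sim$coverage, path)
  p <- sim$params
  kv <- c(name = p$genome$name, length = p$genome$length,
          circular = as.integer(p$genome$circular),
          ori_position = p$genome$ori_position,
          n_chromosomes = p$n_chromosomes,
          replicating_fraction = p$replicating_fraction,
          ori_fraction = p$ori_fraction,
          mean_depth_per_copy = p$mean_depth_per_copy,
          bin_size = p$bin_size, seed = p$seed)
  side <- paste0(path, ".params")
  ok <- try(writeLines(paste(names(kv), kv, sep = "="), side), silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop(sprintf("cannot write parameter sidecar '%s'", side), call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  side <- paste0(path, ".params")
  if (!file.exists(side)) stop(sprintf("missing sidecar '%s'", side), call. = FALSE)
  kvl <- strsplit(readLines(side), "=", fixed = TRUE)
  kv <- stats::setNames(vapply(kvl, `[`, "", 2L), vapply(kvl, `[`, "", 1L))
  g <- genome_def(as.numeric(kv[["length"]]), as.numeric(kv[["ori_position"]]),
                  name = kv[["name"]], circular = kv[["circular"]] == "1")
  params <- sim_params(g, as.numeric(kv[["n_chromosomes"]]),
                       as.numeric(kv[["replicating_fraction"]]),
                       as.numeric(kv[["ori_fraction"]]),
                       as.numeric(kv[["mean_depth_per_copy"]]),
                       bin_size = as.numeric(kv[["bin_size"]]),
                       seed = as.numeric(kv[["seed"]]))
  track <- read_depth(path, g)
  cov <- bin_coverage(track, g, params$bin_size)
  list(params = params, coverage = cov)
}
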