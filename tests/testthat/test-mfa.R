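test_that("bin_coverage averages per-position and interval tracks", {
  g <- genome_def(4, 0, name = "g4")
  track <- data.frame(start = 0:3, end = 1:4, value = c(2, 2, 4, 4))
  expect_equal(bin_coverage(track, g, 2)$values, c(2, 4))

  g10 <- genome_def(10, 0, name = "g10")
  one <- data.frame(start = 0, end = 10, value = 3)
  expect_equal(bin_coverage(one, g10, 5)$values, c(3, 3))

  # bin_size 1 is the identity on a per-position track
  set.seed(5)
  depth <- rpois(10, 8)
  pp <- data.frame(start = 0:9, end = 1:10, value = depth)
  expect_equal(bin_coverage(pp, g10, 1)$values, as.numeric(depth))

  # length-weighted split across a bin edge, and partial last bin
  g7 <- genome_def(7, 0, name = "g7")
  tr <- data.frame(start = c(0, 3), end = c(3, 7), value = c(2, 6))
  # bins [0,5): (2*3 + 6*2)/5 = 3.6 ; [5,7): 6
  expect_equal(bin_coverage(tr, g7, 5)$values, c(3.6, 6))
})

test_that("bin_coverage rejects bad tracks", {
  g <- genome_def(10, 0, name = "g")
  expect_error(bin_coverage(data.frame(start = 0, end = 2, value = -1), g, 2),
               "negative")
  expect_error(bin_coverage(data.frame(start = c(0, 1), end = c(3, 4),
                                       value = c(1, 2)), g, 2), "overlap")
  expect_error(bin_coverage(data.frame(start = 8, end = 12, value = 1), g, 2),
               "genome length")
})

test_that("normalization yields mean exactly 1 and is idempotent", {
  g <- genome_def(4, 0, name = "g")
  cp <- function(v) coverage_profile(g, 1, v)
  expect_equal(normalize_profile(cp(c(2, 2, 2, 2)))$values, rep(1, 4))
  expect_equal(normalize_profile(cp(c(1, 3, 1, 3)))$values, c(0.5, 1.5, 0.5, 1.5))
  expect_equal(normalize_profile(cp(c(0, 4, 4, 0)))$values, c(0, 2, 2, 0))
  expect_error(normalize_profile(cp(c(0, 0, 0, 0))), "no signal")

  set.seed(9)
  v <- rpois(64, 30)
  g64 <- genome_def(64, 0, name = "g64")
  n1 <- normalize_profile(coverage_profile(g64, 1, v))
  expect_equal(mean(n1$values), 1, tolerance = 1e-12)
  n2 <- normalize_profile(coverage_profile(g64, 1, n1$values))
  expect_equal(n2$values, n1$values, tolerance = 1e-12)
})

test_that("gaussian_smooth matches a brute-force circular convolution oracle", {
  n <- 50
  g <- genome_def(n, 0, name = "g")
  set.seed(21)
  v <- runif(n, 0.5, 1.5)
  mfa <- make_profile(g, v, bin_size = 1, sigma = 0)
  for (sigma in c(1, 2.5, 7)) {
    sm <- gaussian_smooth(mfa, sigma = sigma, circular = TRUE)
    # independent oracle: explicit double loop over truncated kernel
    h <- ceiling(4 * sigma)
    w <- dnorm(-h:h, sd = sigma); w <- w / sum(w)
    oracle <- numeric(n)
    for (i in seq_len(n)) {
      for (j in -h:h) {
        oracle[i] <- oracle[i] + w[j + h + 1] * v[((i - 1 + j) %% n) + 1]
      }
    }
    expect_equal(sm$values, oracle, tolerance = 1e-12)
  }
})

test_that("smoothing preserves constants, sigma 0, the circular mean, and shifts", {
  n <- 64
  g <- genome_def(n, 0, name = "g")
  const <- make_profile(g, rep(1.25, n), bin_size = 1)
  expect_equal(gaussian_smooth(const, 5)$values, rep(1.25, n), tolerance = 1e-12)

  set.seed(31)
  v <- runif(n)
  mfa <- make_profile(g, v, bin_size = 1)
  expect_identical(gaussian_smooth(mfa, 0)$values, v)
  sm <- gaussian_smooth(mfa, 4)
  expect_equal(mean(sm$values), mean(v), tolerance = 1e-12)

  # unit impulse reproduces the normalized truncated kernel
  imp <- make_profile(g, c(rep(0, 20), 1, rep(0, n - 21)), bin_size = 1)
  smi <- gaussian_smooth(imp, 2)$values
  w <- dnorm(-8:8, sd = 2); w <- w / sum(w)
  expect_equal(smi[(21 - 8):(21 + 8)], w, tolerance = 1e-12)

  # shift-equivariance: rotate-then-smooth = smooth-then-rotate
  k <- 17
  rot <- function(x) x[((seq_along(x) - 1 + k) %% length(x)) + 1]
  a <- gaussian_smooth(make_profile(g, rot(v), bin_size = 1), 3)$values
  b <- rot(gaussian_smooth(mfa, 3)$values)
  expect_equal(a, b, tolerance = 1e-12)

  # kernel wider than the profile still wraps correctly and keeps the mean
  wide <- gaussian_smooth(mfa, 30)
  expect_equal(mean(wide$values), mean(v), tolerance = 1e-12)
})

test_that("linear smoothing is flagged and distorts only edges", {
  n <- 40
  g <- genome_def(n, 0, name = "g")
  set.seed(41)
  v <- runif(n)
  mfa <- make_profile(g, v, bin_size = 1)
  expect_warning(lin <- gaussian_smooth(mfa, 3, circular = FALSE), "linear")
  circ <- gaussian_smooth(mfa, 3, circular = TRUE)
  mid <- 15:25 # far from both edges: linear and circular agree
  expect_equal(lin$values[mid], circ$values[mid], tolerance = 1e-12)
  expect_error(gaussian_smooth(mfa, -1), "sigma")
})

test_that("full chain on simulated data matches the normalized oracle profile", {
  g <- tiny_genome()
  r <- 0.6; f <- 0.8
  p <- sim_params(g, 4000, r, f, 10, bin_size = 1000, seed = 13)
  sim <- simulate_population(p)
  mfa <- gaussian_smooth(normalize_profile(sim$coverage), sigma = 10)
  mids <- mfakit:::bin_mids(g, 1000)
  target <- expected_copy_number(p, mids) / (1 + r / 2)
  # smoothing rounds the apex kink (~ sigma * slope * sqrt(2/pi) ~ 0.03)
  # and chromosome-sampling noise is genome-scale correlated, so compare
  # loosely bin-wise and more tightly on average
  expect_lt(max(abs(mfa$values - target)), 0.08)
  expect_lt(mean(abs(mfa$values - target)), 0.015)
})
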