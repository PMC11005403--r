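test_that("a flat profile yields height 0 and no detection", {
  g <- tbar_genome()
  flat <- make_profile(g, rep(1, 2010))
  pk <- detect_ori_peak(flat)
  expect_equal(pk$height, 0)
  expect_false(pk$detected)
  expect_equal(pk$area, 0)
})

test_that("a narrow triangular peak is located at the T. barophilus oriC", {
  g <- tbar_genome()
  # flat baseline 1.0 with a tent of half-width 100 kb and apex 1.6 at oriC
  pos <- (0:2009) * 1000
  d <- circular_distance(pos, 1671000, g$length)
  v <- 1 + pmax(0, 0.6 * (1 - d / 100000))
  pk <- detect_ori_peak(make_profile(g, v))
  expect_true(pk$detected)
  expect_lte(abs(pk$apex_position - 1671000), 1000)
  expect_equal(pk$baseline, 1.0)
  expect_equal(pk$height, 0.6, tolerance = 1e-9)
  # tent area = height * support / 2 = 0.6 * 200000 / 2 (trapezoid is exact
  # for a piecewise-linear profile with kinks on the bin grid)
  expect_equal(pk$area, 0.6 * 200000 / 2, tolerance = 1e-9)
})

test_that("apex ties break toward oriC then the lower coordinate", {
  g <- genome_def(100000, 50000, name = "g")
  v <- rep(1, 100)
  v[c(46, 51, 56)] <- 1.5 # bins starting at 45000, 50000, 55000
  pk <- detect_ori_peak(make_profile(g, v, bin_size = 1000), window = 20000)
  expect_equal(pk$apex_position, 50000)
  v2 <- rep(1, 100)
  v2[c(46, 56)] <- 1.5 # equidistant from ori: lower coordinate wins
  pk2 <- detect_ori_peak(make_profile(g, v2, bin_size = 1000), window = 20000)
  expect_equal(pk2$apex_position, 45000)
  expect_error(detect_ori_peak(make_profile(g, v, bin_size = 1000),
                               window = 60000), "L/2")
})

test_that("genome-spanning triangle area equals h * L / 2 and matches a summation oracle", {
  g <- tbar_genome()
  h <- 0.5
  tri <- triangle_profile(g, apex_at = g$ori_position, height = h)
  pk <- detect_ori_peak(tri, baseline = 1.0)
  expect_equal(pk$height, h, tolerance = 1e-12)
  # bounds reach the antipode on both sides
  anti <- (g$ori_position + g$length / 2) %% g$length
  expect_equal(pk$left_bound, anti)
  expect_equal(pk$right_bound, anti)
  expect_equal(pk$area, h * g$length / 2, tolerance = 1e-9)

  # independent per-bin trapezoid summation over the full circle
  n <- 2010
  idx <- ((pk$.left_idx - 1 + 0:n) %% n) + 1
  y <- pmax(tri$values[idx] - 1.0, 0)
  oracle <- sum((y[-1] + y[-length(y)]) / 2) * 1000
  expect_equal(pk$area, oracle, tolerance = 1e-9)

  # linearity: doubling the excess doubles the area
  tri2 <- triangle_profile(g, apex_at = g$ori_position, height = 2 * h)
  pk2 <- detect_ori_peak(tri2, baseline = 1.0)
  expect_equal(pk2$area, 2 * pk$area, tolerance = 1e-9)
})

test_that("ori fraction estimator inverts the noiseless model exactly", {
  g <- tbar_genome()
  mids <- mfakit:::bin_starts(g, 1000)
  noiseless <- function(f, r) {
    p <- sim_params(g, 10, r, f, 1, bin_size = 1000, seed = 1)
    ec <- expected_copy_number(p, mids)
    make_profile(g, ec / mean(ec))
  }
  for (fr in list(c(1, 0.8), c(0.5, 0.6), c(0.25, 0.3))) {
    prof <- noiseless(fr[1], fr[2])
    pk <- detect_ori_peak(prof)
    expect_equal(estimate_ori_fraction(prof, pk, r = fr[2]), fr[1],
                 tolerance = 1e-6)
  }
  flatpk <- detect_ori_peak(make_profile(g, rep(1, 2010)))
  expect_equal(estimate_ori_fraction(make_profile(g, rep(1, 2010)), flatpk,
                                     r = 0.5), 0)
  expect_error(estimate_ori_fraction(noiseless(0.5, 0.6),
                                     detect_ori_peak(noiseless(0.5, 0.6)),
                                     r = 0), "unidentifiable")
})

test_that("(f, r) pairs with equal contrast k give identical normalized profiles", {
  # f and r are not jointly identifiable from shape: pick (f, r) and solve
  # (f', r') with the same k = f r / (1 + r (1 - f) / 2)
  g <- tiny_genome()
  mids <- mfakit:::bin_starts(g, 1000)
  prof <- function(f, r) {
    p <- sim_params(g, 10, r, f, 1, bin_size = 1000, seed = 1)
    ec <- expected_copy_number(p, mids)
    ec / mean(ec)
  }
  f1 <- 0.5; r1 <- 0.6
  k <- f1 * r1 / (1 + r1 * (1 - f1) / 2)
  r2 <- 0.9
  f2 <- k * (1 + r2 / 2) / (r2 * (1 + k / 2))
  expect_false(isTRUE(all.equal(f1, f2)))
  expect_equal(prof(f1, r1), prof(f2, r2), tolerance = 1e-12)
})

test_that("pure-RDR profiles are called origin-less, as in a deltaoriC strain", {
  g <- tbar_genome()
  detections <- vapply(1:10, function(s) {
    mfa <- sim_mfa(g, n = 2000, r = 0.6, f = 0, lambda = 10, seed = s)
    detect_ori_peak(mfa, min_height = 0.05)$detected
  }, logical(1))
  expect_gte(sum(!detections), 9)
})

test_that("timecourse_summary sorts, flags and validates", {
  g <- tbar_genome()
  flat <- make_profile(g, rep(1, 2010))
  one <- timecourse_summary(list(list(label = "s1", hours = 5, mfa = flat)))
  expect_equal(nrow(one), 1L)
  expect_equal(one$height, 0)
  expect_false(one$detected)

  tri <- triangle_profile(g, apex_at = g$ori_position, height = 0.4)
  tc <- timecourse_summary(list(
    list(label = "late", hours = 9, mfa = tri),
    list(label = "early", hours = 2, mfa = flat)
  ))
  expect_equal(tc$label, c("early", "late"))
  expect_true(tc$detected[2] && !tc$detected[1])

  expect_error(timecourse_summary(list()), "non-empty")
  expect_error(timecourse_summary(list(
    list(label = "a", hours = 1, mfa = flat),
    list(label = "a", hours = 2, mfa = flat)
  )), "duplicate")
})

test_that("peak heights increase with the simulated ori fraction", {
  g <- tbar_genome()
  for (seed in 1:5) {
    heights <- vapply(c(0.2, 0.5, 0.9), function(f) {
      mfa <- sim_mfa(g, n = 2000, r = 0.6, f = f, lambda = 10, seed = seed)
      detect_ori_peak(mfa)$height
    }, numeric(1))
    expect_true(all(diff(heights) > 0))
  }
})
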