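test_that("band-pass phases advance linearly for an in-band sinusoid", {
  TR <- 0.72
  t <- (0:399) * TR
  f <- 0.05
  x <- rbind(sin(2 * pi * f * t), sin(2 * pi * f * t))
  pf <- bandpass_phase(x, TR)
  ph <- pf$phases[1, ]
  slope <- mean(diff(ph + cumsum(c(0, diff(ph) < -pi)) * 2 * pi)) / TR
  expect_lt(abs(slope - 2 * pi * f) / (2 * pi * f), 0.01)
  # identical nodes give identical phase rows
  expect_equal(pf$phases[1, ], pf$phases[2, ], tolerance = 1e-12)
  expect_true(all(pf$phases > -pi & pf$phases <= pi + 1e-12))
})

test_that("out-of-band components are strongly attenuated", {
  TR <- 0.72
  t <- (0:399) * TR
  inband <- sin(2 * pi * 0.04 * t)
  outband <- sin(2 * pi * 0.2 * t)
  pf <- bandpass_phase(rbind(inband, outband), TR)
  amp <- apply(pf$filtered, 1, function(v) sqrt(mean(v^2)))
  expect_lt(amp[2] / amp[1], 0.1)
  expect_error(bandpass_phase(rbind(inband), TR, band = c(0.01, 0.8)),
               "band")
})

test_that("local Kuramoto order parameter matches definition and oracle", {
  w <- matrix(1, 4, 4)
  # full synchrony
  ph <- matrix(0.7, 4, 10)
  lk <- local_kuramoto(ph, w)
  expect_equal(lk$R, matrix(1, 4, 10), tolerance = 1e-12)
  # two equally weighted antiphase neighbours cancel
  w2 <- matrix(0, 3, 3)
  w2[1, 2] <- w2[1, 3] <- w2[2, 1] <- w2[3, 1] <- 1
  diag(w2)[2:3] <- 1 # keep positive row sums elsewhere
  ph2 <- matrix(c(0, 0, pi), 3, 1)
  expect_equal(local_kuramoto(ph2, w2)$R[1, 1], 0, tolerance = 1e-12)
  # random input matches the brute-force double loop
  set.seed(14)
  phr <- matrix(runif(16 * 7, -pi, pi), 16, 7)
  lk3 <- local_kuramoto(phr, tiny_kernel)
  expect_equal(lk3$R, oracle_local_R(phr, tiny_kernel), tolerance = 1e-10)
  expect_error(local_kuramoto(phr, matrix(0, 16, 16)), "row sum")
})

test_that("uniform random phases give low mean local order at N = 1000", {
  set.seed(15)
  ph <- matrix(runif(1000 * 5, -pi, pi), 1000, 5)
  # dense shell of centroids so each node has a sizeable EDR neighbourhood
  co <- matrix(rnorm(3000), 1000, 3)
  co <- co / sqrt(rowSums(co^2)) * 40
  w <- exp(-0.18 * as.matrix(dist(co)))
  lk <- local_kuramoto(ph, w)
  expect_gt(mean(lk$R), 0)
  expect_lt(mean(lk$R), 0.2)
  # exact agreement with a direct complex summation for a few nodes
  for (n in c(1, 500, 1000)) {
    z <- sum(w[n, ] / sum(w[n, ]) * exp(1i * ph[, 1]))
    expect_equal(lk$R[n, 1], Mod(z), tolerance = 1e-10)
  }
})

test_that("amplitude turbulence is the pooled standard deviation of R", {
  expect_equal(amplitude_turbulence(matrix(0.7, 5, 9)), 0)
  half <- matrix(c(0, 1), 4, 10)
  expect_equal(amplitude_turbulence(half), 0.5)
  set.seed(16)
  r <- matrix(runif(80), 8, 10)
  oracle <- sqrt(mean(r^2) - mean(r)^2)
  expect_equal(amplitude_turbulence(r), oracle, tolerance = 1e-12)
  expect_error(amplitude_turbulence(matrix(numeric(0), 0, 0)), "empty")
})

test_that("global order parameter and metastability behave at the limits", {
  ph_sync <- matrix(1.2, 6, 8)
  gr <- global_kuramoto(ph_sync)
  expect_equal(gr, rep(1, 8), tolerance = 1e-12)
  expect_equal(metastability(gr), 0)
  # antipodal phase pairs cancel exactly
  ph_anti <- matrix(c(0, pi, 0.4, 0.4 + pi), 4, 3)
  expect_equal(global_kuramoto(ph_anti), rep(0, 3), tolerance = 1e-12)
  # random phases: matches the oracle SD of the modulus of the complex mean
  set.seed(17)
  ph <- matrix(runif(10 * 50, -pi, pi), 10, 50)
  gr2 <- global_kuramoto(ph)
  oracle <- vapply(1:50, function(t) Mod(mean(exp(1i * ph[, t]))), numeric(1))
  expect_equal(gr2, oracle, tolerance = 1e-10)
  expect_equal(metastability(gr2),
               sqrt(mean(oracle^2) - mean(oracle)^2), tolerance = 1e-12)
})

test_that("D and M are invariant under global phase rotation", {
  set.seed(18)
  ph <- matrix(runif(16 * 30, -pi, pi), 16, 30)
  rot <- ((ph + 1.1 + pi) %% (2 * pi)) - pi
  expect_equal(amplitude_turbulence(local_kuramoto(ph, tiny_kernel)),
               amplitude_turbulence(local_kuramoto(rot, tiny_kernel)),
               tolerance = 1e-10)
  expect_equal(metastability(global_kuramoto(ph)),
               metastability(global_kuramoto(rot)), tolerance = 1e-10)
})

test_that("local order with uniform all-ones weights reduces to the global one", {
  set.seed(19)
  ph <- matrix(runif(12 * 20, -pi, pi), 12, 20)
  lk <- local_kuramoto(ph, matrix(1, 12, 12))
  gr <- global_kuramoto(ph)
  for (n in 1:12) expect_equal(lk$R[n, ], gr, tolerance = 1e-10)
})

test_that("functional connectivity is a Pearson correlation matrix", {
  set.seed(20)
  base <- rnorm(100)
  ts <- rbind(base, base, -base, rnorm(100))
  fc <- functional_connectivity(ts)
  expect_equal(fc[1, 2], 1)
  expect_equal(fc[1, 3], -1)
  expect_equal(diag(fc), rep(1, 4))
  # covariance oracle on random data
  ts2 <- matrix(rnorm(6 * 50), 6, 50)
  fc2 <- functional_connectivity(ts2)
  for (i in 1:5) for (j in (i + 1):6) {
    cv <- cov(ts2[i, ], ts2[j, ]) / (sd(ts2[i, ]) * sd(ts2[j, ]))
    expect_equal(fc2[i, j], cv, tolerance = 1e-10)
  }
})

test_that("FC comparison metrics have the documented limits and oracle", {
  set.seed(23)
  a <- functional_connectivity(matrix(rnorm(8 * 60), 8, 60))
  m <- fc_metrics(a, a)
  expect_equal(m$eFC, 0)
  expect_equal(m$corrFC, 1)
  expect_equal(m$ssimFC, 1, tolerance = 1e-6)
  # sign-flipped upper triangle gives corrFC = -1
  b <- -a
  diag(b) <- 1
  expect_equal(fc_metrics(a, b)$corrFC, -1, tolerance = 1e-12)
  # random pair matches the elementwise oracle
  cmat <- functional_connectivity(matrix(rnorm(8 * 60), 8, 60))
  m2 <- fc_metrics(a, cmat)
  ut <- upper.tri(a)
  expect_equal(m2$eFC_raw, sqrt(sum((a[ut] - cmat[ut])^2)), tolerance = 1e-12)
  expect_equal(m2$eFC, m2$eFC_raw / sqrt(sum(ut)), tolerance = 1e-12)
  expect_equal(m2$corrFC, cor(a[ut], cmat[ut]), tolerance = 1e-12)
  expect_true(m2$ssimFC >= -1 && m2$ssimFC <= 1)
  expect_error(fc_metrics(a, matrix(0, 3, 3)), "dimensions")
})

test_that("turbulence and metastability errors are absolute differences", {
  expect_equal(turbulence_error(0.3, 0.3), 0)
  expect_equal(turbulence_error(0.19, 0.20), 0.01)
  expect_equal(turbulence_error(0.1, 0.4), turbulence_error(0.4, 0.1))
  expect_equal(metastability_error(0.19, 0.20), 0.01)
  expect_equal(metastability_error(0.2, 0.5), metastability_error(0.5, 0.2))
})
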