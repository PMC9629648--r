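test_that("single oscillator settles on the analytic limit cycle", {
  p <- model_params(a = 1, omega = 2 * pi * 0.05, beta = 0, nu = 0,
                    n_volumes = 200, discard = 100, dt = 0.72 / 72)
  s <- simulate_hopf(p, one_node, seed = 1)
  r <- sqrt(s$x^2 + s$y^2)
  expect_true(all(abs(r - 1) < 1e-3))

  p2 <- model_params(a = 0.04, omega = 2 * pi * 0.05, beta = 0, nu = 0,
                     n_volumes = 200, discard = 800, dt = 0.72 / 72)
  s2 <- simulate_hopf(p2, one_node, seed = 1)
  expect_true(all(abs(sqrt(s2$x^2 + s2$y^2) - 0.2) < 1e-3))
})

test_that("shear shifts the rotation rate to omega - beta * a", {
  p <- model_params(a = 1, omega = 2 * pi * 0.05, beta = 0.5, nu = 0,
                    n_volumes = 300, discard = 100, dt = 0.72 / 72)
  s <- simulate_hopf(p, one_node, seed = 2)
  th <- atan2(s$y[1, ], s$x[1, ])
  dth <- atan2(sin(diff(th)), cos(diff(th)))
  rate <- mean(dth) / p$TR
  expected <- 2 * pi * 0.05 - 0.5 * 1
  expect_lt(abs(rate - expected) / abs(expected), 0.01)
})

test_that("simulation is bit-identical under a fixed seed", {
  p <- model_params(a = -0.02, omega = tiny_omega, beta = 0.3, G = 0.5,
                    n_volumes = 60)
  s1 <- simulate_hopf(p, tiny_coupling, seed = 7)
  s2 <- simulate_hopf(p, tiny_coupling, seed = 7)
  expect_identical(s1$x, s2$x)
  expect_identical(s1$y, s2$y)
  s3 <- simulate_hopf(p, tiny_coupling, seed = 8)
  expect_false(identical(s1$x, s3$x))
})

test_that("subcritical dynamics decay without noise and shrink with |a|", {
  # nu = 0, a < 0: decay to the origin from small initial conditions
  p <- model_params(a = -0.5, omega = 2 * pi * 0.05, nu = 0,
                    n_volumes = 100, discard = 100)
  s <- simulate_hopf(p, one_node, seed = 3)
  expect_lt(max(abs(s$x) + abs(s$y)), 1e-6)

  # noise-driven amplitude decreases monotonically as |a| grows
  mean_mod <- vapply(c(-0.5, -1, -2), function(a) {
    pp <- model_params(a = a, omega = 2 * pi * 0.05, nu = 0.05,
                       n_volumes = 300, discard = 50)
    ss <- simulate_hopf(pp, one_node, seed = 4)
    mean(sqrt(ss$x^2 + ss$y^2))
  }, numeric(1))
  expect_true(all(diff(mean_mod) < 0))
})

test_that("halving the step changes trajectory statistics by under 2 percent", {
  stats_at <- function(dt) {
    p <- model_params(a = -0.02, omega = tiny_omega, beta = 0.3, G = 0.5,
                      nu = 0.01, n_volumes = 400, dt = dt)
    s <- simulate_hopf(p, tiny_coupling, seed = 5)
    mean(sqrt(s$x^2 + s$y^2))
  }
  m1 <- stats_at(0.72 / 16)
  m2 <- stats_at(0.72 / 32)
  expect_lt(abs(m1 - m2) / m1, 0.02)
})

test_that("divergence raises a structured error naming volume and node", {
  # explosive configuration: strong positive a with huge coupling
  C <- coupling_matrix(matrix(5, 4, 4) - diag(5, 4))
  p <- model_params(a = 2, omega = 2 * pi * 0.05, beta = 6, G = 50,
                    nu = 0, n_volumes = 50, dt = 0.72 / 2)
  err <- tryCatch(simulate_hopf(p, C, seed = 1),
                  hopfwb_divergence = function(e) e)
  expect_s3_class(err, "hopfwb_divergence")
  expect_true(is.numeric(err$volume) && err$volume >= 1)
  expect_true(is.numeric(err$node) && err$node >= 1)
})

test_that("model parameter validation enforces the documented invariants", {
  expect_error(model_params(a = 1, omega = -1), "positive")
  expect_error(model_params(a = 1, omega = 1, dt = 0.5, TR = 0.72),
               "integer multiple")
  expect_error(model_params(a = 1, omega = 1, nu = -0.1))
  expect_error(forcing_spec(F0 = -1), "nonnegative")
  expect_error(forcing_spec(F0 = 1, schedule = "on_then_off"), "n_on")
  p <- model_params(a = 1, omega = 1, dt = 0.1, TR = 0.7)
  expect_equal(p$sub, 7L)
  expect_equal(p$dt, 0.1)
})

test_that("on_then_off forcing schedule marks retained volumes correctly", {
  frc <- forcing_nodes(1, 0.5, 1, schedule = "on_then_off",
                       n_on = 30, n_off = 20)
  p <- model_params(a = -0.02, omega = 2 * pi * 0.05, n_volumes = 50,
                    discard = 10)
  s <- simulate_hopf(p, one_node, frc, seed = 6)
  expect_equal(s$forcing_on, c(rep(TRUE, 30), rep(FALSE, 20)))
  expect_error(simulate_hopf(
    model_params(a = -0.02, omega = 1, n_volumes = 40),
    one_node, frc, seed = 1), "n_on")
})

test_that("node frequency estimation finds in-band spectral peaks", {
  TR <- 0.72
  t <- (0:599) * TR
  set.seed(21)
  x <- rbind(sin(2 * pi * 0.05 * t) + 0.05 * rnorm(600),
             sin(2 * pi * 0.02 * t) + 0.05 * rnorm(600),
             sin(2 * pi * 0.07 * t) + 0.05 * rnorm(600))
  om <- estimate_node_frequencies(x, TR)
  bin <- 2 * pi / (600 * TR)
  # FFT-oracle: peak of the periodogram inside the band
  oracle_peak <- function(v) {
    pw <- Mod(fft(v - mean(v)))^2
    fr <- seq.int(0, 599) / (600 * TR)
    inb <- fr >= 0.008 & fr <= 0.08
    2 * pi * fr[inb][which.max(pw[inb])]
  }
  for (i in 1:3) expect_equal(om[i], oracle_peak(x[i, ]), tolerance = 1e-12)
  expect_lt(abs(om[1] - 2 * pi * 0.05), bin + 1e-12)
  expect_lt(abs(om[2] - 2 * pi * 0.02), bin + 1e-12)
  expect_lt(abs(om[3] - 2 * pi * 0.07), bin + 1e-12)

  # white noise: flat spectrum, falls back to the band midpoint with warning
  set.seed(22)
  wn <- matrix(rnorm(1200), 2, 600)
  expect_warning(omw <- estimate_node_frequencies(wn, TR), "flat")
  expect_equal(as.numeric(omw), rep(2 * pi * 0.044, 2))
  expect_true(all(attr(omw, "fallback")))
})

test_that("multi-subject frequency estimation pools periodograms", {
  TR <- 0.72
  t <- (0:299) * TR
  subj <- lapply(1:4, function(k) {
    set.seed(30 + k)
    rbind(sin(2 * pi * 0.05 * t) + rnorm(300),
          sin(2 * pi * 0.03 * t) + rnorm(300))
  })
  om <- estimate_node_frequencies(subj, TR)
  bin <- 1 / (300 * TR)
  expect_lt(abs(om[1] / (2 * pi) - 0.05), bin + 1e-12)
  expect_lt(abs(om[2] / (2 * pi) - 0.03), bin + 1e-12)
})
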