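test_that("euclidean distances match geometry and a pairwise-loop oracle", {
  p <- as_parcellation(data.frame(name = c("a", "a"), hemi = c("L", "R"),
                                  x = c(0, 3), y = c(0, 4), z = 0))
  d <- euclidean_distances(p)
  expect_equal(d[1, 2], 5)
  expect_equal(diag(d), c(0, 0))

  set.seed(9)
  co <- matrix(rnorm(30, sd = 40), 10, 3)
  d <- euclidean_distances(co)
  oracle <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10)
    oracle[i, j] <- sqrt(sum((co[i, ] - co[j, ])^2))
  expect_equal(d, oracle, tolerance = 1e-12)
  expect_true(all(abs(d - t(d)) < 1e-12))
  # triangle inequality on all triples
  for (i in 1:10) for (j in 1:10) for (k in 1:10)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)

  expect_error(euclidean_distances(matrix(c(0, 0, 0, NA, 1, 1), 2, 3)),
               "finite")
  expect_error(euclidean_distances(matrix(0, 1, 3)), "at least 2")
})

test_that("EDR coupling is the exponential kernel with zero diagonal", {
  d <- matrix(c(0, 10, 10, 0), 2)
  w <- edr_coupling(d, lambda_decay = 0.18)
  expect_equal(w[1, 2], exp(-1.8))
  expect_equal(diag(unclass(w)), c(0, 0))
  # coincident off-diagonal nodes get weight exp(0) = 1
  d0 <- matrix(0, 2, 2)
  expect_equal(edr_coupling(d0)[1, 2], 1)
  expect_error(edr_coupling(d, lambda_decay = 0), "positive")
  expect_error(edr_coupling(d, lambda_decay = -1), "positive")
  # strictly decreasing in distance for fixed lambda
  r <- seq(5, 120, by = 5)
  w <- exp(-0.18 * r)
  dm <- as.matrix(dist(cbind(c(0, cumsum(rep(1, 10))), 0, 0)))
  wm <- edr_coupling(dm)
  ut <- wm[1, -1]
  expect_true(all(diff(ut) < 0))
  # off-diagonal weights in (0, 1]
  w2 <- edr_coupling(tiny_dist)
  off <- w2[upper.tri(w2)]
  expect_true(all(off > 0 & off <= 1))
})

test_that("SC normalization caps, symmetrizes and rejects degenerate input", {
  set.seed(4)
  raw <- matrix(runif(100, 0, 7), 10, 10)
  sc <- normalize_sc(raw, cap = 0.2)
  expect_equal(max(sc), 0.2, tolerance = 1e-12)
  expect_true(all(abs(sc - t(sc)) < 1e-12))
  expect_equal(diag(unclass(sc)), rep(0, 10))
  # already at cap: unchanged
  again <- normalize_sc(unclass(sc), cap = 0.2)
  expect_equal(unclass(again), unclass(sc), tolerance = 1e-12)
  expect_error(normalize_sc(matrix(0, 4, 4)), "degenerate")
  expect_error(normalize_sc(matrix(-1, 2, 2)), "nonnegative")
})

test_that("long-range addition augments the EDR matrix per the rule", {
  d <- tiny_dist
  edr <- edr_coupling(d)
  set.seed(11)
  raw <- matrix(rexp(256), 16, 16)
  sc <- normalize_sc(raw)
  # empty selection: identical to EDR
  none <- add_long_range(edr, sc, d, rule = matrix(FALSE, 16, 16))
  expect_equal(unclass(none), unclass(edr), ignore_attr = TRUE)
  expect_identical(attr(none, "kind"), "EDR_LR")
  # single selected pair: only that entry changes, by the SC weight
  sel <- matrix(FALSE, 16, 16)
  sel[2, 9] <- TRUE
  one <- add_long_range(edr, sc, d, rule = sel)
  expect_equal(one[2, 9], edr[2, 9] + sc[2, 9])
  expect_equal(one[9, 2], one[2, 9])
  changed <- abs(unclass(one) - unclass(edr)) > 0
  expect_equal(sum(changed), 2L)
  # full SC as long-range: elementwise sum
  full <- add_long_range(edr, sc, d, rule = matrix(TRUE, 16, 16))
  expect_equal(unclass(full), unclass(edr) + unclass(sc),
               ignore_attr = TRUE)
  # never decreases any entry
  lr <- add_long_range(edr, sc, d, rule = lr_positive_residuals(k = 10))
  expect_true(all(unclass(lr) - unclass(edr) >= -1e-15))
  expect_error(add_long_range(edr, normalize_sc(matrix(1, 4, 4) - diag(4)), d),
               "dimensions")
})

test_that("positive-residual rule selects SC entries exceeding the EDR fit", {
  d <- tiny_dist
  # construct SC that follows exp decay except two boosted long pairs
  w <- exp(-0.1 * d)
  diag(w) <- 0
  far <- which(d == max(d), arr.ind = TRUE)[1, ]
  w[far[1], far[2]] <- w[far[2], far[1]] <- 0.9
  sel <- lr_positive_residuals(k = 1)(w, d)
  expect_true(sel[far[1], far[2]])
  expect_equal(sum(sel), 2L)
  # distance-threshold rule behaves as documented
  sel2 <- lr_distance_threshold(min_dist = max(d) - 1)(w, d)
  expect_true(sel2[far[1], far[2]])
  expect_false(any(sel2 & d <= max(d) - 1))
})

test_that("homotopic pairing works by region name across hemispheres", {
  # DK-style hemisphere prefixes in the name
  p <- as_parcellation(data.frame(
    name = c("lh.precentral", "rh.precentral", "lh.insula", "rh.insula"),
    hemi = c("L", "R", "L", "R"),
    x = c(-40, 40, -35, 35), y = 0, z = 0))
  hp <- homotopic_pairs(p)
  expect_equal(nrow(hp), 2L)
  expect_equal(p$hemi[hp[, "left"]], c("L", "L"))
  expect_equal(sub("^lh\\.", "", p$name[hp[, "left"]]),
               sub("^rh\\.", "", p$name[hp[, "right"]]))

  # synthetic mirror parcellation: pairing equals the construction
  hp2 <- homotopic_pairs(tiny_parc)
  expect_equal(nrow(hp2), 8L)
  expect_equal(tiny_parc$name[hp2[, "left"]], tiny_parc$name[hp2[, "right"]])
  expect_equal(abs(tiny_parc$x[hp2[, "left"]]), abs(tiny_parc$x[hp2[, "right"]]),
               tolerance = 1e-12)

  expect_error(homotopic_pairs(tiny_parc[-1, ]), "odd")
  bad <- tiny_parc
  bad$name[1] <- "something_else"
  expect_error(homotopic_pairs(bad), "unpaired|duplicated")
})

test_that("coupling matrices produced anywhere are symmetric, nonnegative, zero-diagonal", {
  for (m in list(tiny_coupling, edr_coupling(tiny_dist),
                 normalize_sc(matrix(runif(64), 8, 8)))) {
    expect_true(all(abs(m - t(m)) < 1e-12))
    expect_true(all(m >= 0))
    expect_true(all(diag(unclass(m)) == 0))
  }
  expect_error(coupling_matrix(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  expect_error(coupling_matrix(matrix(c(1, 0, 0, 1), 2)), "diagonal")
  expect_error(coupling_matrix(matrix(c(0, -1, -1, 0), 2)), "nonnegative")
})
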