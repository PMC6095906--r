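# wMNE / sLORETA inverse operators and ROI aggregation.

test_that("identity gain with no regularization reconstructs exactly", {
  lf <- leadfield_stub(diag(5))
  op <- wmne_operator(lf, snr = Inf, depth_exponent = 0)
  expect_equal(op$kernel, diag(5), tolerance = 1e-10)
  expect_equal(op$lambda2, 0)
})

test_that("wMNE localizes single sources under the default geometry", {
  lf <- make_geometry(64, 68, seed = 1)
  op <- wmne_operator(lf, snr = 3, depth_exponent = 0.5)
  set.seed(9)
  hits <- sum(sapply(sample.int(68, 50, replace = TRUE), function(j) {
    which.max((op$kernel %*% lf$gain[, j])^2) == j
  }))
  expect_gte(hits, 45)
})

test_that("depth weighting equalizes deep and superficial source power", {
  sensors <- make_geometry(64, 68, seed = 1)$sensor_positions
  pos <- rbind(c(0, 0, 0.6), c(0.1, 0, 0.9))
  lf <- leadfield_stub(sphere_dipole_gain(sensors, pos))
  set.seed(2)
  s <- matrix(rnorm(2 * 800), 2) # equal-variance sources
  x <- lf$gain %*% s
  ratio_for <- function(gamma) {
    k <- wmne_operator(lf, snr = 3, depth_exponent = gamma)$kernel
    est <- k %*% x
    p <- rowMeans(est^2)
    max(p) / min(p)
  }
  expect_lt(abs(log(ratio_for(0.5))), abs(log(ratio_for(0))))
})

test_that("sLORETA has zero localization error for noiseless dipoles", {
  lf <- make_geometry(64, 68, seed = 1)
  op <- sloreta_operator(lf, snr = 3)
  set.seed(5)
  hits <- sum(sapply(sample.int(68, 50, replace = TRUE), function(j) {
    which.max((op$kernel %*% lf$gain[, j])^2) == j
  }))
  expect_equal(hits, 50L)
  expect_equal(as.numeric(op$kernel %*% rep(0, 64)), rep(0, 68))
})

test_that("sLORETA and wMNE agree up to row scaling at gamma = 0", {
  lf <- make_geometry(32, 20, seed = 3)
  k0 <- wmne_operator(lf, snr = 3, depth_exponent = 0)$kernel
  ks <- sloreta_operator(lf, snr = 3)$kernel
  scales <- ks / k0
  per_row_spread <- apply(scales, 1, function(r) diff(range(r)) / abs(mean(r)))
  expect_lt(max(per_row_spread), 1e-8)
  # identity gain: power ranking identical
  lfi <- leadfield_stub(diag(4))
  x <- matrix(rnorm(4 * 100), 4)
  p0 <- rowMeans((wmne_operator(lfi, 3, 0)$kernel %*% x)^2)
  ps <- rowMeans((sloreta_operator(lfi, 3)$kernel %*% x)^2)
  expect_equal(order(p0), order(ps))
})

test_that("regularization monotonically shrinks the kernel", {
  lf <- make_geometry(32, 40, seed = 2)
  norms <- sapply(c(10, 3, 1), function(snr) {
    norm(wmne_operator(lf, snr = snr, depth_exponent = 0)$kernel, "F")
  })
  expect_true(all(diff(norms) < 0))
})

test_that("applying the inverse is linear with the right shapes", {
  lf <- make_geometry(16, 12, seed = 6)
  op <- wmne_operator(lf)
  set.seed(7)
  x <- array(rnorm(16 * 500 * 3), dim = c(16, 500, 3))
  ep <- eegnetcomp:::new_epoch_set(x, 160, domain = "sensor")
  src <- apply_inverse(ep, op)
  expect_equal(dim(src$epochs), c(12L, 500L, 3L))
  expect_equal(src$domain, "source")

  zero <- ep
  zero$epochs[] <- 0
  expect_true(all(apply_inverse(zero, op)$epochs == 0))

  ep2 <- ep
  ep2$epochs <- 2 * ep$epochs
  expect_equal(apply_inverse(ep2, op)$epochs, 2 * src$epochs, tolerance = 1e-12)

  bad <- eegnetcomp:::new_epoch_set(array(rnorm(10 * 50), c(10, 50, 1)), 160)
  expect_error(apply_inverse(bad, op), class = "invalid_argument")
})

test_that("inverse crime: square gain round-trips the sources", {
  lf <- make_geometry(64, 64, seed = 3)
  sp <- ground_truth_spec(64, matrix(0, 64, 64), target_leaf_fraction = 0.5, seed = 4)
  src <- simulate_sources(sp, duration = 4, fs = 160)
  sen <- project_to_sensors(src, lf, sensor_snr = Inf)
  op <- wmne_operator(lf, snr = Inf, depth_exponent = 0)
  recon <- op$kernel %*% sen$data
  expect_lt(max(abs(recon - src$data)) / max(abs(src$data)), 1e-8)
})

test_that("ROI aggregation flips antiparallel sources before averaging", {
  s <- sin(seq_len(300) / 9)
  gain <- matrix(rnorm(8), 4, 2)
  lf <- leadfield_stub(gain,
    roi_labels = c("A", "A"),
    orientations = rbind(c(0, 0, 1), c(0, 0, -1))
  )
  ep <- eegnetcomp:::new_epoch_set(
    array(rbind(s, -s), c(2, 300, 1)), 160, domain = "source"
  )
  agg <- aggregate_rois(ep, lf)
  expect_equal(dim(agg$epochs)[1], 1L)
  expect_equal(as.numeric(agg$epochs[1, , 1]), s, tolerance = 1e-12)
})

test_that("singleton ROIs aggregate to themselves in atlas order", {
  lf <- make_geometry(16, 68, seed = 2)
  x <- array(rnorm(68 * 100 * 2), c(68, 100, 2))
  ep <- eegnetcomp:::new_epoch_set(x, 160, domain = "source")
  agg <- aggregate_rois(ep, lf)
  expect_equal(agg$epochs, x)
  expect_equal(agg$channel_labels, lf$roi_labels)
  expect_equal(agg$domain, "roi")
})
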