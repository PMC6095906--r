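# Synthetic cohort generator: geometry, oscillator model, forward projection.

test_that("geometry has the study dimensions and full sensor rank", {
  lf <- make_geometry(64, 68, seed = 1)
  expect_equal(dim(lf$gain), c(64L, 68L))
  expect_equal(qr(lf$gain)$rank, 64L)
  expect_true(all(is.finite(lf$gain)))
  expect_equal(sqrt(rowSums(lf$source_orientations^2)), rep(1, 68), tolerance = 1e-12)
  expect_length(unique(lf$roi_labels), 68)
  # every sensor mixes several sources
  expect_true(all(rowSums(abs(lf$gain) > 1e-9) >= 2))
})

test_that("degenerate single-element geometry has strictly positive gain", {
  lf <- make_geometry(1, 1, seed = 7)
  expect_equal(dim(lf$gain), c(1L, 1L))
  expect_gt(lf$gain[1, 1], 0)
})

test_that("deeper dipoles have smaller gain column norms (analytic evaluation)", {
  sensors <- make_geometry(64, 68, seed = 1)$sensor_positions
  g <- sphere_dipole_gain(sensors, rbind(c(0, 0, 0.6), c(0, 0, 0.9)))
  expect_lt(sqrt(sum(g[, 1]^2)), sqrt(sum(g[, 2]^2)))
})

test_that("geometry is deterministic for a fixed seed and validates counts", {
  expect_identical(make_geometry(16, 20, seed = 5), make_geometry(16, 20, seed = 5))
  expect_error(make_geometry(0, 5), class = "invalid_argument")
  expect_error(make_geometry(5, -1), class = "invalid_argument")
})

test_that("simulated recordings have the study duration and sampling", {
  rec <- simulate_sources(pair_spec(seed = 3), duration = 60, fs = 160)
  expect_equal(ncol(rec$data), 9600L)
  expect_equal(rec$fs, 160)
  expect_true(all(is.finite(rec$data)))
  expect_error(simulate_sources(pair_spec(), duration = 0.5), class = "invalid_argument")
})

test_that("uncoupled sources stay at the independent-phase PLV level", {
  # null PLV distribution from independently simulated phase series of the
  # same oscillator model
  set.seed(11)
  null_plv <- replicate(100, {
    sp <- pair_spec(strength = 0, seed = sample.int(1e6, 1))
    ph <- attr(simulate_sources(sp, duration = 15, fs = 160), "phase")
    plv(ph[1, ], ph[2, ])
  })
  bound <- max(null_plv) * 1.1 # small-sample bias bound with slack
  sp0 <- ground_truth_spec(4, matrix(0, 4, 4), target_leaf_fraction = 0.5, seed = 91)
  ph <- attr(simulate_sources(sp0, duration = 15, fs = 160), "phase")
  vals <- c(plv(ph[1, ], ph[2, ]), plv(ph[1, ], ph[3, ]), plv(ph[2, ], ph[4, ]))
  expect_true(all(vals <= bound))
})

test_that("a strongly coupled pair phase-locks while uncoupled pairs do not", {
  stats <- sapply(1:20, function(s) {
    ph <- attr(simulate_sources(pair_spec(strength = 0.9, lag = pi / 2, seed = s)), "phase")
    c(
      coupled = pli(ph[1, ], ph[2, ]),
      uncoupled = max(pli(ph[1, ], ph[3, ]), pli(ph[2, ], ph[3, ]))
    )
  })
  expect_gt(median(stats["coupled", ]), 0.8)
  expect_lt(median(stats["uncoupled", ]), 0.2)
})

test_that("amplitude-coupled pairs share their envelopes", {
  g <- matrix(0, 3, 3)
  g[1, 2] <- g[2, 1] <- 0.8
  sp <- ground_truth_spec(3,
    coupling_graph = matrix(0, 3, 3), amplitude_coupling_graph = g,
    target_leaf_fraction = 2 / 3, seed = 13
  )
  env <- attr(simulate_sources(sp), "envelope")
  expect_gt(aec(env[1, ], env[2, ]), 0.5)
  expect_lt(aec(env[1, ], env[3, ]), 0.3)
})

test_that("forward projection respects the gain, the SNR and linearity", {
  sp <- pair_spec(seed = 2)
  src <- simulate_sources(sp, duration = 10, fs = 160)
  lf_id <- leadfield_stub(diag(3))
  clean <- project_to_sensors(src, lf_id, sensor_snr = Inf)
  expect_equal(clean$data, src$data, ignore_attr = TRUE)
  expect_equal(clean$domain, "sensor")

  lf <- make_geometry(16, 3, seed = 4)
  noisy <- project_to_sensors(src, lf, sensor_snr = 4, seed = 6)
  resid <- noisy$data - lf$gain %*% src$data
  ratio <- mean((lf$gain %*% src$data)^2) / mean(resid^2)
  expect_gt(ratio, 3.6)
  expect_lt(ratio, 4.4)

  # linearity at infinite SNR
  src2 <- simulate_sources(pair_spec(seed = 8), duration = 10, fs = 160)
  mix <- src
  mix$data <- 2 * src$data - 3 * src2$data
  p <- function(r) project_to_sensors(r, lf, sensor_snr = Inf)$data
  expect_equal(p(mix), 2 * p(src) - 3 * p(src2), tolerance = 1e-12)

  bad <- src
  bad$data <- rbind(src$data, src$data)
  expect_error(project_to_sensors(bad, lf), class = "invalid_argument")
})

test_that("a single common source induces the predicted zero-lag mixing", {
  set.seed(21)
  s <- rnorm(4000)
  lf <- leadfield_stub(matrix(c(0.7, -1.3, 0.4), ncol = 1))
  rec <- new_recording(rbind(s), 160, domain = "source")
  sen <- project_to_sensors(rec, lf, sensor_snr = Inf)
  cc <- tcrossprod(sen$data) / length(s)
  g <- lf$gain[, 1]
  expect_equal(cc, outer(g, g) * mean(s^2), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("cohorts are reproducible and respect the jitter switch", {
  a <- make_cohort(1, conditions = default_conditions()["EC"], seed = 42, duration = 4)
  b <- make_cohort(1, conditions = default_conditions()["EC"], seed = 42, duration = 4)
  expect_identical(a$records[[1]]$sensor$data, b$records[[1]]$sensor$data)

  co <- make_cohort(3, seed = 9, duration = 4, jitter = FALSE)
  expect_length(co$records, 6L)
  leafs <- sapply(co$records, function(r) leaf_fraction(build_mst(r$spec$coupling_graph)))
  conds <- sapply(co$records, function(r) r$condition)
  for (cd in unique(conds)) {
    expect_length(unique(leafs[conds == cd]), 1L) # one shared graph per condition
  }
})

test_that("cohort size follows subjects x conditions", {
  co <- make_cohort(5, seed = 3, duration = 4)
  expect_length(co$records, 10L)
  expect_equal(5L * length(default_conditions()), 10L)
})

test_that("ground-truth topology is recoverable from source-level PLI", {
  # Recovery is partial: transitive phase locking along the coupled backbone
  # saturates PLI for indirect pairs, shrinking recovered leaf fractions
  # towards the random-tree baseline (~0.45); the absolute +-0.1 guarantee
  # therefore holds for mid-range targets, and the monotone-sweep test below
  # (mst-topology) covers the response across the full target range.
  err <- sapply(1:20, function(s) {
    g <- sample_coupling_graph(68, target_leaf_fraction = 0.5, strength = 0.9,
                               strength_jitter = 0, seed = s)
    sp <- ground_truth_spec(68, g, target_leaf_fraction = 0.5, seed = s + 500)
    rec <- simulate_sources(sp, duration = 60, fs = 160)
    core <- eegnetcomp:::conn_all(rec$data, 40L, TRUE, FALSE)
    abs(leaf_fraction(build_mst(core$pli)) - 0.5)
  })
  expect_lte(median(err), 0.1)
})

test_that("leaf-controlled trees achieve their target leaf count", {
  for (f in c(0.3, 0.5, 0.8)) {
    set.seed(17)
    edges <- sample_leaf_tree(40, f)
    deg <- tabulate(edges, nbins = 40)
    expect_equal(sum(deg == 1), round(f * 40))
    expect_equal(sum(deg), 2L * 39L) # a tree
  }
  set.seed(18)
  e3 <- sample_leaf_tree(40, 0.9, max_degree = 3)
  expect_lte(max(tabulate(e3, nbins = 40)), 3L)
})
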