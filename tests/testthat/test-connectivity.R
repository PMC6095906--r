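# Connectivity estimators: analytic signal, PLV/PLI/AEC families,
# symmetric orthogonalization.

test_that("analytic signal recovers amplitude and frequency of a cosine", {
  fs <- 160
  t <- seq(1 / fs, 8, by = 1 / fs)
  a <- 2.5
  anl <- analytic_signal(rbind(a * cos(2 * pi * 10 * t)), fs)
  mid <- seq(round(0.5 * fs), length(t) - round(0.5 * fs))
  expect_equal(mean(anl$envelope[1, mid]), a, tolerance = 0.02)
  dphi <- diff(anl$phase[1, mid])
  dphi <- (dphi + pi) %% (2 * pi) - pi # unwrap increments
  slope <- mean(dphi) * fs # rad/s
  expect_equal(slope, 2 * pi * 10, tolerance = 0.01)
})

test_that("a silent channel is flagged with zero envelope", {
  anl <- analytic_signal(rbind(rep(0, 256), sin(seq_len(256) / 5)), 128)
  expect_true(anl$flagged[1])
  expect_false(anl$flagged[2])
  expect_equal(max(anl$envelope[1, ]), 0)
})

test_that("PLV is 1 for consistent phase relations and small under the null", {
  ph <- runif(500, -pi, pi)
  expect_equal(plv(ph, ph), 1)
  expect_equal(plv(ph + pi / 2, ph), 1)
  set.seed(12)
  n <- 1920
  null_draws <- replicate(100, plv(runif(n, -pi, pi), runif(n, -pi, pi)))
  # Rayleigh null: P(PLV > sqrt(-log(a)/n)) = a for independent phases
  expect_gte(mean(null_draws < sqrt(-log(0.01) / n)), 0.97)
  expect_lt(mean(null_draws), 1.52 / sqrt(n))
})

test_that("PLI scores lagged but not zero-lag phase relations", {
  ph <- cumsum(rnorm(800)) / 10
  expect_equal(pli(ph + pi / 2, ph), 1)
  expect_equal(pli(ph, ph), 0)
})

test_that("instantaneous mixing inflates PLV but not PLI", {
  stats <- sapply(1:20, function(s) {
    set.seed(s)
    fs <- 160
    t <- seq(1 / fs, 12, by = 1 / fs)
    osc <- exp(0.3 * rnorm(1)) * cos(2 * pi * 10 * t + cumsum(rnorm(length(t), sd = 0.15)))
    x <- rbind(
      1.0 * osc + 0.01 * sd(osc) * rnorm(length(t)),
      0.6 * osc + 0.01 * sd(osc) * rnorm(length(t))
    )
    anl <- analytic_signal(x, fs)
    c(plv = plv(anl$phase[1, ], anl$phase[2, ]), pli = pli(anl$phase[1, ], anl$phase[2, ]))
  })
  expect_gt(median(stats["plv", ]), 0.9)
  expect_lt(median(stats["pli", ]), 0.15)
})

test_that("AEC handles identical, anti-correlated and degenerate envelopes", {
  e <- abs(sin(seq_len(300) / 11)) + 0.2
  expect_equal(aec(e, e), 1)
  expect_equal(aec(e, max(e) + min(e) - e), 1) # anti-correlated, rectified
  expect_error(aec(e, rep(1, 300)), class = "undefined_pair")
  set.seed(3)
  null_aec <- replicate(100, abs(cor(rnorm(200), rnorm(200))))
  expect_lt(median(null_aec), quantile(null_aec, 0.99))
})

test_that("orthogonalization fixes points, permutes equivariantly, errors on rank loss", {
  set.seed(8)
  q <- qr.Q(qr(matrix(rnorm(400 * 3), 400, 3)))
  x_orth <- t(q) * c(2, 0.5, 1.3)
  expect_equal(symmetric_orthogonalize(x_orth), x_orth, tolerance = 1e-8)

  x <- matrix(rnorm(4 * 300), 4)
  p <- c(3, 1, 4, 2)
  expect_equal(symmetric_orthogonalize(x[p, ]), symmetric_orthogonalize(x)[p, ],
    tolerance = 1e-8
  )

  dup <- rbind(x[1, ], x[1, ], x[2, ])
  expect_error(symmetric_orthogonalize(dup), class = "rank_deficient")
  expect_error(symmetric_orthogonalize(matrix(rnorm(12), 4, 3)), class = "invalid_argument")
})

test_that("orthogonalized output has orthogonal rows near the input", {
  set.seed(9)
  for (k in 1:5) {
    x <- matrix(rnorm(5 * 400), 5)
    x[2, ] <- 0.8 * x[1, ] + 0.3 * x[2, ] # induce correlation
    y <- symmetric_orthogonalize(x)
    gram <- tcrossprod(y)
    expect_lt(max(abs(gram[upper.tri(gram)])) / max(diag(gram)), 1e-8)
    expect_lt(norm(x - y, "F") / norm(x, "F"), 1) # closer to x than the origin
  }
})

test_that("two-channel orthogonalization matches a direct minimization oracle", {
  set.seed(10)
  x <- matrix(rnorm(2 * 200), 2)
  x[2, ] <- x[2, ] + 0.9 * x[1, ]
  y <- symmetric_orthogonalize(x)
  # oracle: brute-force the closest orthogonal pair over a rotation angle in
  # the row space and per-row scales (closed form for the scales)
  base <- qr.Q(qr(t(x)))[, 1:2] # orthonormal basis of the row space
  best <- Inf
  for (theta in seq(0, pi, length.out = 4001)) {
    q1 <- cos(theta) * base[, 1] + sin(theta) * base[, 2]
    q2 <- -sin(theta) * base[, 1] + cos(theta) * base[, 2]
    d1 <- sum(x[1, ] * q1)
    d2 <- sum(x[2, ] * q2)
    dist <- sum((x[1, ] - d1 * q1)^2) + sum((x[2, ] - d2 * q2)^2)
    # the mirrored assignment
    e1 <- sum(x[1, ] * q2)
    e2 <- sum(x[2, ] * q1)
    dist2 <- sum((x[1, ] - e1 * q2)^2) + sum((x[2, ] - e2 * q1)^2)
    best <- min(best, dist, dist2)
  }
  achieved <- norm(x - y, "F")^2
  expect_equal(achieved, best, tolerance = 1e-4)
})

test_that("leakage correction removes shared zero-lag components only", {
  fs <- 160
  t <- seq(1 / fs, 12, by = 1 / fs)
  # pure leakage: two scaled copies of one signal
  set.seed(14)
  base <- cos(2 * pi * 10 * t + cumsum(rnorm(length(t), sd = 0.1))) *
    exp(0.4 * stats::filter(rnorm(length(t), sd = 0.15), 0.98, method = "recursive"))
  x <- rbind(base * 1.2, base * 0.7) + 0.01 * sd(base) * matrix(rnorm(2 * length(t)), 2)
  anl <- analytic_signal(x, fs)
  plain <- aec(anl$envelope[1, ], anl$envelope[2, ])
  corrected <- aec_corrected(x, fs)[1, 2]
  expect_gt(plain, 0.95)
  expect_lt(corrected, 0.1)
})

test_that("genuinely lagged envelope coupling survives leakage correction", {
  ratio <- sapply(1:20, function(s) {
    set.seed(s)
    fs <- 160
    n <- 12 * fs
    lagn <- round(0.1 * fs) # 100 ms
    slow <- stats::filter(rnorm(n + lagn, sd = 0.2), 0.97, method = "recursive")
    m1 <- exp(slow[(lagn + 1):(n + lagn)])
    m2 <- exp(slow[1:n])
    t <- seq_len(n) / fs
    x <- rbind(
      m1 * cos(2 * pi * 10 * t + cumsum(rnorm(n, sd = 0.3))),
      m2 * cos(2 * pi * 10 * t + cumsum(rnorm(n, sd = 0.3)))
    )
    anl <- analytic_signal(x, fs)
    plain <- aec(anl$envelope[1, ], anl$envelope[2, ])
    aec_corrected(x, fs)[1, 2] / plain
  })
  expect_gt(median(ratio), 0.5)
})

test_that("mutually orthogonal input makes corrected and plain AEC agree", {
  set.seed(15)
  q <- t(qr.Q(qr(matrix(rnorm(600 * 3), 600, 3)))) * c(1.5, 1, 2)
  plain <- eegnetcomp:::conn_all(q, 0L, FALSE, TRUE)$aec
  corrected <- aec_corrected(q, 160, edge_trim = 0)
  expect_equal(corrected, plain, tolerance = 1e-6)
})

test_that("connectivity matrices are symmetric per-epoch estimates", {
  set.seed(16)
  co <- simulate_sources(pair_spec(seed = 16, n = 8, leaf = 0.5), duration = 24, fs = 160)
  rec <- new_recording(co$data, 160, domain = "source")
  ep <- segment_epochs(bandpass_filter(rec, 8, 13), 12)
  for (met in c("plv", "pli", "aec", "aec_corrected")) {
    ms <- connectivity_matrix(ep, met)
    expect_length(ms, 2L)
    m <- ms[[1]]
    expect_equal(dim(m), c(8L, 8L))
    expect_equal(unclass(m), t(unclass(m)), ignore_attr = TRUE)
    expect_true(all(diag(m) == 0))
    expect_equal(attr(m, "metric"), met)
  }
})

test_that("a strongly coupled pair dominates the PLV matrix", {
  hits <- sapply(1:20, function(s) {
    rec <- simulate_sources(pair_spec(strength = 0.95, seed = s, n = 6, leaf = 0.5),
      duration = 14, fs = 160
    )
    core <- eegnetcomp:::conn_all(rec$data, 40L, TRUE, FALSE)
    idx <- which(core$plv == max(core$plv), arr.ind = TRUE)[1, ]
    all(sort(idx) == c(1, 2))
  })
  expect_gte(mean(hits), 0.9)
})

test_that("metrics are invariant to channel rescaling", {
  set.seed(17)
  x <- matrix(rnorm(4 * 1000), 4)
  sc <- c(3, 0.2, 1, 10) * x
  a <- eegnetcomp:::conn_all(x, 0L, TRUE, TRUE)
  b <- eegnetcomp:::conn_all(sc, 0L, TRUE, TRUE)
  expect_equal(a$plv, b$plv, tolerance = 1e-12)
  expect_equal(a$pli, b$pli, tolerance = 1e-12)
  expect_equal(a$aec, b$aec, tolerance = 1e-9)
})

test_that("PLI vanishes for symmetric phase-difference distributions", {
  ph <- cumsum(rnorm(1000)) / 20
  delta <- rep(c(0.4, -0.4), 500) # symmetric about zero
  expect_equal(pli(ph + delta, ph), 0)
})

test_that("global connectivity averages the off-diagonal entries", {
  m <- matrix(0.5, 4, 4)
  diag(m) <- 0
  expect_equal(global_connectivity(m), 0.5)
  expect_equal(global_connectivity(matrix(0, 3, 3)), 0)
  m3 <- matrix(0, 3, 3)
  m3[upper.tri(m3)] <- c(0.2, 0.4, 0.9)
  m3 <- m3 + t(m3)
  expect_equal(global_connectivity(m3), 0.5)
  expect_error(global_connectivity(matrix(0, 1, 1)), class = "invalid_argument")
})
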