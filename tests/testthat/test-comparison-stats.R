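# Domain comparison statistics: Spearman, percentile bootstrap, aggregation,
# condition shifts.

test_that("Spearman correlation handles monotone transforms and ties", {
  x <- c(1, 3, 2, 5, 4, 7, 6)
  expect_equal(spearman_rho(x, x^3), 1)
  expect_equal(spearman_rho(x, -x), -1)
  xt <- c(1, 2, 2, 4)
  yt <- c(3, 1, 4, 4)
  expect_equal(spearman_rho(xt, yt), spearman_oracle(xt, yt))
  expect_error(spearman_rho(rep(1, 5), 1:5), class = "undefined_correlation")
  expect_error(spearman_rho(1:2, 1:2), class = "invalid_argument")
  # invariance to strictly monotone transforms
  set.seed(1)
  a <- rnorm(30)
  b <- rnorm(30)
  expect_equal(spearman_rho(a, b), spearman_rho(exp(a), b))
  expect_equal(spearman_rho(a, b), spearman_rho(a, atan(b)))
})

test_that("bootstrap comparison of identical groups brackets zero", {
  set.seed(2)
  pairs <- cbind(rnorm(50), rnorm(50))
  cmp <- bootstrap_compare(pairs, pairs, n_boot = 300, seed = 9)
  expect_equal(cmp$difference, 0)
  expect_lte(cmp$ci[1], 0)
  expect_gte(cmp$ci[2], 0)
  cmp2 <- bootstrap_compare(pairs, pairs, n_boot = 300, seed = 9)
  expect_identical(cmp$ci, cmp2$ci)
})

test_that("the bootstrap CI separates a strong from a null correlation", {
  excl <- sapply(1:20, function(s) {
    set.seed(s)
    xa <- rnorm(200)
    pa <- cbind(xa, xa + rnorm(200, sd = 0.05))
    pb <- cbind(rnorm(200), rnorm(200))
    cmp <- bootstrap_compare(pa, pb, n_boot = 500, seed = 100 + s)
    cmp$ci[1] > 0 || cmp$ci[2] < 0
  })
  expect_gte(mean(excl), 0.95)
})

test_that("degenerate bootstrap resamples are counted and bounded", {
  pairs_degenerate <- cbind(c(1, 1, 2), c(3, 1, 2))
  pairs_ok <- cbind(rnorm(30), rnorm(30))
  expect_error(
    bootstrap_compare(pairs_degenerate, pairs_ok, n_boot = 200, seed = 1),
    class = "degenerate_bootstrap"
  )
})

test_that("bootstrap CI width shrinks with group size", {
  widths <- sapply(1:20, function(s) {
    set.seed(s)
    mk <- function(n) cbind(rnorm(n), rnorm(n))
    w <- function(n) {
      cmp <- bootstrap_compare(mk(n), mk(n), n_boot = 200, seed = 200 + s)
      diff(cmp$ci)
    }
    c(small = w(100), large = w(400))
  })
  expect_lt(median(widths["large", ]), median(widths["small", ]))
})

make_measure_table <- function(n_sub = 4, n_ep = 3, metrics = c("pli", "plv"),
                               measures = c("global", "leaf_fraction"), seed = 1) {
  set.seed(seed)
  grid <- expand.grid(
    subject = sprintf("S%02d", seq_len(n_sub)),
    condition = c("EC", "EO"), epoch = seq_len(n_ep),
    metric = metrics, measure = measures, stringsAsFactors = FALSE
  )
  grid$scalp <- rnorm(nrow(grid))
  grid$source <- grid$scalp * 0.5 + rnorm(nrow(grid), sd = 0.5)
  grid
}

test_that("subject averaging matches a brute-force group-by mean", {
  tab <- make_measure_table()
  avg <- subject_average(tab)
  expect_true(all(is.na(avg$epoch)))
  oracle <- aggregate(scalp ~ subject + condition + metric + measure, tab, mean)
  merged <- merge(avg, oracle, by = c("subject", "condition", "metric", "measure"))
  expect_equal(merged$scalp.x, merged$scalp.y)
  # trivial cases
  one <- tab[tab$subject == "S01" & tab$condition == "EC" &
    tab$metric == "pli" & tab$measure == "global", ]
  one$scalp <- c(0.2, 0.4, 0.3)
  one$source <- 0.7
  a1 <- subject_average(one)
  expect_equal(a1$scalp, 0.3)
  expect_equal(a1$source, 0.7)
})

test_that("domain correlations cover the metric x measure grid at both levels", {
  tab <- make_measure_table(
    n_sub = 6, metrics = c("plv", "pli", "aec", "aec_corrected"),
    measures = c("global", "leaf_fraction", "diameter", "kappa", "hierarchy")
  )
  g_ep <- correlate_domains(tab, "epoch")
  expect_equal(nrow(g_ep), 20L)
  g_su <- correlate_domains(tab, "subject")
  expect_equal(nrow(g_su), 20L)
  expect_true(all(g_ep$n == 36))

  dup <- tab
  dup$source <- dup$scalp
  expect_true(all(correlate_domains(dup, "epoch")$rho == 1))
})

test_that("independent domains give near-zero correlations", {
  ok <- sapply(1:20, function(s) {
    set.seed(s)
    tab <- data.frame(
      subject = sprintf("S%03d", rep(1:100, each = 5)),
      condition = "EC", epoch = rep(1:5, 100),
      metric = "pli", measure = "global",
      scalp = rnorm(500), source = rnorm(500)
    )
    abs(correlate_domains(tab, "epoch")$rho) < 0.15
  })
  expect_gte(mean(ok), 0.9)
})

test_that("condition shifts report direction agreement per metric", {
  base <- expand.grid(
    subject = sprintf("S%02d", 1:5), condition = c("EC", "EO"),
    epoch = 1:2, metric = "pli", measure = "leaf_fraction",
    stringsAsFactors = FALSE
  )
  same <- base
  same$scalp <- ifelse(same$condition == "EC", 0.6, 0.4)
  same$source <- ifelse(same$condition == "EC", 0.55, 0.45)
  expect_equal(condition_shift(same)$direction, "same")

  opp <- same
  opp$source <- ifelse(opp$condition == "EC", 0.45, 0.55)
  expect_equal(condition_shift(opp)$direction, "opposite")

  tie <- same
  tie$scalp <- 0.5
  expect_equal(condition_shift(tie)$direction, "none")

  ec_only <- same[same$condition == "EC", ]
  expect_error(condition_shift(ec_only), class = "invalid_input")

  # swapping the condition labels flips both shifts and keeps the agreement
  swapped <- same
  swapped$condition <- ifelse(same$condition == "EC", "EO", "EC")
  s1 <- condition_shift(same, conditions = c("EC", "EO"))
  s2 <- condition_shift(swapped, conditions = c("EC", "EO"))
  expect_equal(s1$shift_scalp, -s2$shift_scalp)
  expect_equal(s1$direction, s2$direction)
})
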