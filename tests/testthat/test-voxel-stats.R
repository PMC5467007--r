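test_that("window schemes enforce ordering and disjointness", {
  expect_error(window_scheme(c(1L, 50L),
                             list(a = c(40L, 100L))), "after the baseline")
  expect_error(window_scheme(c(1L, 50L),
                             list(a = c(100L, 200L), b = c(150L, 250L))),
               "disjoint")
  # shared endpoints are fine: ranges are half-open
  sch <- window_scheme(c(1L, 50L), list(a = c(150L, 250L),
                                        b = c(250L, 350L)))
  expect_length(intersect(150:249, 250:349), 0)
  expect_equal(length(window_acqs(sch, "a")), 100)
})

test_that("percent change is the baseline-referenced window mean", {
  sch <- tiny_scheme()
  x <- rep(100, 60)
  expect_equal(percent_change(x, sch, "w1"), 0)
  x[20:39] <- 102
  expect_equal(percent_change(x, sch, "w1"), 2)
  y <- rep(200, 60); y[40:59] <- 190
  expect_equal(percent_change(y, sch, "w2"), -5)
  # invariance under global rescaling
  for (c_ in c(0.5, 3, 1000))
    expect_equal(percent_change(c_ * x, sch, "w1"),
                 percent_change(x, sch, "w1"), tolerance = 1e-12)
  expect_error(percent_change(rep(0, 60), sch, "w1"), "zero baseline")
})

test_that("welch_t matches the hand formula and independent oracles", {
  # hand-evaluated case: means 3 vs 4, variances 2.5, n = 5 -> t = 1, df = 8
  r <- welch_t(1:5, 2:6)
  expect_equal(r$statistic, 1.0)
  expect_equal(r$df, 8)
  expect_equal(r$p.value, 2 * pt(-1, 8))

  # identical samples
  r0 <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p.value, 1)

  # degenerate: zero variance, equal vs different means
  expect_equal(welch_t(c(2, 2, 2), c(2, 2))$p.value, 1)
  d <- welch_t(c(2, 2, 2), c(3, 3))
  expect_equal(d$p.value, 0)
  expect_true(d$degenerate)

  # random cases against stats::t.test and a numeric-integration t CDF
  set.seed(99)
  for (i in 1:25) {
    b <- rnorm(sample(3:40, 1), sd = runif(1, 0.5, 3))
    w <- rnorm(sample(3:40, 1), mean = runif(1, -1, 1),
               sd = runif(1, 0.5, 3))
    mine <- welch_t(b, w)
    ref <- t.test(w, b, var.equal = FALSE)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-10)
    expect_equal(mine$p.value, t_p_integrate(mine$statistic, mine$df),
                 tolerance = 1e-10)
  }
})

test_that("fdr_adjust implements the BH step-up exactly", {
  # worked examples
  expect_equal(sum(fdr_adjust(rep(1, 20))$reject), 0)
  r <- fdr_adjust(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(r$reject))            # 0.04 <= 4 * 0.05 / 4
  expect_true(fdr_adjust(0.04, q = 0.05)$reject)   # m = 1 reduces to p <= q
  expect_false(fdr_adjust(0.06, q = 0.05)$reject)
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  # random families against the brute-force oracle
  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(c(1, 5, 50, 500), 1))^sample(1:3, 1)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    mine <- fdr_adjust(p, q)
    want <- bh_oracle(p, q)
    expect_equal(mine$p_adj, want$p_adj, tolerance = 1e-12)
    expect_identical(mine$reject, want$reject)
  }

  # NA entries (untestable voxels) stay NA and are never rejected
  rna <- fdr_adjust(c(0.01, NA, 0.5))
  expect_true(is.na(rna$p_adj[2]))
  expect_false(rna$reject[2])
})

test_that("activation maps obey the threshold-and-FDR activation rule", {
  a <- tiny_atlas()
  sch <- tiny_scheme()

  # noiseless null session: nothing activates
  s0 <- generate_session(a, response_spec(n_baseline = 10L), tiny_config(),
                         "vehicle")
  m0 <- activation_map(s0, a$labels, sch)
  for (w in m0$windows)
    expect_equal(sum(w$activated, na.rm = TRUE), 0)

  # +4% step in region 2: every region-2 voxel activated at +4.0 everywhere
  s4 <- generate_session(a, tiny_spec("drug", 2L), tiny_config(), "drug")
  m4 <- activation_map(s4, a$labels, sch)
  in2 <- a$labels == 2L
  for (w in m4$windows) {
    expect_true(all(w$activated[in2]))
    expect_equal(unique(w$pct_change[in2]), 4.0, tolerance = 1e-9)
    expect_equal(sum(w$activated, na.rm = TRUE), sum(in2))
    expect_true(all(w$sign[in2] == 1))
  }

  # +1.5% response: the 2% amplitude filter gates despite p ~ 0
  s15 <- generate_session(a, tiny_spec("drug", 2L, amplitude = 1.5),
                          tiny_config(), "drug")
  m15 <- activation_map(s15, a$labels, sch)
  for (w in m15$windows) {
    expect_equal(sum(w$activated, na.rm = TRUE), 0)
    expect_lt(min(w$p_adj[in2]), 1e-6)  # the test alone would reject
  }

  # global invariant: activated implies |pct| >= threshold and p_adj <= q
  sN <- generate_session(a, tiny_spec("drug", 1L, amplitude = 2.5),
                         tiny_config(noise_sd = 1), "drug", seed = 8)
  mN <- activation_map(sN, a$labels, sch)
  for (w in mN$windows) {
    act <- which(w$activated)
    expect_true(all(abs(w$pct_change[act]) >= 2.0))
    expect_true(all(w$p_adj[act] <= 0.05))
    expect_true(all(w$p_adj >= w$p_raw, na.rm = TRUE))
  }
})

test_that("voxels with zero baseline are excluded from the FDR family", {
  labs <- array(0L, c(3, 2, 1))
  labs[1:4] <- 1L
  a <- atlas(labs, c(1, 1, 1), data.frame(region_id = 1L,
                                          region_name = "r"))
  dat <- array(100, c(3, 2, 1, 60))
  dat[1, 1, 1, ] <- 0                       # brain voxel with zero baseline
  set.seed(4)
  dat[2, 1, 1, ] <- 100 + rnorm(60)
  s <- bold_session(dat, 6, c(1, 1, 1))
  m <- activation_map(s, labs, tiny_scheme())
  w <- m$windows[[1]]
  expect_true(is.na(w$pct_change[1, 1, 1]))
  expect_false(isTRUE(w$activated[1, 1, 1]))
  expect_false(is.na(w$pct_change[2, 1, 1]))
})
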