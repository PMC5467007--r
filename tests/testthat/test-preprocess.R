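test_that("global mean series averages brain voxels only", {
  a <- tiny_atlas()
  cfg <- tiny_config()
  s <- generate_session(a, response_spec(n_baseline = 10L), cfg, "vehicle")
  expect_equal(global_mean_series(s, a), rep(cfg$baseline_level, 60))

  # changing background voxels leaves the series untouched
  s2 <- s
  bg <- which(as.vector(a$labels) == 0L)[1:5]
  m <- matrix(s2$data, ncol = 60)
  m[bg, ] <- 1e6
  s2$data <- array(m, dim(s2$data))
  expect_equal(global_mean_series(s2, a), global_mean_series(s, a))

  # two brain voxels at 90 and 110 average to 100
  labs <- array(0L, c(2, 1, 1)); labs[] <- 1L
  mini <- atlas(labs, c(1, 1, 1),
                data.frame(region_id = 1L, region_name = "r"))
  ms <- bold_session(array(c(90, 110, 92, 108), c(2, 1, 1, 2)), 6, c(1, 1, 1))
  expect_equal(global_mean_series(ms, mini), c(100, 100))
})

test_that("drift estimation recovers constructed slopes and honours the limit", {
  tr <- 6
  minutes <- (0:499) * tr / 60
  # flat series
  est0 <- estimate_drift(rep(500, 500), tr)
  expect_equal(est0$slope, 0)
  expect_false(est0$corrected)

  # slopes across the +-0.05 %/min range recovered to < 1e-6
  for (s in seq(-0.05, 0.05, by = 0.01)) {
    series <- 1000 * (1 + s * minutes / 100)
    est <- estimate_drift(series, tr)
    expect_lt(abs(est$slope - s), 1e-6)
    expect_equal(est$corrected, abs(s) > 0.015)
  }

  # decision boundary: 0.010 %/min is inside the +-0.015 limit
  series <- 1000 * (1 + 0.010 * minutes / 100)
  expect_false(estimate_drift(series, tr)$corrected)
  series <- 1000 * (1 + 0.02 * minutes / 100)
  expect_true(estimate_drift(series, tr)$corrected)

  expect_error(estimate_drift(numeric(1), tr), "at least 2")
})

test_that("drift correction removes the global trend and nothing else", {
  a <- tiny_atlas()
  cfg <- tiny_config(drift_slope = 0.03, n_acquisitions = 100L)

  # below-limit estimate: session passes through bit-exactly
  s <- generate_session(a, response_spec(n_baseline = 10L), cfg, "vehicle")
  est_low <- estimate_drift(rep(1000, 100), cfg$tr_seconds)
  expect_identical(correct_drift(s, est_low)$data, s$data)

  # pure global ramp becomes constant in time; re-estimate ~ 0
  est <- estimate_drift(global_mean_series(s, a), s$tr_seconds)
  sc <- correct_drift(s, est)
  gm <- global_mean_series(sc, a)
  expect_lt(abs(estimate_drift(gm, s$tr_seconds)$slope), 1e-6)
  expect_equal(max(gm) - min(gm), 0, tolerance = 1e-9)

  # idempotence: correcting twice equals once (second estimate below limit)
  est2 <- estimate_drift(gm, s$tr_seconds)
  scc <- correct_drift(sc, est2)
  expect_equal(scc$data, sc$data, tolerance = 1e-9)

  # a region response superposed multiplicatively on the global trend
  # survives correction with its amplitude intact
  sch <- window_scheme(c(1L, 10L), list(w = c(60L, 100L)))
  minutes <- (0:99) * cfg$tr_seconds / 60
  trend <- 1 + 0.03 * minutes / 100
  resp <- c(rep(0, 10), rep(5, 90))                 # +5% from acq 11
  v3 <- as.vector(a$labels) == 3L
  m <- matrix(0, nrow = length(v3), ncol = 100)
  m[as.vector(a$labels) > 0L, ] <- rep(1000 * trend,
                                       each = sum(a$labels > 0L))
  m[v3, ] <- m[v3, ] * rep(1 + resp / 100, each = sum(v3))
  sr <- bold_session(array(m, c(dim(a$labels), 100)), cfg$tr_seconds,
                     a$voxel_size, "mult", "drug")
  est_r <- estimate_drift(1000 * trend, cfg$tr_seconds)
  src <- correct_drift(sr, est_r)
  v <- which(v3)[1]
  pc <- percent_change(matrix(src$data, ncol = 100)[v, ], sch, "w")
  expect_equal(pc, 5.0, tolerance = 1e-6)
})

test_that("gaussian smoothing preserves constants, mass, and scaling", {
  a <- tiny_atlas()
  cfg <- tiny_config()
  s <- generate_session(a, response_spec(n_baseline = 10L), cfg, "vehicle")

  # fwhm 0 is the identity
  expect_identical(smooth_gaussian(s, 0)$data, s$data)

  # constant volumes are unchanged (reflective boundary + normalized kernel)
  su <- s
  su$data <- array(7, dim(s$data))
  sm <- smooth_gaussian(su, 0.8)
  expect_equal(sm$data, su$data, tolerance = 1e-12)

  # a unit impulse keeps total mass 1
  si <- bold_session(array(0, c(9, 9, 5, 1)), 6, c(0.3125, 0.3125, 1))
  si$data[5, 5, 3, 1] <- 1
  so <- smooth_gaussian(si, 0.8)
  expect_equal(sum(so$data), 1, tolerance = 1e-6)

  # smoothing commutes with global scaling
  set.seed(1)
  sr <- bold_session(array(rnorm(9 * 9 * 5 * 2), c(9, 9, 5, 2)), 6,
                     c(0.3125, 0.3125, 1))
  sr3 <- sr; sr3$data <- 3 * sr$data
  expect_equal(smooth_gaussian(sr3, 0.8)$data,
               3 * smooth_gaussian(sr, 0.8)$data, tolerance = 1e-12)

  expect_error(smooth_gaussian(s, -1), "fwhm")
})

test_that("compiled smoothing matches a direct-summation oracle", {
  # brute-force separable convolution with the same symmetric boundary
  reflect <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  conv_axis <- function(vol, ax, w) {
    r <- (length(w) - 1) / 2
    out <- array(0, dim(vol))
    d <- dim(vol)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      acc <- 0
      for (o in -r:r) {
        idx <- c(i, j, k)
        idx[ax] <- reflect(idx[ax] + o, d[ax])
        acc <- acc + w[o + r + 1] * vol[idx[1], idx[2], idx[3]]
      }
      out[i, j, k] <- acc
    }
    out
  }
  set.seed(42)
  vol <- array(rnorm(6 * 5 * 4), c(6, 5, 4))
  s <- bold_session(array(vol, c(6, 5, 4, 1)), 6, c(0.5, 0.5, 1.0))
  fwhm <- 0.9
  sig <- fwhm / (2 * sqrt(2 * log(2))) / s$voxel_size
  kern <- lapply(sig, function(x) {
    r <- max(1, ceiling(3 * x))
    w <- exp(-((-r:r)^2) / (2 * x^2)); w / sum(w)
  })
  want <- conv_axis(conv_axis(conv_axis(vol, 1, kern[[1]]), 2, kern[[2]]),
                    3, kern[[3]])
  got <- smooth_gaussian(s, fwhm)$data[, , , 1]
  expect_equal(got, want, tolerance = 1e-10)
})
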