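# Small in-code fixtures shared across the suite. Everything is generated at
# test time; nothing binary is stored.

# 12 x 12 x 6 atlas with 4 block regions (deterministic)
tiny_atlas <- function(seed = 7L)
  generate_atlas(c(12L, 12L, 6L), 4L, seed = seed,
                 voxel_size = c(0.3125, 0.3125, 1.0))

# short-session config: 60 acquisitions, no drift/noise unless asked
tiny_config <- function(noise_sd = 0, drift_slope = 0, n_acquisitions = 60L)
  session_config(shape = c(12L, 12L, 6L), n_acquisitions = n_acquisitions,
                 noise_sd = noise_sd, drift_slope = drift_slope,
                 n_baseline = 10L)

# matching scheme: baseline acq 1-10, two disjoint half-open windows
tiny_scheme <- function()
  window_scheme(baseline = c(1L, 10L),
                windows = list(w1 = c(20L, 40L), w2 = c(40L, 60L)))

# response spec with onsets valid for the 10-acquisition tiny baseline
tiny_spec <- function(treatment, region_id, onset = 11L, ramp = 0L,
                      amplitude = 4.0)
  response_spec(treatment, region_id, onset, ramp, amplitude,
                n_baseline = 10L)

# independent Benjamini-Hochberg step-up oracle (brute force)
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  thresh <- seq_len(m) * q / m
  k <- suppressWarnings(max(which(ps <= thresh)))
  reject <- rep(FALSE, m)
  if (is.finite(k)) reject[o[seq_len(k)]] <- TRUE
  # adjusted p: running minimum of m * p_(i) / i from the top
  adj <- rev(cummin(rev(m * ps / seq_len(m))))
  adj <- pmin(adj, 1)
  list(p_adj = adj[order(o)], reject = reject)
}

# independent tie-corrected Kruskal-Wallis oracle
kw_oracle <- function(values, groups) {
  n <- length(values)
  r <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, sum)^2 / tabulate(as.integer(factor(groups)))) -
    3 * (n + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h <- h / corr
  list(H = h, p = stats::pchisq(h, nlevels(factor(groups)) - 1,
                                lower.tail = FALSE))
}

# two-tailed p from the t density by numeric integration (independent of pt)
t_p_integrate <- function(tstat, df)
  2 * stats::integrate(function(u) stats::dt(u, df), lower = abs(tstat),
                       upper = Inf, rel.tol = 1e-12)$value
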