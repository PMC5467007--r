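test_that("volume of activation counts activated voxels per region", {
  a <- tiny_atlas()
  sch <- tiny_scheme()

  # empty mask -> all zero
  s0 <- generate_session(a, response_spec(n_baseline = 10L), tiny_config(),
                         "vehicle")
  v0 <- volume_of_activation(activation_map(s0, a$labels, sch), a$labels)
  expect_true(all(v0$activated_voxels == 0))
  expect_true(all(v0$mean_pct_change == 0))

  # +4% confined to region 3: count = region size there, 0 elsewhere
  s4 <- generate_session(a, tiny_spec("drug", 3L), tiny_config(), "drug")
  m4 <- activation_map(s4, a$labels, sch)
  v4 <- volume_of_activation(m4, a$labels)
  w1 <- v4[v4$window == "w1", ]
  expect_equal(w1$activated_voxels[w1$region_id == 3],
               sum(a$labels == 3L))
  expect_true(all(w1$activated_voxels[w1$region_id != 3] == 0))
  expect_equal(w1$mean_pct_change[w1$region_id == 3], 4, tolerance = 1e-9)

  # conservation: counts sum to the total activated (+) voxels
  tot <- sum(m4$windows[["w1"]]$activated & m4$windows[["w1"]]$sign == 1,
             na.rm = TRUE)
  expect_equal(sum(w1$activated_voxels), tot)

  # negative responses are counted under sign "-" only
  sneg <- generate_session(a, tiny_spec("drug", 2L, amplitude = -4),
                           tiny_config(), "drug")
  mneg <- activation_map(sneg, a$labels, sch)
  expect_equal(sum(volume_of_activation(mneg, a$labels,
                                        "+")$activated_voxels), 0)
  vneg <- volume_of_activation(mneg, a$labels, "-")
  expect_equal(sum(vneg$activated_voxels[vneg$window == "w1"]),
               sum(a$labels == 2L))
})

test_that("volume of activation is monotone under mask growth", {
  a <- tiny_atlas()
  sch <- tiny_scheme()
  s <- generate_session(a, tiny_spec("drug", 1L, amplitude = 3),
                        tiny_config(noise_sd = 1.5), "drug", seed = 21)
  m <- activation_map(s, a$labels, sch)
  v1 <- volume_of_activation(m, a$labels)

  # grow the mask: activate every region-2 voxel too
  m2 <- m
  for (w in names(m2$windows)) {
    m2$windows[[w]]$activated[a$labels == 2L] <- TRUE
    m2$windows[[w]]$sign[a$labels == 2L] <- 1
    m2$windows[[w]]$pct_change[a$labels == 2L] <- 5
  }
  v2 <- volume_of_activation(m2, a$labels)
  expect_true(all(v2$activated_voxels >= v1$activated_voxels))
})

test_that("composite maps average subjects and apply the frequency rule", {
  a <- tiny_atlas()
  sch <- tiny_scheme()
  cfg <- tiny_config(noise_sd = 0.5)
  maps <- lapply(1:4, function(i)
    activation_map(generate_session(a, tiny_spec("drug", 1L), cfg, "drug",
                                    paste0("s", i), seed = i),
                   a$labels, sch))

  # n = 1: composite equals that subject's map on its activated voxels
  c1 <- composite_map(maps[1], "w1", min_frequency = 0.5)
  w <- maps[[1]]$windows[["w1"]]
  expect_equal(c1$mean_pct[c1$retained], w$pct_change[w$activated %in% TRUE])

  # averaging: voxel activated in all subjects gets the mean pct
  c4 <- composite_map(maps, "w1", min_frequency = 0.5)
  vox <- which(a$labels == 1L)[1]
  expect_equal(c4$mean_pct[vox],
               mean(vapply(maps, function(m)
                 m$windows[["w1"]]$pct_change[vox], 0.0)))
  expect_true(c4$retained[vox])

  # frequency rule: a voxel activated in 1 of 4 subjects is dropped
  fake <- maps
  vox2 <- which(a$labels == 2L)[1]
  fake[[1]]$windows[["w1"]]$activated[vox2] <- TRUE
  cf <- composite_map(fake, "w1", min_frequency = 0.5)
  expect_false(cf$retained[vox2])

  # hand-built two-subject average
  expect_equal(mean(c(2, 4)), 3.0)
  counts <- composite_region_counts(c4, a$labels)
  expect_equal(unname(counts["1"]), sum(a$labels == 1L))
  expect_equal(sum(counts[-1]), 0)
})

test_that("kruskal_wallis_region matches rank-based oracles", {
  # all tied
  expect_equal(kruskal_wallis_region(list(A = c(3, 3, 3), B = c(3, 3, 3))),
               list(H = 0, p = 1))

  # two-group case vs the independent tie-corrected oracle
  g2 <- list(A = c(0, 0, 0), B = c(5, 6, 7))
  got <- kruskal_wallis_region(g2)
  want <- kw_oracle(unlist(g2), rep(c("A", "B"), each = 3))
  expect_equal(got$H, want$H, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)

  # random tied count data vs the oracle
  set.seed(6)
  for (i in 1:10) {
    cbg <- list(a = rpois(7, 1), b = rpois(9, 2), c = rpois(8, 1))
    if (length(unique(unlist(cbg))) == 1L) next
    got <- kruskal_wallis_region(cbg)
    want <- kw_oracle(unlist(cbg), rep(names(cbg), lengths(cbg)))
    expect_equal(got$H, want$H, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }

  # in the rejection tail (where decisions are made) the chi-square
  # reference is close to the exact permutation p for a small 3-group case
  vals <- c(0, 0, 1, 2, 4, 5, 6, 3, 7, 8, 9, 10)
  grp <- rep(c("a", "b", "c"), each = 4)
  obs <- kruskal_wallis_region(split(vals, grp))
  hperm <- apply(combn(12, 4), 2, function(ia) {
    rest <- setdiff(1:12, ia)
    apply(combn(rest, 4), 2, function(ib) {
      g <- integer(12); g[ia] <- 1L; g[ib] <- 2L
      kw_oracle(vals, g)$H
    })
  })
  p_perm <- mean(hperm >= obs$H - 1e-12)
  expect_lt(abs(obs$p - p_perm), 0.01)

  expect_error(kruskal_wallis_region(list(A = 1:3)), "2 groups")
})

test_that("comparison tables carry counts, H, p and the significance flag", {
  a <- tiny_atlas()
  sch <- tiny_scheme()
  cfg <- tiny_config(noise_sd = 1)
  spec <- tiny_spec("drug", 1L)
  co <- generate_cohort(a, spec, cfg, c(vehicle = 5L, drug = 5L), seed = 31)
  voa <- do.call(rbind, lapply(co, function(s)
    volume_of_activation(activation_map(s, a$labels, sch), a$labels)))
  tab <- region_comparison_table(voa, c("vehicle", "drug"))
  expect_setequal(names(tab), c("region_id", "window", "count_vehicle",
                                "count_drug", "kw_H", "p_value",
                                "significant"))
  expect_identical(tab$significant, tab$p_value <= 0.05)
  r1 <- tab[tab$region_id == 1 & tab$window == "w1", ]
  expect_lt(r1$p_value, 0.05)
  expect_equal(r1$count_drug, sum(a$labels == 1L))
  expect_equal(r1$count_vehicle, 0)

  sig <- significant_region_table(tab, "w1")
  expect_true(all(diff(sig$p_value) >= 0))
  expect_true(1 %in% sig$region_id)
  expect_false(any(!sig$p_value <= 0.05))
})
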