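test_that("generated marginals recover their percentile anchors", {
  cfg <- generator_config(n_sites = 10000, seed = 11)
  x <- generate_conditions(cfg)
  pc <- condition_percentiles(x)
  anchors <- default_forcing_anchors()
  for (i in seq_len(nrow(pc))) {
    a <- anchors[[pc$variable[i]]]
    got <- unlist(pc[i, c("p5", "p50", "p95")])
    expect_true(all(abs(got - a) <= 0.10 * abs(a)),
                label = paste("percentile recovery for", pc$variable[i]))
  }
})

test_that("generation is deterministic under a fixed seed and obeys invariants", {
  cfg <- generator_config(n_sites = 500, seed = 99)
  x1 <- generate_conditions(cfg)
  x2 <- generate_conditions(cfg)
  expect_identical(as.data.frame(x1), as.data.frame(x2))
  # return-period coherence and range invariants
  for (v in c("water_level", "hs")) {
    m <- as.matrix(as.data.frame(x1)[paste0(v, "_rp", c(2, 5, 10, 25))])
    expect_true(all(m[, -1] - m[, -4] >= 0))
  }
  expect_true(all(x1$hs_rp2 > 0) && all(x1$tp_rp25 > 0))
  expect_true(all(x1$fs_z0 < 0))
  expect_true(all(x1$belt_width >= 25))
})

test_that("degenerate zero-variance anchors return the exact anchor value", {
  anch <- list(water_level = c(1.6, 1.6, 1.6), hs = c(2.8, 2.8, 2.8),
               fs_z0 = c(-1.1, -1.1, -1.1), belt_width = c(400, 400, 400))
  cfg <- generator_config(n_sites = 1, anchors = anch,
                          rp_ratios = list(water_level = rep(1, 4), hs = rep(1, 4)),
                          seed = 3)
  x <- generate_conditions(cfg)
  expect_equal(x$water_level_rp25, 1.6)
  expect_equal(x$hs_rp2, 2.8)
  expect_equal(x$fs_z0, -1.1)
  expect_equal(x$belt_width, 400)
})

test_that("generated rank correlations reproduce the configured dependence", {
  x <- generate_conditions(generator_config(n_sites = 10000, seed = 5))
  target <- default_rank_correlation()
  pairs <- list(c("water_level_rp2", "hs_rp2"), c("hs_rp2", "fs_z0"),
                c("water_level_rp2", "fs_z0"), c("hs_rp2", "belt_width"))
  keys <- list(c("water_level", "hs"), c("hs", "fs_z0"),
               c("water_level", "fs_z0"), c("hs", "belt_width"))
  for (i in seq_along(pairs)) {
    got <- cor(x[[pairs[[i]][1]]], x[[pairs[[i]][2]]], method = "spearman")
    expect_lt(abs(got - target[keys[[i]][1], keys[[i]][2]]), 0.1)
  }
})

test_that("invalid generator configurations are rejected with diagnostics", {
  expect_error(generator_config(anchors = utils::modifyList(
    default_forcing_anchors(), list(hs = c(3, 2.8, 5)))), "infeasible anchors")
  bad <- default_rank_correlation()
  bad["water_level", "hs"] <- 0.99; bad["hs", "water_level"] <- 0.99
  bad["water_level", "fs_z0"] <- 0.99; bad["fs_z0", "water_level"] <- 0.99
  bad["hs", "fs_z0"] <- -0.99; bad["fs_z0", "hs"] <- -0.99
  expect_error(generator_config(rank_corr = bad), "positive semi-definite")
  asym <- default_rank_correlation(); asym[1, 2] <- 0.2
  expect_error(generator_config(rank_corr = asym), "symmetric")
})

test_that("steepness filter retains and rejects the constructed cases", {
  # deep-water k_p = 4*pi^2/(g Tp^2): Hs 2.8 m, Tp 12 s -> k_p Hs/2 ~ 0.038
  ok <- make_sites(hs = 2.8, tp = 12)
  expect_equal(nrow(steepness_filter(ok)), 1)
  # vanishing wave height is always retained
  expect_equal(nrow(steepness_filter(make_sites(hs = 1e-12, tp = 6))), 1)
  # one constructed violator among five (Hs 5 m, Tp 4 s -> k_p Hs/2 ~ 3.1)
  toy <- make_sites(hs = c(2, 2.5, 5, 1, 3), tp = c(12, 11, 4, 9, 13))
  kept <- steepness_filter(toy)
  expect_equal(nrow(kept), 4)
  expect_false(3 %in% kept$site_id)
  rej <- rejection_log(kept)
  expect_true(all(rej$site_id == 3))
  expect_true(all(rej$steepness > 0.142))
})

test_that("steepness filter is idempotent", {
  x <- generate_conditions(generator_config(n_sites = 2000, seed = 8))
  once <- steepness_filter(x)
  twice <- steepness_filter(once)
  expect_equal(bare_df(twice), bare_df(once))
  expect_equal(nrow(rejection_log(twice)), 0)
})

test_that("conditions survive a CSV round trip", {
  x <- generate_conditions(generator_config(n_sites = 50, seed = 2))
  p <- withr::local_tempfile(fileext = ".csv")
  write_conditions(x, p)
  y <- read_conditions(p)
  expect_equal(bare_df(y), bare_df(x), tolerance = 1e-12)
  expect_s3_class(y, "site_conditions")
})
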