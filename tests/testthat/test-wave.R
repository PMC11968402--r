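test_that("dispersion honours deep and shallow asymptotes and the identity", {
  g <- 9.81
  s <- 2 * pi / 8
  expect_equal(dispersion(s, 100), s^2 / g, tolerance = 1e-3)
  s2 <- 2 * pi / 12
  expect_equal(dispersion(s2, 0.3), s2 / sqrt(g * 0.3), tolerance = 5e-3)
  for (h in c(0.2, 1, 5, 40)) {
    for (tp in c(4, 8, 15)) {
      sg <- 2 * pi / tp
      k <- dispersion(sg, h)
      expect_equal(sg^2 / (g * k * tanh(k * h)), 1, tolerance = 1e-10)
      expect_equal(k, k_oracle(sg, h), tolerance = 1e-8)
    }
  }
})

test_that("vegetation dissipation matches the classic single-layer formula", {
  rho <- 1025; g <- 9.81
  h <- 2; hs <- 0.8; tp <- 8; f <- 0.2; CD <- 1.3
  sg <- 2 * pi / tp; k <- dispersion(sg, h)
  veg <- uniform_veg(f)
  got <- veg_dissipation(hs, k, sg, h, veg, section_drag(CD, CD, CD))
  # independent Hrms-based evaluation of the unlayered dissipation
  hrms <- hs / sqrt(2)
  expe <- rho * CD / (2 * sqrt(pi)) * (g * k / (2 * sg))^3 * f *
    (sinh(k * h)^3 + 3 * sinh(k * h)) / (3 * k * cosh(k * h)^3) * hrms^3
  expect_equal(got, expe, tolerance = 1e-12)
  # no vegetation, no dissipation
  expect_equal(veg_dissipation(hs, k, sg, h, uniform_veg(0),
                               section_drag(1, 1, 1)), 0)
})

test_that("splitting a layer into sub-layers leaves dissipation unchanged", {
  h <- 1.8; hs <- 0.7; tp <- 9
  sg <- 2 * pi / tp; k <- dispersion(sg, h)
  sd <- section_drag(1.5, 1.5, 1.5)
  one <- uniform_veg(0.25, z_top = 3)
  two <- uniform_veg(0.25, z_top = 3)
  two$layers <- tibble::tibble(z_bottom = c(0, 1.1), z_top = c(1.1, 3),
                               f = 0.25, b_v = 0.05, section = "trunk")
  expect_equal(veg_dissipation(hs, k, sg, h, two, sd),
               veg_dissipation(hs, k, sg, h, one, sd), tolerance = 1e-12)
})

test_that("dissipation is linear in frontal area at fixed drag", {
  h <- 1.5; hs <- 0.6; tp <- 10
  sg <- 2 * pi / tp; k <- dispersion(sg, h)
  sd <- section_drag(1.2, 0.9, 1.1)
  for (sp in c("pioneer", "red", "black")) {
    e_med <- veg_dissipation(hs, k, sg, h, schematize(sp, "medium"), sd)
    e_den <- veg_dissipation(hs, k, sg, h, schematize(sp, "dense"), sd)
    e_spa <- veg_dissipation(hs, k, sg, h, schematize(sp, "sparse"), sd)
    expect_equal(e_den, 1.2 * e_med, tolerance = 1e-12)
    expect_equal(e_spa, 0.8 * e_med, tolerance = 1e-12)
  }
})

test_that("breaking dissipation switches on near the breaker limit", {
  sg <- 2 * pi / 8
  cfg <- solver_config()
  expect_lt(breaking_dissipation(0.1, 1, sg, cfg), 1e-6)
  near <- breaking_dissipation(0.7, 1, sg, cfg)
  past <- breaking_dissipation(0.73, 1, sg, cfg)
  expect_gt(near, 0)
  expect_gt(past, near)
})

test_that("Collins friction is linear in cf and decays with relative depth", {
  sg <- 2 * pi / 9
  # linearity and the cf = 0 limit
  h <- 2; hs <- 0.8; k <- dispersion(sg, h)
  expect_equal(friction_dissipation(hs, h, k, sg, 0), 0)
  e1 <- friction_dissipation(hs, h, k, sg, 0.015)
  expect_equal(friction_dissipation(hs, h, k, sg, 0.015 * 1.4), 1.4 * e1)
  # kh = 5 vs kh = 0.5: near-bed velocity collapses in deep water
  h_deep <- 5 / k_oracle(sg, 1e6)      # depth giving kh ~ 5 (deep k)
  k_deep <- dispersion(sg, h_deep)
  h_shal <- uniroot(function(h) dispersion(sg, h) * h - 0.5, c(0.01, 50))$root
  k_shal <- dispersion(sg, h_shal)
  e_deep <- friction_dissipation(hs, h_deep, k_deep, sg, 0.015)
  e_shal <- friction_dissipation(hs, h_shal, k_shal, sg, 0.015)
  expect_lt(e_deep, 1e-3 * e_shal)
})

test_that("flat deep water without sinks carries the wave unchanged", {
  tr <- flat_forest_transect(n = 200, bed = -50, cf = 0)
  run <- propagate(tr, 0, 2, 10, NULL, section_drag(1, 1, 1))
  expect_equal(run$hs, rep(2, 200), tolerance = 1e-12)
  expect_equal(max(abs(run$eps_break)), 0)
  expect_equal(max(abs(run$eps_fric)), 0)
})

test_that("vegetation-only decay matches the closed-form 1/(1 + beta x) solution", {
  rho <- 1025; g <- 9.81
  h <- 2; hs0 <- 0.8; tp <- 8; f <- 0.2; CD <- 1
  sg <- 2 * pi / tp; k <- dispersion(sg, h)
  tr <- flat_forest_transect(n = 401, bed = 0, cf = 0)
  run <- propagate(tr, h, hs0, tp, uniform_veg(f), section_drag(CD, CD, CD))
  C <- rho * CD / (4 * sqrt(2 * pi)) * (g * k / (2 * sg))^3 * f *
    (sinh(k * h)^3 + 3 * sinh(k * h)) / (3 * k * cosh(k * h)^3)
  beta <- 8 * C * hs0 / (rho * g * group_velocity(sg, h))
  exact <- hs0 / (1 + beta * (tr$x - tr$x[1]))
  expect_lt(max(abs(run$hs - exact) / exact), 0.005)
})

test_that("the solver saturates breaking waves on a long shallow flat", {
  tr <- flat_forest_transect(n = 401, bed = 0, cf = 0)
  run <- propagate(tr, 0.5, 2, 8, NULL, section_drag(1, 1, 1))
  expect_true(all(run$hs[50:401] <= 1.1 * 0.73 * 0.5))
  expect_true(all(diff(run$hs) <= 1e-12))
})

test_that("energy flux is non-increasing landward on a full transect", {
  tr <- build_transect(-1.1, 500, 0)
  veg <- schematize("red", "dense")
  run <- propagate(tr, 1.6, 2.8, 12, veg)
  wet <- run$flux > 0
  expect_true(all(diff(run$flux[wet]) <= 1e-9 * max(run$flux)))
  expect_true(all(run$hs >= 0))
})

test_that("layer telescoping invariance holds through the full solver", {
  h <- 2; hs0 <- 0.8; tp <- 8
  tr <- flat_forest_transect(n = 201, bed = 0, cf = 0)
  sd <- section_drag(1, 1, 1)
  one <- uniform_veg(0.2, z_top = 3)
  two <- uniform_veg(0.2, z_top = 3)
  two$layers <- tibble::tibble(z_bottom = c(0, 1.3), z_top = c(1.3, 3),
                               f = 0.2, b_v = 0.05, section = "trunk")
  r1 <- propagate(tr, h, hs0, tp, one, sd)
  r2 <- propagate(tr, h, hs0, tp, two, sd)
  expect_equal(r2$hs, r1$hs, tolerance = 1e-10)
})

test_that("halving the grid step changes the landward wave height by < 1%", {
  veg <- schematize("red", "medium")
  for (args in list(list(fs_z0 = -1.1, sl = 500, vz = 0, wl = 1.6, hs = 2.8, tp = 12),
                    list(fs_z0 = -0.6, sl = 1000, vz = 0.5, wl = 3.5, hs = 5, tp = 14))) {
    t5 <- build_transect(args$fs_z0, args$sl, args$vz, dx = 5)
    t25 <- build_transect(args$fs_z0, args$sl, args$vz, dx = 2.5)
    r5 <- propagate(t5, args$wl, args$hs, args$tp, veg)
    r25 <- propagate(t25, args$wl, args$hs, args$tp, veg)
    hb5 <- r5$hs[t5$n_cells]
    hb25 <- r25$hs[t25$n_cells]
    ref <- r5$hs_edge
    expect_lt(abs(hb5 - hb25) / ref, 0.01)
    # also compare mid-forest
    i5 <- t5$forest_start_index + 200; i25 <- t25$forest_start_index + 400
    expect_lt(abs(r5$hs[i5] - r25$hs[i25]) / ref, 0.01)
  }
})

test_that("dry cells and everything landward of them stay dry", {
  n <- 100
  bed <- c(rep(-2, 50), rep(0.45, 50))    # step above the 0.5 m water level
  tr <- transect_profile(seq(2.5, by = 5, length.out = n), bed,
                         rep("forest", n), rep(0, n), 5)
  run <- propagate(tr, 0.5, 0.3, 8, NULL, section_drag(1, 1, 1))
  expect_true(all(run$hs[51:100] == 0))
  expect_true(all(run$hs[1:50] > 0))
})
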