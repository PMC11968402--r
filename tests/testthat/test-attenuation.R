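test_that("relative attenuation is zero at the edge and tracks Hs directly", {
  tr <- build_transect(-1.1, 500, 0)
  run <- propagate(tr, 1.6, 2.8, 12, schematize("red", "medium"))
  ra <- relative_attenuation(run)
  expect_equal(nrow(ra), 1200)
  expect_true(all(diff(ra$R) >= -1e-12))       # sink-only physics
  # direct arithmetic: R = 1 - hs/hs_edge
  i300 <- which(ra$width == 300)
  fsi <- run$forest_start_index
  expect_equal(ra$R[i300], 1 - run$hs[fsi + i300 - 1] / run$hs_edge)
  # a run with a dry forest edge is excluded
  dry <- propagate(tr, -0.5, 2.8, 12, schematize("red", "medium"))
  expect_error(relative_attenuation(dry), "excluded")
})

test_that("halved wave height means 50% attenuation; friction-only decay is exact", {
  # synthetic wave_run with a prescribed hs sequence: halves after 300 m
  run <- structure(list(hs = c(2.0, 1.5, 1.2, 1.0, 0.9, 0.8), hs_edge = 2.0,
                        forest_start_index = 2, dx = 100), class = "wave_run")
  ra <- relative_attenuation(run)
  expect_equal(ra$R[ra$width == 300], 0.5)
  # vegetation-free flat forest with friction only: compare against an
  # independent explicit integration of dHs/dx = -8 eps_f/(rho g cg Hs)
  h <- 1.5; hs0 <- 0.5; tp <- 9; cf <- 0.021; rho <- 1025; g <- 9.81
  sg <- 2 * pi / tp; k <- dispersion(sg, h); cg <- group_velocity(sg, h)
  tr <- flat_forest_transect(n = 201, bed = 0, cf = cf)
  run2 <- propagate(tr, h, hs0, tp, NULL, section_drag(1, 1, 1))
  a <- rho * cf * sg^3 / (64 * sinh(k * h)^3)       # eps_f = a Hs^3
  beta <- 8 * a * hs0 / (rho * g * cg)              # Hs = hs0/(1 + beta x)
  exact <- hs0 / (1 + beta * (tr$x - tr$x[1]))
  expect_lt(max(abs(run2$hs - exact) / exact), 0.005)
})

test_that("foreshore contribution follows its defining ratio", {
  run <- structure(list(hs = c(2.0, 1.5, 0.6, 0.3, 0.2), hs_edge = 0.6,
                        forest_start_index = 3, dx = 5), class = "wave_run")
  expect_equal(foreshore_contribution(run), 1.4 / 1.8)
  # all reduction seaward when the forest does nothing
  run2 <- structure(list(hs = c(2.0, 0.6, 0.6, 0.6), hs_edge = 0.6,
                         forest_start_index = 2, dx = 5), class = "wave_run")
  expect_equal(foreshore_contribution(run2), 1)
  run3 <- structure(list(hs = rep(1, 4), hs_edge = 1, forest_start_index = 2,
                         dx = 5), class = "wave_run")
  expect_error(foreshore_contribution(run3), "degenerate")
})

test_that("ensemble percentiles match closed forms on constructed samples", {
  fake <- function(R) {
    n <- nrow(R)
    structure(list(meta = tibble::tibble(run_id = seq_len(n),
                                         hs_boundary = rep(2, n),
                                         hs_edge = rep(1, n),
                                         hs_back = rep(0.1, n),
                                         status = rep("ok", n)),
                   R = R, widths = seq(5, 50, by = 5), dx = 5),
              class = "attenuation_ensemble")
  }
  # identical runs: zero band everywhere
  ens0 <- fake(matrix(rep(seq(0.1, 1, length.out = 10), each = 25), 25, 10))
  pc0 <- ensemble_percentiles(ens0)
  expect_equal(pc0$band, rep(0, 10))
  expect_true(all(pc0$p5 <= pc0$p50 & pc0$p50 <= pc0$p95))
  # uniform spread 0..1 at one width: type-7 percentiles are exact order stats
  R <- matrix(rep(seq(0, 1, length.out = 101), 10), 101, 10)
  pc <- ensemble_percentiles(fake(R))
  expect_equal(pc$p50[1], 0.5)
  expect_equal(pc$p5[1], 0.05)
  expect_equal(pc$p95[1], 0.95)
  expect_equal(pc$band[1], 90)
  expect_error(ensemble_percentiles(fake(R[1:10, , drop = FALSE])),
               "at least 20")
})

test_that("attenuation_at interpolates and converts to energy consistently", {
  R <- matrix(rep(seq(0, 1, length.out = 101), 10), 101, 10)
  ens <- structure(list(meta = tibble::tibble(run_id = 1:101,
                                              hs_boundary = 2, hs_edge = 1,
                                              hs_back = 0.1,
                                              status = rep("ok", 101)),
                        R = R, widths = seq(5, 50, by = 5), dx = 5),
                   class = "attenuation_ensemble")
  expect_equal(attenuation_at(ens, 0), rep(0, 101))
  expect_equal(attenuation_at(ens, 10), R[, 2])
  expect_equal(attenuation_at(ens, 7.5), 0.5 * (R[, 1] + R[, 2]))
  expect_equal(attenuation_at(ens, 10, type = "energy"), 1 - (1 - R[, 2])^2)
})

test_that("belt widths bin into the policy classes with [a, b) boundaries", {
  got <- classify_widths(c(50, 100, 400, 3335))
  expect_equal(got$n, c(1, 2, 1))
  expect_equal(got$class, c("0-100 m", "100-500 m", ">500 m"))
  empty <- classify_widths(numeric(0))
  expect_equal(empty$n, c(0, 0, 0))
  allmin <- classify_widths(rep(25, 7))
  expect_equal(allmin$n, c(7, 0, 0))
  # site_conditions input uses the belt_width column
  x <- make_sites(hs = c(2, 2), tp = c(10, 10), bw = c(80, 900))
  expect_equal(classify_widths(x)$n, c(1, 0, 1))
})
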