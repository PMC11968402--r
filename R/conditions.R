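# Synthetic multivariate coastal forcing for mangrove transects.
#
# Marginals are three-parameter (shifted) lognormals fitted to (5, 50, 95)
# percentile anchors; dependence is imposed with a Gaussian copula on rank
# scales.  Peak periods are synthesised from Hs through a sampled deep-water
# steepness so that the wave-steepness feasibility filter is exercisable.

#' Default marginal percentile anchors of the global forcing climatology
#'
#' The (5, 50, 95) percentile triplets of the four forcing variables across
#' the global population of mangrove-fronted coastal transects: extreme water
#' level (pooled over the 2/5/10/25-yr return periods, m +MSL), significant
#' wave height (same pooling, m), bed level at the start of the foreshore
#' (m +MSL, negative = subtidal), and mangrove belt width (m).
#'
#' @return Named list of three-element numeric vectors `(p5, p50, p95)`.
#' @export
#' @examples
#' default_forcing_anchors()
default_forcing_anchors <- function() {
  list(
    water_level = c(p5 = 0.7, p50 = 1.6, p95 = 3.5),
    hs          = c(p5 = 1.7, p50 = 2.8, p95 = 5.0),
    fs_z0       = c(p5 = -2.6, p50 = -1.1, p95 = -0.6),
    belt_width  = c(p5 = 50, p50 = 400, p95 = 3335)
  )
}

#' Default rank-correlation matrix among the forcing variables
#'
#' The real climatology preserves the empirical joint structure of the
#' forcing; a synthetic generator has to impose one.  The defaults encode a
#' positive water-level/wave-height association (stormy sites see both), a
#' moderate tendency of larger waves to front deeper foreshores, and a belt
#' width independent of the hydrodynamics.  All values are configurable.
#'
#' @return 4x4 symmetric Spearman rank-correlation matrix with unit diagonal,
#'   rows/columns `water_level`, `hs`, `fs_z0`, `belt_width`.
#' @export
default_rank_correlation <- function() {
  v <- c("water_level", "hs", "fs_z0", "belt_width")
  m <- diag(4)
  dimnames(m) <- list(v, v)
  m["water_level", "hs"] <- m["hs", "water_level"] <- 0.5
  m["hs", "fs_z0"] <- m["fs_z0", "hs"] <- -0.3
  m
}

#' Configuration for the synthetic-conditions generator
#'
#' @param n_sites Number of sites to generate (default 15773, the size of the
#'   global transect population the generator emulates).
#' @param anchors Named list of `(p5, p50, p95)` percentile triplets per
#'   variable, as [default_forcing_anchors()].  Each triplet must be strictly
#'   increasing or fully degenerate (all equal).
#' @param rank_corr Spearman rank-correlation matrix among
#'   `water_level, hs, fs_z0, belt_width` (symmetric, unit diagonal, positive
#'   semi-definite).
#' @param rp_ratios Named list with elements `water_level` and `hs`: the
#'   non-decreasing multiplicative growth of the forcing across the return
#'   periods 2/5/10/25 yr, geometrically renormalised internally so the pooled
#'   percentiles still match the anchors.
#' @param steepness_band Two-element range of the deep-water wave steepness
#'   `Hs/L0` sampled per site to derive Tp from Hs (dimensionless).
#' @param steepness_ceiling Feasibility ceiling on `k_p*Hs/2` used by
#'   [steepness_filter()] (default 0.142).
#' @param belt_width_min Minimum representable mangrove belt width in metres
#'   (default 25, one earth-observation cell; narrower belts are excluded).
#' @param seed Integer top-level seed; all stochastic draws derive child
#'   seeds deterministically from it.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_sites = 15773L,
                             anchors = default_forcing_anchors(),
                             rank_corr = default_rank_correlation(),
                             rp_ratios = list(water_level = c(1, 1.10, 1.17, 1.25),
                                              hs = c(1, 1.10, 1.17, 1.25)),
                             steepness_band = c(0.02, 0.05),
                             steepness_ceiling = 0.142,
                             belt_width_min = 25,
                             seed = 1L) {
  cfg <- structure(list(n_sites = as.integer(n_sites), anchors = anchors,
                        rank_corr = rank_corr, rp_ratios = rp_ratios,
                        steepness_band = steepness_band,
                        steepness_ceiling = steepness_ceiling,
                        belt_width_min = belt_width_min,
                        seed = as.integer(seed)),
                   class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(cfg$n_sites >= 1)
  need <- c("water_level", "hs", "fs_z0", "belt_width")
  if (!all(need %in% names(cfg$anchors)))
    stop("anchors must contain: ", paste(need, collapse = ", "))
  for (v in need) {
    q <- cfg$anchors[[v]]
    if (length(q) != 3 || anyNA(q))
      stop("anchor triplet for '", v, "' must be three finite values")
    degenerate <- (q[3] == q[1])
    if (!degenerate && !(q[1] < q[2] && q[2] < q[3]))
      stop("infeasible anchors for '", v,
           "': percentile triplet must be strictly increasing (or all equal)")
  }
  m <- cfg$rank_corr
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-10)) ||
      !isTRUE(all.equal(unname(diag(m)), rep(1, nrow(m)))))
    stop("rank_corr must be symmetric with unit diagonal")
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("rank_corr is not positive semi-definite (min eigenvalue ",
         signif(min(ev), 3), ")")
  for (v in c("water_level", "hs")) {
    r <- cfg$rp_ratios[[v]]
    if (length(r) != 4 || any(r <= 0) || is.unsorted(r))
      stop("rp_ratios$", v, " must be four positive non-decreasing values")
  }
  stopifnot(length(cfg$steepness_band) == 2,
            cfg$steepness_band[1] > 0,
            cfg$steepness_band[1] <= cfg$steepness_band[2],
            cfg$steepness_ceiling > 0, cfg$belt_width_min >= 0)
  invisible(cfg)
}

# Fit a marginal to a (p5, p50, p95) anchor triplet.  Right-skewed triplets
# get a shifted lognormal (location gamma solves
# (q95-g)(q5-g) = (q50-g)^2); symmetric triplets degenerate to a normal,
# left-skewed ones to a reflected shifted lognormal, equal triplets to a
# point mass.  Returns a quantile function u -> x.
fit_marginal <- function(q, p = c(0.05, 0.5, 0.95)) {
  q <- unname(q)
  z <- qnorm(p[3])
  rng <- q[3] - q[1]
  if (rng <= 0)
    return(list(type = "const", qfun = function(u) rep(q[2], length(u))))
  skew <- (q[3] - q[2]) - (q[2] - q[1])
  if (abs(skew) < 1e-9 * rng) {
    mu <- q[2]; sd <- rng / (2 * z)
    return(list(type = "normal", qfun = function(u) qnorm(u, mu, sd)))
  }
  if (skew > 0) {
    gamma <- (q[1] * q[3] - q[2]^2) / (q[1] + q[3] - 2 * q[2])
    sigma <- log((q[3] - gamma) / (q[2] - gamma)) / z
    mu <- log(q[2] - gamma)
    return(list(type = "shifted_lognormal", gamma = gamma, mu = mu, sigma = sigma,
                qfun = function(u) gamma + exp(mu + sigma * qnorm(u))))
  }
  refl <- fit_marginal(rev(-q), p)
  list(type = "reflected_lognormal",
       qfun = function(u) -refl$qfun(1 - u))
}

norm_ratios <- function(r) r / exp(mean(log(r)))

#' Generate synthetic site conditions
#'
#' Draws `n_sites` multivariate forcing records: a Gaussian copula couples the
#' pooled water level, significant wave height, foreshore start depth and
#' belt width on rank scales; shifted-lognormal marginals map the ranks onto
#' the anchor percentiles; per-return-period values are obtained by scaling
#' the pooled draw with the configured (geometrically renormalised) growth
#' ratios, which enforces return-period monotonicity by construction.  Peak
#' periods follow from a per-site deep-water steepness drawn uniformly in
#' `steepness_band`, inverted through `Tp = sqrt(2*pi*Hs/(g*s))`.
#'
#' @param config A [generator_config()].
#' @return A `site_conditions` tibble with columns `site_id`,
#'   `water_level_rp{2,5,10,25}`, `hs_rp{2,5,10,25}`, `tp_rp{2,5,10,25}`,
#'   `fs_z0`, `belt_width`.  Attributes `generator_config` and `child_seeds`
#'   record the provenance.
#' @export
#' @examples
#' x <- generate_conditions(generator_config(n_sites = 100, seed = 7))
#' condition_percentiles(x)
generate_conditions <- function(config) {
  validate_generator_config(config)
  n <- config$n_sites
  vars <- c("water_level", "hs", "fs_z0", "belt_width")
  rs <- config$rank_corr[vars, vars]
  # latent working scale uses foreshore *depth* (positive-down), so flip signs
  flip <- c(1, 1, -1, 1)
  rp_mat <- 2 * sin(pi * (rs * (flip %o% flip)) / 6)  # Spearman -> Pearson
  ev <- eigen(rp_mat, symmetric = TRUE)
  A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 4)
  seeds <- list(copula = child_seed(config$seed, 1L),
                steepness = child_seed(config$seed, 2L))
  Z <- withr::with_seed(seeds$copula, matrix(rnorm(n * 4), n, 4)) %*% t(A)
  U <- pnorm(Z)

  a <- config$anchors
  wl <- fit_marginal(a$water_level)$qfun(U[, 1])
  hs <- fit_marginal(a$hs)$qfun(U[, 2])
  d_fs <- fit_marginal(rev(-a$fs_z0))$qfun(U[, 3])   # depth below MSL
  bw <- pmax(fit_marginal(a$belt_width)$qfun(U[, 4]), config$belt_width_min)

  cw <- norm_ratios(config$rp_ratios$water_level)
  ch <- norm_ratios(config$rp_ratios$hs)
  wl_rp <- outer(wl, cw)
  hs_rp <- outer(hs, ch)
  s <- withr::with_seed(seeds$steepness,
                        runif(n, config$steepness_band[1], config$steepness_band[2]))
  tp_rp <- sqrt(2 * pi * (hs_rp / s) / .G)

  rp <- c(2, 5, 10, 25)
  out <- tibble::tibble(site_id = seq_len(n))
  for (i in seq_along(rp)) out[[paste0("water_level_rp", rp[i])]] <- wl_rp[, i]
  for (i in seq_along(rp)) out[[paste0("hs_rp", rp[i])]] <- hs_rp[, i]
  for (i in seq_along(rp)) out[[paste0("tp_rp", rp[i])]] <- tp_rp[, i]
  out$fs_z0 <- -d_fs
  out$belt_width <- bw
  attr(out, "generator_config") <- config
  attr(out, "child_seeds") <- seeds
  class(out) <- c("site_conditions", class(out))
  out
}

#' Empirical pooled percentiles of generated conditions
#'
#' Pools the four return-period columns of water level and wave height (the
#' anchor convention) and reports the empirical 5/50/95 percentiles of every
#' forcing variable, for comparison against the generator anchors.
#'
#' @param sites A `site_conditions` table.
#' @return Tibble with columns `variable`, `p5`, `p50`, `p95`.
#' @export
condition_percentiles <- function(sites) {
  pooled <- list(
    water_level = unlist(sites[paste0("water_level_rp", c(2, 5, 10, 25))],
                         use.names = FALSE),
    hs = unlist(sites[paste0("hs_rp", c(2, 5, 10, 25))], use.names = FALSE),
    fs_z0 = sites$fs_z0,
    belt_width = sites$belt_width
  )
  qs <- t(vapply(pooled, quantile, numeric(3), probs = c(0.05, 0.5, 0.95),
                 names = FALSE))
  tibble::tibble(variable = names(pooled),
                 p5 = qs[, 1], p50 = qs[, 2], p95 = qs[, 3])
}

#' Filter records violating the wave-steepness feasibility criterion
#'
#' Removes sites for which the deep-water steepness metric `k_p*Hs/2`, with
#' `k_p = (2*pi/Tp)^2 / g` the deep-water wave number from the peak period,
#' exceeds the ceiling at any return period.  The offshore boundary sits in
#' effectively deep water for the relevant periods, so the deep-water
#' dispersion limit is used.
#'
#' @param sites A `site_conditions` table.
#' @param ceiling Steepness ceiling (default 0.142).
#' @return The surviving rows; attribute `rejection_log` is a tibble
#'   (`site_id`, `return_period`, `steepness`) listing every violation.
#' @export
steepness_filter <- function(sites, ceiling = 0.142) {
  stopifnot(ceiling > 0, nrow(sites) >= 0)
  rps <- c(2, 5, 10, 25)
  viol <- matrix(FALSE, nrow(sites), length(rps))
  logs <- vector("list", length(rps))
  for (i in seq_along(rps)) {
    hs <- sites[[paste0("hs_rp", rps[i])]]
    tp <- sites[[paste0("tp_rp", rps[i])]]
    st <- (2 * pi / tp)^2 / .G * hs / 2
    bad <- st > ceiling
    viol[, i] <- bad
    logs[[i]] <- tibble::tibble(site_id = sites$site_id[bad],
                                return_period = rps[i],
                                steepness = st[bad])
  }
  keep <- !apply(viol, 1, any)
  out <- sites[keep, , drop = FALSE]
  attr(out, "rejection_log") <- do.call(rbind, logs)
  attr(out, "generator_config") <- attr(sites, "generator_config")
  out
}

#' Rejection log of a filtered condition set
#' @param sites Output of [steepness_filter()].
#' @return Tibble of rejected (site, return period) pairs with the violating
#'   steepness value.
#' @export
rejection_log <- function(sites) attr(sites, "rejection_log")

#' Write / read site conditions as CSV
#'
#' Flat tabular interchange format: one row per site, fixed header names as
#' produced by [generate_conditions()].
#'
#' @param sites A `site_conditions` table.
#' @param path File path.
#' @return `read_conditions` returns a `site_conditions` tibble.
#' @export
write_conditions <- function(sites, path) {
  utils::write.csv(as.data.frame(sites), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_conditions
#' @export
read_conditions <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path))
  need <- c("site_id", paste0("water_level_rp", c(2, 5, 10, 25)),
            paste0("hs_rp", c(2, 5, 10, 25)), paste0("tp_rp", c(2, 5, 10, 25)),
            "fs_z0", "belt_width")
  miss <- setdiff(need, names(out))
  if (length(miss)) stop("conditions file misses columns: ",
                         paste(miss, collapse = ", "))
  class(out) <- c("site_conditions", class(out))
  out
}
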