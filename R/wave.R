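# Stationary 1D bulk wave-energy balance: shoaling via flux conservation,
# Battjes-Janssen depth-induced breaking, Collins bottom friction and the
# layered Mendez-Losada vegetation sink.  The marching core lives in
# src/solver.cpp.

#' Solver configuration
#'
#' @param gamma_break Breaker index (0 < gamma < 1.5), default 0.73.
#' @param rho Water density (kg/m^3), default 1025.
#' @param g Gravity (m/s^2).
#' @param dry_threshold Depth (m) below which a cell is dry, default 0.05.
#' @param alpha_bj Breaking dissipation proportionality constant, default 1.
#' @return Object of class `solver_config`.
#' @export
solver_config <- function(gamma_break = 0.73, rho = 1025, g = 9.81,
                          dry_threshold = 0.05, alpha_bj = 1) {
  stopifnot(gamma_break > 0, gamma_break < 1.5, rho > 0, g > 0,
            dry_threshold > 0, alpha_bj > 0)
  structure(list(gamma_break = gamma_break, rho = rho, g = g,
                 dry_threshold = dry_threshold, alpha_bj = alpha_bj),
            class = "solver_config")
}

#' Linear dispersion relation
#'
#' Solves `sigma^2 = g k tanh(k h)` for the wave number k (Newton iteration,
#' relative tolerance better than 1e-10).
#'
#' @param sigma Angular frequency (rad/s, > 0); recycled against `h`.
#' @param h Water depth (m, > 0).
#' @param g Gravity (m/s^2).
#' @return Wave number k (rad/m).
#' @export
#' @examples
#' k <- dispersion(2 * pi / 8, 100)   # effectively deep: k ~ sigma^2/g
dispersion <- function(sigma, h, g = 9.81) {
  stopifnot(all(sigma > 0), all(h > 0))
  k <- dispersion_cpp(as.numeric(sigma), as.numeric(h), g)
  if (any(!is.finite(k))) stop("dispersion failed to converge for sigma = ",
                               sigma[!is.finite(k)][1], ", h = ", h[!is.finite(k)][1])
  k
}

#' Group velocity from linear theory
#'
#' @inheritParams dispersion
#' @return Group velocity (m/s).
#' @export
group_velocity <- function(sigma, h, g = 9.81) {
  k <- dispersion(sigma, h, g)
  kh <- k * h
  n <- 0.5 * (1 + 2 * kh / sinh(2 * kh))
  n * sigma / k
}

veg_arrays <- function(profile, drag) {
  cd_map <- c(roots = drag$roots, trunk = drag$trunk, canopy = drag$canopy)
  list(ztop = profile$layers$z_top, f = profile$layers$f,
       cd = unname(cd_map[profile$layers$section]))
}

#' Vegetation dissipation rate (layered Mendez-Losada)
#'
#' The bulk wave-energy dissipation by a multi-layer vegetation canopy,
#' summed over the layers with the submerged fraction
#' `alpha_i = min(z_top_i, h)/h` and each layer's C_D selected by its section
#' label:
#' \deqn{\varepsilon_v = \sum_i \frac{\rho C_{D,i}}{4\sqrt{2\pi}}
#'   \left(\frac{gk}{2\sigma}\right)^3 f_i
#'   \frac{(\sinh^3 k\alpha_i h - \sinh^3 k\alpha_{i-1}h)
#'         + 3(\sinh k\alpha_i h - \sinh k\alpha_{i-1}h)}
#'        {3k\cosh^3 kh} H_s^3}
#'
#' @param hs Significant wave height (m).
#' @param k Wave number (rad/m).
#' @param sigma Angular frequency (rad/s).
#' @param h Water depth (m, > 0; dry cells handled upstream).
#' @param profile A `vegetation_profile`.
#' @param drag A [section_drag()].
#' @param rho Water density (kg/m^3).
#' @param g Gravity (m/s^2).
#' @return Dissipation rate (W/m^2).
#' @export
veg_dissipation <- function(hs, k, sigma, h, profile, drag, rho = 1025, g = 9.81) {
  stopifnot(all(h > 0))
  va <- veg_arrays(profile, drag)
  eps_veg_cpp(as.numeric(hs), as.numeric(k), as.numeric(sigma), as.numeric(h),
              va$ztop, va$f, va$cd, rho, g)
}

#' Depth-induced breaking dissipation (Battjes-Janssen)
#'
#' Bore-based dissipation `alpha/4 * Q_b * fmean * rho * g * Hmax^2` with
#' `Hmax = gamma_break * h` and the fraction of breaking waves `Q_b` solving
#' `(1 - Q_b)/(-ln Q_b) = (Hrms/Hmax)^2`; effectively zero when
#' `hs << gamma_break * h`.
#'
#' @inheritParams veg_dissipation
#' @param config A [solver_config()].
#' @return Dissipation rate (W/m^2).
#' @export
breaking_dissipation <- function(hs, h, sigma, config = solver_config()) {
  eps_break_cpp(as.numeric(hs), as.numeric(h), as.numeric(sigma),
                config$gamma_break, config$rho, config$g, config$alpha_bj)
}

#' Collins bottom-friction dissipation
#'
#' Drag-law bulk dissipation using the near-bed rms orbital velocity from
#' linear theory, `eps_f = rho * cf * sigma^3 * Hs^3 / (64 sinh^3 kh)`;
#' linear in the Collins coefficient `cf` and zero when `cf = 0`.
#'
#' @inheritParams veg_dissipation
#' @param cf Collins friction coefficient (>= 0).
#' @return Dissipation rate (W/m^2).
#' @export
friction_dissipation <- function(hs, h, k, sigma, cf, rho = 1025) {
  stopifnot(all(cf >= 0))
  eps_fric_cpp(as.numeric(hs), as.numeric(h), as.numeric(k),
               as.numeric(sigma), as.numeric(cf), rho)
}

#' Propagate a wave state along a transect
#'
#' Marches the stationary bulk energy balance
#' `d(E c_g)/dx = -(eps_break + eps_fric + eps_veg)` landward with
#' `E = rho g Hs^2 / 16`, `c_g` from linear theory at the local depth and a
#' constant peak period (no wind input).  The march runs in two phases:
#' offshore+foreshore without vegetation, then - after evaluating the section
#' drag coefficients once from the modelled wave state at the last foreshore
#' cell - through the forest with the vegetation sink active.  Cells at or
#' below the dry threshold, and every cell landward of the first dry cell,
#' carry `hs = 0`.  Steps that would drive the energy flux negative engage
#' recursive sub-stepping and, if exhausted, clamp to zero.
#'
#' @param transect A [transect_profile()].
#' @param water_level Static water surface elevation (m +MSL).
#' @param boundary_hs,boundary_tp Offshore boundary forcing (m, s).
#' @param vegetation A `vegetation_profile`, or `NULL` for a bare transect.
#' @param drag Either [drag_params()] (coefficients evaluated at the forest
#'   edge) or a fixed [section_drag()].
#' @param config A [solver_config()].
#' @return Object of class `wave_run`: per-cell `hs`, `depth`, `eps_break`,
#'   `eps_fric`, `eps_veg`, `flux`, plus `hs_edge`, the drag actually used
#'   and its KC number.
#' @export
propagate <- function(transect, water_level, boundary_hs, boundary_tp,
                      vegetation = NULL, drag = drag_params(),
                      config = solver_config()) {
  stopifnot(inherits(transect, "transect_profile"),
            boundary_hs >= 0, boundary_tp > 0)
  depth <- water_level - transect$bed
  n <- transect$n_cells
  fsi <- transect$forest_start_index
  cf <- transect$friction_coeff
  dx <- transect$dx
  zeros <- numeric(0)

  hs <- numeric(n); e_b <- numeric(n); e_f <- numeric(n); e_v <- numeric(n)
  flux <- numeric(n)

  # phase 1: no vegetation up to the last foreshore cell
  if (fsi > 1) {
    idx1 <- 1:(fsi - 1)
    r1 <- march_cpp(boundary_hs, boundary_tp, depth[idx1], cf[idx1],
                    numeric(fsi - 1), zeros, zeros, zeros, dx,
                    config$gamma_break, config$rho, config$g,
                    config$dry_threshold, config$alpha_bj)
    hs[idx1] <- r1$hs; e_b[idx1] <- r1$eps_break; e_f[idx1] <- r1$eps_fric
    flux[idx1] <- r1$flux
    hs_edge <- r1$hs[fsi - 1]
    h_edge <- depth[fsi - 1]
  } else {
    hs_edge <- if (depth[1] > config$dry_threshold) boundary_hs else 0
    h_edge <- depth[1]
  }

  # drag evaluated once, at the forest edge
  if (inherits(drag, "section_drag")) {
    sd <- drag
  } else if (!is.null(vegetation) && hs_edge > 0 && h_edge > config$dry_threshold) {
    sd <- compute_section_drag(vegetation, hs_edge, boundary_tp, h_edge,
                               params = drag, g = config$g)
  } else {
    sd <- NULL
  }

  # phase 2: through the forest, starting from the edge state
  if (hs_edge > 0) {
    idx2 <- max(fsi - 1, 1):n
    von <- as.numeric(transect$zone[idx2] == "forest")
    if (!is.null(vegetation) && !is.null(sd)) {
      va <- veg_arrays(vegetation, sd)
    } else {
      va <- list(ztop = zeros, f = zeros, cd = zeros)
    }
    r2 <- march_cpp(hs_edge, boundary_tp, depth[idx2], cf[idx2],
                    von, va$ztop, va$f, va$cd, dx,
                    config$gamma_break, config$rho, config$g,
                    config$dry_threshold, config$alpha_bj)
    take <- idx2 >= fsi
    hs[idx2[take]] <- r2$hs[take]
    e_b[idx2[take]] <- r2$eps_break[take]
    e_f[idx2[take]] <- r2$eps_fric[take]
    e_v[idx2[take]] <- r2$eps_veg[take]
    flux[idx2[take]] <- r2$flux[take]
    if (fsi == 1) {  # forest starts at the boundary: phase 2 covers cell 1 too
      hs[1] <- r2$hs[1]; flux[1] <- r2$flux[1]
    }
  }

  structure(list(hs = hs, depth = depth, eps_break = e_b, eps_fric = e_f,
                 eps_veg = e_v, flux = flux, tp = boundary_tp,
                 water_level = water_level, x = transect$x, dx = dx,
                 forest_start_index = fsi, hs_edge = hs_edge,
                 drag = sd, kc = if (is.null(sd)) NA_real_ else sd$kc),
            class = "wave_run")
}

#' @export
print.wave_run <- function(x, ...) {
  cat(sprintf("<wave_run> Tp = %.1f s, water level = %.2f m +MSL\n",
              x$tp, x$water_level))
  cat(sprintf("  Hs: boundary %.2f m -> forest edge %.2f m -> back %.3f m\n",
              x$hs[1], x$hs_edge, x$hs[length(x$hs)]))
  invisible(x)
}
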