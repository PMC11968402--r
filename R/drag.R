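# Keulegan-Carpenter drag closure: a bulk C_D per vertical vegetation
# section (roots / trunk / canopy) from the orbital velocity at the forest
# edge and an effective vegetation length scale.

#' Drag model parameters
#'
#' The bulk drag coefficient follows a power law `C_D = a * KC^b` clipped to
#' `cd_bounds`.  The default coefficients are the implementer's reading of
#' flume calibrations of woody vegetation under extreme conditions
#' (`a = 2.2`, `b = -0.3`); they are configuration, not ground truth, and
#' every ensemble run echoes the values used into its metadata.
#'
#' @param a,b Power-law coefficients (`a > 0`; `b < 0` gives the usual
#'   decrease of drag with KC).
#' @param cd_bounds Two-element clip range for C_D (min > 0).
#' @param length_scale_mode How the KC length scale is computed: `mazda`
#'   (effective vegetation length scale, see [mazda_length_scale()]),
#'   `element_diameter` (frontal-area-weighted mean element diameter) or
#'   `fixed`.
#' @param fixed_length Length scale (m) when `length_scale_mode = "fixed"`.
#' @param per_section Optional named list (`roots`, `trunk`, `canopy`) of
#'   `c(a, b)` pairs overriding the global power law per section.
#' @return Object of class `drag_params`.
#' @export
drag_params <- function(a = 2.2, b = -0.3, cd_bounds = c(0.1, 3.5),
                        length_scale_mode = c("mazda", "element_diameter", "fixed"),
                        fixed_length = NULL, per_section = NULL) {
  length_scale_mode <- match.arg(length_scale_mode)
  stopifnot(a > 0, length(cd_bounds) == 2, cd_bounds[1] > 0,
            cd_bounds[2] >= cd_bounds[1])
  if (length_scale_mode == "fixed" &&
      (is.null(fixed_length) || fixed_length <= 0))
    stop("fixed length_scale_mode requires a positive fixed_length")
  structure(list(a = a, b = b, cd_bounds = cd_bounds,
                 length_scale_mode = length_scale_mode,
                 fixed_length = fixed_length, per_section = per_section),
            class = "drag_params")
}

#' Section drag coefficients
#'
#' @param roots,trunk,canopy Bulk drag coefficients per vertical section.
#' @param kc Optional KC number the values were derived from (metadata).
#' @return Object of class `section_drag`.
#' @export
section_drag <- function(roots, trunk, canopy, kc = NA_real_) {
  stopifnot(roots > 0, trunk > 0, canopy > 0)
  structure(list(roots = roots, trunk = trunk, canopy = canopy, kc = kc),
            class = "section_drag")
}

#' Orbital velocity amplitude from linear wave theory
#'
#' `u = sigma * (hs/2) * cosh(k z) / sinh(k h)` with `sigma = 2*pi/tp` and
#' `k` from the linear dispersion relation; `z` is the evaluation elevation
#' above the bed (default mid-depth), so the drag model can use a single bulk
#' velocity representative of the submerged vegetation column.
#'
#' @param hs Significant wave height at the forest edge (m, >= 0).
#' @param tp Peak period (s, > 0).
#' @param h Water depth (m, > 0).
#' @param z Evaluation elevation above the bed (m), default `h/2`.
#' @param g Gravity (m/s^2).
#' @return Velocity amplitude (m/s).
#' @export
orbital_velocity <- function(hs, tp, h, z = h / 2, g = 9.81) {
  stopifnot(hs >= 0, tp > 0, h > 0, z >= 0)
  sigma <- 2 * pi / tp
  k <- dispersion(sigma, h, g)
  sigma * (hs / 2) * cosh(k * z) / sinh(k * h)
}

#' Keulegan-Carpenter number
#'
#' `KC = u * tp / L`, the orbital excursion relative to the element length
#' scale.
#'
#' @param u Orbital velocity amplitude (m/s).
#' @param tp Wave period (s).
#' @param length_scale Element length scale (m, > 0).
#' @return Dimensionless KC.
#' @export
kc_number <- function(u, tp, length_scale) {
  stopifnot(u >= 0, tp > 0)
  if (any(length_scale <= 0)) stop("length_scale must be positive")
  u * tp / length_scale
}

#' Effective vegetation length scale
#'
#' In `mazda` mode the effective length scale of the submerged vegetation
#' column is the open water volume per unit projected frontal area,
#' `L_E = (h - V) / A`, with `A = sum_i f_i t_i` the submerged frontal area
#' and `V = sum_i (pi/4) b_v_i f_i t_i` the submerged solid volume per unit
#' bed area (`t_i` = submerged thickness of layer i).  `element_diameter`
#' mode returns the frontal-area-weighted mean element diameter, `fixed`
#' mode passes `fixed_length` through.
#'
#' @param profile A `vegetation_profile`.
#' @param h Water depth (m, > 0).
#' @param mode Length-scale mode, see [drag_params()].
#' @param fixed_length Length (m) for `fixed` mode.
#' @return Length scale (m).
#' @export
mazda_length_scale <- function(profile, h,
                               mode = c("mazda", "element_diameter", "fixed"),
                               fixed_length = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (is.null(fixed_length) || fixed_length <= 0)
      stop("fixed mode requires a positive fixed_length")
    return(fixed_length)
  }
  stopifnot(h > 0)
  ly <- profile$layers
  t <- pmax(0, pmin(ly$z_top, h) - pmin(ly$z_bottom, h))
  A <- sum(ly$f * t)
  if (A <= 0) stop("no submerged vegetation at depth h = ", h)
  if (mode == "element_diameter") return(sum(ly$b_v * ly$f * t) / A)
  V <- sum(pi / 4 * ly$b_v * ly$f * t)
  (h - V) / A
}

#' Bulk drag coefficients from the KC number
#'
#' Applies `C_D = a * KC^b` (per section if `per_section` coefficients are
#' configured) and clips to `cd_bounds`.
#'
#' @param kc KC number (> 0).
#' @param params A [drag_params()].
#' @return A [section_drag()].
#' @export
cd_from_kc <- function(kc, params = drag_params()) {
  stopifnot(kc > 0)
  one <- function(sec) {
    ab <- params$per_section[[sec]]
    if (is.null(ab)) ab <- c(params$a, params$b)
    min(max(ab[1] * kc^ab[2], params$cd_bounds[1]), params$cd_bounds[2])
  }
  section_drag(one("roots"), one("trunk"), one("canopy"), kc = kc)
}

#' Section drag from forest-edge conditions
#'
#' Convenience chain evaluated once per scenario, at the forest edge: orbital
#' velocity at mid-depth of the submerged vegetation column, effective length
#' scale per the configured mode, KC number, power-law C_D per section.
#'
#' @param profile A `vegetation_profile`.
#' @param hs_edge Modelled Hs at the last foreshore cell (m, > 0).
#' @param tp Peak period (s).
#' @param h Water depth at the forest edge (m, > 0).
#' @param params A [drag_params()].
#' @param g Gravity (m/s^2).
#' @return A [section_drag()] with attributes `u`, `length_scale`.
#' @export
compute_section_drag <- function(profile, hs_edge, tp, h,
                                 params = drag_params(), g = 9.81) {
  stopifnot(hs_edge > 0, h > 0)
  z_mid <- min(profile$height, h) / 2
  u <- orbital_velocity(hs_edge, tp, h, z = z_mid, g = g)
  L <- mazda_length_scale(profile, h, mode = params$length_scale_mode,
                          fixed_length = params$fixed_length)
  kc <- kc_number(u, tp, L)
  out <- cd_from_kc(kc, params)
  attr(out, "u") <- u
  attr(out, "length_scale") <- L
  out
}
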