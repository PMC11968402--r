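# Discretized coast-normal transects with the three-part geometry:
# offshore ramp (1:20 from -100 m +MSL), foreshore (tidal flat) at one of
# three mild slopes, horizontal forest floor.

#' Construct a transect profile object
#'
#' Low-level constructor with validation; most users call [build_transect()].
#'
#' @param x Cell-centre positions (m), uniform spacing.
#' @param bed Bed elevation per cell (m +MSL), non-decreasing landward.
#' @param zone Per-cell zone label in `offshore`, `foreshore`, `forest`
#'   (contiguous, in that seaward-to-landward order; leading zones may be
#'   absent).
#' @param friction_coeff Per-cell Collins friction coefficient.
#' @param dx Grid spacing (m).
#' @return Object of class `transect_profile`.
#' @export
transect_profile <- function(x, bed, zone, friction_coeff, dx) {
  n <- length(x)
  stopifnot(length(bed) == n, length(zone) == n, length(friction_coeff) == n,
            dx > 0, all(friction_coeff >= 0))
  if (n > 1 && max(abs(diff(x) - dx)) > 1e-9) stop("x must be uniform with spacing dx")
  if (any(diff(bed) < -1e-9)) stop("bed elevation must be non-decreasing landward")
  ord <- c("offshore", "foreshore", "forest")
  if (!all(zone %in% ord)) stop("unknown zone label")
  r <- rle(zone)$values
  if (any(duplicated(r)) || is.unsorted(match(r, ord)))
    stop("zones must be contiguous and ordered offshore -> foreshore -> forest")
  if (!"forest" %in% zone) stop("transect has no forest zone")
  structure(list(x = x, bed = bed, zone = zone, friction_coeff = friction_coeff,
                 dx = dx, n_cells = n,
                 forest_start_index = which(zone == "forest")[1]),
            class = "transect_profile")
}

#' Build a synthetic coast-normal transect
#'
#' The domain (default 8 km at 5 m cells, i.e. 1600 cells) is partitioned,
#' landward to seaward, into: a horizontal forest floor at `veg_z0` occupying
#' the last `forest_length` metres; a foreshore rising from `fs_z0` to
#' `veg_z0` at the prescribed slope, never narrower than
#' `min_foreshore_width` (degenerate geometries are widened to that
#' threshold) and truncated seaward when it does not fit in front of the
#' forest; and an offshore ramp descending at 1:20 towards -100 m +MSL,
#' clipped at that depth where the ramp would undershoot it.  Collins
#' friction is 0 offshore, `cf_foreshore` on the flat and
#' `cf_foreshore * forest_friction_factor` inside the forest.
#'
#' @param fs_z0 Bed level at the start of the foreshore (m +MSL, in (-20, 0]).
#' @param foreshore_slope Slope denominator `d` of the 1:d foreshore
#'   (typically 500, 750 or 1000).
#' @param veg_z0 Forest floor elevation (m +MSL, typically 0 or 0.5).
#' @param forest_length Forest extent (m), default 6000.
#' @param dx Cell size (m), default 5.
#' @param domain_length Domain length (m), default 8000.
#' @param depth_offshore Offshore boundary bed level (m +MSL), default -100.
#' @param cf_foreshore Collins coefficient on the foreshore, default 0.015.
#' @param forest_friction_factor Multiplier inside the forest, default 1.4
#'   (leaf litter and root structure).
#' @param min_foreshore_width Minimum foreshore width (m), default 50.
#' @param forest_bed_slope Optional mild landward bed gradient inside the
#'   forest (rise/run, default 0 = horizontal).
#' @return A [transect_profile()].
#' @export
#' @examples
#' tr <- build_transect(fs_z0 = -1.1, foreshore_slope = 500, veg_z0 = 0)
#' table(tr$zone)
build_transect <- function(fs_z0, foreshore_slope = 500, veg_z0 = 0,
                           forest_length = 6000, dx = 5, domain_length = 8000,
                           depth_offshore = -100, cf_foreshore = 0.015,
                           forest_friction_factor = 1.4,
                           min_foreshore_width = 50, forest_bed_slope = 0) {
  stopifnot(fs_z0 > -20, fs_z0 <= veg_z0, foreshore_slope >= 1,
            forest_length >= dx, dx > 0, forest_bed_slope >= 0)
  forest_start_x <- domain_length - forest_length
  if (forest_start_x < min_foreshore_width)
    stop(sprintf(paste0("geometry does not fit: forest of %.0f m leaves %.0f m ",
                        "for offshore+foreshore (need >= %.0f m)"),
                 forest_length, forest_start_x, min_foreshore_width))
  w_nat <- (veg_z0 - fs_z0) * foreshore_slope
  if (w_nat <= forest_start_x) {
    w <- max(w_nat, min_foreshore_width)
    grad <- (veg_z0 - fs_z0) / w
  } else {
    w <- forest_start_x                 # truncate the deep end of the flat
    grad <- 1 / foreshore_slope
  }
  fs_start_x <- forest_start_x - w

  x <- seq(dx / 2, domain_length - dx / 2, by = dx)
  forest <- x >= forest_start_x
  fore <- x >= fs_start_x & !forest
  off <- !forest & !fore
  bed <- numeric(length(x))
  bed[forest] <- veg_z0 + forest_bed_slope * (x[forest] - forest_start_x)
  bed[fore] <- veg_z0 - (forest_start_x - x[fore]) * grad
  bed_fs <- veg_z0 - w * grad           # level at the seaward toe of the flat
  bed[off] <- pmax(depth_offshore, bed_fs - (fs_start_x - x[off]) / 20)

  zone <- ifelse(forest, "forest", ifelse(fore, "foreshore", "offshore"))
  cf <- ifelse(forest, cf_foreshore * forest_friction_factor,
               ifelse(fore, cf_foreshore, 0))
  out <- transect_profile(x, bed, zone, cf, dx)
  out$fs_z0 <- fs_z0
  out$veg_z0 <- veg_z0
  out$foreshore_width <- w
  out$forest_length <- forest_length
  out
}

#' Output positions inside the forest
#'
#' One position per forest cell, expressed as distance (m) into the forest
#' from the forest edge (the last foreshore cell serves as the zero
#' reference, so the j-th forest cell sits `j*dx` metres in).  A 6 km forest
#' at 5 m cells yields 1200 positions; restricting to the first 2 km yields
#' 400.
#'
#' @param profile A [transect_profile()].
#' @param max_width Optional cap (m) on the distance into the forest.
#' @return Numeric vector of distances (m).
#' @export
forest_output_positions <- function(profile, max_width = NULL) {
  n_forest <- profile$n_cells - profile$forest_start_index + 1
  pos <- seq_len(n_forest) * profile$dx
  if (!is.null(max_width)) pos <- pos[pos <= max_width]
  pos
}

#' Serialize a transect to CSV
#'
#' Long-format gridded file with `x`, `bed`, `zone`, `friction_coeff`
#' columns.
#'
#' @param profile A [transect_profile()].
#' @param path File path.
#' @export
write_transect <- function(profile, path) {
  utils::write.csv(data.frame(x = profile$x, bed = profile$bed,
                              zone = profile$zone,
                              friction_coeff = profile$friction_coeff),
                   path, row.names = FALSE)
  invisible(path)
}

#' @export
print.transect_profile <- function(x, ...) {
  cat(sprintf("<transect_profile> %d cells x %.1f m (%.0f m domain)\n",
              x$n_cells, x$dx, x$n_cells * x$dx))
  for (z in unique(x$zone))
    cat(sprintf("  %-9s %4d cells, bed %7.2f .. %7.2f m +MSL\n", z,
                sum(x$zone == z), min(x$bed[x$zone == z]),
                max(x$bed[x$zone == z])))
  invisible(x)
}
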