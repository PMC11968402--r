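# Seven-layer frontal-area schematizations of pioneer, red (Rhizophora-type)
# and black (Avicennia-type) mangroves at three densities.

#' Default seven-layer vegetation templates (medium density)
#'
#' Frontal width of vegetation per unit bed area, `f = b_v * N_v` (1/m), in
#' seven stacked vertical layers per species, each layer tagged as roots,
#' trunk or canopy and carrying a representative element diameter `b_v` (m).
#' The shapes follow the field's qualitative morphology: red mangroves carry
#' a dense prop-root layer below ~1.5 m, a sparse trunk zone and a canopy
#' increase above ~3 m; black mangroves a moderate pneumatophore carpet, a
#' slender trunk and a mid canopy; pioneer mangroves a dense low shrub that
#' tops out near 3 m and can be fully submerged at high water.  The numeric
#' values are non-calibrated stand-ins chosen from typical literature ranges
#' for these morphologies, not measurements; override them from file with
#' [read_vegetation_templates()] for site-specific work.
#'
#' @return Tibble with columns `species`, `layer_index`, `z_bottom`, `z_top`,
#'   `f_medium`, `b_v`, `section`.
#' @export
vegetation_templates <- function() {
  tb <- function(species, z_top, f, b_v, section) {
    tibble::tibble(species = species, layer_index = seq_along(z_top),
                   z_bottom = c(0, z_top[-length(z_top)]), z_top = z_top,
                   f_medium = f, b_v = b_v, section = section)
  }
  rbind(
    tb("red",
       z_top = c(0.5, 1.0, 1.5, 3.0, 4.5, 6.0, 8.0),
       f = c(0.45, 0.35, 0.25, 0.04, 0.10, 0.15, 0.12),
       b_v = c(0.05, 0.05, 0.05, 0.15, 0.04, 0.03, 0.03),
       section = c("roots", "roots", "roots", "trunk", "canopy", "canopy", "canopy")),
    tb("black",
       z_top = c(0.3, 0.6, 2.5, 4.0, 5.5, 7.0, 9.0),
       f = c(0.30, 0.08, 0.03, 0.08, 0.14, 0.12, 0.08),
       b_v = c(0.01, 0.02, 0.20, 0.04, 0.03, 0.03, 0.03),
       section = c("roots", "roots", "trunk", "canopy", "canopy", "canopy", "canopy")),
    tb("pioneer",
       z_top = c(0.3, 0.8, 1.3, 1.8, 2.2, 2.6, 3.0),
       f = c(0.40, 0.30, 0.35, 0.30, 0.20, 0.10, 0.05),
       b_v = c(0.01, 0.02, 0.02, 0.02, 0.02, 0.02, 0.02),
       section = c("roots", "trunk", "canopy", "canopy", "canopy", "canopy", "canopy"))
  )
}

density_factors <- c(sparse = 0.8, medium = 1.0, dense = 1.2)

#' Build a vegetation profile for a species/density combination
#'
#' Scales the species' medium-density template uniformly per layer by the
#' density factor (sparse = 0.8, dense = 1.2: a +/-20% deviation of the total
#' frontal surface area); layer geometry and section tags are untouched.
#'
#' @param species One of `pioneer`, `red`, `black` (or any species present in
#'   `templates`).
#' @param density One of `sparse`, `medium`, `dense`.
#' @param templates Template table as [vegetation_templates()].
#' @return Object of class `vegetation_profile` with a 7-row `layers` tibble
#'   (`z_bottom`, `z_top`, `f`, `b_v`, `section`).
#' @export
#' @examples
#' p <- schematize("red", "dense")
#' frontal_area(p) / frontal_area(schematize("red", "medium"))  # 1.2
schematize <- function(species, density = c("medium", "sparse", "dense"),
                       templates = vegetation_templates()) {
  density <- match.arg(density, c("medium", "sparse", "dense"))
  ly <- templates[templates$species == species, , drop = FALSE]
  if (nrow(ly) == 0) stop("unknown species '", species, "'")
  ly <- ly[order(ly$layer_index), , drop = FALSE]
  if (nrow(ly) != 7) stop("template for '", species, "' must have exactly 7 layers, got ",
                          nrow(ly))
  if (ly$z_bottom[1] != 0 ||
      any(abs(ly$z_bottom[-1] - ly$z_top[-7]) > 1e-9) ||
      any(ly$z_top <= ly$z_bottom))
    stop("template layers must stack without gaps from the bed")
  if (any(ly$f_medium < 0) || any(ly$b_v <= 0)) stop("template f/b_v out of range")
  fac <- density_factors[[density]]
  structure(list(species = species, density = density, density_factor = fac,
                 layers = tibble::tibble(z_bottom = ly$z_bottom, z_top = ly$z_top,
                                         f = ly$f_medium * fac, b_v = ly$b_v,
                                         section = ly$section),
                 height = max(ly$z_top)),
            class = "vegetation_profile")
}

#' Total frontal area of a vegetation profile
#'
#' `sum_i f_i * (z_top_i - z_bottom_i)` (dimensionless, frontal area per unit
#' bed area integrated over height).
#'
#' @param profile A `vegetation_profile`.
#' @return Scalar.
#' @export
frontal_area <- function(profile) {
  with(profile$layers, sum(f * (z_top - z_bottom)))
}

#' Per-layer submerged fractions
#'
#' The relative water depth covered by vegetation up to the top of layer i:
#' `alpha_i = min(z_top_i, h) / h`, clipped to `[0, 1]`.  Layers entirely
#' above the water surface inherit the previous layer's value, so their
#' dissipation contribution telescopes to zero.
#'
#' @param profile A `vegetation_profile`.
#' @param h Water depth (m), > 0.
#' @return Numeric vector of 7 non-decreasing fractions.
#' @export
submerged_fractions <- function(profile, h) {
  if (!is.numeric(h) || length(h) != 1 || h <= 0)
    stop("h must be a single positive depth (dry cells are handled upstream)")
  pmin(profile$layers$z_top / h, 1)
}

#' Read / write vegetation templates as CSV
#'
#' Columns `species`, `layer_index`, `z_bottom`, `z_top`, `f_medium`,
#' `section` and optionally `b_v` (element diameter, m; defaults to 0.05 when
#' absent).
#'
#' @param path File path.
#' @param templates Template tibble.
#' @return `read_vegetation_templates` returns the template tibble.
#' @export
read_vegetation_templates <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path))
  need <- c("species", "layer_index", "z_bottom", "z_top", "f_medium", "section")
  miss <- setdiff(need, names(out))
  if (length(miss)) stop("template file misses columns: ",
                         paste(miss, collapse = ", "))
  if (is.null(out$b_v)) out$b_v <- 0.05
  out
}

#' @rdname read_vegetation_templates
#' @export
write_vegetation_templates <- function(templates, path) {
  utils::write.csv(as.data.frame(templates), path, row.names = FALSE)
  invisible(path)
}
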