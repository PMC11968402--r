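# Scenario engine: cross representative conditions with the full factorial
# scenario matrix (3 species x 3 densities x 3 slopes x 2 forest bed levels
# x 4 return periods = 216) and orchestrate the solver runs.

#' Full factorial scenario matrix
#'
#' @param species Mangrove types (default pioneer/red/black).
#' @param densities Density levels (default sparse/medium/dense).
#' @param foreshore_slopes Slope denominators (default 500/750/1000).
#' @param veg_z0 Forest floor bed levels (m +MSL, default 0 and 0.5).
#' @param return_periods Return periods (yr, default 2/5/10/25).
#' @return Tibble of scenario tuples with a `scenario_id` column; the default
#'   expansion has 216 rows (9 vegetation structures x 3 slopes x 2 bed
#'   levels x 4 return periods).
#' @export
#' @examples
#' nrow(scenario_matrix())   # 216
scenario_matrix <- function(species = c("pioneer", "red", "black"),
                            densities = c("sparse", "medium", "dense"),
                            foreshore_slopes = c(500, 750, 1000),
                            veg_z0 = c(0, 0.5),
                            return_periods = c(2, 5, 10, 25)) {
  g <- expand.grid(return_period = return_periods, veg_z0 = veg_z0,
                   foreshore_slope = foreshore_slopes, density = densities,
                   species = species, stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  out <- tibble::as_tibble(g[, c("species", "density", "foreshore_slope",
                                 "veg_z0", "return_period")])
  out$scenario_id <- seq_len(nrow(out))
  out
}

#' Run the condition x scenario ensemble
#'
#' One solver run per (condition, scenario) pair: the scenario's return
#' period selects the condition's forcing tuple (Hs, Tp, water level), its
#' slope and forest bed level shape the transect, and its species/density
#' pick the vegetation profile.  Failures and dry-forest-edge runs are
#' recorded in the manifest, never silently dropped; the whole ensemble is
#' deterministic (no random numbers are drawn).
#'
#' @param conditions A `site_conditions` table (typically an MDA subset).
#' @param scenarios A [scenario_matrix()].
#' @param templates Vegetation templates, see [vegetation_templates()].
#' @param drag [drag_params()].
#' @param config [solver_config()].
#' @param forest_length Forest extent (m), default 6000.
#' @param dx Cell size (m), default 5.
#' @param max_width Landward extent (m) over which per-run attenuation curves
#'   are stored (default 2000: the post-processing focus).
#' @param domain_length Domain length (m), default 8000.
#' @return Object of class `attenuation_ensemble` with elements `meta` (the
#'   run manifest: one row per run with scenario tuple, forcing, drag
#'   coefficients used, status and an energy-flux monotonicity flag), `R`
#'   (runs x widths matrix of relative wave-height attenuation referenced to
#'   the forest edge; `NA` rows for excluded runs) and `widths` (m).
#' @export
run_ensemble <- function(conditions, scenarios = scenario_matrix(),
                         templates = vegetation_templates(),
                         drag = drag_params(), config = solver_config(),
                         forest_length = 6000, dx = 5, max_width = 2000,
                         domain_length = 8000) {
  n_c <- nrow(conditions); n_s <- nrow(scenarios); n_r <- n_c * n_s
  stopifnot(n_c >= 1, n_s >= 1)
  widths <- seq(dx, max_width, by = dx)
  n_w <- length(widths)

  veg_cache <- list()
  for (sp in unique(scenarios$species))
    for (de in unique(scenarios$density))
      veg_cache[[paste(sp, de)]] <- schematize(sp, de, templates)

  rp_all <- sort(unique(scenarios$return_period))
  wl_m <- as.matrix(as.data.frame(conditions)[paste0("water_level_rp", rp_all)])
  hs_m <- as.matrix(as.data.frame(conditions)[paste0("hs_rp", rp_all)])
  tp_m <- as.matrix(as.data.frame(conditions)[paste0("tp_rp", rp_all)])
  rp_col <- match(scenarios$return_period, rp_all)

  tr_cache <- vector("list", n_c)
  tr_key <- unique(scenarios[c("foreshore_slope", "veg_z0")])

  R <- matrix(NA_real_, n_r, n_w)
  site_id <- integer(n_r); scen_id <- integer(n_r)
  hs0 <- numeric(n_r); tp0 <- numeric(n_r); wl0 <- numeric(n_r)
  hs_edge <- numeric(n_r); hs_back <- numeric(n_r); kc <- rep(NA_real_, n_r)
  cdr <- rep(NA_real_, n_r); cdt <- rep(NA_real_, n_r); cdc <- rep(NA_real_, n_r)
  status <- character(n_r); flux_mono <- rep(NA, n_r)

  run <- 0L
  for (i in seq_len(n_c)) {
    trs <- list()
    for (t in seq_len(nrow(tr_key))) {
      trs[[t]] <- build_transect(fs_z0 = conditions$fs_z0[i],
                                 foreshore_slope = tr_key$foreshore_slope[t],
                                 veg_z0 = tr_key$veg_z0[t],
                                 forest_length = forest_length, dx = dx,
                                 domain_length = domain_length)
    }
    for (s in seq_len(n_s)) {
      run <- run + 1L
      site_id[run] <- conditions$site_id[i]
      scen_id[run] <- scenarios$scenario_id[s]
      j <- rp_col[s]
      hs0[run] <- hs_m[i, j]; tp0[run] <- tp_m[i, j]; wl0[run] <- wl_m[i, j]
      tr <- trs[[which(tr_key$foreshore_slope == scenarios$foreshore_slope[s] &
                       tr_key$veg_z0 == scenarios$veg_z0[s])]]
      veg <- veg_cache[[paste(scenarios$species[s], scenarios$density[s])]]
      wr <- tryCatch(propagate(tr, wl0[run], hs0[run], tp0[run], veg, drag, config),
                     error = function(e) e)
      if (inherits(wr, "error")) { status[run] <- "failed"; next }
      hs_edge[run] <- wr$hs_edge
      hs_back[run] <- wr$hs[tr$n_cells]
      if (!is.null(wr$drag)) {
        kc[run] <- wr$drag$kc
        cdr[run] <- wr$drag$roots; cdt[run] <- wr$drag$trunk
        cdc[run] <- wr$drag$canopy
      }
      if (wr$hs_edge <= 0) { status[run] <- "dry_edge"; next }
      fsi <- tr$forest_start_index
      R[run, ] <- 1 - wr$hs[fsi:(fsi + n_w - 1)] / wr$hs_edge
      wet <- wr$flux > 0
      flux_mono[run] <- all(diff(wr$flux[wet]) <= 1e-9 * max(wr$flux) + 1e-12)
      status[run] <- "ok"
    }
  }

  meta <- tibble::tibble(
    run_id = seq_len(n_r), site_id = site_id, scenario_id = scen_id,
    species = rep(scenarios$species, times = n_c),
    density = rep(scenarios$density, times = n_c),
    foreshore_slope = rep(scenarios$foreshore_slope, times = n_c),
    veg_z0 = rep(scenarios$veg_z0, times = n_c),
    return_period = rep(scenarios$return_period, times = n_c),
    water_level = wl0, hs_boundary = hs0, tp = tp0,
    hs_edge = hs_edge, hs_back = hs_back, kc = kc,
    cd_roots = cdr, cd_trunk = cdt, cd_canopy = cdc,
    status = status, flux_monotone = flux_mono)

  structure(list(meta = meta, R = R, widths = widths, dx = dx,
                 forest_length = forest_length, scenarios = scenarios,
                 drag = drag, config = config),
            class = "attenuation_ensemble")
}

#' @export
print.attenuation_ensemble <- function(x, ...) {
  tab <- table(x$meta$status)
  cat(sprintf("<attenuation_ensemble> %d runs (%s), widths %g..%g m\n",
              nrow(x$meta),
              paste(names(tab), tab, sep = ": ", collapse = ", "),
              min(x$widths), max(x$widths)))
  invisible(x)
}
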