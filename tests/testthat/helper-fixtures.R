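# Shared fixtures: hand-built condition tables, idealized transects and
# vegetation profiles, and independent linear-wave-theory oracles.

make_sites <- function(hs, tp, wl = 1.6, fs_z0 = -1.1, bw = 400) {
  n <- length(hs)
  out <- tibble::tibble(site_id = seq_len(n))
  for (rp in c(2, 5, 10, 25)) {
    out[[paste0("water_level_rp", rp)]] <- rep_len(wl, n)
    out[[paste0("hs_rp", rp)]] <- hs
    out[[paste0("tp_rp", rp)]] <- rep_len(tp, n)
  }
  out$fs_z0 <- rep_len(fs_z0, n)
  out$belt_width <- rep_len(bw, n)
  class(out) <- c("site_conditions", class(out))
  out
}

flat_forest_transect <- function(n = 401, dx = 5, bed = 0, cf = 0) {
  transect_profile(seq(dx / 2, by = dx, length.out = n), rep(bed, n),
                   rep("forest", n), rep(cf, n), dx)
}

# single homogeneous vegetation layer spanning the full column
uniform_veg <- function(f, b_v = 0.05, z_top = 10, section = "trunk") {
  p <- schematize("red", "medium")
  p$layers <- tibble::tibble(z_bottom = 0, z_top = z_top, f = f, b_v = b_v,
                             section = section)
  p$height <- z_top
  p
}

# plain data frame without provenance attributes, for content comparisons
bare_df <- function(x) {
  x <- as.data.frame(x)
  attr(x, "rejection_log") <- NULL
  attr(x, "generator_config") <- NULL
  attr(x, "child_seeds") <- NULL
  x
}

# independent dispersion oracle (root finding, no shared code with src/)
k_oracle <- function(sigma, h, g = 9.81) {
  uniroot(function(k) sigma^2 - g * k * tanh(k * h),
          c(1e-10, 1e3), tol = 1e-13)$root
}
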