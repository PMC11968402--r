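# Post-processing: attenuation-versus-width percentile curves, uncertainty
# bands, foreshore/forest dissipation splits and width-class tallies.

#' Relative wave-height attenuation along the forest
#'
#' `R(w) = 1 - Hs(forest edge + w) / Hs(forest edge)`; dry tail cells give
#' R = 1 (the wave is fully extinguished).
#'
#' @param run A `wave_run` from [propagate()].
#' @param max_width Optional cap (m) on the distance into the forest.
#' @return Tibble with columns `width` (m) and `R` (fraction).
#' @export
relative_attenuation <- function(run, max_width = NULL) {
  if (run$hs_edge <= 0)
    stop("wave height at the forest edge is zero; run excluded")
  fsi <- run$forest_start_index
  n <- length(run$hs)
  w <- seq_len(n - fsi + 1) * run$dx
  r <- 1 - run$hs[fsi:n] / run$hs_edge
  if (!is.null(max_width)) { keep <- w <= max_width; w <- w[keep]; r <- r[keep] }
  tibble::tibble(width = w, R = r)
}

valid_runs <- function(ens) ens$meta$status == "ok"

#' Foreshore share of the total wave-height reduction
#'
#' The fraction of the offshore-boundary-to-forest-back wave-height reduction
#' that occurs seaward of the forest edge:
#' `(Hs_boundary - Hs_edge) / (Hs_boundary - Hs_back)`.  Runs with no total
#' reduction or a dry forest edge are undefined and return `NA` (ensemble
#' method) or an error (single run).
#'
#' @param x A `wave_run` or an `attenuation_ensemble`.
#' @param ... Unused.
#' @return Fraction(s) in `[0, 1]`.
#' @export
foreshore_contribution <- function(x, ...) UseMethod("foreshore_contribution")

#' @export
foreshore_contribution.wave_run <- function(x, ...) {
  tot <- x$hs[1] - x$hs[length(x$hs)]
  if (x$hs_edge <= 0 || tot <= 0)
    stop("degenerate run: no total reduction or dry forest edge")
  (x$hs[1] - x$hs_edge) / tot
}

#' @export
foreshore_contribution.attenuation_ensemble <- function(x, ...) {
  m <- x$meta
  tot <- m$hs_boundary - m$hs_back
  out <- (m$hs_boundary - m$hs_edge) / tot
  out[!(valid_runs(x) & tot > 0)] <- NA_real_
  out
}

#' Per-run attenuation at a given forest width
#'
#' @param ens An `attenuation_ensemble`.
#' @param width Forest width (m); linearly interpolated between stored grid
#'   widths when needed.
#' @param type `height` for `R = 1 - Hs_w/Hs_edge`, `energy` for
#'   `1 - (Hs_w/Hs_edge)^2`.
#' @return Numeric vector (one value per run; `NA` for excluded runs).
#' @export
attenuation_at <- function(ens, width, type = c("height", "energy")) {
  type <- match.arg(type)
  stopifnot(width >= 0, width <= max(ens$widths))
  if (width == 0) {
    r <- ifelse(valid_runs(ens), 0, NA_real_)
  } else {
    j <- match(width, ens$widths)
    if (!is.na(j)) {
      r <- ens$R[, j]
    } else {
      hi <- which(ens$widths > width)[1]
      w0 <- if (hi == 1) 0 else ens$widths[hi - 1]
      r0 <- if (hi == 1) 0 else ens$R[, hi - 1]
      t <- (width - w0) / (ens$widths[hi] - w0)
      r <- r0 + t * (ens$R[, hi] - r0)
    }
  }
  if (type == "energy") 1 - (1 - r)^2 else r
}

#' Ensemble percentile curves of attenuation versus forest width
#'
#' Per-width 5th/50th/95th percentiles across the valid runs (linear
#' interpolation between order statistics, `stats::quantile` type 7) and the
#' P95-P5 uncertainty band in percentage points.
#'
#' @param ens An `attenuation_ensemble` with at least 20 valid runs.
#' @param probs Percentile levels, default `c(0.05, 0.5, 0.95)`.
#' @return Tibble with columns `width`, `p5`, `p50`, `p95`, `band`.
#' @export
ensemble_percentiles <- function(ens, probs = c(0.05, 0.5, 0.95)) {
  ok <- valid_runs(ens)
  if (sum(ok) < 20) stop("need at least 20 valid runs, have ", sum(ok))
  qs <- apply(ens$R[ok, , drop = FALSE], 2, quantile, probs = probs,
              names = FALSE, type = 7)
  tibble::tibble(width = ens$widths, p5 = qs[1, ], p50 = qs[2, ],
                 p95 = qs[3, ], band = 100 * (qs[3, ] - qs[1, ]))
}

#' Width-class tallies
#'
#' Bins mangrove belt widths into the 0-100 m, 100-500 m and >500 m policy
#' classes (left-closed, right-open boundaries: a 100 m belt falls in the
#' 100-500 m class).
#'
#' @param x A `site_conditions` table (its `belt_width` column) or a numeric
#'   vector of widths (m).
#' @return Tibble with columns `class` and `n`.
#' @export
#' @examples
#' classify_widths(c(50, 100, 400, 3335))
classify_widths <- function(x) {
  w <- if (is.numeric(x)) x else x$belt_width
  cls <- cut(w, breaks = c(0, 100, 500, Inf), right = FALSE,
             labels = c("0-100 m", "100-500 m", ">500 m"))
  tb <- table(cls)
  tibble::tibble(class = names(tb), n = as.integer(tb))
}

#' Headline ensemble statistics
#'
#' The summary quantities of the attenuation analysis: median wave-height
#' attenuation 100/500/1000 m into the forest (%), the P95-P5 uncertainty
#' band at 25 m and 2000 m (percentage points), the median foreshore share of
#' total reduction for the high-incoming-wave subset (boundary Hs at or above
#' its ensemble 95th percentile, %), and the median energy-based attenuation
#' after 500 m of forest (%).
#'
#' @param ens An `attenuation_ensemble`.
#' @return Named list of statistics plus run counts.
#' @export
ensemble_summary <- function(ens) {
  ok <- valid_runs(ens)
  med <- function(w) 100 * median(attenuation_at(ens, w), na.rm = TRUE)
  band <- function(w) {
    r <- attenuation_at(ens, w)
    100 * diff(quantile(r, c(0.05, 0.95), na.rm = TRUE, names = FALSE))
  }
  fc <- foreshore_contribution(ens)
  hsb <- ens$meta$hs_boundary
  thr <- quantile(hsb[ok], 0.95, names = FALSE)
  hi <- ok & hsb >= thr & !is.na(fc)
  list(median_att_100m = med(100), median_att_500m = med(500),
       median_att_1000m = med(1000),
       band_25m = band(25), band_2000m = band(2000),
       foreshore_share_high_waves = 100 * median(fc[hi]),
       energy_att_500m = 100 * median(attenuation_at(ens, 500, "energy"),
                                      na.rm = TRUE),
       n_high_wave_runs = sum(hi), n_runs = nrow(ens$meta), n_valid = sum(ok))
}

#' Write percentile curves to CSV
#'
#' @param pc Output of [ensemble_percentiles()].
#' @param path File path.
#' @export
write_percentile_curves <- function(pc, path) {
  utils::write.csv(as.data.frame(pc), path, row.names = FALSE)
  invisible(path)
}

#' Plot attenuation percentile curves
#'
#' P5/P50/P95 wave-height attenuation versus forest width (requires ggplot2).
#'
#' @param pc Output of [ensemble_percentiles()].
#' @return A ggplot object.
#' @export
plot_attenuation <- function(pc) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_attenuation requires the ggplot2 package")
  ggplot2::ggplot(pc, ggplot2::aes(x = width)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = 100 * p5, ymax = 100 * p95),
                         fill = "seagreen", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = 100 * p50), colour = "seagreen4") +
    ggplot2::labs(x = "forest width (m)", y = "wave-height attenuation (%)") +
    ggplot2::theme_minimal()
}
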