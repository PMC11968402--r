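# Maximum Dissimilarity Algorithm: greedy max-min subset selection covering
# a multivariate condition space with few representatives.

#' Feature matrix for dissimilarity selection
#'
#' Assembles the per-return-period water levels, wave heights and peak
#' periods plus foreshore start depth and belt width into a numeric matrix
#' and min-max normalizes each column (constant columns map to 0, so they
#' never influence distances).  Longitude/latitude-like metadata columns are
#' excluded from the distance space.
#'
#' @param sites A `site_conditions` table or any data frame / matrix of
#'   numeric features.
#' @param features Optional character vector of column names to use.
#' @return Matrix with attribute `normalization` (per-column min / max).
#' @export
condition_matrix <- function(sites, features = NULL) {
  if (is.matrix(sites)) {
    m <- sites
  } else {
    if (is.null(features)) {
      default <- c(paste0("water_level_rp", c(2, 5, 10, 25)),
                   paste0("hs_rp", c(2, 5, 10, 25)),
                   paste0("tp_rp", c(2, 5, 10, 25)), "fs_z0", "belt_width")
      features <- if (all(default %in% names(sites))) default
                  else setdiff(names(sites)[vapply(sites, is.numeric, TRUE)],
                               c("site_id", "lon", "lat", "longitude", "latitude"))
    }
    m <- as.matrix(as.data.frame(sites)[features])
  }
  if (anyNA(m)) stop("condition matrix must not contain missing values")
  lo <- apply(m, 2, min); hi <- apply(m, 2, max)
  rng <- hi - lo
  z <- sweep(sweep(m, 2, lo), 2, ifelse(rng > 0, rng, 1), "/")
  z[, rng == 0] <- 0
  attr(z, "normalization") <- list(min = lo, max = hi)
  z
}

#' Maximum-dissimilarity subset selection
#'
#' Greedy max-min selection in min-max normalized Euclidean space: after
#' seeding, each added point maximizes its minimum distance to the already
#' selected set.  Ties break to the lowest row index, making the selection
#' fully deterministic; the first m elements of an n-selection equal the
#' m-selection (prefix property), and affine rescaling of any raw column
#' leaves the result unchanged.
#'
#' @param sites A `site_conditions` table, data frame or numeric matrix.
#' @param n_select Number of representatives (1..n rows).
#' @param seed_rule `max_norm` (seed = point of maximum normalized Euclidean
#'   norm) or `from_centroid_farthest` (seed = point farthest from the
#'   centroid).
#' @param features Optional feature columns, see [condition_matrix()].
#' @return Integer row indices in selection order.  If the input collapses
#'   to fewer distinct points than `n_select`, the distinct points are
#'   returned with a warning.
#' @export
#' @examples
#' m <- matrix(c(0, 0.1, 1), ncol = 1)
#' mda_select(m, 2)   # 3 (value 1.0), then 1 (value 0)
mda_select <- function(sites, n_select,
                       seed_rule = c("max_norm", "from_centroid_farthest"),
                       features = NULL) {
  seed_rule <- match.arg(seed_rule)
  z <- condition_matrix(sites, features)
  n <- nrow(z)
  stopifnot(n_select >= 1, n_select <= n)
  score <- switch(seed_rule,
    max_norm = rowSums(z^2),
    from_centroid_farthest = rowSums(sweep(z, 2, colMeans(z))^2))
  sel <- integer(n_select)
  sel[1] <- which.max(score)           # which.max ties -> lowest index
  d2min <- rowSums(sweep(z, 2, z[sel[1], ])^2)
  for (m in seq_len(n_select - 1)) {
    if (max(d2min) <= 0) {
      warning("only ", m, " distinct points available; stopping selection early")
      return(sel[seq_len(m)])
    }
    nxt <- which.max(d2min)
    sel[m + 1] <- nxt
    d2min <- pmin(d2min, rowSums(sweep(z, 2, z[nxt, ])^2))
  }
  sel
}

#' Write an MDA-selected subset with its selection order
#'
#' @param sites The full `site_conditions` table.
#' @param indices Output of [mda_select()].
#' @param path CSV path.
#' @export
write_mda_subset <- function(sites, indices, path) {
  out <- as.data.frame(sites)[indices, , drop = FALSE]
  out$selection_order <- seq_along(indices)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
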