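# Declarative run configuration (YAML) driving the full pipeline; used by
# the command-line wrapper in exec/mangrovewave.

#' Read a pipeline run configuration
#'
#' YAML file with optional blocks `generator` (fields of
#' [generator_config()]), `mda` (`n_select`, `seed_rule`), `ensemble`
#' (`forest_length`, `dx`, `max_width`), `drag` (fields of [drag_params()])
#' and `solver` (fields of [solver_config()]).  Missing blocks and fields
#' fall back to the package defaults; the assembled configuration objects are
#' returned so every run can echo the values actually used.
#'
#' @param path YAML file path.
#' @return List with elements `generator`, `mda`, `ensemble`, `drag`,
#'   `solver`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  gen <- y$generator %||% list()
  if (!is.null(gen$anchors)) gen$anchors <- lapply(gen$anchors, unlist)
  if (!is.null(gen$rank_corr)) {
    gen$rank_corr <- matrix(unlist(gen$rank_corr), 4, 4, byrow = TRUE,
                            dimnames = list(c("water_level", "hs", "fs_z0", "belt_width"),
                                            c("water_level", "hs", "fs_z0", "belt_width")))
  }
  list(
    generator = do.call(generator_config, gen),
    mda = utils::modifyList(list(n_select = 200L, seed_rule = "max_norm"),
                            y$mda %||% list()),
    ensemble = utils::modifyList(list(forest_length = 6000, dx = 5,
                                      max_width = 2000),
                                 y$ensemble %||% list()),
    drag = do.call(drag_params, y$drag %||% list()),
    solver = do.call(solver_config, y$solver %||% list())
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# polynomial rolling hash over the deparsed configuration, for run-manifest
# provenance (not cryptographic)
#' Short configuration fingerprint
#' @param x Any R object (a configuration list).
#' @return 8-hex-digit fingerprint string.
#' @export
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
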