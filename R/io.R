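#' Read a raw acquisition from a multi-page TIFF
#'
#' @param path TIFF file with `15 * nz` frames in one of the supported
#'   ordering dialects
#' @param config a [sim_config()]
#' @param ordering frame ordering dialect, see [ordering_dialects()]
#' @param scale multiply pixel values (TIFFs written by [write_stack_tiff()]
#'   store float intensities directly, so the default 1 is usually right)
#' @return a [raw_stack()]
#' @export
read_raw_tiff <- function(path, config, ordering = "pzd", scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- aperm(simplify2array(pages), c(3, 1, 2)) * scale
  canonicalize_ordering(frames, config, ordering)
}

#' Write a volume or frame sequence to a multi-page float TIFF
#'
#' @param x a [raw_stack()] (flattened with `ordering`), a `[z, y, x]` array,
#'   or a list of matrices
#' @param path output path
#' @param ordering dialect used when `x` is a raw stack
#' @export
write_stack_tiff <- function(x, path, ordering = "pzd") {
  if (inherits(x, "raw_stack")) {
    fr <- flatten_stack(x, ordering)
    pages <- lapply(seq_len(dim(fr)[1]), function(i) fr[i, , ])
  } else if (is.array(x) && length(dim(x)) == 3) {
    pages <- lapply(seq_len(dim(x)[1]), function(i) x[i, , ])
  } else if (is.list(x)) {
    pages <- x
  } else stop("unsupported input for TIFF writing")
  mx <- max(vapply(pages, max, 0))
  if (mx > 0) pages <- lapply(pages, function(p) p / mx)  # float TIFF in [0,1]
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read a system configuration (and optional ordering) from YAML or JSON
#'
#' Recognized keys match the [sim_config()] arguments; unknown keys are
#' ignored. An optional top-level `ordering` key selects the frame dialect.
#'
#' @param path YAML (.yml/.yaml) or JSON file
#' @return list with `config` (a [sim_config()]) and `ordering`
#' @export
read_sim_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    yaml::read_yaml(path)
  }
  keys <- intersect(names(vals), names(formals(sim_config)))
  cfg <- do.call(sim_config, vals[keys])
  list(config = cfg, ordering = vals$ordering %||% "pzd")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write per-tile parameter estimates to a TSV report
#'
#' One row per (tile, layer, orientation): tile indices, z key, integer and
#' sub-pixel wave-vector parts, phase, quality and anomaly flag.
#'
#' @param param_field a `param_field` from [resolve_params()] (or a
#'   compatible nested list)
#' @param grid the [tile_grid()]
#' @param path output TSV path
#' @return the data frame, invisibly
#' @export
write_params_tsv <- function(param_field, grid, path) {
  est <- if (inherits(param_field, "param_field")) param_field$estimates else param_field
  rows <- list()
  for (t in seq_along(est)) {
    for (zk in names(est[[t]])) {
      for (d in seq_along(est[[t]][[zk]])) {
        e <- est[[t]][[zk]][[d]]
        rows[[length(rows) + 1]] <- data.frame(
          tile = t, row = grid$ij[t, "i"], col = grid$ij[t, "j"],
          z = zk, orientation = d,
          px = e$p_lateral[1], py = e$p_lateral[2],
          p_sub_x = e$p_sub[1], p_sub_y = e$p_sub[2],
          phi0 = e$phi0, quality = e$quality,
          source = e$source,
          low_confidence = isTRUE(e$low_confidence))
      }
    }
  }
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}
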