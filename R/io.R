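#' Write a risk surface to CSV (and optionally GeoJSON)
#'
#' The CSV always carries the fixed column order `area_id, rr_mean,
#' rr_lower, rr_upper, exceedance, spatial_mean`. When per-area polygon
#' geometry is supplied, a GeoJSON FeatureCollection is written alongside
#' with the same fields as feature properties.
#'
#' @param surface A [risk_surface()] tibble (one row per area).
#' @param path Output CSV path.
#' @param geometry Optional list with one polygon per area: a two-column
#'   matrix of (x, y) ring coordinates (closed or open; rings are closed on
#'   write). See [lattice_geometry()].
#' @param geojson_path GeoJSON output path; defaults to `path` with a
#'   `.geojson` extension.
#' @return `path`, invisibly.
#' @export
write_risk_surface <- function(surface, path, geometry = NULL,
                               geojson_path = NULL) {
  miss <- setdiff(RISK_SURFACE_COLS, names(surface))
  if (length(miss))
    stop("risk surface is missing column(s): ", paste(miss, collapse = ", "))
  surface <- tibble::as_tibble(surface)[RISK_SURFACE_COLS]
  readr::write_csv(surface, path, progress = FALSE)
  if (!is.null(geometry)) {
    if (length(geometry) != nrow(surface))
      stop("geometry has ", length(geometry), " polygons but surface has ",
           nrow(surface), " areas")
    if (is.null(geojson_path))
      geojson_path <- paste0(sub("\\.[Cc][Ss][Vv]$", "", path), ".geojson")
    features <- purrr::map(seq_len(nrow(surface)), function(i) {
      ring <- as.matrix(geometry[[i]])
      if (!isTRUE(all.equal(ring[1, ], ring[nrow(ring), ])))
        ring <- rbind(ring, ring[1, ])
      list(type = "Feature",
           properties = as.list(surface[i, ]),
           geometry = list(type = "Polygon",
                           coordinates = list(
                             lapply(seq_len(nrow(ring)),
                                    function(r) as.numeric(ring[r, ])))))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = features),
                         geojson_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Unit-square polygons for a lattice
#'
#' Convenience geometry for datasets generated on a regular grid: area `i`
#' (row-major) gets the unit square with lower-left corner
#' `(col - 1, rows - row)`.
#'
#' @param rows,cols Lattice dimensions.
#' @return List of `rows * cols` coordinate matrices.
#' @export
lattice_geometry <- function(rows, cols) {
  out <- vector("list", rows * cols)
  k <- 1L
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    x0 <- c - 1; y0 <- rows - r
    out[[k]] <- rbind(c(x0, y0), c(x0 + 1, y0), c(x0 + 1, y0 + 1),
                      c(x0, y0 + 1), c(x0, y0))
    k <- k + 1L
  }
  out
}

#' Read a run configuration from YAML
#'
#' The YAML file mirrors the arguments of [fit_bym()] and [mcmc_config()]:
#' top-level keys `covariates` (list), `spatial`, `heterogeneity`,
#' `prior_beta_variance`, `sigma_upper`, `scale` (mapping), `seed`, and an
#' `mcmc` mapping (`n_iter`, `burn_in`, `n_chains`, `thin`,
#' `adapt_window`, `target_accept`). The seed must be set explicitly.
#'
#' @param path YAML file path.
#' @return List with elements `covariates`, `spatial`, `heterogeneity`,
#'   `prior_beta_variance`, `sigma_upper`, `scale`, `mcmc`
#'   (an [mcmc_config()]).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config must set an explicit integer seed")
  m <- y$mcmc %||% list()
  cfg <- mcmc_config(
    n_iter = m$n_iter %||% 100000, burn_in = m$burn_in %||% 10000,
    n_chains = m$n_chains %||% 2, thin = m$thin %||% 10,
    seed = y$seed, adapt_window = m$adapt_window %||% 50,
    target_accept = m$target_accept %||% 0.44)
  list(covariates = as.character(unlist(y$covariates %||% character(0))),
       spatial = y$spatial %||% TRUE,
       heterogeneity = y$heterogeneity %||% TRUE,
       prior_beta_variance = y$prior_beta_variance %||% 1e5,
       sigma_upper = y$sigma_upper %||% 1,
       scale = unlist(y$scale %||% NULL),
       mcmc = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Choropleth of a risk surface on a lattice
#'
#' @param surface A [risk_surface()] tibble.
#' @param rows,cols Lattice dimensions (areas row-major, as produced by
#'   [lattice_graph()]).
#' @param value Which field to map: `"risk"` (posterior mean relative
#'   risk), `"spatial"` (posterior mean spatial component) or
#'   `"exceedance"`.
#' @return A ggplot.
#' @export
plot_risk_map <- function(surface, rows, cols,
                          value = c("risk", "spatial", "exceedance")) {
  value <- match.arg(value)
  if (nrow(surface) != rows * cols)
    stop("surface has ", nrow(surface), " areas; expected ", rows * cols)
  col <- switch(value, risk = "rr_mean", spatial = "spatial_mean",
                exceedance = "exceedance")
  df <- dplyr::mutate(tibble::as_tibble(surface),
                      row = (dplyr::row_number() - 1) %/% cols + 1,
                      col = (dplyr::row_number() - 1) %% cols + 1)
  mid <- switch(value, risk = 1, spatial = 0, exceedance = 0.5)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = rows + 1 - .data$row,
                                   fill = .data[[col]])) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::scale_fill_gradient2(midpoint = mid, low = "#2166ac",
                                  mid = "white", high = "#b2182b") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = col)
}
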