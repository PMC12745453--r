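# Readers and writers for the package's plain-text interchange formats:
# observation-record / MET / remap / fraction / point CSVs, GeoJSON
# boundaries and map exports, and JSON model serialization.

#' Read behavior observation records
#'
#' CSV with header
#' `plot_id,session,code,count,age_group,gender,observer_id` (the codable
#' fields of a SOPARC observation form). Extra columns are kept.
#'
#' @param path CSV file path.
#' @return A validated records tibble.
#' @export
read_behavior_records <- function(path) {
  validate_records(readr::read_csv(path, show_col_types = FALSE))
}

#' Read a MET lookup table
#'
#' Either a CSV with columns `code,met` or a JSON object mapping code to
#' MET value.
#'
#' @param path File path (`.json` or CSV).
#' @return A validated tibble with `code`, `met`.
#' @export
read_met_table <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    vals <- jsonlite::read_json(path, simplifyVector = TRUE)
    met <- tibble::tibble(code = as.integer(names(vals)),
                          met = as.numeric(unlist(vals)))
  } else {
    met <- readr::read_csv(path, show_col_types = FALSE)
  }
  validate_met_table(met)
}

#' Read a class remap table
#'
#' CSV mapping segmentation class ids to landscape features; columns may
#' be named `class_id,feature` or `source_id,target`.
#'
#' @param path CSV file path.
#' @return A validated remap tibble.
#' @export
read_remap_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  names(df)[names(df) == "source_id"] <- "class_id"
  names(df)[names(df) == "target"] <- "feature"
  validate_remap_table(df)
}

#' Read an integer label map from CSV
#'
#' A headerless CSV of integer class ids, one image row per line.
#'
#' @param path CSV file path.
#' @return Integer matrix.
#' @export
read_label_map_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m
}

#' Read a per-image fraction table
#'
#' CSV with `image_id` plus feature-fraction columns (and optionally
#' `plot_id`), validated through [fraction_table()].
#'
#' @param path CSV file path.
#' @return A fraction tibble.
#' @export
read_fraction_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  out <- fraction_table(df)
  extra <- setdiff(names(df), names(out))
  dplyr::bind_cols(out, df[extra])
}

#' Read geotagged image points
#'
#' CSV with `image_id,x,y,resolution,is_landscape,duplicate_key` plus the
#' 11 feature columns.
#'
#' @param path CSV file path.
#' @return A points tibble.
#' @export
read_points_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  assert_features_present(df, "points file")
  df
}

#' Read a park boundary from GeoJSON
#'
#' Accepts a Polygon or MultiPolygon geometry, bare or wrapped in a
#' Feature / FeatureCollection (first feature used). Coordinates must be
#' projected in metres.
#'
#' @param path GeoJSON file path.
#' @return A `park_boundary`.
#' @export
read_boundary_geojson <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (identical(g$type, "FeatureCollection")) g <- g$features[[1]]
  if (identical(g$type, "Feature")) g <- g$geometry
  ring_matrix <- function(ring) {
    do.call(rbind, purrr::map(ring, ~ c(.x[[1]], .x[[2]])))
  }
  poly_from_rings <- function(rings) {
    list(outer = ring_matrix(rings[[1]]),
         holes = purrr::map(rings[-1], ring_matrix))
  }
  polys <- switch(
    g$type,
    Polygon = list(poly_from_rings(g$coordinates)),
    MultiPolygon = purrr::map(g$coordinates, poly_from_rings),
    ps_abort(paste0("unsupported GeoJSON geometry: ", g$type %||% "none"),
             "parkscape_boundary_error")
  )
  park_boundary(polys)
}

#' Write a park boundary to GeoJSON
#'
#' @param boundary A `park_boundary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_boundary_geojson <- function(boundary, path) {
  ring_list <- function(m) purrr::map(seq_len(nrow(m)),
                                      ~ c(m[.x, 1], m[.x, 2]))
  coords <- purrr::map(boundary$polygons, function(p) {
    c(list(ring_list(p$outer)), purrr::map(p$holes, ring_list))
  })
  geom <- if (length(coords) == 1) {
    list(type = "Polygon", coordinates = coords[[1]])
  } else {
    list(type = "MultiPolygon", coordinates = coords)
  }
  obj <- list(type = "Feature", geometry = geom,
              properties = list(name = "park"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export classified fishnet cells as map files
#'
#' Writes a GeoJSON FeatureCollection (one square polygon per cell with
#' its scores and Jenks classes as properties; no-data cells carry nulls)
#' and/or a flat CSV of the same table.
#'
#' @param cells Classified cells from [classify_cells()].
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("geojson", "csv")`.
#' @param stem Base file name (default `"map"`).
#' @return Named character vector of written paths, invisibly.
#' @export
export_maps <- function(cells, dir, formats = c("geojson", "csv"),
                        stem = "map") {
  formats <- match.arg(formats, several.ok = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  score_cols <- intersect(c("OBI", "EBI", "LBI", "SBI"), names(cells))
  class_cols <- intersect(paste0("class_", score_cols), names(cells))
  paths <- character()
  if ("geojson" %in% formats) {
    p <- file.path(dir, paste0(stem, ".geojson"))
    features <- purrr::map(seq_len(nrow(cells)), function(i) {
      cl <- cells[i, ]
      ring <- list(c(cl$xmin, cl$ymin), c(cl$xmax, cl$ymin),
                   c(cl$xmax, cl$ymax), c(cl$xmin, cl$ymax),
                   c(cl$xmin, cl$ymin))
      props <- c(
        list(cell_id = cl$cell_id, row = cl$row, col = cl$col,
             n_points = cl$n_points),
        as.list(cl[c(score_cols, class_cols)])
      )
      list(type = "Feature",
           geometry = list(type = "Polygon", coordinates = list(ring)),
           properties = props)
    })
    jsonlite::write_json(
      list(type = "FeatureCollection", features = features),
      p, auto_unbox = TRUE, digits = NA, na = "null")
    paths["geojson"] <- p
  }
  if ("csv" %in% formats) {
    p <- file.path(dir, paste0(stem, ".csv"))
    readr::write_csv(
      cells[c("cell_id", "row", "col", "xmin", "ymin", "xmax", "ymax",
              "n_points", score_cols, class_cols)],
      p)
    paths["csv"] <- p
  }
  invisible(paths)
}

#' Re-import an exported cell map
#'
#' Round-trip reader for the GeoJSON written by [export_maps()].
#'
#' @param path GeoJSON file path.
#' @return A tibble of cells with bounds, scores and classes.
#' @export
read_map_geojson <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  purrr::map_dfr(g$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    xs <- purrr::map_dbl(ring, 1)
    ys <- purrr::map_dbl(ring, 2)
    props <- purrr::map(f$properties, ~ if (is.null(.x)) NA else .x)
    dplyr::bind_cols(
      tibble::as_tibble(props),
      tibble::tibble(xmin = min(xs), ymin = min(ys),
                     xmax = max(xs), ymax = max(ys))
    )
  })
}

#' Serialize intensity models to JSON
#'
#' @param models Named list of `intensity_model`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_models_json <- function(models, path) {
  obj <- purrr::map(models, function(m) {
    list(outcome = m$outcome, intercept = m$intercept,
         coefficients = as.list(m$coefficients),
         diagnostics = list(r.squared = m$r.squared,
                            adj.r.squared = m$adj.r.squared,
                            f.p.value = m$f.p.value, n = m$n))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read intensity models from JSON
#'
#' @param path JSON path written by [write_models_json()].
#' @return Named list of `intensity_model`s.
#' @export
read_models_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  purrr::map(obj, function(m) {
    d <- m$diagnostics %||% list()
    num_or_na <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
    new_intensity_model(
      outcome = m$outcome, intercept = as.numeric(m$intercept),
      coefficients = unlist(m$coefficients),
      r.squared = num_or_na(d$r.squared),
      adj.r.squared = num_or_na(d$adj.r.squared),
      f.p.value = num_or_na(d$f.p.value),
      n = if (is.null(d$n)) NA_integer_ else as.integer(d$n)
    )
  })
}

#' Model report in regression-table layout
#'
#' Stacks the coefficient tables of several models into one tibble shaped
#' like a standard multiple-regression report (outcome, term, estimate B,
#' std. error, t-value, p-value) with the fit statistics repeated per
#' outcome.
#'
#' @param models Named list of `intensity_model`s.
#' @return A tibble.
#' @export
model_report <- function(models) {
  purrr::map_dfr(models, function(m) {
    dplyr::bind_cols(
      tibble::tibble(outcome = m$outcome),
      tidy(m),
      tibble::tibble(r.squared = m$r.squared,
                     adj.r.squared = m$adj.r.squared,
                     f.p.value = m$f.p.value)
    )
  })
}
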