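# Fishnet mapping: filter geotagged images, tile the park with 30 m cells,
# average features per cell, predict the four indices, classify with Jenks.
# Geometry is deliberately lightweight: boundaries are polygons in projected
# metric coordinates (GeoJSON Polygon/MultiPolygon), cells are axis-aligned
# squares, and containment uses even-odd ring tests.

#' Construct a park boundary
#'
#' @param polygons A list of polygons, each a list with an `outer` ring
#'   (two-column matrix of x,y vertices, metres, closed or open) and an
#'   optional list of `holes` rings. A single matrix is treated as one
#'   hole-free polygon.
#' @return A `park_boundary` object.
#' @export
#' @examples
#' b <- park_boundary(cbind(c(0, 90, 90, 0), c(0, 0, 60, 60)))
park_boundary <- function(polygons) {
  if (is.matrix(polygons)) polygons <- list(list(outer = polygons))
  polygons <- purrr::map(polygons, function(p) {
    if (is.matrix(p)) p <- list(outer = p)
    p$outer <- close_ring(as.matrix(p$outer))
    p$holes <- purrr::map(p$holes %||% list(),
                          function(h) close_ring(as.matrix(h)))
    p
  })
  structure(list(polygons = polygons), class = "park_boundary")
}

close_ring <- function(m) {
  if (nrow(m) < 3) {
    ps_abort("polygon ring needs at least 3 vertices",
             "parkscape_boundary_error")
  }
  if (!all(m[1, ] == m[nrow(m), ])) m <- rbind(m, m[1, ])
  m
}

boundary_bbox <- function(boundary) {
  xs <- unlist(purrr::map(boundary$polygons, ~ .x$outer[, 1]))
  ys <- unlist(purrr::map(boundary$polygons, ~ .x$outer[, 2]))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

# point-in-boundary, even-odd with holes; boundary points count as inside
points_in_boundary <- function(x, y, boundary) {
  inside <- rep(FALSE, length(x))
  for (p in boundary$polygons) {
    io <- pracma::inpolygon(x, y, p$outer[, 1], p$outer[, 2],
                            boundary = TRUE)
    for (h in p$holes) {
      on_edge <- pracma::inpolygon(x, y, h[, 1], h[, 2],
                                   boundary = TRUE) &
                 !pracma::inpolygon(x, y, h[, 1], h[, 2],
                                    boundary = FALSE)
      in_hole <- pracma::inpolygon(x, y, h[, 1], h[, 2],
                                   boundary = FALSE) & !on_edge
      io <- io & !in_hole
    }
    inside <- inside | io
  }
  inside
}

seg_intersects <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) {
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  }
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) - 1e-12 <= c[1] && c[1] <= max(a[1], b[1]) + 1e-12 &&
      min(a[2], b[2]) - 1e-12 <= c[2] && c[2] <= max(a[2], b[2]) + 1e-12
  }
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
    (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
}

rect_intersects_boundary <- function(xmin, ymin, xmax, ymax, boundary) {
  cx <- c(xmin, xmax, xmax, xmin)
  cy <- c(ymin, ymin, ymax, ymax)
  if (any(points_in_boundary(cx, cy, boundary))) return(TRUE)
  rect <- rbind(c(xmin, ymin), c(xmax, ymin), c(xmax, ymax),
                c(xmin, ymax), c(xmin, ymin))
  for (p in boundary$polygons) {
    for (ring in c(list(p$outer), p$holes)) {
      vx <- ring[, 1]; vy <- ring[, 2]
      if (any(vx >= xmin & vx <= xmax & vy >= ymin & vy <= ymax)) {
        return(TRUE)
      }
      for (i in seq_len(nrow(ring) - 1)) {
        for (j in 1:4) {
          if (seg_intersects(ring[i, ], ring[i + 1, ],
                             rect[j, ], rect[j + 1, ])) {
            return(TRUE)
          }
        }
      }
    }
  }
  FALSE
}

#' Filter geotagged image points
#'
#' Keeps points that meet the resolution floor, are landscape-related, and
#' are the first occurrence of their content hash; a per-reason rejection
#' log is returned alongside. Rejection reasons are checked in the order
#' low_resolution, non_landscape, duplicate.
#'
#' @param points Tibble with at least `image_id`, `resolution` (short-side
#'   pixels), `is_landscape` (logical) and `duplicate_key` columns.
#' @param min_resolution Minimum short-side resolution in pixels
#'   (default 1080).
#' @return A list: `points` (retained tibble), `rejected` (tibble with a
#'   `reason` column) and `log` (tibble of per-reason counts, including
#'   `retained`).
#' @export
filter_images <- function(points, min_resolution = 1080) {
  points <- tibble::as_tibble(points)
  dup <- duplicated(points$duplicate_key) & !is.na(points$duplicate_key)
  reason <- dplyr::case_when(
    points$resolution < min_resolution ~ "low_resolution",
    !points$is_landscape ~ "non_landscape",
    dup ~ "duplicate",
    TRUE ~ NA_character_
  )
  keep <- is.na(reason)
  n_by <- c(sum(keep), sum(reason == "low_resolution", na.rm = TRUE),
            sum(reason == "non_landscape", na.rm = TRUE),
            sum(reason == "duplicate", na.rm = TRUE))
  log <- tibble::tibble(
    reason = c("retained", "low_resolution", "non_landscape", "duplicate"),
    n = n_by
  )
  list(points = points[keep, ],
       rejected = dplyr::mutate(points[!keep, ], reason = reason[!keep]),
       log = log)
}

#' Build a fishnet grid over a park boundary
#'
#' Tiles the boundary's bounding box with square cells of side
#' `cell_size`, origin at the bounding-box minimum, and keeps the cells
#' that intersect the boundary polygon. Coordinates must be projected in
#' metres; inputs that look like geographic degrees are rejected.
#'
#' @param boundary A `park_boundary` (see [park_boundary()],
#'   [read_boundary_geojson()]).
#' @param cell_size Cell side length in metres (default 30).
#' @return A tibble of cells: `cell_id`, `row`, `col`, `xmin`, `ymin`,
#'   `xmax`, `ymax`. Rows and columns are indexed from the grid origin.
#' @export
#' @examples
#' b <- park_boundary(cbind(c(0, 90, 90, 0), c(0, 0, 60, 60)))
#' nrow(build_fishnet(b))  # 6
build_fishnet <- function(boundary, cell_size = 30) {
  if (!inherits(boundary, "park_boundary")) {
    boundary <- park_boundary(boundary)
  }
  bb <- boundary_bbox(boundary)
  w <- bb["xmax"] - bb["xmin"]
  h <- bb["ymax"] - bb["ymin"]
  if (w <= 0 || h <= 0) {
    ps_abort("degenerate boundary: zero-area bounding box",
             "parkscape_boundary_error")
  }
  if (w < 1 && h < 1 && abs(bb["xmin"]) <= 180 && abs(bb["ymax"]) <= 90) {
    ps_abort(paste0("boundary coordinates look geographic (degrees); ",
                    "project to a metric CRS before mapping"),
             "parkscape_boundary_error")
  }
  ncol <- ceiling(w / cell_size - 1e-9)
  nrow <- ceiling(h / cell_size - 1e-9)
  grid <- tidyr::expand_grid(row = seq_len(nrow), col = seq_len(ncol)) |>
    dplyr::mutate(
      xmin = bb[["xmin"]] + (.data$col - 1) * cell_size,
      ymin = bb[["ymin"]] + (.data$row - 1) * cell_size,
      xmax = .data$xmin + cell_size,
      ymax = .data$ymin + cell_size
    )
  keep <- purrr::pmap_lgl(grid[c("xmin", "ymin", "xmax", "ymax")],
                          function(xmin, ymin, xmax, ymax) {
    rect_intersects_boundary(xmin, ymin, xmax, ymax, boundary)
  })
  grid <- grid[keep, ]
  grid |>
    dplyr::mutate(cell_id = paste0("r", .data$row, "c", .data$col),
                  .before = 1)
}

#' Assign image points to fishnet cells
#'
#' Spatial join of points onto cells using half-open cell intervals
#' `[min, min + cell_size)` in both axes, so a point on a shared edge
#' belongs to the higher-index cell; the outermost upper edges of the grid
#' are closed. Points falling outside every retained cell are returned
#' with `cell_id` `NA` and counted in the log.
#'
#' @param points Tibble with `x`, `y` columns (projected metres).
#' @param cells Fishnet tibble from [build_fishnet()].
#' @return The points tibble with `cell_id`, `row` and `col` columns added
#'   (NA where unassigned), with an `"assignment_log"` attribute holding
#'   assigned/unassigned counts.
#' @export
assign_points <- function(points, cells) {
  points <- tibble::as_tibble(points)
  if (nrow(cells) == 0) ps_abort("empty fishnet", "parkscape_boundary_error")
  cs <- cells$xmax[1] - cells$xmin[1]
  x0 <- min(cells$xmin)
  y0 <- min(cells$ymin)
  max_col <- max(cells$col)
  max_row <- max(cells$row)
  col <- floor((points$x - x0) / cs) + 1
  row <- floor((points$y - y0) / cs) + 1
  # closed outermost edges: points exactly on the grid's upper bounds
  col[points$x == x0 + max_col * cs] <- max_col
  row[points$y == y0 + max_row * cs] <- max_row
  key <- paste0("r", row, "c", col)
  hit <- key %in% cells$cell_id & col >= 1 & row >= 1 &
    col <= max_col & row <= max_row
  out <- points
  out$cell_id <- ifelse(hit, key, NA_character_)
  out$row <- ifelse(hit, row, NA_real_)
  out$col <- ifelse(hit, col, NA_real_)
  attr(out, "assignment_log") <- tibble::tibble(
    status = c("assigned", "unassigned"),
    n = c(sum(hit), sum(!hit))
  )
  out
}

#' Average point features within each cell
#'
#' For every cell, the arithmetic mean of the feature fractions of its
#' assigned points. Cells with no points keep `NA` features (`n_points`
#' 0) and are excluded from prediction and classification downstream.
#'
#' @param cells Fishnet tibble.
#' @param points Assigned points from [assign_points()], carrying the 11
#'   feature columns.
#' @return The cells tibble with `n_points` and mean feature columns.
#' @export
cell_features <- function(cells, points) {
  assert_features_present(points, "points")
  means <- points |>
    dplyr::filter(!is.na(.data$cell_id)) |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      n_points = dplyr::n(),
      dplyr::across(dplyr::all_of(landscape_features()), mean),
      .groups = "drop"
    )
  cells |>
    dplyr::left_join(means, by = "cell_id") |>
    dplyr::mutate(n_points = dplyr::coalesce(.data$n_points, 0L))
}

#' Predict intensity indices for fishnet cells
#'
#' Applies the four intensity models to each data cell's mean features.
#' Cells without points stay `NA`.
#'
#' @param cells Cells with mean features from [cell_features()].
#' @param models Named list of `intensity_model`s (default
#'   [reference_models()]).
#' @return The cells tibble with one score column per model outcome.
#' @export
predict_cells <- function(cells, models = reference_models()) {
  has_data <- cells$n_points > 0
  for (nm in names(models)) {
    v <- rep(NA_real_, nrow(cells))
    if (any(has_data)) {
      v[has_data] <- predict(models[[nm]], cells[has_data, ])
    }
    cells[[nm]] <- v
  }
  cells
}

#' Classify cell scores with Jenks natural breaks
#'
#' Runs [jenks_breaks()] on the data cells of each score column and
#' attaches integer class labels (1 = lowest intensity). When a column has
#' fewer distinct values than `k`, the number of classes is reduced to the
#' distinct count with a warning.
#'
#' @param cells Cells with score columns from [predict_cells()].
#' @param k Number of classes (default 5).
#' @param indices Score columns to classify (default the four indices
#'   present).
#' @return The cells tibble with `class_<index>` columns; the
#'   `jenks_breaks` objects are attached as attribute `"breaks"`.
#' @export
classify_cells <- function(cells, k = 5,
                           indices = intersect(c("OBI", "EBI", "LBI", "SBI"),
                                               names(cells))) {
  breaks <- list()
  for (idx in indices) {
    vals <- cells[[idx]]
    ok <- !is.na(vals)
    lab <- rep(NA_integer_, nrow(cells))
    if (any(ok)) {
      k_use <- min(k, length(unique(vals[ok])))
      if (k_use < k) {
        warning("reducing k to ", k_use, " for ", idx,
                " (too few distinct values)", call. = FALSE)
      }
      jb <- jenks_breaks(vals[ok], k_use)
      lab[ok] <- jb$classes
      breaks[[idx]] <- jb
    }
    cells[[paste0("class_", idx)]] <- lab
  }
  attr(cells, "breaks") <- breaks
  cells
}
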