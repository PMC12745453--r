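#' Packaged default class remap table
#'
#' Maps ADE20K scene-parsing class indices (1-based, 150-class vocabulary)
#' onto the eleven landscape features. The mapping is a reconstruction built
#' from the class semantics (e.g. road/sidewalk/path to `pavement`,
#' earth/sand/rock/dirt-track to `rough_ground`, bench/seat/chair to
#' `resting_facility`, awning/canopy/tent to `shading_facility`); override
#' it with a study-specific table wherever the upstream segmentation labels
#' differ.
#'
#' @return A tibble with columns `class_id` (integer) and `feature`
#'   (one of [landscape_features()]).
#' @export
default_remap_table <- function() {
  m <- list(
    sky = 3L,
    water = c(22L, 27L, 61L, 110L, 114L, 129L),
    tree = c(5L, 73L),
    shrub = c(18L, 67L),
    grass = c(10L, 30L),
    building = c(2L, 26L, 49L, 85L),
    pavement = c(7L, 12L, 53L, 55L, 122L),
    rough_ground = c(14L, 17L, 35L, 47L, 69L, 92L, 95L),
    resting_facility = c(20L, 32L, 70L),
    service_facility = c(44L, 88L, 89L, 105L, 139L),
    shading_facility = c(87L, 107L, 115L)
  )
  tibble::tibble(
    class_id = unlist(m, use.names = FALSE),
    feature = rep(names(m), lengths(m))
  )
}

#' Landscape feature fractions from a segmentation label map
#'
#' Converts one per-pixel integer label map (the output of a semantic
#' segmentation model) into the fraction of the image occupied by each of
#' the eleven landscape features, via a class-to-feature remap table.
#' Pixels whose class maps to no feature are counted as `other`, so the
#' eleven fractions plus `other` always sum to exactly 1.
#'
#' @param labels Integer matrix of class ids (H x W), or a data frame /
#'   matrix coercible to one.
#' @param remap Remap table with columns `class_id`, `feature`; a `feature`
#'   of `"other"` is allowed. Defaults to [default_remap_table()].
#' @param image_id Identifier recorded in the output row.
#' @param unknown How to treat class ids absent from `remap`: `"other"`
#'   (default, with a warning listing the ids) or `"error"`.
#' @return A one-row tibble: `image_id`, the 11 feature fractions, `other`.
#' @export
#' @examples
#' m <- matrix(c(3L, 3L, 5L, 5L), 2)  # two sky + two tree pixels
#' remap_labels(m)[, c("sky", "tree")]
remap_labels <- function(labels, remap = default_remap_table(),
                         image_id = "image", unknown = c("other", "error")) {
  unknown <- match.arg(unknown)
  labels <- as.matrix(labels)
  if (length(labels) == 0) {
    ps_abort("empty label map", "parkscape_invalid_image")
  }
  storage.mode(labels) <- "integer"
  if (any(is.na(labels)) || any(labels < 0)) {
    ps_abort("label maps must contain non-negative integer class ids",
             "parkscape_invalid_image")
  }
  remap <- validate_remap_table(remap)
  ids <- as.vector(labels)
  unmapped <- setdiff(unique(ids), remap$class_id)
  if (length(unmapped) > 0) {
    if (unknown == "error") {
      ps_abort(paste0("class id(s) not in remap table: ",
                      paste(sort(unmapped), collapse = ", ")),
               "parkscape_remap_error")
    }
    warning("unmapped class id(s) counted as 'other': ",
            paste(sort(unmapped), collapse = ", "), call. = FALSE)
  }
  feat <- remap$feature[match(ids, remap$class_id)]
  feat[is.na(feat)] <- "other"
  counts <- table(factor(feat, levels = c(landscape_features(), "other")))
  fr <- as.numeric(counts) / length(ids)
  out <- tibble::as_tibble(as.list(stats::setNames(fr, names(counts))))
  dplyr::bind_cols(tibble::tibble(image_id = image_id), out)
}

validate_remap_table <- function(remap) {
  if (!all(c("class_id", "feature") %in% names(remap))) {
    ps_abort("remap table needs columns `class_id` and `feature`",
             "parkscape_remap_error")
  }
  remap <- tibble::as_tibble(remap)
  remap$class_id <- as.integer(remap$class_id)
  if (anyDuplicated(remap$class_id) > 0) {
    ps_abort("remap table maps some class id to more than one feature",
             "parkscape_remap_error")
  }
  bad <- setdiff(unique(remap$feature), c(landscape_features(), "other"))
  if (length(bad) > 0) {
    ps_abort(paste0("unknown target feature(s): ", paste(bad, collapse = ", ")),
             "parkscape_remap_error")
  }
  remap
}

#' Validate a per-image feature-fraction table
#'
#' Ingest path for studies that only have per-image class fractions rather
#' than raw label maps. Missing feature columns are filled with zero; the
#' eleven fractions of each row must lie in `[0, 1]` and sum to at most 1
#' (the remainder is reported as `other`), giving the same downstream
#' semantics as [remap_labels()].
#'
#' @param rows Data frame with an `image_id` column and any subset of the
#'   feature columns.
#' @return A tibble with `image_id`, all 11 features and `other`.
#' @export
fraction_table <- function(rows) {
  rows <- tibble::as_tibble(rows)
  if (!"image_id" %in% names(rows)) {
    rows$image_id <- paste0("image_", seq_len(nrow(rows)))
  }
  for (f in landscape_features()) {
    if (!f %in% names(rows)) rows[[f]] <- 0
  }
  frac <- as.matrix(rows[landscape_features()])
  if (any(!is.finite(frac)) || any(frac < 0) || any(frac > 1)) {
    ps_abort("fractions must be finite and in [0, 1]",
             "parkscape_fraction_error")
  }
  rs <- rowSums(frac)
  if (any(rs > 1 + 1e-6)) {
    ps_abort(paste0("row fraction sum exceeds 1 for image(s): ",
                    paste(rows$image_id[rs > 1 + 1e-6], collapse = ", ")),
             "parkscape_fraction_error")
  }
  dplyr::bind_cols(
    rows[c("image_id", landscape_features())],
    tibble::tibble(other = pmax(0, 1 - rs))
  )
}

#' Average per-image fractions into per-plot landscape profiles
#'
#' A plot's landscape profile is the arithmetic mean of the feature
#' fractions of its images (all photo points and directions pooled).
#'
#' @param fractions Per-image fraction tibble (as from [remap_labels()] or
#'   [fraction_table()]) with a `plot_id` column.
#' @return A tibble with one row per plot: `plot_id`, the 11 mean feature
#'   fractions and `n_images`.
#' @export
aggregate_plots <- function(fractions) {
  fractions <- tibble::as_tibble(fractions)
  if (!"plot_id" %in% names(fractions)) {
    ps_abort("fractions need a `plot_id` column", "parkscape_fraction_error")
  }
  if (nrow(fractions) == 0) {
    ps_abort("no images to aggregate", "parkscape_fraction_error")
  }
  assert_features_present(fractions, "fraction table")
  fractions |>
    dplyr::group_by(.data$plot_id) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(landscape_features()), mean),
      n_images = dplyr::n(),
      .groups = "drop"
    )
}

#' Plan a plot photography campaign
#'
#' The field protocol photographs each 30 m plot from at least nine
#' shooting points, in the four cardinal directions at each point. This
#' helper enumerates the photo slots of such a campaign.
#'
#' @param n_plots Number of measurement plots.
#' @param points_per_plot Shooting points per plot (default 9).
#' @param directions Directions per point (default 4: E, S, W, N).
#' @return A tibble of planned slots (`plot`, `point`, `direction`) with
#'   `n_plots * points_per_plot * directions` rows.
#' @export
#' @examples
#' nrow(photo_protocol_plan(68))  # 2448
photo_protocol_plan <- function(n_plots, points_per_plot = 9,
                                directions = 4) {
  if (any(c(n_plots, points_per_plot, directions) < 1)) {
    ps_abort("all plan arguments must be >= 1", "parkscape_plan_error")
  }
  dir_names <- c("E", "S", "W", "N")
  dirs <- if (directions <= 4) dir_names[seq_len(directions)]
          else as.character(seq_len(directions))
  tidyr::expand_grid(
    plot = seq_len(n_plots),
    point = seq_len(points_per_plot),
    direction = dirs
  )
}

#' Descriptive statistics of landscape profiles
#'
#' Per-group (typically per-park) mean and standard deviation of each
#' landscape feature, plus a pooled `Overall` group across all profiles.
#' The sample SD (denominator n-1) is the default; population SD is
#' available for compatibility with other software. Groups of a single
#' profile report SD 0 and are flagged.
#'
#' @param profiles Plot-level profile tibble with feature columns.
#' @param group Name of the grouping column (default `"park_id"`); if the
#'   column is absent all profiles form one group.
#' @param sd_type `"sample"` (default) or `"population"`.
#' @return A long tibble: `group`, `feature`, `mean`, `sd`, `n`,
#'   `sd_degenerate` (TRUE when n = 1).
#' @export
landscape_stats <- function(profiles, group = "park_id",
                            sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  profiles <- tibble::as_tibble(profiles)
  assert_features_present(profiles, "profiles")
  if (nrow(profiles) == 0) ps_abort("no profiles", "parkscape_fraction_error")
  grp <- if (group %in% names(profiles)) as.character(profiles[[group]])
         else rep("all", nrow(profiles))
  sd_fun <- function(x) {
    n <- length(x)
    if (n < 2) return(0)
    s <- stats::sd(x)
    if (sd_type == "population") s * sqrt((n - 1) / n) else s
  }
  one_group <- function(df, label) {
    df |>
      tidyr::pivot_longer(dplyr::all_of(landscape_features()),
                          names_to = "feature", values_to = "value") |>
      dplyr::group_by(.data$feature) |>
      dplyr::summarise(mean = mean(.data$value), sd = sd_fun(.data$value),
                       n = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(group = label, sd_degenerate = .data$n < 2) |>
      dplyr::select("group", "feature", "mean", "sd", "n", "sd_degenerate")
  }
  per_group <- profiles |>
    dplyr::mutate(.grp = grp) |>
    dplyr::group_split(.data$.grp) |>
    purrr::map_dfr(function(df) one_group(df, df$.grp[1]))
  dplyr::bind_rows(one_group(profiles, "Overall"), per_group) |>
    dplyr::mutate(feature = factor(.data$feature,
                                   levels = landscape_features())) |>
    dplyr::arrange(.data$group != "Overall", .data$group, .data$feature) |>
    dplyr::mutate(feature = as.character(.data$feature))
}
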