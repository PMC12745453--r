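# Orchestration of the two workflows: the plot-scale study replica
# (profiles -> scores -> screening -> models) and the park-wide mapping
# (filter -> fishnet -> join -> average -> predict -> classify -> export).

#' Run the plot-scale study workflow
#'
#' Executes the full analysis chain on supplied or synthetic data:
#' landscape profiles and behavior records are scored into intensity
#' indices, features are screened by correlation and variance inflation,
#' and one regression model is fitted per index over the surviving
#' features. All tabular results are written as CSV, the models as JSON,
#' and a machine-readable run log records the seed and per-stage row
#' counts. Reruns with the same inputs and seed are byte-identical.
#'
#' @param out_dir Output directory.
#' @param profiles,records Input tibbles; when `NULL` both are generated
#'   from `cfg`.
#' @param cfg A [synth_config()] used when generating (default seed 1).
#' @param met MET table.
#' @param method Correlation method for screening.
#' @param vif_threshold VIF retention threshold (default 10).
#' @param p_screen Correlation p-value below which a feature counts as
#'   relevant for an outcome (default 0.05).
#' @param exact_records Use the generator's exact fractional-count mode.
#' @return A list: `profiles`, `scores`, `screen`, `vif`, `models`,
#'   `paths`, `log`.
#' @export
run_study <- function(out_dir, profiles = NULL, records = NULL,
                      cfg = synth_config(), met = default_met_table(),
                      method = c("spearman", "pearson"),
                      vif_threshold = 10, p_screen = 0.05,
                      exact_records = FALSE) {
  method <- match.arg(method)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  synthetic <- is.null(profiles) || is.null(records)
  if (is.null(profiles)) profiles <- gen_profiles(cfg)
  if (is.null(records)) {
    records <- gen_behavior_records(profiles, cfg, met,
                                    exact = exact_records)$records
  }
  scores <- score_plots(records, met)
  scored <- dplyr::semi_join(profiles, scores, by = "plot_id")
  screen <- correlation_screen(scored, scores, method = method)
  vf <- vif_filter(scored, landscape_features(), threshold = vif_threshold)
  models <- purrr::map(
    stats::setNames(c("OBI", "EBI", "LBI", "SBI"),
                    c("OBI", "EBI", "LBI", "SBI")),
    function(outcome) {
      relevant <- screen |>
        dplyr::filter(.data$outcome == !!outcome,
                      !is.na(.data$p.value), .data$p.value < p_screen) |>
        dplyr::pull("feature")
      feats <- intersect(vf$retained, relevant)
      if (length(feats) == 0) {
        # no feature passes the screen: fall back to the retained set so a
        # model is always reportable; its terms will simply be weak
        feats <- vf$retained
      }
      fit_intensity_model(scored, scores, outcome, feats)
    }
  )
  paths <- c(
    profiles = file.path(out_dir, "profiles.csv"),
    scores = file.path(out_dir, "scores.csv"),
    landscape_stats = file.path(out_dir, "landscape_stats.csv"),
    intensity_stats = file.path(out_dir, "intensity_stats.csv"),
    screen = file.path(out_dir, "correlation_screen.csv"),
    vif = file.path(out_dir, "vif.csv"),
    model_report = file.path(out_dir, "model_report.csv"),
    models = file.path(out_dir, "models.json"),
    log = file.path(out_dir, "run_log.json")
  )
  readr::write_csv(profiles, paths["profiles"])
  readr::write_csv(scores, paths["scores"])
  readr::write_csv(landscape_stats(profiles), paths["landscape_stats"])
  int_stats <- scores |>
    dplyr::left_join(profiles[c("plot_id",
                                intersect("park_id", names(profiles)))],
                     by = "plot_id") |>
    tidyr::pivot_longer(dplyr::all_of(c("OBI", "EBI", "LBI", "SBI")),
                        names_to = "index", values_to = "value") |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c("park_id", "index")))) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = stats::sd(.data$value), n = dplyr::n(),
                     .groups = "drop")
  readr::write_csv(int_stats, paths["intensity_stats"])
  readr::write_csv(screen, paths["screen"])
  readr::write_csv(
    tibble::tibble(feature = names(vf$vif), vif = unname(vf$vif),
                   retained = TRUE) |>
      dplyr::bind_rows(dplyr::mutate(vf$dropped, retained = FALSE)),
    paths["vif"])
  readr::write_csv(model_report(models), paths["model_report"])
  write_models_json(models, paths["models"])
  log <- list(
    stage = "study", seed = cfg$seed, synthetic = synthetic,
    n_plots = nrow(profiles), n_records = nrow(records),
    n_scored_plots = nrow(scores),
    vif_retained = vf$retained,
    package_version = as.character(utils::packageVersion("parkscape"))
  )
  jsonlite::write_json(log, paths["log"], auto_unbox = TRUE, digits = NA)
  list(profiles = profiles, scores = scores, screen = screen, vif = vf,
       models = models, paths = paths, log = log)
}

#' Run the park-wide mapping workflow
#'
#' Filters geotagged image points, builds the fishnet over the park
#' boundary, joins points to cells, averages features, predicts the four
#' intensity indices and classifies them with Jenks breaks, then exports
#' GeoJSON + CSV maps. Per-stage counts are logged; retained plus rejected
#' always equals the input point count.
#'
#' @param out_dir Output directory.
#' @param boundary `park_boundary` (or `NULL` to generate from `cfg`).
#' @param points Points tibble (or `NULL` to generate).
#' @param models Named list of `intensity_model`s (default
#'   [reference_models()]).
#' @param cfg A [synth_config()] for generation.
#' @param cell_size Fishnet cell side, metres (default 30).
#' @param k Number of Jenks classes (default 5).
#' @param min_resolution Image resolution floor (default 1080).
#' @return A list of class `parkscape_map`: `cells` (classified tibble),
#'   `breaks`, `boundary`, `filter_log`, `paths`, `log`.
#' @export
run_mapping <- function(out_dir, boundary = NULL, points = NULL,
                        models = reference_models(), cfg = synth_config(),
                        cell_size = 30, k = 5, min_resolution = 1080) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.null(boundary) || is.null(points)) {
    gen <- gen_geo_images(cfg)
    boundary <- boundary %||% gen$boundary
    points <- points %||% gen$points
  }
  n_input <- nrow(points)
  flt <- filter_images(points, min_resolution = min_resolution)
  if (nrow(flt$points) == 0) {
    ps_abort("no image points survive filtering", "parkscape_empty_input")
  }
  cells <- build_fishnet(boundary, cell_size = cell_size)
  assigned <- assign_points(flt$points, cells)
  cells <- cell_features(cells, assigned)
  cells <- predict_cells(cells, models)
  cells <- classify_cells(cells, k = k)
  paths <- export_maps(cells, out_dir)
  paths["boundary"] <- write_boundary_geojson(
    boundary, file.path(out_dir, "boundary.geojson"))
  log <- list(
    stage = "mapping", seed = cfg$seed,
    n_points_input = n_input,
    n_points_retained = nrow(flt$points),
    n_points_rejected = nrow(flt$rejected),
    n_points_assigned = sum(!is.na(assigned$cell_id)),
    n_cells = nrow(cells),
    n_data_cells = sum(cells$n_points > 0),
    cell_size = cell_size, k = k
  )
  log_path <- file.path(out_dir, "mapping_log.json")
  jsonlite::write_json(log, log_path, auto_unbox = TRUE, digits = NA)
  paths["log"] <- log_path
  structure(
    list(cells = cells, breaks = attr(cells, "breaks"),
         boundary = boundary, filter_log = flt$log, paths = paths,
         log = log),
    class = "parkscape_map"
  )
}

#' @export
print.parkscape_map <- function(x, ...) {
  cat("<parkscape_map>", nrow(x$cells), "cells (",
      sum(x$cells$n_points > 0), "with data ),",
      length(x$breaks), "classified indices\n")
  invisible(x)
}
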