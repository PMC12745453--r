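#' Score behavior observations into MET-weighted intensity indices
#'
#' Computes, for each plot, the exercise (`EBI`), leisure (`LBI`) and social
#' (`SBI`) behavior-intensity indices as the sum of `MET * participant count`
#' over the plot's records in that category, and the overall index
#' `OBI = EBI + LBI + SBI`. Units are MET-persons. Records from all of a
#' plot's observation sessions are pooled; filter `records` beforehand for
#' per-session scores.
#'
#' @param records Data frame of observation records with at least `plot_id`,
#'   `code` and `count` columns (one row per observed activity).
#' @param met MET lookup, a data frame with columns `code` and `met`.
#'   Defaults to [default_met_table()].
#' @return A tibble with one row per plot: `plot_id`, `EBI`, `LBI`, `SBI`,
#'   `OBI`. An empty record set yields a zero-row tibble.
#' @export
#' @examples
#' recs <- tibble::tibble(plot_id = "P1", code = 106L, count = 5L)
#' met  <- tibble::tibble(code = 106L, met = 3)
#' score_plots(recs, met)  # EBI 15, OBI 15
score_plots <- function(records, met = default_met_table()) {
  met <- validate_met_table(met)
  records <- validate_records(records)
  if (nrow(records) == 0) {
    return(tibble::tibble(plot_id = character(), EBI = double(),
                          LBI = double(), SBI = double(), OBI = double()))
  }
  missing <- setdiff(unique(records$code), met$code)
  if (length(missing) > 0) {
    ps_abort(
      paste0("no MET value for code(s): ", paste(sort(missing), collapse = ", ")),
      "parkscape_met_config"
    )
  }
  records |>
    dplyr::mutate(category = category_of(.data$code)) |>
    dplyr::left_join(met, by = "code") |>
    dplyr::mutate(contrib = .data$met * .data$count) |>
    dplyr::group_by(.data$plot_id, .data$category) |>
    dplyr::summarise(intensity = sum(.data$contrib), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "category", values_from = "intensity",
                       values_fill = 0) |>
    add_missing_cols(c("EB", "LB", "SB")) |>
    dplyr::transmute(
      plot_id = .data$plot_id,
      EBI = .data$EB, LBI = .data$LB, SBI = .data$SB,
      OBI = .data$EB + .data$LB + .data$SB
    ) |>
    dplyr::arrange(.data$plot_id)
}

add_missing_cols <- function(df, cols) {
  for (cl in setdiff(cols, names(df))) df[[cl]] <- 0
  df
}

validate_records <- function(records) {
  need <- c("plot_id", "code", "count")
  if (!all(need %in% names(records))) {
    ps_abort(paste0("records need columns: ", paste(need, collapse = ", ")),
             "parkscape_record_config")
  }
  records <- tibble::as_tibble(records)
  records$code <- as.integer(records$code)
  if (any(records$count < 0)) {
    ps_abort("participant counts must be >= 0", "parkscape_record_config")
  }
  tax_codes <- behavior_taxonomy()$code
  unknown <- setdiff(unique(records$code), tax_codes)
  if (length(unknown) > 0) {
    ps_abort(
      paste0("code(s) not in taxonomy: ", paste(sort(unknown), collapse = ", ")),
      "parkscape_unknown_code"
    )
  }
  records
}

#' Per-subcategory participation summary
#'
#' Sums participant counts per behavior code and reports each code's
#' percentage share of all observed participants, rounded half-up to two
#' decimals (the convention used for printed shares).
#'
#' @param records Data frame of observation records (`plot_id`, `code`,
#'   `count`, ...).
#' @return A tibble with `code`, `name`, `category`, `n` (participants) and
#'   `share_pct`, sorted by decreasing `n`.
#' @export
#' @examples
#' recs <- tibble::tibble(plot_id = "P", code = c(202L, 202L, 208L),
#'                        count = c(2L, 1L, 1L))
#' behavior_summary(recs)
behavior_summary <- function(records) {
  records <- validate_records(records)
  total <- sum(records$count)
  if (nrow(records) == 0 || total == 0) {
    ps_abort("no participants to summarise", "parkscape_empty_summary")
  }
  records |>
    dplyr::group_by(code = .data$code) |>
    dplyr::summarise(n = sum(.data$count), .groups = "drop") |>
    dplyr::left_join(behavior_taxonomy(), by = "code") |>
    dplyr::mutate(share_pct = round_half_up(100 * .data$n / total, 2)) |>
    dplyr::select("code", "name", "category", "n", "share_pct") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$code)
}

#' Participant shares by demographic stratum
#'
#' Participant-weighted percentage shares for each level of the requested
#' stratification columns (age group, gender, session, ...), one tibble
#' section per stratifier. Shares use half-up rounding to two decimals.
#'
#' @param records Data frame of observation records including the
#'   stratification columns.
#' @param by Character vector of column names to stratify by.
#' @return A tibble with `stratifier`, `level`, `n`, `share_pct`.
#' @export
#' @examples
#' recs <- tibble::tibble(plot_id = "P", code = 202L, count = c(3L, 1L),
#'                        gender = c("female", "male"))
#' demographic_summary(recs, by = "gender")
demographic_summary <- function(records,
                                by = c("age_group", "gender", "session")) {
  records <- validate_records(records)
  by <- intersect(by, names(records))
  if (length(by) == 0) {
    ps_abort("no stratification columns present in records",
             "parkscape_record_config")
  }
  total <- sum(records$count)
  if (total == 0) {
    ps_abort("no participants to summarise", "parkscape_empty_summary")
  }
  purrr::map_dfr(by, function(col) {
    records |>
      dplyr::group_by(level = as.character(.data[[col]])) |>
      dplyr::summarise(n = sum(.data$count), .groups = "drop") |>
      dplyr::mutate(stratifier = col,
                    share_pct = round_half_up(100 * .data$n / total, 2)) |>
      dplyr::select("stratifier", "level", "n", "share_pct") |>
      dplyr::arrange(dplyr::desc(.data$n))
  })
}
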