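# Bundled reference tables from the seven-park Shanghai field campaign the
# package's default calibration is built around. Values are stored as
# printed in the campaign's summary tables; they are inputs (calibration
# targets and packaged predictive equations), not outputs of this package.

#' Packaged predictive intensity models
#'
#' The four reduced-form predictive equations relating landscape fractions
#' to behavior intensity (significant terms only), as an
#' `intensity_model` list ready for [predict()] or [predict_cells()]:
#' \describe{
#'   \item{OBI}{`281.63 + 857.13 sky + 1040.91 pavement - 1736.40 rough_ground`}
#'   \item{EBI}{`-167.14 + 762.37 tree + 1462.50 pavement - 1553.52 rough_ground - 27547.01 resting_facility`}
#'   \item{LBI}{`119.00 + 585.04 shrub`}
#'   \item{SBI}{`-106.58 + 1261.75 sky`}
#' }
#' R-squared diagnostics are carried from the source model fits; standard
#' errors, t and p values are not reproduced for the reduced forms.
#' [reference_models_full()] returns the full fitted term sets including
#' non-significant terms.
#'
#' @return Named list of four `intensity_model` objects
#'   (`OBI`, `EBI`, `LBI`, `SBI`).
#' @export
#' @examples
#' predict(reference_models()$OBI, tibble::tibble(
#'   sky = 0, pavement = 0, rough_ground = 0))  # 281.63
reference_models <- function() {
  list(
    OBI = new_intensity_model(
      "OBI", 281.63,
      c(sky = 857.13, pavement = 1040.91, rough_ground = -1736.40),
      r.squared = 0.297, adj.r.squared = 0.252, f.p.value = 0.000157,
      n = 68L),
    EBI = new_intensity_model(
      "EBI", -167.14,
      c(tree = 762.37, pavement = 1462.50, rough_ground = -1553.52,
        resting_facility = -27547.01),
      r.squared = 0.463, adj.r.squared = 0.410, f.p.value = 6.86e-07,
      n = 68L),
    LBI = new_intensity_model(
      "LBI", 119.00, c(shrub = 585.04),
      r.squared = 0.134, adj.r.squared = 0.108, f.p.value = 0.00918,
      n = 68L),
    SBI = new_intensity_model(
      "SBI", -106.58, c(sky = 1261.75),
      r.squared = 0.433, adj.r.squared = 0.377, f.p.value = 3.24e-06,
      n = 68L)
  )
}

#' Full fitted term sets of the packaged models
#'
#' Like [reference_models()] but with every term of the source model fits
#' (including non-significant ones, e.g. water in the OBI model), with
#' estimates and standard errors as printed in the source table. t and p
#' values are omitted rather than copied because the printed t-value signs
#' are internally inconsistent with the estimates.
#'
#' @return Named list of four `intensity_model` objects.
#' @export
reference_models_full <- function() {
  tt <- function(terms, est, se) {
    tibble::tibble(term = terms, estimate = est, std.error = se,
                   statistic = NA_real_, p.value = NA_real_)
  }
  obi_t <- c("(Intercept)", "sky", "water", "pavement", "rough_ground")
  obi_b <- c(281.63, 857.13, 812.55, 1040.91, -1736.40)
  obi_s <- c(130.46, 331.32, 973.18, 505.92, 873.98)
  ebi_t <- c("(Intercept)", "water", "tree", "grass", "pavement",
             "rough_ground", "resting_facility")
  ebi_b <- c(-167.14, 539.54, 762.37, 147.14, 1462.50, -1553.52, -27547.01)
  ebi_s <- c(124.97, 711.73, 206.27, 402.78, 400.58, 606.02, 12413.63)
  lbi_t <- c("(Intercept)", "shrub", "rough_ground")
  lbi_b <- c(119.00, 585.04, -473.24)
  lbi_s <- c(23.15, 237.29, 261.63)
  sbi_t <- c("(Intercept)", "sky", "tree", "shrub", "building",
             "rough_ground", "service_facility")
  sbi_b <- c(-106.58, 1261.75, 118.39, -540.11, 1447.28, 152.50, 10657.09)
  sbi_s <- c(210.36, 389.71, 333.11, 452.20, 1163.77, 539.41, 36168.39)
  mk <- function(outcome, terms, est, se, r2, ar2, fp) {
    new_intensity_model(
      outcome, est[1], stats::setNames(est[-1], terms[-1]),
      term_table = tt(terms, est, se),
      r.squared = r2, adj.r.squared = ar2, f.p.value = fp, n = 68L)
  }
  list(
    OBI = mk("OBI", obi_t, obi_b, obi_s, 0.297, 0.252, 0.000157),
    EBI = mk("EBI", ebi_t, ebi_b, ebi_s, 0.463, 0.410, 6.86e-07),
    LBI = mk("LBI", lbi_t, lbi_b, lbi_s, 0.134, 0.108, 0.00918),
    SBI = mk("SBI", sbi_t, sbi_b, sbi_s, 0.433, 0.377, 3.24e-06)
  )
}

#' Reference landscape composition statistics
#'
#' Per-park and overall mean and standard deviation of each landscape
#' feature across the seven surveyed parks (fractions in `[0, 1]`). These
#' are the default calibration of the synthetic profile generator.
#'
#' @return A tibble: `group` (`"Overall"`, `"UP-1"` ... `"UP-7"`),
#'   `feature`, `mean`, `sd`.
#' @export
reference_landscape_stats <- function() {
  groups <- c("Overall", paste0("UP-", 1:7))
  # rows ordered as landscape_features(); per row: 8 means then 8 sds
  means <- list(
    sky          = c(14.76, 15.55, 17.82,  6.07, 12.38,  9.33, 14.38, 22.20),
    water        = c( 2.07,  1.62,  1.64,  3.64,  0.82,  2.08,  0.88,  3.74),
    tree         = c(36.26, 31.27, 26.94, 41.51, 44.65, 37.19, 39.11, 30.36),
    shrub        = c( 6.05,  8.80,  7.16,  8.83,  9.35,  7.48,  3.66,  3.08),
    grass        = c( 4.59,  3.98,  1.01,  6.87,  3.23,  3.30,  5.43,  6.23),
    building     = c( 2.88,  2.41,  4.64,  5.05,  1.02,  3.97,  3.01,  2.00),
    pavement     = c(12.89, 14.51, 14.77,  7.76, 11.63, 14.58, 15.95, 10.03),
    rough_ground = c( 5.48,  2.99,  5.86,  4.92,  5.57,  6.02,  4.72,  6.55),
    resting_facility = c(0.14, 0.11, 0.04, 0.26, 0.08, 0.10, 0.19, 0.15),
    service_facility = c(0.05, 0.06, 0.09, 0.09, 0.03, 0.07, 0.04, 0.04),
    shading_facility = c(4.31, 4.77, 4.06, 4.05, 2.51, 5.35, 4.15, 4.34)
  )
  sds <- list(
    sky          = c(0.09, 0.10, 0.06, 0.08, 0.04, 0.05, 0.09, 0.09),
    water        = c(0.03, 0.01, 0.03, 0.03, 0.01, 0.03, 0.01, 0.05),
    tree         = c(0.11, 0.09, 0.07, 0.08, 0.06, 0.07, 0.10, 0.13),
    shrub        = c(0.04, 0.03, 0.03, 0.08, 0.03, 0.02, 0.03, 0.03),
    grass        = c(0.06, 0.06, 0.01, 0.09, 0.03, 0.02, 0.08, 0.05),
    building     = c(0.02, 0.01, 0.02, 0.03, 0.01, 0.03, 0.02, 0.02),
    pavement     = c(0.07, 0.06, 0.07, 0.03, 0.05, 0.08, 0.08, 0.05),
    rough_ground = c(0.04, 0.01, 0.02, 0.05, 0.02, 0.04, 0.04, 0.05),
    resting_facility = rep(0.001, 8),
    service_facility = rep(0.0005, 8),
    shading_facility = c(0.05, 0.05, 0.03, 0.05, 0.01, 0.07, 0.03, 0.04)
  )
  purrr::map_dfr(landscape_features(), function(f) {
    tibble::tibble(group = groups, feature = f,
                   mean = means[[f]] / 100, sd = sds[[f]])
  }) |>
    dplyr::arrange(.data$group != "Overall", .data$group)
}

#' Reference behavior-intensity statistics
#'
#' Per-park and overall mean and SD of the four intensity indices, as
#' printed in the source campaign's summary. Note a documented
#' inconsistency: for UP-7 (and the Overall column) the printed category
#' means do not sum to the printed OBI mean (432.30 vs 419.79 for UP-7),
#' which cannot be reconciled without the raw records; the other six parks
#' satisfy `OBI = EBI + LBI + SBI` exactly.
#'
#' @return A tibble: `group`, `index`, `mean`, `sd`.
#' @export
reference_intensity_stats <- function() {
  groups <- c("Overall", paste0("UP-", 1:7))
  tab <- list(
    OBI = list(mean = c(463.98, 523.30, 487.34, 460.58, 470.86, 482.25,
                        465.49, 419.79),
               sd   = c(253.36, 253.17, 175.55, 315.84, 208.80, 222.33,
                        311.46, 279.50)),
    EBI = list(mean = c(192.91, 148.30, 189.80,  92.02, 228.14, 263.03,
                        252.38, 108.98),
               sd   = c(187.37, 151.38, 134.28,  58.66, 193.84, 184.42,
                        239.99, 154.47)),
    LBI = list(mean = c(128.47, 182.30, 119.94, 177.60, 172.47, 137.83,
                         80.27, 109.62),
               sd   = c( 84.11,  45.51,  95.01,  88.52, 124.12,  65.18,
                         49.04,  78.02)),
    SBI = list(mean = c(145.55, 192.70, 177.60, 190.96,  70.25,  81.39,
                        132.84, 213.70),
               sd   = c(170.37,  91.36,  85.15, 241.85,  49.77,  60.95,
                        191.09, 240.07))
  )
  purrr::map_dfr(names(tab), function(i) {
    tibble::tibble(group = groups, index = i,
                   mean = tab[[i]]$mean, sd = tab[[i]]$sd)
  })
}

#' Reference sampling design
#'
#' The seven surveyed parks with their size, type and number of 30 m
#' measurement plots (68 plots in total).
#'
#' @return A tibble: `park_id`, `park`, `size_ha`, `type`, `n_plots`.
#' @export
reference_plot_design <- function() {
  tibble::tibble(
    park_id = paste0("UP-", 1:7),
    park = c("Jiangpu", "Quyang", "Fuxing", "Jinqiao", "Zhabei",
             "Zhongshan", "Daning"),
    size_ha = c(3.08, 6.47, 7.68, 11, 13.35, 20, 58.46),
    type = c("community", "community", "comprehensive", "community",
             "comprehensive", "comprehensive", "comprehensive"),
    n_plots = c(5L, 5L, 5L, 10L, 12L, 15L, 16L)
  )
}
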