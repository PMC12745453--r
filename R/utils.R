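# shared helpers and constants

#' The eleven landscape features
#'
#' Canonical names (and order) of the landscape composition features used
#' throughout the package: six natural elements (sky, water, tree, shrub,
#' grass, rough or uneven ground) and five artificial ones (building,
#' pavement, resting/service/shading facilities). Fractions are stored in
#' `[0, 1]`; any unmapped remainder of a scene is accounted for as `"other"`
#' and is never one of the eleven.
#'
#' @return Character vector of length 11.
#' @export
#' @examples
#' landscape_features()
landscape_features <- function() {
  c("sky", "water", "tree", "shrub", "grass", "building", "pavement",
    "rough_ground", "resting_facility", "service_facility",
    "shading_facility")
}

# round half up (printed shares use commercial rounding, not banker's)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# abort with a classed condition so callers can test on class
ps_abort <- function(msg, class) {
  rlang::abort(msg, class = c(class, "parkscape_error"))
}

assert_features_present <- function(df, what = "input") {
  missing <- setdiff(landscape_features(), names(df))
  if (length(missing) > 0) {
    ps_abort(
      paste0(what, " lacks feature column(s): ",
             paste(missing, collapse = ", ")),
      "parkscape_missing_feature"
    )
  }
  invisible(df)
}
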