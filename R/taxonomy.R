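#' Health-behavior taxonomy
#'
#' The 34 coded health-behavior subcategories observed in parks, grouped
#' into three categories by the leading digit of the 3-digit code:
#' exercise behavior (`EB`, codes 101--116), leisure behavior (`LB`,
#' 201--211) and social behavior (`SB`, 301--307). This is the coding frame
#' used on SOPARC-style observation forms.
#'
#' @return A tibble with columns `code` (integer), `name` (character) and
#'   `category` (one of `"EB"`, `"LB"`, `"SB"`).
#' @export
#' @examples
#' tax <- behavior_taxonomy()
#' dplyr::count(tax, category)
behavior_taxonomy <- function() {
  eb <- c(
    "101" = "stretching",          "102" = "tai chi",
    "103" = "bicycling",           "104" = "aerobic dance",
    "105" = "badminton",           "106" = "running",
    "107" = "frisbee playing",     "108" = "tennis",
    "109" = "kickball",            "110" = "calisthenics",
    "111" = "tai chi chuan",       "112" = "social dancing",
    "113" = "kicking shuttlecock", "114" = "rope jumping",
    "115" = "skating",             "116" = "scooter riding"
  )
  lb <- c(
    "201" = "sleeping",        "202" = "sitting",
    "203" = "standing",        "204" = "drawing",
    "205" = "walking",         "206" = "photography",
    "207" = "chess game",      "208" = "card game",
    "209" = "feeding animals", "210" = "bird watching",
    "211" = "playing with sand"
  )
  sb <- c(
    "301" = "reunion activities",          "302" = "group conversation",
    "303" = "playing musical instruments", "304" = "singing",
    "305" = "parent-child activities",     "306" = "camping",
    "307" = "children's games"
  )
  all <- c(eb, lb, sb)
  tibble::tibble(
    code = as.integer(names(all)),
    name = unname(all),
    category = category_of(as.integer(names(all)))
  )
}

#' Behavior category from a 3-digit code
#'
#' The leading digit of a behavior code determines its category:
#' `1xx` is exercise (`EB`), `2xx` leisure (`LB`), `3xx` social (`SB`).
#'
#' @param code Integer vector of 3-digit behavior codes (100--399).
#' @return Character vector of categories (`"EB"`, `"LB"`, `"SB"`).
#' @export
#' @examples
#' category_of(c(101L, 202L, 307L))
category_of <- function(code) {
  code <- as.integer(code)
  bad <- is.na(code) | code < 100L | code > 399L
  if (any(bad)) {
    ps_abort(
      paste0("unknown behavior code(s): ",
             paste(unique(code[bad]), collapse = ", "),
             " (expected 3-digit codes 1xx/2xx/3xx)"),
      "parkscape_unknown_code"
    )
  }
  c("EB", "LB", "SB")[code %/% 100L]
}

#' Packaged default MET table
#'
#' Metabolic Equivalent of Task (MET) values for each taxonomy code,
#' expressing the energy cost of the activity as a multiple of resting
#' metabolic rate. The packaged values follow the conventions of the 2011
#' Adult Compendium of Physical Activities and are a documented stand-in:
#' studies should supply their own table via [read_met_table()] or a
#' two-column data frame when field-specific values are available
#' (e.g. locally derived METs for scooter riding or shuttlecock kicking).
#'
#' @return A tibble with columns `code` (integer) and `met` (positive double).
#' @seealso [score_plots()], [read_met_table()]
#' @export
#' @examples
#' met <- default_met_table()
#' range(met$met)
default_met_table <- function() {
  vals <- c(
    # exercise
    "101" = 2.3, "102" = 3.0, "103" = 7.5, "104" = 7.3, "105" = 5.5,
    "106" = 7.0, "107" = 3.0, "108" = 7.3, "109" = 7.0, "110" = 3.8,
    "111" = 3.3, "112" = 5.5, "113" = 5.0, "114" = 11.0, "115" = 7.0,
    "116" = 5.0,
    # leisure
    "201" = 1.0, "202" = 1.3, "203" = 1.5, "204" = 1.8, "205" = 3.5,
    "206" = 2.0, "207" = 1.5, "208" = 1.5, "209" = 2.5, "210" = 2.5,
    "211" = 3.0,
    # social
    "301" = 1.5, "302" = 1.5, "303" = 2.0, "304" = 2.0, "305" = 3.5,
    "306" = 2.5, "307" = 5.0
  )
  tibble::tibble(code = as.integer(names(vals)), met = unname(vals))
}

# validate a user MET table and return it normalised
validate_met_table <- function(met) {
  if (!all(c("code", "met") %in% names(met))) {
    ps_abort("MET table needs columns `code` and `met`",
             "parkscape_met_config")
  }
  met <- tibble::as_tibble(met)
  met$code <- as.integer(met$code)
  if (anyDuplicated(met$code) > 0) {
    ps_abort("MET table has duplicated codes", "parkscape_met_config")
  }
  if (any(!is.finite(met$met) | met$met <= 0)) {
    ps_abort("MET values must be finite and strictly positive",
             "parkscape_met_config")
  }
  met
}
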