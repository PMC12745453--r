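#' Intraclass correlation coefficient for observer reliability
#'
#' Single-measure ICC of an n-targets x k-raters matrix, computed from the
#' ANOVA mean squares (Shrout--Fleiss forms):
#' \describe{
#'   \item{ICC1_1}{one-way random: `(MSB - MSW) / (MSB + (k-1) MSW)`}
#'   \item{ICC2_1}{two-way random, absolute agreement:
#'     `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`}
#'   \item{ICC3_1}{two-way mixed, consistency:
#'     `(MSR - MSE) / (MSR + (k-1) MSE)`}
#' }
#' `ICC2_1` is the default, the standard choice for SOPARC dual-observer
#' reliability (raters a random sample, absolute agreement of counts).
#'
#' @param m Numeric matrix (or data frame), rows = rated targets,
#'   columns = raters; at least 2 x 2, no missing cells.
#' @param form One of `"ICC2_1"`, `"ICC1_1"`, `"ICC3_1"`.
#' @return A tibble: `form`, `icc`, `ms_rows`, `ms_cols`, `ms_error`,
#'   `ms_within`, `n_targets`, `n_raters`.
#' @export
#' @examples
#' m <- cbind(a = c(1, 4, 7, 10), b = c(2, 4, 8, 9))
#' icc(m)
icc <- function(m, form = c("ICC2_1", "ICC1_1", "ICC3_1")) {
  form <- match.arg(form)
  m <- as.matrix(m)
  if (anyNA(m)) ps_abort("rating matrix has missing cells",
                         "parkscape_icc_error")
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2 || k < 2) {
    ps_abort("need at least 2 targets and 2 raters", "parkscape_icc_error")
  }
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ss_within <- ss_tot - ss_rows
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  msw <- ss_within / (n * (k - 1))
  if (ss_tot == 0) {
    warning("zero total variance: ICC undefined", call. = FALSE)
    val <- NA_real_
  } else {
    val <- switch(form,
      ICC1_1 = (msr - msw) / (msr + (k - 1) * msw),
      ICC2_1 = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
      ICC3_1 = (msr - mse) / (msr + (k - 1) * mse)
    )
  }
  tibble::tibble(form = form, icc = val, ms_rows = msr, ms_cols = msc,
                 ms_error = mse, ms_within = msw,
                 n_targets = n, n_raters = k)
}

#' Percent agreement between two observers
#'
#' Share of paired categorical codes on which two observers agree, as a
#' percentage rounded half-up to one decimal. Optionally stratified by a
#' grouping vector (e.g. behavior category).
#'
#' @param a,b Equal-length vectors of codes from the two observers.
#' @param by Optional stratification vector of the same length.
#' @return A tibble: `stratum` (`"overall"` or the stratum levels),
#'   `n_pairs`, `n_agree`, `agreement_pct`.
#' @export
#' @examples
#' percent_agreement(c(1, 2, 3, 4), c(1, 2, 3, 9))  # 75.0
percent_agreement <- function(a, b, by = NULL) {
  if (length(a) != length(b) || length(a) == 0) {
    ps_abort("need equally sized, nonempty code vectors",
             "parkscape_agreement_error")
  }
  match_ <- a == b
  overall <- tibble::tibble(
    stratum = "overall", n_pairs = length(a), n_agree = sum(match_),
    agreement_pct = round_half_up(100 * mean(match_), 1)
  )
  if (is.null(by)) return(overall)
  strata <- tibble::tibble(stratum = as.character(by), ok = match_) |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(n_pairs = dplyr::n(), n_agree = sum(.data$ok),
                     .groups = "drop") |>
    dplyr::mutate(agreement_pct = round_half_up(
      100 * .data$n_agree / .data$n_pairs, 1))
  dplyr::bind_rows(overall, strata)
}
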