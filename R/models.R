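#' Correlation screen between landscape features and intensity scores
#'
#' Rank (Spearman, default) or product-moment (Pearson) correlation of each
#' landscape feature against each intensity index, with two-sided p-values.
#' Ties are handled by average ranks. Constant features have undefined
#' correlation and are reported as `NA` with a warning.
#'
#' @param profiles Plot-level profile tibble (feature columns + `plot_id`).
#' @param scores Intensity tibble from [score_plots()] (`plot_id`, `EBI`,
#'   `LBI`, `SBI`, `OBI`).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param features Features to screen (default all 11).
#' @param outcomes Outcomes to screen (default the four indices).
#' @return A tibble: `feature`, `outcome`, `estimate`, `p.value`, `method`, `n`.
#' @export
correlation_screen <- function(profiles, scores,
                               method = c("spearman", "pearson"),
                               features = landscape_features(),
                               outcomes = c("OBI", "EBI", "LBI", "SBI")) {
  method <- match.arg(method)
  df <- dplyr::inner_join(tibble::as_tibble(profiles),
                          tibble::as_tibble(scores), by = "plot_id")
  if (nrow(df) < 3) {
    ps_abort("need at least 3 paired observations", "parkscape_screen_error")
  }
  grid <- tidyr::expand_grid(feature = features, outcome = outcomes)
  purrr::pmap_dfr(grid, function(feature, outcome) {
    x <- df[[feature]]
    y <- df[[outcome]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("constant variable: correlation undefined for ", feature,
              " vs ", outcome, call. = FALSE)
      return(tibble::tibble(feature = feature, outcome = outcome,
                            estimate = NA_real_, p.value = NA_real_,
                            method = method, n = length(x)))
    }
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = method, exact = FALSE)
    )
    tibble::tibble(feature = feature, outcome = outcome,
                   estimate = unname(ct$estimate),
                   p.value = ct$p.value, method = method, n = length(x))
  })
}

#' Iterative variance-inflation-factor filter
#'
#' Computes `VIF_j = 1 / (1 - R^2_j)` for each candidate feature, where
#' `R^2_j` comes from regressing feature j on the remaining candidates.
#' While any VIF is at or above the threshold, the worst offender is
#' dropped and VIFs recomputed. Exactly collinear features (infinite VIF)
#' are dropped immediately.
#'
#' @param profiles Plot-level profile tibble.
#' @param features Candidate feature names.
#' @param threshold Retention threshold; features are kept while
#'   `VIF < threshold` (default 10).
#' @return A list with `retained` (character), `vif` (named numeric of the
#'   final VIFs) and `dropped` (tibble of `feature`, `vif`, `step`).
#' @export
#' @examples
#' p <- tibble::tibble(plot_id = 1:20, a = rnorm(20), b = rnorm(20))
#' vif_filter(p, c("a", "b"))$vif
vif_filter <- function(profiles, features = landscape_features(),
                       threshold = 10) {
  df <- tibble::as_tibble(profiles)
  missing <- setdiff(features, names(df))
  if (length(missing) > 0) {
    ps_abort(paste0("missing feature column(s): ",
                    paste(missing, collapse = ", ")),
             "parkscape_missing_feature")
  }
  if (nrow(df) < length(features) + 2) {
    ps_abort("need at least (candidates + 2) observations",
             "parkscape_screen_error")
  }
  dropped <- tibble::tibble(feature = character(), vif = double(),
                            step = integer())
  step <- 0L
  kept <- features
  repeat {
    v <- vif_values(df, kept)
    if (length(kept) < 2 || all(v < threshold)) break
    step <- step + 1L
    worst <- names(v)[which.max(v)]
    dropped <- dplyr::bind_rows(
      dropped, tibble::tibble(feature = worst, vif = unname(v[worst]),
                              step = step))
    kept <- setdiff(kept, worst)
  }
  list(retained = kept, vif = vif_values(df, kept), dropped = dropped)
}

vif_values <- function(df, features) {
  if (length(features) < 2) {
    return(stats::setNames(rep(1, length(features)), features))
  }
  x <- as.data.frame(df[features])
  out <- vapply(features, function(f) {
    fit <- stats::lm(stats::reformulate(setdiff(features, f), response = f),
                     data = x)
    # exact collinearity is handled below; lm's perfect-fit warning is noise
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  out
}

#' Fit a landscape-to-intensity regression model
#'
#' Ordinary least squares of one intensity index on a set of landscape
#' feature fractions, with intercept. The result is an `intensity_model`
#' carrying the coefficient table (estimate, SE, t, two-sided p), R^2,
#' adjusted R^2 and the overall F-test p-value; [generics::tidy()] and
#' [generics::glance()] methods expose them in broom style.
#'
#' @param profiles Plot-level profile tibble.
#' @param scores Intensity tibble (`plot_id` + outcome columns).
#' @param outcome One of `"OBI"`, `"EBI"`, `"LBI"`, `"SBI"`.
#' @param features Predictor features (typically the VIF-retained,
#'   correlation-relevant subset).
#' @return An `intensity_model` object.
#' @export
fit_intensity_model <- function(profiles, scores, outcome, features) {
  df <- dplyr::inner_join(tibble::as_tibble(profiles),
                          tibble::as_tibble(scores), by = "plot_id")
  if (nrow(df) <= length(features) + 1) {
    ps_abort("too few observations for the requested model",
             "parkscape_fit_error")
  }
  fit <- stats::lm(stats::reformulate(features, response = outcome),
                   data = df)
  if (anyNA(stats::coef(fit))) {
    ps_abort("singular fit: predictors are rank deficient after filtering",
             "parkscape_fit_error")
  }
  sm <- summary(fit)
  ct <- stats::coef(sm)
  f <- sm$fstatistic
  f_p <- if (is.null(f)) NA_real_ else
    unname(stats::pf(f[1], f[2], f[3], lower.tail = FALSE))
  new_intensity_model(
    outcome = outcome,
    intercept = unname(ct["(Intercept)", "Estimate"]),
    coefficients = stats::setNames(ct[features, "Estimate"], features),
    term_table = tibble::tibble(
      term = rownames(ct),
      estimate = ct[, "Estimate"],
      std.error = ct[, "Std. Error"],
      statistic = ct[, "t value"],
      p.value = ct[, "Pr(>|t|)"]
    ),
    r.squared = sm$r.squared,
    adj.r.squared = sm$adj.r.squared,
    f.p.value = f_p,
    n = nrow(df),
    fitted = fit
  )
}

new_intensity_model <- function(outcome, intercept, coefficients,
                                term_table = NULL, r.squared = NA_real_,
                                adj.r.squared = NA_real_,
                                f.p.value = NA_real_, n = NA_integer_,
                                fitted = NULL) {
  stray <- setdiff(names(coefficients), landscape_features())
  if (length(stray) > 0) {
    ps_abort(paste0("unknown feature(s) in model: ",
                    paste(stray, collapse = ", ")),
             "parkscape_missing_feature")
  }
  structure(
    list(outcome = outcome, intercept = intercept,
         coefficients = coefficients, term_table = term_table,
         r.squared = r.squared, adj.r.squared = adj.r.squared,
         f.p.value = f.p.value, n = n, fitted = fitted),
    class = "intensity_model"
  )
}

#' @export
print.intensity_model <- function(x, ...) {
  cat("<intensity_model> outcome:", x$outcome, "\n")
  cat("  ", x$outcome, " = ", format(x$intercept), sep = "")
  for (f in names(x$coefficients)) {
    b <- x$coefficients[[f]]
    cat(if (b >= 0) " + " else " - ", format(abs(b)), " x ", f, sep = "")
  }
  cat("\n")
  if (!is.na(x$r.squared)) {
    cat("  R^2 =", format(x$r.squared),
        " adj. R^2 =", format(x$adj.r.squared), "\n")
  }
  invisible(x)
}

#' Predict intensity from a landscape profile
#'
#' Evaluates `intercept + sum(coefficient_f * fraction_f)` for each row of
#' `newdata`. Predictions are not clamped and may be negative (some fitted
#' intercepts are); set `floor_zero = TRUE` to truncate at zero.
#'
#' @param object An `intensity_model`.
#' @param newdata Data frame supplying every feature the model uses, or a
#'   named numeric vector for a single profile.
#' @param floor_zero Truncate negative predictions at 0 (default FALSE).
#' @param ... Unused.
#' @return Numeric vector of predictions (MET-persons).
#' @export
#' @examples
#' m <- reference_models()$LBI
#' predict(m, tibble::tibble(shrub = c(0, 0.10)))  # 119.00, 177.504
predict.intensity_model <- function(object, newdata, floor_zero = FALSE,
                                    ...) {
  if (is.numeric(newdata) && !is.null(names(newdata))) {
    newdata <- tibble::as_tibble(as.list(newdata))
  }
  newdata <- tibble::as_tibble(newdata)
  need <- names(object$coefficients)
  missing <- setdiff(need, names(newdata))
  if (length(missing) > 0) {
    ps_abort(paste0("prediction input lacks feature(s): ",
                    paste(missing, collapse = ", ")),
             "parkscape_missing_feature")
  }
  x <- as.matrix(newdata[need])
  pred <- as.numeric(object$intercept + x %*% object$coefficients)
  if (floor_zero) pred <- pmax(0, pred)
  pred
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an intensity model's coefficient table
#'
#' @param x An `intensity_model`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate` and, when the model was fitted
#'   from data (rather than loaded from the bundled reference tables),
#'   `std.error`, `statistic`, `p.value`.
#' @method tidy intensity_model
#' @export
tidy.intensity_model <- function(x, ...) {
  if (!is.null(x$term_table)) return(tibble::as_tibble(x$term_table))
  tibble::tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}

#' One-row model summary
#'
#' @param x An `intensity_model`.
#' @param ... Unused.
#' @return A tibble with `outcome`, `r.squared`, `adj.r.squared`,
#'   `f.p.value`, `n`.
#' @method glance intensity_model
#' @export
glance.intensity_model <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, r.squared = x$r.squared,
                 adj.r.squared = x$adj.r.squared,
                 f.p.value = x$f.p.value, n = x$n)
}
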