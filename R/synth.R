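# Seeded synthetic-data generator. Defaults emulate the study conditions
# the package is calibrated to: 68 plots across seven parks, landscape
# fractions at the reference means/SDs, intensity driven by the packaged
# predictive equations plus Gaussian noise, and a 7.68 ha park with
# crowdsourced image points for the mapping stage.

#' Synthetic-data generator configuration
#'
#' @param seed Integer seed; every generator derives its own sub-seed from
#'   it, so outputs are bit-reproducible and independent across stages.
#' @param n_plots Number of measurement plots (default 68; when 68, plots
#'   are allocated to the seven reference parks by the reference design).
#' @param feature_means,feature_sds Named per-feature means / SDs of the
#'   fraction distributions (defaults: the reference overall column).
#' @param noise_sd Named per-outcome residual SD of the intensity targets,
#'   MET-persons (defaults derived from the reference fits' unexplained
#'   variance: `sqrt(1 - R^2) * SD(outcome)`).
#' @param true_models Named list of generating `intensity_model`s (default
#'   [reference_models()]).
#' @param park_extent `c(width, height)` of the synthetic park in metres
#'   (default 320 x 240 m = 7.68 ha).
#' @param n_images Number of geotagged image points (default 500).
#' @param image_noise_sd SD of per-image feature noise around the smooth
#'   spatial field (default 0.05).
#' @param frac_low_res,frac_non_landscape,frac_duplicate Fractions of
#'   points flagged to exercise [filter_images()].
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_plots = 68L,
                         feature_means = NULL, feature_sds = NULL,
                         noise_sd = c(EBI = 137, LBI = 78, SBI = 128),
                         true_models = reference_models(),
                         park_extent = c(320, 240),
                         n_images = 500L, image_noise_sd = 0.05,
                         frac_low_res = 0.05, frac_non_landscape = 0.03,
                         frac_duplicate = 0.02) {
  ref <- reference_landscape_stats() |> dplyr::filter(.data$group == "Overall")
  means <- stats::setNames(ref$mean, ref$feature)
  sds <- stats::setNames(ref$sd, ref$feature)
  if (!is.null(feature_means)) means[names(feature_means)] <- feature_means
  if (!is.null(feature_sds)) sds[names(feature_sds)] <- feature_sds
  if (any(means < 0 | means > 1)) {
    ps_abort("feature means must lie in [0, 1]", "parkscape_config_error")
  }
  if (sum(means) > 1) {
    ps_abort("infeasible feature means: they sum to more than 1",
             "parkscape_config_error")
  }
  if (any(sds < 0) || any(noise_sd < 0)) {
    ps_abort("standard deviations must be >= 0", "parkscape_config_error")
  }
  structure(
    list(seed = as.integer(seed), n_plots = as.integer(n_plots),
         feature_means = means, feature_sds = sds, noise_sd = noise_sd,
         true_models = true_models, park_extent = park_extent,
         n_images = as.integer(n_images), image_noise_sd = image_noise_sd,
         frac_low_res = frac_low_res,
         frac_non_landscape = frac_non_landscape,
         frac_duplicate = frac_duplicate),
    class = "synth_config"
  )
}

# independent sub-streams per generator stage (kept below 2^31)
sub_seed <- function(cfg, offset) {
  (cfg$seed %% 1000003L) * 1009L + offset
}

#' Generate synthetic landscape profiles
#'
#' Draws each plot's feature fractions independently from normals at the
#' configured means/SDs truncated (clipped) to `[0, 1]`. If the eleven
#' fractions of a plot sum to more than 0.95 they are rescaled to 0.95,
#' leaving at least 5 percent of the scene unmapped ("other"), as real
#' segmentations do.
#'
#' @param cfg A [synth_config()].
#' @return A profile tibble: `plot_id`, `park_id`, the 11 features,
#'   `n_images`.
#' @export
gen_profiles <- function(cfg) {
  set.seed(sub_seed(cfg, 1L))
  feats <- landscape_features()
  n <- cfg$n_plots
  m <- vapply(feats, function(f) {
    pmin(1, pmax(0, stats::rnorm(n, cfg$feature_means[[f]],
                                 cfg$feature_sds[[f]])))
  }, numeric(n))
  m <- matrix(m, nrow = n, dimnames = list(NULL, feats))
  rs <- rowSums(m)
  over <- rs > 0.95
  m[over, ] <- m[over, , drop = FALSE] * (0.95 / rs[over])
  design <- reference_plot_design()
  park <- if (n == sum(design$n_plots)) {
    rep(design$park_id, design$n_plots)
  } else {
    rep("SYN-1", n)
  }
  dplyr::bind_cols(
    tibble::tibble(plot_id = sprintf("plot_%02d", seq_len(n)),
                   park_id = park),
    tibble::as_tibble(m)
  ) |>
    dplyr::mutate(n_images = 36L)
}

#' Generate synthetic behavior records
#'
#' For each plot, draws target category intensities
#' `max(0, prediction_from_true_models + N(0, noise_sd))` and decomposes
#' each target into observation records by greedily drawing codes from the
#' category and integer participant counts until the remaining intensity is
#' below the category's smallest MET; the realised score therefore lands
#' within one MET unit of the target, and `OBI` emerges as the category
#' sum. With `exact = TRUE` each category becomes a single record with a
#' fractional count, so scores match targets to machine precision (an
#' idealised mode for model-recovery experiments).
#'
#' @param profiles Profile tibble from [gen_profiles()].
#' @param cfg A [synth_config()].
#' @param met MET table covering the taxonomy.
#' @param exact Emit fractional-count records reproducing targets exactly.
#' @return A list: `records` (tibble in the observation-form layout) and
#'   `targets` (tibble of the generating truth per plot).
#' @export
gen_behavior_records <- function(profiles, cfg, met = default_met_table(),
                                 exact = FALSE) {
  set.seed(sub_seed(cfg, 2L))
  met <- validate_met_table(met)
  tax <- behavior_taxonomy() |> dplyr::left_join(met, by = "code")
  if (anyNA(tax$met)) {
    ps_abort("MET table does not cover the taxonomy", "parkscape_met_config")
  }
  cats <- split(tax, tax$category)
  if (any(lengths(cats) == 0)) {
    ps_abort("taxonomy category is empty", "parkscape_config_error")
  }
  sessions <- as.vector(outer(c("weekday", "weekend"),
                              c("am", "noon", "pm"), paste, sep = "-"))
  sess_p <- as.vector(outer(c(0.44, 0.56), rep(1 / 3, 3)))
  ages <- c("older_adult", "adult", "child", "adolescent")
  age_p <- c(0.69, 0.22, 0.08, 0.01)
  out <- vector("list", nrow(profiles))
  targets <- vector("list", nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    prof <- profiles[i, ]
    rows <- list()
    tgt <- c(EBI = NA_real_, LBI = NA_real_, SBI = NA_real_)
    for (x in c("EBI", "LBI", "SBI")) {
      mu <- predict(cfg$true_models[[x]], prof)
      target <- max(0, mu + stats::rnorm(1, 0, cfg$noise_sd[[x]]))
      tgt[x] <- target
      cat_tab <- cats[[substr(x, 1, 2)]]
      if (exact) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          code = cat_tab$code[1], count = target / cat_tab$met[1])
        next
      }
      remaining <- target
      while (remaining >= min(cat_tab$met)) {
        ok <- which(cat_tab$met <= remaining)
        pick <- cat_tab[ok[sample.int(length(ok), 1)], ]
        max_count <- floor(remaining / pick$met)
        count <- sample.int(min(max_count, 15L), 1)
        rows[[length(rows) + 1]] <- tibble::tibble(code = pick$code,
                                                   count = count)
        remaining <- remaining - pick$met * count
      }
    }
    recs <- dplyr::bind_rows(rows)
    n <- nrow(recs)
    if (n > 0) {
      recs$plot_id <- prof$plot_id
      recs$session <- sample(sessions, n, replace = TRUE, prob = sess_p)
      recs$age_group <- sample(ages, n, replace = TRUE, prob = age_p)
      recs$gender <- sample(c("female", "male"), n, replace = TRUE,
                            prob = c(0.52, 0.48))
      recs$observer_id <- sample(c("obs-1", "obs-2"), n, replace = TRUE)
      out[[i]] <- recs[c("plot_id", "session", "code", "count",
                         "age_group", "gender", "observer_id")]
    }
    targets[[i]] <- tibble::tibble(plot_id = prof$plot_id,
                                   EBI = unname(tgt["EBI"]),
                                   LBI = unname(tgt["LBI"]),
                                   SBI = unname(tgt["SBI"]),
                                   OBI = sum(tgt))
  }
  list(records = dplyr::bind_rows(out), targets = dplyr::bind_rows(targets))
}

#' Generate a synthetic park with geotagged image points
#'
#' A rectangular boundary of the configured extent with `n_images` points
#' uniform over it. Each point's feature fractions follow a smooth spatial
#' field (a low-frequency sinusoidal modulation of the configured feature
#' means) plus Gaussian noise, clipped to `[0, 1]` and rescaled as in
#' [gen_profiles()]. Configurable fractions of points are flagged
#' low-resolution, non-landscape or duplicate to exercise
#' [filter_images()].
#'
#' @param cfg A [synth_config()].
#' @return A list: `boundary` (a `park_boundary`) and `points` (tibble
#'   with id, coordinates, metadata flags and the 11 feature columns).
#' @export
gen_geo_images <- function(cfg) {
  set.seed(sub_seed(cfg, 3L))
  w <- cfg$park_extent[1]
  h <- cfg$park_extent[2]
  boundary <- park_boundary(cbind(c(0, w, w, 0), c(0, 0, h, h)))
  n <- cfg$n_images
  x <- stats::runif(n, 0, w)
  y <- stats::runif(n, 0, h)
  feats <- landscape_features()
  m <- vapply(seq_along(feats), function(j) {
    f <- feats[j]
    phase <- stats::runif(2, 0, 2 * pi)
    field <- cfg$feature_means[[f]] *
      (1 + 0.5 * sin(2 * pi * x / w + phase[1]) *
             cos(2 * pi * y / h + phase[2]))
    pmin(1, pmax(0, field + stats::rnorm(n, 0, cfg$image_noise_sd)))
  }, numeric(n))
  m <- matrix(m, nrow = n, dimnames = list(NULL, feats))
  rs <- rowSums(m)
  over <- rs > 0.95
  m[over, ] <- m[over, , drop = FALSE] * (0.95 / rs[over])
  n_low <- round(cfg$frac_low_res * n)
  n_nl <- round(cfg$frac_non_landscape * n)
  n_dup <- round(cfg$frac_duplicate * n)
  flagged <- sample.int(n, min(n, n_low + n_nl + n_dup))
  low <- flagged[seq_len(n_low)]
  nl <- flagged[n_low + seq_len(n_nl)]
  dup <- flagged[n_low + n_nl + seq_len(n_dup)]
  resolution <- rep(1920L, n)
  resolution[low] <- 720L
  is_landscape <- rep(TRUE, n)
  is_landscape[nl] <- FALSE
  duplicate_key <- sprintf("k%05d", seq_len(n))
  for (d in dup) {
    pool <- setdiff(seq_len(d - 1), c(dup, low, nl))
    if (length(pool) > 0) duplicate_key[d] <- duplicate_key[sample(pool, 1)]
  }
  points <- dplyr::bind_cols(
    tibble::tibble(image_id = sprintf("img_%04d", seq_len(n)),
                   x = x, y = y, resolution = resolution,
                   is_landscape = is_landscape,
                   duplicate_key = duplicate_key),
    tibble::as_tibble(m)
  )
  list(boundary = boundary, points = points)
}

#' Generate a rating matrix with known intraclass correlation
#'
#' Targets are drawn with between-target variance `true_icc` and residual
#' variance `1 - true_icc`, so the population single-measure ICC equals
#' `true_icc` (no rater effect, matching the two-way random model).
#'
#' @param cfg A [synth_config()] (supplies the seed).
#' @param true_icc Target ICC in `[0, 1]`.
#' @param n_targets,n_raters Matrix dimensions (defaults 200 x 2).
#' @return Numeric matrix `n_targets` x `n_raters`.
#' @export
gen_rating_matrix <- function(cfg, true_icc, n_targets = 200,
                              n_raters = 2) {
  if (true_icc < 0 || true_icc > 1) {
    ps_abort("true_icc must lie in [0, 1]", "parkscape_config_error")
  }
  set.seed(sub_seed(cfg, 4L))
  t_eff <- stats::rnorm(n_targets, 0, sqrt(true_icc))
  m <- t_eff + matrix(stats::rnorm(n_targets * n_raters, 0,
                                   sqrt(1 - true_icc)),
                      n_targets, n_raters)
  dimnames(m) <- list(sprintf("t%03d", seq_len(n_targets)),
                      sprintf("rater_%d", seq_len(n_raters)))
  m
}
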