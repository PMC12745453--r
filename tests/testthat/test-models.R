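profiles_scores <- function(n = 30, seed = 2) {
  set.seed(seed)
  p <- tibble::tibble(plot_id = sprintf("p%02d", 1:n),
                      sky = runif(n, 0, 0.3),
                      shrub = runif(n, 0, 0.2),
                      pavement = runif(n, 0, 0.3),
                      rough_ground = runif(n, 0, 0.15))
  s <- tibble::tibble(plot_id = p$plot_id,
                      OBI = predict(reference_models()$OBI, p),
                      EBI = rnorm(n, 100, 20),
                      LBI = rnorm(n, 100, 20),
                      SBI = rnorm(n, 100, 20))
  list(profiles = p, scores = s)
}

test_that("correlation screen recovers perfect monotone relations", {
  n <- 12
  p <- tibble::tibble(plot_id = as.character(1:n), sky = (1:n) / n)
  s <- tibble::tibble(plot_id = p$plot_id, OBI = (1:n)^2,
                      EBI = -(1:n), LBI = 1:n, SBI = 1:n)
  sc <- correlation_screen(p, s, features = "sky",
                           outcomes = c("OBI", "EBI"))
  expect_equal(sc$estimate[sc$outcome == "OBI"], 1)
  expect_equal(sc$estimate[sc$outcome == "EBI"], -1)
  expect_equal(unique(sc$method), "spearman")
})

test_that("spearman with ties matches the average-rank oracle", {
  p <- tibble::tibble(plot_id = as.character(1:8),
                      sky = c(0.1, 0.1, 0.2, 0.2, 0.2, 0.3, 0.4, 0.4))
  s <- tibble::tibble(plot_id = p$plot_id,
                      OBI = c(5, 7, 7, 9, 11, 11, 13, 20),
                      EBI = 0, LBI = 0, SBI = 0)
  sc <- suppressWarnings(
    correlation_screen(p, s, features = "sky", outcomes = "OBI"))
  oracle <- cor(rank(p$sky), rank(s$OBI))
  expect_equal(sc$estimate, oracle)
})

test_that("constant features are reported NA with a warning", {
  p <- tibble::tibble(plot_id = as.character(1:5), sky = 0.2)
  s <- tibble::tibble(plot_id = p$plot_id, OBI = rnorm(5))
  expect_warning(sc <- correlation_screen(p, s, features = "sky",
                                          outcomes = "OBI"), "constant")
  expect_true(is.na(sc$estimate))
})

test_that("pearson mode matches cor.test", {
  ps <- profiles_scores()
  sc <- correlation_screen(ps$profiles, ps$scores, method = "pearson",
                           features = "sky", outcomes = "OBI")
  ct <- cor.test(ps$profiles$sky, ps$scores$OBI)
  expect_equal(sc$estimate, unname(ct$estimate))
  expect_equal(sc$p.value, ct$p.value)
})

test_that("orthogonal predictors both get VIF 1 and are retained", {
  x <- rep(c(-1, 1), 10)
  y <- rep(c(-1, -1, 1, 1), 5)
  p <- tibble::tibble(plot_id = as.character(1:20), sky = x, tree = y)
  vf <- vif_filter(p, c("sky", "tree"))
  expect_equal(unname(vf$vif), c(1, 1))
  expect_setequal(vf$retained, c("sky", "tree"))
  # order invariance for orthogonal designs
  vf2 <- vif_filter(p, c("tree", "sky"))
  expect_setequal(vf2$retained, vf$retained)
})

test_that("a duplicated column is dropped as exactly collinear", {
  set.seed(4)
  p <- tibble::tibble(plot_id = as.character(1:20), sky = runif(20))
  p$tree <- p$sky
  p$grass <- runif(20)
  vf <- vif_filter(p, c("sky", "tree", "grass"))
  expect_equal(length(vf$retained), 2)
  expect_true("grass" %in% vf$retained)
  expect_equal(nrow(vf$dropped), 1)
  expect_true(is.infinite(vf$dropped$vif))
})

test_that("VIF at sample correlation 0.9 matches the closed form", {
  # build two predictors with exact sample correlation 0.9
  set.seed(8)
  n <- 40
  a <- rnorm(n)
  b <- rnorm(n)
  b <- residuals(lm(b ~ a))
  std <- function(v) (v - mean(v)) / sd(v)
  x1 <- std(a)
  x2 <- 0.9 * x1 + sqrt(1 - 0.81) * std(b)
  expect_equal(cor(x1, x2), 0.9, tolerance = 1e-12)
  p <- tibble::tibble(plot_id = as.character(1:n), sky = x1, tree = x2)
  vf <- vif_filter(p, c("sky", "tree"))
  expect_equal(unname(vf$vif), rep(1 / (1 - 0.81), 2), tolerance = 1e-3)
  expect_setequal(vf$retained, c("sky", "tree"))
})

test_that("in-package VIF agrees with car::vif", {
  skip_if_not_installed("car")
  set.seed(12)
  n <- 50
  p <- tibble::tibble(plot_id = as.character(1:n),
                      sky = runif(n), tree = runif(n), grass = runif(n))
  p$tree <- p$tree + 0.8 * p$sky
  ours <- vif_values(p, c("sky", "tree", "grass"))
  y <- rnorm(n)
  theirs <- car::vif(lm(y ~ sky + tree + grass, data = p))
  expect_equal(unname(ours), unname(theirs[c("sky", "tree", "grass")]),
               tolerance = 1e-10)
})

test_that("noiseless data from the packaged OBI equation is recovered", {
  ps <- profiles_scores(n = 40, seed = 3)
  fit <- suppressWarnings(
    fit_intensity_model(ps$profiles, ps$scores, "OBI",
                        c("sky", "pavement", "rough_ground")))
  expect_equal(fit$intercept, 281.63, tolerance = 1e-9)
  expect_equal(unname(fit$coefficients),
               c(857.13, 1040.91, -1736.40), tolerance = 1e-9)
  expect_equal(fit$r.squared, 1, tolerance = 1e-12)
})

test_that("degenerate fits behave sensibly", {
  ps <- profiles_scores(n = 25, seed = 6)
  const <- dplyr::mutate(ps$scores, OBI = 7)
  fit <- suppressWarnings(fit_intensity_model(ps$profiles, const, "OBI", "sky"))
  expect_equal(fit$intercept, 7, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients), 0, tolerance = 1e-10)

  line <- dplyr::mutate(ps$scores, OBI = 3 + 2 * ps$profiles$sky)
  fl <- suppressWarnings(fit_intensity_model(ps$profiles, line, "OBI", "sky"))
  expect_equal(fl$intercept, 3, tolerance = 1e-9)
  expect_equal(unname(fl$coefficients["sky"]), 2, tolerance = 1e-9)

  dup <- dplyr::mutate(ps$profiles, tree = sky)
  expect_error(fit_intensity_model(dup, ps$scores, "OBI",
                                   c("sky", "tree")),
               class = "parkscape_fit_error")
})

test_that("OLS residuals are orthogonal to predictors and sum to zero", {
  set.seed(10)
  ps <- profiles_scores(n = 35, seed = 10)
  noisy <- dplyr::mutate(ps$scores, OBI = OBI + rnorm(35, 0, 50))
  fit <- fit_intensity_model(ps$profiles, noisy, "OBI",
                             c("sky", "pavement", "rough_ground"))
  r <- residuals(fit$fitted)
  expect_equal(sum(r), 0, tolerance = 1e-8)
  for (f in c("sky", "pavement", "rough_ground")) {
    expect_equal(sum(r * ps$profiles[[f]]), 0, tolerance = 1e-8)
  }
})

test_that("packaged models carry the published coefficients", {
  m <- reference_models()
  expect_equal(m$LBI$intercept, 119.00)
  expect_equal(unname(m$LBI$coefficients["shrub"]), 585.04)
  expect_equal(unname(m$SBI$coefficients["sky"]), 1261.75)
  expect_equal(unname(m$EBI$coefficients["resting_facility"]), -27547.01)
  expect_equal(m$OBI$intercept, 281.63)
  full <- reference_models_full()
  expect_true("water" %in% names(full$OBI$coefficients))
  expect_equal(unname(full$SBI$coefficients["service_facility"]), 10657.09)
  expect_equal(full$EBI$r.squared, 0.463)
})

test_that("prediction is the affine form, unclamped by default", {
  m <- reference_models()
  zero <- tibble::as_tibble(as.list(setNames(rep(0, 11),
                                             landscape_features())))
  expect_equal(predict(m$OBI, zero), 281.63)
  expect_equal(predict(m$LBI, zero), 119.00)
  expect_equal(predict(m$LBI, tibble::tibble(shrub = 0.10)), 177.504)
  expect_equal(predict(m$EBI, zero), -167.14)
  expect_equal(predict(m$EBI, zero, floor_zero = TRUE), 0)
  expect_error(predict(m$OBI, tibble::tibble(sky = 0.1)),
               "pavement", class = "parkscape_missing_feature")
})

test_that("prediction is linear in the feature vector", {
  m <- reference_models_full()$EBI
  set.seed(14)
  feats <- names(m$coefficients)
  x <- tibble::as_tibble(as.list(setNames(runif(length(feats)), feats)))
  y <- tibble::as_tibble(as.list(setNames(runif(length(feats)), feats)))
  zero <- tibble::as_tibble(as.list(setNames(rep(0, length(feats)), feats)))
  lhs <- predict(m, x + y) - predict(m, zero)
  rhs <- (predict(m, x) - predict(m, zero)) +
    (predict(m, y) - predict(m, zero))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("tidy and glance expose broom-style summaries", {
  ps <- profiles_scores(n = 30, seed = 20)
  fit <- fit_intensity_model(ps$profiles, ps$scores, "EBI",
                             c("sky", "shrub"))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic",
                     "p.value"))
  expect_equal(nrow(td), 3)
  gl <- glance(fit)
  expect_equal(gl$outcome, "EBI")
  expect_lte(gl$adj.r.squared, gl$r.squared)
  # reduced reference models tidy to terms + estimates only
  td_ref <- tidy(reference_models()$LBI)
  expect_equal(td_ref$estimate, c(119.00, 585.04))
})
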