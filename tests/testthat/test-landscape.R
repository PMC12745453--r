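simple_remap <- function() {
  tibble::tibble(class_id = c(1L, 2L, 3L, 4L),
                 feature = c("sky", "tree", "pavement", "other"))
}

test_that("remap_labels turns pixel counts into fractions", {
  all_tree <- matrix(2L, 2, 2)
  fv <- remap_labels(all_tree, simple_remap())
  expect_equal(fv$tree, 1)
  expect_equal(sum(fv[landscape_features()]), 1)

  half_sky <- matrix(c(1L, 1L, 4L, 4L), 2)
  fv2 <- remap_labels(half_sky, simple_remap())
  expect_equal(fv2$sky, 0.5)
  expect_equal(sum(fv2[landscape_features()]), 0.5)
  expect_equal(fv2$other, 0.5)
})

test_that("remap fractions match an independent pixel-count oracle", {
  set.seed(11)
  remap <- default_remap_table()
  for (i in 1:10) {
    m <- matrix(sample(c(remap$class_id, 999L), 100, replace = TRUE),
                10, 10)
    fv <- suppressWarnings(remap_labels(m, remap))
    feat <- remap$feature[match(as.vector(m), remap$class_id)]
    for (f in c("tree", "pavement", "sky")) {
      expect_equal(fv[[f]], sum(feat == f, na.rm = TRUE) / 100)
    }
    # conservation: 11 features + other account for every pixel
    expect_equal(sum(fv[c(landscape_features(), "other")]), 1)
  }
})

test_that("remap is safe under class-id relabelling", {
  set.seed(3)
  remap <- simple_remap()
  m <- matrix(sample(remap$class_id, 36, replace = TRUE), 6)
  fv <- remap_labels(m, remap)
  shift <- 100L
  fv2 <- remap_labels(m + shift,
                      dplyr::mutate(remap, class_id = class_id + shift))
  expect_equal(fv2[-1], fv[-1])
})

test_that("unknown ids warn under default mode and error under strict", {
  m <- matrix(c(1L, 77L), 1)
  expect_warning(fv <- remap_labels(m, simple_remap()), "77")
  expect_equal(fv$other, 0.5)
  expect_error(remap_labels(m, simple_remap(), unknown = "error"),
               class = "parkscape_remap_error")
  expect_error(remap_labels(matrix(integer(), 0, 0), simple_remap()),
               class = "parkscape_invalid_image")
})

test_that("fraction_table matches remap_labels on the same image", {
  set.seed(21)
  remap <- default_remap_table()
  m <- matrix(sample(remap$class_id, 64, replace = TRUE), 8)
  via_map <- remap_labels(m, remap)
  via_table <- fraction_table(via_map[c("image_id", landscape_features())])
  expect_equal(via_table, via_map[names(via_table)])

  row <- tibble::tibble(image_id = "a", sky = 0.2, tree = 0.5)
  ft <- fraction_table(row)
  expect_equal(ft$sky, 0.2)
  expect_equal(ft$grass, 0)
  expect_equal(ft$other, 0.3)
  expect_error(fraction_table(tibble::tibble(sky = 0.7, tree = 0.5)),
               class = "parkscape_fraction_error")
})

test_that("plot aggregation is the per-feature column mean", {
  f1 <- fraction_table(tibble::tibble(image_id = "a", sky = 0.2))
  f2 <- fraction_table(tibble::tibble(image_id = "b", sky = 0.4))
  both <- dplyr::bind_rows(f1, f2) |> dplyr::mutate(plot_id = "P")
  agg <- aggregate_plots(both)
  expect_equal(agg$sky, 0.3)
  expect_equal(agg$n_images, 2)

  # idempotence on identical vectors
  same <- dplyr::bind_rows(f1, f1) |> dplyr::mutate(plot_id = "P")
  expect_equal(aggregate_plots(same)$sky, 0.2)

  # 36 random vectors against a brute-force column average
  set.seed(5)
  rows <- tibble::tibble(image_id = sprintf("i%02d", 1:36),
                         sky = runif(36, 0, 0.3),
                         tree = runif(36, 0, 0.5))
  ft <- fraction_table(rows) |> dplyr::mutate(plot_id = "P")
  agg36 <- aggregate_plots(ft)
  expect_equal(agg36$sky, mean(rows$sky))
  expect_equal(agg36$tree, mean(rows$tree))
  expect_error(aggregate_plots(ft[0, ]), class = "parkscape_fraction_error")
})

test_that("aggregation is consistent across batch splits", {
  set.seed(9)
  rows <- fraction_table(tibble::tibble(image_id = sprintf("i%d", 1:10),
                                        sky = runif(10, 0, 0.5))) |>
    dplyr::mutate(plot_id = "P")
  whole <- aggregate_plots(rows)
  b1 <- aggregate_plots(rows[1:4, ])
  b2 <- aggregate_plots(rows[5:10, ])
  expect_equal((4 * b1$sky + 6 * b2$sky) / 10, whole$sky)
})

test_that("photo protocol plan enumerates plot x point x direction", {
  plan <- photo_protocol_plan(68, 9, 4)
  expect_equal(nrow(plan), 2448)
  expect_equal(nrow(photo_protocol_plan(1, 9, 4)), 36)
  expect_equal(nrow(photo_protocol_plan(1, 1, 1)), 1)
  expect_equal(nrow(dplyr::distinct(plan)), 2448)
  expect_error(photo_protocol_plan(0), class = "parkscape_plan_error")
})

test_that("landscape stats match two-point hand formulas", {
  profs <- fraction_table(
    tibble::tibble(image_id = c("a", "b"), sky = c(0.1, 0.3),
                   tree = c(0.5, 0.5))) |>
    dplyr::mutate(plot_id = c("P1", "P2"), park_id = "U1")
  st <- landscape_stats(profs, group = "park_id")
  sky <- st[st$group == "U1" & st$feature == "sky", ]
  expect_equal(sky$mean, 0.2)
  expect_equal(sky$sd, sd(c(0.1, 0.3)))
  tree <- st[st$group == "U1" & st$feature == "tree", ]
  expect_equal(tree$sd, 0)
  # pooled block present and equal here (single group)
  expect_equal(st[st$group == "Overall" & st$feature == "sky", ]$mean, 0.2)
  # population SD option
  stp <- landscape_stats(profs, group = "park_id", sd_type = "population")
  expect_equal(stp[stp$group == "U1" & stp$feature == "sky", ]$sd,
               sd(c(0.1, 0.3)) * sqrt(1 / 2))

  single <- landscape_stats(profs[1, ], group = "park_id")
  expect_true(all(single$sd == 0))
  expect_true(all(single$sd_degenerate))
})
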