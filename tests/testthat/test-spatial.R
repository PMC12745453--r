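make_points <- function(df) {
  defaults <- tibble::tibble(resolution = 1920L, is_landscape = TRUE)
  out <- dplyr::bind_cols(df, defaults[rep(1, nrow(df)), ])
  if (!"duplicate_key" %in% names(df)) {
    out$duplicate_key <- sprintf("k%03d", seq_len(nrow(df)))
  }
  if (!"image_id" %in% names(df)) {
    out$image_id <- sprintf("img%03d", seq_len(nrow(df)))
  }
  out
}

test_that("image filtering applies resolution, landscape and dedup rules", {
  pts <- tibble::tibble(
    image_id = sprintf("i%02d", 1:10),
    x = 1:10, y = 1:10,
    resolution = c(720L, 1080L, 1920L, 900L, rep(1920L, 6)),
    is_landscape = c(rep(TRUE, 6), FALSE, rep(TRUE, 3)),
    duplicate_key = c(letters[1:8], "h", "j")   # i09 duplicates i08
  )
  flt <- filter_images(pts)
  expect_equal(nrow(flt$points), 6)
  expect_equal(sum(flt$log$n[flt$log$reason != "retained"]), 4)
  expect_equal(flt$log$n[flt$log$reason == "low_resolution"], 2)
  expect_equal(flt$log$n[flt$log$reason == "non_landscape"], 1)
  expect_equal(flt$log$n[flt$log$reason == "duplicate"], 1)
  expect_false("i09" %in% flt$points$image_id)
  # first occurrence of a duplicate key is kept
  expect_true("i08" %in% flt$points$image_id)
  # retained + rejected = input
  expect_equal(nrow(flt$points) + nrow(flt$rejected), nrow(pts))
})

test_that("fishnet tiles a rectangle into the expected cells", {
  cells <- build_fishnet(rect_boundary(90, 60))
  expect_equal(nrow(cells), 6)
  expect_equal(max(cells$col), 3)
  expect_equal(max(cells$row), 2)
  expect_true(all(cells$xmax - cells$xmin == 30))
  one <- build_fishnet(rect_boundary(30, 30))
  expect_equal(nrow(one), 1)
})

test_that("fishnet over an L-shaped park keeps exactly the touched cells", {
  # L-shape: 75 x 75 bbox with the far corner bitten out above/right of 45
  b <- park_boundary(cbind(c(0, 75, 75, 45, 45, 0),
                           c(0, 0, 45, 45, 75, 75)))
  cells <- build_fishnet(b)
  expect_equal(nrow(cells), 8)
  expect_false("r3c3" %in% cells$cell_id)
})

test_that("degenerate and geographic boundaries are rejected", {
  expect_error(park_boundary(cbind(c(0, 1), c(0, 1))),
               class = "parkscape_boundary_error")
  lonlat <- park_boundary(cbind(c(121.4, 121.41, 121.41, 121.4),
                                c(31.2, 31.2, 31.21, 31.21)))
  expect_error(build_fishnet(lonlat), "geographic",
               class = "parkscape_boundary_error")
})

test_that("point assignment follows the half-open convention", {
  cells <- build_fishnet(rect_boundary(60, 60))
  pts <- make_points(tibble::tibble(
    x = c(0, 30, 60, 15),
    y = c(0, 30, 60, 45)
  ))
  asg <- assign_points(pts, cells)
  expect_equal(asg$cell_id[1], "r1c1")   # lower-left corner: its own cell
  expect_equal(asg$cell_id[2], "r2c2")   # shared edge: higher-index cell
  expect_equal(asg$cell_id[3], "r2c2")   # outermost edges closed
  expect_equal(asg$cell_id[4], "r2c1")
})

test_that("assignment matches a brute-force containment scan", {
  set.seed(31)
  b <- park_boundary(cbind(c(0, 75, 75, 45, 45, 0),
                           c(0, 0, 45, 45, 75, 75)))
  cells <- build_fishnet(b)
  pts <- make_points(tibble::tibble(x = runif(100, 0, 90),
                                    y = runif(100, 0, 90)))
  asg <- assign_points(pts, cells)
  oracle <- vapply(seq_len(nrow(pts)), function(i) {
    hits <- which(
      (pts$x[i] >= cells$xmin & pts$x[i] < cells$xmax |
         (pts$x[i] == cells$xmax & cells$col == max(cells$col))) &
      (pts$y[i] >= cells$ymin & pts$y[i] < cells$ymax |
         (pts$y[i] == cells$ymax & cells$row == max(cells$row))))
    if (length(hits) == 0) NA_character_ else cells$cell_id[hits]
  }, character(1))
  expect_equal(asg$cell_id, oracle)
  # partition: every point inside the grid hits exactly one cell
  log <- attr(asg, "assignment_log")
  expect_equal(sum(log$n), 100)
})

test_that("cell features are point means and empty cells stay no-data", {
  cells <- build_fishnet(rect_boundary(60, 30))
  pts <- make_points(tibble::tibble(x = c(5, 10, 40), y = c(5, 10, 40)))
  pts <- dplyr::bind_cols(
    pts,
    fraction_table(tibble::tibble(image_id = pts$image_id,
                                  sky = c(0.1, 0.3, 0.8)))[-1])
  asg <- assign_points(pts, cells)
  cf <- cell_features(cells, asg)
  expect_equal(cf$sky[cf$cell_id == "r1c1"], 0.2)
  expect_equal(cf$n_points[cf$cell_id == "r1c2"], 0)
  expect_true(is.na(cf$sky[cf$cell_id == "r1c2"]))
})

test_that("cell predictions follow the packaged equations", {
  cells <- build_fishnet(rect_boundary(60, 30))
  zero <- fraction_table(tibble::tibble(image_id = "z"))[-1]
  pts <- make_points(tibble::tibble(x = c(5, 40), y = c(5, 5)))
  pts <- dplyr::bind_cols(pts, dplyr::bind_rows(zero, zero))
  pts$sky[2] <- 0.5
  cf <- cell_features(cells, assign_points(pts, cells))
  pred <- predict_cells(cf, reference_models())
  expect_equal(pred$OBI[pred$cell_id == "r1c1"], 281.63)
  expect_equal(pred$SBI[pred$cell_id == "r1c1"], -106.58)
  expect_equal(pred$SBI[pred$cell_id == "r1c2"], -106.58 + 1261.75 * 0.5)
  expect_true(all(is.na(pred$OBI[pred$n_points == 0])))
})

test_that("classification labels data cells and skips empty ones", {
  cells <- build_fishnet(rect_boundary(90, 60))
  set.seed(41)
  pts <- make_points(tibble::tibble(x = runif(40, 0, 90),
                                    y = runif(40, 0, 60)))
  pts <- dplyr::bind_cols(
    pts, fraction_table(tibble::tibble(image_id = pts$image_id,
                                       sky = runif(40, 0, 0.4)))[-1])
  cl <- suppressWarnings(
    cell_features(cells, assign_points(pts, cells)) |>
      predict_cells() |>
      classify_cells(k = 3))
  expect_true(all(cl$class_OBI[cl$n_points > 0] %in% 1:3))
  expect_true(all(is.na(cl$class_OBI[cl$n_points == 0])))
  br <- attr(cl, "breaks")
  expect_s3_class(br$OBI, "jenks_breaks")
  # class labels increase with score
  ok <- !is.na(cl$OBI)
  expect_gte(min(diff(cl$class_OBI[ok][order(cl$OBI[ok])])), 0)
})

test_that("translation leaves assignment, means and classes unchanged", {
  set.seed(51)
  pts <- make_points(tibble::tibble(x = runif(30, 0, 90),
                                    y = runif(30, 0, 60)))
  pts <- dplyr::bind_cols(
    pts, fraction_table(tibble::tibble(image_id = pts$image_id,
                                       sky = runif(30, 0, 0.4)))[-1])
  run <- function(dx, dy) {
    b <- rect_boundary(90, 60, dx, dy)
    p <- dplyr::mutate(pts, x = x + dx, y = y + dy)
    cl <- cell_features(build_fishnet(b), assign_points(p, build_fishnet(b)))
    cl <- suppressWarnings(classify_cells(predict_cells(cl), k = 3))
    cl[c("cell_id", "row", "col", "n_points", "sky", "OBI", "class_OBI")]
  }
  expect_equal(run(0, 0), run(1500, -2400))
})
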