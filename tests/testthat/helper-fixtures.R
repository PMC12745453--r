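# in-code fixtures shared across test files

# minimal MET table with easy arithmetic
fixture_met <- function() {
  tibble::tibble(
    code = c(101L, 106L, 112L, 201L, 202L, 205L, 301L, 302L, 307L),
    met = c(2.5, 3.0, 4.0, 1.0, 1.5, 3.5, 1.5, 2.0, 5.0)
  )
}

fixture_records <- function() {
  tibble::tibble(
    plot_id = c("P1", "P1", "P1", "P2"),
    session = "weekday-am",
    code = c(106L, 202L, 302L, 112L),
    count = c(5L, 4L, 2L, 3L),
    age_group = c("older_adult", "adult", "older_adult", "child"),
    gender = c("female", "male", "female", "female"),
    observer_id = "obs-1"
  )
}

# random records over the full taxonomy, one plot per set
random_records <- function(n_plots, max_rows = 8, seed = 1) {
  set.seed(seed)
  tax <- parkscape::behavior_taxonomy()
  purrr::map_dfr(seq_len(n_plots), function(i) {
    n <- sample.int(max_rows, 1)
    tibble::tibble(
      plot_id = sprintf("rp%04d", i),
      code = sample(tax$code, n, replace = TRUE),
      count = sample(0:20, n, replace = TRUE)
    )
  })
}

# exhaustive Fisher-partition oracle: minimal within-class SSD over all
# contiguous k-partitions of the sorted values
oracle_jenks_ssw <- function(values, k) {
  v <- sort(values)
  n <- length(v)
  ssd <- function(x) sum((x - mean(x))^2)
  if (k == 1) return(ssd(v))
  best <- Inf
  splits <- utils::combn(n - 1, k - 1, simplify = FALSE)
  for (s in splits) {
    idx <- c(0, s, n)
    cost <- sum(vapply(seq_len(k), function(i) {
      ssd(v[(idx[i] + 1):idx[i + 1]])
    }, numeric(1)))
    if (cost < best) best <- cost
  }
  best
}

# square test boundary helpers
rect_boundary <- function(w, h, x0 = 0, y0 = 0) {
  parkscape::park_boundary(
    cbind(c(x0, x0 + w, x0 + w, x0), c(y0, y0, y0 + h, y0 + h)))
}
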