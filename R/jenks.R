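#' Jenks natural-breaks classification
#'
#' Optimal one-dimensional classification into `k` classes minimising the
#' total within-class sum of squared deviations (Fisher's dynamic-
#' programming partition of the sorted values). The result is deterministic:
#' among equally optimal partitions the one with the smaller upper class is
#' chosen. The goodness of variance fit
#' `GVF = 1 - SSD_within / SSD_total` is reported (0 for `k = 1` by
#' convention, 1 when every class is a single distinct value).
#'
#' @param values Numeric vector (at least `k` distinct finite values).
#' @param k Number of classes (>= 1).
#' @return A list of class `jenks_breaks`: `k`, `breaks` (the `k + 1`
#'   class boundaries: minimum, the k-1 interior cuts at class maxima,
#'   maximum), `gvf`, and `classes` (integer class label in `1..k` for each
#'   input value; class 1 holds the smallest values).
#' @export
#' @examples
#' jenks_breaks(c(1, 2, 3, 10, 11, 12), k = 2)$classes
jenks_breaks <- function(values, k) {
  if (length(k) != 1 || is.na(k) || k < 1) {
    ps_abort("k must be a positive integer", "parkscape_jenks_error")
  }
  k <- as.integer(k)
  if (any(!is.finite(values))) {
    ps_abort("values must be finite", "parkscape_jenks_error")
  }
  n_distinct <- length(unique(values))
  if (n_distinct < k) {
    ps_abort(paste0("k = ", k, " exceeds the ", n_distinct,
                    " distinct value(s)"),
             "parkscape_jenks_error")
  }
  ord <- sort(values)
  n <- length(ord)
  cs <- cumsum(ord)
  cs2 <- cumsum(ord^2)
  # within-class SSD of sorted[i..j]
  ssd <- function(i, j) {
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    m <- j - i + 1
    max(0, s2 - s^2 / m)
  }
  # cost[c, j]: minimal SSD of first j values in c classes
  cost <- matrix(Inf, k, n)
  from <- matrix(NA_integer_, k, n)
  for (j in 1:n) cost[1, j] <- ssd(1, j)
  if (k > 1) {
    for (cl in 2:k) {
      for (j in cl:n) {
        best <- Inf
        arg <- NA_integer_
        for (s in (cl - 1):(j - 1)) {   # previous class ends at s
          cand <- cost[cl - 1, s] + ssd(s + 1, j)
          if (cand <= best) {           # ties -> larger s: smaller upper class
            best <- cand
            arg <- s
          }
        }
        cost[cl, j] <- best
        from[cl, j] <- arg
      }
    }
  }
  # recover class end-indices
  ends <- integer(k)
  j <- n
  for (cl in k:1) {
    ends[cl] <- j
    j <- if (cl > 1) from[cl, j] else 0L
  }
  cuts <- ord[ends]                    # class maxima, strictly increasing
  breaks <- c(ord[1], cuts)
  # class membership is by value <= its class maximum
  labels <- vapply(values, function(v) {
    which(v <= cuts + 1e-12)[1]
  }, integer(1))
  sst <- sum((values - mean(values))^2)
  ssw <- cost[k, n]
  gvf <- if (k == 1 || sst == 0) {
    if (k == 1) 0 else 1
  } else {
    1 - ssw / sst
  }
  structure(list(k = k, breaks = breaks, gvf = gvf, classes = labels,
                 ssd_within = ssw, ssd_total = sst),
            class = "jenks_breaks")
}

#' @export
print.jenks_breaks <- function(x, ...) {
  cat("<jenks_breaks> k =", x$k, " gvf =", format(x$gvf, digits = 4), "\n")
  cat("  breaks:", paste(format(x$breaks, digits = 6), collapse = " | "),
      "\n")
  invisible(x)
}
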