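#' Jenks natural-breaks classification
#'
#' Exact Fisher-Jenks optimal 1-D classification: partitions sorted values
#' into `k` contiguous classes minimizing the total within-class sum of
#' squared deviations. Implemented as dynamic programming over class counts
#' with O(1) segment costs from prefix sums (exact optimum, not the
#' iterative heuristic). Ties between equally optimal partitions are broken
#' toward the smallest upper bound of the lower class.
#'
#' @param values numeric vector (NAs dropped); needs at least `k` distinct
#'   values.
#' @param k number of classes, >= 2.
#' @return An object of class `temperature_levels`: list with `breaks` (the
#'   k-1 interior break values, ascending), `k`, and `wss` (the minimized
#'   total within-class sum of squares).
#' @examples
#' jenks_breaks(c(1, 2, 3, 10, 11, 12), k = 2)$breaks # splits 3 | 10
#' @export
jenks_breaks <- function(values, k) {
  x <- sort(as.numeric(values[!is.na(values)]))
  n <- length(x)
  stopifnot(k >= 2)
  if (length(unique(x)) < k)
    stop("need at least ", k, " distinct values for ", k, " classes")
  # segment cost SSD(i..j) in O(1): sum of squares about the segment mean
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  seg_cost <- function(i, j) {
    # vectorized over i
    s <- cs[j] - ifelse(i > 1, cs[i - 1], 0)
    s2 <- cs2[j] - ifelse(i > 1, cs2[i - 1], 0)
    m <- j - i + 1
    pmax(s2 - s^2 / m, 0)
  }
  # D[c, j]: minimal cost of splitting x[1..j] into c classes
  D <- matrix(Inf, k, n)
  split_at <- matrix(0L, k, n) # first index of the last class
  D[1, ] <- seg_cost(1L, seq_len(n))
  split_at[1, ] <- 1L
  for (cc in 2:k) {
    for (j in cc:n) {
      i <- cc:j # candidate start of the last class
      tot <- D[cc - 1, i - 1] + seg_cost(i, j)
      best <- which.min(tot) # earliest minimizer: smallest upper bound below
      D[cc, j] <- tot[best]
      split_at[cc, j] <- i[best]
    }
  }
  # backtrack class boundaries
  starts <- integer(k)
  j <- n
  for (cc in k:1) {
    starts[cc] <- split_at[cc, j]
    j <- starts[cc] - 1L
  }
  breaks <- x[starts[-1] - 1L] # upper bound of each lower class
  structure(list(breaks = breaks, k = k, wss = D[k, n]),
            class = "temperature_levels")
}

#' @export
print.temperature_levels <- function(x, ...) {
  cat(sprintf("<temperature_levels> %d classes, interior breaks: %s (wss %.4g)\n",
              x$k, paste(signif(x$breaks, 6), collapse = ", "), x$wss))
  invisible(x)
}

#' Temperature levels from explicit breakpoints
#'
#' Wraps a set of interior breakpoints (e.g. natural breaks computed
#' elsewhere) for use with [classify_lst()].
#'
#' @param breaks strictly ascending numeric vector of interior breakpoints;
#'   `k - 1` values define `k` classes.
#' @return `temperature_levels` object.
#' @export
temperature_levels <- function(breaks) {
  breaks <- as.numeric(breaks)
  stopifnot(length(breaks) >= 1, !is.unsorted(breaks, strictly = TRUE))
  structure(list(breaks = breaks, k = length(breaks) + 1L, wss = NA_real_),
            class = "temperature_levels")
}

#' Five-level LST class labels
#' @return Character vector: low, mild_low, medium, sub_high, high.
#' @export
lst_level_labels <- function() c("low", "mild_low", "medium", "sub_high", "high")

#' Classify an LST grid into temperature levels
#'
#' Assigns each cell to a class by the interior breakpoints. Intervals are
#' lower-closed / upper-open, so a cell exactly on a break goes to the upper
#' class; the top class is closed above. With 5 classes the labels are
#' low, mild_low, medium, sub_high, high.
#'
#' @param lst `raster_grid` (or numeric vector) of LST.
#' @param levels `temperature_levels`.
#' @return Integer matrix (or vector) of class indices 1..k, with the level
#'   labels attached as attribute `labels` when k = 5.
#' @examples
#' lv <- temperature_levels(c(28.32, 30.15, 31.56, 33.23))
#' classify_lst(c(24.73, 30.15, 37.63), lv) # 1, 3, 5
#' @export
classify_lst <- function(lst, levels) {
  idx <- findInterval(as.numeric(lst), levels$breaks) + 1L
  out <- if (is.matrix(lst)) matrix(idx, nrow(lst), ncol(lst)) else idx
  if (levels$k == 5L) attr(out, "labels") <- lst_level_labels()
  out
}
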