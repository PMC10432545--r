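# shared fixture builders

# tiny constant-value grid
const_grid <- function(value, nr = 4, nc = 4, cell = 30) {
  raster_grid(matrix(value, nr, nc), cell)
}

# small scene spec with one canopy rectangle on impervious background
one_rect_spec <- function(nr = 20, nc = 20, sd_lst = 0, seed = 7L) {
  scene_spec(
    nr, nc, cell_size = 10,
    class_layout = list(scene_rect("tree_canopy", 5L, 5L, 10L, 10L)),
    per_class_lst = list(tree_canopy = c(29.98, sd_lst),
                         impervious = c(31.44, sd_lst)),
    per_class_ndvi = list(tree_canopy = c(0.7, 0), impervious = c(0.05, 0)),
    seed = seed)
}

# brute-force Jenks oracle: minimal within-class SS over all contiguous
# partitions of the sorted values into k classes (prefix sums keep the
# enumeration fast enough for n <= 25)
jenks_oracle_wss <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  segc <- function(i, j) { # SS of x[i..j] about its mean
    s <- cs[j + 1] - cs[i]
    (cs2[j + 1] - cs2[i]) - s^2 / (j - i + 1)
  }
  splits <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (col in seq_len(ncol(splits))) {
    cut_at <- c(0, splits[, col], n)
    tot <- 0
    for (cc in seq_len(k)) tot <- tot + segc(cut_at[cc] + 1, cut_at[cc + 1])
    if (tot < best) best <- tot
  }
  max(best, 0)
}

# within-class SS realised by a set of interior break values
wss_of_breaks <- function(values, breaks) {
  x <- sort(values)
  cls <- findInterval(x, breaks, left.open = TRUE) + 1L
  sum(vapply(split(x, cls), function(s) sum((s - mean(s))^2), numeric(1)))
}
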