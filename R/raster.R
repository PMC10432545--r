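#' Raster grid
#'
#' Lightweight carrier for a single-band raster: a numeric matrix (row-major,
#' 0-based cell indexing in the patch routines) plus the cell size in metres.
#' `NA` is the nodata sentinel and propagates through every arithmetic stage.
#'
#' @param values numeric matrix of cell values.
#' @param cell_size side length of a square cell, metres. Must be > 0.
#' @return An object of class `raster_grid`: the matrix with a `cell_size`
#'   attribute.
#' @examples
#' g <- raster_grid(matrix(1:6, 2, 3), cell_size = 30)
#' cell_size(g)
#' @export
raster_grid <- function(values, cell_size) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(is.numeric(cell_size), length(cell_size) == 1L, cell_size > 0)
  structure(values, cell_size = as.numeric(cell_size),
            class = c("raster_grid", "matrix", "array"))
}

#' @rdname raster_grid
#' @param x a `raster_grid` or `land_cover_map`.
#' @export
cell_size <- function(x) attr(x, "cell_size")

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid> %d x %d cells, cell %g m, %d nodata\n",
              nrow(x), ncol(x), cell_size(x), sum(is.na(x))))
  rng <- suppressWarnings(range(x, na.rm = TRUE))
  if (all(is.finite(rng))) cat(sprintf("  values in [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

# Two grids live on the same geometry: same dims and cell size.
check_congruent <- function(...) {
  gs <- list(...)
  d <- dim(gs[[1]]); cs <- cell_size(gs[[1]])
  for (g in gs[-1]) {
    if (!identical(dim(g), d))
      stop("grids are not congruent: dimensions differ (",
           paste(d, collapse = "x"), " vs ", paste(dim(g), collapse = "x"), ")")
    if (!isTRUE(all.equal(cell_size(g), cs)))
      stop("grids are not congruent: cell sizes differ")
  }
  invisible(TRUE)
}

#' Land-cover classes
#'
#' The five-class legend used throughout: water body, tree canopy, grassland,
#' bare land, and impervious surface (buildings, roads).
#'
#' @return Character vector of the five class labels, in legend order.
#' @export
landcover_classes <- function() {
  c("water", "tree_canopy", "grassland", "bare_land", "impervious")
}

#' Categorical land-cover map
#'
#' A categorical grid over a fixed legend, sharing geometry with the rasters
#' it overlays. Stored as an integer matrix of legend indices.
#'
#' @param values integer matrix of legend indices, or character matrix of
#'   class labels. `NA` = nodata.
#' @param cell_size cell side, metres.
#' @param legend character vector of class labels; defaults to the five-class
#'   urban legend of [landcover_classes()].
#' @return An object of class `land_cover_map`.
#' @examples
#' m <- land_cover_map(matrix(c(1, 2, 2, 5), 2, 2), cell_size = 30)
#' table(landcover_labels(m))
#' @export
land_cover_map <- function(values, cell_size, legend = landcover_classes()) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.character(values)) {
    idx <- match(values, legend)
    if (any(is.na(idx) & !is.na(values)))
      stop("unknown class label(s): ",
           paste(unique(values[is.na(idx) & !is.na(values)]), collapse = ", "))
    values <- matrix(idx, nrow(values), ncol(values))
  }
  storage.mode(values) <- "integer"
  bad <- !is.na(values) & (values < 1L | values > length(legend))
  if (any(bad)) stop("class index outside the legend at ", sum(bad), " cell(s)")
  stopifnot(cell_size > 0)
  structure(values, cell_size = as.numeric(cell_size), legend = legend,
            class = c("land_cover_map", "matrix", "array"))
}

#' @rdname land_cover_map
#' @param x a `land_cover_map`.
#' @export
landcover_legend <- function(x) attr(x, "legend")

#' @rdname land_cover_map
#' @export
landcover_labels <- function(x) {
  matrix(landcover_legend(x)[as.integer(x)], nrow(x), ncol(x))
}

#' @export
print.land_cover_map <- function(x, ...) {
  cat(sprintf("<land_cover_map> %d x %d cells, cell %g m\n",
              nrow(x), ncol(x), cell_size(x)))
  tab <- table(factor(landcover_legend(x)[as.integer(x)],
                      levels = landcover_legend(x)))
  print(tab)
  invisible(x)
}

#' Read and write delimited-text grids
#'
#' Plain-text raster exchange: a two-line header (`cell_size`, `nrows ncols`)
#' followed by whitespace-delimited rows. `NA` encodes nodata. Lossless at
#' the printed precision (17 significant digits, i.e. full double).
#'
#' @param x a `raster_grid` (or `land_cover_map` for [write_grid()]).
#' @param path file path.
#' @return [read_grid()] returns a `raster_grid`; [write_grid()] returns
#'   `path` invisibly.
#' @export
write_grid <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("cell_size %.17g", cell_size(x)),
               sprintf("dim %d %d", nrow(x), ncol(x))), con)
  m <- matrix(as.numeric(x), nrow(x), ncol(x))
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  hdr <- readLines(path, n = 2L)
  cs <- as.numeric(strsplit(hdr[1], " ")[[1]][2])
  dm <- as.integer(strsplit(hdr[2], " ")[[1]][2:3])
  m <- as.matrix(utils::read.table(path, skip = 2L, header = FALSE,
                                   na.strings = "NA"))
  dimnames(m) <- NULL
  if (!identical(dim(m), dm)) stop("grid body does not match header dimensions")
  raster_grid(m, cs)
}
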