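#' Canopy patch size classes
#'
#' Area thresholds (hm2; 1 hm2 = 10 000 m2) for the five patch size levels:
#' small <= 0.05 < medium <= 0.20 < large <= 1.00 < super_large <= 5.00 <
#' extra_large. Boundaries are inclusive on the lower class.
#'
#' @param area_hm2 numeric vector of patch areas in hm2, > 0.
#' @param thresholds upper bounds (hm2) of the first four classes.
#' @return factor with levels small, medium, large, super_large,
#'   extra_large.
#' @examples
#' classify_size(c(0.05, 0.12, 5.00, 5.01))
#' @export
classify_size <- function(area_hm2,
                          thresholds = c(small = 0.05, medium = 0.20,
                                         large = 1.00, super_large = 5.00)) {
  if (any(is.na(area_hm2)) || any(area_hm2 <= 0))
    stop("patch areas must be positive")
  labs <- size_class_labels()
  idx <- findInterval(area_hm2, thresholds, left.open = TRUE) + 1L
  factor(labs[idx], levels = labs)
}

#' @rdname classify_size
#' @export
size_class_labels <- function() {
  c("small", "medium", "large", "super_large", "extra_large")
}

#' Patch shape index
#'
#' Perimeter of the patch normalized by the perimeter of the circle of equal
#' area, `A = E / (2 sqrt(pi S))` with perimeter E and area S in
#' metre-based units (m, m2). Equals 1 for a circle; a square gives
#' 2/sqrt(pi) ~ 1.1284 regardless of size; larger values mean more
#' convoluted outlines.
#'
#' @param perimeter_m patch perimeter, metres, > 0.
#' @param area_m2 patch area, square metres, > 0.
#' @return unitless shape index.
#' @examples
#' shape_index(25170, 653200) # 8.79: the largest Luoping forest-park patch
#' @export
shape_index <- function(perimeter_m, area_m2) {
  if (any(perimeter_m <= 0) || any(area_m2 <= 0))
    stop("perimeter and area must be positive")
  perimeter_m / (2 * sqrt(pi * area_m2))
}

# logical mask -> exposed-edge count (cell edges adjacent to a non-member
# cell or the grid boundary)
mask_edge_count <- function(mask) {
  mask[is.na(mask)] <- FALSE
  nr <- nrow(mask); nc <- ncol(mask)
  up <- rbind(FALSE, mask[-nr, , drop = FALSE])
  down <- rbind(mask[-1, , drop = FALSE], FALSE)
  left <- cbind(FALSE, mask[, -nc, drop = FALSE])
  right <- cbind(mask[, -1, drop = FALSE], FALSE)
  sum(mask & !up) + sum(mask & !down) + sum(mask & !left) + sum(mask & !right)
}

#' Raster patch perimeter
#'
#' Exposed-cell-edge perimeter of a cell mask: every edge of a member cell
#' that borders a non-member cell or the grid boundary contributes one cell
#' side. This raster-native perimeter exceeds the smoothed vector perimeter
#' of the same region, so metrics derived from it are compared against
#' synthetic geometry, not against vector-digitized tables.
#'
#' @param mask logical matrix, `TRUE` for member cells.
#' @param cell_size cell side, metres.
#' @return perimeter in metres.
#' @examples
#' patch_perimeter(matrix(TRUE, 10, 10), cell_size = 1) # 40
#' @export
patch_perimeter <- function(mask, cell_size) {
  stopifnot(any(mask, na.rm = TRUE), cell_size > 0)
  mask_edge_count(mask) * cell_size
}

#' Extract patches of one land-cover class
#'
#' Maximal connected components of the target class, under 4- (edge) or 8-
#' (edge + corner) connectivity. The default 8 treats diagonally touching
#' crowns as one contiguous canopy, matching object-based canopy
#' delineation practice. Components are found on the adjacency graph of the
#' target cells (igraph).
#'
#' @param landcover a [land_cover_map()].
#' @param target_class class label, default `"tree_canopy"`.
#' @param connectivity 4 or 8.
#' @param lst optional congruent LST `raster_grid`; adds per-patch mean LST.
#' @param bare_mean_lst optional scene-wide bare-land mean LST (degC); with
#'   `lst` adds the per-patch cooling rate (see [cooling_rate()]).
#' @return A data.frame of class `patch_table`, one row per patch, ordered
#'   by decreasing area: `patch_no`, `n_cells`, `area_m2`, `area_hm2`,
#'   `perimeter_m`, `perimeter_km`, `shape_index`, `size_class`, and when
#'   LST is supplied `mean_lst_c` (+ `cooling_rate_pct` with a baseline).
#'   The list of cell masks is attached as attribute `masks`.
#' @examples
#' m <- land_cover_map(matrix(c(2, 5, 5, 2), 2, 2), cell_size = 10)
#' extract_patches(m, connectivity = 4) # two 1-cell patches
#' extract_patches(m, connectivity = 8) # one 2-cell patch
#' @export
extract_patches <- function(landcover, target_class = "tree_canopy",
                            connectivity = 8, lst = NULL,
                            bare_mean_lst = NULL) {
  legend <- landcover_legend(landcover)
  id <- match(target_class, legend)
  if (is.na(id)) stop("unknown class: ", target_class)
  stopifnot(connectivity %in% c(4, 8))
  if (!is.null(lst)) check_congruent(landcover, lst)
  nr <- nrow(landcover); nc <- ncol(landcover)
  cells <- which(unclass(landcover) == id)
  cs <- cell_size(landcover)
  empty <- patch_table_frame(NULL, cs, lst = lst, bare_mean_lst = bare_mean_lst)
  if (length(cells) == 0L) return(empty)

  comp <- label_components(cells, nr, nc, connectivity)
  masks <- lapply(split(cells, comp), function(ix) {
    m <- matrix(FALSE, nr, nc); m[ix] <- TRUE; m
  })
  patch_table_frame(masks, cs, lst = lst, bare_mean_lst = bare_mean_lst)
}

# connected components of a cell-index set via the adjacency graph
label_components <- function(cells, nr, nc, connectivity) {
  pos <- integer(nr * nc)
  pos[cells] <- seq_along(cells)
  r <- ((cells - 1L) %% nr) + 1L
  c_ <- ((cells - 1L) %/% nr) + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  edges <- list()
  for (o in offs) {
    r2 <- r + o[1]; c2 <- c_ + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- pos[nb] > 0L
    edges[[length(edges) + 1L]] <-
      cbind(pos[cells[ok]][hit], pos[nb][hit])
  }
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(cells), directed = FALSE)
  if (NROW(el)) g <- igraph::add_edges(g, t(el))
  igraph::components(g)$membership
}

patch_table_frame <- function(masks, cs, lst = NULL, bare_mean_lst = NULL) {
  if (is.null(masks) || length(masks) == 0L) {
    out <- data.frame(patch_no = integer(), n_cells = integer(),
                      area_m2 = numeric(), area_hm2 = numeric(),
                      perimeter_m = numeric(), perimeter_km = numeric(),
                      shape_index = numeric(),
                      size_class = factor(character(),
                                          levels = size_class_labels()))
    if (!is.null(lst)) out$mean_lst_c <- numeric()
    if (!is.null(lst) && !is.null(bare_mean_lst))
      out$cooling_rate_pct <- numeric()
    class(out) <- c("patch_table", "data.frame")
    attr(out, "masks") <- list()
    return(out)
  }
  n_cells <- vapply(masks, sum, integer(1))
  area_m2 <- n_cells * cs^2
  perim_m <- vapply(masks, mask_edge_count, numeric(1)) * cs
  ord <- order(-area_m2)
  masks <- masks[ord]; n_cells <- n_cells[ord]
  area_m2 <- area_m2[ord]; perim_m <- perim_m[ord]
  out <- data.frame(
    patch_no = seq_along(masks),
    n_cells = n_cells,
    area_m2 = area_m2,
    area_hm2 = area_m2 / 1e4,
    perimeter_m = perim_m,
    perimeter_km = perim_m / 1e3,
    shape_index = shape_index(perim_m, area_m2),
    size_class = classify_size(area_m2 / 1e4),
    row.names = NULL)
  if (!is.null(lst)) {
    out$mean_lst_c <- vapply(masks, function(m) mean(lst[m], na.rm = TRUE),
                             numeric(1))
    if (!is.null(bare_mean_lst))
      out$cooling_rate_pct <- cooling_rate(out$mean_lst_c, bare_mean_lst)
  }
  class(out) <- c("patch_table", "data.frame")
  attr(out, "masks") <- masks
  out
}

#' Patch composition summary by size level
#'
#' Per size-class counts, total area, share of the total patch area, and
#' (when available) area-weighted mean LST — the hierarchical composition
#' table of a canopy patch mosaic.
#'
#' @param patches a `patch_table` (from [extract_patches()] or
#'   [load_patch_table()]), or any data.frame with `area_hm2` and either
#'   `size_class` or enough to derive it; optional `mean_lst_c`.
#' @return data.frame with one row per size level plus a `total` row:
#'   `level`, `n_patches`, `area_hm2`, `area_pct`, and `mean_lst_c` when
#'   LST is present. Shares sum to 100 up to rounding.
#' @export
patch_level_summary <- function(patches) {
  stopifnot(nrow(patches) > 0)
  sc <- if ("size_class" %in% names(patches)) patches$size_class
        else classify_size(patches$area_hm2)
  sc <- factor(sc, levels = size_class_labels())
  n <- as.integer(table(sc))
  area <- as.numeric(tapply(patches$area_hm2, sc, sum, default = 0))
  tot <- sum(patches$area_hm2)
  out <- data.frame(level = size_class_labels(), n_patches = n,
                    area_hm2 = area, area_pct = 100 * area / tot)
  if ("mean_lst_c" %in% names(patches)) {
    wmean <- function(i) {
      sel <- which(as.integer(sc) == i)
      if (!length(sel)) return(NA_real_)
      stats::weighted.mean(patches$mean_lst_c[sel], patches$area_hm2[sel])
    }
    out$mean_lst_c <- vapply(seq_along(size_class_labels()), wmean, numeric(1))
  }
  total_row <- data.frame(level = "total", n_patches = sum(n),
                          area_hm2 = tot, area_pct = 100)
  if ("mean_lst_c" %in% names(out)) total_row$mean_lst_c <- NA_real_
  rbind(out, total_row)
}
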