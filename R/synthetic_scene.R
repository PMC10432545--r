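#' Scene specification for the synthetic-scene generator
#'
#' Describes a synthetic urban scene: a categorical mosaic painted from
#' shape primitives over a background class, with per-class LST and NDVI
#' distributions. Later shapes overwrite earlier ones (painter's rule), so
#' overlaps are not an error; a shape that exceeds the grid bounds is.
#'
#' @param n_rows,n_cols grid dimensions, positive integers.
#' @param cell_size cell side, metres.
#' @param class_layout list of shapes from [scene_rect()] / [scene_disc()],
#'   painted in order over the background.
#' @param per_class_lst named list/vector pairs: for each class,
#'   `c(mean, sd)` of LST in degrees Celsius (sd >= 0).
#' @param per_class_ndvi named list: for each class, `c(mean, sd)` of NDVI;
#'   draws are clipped to \[-1, 1\].
#' @param background_class class label for unpainted cells.
#' @param seed integer seed; the generator is bit-reproducible given the
#'   full spec.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(n_rows, n_cols, cell_size = 30,
                       class_layout = list(),
                       per_class_lst,
                       per_class_ndvi,
                       background_class = "impervious",
                       seed = 1L) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0)
  lst_sd <- vapply(per_class_lst, `[`, numeric(1), 2L)
  ndvi_sd <- vapply(per_class_ndvi, `[`, numeric(1), 2L)
  if (any(lst_sd < 0) || any(ndvi_sd < 0)) stop("all sd must be >= 0")
  cls <- union(background_class,
               vapply(class_layout, function(s) s$class, character(1)))
  missing_lst <- setdiff(cls, names(per_class_lst))
  if (length(missing_lst)) stop("no LST distribution for: ",
                                paste(missing_lst, collapse = ", "))
  missing_ndvi <- setdiff(cls, names(per_class_ndvi))
  if (length(missing_ndvi)) stop("no NDVI distribution for: ",
                                 paste(missing_ndvi, collapse = ", "))
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size = cell_size, class_layout = class_layout,
                 per_class_lst = per_class_lst,
                 per_class_ndvi = per_class_ndvi,
                 background_class = background_class,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Layout shapes
#'
#' Axis-aligned rectangle / disc primitives for [scene_spec()]. Positions
#' are 1-based cell indices (row, col).
#'
#' @param class class label the shape paints.
#' @param row,col top-left cell of the rectangle / centre of the disc.
#' @param height,width rectangle extent in cells.
#' @param radius disc radius in cells; a cell belongs to the disc when its
#'   centre is within `radius` cells of the centre cell.
#' @return Shape descriptor list.
#' @export
scene_rect <- function(class, row, col, height, width) {
  stopifnot(height >= 1, width >= 1)
  list(kind = "rect", class = class, row = as.integer(row),
       col = as.integer(col), height = as.integer(height),
       width = as.integer(width))
}

#' @rdname scene_rect
#' @export
scene_disc <- function(class, row, col, radius) {
  stopifnot(radius > 0)
  list(kind = "disc", class = class, row = as.integer(row),
       col = as.integer(col), radius = radius)
}

paint_layout <- function(spec) {
  legend <- landcover_classes()
  cls <- matrix(match(spec$background_class, legend),
                spec$n_rows, spec$n_cols)
  for (s in spec$class_layout) {
    id <- match(s$class, legend)
    if (is.na(id)) stop("unknown class in layout: ", s$class)
    if (s$kind == "rect") {
      r2 <- s$row + s$height - 1L; c2 <- s$col + s$width - 1L
      if (s$row < 1L || s$col < 1L || r2 > spec$n_rows || c2 > spec$n_cols)
        stop(sprintf("rect '%s' at (%d,%d) size %dx%d exceeds the %dx%d grid",
                     s$class, s$row, s$col, s$height, s$width,
                     spec$n_rows, spec$n_cols))
      cls[s$row:r2, s$col:c2] <- id
    } else {
      if (s$row - s$radius < 1 || s$col - s$radius < 1 ||
          s$row + s$radius > spec$n_rows || s$col + s$radius > spec$n_cols)
        stop(sprintf("disc '%s' at (%d,%d) radius %g exceeds the %dx%d grid",
                     s$class, s$row, s$col, s$radius,
                     spec$n_rows, spec$n_cols))
      rr <- outer(seq_len(spec$n_rows) - s$row, seq_len(spec$n_cols) - s$col,
                  function(a, b) a^2 + b^2)
      cls[rr <= s$radius^2] <- id
    }
  }
  cls
}

#' Generate a synthetic scene
#'
#' Paints the land-cover mosaic, draws a ground-truth LST field and per-cell
#' NDVI from the per-class Gaussian distributions (independent cells, no
#' spatial autocorrelation), synthesizes red/NIR reflectance that reproduce
#' the drawn NDVI exactly (`nir = 0.3 (1 + NDVI)`, `red = 0.3 (1 - NDVI)`;
#' only the NDVI ratio matters downstream), and forward-models at-sensor
#' thermal radiance through the same emissivity and atmospheric model the
#' retrieval chain inverts — so retrieval on a generated scene recovers
#' `lst_true` up to numerical round-off.
#'
#' @param spec a [scene_spec()].
#' @param atmos,planck,emis_params forward-model parameters; defaults match
#'   the retrieval defaults.
#' @return A list of class `synthetic_scene` with elements `landcover`
#'   (`land_cover_map`), `lst_true`, `red`, `nir`, `ndvi_true`, `radiance`
#'   (`raster_grid`s), and `spec`.
#' @examples
#' sc <- generate_scene(default_scene_spec(n_rows = 80, n_cols = 80))
#' zonal_mean_lst(sc$lst_true, sc$landcover)
#' @export
generate_scene <- function(spec,
                           atmos = atmospheric_profile(),
                           planck = planck_constants(),
                           emis_params = emissivity_params()) {
  stopifnot(inherits(spec, "scene_spec"))
  cls <- paint_layout(spec)
  set.seed(spec$seed)
  n <- length(cls)
  legend <- landcover_classes()
  lst <- numeric(n)
  nd <- numeric(n)
  for (id in sort(unique(as.integer(cls)))) {
    lab <- legend[id]
    sel <- which(cls == id)
    p <- spec$per_class_lst[[lab]]
    lst[sel] <- stats::rnorm(length(sel), p[1], p[2])
    q <- spec$per_class_ndvi[[lab]]
    nd[sel] <- pmin(pmax(stats::rnorm(length(sel), q[1], q[2]), -1), 1)
  }
  dim(lst) <- dim(nd) <- dim(cls)
  cs <- spec$cell_size
  lst_true <- raster_grid(lst, cs)
  ndvi_true <- raster_grid(nd, cs)
  nir <- raster_grid(0.3 * (1 + nd), cs)
  red <- raster_grid(0.3 * (1 - nd), cs)
  pv <- vegetation_fraction(ndvi_true, emis_params)
  eps <- emissivity(pv, emis_params)
  radiance <- forward_radiance(lst_true, eps, atmos, planck)
  structure(list(landcover = land_cover_map(cls, cs, legend),
                 lst_true = lst_true, red = red, nir = nir,
                 ndvi_true = ndvi_true, radiance = radiance, spec = spec),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d x %d cells, cell %g m, seed %d\n",
              nrow(x$lst_true), ncol(x$lst_true), cell_size(x$lst_true),
              x$spec$seed))
  invisible(x)
}

#' Forward thermal radiance model
#'
#' At-sensor radiance from surface temperature through the single-channel
#' radiative transfer: `L = (eps B(T) + (1 - eps) L_down) tau + L_up`, with
#' the Planck blackbody radiance `B(T) = K1 / (exp(K2 / T_K) - 1)` at the
#' kelvin temperature `T_K = T + 273.15`. This is the exact inverse of the
#' [retrieve_lst()] correction chain at fixed emissivity.
#'
#' @param lst_true `raster_grid` of surface temperature, degrees Celsius.
#' @param epsilon emissivity `raster_grid` or scalar, in (0, 1].
#' @param atmos [atmospheric_profile()].
#' @param planck [planck_constants()].
#' @return `raster_grid` of at-sensor radiance, W/m2/sr/um.
#' @export
forward_radiance <- function(lst_true, epsilon,
                             atmos = atmospheric_profile(),
                             planck = planck_constants()) {
  eps <- unclass(epsilon)
  if (any(!is.na(eps) & (eps <= 0 | eps > 1)))
    stop("emissivity must lie in (0, 1]")
  tk <- unclass(lst_true) + kelvin_offset
  if (any(!is.na(tk) & tk <= 0)) stop("non-positive kelvin temperature")
  b <- planck$K1 / (exp(planck$K2 / tk) - 1)
  l <- (eps * b + (1 - eps) * atmos$L_down) * atmos$tau + atmos$L_up
  raster_grid(l, cell_size(lst_true))
}

#' Default five-class demo scene
#'
#' A scene emulating the statistical structure of the Luoping County study
#' area: four painted quarters (water, tree canopy, grassland, bare land)
#' over an impervious background, class LST means 28.43 / 29.98 / 30.09 /
#' 30.21 / 31.44 degC (the class ordering impervious > bare > grass >
#' canopy > water), within-class sd 0.3 degC, and class-typical NDVI. At
#' the default 320 x 320 size every class has >= 10^4 cells.
#'
#' @param n_rows,n_cols grid size; quarters scale with the grid.
#' @param sd_lst within-class LST standard deviation, degC.
#' @param seed integer seed.
#' @return A [scene_spec()].
#' @export
default_scene_spec <- function(n_rows = 320, n_cols = 320, sd_lst = 0.3,
                               seed = 1L) {
  h <- max(1L, as.integer(floor(n_rows * 0.45)))
  w <- max(1L, as.integer(floor(n_cols * 0.45)))
  r2 <- n_rows - h + 1L - 1L # top-left row of the lower quarters
  c2 <- n_cols - w + 1L - 1L
  scene_spec(
    n_rows, n_cols, cell_size = 30,
    class_layout = list(
      scene_rect("water", 1L, 1L, h, w),
      scene_rect("tree_canopy", 1L, c2 + 1L, h, w),
      scene_rect("grassland", r2 + 1L, 1L, h, w),
      scene_rect("bare_land", r2 + 1L, c2 + 1L, h, w)),
    per_class_lst = list(
      water = c(28.43, sd_lst), tree_canopy = c(29.98, sd_lst),
      grassland = c(30.09, sd_lst), bare_land = c(30.21, sd_lst),
      impervious = c(31.44, sd_lst)),
    per_class_ndvi = list(
      water = c(-0.10, 0.02), tree_canopy = c(0.70, 0.03),
      grassland = c(0.45, 0.03), bare_land = c(0.10, 0.02),
      impervious = c(0.05, 0.02)),
    background_class = "impervious",
    seed = seed)
}

#' Write / read a synthetic scene as text grids
#'
#' One delimited-text grid per band plus a JSON sidecar recording the
#' generating [scene_spec()] for provenance.
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if missing).
#' @return [write_scene()] the directory, invisibly; [read_scene_spec()]
#'   the `scene_spec` rebuilt from the sidecar.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (band in c("lst_true", "red", "nir", "radiance"))
    write_grid(scene[[band]], file.path(dir, paste0(band, ".txt")))
  write_grid(scene$landcover, file.path(dir, "landcover.txt"))
  sp <- scene$spec
  jsonlite::write_json(sp, file.path(dir, "scene_spec.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' @rdname write_scene
#' @param path path to a `scene_spec.json` sidecar.
#' @export
read_scene_spec <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  shapes <- lapply(seq_len(NROW(j$class_layout)), function(i) {
    s <- as.list(j$class_layout[i, ])
    if (s$kind == "rect")
      scene_rect(s$class, s$row, s$col, s$height, s$width)
    else scene_disc(s$class, s$row, s$col, s$radius)
  })
  scene_spec(j$n_rows, j$n_cols, j$cell_size, shapes,
             per_class_lst = lapply(j$per_class_lst, as.numeric),
             per_class_ndvi = lapply(j$per_class_ndvi, as.numeric),
             background_class = j$background_class, seed = j$seed)
}
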