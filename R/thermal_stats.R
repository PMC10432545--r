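#' Zonal LST statistics by land-cover class
#'
#' Mean LST, cell count, area and area share for every land-cover class,
#' computed over cells valid in both grids. Classes with no valid cells are
#' omitted.
#'
#' @param lst LST `raster_grid` (degC).
#' @param landcover congruent [land_cover_map()].
#' @return data.frame: `class`, `n_cells`, `area_hm2`, `area_pct`,
#'   `mean_lst_c`, ordered by the legend. Shares sum to 100.
#' @export
zonal_mean_lst <- function(lst, landcover) {
  check_congruent(lst, landcover)
  legend <- landcover_legend(landcover)
  ok <- !is.na(unclass(lst)) & !is.na(unclass(landcover))
  if (!any(ok)) stop("no cells valid in both the LST grid and the land-cover map")
  cls <- factor(legend[as.integer(landcover)[ok]], levels = legend)
  v <- as.numeric(lst)[ok]
  n <- as.integer(table(cls))
  mu <- as.numeric(tapply(v, cls, mean))
  cs <- cell_size(landcover)
  out <- data.frame(class = legend, n_cells = n,
                    area_hm2 = n * cs^2 / 1e4,
                    area_pct = 100 * n / sum(n),
                    mean_lst_c = mu)
  out[out$n_cells > 0, , drop = FALSE]
}

#' Patch cooling rate
#'
#' Percentage reduction of a canopy patch's mean LST relative to the
#' scene-wide bare-land mean:
#' `100 * (bare - patch) / bare`, both in degrees Celsius. Negative when
#' the patch is warmer than bare land. The Celsius scale (not kelvin) is
#' physically arbitrary but is the convention of the urban-canopy cooling
#' literature this reproduces, and the baseline is a single global
#' bare-land mean, not a per-patch neighbourhood.
#'
#' @param patch_mean_lst patch mean LST, degC (vectorized).
#' @param bare_mean_lst scene-wide bare-land mean LST, degC, non-zero.
#' @return cooling rate in percent.
#' @examples
#' cooling_rate(27.089, 30.21) # 10.33
#' @export
cooling_rate <- function(patch_mean_lst, bare_mean_lst) {
  stopifnot(length(bare_mean_lst) == 1L)
  if (is.na(bare_mean_lst) || bare_mean_lst == 0)
    stop("bare-land mean LST baseline must be non-zero")
  100 * (bare_mean_lst - patch_mean_lst) / bare_mean_lst
}

#' Canopy coverage and planting-potential arithmetic
#'
#' Current canopy coverage, the possible additional canopy area (PUTC:
#' bare land plus grassland, the classes available for planting), the
#' coverage increase it would allow, and the resulting maximum coverage.
#' Percentages are on the 0-100 scale; rounding happens only at
#' presentation.
#'
#' @param class_areas_hm2 named numeric vector of class areas in hm2; names
#'   from [landcover_classes()] (missing classes count as 0).
#' @param total_area_hm2 total study-area extent, hm2, > 0.
#' @return A list of class `coverage_report`: `total_area_hm2`,
#'   `canopy_area_hm2`, `canopy_coverage_pct`, `putc_area_hm2`,
#'   `potential_increase_pct`, `max_coverage_pct`, plus per-class shares in
#'   `class_share_pct`. Satisfies `max = current + potential` exactly.
#' @examples
#' coverage_metrics(c(tree_canopy = 731.37, bare_land = 480.79,
#'                    grassland = 57.48, impervious = 1615.71,
#'                    water = 12.35), total_area_hm2 = 2897.7)
#' @export
coverage_metrics <- function(class_areas_hm2, total_area_hm2) {
  stopifnot(total_area_hm2 > 0, all(class_areas_hm2 >= 0))
  if (sum(class_areas_hm2) > total_area_hm2 * (1 + 1e-9))
    stop("class areas exceed the total study area")
  area_of <- function(cl) {
    if (cl %in% names(class_areas_hm2)) unname(class_areas_hm2[[cl]]) else 0
  }
  canopy <- area_of("tree_canopy")
  putc <- area_of("bare_land") + area_of("grassland")
  cov <- 100 * canopy / total_area_hm2
  pot <- 100 * putc / total_area_hm2
  structure(list(
    total_area_hm2 = total_area_hm2,
    canopy_area_hm2 = canopy,
    canopy_coverage_pct = cov,
    putc_area_hm2 = putc,
    potential_increase_pct = pot,
    max_coverage_pct = cov + pot,
    class_share_pct = 100 * class_areas_hm2 / total_area_hm2),
    class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<coverage_report> total %.2f hm2\n",
    "  canopy %.2f hm2 (%.2f%%)\n",
    "  possible additional canopy (bare land + grassland) %.2f hm2\n",
    "  potential increase %.2f%% -> maximum coverage %.2f%%\n"),
    x$total_area_hm2, x$canopy_area_hm2, x$canopy_coverage_pct,
    x$putc_area_hm2, x$potential_increase_pct, x$max_coverage_pct))
  invisible(x)
}
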