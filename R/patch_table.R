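#' Load a canopy patch table
#'
#' Reads a patch-metrics CSV with the fixed header `patch_no, area_hm2,
#' perimeter_km, shape_index, cooling_rate_pct` (extra columns are kept).
#' Unicode minus signs (U+2212), as produced by some table transcriptions,
#' are normalized to ASCII before parsing. Row order is preserved — the
#' Durbin-Watson statistic is defined on it.
#'
#' @param path CSV path; default the packaged Luoping County table of all
#'   63 super-large and extra-large canopy patches (areas > 1 hm2).
#' @return data.frame of class `patch_table`, rows in file order.
#' @examples
#' pt <- load_patch_table()
#' nrow(pt) # 63
#' @export
load_patch_table <- function(path = luoping_patch_path()) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines) || !nzchar(trimws(lines[1])))
    stop("empty patch table: ", path)
  lines <- gsub("−", "-", lines)
  d <- utils::read.csv(text = lines, stringsAsFactors = FALSE)
  need <- c("patch_no", "area_hm2", "perimeter_km", "shape_index",
            "cooling_rate_pct")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  for (col in need) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s', row %d: '%s'",
                   col, bad[1], d[[col]][bad[1]]))
    d[[col]] <- v
  }
  if (!nrow(d)) stop("patch table has no rows: ", path)
  d$size_class <- classify_size(d$area_hm2)
  class(d) <- c("patch_table", "data.frame")
  d
}

#' @rdname load_patch_table
#' @export
luoping_patch_path <- function() {
  system.file("extdata", "table4_patches.csv", package = "canopytherm",
              mustWork = TRUE)
}

#' Write a patch table as CSV
#' @param patches a `patch_table` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_patch_table <- function(patches, path) {
  d <- as.data.frame(patches)
  d <- d[, setdiff(names(d), "model"), drop = FALSE]
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every tunable of the analysis — atmospheric profile, Planck
#' constants, emissivity model, patch size thresholds, connectivity,
#' stepwise alpha, seed — with JSON (de)serialization that round-trips
#' losslessly.
#'
#' @param atmos,planck,emis_params retrieval parameter bundles.
#' @param size_thresholds upper area bounds (hm2) of the first four patch
#'   size classes.
#' @param connectivity patch connectivity, 4 or 8.
#' @param alpha stepwise removal threshold.
#' @param seed integer seed for the synthetic-scene stages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(atmos = atmospheric_profile(),
                            planck = planck_constants(),
                            emis_params = emissivity_params(),
                            size_thresholds = c(small = 0.05, medium = 0.20,
                                                large = 1.00,
                                                super_large = 5.00),
                            connectivity = 8, alpha = 0.05, seed = 1L) {
  stopifnot(connectivity %in% c(4, 8), alpha > 0, alpha < 1)
  structure(list(atmos = atmos, planck = planck, emis_params = emis_params,
                 size_thresholds = size_thresholds,
                 connectivity = connectivity, alpha = alpha,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$size_thresholds <- as.list(x$size_thresholds) # keep names in JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(
    atmos = do.call(atmospheric_profile, as.list(j$atmos)),
    planck = do.call(planck_constants, as.list(j$planck)),
    emis_params = do.call(emissivity_params, as.list(j$emis_params)),
    size_thresholds = unlist(j$size_thresholds),
    connectivity = j$connectivity, alpha = j$alpha, seed = j$seed)
}

#' Reference values of the Luoping County canopy study
#'
#' The published summary statistics of the Luoping County (Yunnan) urban
#' built-up area that this package's analysis recomputes: land-cover areas
#' (hm2), class mean LSTs (degC), and the correlation/regression results on
#' the 63-patch table.
#'
#' @return named list of reference constants.
#' @export
luoping_reference <- function() {
  list(
    total_area_hm2 = 2897.7,
    class_areas_hm2 = c(tree_canopy = 731.37, impervious = 1615.71,
                        bare_land = 480.79, grassland = 57.48,
                        water = 12.35),
    class_mean_lst_c = c(impervious = 31.44, bare_land = 30.21,
                         grassland = 30.09, tree_canopy = 29.98,
                         water = 28.43),
    lst_range_c = c(24.73, 37.63),
    lst_level_breaks_c = c(28.32, 30.15, 31.56, 33.23),
    extra_large_area_hm2 = 438.19,
    canopy_coverage_pct = 25.24,
    potential_increase_pct = 18.58,
    max_coverage_pct = 43.82,
    pearson_r = c(area = 0.319, perimeter = 0.313, shape_index = 0.218),
    ols_area = c(slope = 0.118, intercept = 0.148, r_squared = 0.103,
                 durbin_watson = 1.955),
    ols_perimeter = c(slope = 0.275, intercept = -0.172, r_squared = 0.098,
                      durbin_watson = 2.007))
}

#' Recompute the Luoping reference analysis
#'
#' Runs the full patch-table analysis on the packaged 63-patch Luoping
#' table — shape-index recomputation from area and perimeter, Pearson
#' correlations of area / perimeter / shape index with cooling rate, the
#' two simple regressions with Durbin-Watson in patch-number order,
#' backward stepwise elimination, and the coverage arithmetic — and
#' compares each quantity with its published reference value at a stated
#' tolerance. The patch table must be in patch-number order (1..n); a
#' re-sorted table is refused because the Durbin-Watson statistic depends
#' on row order.
#'
#' @param patches patch table (default the packaged fixture).
#' @param config [pipeline_config()] (supplies `alpha`).
#' @return data.frame of class `reference_report`: `quantity`, `computed`,
#'   `reference`, `tolerance`, `pass`; attribute `stepwise` carries the
#'   [backward_stepwise()] result.
#' @export
luoping_reference_report <- function(patches = load_patch_table(),
                                     config = pipeline_config()) {
  if (!identical(as.integer(patches$patch_no), seq_len(nrow(patches))))
    stop("patch table is not in patch-number order; ",
         "Durbin-Watson reproduction requires the original row order")
  ref <- luoping_reference()
  a_re <- shape_index(patches$perimeter_km * 1000, patches$area_hm2 * 1e4)
  cors <- lapply(c(area = "area_hm2", perimeter = "perimeter_km",
                   shape_index = "shape_index"),
                 function(v) pearson_cor(patches[[v]],
                                         patches$cooling_rate_pct))
  f_a <- ols_simple(patches$cooling_rate_pct, patches$area_hm2)
  f_p <- ols_simple(patches$cooling_rate_pct, patches$perimeter_km)
  sw <- backward_stepwise(patches$cooling_rate_pct,
                          patches[c("area_hm2", "perimeter_km",
                                    "shape_index")],
                          alpha = config$alpha)
  cov <- coverage_metrics(ref$class_areas_hm2, ref$total_area_hm2)

  row <- function(quantity, computed, reference, tolerance) {
    data.frame(quantity = quantity, computed = computed,
               reference = reference, tolerance = tolerance)
  }
  out <- rbind(
    row("shape_index_max_abs_dev", max(abs(a_re - patches$shape_index)),
        0, 0.02),
    row("shape_index_patch_1", a_re[1], patches$shape_index[1], 0.01),
    row("shape_index_patch_2", a_re[2], patches$shape_index[2], 0.01),
    row("pearson_r_area", cors$area$r, ref$pearson_r[["area"]], 0.005),
    row("pearson_r_perimeter", cors$perimeter$r,
        ref$pearson_r[["perimeter"]], 0.005),
    row("pearson_r_shape_index", cors$shape_index$r,
        ref$pearson_r[["shape_index"]], 0.005),
    row("ols_area_slope", f_a$slope, ref$ols_area[["slope"]], 0.005),
    row("ols_area_intercept", f_a$intercept, ref$ols_area[["intercept"]],
        0.005),
    row("ols_area_r_squared", f_a$r_squared, ref$ols_area[["r_squared"]],
        0.005),
    row("ols_area_durbin_watson", f_a$durbin_watson,
        ref$ols_area[["durbin_watson"]], 0.01),
    row("ols_perimeter_slope", f_p$slope, ref$ols_perimeter[["slope"]],
        0.005),
    row("ols_perimeter_intercept", f_p$intercept,
        ref$ols_perimeter[["intercept"]], 0.005),
    row("ols_perimeter_r_squared", f_p$r_squared,
        ref$ols_perimeter[["r_squared"]], 0.005),
    row("ols_perimeter_durbin_watson", f_p$durbin_watson,
        ref$ols_perimeter[["durbin_watson"]], 0.01),
    row("stepwise_removes_shape_index",
        as.numeric("shape_index" %in% sw$removed$predictor), 1, 0),
    row("canopy_coverage_pct", cov$canopy_coverage_pct,
        ref$canopy_coverage_pct, 0.005),
    row("potential_increase_pct", cov$potential_increase_pct,
        ref$potential_increase_pct, 0.005),
    row("max_coverage_pct", cov$max_coverage_pct, ref$max_coverage_pct,
        0.005),
    row("impervious_share_pct",
        cov$class_share_pct[["impervious"]], 55.76, 0.005),
    row("extra_large_area_share_pct",
        100 * ref$extra_large_area_hm2 / ref$class_areas_hm2[["tree_canopy"]],
        59.91, 0.005))
  out$pass <- abs(out$computed - out$reference) <= out$tolerance
  attr(out, "stepwise") <- sw
  class(out) <- c("reference_report", "data.frame")
  out
}

#' @export
print.reference_report <- function(x, ...) {
  d <- as.data.frame(x)
  d$computed <- signif(d$computed, 6)
  cat(sprintf("Luoping reference analysis: %d/%d checks pass\n",
              sum(d$pass), nrow(d)))
  print(d, row.names = FALSE)
  invisible(x)
}
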