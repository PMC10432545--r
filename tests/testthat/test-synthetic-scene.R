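test_that("zero-noise scene paints exact class values with painter's rule", {
  sc <- generate_scene(one_rect_spec())
  lab <- landcover_labels(sc$landcover)
  expect_equal(sum(lab == "tree_canopy"), 100)
  expect_true(all(sc$lst_true[lab == "tree_canopy"] == 29.98))
  expect_true(all(sc$lst_true[lab == "impervious"] == 31.44))
  # reflectance bands reproduce the target NDVI exactly
  nd <- ndvi(sc$red, sc$nir)
  expect_equal(unclass(nd), unclass(sc$ndvi_true), tolerance = 1e-12)
  # later shapes overwrite earlier: stack a rect over the canopy block
  spec2 <- one_rect_spec()
  spec2$class_layout <- c(spec2$class_layout,
                          list(scene_rect("impervious", 5L, 5L, 10L, 10L)))
  sc2 <- generate_scene(spec2)
  expect_equal(sum(landcover_labels(sc2$landcover) == "tree_canopy"), 0)
})

test_that("same seed gives bit-identical scenes; different seed differs", {
  a <- generate_scene(default_scene_spec(n_rows = 50, n_cols = 50, seed = 42L))
  b <- generate_scene(default_scene_spec(n_rows = 50, n_cols = 50, seed = 42L))
  expect_identical(a$lst_true, b$lst_true)
  expect_identical(a$radiance, b$radiance)
  c_ <- generate_scene(default_scene_spec(n_rows = 50, n_cols = 50, seed = 43L))
  expect_false(identical(unclass(a$lst_true), unclass(c_$lst_true)))
})

test_that("class-conditional LST means are unbiased at large n", {
  sc <- generate_scene(default_scene_spec(seed = 11L)) # >= 1e4 cells/class
  zs <- zonal_mean_lst(sc$lst_true, sc$landcover)
  target <- c(water = 28.43, tree_canopy = 29.98, grassland = 30.09,
              bare_land = 30.21, impervious = 31.44)
  for (cl in names(target)) {
    i <- zs$class == cl
    expect_gte(zs$n_cells[i], 1e4)
    expect_lt(abs(zs$mean_lst_c[i] - target[[cl]]),
              3 * 0.3 / sqrt(zs$n_cells[i]))
  }
})

test_that("layout shapes exceeding the grid are rejected", {
  spec <- one_rect_spec()
  spec$class_layout <- list(scene_rect("tree_canopy", 15L, 15L, 10L, 10L))
  expect_error(generate_scene(spec), "exceeds")
  spec$class_layout <- list(scene_disc("water", 3L, 3L, 5))
  expect_error(generate_scene(spec), "exceeds")
})

test_that("disc shapes paint cells within the radius", {
  spec <- scene_spec(
    21, 21, cell_size = 1,
    class_layout = list(scene_disc("water", 11L, 11L, 5)),
    per_class_lst = list(water = c(28.43, 0), impervious = c(31.44, 0)),
    per_class_ndvi = list(water = c(-0.1, 0), impervious = c(0.05, 0)))
  sc <- generate_scene(spec)
  lab <- landcover_labels(sc$landcover)
  expect_equal(lab[11, 11], "water")
  expect_equal(lab[11, 16], "water")   # exactly on the radius
  expect_equal(lab[11, 17], "impervious")
  expect_equal(sum(lab == "water"), 81) # |{(i,j): i^2+j^2 <= 25}|
})

test_that("forward radiance matches the Planck law in a degenerate atmosphere", {
  pl <- planck_constants()
  atm <- atmospheric_profile(tau = 1, L_up = 0, L_down = 0)
  g <- const_grid(300 - 273.15)
  out <- forward_radiance(g, 1, atm, pl)
  expect_equal(out[1, 1], pl$K1 / (exp(pl$K2 / 300) - 1), tolerance = 1e-12)
  # frozen direct evaluation at T = 302.8 K
  g2 <- const_grid(302.8 - 273.15)
  expect_equal(forward_radiance(g2, 1, atm, pl)[1, 1], 10.0007972,
               tolerance = 1e-7)
})

test_that("forward radiance applies emissivity and path terms linearly", {
  pl <- planck_constants()
  atm <- atmospheric_profile(tau = 0.91, L_up = 0.75, L_down = 1.29)
  t_c <- 30
  b <- pl$K1 / (exp(pl$K2 / (t_c + 273.15)) - 1)
  out <- forward_radiance(const_grid(t_c), 0.99, atm, pl)
  expect_equal(out[1, 1], 0.91 * (0.99 * b + 0.01 * 1.29) + 0.75,
               tolerance = 1e-12)
})

test_that("forward radiance rejects non-physical inputs", {
  expect_error(forward_radiance(const_grid(-300), 1), "kelvin")
  expect_error(forward_radiance(const_grid(20), 1.5), "emissivity")
  expect_error(forward_radiance(const_grid(20), 0), "emissivity")
})

test_that("scene write/read round-trips grids and spec", {
  dir <- withr::local_tempdir()
  sc <- generate_scene(one_rect_spec(sd_lst = 0.2))
  write_scene(sc, dir)
  back <- read_grid(file.path(dir, "lst_true.txt"))
  expect_equal(unclass(back), unclass(sc$lst_true), tolerance = 1e-12)
  expect_equal(cell_size(back), cell_size(sc$lst_true))
  spec2 <- read_scene_spec(file.path(dir, "scene_spec.json"))
  sc2 <- generate_scene(spec2)
  expect_equal(unclass(sc2$lst_true), unclass(sc$lst_true), tolerance = 1e-12)
})
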