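test_that("single block extracts as one patch with exact geometry", {
  m <- matrix(5L, 12, 12)
  m[2:11, 2:11] <- 2L
  lc <- land_cover_map(m, cell_size = 1)
  pt <- extract_patches(lc, "tree_canopy")
  expect_equal(nrow(pt), 1)
  expect_equal(pt$area_m2, 100)
  expect_equal(pt$perimeter_m, 40)
  expect_equal(pt$shape_index, 2 / sqrt(pi), tolerance = 1e-9)
})

test_that("connectivity 4 vs 8 semantics on diagonal-touching blocks", {
  m <- matrix(5L, 6, 6)
  m[1:2, 1:2] <- 2L
  m[3:4, 3:4] <- 2L # touches the first block only at a corner
  lc <- land_cover_map(m, cell_size = 1)
  expect_equal(nrow(extract_patches(lc, connectivity = 4)), 2)
  expect_equal(nrow(extract_patches(lc, connectivity = 8)), 1)
  # hand-enumerated mixed fixture: three 4-components, two 8-components
  m2 <- matrix(5L, 5, 7)
  m2[1, 1] <- 2L; m2[2, 2] <- 2L            # diagonal pair
  m2[4, 5] <- 2L; m2[4, 6] <- 2L; m2[5, 6] <- 2L # L-shaped triple
  lc2 <- land_cover_map(m2, cell_size = 1)
  expect_equal(nrow(extract_patches(lc2, connectivity = 4)), 3)
  expect_equal(nrow(extract_patches(lc2, connectivity = 8)), 2)
})

test_that("empty class and unknown class behave as specified", {
  lc <- land_cover_map(matrix(5L, 3, 3), cell_size = 1)
  expect_equal(nrow(extract_patches(lc, "tree_canopy")), 0)
  expect_error(extract_patches(lc, "forest"), "unknown class")
})

test_that("patch masks are disjoint and conserve the class area", {
  sc <- generate_scene(default_scene_spec(n_rows = 60, n_cols = 60, seed = 9L))
  spec <- sc$spec
  spec$class_layout <- c(spec$class_layout,
                         list(scene_disc("tree_canopy", 30L, 30L, 6)))
  sc <- generate_scene(spec)
  pt <- extract_patches(sc$landcover, "tree_canopy", connectivity = 8)
  n_class <- sum(unclass(sc$landcover) == 2L)
  expect_equal(sum(pt$n_cells), n_class)
  masks <- attr(pt, "masks")
  expect_equal(sum(Reduce(`+`, lapply(masks, as.numeric))), n_class)
  expect_true(all(Reduce(`+`, lapply(masks, as.numeric)) <= 1))
  expect_true(all(pt$shape_index >= 1))
})

test_that("exposed-edge perimeter counts boundary and interior edges", {
  expect_equal(patch_perimeter(matrix(TRUE, 1, 1), 1), 4)
  expect_equal(patch_perimeter(matrix(TRUE, 10, 10), 1), 40)
  l_mask <- matrix(FALSE, 2, 2)
  l_mask[1, 1] <- l_mask[2, 1] <- l_mask[2, 2] <- TRUE
  expect_equal(patch_perimeter(l_mask, 1), 8)
  # grid-edge cells count as exposed
  expect_equal(patch_perimeter(matrix(TRUE, 2, 2), 2), 16)
})

test_that("shape index closed forms and published patch values", {
  # square of any side: 2/sqrt(pi), scale-free
  for (a in c(1, 17, 400))
    expect_equal(shape_index(4 * a, a^2), 2 / sqrt(pi), tolerance = 1e-12)
  # the two largest Luoping patches, from printed area/perimeter
  expect_equal(shape_index(25170, 653200), 8.79, tolerance = 0.01)
  expect_equal(shape_index(32290, 645400), 11.34, tolerance = 0.01)
  # unit-coherence identity: A(E km, S hm2) = 5 E_km / sqrt(pi S_hm2)
  e_km <- 3.2; s_hm2 <- 4.7
  expect_equal(shape_index(e_km * 1000, s_hm2 * 1e4),
               5 * e_km / sqrt(pi * s_hm2), tolerance = 1e-12)
  expect_error(shape_index(0, 10), "positive")
  expect_error(shape_index(10, -1), "positive")
})

test_that("size classes respect the inclusive lower boundaries", {
  got <- classify_size(c(0.05, 0.051, 0.12, 0.20, 0.21, 1.00, 1.01,
                         5.00, 5.01))
  expect_equal(as.character(got),
               c("small", "medium", "medium", "medium", "large", "large",
                 "super_large", "super_large", "extra_large"))
  expect_error(classify_size(0), "positive")
})

test_that("level summary counts, shares and weighted LST add up", {
  d <- data.frame(area_hm2 = c(0.04, 0.10, 0.50, 2.0, 6.0),
                  mean_lst_c = c(31, 31, 30.5, 30, 29.5))
  s <- patch_level_summary(d)
  expect_equal(s$n_patches[1:5], rep(1L, 5))
  expect_equal(sum(s$area_pct[1:5]), 100, tolerance = 1e-9)
  expect_equal(s$area_hm2[s$level == "total"], 8.64)
  # share of the top level when level areas match the published composition
  areas <- c(14.27, 63.89, 122.68, 92.34, 438.19)
  d2 <- data.frame(area_hm2 = areas,
                   size_class = factor(size_class_labels(),
                                       levels = size_class_labels()))
  s2 <- patch_level_summary(d2)
  expect_equal(s2$area_pct[s2$level == "extra_large"], 59.91,
               tolerance = 0.005)
  # empty level reports zero
  s3 <- patch_level_summary(data.frame(area_hm2 = c(0.01, 7)))
  expect_equal(s3$n_patches[s3$level == "medium"], 0L)
  expect_equal(s3$area_pct[s3$level == "medium"], 0)
})

test_that("patch mean LST and cooling rate attach when LST is supplied", {
  sc <- generate_scene(one_rect_spec())
  pt <- extract_patches(sc$landcover, "tree_canopy", lst = sc$lst_true,
                        bare_mean_lst = 30.21)
  expect_equal(pt$mean_lst_c, 29.98, tolerance = 1e-12)
  expect_equal(pt$cooling_rate_pct,
               100 * (30.21 - 29.98) / 30.21, tolerance = 1e-12)
})
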