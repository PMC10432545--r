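test_that("pearson correlation: exact linearity, affine invariance, oracle", {
  x <- c(1.2, 3.4, 2.2, 5.6, 4.1, 0.3, 2.9)
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_lt(pearson_cor(x, 2 * x + 1)$p, 1e-10)
  set.seed(21)
  y <- x + rnorm(7)
  a <- pearson_cor(x, y)
  b <- pearson_cor(10 * x - 3, 0.5 * y + 7) # positive affine maps
  expect_equal(a$r, b$r, tolerance = 1e-12)
  # matches the stats::cor.test oracle, r and p
  ct <- cor.test(x, y)
  expect_equal(a$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(a$p, ct$p.value, tolerance = 1e-12)
  expect_error(pearson_cor(x, rep(1, 7)), "variance")
})

test_that("patch-table correlations match the published coefficients", {
  pt <- load_patch_table()
  r_area <- pearson_cor(pt$area_hm2, pt$cooling_rate_pct)
  r_perim <- pearson_cor(pt$perimeter_km, pt$cooling_rate_pct)
  r_shape <- pearson_cor(pt$shape_index, pt$cooling_rate_pct)
  expect_equal(r_area$r, 0.319, tolerance = 0.005)
  expect_equal(r_perim$r, 0.313, tolerance = 0.005)
  expect_equal(r_shape$r, 0.218, tolerance = 0.005)
  expect_lt(r_area$p, 0.05)
  expect_lt(r_perim$p, 0.05)
  expect_gt(r_shape$p, 0.05) # published P = 0.086
})

test_that("simple OLS matches the published regressions and R2 = r2", {
  pt <- load_patch_table()
  f_a <- ols_simple(pt$cooling_rate_pct, pt$area_hm2)
  expect_lt(abs(f_a$slope - 0.118), 0.005)
  expect_lt(abs(f_a$intercept - 0.148), 0.005)
  expect_lt(abs(f_a$r_squared - 0.103), 0.005)
  f_p <- ols_simple(pt$cooling_rate_pct, pt$perimeter_km)
  expect_lt(abs(f_p$slope - 0.275), 0.005)
  expect_lt(abs(f_p$intercept - (-0.172)), 0.005)
  expect_lt(abs(f_p$r_squared - 0.098), 0.005)
  # R2 of the simple fit equals the squared Pearson r
  expect_equal(f_a$r_squared,
               pearson_cor(pt$area_hm2, pt$cooling_rate_pct)$r^2,
               tolerance = 1e-12)
  # degenerate constant response: slope 0, R2 reported as 0
  f_c <- suppressWarnings(ols_simple(rep(3, 10), 1:10)) # exact fit by design
  expect_equal(f_c$slope, 0)
  expect_equal(f_c$intercept, 3)
  expect_equal(f_c$r_squared, 0)
  expect_error(ols_simple(1:5, rep(2, 5)), "degenerate")
})

test_that("Durbin-Watson: closed forms, oracle, white-noise range", {
  expect_error(durbin_watson(rep(0, 5)), "all-zero")
  # perfectly persistent residuals
  expect_equal(durbin_watson(rep(2.5, 8)), 0)
  # alternating +-c of length n: 4(n-1)/n
  for (n in c(4, 9, 50)) {
    e <- rep(c(1.3, -1.3), length.out = n)
    expect_equal(durbin_watson(e), 4 * (n - 1) / n, tolerance = 1e-12)
  }
  # agrees with the lmtest oracle on a real fit
  pt <- load_patch_table()
  fit <- lm(cooling_rate_pct ~ area_hm2, pt)
  expect_equal(durbin_watson(unname(resid(fit))),
               unname(lmtest::dwtest(fit)$statistic), tolerance = 1e-10)
  # white noise sits near 2
  set.seed(31)
  expect_true(abs(durbin_watson(rnorm(1e4)) - 2) < 0.1)
})

test_that("Durbin-Watson of the published regressions in row order", {
  pt <- load_patch_table()
  f_a <- ols_simple(pt$cooling_rate_pct, pt$area_hm2)
  f_p <- ols_simple(pt$cooling_rate_pct, pt$perimeter_km)
  expect_equal(f_a$durbin_watson, 1.955, tolerance = 0.01)
  expect_equal(f_p$durbin_watson, 2.007, tolerance = 0.01)
  # the statistic depends on row order: shuffling changes it
  set.seed(8)
  shuf <- sample(nrow(pt))
  f_s <- ols_simple(pt$cooling_rate_pct[shuf], pt$area_hm2[shuf])
  expect_false(isTRUE(all.equal(f_s$durbin_watson, f_a$durbin_watson,
                                tolerance = 1e-6)))
})

test_that("backward stepwise removes insignificant predictors in p order", {
  set.seed(41)
  x <- rnorm(40)
  noise <- rnorm(40)
  # y = x exactly, so lm warns about a perfect fit; that is the point here
  sw <- suppressWarnings(backward_stepwise(x, list(x = x, noise = noise)))
  expect_equal(sw$retained, "x")
  expect_equal(sw$removed$predictor, "noise")
  # single significant predictor: nothing removed
  sw1 <- backward_stepwise(2 * x + rnorm(40, sd = 0.1), list(x = x))
  expect_equal(nrow(sw1$removed), 0)
  expect_equal(sw1$retained, "x")
})

test_that("stepwise on the patch table eliminates the shape index", {
  pt <- load_patch_table()
  sw <- backward_stepwise(pt$cooling_rate_pct,
                          pt[c("area_hm2", "perimeter_km", "shape_index")],
                          alpha = 0.05)
  expect_true("shape_index" %in% sw$removed$predictor)
  expect_true("area_hm2" %in% sw$retained)
  # removal order is deterministic: worst p first
  expect_equal(sw$removed$predictor[1], "perimeter_km")
  expect_true(all(diff(sw$removed$step) == 1))
  # the reported simple fit for area is the published regression
  expect_equal(sw$simple_fits$area_hm2$slope, 0.118, tolerance = 0.005)
})
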