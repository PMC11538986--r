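test_that("UD mass is conserved and concentrates on the data", {
  set.seed(21)
  tr <- mk_track(x = rnorm(200, 1000, 40), y = rnorm(200, 2000, 40))
  ud <- estimate_ud(tr, cell_m = 50)
  expect_equal(sum(ud$z), 1, tolerance = 1e-9)
  expect_true(all(ud$z >= 0))
  mode_idx <- which(ud$z == max(ud$z), arr.ind = TRUE)[1, ]
  expect_lt(abs(ud$x[mode_idx[1]] - 1000), 150)
  expect_lt(abs(ud$y[mode_idx[2]] - 2000), 150)
  expect_error(estimate_ud(mk_track(rep(5, 40), rep(5, 40))), "bandwidth")
  expect_error(estimate_ud(mk_track(1:10, 1:10)), "at least 30")
})

test_that("KDE approximates a known Gaussian density (L1 < 0.05)", {
  set.seed(22)
  n <- 5000
  sigma <- 500
  h <- 200
  tr <- mk_track(x = rnorm(n, 0, sigma), y = rnorm(n, 0, sigma))
  ud <- estimate_ud(tr, bandwidth = h, cell_m = 50)
  # the KDE estimates the kernel-convolved density N(0, sigma^2 + h^2)
  s_eff <- sqrt(sigma^2 + h^2)
  truth <- outer(stats::dnorm(ud$x, 0, s_eff), stats::dnorm(ud$y, 0, s_eff)) *
    ud$cell^2
  expect_lt(sum(abs(ud$z - truth / sum(truth))), 0.05)
})

test_that("home range covers the requested mass with sane geometry", {
  set.seed(23)
  tr <- mk_track(x = rnorm(500, 0, 300), y = rnorm(500, 0, 300))
  ud <- estimate_ud(tr, cell_m = 50)
  hr_all <- home_range(ud, level = 1.0)
  expect_gte(sum(hr_all$cells$mass), 1 - 1e-9)  # all non-negligible cells
  expect_lte(nrow(hr_all$cells), sum(ud$z > 0))
  # area monotone nondecreasing in level
  areas <- vapply(c(0.5, 0.8, 0.95, 1.0),
                  function(l) home_range(ud, l)$area_m2, numeric(1))
  expect_true(all(diff(areas) >= 0))
  # two separated equal clusters are both inside the 95% range
  tr2 <- mk_track(x = c(rnorm(250, 0, 50), rnorm(250, 5000, 50)),
                  y = rep(0, 500))
  hr2 <- home_range(estimate_ud(tr2, bandwidth = 50, cell_m = 50), 0.95)
  expect_true(any(abs(hr2$cells$x - 0) < 200))
  expect_true(any(abs(hr2$cells$x - 5000) < 200))
})

test_that("isotropic-Gaussian 95% area matches the analytic ellipse", {
  set.seed(24)
  n <- 5000; sigma <- 500
  tr <- mk_track(x = rnorm(n, 0, sigma), y = rnorm(n, 0, sigma))
  ud <- estimate_ud(tr, bandwidth = 60, cell_m = 25)
  hr <- home_range(ud, 0.95)
  analytic <- pi * stats::qchisq(0.95, 2) * sigma^2
  expect_equal(hr$area_m2, analytic, tolerance = 0.1)
})

test_that("UD rasters round-trip through the ASCII grid format", {
  set.seed(25)
  tr <- mk_track(x = rnorm(100, 0, 200), y = rnorm(100, 0, 200))
  ud <- estimate_ud(tr, cell_m = 50)
  f <- withr::local_tempfile(fileext = ".asc")
  write_ud(ud, f)
  back <- read_ud(f)
  expect_equal(back$x, ud$x)
  expect_equal(back$y, ud$y)
  expect_equal(back$z, ud$z, tolerance = 1e-8)
  expect_equal(bhattacharyya_affinity(ud, back), 1, tolerance = 1e-8)
})

test_that("overlap proportions follow the geometry", {
  mk_hr <- function(ixs, iys, cell = 50) {
    cells <- expand.grid(ix = ixs, iy = iys)
    structure(list(cells = tibble::tibble(ix = cells$ix, iy = cells$iy),
                   area_m2 = nrow(cells) * cell^2, level = 0.95,
                   cell = cell), class = "home_range")
  }
  a <- mk_hr(1:10, 1:10)
  expect_equal(unname(overlap_proportion(a, a)), c(1, 1))
  b <- mk_hr(50:60, 50:60)
  expect_equal(unname(overlap_proportion(a, b)), c(0, 0))
  half <- mk_hr(1:10, 1:5)  # nested, half the area
  expect_equal(unname(overlap_proportion(half, a)), c(1, 0.5))
})

test_that("Bhattacharyya affinity matches the Gaussian closed form", {
  ua <- gaussian_ud(c(0, 0), sigma = 1, cell = 0.05)
  expect_equal(bhattacharyya_affinity(ua, ua), 1, tolerance = 1e-9)
  for (d in c(0.5, 1, 2)) {
    ub <- gaussian_ud(c(d, 0), sigma = 1, cell = 0.05)
    expect_equal(bhattacharyya_affinity(ua, ub), exp(-d^2 / 8),
                 tolerance = 1e-3)
    expect_equal(bhattacharyya_affinity(ua, ub),
                 bhattacharyya_affinity(ub, ua), tolerance = 1e-12)
  }
  far <- gaussian_ud(c(50, 0), sigma = 1, cell = 0.05)
  expect_equal(bhattacharyya_affinity(ua, far), 0, tolerance = 1e-6)
  # monotone decline as the UDs are pulled apart
  ba <- vapply(seq(0, 3, by = 0.5), function(d)
    bhattacharyya_affinity(ua, gaussian_ud(c(d, 0), 1, 0.05)), numeric(1))
  expect_true(all(diff(ba) < 0))
  expect_true(all(ba >= 0 & ba <= 1))
})
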