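test_that("ribbon diameters read the ribbon width within one pixel", {
  m <- matrix(FALSE, 40, 160)
  m[16:24, 10:150] <- TRUE  # width 9 px = 0.45 um at 0.05 um/px
  sk <- skeletonize_mask(m, 5, 0.05)
  d <- local_diameters(m, sk, 0.05)
  incl <- d$d_um[!d$excluded]
  expect_gt(length(incl), 50)
  expect_true(all(abs(incl - 0.45) <= 0.05 + 1e-9))
})

test_that("a disk's central diameter sample matches its true diameter", {
  H <- 64
  m <- matrix(FALSE, H, H)
  ctr <- c(32, 32); r <- 15
  for (i in 1:H) for (j in 1:H)
    if ((i - ctr[1])^2 + (j - ctr[2])^2 <= r^2) m[i, j] <- TRUE
  sk <- skeletonize_mask(m, 0, 0.1)
  d <- local_diameters(m, sk, 0.1)
  expect_lte(abs(max(d$d_um) - 2 * r * 0.1), 2 * 0.1)
})

test_that("fiber statistics match hand-computed values", {
  s <- fiber_stats(c(0.2, 0.4, 0.4, 1.0), min_n = 4)
  expect_equal(s$mean_um, 0.5)
  expect_equal(s$median_um, 0.4)
  expect_true(s$positively_skewed)
  expect_equal(s$sd_um, sqrt(mean((c(0.2, 0.4, 0.4, 1.0) - 0.5)^2)))
  expect_equal(sum(s$histogram$counts), s$n)

  s2 <- fiber_stats(rep(0.5, 100))
  expect_equal(s2$mean_um, 0.5)
  expect_equal(s2$median_um, 0.5)
  expect_equal(s2$sd_um, 0)
  expect_false(s2$positively_skewed)

  # a distribution with mean 0.57 and median 0.48 is positively skewed
  s3 <- fiber_stats(c(0.33, 0.48, 0.90), min_n = 3)
  expect_equal(s3$mean_um, 0.57)
  expect_equal(s3$median_um, 0.48)
  expect_true(s3$positively_skewed)

  expect_warning(fiber_stats(c(0.4, 0.5), min_n = 100), "unstable")
  expect_error(fiber_stats(numeric(0)), class = "fm_validation_error")
})

test_that("pore equivalent diameters and class fractions follow their definitions", {
  # two rectangular holes: 100 px and 300 px at 0.1 um/px -> 1 and 3 um^2
  m <- matrix(TRUE, 60, 60)
  m[11:20, 11:20] <- FALSE   # 100 px
  m[31:45, 31:50] <- FALSE   # 300 px
  pt <- pore_distribution(m, 0.1, bins_um = c(0, 1.5, Inf))
  expect_equal(sort(pt$pores$area_um2), c(1, 3))
  expect_equal(pt$pores$d_eq_um, 2 * sqrt(pt$pores$area_um2 / pi))
  # d_eq(1 um^2) = 1.128 < 1.5 ; d_eq(3 um^2) = 1.954 > 1.5
  expect_equal(pt$classes$void_area_fraction, c(0.25, 0.75))
  expect_equal(pt$border_excluded_count, 0L)

  # a hole of area pi um^2 has equivalent diameter 2 um by definition
  d_eq <- 2 * sqrt(pi / pi)
  expect_equal(d_eq, 2)
})

test_that("border-touching pores are excluded but fully accounted", {
  m <- matrix(TRUE, 30, 30)
  m[1:5, 10:14] <- FALSE    # touches top border
  m[15:20, 15:20] <- FALSE  # interior
  pt <- pore_distribution(m, 0.05)
  expect_equal(pt$border_excluded_count, 1L)
  expect_equal(nrow(pt$pores), 1L)
  expect_identical(pt$included_pore_px + pt$border_pore_px + pt$fiber_px,
                   pt$total_px)
})

test_that("an all-foreground mask yields an empty pore table", {
  pt <- pore_distribution(matrix(TRUE, 20, 20), 0.05)
  expect_equal(nrow(pt$pores), 0L)
  expect_equal(pt$border_excluded_count, 0L)
})

test_that("pore accounting is exact in pixels on synthetic meshes", {
  sim <- fixture_mesh()
  pt <- pore_distribution(sim$truth$fiber_mask, 0.05)
  expect_identical(pt$included_pore_px + pt$border_pore_px + pt$fiber_px,
                   pt$total_px)
  expect_identical(pt$total_px, 1024L * 1024L)
  if (nrow(pt$pores) > 1)
    expect_equal(sum(pt$classes$void_area_fraction), 1)
})

test_that("surface area per unit length is pi times the diameter", {
  expect_equal(surface_area_per_unit_length(1), pi)
  expect_equal(surface_area_per_unit_length(2), 2 * pi)
  expect_equal(surface_area_per_unit_length(2) /
               surface_area_per_unit_length(1), 2)
  expect_equal(surface_area_per_unit_length(0.51), 1.6022, tolerance = 1e-4)
  expect_error(surface_area_per_unit_length(0), class = "fm_validation_error")
  expect_error(surface_area_per_unit_length(-1), class = "fm_validation_error")
})

test_that("both surface-area modes agree for constant diameters", {
  m <- matrix(FALSE, 40, 220)
  m[16:24, 11:211] <- TRUE
  sk <- skeletonize_mask(m, 5, 0.05)
  d <- local_diameters(m, sk, 0.05)
  ea <- total_surface_area(sk, d, 0.05, mode = "mean_diameter")
  eb <- total_surface_area(sk, d, 0.05, mode = "per_pixel")
  L <- total_length(sk)
  expect_equal(ea$total_area_um2, L * pi * ea$A_star_um / pi)
  expect_equal(ea$A_star_um, pi * mean(d$d_um[!d$excluded]))
  # constant-diameter identity: modes agree up to flagged border samples
  expect_lt(abs(eb$total_area_um2 / ea$total_area_um2 - 1), 0.02)
})

test_that("empty skeletons give a zero surface-area estimate", {
  sk <- skeletonize_mask(matrix(FALSE, 10, 10), calibration = 0.05)
  d <- local_diameters(matrix(FALSE, 10, 10), sk, 0.05)
  e <- total_surface_area(sk, d, 0.05)
  expect_equal(e$total_area_um2, 0)
  expect_equal(e$normalized, 0)
})

test_that("per-pixel surface area matches the analytic truth and the
           cylinder-projection identity on non-overlapping meshes", {
  sim <- fixture_mesh()
  b <- fixture_bundle()
  est <- b$surface_area$total_area_um2
  expect_lt(abs(est / sim$truth$analytic_surface_area_um2 - 1), 0.15)
  proj <- pi * sum(sim$truth$fiber_mask) * 0.05^2
  expect_lt(abs(est / proj - 1), 0.15)
})

test_that("diameter recovery: mean and median within 10%, skew detected", {
  sim <- fixture_mesh()
  b <- fixture_bundle()
  td <- truth_diams(sim$truth)
  expect_lt(abs(b$fiber_stats$mean_um / mean(td) - 1), 0.10)
  expect_lt(abs(b$fiber_stats$median_um / median(td) - 1), 0.10)
  expect_true(b$fiber_stats$positively_skewed)  # sigma_log 0.586 >= 0.3
  # per-fiber subsampling agrees with the truth per fiber
  pf <- per_fiber_diameters(b$diameters, sim$truth$label)
  expect_equal(length(pf), length(td))
  expect_lt(abs(mean(pf) / mean(td) - 1), 0.10)
})

test_that("surface-area comparison is scale-free and errors on zero", {
  b <- fixture_bundle()
  expect_equal(compare_surface_areas(b$surface_area, b$surface_area), 1.0)
  zero <- total_surface_area(
    skeletonize_mask(matrix(FALSE, 10, 10), calibration = 0.05),
    local_diameters(matrix(FALSE, 10, 10),
                    skeletonize_mask(matrix(FALSE, 10, 10), calibration = 0.05),
                    0.05),
    0.05)
  expect_error(compare_surface_areas(b$surface_area, zero),
               class = "fm_computation_error")
})
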