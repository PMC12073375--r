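test_that("empty mesh yields a blank image with zero totals", {
  sim <- generate_mesh(mesh_spec(128, 128, n_fibers = 0, noise_sd = 0, seed = 1))
  expect_equal(sim$truth$total_centerline_length_um, 0)
  expect_equal(sim$truth$fiber_area_fraction, 0)
  expect_equal(sim$truth$analytic_surface_area_um2, 0)
  expect_true(all(sim$image == 0.2))
  expect_false(any(sim$truth$fiber_mask))
})

test_that("a single spanning horizontal fiber has analytic length and coverage", {
  spec <- mesh_spec(512, 512, um_per_px = 0.05, n_fibers = 0, noise_sd = 0)
  d_px <- 10
  sim <- render_mesh(list(rbind(c(256.5, 0.5), c(256.5, 512.5))),
                     d_px * 0.05, spec)
  expect_equal(sim$truth$total_centerline_length_um, 512 * 0.05)
  # coverage = band area / image area, up to end-cap pixels at the borders
  expect_lt(abs(sim$truth$fiber_area_fraction - d_px * 512 / 512^2),
            2 * d_px^2 / 512^2)
  expect_equal(sim$truth$analytic_surface_area_um2,
               pi * (d_px * 0.05) * 512 * 0.05)
})

test_that("identical spec and seed reproduce the mesh bit-for-bit", {
  spec <- mesh_spec(256, 256, n_fibers = 8, seed = 42)
  a <- generate_mesh(spec)
  b <- generate_mesh(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$fiber_mask, b$truth$fiber_mask)
  expect_identical(a$truth$fibers, b$truth$fibers)
  spec2 <- mesh_spec(256, 256, n_fibers = 8, seed = 43)
  c <- generate_mesh(spec2)
  expect_false(identical(a$image, c$image))
})

test_that("fiber and void masks partition the image exactly", {
  for (seed in c(3, 9)) {
    sim <- generate_mesh(mesh_spec(200, 300, n_fibers = 10, seed = seed))
    expect_false(any(sim$truth$fiber_mask & sim$truth$void_mask))
    expect_true(all(sim$truth$fiber_mask | sim$truth$void_mask))
  }
})

test_that("total length equals the sum of per-fiber polyline lengths", {
  sim <- generate_mesh(mesh_spec(300, 300, n_fibers = 12, seed = 5,
                                 curvature = 0.05))
  per_fiber <- vapply(sim$truth$fibers, `[[`, 0, "length_um")
  expect_equal(sim$truth$total_centerline_length_um, sum(per_fiber))
  expect_equal(sim$truth$analytic_surface_area_um2,
               sum(pi * truth_diams(sim$truth) * per_fiber))
})

test_that("non-overlapping placement produces pairwise disjoint strokes", {
  spec <- mesh_spec(512, 512, n_fibers = 15, placement = "segment",
                    fiber_length_um = c(4, 8), allow_overlap = FALSE,
                    law = diameter_law("constant", 0.5), seed = 13)
  sim <- generate_mesh(spec)
  # re-render each fiber alone; their pixel sets must not intersect
  total <- 0L
  for (f in sim$truth$fibers) {
    single <- render_mesh(list(f$polyline_px), f$diameter_um, spec)
    total <- total + sum(single$truth$fiber_mask)
  }
  expect_identical(total, sum(sim$truth$fiber_mask))
})

test_that("sample_diameters matches closed-form lognormal moments", {
  d <- sample_diameters(diameter_law("constant", 0.5), 3, seed = 1)
  expect_identical(d, c(0.5, 0.5, 0.5))
  d0 <- sample_diameters(diameter_law("lognormal", 0.7, 0), 10, seed = 1)
  expect_true(all(d0 == 0.7))
  law <- diameter_law("lognormal", median_um = 0.48, sigma_log = 0.586)
  d <- sample_diameters(law, 1e5, seed = 2)
  expect_true(all(d > 0))
  m_expect <- 0.48 * exp(0.586^2 / 2)  # ~0.570
  expect_lt(abs(mean(d) / m_expect - 1), 0.02)
  expect_lt(abs(median(d) / 0.48 - 1), 0.02)
})

test_that("invalid specs are rejected with the offending field named", {
  expect_error(mesh_spec(fg_intensity = 0.2, bg_intensity = 0.8),
               "fg_intensity", class = "fm_validation_error")
  expect_error(mesh_spec(um_per_px = -1), "um_per_px",
               class = "fm_validation_error")
  expect_error(mesh_spec(um_per_px = 0.5),
               "2 px", class = "fm_validation_error")  # 0.96 px median
  expect_error(mesh_spec(n_fibers = 2.5), "n_fibers",
               class = "fm_validation_error")
  expect_error(sample_diameters(list(kind = "weird"), 5, 1),
               class = "fm_validation_error")
})

test_that("ground truth round-trips through JSON and the label TIFF", {
  sim <- generate_mesh(mesh_spec(128, 128, n_fibers = 4, seed = 6))
  jp <- withr::local_tempfile(fileext = ".json")
  lp <- withr::local_tempfile(fileext = ".tif")
  write_mesh_truth(sim$truth, jp, lp)
  back <- read_mesh_truth(jp)
  expect_equal(back$total_centerline_length_um,
               sim$truth$total_centerline_length_um)
  expect_equal(back$fibers[[2]]$diameter_um, sim$truth$fibers[[2]]$diameter_um)
  lab <- round(tiff::readTIFF(lp) * 65535)
  expect_identical(lab > 0, unname(sim$truth$label > 0))
  expect_equal(sort(unique(as.vector(lab))), c(0, seq_along(sim$truth$fibers)))
})

test_that("scale bars live in a reserved margin outside the truth masks", {
  spec <- mesh_spec(256, 256, n_fibers = 6, seed = 8, noise_sd = 0,
                    scale_bar = list(length_um = 5, thickness_px = 4))
  sim <- generate_mesh(spec)
  bar_rows <- (256 - 19):256  # the reserved margin: thickness + 16 rows
  expect_false(any(sim$truth$fiber_mask[bar_rows, ]))
  expect_true(any(sim$image[bar_rows, ] == 1))  # the bar itself is drawn
  bar_px <- sum(sim$image[bar_rows, ] == 1)
  expect_equal(bar_px, 4 * round(5 / spec$um_per_px))
})
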