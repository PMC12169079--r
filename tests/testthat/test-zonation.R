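test_that("an empty portal mask leaves all tissue as lobule", {
  nr <- 60; nc <- 60
  empty <- matrix(FALSE, nr, nc)
  masks <- mask_bundle(matrix(TRUE, nr, nc), empty, empty, empty, pixel_size_um = 2)
  zm <- build_zone_map(masks, 50)
  expect_equal(zm$areas_mm2[["PORTAL"]], 0)
  expect_equal(zm$areas_mm2[["PORTAL_INTERFACE"]], 0)
  expect_equal(zm$areas_mm2[["LOBULAR_INTERFACE"]], 0)
  expect_equal(zm$areas_mm2[["LOBULE_EXTRASINUSOIDAL"]], zm$total_tissue_mm2)
})

test_that("a disk portal yields the analytic annulus areas", {
  # 100 um radius portal at 1 um/px; 50 um band
  masks <- disk_masks(nr = 400, nc = 400, ps = 1, centre = c(200, 200), radius_um = 100)
  zm <- build_zone_map(masks, 50)
  pi_px <- sum(zm$labels == ZONE_LEVELS[["PORTAL_INTERFACE"]])
  core_px <- sum(zm$labels == ZONE_LEVELS[["PORTAL"]])
  expect_lt(abs(pi_px - pi * (100^2 - 50^2)) / (pi * (100^2 - 50^2)), 0.03)
  expect_lt(abs(core_px - pi * 50^2) / (pi * 50^2), 0.03)
})

test_that("zone labels partition the tissue", {
  masks <- disk_masks(nr = 150, nc = 120, ps = 2, centre = c(110, 140),
                      radius_um = 60, duct_radius_um = 10, sinusoid_rows = c(10:12, 100:103))
  zm <- build_zone_map(masks, 50)
  tissue <- masks$hepatocyte | masks$portal | masks$sinusoid | masks$duct
  expect_true(all(zm$labels[tissue] > 0))
  expect_true(all(zm$labels[!tissue] == 0))
  expect_equal(sum(zm$areas_mm2), sum(tissue) * 4 * 1e-6)
  za <- zone_areas(zm)
  expect_equal(sum(za$area_mm2), attr(za, "total_tissue_mm2"))
})

test_that("interface bands match a brute-force distance check", {
  # two-disk geometry on a small raster; band 20 um at 2 um/px
  masks1 <- disk_masks(nr = 100, nc = 100, ps = 2, centre = c(70, 60), radius_um = 40)
  px <- (seq_len(100) - 0.5) * 2
  d2 <- outer((px - 150)^2, (px - 140)^2, "+")
  portal <- masks1$portal | (d2 <= 30^2)
  sin_m <- matrix(FALSE, 100, 100); sin_m[5:7, ] <- TRUE
  sin_m <- sin_m & !portal
  masks <- mask_bundle(!portal & !sin_m, portal, sin_m,
                       matrix(FALSE, 100, 100), pixel_size_um = 2)
  band <- 20
  zm <- build_zone_map(masks, band)
  lobule <- !portal
  d_to_lob <- brute_force_distance(lobule, 2)
  d_to_por <- brute_force_distance(portal, 2)
  expect_identical(zm$labels == ZONE_LEVELS[["PORTAL_INTERFACE"]],
                   portal & d_to_lob <= band)
  expect_identical(zm$labels == ZONE_LEVELS[["LOBULAR_INTERFACE"]],
                   lobule & d_to_por <= band)
})

test_that("a band equal to the pixel size gives one-pixel bands on a straight edge", {
  nr <- 40; nc <- 40; ps <- 5
  portal <- matrix(FALSE, nr, nc); portal[, 1:20] <- TRUE
  masks <- mask_bundle(!portal, portal, matrix(FALSE, nr, nc),
                       matrix(FALSE, nr, nc), pixel_size_um = ps)
  zm <- build_zone_map(masks, band_width_um = ps)
  expect_true(all(zm$labels[, 20] == ZONE_LEVELS[["PORTAL_INTERFACE"]]))
  expect_true(all(zm$labels[, 19] == ZONE_LEVELS[["PORTAL"]]))
  expect_true(all(zm$labels[, 21] == ZONE_LEVELS[["LOBULAR_INTERFACE"]]))
  expect_true(all(zm$labels[, 22] == ZONE_LEVELS[["LOBULE_EXTRASINUSOIDAL"]]))
  expect_error(build_zone_map(masks, band_width_um = 0), "band_width_um")
})

test_that("zone areas are stable under raster refinement", {
  za <- lapply(c(2, 1), function(ps) {
    masks <- disk_masks(nr = round(400 / ps), nc = round(400 / ps), ps = ps,
                        centre = c(200, 200), radius_um = 80)
    build_zone_map(masks, 50)$areas_mm2
  })
  for (z in c("PORTAL", "PORTAL_INTERFACE", "LOBULAR_INTERFACE",
              "LOBULE_EXTRASINUSOIDAL")) {
    expect_lt(abs(za[[1]][[z]] - za[[2]][[z]]) / max(za[[2]][[z]], 1e-9), 0.03)
  }
})

test_that("mask validation rejects inconsistent input", {
  nr <- 10; nc <- 10
  m <- matrix(FALSE, nr, nc)
  expect_error(mask_bundle(m, matrix(FALSE, nr, nc + 1), m, m, 1), "dimensions")
  bad <- matrix(0.5, nr, nc)
  expect_error(mask_bundle(bad, m, m, m, 1), "not binary")
})
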