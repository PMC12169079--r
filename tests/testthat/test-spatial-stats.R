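zm_fixture <- local({
  masks <- disk_masks(nr = 150, nc = 150, ps = 2, centre = c(150, 150),
                      radius_um = 70, duct_radius_um = 12,
                      sinusoid_rows = c(10:13, 120:124))
  build_zone_map(masks, 50)
})

test_that("cells are assigned the zone of their centroid pixel", {
  # pick one pixel of each zone and place a cell at its centre
  cells <- do.call(rbind, lapply(names(ZONE_LEVELS), function(z) {
    idx <- which(zm_fixture$labels == ZONE_LEVELS[[z]])[1]
    nr <- nrow(zm_fixture$labels)
    row <- ((idx - 1) %% nr) + 1
    col <- ((idx - 1) %/% nr) + 1
    data.frame(cell_id = z, x_um = (col - 0.5) * 2, y_um = (row - 0.5) * 2,
               cell_type = "CD8_T", stringsAsFactors = FALSE)
  }))
  out <- assign_zones(cells, zm_fixture)
  expect_equal(out$zone, names(ZONE_LEVELS))

  empty <- assign_zones(cells[0, ], zm_fixture)
  expect_equal(nrow(empty), 0L)

  outside <- cells
  outside$x_um[1] <- 1e6
  expect_warning(out2 <- assign_zones(outside, zm_fixture), "outside")
  expect_true(is.na(out2$zone[1]))
  expect_equal(attr(out2, "n_outside"), 1L)
})

test_that("assigned zones equal generator ground truth for all interior cells", {
  gc1 <- generate_cells(zm_fixture, cell_sim_params(
    base_density_per_mm2 = c(CD8_T = 800, Other = 1500),
    clone_labels = "clone1", clone_freq_in_cd8 = 0.1,
    pi_enrichment_factor = 2, seed = 21
  ))
  cells <- assign_zones(gc1$cells, zm_fixture)
  expect_gt(nrow(cells), 100)
  expect_true(all(cells$zone == cells$true_zone))
})

test_that("zone statistics report consistent fractions and densities", {
  gc1 <- generate_cells(zm_fixture, cell_sim_params(
    base_density_per_mm2 = c(CD8_T = 500), seed = 3
  ))
  cells <- assign_zones(gc1$cells, zm_fixture)
  zs <- zone_statistics(cells, zm_fixture)
  expect_equal(sum(zs$fraction), 1, tolerance = 1e-9)
  expect_equal(zs$density_per_mm2, zs$n_cells / zs$area_mm2)
  expect_equal(attr(zs, "overall_density_per_mm2"),
               sum(zs$n_cells) / zm_fixture$total_tissue_mm2)
  # all selected cells in one zone
  one <- zone_statistics(cells, zm_fixture,
                         subset = cells$zone == "LOBULE_EXTRASINUSOIDAL")
  expect_equal(one$fraction[one$zone == "LOBULE_EXTRASINUSOIDAL"], 1)
  expect_equal(sum(one$fraction), 1)
})

test_that("marker fractions are computed within the selection", {
  cells <- data.frame(
    cell_id = sprintf("c%d", 1:40), x_um = 150, y_um = 150,
    cell_type = "CD8_T",
    marker_GranzymeB = rep(c(TRUE, FALSE), 20),
    stringsAsFactors = FALSE
  )
  cells <- assign_zones(cells, zm_fixture)
  zs <- zone_statistics(cells, zm_fixture, markers = "GranzymeB")
  z <- cells$zone[1]
  expect_equal(zs$frac_GranzymeB[zs$zone == z], 0.5)
  expect_error(zone_statistics(cells, zm_fixture, markers = "Missing"), "not found")
})

test_that("the Fisher comparison matches trivial and oracle cases", {
  equal <- proportion_test(rbind(c(10, 90), c(10, 90)))
  expect_equal(equal$odds_ratio, 1)
  expect_equal(equal$p_value, 1)
  expect_false(equal$continuity)

  skewed <- proportion_test(rbind(c(8, 2), c(1, 9)))
  expect_equal(skewed$p_value, fisher_oracle(rbind(c(8, 2), c(1, 9))),
               tolerance = 1e-12)

  zero <- proportion_test(rbind(c(0, 10), c(5, 5)))
  expect_true(zero$continuity)
  expect_gt(zero$odds_ratio, 0)

  cells_a <- data.frame(marker_M = c(TRUE, TRUE, FALSE))
  cells_b <- data.frame(marker_M = c(FALSE, FALSE, TRUE))
  pt <- proportion_test(cells_a, cells_b, marker = "M")
  expect_equal(unname(pt$table[1, ]), c(2, 1))
  expect_error(proportion_test(cells_a, cells_b, marker = "X"), "absent")
})

test_that("enrichment test is null on the full selection and reproducible", {
  gc1 <- generate_cells(zm_fixture, cell_sim_params(
    base_density_per_mm2 = c(CD8_T = 400), seed = 8
  ))
  cells <- assign_zones(gc1$cells, zm_fixture)
  full <- zone_enrichment_test(cells, rep(TRUE, nrow(cells)), n_perm = 199, seed = 1)
  expect_true(all(full$statistic == 0))
  expect_true(all(full$p_value == 1))

  sel <- seq_len(nrow(cells)) %% 7 == 0
  e1 <- zone_enrichment_test(cells, sel, n_perm = 199, seed = 5)
  e2 <- zone_enrichment_test(cells, sel, n_perm = 199, seed = 5)
  expect_identical(e1, e2)
  # relabelling cell ids does not change the result
  cells2 <- cells
  cells2$cell_id <- rev(cells2$cell_id)
  e3 <- zone_enrichment_test(cells2, sel, n_perm = 199, seed = 5)
  expect_equal(e3$p_value, e1$p_value)

  expect_error(zone_enrichment_test(cells, sel, n_perm = 50), "n_perm")
})
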