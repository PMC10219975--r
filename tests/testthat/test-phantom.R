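test_that("cell counts follow the region densities", {
  # zero-rate region stays empty
  reg0 <- region_model(1, "empty", c(0, 1000), c(0, 1000), c(0, 1000), 0)
  ph0 <- generate_tissue_phantom(c(1000, 1000, 1000), reg0, seed = 1)
  expect_equal(nrow(ph0$cells), 0)

  # Poisson concentration: 1 mm^3 at 1000 cells/mm^3. The oracle is the
  # Poisson distribution itself: |N - 1000| <= 3 * sqrt(1000) holds for
  # all of a fixed panel of seeds.
  reg <- region_model(1, "bulk", c(0, 1000), c(0, 1000), c(0, 1000), 1000)
  for (s in 1:8) {
    ph <- generate_tissue_phantom(c(1000, 1000, 1000), reg, seed = s)
    expect_lt(abs(nrow(ph$cells) - 1000), 3 * sqrt(1000))
  }

  # 2:1 density contrast with D*V >= 500 recovers a ratio in [1.6, 2.4]
  regs <- dplyr::bind_rows(
    region_model(1, "hi", c(0, 500), c(0, 1000), c(0, 1000), 2000),
    region_model(2, "lo", c(500, 1000), c(0, 1000), c(0, 1000), 1000)
  )
  for (s in 1:5) {
    ph <- generate_tissue_phantom(c(1000, 1000, 1000), regs, seed = s)
    counts <- table(ph$cells$region_id)
    expect_gt(counts[["1"]] / counts[["2"]], 1.6)
    expect_lt(counts[["1"]] / counts[["2"]], 2.4)
  }
})

test_that("phantom generation is seed-deterministic and conserves counts", {
  regs <- dplyr::bind_rows(
    region_model(1, "a", c(0, 400), c(0, 400), c(0, 200), 8000),
    region_model(2, "b", c(400, 800), c(0, 400), c(0, 200), 4000)
  )
  p1 <- generate_tissue_phantom(c(800, 400, 200), regs, seed = 42)
  p2 <- generate_tissue_phantom(c(800, 400, 200), regs, seed = 42)
  expect_identical(p1$cells, p2$cells)
  p3 <- generate_tissue_phantom(c(800, 400, 200), regs, seed = 43)
  expect_false(identical(p1$cells, p3$cells))
  # count conservation across regions
  expect_equal(sum(table(p1$cells$region_id)), nrow(p1$cells))
  # every cell inside its region and the box
  expect_true(all(p1$cells$x >= 0 & p1$cells$x <= 800))
  expect_true(all(p1$cells$z >= 0 & p1$cells$z <= 200))
  expect_true(all(p1$cells$soma_radius >= p1$cells$nucleus_radius))
})

test_that("region geometry is validated", {
  over <- dplyr::bind_rows(
    region_model(1, "a", c(0, 600), c(0, 400), c(0, 200), 100),
    region_model(2, "b", c(500, 800), c(0, 400), c(0, 200), 100)
  )
  expect_error(generate_tissue_phantom(c(800, 400, 200), over, seed = 1),
               "overlap")
  zero <- region_model(1, "z", c(100, 100), c(0, 400), c(0, 200), 100)
  expect_error(generate_tissue_phantom(c(800, 400, 200), zero, seed = 1),
               "zero-volume")
  outside <- region_model(1, "o", c(0, 900), c(0, 400), c(0, 200), 100)
  expect_error(generate_tissue_phantom(c(800, 400, 200), outside, seed = 1),
               "outside")
})

test_that("empirical density converges to nominal with volume", {
  sides <- c(300, 700, 1500)
  for (side in sides) {
    reg <- region_model(1, "bulk", c(0, side), c(0, side), c(0, side), 5000)
    ph <- generate_tissue_phantom(rep(side, 3), reg, seed = 7)
    vol <- (side / 1000)^3
    expected <- 5000 * vol
    expect_lt(abs(nrow(ph$cells) - expected), 3 * sqrt(expected) + 1)
  }
})

test_that("bead phantoms respect count, diameter and separation", {
  b1 <- generate_bead_phantom(1, c(50, 50, 50), min_separation_um = 10,
                              seed = 1)
  expect_equal(nrow(b1$beads), 1)

  b10 <- generate_bead_phantom(10, c(300, 300, 100),
                               min_separation_um = 30, seed = 2)
  expect_equal(nrow(b10$beads), 10)
  expect_true(all(b10$beads$diameter_um == 4))
  d <- as.matrix(dist(b10$beads[, c("x", "y", "z")]))
  expect_true(all(d[upper.tri(d)] >= 30))

  # infeasible placement errors out after bounded retries
  expect_error(
    generate_bead_phantom(2, c(50, 50, 50), min_separation_um = 500,
                          seed = 3, max_tries = 200),
    "could not place")
  expect_error(
    generate_bead_phantom(2, c(50, 50, 50), min_separation_um = 3, seed = 1),
    "exceed")
})

test_that("label voxelisation reproduces region geometry", {
  reg <- region_model(3, "all", c(0, 100), c(0, 100), c(0, 100), 0)
  ph <- generate_tissue_phantom(c(100, 100, 100), reg, seed = 1)
  vol <- voxelize_labels(ph, 10)
  expect_true(all(vol == 3L))

  halves <- dplyr::bind_rows(
    region_model(1, "left", c(0, 50), c(0, 100), c(0, 100), 0),
    region_model(2, "right", c(50, 100), c(0, 100), c(0, 100), 0)
  )
  ph2 <- generate_tissue_phantom(c(100, 100, 100), halves, seed = 1)
  vol2 <- voxelize_labels(ph2, 10)
  n_total <- length(vol2)
  slab <- prod(dim(vol2)[c(1, 3)]) # one x-slab of voxels
  expect_lte(abs(sum(vol2 == 1L) - n_total / 2), slab)
  expect_lte(abs(sum(vol2 == 2L) - n_total / 2), slab)

  # empty phantom (no regions) is all background
  bead <- generate_bead_phantom(1, c(50, 50, 50), min_separation_um = 10,
                                seed = 1)
  expect_true(all(voxelize_labels(bead, 10) == 0L))

  expect_warning(voxelize_labels(ph2, 60), "spacing")
})

test_that("ground-truth section visibility follows the 1/e cutoff", {
  sched <- schedule_sections(200, 50, attenuation_depth_um = NULL)
  cells <- tibble::tibble(
    x = 50, y = 50,
    z = c(0, 19.9, 20.1, 50, 69.9, 169.5)
  )
  ph <- planted_phantom(cells, box_um = c(100, 100, 200))
  tab <- ground_truth_section_table(ph, sched, d_um = 20,
                                    visibility_cutoff = exp(-1))
  # z* = -d log(1/e) = 20 um
  expect_setequal(tab$cell_id[tab$section_index == 1], c(1, 2))
  expect_setequal(tab$cell_id[tab$section_index == 2], c(4, 5))
  expect_setequal(tab$cell_id[tab$section_index == 4], 6)
  expect_false(3 %in% tab$cell_id)

  # with thickness > z*, no cell is counted twice (200-cell phantom)
  reg <- region_model(1, "bulk", c(0, 400), c(0, 400), c(0, 500), 2500)
  big <- generate_tissue_phantom(c(400, 400, 500), reg, seed = 5)
  sched2 <- schedule_sections(500, 50)
  tab2 <- ground_truth_section_table(big, sched2, d_um = 20)
  expect_equal(anyDuplicated(tab2$cell_id), 0)
})
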