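test_that("segmentation recovers planted well-separated cells", {
  oc <- optical_config(fov_mm = c(0.6, 0.4), gain = 25)
  gx <- expand.grid(x = seq(30, 570, length.out = 10),
                    y = seq(30, 370, length.out = 5))
  cells <- withr::with_seed(4, tibble::tibble(
    x = gx$x, y = gx$y, z = runif(50, 2, 10),
    amp_pi = rlnorm(50, -0.045, 0.3)
  ))
  ph <- planted_phantom(cells, box_um = c(600, 400, 40))
  img <- render_block_face(ph, oc, seed = 5)
  seg <- segment_cells(img)
  expect_gte(nrow(seg$cells), 48)
  expect_lte(nrow(seg$cells), 52)
  err <- vapply(seq_len(50), function(k) {
    min(sqrt((seg$cells$x_um - cells$x[k])^2 +
               (seg$cells$y_um - cells$y[k])^2))
  }, numeric(1))
  expect_lt(max(err), 2)
  expect_true(all(seg$cells$area_um2 > 0))

  # blank image: empty record list, not an error
  blank <- render_block_face(
    planted_phantom(cells[0, ], box_um = c(100, 100, 40)),
    small_optics(), seed = 2)
  expect_equal(nrow(segment_cells(blank)$cells), 0)
})

test_that("touching cells with overlapping somata are split", {
  pair <- tibble::tibble(x = c(96, 104), y = 100, z = 5)
  ph <- planted_phantom(pair)
  img <- render_block_face(ph, small_optics(), noise = FALSE, seed = 1)
  seg <- segment_cells(img)
  expect_equal(nrow(seg$cells), 2)
})

test_that("cells are assigned the region label at their centroid", {
  regs <- dplyr::bind_rows(
    region_model(1, "left", c(0, 100), c(0, 200), c(0, 50), 0),
    region_model(2, "right", c(100, 200), c(0, 200), c(0, 50), 0)
  )
  ph <- generate_tissue_phantom(c(200, 200, 50), regs, seed = 1)
  lab <- region_label_image(ph, 2)
  cells <- tibble::tibble(x_um = c(50, 150, 99.5, 100.5, 500),
                          y_um = c(100, 100, 100, 100, 100))
  out <- assign_regions(cells, lab)
  expect_equal(out$region_id, c(1L, 2L, 1L, 2L, 0L))

  # ground-truth fixture: interior cells assigned perfectly
  cfg <- habenula_fixture_config(3)
  ph2 <- duvtomo:::phantom_from_config(cfg)
  lab2 <- region_label_image(ph2, 2)
  truth <- assign_regions(
    tibble::tibble(x_um = ph2$cells$x, y_um = ph2$cells$y), lab2)
  interior <- with(ph2$cells,
                   pmin(abs(x - 100), abs(x - 400), abs(x - 700),
                        abs(y - 100), abs(y - 500)) > 5)
  expect_true(all(truth$region_id[interior] ==
                    ph2$cells$region_id[interior]))
})

test_that("counts and densities are conserved and scale-correct", {
  cells <- tibble::tibble(
    section_index = rep(1:2, c(10, 4)),
    region_id = c(rep(1L, 10), rep(2L, 3), 0L)
  )
  areas <- tibble::tibble(region_id = c(1L, 2L), area_mm2 = c(0.1, 0.05))
  rc <- count_and_density(cells, areas)
  expect_equal(rc$density_per_mm2[rc$section_index == 1 &
                                    rc$region_id == 1], 100)
  expect_equal(sum(rc$n_cells), nrow(cells))
  bad_areas <- tibble::tibble(region_id = c(1L, 2L), area_mm2 = c(0.1, 0))
  expect_error(count_and_density(cells, bad_areas), "zero area")
})

test_that("region-tree aggregation preserves counts at every level", {
  # single node
  t1 <- aggregate_region_tree(
    tibble::tibble(node = "root", count = 12),
    tibble::tibble(node = "root", parent = NA_character_))
  expect_equal(t1$pct_root, 100)

  # forced two-leaf split
  tree <- tibble::tibble(node = c("root", "a", "b"),
                         parent = c(NA, "root", "root"))
  t2 <- aggregate_region_tree(
    tibble::tibble(node = c("a", "b"), count = c(30, 70)), tree)
  expect_equal(t2$pct_root[t2$node == "a"], 30)
  expect_equal(t2$pct_root[t2$node == "b"], 70)
  expect_equal(t2$total_count[t2$node == "root"], 100)

  # three-level tree: child sums equal parent totals everywhere
  tree3 <- tibble::tibble(
    node = c("root", "A", "B", "A1", "A2", "B1"),
    parent = c(NA, "root", "root", "A", "A", "B"))
  counts3 <- tibble::tibble(node = c("A1", "A2", "B1", "B"),
                            count = c(5, 7, 11, 2))
  t3 <- aggregate_region_tree(counts3, tree3)
  tot <- function(n) t3$total_count[t3$node == n]
  expect_equal(tot("A"), tot("A1") + tot("A2"))
  expect_equal(tot("B"), 13) # own 2 + child 11
  expect_equal(tot("root"), 25)
  expect_equal(t3$pct_root[t3$node == "root"], 100)
  kids_pct <- t3$pct_parent[t3$node %in% c("A1", "A2")]
  expect_equal(sum(kids_pct), 100)

  # cycles are rejected
  cyc <- tibble::tibble(node = c("root", "a", "b"),
                        parent = c(NA, "b", "a"))
  expect_error(
    aggregate_region_tree(tibble::tibble(node = "a", count = 1), cyc))
})

test_that("paired t matches the hand formula and t.test", {
  same <- c(3, 5, 2, 8)
  r0 <- paired_t(same, same)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  a <- c(2.0, 4.0, 3.0); b <- c(1.0, 1.5, 2.5)
  r <- paired_t(a, b)
  expect_equal(r$statistic, 2.2188, tolerance = 1e-4)
  expect_equal(r$df, 2)
  # independent oracle: stats::t.test
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(r$statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r$p_value, tt$p.value, tolerance = 1e-12)

  # ten paired sections give the df = 9 convention
  set.seed(1)
  r10 <- paired_t(rnorm(10, 5), rnorm(10, 3))
  expect_equal(r10$df, 9)

  expect_warning(rz <- paired_t(c(2, 3, 4), c(1, 2, 3)), "zero-variance")
  expect_true(rz$flagged)
  expect_error(paired_t(1:3, 1:4), "lengths")
})

test_that("Welch ANOVA, Tukey and Shapiro-Wilk behave as specified", {
  # hand-computed Welch oracle on a small example
  g1 <- c(1, 2, 3, 4); g2 <- c(2, 4, 6, 9); g3 <- c(10, 12, 11, 14)
  vals <- c(g1, g2, g3); grp <- rep(letters[1:3], each = 4)
  w <- group_stats(vals, grp)
  wi <- vapply(list(g1, g2, g3), function(g) length(g) / var(g), numeric(1))
  mw <- sum(wi * vapply(list(g1, g2, g3), mean, numeric(1))) / sum(wi)
  k <- 3
  num <- sum(wi * (vapply(list(g1, g2, g3), mean, numeric(1)) - mw)^2) / (k - 1)
  lam <- sum((1 - wi / sum(wi))^2 / (vapply(list(g1, g2, g3), length,
                                            numeric(1)) - 1)) / (k^2 - 1)
  F_hand <- num / (1 + 2 * (k - 2) * lam)
  expect_equal(w$welch$F, F_hand, tolerance = 1e-10)
  expect_gt(w$welch$df2 %% 1, 0) # Satterthwaite df is fractional here
  expect_true(w$shapiro$W > 0 && w$shapiro$W <= 1)

  # a 3-sigma shifted group is detected and flagged by Tukey
  set.seed(9)
  base <- rnorm(30)
  shifted <- c(base[1:20], base[21:30] + 3)
  gs <- group_stats(shifted, rep(c("a", "b", "c"), each = 10))
  expect_lt(gs$welch$p_value, 0.01)
  worst <- gs$tukey$pair[which.min(gs$tukey$p_adj)]
  expect_true(grepl("c", worst))

  # degenerate constant groups are flagged
  expect_warning(
    gflat <- group_stats(rep(c(1, 2), each = 3), rep(c("a", "b"), each = 3)),
    "zero-variance")
  expect_true(gflat$flagged)
  expect_true(is.na(gflat$welch$F))
  expect_error(group_stats(1:4, c("a", "a", "a", "b")), "n >= 2")
})

test_that("density is invariant to intensity scale and pixel size", {
  cells <- withr::with_seed(2, tibble::tibble(
    x = runif(40, 20, 180), y = runif(40, 20, 180), z = runif(40, 2, 12)))
  ph <- planted_phantom(cells)
  reg <- region_model(1, "all", c(0, 200), c(0, 200), c(0, 200), 0)
  ph$regions <- reg
  ph$cells$region_id <- 1L
  count_at <- function(pix, gain) {
    oc <- optical_config(fov_mm = c(0.2, 0.2), pixel_size_um = pix,
                         gain = gain)
    img <- render_block_face(ph, oc, noise = FALSE, seed = 1)
    seg <- segment_cells(img)
    lab <- region_label_image(ph, pix)
    cc <- assign_regions(seg$cells, lab)
    cc$section_index <- 1L
    rc <- count_and_density(cc, region_areas_from_labels(lab))
    rc$density_per_mm2[rc$region_id == 1]
  }
  d_ref <- count_at(2, 25)
  expect_equal(count_at(2, 50), d_ref, tolerance = 0.1) # brighter image
  expect_equal(count_at(1, 25), d_ref, tolerance = 0.1) # finer pixels
})
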