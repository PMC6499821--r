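rect_ring <- function(x0, x1, y0, y1)
  rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))

test_that("planar grids tile the extent with centroids at cell centers", {
  g <- make_grid(1, "planar", extent = c(0, 6, 0, 6))
  expect_equal(nrow(g), 36)
  expect_setequal(g$x, unique(rep(0:5 + 0.5, 6)))
  expect_equal(g$x[g$row == 0 & g$col == 2], 2.5)
  expect_equal(g$y[g$row == 3 & g$col == 0], 3.5)
  expect_error(make_grid(-1, "planar", extent = c(0, 6, 0, 6)), "positive")
})

test_that("spherical grids have exactly equal-area cells", {
  g <- make_grid(1000, "spherical")
  expect_true(all(abs(g$area / g$area[1] - 1) < 1e-6))
  expect_true(all(abs(g$lat) <= 90))
  expect_true(all(abs(g$lon) <= 180))
})

test_that("an extent smaller than one cell still yields one cell", {
  g <- make_grid(10, "planar", extent = c(0, 3, 0, 2))
  expect_equal(nrow(g), 1)
})

test_that("overlay counts languages per cell and drops empty cells", {
  g <- make_grid(1, "planar", extent = c(0, 2, 0, 2))
  whole <- language_record("all", "F", rect_ring(-0.5, 2.5, -0.5, 2.5), 10)
  ov <- overlay_languages(g, list(whole))
  expect_equal(nrow(ov), 4)
  expect_true(all(ov$diversity == 1))

  a <- language_record("a", "F1", rect_ring(0.2, 0.8, 0.2, 0.8), 5)
  b <- language_record("b", "F2", rect_ring(1.2, 1.8, 1.2, 1.8), 7)
  ov2 <- overlay_languages(g, list(a, b))
  expect_equal(nrow(ov2), 2)
  expect_true(all(ov2$diversity == 1))
  expect_setequal(unlist(ov2$occupants), c("a", "b"))

  # two same-family languages sharing a cell
  c1 <- language_record("c1", "F", rect_ring(0.1, 0.9, 0.1, 0.9), 1)
  c2 <- language_record("c2", "F", rect_ring(0.2, 0.7, 0.2, 0.7), 2)
  ov3 <- overlay_languages(g, list(c1, c2))
  expect_equal(ov3$diversity[1], 2)
  expect_equal(ov3$n_families[1], 1)
  expect_equal(ov3$min_pop[1], 1)
  expect_equal(ov3$avg_pop[1], 1.5)
})

test_that("a boundary touch counts as presence", {
  g <- make_grid(1, "planar", extent = c(0, 2, 0, 1))
  # polygon inside cell (1, y) touching the shared edge x = 1
  r <- language_record("t", "F", rect_ring(1, 1.5, 0.25, 0.75), 1)
  ov <- overlay_languages(g, list(r))
  expect_equal(sort(ov$col), c(0, 1))   # touch on x = 1 counts for the left cell
})

test_that("overlay is monotone and covers every intersecting language", {
  set.seed(13)
  g <- make_grid(1, "planar", extent = c(0, 5, 0, 5))
  mk <- function(id, fam) {
    cx <- runif(1, 0, 5); cy <- runif(1, 0, 5); r <- runif(1, 0.3, 1.5)
    th <- seq(0, 2 * pi, length.out = 17)[-17]
    language_record(id, fam, cbind(cx + r * cos(th), cy + r * sin(th)), 1)
  }
  langs <- lapply(1:6, function(i) mk(paste0("L", i), paste0("F", i %% 3)))
  ov1 <- overlay_languages(g, langs[1:5])
  ov2 <- overlay_languages(g, langs)
  common <- intersect(ov1$cell_id, ov2$cell_id)
  expect_true(all(ov1$cell_id %in% ov2$cell_id))
  expect_true(all(ov2$diversity[match(common, ov2$cell_id)] >=
                  ov1$diversity[match(common, ov1$cell_id)]))
  # every language occupies at least one cell
  expect_true(all(vapply(langs, function(l) l$language_id, "") %in%
                  unique(unlist(ov2$occupants))))
})

test_that("land fraction is clipped area with the small-island floor", {
  g <- make_grid(1, "planar", extent = c(0, 2, 0, 1))
  occ <- language_record("x", "F", rect_ring(0, 2, 0, 1), 1)
  cells <- overlay_languages(g, list(occ))
  # full land
  lf <- land_fraction(cells, list(rect_ring(-1, 3, -1, 2)))
  expect_equal(lf$land_fraction, c(1, 1))
  # half of the first cell
  lf2 <- land_fraction(cells, list(rect_ring(0, 0.5, 0, 1)))
  expect_equal(lf2$land_fraction[lf2$col == 0], 0.5)
  # a 0.3% island in an occupied cell floors at 0.01
  island <- rect_ring(0.4, 0.4 + 0.06, 0.4, 0.4 + 0.05)   # area 0.003
  lf3 <- land_fraction(cells, list(island))
  expect_equal(lf3$land_fraction[lf3$col == 0], 0.01)
  expect_error(land_fraction(cells, list()), "empty landmask")
})

test_that("subsampling keeps the right residue classes", {
  g <- make_grid(1, "planar", extent = c(0, 6, 0, 6))
  expect_equal(nrow(subsample_cells(g, 1)), 36)
  s3 <- subsample_cells(g, 3, 0, 0)
  expect_equal(nrow(s3), 4)
  expect_true(all(s3$row %% 3 == 0 & s3$col %% 3 == 0))
  expect_error(subsample_cells(g, 3, 3, 0), "offsets")
})

test_that("step-3 regimes are nine and partition the cells", {
  g <- make_grid(1, "planar", extent = c(0, 7, 0, 5))
  regs <- subsample_regimes(g, 3)
  expect_length(regs, 9)
  ids <- unname(unlist(lapply(regs, `[[`, "cell_id")))
  expect_equal(sort(ids), sort(g$cell_id))   # each cell in exactly one regime
  expect_equal(anyDuplicated(ids), 0)
})

test_that("language records validate and repair their polygons", {
  expect_error(language_record("bad", "F", rbind(c(0, 0), c(1, 1), c(2, 2)), 1),
               "invalid polygon for language bad")
  expect_error(language_record("neg", "F", rect_ring(0, 1, 0, 1), -5),
               "non-negative")
  # consecutive duplicate vertices are repaired
  ring <- rbind(c(0, 0), c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  rec <- language_record("ok", "F", ring, 3)
  expect_equal(nrow(rec$ring), 4)
})
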