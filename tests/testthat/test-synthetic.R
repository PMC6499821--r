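test_that("the generator is deterministic under its seed", {
  s1 <- small_sim(31)
  s2 <- small_sim(31)
  expect_identical(s1$cells$log_diversity, s2$cells$log_diversity)
  expect_identical(s1$cells$temp_mean, s2$cells$temp_mean)
  expect_identical(write_newick(s1$tree), write_newick(s2$tree))
  s3 <- small_sim(32)
  expect_false(identical(s1$cells$log_diversity, s3$cells$log_diversity))
})

test_that("families, isolates and speaker counts are generated as configured", {
  cfg <- small_config(33)
  langs <- gen_languages(cfg)
  fams <- unique(language_families(langs$taxonomy))
  expect_length(fams, cfg$n_families)
  sizes <- table(language_families(langs$taxonomy))
  iso <- names(sizes)[sizes == 1]
  for (f in iso) {
    # singleton families are isolates: path is the language id itself
    p <- taxonomy_paths(langs$taxonomy)[[f]]
    expect_identical(p, f)
  }
  speakers <- vapply(langs$records, `[[`, 0, "speakers")
  expect_true(all(speakers >= 0))
  expect_gt(stats::sd(log1p(speakers)), 0.5)  # heavy-tailed populations
})

test_that("tight family dispersion makes phylogenetic similarity spatial", {
  cfg <- small_config(34, dispersion_km = 150, n_families = 12)
  sim <- suppressWarnings(simulate_language_data(cfg))
  D <- sim$D; P <- sim$P
  near <- D > 0 & D <= 1500
  far <- D >= 4000
  expect_gt(mean(P[near]), mean(P[far]))
})

test_that("covariate fields honor their correlation range", {
  g <- make_grid(1, "planar", extent = c(0, 20, 0, 20))
  neighbor_cor <- function(cells, v) {
    key <- paste(cells$row, cells$col)
    idx <- match(paste(cells$row, cells$col + 1), key)
    ok <- !is.na(idx)
    stats::cor(v[ok], v[idx[ok]])
  }
  cfg_long <- small_config(35, covariates = "f", cov_range_km = 10, n_biomes = 0)
  cfg_short <- small_config(35, covariates = "f", cov_range_km = 1e-3, n_biomes = 0)
  long <- gen_covariates(cfg_long, g)
  short <- gen_covariates(cfg_short, g)
  expect_gt(neighbor_cor(long, long$f), 0.8)
  expect_lt(abs(neighbor_cor(short, short$f)), 0.15)
})

test_that("shared parent fields create correlated predictors", {
  g <- make_grid(1, "planar", extent = c(0, 15, 0, 15))
  cfg <- small_config(36, covariates = c("a", "b"), cov_range_km = 3,
                      n_biomes = 0)
  cells <- gen_covariates(cfg, g, mix = list(b = list(parent = "a", rho = 0.9)))
  expect_gt(stats::cor(cells$a, cells$b), 0.7)
})

test_that("responses follow the configured model exactly when noiseless", {
  sim <- small_sim(37)
  cells <- redraw_response(sim, seed = 1, sigma2 = 0)
  b <- sim$config$b
  X <- cbind(1, as.matrix(cells[setdiff(names(b), "(Intercept)")]))
  expect_equal(cells$log_diversity, drop(X %*% b[c("(Intercept)",
                                                   setdiff(names(b), "(Intercept)"))]),
               tolerance = 1e-12)
})

test_that("iid responses carry no spatial autocorrelation", {
  sim <- small_sim(38)
  n <- nrow(sim$cells)
  # Moran's I with inverse-distance weights, expectation -1/(n-1) under iid
  W <- 1 / (sim$D + diag(n)); diag(W) <- 0
  moran <- function(z) {
    zc <- z - mean(z)
    n / sum(W) * sum(W * outer(zc, zc)) / sum(zc^2)
  }
  set.seed(50)
  vals <- replicate(30, {
    cells <- redraw_response(sim, seed = sample.int(1e6, 1), alpha = 0,
                             b = c("(Intercept)" = 0))
    moran(cells$log_diversity)
  })
  expect_lt(abs(mean(vals) - (-1 / (n - 1))), 0.05)
  # strongly spatial responses show positive autocorrelation
  cells_sp <- redraw_response(sim, seed = 2, alpha = 0.9, beta = 0,
                              b = c("(Intercept)" = 0))
  expect_gt(moran(cells_sp$log_diversity), 0.05)
})

test_that("a short recovery run pins the coefficients within uncertainty", {
  sim <- small_sim(39)
  b <- sim$config$b
  fit <- lsgls(log_diversity ~ land_fraction + temp_seasonality + precip_mean + npp,
               sim$cells, P = sim$P, D = sim$D, control = fast_control())
  z <- abs(coef(fit)[names(b)] - b) / fit$se[names(b)]
  expect_true(all(z < 4))
})

test_that("occupied-cell subsetting keeps exactly the requested n", {
  cfg <- small_config(40)
  sim <- suppressWarnings(simulate_language_data(cfg, n_cells = 12))
  expect_equal(nrow(sim$cells), 12)
  expect_equal(dim(sim$P), c(12L, 12L))
  expect_error(suppressWarnings(simulate_language_data(cfg, n_cells = 10000)),
               "occupied")
})
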