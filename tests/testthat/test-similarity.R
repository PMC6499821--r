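test_that("phylosor endpoints and the worked four-tip value are exact", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(phylosor_pair(tr, c("A", "B"), c("B", "A")), 1)
  expect_equal(phylosor_pair(tr, c("A", "B"), c("C", "D")), 0)
  expect_equal(phylosor_pair(tr, c("A", "B"), c("A", "C")), 4 / 7)
  expect_equal(phylosor_pair(tr, c("A", "C"), c("A", "B")), 4 / 7)  # symmetry
  expect_error(phylosor_pair(tr, c("A", "Z"), "B"), "tip not in tree: Z")
  expect_error(phylosor_pair(tr, character(0), "B"), "non-empty")
})

test_that("sharing an additional tip cannot decrease similarity", {
  set.seed(21)
  for (i in 1:10) {
    tr <- language_tree(rand_taxonomy(3, 4))
    tips <- tr$tip.label
    if (length(tips) < 4) next
    tj <- sample(tips, sample(2:length(tips), 1))
    ti <- sample(tips, sample(seq_along(tips), 1))
    extra <- setdiff(tj, ti)
    if (!length(extra)) next
    s0 <- phylosor_pair(tr, ti, tj)
    s1 <- phylosor_pair(tr, c(ti, extra[1]), tj)
    expect_gte(s1, s0 - 1e-12)
  }
})

test_that("the similarity matrix matches pairwise computation", {
  sim <- small_sim(3)
  cells <- sim$cells[1:10, ]
  P <- suppressWarnings(phylosor_matrix(sim$tree, cells, repair = FALSE))
  expect_true(isSymmetric(P))
  expect_equal(unname(diag(P)), rep(1, 10))
  for (i in c(1, 4, 8)) for (j in c(2, 6, 10)) {
    expect_equal(P[i, j],
                 phylosor_pair(sim$tree, cells$occupants[[i]], cells$occupants[[j]]))
  }
})

test_that("disjoint-family cells give the identity matrix, identical cells all ones", {
  tax <- data.frame(language_id = c("a", "b", "c"),
                    level_1 = c("F1", "F2", "F3"))
  tr <- language_tree(tax)
  P <- phylosor_matrix(tr, list("a", "b", "c"))
  expect_equal(unname(P), diag(3))
  P2 <- phylosor_matrix(tr, list(c("a", "b"), c("b", "a")), repair = FALSE)
  expect_equal(unname(P2), matrix(1, 2, 2))
  expect_error(phylosor_matrix(tr, list("a", character(0))), "empty occupant")
})

test_that("great-circle distances follow the haversine closed form", {
  cells <- data.frame(cell_id = c("p", "q", "r"),
                      lon = c(0, 180, 90), lat = c(0, 0, 0))
  d <- greatcircle_matrix(cells)
  expect_equal(d["p", "p"], 0)
  expect_equal(d["p", "q"], pi * 6371, tolerance = 1e-6)
  expect_equal(d["p", "r"], pi * 6371 / 2, tolerance = 1e-6)
  bad <- data.frame(lon = 0, lat = 95)
  expect_error(greatcircle_matrix(bad), "latitudes")
})

test_that("the Gaussian kernel decays monotonically from 1 to 0", {
  d <- matrix(c(0, 1000, 1000, 0), 2)
  expect_equal(gaussian_decay(d, 1000)[1, 2], exp(-1))
  expect_equal(diag(gaussian_decay(d, 500)), c(1, 1))
  dd <- seq(0, 5000, by = 250)
  v <- gaussian_decay(matrix(dd, 1), 1500)
  expect_true(all(diff(drop(v)) < 0))
  expect_error(gaussian_decay(d, 0), "positive")
  expect_error(gaussian_decay(d, -2), "positive")
})

test_that("the Gaussian kernel on planar coordinates is positive definite", {
  set.seed(22)
  for (i in 1:5) {
    pts <- cbind(runif(30, 0, 5000), runif(30, 0, 3000))
    K <- gaussian_decay(as.matrix(dist(pts)), runif(1, 300, 3000))
    expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("positive-definiteness repair is bounded and warns", {
  # a slightly indefinite correlation-like matrix
  M <- matrix(0.7, 4, 4); diag(M) <- 1
  M[1, 2] <- M[2, 1] <- -0.5
  expect_lt(min(eigen(M, only.values = TRUE)$values), 0)
  expect_warning(R <- repair_pd(M, max_change = 0.5), "repaired")
  expect_equal(unname(diag(R)), rep(1, 4))
  expect_gt(min(eigen(R, only.values = TRUE)$values), 0)
  expect_lt(max(abs(R - M)), 0.5)
  expect_error(suppressWarnings(repair_pd(M, max_change = 1e-6)), "max_change")
  # an already-PD matrix passes through untouched
  ok <- diag(3)
  expect_identical(repair_pd(ok), ok)
})
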