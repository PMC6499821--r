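# Independent brute-force PhyloSor oracle: walks every edge and enumerates
# its descendant tips recursively, then sums branch lengths by membership.
# Deliberately shares no code with the package's matrix-product implementation.
oracle_phylosor <- function(tree, taxa_i, taxa_j) {
  n_tip <- length(tree$tip.label)
  desc_tips <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc_tips))
  }
  bl_i <- bl_j <- shared <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- desc_tips(tree$edge[e, 2])
    len <- tree$edge.length[e]
    in_i <- any(tips %in% taxa_i)
    in_j <- any(tips %in% taxa_j)
    if (in_i) bl_i <- bl_i + len
    if (in_j) bl_j <- bl_j + len
    if (in_i && in_j) shared <- shared + len
  }
  2 * shared / (bl_i + bl_j)
}

# random taxonomy table: families of random size, optional subgroups,
# singletons become isolates
rand_taxonomy <- function(n_families = 4, max_langs = 4) {
  ids <- character(0); paths <- list()
  for (f in seq_len(n_families)) {
    fam <- sprintf("Fam%02d", f)
    size <- sample(max_langs, 1)
    grouped <- size > 1 && stats::runif(1) < 0.5
    for (i in seq_len(size)) {
      id <- sprintf("%s_l%d", fam, i)
      ids <- c(ids, id)
      paths[[id]] <- if (size == 1) id
                     else if (grouped) c(fam, paste0(fam, "_g", 1 + i %% 2))
                     else fam
    }
  }
  tax <- data.frame(language_id = ids, stringsAsFactors = FALSE)
  tax$path <- unname(paths)
  tax
}

# small planar synthetic dataset for fast GLS tests
small_config <- function(seed = 1, n_families = 10, mean_languages = 4,
                         radius_meanlog = log(600), ...) {
  synth_config(seed = seed, mode = "planar", extent = c(0, 8000, 0, 5000),
               cell_km = 1000, n_continents = 2, continent_radius_km = 3000,
               n_families = n_families, mean_languages = mean_languages,
               radius_meanlog = radius_meanlog, ...)
}

small_sim <- function(seed = 1, ...) {
  suppressWarnings(simulate_language_data(small_config(seed, ...)))
}

# redraw the response of an existing simulated dataset with new parameters /
# noise seed, holding grid, languages, covariates, P and D fixed
redraw_response <- function(sim, seed, alpha = NULL, beta = NULL,
                            gamma_km = NULL, sigma2 = NULL, b = NULL) {
  cfg <- sim$config
  cfg$seed <- seed
  if (!is.null(alpha)) cfg$alpha <- alpha
  if (!is.null(beta)) cfg$beta <- beta
  if (!is.null(gamma_km)) cfg$gamma_km <- gamma_km
  if (!is.null(sigma2)) cfg$sigma2 <- sigma2
  if (!is.null(b)) cfg$b <- b
  gen_response(cfg, sim$cells, sim$P, sim$D)
}

fast_control <- function(...) lsgls_control(n_starts = 2L, ...)
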