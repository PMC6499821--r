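#' Configuration for the synthetic language-diversity generator
#'
#' Bundles every knob of the generator: grid layout, continental landmask,
#' family structure and range geometry, Gaussian-random-field covariates,
#' and the true GLS parameters from which responses are drawn.  Defaults
#' emulate a low-resolution global analysis: 1000 km equal-area cells on
#' the sphere, a few continents, families of spatially clustered languages
#' with log-normal speaker counts, and a response whose residuals carry
#' both phylogenetic and Gaussian-decay spatial correlation.
#'
#' Separate seed streams (offsets of `seed`) drive the landmask, the
#' languages, the covariate fields and the response noise, so one component
#' can be varied while the others are held fixed.
#'
#' @param seed integer master seed.
#' @param mode,cell_km,extent grid layout; see [make_grid()].
#' @param n_continents,continent_radius_km landmask: number of continental
#'   discs and their nominal radius (km).
#' @param n_families number of language families.
#' @param mean_languages mean languages per family (sizes are
#'   `1 + Poisson(mean_languages - 1)`; singleton families become
#'   isolates).
#' @param subgroup_prob probability a multi-language family is split into
#'   two taxonomic subgroups.
#' @param dispersion_km Gaussian scatter of language range centers around
#'   the family homeland (km); small values give tight family clusters and
#'   strong spatial structure in the phylogenetic similarity matrix.
#' @param radius_meanlog,radius_sdlog log-normal parameters of the range
#'   radius (km).
#' @param speakers_meanlog,speakers_sdlog log-normal speaker counts.
#' @param covariates character vector of covariate column names to
#'   generate.
#' @param cov_range_km Gaussian-random-field correlation range (km),
#'   scalar or named per covariate.
#' @param cov_sd marginal standard deviation of the fields.
#' @param n_biomes number of biome categories (0 disables the biome
#'   column).
#' @param alpha,beta,gamma_km,sigma2 true correlation parameters and
#'   residual variance of the response model.
#' @param b named true coefficients; names must be `"(Intercept)"`,
#'   `"land_fraction"` or generated covariate names.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         mode = c("spherical", "planar"),
                         cell_km = 1000,
                         extent = NULL,
                         n_continents = 4L,
                         continent_radius_km = 3500,
                         n_families = 40L,
                         mean_languages = 5,
                         subgroup_prob = 0.5,
                         dispersion_km = 500,
                         radius_meanlog = log(400),
                         radius_sdlog = 0.5,
                         speakers_meanlog = 8.5,
                         speakers_sdlog = 1.8,
                         covariates = c("temp_mean", "precip_mean",
                                        "temp_seasonality", "precip_seasonality",
                                        "npp", "growing_season",
                                        "altitude_mean", "altitude_range",
                                        "roughness", "river_density",
                                        "pop_density",
                                        "plant_richness", "amphibian_richness",
                                        "mammal_richness", "bird_richness"),
                         cov_range_km = 2500,
                         cov_sd = 1,
                         n_biomes = 4L,
                         alpha = 0.6, beta = 0.5, gamma_km = 1500,
                         sigma2 = 0.3,
                         b = c("(Intercept)" = 1.5, land_fraction = 0.5,
                               temp_seasonality = -0.4, precip_mean = 0.3,
                               npp = 0.2)) {
  mode <- match.arg(mode)
  stopifnot(cell_km > 0, n_families >= 1, mean_languages >= 1,
            dispersion_km >= 0, continent_radius_km > 0,
            alpha >= 0, alpha <= 1, beta >= 0, beta <= 1,
            gamma_km > 0, sigma2 >= 0, cov_sd > 0)
  if (mode == "planar" && is.null(extent))
    extent <- c(0, 12000, 0, 8000)
  structure(as.list(environment()), class = "synth_config")
}

#' Grid implied by a synthetic configuration
#' @param config a [synth_config()].
#' @return cell table skeleton from [make_grid()].
#' @export
synth_grid <- function(config) {
  make_grid(config$cell_km, mode = config$mode, extent = config$extent)
}

#' Generate a synthetic continental landmask
#'
#' Continents are random discs (with mild radius variation) in the
#' projected plane; homelands and ranges are anchored to them and the
#' land-coverage covariate is computed against them.
#'
#' @param config a [synth_config()].
#' @return list of polygon rings.
#' @export
gen_landmask <- function(config) {
  g <- attr(synth_grid(config), "grid")
  ext <- g$extent
  set.seed(config$seed + 101L)
  lapply(seq_len(config$n_continents), function(i) {
    r <- config$continent_radius_km * stats::runif(1, 0.7, 1.3)
    cx <- stats::runif(1, ext[1] + r / 2, ext[2] - r / 2)
    cy <- stats::runif(1, ext[3] + r / 2, ext[4] - r / 2)
    .disc_ring(cx, cy, r, 48L)
  })
}

#' Generate synthetic languages with clustered family ranges
#'
#' Families receive homeland centers on land (uniform over the landmask);
#' each language's range is a disc whose center is Gaussian-dispersed
#' around the family homeland, so related languages cluster in space --
#' the feature that makes phylogenetic similarity spatially structured.
#' Family sizes are Poisson; singleton families are isolates (their
#' classification path is the language id itself); larger families may be
#' split into two subgroups.  Speaker counts are log-normal.
#'
#' @param config a [synth_config()].
#' @param landmask landmask rings, defaults to [gen_landmask()] under the
#'   same config.
#' @return list with `taxonomy` (data frame with `language_id` and a `path`
#'   list-column) and `records` (list of [language_record()]).
#' @export
gen_languages <- function(config, landmask = gen_landmask(config)) {
  g <- attr(synth_grid(config), "grid")
  ext <- g$extent
  set.seed(config$seed + 202L)

  sample_on_land <- function() {
    for (i in 1:1000) {
      px <- stats::runif(1, ext[1], ext[2]); py <- stats::runif(1, ext[3], ext[4])
      for (ring in landmask)
        if (.point_in_ring(px, py, ring)) return(c(px, py))
    }
    c(stats::runif(1, ext[1], ext[2]), stats::runif(1, ext[3], ext[4]))
  }

  records <- list(); tax_ids <- character(0); tax_paths <- list()
  for (f in seq_len(config$n_families)) {
    fam <- sprintf("F%02d", f)
    size <- 1L + stats::rpois(1, config$mean_languages - 1)
    home <- sample_on_land()
    split_groups <- size > 1L && stats::runif(1) < config$subgroup_prob
    groups <- if (split_groups)
      sample(paste0(fam, c("a", "b")), size, replace = TRUE) else rep(NA, size)
    for (i in seq_len(size)) {
      id <- sprintf("%s_L%02d", fam, i)
      path <- if (size == 1L) id                       # isolate
              else if (split_groups) c(fam, groups[i])
              else fam
      ok <- FALSE
      for (try in 1:100) {
        ctr <- home + stats::rnorm(2, sd = config$dispersion_km)
        r <- stats::rlnorm(1, config$radius_meanlog, config$radius_sdlog)
        if (ctr[1] + r > ext[1] && ctr[1] - r < ext[2] &&
            ctr[2] + r > ext[3] && ctr[2] - r < ext[4]) { ok <- TRUE; break }
      }
      if (!ok) stop("could not place range inside the extent for language ", id)
      speakers <- round(stats::rlnorm(1, config$speakers_meanlog,
                                      config$speakers_sdlog))
      records[[id]] <- language_record(id, path, .disc_ring(ctr[1], ctr[2], r),
                                       speakers)
      tax_ids <- c(tax_ids, id); tax_paths[[id]] <- path
    }
  }
  taxonomy <- data.frame(language_id = tax_ids, stringsAsFactors = FALSE)
  taxonomy$path <- unname(tax_paths)
  list(taxonomy = taxonomy, records = unname(records))
}

#' Generate spatially autocorrelated covariates
#'
#' Each covariate is a draw from a Gaussian random field over the cell
#' centroids with squared-exponential covariance
#' `cov_sd^2 exp(-(h / range)^2)` (h = Euclidean distance in the projected
#' plane).  Optionally a covariate can be mixed with a parent field to
#' create correlated predictors for collinearity experiments, and a biome
#' category can be derived by slicing one extra field into quantile bins.
#'
#' @param config a [synth_config()].
#' @param cells cell table (centroids are taken from `x`, `y`).
#' @param mix optional named list: `mix$child = list(parent = "name",
#'   rho = 0.8)` replaces `child` with `rho * parent + sqrt(1 - rho^2) *
#'   child`.
#' @return the cell table with covariate columns (and `biome` factor when
#'   configured) appended.
#' @export
gen_covariates <- function(config, cells, mix = NULL) {
  n <- nrow(cells)
  set.seed(config$seed + 303L)
  h <- as.matrix(stats::dist(cbind(cells$x, cells$y)))
  ranges <- config$cov_range_km
  field <- function(range_km) {
    S <- config$cov_sd^2 * exp(-(h / range_km)^2)
    U <- tryCatch(chol(S + diag(1e-8, n)), error = function(e)
      tryCatch(chol(S + diag(1e-4, n)), error = function(e2)
        stop("covariate covariance is not positive definite even after jitter")))
    drop(crossprod(U, stats::rnorm(n)))
  }
  for (nm in config$covariates) {
    r <- if (length(ranges) > 1L && nm %in% names(ranges)) ranges[[nm]] else ranges[[1]]
    cells[[nm]] <- field(r)
  }
  if (!is.null(mix)) {
    for (child in names(mix)) {
      rho <- mix[[child]]$rho
      parent <- cells[[mix[[child]]$parent]]
      cells[[child]] <- rho * parent + sqrt(1 - rho^2) * cells[[child]]
    }
  }
  if (config$n_biomes > 0L) {
    bf <- field(ranges[[1]])
    cells$biome <- cut(bf, breaks = stats::quantile(bf, probs =
                         seq(0, 1, length.out = config$n_biomes + 1L)),
                       labels = paste0("B", seq_len(config$n_biomes)),
                       include.lowest = TRUE)
  }
  cells
}

#' Generate responses from the GLS model with known parameters
#'
#' Draws `y ~ MVN(X b, sigma2 C)` with
#' `C = (1 - alpha) I + alpha [beta P + (1 - beta) exp(-(d/gamma)^2)]` at
#' the configuration's true parameters.  The response is generated directly
#' on the log scale, matching the fitted model; `diversity_sim` adds an
#' exponentiated, rounded count for robustness experiments.
#'
#' @param config a [synth_config()].
#' @param cells cell table carrying the covariates named in `config$b`.
#' @param P,D similarity and distance matrices for these cells.
#' @return the cell table with a `log_diversity` column (and
#'   `diversity_sim`).
#' @export
gen_response <- function(config, cells, P, D) {
  b <- config$b
  Xcols <- setdiff(names(b), "(Intercept)")
  missing <- setdiff(Xcols, names(cells))
  if (length(missing))
    stop("cells lack covariates named in b: ", paste(missing, collapse = ", "))
  X <- cbind("(Intercept)" = 1, as.matrix(cells[Xcols]))
  n <- nrow(cells)
  C <- build_correlation(config$alpha, config$beta, config$gamma_km, P, D)
  U <- chol(C)
  set.seed(config$seed + 404L)
  y <- drop(X %*% b[colnames(X)]) +
    sqrt(config$sigma2) * drop(crossprod(U, stats::rnorm(n)))
  cells$log_diversity <- y
  cells$diversity_sim <- pmax(1, round(exp(y)))
  cells
}

#' Simulate a complete synthetic language-diversity dataset
#'
#' Runs the full generator pipeline: grid, landmask, languages, polygon
#' overlay (dropping unoccupied cells), land coverage, covariates, language
#' tree, PhyloSor and distance matrices, and the model response.
#'
#' @param config a [synth_config()].
#' @param n_cells optional: keep a random (seeded) subset of exactly this
#'   many occupied cells before computing matrices.
#' @return list with `cells`, `tree`, `taxonomy`, `languages`, `landmask`,
#'   `P`, `D` and the `config`.
#' @export
simulate_language_data <- function(config = synth_config(), n_cells = NULL) {
  grid <- synth_grid(config)
  landmask <- gen_landmask(config)
  langs <- gen_languages(config, landmask)
  cells <- overlay_languages(grid, langs$records)
  cells <- land_fraction(cells, landmask)
  if (!is.null(n_cells)) {
    if (nrow(cells) < n_cells)
      stop("only ", nrow(cells), " occupied cells; cannot keep ", n_cells)
    set.seed(config$seed + 505L)
    keep <- sort(sample(nrow(cells), n_cells))
    g_attr <- attr(cells, "grid")
    cells <- cells[keep, , drop = FALSE]
    rownames(cells) <- NULL
    attr(cells, "grid") <- g_attr
  }
  cells <- gen_covariates(config, cells)
  tree <- language_tree(langs$taxonomy)
  P <- suppressWarnings(phylosor_matrix(tree, cells))
  D <- greatcircle_matrix(cells)
  cells <- gen_response(config, cells, P, D)
  list(cells = cells, tree = tree, taxonomy = langs$taxonomy,
       languages = langs$records, landmask = landmask,
       P = P, D = D, config = config)
}
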