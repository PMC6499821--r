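# Edge-by-tip incidence of a tree: E[e, t] = 1 if tip t descends from edge e.
# Computed by a single postorder accumulation.
.edge_tip_incidence <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  desc <- matrix(FALSE, n_node, n_tip)
  desc[cbind(seq_len(n_tip), seq_len(n_tip))] <- TRUE
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    desc[p, ] <- desc[p, ] | desc[ch, ]
  }
  E <- desc[tree$edge[, 2], , drop = FALSE]
  storage.mode(E) <- "double"
  colnames(E) <- tree$tip.label
  E
}

#' PhyloSor similarity between two sets of languages
#'
#' Soerensen-type similarity on shared branch length: each set of tips spans
#' a rooted subtree (the union of the paths from its tips to the root), and
#' `phylosor = 2 * BL_shared / (BL_i + BL_j)` where `BL` is total branch
#' length of a spanning subtree and `BL_shared` the length of branches lying
#' in both.  Because the spanning subtrees include the path to the root, two
#' sets drawn from disjoint families of a star-based tree share no branches
#' and score 0, while identical sets score 1.
#'
#' @param tree an [ape::phylo] language tree (e.g. from [language_tree()]).
#' @param taxa_i,taxa_j non-empty character vectors of tip labels.
#' @param include_root_path logical; count branches on the path to the root
#'   (default `TRUE`, which realizes the 0-for-disjoint-families endpoint).
#'   `FALSE` restricts each spanning subtree to the crown subtree of the
#'   set's most recent common ancestor (sensitivity analysis only).
#' @return similarity in `[0, 1]`.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' phylosor_pair(tr, c("A", "B"), c("A", "C"))  # 4/7
#' @export
phylosor_pair <- function(tree, taxa_i, taxa_j, include_root_path = TRUE) {
  for (taxa in list(taxa_i, taxa_j)) {
    if (length(taxa) == 0L) stop("taxa sets must be non-empty")
    missing <- setdiff(taxa, tree$tip.label)
    if (length(missing))
      stop("tip not in tree: ", paste(missing, collapse = ", "))
  }
  E <- .edge_tip_incidence(tree)
  len <- tree$edge.length
  in_i <- (E[, unique(taxa_i), drop = FALSE] %*% rep(1, length(unique(taxa_i)))) > 0
  in_j <- (E[, unique(taxa_j), drop = FALSE] %*% rep(1, length(unique(taxa_j)))) > 0
  if (!include_root_path) {
    in_i <- in_i & !.all_taxa_edges(E, taxa_i)
    in_j <- in_j & !.all_taxa_edges(E, taxa_j)
  }
  bl_i <- sum(len[in_i]); bl_j <- sum(len[in_j])
  shared <- sum(len[in_i & in_j])
  2 * shared / (bl_i + bl_j)
}

# edges whose descendant tips are a superset of the taxa set (the path above
# the MRCA) -- excluded when include_root_path = FALSE
.all_taxa_edges <- function(E, taxa) {
  taxa <- unique(taxa)
  rowSums(E[, taxa, drop = FALSE]) == length(taxa)
}

#' PhyloSor similarity matrix over grid cells
#'
#' Computes [phylosor_pair()] for every pair of cells from their occupant
#' language sets, as a single matrix product over the edge-by-tip incidence
#' of the tree.
#'
#' @param tree language tree whose tips cover every occupant.
#' @param cells cell table with an `occupants` list-column (from
#'   [overlay_languages()]), or a plain list of character vectors.
#' @param repair apply [repair_pd()] to the result (PhyloSor matrices are
#'   not guaranteed positive definite).  Default `TRUE`.
#' @param ... passed to [repair_pd()].
#' @return symmetric matrix with unit diagonal, entries in `[0, 1]`,
#'   dimnames from `cell_id` when available.
#' @export
phylosor_matrix <- function(tree, cells, repair = TRUE, ...) {
  occ <- if (is.data.frame(cells)) {
    if (!"occupants" %in% names(cells)) stop("cells lacks an occupants column")
    cells$occupants
  } else cells
  if (any(lengths(occ) == 0L))
    stop("empty occupant set; drop unoccupied cells before computing PhyloSor")
  all_ids <- unique(unlist(occ))
  missing <- setdiff(all_ids, tree$tip.label)
  if (length(missing))
    stop("tip not in tree: ", paste(missing, collapse = ", "))
  E <- .edge_tip_incidence(tree)
  len <- tree$edge.length
  M <- vapply(occ, function(o) as.numeric(colnames(E) %in% o), numeric(ncol(E)))
  A <- (E %*% M) > 0          # edge present in cell's spanning subtree
  storage.mode(A) <- "double"
  S <- crossprod(A * sqrt(len))     # S[i,j] = shared branch length
  bl <- diag(S)
  P <- 2 * S / outer(bl, bl, "+")
  if (is.data.frame(cells) && "cell_id" %in% names(cells))
    dimnames(P) <- list(cells$cell_id, cells$cell_id)
  if (repair) P <- repair_pd(P, ...)
  P
}

#' Great-circle (or planar) distance matrix between cell centroids
#'
#' Spherical cells use the haversine great-circle distance with Earth radius
#' 6371 km; planar cells use Euclidean distance on their projected
#' coordinates.
#'
#' @param cells cell table with `lon`/`lat` (spherical) or `x`/`y` (planar)
#'   centroid columns.
#' @return symmetric distance matrix in km with zero diagonal.
#' @export
greatcircle_matrix <- function(cells) {
  g <- attr(cells, "grid")
  spherical <- if (!is.null(g)) g$mode == "spherical" else all(is.finite(cells$lat))
  if (spherical) {
    if (any(!is.finite(cells$lat)) || any(abs(cells$lat) > 90))
      stop("latitudes must lie in [-90, 90]")
    pts <- cbind(cells$lon, cells$lat)
    d <- geosphere::distm(pts, pts,
                          fun = function(p1, p2)
                            geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM))
  } else {
    d <- as.matrix(stats::dist(cbind(cells$x, cells$y)))
  }
  dimnames(d) <- if ("cell_id" %in% names(cells))
    list(cells$cell_id, cells$cell_id) else NULL
  d
}

#' Gaussian distance-decay kernel
#'
#' Entrywise `exp(-(d / gamma)^2)`: the expected residual similarity of two
#' cells decays as a Gaussian of the distance between them, with `gamma`
#' (km) the decay scale.
#'
#' @param d distance matrix (km).
#' @param gamma decay scale, km; must be positive.
#' @return matrix with unit diagonal and entries in `(0, 1]`.
#' @export
gaussian_decay <- function(d, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1 || is.na(gamma) || gamma <= 0)
    stop("gamma must be a positive scalar")
  exp(-(d / gamma)^2)
}

#' Repair a correlation-like matrix to positive definiteness
#'
#' Eigenvalues below `eig_floor` are clamped up to it and the diagonal is
#' rescaled back to 1.  A warning reports the largest entrywise
#' perturbation; if it exceeds `max_change` the matrix is considered too
#' indefinite to repair and an error is raised.
#'
#' @param M symmetric matrix with unit diagonal.
#' @param eig_floor smallest admissible eigenvalue (default `1e-8`).
#' @param max_change largest admissible entry perturbation (default `0.01`).
#' @return a positive-definite matrix with unit diagonal.
#' @export
repair_pd <- function(M, eig_floor = 1e-8, max_change = 0.01) {
  ee <- eigen((M + t(M)) / 2, symmetric = TRUE)
  if (min(ee$values) >= eig_floor) return(M)
  v <- pmax(ee$values, eig_floor)
  M2 <- ee$vectors %*% (v * t(ee$vectors))
  s <- 1 / sqrt(diag(M2))
  M2 <- M2 * outer(s, s)
  diag(M2) <- 1
  delta <- max(abs(M2 - M))
  if (delta > max_change)
    stop("matrix is too far from positive definite: largest repair perturbation ",
         signif(delta, 3), " exceeds max_change = ", max_change)
  warning("repaired matrix to positive definiteness (largest entry change ",
          signif(delta, 3), ")")
  dimnames(M2) <- dimnames(M)
  M2
}
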