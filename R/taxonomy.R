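#' Build a language tree from a tabular taxonomy
#'
#' Converts a taxonomy table (one row per language, with its classification
#' path from family outward) into a rooted [ape::phylo] tree.  The tree is a
#' star at the base: every family hangs directly off the root, so any two
#' languages from different families are at the maximum patristic distance
#' from each other, reflecting the absence of accepted relationships between
#' language families.
#'
#' Branch lengths follow an ultrametric depth-normalization: the root-to-tip
#' depth is fixed at 1 for every tip, and each internal node sits at depth
#' `level / max_levels`, where `level` is its position along the
#' classification path and `max_levels` is the longest root-to-tip chain
#' passing through it.  Under this convention the patristic distance between
#' tips of different families is exactly 2 (the matrix maximum) and PhyloSor
#' similarities are scale-free.  `edge_lengths = "unit"` instead assigns
#' length 1 to every edge (non-ultrametric; intended for sensitivity
#' analysis only).
#'
#' A language whose classification path is just its own id (an isolate) is
#' attached directly under the root with branch length 1; isolates therefore
#' count as distinct families.
#'
#' @param taxonomy a data frame with a `language_id` column plus either a
#'   `path` list-column of character vectors (outermost group first) or
#'   ragged `level_1`, `level_2`, ... columns (empty strings / `NA` ignored).
#' @param edge_lengths `"depth"` (default, depth-normalized ultrametric) or
#'   `"unit"`.
#' @return an object of class `phylo`, with tips named by `language_id`.
#' @examples
#' tax <- data.frame(language_id = c("A", "B", "C"),
#'                   level_1 = c("F1", "F2", "F2"),
#'                   level_2 = c("", "G1", "G1"))
#' tr <- language_tree(tax)
#' cophenetic(tr)  # A is at distance 2 from B and C
#' @export
language_tree <- function(taxonomy, edge_lengths = c("depth", "unit")) {
  edge_lengths <- match.arg(edge_lengths)
  paths <- taxonomy_paths(taxonomy)
  ids <- names(paths)
  if (anyDuplicated(ids))
    stop("duplicate language_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(ids))) stop("empty language_id")

  # Node chain for a tip: root / path[1] / ... / path[k] / id, with the tip
  # merged into the last path node when the path ends at the id itself
  # (isolate convention).
  chains <- lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    if (length(p) == 0L)
      stop("empty classification path for language ", ids[i])
    if (p[length(p)] == ids[i]) p else c(p, ids[i])
  })
  names(chains) <- ids

  ROOT <- "\r__root__\r"
  # Nodes are keyed by their full prefix so identically named groups in
  # different families stay distinct.
  key <- function(v) if (length(v) == 0L) ROOT else paste(v, collapse = "\r")
  tip_keys <- vapply(chains, key, "")
  if (anyDuplicated(tip_keys)) {
    clash <- ids[duplicated(tip_keys) | duplicated(tip_keys, fromLast = TRUE)]
    stop("inconsistent taxonomy: identical classification chains for languages ",
         paste(clash, collapse = ", "))
  }
  internal_of_tip <- vapply(chains, function(ch) key(ch[-length(ch)]), "")
  if (any(internal_of_tip %in% tip_keys)) {
    bad <- ids[internal_of_tip %in% tip_keys]
    stop("inconsistent taxonomy: classification path of language ",
         paste(bad, collapse = ", "),
         " passes through another language's tip position")
  }

  children <- new.env(parent = emptyenv())   # key -> character vector of child keys
  label <- new.env(parent = emptyenv())      # key -> node label
  assign(ROOT, character(0), envir = children)
  assign(ROOT, "", envir = label)
  for (i in seq_along(chains)) {
    ch <- chains[[i]]
    for (j in seq_along(ch)) {
      k <- key(ch[seq_len(j)])
      pk <- key(ch[seq_len(j - 1L)])
      kids <- if (!is.null(children[[pk]])) children[[pk]] else character(0)
      if (!k %in% kids) assign(pk, c(kids, k), envir = children)
      if (is.null(children[[k]])) assign(k, character(0), envir = children)
      assign(k, ch[j], envir = label)
    }
  }

  # max levels of any root-to-tip chain passing through each node
  maxlev <- new.env(parent = emptyenv())
  walk_maxlev <- function(k, level) {
    kids <- children[[k]]
    m <- if (length(kids) == 0L) level
         else max(vapply(kids, walk_maxlev, 0, level = level + 1L))
    assign(k, m, envir = maxlev)
    m
  }
  walk_maxlev(ROOT, 0L)

  n_tip <- length(tip_keys)
  edges <- list(); lens <- numeric(0)
  tip_lab <- character(n_tip)
  counter <- new.env(parent = emptyenv())
  counter$tip <- 0L; counter$int <- n_tip + 1L

  build <- function(k, level, parent_idx, parent_depth) {
    kids <- children[[k]]
    ord <- order(vapply(kids, function(x) label[[x]], ""), method = "radix")
    for (ck in kids[ord]) {
      is_tip <- length(children[[ck]]) == 0L
      d <- (level + 1L) / maxlev[[ck]]   # node depth under depth-normalization
      if (is_tip) {
        counter$tip <- counter$tip + 1L
        idx <- counter$tip
        tip_lab[idx] <<- label[[ck]]
      } else {
        counter$int <- counter$int + 1L
        idx <- counter$int
      }
      edges[[length(edges) + 1L]] <<- c(parent_idx, idx)
      lens[length(lens) + 1L] <<- if (edge_lengths == "depth") d - parent_depth else 1
      if (!is_tip) build(ck, level + 1L, idx, d)
    }
  }
  build(ROOT, 0L, n_tip + 1L, 0)

  tr <- structure(list(
    edge = do.call(rbind, edges),
    edge.length = lens,
    tip.label = tip_lab,
    Nnode = counter$int - n_tip
  ), class = "phylo", order = "cladewise")
  if (tr$Nnode > 1L) tr <- ape::collapse.singles(tr)
  tr
}

#' Extract classification paths from a taxonomy table
#'
#' @param taxonomy data frame as in [language_tree()].
#' @return named list of character vectors (outermost group first), one per
#'   language.
#' @export
taxonomy_paths <- function(taxonomy) {
  if (!is.data.frame(taxonomy) || !"language_id" %in% names(taxonomy))
    stop("taxonomy must be a data frame with a language_id column")
  ids <- as.character(taxonomy$language_id)
  if ("path" %in% names(taxonomy)) {
    paths <- lapply(taxonomy$path, function(p) as.character(p[!is.na(p) & nzchar(p)]))
  } else {
    lev <- grep("^level_[0-9]+$", names(taxonomy), value = TRUE)
    if (length(lev) == 0L)
      stop("taxonomy needs a 'path' list-column or level_1..level_k columns")
    lev <- lev[order(as.integer(sub("^level_", "", lev)))]
    m <- as.matrix(taxonomy[lev])
    paths <- lapply(seq_len(nrow(m)), function(i) {
      v <- as.character(m[i, ])
      v[!is.na(v) & nzchar(v)]
    })
  }
  names(paths) <- ids
  paths
}

#' Family of each language in a taxonomy
#'
#' The family is the outermost level of the classification path; for an
#' isolate (path equal to the language id) the family is the language itself.
#'
#' @inheritParams taxonomy_paths
#' @return named character vector mapping language_id to family.
#' @export
language_families <- function(taxonomy) {
  paths <- taxonomy_paths(taxonomy)
  vapply(paths, `[`, "", 1L)
}

#' Read a taxonomy table from CSV
#'
#' Expects a `language_id` column and ragged `level_1..level_k` columns
#' (empty cells allowed).
#'
#' @param file path to a CSV file.
#' @return data frame suitable for [language_tree()].
#' @export
read_taxonomy_csv <- function(file) {
  utils::read.csv(file, stringsAsFactors = FALSE, colClasses = "character")
}
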