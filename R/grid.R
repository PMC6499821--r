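EARTH_RADIUS_KM <- 6371

#' Construct an equal-area analysis grid
#'
#' Builds the cell table skeleton for a grid of (nominally) square cells.
#' In `"spherical"` mode cells are laid out in a cylindrical equal-area
#' projection of the sphere (x = R * lon_rad, y = R * sin(lat_rad), R = 6371
#' km), so every cell has exactly the same area; cell dimensions are
#' adjusted to the nearest tiling of the extent.  In `"planar"` mode the
#' grid lives on a flat toy plane with Euclidean geometry.
#'
#' @param cell_size_km nominal cell edge, km.
#' @param mode `"spherical"` (default, global extent unless given) or
#'   `"planar"` (requires `extent`).
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` in projected km; in
#'   spherical mode defaults to the whole globe.
#' @return a data frame with one row per cell: `cell_id`, `row`, `col`
#'   (0-based), centroid `x`, `y` (projected km) and `lon`, `lat` (degrees;
#'   `NA` in planar mode), `land_fraction` (initialized to 1) and `area`
#'   (km^2).  The grid layout is stored in `attr(, "grid")`.
#' @export
make_grid <- function(cell_size_km, mode = c("spherical", "planar"), extent = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(cell_size_km) || cell_size_km <= 0)
    stop("cell_size_km must be positive")
  if (is.null(extent)) {
    if (mode == "planar") stop("planar mode requires an extent")
    R <- EARTH_RADIUS_KM
    extent <- c(-pi * R, pi * R, -R, R)
  }
  stopifnot(length(extent) == 4, extent[2] > extent[1], extent[4] > extent[3])
  width <- extent[2] - extent[1]; height <- extent[4] - extent[3]
  ncol <- max(1L, round(width / cell_size_km))
  nrow <- max(1L, round(height / cell_size_km))
  cw <- width / ncol; ch <- height / nrow
  cells <- expand.grid(col = 0:(ncol - 1L), row = 0:(nrow - 1L))
  cells <- cells[c("row", "col")]
  cells$x <- extent[1] + (cells$col + 0.5) * cw
  cells$y <- extent[3] + (cells$row + 0.5) * ch
  if (mode == "spherical") {
    R <- EARTH_RADIUS_KM
    if (any(abs(cells$y) > R)) stop("extent exceeds the sphere in y")
    cells$lon <- cells$x / R * 180 / pi
    cells$lat <- asin(pmin(1, pmax(-1, cells$y / R))) * 180 / pi
  } else {
    cells$lon <- NA_real_; cells$lat <- NA_real_
  }
  cells$land_fraction <- 1
  cells$area <- cw * ch
  cells <- cbind(cell_id = sprintf("r%03dc%03d", cells$row, cells$col), cells,
                 stringsAsFactors = FALSE)
  attr(cells, "grid") <- list(mode = mode, extent = extent, nrow = nrow,
                              ncol = ncol, cell_w = cw, cell_h = ch,
                              cell_size_km = cell_size_km)
  cells
}

.grid_spec <- function(cells) {
  g <- attr(cells, "grid")
  if (is.null(g)) stop("cell table has lost its grid attribute; rebuild with make_grid()")
  g
}

.cell_rect <- function(g, row, col) {
  c(xmin = g$extent[1] + col * g$cell_w, xmax = g$extent[1] + (col + 1) * g$cell_w,
    ymin = g$extent[3] + row * g$cell_h, ymax = g$extent[3] + (row + 1) * g$cell_h)
}

#' Create a language record
#'
#' @param language_id unique language identifier.
#' @param path classification path, outermost group (family) first; for an
#'   isolate, just the language id.
#' @param ring polygon ring (n x 2 matrix of projected km coordinates)
#'   delimiting the language's homeland range.  Consecutive duplicate
#'   vertices are dropped as a repair step; a ring that is still degenerate
#'   raises an error naming the language.
#' @param speakers non-negative number of native (L1) speakers.
#' @return a `language_record` list.
#' @export
language_record <- function(language_id, path, ring, speakers = 0) {
  ring <- as.matrix(ring)
  ring <- ring[c(TRUE, rowSums(abs(diff(ring))) > 0), , drop = FALSE]
  if (nrow(ring) > 1L && all(ring[1, ] == ring[nrow(ring), ]))
    ring <- ring[-nrow(ring), , drop = FALSE]   # store rings open
  if (!.ring_valid(ring))
    stop("invalid polygon for language ", language_id)
  if (!is.numeric(speakers) || length(speakers) != 1 || is.na(speakers) || speakers < 0)
    stop("speakers must be a non-negative number for language ", language_id)
  structure(list(language_id = as.character(language_id),
                 path = as.character(path),
                 ring = unname(ring),
                 speakers = as.numeric(speakers)),
            class = "language_record")
}

#' Overlay language ranges on a grid
#'
#' Fills the per-cell diversity summaries: `occupants` (ids of languages
#' whose range polygon intersects the cell, boundary touch included),
#' `diversity` (their count), `n_families` (number of distinct families,
#' isolates counting as their own family), and `min_pop` / `avg_pop`
#' (minimum and mean speaker count over occupants).  Cells that no language
#' range touches are dropped.
#'
#' @param cells a cell table from [make_grid()].
#' @param languages a list of [language_record()] objects.
#' @param drop_empty drop cells with no occupants (default `TRUE`).
#' @return the cell table with occupancy columns; `occupants` is a
#'   list-column of character vectors.
#' @export
overlay_languages <- function(cells, languages, drop_empty = TRUE) {
  g <- .grid_spec(cells)
  if (length(languages) == 0L) stop("no language records supplied")
  keymap <- stats::setNames(seq_len(nrow(cells)), paste(cells$row, cells$col))
  occ <- rep(list(character(0)), nrow(cells))
  fam <- speakers <- list()
  for (rec in languages) {
    if (!inherits(rec, "language_record")) stop("languages must be language_record objects")
    fam[[rec$language_id]] <- rec$path[1]
    speakers[[rec$language_id]] <- rec$speakers
    bb <- apply(rec$ring, 2, range)
    # candidate window padded by one cell so exact boundary touches are kept
    c0 <- max(0L, floor((bb[1, 1] - g$extent[1]) / g$cell_w) - 1L)
    c1 <- min(g$ncol - 1L, floor((bb[2, 1] - g$extent[1]) / g$cell_w) + 1L)
    r0 <- max(0L, floor((bb[1, 2] - g$extent[3]) / g$cell_h) - 1L)
    r1 <- min(g$nrow - 1L, floor((bb[2, 2] - g$extent[3]) / g$cell_h) + 1L)
    if (c1 < c0 || r1 < r0) next
    for (r in r0:r1) for (cc in c0:c1) {
      i <- keymap[paste(r, cc)]
      if (is.na(i)) next
      rect <- .cell_rect(g, r, cc)
      if (.ring_rect_intersects(rec$ring, rect[1], rect[2], rect[3], rect[4]))
        occ[[i]] <- c(occ[[i]], rec$language_id)
    }
  }
  fam <- unlist(fam); speakers <- unlist(speakers)
  cells$occupants <- I(occ)
  cells$diversity <- lengths(occ)
  cells$n_families <- vapply(occ, function(o) length(unique(fam[o])), 0L)
  cells$min_pop <- vapply(occ, function(o)
    if (length(o)) min(speakers[o]) else NA_real_, 0)
  cells$avg_pop <- vapply(occ, function(o)
    if (length(o)) mean(speakers[o]) else NA_real_, 0)
  if (drop_empty) {
    keep <- cells$diversity >= 1L
    g_attr <- attr(cells, "grid")
    cells <- cells[keep, , drop = FALSE]
    rownames(cells) <- NULL
    attr(cells, "grid") <- g_attr
  }
  cells
}

#' Compute per-cell land coverage from a landmask
#'
#' The land fraction is the share of the cell's area intersecting the
#' landmask polygons (assumed non-overlapping).  Occupied cells whose
#' fraction falls below 0.01 -- small islands -- are floored at 0.01, so
#' land coverage is usable as a regression offset for every cell that
#' contains a language.
#'
#' @param cells cell table (occupancy columns optional).
#' @param landmask list of polygon rings (n x 2 matrices, projected km).
#' @return the cell table with `land_fraction` updated.
#' @export
land_fraction <- function(cells, landmask) {
  g <- .grid_spec(cells)
  if (length(landmask) == 0L) stop("empty landmask")
  frac <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    rect <- .cell_rect(g, cells$row[i], cells$col[i])
    a <- 0
    for (ring in landmask) {
      bb <- apply(as.matrix(ring), 2, range)
      if (bb[2, 1] < rect[1] || bb[1, 1] > rect[2] ||
          bb[2, 2] < rect[3] || bb[1, 2] > rect[4]) next
      clipped <- .clip_ring_rect(ring, rect[1], rect[2], rect[3], rect[4])
      if (!is.null(clipped)) a <- a + .ring_area(clipped)
    }
    frac[i] <- min(1, a / cells$area[i])
  }
  occupied <- if ("diversity" %in% names(cells)) cells$diversity >= 1L
              else rep(FALSE, nrow(cells))
  frac[occupied & frac < 0.01] <- 0.01
  cells$land_fraction <- frac
  cells
}

#' Systematic grid-cell subsampling
#'
#' Keeps cells whose (row - row_offset) and (col - col_offset) are both
#' multiples of `step`.  Subsampling curbs near-singular correlation
#' matrices caused by adjacent, nearly identical cells; `step = 2` keeps a
#' cell every two rows and columns, `step = 3` every three.
#'
#' @param cells cell table.
#' @param step sampling period (>= 1).
#' @param row_offset,col_offset offsets in `0:(step-1)`.
#' @return the retained subset of the cell table.
#' @seealso [subsample_regimes()] for all offset combinations at a step.
#' @export
subsample_cells <- function(cells, step, row_offset = 0L, col_offset = 0L) {
  step <- as.integer(step)
  if (step < 1L) stop("step must be >= 1")
  if (row_offset < 0L || row_offset >= step || col_offset < 0L || col_offset >= step)
    stop("offsets must lie in 0:(step-1)")
  keep <- (cells$row - row_offset) %% step == 0L & (cells$col - col_offset) %% step == 0L
  g_attr <- attr(cells, "grid")
  out <- cells[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "grid") <- g_attr
  out
}

#' All subsampling regimes at a given step
#'
#' @inheritParams subsample_cells
#' @return a list of `step^2` cell tables, one per (row_offset, col_offset)
#'   pair; every cell of the input appears in exactly one regime.  `step = 3`
#'   gives the nine regimes used for high-resolution analyses.
#' @export
subsample_regimes <- function(cells, step) {
  step <- as.integer(step)
  if (step < 1L) stop("step must be >= 1")
  offs <- expand.grid(row_offset = 0:(step - 1L), col_offset = 0:(step - 1L))
  out <- lapply(seq_len(nrow(offs)), function(i)
    subsample_cells(cells, step, offs$row_offset[i], offs$col_offset[i]))
  names(out) <- sprintf("r%d_c%d", offs$row_offset, offs$col_offset)
  out
}
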