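#' Write language records to GeoJSON
#'
#' Each record becomes a Polygon feature with properties `language_id`,
#' `path` (classification, outermost first) and `speakers`.  Coordinates
#' are written as stored (projected km for synthetic data).
#'
#' @param languages list of [language_record()] objects.
#' @param file output path.
#' @export
write_languages_geojson <- function(languages, file) {
  feats <- lapply(languages, function(rec) {
    ring <- .close_ring(rec$ring)
    list(type = "Feature",
         properties = list(language_id = rec$language_id,
                           path = as.list(rec$path),
                           speakers = rec$speakers),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read language records from GeoJSON
#'
#' @param file path to a FeatureCollection of Polygon features with
#'   `language_id`, `path`, `speakers` properties.
#' @return list of [language_record()] objects.
#' @export
read_languages_geojson <- function(file) {
  fc <- jsonlite::read_json(file)
  if (is.null(fc$type) || fc$type != "FeatureCollection")
    stop("not a GeoJSON FeatureCollection")
  lapply(fc$features, function(ft) {
    coords <- ft$geometry$coordinates[[1]]
    ring <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
    language_record(ft$properties$language_id,
                    unlist(ft$properties$path),
                    ring,
                    ft$properties$speakers)
  })
}

#' Write a cell table to CSV
#'
#' The `occupants` list-column is flattened to a `;`-separated string.
#' Grid-layout attributes do not survive the round trip; recompute
#' geometry-dependent quantities before writing.
#'
#' @param cells cell table.
#' @param file output path.
#' @export
write_cells_csv <- function(cells, file) {
  out <- as.data.frame(cells)
  if ("occupants" %in% names(out))
    out$occupants <- vapply(cells$occupants, paste, "", collapse = ";")
  utils::write.csv(out, file, row.names = FALSE)
  invisible(file)
}

#' Read a cell table from CSV
#'
#' @param file path written by [write_cells_csv()].
#' @return data frame; `occupants` is restored as a list-column.
#' @export
read_cells_csv <- function(file) {
  cells <- utils::read.csv(file, stringsAsFactors = FALSE)
  if ("occupants" %in% names(cells))
    cells$occupants <- I(strsplit(cells$occupants, ";", fixed = TRUE))
  cells
}

#' Write / read a similarity or distance matrix as CSV with cell ids
#'
#' @param M symmetric matrix with cell-id dimnames.
#' @param file path.
#' @export
write_matrix_csv <- function(M, file) {
  utils::write.csv(as.data.frame(M), file, row.names = TRUE)
  invisible(file)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(file) {
  df <- utils::read.csv(file, row.names = 1, check.names = FALSE)
  as.matrix(df)
}
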