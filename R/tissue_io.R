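#' Write a tissue to JSON
#'
#' The on-disk format is a plain JSON document:
#' `{domain: {width, height, units: "um"},`
#' `cells: [{id, boundary: [[x, y], ...], receptors: [{x, y, affinity, capacity}]}]}`.
#' Coordinates are serialized at full double precision so a write-then-read
#' round trip reproduces every field exactly.
#'
#' @param tissue a `tissue_domain`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tissue <- function(tissue, path) {
  doc <- list(
    domain = list(width = tissue$width, height = tissue$height, units = "um"),
    cells = lapply(tissue$cells, function(cl) {
      b <- polygon_ring(cl$boundary)
      list(id = cl$id,
           boundary = lapply(seq_len(nrow(b)), function(i) c(b[i, 1], b[i, 2])),
           receptors = lapply(seq_len(nrow(cl$receptors)), function(i) {
             r <- cl$receptors[i, ]
             list(x = r$x, y = r$y, affinity = r$affinity, capacity = r$capacity)
           }))
    }))
  # 17 significant digits round-trip IEEE doubles exactly
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17), pretty = FALSE)
  writeLines(json, path)
  invisible(path)
}

#' Read a tissue from JSON
#'
#' Reads the format written by [write_tissue()] and validates every
#' structural invariant (receptors on boundary, non-overlapping simple
#' polygons, capacities >= 1, unique ordered cell ids); a violation raises an
#' error naming the offending cell/receptor.
#'
#' @param path JSON file path.
#' @return a validated `tissue_domain`.
#' @export
read_tissue <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$domain) || is.null(doc$cells))
    stop("not a tissue file: missing 'domain' or 'cells'")
  cells <- lapply(doc$cells, function(cl) {
    b <- do.call(rbind, lapply(cl$boundary, function(v) as.numeric(unlist(v))))
    rec <- do.call(rbind, lapply(cl$receptors, function(r) {
      data.frame(x = as.numeric(r$x), y = as.numeric(r$y),
                 affinity = as.numeric(r$affinity),
                 capacity = as.numeric(r$capacity))
    }))
    list(id = as.integer(cl$id), boundary = b, receptors = rec)
  })
  tissue_domain(doc$domain$width, doc$domain$height, cells)
}
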