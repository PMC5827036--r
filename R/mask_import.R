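#' Import a tissue from a segmentation mask and an intensity image
#'
#' Builds a `tissue_domain` from a labeled cell mask (integers 1..N marking
#' cell interiors, 0 background) co-registered with a scalar intensity image,
#' the way digitized intravital microscopy is turned into a virtual tissue:
#' one boundary polygon is traced per label (outer contour, simplified to at
#' most `max_vertices` vertices), pseudo-receptors are placed every
#' `receptor_spacing` um of arc length along the contour, and each receptor's
#' affinity is `affinity_rule(mean intensity within a 1-px radius of the
#' receptor position)`, supporting intensity-derived per-receptor affinity
#' heterogeneity.
#'
#' Contour tracing uses `EBImage::ocontour()`.
#'
#' @param label_mask integer matrix (or PNG/TIFF path) with labels 1..N; a
#'   label touching the image border is rejected as an incomplete cell.
#' @param intensity_image numeric matrix (or image path) of the same shape.
#' @param pixel_size um per pixel.
#' @param receptor_spacing arc-length distance between receptors (um).
#' @param affinity_rule function mapping a mean boundary intensity to an
#'   affinity in \[0, 1\].
#' @param capacity ligand slots per receptor.
#' @param max_vertices contour simplification limit.
#' @return a validated `tissue_domain`; cells are re-indexed by increasing
#'   centroid x.
#' @export
import_tissue_from_masks <- function(label_mask, intensity_image, pixel_size,
                                     receptor_spacing = 2,
                                     affinity_rule = function(i) 1.0,
                                     capacity = 5, max_vertices = 200) {
  if (!requireNamespace("EBImage", quietly = TRUE))
    stop("mask import requires the EBImage package")
  label_mask <- .read_image_matrix(label_mask, integer = TRUE)
  intensity_image <- .read_image_matrix(intensity_image)
  if (!all(dim(label_mask) == dim(intensity_image)))
    stop("label mask and intensity image must share the same shape")
  labels <- sort(setdiff(unique(as.vector(label_mask)), 0))
  if (length(labels) == 0) stop("empty mask: no labels found")

  nr <- nrow(label_mask); nc <- ncol(label_mask)
  border <- unique(c(label_mask[1, ], label_mask[nr, ],
                     label_mask[, 1], label_mask[, nc]))
  bad <- intersect(labels, border)
  if (length(bad) > 0)
    stop("label ", bad[1], " touches the image border (incomplete cell)")

  cells <- lapply(labels, function(lb) {
    contour <- EBImage::ocontour(EBImage::Image(label_mask == lb))[[1]]
    # pixel indices -> um, center-of-pixel convention
    poly <- (contour + 0.5) * pixel_size
    # circular moving average removes the pixel staircase, which would
    # otherwise inflate the traced perimeter by up to 4/pi
    poly <- .smooth_contour(poly)
    # boundary-pixel centers lie half a pixel inside the true edge
    poly <- .offset_polygon(poly, pixel_size / 2)
    poly <- .simplify_polygon(poly, max_vertices)
    if (polygon_signed_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
    circumference <- polygon_perimeter(poly)
    m <- max(1L, floor(circumference / receptor_spacing))
    pts <- polygon_arc_points(poly, (seq_len(m) - 0.5) * circumference / m)
    aff <- vapply(seq_len(m), function(i) {
      affinity_rule(.mean_intensity_near(intensity_image, pts[i, ] / pixel_size))
    }, numeric(1))
    list(boundary = poly,
         receptors = data.frame(x = pts[, 1], y = pts[, 2],
                                affinity = aff, capacity = capacity))
  })

  cx <- vapply(cells, function(cl) polygon_centroid(cl$boundary)[1], numeric(1))
  cells <- cells[order(cx)]
  for (l in seq_along(cells)) cells[[l]]$id <- l
  tissue_domain(nrow(label_mask) * pixel_size, ncol(label_mask) * pixel_size,
                cells)
}

.read_image_matrix <- function(img, integer = FALSE) {
  if (is.character(img)) {
    ext <- tolower(tools::file_ext(img))
    img <- switch(ext,
      png = png::readPNG(img),
      tif = , tiff = tiff::readTIFF(img),
      stop("unsupported image format: ", ext))
    if (length(dim(img)) == 3) img <- img[, , 1]
    if (integer) img <- round(img * 255)
  }
  m <- as.matrix(img)
  if (integer) storage.mode(m) <- "integer"
  m
}

# circular moving average over a window scaled to the contour length
.smooth_contour <- function(poly, window = NULL) {
  n <- nrow(poly)
  if (is.null(window)) window <- max(3L, min(9L, round(n / 20)))
  if (n < 2 * window) return(poly)
  half <- window %/% 2
  idx <- function(i) ((i - 1) %% n) + 1
  out <- poly
  for (i in seq_len(n)) {
    sel <- idx((i - half):(i + half))
    out[i, ] <- colMeans(poly[sel, , drop = FALSE])
  }
  out
}

# shift every vertex outward along its normal (mean of adjacent edge normals)
.offset_polygon <- function(poly, d) {
  n <- nrow(poly)
  nxt <- c(2:n, 1); prv <- c(n, 1:(n - 1))
  ccw <- polygon_signed_area(poly) > 0
  tang <- poly[nxt, ] - poly[prv, ]
  len <- sqrt(rowSums(tang^2))
  len[len == 0] <- 1
  normal <- cbind(tang[, 2], -tang[, 1]) / len # outward for CCW rings
  if (!ccw) normal <- -normal
  poly + d * normal
}

# uniform decimation to at most max_vertices vertices
.simplify_polygon <- function(poly, max_vertices) {
  n <- nrow(poly)
  if (n <= max_vertices) return(poly)
  keep <- unique(round(seq(1, n, length.out = max_vertices + 1)))[-1]
  poly[keep, , drop = FALSE]
}

# mean intensity in a 1-px-radius neighborhood of a (row, col) pixel position
.mean_intensity_near <- function(img, px) {
  r <- max(1L, min(nrow(img), round(px[1] + 0.5)))
  c <- max(1L, min(ncol(img), round(px[2] + 0.5)))
  rows <- max(1L, r - 1L):min(nrow(img), r + 1L)
  cols <- max(1L, c - 1L):min(ncol(img), c + 1L)
  sel <- expand.grid(rows, cols)
  keep <- (sel[, 1] - r)^2 + (sel[, 2] - c)^2 <= 1
  mean(img[cbind(sel[keep, 1], sel[keep, 2])])
}
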