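#' Cartilage segmentation geometry
#'
#' Container for one segmented ultrasound cross-section of the distal femoral
#' cartilage: the cartilage--bone interface polyline (deep boundary, greater
#' image y), the synovial--cartilage polyline (superficial boundary), and the
#' manually marked centre of the intercondylar notch. All coordinates are in
#' mm with the image y-axis pointing downward; polylines are ordered
#' lateral to medial along increasing x.
#'
#' @param bone_polyline two-column matrix (x_mm, y_mm) of the cartilage--bone
#'   interface, at least 2 points.
#' @param synovial_polyline two-column matrix of the synovial--cartilage
#'   boundary, at least 2 points.
#' @param notch_point length-2 numeric, the notch centre in mm. Must lie
#'   within the lateral--medial extent of the boundaries.
#' @param pixel_spacing mm per pixel for mask-derived inputs, or `NA` for
#'   vector input.
#' @param image_id label carried through to per-image outputs.
#' @return An object of class `cartilage_segmentation`.
#' @examples
#' bone <- cbind(seq(0, 38.4, length.out = 50), 10)
#' syno <- cbind(seq(0, 38.4, length.out = 50), 7)
#' seg <- cartilage_segmentation(bone, syno, notch_point = c(19.2, 10))
#' seg
#' @export
cartilage_segmentation <- function(bone_polyline, synovial_polyline,
                                   notch_point, pixel_spacing = NA_real_,
                                   image_id = "image") {
  bone_polyline <- as_poly_matrix(bone_polyline, "bone_polyline")
  synovial_polyline <- as_poly_matrix(synovial_polyline, "synovial_polyline")
  notch_point <- as.numeric(notch_point)
  if (length(notch_point) != 2L || anyNA(notch_point))
    stop("notch_point must be a finite (x, y) pair in mm", call. = FALSE)
  if (!is_simple_polyline(bone_polyline))
    stop("bone_polyline is self-intersecting", call. = FALSE)
  if (!is_simple_polyline(synovial_polyline))
    stop("synovial_polyline is self-intersecting", call. = FALSE)
  ext <- range(c(bone_polyline[, 1L], synovial_polyline[, 1L]))
  if (notch_point[1L] < ext[1L] || notch_point[1L] > ext[2L])
    stop(sprintf(
      "notch_point x = %.3f mm lies outside the lateral-medial extent [%.3f, %.3f] mm",
      notch_point[1L], ext[1L], ext[2L]), call. = FALSE)
  poly <- cartilage_polygon(bone_polyline, synovial_polyline)
  area <- abs(polygon_area_signed(poly))
  if (area <= 0)
    stop("the closed cartilage polygon has zero area", call. = FALSE)
  structure(
    list(bone_polyline = bone_polyline,
         synovial_polyline = synovial_polyline,
         notch_point = notch_point,
         pixel_spacing = pixel_spacing,
         image_id = as.character(image_id)),
    class = "cartilage_segmentation")
}

as_poly_matrix <- function(p, what) {
  p <- as.matrix(p)
  if (ncol(p) != 2L || nrow(p) < 2L || anyNA(p) || !is.numeric(p))
    stop(sprintf("%s must be a numeric matrix with >= 2 rows and 2 columns", what),
         call. = FALSE)
  storage.mode(p) <- "double"
  dimnames(p) <- list(NULL, c("x_mm", "y_mm"))
  p
}

# Closed cartilage cross-section polygon: bone boundary lateral->medial, then
# synovial boundary medial->lateral (joined at the two ends).
cartilage_polygon <- function(bone, synovial) {
  rbind(bone, synovial[rev(seq_len(nrow(synovial))), , drop = FALSE])
}

#' @export
print.cartilage_segmentation <- function(x, ...) {
  ext <- range(c(x$bone_polyline[, 1L], x$synovial_polyline[, 1L]))
  cat("Cartilage segmentation:", x$image_id, "\n")
  cat(sprintf("  lateral-medial extent: %.3f to %.3f mm (width %.3f mm)\n",
              ext[1L], ext[2L], diff(ext)))
  cat(sprintf("  bone interface: %d points, arc length %.3f mm\n",
              nrow(x$bone_polyline), polyline_length(x$bone_polyline)))
  cat(sprintf("  synovial boundary: %d points\n", nrow(x$synovial_polyline)))
  cat(sprintf("  notch: (%.3f, %.3f) mm\n", x$notch_point[1L], x$notch_point[2L]))
  if (!is.na(x$pixel_spacing))
    cat(sprintf("  pixel spacing: %.4f mm/px\n", x$pixel_spacing))
  invisible(x)
}

#' Extract boundary polylines from a binary cartilage mask
#'
#' Converts a segmentation mask to the boundary-polyline representation used
#' throughout the package. The largest connected foreground component is
#' retained, interior holes are filled, and for every occupied pixel column
#' the outer edge of the deepest pixel (greater y) becomes a bone-interface
#' vertex and the outer edge of the shallowest one a synovial vertex, so an
#' axis-aligned solid band recovers its exact physical outline. Pixel
#' centres map to mm as (index - 0.5) * spacing with 1-based matrix
#' indices, i.e. a 0-based pixel i has centre (i + 0.5) * spacing; traced
#' boundaries deviate from the true ones by at most half a pixel.
#'
#' @param mask logical or 0/1 matrix (rows = image y, columns = image x), or
#'   the path of a PNG file holding such a mask.
#' @param pixel_spacing mm per pixel (isotropic).
#' @param notch_hint approximate notch position in mm; snapped to the deepest
#'   synovial point within `snap_mm` of its abscissa (ties broken toward the
#'   hint).
#' @param snap_mm half-width of the snapping window in mm; `0` disables
#'   snapping and uses the hint as given.
#' @param image_id label for the resulting segmentation.
#' @return A [cartilage_segmentation].
#' @export
boundaries_from_mask <- function(mask, pixel_spacing, notch_hint,
                                 snap_mm = 2, image_id = "mask") {
  if (is.character(mask)) mask <- read_mask_png(mask)
  mask <- mask_as_logical(mask)
  if (!any(mask)) stop("mask is empty: no foreground pixels", call. = FALSE)
  if (!is.numeric(pixel_spacing) || pixel_spacing <= 0)
    stop("pixel_spacing must be a positive mm/px scalar", call. = FALSE)

  lab <- EBImage::bwlabel(mask * 1)
  sizes <- tabulate(lab[lab > 0])
  biggest <- which(sizes == max(sizes))
  if (length(biggest) > 1L)
    stop(sprintf(
      "mask is ambiguous: %d equally sized largest components (%d px each)",
      length(biggest), max(sizes)), call. = FALSE)
  comp <- lab == biggest
  comp <- EBImage::fillHull(comp * 1) > 0

  cols <- which(colSums(comp) > 0L)
  top <- apply(comp[, cols, drop = FALSE], 2L, function(v) which(v)[1L])
  bot <- apply(comp[, cols, drop = FALSE], 2L, function(v) {
    w <- which(v); w[length(w)]
  })
  # column centres in x, extended to the outer pixel edges at both ends
  x_mm <- (cols - 0.5) * pixel_spacing
  x_mm[1L] <- (cols[1L] - 1L) * pixel_spacing
  x_mm[length(x_mm)] <- cols[length(cols)] * pixel_spacing
  bone <- cbind(x_mm, bot * pixel_spacing)           # deep outer edge
  synovial <- cbind(x_mm, (top - 1L) * pixel_spacing)  # superficial outer edge

  notch <- snap_notch(synovial, notch_hint, snap_mm)
  cartilage_segmentation(bone, synovial, notch,
                         pixel_spacing = pixel_spacing, image_id = image_id)
}

mask_as_logical <- function(mask) {
  if (is.logical(mask)) return(mask)
  m <- as.matrix(mask)
  if (!is.numeric(m)) stop("mask must be logical or numeric 0/1", call. = FALSE)
  m > 0.5
}

read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img > 0.5
}

snap_notch <- function(synovial, notch_hint, snap_mm) {
  notch_hint <- as.numeric(notch_hint)
  if (snap_mm <= 0) return(notch_hint)
  near <- abs(synovial[, 1L] - notch_hint[1L]) <= snap_mm
  if (!any(near)) return(notch_hint)
  cand <- synovial[near, , drop = FALSE]
  deepest <- cand[, 2L] >= max(cand[, 2L]) - 1e-9  # deepest = greatest image y
  cand <- cand[deepest, , drop = FALSE]
  cand[which.min(abs(cand[, 1L] - notch_hint[1L])), ]  # tie-break: nearest
}

#' Suggest a notch point automatically
#'
#' Proposes the deepest point (greatest image y, i.e. closest to the bone)
#' of the synovial--cartilage boundary within the central portion of the
#' cartilage width. Intended as a starting suggestion only: the notch used
#' in measurements must always be supplied explicitly, mirroring manual
#' identification on the images.
#'
#' @param seg a [cartilage_segmentation] (its notch point is ignored).
#' @param central_fraction search window as a fraction of the lateral-medial
#'   extent, centred on its midpoint.
#' @return Length-2 numeric (x_mm, y_mm).
#' @export
suggest_notch <- function(seg, central_fraction = 0.5) {
  stopifnot(inherits(seg, "cartilage_segmentation"))
  s <- seg$synovial_polyline
  ext <- range(s[, 1L])
  half <- central_fraction * diff(ext) / 2
  mid <- mean(ext)
  keep <- abs(s[, 1L] - mid) <= half
  cand <- s[keep, , drop = FALSE]
  if (nrow(cand) == 0L) cand <- s
  unname(cand[which.max(cand[, 2L]), ])
}
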