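#' Partition the cartilage width into lateral, intercondylar and medial zones
#'
#' The intercondylar zone is centred on the manually marked notch abscissa.
#' Under the default absolute convention its half-width is a fixed distance
#' in mm (4.8 mm, so the zone spans 4.8 mm on either side of the notch);
#' under the fraction convention it is a fraction (default the middle 25%)
#' of the imaged lateral--medial cartilage extent. The lateral zone lies
#' below the lower bound and the medial zone above the upper bound.
#'
#' If the notch sits closer than the half-width to either edge of the
#' extent, the intercondylar zone is truncated at that edge and the
#' partition is flagged with a warning status.
#'
#' @param seg a [cartilage_segmentation].
#' @param half_width intercondylar half-width in mm (absolute convention).
#' @param fraction fraction of the cartilage width given to the
#'   intercondylar zone (fraction convention).
#' @param convention `"absolute_mm"` (default) or `"fraction_of_extent"`.
#' @return An object of class `zone_partition`: list with `bounds` (lower
#'   and upper abscissae in mm), `extent`, `notch_x`, `half_width` actually
#'   used, `convention`, and `status` (`"ok"` or `"truncated"`).
#' @examples
#' bone <- cbind(seq(0, 38.4, length.out = 100), 10)
#' syno <- cbind(seq(0, 38.4, length.out = 100), 7)
#' seg <- cartilage_segmentation(bone, syno, notch_point = c(19.2, 10))
#' partition_zones(seg)                     # bounds at 14.4 and 24.0 mm
#' partition_zones(seg, convention = "fraction_of_extent", fraction = 0.25)
#' @export
partition_zones <- function(seg, half_width = 4.8, fraction = 0.25,
                            convention = c("absolute_mm",
                                           "fraction_of_extent")) {
  stopifnot(inherits(seg, "cartilage_segmentation"))
  convention <- match.arg(convention)
  ext <- range(c(seg$bone_polyline[, 1L], seg$synovial_polyline[, 1L]))
  notch_x <- seg$notch_point[1L]
  hw <- switch(convention,
               absolute_mm = half_width,
               fraction_of_extent = fraction * diff(ext) / 2)
  if (!is.numeric(hw) || hw <= 0)
    stop("intercondylar half-width must be positive", call. = FALSE)
  if (2 * hw > diff(ext) + 1e-12)
    stop(sprintf(
      "intercondylar span %.3f mm exceeds the cartilage extent %.3f mm",
      2 * hw, diff(ext)), call. = FALSE)
  bounds <- c(notch_x - hw, notch_x + hw)
  status <- "ok"
  if (bounds[1L] < ext[1L] || bounds[2L] > ext[2L]) {
    status <- "truncated"
    warning(sprintf(paste0(
      "notch at x = %.3f mm is closer than %.3f mm to the image edge; ",
      "the intercondylar zone is truncated"), notch_x, hw), call. = FALSE)
    bounds <- pmin(pmax(bounds, ext[1L]), ext[2L])
  }
  structure(list(bounds = bounds, extent = ext, notch_x = notch_x,
                 half_width = hw, fraction = fraction,
                 convention = convention, status = status),
            class = "zone_partition")
}

#' @export
print.zone_partition <- function(x, ...) {
  cat(sprintf("Zone partition (%s): lateral < %.3f mm | intercondylar | medial > %.3f mm\n",
              x$convention, x$bounds[1L], x$bounds[2L]))
  cat(sprintf("  extent [%.3f, %.3f] mm, notch x = %.3f mm, half-width %.3f mm%s\n",
              x$extent[1L], x$extent[2L], x$notch_x, x$half_width,
              if (x$status != "ok") paste0(" [", x$status, "]") else ""))
  invisible(x)
}

#' Measure per-zone cartilage thickness
#'
#' Clips the closed cartilage polygon to the vertical slab of each zone
#' (inserting vertices exactly at the zone bounds) and computes, per zone,
#' the cross-sectional area (shoelace formula), the arc length of the
#' cartilage--bone interface within the slab, and their ratio, the
#' cartilage thickness. Zone areas sum to the total polygon area and
#' interface lengths to the total bone arc length to floating tolerance;
#' both identities are asserted on every call.
#'
#' @param seg a [cartilage_segmentation].
#' @param part a [zone_partition]; computed from `seg` with default
#'   parameters when omitted.
#' @param check_tol relative tolerance for the conservation assertions.
#' @return A data frame of class `zone_measurements` with columns `zone`
#'   (`lateral`, `intercondylar`, `medial`), `area_mm2`,
#'   `interface_length_mm`, `thickness_mm`, plus attributes `image_id` and
#'   `partition`. Empty zones (zero width) carry zero area/length and `NA`
#'   thickness.
#' @examples
#' bone <- cbind(seq(0, 38.4, length.out = 100), 10)
#' syno <- cbind(seq(0, 38.4, length.out = 100), 7)
#' seg <- cartilage_segmentation(bone, syno, notch_point = c(19.2, 10))
#' measure_zones(seg)   # 3 mm everywhere
#' @export
measure_zones <- function(seg, part = partition_zones(seg),
                          check_tol = 1e-9) {
  stopifnot(inherits(seg, "cartilage_segmentation"),
            inherits(part, "zone_partition"))
  poly <- cartilage_polygon(seg$bone_polyline, seg$synovial_polyline)
  total_area <- abs(polygon_area_signed(poly))
  total_len <- polyline_length(seg$bone_polyline)
  ext <- part$extent
  cuts <- rbind(c(ext[1L] - 1, part$bounds[1L]),
                part$bounds,
                c(part$bounds[2L], ext[2L] + 1))
  zones <- c("lateral", "intercondylar", "medial")
  rows <- lapply(seq_len(3L), function(i) {
    lo <- cuts[i, 1L]; hi <- cuts[i, 2L]
    if (hi - lo <= 0) {
      return(data.frame(zone = zones[i], area_mm2 = 0,
                        interface_length_mm = 0, thickness_mm = NA_real_))
    }
    clipped <- clip_polygon_slab(poly, lo, hi)
    area <- abs(polygon_area_signed(clipped))
    pieces <- clip_polyline_slab(seg$bone_polyline, lo, hi)
    len <- sum(vapply(pieces, polyline_length, numeric(1)))
    if (len == 0 && area > check_tol * max(total_area, 1))
      stop(sprintf(
        "degenerate geometry: zone '%s' has area %.6g mm2 but zero bone interface",
        zones[i], area), call. = FALSE)
    data.frame(zone = zones[i], area_mm2 = area, interface_length_mm = len,
               thickness_mm = if (len > 0) area / len else NA_real_)
  })
  out <- do.call(rbind, rows)
  scale_a <- max(total_area, .Machine$double.eps)
  scale_l <- max(total_len, .Machine$double.eps)
  if (abs(sum(out$area_mm2) - total_area) > check_tol * scale_a)
    stop("zone areas do not sum to the total cartilage area", call. = FALSE)
  if (abs(sum(out$interface_length_mm) - total_len) > check_tol * scale_l)
    stop("zone interface lengths do not sum to the total bone arc length",
         call. = FALSE)
  structure(out, class = c("zone_measurements", "data.frame"),
            image_id = seg$image_id, partition = part)
}

#' @export
print.zone_measurements <- function(x, ...) {
  cat("Zone measurements for image:", attr(x, "image_id"), "\n")
  df <- as.data.frame(x)
  df$area_mm2 <- round(df$area_mm2, 3)
  df$interface_length_mm <- round(df$interface_length_mm, 3)
  df$thickness_mm <- round(df$thickness_mm, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Average triplicate images into a site reading
#'
#' Measures every image of one site and averages per-zone thickness across
#' the images (arithmetic mean, the per-image values being retained for
#' reliability analysis). Three images per site is the expected protocol,
#' but any positive number is accepted.
#'
#' @param images list of [cartilage_segmentation] objects of the same site.
#' @param site site label (e.g. `"right_lateral"`).
#' @param ... partition parameters forwarded to [partition_zones()].
#' @return An object of class `site_reading`: list with `site`, `n_images`,
#'   `per_image` (long data frame of per-image zone measurements) and
#'   `mean` (data frame of per-zone mean thickness).
#' @export
site_reading <- function(images, site = "site", ...) {
  if (inherits(images, "cartilage_segmentation")) images <- list(images)
  if (length(images) == 0L)
    stop("at least one image is required for a site reading", call. = FALSE)
  per <- lapply(seq_along(images), function(i) {
    seg <- images[[i]]
    m <- measure_zones(seg, partition_zones(seg, ...))
    cbind(image = i, image_id = attr(m, "image_id"), as.data.frame(m))
  })
  per <- do.call(rbind, per)
  mean_df <- aggregate(thickness_mm ~ zone, data = per, FUN = mean)
  mean_df <- mean_df[match(c("lateral", "intercondylar", "medial"),
                           mean_df$zone), ]
  rownames(mean_df) <- NULL
  structure(list(site = site, n_images = length(images),
                 per_image = per, mean = mean_df),
            class = "site_reading")
}

#' @export
print.site_reading <- function(x, ...) {
  cat(sprintf("Site reading '%s' (%d image%s)\n", x$site, x$n_images,
              if (x$n_images == 1L) "" else "s"))
  df <- x$mean
  df$thickness_mm <- round(df$thickness_mm, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
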