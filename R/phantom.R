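#' Specify an analytic cartilage phantom
#'
#' Phantoms are bands of known thickness laid over a flat or circular-arc
#' bone curve, used to validate the zone-measurement pipeline against ground
#' truth that is computed from the continuous geometry rather than from any
#' discretised polyline or mask.
#'
#' @param profile cartilage thickness in mm: either a single positive number
#'   (constant thickness) or a vectorised function `t(x)` of the
#'   lateral--medial coordinate `x` in mm, strictly positive on
#'   `[0, width]`.
#' @param width lateral--medial extent of the band in mm.
#' @param notch_x abscissa of the intercondylar notch in mm, inside
#'   `(0, width)`.
#' @param bone bone-curve description: `list(type = "flat")` (default, at
#'   depth `y_ref`) or `list(type = "arc", radius = , orientation = )` with
#'   radius in mm and orientation `"convex"` (condyle bulging toward the
#'   probe; cartilage offset away from the arc centre) or `"concave"`
#'   (cartilage offset toward the centre, only valid while `t(x) < radius`).
#' @param pixel_spacing mm per pixel used when rasterising.
#' @param n_points number of vertices per boundary polyline.
#' @param y_ref image depth in mm of the bone curve apex (y-axis points
#'   down; the cartilage lies above the bone, at smaller y).
#' @return An object of class `phantom_spec`.
#' @seealso [make_phantom()]
#' @export
phantom_spec <- function(profile = 3.0, width = 38.4, notch_x = width / 2,
                         bone = list(type = "flat"), pixel_spacing = 0.05,
                         n_points = 801L, y_ref = 10) {
  tfun <- if (is.function(profile)) profile else {
    force(profile); function(x) rep_len(profile, length(x))
  }
  xs <- seq(0, width, length.out = 2048L)
  tv <- tfun(xs)
  if (any(!is.finite(tv)) || any(tv <= 0))
    stop("thickness profile must be strictly positive over the band", call. = FALSE)
  if (!is.numeric(width) || width <= 0) stop("width must be > 0", call. = FALSE)
  if (notch_x <= 0 || notch_x >= width)
    stop("notch_x must lie strictly inside (0, width)", call. = FALSE)
  if (pixel_spacing <= 0) stop("pixel_spacing must be > 0", call. = FALSE)
  bone$type <- match.arg(bone$type, c("flat", "arc"))
  if (bone$type == "arc") {
    if (is.null(bone$radius) || bone$radius <= 0)
      stop("arc bone curve needs a positive radius (mm)", call. = FALSE)
    if (width / 2 > bone$radius)
      stop("arc of this radius cannot span the requested width", call. = FALSE)
    bone$orientation <- match.arg(bone$orientation %||% "convex",
                                  c("convex", "concave"))
    if (bone$orientation == "concave") {
      bad <- tv >= bone$radius
      if (any(bad)) {
        rng <- range(xs[bad])
        stop(sprintf(paste0(
          "self-intersecting offset: thickness reaches the curvature radius ",
          "(%.1f mm) for x in [%.2f, %.2f] mm"),
          bone$radius, rng[1L], rng[2L]), call. = FALSE)
      }
    }
  }
  structure(list(profile = tfun, width = width, notch_x = notch_x,
                 bone = bone, pixel_spacing = pixel_spacing,
                 n_points = as.integer(n_points), y_ref = y_ref),
            class = "phantom_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Continuous geometry of a phantom: parametric bone and synovial curves plus
# the piecewise lower/upper boundary functions of x used for quadrature.
phantom_curves <- function(spec) {
  w <- spec$width; tfun <- spec$profile; y0 <- spec$y_ref
  if (spec$bone$type == "flat") {
    list(
      bone_xy = function(x) cbind(x, rep_len(y0, length(x))),
      syn_xy = function(x) cbind(x, y0 - tfun(x)),
      bone_xrange = c(0, w), syn_xrange = c(0, w),
      bone_y = function(x) rep_len(y0, length(x)),
      syn_y = function(x) y0 - tfun(x),
      bone_arclen = function(a, b) b - a,
      closure = NULL)
  } else {
    R <- spec$bone$radius
    sgn <- if (spec$bone$orientation == "convex") 1 else -1
    cx <- w / 2
    # convex: centre below the apex (y = y0 + R); concave: centre above.
    cy <- y0 + sgn * R
    th_max <- asin((w / 2) / R)
    th_of_x <- function(x) asin((x - cx) / R)
    bone_y <- function(x) cy - sgn * R * cos(th_of_x(x))
    bone_xy <- function(x) cbind(x, bone_y(x))
    # synovial point for bone parameter theta: radial offset toward the probe
    syn_at <- function(th) {
      xb <- cx + R * sin(th)
      r <- R + sgn * tfun(xb)
      cbind(cx + r * sin(th), cy - sgn * r * cos(th))
    }
    th_grid <- seq(-th_max, th_max, length.out = 4096L)
    syn_grid <- syn_at(th_grid)
    if (any(diff(syn_grid[, 1L]) <= 0))
      stop("self-intersecting offset: synovial curve folds back in x", call. = FALSE)
    syn_xrange <- range(syn_grid[, 1L])
    # invert x_syn(theta) by monotone root finding
    th_of_syn_x <- function(x) {
      vapply(x, function(xi) {
        stats::uniroot(function(th) syn_at(th)[1L] - xi,
                       lower = -th_max, upper = th_max,
                       tol = 1e-12)$root
      }, numeric(1))
    }
    syn_y <- function(x) syn_at(th_of_syn_x(x))[, 2L]
    ends <- rbind(cbind(bone_xy(0), syn_at(-th_max)),
                  cbind(bone_xy(w), syn_at(th_max)))
    # straight closure segments joining bone ends to synovial ends
    closure <- lapply(1:2, function(i) {
      b <- ends[i, 1:2]; s <- ends[i, 3:4]
      xr <- sort(c(b[1L], s[1L]))
      f <- if (abs(s[1L] - b[1L]) < 1e-12) NULL else {
        function(x) b[2L] + (x - b[1L]) * (s[2L] - b[2L]) / (s[1L] - b[1L])
      }
      list(xrange = xr, y = f)
    })
    list(bone_xy = bone_xy, syn_xy = NULL, syn_at = syn_at,
         bone_xrange = c(0, w), syn_xrange = syn_xrange,
         bone_y = bone_y, syn_y = syn_y,
         bone_arclen = function(a, b) R * (th_of_x(b) - th_of_x(a)),
         closure = closure, th_max = th_max, sgn = sgn)
  }
}

#' Generate a cartilage phantom with analytic ground truth
#'
#' Samples the bone and synovial boundaries of the phantom as polylines,
#' places the notch on the bone curve at `notch_x`, and computes per-zone
#' ground-truth measurements (area, cartilage--bone interface arc length and
#' their ratio, the thickness) by adaptive quadrature on the continuous
#' curves. Optionally rasterises the band into a binary mask at the phantom's
#' pixel spacing.
#'
#' Zones use the same vertical-slab convention as [measure_zones()], so the
#' ground truth is directly comparable with measurements taken on the
#' discretised output.
#'
#' @param spec a [phantom_spec].
#' @param rasterize if `TRUE`, also return a binary mask (`TRUE` inside the
#'   cartilage band) with pixel centres at `(index - 0.5) * pixel_spacing`.
#' @param half_width,fraction,convention zone-partition parameters used for
#'   the emitted ground truth; see [partition_zones()].
#' @return A list of class `cartilage_phantom` with elements `segmentation`
#'   (a [cartilage_segmentation]), `ground_truth` (data frame with one row
#'   per zone: `zone`, `area_mm2`, `interface_length_mm`, `thickness_mm`),
#'   `spec`, and, when rasterised, `mask` plus `mask_origin_mm`.
#' @examples
#' ph <- make_phantom(phantom_spec(profile = 3, width = 38.4))
#' ph$ground_truth
#' @export
make_phantom <- function(spec, rasterize = FALSE, half_width = 4.8,
                         fraction = 0.25,
                         convention = c("absolute_mm", "fraction_of_extent")) {
  stopifnot(inherits(spec, "phantom_spec"))
  convention <- match.arg(convention)
  cur <- phantom_curves(spec)
  n <- spec$n_points

  bone <- cur$bone_xy(seq(0, spec$width, length.out = n))
  syn <- if (spec$bone$type == "flat") {
    cur$syn_xy(seq(0, spec$width, length.out = n))
  } else {
    cur$syn_at(seq(-cur$th_max, cur$th_max, length.out = n))
  }
  if (!is_simple_polyline(syn)) {
    stop("self-intersecting offset: synovial polyline is not simple", call. = FALSE)
  }
  notch <- cur$bone_xy(spec$notch_x)[1L, ]
  seg <- cartilage_segmentation(bone, syn, notch,
                                pixel_spacing = spec$pixel_spacing,
                                image_id = "phantom")

  ext <- range(c(bone[, 1L], syn[, 1L]))
  hw <- if (convention == "absolute_mm") half_width else fraction * diff(ext) / 2
  bounds <- c(spec$notch_x - hw, spec$notch_x + hw)
  gt <- phantom_ground_truth(cur, ext, bounds)

  out <- list(segmentation = seg, ground_truth = gt, spec = spec,
              zone_bounds = bounds)
  if (rasterize) {
    m <- rasterize_phantom(seg, spec$pixel_spacing)
    out$mask <- m$mask
    out$mask_origin_mm <- m$origin
  }
  class(out) <- "cartilage_phantom"
  out
}

# Quadrature ground truth for the three vertical-slab zones. The cartilage
# cross-section is bounded below (greater y) by the bone curve, above by the
# synovial curve, with straight closure segments joining their endpoints
# wherever one curve spans x that the other does not.
phantom_ground_truth <- function(cur, ext, bounds) {
  zones <- rbind(c(ext[1L], bounds[1L]),
                 c(bounds[1L], bounds[2L]),
                 c(bounds[2L], ext[2L]))
  on_closure <- function(x, fallback) {
    y <- fallback
    for (cl in cur$closure %||% list()) {
      if (is.null(cl$y)) next
      inc <- is.na(y) & x >= cl$xrange[1L] & x <= cl$xrange[2L]
      y[inc] <- cl$y(x[inc])
    }
    y
  }
  lower_y <- function(x) {
    y <- rep(NA_real_, length(x))
    inb <- x >= cur$bone_xrange[1L] & x <= cur$bone_xrange[2L]
    y[inb] <- cur$bone_y(x[inb])
    on_closure(x, y)
  }
  upper_y <- function(x) {
    y <- rep(NA_real_, length(x))
    ins <- x >= cur$syn_xrange[1L] & x <= cur$syn_xrange[2L]
    y[ins] <- cur$syn_y(x[ins])
    on_closure(x, y)
  }
  hull <- range(c(cur$bone_xrange, cur$syn_xrange))
  width_fun <- function(x) lower_y(x) - upper_y(x)
  rows <- lapply(seq_len(3L), function(i) {
    a <- max(zones[i, 1L], hull[1L])
    b <- min(zones[i, 2L], hull[2L])
    if (b <= a) {
      return(data.frame(zone = c("lateral", "intercondylar", "medial")[i],
                        area_mm2 = 0, interface_length_mm = 0,
                        thickness_mm = NA_real_))
    }
    edges <- c(cur$bone_xrange, cur$syn_xrange)
    brk <- sort(unique(c(a, b, edges[edges > a & edges < b])))
    area <- sum(vapply(seq_len(length(brk) - 1L), function(k) {
      stats::integrate(width_fun, brk[k], brk[k + 1L],
                       rel.tol = 1e-10, subdivisions = 400L)$value
    }, numeric(1)))
    la <- max(zones[i, 1L], cur$bone_xrange[1L])
    lb <- min(zones[i, 2L], cur$bone_xrange[2L])
    len <- if (lb > la) cur$bone_arclen(la, lb) else 0
    data.frame(zone = c("lateral", "intercondylar", "medial")[i],
               area_mm2 = area, interface_length_mm = len,
               thickness_mm = if (len > 0) area / len else NA_real_)
  })
  do.call(rbind, rows)
}

#' Rasterise a segmentation into a binary mask
#'
#' @param seg a [cartilage_segmentation].
#' @param pixel_spacing mm per pixel.
#' @param margin_px background margin added on every side.
#' @return List with `mask` (logical matrix, rows = y), and `origin`
#'   (mm coordinates of the pixel-grid origin, i.e. the outer corner of
#'   pixel (1,1)).
#' @export
rasterize_phantom <- function(seg, pixel_spacing = seg$pixel_spacing,
                              margin_px = 4L) {
  stopifnot(inherits(seg, "cartilage_segmentation"))
  poly <- cartilage_polygon(seg$bone_polyline, seg$synovial_polyline)
  xr <- range(poly[, 1L]); yr <- range(poly[, 2L])
  ox <- xr[1L] - margin_px * pixel_spacing
  oy <- yr[1L] - margin_px * pixel_spacing
  ncol <- ceiling((xr[2L] - ox) / pixel_spacing) + margin_px
  nrow <- ceiling((yr[2L] - oy) / pixel_spacing) + margin_px
  xc <- ox + (seq_len(ncol) - 0.5) * pixel_spacing
  yc <- oy + (seq_len(nrow) - 0.5) * pixel_spacing
  px <- rep(xc, each = nrow)
  py <- rep(yc, times = ncol)
  mask <- matrix(points_in_polygon(px, py, poly), nrow = nrow, ncol = ncol)
  list(mask = mask, origin = c(ox, oy))
}

#' @export
print.cartilage_phantom <- function(x, ...) {
  cat("Cartilage phantom (", x$spec$bone$type, " bone curve)\n", sep = "")
  cat(sprintf("  width %.2f mm, notch at x = %.2f mm\n",
              x$spec$width, x$spec$notch_x))
  cat("  ground truth (vertical-slab zones):\n")
  print(x$ground_truth, row.names = FALSE, digits = 6)
  invisible(x)
}
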