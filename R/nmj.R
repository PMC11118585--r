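## Neuromuscular-junction quantification in extraocular-muscle confocal
## stacks: max projection, ROI-restricted intensity thresholding, % area
## labeled, connected-component particle statistics.

#' Polygonal muscle ROI
#'
#' @param vertices Two-column matrix (or list of `c(x, y)` pairs) of polygon
#'   vertices in pixel coordinates, 0-based, `x` = column. At least 3
#'   vertices; the polygon must be simple (non-self-intersecting).
#' @param muscle Muscle label (`"SO"`, `"SR"`, `"IR"`, `"IO"`, or other).
#' @return An object of class `muscle_roi`.
#' @export
muscle_roi <- function(vertices, muscle = NA_character_) {
  if (is.list(vertices)) vertices <- do.call(rbind, vertices)
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L) {
    stop_invalid("`vertices` must be an n x 2 matrix with n >= 3")
  }
  if (polygon_self_intersects(vertices)) {
    stop_invalid("ROI polygon is self-intersecting")
  }
  structure(list(vertices = vertices, muscle = muscle), class = "muscle_roi")
}

# O(n^2) segment-intersection test over non-adjacent edges.
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), ])
  ccw <- function(ax, ay, bx, by, cx, cy) (cy - ay) * (bx - ax) - (by - ay) * (cx - ax)
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent through wrap-around
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- ccw(a[1], a[2], a[3], a[4], b[1], b[2])
      d2 <- ccw(a[1], a[2], a[3], a[4], b[3], b[4])
      d3 <- ccw(b[1], b[2], b[3], b[4], a[1], a[2])
      d4 <- ccw(b[1], b[2], b[3], b[4], a[3], a[4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Rasterize a polygon ROI onto an image grid
#'
#' A pixel belongs to the ROI when its center falls inside the polygon
#' (center-in-polygon rule; point-in-polygon via `mgcv::in.out`). Pixel
#' (row r, col c) of a matrix has center (x, y) = (c - 0.5, r - 0.5) in the
#' 0-based ROI coordinate convention.
#'
#' @param roi A [muscle_roi()].
#' @param dim Image dimensions `c(nrow, ncol)`.
#' @return Logical matrix of the ROI interior.
#' @export
roi_mask <- function(roi, dim) {
  nr <- dim[1]; nc <- dim[2]
  cx <- rep(seq_len(nc) - 0.5, each = nr)
  cy <- rep(seq_len(nr) - 0.5, times = nc)
  bnd <- roi$vertices
  if (any(bnd[1, ] != bnd[nrow(bnd), ])) bnd <- rbind(bnd, bnd[1, ])
  inside <- mgcv::in.out(bnd, cbind(cx, cy))
  matrix(inside, nrow = nr, ncol = nc)
}

#' Maximum intensity projection of a confocal stack
#'
#' @param stack 3-D array (y, x, z) or a 2-D matrix (returned unchanged).
#' @return 2-D matrix of per-pixel maxima over z.
#' @export
max_projection <- function(stack) {
  if (is.matrix(stack)) return(stack)
  d <- dim(stack)
  if (is.null(d) || length(d) != 3L || d[3] < 1L) {
    stop_invalid("`stack` must be a 2-D matrix or 3-D (y, x, z) array")
  }
  apply(stack, c(1, 2), max)
}

#' Threshold an image within a muscle ROI
#'
#' Separates the brightest signal (postsynaptic NMJ label) from the weakest
#' (muscle fiber). The threshold is computed from ROI-interior pixels only:
#' `"otsu"` (default; `EBImage::otsu` on the ROI pixel histogram, an
#' automatic, documented stand-in for manual rater thresholding),
#' `"percentile"` (the `percentile`-quantile of ROI intensities), or
#' `"fixed"` (`value`). The mask is TRUE where intensity exceeds the
#' threshold and the pixel is inside the ROI.
#'
#' @param image 2-D intensity matrix (e.g. a max projection).
#' @param roi A [muscle_roi()] (>= 100 interior pixels required).
#' @param method `"otsu"`, `"percentile"` or `"fixed"`.
#' @param percentile Quantile in (0, 1) for `method = "percentile"`.
#' @param value Threshold for `method = "fixed"`.
#' @return List with `mask` (logical matrix), `threshold_value`, `method`,
#'   and the `roi_mask` used.
#' @export
threshold_mask <- function(image, roi, method = c("otsu", "percentile", "fixed"),
                           percentile = 0.95, value = NULL) {
  method <- match.arg(method)
  if (!is.matrix(image)) stop_invalid("`image` must be a 2-D matrix")
  rmask <- roi_mask(roi, dim(image))
  npx <- sum(rmask)
  if (npx < 100L) stop_invalid("ROI covers %d pixels; >= 100 required", npx)
  px <- image[rmask]
  thr <- switch(method,
    otsu = {
      if (stats::sd(px) < 1e-12) {
        warning("uniform ROI intensities; no suprathreshold class", call. = FALSE)
        max(px)  # nothing exceeds it
      } else {
        rng <- range(px)
        as.numeric(EBImage::otsu(EBImage::Image(px, dim = c(length(px), 1)),
                                 range = rng, levels = 256))
      }
    },
    percentile = {
      check_number(percentile, "percentile", positive = TRUE)
      if (percentile >= 1) stop_invalid("`percentile` must be in (0, 1)")
      as.numeric(stats::quantile(px, percentile))
    },
    fixed = {
      if (is.null(value)) stop_invalid("`value` required for fixed threshold")
      check_number(value, "value")
      value
    }
  )
  list(mask = (image > thr) & rmask, threshold_value = thr, method = method,
       roi_mask = rmask)
}

#' Percent of ROI area labeled
#'
#' 100 x (suprathreshold pixels inside the ROI) / (pixels inside the ROI).
#' Pixels outside the ROI never contribute.
#'
#' @param mask Logical matrix of suprathreshold pixels.
#' @param roi A [muscle_roi()] or a precomputed logical ROI matrix.
#' @return Percentage in \[0, 100\].
#' @export
percent_area <- function(mask, roi) {
  rmask <- if (inherits(roi, "muscle_roi")) roi_mask(roi, dim(mask)) else roi
  total <- sum(rmask)
  if (total == 0L) stop_invalid("ROI contains no pixels")
  100 * sum(mask & rmask) / total
}

# 8-connectivity labeling: EBImage::bwlabel is 4-connectivity, so labels
# touching diagonally are merged with a union-find pass.
label_components_8 <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow = nrow(mask))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  parent <- seq_len(nlab)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  union2 <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[rb] <<- ra }
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]      # down-right diagonal
  sel <- a > 0L & b > 0L & a != b
  if (any(sel)) mapply(union2, a[sel], b[sel])
  a <- lab[-1, -nc]; b <- lab[-nr, -1]      # up-right diagonal
  sel <- a > 0L & b > 0L & a != b
  if (any(sel)) mapply(union2, a[sel], b[sel])
  roots <- vapply(seq_len(nlab), find, integer(1))
  dense <- match(roots, unique(roots))
  out <- lab
  out[lab > 0L] <- dense[lab[lab > 0L]]
  out
}

#' Particle statistics of a binary mask
#'
#' Connected components with 8-connectivity, minimum size one pixel and no
#' maximum ("1-infinity"), with sizes converted from pixels to um^2 via the
#' squared pixel size. Particle size is reported as area (um^2): particles
#' are 2-D regions of the projection.
#'
#' @param mask Logical matrix.
#' @param pixel_size_um Pixel size in um/pixel.
#' @return List with `particle_count`, `mean_particle_size_um2` (`NA` when
#'   the mask is empty) and `sizes_um2`.
#' @export
particle_stats <- function(mask, pixel_size_um) {
  check_number(pixel_size_um, "pixel_size_um", positive = TRUE)
  if (!any(mask)) {
    return(list(particle_count = 0L, mean_particle_size_um2 = NA_real_,
                sizes_um2 = numeric(0)))
  }
  lab <- label_components_8(mask)
  sizes_px <- tabulate(lab[lab > 0L])
  sizes <- sizes_px * pixel_size_um^2
  list(particle_count = length(sizes),
       mean_particle_size_um2 = mean(sizes),
       sizes_um2 = sizes)
}

#' Quantify NMJ labeling in one muscle
#'
#' The full per-muscle pipeline: maximum intensity projection, light
#' Gaussian denoising, ROI-restricted thresholding, binarization, % area
#' labeled and particle statistics. The denoising step (default sigma 1 px)
#' suppresses single-pixel noise excursions that an automatic threshold
#' would otherwise count as labeled area or spurious particles — the
#' standard despeckling a rater performs implicitly when thresholding by
#' eye; set `smooth_sigma = 0` to threshold raw pixels. The threshold and
#' method are recorded for reproducibility. Deterministic: identical inputs
#' give identical output.
#'
#' @param stack 3-D (y, x, z) array or 2-D projection.
#' @param roi A [muscle_roi()].
#' @param pixel_size_um Pixel size, um/pixel.
#' @param channel Label channel (`"aBTX"` postsynaptic or `"SV2A"`
#'   presynaptic); metadata only — identical pixels give identical numbers.
#' @param method,percentile,value Passed to [threshold_mask()].
#' @param smooth_sigma Gaussian blur sigma (pixels) applied to the
#'   projection before thresholding; 0 disables.
#' @return An object of class `nmj_quant`: `percent_area`, `particle_count`,
#'   `mean_particle_size_um2`, `threshold_value`, `method`, `channel`,
#'   `muscle`.
#' @export
quantify_muscle <- function(stack, roi, pixel_size_um,
                            channel = c("aBTX", "SV2A"),
                            method = "otsu", percentile = 0.95, value = NULL,
                            smooth_sigma = 1) {
  channel <- match.arg(channel)
  proj <- max_projection(stack)
  if (smooth_sigma > 0) {
    proj <- as.matrix(EBImage::gblur(EBImage::Image(proj),
                                     sigma = smooth_sigma))
  }
  th <- threshold_mask(proj, roi, method = method, percentile = percentile,
                       value = value)
  pa <- percent_area(th$mask, th$roi_mask)
  ps <- particle_stats(th$mask, pixel_size_um)
  structure(
    list(percent_area = pa, particle_count = ps$particle_count,
         mean_particle_size_um2 = ps$mean_particle_size_um2,
         sizes_um2 = ps$sizes_um2, threshold_value = th$threshold_value,
         method = th$method, channel = channel, muscle = roi$muscle,
         pixel_size_um = pixel_size_um),
    class = "nmj_quant"
  )
}

#' @export
print.nmj_quant <- function(x, ...) {
  cat(sprintf("<nmj_quant> %s %s: %.2f%% area labeled, %d particles (mean %.2f um^2), threshold %.4g (%s)\n",
              ifelse(is.na(x$muscle), "muscle", x$muscle), x$channel,
              x$percent_area, x$particle_count,
              ifelse(x$particle_count > 0, x$mean_particle_size_um2, NA),
              x$threshold_value, x$method))
  invisible(x)
}
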