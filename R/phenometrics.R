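# Top-view RGB phenometrics: segmentation, greenness, canopy area,
# shape metrics and the canopy expansion rate.

#' Construct an RGBImage
#'
#' @param pixels Numeric `H x W x 3` array, channels R, G, B.  Values in
#'   `[0, 1]` are rescaled to 0-255; values already on 0-255 are kept.
#' @param mmPerPx Physical pixel size, mm.
#' @return An [RGBImage-class].
#' @export
rgbImage <- function(pixels, mmPerPx = 1) {
  pixels <- unclass(pixels)
  if (max(pixels, na.rm = TRUE) <= 1) pixels <- pixels * 255
  new("RGBImage", pixels = pixels, mmPerPx = as.numeric(mmPerPx))
}

#' Read/write a PNG plant image
#'
#' @param path PNG path.
#' @param mmPerPx Physical pixel size, mm.
#' @return `readRGBImage()` an [RGBImage-class]; `writeRGBImage()`
#'   invisibly `path`.
#' @export
readRGBImage <- function(path, mmPerPx = 1) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L && dim(px)[3L] >= 3L) px <- px[, , 1:3]
  rgbImage(px, mmPerPx)
}

#' @rdname readRGBImage
#' @param img An [RGBImage-class].
#' @export
writeRGBImage <- function(img, path) {
  png::writePNG(img@pixels / 255, path)
  invisible(path)
}

#' @rdname mmPerPx
#' @export
setGeneric("mmPerPx", function(x) standardGeneric("mmPerPx"))

#' Physical pixel size accessor
#' @param x An [RGBImage-class].
#' @return mm per pixel edge.
#' @aliases mmPerPx
#' @export
setMethod("mmPerPx", "RGBImage", function(x) x@mmPerPx)

setMethod("show", "RGBImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("RGBImage %d x %d px at %.3g mm/px\n", d[1], d[2], object@mmPerPx))
})

#' Accessors for CanopyMask
#'
#' @param x A [CanopyMask-class].
#' @return `maskMatrix()` the logical matrix; `maskProvenance()` the
#'   thresholding parameters it was produced with.
#' @export
maskMatrix <- function(x) x@mask

#' @rdname maskMatrix
#' @export
maskProvenance <- function(x) x@provenance

setMethod("show", "CanopyMask", function(object) {
  cat(sprintf("CanopyMask %d x %d px, %d foreground (%s)\n",
              nrow(object@mask), ncol(object@mask), sum(object@mask),
              object@provenance$method %||% "unknown"))
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Segment the plant canopy by colour thresholding
#'
#' Three threshold spaces are available:
#' * `"exg"` (default): excess-green rule `2G - R - B > tau` on the 0-255
#'   scale; robust against achromatic soil/tray backgrounds without
#'   published per-channel bounds.
#' * `"rgb"`: per-channel `[min, max]` bounds, a 2 x 3 matrix
#'   (rows min/max, columns R, G, B).
#' * `"hsv"`: bounds on hue, saturation, value in `[0, 1]`, same layout.
#'
#' @param img An [RGBImage-class].
#' @param method `"exg"`, `"rgb"` or `"hsv"`.
#' @param tau Excess-green threshold (default 40).
#' @param bounds 2 x 3 bounds matrix for `"rgb"`/`"hsv"`.
#' @param largestOnly Keep only the largest 8-connected component
#'   (default `FALSE`).
#' @return A [CanopyMask-class].
#' @export
segmentCanopy <- function(img, method = c("exg", "rgb", "hsv"), tau = 40,
                          bounds = NULL, largestOnly = FALSE) {
  method <- match.arg(method)
  stopifnot(is(img, "RGBImage"))
  px <- img@pixels
  r <- px[, , 1]; g <- px[, , 2]; b <- px[, , 3]
  if (method == "exg") {
    mask <- (2 * g - r - b) > tau
    prov <- list(method = "exg", tau = tau)
  } else {
    if (is.null(bounds) || !all(dim(bounds) == c(2L, 3L))) {
      stop("config error: bounds must be a 2 x 3 [min; max] matrix")
    }
    if (any(bounds[1, ] > bounds[2, ])) {
      stop("config error: threshold min exceeds max")
    }
    if (method == "rgb") {
      ch <- list(r, g, b)
    } else {
      hsv <- grDevices::rgb2hsv(rbind(as.vector(r), as.vector(g), as.vector(b)),
                                maxColorValue = 255)
      ch <- lapply(1:3, function(i) matrix(hsv[i, ], nrow(r), ncol(r)))
    }
    mask <- Reduce(`&`, lapply(1:3, function(i) {
      ch[[i]] >= bounds[1, i] & ch[[i]] <= bounds[2, i]
    }))
    prov <- list(method = method, bounds = bounds)
  }
  if (largestOnly && any(mask)) mask <- .largestComponent(mask)
  prov$largestOnly <- largestOnly
  new("CanopyMask", mask = mask, provenance = prov)
}

# Largest 8-connected component of a logical matrix.
.largestComponent <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labm <- EBImage::imageData(lab)
  counts <- tabulate(labm[labm > 0])
  labm == which.max(counts)
}

#' Canopy greenness index
#'
#' `(2 avgG - avgR - avgB) / (2 avgR + avgG + avgB)`, where avgR/avgG/avgB
#' are channel means over the segmented canopy pixels (channels are averaged
#' first, then the index is formed — not a per-pixel index mean).
#'
#' @param img An [RGBImage-class].
#' @param mask A [CanopyMask-class] (or logical matrix) of the same shape.
#' @return Dimensionless greenness; 2 for pure green, 0 for any grey.
#' @examples
#' px <- array(0, c(2, 2, 3)); px[, , 2] <- 255
#' greenness(rgbImage(px), matrix(TRUE, 2, 2))
#' @export
greenness <- function(img, mask) {
  stopifnot(is(img, "RGBImage"))
  m <- if (is(mask, "CanopyMask")) mask@mask else mask
  if (!any(m)) stop("undefined-metric error: empty mask")
  avg <- vapply(1:3, function(i) mean(img@pixels[, , i][m]), numeric(1))
  den <- 2 * avg[1] + avg[2] + avg[3]
  if (den == 0) stop("undefined-metric error: zero denominator (all-black canopy)")
  (2 * avg[2] - avg[1] - avg[3]) / den
}

#' Canopy area in physical units
#'
#' @param mask A [CanopyMask-class] or logical matrix.
#' @param mmPerPx Physical pixel size, mm.
#' @return Area in mm2 (`pixel count * mmPerPx^2`).
#' @export
canopyArea <- function(mask, mmPerPx = 1) {
  m <- if (is(mask, "CanopyMask")) mask@mask else mask
  sum(m) * mmPerPx^2
}

#' Canopy area expansion rate
#'
#' Averaged-log relative expansion rate between two sampling days:
#' `(mean(ln A2) - mean(ln A1)) / (t2 - t1)` per day, where `A1`, `A2` are
#' per-plant canopy areas at days `t1 < t2`.
#'
#' @param areas_t1,areas_t2 Positive per-plant areas (mm2) at `t1`, `t2`.
#' @param t1_das,t2_das Sampling days (days after sowing), `t2 > t1`.
#' @return Expansion rate, day-1.
#' @examples
#' expansionRate(c(100, 120), c(200, 240), 12, 28)  # ln(2)/16
#' @export
expansionRate <- function(areas_t1, areas_t2, t1_das, t2_das) {
  if (t2_das <= t1_das) stop("t2 must be later than t1")
  if (any(areas_t1 <= 0) || any(areas_t2 <= 0)) {
    stop("areas must be > 0 for log transformation")
  }
  (mean(log(areas_t2)) - mean(log(areas_t1))) / (t2_das - t1_das)
}

# Oriented-contour perimeter of the largest component: sum of steps between
# successive 8-connected boundary pixels, diagonals weighted sqrt(2).
.contourPerimeter <- function(m) {
  oc <- EBImage::ocontour(EBImage::Image(m * 1))
  pts <- oc[[which.max(vapply(oc, nrow, integer(1)))]]
  if (nrow(pts) < 2L) return(4)  # isolated pixel: unit square
  d <- sqrt(rowSums((pts - pts[c(2:nrow(pts), 1), ])^2))
  sum(d)
}

#' Canopy roundness
#'
#' Isoperimetric ratio `4 pi A / P^2` of the largest connected component,
#' clamped to `[0, 1]`; 1 for a disk in the continuum limit.  The perimeter
#' is the oriented boundary-pixel contour length with diagonal steps
#' weighted `sqrt(2)`.
#'
#' @param mask A [CanopyMask-class] or logical matrix, nonempty.
#' @return Roundness in `[0, 1]`.
#' @export
roundness <- function(mask) {
  m <- if (is(mask, "CanopyMask")) mask@mask else mask
  if (!any(m)) stop("undefined-metric error: empty mask")
  m <- .largestComponent(m)
  a <- sum(m)
  p <- .contourPerimeter(m)
  min(1, 4 * pi * a / p^2)
}

#' Canopy compactness
#'
#' Area of the largest connected component divided by the area of its
#' convex hull (hull taken over pixel corner points so that a convex blob
#' scores 1 up to rasterisation), clamped to `(0, 1]`.  Filling a concavity
#' can only increase it.
#'
#' @param mask A [CanopyMask-class] or logical matrix, nonempty.
#' @return Compactness in `(0, 1]`.
#' @export
compactness <- function(mask) {
  m <- if (is(mask, "CanopyMask")) mask@mask else mask
  if (!any(m)) stop("undefined-metric error: empty mask")
  m <- .largestComponent(m)
  idx <- which(m, arr.ind = TRUE)
  corners <- rbind(
    idx + matrix(c(-0.5, -0.5), nrow(idx), 2, byrow = TRUE),
    idx + matrix(c(-0.5, 0.5), nrow(idx), 2, byrow = TRUE),
    idx + matrix(c(0.5, -0.5), nrow(idx), 2, byrow = TRUE),
    idx + matrix(c(0.5, 0.5), nrow(idx), 2, byrow = TRUE))
  h <- grDevices::chull(corners)
  hp <- corners[h, , drop = FALSE]
  n <- nrow(hp)
  if (n < 3L) return(1)
  j <- c(2:n, 1)
  hullArea <- abs(sum(hp[, 1] * hp[j, 2] - hp[j, 1] * hp[, 2])) / 2
  min(1, sum(m) / hullArea)
}

#' Measure one plant image
#'
#' Convenience wrapper joining segmentation and all per-plant metrics into
#' one tidy row.
#'
#' @param img An [RGBImage-class].
#' @param mask Optional precomputed [CanopyMask-class]; segmented with
#'   defaults otherwise.
#' @param plant_id,das Identifiers carried into the output.
#' @return One-row `data.frame`: `plant_id`, `das`, `area_mm2`,
#'   `greenness`, `roundness`, `compactness`.  Shape metrics are `NA` for
#'   an empty mask (flagged, not an error, so series processing continues).
#' @export
measureCanopy <- function(img, mask = NULL, plant_id = NA_character_,
                          das = NA_real_) {
  if (is.null(mask)) mask <- segmentCanopy(img)
  m <- if (is(mask, "CanopyMask")) mask@mask else mask
  if (!any(m)) {
    return(data.frame(plant_id = plant_id, das = das, area_mm2 = 0,
                      greenness = NA_real_, roundness = NA_real_,
                      compactness = NA_real_))
  }
  data.frame(plant_id = plant_id, das = das,
             area_mm2 = canopyArea(m, img@mmPerPx),
             greenness = greenness(img, m),
             roundness = roundness(m),
             compactness = compactness(m))
}
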