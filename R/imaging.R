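# Image analysis: threshold-based object detection and 3-class
# classification on cytospin-like fields, and lateral-position extraction
# from in-channel frames. Synthetic renderers provide ground truth.
#
# Intensity convention: dark objects on a light background, as in
# Giemsa-stained bright-field images. Enucleated cells render as uniform
# mid-intensity disks, nucleated cells as disks with a darker concentric
# nuclear core, free nuclei as small dark disks.

#' Specification of a synthetic cytospin field
#'
#' @param widthPx,heightPx frame size in pixels.
#' @param scale um per pixel.
#' @param objects data.frame with columns `class`, `x_px`, `y_px`,
#'   `diameter_um`.
#' @param background background intensity in [0, 1].
#' @param noiseSd additive Gaussian noise SD.
#' @param cellIntensity intensity of cytoplasm (enucleated and nucleated
#'   rim).
#' @param nucleusIntensity intensity of nuclear material (nuclei and
#'   nucleated cores).
#' @param coreFraction nuclear core diameter as a fraction of the cell
#'   diameter for nucleated cells.
#' @param spread optional named per-class area inflation factors emulating
#'   the cytospin spreading artifact (deformable cells flatten on the slide
#'   and appear larger); applied to the rendered, not the true, diameter.
#' @param allowOverlap permit overlapping objects (ground-truth tests
#'   require non-overlap).
#' @return list of class `cytospinSpec`.
#' @export
cytospinSpec <- function(widthPx = 512, heightPx = 512, scale = 0.5,
                         objects = data.frame(), background = 0.92,
                         noiseSd = 0.01, cellIntensity = 0.62,
                         nucleusIntensity = 0.22, coreFraction = 0.55,
                         spread = NULL, allowOverlap = FALSE) {
  .assertPositive(scale, "scale")
  structure(list(widthPx = widthPx, heightPx = heightPx, scale = scale,
                 objects = objects, background = background,
                 noiseSd = noiseSd, cellIntensity = cellIntensity,
                 nucleusIntensity = nucleusIntensity,
                 coreFraction = coreFraction, spread = spread,
                 allowOverlap = allowOverlap),
            class = "cytospinSpec")
}

# Paint a disk into matrix `img` (x = column, y = row coordinates in px).
.paintDisk <- function(img, x, y, rPx, value) {
  cols <- max(1L, floor(x - rPx)):min(ncol(img), ceiling(x + rPx))
  rows <- max(1L, floor(y - rPx)):min(nrow(img), ceiling(y + rPx))
  for (cc in cols) {
    dy2 <- rPx^2 - (cc - x)^2
    if (dy2 < 0) next
    dy <- sqrt(dy2)
    rr <- rows[rows >= y - dy & rows <= y + dy]
    img[rr, cc] <- value
  }
  img
}

#' Render a synthetic cytospin field
#'
#' @param spec a [cytospinSpec()].
#' @param seed integer seed for the additive noise.
#' @return list with `image` (numeric matrix in [0, 1], rows = y) and
#'   `truth` (the object table with rendered diameters).
#' @export
renderCytospin <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "cytospinSpec"))
  obj <- spec$objects
  img <- matrix(spec$background, nrow = spec$heightPx, ncol = spec$widthPx)
  if (nrow(obj) == 0L) {
    img <- .addNoise(img, spec$noiseSd, seed)
    return(list(image = img, truth = obj))
  }
  renderedD <- obj$diameter_um
  if (!is.null(spec$spread)) {
    # area inflation -> diameter scales by sqrt of the factor
    f <- spec$spread[obj$class]
    f[is.na(f)] <- 1
    renderedD <- renderedD * sqrt(f)
  }
  rPx <- renderedD / (2 * spec$scale)
  if (any(obj$x_px - rPx < 1 | obj$x_px + rPx > spec$widthPx |
          obj$y_px - rPx < 1 | obj$y_px + rPx > spec$heightPx))
    stop("objects must lie fully inside the frame", call. = FALSE)
  if (!spec$allowOverlap && nrow(obj) > 1L) {
    dx <- outer(obj$x_px, obj$x_px, "-")
    dy <- outer(obj$y_px, obj$y_px, "-")
    dd <- sqrt(dx^2 + dy^2)
    rsum <- outer(rPx, rPx, "+")
    diag(dd) <- Inf
    if (any(dd <= rsum))
      stop("overlapping objects; set allowOverlap = TRUE to permit",
           call. = FALSE)
  }
  for (i in seq_len(nrow(obj))) {
    cl <- obj$class[i]
    if (cl == "nucleus") {
      img <- .paintDisk(img, obj$x_px[i], obj$y_px[i], rPx[i],
                        spec$nucleusIntensity)
    } else {
      img <- .paintDisk(img, obj$x_px[i], obj$y_px[i], rPx[i],
                        spec$cellIntensity)
      if (cl == "nucleated")
        img <- .paintDisk(img, obj$x_px[i], obj$y_px[i],
                          rPx[i] * spec$coreFraction,
                          spec$nucleusIntensity)
    }
  }
  truth <- obj
  truth$rendered_diameter_um <- renderedD
  list(image = .addNoise(img, spec$noiseSd, seed), truth = truth)
}

.addNoise <- function(img, sd, seed) {
  if (sd <= 0) return(img)
  noisy <- img + withSeed(seed, stats::rnorm(length(img), 0, sd))
  pmin(pmax(noisy, 0), 1)
}

#' Random non-overlapping cytospin layout
#'
#' Places the requested number of objects of each class at random
#' non-overlapping positions, drawing diameters from per-class normal
#' distributions.
#'
#' @param counts named counts per class (enucleated/nucleated/nucleus).
#' @param diameters named list of `c(mean, sd)` diameters in um; defaults
#'   reflect the relative sizes of the three classes.
#' @param seed integer seed.
#' @param ... passed to [cytospinSpec()].
#' @return a `cytospinSpec` with a populated object table.
#' @export
randomCytospinSpec <- function(counts = c(enucleated = 10, nucleated = 5,
                                          nucleus = 5),
                               diameters = list(enucleated = c(8, 0.8),
                                                nucleated = c(11, 1.0),
                                                nucleus = c(5.5, 0.5)),
                               seed = 1, ...) {
  spec <- cytospinSpec(...)
  withSeed(seed, {
    cls <- rep(names(counts), counts)
    n <- length(cls)
    d <- vapply(cls, function(cl)
      max(3, stats::rnorm(1, diameters[[cl]][1], diameters[[cl]][2])), 0)
    rPx <- d / (2 * spec$scale)
    x <- numeric(n); y <- numeric(n)
    for (i in seq_len(n)) {
      for (try in 1:2000) {
        xi <- stats::runif(1, rPx[i] + 2, spec$widthPx - rPx[i] - 2)
        yi <- stats::runif(1, rPx[i] + 2, spec$heightPx - rPx[i] - 2)
        if (i == 1L ||
            all(sqrt((x[seq_len(i - 1L)] - xi)^2 +
                     (y[seq_len(i - 1L)] - yi)^2) >
                rPx[seq_len(i - 1L)] + rPx[i] + 2)) {
          x[i] <- xi; y[i] <- yi; break
        }
        if (try == 2000)
          stop("could not place objects without overlap; frame too small",
               call. = FALSE)
      }
    }
    spec$objects <- data.frame(class = cls, x_px = x, y_px = y,
                               diameter_um = d)
  })
  spec
}

#' Segment objects in a grayscale image by thresholding
#'
#' Global threshold (Otsu's bimodal method by default, or a fixed value),
#' connected-component labelling, and a minimum-area filter. Dark objects
#' on a light background are assumed unless `darkObjects = FALSE`.
#'
#' @param image numeric matrix in [0, 1] (rows = y, columns = x).
#' @param scale um per pixel.
#' @param method `"otsu"` or `"fixed"`.
#' @param fixedValue threshold when `method = "fixed"`.
#' @param minArea um^2; components below this are discarded (default 15,
#'   the debris boundary).
#' @param darkCutoff intensity below which a pixel counts as nuclear
#'   material, for the internal dark fraction.
#' @param darkObjects objects darker than background (default TRUE).
#' @return data.frame with one row per object: `object_id`, `x_px`,
#'   `y_px` (centroid), `area_um2`, `diameter_um` (equivalent circle),
#'   `mean_intensity`, `dark_fraction`. Empty or constant images yield an
#'   empty table.
#' @export
segmentObjects <- function(image, scale = 0.5,
                           method = c("otsu", "fixed"), fixedValue = NULL,
                           minArea = 15, darkCutoff = 0.45,
                           darkObjects = TRUE) {
  method <- match.arg(method)
  emptyResult <- data.frame(object_id = integer(0), x_px = numeric(0),
                            y_px = numeric(0), area_um2 = numeric(0),
                            diameter_um = numeric(0),
                            mean_intensity = numeric(0),
                            dark_fraction = numeric(0))
  if (length(image) == 0L || diff(range(image)) < 1e-6)
    return(emptyResult)
  thr <- if (method == "fixed") {
    if (is.null(fixedValue))
      stop("fixedValue required for method = 'fixed'", call. = FALSE)
    fixedValue
  } else {
    EBImage::otsu(EBImage::Image(t(image)), range = range(image))
  }
  mask <- if (darkObjects) image < thr else image > thr
  lab <- EBImage::bwlabel(EBImage::Image(t(mask * 1)))
  labm <- t(EBImage::imageData(lab))  # back to rows = y
  nlab <- max(labm)
  if (nlab == 0L) return(emptyResult)
  px <- which(labm > 0)
  ids <- labm[px]
  rows <- (px - 1L) %% nrow(labm) + 1L
  cols <- (px - 1L) %/% nrow(labm) + 1L
  ints <- image[px]
  areaPx <- tabulate(ids, nlab)
  out <- data.frame(
    object_id = seq_len(nlab),
    x_px = as.numeric(tapply(cols, ids, mean)),
    y_px = as.numeric(tapply(rows, ids, mean)),
    area_um2 = areaPx * scale^2,
    diameter_um = sqrt(4 * areaPx * scale^2 / pi),
    mean_intensity = as.numeric(tapply(ints, ids, mean)),
    dark_fraction = as.numeric(tapply(ints < darkCutoff, ids, mean)))
  out <- out[out$area_um2 >= minArea, , drop = FALSE]
  out$object_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Classify segmented objects into the three classes
#'
#' Small dark objects are free nuclei; larger objects are nucleated when a
#' sufficient fraction of their pixels is nuclear-dark (they contain a
#' stained nucleus) and enucleated otherwise.
#'
#' @param objects table from [segmentObjects()].
#' @param nucleusMaxArea um^2; dark objects at or below this are nuclei.
#' @param darkFractionCut minimum internal dark fraction for a nucleated
#'   call.
#' @return the table with a `class` column, plus a `counts` attribute.
#' @export
classifyObjects <- function(objects, nucleusMaxArea = 30,
                            darkFractionCut = 0.15) {
  cls <- ifelse(objects$area_um2 <= nucleusMaxArea &
                  objects$dark_fraction >= darkFractionCut, "nucleus",
         ifelse(objects$dark_fraction >= darkFractionCut, "nucleated",
                "enucleated"))
  objects$class <- cls
  attr(objects, "counts") <- table(factor(cls, .bioClasses()))
  objects
}

# ---------------------------------------------------------------------------
# In-channel frames

#' Specification of an in-channel frame region of interest
#'
#' Lateral position is measured as the distance from the object centroid to
#' the outer wall of the spiral channel, along the x axis of the ROI.
#'
#' @param wallPx x pixel coordinate of the outer wall.
#' @param scale um per pixel.
#' @param channelWidth um (default 170).
#' @param widthPx,heightPx frame size in pixels.
#' @param background,noiseSd,cellIntensity as in [cytospinSpec()].
#' @return list of class `channelFrameSpec`.
#' @export
channelFrameSpec <- function(wallPx = 20, scale = 1, channelWidth = 170,
                             widthPx = wallPx + ceiling(channelWidth /
                                                          scale) + 20,
                             heightPx = 256, background = 0.92,
                             noiseSd = 0.01, cellIntensity = 0.3) {
  .assertPositive(scale, "scale")
  structure(list(wallPx = wallPx, scale = scale,
                 channelWidth = channelWidth, widthPx = widthPx,
                 heightPx = heightPx, background = background,
                 noiseSd = noiseSd, cellIntensity = cellIntensity),
            class = "channelFrameSpec")
}

#' Render an in-channel frame with cells at given lateral positions
#'
#' Cells are painted as dark blobs whose centroid x coordinate encodes the
#' lateral position (um from the outer wall); y positions are spaced so
#' blobs never overlap.
#'
#' @param positions lateral positions in um from the outer wall.
#' @param spec a [channelFrameSpec()]; its `heightPx` is grown as needed.
#' @param diameter blob diameter in um.
#' @param seed seed for the noise.
#' @return list with `image` and `truth` (positions and centroid pixels).
#' @export
renderChannelFrame <- function(positions, spec = channelFrameSpec(),
                               diameter = 8, seed = 1) {
  stopifnot(inherits(spec, "channelFrameSpec"))
  n <- length(positions)
  rPx <- diameter / (2 * spec$scale)
  pitch <- ceiling(2 * rPx + 4)
  heightPx <- max(spec$heightPx, (n + 1L) * pitch)
  xPx <- spec$wallPx + positions / spec$scale
  if (any(xPx - rPx < 1 | xPx + rPx > spec$widthPx))
    stop("positions render outside the frame; widen the ROI", call. = FALSE)
  img <- matrix(spec$background, nrow = heightPx, ncol = spec$widthPx)
  yPx <- pitch * seq_len(n)
  for (i in seq_len(n))
    img <- .paintDisk(img, xPx[i], yPx[i], rPx, spec$cellIntensity)
  list(image = .addNoise(img, spec$noiseSd, seed),
       truth = data.frame(position_um = positions, x_px = xPx, y_px = yPx))
}

#' Extract lateral positions from an in-channel frame
#'
#' Segments the frame as [segmentObjects()] and converts each centroid to a
#' distance from the outer wall: `(x_px - wallPx) * scale`. Centroids
#' outside [0, channelWidth] are flagged (`in_channel = FALSE`) and, by
#' default, excluded from the returned vector-like use; set
#' `keepAll = TRUE` to retain them (useful when the ROI deliberately
#' extends beyond the channel).
#'
#' @param frame numeric image matrix.
#' @param spec a [channelFrameSpec()].
#' @param keepAll keep flagged out-of-channel centroids (default FALSE).
#' @param ... passed to [segmentObjects()].
#' @return data.frame with `position_um`, `in_channel`, `x_px`, `y_px`,
#'   `area_um2`.
#' @export
extractLateralPositions <- function(frame, spec = channelFrameSpec(),
                                    keepAll = FALSE, ...) {
  stopifnot(inherits(spec, "channelFrameSpec"))
  obj <- segmentObjects(frame, scale = spec$scale, ...)
  pos <- (obj$x_px - spec$wallPx) * spec$scale
  inCh <- pos >= 0 & pos <= spec$channelWidth
  out <- data.frame(position_um = pos, in_channel = inCh,
                    x_px = obj$x_px, y_px = obj$y_px,
                    area_um2 = obj$area_um2)
  if (!keepAll) out <- out[out$in_channel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read grayscale images
#'
#' Thin wrappers over EBImage for PNG/TIFF round-tripping of the matrix
#' convention used here (rows = y).
#'
#' @param image numeric matrix in [0, 1].
#' @param path file path (.png or .tif).
#' @return `path` (write) or the image matrix (read).
#' @export
writeImageFile <- function(image, path) {
  EBImage::writeImage(EBImage::Image(t(image)), path)
  invisible(path)
}

#' @rdname writeImageFile
#' @export
readImageFile <- function(path) {
  img <- EBImage::readImage(path)
  d <- EBImage::imageData(img)
  if (length(dim(d)) > 2L) d <- d[, , 1]
  t(d)
}
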