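test_that("the renderer honours its spec and ground truth", {
  blank <- renderCytospin(cytospinSpec(noiseSd = 0), seed = 1)
  expect_equal(unique(as.vector(blank$image)), 0.92)
  expect_equal(nrow(blank$truth), 0L)
  spec <- randomCytospinSpec(seed = 131)
  field <- renderCytospin(spec, seed = 132)
  expect_equal(nrow(field$truth), 20L)
  # rendered disk areas match the analytic pi d^2 / 4 within 5%
  noiseless <- cytospinSpec(objects = data.frame(
    class = c("enucleated", "nucleus"), x_px = c(100, 300),
    y_px = c(100, 300), diameter_um = c(8, 6)), noiseSd = 0)
  img <- renderCytospin(noiseless, seed = 1)$image
  obj <- segmentObjects(img, scale = 0.5, minArea = 5)
  expect_equal(nrow(obj), 2L)
  analytic <- pi * c(6, 8)^2 / 4  # sorted by x: nucleus at x=150? no, x px
  obj <- obj[order(obj$x_px), ]
  expect_equal(obj$area_um2, pi * c(8, 6)^2 / 4, tolerance = 0.05)
  # overlap is rejected unless allowed
  clash <- cytospinSpec(objects = data.frame(
    class = c("nucleus", "nucleus"), x_px = c(100, 104), y_px = c(100, 100),
    diameter_um = c(6, 6)), noiseSd = 0)
  expect_error(renderCytospin(clash), "overlap")
  clash$allowOverlap <- TRUE
  expect_silent(renderCytospin(clash))
  # objects must fit in the frame
  outside <- cytospinSpec(objects = data.frame(
    class = "nucleus", x_px = 2, y_px = 2, diameter_um = 10), noiseSd = 0)
  expect_error(renderCytospin(outside), "inside the frame")
})

test_that("segmentation finds exactly the planted objects", {
  spec <- randomCytospinSpec(counts = c(enucleated = 10, nucleated = 5,
                                        nucleus = 5), seed = 141)
  field <- renderCytospin(spec, seed = 142)
  obj <- segmentObjects(field$image, scale = spec$scale)
  expect_equal(nrow(obj), 20L)
  # blank and constant images yield no objects, not an error
  expect_equal(nrow(segmentObjects(matrix(0.9, 50, 50))), 0L)
  expect_equal(nrow(segmentObjects(matrix(0, 0, 0))), 0L)
  # the min-area filter dominates when set above all object sizes
  expect_equal(nrow(segmentObjects(field$image, scale = spec$scale,
                                   minArea = 1e5)), 0L)
  # fixed-threshold override behaves like the automatic one here
  obj2 <- segmentObjects(field$image, scale = spec$scale,
                         method = "fixed", fixedValue = 0.8)
  expect_equal(nrow(obj2), 20L)
  expect_error(segmentObjects(field$image, method = "fixed"), "fixedValue")
})

test_that("object classification follows the size and darkness rules", {
  # small, dark throughout -> nucleus
  rules <- data.frame(area_um2 = 20, dark_fraction = 1.0)
  expect_equal(classifyObjects(rules)$class, "nucleus")
  # large with a 30% dark core, cut 0.1 -> nucleated
  rules2 <- data.frame(area_um2 = 95, dark_fraction = 0.30)
  expect_equal(classifyObjects(rules2, darkFractionCut = 0.1)$class,
               "nucleated")
  # large and uniformly pale -> enucleated
  rules3 <- data.frame(area_um2 = 50, dark_fraction = 0.0)
  expect_equal(classifyObjects(rules3)$class, "enucleated")
})

test_that("3-class labels match ground truth on rendered fields", {
  spec <- randomCytospinSpec(counts = c(enucleated = 12, nucleated = 8,
                                        nucleus = 8), seed = 151,
                             widthPx = 640, heightPx = 640)
  spec$noiseSd <- 0
  field <- renderCytospin(spec, seed = 152)
  obj <- classifyObjects(segmentObjects(field$image, scale = spec$scale))
  expect_equal(nrow(obj), nrow(field$truth))
  nearest <- apply(field$truth[, c("x_px", "y_px")], 1, function(p)
    which.min((obj$x_px - p[1])^2 + (obj$y_px - p[2])^2))
  acc0 <- mean(obj$class[nearest] == field$truth$class)
  expect_gte(acc0, 0.95)
  # accuracy does not improve when heavy noise is added
  spec$noiseSd <- 0.25
  noisy <- renderCytospin(spec, seed = 153)
  objN <- classifyObjects(segmentObjects(noisy$image, scale = spec$scale))
  accN <- if (nrow(objN)) {
    nearestN <- apply(field$truth[, c("x_px", "y_px")], 1, function(p)
      which.min((objN$x_px - p[1])^2 + (objN$y_px - p[2])^2))
    mean(objN$class[nearestN] == field$truth$class)
  } else 0
  expect_lte(accN, acc0)
})

test_that("lateral positions are recovered from channel frames", {
  cs <- channelFrameSpec(wallPx = 40, scale = 1)
  one <- renderChannelFrame(36, cs, seed = 161)
  got <- extractLateralPositions(one$image, cs)
  expect_equal(nrow(got), 1L)
  expect_equal(got$position_um, 36, tolerance = 0.5)
  # a blob at the wall reads ~0 um and stays flagged in-channel
  atWall <- renderChannelFrame(0, channelFrameSpec(wallPx = 40, scale = 1),
                               diameter = 8, seed = 162)
  gotWall <- extractLateralPositions(atWall$image,
                                     channelFrameSpec(wallPx = 40,
                                                      scale = 1),
                                     keepAll = TRUE)
  expect_equal(gotWall$position_um, 0, tolerance = 0.5)
  # centroids outside the channel are flagged and excluded by default
  wide <- channelFrameSpec(wallPx = 60, scale = 1)
  out <- renderChannelFrame(c(-10, 50), wide, seed = 163)
  kept <- extractLateralPositions(out$image, wide)
  expect_equal(nrow(kept), 1L)
  all_ <- extractLateralPositions(out$image, wide, keepAll = TRUE)
  expect_equal(nrow(all_), 2L)
  expect_equal(sum(all_$in_channel), 1L)
})

test_that("position extraction is affine-equivariant in the wall origin", {
  cs <- channelFrameSpec(wallPx = 30, scale = 1)
  frame <- renderChannelFrame(c(20, 80, 140), cs, seed = 171)
  a <- extractLateralPositions(frame$image, cs)
  shifted <- channelFrameSpec(wallPx = 10, scale = 1)
  b <- extractLateralPositions(frame$image, shifted, keepAll = TRUE)
  expect_equal(sort(b$position_um), sort(a$position_um) + 20,
               tolerance = 1e-9)
})

test_that("200 planted positions recover the planted parameters", {
  set.seed(181)
  planted <- rnorm(200, 36, 21)
  cs <- channelFrameSpec(wallPx = 100, scale = 1, widthPx = 320)
  frame <- renderChannelFrame(planted, cs, seed = 182)
  got <- extractLateralPositions(frame$image, cs, keepAll = TRUE)
  expect_equal(nrow(got), 200L)
  expect_lt(abs(mean(got$position_um) - 36), 3 * 21 / sqrt(200))
  expect_lt(abs(sd(got$position_um) - 21), 3 * 21 / sqrt(2 * 200))
  # per-blob geometry identity: extraction reproduces the planted sample
  expect_equal(sort(got$position_um), sort(planted), tolerance = 0.5)
})

test_that("image files round-trip through PNG", {
  spec <- randomCytospinSpec(counts = c(nucleus = 3), seed = 191)
  img <- renderCytospin(spec, seed = 192)$image
  f <- tempfile(fileext = ".png")
  writeImageFile(img, f)
  back <- readImageFile(f)
  expect_equal(dim(back), dim(img))
  expect_lt(max(abs(back - img)), 0.01)  # 8-bit quantisation only
})
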