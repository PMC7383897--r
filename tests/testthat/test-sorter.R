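model <- defaultFocusingModel()

test_that("ROC construction behaves at the extremes", {
  set.seed(71)
  x <- rnorm(5000, 50, 10)
  y <- rnorm(5000, 50, 10)
  expect_equal(rocCurve(x, y)$auc, 0.5, tolerance = 0.01)
  # perfect separation: target strictly below contaminant
  expect_equal(rocCurve(runif(100, 0, 40), runif(100, 60, 100))$auc, 1.0)
  expect_error(rocCurve(numeric(0), y), "non-empty")
  r <- rocCurve(x, y)
  expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))
  expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
  expect_equal(c(max(r$fpr), max(r$tpr)), c(1, 1))
})

test_that("empirical AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(72)
  target <- rnorm(2000, 36, 21)
  contaminant <- rnorm(2000, 103, 32)
  ours <- rocCurve(target, contaminant)$auc
  ref <- pROC::auc(pROC::roc(
    response = c(rep(1, length(target)), rep(0, length(contaminant))),
    predictor = c(target, contaminant),
    direction = ">", quiet = TRUE))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-10)
})

test_that("AUC is antisymmetric under swapping the classes", {
  set.seed(73)
  a <- rnorm(3000, 36, 21)
  b <- rnorm(3000, 103, 32)
  expect_equal(rocCurve(a, b)$auc, 1 - rocCurve(b, a)$auc,
               tolerance = 1e-12)
})

test_that("gaussianAuc gives the closed-form normal overlap", {
  expect_equal(gaussianAuc(50, 10, 50, 12), 0.5)
  expect_equal(gaussianAuc(36, 21, 103, 32), 0.960, tolerance = 5e-4)
  expect_gt(gaussianAuc(36, 21, 154, 18), 0.999)
})

test_that("positions map to outlets with the documented boundaries", {
  bins <- defaultOutletBins()
  expect_equal(positionsToOutlets(c(1, 20, 42.4), bins),
               c(A = 3L, B = 0L, C = 0L, D = 0L))
  # half-open convention: an edge position belongs to the inner bin
  expect_equal(positionsToOutlets(42.5, bins)[["B"]], 1L)
  expect_equal(positionsToOutlets(170, bins)[["D"]], 1L)
  set.seed(74)
  x <- runif(1000, 0, 170)
  expect_equal(sum(positionsToOutlets(x, bins)), 1000L)
  expect_error(positionsToOutlets(171, bins), "outside")
})

test_that("flow-rate selection picks 1 ml/min and reports the AUC table", {
  sel <- selectFlowRate(model, nPerClass = 2e4, seed = 81)
  expect_equal(sel$flowRate, 1.0)
  tab <- sel$aucTable
  # missing model entries surface as NA, never interpolated
  expect_true(is.na(tab$auc_vs_nuclei[tab$flow_rate == 0.2]))
  expect_true(is.na(tab$auc_vs_nucleated[tab$flow_rate == 0.8]))
  expect_lt(abs(tab$auc_vs_nucleated[tab$flow_rate == 0.2] - 0.62), 0.015)
  # 1 ml/min dominates all lower rates for enucleated-vs-nuclei
  vsNuclei <- tab$auc_vs_nuclei[!is.na(tab$auc_vs_nuclei)]
  expect_equal(max(vsNuclei), tab$auc_vs_nuclei[tab$flow_rate == 1.0])
  # deterministic given the seed
  sel2 <- selectFlowRate(model, nPerClass = 2e4, seed = 81)
  expect_identical(sel$aucTable, sel2$aucTable)
  # single candidate trivially selected
  expect_equal(selectFlowRate(model, candidates = 0.4, seed = 1)$flowRate,
               0.4)
  noData <- FocusingModel(data.frame(class = "nucleated", flow_rate = 1,
                                     mean = 103, sd = 32))
  expect_error(selectFlowRate(noData, candidates = 1, seed = 1),
               "no candidate")
})

test_that("simulateSort conserves events and routes classes as modelled", {
  p <- noDebris(donorPreset("I"))
  tab <- generateEvents(p, 20000, seed = 91)
  res <- simulateSort(tab, model, 1.0, seed = 92)
  total <- sum(vapply(res$outlets, length, 0L))
  expect_equal(total, length(tab))
  expect_true(all(res$positions >= 0 & res$positions <= 170))
  # truncated-normal bin-mass oracle: fraction of nuclei in outlet D at
  # 1 ml/min, for positions ~ N(154, 18) truncated to [0, 170]
  pD <- (pnorm(170, 154, 18) - pnorm(127.5, 154, 18)) /
    (pnorm(170, 154, 18) - pnorm(0, 154, 18))
  nucD <- sum(eventData(res$outlets$D)$true_class == "nucleus")
  nucAll <- sum(eventData(tab)$true_class == "nucleus")
  expect_equal(nucD / nucAll, pD, tolerance = 3 * sqrt(pD * (1 - pD) /
                                                         nucAll) / pD)
  expect_gt(nucD / nucAll, 0.85)
  # missing class entry errors with the class named
  expect_error(simulateSort(tab, model, 0.2, seed = 1), "nucleus")
})

test_that("near-degenerate position SDs give deterministic outlets", {
  m0 <- FocusingModel(data.frame(
    class = c("enucleated", "nucleated", "nucleus"),
    flow_rate = 1, mean = c(36, 103, 154), sd = 1e-9))
  tab <- generateEvents(noDebris(donorPreset("I")), 300, seed = 93)
  res <- simulateSort(tab, m0, 1, seed = 94)
  d <- eventData(tab)
  expect_true(all(res$outlet[d$true_class == "enucleated"] == "A"))
  expect_true(all(res$outlet[d$true_class == "nucleated"] == "C"))
  expect_true(all(res$outlet[d$true_class == "nucleus"] == "D"))
})

test_that("the focusing model YAML round-trips the printed values", {
  f <- tempfile(fileext = ".yaml")
  writeFocusingModel(model, f)
  m2 <- readFocusingModel(f)
  expect_equal(m2@width, 170)
  e <- modelEntry(m2, "enucleated", 1.0)
  expect_equal(c(e$mean, e$sd), c(36, 21))
  e2 <- modelEntry(m2, "nucleus", 0.4)
  expect_equal(c(e2$mean, e2$sd), c(151, 23))
  expect_null(modelEntry(m2, "nucleus", 0.2, required = FALSE))
  o1 <- model@entries[order(model@entries$class, model@entries$flow_rate), ]
  o2 <- m2@entries[order(m2@entries$class, m2@entries$flow_rate), ]
  expect_equal(o1, o2, ignore_attr = TRUE)
})
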