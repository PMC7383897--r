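mkCounts <- function(m, ...) {
  CountTable(matrix(m, nrow = 3, byrow = TRUE,
                    dimnames = list(c("enucleated", "nucleated", "nucleus"),
                                    LETTERS[1:(length(m) / 3)])), ...)
}

test_that("separation efficiency normalises each class over outlets", {
  ct <- mkCounts(c(90, 5, 3, 2,
                   0, 0, 100, 0,
                   0, 0, 0, 50))
  eff <- separationEfficiency(ct)
  expect_equal(unname(eff["enucleated", ]), c(0.90, 0.05, 0.03, 0.02))
  expect_equal(unname(eff["nucleated", ]), c(0, 0, 1, 0))
  expect_equal(unname(rowSums(eff)), rep(1, 3))
  # an all-zero class is undefined, reported as NA
  ct0 <- mkCounts(c(1, 1, 1, 1, 0, 0, 0, 0, 2, 2, 2, 2))
  expect_true(all(is.na(separationEfficiency(ct0)["nucleated", ])))
})

test_that("purity gives per-outlet percentages summing to 100", {
  ct <- mkCounts(c(70, 0, 0, 0,
                   25, 10, 0, 0,
                   5, 0, 0, 3))
  pur <- purity(ct)
  expect_equal(pur["enucleated", "A"], 70)
  expect_equal(pur["nucleated", "B"], 100)  # single-class outlet
  expect_equal(unname(colSums(pur)[c("A", "B", "D")]), c(100, 100, 100))
  expect_true(all(is.na(pur[, "C"])))  # empty outlet flagged as NA
})

test_that("enrichment compares outlet to inlet concentrations", {
  # the whole class into one of four quarter-volume outlets: ratio 4
  ct <- mkCounts(c(100, 0, 0, 0,
                   0, 0, 200, 0,
                   25, 25, 25, 25))
  enr <- enrichmentRatio(ct)
  expect_equal(enr["enucleated", "A"], 4)
  expect_equal(enr["enucleated", "B"], 0)
  expect_equal(unname(enr["nucleus", ]), rep(1, 4))  # uniform spread
  # enrichment consistency under the equal split:
  # sum_i enrichment * volume_i / volume_inlet = 1 for every class
  w <- ct@outletVolumes / ct@inletVolume
  expect_equal(unname(enr %*% w)[, 1], rep(1, 3))
})

test_that("metric identities hold exactly on randomized count tables", {
  set.seed(101)
  for (rep in 1:20) {
    m <- matrix(rpois(12, lambda = sample(5:200, 1)), nrow = 3,
                dimnames = list(c("enucleated", "nucleated", "nucleus"),
                                LETTERS[1:4]))
    m[1, ] <- m[1, ] + 1  # keep every class represented
    m[2, ] <- m[2, ] + 1
    m[3, ] <- m[3, ] + 1
    ct <- CountTable(m)
    expect_equal(unname(rowSums(separationEfficiency(ct))), rep(1, 3),
                 tolerance = 1e-12)
    expect_equal(unname(colSums(purity(ct))), rep(100, 4),
                 tolerance = 1e-12)
  }
})

test_that("expected-value filtration reproduces the purity/loss trade-off", {
  got <- applyFilter(c(enucleated = 70, nucleated = 25, nucleus = 5))
  # arithmetic oracle: 28 / (28 + 0.1 + 0.02)
  expect_equal(unname(got$purity["enucleated"]),
               100 * 28 / (28 + 0.1 + 0.02), tolerance = 1e-12)
  expect_gte(got$purity[["enucleated"]], 99)
  expect_equal(unname(got$loss["enucleated"]), 0.60, tolerance = 1e-12)
  # identity and annihilation limits
  all1 <- FilterModel(passage = c(enucleated = 1, nucleated = 1,
                                  nucleus = 1))
  expect_equal(applyFilter(c(enucleated = 10, nucleated = 5), all1)$post,
               c(enucleated = 10, nucleated = 5))
  kill <- FilterModel(passage = c(enucleated = 1, nucleated = 0))
  expect_equal(applyFilter(c(enucleated = 10, nucleated = 5),
                           kill)$post[["nucleated"]], 0)
})

test_that("stochastic filtration converges to the expected-value mode", {
  counts <- c(enucleated = 1e5, nucleated = 4e4, nucleus = 1e4)
  exp_ <- applyFilter(counts)
  sto <- applyFilter(counts, mode = "stochastic", seed = 111)
  for (cl in names(counts)) {
    p <- FilterModel()@passage[cl]
    tol <- 3 * sqrt(counts[cl] * p * (1 - p))
    expect_lt(abs(sto$post[cl] - exp_$post[cl]), tol)
  }
  # mass balance: the filter never creates cells
  expect_true(all(sto$post <= counts))
})

test_that("batch recovery accounts for dead volume and sedimentation", {
  got <- batchRecovery(BatchSpec(batchVolume = 10, deadVolume = 1.5))
  expect_equal(got$usableVolume, 8.5)
  expect_equal(got$recoveryFraction, 0.85 * 0.95)
  nodead <- batchRecovery(BatchSpec(deadVolume = 0))
  expect_equal(nodead$recoveryFraction, 0.95)
  expect_gt(got$recoveryFraction, 0); expect_lte(got$recoveryFraction, 1)
  expect_error(BatchSpec(batchVolume = 1, deadVolume = 1.5), "smaller")
  got2 <- batchRecovery(BatchSpec(), injectedCells = 1e6)
  expect_equal(got2$recoveredCells, 1e6 * 0.85 * 0.95)
})

test_that("fullProcess produces a coherent two-stage report", {
  rep1 <- fullProcess(donorPreset("I"), n = 1e5, seed = 121)
  eff <- rep1$efficiency
  expect_equal(unname(rowSums(eff)), rep(1, 3), tolerance = 1e-12)
  pur <- rep1$purity
  ok <- !is.na(colSums(pur))
  expect_equal(unname(colSums(pur)[ok]), rep(100, sum(ok)),
               tolerance = 1e-9)
  # sorting conserves events exactly
  expect_equal(sum(rep1$counts@counts) /
                 (1 - rep1$gating$debrisFraction) , 1e5, tolerance = 0.01)
  # filtration of outlet A reaches the calibrated purity regime
  expect_gte(rep1$filter$purity[["enucleated"]], 99)
  expect_true(all(rep1$filter$post <= rep1$filter$pre))
  # empty run: report, not error
  rep0 <- fullProcess(donorPreset("I"), n = 0, seed = 1)
  expect_true(rep0$empty)
  # JSON export round-trips
  f <- tempfile(fileext = ".json")
  writeReport(rep1, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$donor, "I")
  expect_equal(back$filter$purity_percent$enucleated,
               rep1$filter$purity[["enucleated"]], tolerance = 1e-9)
})
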