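# The sorting stage: phenomenological focusing model, ROC/AUC operating
# point selection, outlet binning, and the Monte-Carlo sort.

#' Construct a FocusingModel
#'
#' @param entries data.frame with columns `class`, `flow_rate` (ml/min),
#'   `mean` (um from outer wall) and `sd` (um).
#' @param width channel width in um.
#' @return a `FocusingModel`.
#' @export
FocusingModel <- function(entries, width = 170) {
  new("FocusingModel", entries = entries, width = width)
}

#' The measured lateral equilibrium positions
#'
#' Mean +/- SD lateral equilibrium positions (um from the outer wall) of
#' FACS-presorted enucleated cells, nucleated cells and free nuclei in the
#' 170 x 30 um^2 spiral channel at 0.2-1.0 ml/min. At low flow rates all
#' classes sit near the inner wall; at 1 ml/min the deformability-induced
#' lift carries enucleated cells to 36 +/- 21 um from the outer wall while
#' nucleated cells (103 +/- 32 um) and nuclei (154 +/- 18 um) stay inward.
#' Combinations that were not measured (nucleated at 0.8, nuclei at 0.2
#' ml/min) are absent and are never interpolated.
#'
#' @param width channel width in um.
#' @return a `FocusingModel`.
#' @export
defaultFocusingModel <- function(width = 170) {
  e <- rbind(
    data.frame(class = "enucleated",
               flow_rate = c(0.2, 0.4, 0.6, 0.8, 1.0),
               mean = c(100, 123, 131, 103, 36),
               sd = c(24, 22, 23, 33, 21)),
    data.frame(class = "nucleated",
               flow_rate = c(0.2, 0.4, 0.6, 1.0),
               mean = c(110, 125, 134, 103),
               sd = c(20, 15, 11, 32)),
    data.frame(class = "nucleus",
               flow_rate = c(0.4, 0.6, 0.8, 1.0),
               mean = c(151, 156, 158, 154),
               sd = c(23, 11, 11, 18)))
  FocusingModel(e, width = width)
}

#' Look up one model entry
#'
#' @param model a `FocusingModel`.
#' @param cls cell class.
#' @param flowRate ml/min.
#' @param required error (rather than return NULL) when absent.
#' @return list `(mean, sd)` or NULL.
#' @export
modelEntry <- function(model, cls, flowRate, required = TRUE) {
  stopifnot(is(model, "FocusingModel"))
  e <- model@entries
  hit <- e$class == cls & abs(e$flow_rate - flowRate) < 1e-9
  if (!any(hit)) {
    if (required)
      stop(sprintf(
        "no lateral-position data for class '%s' at %g ml/min", cls,
        flowRate), call. = FALSE)
    return(NULL)
  }
  list(mean = e$mean[hit][1], sd = e$sd[hit][1])
}

#' Sample lateral positions for a class at a flow rate
#'
#' Draws from the model's normal position distribution for the requested
#' (class, flow rate); with `truncate = TRUE` the draw is rejection-sampled
#' into the physical channel [0, width]. Missing combinations raise an
#' explicit "no data" error - positions are never extrapolated.
#'
#' @param model a `FocusingModel`.
#' @param cls cell class.
#' @param flowRate ml/min.
#' @param n number of draws.
#' @param seed integer seed.
#' @param truncate restrict draws to [0, width] (default FALSE).
#' @return numeric vector of positions (um from the outer wall).
#' @export
sampleLateralPositions <- function(model, cls, flowRate, n, seed,
                                   truncate = FALSE) {
  entry <- modelEntry(model, cls, flowRate, required = TRUE)
  if (n < 0) stop("'n' must be non-negative", call. = FALSE)
  withSeed(seed, .rposition(n, entry$mean, entry$sd,
                            if (truncate) c(0, model@width) else NULL))
}

# Normal draw, optionally rejection-sampled into [lo, hi].
.rposition <- function(n, mean, sd, bounds = NULL) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  if (!is.null(bounds)) {
    bad <- which(x < bounds[1] | x > bounds[2])
    while (length(bad)) {
      x[bad] <- stats::rnorm(length(bad), mean, sd)
      bad <- bad[x[bad] < bounds[1] | x[bad] > bounds[2]]
    }
  }
  x
}

# ---------------------------------------------------------------------------
# ROC / AUC

#' ROC curve on lateral positions
#'
#' For each cutoff x, the true positive rate is the fraction of target
#' (enucleated) positions at or below x - nearer the outer wall - and the
#' false positive rate the corresponding fraction of contaminant positions.
#' The AUC is the trapezoid area over (FPR, TPR). Lower position = positive
#' is the orientation under which a class focused nearer the outer wall
#' scores AUC > 0.5 against one focused inward.
#'
#' @param target positions of the target class (um).
#' @param contaminant positions of the contaminant class (um).
#' @return list of class `ROCResult`: `cutoffs`, `tpr`, `fpr`, `auc`.
#' @export
rocCurve <- function(target, contaminant) {
  if (length(target) == 0L || length(contaminant) == 0L)
    stop("both position samples must be non-empty", call. = FALSE)
  cutoffs <- sort(unique(c(target, contaminant)))
  tpr <- stats::ecdf(target)(cutoffs)
  fpr <- stats::ecdf(contaminant)(cutoffs)
  # anchor the curve at (0,0); (1,1) is reached at the largest cutoff
  fpr <- c(0, fpr); tpr <- c(0, tpr)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(cutoffs = c(-Inf, cutoffs), tpr = tpr, fpr = fpr,
                 auc = auc),
            class = "ROCResult")
}

#' @export
print.ROCResult <- function(x, ...) {
  cat(sprintf("ROC over %d cutoffs; AUC = %.4f\n", length(x$cutoffs),
              x$auc))
  invisible(x)
}

#' Closed-form AUC for two normal position distributions
#'
#' With lower positions counted as positive, the probability that a target
#' draw lies below an independent contaminant draw is
#' `pnorm((mean2 - mean1) / sqrt(sd1^2 + sd2^2))` - the analytic value the
#' empirical trapezoid AUC converges to.
#'
#' @param mean1,sd1 target (positive-class) position distribution.
#' @param mean2,sd2 contaminant position distribution.
#' @return AUC in [0, 1].
#' @export
gaussianAuc <- function(mean1, sd1, mean2, sd2) {
  if (sd1 < 0 || sd2 < 0) stop("SDs must be non-negative", call. = FALSE)
  stats::pnorm((mean2 - mean1) / sqrt(sd1^2 + sd2^2))
}

# ---------------------------------------------------------------------------
# Outlet binning and flow-rate selection

#' Assign lateral positions to outlets
#'
#' Bin i collects positions in [edge_i, edge_{i+1}); the last bin is closed
#' at the channel width, so a position exactly on an interior edge (e.g.
#' 42.5 um) goes to the inner of the two adjacent outlets (B for the default
#' bins).
#'
#' @param positions numeric positions in [0, width].
#' @param bins an `OutletBins`.
#' @return named integer vector of counts per outlet (sums to
#'   `length(positions)`).
#' @export
positionsToOutlets <- function(positions, bins = defaultOutletBins()) {
  stopifnot(is(bins, "OutletBins"))
  validObject(bins)
  edges <- bins@edges
  if (length(positions) &&
      (min(positions) < edges[1] || max(positions) > edges[length(edges)]))
    stop("positions outside [0, channel width]; truncate upstream",
         call. = FALSE)
  idx <- findInterval(positions, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(bins@labels))
  stats::setNames(as.integer(counts), bins@labels)
}

#' Select the operating flow rate by ROC analysis
#'
#' For each candidate flow rate, positions are simulated for the enucleated
#' target and each contaminant class with model entries at that rate, and
#' the two AUCs (enucleated vs nucleated, enucleated vs nuclei) computed
#' with [rocCurve()]. The chosen rate maximises the smallest available AUC;
#' exact ties go to the higher flow rate (throughput preference). AUCs for
#' absent model entries are reported as NA, never interpolated.
#'
#' @param model a `FocusingModel`.
#' @param candidates flow rates to evaluate (ml/min).
#' @param nPerClass simulated positions per class (default 1e4).
#' @param seed integer root seed; per-candidate streams are derived from it.
#' @return list with `flowRate` (the selection) and `aucTable` (data.frame
#'   `flow_rate`, `auc_vs_nucleated`, `auc_vs_nuclei`, `score`).
#' @export
selectFlowRate <- function(model, candidates = c(0.2, 0.4, 0.6, 0.8, 1.0),
                           nPerClass = 10000, seed = 1) {
  stopifnot(is(model, "FocusingModel"))
  rows <- lapply(seq_along(candidates), function(i) {
    q <- candidates[i]
    if (is.null(modelEntry(model, "enucleated", q, required = FALSE)))
      return(data.frame(flow_rate = q, auc_vs_nucleated = NA_real_,
                        auc_vs_nuclei = NA_real_, score = NA_real_))
    enu <- sampleLateralPositions(model, "enucleated", q, nPerClass,
                                  deriveSeed(seed, 3L * i))
    aucFor <- function(cls, off) {
      if (is.null(modelEntry(model, cls, q, required = FALSE)))
        return(NA_real_)
      pos <- sampleLateralPositions(model, cls, q, nPerClass,
                                    deriveSeed(seed, 3L * i + off))
      rocCurve(enu, pos)$auc
    }
    a1 <- aucFor("nucleated", 1L)
    a2 <- aucFor("nucleus", 2L)
    score <- if (all(is.na(c(a1, a2)))) NA_real_ else min(c(a1, a2),
                                                          na.rm = TRUE)
    data.frame(flow_rate = q, auc_vs_nucleated = a1, auc_vs_nuclei = a2,
               score = score)
  })
  tab <- do.call(rbind, rows)
  if (all(is.na(tab$score)))
    stop("no candidate flow rate has enucleated plus a contaminant entry",
         call. = FALSE)
  best <- max(tab$score, na.rm = TRUE)
  chosen <- max(tab$flow_rate[!is.na(tab$score) & tab$score == best])
  list(flowRate = chosen, aucTable = tab)
}

#' Simulate sorting of an event table through the spiral channel
#'
#' Each event draws a lateral position from its (true) class distribution
#' at the operating flow rate, truncated to the physical channel, and is
#' routed to the outlet whose section contains the position. Events are
#' conserved exactly across outlets. Debris events, when present, follow
#' the free-nuclei distribution (small rigid fragments focus at the inner
#' wall); this is configurable via `debrisLike`.
#'
#' @param events an `EventTable`.
#' @param model a `FocusingModel`.
#' @param flowRate operating flow rate (ml/min).
#' @param bins an `OutletBins`.
#' @param seed integer seed.
#' @param debrisLike class whose position distribution debris follows.
#' @return list with `outlets` (named list of per-outlet `EventTable`),
#'   `positions` (per input event) and `outlet` (assigned label per event).
#' @export
simulateSort <- function(events, model, flowRate,
                         bins = defaultOutletBins(), seed = 1,
                         debrisLike = "nucleus") {
  stopifnot(is(events, "EventTable"), is(model, "FocusingModel"))
  d <- events@data
  if (nrow(d) == 0L) {
    empty <- stats::setNames(
      lapply(bins@labels, function(l) EventTable(data.frame())),
      bins@labels)
    return(list(outlets = empty, positions = numeric(0),
                outlet = character(0)))
  }
  classes <- unique(d$true_class)
  drawClass <- function(cl) if (cl == "debris") debrisLike else cl
  for (cl in classes) modelEntry(model, drawClass(cl), flowRate)
  positions <- numeric(nrow(d))
  for (i in seq_along(classes)) {
    cl <- classes[i]
    idx <- which(d$true_class == cl)
    positions[idx] <- sampleLateralPositions(
      model, drawClass(cl), flowRate, length(idx),
      deriveSeed(seed, 29L + i), truncate = TRUE)
  }
  edges <- bins@edges
  outletIdx <- findInterval(positions, edges, rightmost.closed = TRUE)
  outlet <- bins@labels[outletIdx]
  outlets <- stats::setNames(lapply(bins@labels, function(l) {
    sub <- d[outlet == l, , drop = FALSE]
    EventTable(sub, presetId = events@presetId, seed = seed)
  }), bins@labels)
  list(outlets = outlets, positions = positions, outlet = outlet)
}

# ---------------------------------------------------------------------------
# YAML interface

#' Write / read a focusing model as YAML
#'
#' Layout: `width`, then `classes: {class: {flow_rate: {mean, sd}}}`.
#'
#' @param model a `FocusingModel`.
#' @param path file path.
#' @return `path` (write) or a `FocusingModel` (read).
#' @export
writeFocusingModel <- function(model, path) {
  e <- model@entries
  classes <- lapply(split(e, e$class), function(s) {
    stats::setNames(lapply(seq_len(nrow(s)), function(i)
      list(mean = s$mean[i], sd = s$sd[i])),
      format(s$flow_rate, trim = TRUE))
  })
  yaml::write_yaml(list(width = model@width, classes = classes), path)
  invisible(path)
}

#' @rdname writeFocusingModel
#' @export
readFocusingModel <- function(path) {
  raw <- yaml::read_yaml(path)
  rows <- list()
  for (cl in names(raw$classes))
    for (q in names(raw$classes[[cl]]))
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, flow_rate = as.numeric(q),
        mean = raw$classes[[cl]][[q]]$mean,
        sd = raw$classes[[cl]][[q]]$sd)
  FocusingModel(do.call(rbind, rows), width = raw$width)
}
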