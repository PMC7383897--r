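# Gating: the DNA x area classification of cytometry events.
#
# Strategy: events at or below the debris area boundary are excluded as
# debris; the remaining events are split on the DNA (DRAQ5) channel into a
# DNA-negative region (enucleated cells, inherently DNA-) and a DNA-positive
# region, which is split on projected area into nucleated cells (large) and
# free-floating nuclei (small). The DNA-positive gate is placed per
# experiment from an unstained control.

#' Classify events with a gate configuration
#'
#' Boundary conventions (documented and tested): debris is inclusive at the
#' area boundary (`area <= debrisAreaMax`); DNA-positive means
#' `dna_au >= dnaThreshold`; nucleated means `area >= nucleatedMinArea`.
#'
#' @param events an `EventTable`, or a data.frame with `area_um2` and
#'   `dna_au` columns.
#' @param gates a validated `GateConfig` with both thresholds set.
#' @return character vector of class labels, one per event.
#' @export
classifyEvents <- function(events, gates) {
  stopifnot(is(gates, "GateConfig"))
  validObject(gates)
  if (is.na(gates@dnaThreshold) || is.na(gates@nucleatedMinArea))
    stop("gates must have dnaThreshold and nucleatedMinArea set",
         call. = FALSE)
  d <- if (is(events, "EventTable")) events@data else events
  if (nrow(d) == 0L) return(character(0))
  if (any(d$area_um2 < 0, na.rm = TRUE) || any(d$dna_au < 0, na.rm = TRUE))
    stop("negative area or DNA signal", call. = FALSE)
  out <- ifelse(d$area_um2 <= gates@debrisAreaMax, "debris",
         ifelse(d$dna_au < gates@dnaThreshold, "enucleated",
         ifelse(d$area_um2 >= gates@nucleatedMinArea, "nucleated",
                "nucleus")))
  out
}

#' Fit the DNA-positive threshold from an unstained control
#'
#' The DNA gate is placed at a high quantile of the unstained (background)
#' DNA signal, so that at most `1 - quantile` of control events fall in the
#' DNA-positive region.
#'
#' @param unstained `EventTable` (or data.frame with `dna_au`) of control
#'   events; must be non-empty.
#' @param quantile background quantile, strictly in (0, 1); default 0.995.
#' @return the threshold (a.u.).
#' @export
fitDnaThreshold <- function(unstained, quantile = 0.995) {
  d <- if (is(unstained, "EventTable")) unstained@data else unstained
  if (is.null(d) || nrow(d) == 0L)
    stop("unstained control table is empty", call. = FALSE)
  if (!is.numeric(quantile) || length(quantile) != 1L ||
      quantile <= 0 || quantile >= 1)
    stop("'quantile' must lie strictly between 0 and 1", call. = FALSE)
  unname(stats::quantile(d$dna_au, probs = quantile))
}

#' Default gate for a donor preset
#'
#' The nucleated-vs-nucleus area cut is not a universal constant; the
#' default places it at the midpoint of the preset's nucleated and nucleus
#' mean areas, keeping the gate consistent with whatever preset generated
#' the data. The DNA threshold defaults to the 0.995 quantile of the
#' preset's background distribution.
#'
#' @param preset a `DonorPreset`.
#' @param debrisAreaMax debris boundary (um^2).
#' @param dnaQuantile background quantile for the DNA gate.
#' @return a `GateConfig`.
#' @export
defaultGates <- function(preset, debrisAreaMax = 15, dnaQuantile = 0.995) {
  stopifnot(is(preset, "DonorPreset"))
  thr <- stats::qlnorm(dnaQuantile, preset@dnaBackground[1],
                       preset@dnaBackground[2])
  cut <- (preset@params$nucleated$area[1] +
            preset@params$nucleus$area[1]) / 2
  GateConfig(debrisAreaMax = debrisAreaMax, dnaThreshold = thr,
             nucleatedMinArea = cut)
}

#' Gate a full event table
#'
#' Applies [classifyEvents()] per row, reports the sample composition
#' (fractions per biological class over non-debris events) and, when the
#' table carries ground truth, the confusion matrix of gated versus true
#' labels.
#'
#' @param events an `EventTable`.
#' @param gates a `GateConfig`.
#' @return list with elements `table` (the `EventTable` with a
#'   `gated_class` column), `fractions` (named numeric over the biological
#'   classes; `NaN` and flagged empty when all events are debris),
#'   `debrisFraction`, `allDebris` flag, `accuracy` and `confusion`
#'   (NULL without ground truth).
#' @export
gateTable <- function(events, gates) {
  stopifnot(is(events, "EventTable"))
  labels <- classifyEvents(events, gates)
  d <- events@data
  d$gated_class <- labels
  nonDebris <- labels[labels != "debris"]
  allDebris <- length(labels) > 0L && length(nonDebris) == 0L
  fractions <- if (length(nonDebris))
    prop.table(table(factor(nonDebris, .bioClasses())))
  else stats::setNames(rep(NaN, 3L), .bioClasses())
  confusion <- NULL; accuracy <- NA_real_
  if (nrow(d) > 0L && !all(is.na(d$true_class))) {
    confusion <- table(true = factor(d$true_class, cellClassLevels()),
                       gated = factor(labels, cellClassLevels()))
    accuracy <- sum(diag(confusion)) / sum(confusion)
  }
  out <- events
  out@data <- d
  list(table = out,
       fractions = stats::setNames(as.numeric(fractions), .bioClasses()),
       debrisFraction = if (length(labels)) mean(labels == "debris")
                        else NA_real_,
       allDebris = allDebris, accuracy = accuracy, confusion = confusion)
}

#' Write / read gate configurations as YAML
#' @param gates a `GateConfig`.
#' @param path file path.
#' @return `path` (write) or a `GateConfig` (read).
#' @export
writeGateConfig <- function(gates, path) {
  yaml::write_yaml(list(debris_area_max = gates@debrisAreaMax,
                        dna_threshold = gates@dnaThreshold,
                        nucleated_min_area = gates@nucleatedMinArea), path)
  invisible(path)
}

#' @rdname writeGateConfig
#' @export
readGateConfig <- function(path) {
  g <- yaml::read_yaml(path)
  GateConfig(debrisAreaMax = g$debris_area_max,
             dnaThreshold = g$dna_threshold,
             nucleatedMinArea = g$nucleated_min_area)
}
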