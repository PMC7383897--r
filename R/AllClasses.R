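#' @import methods
NULL

# ---------------------------------------------------------------------------
# EventTable

#' EventTable: a table of (simulated or measured) cytometry events
#'
#' One row per object observed in flow: its true class (when known),
#' equivalent diameter and projected area, deformability, and DNA (DRAQ5)
#' and CD235a fluorescence signals. Carries provenance (preset id, seed,
#' requested n) so that generated tables are reproducible.
#'
#' @slot data data.frame with columns `event_id`, `true_class`,
#'   `diameter_um`, `area_um2`, `deformability`, `dna_au`, `cd235a_au`.
#' @slot presetId character, id of the generating preset ("" for imported
#'   tables).
#' @slot seed integer seed used at generation (NA for imported tables).
#'
#' @export
setClass("EventTable",
  representation(data = "data.frame", presetId = "character",
                 seed = "integer"),
  prototype(data = data.frame(), presetId = "", seed = NA_integer_))

.eventColumns <- function() {
  c("event_id", "true_class", "diameter_um", "area_um2", "deformability",
    "dna_au", "cd235a_au")
}

setValidity("EventTable", function(object) {
  d <- object@data
  if (nrow(d) == 0L) return(TRUE)
  missing <- setdiff(.eventColumns(), names(d))
  if (length(missing))
    return(paste("missing columns:", paste(missing, collapse = ", ")))
  if (!all(d$true_class %in% c(cellClassLevels(), NA)))
    return("true_class contains unknown labels")
  num <- c("diameter_um", "area_um2", "deformability", "dna_au", "cd235a_au")
  for (cl in num) if (any(d[[cl]] < 0, na.rm = TRUE))
    return(paste(cl, "must be non-negative"))
  if (any(d$area_um2 <= 0) || any(d$diameter_um <= 0))
    return("area and diameter must be positive")
  TRUE
})

# ---------------------------------------------------------------------------
# DonorPreset

#' DonorPreset: per-donor generative parameters for synthetic event tables
#'
#' Class fractions over the three biological classes plus per-class
#' location/scale parameters: normal for projected area and deformability,
#' log-normal for the fluorescence channels. DNA signal of enucleated events
#' is drawn from the unstained background distribution (`dnaBackground`),
#' reflecting their DNA-negative phenotype.
#'
#' @slot donorId character identifier.
#' @slot fractions named numeric over enucleated/nucleated/nucleus, sums to 1.
#' @slot params named list (one element per biological class), each a list
#'   with `area = c(mean, sd)` (um^2), `deformability = c(mean, sd)`,
#'   `cd235a = c(meanlog, sdlog)` (a.u.), and for DNA-positive classes
#'   `dna = c(meanlog, sdlog)`.
#' @slot dnaBackground numeric `c(meanlog, sdlog)` of the unstained DNA
#'   channel.
#' @slot debrisFraction fraction of events rendered as sub-15 um^2 debris
#'   when debris generation is enabled.
#'
#' @export
setClass("DonorPreset",
  representation(donorId = "character", fractions = "numeric",
                 params = "list", dnaBackground = "numeric",
                 debrisFraction = "numeric"))

setValidity("DonorPreset", function(object) {
  fr <- object@fractions
  if (!setequal(names(fr), .bioClasses()))
    return("fractions must be named over enucleated/nucleated/nucleus")
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-8)
    return("fractions must be a simplex (non-negative, summing to 1)")
  if (!all(.bioClasses() %in% names(object@params)))
    return("params must cover all three biological classes")
  dm <- vapply(.bioClasses(),
               function(cl) object@params[[cl]]$deformability[1], 0)
  # Deformability ordering holds across donors: nuclei are the stiffest,
  # enucleated cells the most deformable. Size orderings are donor-specific
  # and deliberately not enforced.
  if (!(dm["nucleus"] < dm["nucleated"] && dm["nucleated"] < dm["enucleated"]))
    return("deformability means must order nucleus < nucleated < enucleated")
  am <- vapply(.bioClasses(), function(cl) object@params[[cl]]$area[1], 0)
  if (am["nucleus"] >= am["nucleated"])
    return("nuclei must be smaller on average than nucleated cells")
  if (object@debrisFraction < 0 || object@debrisFraction >= 1)
    return("debrisFraction must be in [0, 1)")
  if (length(object@dnaBackground) != 2L)
    return("dnaBackground must be c(meanlog, sdlog)")
  TRUE
})

# ---------------------------------------------------------------------------
# GateConfig

#' GateConfig: parameters of the gating classifier
#'
#' Events at or below `debrisAreaMax` are debris; remaining events with DNA
#' signal below `dnaThreshold` are enucleated (DNA-negative); DNA-positive
#' events at or above `nucleatedMinArea` are nucleated cells, smaller ones
#' free nuclei. CD235a is carried through but not used by the default gate.
#'
#' @slot debrisAreaMax um^2; events with area <= this are debris
#'   (boundary inclusive).
#' @slot dnaThreshold a.u.; DNA-positive means signal >= threshold.
#' @slot nucleatedMinArea um^2; DNA-positive events with area >= this are
#'   nucleated.
#'
#' @export
setClass("GateConfig",
  representation(debrisAreaMax = "numeric", dnaThreshold = "numeric",
                 nucleatedMinArea = "numeric"))

setValidity("GateConfig", function(object) {
  if (object@debrisAreaMax <= 0) return("debrisAreaMax must be positive")
  if (!is.na(object@dnaThreshold) && object@dnaThreshold < 0)
    return("dnaThreshold must be non-negative")
  if (!is.na(object@nucleatedMinArea) && object@nucleatedMinArea <= 0)
    return("nucleatedMinArea must be positive")
  TRUE
})

# ---------------------------------------------------------------------------
# ChannelGeometry / Fluid

#' ChannelGeometry: spiral channel cross-section and layout
#'
#' Defaults are the 170 x 30 um^2 rectangular cross-section, six loops and
#' four balanced outlets of the sorting device. The curvature radius has no
#' universal default and is `NA` unless configured; Dean numbers are only
#' reported when it is set.
#'
#' @slot width um (default 170).
#' @slot height um (default 30).
#' @slot loops number of spiral loops (default 6).
#' @slot curvatureRadius um, `NA` when unset.
#' @slot nOutlets number of balanced outlets (default 4).
#'
#' @export
setClass("ChannelGeometry",
  representation(width = "numeric", height = "numeric", loops = "numeric",
                 curvatureRadius = "numeric", nOutlets = "numeric"),
  prototype(width = 170, height = 30, loops = 6,
            curvatureRadius = NA_real_, nOutlets = 4))

setValidity("ChannelGeometry", function(object) {
  if (object@width <= 0 || object@height <= 0)
    return("width and height must be positive")
  if (!is.na(object@curvatureRadius) && object@curvatureRadius <= 0)
    return("curvatureRadius must be positive when set")
  if (object@nOutlets < 1) return("nOutlets must be >= 1")
  TRUE
})

#' Fluid: density and dynamic viscosity of the carrier medium
#'
#' Defaults are water-like (the PBS processing buffer): 1000 kg/m^3 and
#' 0.001 Pa s.
#'
#' @slot density kg/m^3.
#' @slot viscosity Pa s.
#' @export
setClass("Fluid",
  representation(density = "numeric", viscosity = "numeric"),
  prototype(density = 1000, viscosity = 0.001))

setValidity("Fluid", function(object) {
  if (object@density <= 0 || object@viscosity <= 0)
    return("density and viscosity must be positive")
  TRUE
})

# ---------------------------------------------------------------------------
# FocusingModel

#' FocusingModel: phenomenological lateral-position model
#'
#' The spiral channel focuses each subpopulation at a characteristic lateral
#' equilibrium position (distance from the outer wall). Rather than solving
#' the inertial/Dean/deformability force balance, the model stores, per
#' (cell class, flow rate), the mean and SD of the measured position
#' distribution and samples from a (optionally truncated) normal.
#' Combinations that were never measured are explicitly absent and are
#' never interpolated.
#'
#' @slot entries data.frame with columns `class`, `flow_rate` (ml/min),
#'   `mean` (um), `sd` (um).
#' @slot width channel width in um (position support is [0, width]).
#'
#' @export
setClass("FocusingModel",
  representation(entries = "data.frame", width = "numeric"))

setValidity("FocusingModel", function(object) {
  e <- object@entries
  need <- c("class", "flow_rate", "mean", "sd")
  if (!all(need %in% names(e)))
    return("entries needs columns class, flow_rate, mean, sd")
  if (!all(e$class %in% .bioClasses()))
    return("entries$class contains unknown labels")
  if (any(e$sd <= 0)) return("position SDs must be positive")
  if (any(e$mean < 0 | e$mean > object@width))
    return("position means must lie within [0, width]")
  if (anyDuplicated(e[, c("class", "flow_rate")]))
    return("duplicate (class, flow_rate) entries")
  if (object@width <= 0) return("width must be positive")
  TRUE
})

# ---------------------------------------------------------------------------
# OutletBins

#' OutletBins: lateral sections of the channel mapped to outlets
#'
#' Strictly increasing edges from the outer wall (0) to the channel width;
#' bin i collects positions in [edge_i, edge_{i+1}), the last bin is closed.
#' The default splits the 170 um channel into four equal 42.5 um sections
#' labelled A (outer wall) through D (inner wall).
#'
#' @slot edges numeric, strictly increasing, first = 0.
#' @slot labels outlet labels, one fewer than edges.
#' @export
setClass("OutletBins",
  representation(edges = "numeric", labels = "character"))

setValidity("OutletBins", function(object) {
  if (length(object@edges) < 2L) return("need at least two edges")
  if (any(diff(object@edges) <= 0)) return("edges must be strictly increasing")
  if (object@edges[1] != 0) return("first edge must be 0 (outer wall)")
  if (length(object@labels) != length(object@edges) - 1L)
    return("need one label per bin")
  TRUE
})

# ---------------------------------------------------------------------------
# CountTable

#' CountTable: cell-class by outlet counts
#'
#' The operand of the separation-performance metrics. Rows are cell classes,
#' columns outlets. Inlet counts and per-outlet volumes are carried so that
#' enrichment ratios can be computed on concentrations; under the equal
#' laminar flow split each outlet receives 1/n of the inlet volume.
#'
#' @slot counts numeric matrix, classes x outlets, non-negative.
#' @slot inlet named numeric, inlet count per class.
#' @slot outletVolumes numeric, volume collected per outlet (ml).
#' @slot inletVolume numeric, inlet volume (ml).
#' @export
setClass("CountTable",
  representation(counts = "matrix", inlet = "numeric",
                 outletVolumes = "numeric", inletVolume = "numeric"))

setValidity("CountTable", function(object) {
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (is.null(rownames(object@counts)) || is.null(colnames(object@counts)))
    return("counts must have class rownames and outlet colnames")
  if (!all(names(object@inlet) == rownames(object@counts)))
    return("inlet names must match count rownames")
  if (length(object@outletVolumes) != ncol(object@counts))
    return("one volume per outlet required")
  if (any(object@outletVolumes <= 0) || object@inletVolume <= 0)
    return("volumes must be positive")
  TRUE
})

# ---------------------------------------------------------------------------
# FilterModel / BatchSpec

#' FilterModel: membrane filtration stage
#'
#' Dead-end filtration through a track-etched membrane modelled as an
#' independent Bernoulli passage per cell with a class-specific probability.
#' The default probabilities are calibrated, not measured: they reproduce
#' the reported aggregate behaviour of the 3 um membrane (around 99 percent
#' post-filter purity from a 70/30 outlet-A composition, with 50-70 percent
#' of enucleated cells lost and near-total removal of nucleated cells and
#' nuclei).
#'
#' @slot poreSize um (default 3).
#' @slot passage named numeric in [0,1] per class; defaults
#'   enucleated 0.40, nucleated 0.004, nucleus 0.004, debris 0.5.
#' @export
setClass("FilterModel",
  representation(poreSize = "numeric", passage = "numeric"))

setValidity("FilterModel", function(object) {
  if (object@poreSize <= 0) return("poreSize must be positive")
  if (any(object@passage < 0 | object@passage > 1))
    return("passage probabilities must be in [0, 1]")
  TRUE
})

#' BatchSpec: batchwise processing and dead-volume accounting
#'
#' The device is primed with cell-free buffer; the first `deadVolume` ml of
#' eluate (the stabilisation period) is discarded. A configurable
#' sedimentation/dilution loss accounts for the slight (~5 percent)
#' variation in actual recovery over a batch.
#'
#' @slot batchVolume ml (default 10).
#' @slot deadVolume ml (default 1.5).
#' @slot processingMinutes minutes per batch (default 10).
#' @slot sedimentationLoss fraction lost to sedimentation/dilution
#'   (default 0.05).
#' @export
setClass("BatchSpec",
  representation(batchVolume = "numeric", deadVolume = "numeric",
                 processingMinutes = "numeric", sedimentationLoss = "numeric"),
  prototype(batchVolume = 10, deadVolume = 1.5, processingMinutes = 10,
            sedimentationLoss = 0.05))

setValidity("BatchSpec", function(object) {
  if (object@batchVolume <= 0) return("batchVolume must be positive")
  if (object@deadVolume < 0 || object@deadVolume >= object@batchVolume)
    return("deadVolume must be non-negative and smaller than batchVolume")
  if (object@sedimentationLoss < 0 || object@sedimentationLoss >= 1)
    return("sedimentationLoss must be in [0, 1)")
  TRUE
})
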