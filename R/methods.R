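# Constructors, accessors and show methods for the S4 containers.

#' Construct an EventTable
#'
#' @param data data.frame of events (see [EventTable-class]).
#' @param presetId id of the generating preset, if any.
#' @param seed generation seed, if any.
#' @return an `EventTable`.
#' @export
EventTable <- function(data = data.frame(), presetId = "",
                       seed = NA_integer_) {
  if (nrow(data) > 0L) {
    data$true_class <- as.character(data$true_class)
    data <- data[, .eventColumns()]
    rownames(data) <- NULL
  }
  new("EventTable", data = data, presetId = presetId,
      seed = as.integer(seed))
}

#' Event data accessor
#' @param x an `EventTable`.
#' @return the underlying data.frame.
#' @export
eventData <- function(x) {
  stopifnot(is(x, "EventTable"))
  x@data
}

#' Number of events
#' @param x an `EventTable`.
#' @export
setMethod("length", "EventTable", function(x) nrow(x@data))

setMethod("show", "EventTable", function(object) {
  cat(sprintf("EventTable with %d events", nrow(object@data)))
  if (nzchar(object@presetId))
    cat(sprintf(" (preset '%s', seed %s)", object@presetId, object@seed))
  cat("\n")
  if (nrow(object@data)) {
    tab <- table(factor(object@data$true_class, cellClassLevels()))
    cat("  true classes:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
})

#' Construct a ChannelGeometry
#'
#' @param width,height cross-section in um.
#' @param loops number of spiral loops.
#' @param curvatureRadius um; `NA` (unset) by default.
#' @param nOutlets number of balanced outlets.
#' @return a `ChannelGeometry`.
#' @export
ChannelGeometry <- function(width = 170, height = 30, loops = 6,
                            curvatureRadius = NA_real_, nOutlets = 4) {
  new("ChannelGeometry", width = width, height = height, loops = loops,
      curvatureRadius = curvatureRadius, nOutlets = nOutlets)
}

setMethod("show", "ChannelGeometry", function(object) {
  cat(sprintf("Spiral channel: %g x %g um^2, %g loops, %g outlets",
              object@width, object@height, object@loops, object@nOutlets))
  if (!is.na(object@curvatureRadius))
    cat(sprintf(", R = %g um", object@curvatureRadius))
  cat("\n")
})

#' Construct a Fluid
#' @param density kg/m^3.
#' @param viscosity Pa s.
#' @return a `Fluid`.
#' @export
Fluid <- function(density = 1000, viscosity = 0.001) {
  new("Fluid", density = density, viscosity = viscosity)
}

#' Construct a GateConfig
#'
#' @param debrisAreaMax um^2, debris boundary (inclusive); default 15.
#' @param dnaThreshold a.u.; typically fitted from an unstained control via
#'   [fitDnaThreshold()].
#' @param nucleatedMinArea um^2, nucleated-vs-nucleus area cut.
#' @return a `GateConfig`.
#' @export
GateConfig <- function(debrisAreaMax = 15, dnaThreshold = NA_real_,
                       nucleatedMinArea = NA_real_) {
  new("GateConfig", debrisAreaMax = debrisAreaMax,
      dnaThreshold = dnaThreshold, nucleatedMinArea = nucleatedMinArea)
}

setMethod("show", "GateConfig", function(object) {
  cat(sprintf(
    "GateConfig: debris <= %g um^2; DNA+ >= %s a.u.; nucleated >= %s um^2\n",
    object@debrisAreaMax, format(object@dnaThreshold),
    format(object@nucleatedMinArea)))
})

#' Construct an OutletBins
#'
#' @param edges strictly increasing bin edges in um from the outer wall.
#' @param labels one label per bin.
#' @return an `OutletBins`.
#' @export
OutletBins <- function(edges, labels = LETTERS[seq_len(length(edges) - 1L)]) {
  new("OutletBins", edges = edges, labels = labels)
}

#' Default outlet sections of the sorting channel
#'
#' Four equal 42.5 um sections of the 170 um wide channel, labelled A
#' (outer wall) to D (inner wall).
#'
#' @param width channel width in um.
#' @param n number of outlets.
#' @return an `OutletBins`.
#' @export
defaultOutletBins <- function(width = 170, n = 4) {
  OutletBins(seq(0, width, length.out = n + 1L))
}

setMethod("show", "OutletBins", function(object) {
  cat("OutletBins:",
      paste(sprintf("%s [%g, %g%s", object@labels, head(object@edges, -1),
                    object@edges[-1],
                    c(rep(")", length(object@labels) - 1L), "]")),
            collapse = ", "), "um\n")
})

#' Construct a FilterModel
#'
#' @param poreSize membrane pore size in um.
#' @param passage named per-class passage probabilities.
#' @return a `FilterModel`.
#' @export
FilterModel <- function(poreSize = 3,
                        passage = c(enucleated = 0.40, nucleated = 0.004,
                                    nucleus = 0.004, debris = 0.5)) {
  new("FilterModel", poreSize = poreSize, passage = passage)
}

setMethod("show", "FilterModel", function(object) {
  cat(sprintf("FilterModel: %g um pores; passage: %s\n", object@poreSize,
              paste(sprintf("%s=%g", names(object@passage), object@passage),
                    collapse = ", ")))
})

#' Construct a BatchSpec
#' @param batchVolume,deadVolume,processingMinutes,sedimentationLoss see
#'   [BatchSpec-class].
#' @return a `BatchSpec`.
#' @export
BatchSpec <- function(batchVolume = 10, deadVolume = 1.5,
                      processingMinutes = 10, sedimentationLoss = 0.05) {
  new("BatchSpec", batchVolume = batchVolume, deadVolume = deadVolume,
      processingMinutes = processingMinutes,
      sedimentationLoss = sedimentationLoss)
}

setMethod("show", "FocusingModel", function(object) {
  cat(sprintf("FocusingModel (channel width %g um), %d entries:\n",
              object@width, nrow(object@entries)))
  e <- object@entries[order(object@entries$class, object@entries$flow_rate), ]
  for (cl in unique(e$class)) {
    s <- e[e$class == cl, ]
    cat(sprintf("  %-10s %s\n", cl,
                paste(sprintf("%g ml/min: %g+/-%g", s$flow_rate, s$mean,
                              s$sd), collapse = "; ")))
  }
})

setMethod("show", "CountTable", function(object) {
  cat("CountTable (classes x outlets):\n")
  print(object@counts)
  cat("inlet:", paste(sprintf("%s=%g", names(object@inlet), object@inlet),
                      collapse = ", "), "\n")
})

#' Counts accessor
#' @param x a `CountTable`.
#' @return the class x outlet count matrix.
#' @export
countsMatrix <- function(x) {
  stopifnot(is(x, "CountTable"))
  x@counts
}
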