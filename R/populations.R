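# Synthetic populations: donor presets and event-table generation.
#
# The generator emulates the statistical structure of deformability
# cytometry measurements of the erythroid differentiation end product:
# three subpopulations (enucleated cells, nucleated cells, free-floating
# nuclei) with donor-dependent size overlaps, plus optional sub-15 um^2
# debris. Areas and deformabilities are normal, fluorescence channels
# log-normal; absolute preset values are calibrated so that the pairwise
# area overlaps (two-sample AUCs) match the characterisation of the three
# donors rather than asserting absolute sizes.

#' Construct a DonorPreset
#'
#' @param donorId identifier.
#' @param fractions named simplex over enucleated/nucleated/nucleus.
#' @param params per-class distribution parameters; see [DonorPreset-class].
#' @param dnaBackground `c(meanlog, sdlog)` of the unstained DNA channel.
#' @param debrisFraction fraction of debris events when debris is enabled.
#' @return a `DonorPreset`.
#' @export
makeDonorPreset <- function(donorId, fractions, params,
                            dnaBackground = c(3.0, 0.4),
                            debrisFraction = 0.05) {
  new("DonorPreset", donorId = donorId,
      fractions = fractions[.bioClasses()], params = params,
      dnaBackground = dnaBackground, debrisFraction = debrisFraction)
}

.classParams <- function(area, deformability, cd235a,
                         dna = c(7.0, 0.5)) {
  list(area = area, deformability = deformability, cd235a = cd235a,
       dna = dna)
}

#' Built-in donor presets
#'
#' Three presets encoding the qualitative donor-to-donor differences seen in
#' the end product of cord-blood CD34+ erythropoiesis:
#'
#' * **I** - enucleated cells overlap free nuclei in size with a small shift
#'   to the larger side (area AUC enucleated-vs-nuclei ~ 0.68); nucleated
#'   cells clearly the largest.
#' * **II** - enucleated cells are the smallest and stiffest of the three
#'   donors' enucleated populations (though still the most deformable class
#'   within the donor), and the least abundant.
#' * **III** - enucleated cells larger than nuclei (area AUC ~ 0.95) but
#'   substantially overlapping nucleated cells (area AUC ~ 0.56).
#'
#' Enucleated cells constitute 10-35 percent of each starting sample; nuclei
#' are always the stiffest class and enucleated cells the most deformable.
#'
#' @return named list of `DonorPreset` objects ("I", "II", "III").
#' @export
donorPresets <- function() {
  list(
    I = makeDonorPreset("I",
      fractions = c(enucleated = 0.30, nucleated = 0.45, nucleus = 0.25),
      params = list(
        enucleated = .classParams(c(48, 14), c(0.045, 0.010), c(6.0, 0.4)),
        nucleated  = .classParams(c(80, 15), c(0.020, 0.006), c(6.2, 0.4)),
        nucleus    = .classParams(c(40, 10), c(0.012, 0.004), c(4.8, 0.5)))),
    II = makeDonorPreset("II",
      fractions = c(enucleated = 0.12, nucleated = 0.55, nucleus = 0.33),
      params = list(
        enucleated = .classParams(c(36, 9),  c(0.030, 0.008), c(6.0, 0.4)),
        nucleated  = .classParams(c(80, 15), c(0.020, 0.006), c(6.2, 0.4)),
        nucleus    = .classParams(c(38, 9),  c(0.012, 0.004), c(4.8, 0.5)))),
    III = makeDonorPreset("III",
      fractions = c(enucleated = 0.35, nucleated = 0.45, nucleus = 0.20),
      params = list(
        enucleated = .classParams(c(71, 16),   c(0.045, 0.010), c(6.0, 0.4)),
        nucleated  = .classParams(c(74.3, 15), c(0.020, 0.006), c(6.2, 0.4)),
        nucleus    = .classParams(c(40, 10),   c(0.012, 0.004), c(4.8, 0.5))))
  )
}

#' Fetch one built-in donor preset
#' @param id "I", "II" or "III".
#' @return a `DonorPreset`.
#' @export
donorPreset <- function(id) {
  p <- donorPresets()
  if (!id %in% names(p))
    stop("unknown donor preset '", id, "'; available: ",
         paste(names(p), collapse = ", "), call. = FALSE)
  p[[id]]
}

# Positive-truncated normal draw by rejection (means are several SDs above
# zero for all presets, so rejection is cheap).
.rnormPos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
  }
  x
}

#' Generate a synthetic event table
#'
#' Assigns each of `n` events a class by multinomial sampling from the
#' preset fractions (optionally diluted by the preset's debris fraction),
#' then draws per-class attributes: projected area and deformability from
#' normals, fluorescence signals from log-normals. Enucleated (and debris)
#' DNA signals come from the unstained background distribution. Diameter is
#' the area-equivalent circle diameter, so `area = pi d^2 / 4` holds exactly.
#'
#' @param preset a `DonorPreset`.
#' @param n number of events (>= 0).
#' @param seed integer seed; identical (preset, n, seed) give identical
#'   tables.
#' @param includeDebris generate the preset's debris fraction of sub-15 um^2
#'   fragments (default TRUE).
#' @return an `EventTable`.
#' @export
generateEvents <- function(preset, n, seed, includeDebris = TRUE) {
  stopifnot(is(preset, "DonorPreset"))
  validObject(preset)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0 ||
      n != round(n))
    stop("'n' must be a single non-negative integer", call. = FALSE)
  n <- as.integer(n)
  if (n == 0L)
    return(EventTable(data.frame(), presetId = preset@donorId, seed = seed))

  df <- if (includeDebris) preset@debrisFraction else 0
  probs <- c(preset@fractions * (1 - df), debris = df)

  dat <- withSeed(seed, {
    cls <- sample(names(probs), n, replace = TRUE, prob = probs)
    area <- numeric(n); deform <- numeric(n)
    dna <- numeric(n); cd <- numeric(n)
    for (cl in .bioClasses()) {
      idx <- which(cls == cl)
      if (!length(idx)) next
      p <- preset@params[[cl]]
      area[idx] <- .rnormPos(length(idx), p$area[1], p$area[2])
      deform[idx] <- pmax(stats::rnorm(length(idx), p$deformability[1],
                                       p$deformability[2]), 0)
      cd[idx] <- stats::rlnorm(length(idx), p$cd235a[1], p$cd235a[2])
      dna[idx] <- if (cl == "enucleated")
        stats::rlnorm(length(idx), preset@dnaBackground[1],
                      preset@dnaBackground[2])
      else stats::rlnorm(length(idx), p$dna[1], p$dna[2])
    }
    idx <- which(cls == "debris")
    if (length(idx)) {
      # Small fragments: area within (0, 15] um^2.
      area[idx] <- pmin(.rnormPos(length(idx), 8, 3), 15)
      deform[idx] <- pmax(stats::rnorm(length(idx), 0.02, 0.01), 0)
      dna[idx] <- stats::rlnorm(length(idx), preset@dnaBackground[1],
                                preset@dnaBackground[2])
      cd[idx] <- stats::rlnorm(length(idx), 2.0, 0.5)
    }
    data.frame(event_id = seq_len(n), true_class = cls,
               diameter_um = sqrt(4 * area / pi), area_um2 = area,
               deformability = deform, dna_au = dna, cd235a_au = cd,
               stringsAsFactors = FALSE)
  })
  EventTable(dat, presetId = preset@donorId, seed = seed)
}

#' Generate an unstained control table
#'
#' Same populations as [generateEvents()] but every DNA signal is drawn from
#' the background (unstained) distribution, emulating the control sample
#' used to place the DNA-positive gate.
#'
#' @inheritParams generateEvents
#' @return an `EventTable`.
#' @export
generateUnstainedEvents <- function(preset, n, seed, includeDebris = TRUE) {
  tab <- generateEvents(preset, n, seed, includeDebris = includeDebris)
  if (length(tab) == 0L) return(tab)
  d <- tab@data
  d$dna_au <- withSeed(deriveSeed(seed, 17L),
                       stats::rlnorm(nrow(d), preset@dnaBackground[1],
                                     preset@dnaBackground[2]))
  EventTable(d, presetId = paste0(tab@presetId, "-unstained"), seed = seed)
}

# ---------------------------------------------------------------------------
# CSV and YAML interfaces

#' Write an event table to CSV
#'
#' Columns `event_id,true_class,diameter_um,area_um2,deformability,dna_au,
#' cd235a_au`, UTF-8, "." decimal separator.
#'
#' @param x an `EventTable`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeEventTable <- function(x, path) {
  stopifnot(is(x, "EventTable"))
  d <- x@data
  if (nrow(d) == 0L)
    d <- stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = length(.eventColumns()))),
      .eventColumns())
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an event table from CSV
#'
#' @param path CSV file in the format written by [writeEventTable()];
#'   `true_class` is optional for user-supplied tables.
#' @return an `EventTable`.
#' @export
readEventTable <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       fileEncoding = "UTF-8")
  if (!"true_class" %in% names(d)) d$true_class <- NA_character_
  if (!"event_id" %in% names(d)) d$event_id <- seq_len(nrow(d))
  if (!"diameter_um" %in% names(d) && "area_um2" %in% names(d))
    d$diameter_um <- sqrt(4 * d$area_um2 / pi)
  EventTable(d)
}

#' Write donor presets to YAML
#'
#' One YAML document per donor, keyed by donor id.
#'
#' @param presets named list of `DonorPreset`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeDonorPresets <- function(presets, path) {
  out <- lapply(presets, function(p) list(
    donor_id = p@donorId,
    fractions = as.list(p@fractions),
    dna_background = list(meanlog = p@dnaBackground[1],
                          sdlog = p@dnaBackground[2]),
    debris_fraction = p@debrisFraction,
    classes = lapply(p@params, function(q) list(
      area = list(mean = q$area[1], sd = q$area[2]),
      deformability = list(mean = q$deformability[1],
                           sd = q$deformability[2]),
      dna = list(meanlog = q$dna[1], sdlog = q$dna[2]),
      cd235a = list(meanlog = q$cd235a[1], sdlog = q$cd235a[2])))))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Read donor presets from YAML
#' @param path file written by [writeDonorPresets()].
#' @return named list of `DonorPreset`.
#' @export
readDonorPresets <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(p) makeDonorPreset(
    donorId = p$donor_id,
    fractions = unlist(p$fractions)[.bioClasses()],
    params = lapply(p$classes, function(q) .classParams(
      c(q$area$mean, q$area$sd),
      c(q$deformability$mean, q$deformability$sd),
      c(q$cd235a$meanlog, q$cd235a$sdlog),
      c(q$dna$meanlog, q$dna$sdlog))),
    dnaBackground = c(p$dna_background$meanlog, p$dna_background$sdlog),
    debrisFraction = p$debris_fraction))
}
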