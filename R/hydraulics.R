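# Channel design calculations: hydraulic diameter, Reynolds and Dean
# numbers, the particle crowding parameter, and the laminar outlet split.
# Interface units are um and ml/min; conversions to SI are internal.

#' Hydraulic diameter of a rectangular duct
#'
#' `Dh = 2 H W / (H + W)`; the length scale entering Re and De.
#'
#' @param geom a `ChannelGeometry`.
#' @return Dh in um.
#' @export
hydraulicDiameter <- function(geom = ChannelGeometry()) {
  stopifnot(is(geom, "ChannelGeometry"))
  validObject(geom)
  2 * geom@height * geom@width / (geom@height + geom@width)
}

#' Mean flow velocity in the channel
#'
#' `U = Q / (W H)` converted to SI: at the default cross-section,
#' 1 ml/min corresponds to 3.27 m/s.
#'
#' @param Q volumetric flow rate in ml/min (>= 0).
#' @param geom a `ChannelGeometry`.
#' @return mean velocity in m/s.
#' @export
meanVelocity <- function(Q, geom = ChannelGeometry()) {
  stopifnot(is(geom, "ChannelGeometry"))
  if (any(Q < 0)) stop("flow rate must be non-negative", call. = FALSE)
  .mlmin_to_m3s(Q) / (.um_to_m(geom@width) * .um_to_m(geom@height))
}

#' Channel Reynolds number
#'
#' `Re = rho U Dh / mu`, the ratio of inertial to viscous forces of the
#' unperturbed channel flow.
#'
#' @param fluid a `Fluid`.
#' @param U mean velocity in m/s.
#' @param Dh hydraulic diameter in um.
#' @return dimensionless Re.
#' @export
reynoldsNumber <- function(fluid = Fluid(), U, Dh) {
  stopifnot(is(fluid, "Fluid"))
  validObject(fluid)
  if (any(U < 0)) stop("velocity must be non-negative", call. = FALSE)
  .assertPositive(Dh[1], "Dh")
  fluid@density * U * .um_to_m(Dh) / fluid@viscosity
}

#' Dean number
#'
#' `De = Re sqrt(Dh / R)` quantifies the secondary (Dean vortex) flow in a
#' curved channel of curvature radius R.
#'
#' @param Re channel Reynolds number.
#' @param Dh hydraulic diameter in um.
#' @param R curvature radius in um; required.
#' @return dimensionless De.
#' @export
deanNumber <- function(Re, Dh, R) {
  if (missing(R) || is.null(R) || is.na(R))
    stop("curvature radius required for the Dean number", call. = FALSE)
  .assertPositive(R, "R")
  .assertPositive(Dh, "Dh")
  Re * sqrt(Dh / R)
}

#' Particle crowding parameter
#'
#' `alpha = 6 W H VF / (pi a^2)`: the number of particle diameters per unit
#' channel length. For alpha > 1 steric interactions can prevent focusing
#' into a tight single stream. The volume fraction may be given directly or
#' derived from a number concentration as `VF = c pi a^3 / 6` (spherical
#' particles of diameter `a`).
#'
#' @param geom a `ChannelGeometry`.
#' @param diameter particle diameter `a` in um.
#' @param volumeFraction dimensionless VF in [0, 1), optional.
#' @param concentration number concentration in cells/ml, optional
#'   alternative to `volumeFraction`.
#' @return list with `alpha`, `volumeFraction`, and `singleStreamOk`
#'   (`alpha <= 1`).
#' @export
crowdingAlpha <- function(geom = ChannelGeometry(), diameter,
                          volumeFraction = NULL, concentration = NULL) {
  stopifnot(is(geom, "ChannelGeometry"))
  .assertPositive(diameter, "diameter")
  vfFromConc <- if (!is.null(concentration)) {
    .assertNonNegative(concentration, "concentration")
    # cells/ml * um^3 -> dimensionless: 1 ml = 1e12 um^3
    concentration * pi * diameter^3 / 6 / 1e12
  } else NULL
  if (is.null(volumeFraction) && is.null(vfFromConc))
    stop("provide volumeFraction or concentration", call. = FALSE)
  if (!is.null(volumeFraction) && !is.null(vfFromConc) &&
      abs(volumeFraction - vfFromConc) > 1e-6 * max(volumeFraction, 1e-12))
    stop("volumeFraction and concentration are inconsistent", call. = FALSE)
  vf <- if (!is.null(volumeFraction)) volumeFraction else vfFromConc
  if (vf < 0 || vf >= 1)
    stop("volume fraction must lie in [0, 1)", call. = FALSE)
  alpha <- 6 * geom@width * geom@height * vf / (pi * diameter^2)
  list(alpha = alpha, volumeFraction = vf, singleStreamOk = alpha <= 1)
}

#' Equal laminar split of the outlet flow
#'
#' In the laminar regime the channel flow divides into `nOutlets` equal
#' portions with identical volumetric throughput.
#'
#' @param Q inlet flow rate in ml/min (>= 0).
#' @param geom a `ChannelGeometry`.
#' @return numeric vector of per-outlet flow rates summing exactly to `Q`.
#' @export
outletFlowSplit <- function(Q, geom = ChannelGeometry()) {
  stopifnot(is(geom, "ChannelGeometry"))
  if (Q < 0) stop("flow rate must be non-negative", call. = FALSE)
  rep(Q / geom@nOutlets, geom@nOutlets)
}

#' Operating-condition table
#'
#' One row per flow rate with mean velocity, the velocity rounded to two
#' significant figures, Reynolds numbers computed from both, and (when the
#' curvature radius is configured) Dean numbers. The `Re` column follows
#' the reporting convention of deriving Re from the rounded (or supplied)
#' velocity, which yields the canonical 33-168 range over 0.2-1.0 ml/min at
#' the default geometry; `Re_exact` carries the unrounded value. A
#' `velocities` vector (m/s, e.g. values quoted at a different precision)
#' overrides the 2-significant-figure convention row by row.
#'
#' @param flowRates vector of flow rates in ml/min.
#' @param geom a `ChannelGeometry`.
#' @param fluid a `Fluid`.
#' @param velocities optional reported velocities (m/s) used for the `Re`
#'   column instead of `signif(U, 2)`.
#' @return data.frame with columns `flow_rate_ml_min`, `velocity_m_s`,
#'   `velocity_2sf`, `Re`, `Re_exact` and optionally `De`.
#' @export
operatingTable <- function(flowRates = c(0.2, 0.4, 0.6, 0.8, 1.0),
                           geom = ChannelGeometry(), fluid = Fluid(),
                           velocities = NULL) {
  if (any(flowRates < 0))
    stop("flow rates must be non-negative", call. = FALSE)
  Dh <- hydraulicDiameter(geom)
  U <- meanVelocity(flowRates, geom)
  U2 <- if (is.null(velocities)) signif(U, 2) else velocities
  out <- data.frame(flow_rate_ml_min = flowRates,
                    velocity_m_s = U,
                    velocity_2sf = U2,
                    Re = round(reynoldsNumber(fluid, U2, Dh)),
                    Re_exact = reynoldsNumber(fluid, U, Dh))
  if (!is.na(geom@curvatureRadius))
    out$De <- round(deanNumber(out$Re, Dh, geom@curvatureRadius))
  out
}
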