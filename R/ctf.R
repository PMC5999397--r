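# Acquisition-physics calculators: electron wavelength, CTF phase, the
# 90-degrees-out-of-phase defocus-error resolution limit, defocus spreads
# from tilted fields of view and particle bilayers, duplicate-defocus
# rescue candidates, and cosine dose schemes for tilt series.

#' Relativistic electron wavelength
#'
#' lambda = 12.2639 / sqrt(V (1 + 0.97845e-6 V)) with V in volts.
#'
#' @param kv accelerating voltage in kV (> 0).
#' @return wavelength in ångström (0.01969 at 300 kV).
#' @export
electronWavelength <- function(kv) {
  if (any(kv <= 0)) stop("voltage must be positive")
  V <- kv * 1000
  12.2639 / sqrt(V * (1 + 0.97845e-6 * V))
}

#' CTF phase
#'
#' gamma(s) = -pi lambda dz s^2 + (pi/2) Cs lambda^3 s^4, underfocus
#' positive. Only phase differences matter for the defocus-error
#' criterion, so the sign convention is internal; the difference between
#' defoci z and z + delta is pi lambda delta s^2 at every s, independent
#' of Cs.
#'
#' @param s spatial frequency, 1/ångström (>= 0).
#' @param defocus defocus in ångström (underfocus positive).
#' @param kv voltage, kV.
#' @param cs spherical aberration, mm.
#' @return phase in radians.
#' @export
ctfPhase <- function(s, defocus, kv = 300, cs = 2.7) {
  stopifnot(all(s >= 0))
  lambda <- electronWavelength(kv)
  csA <- cs * 1e7  # mm -> Angstrom
  -pi * lambda * defocus * s^2 + (pi / 2) * csA * lambda^3 * s^4
}

#' Resolution limit from a defocus error
#'
#' Two CTFs differing by a defocus error dz dephase by pi lambda dz s^2;
#' the usable resolution ends where they are 90 degrees out of phase
#' (threshold pi/2), giving d = 1/s = sqrt(2 lambda dz). A zero error has
#' no limit, reported as the sentinel \code{NA} with attribute
#' \code{noLimit}.
#'
#' A worked example: a field of view 4096 ångström wide tilted by 10
#' degrees puts its worst particle 2048 tan(10) = 361 ångström from the
#' fitted defocus, limiting it to about 4 ångström at 300 kV. (Published
#' companion figures of about 2.5 and 6 ångström for 100 and 500 ångström
#' offsets are approximate sketches without a stated voltage and are not
#' reproduced by any single criterion.)
#'
#' @param dz defocus error, ångström (>= 0).
#' @param kv voltage, kV.
#' @param phaseThreshold radians (default pi/2).
#' @return resolution limit d in ångström, or NA with attr noLimit = TRUE
#'   when dz = 0.
#' @examples
#' defocusErrorResolutionLimit(2048 * tan(10 * pi / 180))  # ~3.77 A
#' @export
defocusErrorResolutionLimit <- function(dz, kv = 300,
                                        phaseThreshold = pi / 2) {
  if (any(dz < 0)) stop("defocus error must be >= 0")
  lambda <- electronWavelength(kv)
  d <- sqrt(pi * lambda * dz / phaseThreshold)
  if (length(dz) == 1L && dz == 0) {
    d <- NA_real_
    attr(d, "noLimit") <- TRUE
  } else {
    d[dz == 0] <- NA_real_
  }
  d
}

#' Worst-case defocus offset in a tilted field of view
#'
#' (field_width / 2) * tan(tilt): the deviation of the field corner from
#' the centre defocus.
#'
#' @param fieldWidth field width, ångström.
#' @param tilt degrees, < 90.
#' @return offset in ångström.
#' @export
tiltDefocusOffset <- function(fieldWidth, tilt) {
  stopifnot(fieldWidth > 0)
  if (any(tilt >= 90)) stop("tilt must be below 90 degrees")
  (fieldWidth / 2) * tan(.deg2rad(tilt))
}

#' Defocus deviation of a particle bilayer
#'
#' Whole-image defocus fits land midway between two particle layers;
#' each layer then sits thickness / 2 from the fitted defocus.
#'
#' @param thickness layer separation, nm (>= 0).
#' @return deviation from the midway estimate, nm.
#' @export
bilayerDefocusOffset <- function(thickness) {
  stopifnot(all(thickness >= 0))
  thickness / 2
}

#' Duplicate-defocus rescue candidates
#'
#' For a bilayer, each particle can be duplicated and CTF-corrected with
#' (midway defocus + thickness/2) and (midway defocus - thickness/2),
#' keeping whichever aligns better downstream.
#'
#' @param midway midway defocus, µm.
#' @param thickness layer separation, nm (>= 0).
#' @return numeric(2): the (+, -) defocus pair in µm, ordered high first;
#'   its midpoint equals \code{midway} exactly.
#' @export
duplicateDefocusCandidates <- function(midway, thickness) {
  stopifnot(thickness >= 0)
  half <- thickness / 2 / 1000  # nm -> um
  c(midway + half, midway - half)
}

#' Cosine dose scheme for a tilt series
#'
#' dose(theta) = dose0 / cos(theta): higher tilts receive proportionally
#' more dose so each image keeps constant effective exposure.
#'
#' @param dose0 zero-tilt dose, e-/Å^2.
#' @param angles tilt angles, degrees, each with |angle| < 90.
#' @return list(angles, doses, total).
#' @examples
#' tiltDoseSeries(2, seq(-45, 45, by = 3))$total  # ~70.2 e-/A^2
#' @export
tiltDoseSeries <- function(dose0, angles) {
  if (any(abs(angles) >= 90)) stop("tilt angles must satisfy |angle| < 90")
  doses <- dose0 / cos(.deg2rad(angles))
  list(angles = angles, doses = doses, total = sum(doses))
}
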