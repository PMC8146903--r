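# Nitroxide spin-label EPR: hyperfine extrema, order parameter (Marsh ratio
# form) and polarity (2Azz) extraction, and depth profiles across n-PC
# labelled membranes.
#
# Conventions: magnetic field in gauss internally (mT accepted on input,
# 1 mT = 10 G); order-parameter spectra are recorded in the motionally
# narrowed regime (310 K by convention), polarity spectra at the rigid limit
# (120 K), where the outermost extrema separation equals 2Azz.

.label_positions <- c("T-PC", "5-PC", "7-PC", "10-PC", "16-PC")

#' Construct a first-derivative EPR spectrum
#'
#' @param field magnetic field grid, strictly increasing.  Gauss by default;
#'   set `unit = "mT"` to convert on input.
#' @param amplitude first-derivative signal.
#' @param temperature_K acquisition temperature; 310 K for order-parameter
#'   (fluid) spectra, 120 K for rigid-limit polarity spectra.
#' @param label_position one of "T-PC", "5-PC", "7-PC", "10-PC", "16-PC".
#' @param unit field unit of the input grid, "G" or "mT".
#' @return an `epr_spectrum`: data.frame with columns `field_G`, `amplitude`.
#' @export
epr_spectrum <- function(field, amplitude, temperature_K = 310,
                         label_position = "5-PC", unit = c("G", "mT")) {
  unit <- match.arg(unit)
  if (unit == "mT") field <- field * 10
  check_strictly_increasing(field, "field grid")
  if (length(amplitude) != length(field))
    stop_param("field/amplitude lengths differ")
  label_position <- match.arg(label_position, .label_positions)
  structure(data.frame(field_G = as.numeric(field),
                       amplitude = as.numeric(amplitude)),
            temperature_K = temperature_K, label_position = label_position,
            class = c("epr_spectrum", "data.frame"))
}

#' Single-crystal nitroxide hyperfine tensor constants
#'
#' Defaults (Axx, Ayy, Azz) = (6.3, 5.8, 33.6) G are a common doxyl-label
#' convention; adjust to the probe and host polarity at hand.
#'
#' @param Axx,Ayy,Azz principal hyperfine components in gauss; Azz must be
#'   the largest.
#' @return a `tensor_constants` list including the isotropic coupling
#'   `a_N = (Axx + Ayy + Azz) / 3`.
#' @export
tensor_constants <- function(Axx = 6.3, Ayy = 5.8, Azz = 33.6) {
  if (Azz <= Axx || Azz <= Ayy)
    stop_param("Azz must exceed Axx and Ayy")
  structure(list(Axx = Axx, Ayy = Ayy, Azz = Azz,
                 a_N = (Axx + Ayy + Azz) / 3),
            class = "tensor_constants")
}

# Outermost prominent extrema of a first-derivative spectrum: the leftmost
# local maximum and the rightmost local minimum, parabolic-refined.
.outer_extrema <- function(spec, prominence = 0.02) {
  ex <- local_extrema(spec$amplitude, prominence)
  if (length(ex$max) == 0L || length(ex$min) == 0L)
    stop_param("spectrum has no resolved extrema")
  i_lo <- min(ex$max)
  i_hi <- max(ex$min)
  n <- nrow(spec)
  if (i_lo <= 2L || i_hi >= n - 1L)
    stop_param("outermost extrema touch the field-grid boundary; widen the sweep")
  c(low = parabolic_refine(spec$field_G, spec$amplitude, i_lo),
    high = parabolic_refine(spec$field_G, spec$amplitude, i_hi))
}

#' Outer hyperfine extrema separation (2A parallel prime)
#'
#' Field distance between the outermost low-field maximum and outermost
#' high-field minimum of the first-derivative spectrum, refined by 3-point
#' parabolic interpolation.  At the rigid limit this separation equals 2Azz.
#'
#' @param spec an [epr_spectrum()].
#' @param prominence minimum extremum amplitude relative to the spectral
#'   range, to ignore noise ripples; default 0.02.
#' @return separation in gauss.
#' @export
outer_extrema_splitting <- function(spec, prominence = 0.02) {
  stopifnot(inherits(spec, "epr_spectrum"))
  ext <- .outer_extrema(spec, prominence)
  unname(ext["high"] - ext["low"])
}

#' Inner hyperfine extrema separation (2A perpendicular prime)
#'
#' Field distance between the leftmost prominent minimum and the rightmost
#' prominent maximum (the inner extrema of a motionally narrowed axial
#' spectrum).  With `correct = TRUE` the Hubbell-McConnell-style linewidth
#' correction
#' `A_perp = A_perp' + 1.4 * (1 - (A_par' - A_perp')/(Azz - (Axx+Ayy)/2))` G
#' is applied to the returned half-splitting.
#'
#' @param spec an [epr_spectrum()].
#' @param constants a [tensor_constants()] (needed when `correct = TRUE`).
#' @param correct apply the inner-splitting correction; default FALSE.
#' @param prominence as in [outer_extrema_splitting()].
#' @return the full inner separation 2*A_perp in gauss (after correction if
#'   requested).
#' @export
inner_extrema_splitting <- function(spec, constants = tensor_constants(),
                                    correct = FALSE, prominence = 0.02) {
  stopifnot(inherits(spec, "epr_spectrum"))
  ex <- local_extrema(spec$amplitude, prominence)
  if (length(ex$max) < 2L || length(ex$min) < 2L)
    stop_param(paste("inner extrema unresolved; spectrum may be at the rigid",
                     "limit (use polarity_2Azz)"))
  i_min <- min(ex$min)   # low-field inner minimum
  i_max <- max(ex$max)   # high-field inner maximum
  b_lo <- parabolic_refine(spec$field_G, spec$amplitude, i_min)
  b_hi <- parabolic_refine(spec$field_G, spec$amplitude, i_max)
  if (b_hi <= b_lo)
    stop_param("inner extrema ordering degenerate; spectrum unresolved")
  A_perp <- (b_hi - b_lo) / 2
  if (correct) {
    A_par <- outer_extrema_splitting(spec, prominence) / 2
    delta <- constants$Azz - (constants$Axx + constants$Ayy) / 2
    A_perp <- A_perp + 1.4 * (1 - (A_par - A_perp) / delta)
  }
  2 * A_perp
}

#' Hyperfine extrema record for the Marsh order-parameter formula
#'
#' Convenience extractor: reads both splittings from one motionally narrowed
#' spectrum.
#'
#' @param spec an [epr_spectrum()].
#' @param constants a [tensor_constants()].
#' @param correct apply the inner-splitting correction (see
#'   [inner_extrema_splitting()]); default FALSE.
#' @param prominence extremum prominence threshold.
#' @return a `hyperfine_extrema` list with `A_par_obs`, `A_perp_obs` (gauss)
#'   and `correction_applied`.
#' @export
hyperfine_extrema <- function(spec, constants = tensor_constants(),
                              correct = FALSE, prominence = 0.02) {
  A_par <- outer_extrema_splitting(spec, prominence) / 2
  A_perp <- inner_extrema_splitting(spec, constants, correct, prominence) / 2
  if (A_perp <= 0 || A_par < A_perp)
    stop_param("extracted extrema violate A_par >= A_perp > 0")
  structure(list(A_par_obs = A_par, A_perp_obs = A_perp,
                 correction_applied = correct),
            class = "hyperfine_extrema")
}

#' Segmental order parameter from hyperfine extrema (Marsh ratio form)
#'
#' `S = (A_par' - A_perp') / (Azz - (Axx + Ayy)/2) * a_N / a_N'` with
#' `a_N' = (A_par' + 2 A_perp') / 3`.  The polarity factor `a_N / a_N'`
#' rescales for the difference between the crystal-host and membrane
#' polarity; it can be switched off to match other conventions.
#'
#' @param extrema a [hyperfine_extrema()] record, or any list with
#'   `A_par_obs` and `A_perp_obs` in gauss.
#' @param constants a [tensor_constants()].
#' @param polarity_correction include the `a_N / a_N'` factor; default TRUE.
#' @return order parameter S, dimensionless; values outside [-0.5, 1] are
#'   clamped with a warning.
#' @export
order_parameter <- function(extrema, constants = tensor_constants(),
                            polarity_correction = TRUE) {
  A_par <- extrema$A_par_obs; A_perp <- extrema$A_perp_obs
  a_N_prime <- (A_par + 2 * A_perp) / 3
  if (a_N_prime <= 0) stop_param("observed isotropic coupling a_N' <= 0")
  delta <- constants$Azz - (constants$Axx + constants$Ayy) / 2
  S <- (A_par - A_perp) / delta
  if (polarity_correction) S <- S * constants$a_N / a_N_prime
  if (S > 1 || S < -0.5) {
    warning(sprintf("order parameter %.3f outside [-0.5, 1]; clamped", S))
    S <- max(min(S, 1), -0.5)
  }
  S
}

#' Membrane polarity from a rigid-limit spectrum (2Azz)
#'
#' At the rigid limit the outermost extrema separation of the powder
#' spectrum equals 2Azz, which grows with local polarity (water
#' penetration).
#'
#' @param spec a rigid-limit (frozen, 120 K convention) [epr_spectrum()].
#' @param prominence extremum prominence threshold.
#' @return 2Azz in gauss.
#' @export
polarity_2Azz <- function(spec, prominence = 0.02) {
  outer_extrema_splitting(spec, prominence)
}

#' Assemble an order or polarity depth profile from labelled spectra
#'
#' @param spectra list of [epr_spectrum()] objects, one per label position.
#' @param mode "order" (fluid spectra, Marsh S) or "polarity" (rigid-limit
#'   spectra, 2Azz in gauss).
#' @param constants a [tensor_constants()] (order mode).
#' @param correct inner-splitting correction flag passed through (order mode).
#' @return a data.frame with columns `label_position` and `S` or `Azz2`,
#'   ordered by chain depth.  For membrane-like inputs an order profile is
#'   expected to fall from 5-PC to 16-PC; a violation triggers a warning.
#' @export
assemble_profile <- function(spectra, mode = c("order", "polarity"),
                             constants = tensor_constants(), correct = FALSE) {
  mode <- match.arg(mode)
  stopifnot(length(spectra) >= 1L,
            all(vapply(spectra, inherits, TRUE, "epr_spectrum")))
  temps <- vapply(spectra, attr, 0, "temperature_K")
  if (length(unique(temps)) > 1L)
    stop_param("mixed acquisition temperatures within one profile mode")
  pos <- vapply(spectra, attr, "", "label_position")
  if (anyDuplicated(pos))
    stop_param("duplicate label positions in profile input")
  ord <- order(match(pos, .label_positions))
  spectra <- spectra[ord]; pos <- pos[ord]
  val <- if (mode == "order") {
    vapply(spectra, function(s)
      order_parameter(hyperfine_extrema(s, constants, correct), constants), 0)
  } else {
    vapply(spectra, polarity_2Azz, 0)
  }
  out <- data.frame(label_position = pos, value = val)
  names(out)[2] <- if (mode == "order") "S" else "Azz2"
  if (mode == "order") {
    chain <- out$S[out$label_position %in% c("5-PC", "7-PC", "10-PC", "16-PC")]
    if (length(chain) >= 2L && any(diff(chain) > 1e-8))
      warning("order profile is not non-increasing with chain depth")
  }
  out
}

#' Invert the Marsh formula: hyperfine extrema producing a target S
#'
#' Solves for (A_par', A_perp') with the observed isotropic coupling pinned
#' to the crystal a_N (so the polarity factor is 1):
#' `A_par' = a_N + (2/3) S d`, `A_perp' = a_N - (1/3) S d`,
#' `d = Azz - (Axx + Ayy)/2`.  Used to design synthetic spectra with known
#' ground-truth order.
#'
#' @param S target order parameter in [0, 1).
#' @param constants a [tensor_constants()].
#' @return list with `A_par`, `A_perp` in gauss.
#' @export
hyperfine_for_order <- function(S, constants = tensor_constants()) {
  if (S < 0 || S >= 1) stop_param("target S must be in [0, 1)")
  delta <- constants$Azz - (constants$Axx + constants$Ayy) / 2
  list(A_par = constants$a_N + 2 / 3 * S * delta,
       A_perp = constants$a_N - 1 / 3 * S * delta)
}
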