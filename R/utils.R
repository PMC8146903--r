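#' @keywords internal
"_PACKAGE"

#' @importFrom stats lm coef vcov sd aov TukeyHSD shapiro.test t.test rnorm
#'   rpois runif setNames approx predict pt
#' @importFrom utils read.table write.table head tail
#' @importFrom grDevices chull
NULL

# Quantum yield of singlet-oxygen generation by the TPP sensitizer in benzene,
# carried as metadata on synthetic decay series (not used in any computation).
TPP_SINGLET_OXYGEN_YIELD <- 0.63

# amu/A^3 -> kg/m^3
AMU_PER_A3_TO_KG_PER_M3 <- 1660.539

.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     P = 30.974, S = 32.06, NA. = 22.990)

#' Guess the chemical element from an atom name
#'
#' First alphabetic character of the atom name, following the PDB/GRO habit
#' of naming atoms by element plus an index (C12, OP1, HW2 ...).
#'
#' @param name character vector of atom names.
#' @return character vector of element symbols.
#' @keywords internal
element_from_name <- function(name) {
  el <- toupper(substr(gsub("[^A-Za-z].*$", "", name), 1L, 1L))
  el[el == ""] <- "C"
  el
}

#' Atomic mass lookup (amu)
#' @param element character vector of element symbols.
#' @return numeric vector of masses in amu.
#' @keywords internal
mass_from_element <- function(element) {
  m <- .element_masses[toupper(element)]
  m[is.na(m)] <- 12.011
  unname(m)
}

stop_param <- function(...) stop(sprintf(...), call. = FALSE)

# Coefficient of determination of an lm fit, honouring case weights.
# Computed directly so that near-perfect fits do not trigger summary.lm's
# reliability warning.
.r_squared <- function(fit) {
  y <- fit$model[[1]]
  w <- fit$weights
  if (is.null(w)) w <- rep(1, length(y))
  res <- stats::residuals(fit)
  ss_tot <- sum(w * (y - sum(w * y) / sum(w))^2)
  if (ss_tot == 0) return(1)
  1 - sum(w * res^2) / ss_tot
}

check_strictly_increasing <- function(x, what) {
  if (length(x) > 1L && any(diff(x) <= 0))
    stop_param("%s must be strictly increasing", what)
  invisible(TRUE)
}

#' Ground-truth record attached to every synthetic dataset
#'
#' @param kind one of "decay_series", "o2_trace", "epr_spectrum",
#'   "trajectory", "raman".
#' @param params named list of generating parameters.
#' @param seed integer RNG seed used (NA for deterministic generators).
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(kind, params, seed = NA_integer_) {
  kind <- match.arg(kind, c("decay_series", "o2_trace", "epr_spectrum",
                            "trajectory", "raman"))
  structure(list(kind = kind, params = params, seed = seed),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth [", x$kind, "], seed ", x$seed, "\n", sep = "")
  for (nm in names(x$params)) {
    v <- x$params[[nm]]
    if (is.numeric(v) && length(v) <= 6)
      cat("  ", nm, ": ", paste(signif(v, 6), collapse = ", "), "\n", sep = "")
    else
      cat("  ", nm, ": <", class(v)[1], " length ", length(v), ">\n", sep = "")
  }
  invisible(x)
}

#' Retrieve the ground truth stored on a synthetic dataset
#' @param x a synthetic dataset produced by one of the generators.
#' @return the `ground_truth` object, or NULL if absent.
#' @export
get_ground_truth <- function(x) attr(x, "ground_truth", exact = TRUE)

# Refine the position of a grid extremum by 3-point parabolic interpolation.
# Returns the refined x position; falls back to the grid point at boundaries.
parabolic_refine <- function(x, y, i) {
  n <- length(x)
  if (i <= 1L || i >= n) return(x[i])
  y1 <- y[i - 1L]; y2 <- y[i]; y3 <- y[i + 1L]
  denom <- y1 - 2 * y2 + y3
  if (denom == 0) return(x[i])
  delta <- 0.5 * (y1 - y3) / denom
  # constrain to the bracketing interval
  delta <- max(min(delta, 1), -1)
  x[i] + delta * (x[i + 1L] - x[i])
}

# Local extrema indices of a sampled curve.  `prominence` is the minimum
# |y| (relative to the global amplitude range) for an extremum to count.
local_extrema <- function(y, prominence = 0.02) {
  n <- length(y)
  d <- diff(y)
  up <- d[-(n - 1L)] > 0 & d[-1] <= 0   # rising then falling -> max
  dn <- d[-(n - 1L)] < 0 & d[-1] >= 0   # falling then rising -> min
  imax <- which(up) + 1L
  imin <- which(dn) + 1L
  amp <- max(abs(y))
  if (amp == 0) return(list(max = integer(0), min = integer(0)))
  list(max = imax[abs(y[imax]) >= prominence * amp],
       min = imin[abs(y[imin]) >= prominence * amp])
}
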