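# EPR oximetry: oxygen-uptake rates during free-radical (Fenton) induced
# lipid peroxidation, and treatment-vs-control comparison.

#' Construct an oxygen (or spin-probe linewidth) time series
#'
#' @param time_min time in minutes, strictly increasing, >= 5 points.
#' @param value oxygen concentration in uM, or peak-to-peak linewidth in mT.
#' @param value_kind "concentration" or "linewidth".
#' @param sample_label free-text label.
#' @return an `o2_trace`: data.frame with columns `time_min`, `value`.
#' @export
o2_trace <- function(time_min, value, value_kind = c("concentration", "linewidth"),
                     sample_label = "") {
  value_kind <- match.arg(value_kind)
  if (length(time_min) < 5L)
    stop_param("an oxygen trace needs at least 5 points, got %d", length(time_min))
  check_strictly_increasing(time_min, "time grid")
  if (length(value) != length(time_min)) stop_param("time/value lengths differ")
  if (value_kind == "concentration" && any(value < 0))
    stop_param("oxygen concentrations must be >= 0")
  structure(data.frame(time_min = as.numeric(time_min),
                       value = as.numeric(value)),
            value_kind = value_kind, sample_label = sample_label,
            class = c("o2_trace", "data.frame"))
}

#' Linear spin-probe linewidth / oxygen calibration
#'
#' Linewidth of an oxygen-sensitive nitroxide probe (e.g. mHCTPO) grows
#' linearly with dissolved O2: `linewidth = baseline + sensitivity * [O2]`.
#' The defaults are package conventions for a working model, not measured
#' calibration constants; supply instrument values for real data.
#'
#' @param baseline_linewidth linewidth at zero oxygen, mT.
#' @param sensitivity mT per uM oxygen; must be positive.
#' @return a `calibration_model` list.
#' @export
calibration_model <- function(baseline_linewidth = 0.014,
                              sensitivity = 5e-5) {
  if (sensitivity <= 0) stop_param("calibration sensitivity must be positive")
  structure(list(baseline_linewidth = baseline_linewidth,
                 sensitivity = sensitivity),
            class = "calibration_model")
}

#' Convert a linewidth trace to oxygen concentration
#'
#' `[O2](t) = (linewidth(t) - baseline) / sensitivity`, clipped at zero.
#' Clipping is reported through the `n_clipped` attribute and a warning when
#' any point is affected.
#'
#' @param trace an `o2_trace` of kind "linewidth".
#' @param calib a [calibration_model()].
#' @return an `o2_trace` of kind "concentration".
#' @export
linewidth_to_conc <- function(trace, calib) {
  stopifnot(inherits(trace, "o2_trace"), inherits(calib, "calibration_model"))
  if (attr(trace, "value_kind") != "linewidth")
    stop_param("trace is not a linewidth trace")
  conc <- (trace$value - calib$baseline_linewidth) / calib$sensitivity
  n_clipped <- sum(conc < 0)
  if (n_clipped > 0)
    warning(sprintf("%d implied concentrations were negative and clipped to 0",
                    n_clipped))
  out <- o2_trace(trace$time_min, pmax(conc, 0),
                  value_kind = "concentration",
                  sample_label = attr(trace, "sample_label"))
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Map a concentration trace through a calibration to linewidth
#' @param trace an `o2_trace` of kind "concentration".
#' @param calib a [calibration_model()].
#' @return an `o2_trace` of kind "linewidth".
#' @export
conc_to_linewidth <- function(trace, calib) {
  stopifnot(inherits(trace, "o2_trace"), inherits(calib, "calibration_model"))
  if (attr(trace, "value_kind") != "concentration")
    stop_param("trace is not a concentration trace")
  o2_trace(trace$time_min,
           calib$baseline_linewidth + calib$sensitivity * trace$value,
           value_kind = "linewidth",
           sample_label = attr(trace, "sample_label"))
}

#' Initial oxygen-uptake rate by windowed linear regression
#'
#' The uptake rate dO2/dt is estimated as minus the ordinary-least-squares
#' slope of concentration vs time over the stated window.  Fenton-driven
#' uptake is steepest early, so the default window is the first 10 minutes.
#'
#' @param trace an `o2_trace` of kind "concentration".
#' @param window length-2 numeric `(t_start, t_end)` in minutes.
#' @return a `rate_estimate`: list with `rate` (uM/min, positive =
#'   consumption), `se`, `window`, `r_squared`, `n`.
#' @export
initial_uptake_rate <- function(trace, window = c(0, 10)) {
  stopifnot(inherits(trace, "o2_trace"))
  if (attr(trace, "value_kind") != "concentration")
    stop_param("uptake rate needs a concentration trace; convert linewidth first")
  keep <- trace$time_min >= window[1] & trace$time_min <= window[2]
  if (sum(keep) < 5L)
    stop_param("fit window [%g, %g] min contains %d points; need >= 5",
               window[1], window[2], sum(keep))
  fit <- lm(value ~ time_min, data = trace[keep, ])
  sl <- coef(fit)[2]
  structure(list(rate = -unname(sl),
                 se = unname(suppressWarnings(sqrt(diag(vcov(fit))))[2]),
                 window = as.numeric(window),
                 r_squared = .r_squared(fit),
                 n = sum(keep),
                 sample_label = attr(trace, "sample_label")),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("Oxygen uptake rate: %.3f +/- %.3f uM/min (window %g-%g min, n=%d)\n",
              x$rate, x$se, x$window[1], x$window[2], x$n))
  invisible(x)
}

#' Compare oxygen-uptake rates between a treatment and a control group
#'
#' Reports the percent reduction of the treatment mean relative to the
#' control mean and, with >= 2 replicates per group, a two-sided Welch
#' t-test at alpha = 0.05.
#'
#' @param treatment,control lists of `rate_estimate` objects (or numeric
#'   vectors of rates in uM/min).
#' @param alpha significance level for the flag (default 0.05).
#' @param negative_control_ceiling rates at or below this value (uM/min) are
#'   flagged as background, i.e. indistinguishable from a no-Fenton control;
#'   default 1.48.
#' @return a `rate_comparison` list with group means/SDs, `percent_reduction`,
#'   `p_value`, `significant`, `t_statistic`, `df` and background flags.
#' @export
compare_rates <- function(treatment, control, alpha = 0.05,
                          negative_control_ceiling = 1.48) {
  as_rates <- function(x) {
    if (is.numeric(x)) return(as.numeric(x))
    vapply(x, function(e) {
      stopifnot(inherits(e, "rate_estimate")); e$rate
    }, 0)
  }
  rt <- as_rates(treatment); rc <- as_rates(control)
  if (length(rt) < 1L || length(rc) < 1L) stop_param("empty rate group")
  pr <- 100 * (mean(rc) - mean(rt)) / mean(rc)
  if (length(rt) >= 2L && length(rc) >= 2L) {
    if (sd(rt) == 0 && sd(rc) == 0) {
      tt <- list(p.value = 1, statistic = c(t = 0),
                 parameter = c(df = length(rt) + length(rc) - 2))
    } else {
      tt <- t.test(rt, rc, var.equal = FALSE)
    }
    p <- tt$p.value; tstat <- unname(tt$statistic); df <- unname(tt$parameter)
  } else {
    p <- NA_real_; tstat <- NA_real_; df <- NA_real_
  }
  structure(list(mean_treatment = mean(rt), sd_treatment = sd(rt),
                 mean_control = mean(rc), sd_control = sd(rc),
                 n_treatment = length(rt), n_control = length(rc),
                 percent_reduction = pr,
                 t_statistic = tstat, df = df, p_value = p,
                 significant = isTRUE(p < alpha),
                 treatment_background = rt <= negative_control_ceiling,
                 control_background = rc <= negative_control_ceiling),
            class = "rate_comparison")
}

#' @export
print.rate_comparison <- function(x, ...) {
  cat(sprintf("Uptake rates: control %.2f +/- %.2f, treatment %.2f +/- %.2f uM/min\n",
              x$mean_control, x$sd_control, x$mean_treatment, x$sd_treatment))
  cat(sprintf("  reduction %.1f%%, Welch t = %.3f (df %.2f), p = %.4g%s\n",
              x$percent_reduction, x$t_statistic, x$df, x$p_value,
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}
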