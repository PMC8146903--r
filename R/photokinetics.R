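# Singlet-oxygen phosphorescence decay kinetics and Stern-Volmer analysis.
#
# A singlet-oxygen signal at 1270 nm decays (pseudo-)first order with rate
# k_obs = k0 + kq * [Q].  Fitting each decay and regressing k_obs on the
# quencher concentration yields the intrinsic decay constant k0 (intercept),
# its reciprocal the unquenched lifetime, and the bimolecular quenching
# constant kq (slope).

#' Construct a photon-count decay trace
#'
#' @param time_us time grid in microseconds, strictly increasing, >= 20 points.
#' @param counts non-negative photon counts (reals allowed for expectations).
#' @param quencher_conc quencher concentration in mol/L.
#' @param label free-text sample label.
#' @return a `decay_trace`: data.frame with columns `time_us`, `counts` and
#'   attributes `quencher_conc`, `label`.
#' @export
decay_trace <- function(time_us, counts, quencher_conc = 0, label = "") {
  if (length(time_us) < 20L)
    stop_param("a decay trace needs at least 20 points, got %d", length(time_us))
  check_strictly_increasing(time_us, "time grid")
  if (length(counts) != length(time_us))
    stop_param("time and counts lengths differ")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop_param("counts must be finite and non-negative")
  if (quencher_conc < 0) stop_param("quencher concentration must be >= 0")
  structure(data.frame(time_us = as.numeric(time_us),
                       counts = as.numeric(counts)),
            quencher_conc = as.numeric(quencher_conc),
            label = label,
            class = c("decay_trace", "data.frame"))
}

#' Fit a monoexponential decay with baseline
#'
#' Least-squares fit of `counts = A * exp(-k * t) + b` by the
#' Levenberg-Marquardt algorithm.  Starting values are derived
#' deterministically: k from a log-linear regression on the upper half of the
#' background-subtracted decay, A from the maximum count, b from the tail
#' mean.
#'
#' @param trace a [decay_trace()].
#' @param init optional named list with starting values `k` (1/s),
#'   `A` (counts), `b` (counts); any subset may be given.
#' @param skip_initial number of microseconds to drop from the start of the
#'   trace (excitation artifact gating); default 0.
#' @return a `decay_fit`: list with `k_obs` (1/s), `amplitude`, `background`,
#'   their standard errors (`k_se`, `A_se`, `b_se`), `chisq_red` (reduced
#'   chi-square with Poisson-style variance max(model, 1)), `converged`,
#'   `quencher_conc` carried from the trace, and the `fitted` curve.
#' @export
fit_monoexponential <- function(trace, init = NULL, skip_initial = 0) {
  stopifnot(inherits(trace, "decay_trace"))
  keep <- trace$time_us >= trace$time_us[1] + skip_initial
  t_s <- trace$time_us[keep] * 1e-6
  y <- trace$counts[keep]
  if (all(y == 0)) stop_param("all-zero counts: nothing to fit")
  if (length(unique(y)) == 1L) stop_param("constant counts: nothing to fit")

  b0 <- mean(tail(y, max(5L, length(y) %/% 10L)))
  A0 <- max(y) - b0
  if (A0 <= 0) A0 <- max(y)
  # log-linear start for k on the upper half of the decay
  pos <- y - b0 > 0.5 * A0 * 1e-3 & y - b0 > 0
  upper <- which(pos & (y - b0) >= 0.5 * A0)
  if (length(upper) < 3L) upper <- head(which(pos), max(3L, sum(pos) %/% 2L))
  k0 <- if (length(upper) >= 3L) {
    sl <- coef(lm(log(y[upper] - b0) ~ t_s[upper]))[2]
    if (is.finite(sl) && sl < 0) -sl else 1 / (max(t_s) / 3)
  } else 1 / (max(t_s) / 3)

  start <- list(A = A0, k = unname(k0), b = b0)
  if (!is.null(init)) start[names(init)] <- init

  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-k * t_s) + b,
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop_param("decay fit failed to converge: %s",
                                   conditionMessage(e)))
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  mu <- pmax(predict(fit), 1)
  chisq_red <- sum((y - predict(fit))^2 / mu) / (length(y) - 3L)
  structure(list(k_obs = unname(cf["k"]),
                 amplitude = unname(cf["A"]),
                 background = unname(cf["b"]),
                 k_se = unname(se["k"]), A_se = unname(se["A"]),
                 b_se = unname(se["b"]),
                 chisq_red = chisq_red,
                 converged = fit$convInfo$isConv,
                 quencher_conc = attr(trace, "quencher_conc"),
                 fitted = predict(fit),
                 time_us = trace$time_us[keep]),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Monoexponential decay fit: k_obs = %.4g +/- %.2g 1/s\n",
              x$k_obs, x$k_se))
  cat(sprintf("  amplitude %.4g, background %.4g, reduced chi-sq %.3f\n",
              x$amplitude, x$background, x$chisq_red))
  invisible(x)
}

#' Stern-Volmer regression of pseudo-first-order rate constants
#'
#' Weighted linear regression `k_obs = k0 + kq * c` across quencher
#' concentrations.  Default weights are 1/SE(k_obs)^2; pass
#' `weighted = FALSE` for an ordinary fit.
#'
#' @param fits list of `decay_fit` objects (or a numeric vector of k_obs
#'   values, in which case `k_se` may supply the errors).
#' @param concentrations quencher concentrations in mol/L, one per fit.
#' @param weighted logical; weight by 1/SE^2 when SEs are available.
#' @param k_se optional numeric vector of standard errors when `fits` is
#'   numeric.
#' @return a `quenching_result`: list with `k0` (1/s), `kq` (1/(M s)),
#'   `lifetime0_us` (= 1e6/k0), `k0_se`, `kq_se`, `r_squared`, and the
#'   per-concentration `table`.
#' @export
stern_volmer <- function(fits, concentrations, weighted = TRUE, k_se = NULL) {
  if (is.list(fits) && all(vapply(fits, inherits, TRUE, "decay_fit"))) {
    k_obs <- vapply(fits, `[[`, 0, "k_obs")
    se <- vapply(fits, `[[`, 0, "k_se")
  } else {
    k_obs <- as.numeric(fits)
    se <- if (is.null(k_se)) rep(NA_real_, length(k_obs)) else k_se
  }
  c_M <- as.numeric(concentrations)
  if (length(c_M) != length(k_obs))
    stop_param("need one concentration per fit")
  if (length(unique(c_M)) < 3L)
    stop_param("Stern-Volmer regression needs >= 3 distinct concentrations")
  w <- if (weighted && all(is.finite(se)) && all(se > 0)) 1 / se^2 else NULL
  fit <- lm(k_obs ~ c_M, weights = w)
  cf <- coef(fit)
  # vcov.lm warns on numerically perfect fits (noiseless synthetic input);
  # the zero standard errors it returns are exactly what we want there
  ses <- suppressWarnings(sqrt(diag(vcov(fit))))
  k0 <- unname(cf[1]); kq <- unname(cf[2])
  structure(list(k0 = k0, kq = kq,
                 lifetime0_us = 1e6 / k0,
                 k0_se = unname(ses[1]), kq_se = unname(ses[2]),
                 r_squared = .r_squared(fit),
                 table = data.frame(conc_M = c_M, k_obs = k_obs, k_se = se)),
            class = "quenching_result")
}

#' @export
print.quenching_result <- function(x, ...) {
  cat(sprintf("Stern-Volmer: kq = (%.3g +/- %.2g) 1/(M s)\n", x$kq, x$kq_se))
  cat(sprintf("  k0 = (%.3g +/- %.2g) 1/s, lifetime = %.2f us, R^2 = %.4f\n",
              x$k0, x$k0_se, x$lifetime0_us, x$r_squared))
  invisible(x)
}

#' Unquenched singlet-oxygen lifetime from the intrinsic decay constant
#'
#' @param k0 intrinsic decay constant in 1/s; must be positive.
#' @return lifetime in microseconds, `1e6 / k0`.
#' @export
lifetime_us <- function(k0) {
  if (any(k0 <= 0)) stop_param("decay constant must be positive")
  1e6 / k0
}
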