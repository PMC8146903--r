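# Semiquantitative Raman analysis: replicate averaging, baseline
# correction, band integration, the 2937/1453 1/cm CH-stretch/CH-bend band
# ratio, and group comparison (normality, one-way ANOVA, Tukey HSD).

#' Construct a Raman spectrum
#'
#' @param wavenumber grid in 1/cm, strictly increasing.
#' @param intensity counts, finite.
#' @param sample_label free-text sample label.
#' @param replicate replicate id.
#' @return a `raman_spectrum` data.frame with columns `wavenumber`,
#'   `intensity`.
#' @export
raman_spectrum <- function(wavenumber, intensity, sample_label = "",
                           replicate = 1L) {
  check_strictly_increasing(wavenumber, "wavenumber grid")
  if (length(intensity) != length(wavenumber))
    stop_param("wavenumber/intensity lengths differ")
  if (any(!is.finite(intensity))) stop_param("intensities must be finite")
  structure(data.frame(wavenumber = as.numeric(wavenumber),
                       intensity = as.numeric(intensity)),
            sample_label = sample_label, replicate = replicate,
            class = c("raman_spectrum", "data.frame"))
}

#' Point-wise mean and SD of replicate spectra
#'
#' @param replicates list of [raman_spectrum()] objects on identical grids
#'   (or set `resample = TRUE` to interpolate all onto the first grid).
#' @param resample linearly interpolate onto a common grid when grids
#'   differ.
#' @return data.frame with columns `wavenumber`, `mean`, `sd`, `n`.
#' @export
average_spectra <- function(replicates, resample = FALSE) {
  stopifnot(length(replicates) >= 1L,
            all(vapply(replicates, inherits, TRUE, "raman_spectrum")))
  grid <- replicates[[1]]$wavenumber
  same <- all(vapply(replicates, function(s)
    length(s$wavenumber) == length(grid) && all(s$wavenumber == grid), TRUE))
  if (!same) {
    if (!resample)
      stop_param("replicate grids differ; pass resample = TRUE to interpolate")
    replicates <- lapply(replicates, function(s)
      raman_spectrum(grid, approx(s$wavenumber, s$intensity, xout = grid,
                                  rule = 2)$y))
  }
  mat <- vapply(replicates, `[[`, numeric(length(grid)), "intensity")
  data.frame(wavenumber = grid,
             mean = rowMeans(mat),
             sd = apply(mat, 1, sd),
             n = length(replicates))
}

#' Baseline correction
#'
#' `"polynomial"`: iterative polynomial fitting (fit, clip points above the
#' fit to the fit, refit) so bands do not drag the baseline up; removes a
#' pure polynomial baseline of the declared degree exactly on band-free
#' spectra.  `"rubberband"`: lower convex-hull envelope, linearly
#' interpolated.
#'
#' @param spec a [raman_spectrum()].
#' @param method "polynomial" or "rubberband".
#' @param degree polynomial degree (>= 0).
#' @param max_iter,tol iteration controls for the polynomial method.
#' @return the baseline-corrected [raman_spectrum()]; the removed baseline
#'   is attached as attribute `baseline`.
#' @export
baseline_correct <- function(spec, method = c("polynomial", "rubberband"),
                             degree = 3, max_iter = 50, tol = 1e-8) {
  stopifnot(inherits(spec, "raman_spectrum"))
  method <- match.arg(method)
  x <- spec$wavenumber; y <- spec$intensity
  if (method == "polynomial") {
    if (degree < 0) stop_param("polynomial degree must be >= 0")
    xs <- (x - min(x)) / (max(x) - min(x))   # conditioning
    yw <- y
    for (it in seq_len(max_iter)) {
      fit <- lm(yw ~ poly(xs, degree = max(degree, 1), raw = TRUE))
      bl <- unname(predict(fit))
      if (degree == 0) bl <- rep(mean(yw), length(yw))
      new_yw <- pmin(yw, bl)
      if (max(abs(new_yw - yw)) < tol * max(abs(y), 1)) { yw <- new_yw; break }
      yw <- new_yw
    }
    baseline <- bl
  } else {
    hull <- chull(x, y)
    # keep the lower envelope: hull points from min-x to max-x going below
    hull <- sort(hull)
    lower <- hull
    # a point is on the lower hull if no interpolation of its neighbours
    # lies below it; build by walking the sorted hull with a cross-product
    pts <- cbind(x[hull], y[hull])
    keep <- rep(TRUE, nrow(pts))
    i <- 1L
    lower_idx <- c(1L)
    for (j in 2:nrow(pts)) {
      while (length(lower_idx) >= 2L) {
        a <- pts[lower_idx[length(lower_idx) - 1L], ]
        b <- pts[lower_idx[length(lower_idx)], ]
        cr <- (b[1] - a[1]) * (pts[j, 2] - a[2]) -
          (b[2] - a[2]) * (pts[j, 1] - a[1])
        if (cr < 0) lower_idx <- lower_idx[-length(lower_idx)] else break
      }
      lower_idx <- c(lower_idx, j)
    }
    hx <- pts[lower_idx, 1]; hy <- pts[lower_idx, 2]
    baseline <- approx(hx, hy, xout = x, rule = 2)$y
  }
  out <- raman_spectrum(x, y - baseline,
                        sample_label = attr(spec, "sample_label"),
                        replicate = attr(spec, "replicate"))
  attr(out, "baseline") <- baseline
  out
}

#' Definition of an integration band
#'
#' @param center band centre, 1/cm.
#' @param window length-2 numeric `(low, high)` integration window, 1/cm;
#'   must bracket the centre.
#' @param anchor_width width (1/cm) of the local-baseline anchor regions
#'   just inside each window edge; 0 disables the local baseline.
#' @return a `band_definition` list.
#' @export
band_definition <- function(center, window, anchor_width = 0) {
  if (!(window[1] < center && center < window[2]))
    stop_param("band window must bracket the centre")
  structure(list(center = center, window = as.numeric(window),
                 anchor_width = anchor_width),
            class = "band_definition")
}

# Default marker bands: CH-stretch region band at 2937 1/cm (solute
# abundance marker) over 2850-3000, CH-bend at 1453 1/cm (internal
# reference) over 1420-1480.
#' @rdname band_definition
#' @export
band_2937 <- function() band_definition(2937, c(2850, 3000))
#' @rdname band_definition
#' @export
band_1453 <- function() band_definition(1453, c(1420, 1480))

#' Trapezoidal band integral
#'
#' Integral of intensity over the band window after subtracting a local
#' linear baseline drawn between the mean intensities of the two anchor
#' regions (skipped when `anchor_width = 0`).
#'
#' @param spec a [raman_spectrum()] (typically baseline-corrected).
#' @param band a [band_definition()].
#' @return band area (counts * 1/cm).
#' @export
band_integral <- function(spec, band) {
  stopifnot(inherits(spec, "raman_spectrum"), inherits(band, "band_definition"))
  x <- spec$wavenumber; y <- spec$intensity
  if (band$window[1] < min(x) || band$window[2] > max(x))
    stop_param("band window [%g, %g] outside the spectral grid",
               band$window[1], band$window[2])
  keep <- x >= band$window[1] & x <= band$window[2]
  xs <- x[keep]; ys <- y[keep]
  if (band$anchor_width > 0) {
    lo <- keep & x <= band$window[1] + band$anchor_width
    hi <- keep & x >= band$window[2] - band$anchor_width
    bx <- c(mean(x[lo]), mean(x[hi])); by <- c(mean(y[lo]), mean(y[hi]))
    ys <- ys - approx(bx, by, xout = xs, rule = 2)$y
  }
  pracma::trapz(xs, ys)
}

#' CH-stretch / CH-bend band ratio (2937 / 1453)
#'
#' Ratio of the baseline-corrected band integrals; invariant to overall
#' intensity scaling.  Applied to membrane fractions it semiquantifies the
#' abundance of a CH-stretch-rich solute against the lipid CH-bend
#' reference.
#'
#' @param spec a [raman_spectrum()].
#' @param numerator,denominator [band_definition()]s; default the 2937 and
#'   1453 1/cm marker bands.
#' @param correct_baseline run [baseline_correct()] first (polynomial,
#'   `degree`).
#' @param degree baseline polynomial degree when correcting.
#' @return the dimensionless ratio.
#' @export
band_ratio <- function(spec, numerator = band_2937(),
                       denominator = band_1453(),
                       correct_baseline = TRUE, degree = 3) {
  if (correct_baseline)
    spec <- baseline_correct(spec, "polynomial", degree = degree)
  num <- band_integral(spec, numerator)
  den <- band_integral(spec, denominator)
  if (den <= 0)
    stop_param("denominator band integral %.3g is not positive", den)
  num / den
}

#' Compare band ratios between groups
#'
#' Shapiro-Wilk normality per group, one-way ANOVA across groups, and Tukey
#' HSD pairwise comparisons, with significance flags at `alpha`.
#'
#' @param ... named numeric vectors of per-replicate ratios (>= 3 replicates
#'   each), e.g. `DSM = c(...), DRM = c(...)`.
#' @param alpha significance level.
#' @return a `ratio_comparison` list: per-group `summary` (mean, SE, n,
#'   Shapiro-Wilk p), `anova_p`, `tukey` table, `significant`.
#' @export
group_compare <- function(..., alpha = 0.05) {
  groups <- list(...)
  if (length(groups) == 1L && is.list(groups[[1]]) && is.null(names(groups)))
    groups <- groups[[1]]
  if (length(groups) < 2L) stop_param("need at least two groups")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop_param("groups must be named")
  n <- vapply(groups, length, 0L)
  if (any(n < 3L)) stop_param("each group needs >= 3 replicates")
  summ <- data.frame(
    group = names(groups),
    n = n,
    mean = vapply(groups, mean, 0),
    se = vapply(groups, function(g) sd(g) / sqrt(length(g)), 0),
    shapiro_p = vapply(groups, function(g) {
      if (sd(g) == 0) NA_real_ else shapiro.test(g)$p.value
    }, 0))
  df <- data.frame(ratio = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups), times = n)))
  if (sd(df$ratio) == 0) {
    anova_p <- 1
    tk <- data.frame(comparison = character(0), diff = numeric(0),
                     p_adj = numeric(0))
  } else {
    fit <- aov(ratio ~ group, data = df)
    anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tkm <- TukeyHSD(fit)$group
    tk <- data.frame(comparison = rownames(tkm), diff = tkm[, "diff"],
                     p_adj = tkm[, "p adj"], row.names = NULL)
  }
  structure(list(summary = summ, anova_p = anova_p, tukey = tk,
                 significant = isTRUE(anova_p < alpha), alpha = alpha),
            class = "ratio_comparison")
}

#' @export
print.ratio_comparison <- function(x, ...) {
  cat("Band-ratio group comparison\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("one-way ANOVA p = %.4g%s\n", x$anova_p,
              if (x$significant) " *" else ""))
  if (nrow(x$tukey)) print(x$tukey, row.names = FALSE)
  invisible(x)
}
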