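# Synthetic-data generators.  Every generator returns a dataset carrying a
# ground_truth attribute with the exact parameters and seed used, and is
# bit-reproducible for identical (params, seed).

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  if (!is.na(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Generate a series of singlet-oxygen phosphorescence decays
#'
#' Expectation per trace: `I(t) = amplitude * exp(-(k0 + kq * c) * t) +
#' background`.  With `noise = "poisson"` each bin is a Poisson draw with
#' that mean (photon-counting statistics); `"gaussian"` adds i.i.d. noise of
#' SD `sigma` (clipped at zero) as a fast alternative; `"none"` returns the
#' expectation itself.
#'
#' @param k0 intrinsic decay constant, 1/s; must be positive.
#' @param kq bimolecular quenching constant, 1/(M s); >= 0.
#' @param concentrations quencher concentrations in mol/L, non-negative and
#'   strictly increasing.  Default: five evenly spaced values across
#'   5.2-19.1 mM (typical titration span for bile-acid quenchers).
#' @param amplitude initial expected counts above background; must be positive.
#' @param background constant expected background counts; >= 0.
#' @param time_grid_us time grid in microseconds, strictly increasing.
#' @param noise "poisson", "gaussian" or "none".
#' @param sigma Gaussian noise SD (counts), used when `noise = "gaussian"`.
#' @param seed integer RNG seed.
#' @return list of [decay_trace()] objects with a shared `ground_truth`
#'   attribute (which also carries the TPP singlet-oxygen quantum yield 0.63
#'   as sensitizer metadata).
#' @export
gen_decay_series <- function(k0, kq, concentrations = seq(5.2e-3, 19.1e-3,
                                                          length.out = 5),
                             amplitude = 2e4, background = 20,
                             time_grid_us = seq(0, 500, length.out = 251),
                             noise = c("poisson", "gaussian", "none"),
                             sigma = 10, seed = 1L) {
  noise <- match.arg(noise)
  if (k0 <= 0) stop_param("k0 must be positive")
  if (kq < 0) stop_param("kq must be >= 0")
  if (length(concentrations) == 0L) stop_param("empty concentration list")
  if (any(concentrations < 0)) stop_param("concentrations must be >= 0")
  check_strictly_increasing(concentrations, "concentration list")
  if (amplitude <= 0) stop_param("amplitude must be positive")
  if (background < 0) stop_param("background must be >= 0")
  check_strictly_increasing(time_grid_us, "time grid")

  gt <- ground_truth("decay_series",
                     list(k0 = k0, kq = kq, concentrations = concentrations,
                          amplitude = amplitude, background = background,
                          noise = noise,
                          sensitizer_phi_delta = TPP_SINGLET_OXYGEN_YIELD),
                     seed)
  t_s <- time_grid_us * 1e-6
  traces <- with_seed(seed, lapply(concentrations, function(cc) {
    mu <- amplitude * exp(-(k0 + kq * cc) * t_s) + background
    y <- switch(noise,
                none = mu,
                poisson = rpois(length(mu), mu),
                gaussian = pmax(mu + rnorm(length(mu), 0, sigma), 0))
    decay_trace(time_grid_us, y, quencher_conc = cc,
                label = sprintf("c=%.4g M", cc))
  }))
  attr(traces, "ground_truth") <- gt
  traces
}

#' Generate a linear oxygen-uptake trace
#'
#' Expectation `[O2](t) = initial_conc - rate * t` with i.i.d. Gaussian
#' noise of SD `sigma`; optionally mapped to spin-probe linewidth through a
#' [calibration_model()].
#'
#' @param rate uptake rate in uM/min; >= 0.
#' @param initial_conc starting oxygen concentration, uM; must be at least
#'   `rate * duration` so the trace never goes negative.
#' @param duration trace length in minutes; must be positive.
#' @param dt_min sampling interval in minutes (default 0.1 = one point per
#'   6 s).
#' @param sigma Gaussian noise SD in uM.
#' @param seed integer RNG seed.
#' @param as_linewidth return the trace mapped to linewidth units.
#' @param calib calibration used when `as_linewidth = TRUE`.
#' @param sample_label label stored on the trace.
#' @return an [o2_trace()] with a `ground_truth` attribute.
#' @export
gen_o2_trace <- function(rate, initial_conc = 250, duration = 10,
                         dt_min = 0.1, sigma = 0.5, seed = 1L,
                         as_linewidth = FALSE, calib = calibration_model(),
                         sample_label = "") {
  if (rate < 0) stop_param("rate must be >= 0")
  if (duration <= 0) stop_param("duration must be positive")
  if (initial_conc < rate * duration)
    stop_param("initial concentration %.3g uM would go negative at rate %.3g uM/min over %.3g min",
               initial_conc, rate, duration)
  tt <- seq(0, duration, by = dt_min)
  gt <- ground_truth("o2_trace",
                     list(rate = rate, initial_conc = initial_conc,
                          duration = duration, sigma = sigma,
                          as_linewidth = as_linewidth), seed)
  y <- with_seed(seed, pmax(initial_conc - rate * tt +
                              rnorm(length(tt), 0, sigma), 0))
  out <- o2_trace(tt, y, value_kind = "concentration",
                  sample_label = sample_label)
  if (as_linewidth) out <- conc_to_linewidth(out, calib)
  attr(out, "ground_truth") <- gt
  out
}

#' Generate an axially averaged nitroxide first-derivative spectrum
#'
#' Sum of three 14N hyperfine components (m_I = -1, 0, +1).  Each m_I = +/-1
#' component is modelled as the Gaussian-smoothed powder span between the
#' parallel (A_par) and perpendicular (A_perp) turning points, whose
#' first derivative peaks exactly at the turning-point fields; the m_I = 0
#' line is a derivative Gaussian at the centre.  This places the outermost
#' extrema at `center +/- A_par` and the inner extrema at
#' `center +/- A_perp`, which is all that splitting-based analysis needs;
#' it is not a spin-Hamiltonian simulation.
#'
#' @param A_par parallel (outer) hyperfine coupling, gauss.  At the rigid
#'   limit this is Azz.
#' @param A_perp perpendicular (inner) hyperfine coupling, gauss;
#'   `A_par >= A_perp > 0`.
#' @param linewidth Gaussian smoothing SD, gauss.
#' @param field optional absolute field grid (gauss); default spans
#'   `center +/- (A_par + 15)` at `step` spacing.
#' @param center spectral centre field, gauss.
#' @param step grid spacing when `field` is NULL.
#' @param rigid_limit flag recorded in the ground truth: the spectrum
#'   represents a frozen sample and `A_par` is Azz (so the outer splitting
#'   is 2Azz).
#' @param temperature_K stored on the spectrum; defaults to 120 when
#'   `rigid_limit` else 310.
#' @param label_position n-PC label position tag.
#' @param noise_sigma additive Gaussian amplitude noise (relative to the
#'   maximum absolute amplitude).
#' @param seed RNG seed (used only when `noise_sigma > 0`).
#' @return an [epr_spectrum()] with a `ground_truth` attribute.
#' @export
gen_nitroxide_spectrum <- function(A_par, A_perp, linewidth = 0.4,
                                   field = NULL, center = 3350, step = 0.05,
                                   rigid_limit = FALSE,
                                   temperature_K = if (rigid_limit) 120 else 310,
                                   label_position = "5-PC",
                                   noise_sigma = 0, seed = 1L) {
  if (!(A_par >= A_perp) || A_perp <= 0)
    stop_param("need A_par >= A_perp > 0")
  if (linewidth <= 0) stop_param("linewidth must be positive")
  if (is.null(field))
    field <- seq(center - A_par - 15, center + A_par + 15, by = step)
  check_strictly_increasing(field, "field grid")
  if (min(field) > center - A_par - 3 * linewidth ||
      max(field) < center + A_par + 3 * linewidth)
    stop_param("field grid too narrow to contain the outer extrema")

  g <- function(x) exp(-x^2 / (2 * linewidth^2))
  dg <- function(x) -x / linewidth^2 * g(x)   # derivative of the Gaussian
  span <- A_par - A_perp
  amp <- numeric(length(field))
  b <- field - center
  if (span > 2 * linewidth) {
    # powder span components: absorption is a smoothed plateau between the
    # turning points, so the derivative is the difference of edge Gaussians
    amp <- amp +
      (g(b + A_par) - g(b + A_perp)) / span +   # m_I = -1
      (g(b - A_perp) - g(b - A_par)) / span     # m_I = +1
  } else {
    # (near-)isotropic limit: single lines at +/- mean coupling
    a_iso <- (A_par + A_perp) / 2
    amp <- amp + dg(b + a_iso) * linewidth + dg(b - a_iso) * linewidth
  }
  amp <- amp + dg(b) * linewidth                # m_I = 0
  if (noise_sigma > 0)
    amp <- with_seed(seed,
                     amp + rnorm(length(amp), 0, noise_sigma * max(abs(amp))))
  gt <- ground_truth("epr_spectrum",
                     list(A_par = A_par, A_perp = A_perp,
                          linewidth = linewidth, center = center,
                          rigid_limit = rigid_limit,
                          Azz2 = if (rigid_limit) 2 * A_par else NA_real_),
                     if (noise_sigma > 0) seed else NA_integer_)
  out <- epr_spectrum(field, amp, temperature_K = temperature_K,
                      label_position = label_position)
  attr(out, "ground_truth") <- gt
  out
}

#' Generate a toy bilayer trajectory with known segmental order
#'
#' Chains are built segment-by-segment so that every analysed segmental
#' vector (C(n-1) -> C(n+1)) has polar angle theta drawn with
#' `E[cos^2 theta] = (2 S_target + 1) / 3`, i.e. the molecular order
#' parameter `S_mol = <0.5 (3 cos^2 theta - 1)>` equals `S_target` per
#' segment in expectation (cos^2 theta is sampled uniformly on a symmetric
#' interval about that mean).  Each chain residue ("LIP") carries a
#' phosphorus atom at the headgroup so the bilayer midplane can be located;
#' waters ("SOL", 3-site) fill the solvent slabs and solute residues
#' ("TUD") with named donor/acceptor atoms are placed at controllable
#' depths.
#'
#' @param n_chains number of chains (split evenly over the two leaflets).
#' @param chain_length carbons per chain (>= 4).
#' @param S_target target order parameter in [-0.5, 1]; scalar or one value
#'   per analysable segment (carbons 2..chain_length-1).
#' @param n_frames number of frames (>= 1).
#' @param n_solutes number of solute residues.
#' @param solute_z signed z positions (angstrom, midplane 0) for the
#'   solutes; scalar or vector recycled; default alternates the two
#'   interphase regions.
#' @param n_waters number of water molecules.
#' @param box orthorhombic box lengths (angstrom); default sized from the
#'   chain count and length.
#' @param bond_z projected carbon spacing along the chain axis (angstrom).
#' @param seed RNG seed.
#' @return an [md_trajectory()] with a `ground_truth` attribute and a
#'   `chain_topology` attribute describing the chains.
#' @export
gen_bilayer_trajectory <- function(n_chains = 16, chain_length = 16,
                                   S_target = 0.4, n_frames = 10,
                                   n_solutes = 2, solute_z = NULL,
                                   n_waters = 100, box = NULL,
                                   bond_z = 1.25, seed = 1L) {
  if (n_frames < 1L) stop_param("need at least one frame")
  if (chain_length < 4L) stop_param("chain_length must be >= 4")
  n_seg <- chain_length - 2L
  if (length(S_target) == 1L) S_target <- rep(S_target, n_seg)
  if (length(S_target) != n_seg)
    stop_param("S_target must be scalar or length chain_length - 2")
  if (any(S_target < -0.5 | S_target > 1))
    stop_param("S_target must lie in [-0.5, 1]")

  seg_len <- 2 * bond_z                     # |C(n-1) -> C(n+1)|
  z_head <- chain_length * bond_z + 4      # headgroup depth
  n_up <- ceiling(n_chains / 2); n_dn <- n_chains - n_up
  per_row <- ceiling(sqrt(max(n_up, n_dn)))
  spacing <- 8
  if (is.null(box))
    box <- c(per_row * spacing + spacing, per_row * spacing + spacing,
             2 * z_head + 30)
  if (is.null(solute_z))
    solute_z <- rep_len(c(z_head, -z_head), max(n_solutes, 1L))
  solute_z <- rep_len(solute_z, max(n_solutes, 1L))

  m <- (2 * S_target + 1) / 3               # target E[cos^2 theta]
  w <- pmin(m, 1 - m)                       # uniform half-width, keeps mean
  solute_atoms <- c("OS", "NH", "HN", "OE1", "OH3", "HO3", "OH7", "HO7", "C12")

  build <- with_seed(seed, {
    resid <- 0L
    chain_ids <- vector("list", n_chains)
    rows <- list()  # per-atom static table
    frame_xyz <- vector("list", n_frames)
    for (f in seq_len(n_frames)) frame_xyz[[f]] <- list()
    atom_count <- 0L

    add_atom <- function(name, resname, rid, xyz_by_frame) {
      atom_count <<- atom_count + 1L
      rows[[atom_count]] <<- data.frame(name = name, resname = resname,
                                        resid = rid)
      for (f in seq_len(n_frames))
        frame_xyz[[f]][[atom_count]] <<- xyz_by_frame[f, ]
      atom_count
    }

    for (ic in seq_len(n_chains)) {
      up <- ic <= n_up
      k <- if (up) ic else ic - n_up
      x0 <- ((k - 1L) %% per_row) * spacing + spacing / 2
      y0 <- ((k - 1L) %/% per_row) * spacing + spacing / 2
      s <- if (up) 1 else -1
      resid <- resid + 1L
      # carbon positions, per frame
      cxyz <- array(0, dim = c(chain_length, 3, n_frames))
      for (f in seq_len(n_frames)) {
        c1 <- c(x0, y0, s * (z_head - 1))
        c2 <- c(x0 + 0.4, y0, s * (z_head - 1 - bond_z))
        cxyz[1, , f] <- c1; cxyz[2, , f] <- c2
        for (n in 2:(chain_length - 1L)) {
          mm <- m[n - 1L]; ww <- w[n - 1L]
          c2th <- if (ww > 0) runif(1, mm - ww, mm + ww) else mm
          cth <- sqrt(max(min(c2th, 1), 0))
          sth <- sqrt(max(1 - cth^2, 0))
          phi <- runif(1, 0, 2 * pi)
          u <- c(sth * cos(phi), sth * sin(phi), -s * cth)
          cxyz[n + 1L, , f] <- cxyz[n - 1L, , f] + seg_len * u
        }
      }
      # headgroup phosphorus sits just above C1
      pmat <- matrix(cxyz[1, , ], nrow = 3)   # 3 x n_frames
      pmat[3, ] <- pmat[3, ] + s * 1.8
      add_atom("P", "LIP", resid, t(pmat))
      ids <- integer(chain_length)
      for (n in seq_len(chain_length))
        ids[n] <- add_atom(sprintf("C%d", n), "LIP", resid,
                           t(matrix(cxyz[n, , ], nrow = 3)))
      chain_ids[[ic]] <- ids
    }

    for (isol in seq_len(n_solutes)) {
      resid <- resid + 1L
      ctr <- c(runif(1, 2, box[1] - 2), runif(1, 2, box[2] - 2),
               solute_z[isol])
      for (an in solute_atoms) {
        off <- runif(3, -1.5, 1.5)
        pos <- matrix(rep(ctr + off, n_frames), ncol = 3, byrow = TRUE)
        add_atom(an, "TUD", resid, pos)
      }
    }

    half_solvent <- box[3] / 2
    if (n_waters > 0L && half_solvent - 1 <= z_head + 3)
      stop_param("box z-length %.1f A leaves no solvent slab above the leaflets",
                 box[3])
    for (iw in seq_len(n_waters)) {
      resid <- resid + 1L
      side <- if (iw %% 2L == 0L) 1 else -1
      zw <- side * runif(1, z_head + 3, half_solvent - 1)
      ow <- c(runif(1, 0, box[1]), runif(1, 0, box[2]), zw)
      # random rigid water orientation
      ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
      perp <- rnorm(3); perp <- perp - sum(perp * ax) * ax
      perp <- perp / sqrt(sum(perp^2))
      h1 <- ow + 0.9572 * ax
      ang <- 104.52 * pi / 180
      h2 <- ow + 0.9572 * (cos(ang) * ax + sin(ang) * perp)
      add_atom("OW", "SOL", resid, matrix(rep(ow, n_frames), ncol = 3, byrow = TRUE))
      add_atom("HW1", "SOL", resid, matrix(rep(h1, n_frames), ncol = 3, byrow = TRUE))
      add_atom("HW2", "SOL", resid, matrix(rep(h2, n_frames), ncol = 3, byrow = TRUE))
    }

    atoms <- do.call(rbind, rows)
    coords <- array(0, dim = c(atom_count, 3, n_frames))
    for (f in seq_len(n_frames))
      coords[, , f] <- do.call(rbind, frame_xyz[[f]])
    list(atoms = atoms, coords = coords, chain_ids = chain_ids)
  })

  traj <- md_trajectory(build$atoms, build$coords, box = box)
  attr(traj, "chain_topology") <- chain_topology(build$chain_ids)
  attr(traj, "ground_truth") <-
    ground_truth("trajectory",
                 list(n_chains = n_chains, chain_length = chain_length,
                      S_target = S_target, n_frames = n_frames,
                      n_solutes = n_solutes, solute_z = solute_z,
                      n_waters = n_waters, box = box, z_head = z_head),
                 seed)
  traj
}

#' Generate a minimal donor/acceptor configuration for hydrogen-bond tests
#'
#' `n_pairs` hydroxyl donors (O-H, residue "DON") each paired with one
#' acceptor oxygen (residue "ACC") at a stated donor-acceptor distance and
#' H-donor-acceptor angle; single frame.
#'
#' @param n_pairs number of donor/acceptor pairs.
#' @param distance donor-acceptor O...O distance, angstrom.
#' @param angle H-D-A angle in degrees.
#' @param box orthorhombic box lengths, angstrom.
#' @param seed RNG seed (pair placement and orientations).
#' @return an [md_trajectory()] with a `ground_truth` attribute.
#' @export
gen_hbond_config <- function(n_pairs = 10, distance = 2.8, angle = 5,
                             box = c(40, 40, 40), seed = 1L) {
  if (distance <= 0) stop_param("distance must be positive")
  if (angle < 0 || angle > 180) stop_param("angle must be in [0, 180] degrees")
  res <- with_seed(seed, {
    rows <- list(); xyz <- list(); rid <- 0L
    for (i in seq_len(n_pairs)) {
      d <- runif(3, 5, box - 5)
      ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
      a <- d + distance * ax
      perp <- rnorm(3); perp <- perp - sum(perp * ax) * ax
      perp <- perp / sqrt(sum(perp^2))
      th <- angle * pi / 180
      h <- d + 0.96 * (cos(th) * ax + sin(th) * perp)
      rid <- rid + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        name = c("OD", "HD"), resname = "DON", resid = rid)
      xyz[[length(xyz) + 1L]] <- rbind(d, h)
      rid <- rid + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        name = "OA", resname = "ACC", resid = rid)
      xyz[[length(xyz) + 1L]] <- rbind(a)
    }
    list(atoms = do.call(rbind, rows), xyz = do.call(rbind, xyz))
  })
  coords <- array(res$xyz, dim = c(nrow(res$atoms), 3, 1))
  traj <- md_trajectory(res$atoms, coords, box = box)
  attr(traj, "ground_truth") <-
    ground_truth("trajectory",
                 list(n_pairs = n_pairs, distance = distance, angle = angle,
                      box = box), seed)
  traj
}

#' Generate a multi-band Raman spectrum
#'
#' Sum of Gaussian bands (given by centre, area and SD width) plus a
#' polynomial baseline plus optional Gaussian noise.
#'
#' @param bands data.frame with columns `center` (1/cm), `area` (counts *
#'   1/cm) and `width` (Gaussian SD, 1/cm); may have zero rows.
#' @param baseline_coeffs polynomial baseline coefficients, lowest order
#'   first, evaluated in `(wavenumber - min(grid)) / 1000` to keep
#'   magnitudes tame.
#' @param noise_sigma additive Gaussian noise SD (counts).
#' @param grid wavenumber grid in 1/cm, strictly increasing.
#' @param seed RNG seed.
#' @param sample_label,replicate stored on the spectrum.
#' @return a [raman_spectrum()] with a `ground_truth` attribute.
#' @export
gen_raman_spectrum <- function(bands = data.frame(center = c(2937, 1453),
                                                  area = c(200, 100),
                                                  width = c(15, 10)),
                               baseline_coeffs = 0, noise_sigma = 0,
                               grid = seq(400, 3100, by = 1), seed = 1L,
                               sample_label = "", replicate = 1L) {
  check_strictly_increasing(grid, "wavenumber grid")
  if (nrow(bands) > 0) {
    if (any(bands$width <= 0)) stop_param("band widths must be positive")
    if (any(bands$center < min(grid) | bands$center > max(grid)))
      stop_param("band centers must lie inside the wavenumber grid")
  }
  x <- (grid - min(grid)) / 1000
  intensity <- as.numeric(outer(x, seq_along(baseline_coeffs) - 1, `^`) %*%
                            baseline_coeffs)
  if (nrow(bands) > 0) {
    for (i in seq_len(nrow(bands)))
      intensity <- intensity + bands$area[i] / (bands$width[i] * sqrt(2 * pi)) *
        exp(-(grid - bands$center[i])^2 / (2 * bands$width[i]^2))
  }
  if (noise_sigma > 0)
    intensity <- with_seed(seed,
                           intensity + rnorm(length(grid), 0, noise_sigma))
  out <- raman_spectrum(grid, intensity, sample_label = sample_label,
                        replicate = replicate)
  attr(out, "ground_truth") <-
    ground_truth("raman",
                 list(bands = bands, baseline_coeffs = baseline_coeffs,
                      noise_sigma = noise_sigma),
                 if (noise_sigma > 0) seed else NA_integer_)
  out
}
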