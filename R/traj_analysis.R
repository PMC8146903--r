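# Structural descriptors from bilayer trajectories: molecular order
# parameter profiles with block-averaged errors, geometric hydrogen-bond
# census, mass-density profiles along the normal, radial distribution
# functions, and solute depth traces.

# Minimum-image displacement for orthorhombic boxes.
.min_image <- function(d, box) d - round(d / box) * box

.resolve_selection <- function(traj, sel) {
  if (is.numeric(sel)) return(as.integer(sel))
  if (is.list(sel)) return(do.call(select_atoms, c(list(traj), sel)))
  stop_param("selection must be atom indices or a list of select_atoms() filters")
}

.resolve_frames <- function(traj, frame_range) {
  nf <- n_frames(traj)
  if (is.null(frame_range)) return(seq_len(nf))
  fr <- as.integer(frame_range)
  if (length(fr) == 2L && fr[2] >= fr[1]) fr <- fr[1]:fr[2]
  if (any(fr < 1L | fr > nf)) stop_param("frame range outside 1..%d", nf)
  fr
}

# Frames making up the analysis window: by default the final 40% of the
# trajectory, treating the earlier part as equilibration.
production_frames <- function(traj, fraction = 0.4) {
  nf <- n_frames(traj)
  start <- max(1L, nf - ceiling(fraction * nf) + 1L)
  start:nf
}

#' Bilayer midplane position per frame
#'
#' Mean z-coordinate of the lipid phosphorus atoms (the standard midplane
#' proxy for a symmetric bilayer).
#'
#' @param traj an [md_trajectory()].
#' @param phosphorus_sel selection of phosphorus atoms; default all element-P
#'   atoms.
#' @return numeric vector, one midplane z (angstrom) per frame.
#' @export
midplane_z <- function(traj, phosphorus_sel = NULL) {
  idx <- if (is.null(phosphorus_sel)) select_atoms(traj, element = "P")
         else .resolve_selection(traj, phosphorus_sel)
  if (length(idx) == 0L)
    stop_param("no phosphorus atoms found to define the midplane")
  apply(traj$coords[idx, 3, , drop = FALSE], 3, mean)
}

#' Molecular order parameter profile S_mol with block-averaged errors
#'
#' For each analysable carbon n (2..len-1) of each chain,
#' `S_mol(n) = < 0.5 (3 cos^2 theta_n - 1) >` where `theta_n` is the angle
#' between the segmental vector C(n-1) -> C(n+1) and the bilayer normal,
#' averaged over chains and frames.  Standard errors come from
#' non-overlapping block averaging over the frame axis (default 5 equal
#' blocks of the analysed range).  Carbons inside a declared double bond
#' are tagged `sp2` in the output so they can be excluded or remapped
#' downstream; the segmental vector itself is left unchanged.
#'
#' @param traj an [md_trajectory()].
#' @param topo a [chain_topology()]; defaults to the `chain_topology`
#'   attribute placed by [gen_bilayer_trajectory()].
#' @param normal bilayer normal axis, "x", "y" or "z".
#' @param frame_range frames to analyse (indices or c(first, last)); default
#'   the final 40% of the trajectory.
#' @param n_blocks number of error-analysis blocks.
#' @return data.frame with columns `carbon`, `S_mol`, `se`, `n_blocks`,
#'   `block_length`, `sp2`.
#' @export
smol_profile <- function(traj, topo = attr(traj, "chain_topology"),
                         normal = "z", frame_range = NULL, n_blocks = 5L) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (is.null(topo)) stop_param("no chain topology supplied")
  stopifnot(inherits(topo, "chain_topology"))
  ax <- match(match.arg(normal, c("x", "y", "z")), c("x", "y", "z"))
  frames <- if (is.null(frame_range)) production_frames(traj)
            else .resolve_frames(traj, frame_range)
  len <- length(topo$chains[[1]])
  if (any(vapply(topo$chains, length, 0L) != len))
    stop_param("all chains must have equal length")
  n_atoms <- nrow(traj$atoms)
  for (ch in topo$chains)
    if (any(ch < 1L | ch > n_atoms)) stop_param("chain atom id outside trajectory")
  sp2_carbons <- unique(unlist(topo$double_bonds))
  carbons <- 2:(len - 1L)
  # per (frame, segment): mean over chains of the instantaneous S
  per_frame <- array(NA_real_, dim = c(length(frames), length(carbons)))
  for (fi in seq_along(frames)) {
    xyz <- traj$coords[, , frames[fi]]
    for (si in seq_along(carbons)) {
      n <- carbons[si]
      s_vals <- vapply(topo$chains, function(ch) {
        v <- xyz[ch[n + 1L], ] - xyz[ch[n - 1L], ]
        ct2 <- v[ax]^2 / sum(v^2)
        0.5 * (3 * ct2 - 1)
      }, 0)
      per_frame[fi, si] <- mean(s_vals)
    }
  }
  s_mean <- colMeans(per_frame)
  # block averaging over frames
  nb <- min(n_blocks, length(frames))
  block_id <- cut(seq_along(frames), nb, labels = FALSE)
  se <- vapply(seq_along(carbons), function(si) {
    bm <- tapply(per_frame[, si], block_id, mean)
    if (nb > 1L) sd(bm) / sqrt(nb) else NA_real_
  }, 0)
  data.frame(carbon = carbons, S_mol = s_mean, se = se,
             n_blocks = nb,
             block_length = length(frames) / nb,
             sp2 = carbons %in% sp2_carbons)
}

#' Geometric hydrogen-bond criteria
#'
#' The default cutoffs (donor-acceptor distance <= 3.5 angstrom,
#' H-donor-acceptor angle <= 30 degrees) are the common geometric
#' definition for water-like hydrogen bonds.
#'
#' @param max_da_distance maximum donor-acceptor heavy-atom distance,
#'   angstrom.
#' @param max_hda_angle maximum H-donor-acceptor angle, degrees, in (0, 90].
#' @param dh_cutoff covalent D-H assignment cutoff, angstrom.
#' @return an `hbond_criteria` list.
#' @export
hbond_criteria <- function(max_da_distance = 3.5, max_hda_angle = 30,
                           dh_cutoff = 1.2) {
  if (max_da_distance <= 0) stop_param("distance cutoff must be positive")
  if (max_hda_angle <= 0 || max_hda_angle > 90)
    stop_param("angle cutoff must be in (0, 90] degrees")
  structure(list(max_da_distance = max_da_distance,
                 max_hda_angle = max_hda_angle,
                 dh_cutoff = dh_cutoff),
            class = "hbond_criteria")
}

# Map each donor-capable heavy atom (O, N) to its covalently attached
# hydrogens, using frame-1 geometry and same-residue membership.
.donor_hydrogens <- function(traj, criteria) {
  at <- traj$atoms
  xyz <- traj$coords[, , 1]
  heavies <- which(at$element %in% c("O", "N"))
  hyds <- which(at$element == "H")
  out <- vector("list", nrow(at))
  for (h in hyds) {
    cand <- heavies[at$resid[heavies] == at$resid[h]]
    if (length(cand) == 0L) next
    d2 <- colSums((t(xyz[cand, , drop = FALSE]) - xyz[h, ])^2)
    j <- cand[which.min(d2)]
    if (sqrt(min(d2)) <= criteria$dh_cutoff)
      out[[j]] <- c(out[[j]], h)
  }
  out
}

# Count hydrogen bonds donor-group -> acceptor-group in one frame.
.count_hbonds_frame <- function(xyz, box, donors, donor_h, acceptors, criteria) {
  count <- 0L
  cos_min <- cos(criteria$max_hda_angle * pi / 180)
  for (d in donors) {
    hs <- donor_h[[d]]
    if (is.null(hs)) next
    acc <- acceptors[acceptors != d]
    if (length(acc) == 0L) next
    dv <- .min_image(t(xyz[acc, , drop = FALSE]) - xyz[d, ], box)
    da <- sqrt(colSums(dv^2))
    near <- which(da <= criteria$max_da_distance & da > 1e-6)
    for (k in near) {
      a <- acc[k]
      for (h in hs) {
        dh <- .min_image(xyz[h, ] - xyz[d, ], box)
        cosang <- sum(dh * dv[, k]) / (sqrt(sum(dh^2)) * da[k])
        if (cosang >= cos_min) { count <- count + 1L; break }
      }
    }
  }
  count
}

#' Hydrogen-bond census between atom groups
#'
#' Counts, per frame and per group pair, hydrogen bonds satisfying the
#' geometric criteria (donor-acceptor distance and H-donor-acceptor angle).
#' Donors are O/N atoms of a group that carry covalent hydrogens; acceptors
#' are O/N atoms.  Both directions (donor in A / acceptor in B and vice
#' versa) are counted.  Results are reported as time mean and SD, divided
#' by `per_molecule` so a census over several solute copies can be
#' expressed per molecule.
#'
#' @param traj an [md_trajectory()].
#' @param groups named list of selections (atom indices or
#'   [select_atoms()] filter lists).
#' @param pairs list of length-2 character vectors naming the group pairs
#'   to tally.
#' @param criteria an [hbond_criteria()].
#' @param frame_range frames to analyse; default all.
#' @param per_molecule divisor applied to counts (e.g. number of solute
#'   molecules); default 1.
#' @return data.frame with columns `group_a`, `group_b`, `mean`, `sd`,
#'   `n_frames`.
#' @export
hbond_census <- function(traj, groups, pairs, criteria = hbond_criteria(),
                         frame_range = NULL, per_molecule = 1) {
  stopifnot(inherits(traj, "md_trajectory"), inherits(criteria, "hbond_criteria"))
  frames <- .resolve_frames(traj, frame_range)
  idx <- lapply(groups, .resolve_selection, traj = traj)
  for (nm in names(idx))
    if (length(idx[[nm]]) == 0L) stop_param("group '%s' selects no atoms", nm)
  donor_h <- .donor_hydrogens(traj, criteria)
  at <- traj$atoms
  res <- lapply(pairs, function(pr) {
    ia <- idx[[pr[1]]]; ib <- idx[[pr[2]]]
    don_a <- ia[at$element[ia] %in% c("O", "N") &
                  !vapply(donor_h[ia], is.null, TRUE)]
    don_b <- ib[at$element[ib] %in% c("O", "N") &
                  !vapply(donor_h[ib], is.null, TRUE)]
    acc_a <- ia[at$element[ia] %in% c("O", "N")]
    acc_b <- ib[at$element[ib] %in% c("O", "N")]
    counts <- vapply(frames, function(f) {
      xyz <- traj$coords[, , f]
      box <- traj$box[, f]
      .count_hbonds_frame(xyz, box, don_a, donor_h, acc_b, criteria) +
        .count_hbonds_frame(xyz, box, don_b, donor_h, acc_a, criteria)
    }, 0L)
    counts <- counts / per_molecule
    data.frame(group_a = pr[1], group_b = pr[2],
               mean = mean(counts), sd = sd(counts),
               n_frames = length(frames))
  })
  do.call(rbind, res)
}

#' Mass-density profile along the bilayer normal
#'
#' Per frame, atoms of each selection are binned by z relative to the
#' bilayer midplane (mean lipid-phosphorus z) and converted to mass density
#' in kg/m^3.  Bin widths are uniform; the z span covers one full box
#' length centred on the midplane, with atoms wrapped by periodicity.
#'
#' @param traj an [md_trajectory()].
#' @param selections named list of selections.
#' @param bin_width target bin width, angstrom (adjusted so bins tile the
#'   box exactly).
#' @param frame_range frames to analyse; default all.
#' @param center "midplane" (default) subtracts the phosphorus midplane;
#'   "box" uses the geometric box centre (for systems without lipids).
#' @return a `density_profile` data.frame: `z` (bin centres, angstrom) and
#'   one density column per selection; attributes `bin_width` and `area_A2`.
#' @export
mass_density_profile <- function(traj, selections, bin_width = 1,
                                 frame_range = NULL,
                                 center = c("midplane", "box")) {
  stopifnot(inherits(traj, "md_trajectory"))
  center <- match.arg(center)
  frames <- .resolve_frames(traj, frame_range)
  idx <- lapply(selections, .resolve_selection, traj = traj)
  lz <- traj$box[3, 1]
  area <- traj$box[1, 1] * traj$box[2, 1]
  if (area <= 0) stop_param("zero-area box")
  n_bins <- max(1L, round(lz / bin_width))
  bw <- lz / n_bins
  edges <- seq(-lz / 2, lz / 2, length.out = n_bins + 1L)
  mid <- if (center == "midplane") midplane_z(traj) else
    rep(lz / 2, n_frames(traj))
  out <- matrix(0, nrow = n_bins, ncol = length(idx),
                dimnames = list(NULL, names(idx)))
  for (f in frames) {
    z <- traj$coords[, 3, f] - mid[f]
    z <- z - round(z / lz) * lz            # wrap into [-lz/2, lz/2)
    z[z >= lz / 2] <- z[z >= lz / 2] - lz
    for (j in seq_along(idx)) {
      sel <- idx[[j]]
      bin <- pmin(pmax(floor((z[sel] + lz / 2) / bw) + 1L, 1L), n_bins)
      m <- tapply(traj$atoms$mass[sel], bin, sum)
      out[as.integer(names(m)), j] <- out[as.integer(names(m)), j] + m
    }
  }
  dens <- out / (area * bw * length(frames)) * AMU_PER_A3_TO_KG_PER_M3
  res <- data.frame(z = (edges[-1] + edges[-length(edges)]) / 2, dens,
                    check.names = FALSE)
  attr(res, "bin_width") <- bw
  attr(res, "area_A2") <- area
  class(res) <- c("density_profile", "data.frame")
  res
}

#' Radial distribution function between two selections
#'
#' Standard pair-distance histogram under the orthorhombic minimum-image
#' convention, normalised by the ideal-gas shell expectation, averaged over
#' frames.
#'
#' @param traj an [md_trajectory()].
#' @param reference,target selections (indices or filter lists).
#' @param r_max maximum distance, angstrom; must not exceed half the
#'   smallest box length.
#' @param bin_width histogram bin width, angstrom.
#' @param frame_range frames to analyse; default all.
#' @return an `rdf_result` data.frame with columns `r` (bin centres) and
#'   `g`; attribute `n_pairs` (histogram counts).
#' @export
rdf <- function(traj, reference, target, r_max, bin_width = 0.2,
                frame_range = NULL) {
  stopifnot(inherits(traj, "md_trajectory"))
  frames <- .resolve_frames(traj, frame_range)
  half_min <- min(traj$box) / 2
  if (r_max > half_min + 1e-9)
    stop_param("r_max %.2f exceeds half the smallest box length (%.2f A)",
               r_max, half_min)
  iref <- .resolve_selection(traj, reference)
  itgt <- .resolve_selection(traj, target)
  if (length(iref) == 0L || length(itgt) == 0L)
    stop_param("empty reference or target selection")
  n_bins <- ceiling(r_max / bin_width)
  edges <- seq(0, n_bins * bin_width, by = bin_width)
  counts <- numeric(n_bins)
  n_common <- length(intersect(iref, itgt))
  for (f in frames) {
    xyz <- traj$coords[, , f]
    box <- traj$box[, f]
    for (i in iref) {
      dv <- .min_image(t(xyz[itgt, , drop = FALSE]) - xyz[i, ], box)
      d <- sqrt(colSums(dv^2))
      d <- d[d > 1e-9 & d < edges[n_bins + 1L]]
      if (length(d) == 0L) next
      h <- tabulate(floor(d / bin_width) + 1L, nbins = n_bins)
      counts <- counts + h
    }
  }
  vol <- prod(traj$box[, 1])
  n_pairs <- length(iref) * length(itgt) - n_common
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-(n_bins + 1L)]^3)
  ideal <- n_pairs / vol * shell * length(frames)
  structure(data.frame(r = (edges[-1] + edges[-(n_bins + 1L)]) / 2,
                       g = counts / ideal),
            n_pairs = counts,
            class = c("rdf_result", "data.frame"))
}

#' Solute depth traces and residency classification
#'
#' Per-frame centre-of-mass z of each solute residue relative to the
#' bilayer midplane, with residency classes: core (|z| < `core_z`),
#' interphase (`core_z` <= |z| < `water_z`), water phase otherwise.
#'
#' @param traj an [md_trajectory()].
#' @param solute selection of solute atoms (indices or filter list); default
#'   residue name "TUD".
#' @param core_z,water_z residency thresholds in angstrom.
#' @return data.frame with columns `resid`, `frame`, `z`, `residency`, plus
#'   a `summary` attribute with the per-solute majority class.
#' @export
solute_z_traces <- function(traj, solute = list(resname = "TUD"),
                            core_z = 8, water_z = 24) {
  stopifnot(inherits(traj, "md_trajectory"))
  idx <- .resolve_selection(traj, solute)
  if (length(idx) == 0L) stop_param("empty solute selection")
  mid <- midplane_z(traj)
  rid <- traj$atoms$resid[idx]
  nf <- n_frames(traj)
  res <- list()
  for (r in unique(rid)) {
    ai <- idx[rid == r]
    w <- traj$atoms$mass[ai]
    z <- vapply(seq_len(nf), function(f)
      sum(traj$coords[ai, 3, f] * w) / sum(w) - mid[f], 0)
    residency <- ifelse(abs(z) < core_z, "core",
                        ifelse(abs(z) < water_z, "interphase", "water"))
    res[[length(res) + 1L]] <- data.frame(resid = r, frame = seq_len(nf),
                                          z = z, residency = residency)
  }
  out <- do.call(rbind, res)
  maj <- vapply(split(out$residency, out$resid),
                function(x) names(sort(table(x), decreasing = TRUE))[1], "")
  attr(out, "summary") <- data.frame(resid = as.integer(names(maj)),
                                     residency = unname(maj))
  out
}
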