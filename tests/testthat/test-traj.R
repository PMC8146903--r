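# Direct-averaging oracle: plain loops over the segmental vectors.
smol_oracle <- function(traj, topo, frames) {
  vals <- list()
  len <- length(topo$chains[[1]])
  for (n in 2:(len - 1)) {
    acc <- c()
    for (f in frames) {
      for (ch in topo$chains) {
        v <- traj$coords[ch[n + 1], , f] - traj$coords[ch[n - 1], , f]
        ct <- v[3] / sqrt(sum(v^2))
        acc <- c(acc, 0.5 * (3 * ct^2 - 1))
      }
    }
    vals[[n - 1]] <- mean(acc)
  }
  unlist(vals)
}

test_that("S_mol hits the analytic limits for all-trans and perpendicular chains", {
  up <- gen_bilayer_trajectory(n_chains = 4, chain_length = 8, S_target = 1,
                               n_frames = 2, n_solutes = 0, n_waters = 0,
                               seed = 1)
  prof <- smol_profile(up, frame_range = c(1, 2))
  expect_equal(prof$S_mol, rep(1, 6), tolerance = 1e-12)
  flat <- gen_bilayer_trajectory(n_chains = 4, chain_length = 8,
                                 S_target = -0.5, n_frames = 2,
                                 n_solutes = 0, n_waters = 0, seed = 1)
  prof2 <- smol_profile(flat, frame_range = c(1, 2))
  expect_equal(prof2$S_mol, rep(-0.5, 6), tolerance = 1e-12)
})

test_that("S_mol estimator matches the direct-averaging oracle and recovers 0.4", {
  traj <- gen_bilayer_trajectory(n_chains = 20, chain_length = 12,
                                 S_target = 0.4, n_frames = 50,
                                 n_solutes = 0, n_waters = 0, seed = 7)
  topo <- attr(traj, "chain_topology")
  prof <- smol_profile(traj, frame_range = c(1, 50))
  oracle <- smol_oracle(traj, topo, 1:50)
  expect_equal(prof$S_mol, oracle, tolerance = 1e-10)
  # 20 chains x 10 segments x 50 frames = 1e4 segment samples
  expect_true(all(abs(prof$S_mol - 0.4) < 3 * prof$se))
  expect_true(all(prof$S_mol >= -0.5 & prof$S_mol <= 1))
  expect_true(all(prof$se > 0))
})

test_that("S_mol is invariant under rotation about the normal and frame order", {
  traj <- gen_bilayer_trajectory(n_chains = 6, chain_length = 8,
                                 S_target = 0.3, n_frames = 10,
                                 n_solutes = 0, n_waters = 0, seed = 3)
  prof <- smol_profile(traj, frame_range = c(1, 10))
  th <- 0.83
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- traj
  for (f in 1:10) rot$coords[, , f] <- traj$coords[, , f] %*% R
  prof_rot <- smol_profile(rot, topo = attr(traj, "chain_topology"),
                           frame_range = c(1, 10))
  expect_equal(prof$S_mol, prof_rot$S_mol, tolerance = 1e-10)
  perm <- traj
  ord <- rev(1:10)
  perm$coords <- traj$coords[, , ord]
  prof_perm <- smol_profile(perm, topo = attr(traj, "chain_topology"),
                            frame_range = c(1, 10))
  expect_equal(sort(prof$S_mol), sort(prof_perm$S_mol), tolerance = 1e-10)
})

test_that("sp2-tagged carbons are marked for declared double bonds", {
  traj <- gen_bilayer_trajectory(n_chains = 2, chain_length = 12,
                                 S_target = 0.4, n_frames = 2,
                                 n_solutes = 0, n_waters = 0, seed = 2)
  topo <- attr(traj, "chain_topology")
  topo9 <- chain_topology(topo$chains, double_bonds = list(c(9, 10)))
  prof <- smol_profile(traj, topo = topo9, frame_range = c(1, 2))
  expect_identical(prof$sp2, prof$carbon %in% c(9, 10))
})

test_that("hydrogen-bond counting honours distance and angle cutoffs", {
  near <- gen_hbond_config(n_pairs = 1, distance = 2.8, angle = 5, seed = 1)
  cen <- hbond_census(near, groups = list(d = list(resname = "DON"),
                                          a = list(resname = "ACC")),
                      pairs = list(c("d", "a")))
  expect_equal(cen$mean, 1)
  far <- gen_hbond_config(n_pairs = 1, distance = 4.0, angle = 5, seed = 1)
  cen2 <- hbond_census(far, groups = list(d = list(resname = "DON"),
                                          a = list(resname = "ACC")),
                       pairs = list(c("d", "a")))
  expect_equal(cen2$mean, 0)
  bent <- gen_hbond_config(n_pairs = 1, distance = 2.8, angle = 60, seed = 1)
  cen3 <- hbond_census(bent, groups = list(d = list(resname = "DON"),
                                           a = list(resname = "ACC")),
                       pairs = list(c("d", "a")))
  expect_equal(cen3$mean, 0)
})

test_that("census equals an exhaustive O(N^2) pair-enumeration oracle", {
  traj <- gen_bilayer_trajectory(n_chains = 2, chain_length = 6,
                                 S_target = 0.4, n_frames = 1,
                                 n_solutes = 4, n_waters = 40, seed = 9,
                                 box = c(30, 30, 70))
  crit <- hbond_criteria()
  groups <- list(tud = list(resname = "TUD"), water = list(resname = "SOL"))
  cen <- hbond_census(traj, groups, pairs = list(c("tud", "water")), crit)

  # oracle: enumerate every donor-H / acceptor combination with plain loops
  at <- traj$atoms; xyz <- traj$coords[, , 1]; box <- traj$box[, 1]
  mi <- function(d) d - round(d / box) * box
  donors_of <- function(res) which(at$resname == res & at$element %in% c("O", "N"))
  hyd <- which(at$element == "H")
  n_bonds <- 0L
  for (dir in list(c("TUD", "SOL"), c("SOL", "TUD"))) {
    for (d in donors_of(dir[1])) {
      hs <- c()
      for (h in hyd[at$resid[hyd] == at$resid[d]]) {
        if (sqrt(sum((xyz[h, ] - xyz[d, ])^2)) <= crit$dh_cutoff) hs <- c(hs, h)
      }
      if (length(hs) == 0) next
      for (a in donors_of(dir[2])) {
        dv <- mi(xyz[a, ] - xyz[d, ])
        da <- sqrt(sum(dv^2))
        if (da > crit$max_da_distance || da < 1e-6) next
        for (h in hs) {
          hv <- mi(xyz[h, ] - xyz[d, ])
          ang <- acos(sum(hv * dv) / (sqrt(sum(hv^2)) * da)) * 180 / pi
          if (ang <= crit$max_hda_angle) { n_bonds <- n_bonds + 1L; break }
        }
      }
    }
  }
  expect_equal(cen$mean, n_bonds)
})

test_that("census is invariant to atom-order permutation and integer per frame", {
  traj <- gen_hbond_config(n_pairs = 8, distance = 3.0, angle = 20, seed = 4)
  groups <- list(d = list(resname = "DON"), a = list(resname = "ACC"))
  cen <- hbond_census(traj, groups, pairs = list(c("d", "a")))
  expect_equal(cen$mean, round(cen$mean))
  perm <- sample(nrow(traj$atoms))
  traj2 <- md_trajectory(traj$atoms[perm, ],
                         traj$coords[perm, , , drop = FALSE], traj$box)
  cen2 <- hbond_census(traj2, groups, pairs = list(c("d", "a")))
  expect_equal(cen$mean, cen2$mean)
})

test_that("density profile conserves mass and respects slab support", {
  # uniform single-atom gas, no lipids: use box centring
  set.seed(5)
  n <- 400
  atoms <- data.frame(name = "AR", resname = "GAS", resid = seq_len(n),
                      element = "C", mass = 18)
  coords <- array(runif(n * 3 * 2, 0, 30), dim = c(n, 3, 2))
  traj <- md_trajectory(atoms, coords, box = c(30, 30, 30))
  dp <- mass_density_profile(traj, list(gas = seq_len(n)), bin_width = 3,
                             center = "box")
  bulk <- n * 18 / 30^3 * 1660.539
  expect_true(all(abs(dp$gas - bulk) / bulk < 0.25))
  # conservation: sum over bins of rho * bin volume = total mass (exact)
  total <- sum(dp$gas) * attr(dp, "bin_width") * attr(dp, "area_A2") / 1660.539
  expect_equal(total, n * 18, tolerance = 1e-10)
  # slab: atoms confined to |z - 15| < 5 leave outer bins empty
  coords2 <- coords
  coords2[, 3, ] <- runif(n * 2, 10, 20)
  slab <- md_trajectory(atoms, coords2, box = c(30, 30, 30))
  dps <- mass_density_profile(slab, list(gas = seq_len(n)), bin_width = 1,
                              center = "box")
  expect_true(all(dps$gas[abs(dps$z) > 6] == 0))
})

test_that("RDF matches a brute-force oracle and the ideal-gas limit", {
  set.seed(11)
  n <- 250
  atoms <- data.frame(name = "X", resname = "GAS", resid = seq_len(n),
                      element = "C", mass = 1)
  coords <- array(runif(n * 3 * 4, 0, 25), dim = c(n, 3, 4))
  traj <- md_trajectory(atoms, coords, box = c(25, 25, 25))
  res <- rdf(traj, seq_len(n), seq_len(n), r_max = 10, bin_width = 0.5)
  # brute force, same bins
  counts <- numeric(20)
  for (f in 1:4) {
    for (i in 1:n) for (j in 1:n) {
      if (i == j) next
      d <- coords[i, , f] - coords[j, , f]
      d <- d - round(d / 25) * 25
      r <- sqrt(sum(d^2))
      if (r < 10) counts[floor(r / 0.5) + 1] <- counts[floor(r / 0.5) + 1] + 1
    }
  }
  expect_equal(attr(res, "n_pairs"), counts)
  # ideal-gas plateau beyond the first bins
  expect_true(all(abs(res$g[res$r > 2] - 1) < 0.1))
})

test_that("RDF first peak of a simple-cubic lattice sits at the spacing", {
  a <- 5
  g <- expand.grid(x = 0:4, y = 0:4, z = 0:4) * a
  n <- nrow(g)
  atoms <- data.frame(name = "X", resname = "LAT", resid = seq_len(n),
                      element = "C", mass = 1)
  coords <- array(unlist(g), dim = c(n, 3, 1))
  traj <- md_trajectory(atoms, coords, box = c(25, 25, 25))
  res <- rdf(traj, seq_len(n), seq_len(n), r_max = 12, bin_width = 0.5)
  first <- which(res$g > 0)[1]
  expect_true(res$r[first] - 0.25 <= a && a <= res$r[first] + 0.25)
  expect_error(rdf(traj, 1:n, 1:n, r_max = 20), "half the smallest")
})

test_that("solute depth traces are midplane-relative and mirror-antisymmetric", {
  traj <- gen_bilayer_trajectory(n_chains = 8, chain_length = 8,
                                 S_target = 0.5, n_frames = 3,
                                 n_solutes = 1, solute_z = 15,
                                 n_waters = 0, seed = 6)
  zt <- solute_z_traces(traj)
  # midplane oracle: mean phosphorus z, computed independently
  p_idx <- which(traj$atoms$name == "P")
  mid_oracle <- vapply(1:3, function(f) mean(traj$coords[p_idx, 3, f]), 0)
  expect_equal(midplane_z(traj), mid_oracle, tolerance = 1e-12)
  # solute is static: the mass-weighted COM z is constant across frames
  t_idx <- which(traj$atoms$resname == "TUD")
  com_z <- sum(traj$coords[t_idx, 3, 1] * traj$atoms$mass[t_idx]) /
    sum(traj$atoms$mass[t_idx])
  expect_equal(zt$z, rep(com_z, 3) - mid_oracle, tolerance = 1e-9)
  # mirrored system: z -> -z negates the trace
  mir <- traj
  mir$coords[, 3, ] <- -mir$coords[, 3, ]
  ztm <- solute_z_traces(mir)
  expect_equal(ztm$z, -zt$z, tolerance = 1e-9)
  expect_equal(attr(zt, "summary")$residency, "interphase")
})

test_that("trajectory containers validate their invariants", {
  atoms <- data.frame(name = c("C1", "C2"), resname = "LIP", resid = 1)
  expect_error(md_trajectory(atoms, array(0, c(3, 3, 1)), c(10, 10, 10)),
               "n_atoms")
  expect_error(md_trajectory(atoms, array(0, c(2, 3, 1)), c(0, 10, 10)),
               "positive")
  expect_error(chain_topology(list(c(1, 2))), ">= 3 carbons")
  expect_error(chain_topology(list(1:5), double_bonds = list(c(2, 5))),
               "adjacent")
  expect_error(gen_bilayer_trajectory(S_target = 1.2), "\\[-0.5, 1\\]")
})
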