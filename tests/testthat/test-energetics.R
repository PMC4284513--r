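test_that("switching factor matches the CHARMM polynomial and its knots", {
  sch <- nonbonded_scheme()
  expect_equal(switching_factor(7.9, sch), 1)
  expect_equal(switching_factor(11.0, sch), 0)
  ## direct evaluation of the polynomial at r = 9.5
  r <- 9.5; s <- 8; cc <- 11
  expect_equal(switching_factor(r, sch),
               (cc^2 - r^2)^2 * (cc^2 + 2 * r^2 - 3 * s^2) / (cc^2 - s^2)^3)
  ## continuity of value and first derivative at both knots
  h <- 1e-7
  for (knot in c(8, 11)) {
    expect_equal(switching_factor(knot - h, sch), switching_factor(knot + h, sch),
                 tolerance = 1e-5)
    d_in <- (switching_factor(knot - h, sch) - switching_factor(knot - 2 * h, sch)) / h
    d_out <- (switching_factor(knot + 2 * h, sch) - switching_factor(knot + h, sch)) / h
    expect_equal(d_in, d_out, tolerance = 1e-4)
  }
})

test_that("pair energies recover the LJ minimum and bare Coulomb arithmetic", {
  sch <- nonbonded_scheme()
  ## at r = rmin (inside the plateau) the vdW term is exactly -eps
  pe <- pair_energy(3.7, qi = 0, qj = 0, eps_ij = 0.25, rmin_ij = 3.7, sch)
  expect_equal(pe$e_vdw, -0.25)
  ## unit charges at 3.2 Angstrom
  pe2 <- pair_energy(3.2, 1, 1, eps_ij = 0, rmin_ij = 3.5, sch)
  expect_equal(pe2$e_elec, 332.0636 / 3.2)
  ## beyond the cutoff everything is zero
  pe3 <- pair_energy(11.5, 1, -1, eps_ij = 0.2, rmin_ij = 3.5, sch)
  expect_equal(c(pe3$e_vdw, pe3$e_elec), c(0, 0))
  expect_error(pair_energy(0, 1, 1, 0.1, 3), "r must be > 0")
})

test_that("the switched total energy is continuous across the taper", {
  sch <- nonbonded_scheme()
  r <- seq(7.9, 11.1, by = 0.001)
  pe <- pair_energy(r, 1, -1, eps_ij = 0.2, rmin_ij = 3.6, sch)
  tot <- pe$e_vdw + pe$e_elec
  jumps <- abs(diff(tot))
  ## continuity: jumps bounded by grid * max|dE/dr| (~ 20 kcal/mol/A here),
  ## and halving the grid halves the max jump
  expect_lt(max(jumps), 0.025)
  r_fine <- seq(7.9, 11.1, by = 0.0005)
  pef <- pair_energy(r_fine, 1, -1, eps_ij = 0.2, rmin_ij = 3.6, sch)
  expect_lt(max(abs(diff(pef$e_vdw + pef$e_elec))), 0.6 * max(jumps))
  ## like charges inside switch_on: positive and monotonically decreasing
  r2 <- seq(2, 7.9, by = 0.01)
  ee <- pair_energy(r2, 1, 1, 0, 3, sch)$e_elec
  expect_true(all(ee > 0) && all(diff(ee) < 0))
})

test_that("group energies equal the exhaustive pairwise oracle", {
  sch <- nonbonded_scheme()
  ## two unit charges 5 Angstrom apart, no LJ
  topo <- topology(data.frame(name = c("A", "B"), residue_number = 1:2,
                              residue_name = "UNK", subunit = "A",
                              charge = c(1, 1), lj_epsilon = 0,
                              lj_rmin_half = 1))
  coords <- rbind(c(0, 0, 0), c(0, 0, 5))
  ge <- group_energy(coords, c(50, 50, 50), topo, 1, 2, sch)
  expect_equal(unname(ge), c(0, 332.0636 / 5, 332.0636 / 5))
  ## random systems vs brute force
  for (seed in 1:10) {
    rs <- random_system(20, box = 30, seed = seed)
    ga <- 1:10; gb <- 11:20
    got <- group_energy(rs$coords, rs$box, rs$topo, ga, gb, sch)
    want <- brute_group_energy(rs$coords, rs$box, rs$topo, ga, gb, sch)
    expect_equal(got, want, tolerance = 1e-10)
  }
  ## all pairs beyond the cutoff
  coords_far <- rbind(c(0, 0, 0), c(0, 0, 20))
  ge0 <- group_energy(coords_far, c(60, 60, 60), topo, 1, 2, sch)
  expect_equal(unname(ge0), c(0, 0, 0))
  expect_error(group_energy(coords, c(50, 50, 50), topo, 1:2, 2, sch),
               "overlap")
})

test_that("per-residue decomposition conserves the group total each frame", {
  sys <- gen_region_system(n_frames = 12, seed = 3)
  dec <- per_residue_decomposition(sys$trajectory, sys$topology)
  expect_equal(sum(dec$profile_a$e_total), unname(dec$group["e_total"]),
               tolerance = 1e-9)
  expect_equal(sum(dec$profile_b$e_total), unname(dec$group["e_total"]),
               tolerance = 1e-9)
  expect_equal(dec$profile_a$e_total,
               dec$profile_a$e_vdw + dec$profile_a$e_elec, tolerance = 1e-12)
  ## frame-by-frame conservation against single-frame decompositions
  for (f in c(1, 7)) {
    d1 <- per_residue_decomposition(sys$trajectory, sys$topology, frames = f,
                                    n_blocks = 1)
    expect_equal(sum(d1$profile_a$e_total), d1$per_frame_total[1],
                 tolerance = 1e-9)
    expect_equal(sum(d1$profile_b$e_total), d1$per_frame_total[1],
                 tolerance = 1e-9)
  }
})

test_that("like-charged residue pairs contribute repulsively, opposite attract", {
  mk <- function(qa, qb) {
    topo <- topology(data.frame(
      name = "CA", residue_number = c(250, 350),
      residue_name = "GLY", subunit = "A",
      charge = c(qa, qb), lj_epsilon = 0.05, lj_rmin_half = 2))
    traj <- trajectory(rbind(c(0, 0, 0), c(5, 0, 0)), box = c(60, 60, 60))
    per_residue_decomposition(traj, topo, regionA = c(240, 260),
                              regionB = c(340, 360), n_blocks = 1)
  }
  rep_case <- mk(1, 1)
  expect_gt(rep_case$profile_a$e_total, 0)
  expect_gt(rep_case$profile_b$e_total, 0)
  att_case <- mk(1, -1)
  expect_lt(att_case$profile_a$e_total, 0)
})

test_that("decomposition refuses unparameterized atoms, naming them", {
  topo <- topology(data.frame(
    name = c("CA", "CA"), residue_number = c(250, 350),
    residue_name = c("ARG", "LYS"), subunit = "A",
    charge = c(1, NA), lj_epsilon = c(0.1, NA), lj_rmin_half = c(2, NA)))
  traj <- trajectory(rbind(c(0, 0, 0), c(5, 0, 0)), box = c(60, 60, 60))
  expect_error(per_residue_decomposition(traj, topo, c(240, 260), c(340, 360)),
               "LYS350")
})

test_that("block errors use consecutive near-equal blocks", {
  ## hand-computed: block means 1..5, population SD
  x <- c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5)
  expect_equal(block_error(x, 5), sqrt(mean((1:5 - 3)^2)))
  expect_equal(block_error(rep(7, 20), 5), 0)
  ## permuting frames within blocks leaves the SE unchanged
  xp <- c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5)[c(2, 1, 4, 3, 5, 6, 8, 7, 10, 9)]
  expect_equal(block_error(xp, 5), block_error(x, 5))
  expect_error(block_error(1:3, 5), "fewer frames")
})

test_that("bridge-frame exclusion removes exactly the bridged frames", {
  ## an ARG and a GLU whose side chains oscillate across the 3.2 cutoff
  topo <- topology(data.frame(
    name = c("NE", "NH1", "NH2", "OE1", "OE2"),
    residue_number = c(249, 249, 249, 358, 358),
    residue_name = c("ARG", "ARG", "ARG", "GLU", "GLU"),
    subunit = "A", stringsAsFactors = FALSE))
  nf <- 6
  coords <- array(0, c(nf, 5, 3))
  coords[, 2, 1] <- 1; coords[, 3, 1] <- -1      # static N positions
  gap <- ifelse(seq_len(nf) %% 2 == 0, 2.8, 6)   # alternating contact
  coords[, 4, 3] <- gap; coords[, 5, 3] <- gap + 1
  traj <- trajectory(coords, box = c(50, 50, 50))
  occ <- residue_pair_occupancy(traj, topo, "A:249", "A:358")
  expect_equal(occ, seq_len(nf) %% 2 == 0)
  expect_equal(exclude_bridge_frames(traj, topo, "A:249", "A:358"),
               which(seq_len(nf) %% 2 == 1))
  ## all-bridged -> empty; never-bridged -> all frames
  coords[, 4, 3] <- 2.5; coords[, 5, 3] <- 3.0
  expect_length(exclude_bridge_frames(trajectory(coords, box = c(50, 50, 50)),
                                      topo, "A:249", "A:358"), 0)
  coords[, 4, 3] <- 9; coords[, 5, 3] <- 10
  expect_equal(exclude_bridge_frames(trajectory(coords, box = c(50, 50, 50)),
                                     topo, "A:249", "A:358"), 1:nf)
  ## two basic residues cannot define an acid-base bridge
  expect_error(residue_pair_occupancy(traj, topo, "A:249", "A:249"),
               "basic and one acidic")
})
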