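test_that("generators are bit-reproducible for a fixed seed", {
  s1 <- gen_toy_trajectory(toy_system_spec(n_subunits = 1, n_frames = 20, seed = 6))
  s2 <- gen_toy_trajectory(toy_system_spec(n_subunits = 1, n_frames = 20, seed = 6))
  expect_identical(s1$trajectory$coords, s2$trajectory$coords)
  g1 <- gen_gating_curve(seed = 3); g2 <- gen_gating_curve(seed = 3)
  expect_identical(g1$curve$response, g2$curve$response)
  a1 <- gen_synthetic_alignment(seed = 2); a2 <- gen_synthetic_alignment(seed = 2)
  expect_identical(a1$sequences, a2$sequences)
  ## and the generator does not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(gen_toy_trajectory(toy_system_spec(n_subunits = 1,
                                                             n_frames = 2,
                                                             seed = 1)))
  expect_identical(runif(1), before)
})

test_that("degenerate contact probabilities are realized exactly", {
  spec <- toy_system_spec(n_subunits = 1, n_frames = 30, seed = 8)
  p <- spec$p_star; p[] <- 0
  sys0 <- gen_toy_trajectory(toy_system_spec(n_subunits = 1, n_frames = 30,
                                             seed = 8, p_star = p))
  cs0 <- detect_bridges(sys0$trajectory, sys0$topology)
  expect_false(any(cs0$occupancy))
  p[] <- 1
  sys1 <- gen_toy_trajectory(toy_system_spec(n_subunits = 1, n_frames = 30,
                                             seed = 8, p_star = p))
  cs1 <- detect_bridges(sys1$trajectory, sys1$topology)
  expect_true(all(cs1$occupancy[, , 1]))
})

test_that("generated systems satisfy the topology/trajectory invariants and round-trip", {
  spec <- toy_system_spec(n_subunits = 2, n_frames = 5, seed = 3)
  sys <- gen_toy_trajectory(spec)
  expect_silent(kvcoupling:::validate_topology(sys$topology))
  expect_equal(sys$trajectory$n_atoms, nrow(sys$topology$atoms))
  expect_true(all(sys$trajectory$box > 2 * 3.2))
  f <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(sys$trajectory, f, sys$topology)
  back <- read_trajectory(f, topology = sys$topology)
  expect_equal(back$coords, sys$trajectory$coords, tolerance = 1e-6)
})

test_that("contact distances fall strictly inside the prescribed bands", {
  spec <- toy_system_spec(n_subunits = 1, n_frames = 50, seed = 12)
  sys <- gen_toy_trajectory(spec)
  topo <- sys$topology; traj <- sys$trajectory
  don <- topo$selections$basic_nitrogens
  acc <- topo$selections$pip2_phosphate_oxygens
  a <- topo$atoms
  ## distance between each residue bead and its own pair bead
  rk <- paste0(a$subunit[don], ":", a$residue_number[don])
  for (f in c(1, 25, 50)) {
    for (i in seq_along(don)) {
      ## pair bead order matches residue order within the lipid block
      d <- sqrt(sum((traj$coords[f, don[i], ] - traj$coords[f, acc[i], ])^2))
      expect_true((d >= 2.6 & d <= 3.19) || (d >= 5 & d <= 12))
    }
  }
})

test_that("the Markov dwell model preserves the stationary contact probability", {
  spec <- toy_system_spec(n_subunits = 1, n_frames = 4000, seed = 21,
                          dwell_frames = 10)
  sys <- gen_toy_trajectory(spec)
  cs <- detect_bridges(sys$trajectory, sys$topology)
  tab <- formation_probability(cs, pool_subunits = FALSE)
  targets <- sys$p_star[tab$residue_key, 1]
  ## correlated frames: allow a generous multiple of the iid binomial SE
  se <- sqrt(pmax(targets * (1 - targets), 1e-12) / 4000)
  expect_true(all(abs(tab$probability - targets) <= 10 * se + 0.01))
})

test_that("two-condition systems carry their prescribed differences", {
  spec <- toy_system_spec(n_subunits = 2, n_frames = 300, seed = 30)
  pair <- gen_two_condition_system(spec, delta_p = c("354" = 0.34),
                                   displacement = 2, axis = c(0, 0, 1))
  ## probability delta recovered and flagged for the targeted residue only
  ta <- formation_probability(detect_bridges(pair$system_a$trajectory,
                                             pair$system_a$topology))
  tb <- formation_probability(detect_bridges(pair$system_b$trajectory,
                                             pair$system_b$topology))
  ta$sd <- 0.08   # representative WT run-to-run spread for the flag rule
  cmp <- compare_probability_tables(ta, tb)
  expect_equal(cmp$delta[cmp$residue_key == "354"], 0.34, tolerance = 0.1)
  expect_true(cmp$significant[cmp$residue_key == "354"])
  expect_false(any(cmp$significant[cmp$residue_key != "354"]))
  ## headgroup displacement recovered along the axis
  pa <- headgroup_positions(pair$system_a$trajectory, pair$system_a$topology)
  pb <- headgroup_positions(pair$system_b$trajectory, pair$system_b$topology)
  sh <- headgroup_shift(pa, pb, pair$truth$axis_from, pair$truth$axis_to)
  expect_equal(sh$mean, 2, tolerance = 0.1)
  ## zero-difference spec: no flags, shift about zero
  pair0 <- gen_two_condition_system(spec)
  t0a <- formation_probability(detect_bridges(pair0$system_a$trajectory,
                                              pair0$system_a$topology))
  t0b <- formation_probability(detect_bridges(pair0$system_b$trajectory,
                                              pair0$system_b$topology))
  t0a$sd <- 0.08
  cmp0 <- compare_probability_tables(t0a, t0b)
  expect_false(any(cmp0$significant))
  p0a <- headgroup_positions(pair0$system_a$trajectory, pair0$system_a$topology)
  p0b <- headgroup_positions(pair0$system_b$trajectory, pair0$system_b$topology)
  expect_lt(abs(headgroup_shift(p0a, p0b, c(0, 0, 0), c(0, 0, 1))$mean), 0.2)
  expect_error(gen_two_condition_system(spec, delta_p = c("999" = 0.1)),
               "not in residue set")
})

test_that("synthetic gating curves honour their spec", {
  ## zero noise reproduces the exact Boltzmann values
  g <- gen_gating_curve(v_half = -20, z = 2, noise_sd = 0, seed = 1)
  expect_equal(g$curve$response,
               boltzmann(g$curve$voltages, -20, 2), tolerance = 1e-12)
  ## a -30 mV shift between two specs is recovered by the fitted shift
  ga <- gen_gating_curve(v_half = -20, z = 2, noise_sd = 0.01, seed = 2)
  gb <- gen_gating_curve(v_half = -50, z = 2, noise_sd = 0.01, seed = 3)
  sh <- curve_shift(fit_boltzmann(ga$curve), fit_boltzmann(gb$curve))
  expect_equal(sh$delta_v_half, -30, tolerance = 2)
  ## clipping bounds
  gc <- gen_gating_curve(noise_sd = 0.5, seed = 4)
  expect_true(all(gc$curve$response >= -0.2 & gc$curve$response <= 1.2))
})

test_that("synthetic fluorescence traces expose their ground truth", {
  g <- gen_fluorescence_trace(baseline_intercept = 10, baseline_slope = 0,
                              pulse_amplitude = 1)
  inp <- g$trace$times >= 2
  expect_equal(unique(g$truth$dff[inp]), 0.1)
  expect_error(gen_fluorescence_trace(baseline_intercept = 0.5,
                                      baseline_slope = -1),
               "crosses zero")
})

test_that("the synthetic alignment realizes its prescribed identity structure", {
  aln <- gen_synthetic_alignment()
  expect_equal(as.numeric(percent_identity(aln, "PD")), 36)
  expect_equal(as.numeric(percent_identity(aln, "VSD",
                                           exclude = "S2-S3 loop")), 25)
  ## the reference is gapped inside the loop, nowhere else
  s1 <- strsplit(aln$sequences[[1]], "")[[1]]
  gaps <- which(s1 == "-")
  expect_true(all(gaps >= 61 & gaps <= 110))
  expect_length(gaps, 30)
  ## other identity targets are honoured too
  aln2 <- gen_synthetic_alignment(pd_identity = 0.5, vsd_identity = 0.1,
                                  seed = 5)
  expect_equal(as.numeric(percent_identity(aln2, "PD")), 50)
  expect_equal(as.numeric(percent_identity(aln2, "VSD",
                                           exclude = "S2-S3 loop")), 10)
})
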