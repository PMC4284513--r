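test_that("minimum group distance honours the minimum-image convention", {
  coords <- rbind(c(0, 0, 0), c(0, 0, 3), c(0, 0, 9), c(0, 0, 1), c(0, 0, 49))
  box <- c(50, 50, 50)
  expect_equal(min_group_distance(coords, box, 1, c(2, 3)), 3.0)
  ## periodic wrap: z = 1 vs z = 49 in a 50 box is 2 apart
  expect_equal(min_group_distance(coords, box, 4, 5), 2.0)
  expect_error(min_group_distance(coords, box, integer(0), 1), "non-empty")
})

test_that("minimum group distance matches the exhaustive pair oracle", {
  set.seed(21)
  for (rep in 1:20) {
    n <- 12
    coords <- matrix(runif(n * 3, 0, 30), n, 3)
    box <- c(30, 25, 35)
    donors <- sample(n, 5); acceptors <- sample(setdiff(1:n, donors), 7)
    expect_equal(min_group_distance(coords, box, donors, acceptors),
                 brute_min_distance(coords, box, donors, acceptors))
  }
})

test_that("the 3.2 Angstrom bridge criterion is strictly less-than", {
  at319 <- pair_at_distance(3.19)
  at320 <- pair_at_distance(3.20)
  expect_true(detect_bridges(at319$traj, at319$topo)$occupancy[1, 1, 1])
  expect_false(detect_bridges(at320$traj, at320$topo)$occupancy[1, 1, 1])
})

test_that("bridge detection is frame-independent and column-exact", {
  spec <- toy_system_spec(n_subunits = 1, n_frames = 40, seed = 5)
  ## force one residue always bound, all others never
  p <- spec$p_star; p[] <- 0; p["A:249", 1] <- 1
  spec <- toy_system_spec(n_subunits = 1, n_frames = 40, seed = 5, p_star = p)
  sys <- gen_toy_trajectory(spec)
  cs <- detect_bridges(sys$trajectory, sys$topology)
  expect_true(all(cs$occupancy[, "A:249", 1]))
  expect_true(all(!cs$occupancy[, setdiff(cs$residues, "A:249"), ]))
  ## shuffling frames permutes occupancy rows identically
  perm <- sample(40)
  shuf <- trajectory(sys$trajectory$coords[perm, , , drop = FALSE],
                     times = sys$trajectory$times,
                     box = sys$trajectory$box[perm, , drop = FALSE])
  cs2 <- detect_bridges(shuf, sys$topology)
  expect_identical(cs2$occupancy[, , 1], cs$occupancy[perm, , 1])
})

test_that("occupancy at a smaller cutoff is a subset of a larger one", {
  spec <- toy_system_spec(n_subunits = 2, n_frames = 50, seed = 9,
                          noncontact_band = c(3.5, 12))
  sys <- gen_toy_trajectory(spec)
  occ_small <- detect_bridges(sys$trajectory, sys$topology, cutoff = 3.2)$occupancy
  occ_large <- detect_bridges(sys$trajectory, sys$topology, cutoff = 4.5)$occupancy
  expect_true(all(occ_large[occ_small]))
})

test_that("detection refuses invalid setups", {
  p <- pair_at_distance(3.0)
  topo_nosel <- topology(p$topo$atoms)
  expect_error(detect_bridges(p$traj, topo_nosel), "basic_nitrogens")
  small <- pair_at_distance(3.0, box = 6)   # box < 2 * cutoff
  expect_error(detect_bridges(small$traj, small$topo), "minimum image")
})

test_that("per-lipid averages match a direct per-frame recount", {
  set.seed(31)
  occ <- array(runif(60 * 5 * 3) < 0.4, c(60, 5, 3))
  cs <- make_cs(occ, paste0("A:", 1:5), paste0("PIP:A:", 1:3))
  s <- per_lipid_average(cs)
  for (l in 1:3) {
    expect_equal(s$mean_bridges_per_frame[l], mean(rowSums(occ[, , l])))
    expect_setequal(s$partners[[l]], paste0("A:", which(colSums(occ[, , l]) > 0)))
  }
  ## deterministic toy cases
  occ2 <- array(FALSE, c(10, 3, 1)); occ2[, 1:2, 1] <- TRUE
  s2 <- per_lipid_average(make_cs(occ2, paste0("A:", 1:3), "PIP:A:1"))
  expect_equal(s2$mean_bridges_per_frame, 2.0)
  occ3 <- array(FALSE, c(10, 1, 1)); occ3[1:5, 1, 1] <- TRUE
  s3 <- per_lipid_average(make_cs(occ3, "A:1", "PIP:A:1"))
  expect_equal(s3$mean_bridges_per_frame, 0.5)
})

test_that("intrasubunit classification needs two site regions on one subunit", {
  rm <- c("190" = "S2-S3", "249" = "S4-S5", "354" = "S6", "259" = "S4-S5")
  mk <- function(partners, same) {
    s <- data.frame(lipid_key = "PIP:A:1", mean_bridges_per_frame = 1,
                    n_partners = length(partners), same_subunit = same)
    s$partners <- I(list(partners))
    s
  }
  expect_equal(unname(classify_intrasubunit(
    mk(c("A:190", "A:249", "A:354"), TRUE), rm)), "intrasubunit")
  ## spanning two subunits
  expect_equal(unname(classify_intrasubunit(
    mk(c("A:190", "B:249"), FALSE), rm)), "other")
  ## a single region only
  expect_equal(unname(classify_intrasubunit(
    mk(c("A:249", "A:259"), TRUE), rm)), "other")
  expect_error(classify_intrasubunit(mk(c("A:999"), TRUE), rm), "region map")
})

test_that("formation probabilities pool frames and report across-run spread", {
  ## one run, 250 frames, 125 formed -> 0.5
  occ <- array(FALSE, c(250, 1, 1)); occ[1:125, 1, 1] <- TRUE
  tab <- formation_probability(make_cs(occ, "A:249", "PIP:A:1"),
                               pool_subunits = FALSE)
  expect_equal(tab$probability, 0.5)
  expect_equal(tab$sd, 0)
  expect_true(tab$single_run)

  ## two runs at 0.4 and 0.6 with equal frames: pooled 0.5;
  ## population SD (divide by n_runs) 0.1, sample SD 0.1414...
  mk_run <- function(p) {
    o <- array(FALSE, c(100, 1, 1)); o[seq_len(100 * p), 1, 1] <- TRUE
    make_cs(o, "A:249", "PIP:A:1")
  }
  runs <- list(mk_run(0.4), mk_run(0.6))
  tab2 <- formation_probability(runs, pool_subunits = FALSE)
  expect_equal(tab2$probability, 0.5)
  expect_equal(tab2$sd, 0.1)
  tab2s <- formation_probability(runs, pool_subunits = FALSE,
                                 sd_convention = "sample")
  expect_equal(tab2s$sd, sqrt(0.02), tolerance = 1e-12)

  ## all-false occupancy
  o0 <- array(FALSE, c(50, 1, 1))
  tab3 <- formation_probability(make_cs(o0, "A:249", "PIP:A:1"))
  expect_equal(tab3$probability, 0)
  expect_equal(tab3$sd, 0)
  expect_error(formation_probability(make_cs(array(FALSE, c(0, 1, 1)),
                                             "A:249", "PIP:A:1")),
               "zero frames")
})

test_that("subunit pooling concatenates copies and OR-combines lipids", {
  ## residue 249 on subunits A and B; two lipids; A bridges lipid 1 in 30
  ## of 100 frames, B bridges lipid 2 in 70 of 100
  occ <- array(FALSE, c(100, 2, 2))
  occ[1:30, 1, 1] <- TRUE
  occ[1:70, 2, 2] <- TRUE
  cs <- make_cs(occ, c("A:249", "B:249"), c("PIP:A:1", "PIP:B:2"))
  pooled <- formation_probability(cs, pool_subunits = TRUE)
  expect_equal(pooled$residue_key, "249")
  expect_equal(pooled$probability, 0.5)   # (30 + 70) / 200
  expect_equal(pooled$n_frames_total, 200)
  ## pooled probability equals the frame-weighted mean of per-subunit ones
  unpooled <- formation_probability(cs, pool_subunits = FALSE)
  expect_equal(pooled$probability,
               sum(unpooled$probability * unpooled$n_frames_total) /
                 sum(unpooled$n_frames_total))
})

test_that("probability categories follow the published bins", {
  expect_equal(categorize(c(0.80, 0.76, 0.42, 0.25, 0.50, 0.0)),
               c("frequent", "frequent", "moderate", "moderate", "moderate",
                 "none"))
  ## boundaries: 0.75 is not frequent; just above 0.50 is intermittent
  expect_equal(categorize(c(0.75, 0.51, 0.10)),
               c("intermittent", "intermittent", "intermittent"))
  expect_error(categorize(1.2), "out of")
})

test_that("probability table comparison flags changes beyond the WT error bar", {
  a <- make_ptab(c("354", "358"), c(0.26, 0.42), sd = 0.05)
  b <- make_ptab(c("354", "358"), c(0.60, 0.45))
  cmp <- compare_probability_tables(a, b)
  expect_equal(cmp$delta, c(0.34, 0.03), tolerance = 1e-12)
  expect_equal(cmp$significant, c(TRUE, FALSE))
  ## identical tables: no deltas, no flags
  cmp0 <- compare_probability_tables(a, a)
  expect_true(all(cmp0$delta == 0) && !any(cmp0$significant))
  expect_error(compare_probability_tables(a, make_ptab("999", 0.5)),
               "no residue keys")
})

test_that("estimated probabilities recover generator targets within binomial error", {
  spec <- toy_system_spec(n_subunits = 2, n_frames = 400, seed = 42)
  sys <- gen_toy_trajectory(spec)
  cs <- detect_bridges(sys$trajectory, sys$topology)
  tab <- formation_probability(cs, pool_subunits = FALSE)
  targets <- sys$p_star[cbind(tab$residue_key,
                              paste0("PIP:", sub(":.*", "", tab$residue_key),
                                     ":", 1000 + match(sub(":.*", "", tab$residue_key),
                                                       c("A", "B"))))]
  se <- sqrt(pmax(targets * (1 - targets), 1e-12) / 400)
  expect_true(all(abs(tab$probability - targets) <= pmax(3 * se, 1e-9)))
})
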