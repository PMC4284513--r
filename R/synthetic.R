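#' Default basic-residue layout of the intrasubunit PIP2 site
#'
#' One row per basic residue of the toy channel subunit, with its region
#' (S2-S3 loop, S4-S5 linker, S4, S6 terminus), residue type and the default
#' target lipid-contact probability. The defaults mirror the wild-type
#' activated/open interaction pattern of Kv7.1: R190, R195 and R249 engage
#' the lipid frequently (p > 0.75), K183/R192/K354/K358 moderately
#' (0.25-0.50, with K354 at 0.26 and K358 at 0.42), and K196/R259 only
#' intermittently.
#'
#' @return data.frame with `residue_number`, `region`, `residue_name`,
#'   `p_contact`.
#' @export
default_site_residues <- function() {
  data.frame(
    residue_number = c(183L, 190L, 192L, 195L, 196L, 249L, 259L, 354L, 358L),
    region = c("S2-S3", "S2-S3", "S2-S3", "S2-S3", "S2-S3",
               "S4-S5", "S4-S5", "S6", "S6"),
    residue_name = c("LYS", "ARG", "ARG", "ARG", "LYS",
                     "ARG", "ARG", "LYS", "LYS"),
    p_contact = c(0.35, 0.85, 0.30, 0.80, 0.10, 0.85, 0.10, 0.26, 0.42),
    stringsAsFactors = FALSE)
}

#' Specification of a toy membrane-protein / lipid system
#'
#' Describes the synthetic system [gen_toy_trajectory()] realizes: a rigid
#' scaffold of basic-residue beads (4 subunits by default, one bead per
#' residue carrying the charged-group nitrogen), one PIP2-like lipid per
#' subunit (3 phosphorus marker beads P1/P4/P5 plus one phosphate-oxygen
#' bead per residue-lipid pair), and a target contact-probability matrix
#' `p_star`. In every frame, the oxygen bead of a pair sits at a distance
#' drawn uniformly from `contact_band` (strictly inside the 3.2 Angstrom
#' bridge cutoff) with probability `p_star`, otherwise uniformly from
#' `noncontact_band` (strictly outside), so target probabilities are
#' realized exactly in expectation.
#'
#' @param n_subunits number of subunit copies (default 4).
#' @param residues data.frame as [default_site_residues()].
#' @param n_lipids number of lipids; default one per subunit, each assigned
#'   to its own subunit (1 lipid : 1 subunit stoichiometry).
#' @param p_star optional full residue x lipid target matrix; by default a
#'   residue's `p_contact` applies to its own subunit's lipid and 0 to all
#'   others.
#' @param n_frames frames to generate (default 250, i.e. one analysis
#'   window's worth of configurations).
#' @param frame_dt frame spacing in ns (default 0.2, so 250 frames span
#'   50 ns).
#' @param contact_band,noncontact_band distance bands (Angstrom).
#' @param spacing residue-scaffold grid spacing (Angstrom); must exceed
#'   twice the outer non-contact distance so pair beads never stray near
#'   foreign residues.
#' @param dwell_frames optional mean dwell (frames) of the formed state; when
#'   set, contacts follow a two-state Markov chain with this mean bound
#'   lifetime and stationary probability `p_star` (mimicking long-lived
#'   bridges) instead of frame-independent Bernoulli draws.
#' @param seed RNG seed (generation is bit-reproducible given the seed).
#' @return list of class `"toy_system_spec"`.
#' @export
toy_system_spec <- function(n_subunits = 4, residues = default_site_residues(),
                            n_lipids = n_subunits, p_star = NULL,
                            n_frames = 250, frame_dt = 0.2,
                            contact_band = c(2.6, 3.19),
                            noncontact_band = c(5, 12),
                            spacing = 26, dwell_frames = NULL, seed = 1) {
  stopifnot(n_subunits >= 1, n_lipids >= 1, n_frames >= 1)
  if (spacing <= 2 * noncontact_band[2])
    stop("spacing must exceed twice the outer non-contact distance")
  subunits <- LETTERS[seq_len(n_subunits)]
  rkeys <- as.vector(outer(residues$residue_number, subunits,
                           function(r, s) paste0(s, ":", r)))
  lkeys <- paste0("PIP:", subunits[((seq_len(n_lipids) - 1) %% n_subunits) + 1],
                  ":", 1000 + seq_len(n_lipids))
  if (is.null(p_star)) {
    p_star <- matrix(0, length(rkeys), n_lipids,
                     dimnames = list(rkeys, lkeys))
    for (l in seq_len(n_lipids)) {
      sub <- strsplit(lkeys[l], ":")[[1]][2]
      own <- paste0(sub, ":", residues$residue_number)
      p_star[own, l] <- residues$p_contact
    }
  } else {
    p_star <- as.matrix(p_star)
    if (!all(dim(p_star) == c(length(rkeys), n_lipids)))
      stop("p_star must be ", length(rkeys), " x ", n_lipids)
    dimnames(p_star) <- list(rkeys, lkeys)
  }
  if (any(p_star < 0 | p_star > 1)) stop("p_star entries must be in [0, 1]")
  structure(list(n_subunits = n_subunits, residues = residues,
                 n_lipids = n_lipids, p_star = p_star, n_frames = n_frames,
                 frame_dt = frame_dt, contact_band = contact_band,
                 noncontact_band = noncontact_band, spacing = spacing,
                 dwell_frames = dwell_frames, seed = seed,
                 subunits = subunits, residue_keys = rkeys,
                 lipid_keys = lkeys),
            class = "toy_system_spec")
}

## Default per-atom nonbonded parameters of the toy beads.
toy_parameter_table <- function() {
  df <- data.frame(
    residue_name = c("ARG", "LYS", "PIP", "PIP", "PIP", "PIP"),
    atom_name = c("NH1", "NZ", "O1P", "P1", "P4", "P5"),
    charge_e = c(1.0, 1.0, -1.0, 1.1, 1.1, 1.1),
    lj_epsilon_kcal = c(0.20, 0.20, 0.12, 0.585, 0.585, 0.585),
    lj_rmin_half_A = c(1.85, 1.85, 1.70, 2.15, 2.15, 2.15),
    stringsAsFactors = FALSE)
  class(df) <- c("nb_parameters", "data.frame")
  df
}

## Random unit vectors, n x 3.
runit <- function(n) {
  v <- matrix(rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

#' Generate a toy trajectory with prescribed contact statistics
#'
#' Realizes a [toy_system_spec()]: returns the topology (with
#' `basic_nitrogens`, `pip2_phosphate_oxygens` and `headgroup_P` selections
#' registered), the trajectory, the matching nonbonded parameter table (+1 e
#' on the basic nitrogens, -1 e on the phosphate oxygens by default) and the
#' ground-truth target probability matrix. Bit-reproducible for a fixed
#' seed.
#'
#' @param spec a [toy_system_spec()].
#' @param headgroup_offset displacement of the lipid P1/P4/P5 marker triplet
#'   relative to its subunit centroid (Angstrom); used by the two-condition
#'   generator to prescribe headgroup shifts.
#' @return list of class `"toy_system"` with `topology`, `trajectory`,
#'   `parameters`, `p_star`, `region_map`, `spec`.
#' @export
gen_toy_trajectory <- function(spec, headgroup_offset = c(0, 0, 13)) {
  stopifnot(inherits(spec, "toy_system_spec"))
  sp <- spec$spacing
  nres_ps <- nrow(spec$residues)
  nres <- nres_ps * spec$n_subunits
  ## rigid scaffold: subunits along x, residues along y
  res_pos <- matrix(0, nres, 3)
  res_sub <- character(nres); res_no <- integer(nres)
  res_name <- character(nres)
  k <- 0L
  for (s in seq_len(spec$n_subunits)) for (j in seq_len(nres_ps)) {
    k <- k + 1L
    res_pos[k, ] <- c(s * sp, j * sp, sp)
    res_sub[k] <- spec$subunits[s]
    res_no[k] <- spec$residues$residue_number[j]
    res_name[k] <- spec$residues$residue_name[j]
  }
  box <- c((spec$n_subunits + 1) * sp, (nres_ps + 1) * sp, 2 * sp)
  if (any(box <= 2 * 3.2)) stop("box too small for the bridge cutoff")
  natom_lipid <- 3L + nres          # P1 P4 P5 + one O bead per residue pair
  natoms <- nres + spec$n_lipids * natom_lipid
  atoms <- data.frame(
    name = c(ifelse(res_name == "ARG", "NH1", "NZ"),
             rep(c("P1", "P4", "P5", rep("O1P", nres)), spec$n_lipids)),
    residue_number = c(res_no,
                       rep(1000L + seq_len(spec$n_lipids), each = natom_lipid)),
    residue_name = c(res_name, rep("PIP", spec$n_lipids * natom_lipid)),
    subunit = c(res_sub,
                rep(vapply(strsplit(spec$lipid_keys, ":"), `[`, "", 2),
                    each = natom_lipid)),
    stringsAsFactors = FALSE)
  ## lipid marker anchor: centroid of its subunit's residues + offset
  lipid_anchor <- t(vapply(seq_len(spec$n_lipids), function(l) {
    sub <- strsplit(spec$lipid_keys[l], ":")[[1]][2]
    colMeans(res_pos[res_sub == sub, , drop = FALSE]) + headgroup_offset
  }, numeric(3)))
  nf <- spec$n_frames
  coords <- array(0, c(nf, natoms, 3))
  contact <- array(FALSE, c(nf, nres, spec$n_lipids))
  with_seed(spec$seed, {
    ## contact indicators per pair
    for (r in seq_len(nres)) for (l in seq_len(spec$n_lipids)) {
      p <- spec$p_star[r, l]
      contact[, r, l] <- if (is.null(spec$dwell_frames)) {
        runif(nf) < p
      } else if (p <= 0) rep(FALSE, nf) else if (p >= 1) rep(TRUE, nf) else {
        ## two-state Markov chain: P(on->off) = 1/dwell, stationary prob p
        b <- 1 / spec$dwell_frames
        a <- min(1, p * b / (1 - p))
        st <- logical(nf)
        st[1] <- runif(1) < p
        for (f in 2:nf)
          st[f] <- if (st[f - 1]) runif(1) >= b else runif(1) < a
        st
      }
    }
    for (f in seq_len(nf)) {
      coords[f, seq_len(nres), ] <- res_pos
      for (l in seq_len(spec$n_lipids)) {
        base <- nres + (l - 1L) * natom_lipid
        jit <- matrix(rnorm(9, 0, 0.3), 3, 3)
        pm <- matrix(lipid_anchor[l, ], 3, 3, byrow = TRUE) +
          outer(c(-1, 0, 1), c(1.5, 0, 0)) + jit
        coords[f, base + 1:3, ] <- pm
        rad <- ifelse(contact[f, , l],
                      runif(nres, spec$contact_band[1], spec$contact_band[2]),
                      runif(nres, spec$noncontact_band[1],
                            spec$noncontact_band[2]))
        coords[f, base + 3L + seq_len(nres), ] <- res_pos + rad * runit(nres)
      }
    }
  })
  topo <- topology(atoms)
  topo <- add_selection(topo, "basic_nitrogens", which(atoms$name %in% c("NH1", "NZ")))
  topo <- add_selection(topo, "pip2_phosphate_oxygens", which(atoms$name == "O1P"))
  topo <- add_selection(topo, "headgroup_P", which(atoms$name %in% c("P1", "P4", "P5")))
  topo <- assign_parameters(topo, toy_parameter_table(), warn = FALSE)
  traj <- trajectory(coords, times = spec$frame_dt * (seq_len(nf) - 1L),
                     box = box)
  region_map <- setNames(spec$residues$region,
                         as.character(spec$residues$residue_number))
  structure(list(topology = topo, trajectory = traj,
                 parameters = toy_parameter_table(),
                 p_star = spec$p_star, region_map = region_map, spec = spec),
            class = "toy_system")
}

#' Generate a matched pair of systems with prescribed differences
#'
#' Builds two toy systems (e.g. WT vs mutant) from one base spec: condition
#' b's target contact probabilities differ by `delta_p` (named by residue
#' number) and its lipid headgroup markers are displaced by `displacement`
#' Angstrom along `axis`. The prescribed ground truth is returned alongside
#' for recovery tests of [compare_probability_tables()] and
#' [headgroup_shift()].
#'
#' @param spec_a base [toy_system_spec()] (condition a).
#' @param delta_p named numeric, probability changes keyed by residue number
#'   (applied to every subunit copy, clamped to `[0, 1]`).
#' @param displacement headgroup displacement (Angstrom) of condition b.
#' @param axis length-3 direction of the displacement (normalized
#'   internally).
#' @param seed_b seed for condition b (defaults to `spec_a$seed + 1`).
#' @return list with `system_a`, `system_b` and `truth` (`delta_p`,
#'   `displacement`, `axis`, landmark points `axis_from`/`axis_to`).
#' @export
gen_two_condition_system <- function(spec_a, delta_p = numeric(0),
                                     displacement = 0, axis = c(0, 0, 1),
                                     seed_b = spec_a$seed + 1) {
  stopifnot(inherits(spec_a, "toy_system_spec"))
  axis <- axis / sqrt(sum(axis^2))
  res_b <- spec_a$residues
  if (length(delta_p)) {
    hit <- match(names(delta_p), as.character(res_b$residue_number))
    if (anyNA(hit))
      stop("delta_p names not in residue set: ",
           paste(names(delta_p)[is.na(hit)], collapse = ", "))
    res_b$p_contact[hit] <- pmin(1, pmax(0, res_b$p_contact[hit] + delta_p))
  }
  spec_b <- toy_system_spec(
    n_subunits = spec_a$n_subunits, residues = res_b,
    n_lipids = spec_a$n_lipids, n_frames = spec_a$n_frames,
    frame_dt = spec_a$frame_dt, contact_band = spec_a$contact_band,
    noncontact_band = spec_a$noncontact_band, spacing = spec_a$spacing,
    dwell_frames = spec_a$dwell_frames, seed = seed_b)
  sys_a <- gen_toy_trajectory(spec_a)
  sys_b <- gen_toy_trajectory(spec_b,
                              headgroup_offset = c(0, 0, 13) +
                                displacement * axis)
  list(system_a = sys_a, system_b = sys_b,
       truth = list(delta_p = delta_p, displacement = displacement,
                    axis = axis, axis_from = c(0, 0, 0), axis_to = axis))
}

#' Generate a synthetic Boltzmann gating curve with known ground truth
#'
#' `response = boltzmann(V) + N(0, noise_sd)`, clipped to `[-0.2, 1.2]`;
#' deterministic for a fixed seed.
#'
#' @param v_half,z true Boltzmann parameters (mV, e).
#' @param voltages test voltages (mV).
#' @param noise_sd additive Gaussian noise SD.
#' @param kind `"FV"` or `"GV"`.
#' @param temperature K.
#' @param seed RNG seed.
#' @return list with `curve` (a [gating_curve()]) and `truth`.
#' @export
gen_gating_curve <- function(v_half = -20, z = 2,
                             voltages = seq(-75, 35, by = 10),
                             noise_sd = 0.02, kind = "FV",
                             temperature = 293.15, seed = 1) {
  stopifnot(noise_sd >= 0)
  y0 <- boltzmann(voltages, v_half, z, temperature)
  y <- with_seed(seed, y0 + rnorm(length(voltages), 0, noise_sd))
  y <- pmin(1.2, pmax(-0.2, y))
  list(curve = gating_curve(voltages, y, kind = kind),
       truth = list(v_half = v_half, z = z, noise_sd = noise_sd,
                    temperature = temperature, seed = seed))
}

#' Generate a synthetic fluorescence trace with linear baseline drift
#'
#' A 2 s baseline segment at the holding potential followed by a test pulse:
#' `F(t) = intercept + slope * t + amplitude * [t in pulse] + N(0, noise_sd)`.
#' The ground-truth dF/F during the pulse is
#' `amplitude / (intercept + slope * t)`.
#'
#' @param baseline_intercept,baseline_slope baseline line (a.u., a.u./s);
#'   the intercept must keep the baseline away from zero over the record.
#' @param pulse_amplitude fluorescence step during the pulse (a.u.).
#' @param noise_sd additive Gaussian noise SD (a.u.).
#' @param dt sample interval (s).
#' @param baseline_duration,pulse_duration segment lengths (s).
#' @param holding_voltage mV.
#' @param seed RNG seed.
#' @return list with `trace` (an [ephys_trace()]) and `truth` (including the
#'   per-sample ground-truth dF/F).
#' @export
gen_fluorescence_trace <- function(baseline_intercept = 10,
                                   baseline_slope = -0.2,
                                   pulse_amplitude = 1, noise_sd = 0,
                                   dt = 0.01, baseline_duration = 2,
                                   pulse_duration = 1,
                                   holding_voltage = -80, seed = 1) {
  t <- seq(0, baseline_duration + pulse_duration, by = dt)
  base <- baseline_intercept + baseline_slope * t
  if (min(abs(base)) < 1e-6 || min(base) <= 0 && max(base) >= 0)
    stop("baseline line crosses zero over the record; move the intercept")
  inp <- t >= baseline_duration
  f <- base + pulse_amplitude * inp
  if (noise_sd > 0) f <- with_seed(seed, f + rnorm(length(t), 0, noise_sd))
  trace <- ephys_trace(t, f, pulse_start = baseline_duration,
                       pulse_end = baseline_duration + pulse_duration,
                       holding_voltage = holding_voltage)
  list(trace = trace,
       truth = list(dff = ifelse(inp, pulse_amplitude / base, 0),
                    baseline = base, pulse_amplitude = pulse_amplitude))
}

#' Generate a toy two-region system for energy decompositions
#'
#' A single-subunit scaffold with one bead per residue for the S4-S5 linker
#' (residues 247-260) and the S6 helix (residues 323-358), charges and LJ
#' parameters set directly on the topology (R249 and K358 carry +1 e, two
#' acidic beads carry -1 e, the rest alternate small partial charges), and
#' per-frame Gaussian positional jitter around a geometry that spans the
#' switching region of the potential. Intended for conservation and oracle
#' tests of [per_residue_decomposition()].
#'
#' @param n_frames frames (default 100).
#' @param jitter positional jitter SD (Angstrom).
#' @param seed RNG seed.
#' @return list with `topology` and `trajectory`.
#' @export
gen_region_system <- function(n_frames = 100, jitter = 0.5, seed = 1) {
  resA <- 247:260; resB <- 323:358
  nA <- length(resA); nB <- length(resB)
  qA <- rep_len(c(0.25, -0.25), nA); qA[resA == 249] <- 1
  qA[resA == 254] <- -1
  qB <- rep_len(c(-0.2, 0.2), nB); qB[resB == 358] <- 1
  qB[resB == 340] <- -1
  atoms <- data.frame(
    name = "CA",
    residue_number = c(resA, resB),
    residue_name = "GLY",
    subunit = "A",
    charge = c(qA, qB),
    lj_epsilon = 0.1,
    lj_rmin_half = 2.0,
    stringsAsFactors = FALSE)
  ## two roughly parallel strands 5-14 Angstrom apart so pairs populate the
  ## plateau, the switching window and the beyond-cutoff regime
  posA <- cbind(0, 3.0 * seq_len(nA), 0)
  posB <- cbind(5 + 9 * (seq_len(nB) - 1) / (nB - 1), 3.0 * seq_len(nB) - 20, 0)
  pos <- rbind(posA, posB)
  na <- nrow(pos)
  coords <- array(0, c(n_frames, na, 3))
  with_seed(seed, {
    for (f in seq_len(n_frames))
      coords[f, , ] <- pos + matrix(rnorm(3 * na, 0, jitter), na, 3)
  })
  list(topology = topology(atoms),
       trajectory = trajectory(coords, times = 0.1 * (seq_len(n_frames) - 1),
                               box = c(80, 120, 80)))
}

#' Generate a synthetic two-channel alignment with prescribed identities
#'
#' Constructs, by design, a gapped two-sequence alignment carrying the
#' identity structure reported for the Kv1.2/Kv7.1 comparison: a
#' pore-domain region with a prescribed identity (36% by default), a
#' voltage-sensor region whose identity excluding the S2-S3 loop is
#' prescribed (25% by default), and an S2-S3 loop block where the reference
#' sequence is gapped (the loop is drastically different and shorter in the
#' reference channel). This is a *synthetic stand-in*: the residues are
#' random, only the region/identity/gap structure is meaningful.
#'
#' @param pd_identity,vsd_identity target identities (fractions) over the PD
#'   region and the VSD region excluding the S2-S3 loop; realized exactly on
#'   the reference-sequence non-gap columns.
#' @param seed RNG seed.
#' @return a [seq_alignment()] with regions `"VSD"` (columns 1-170),
#'   `"S2-S3 loop"` (61-110) and `"PD"` (171-270), sequences named
#'   `Kv1.2_synthetic` and `Kv7.1_synthetic`.
#' @export
gen_synthetic_alignment <- function(pd_identity = 0.36, vsd_identity = 0.25,
                                    seed = 1) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  n_vsd <- 170L; loop <- 61:110; n_pd <- 100L
  vsd_core <- setdiff(seq_len(n_vsd), loop)       # 120 columns
  pd_cols <- n_vsd + seq_len(n_pd)
  len <- n_vsd + n_pd
  with_seed(seed, {
    s1 <- sample(aa, len, replace = TRUE)
    s2 <- vapply(s1, function(x) sample(setdiff(aa, x), 1), "")
    set_matches <- function(cols, frac) {
      k <- round(frac * length(cols))
      hit <- sample(cols, k)
      s2[hit] <<- s1[hit]
    }
    set_matches(vsd_core, vsd_identity)
    set_matches(pd_cols, pd_identity)
    ## the loop is shorter and unrelated in the reference: gap 30 of its 50
    ## columns in the reference, keep the rest mismatched
    gapped <- sample(loop, 30)
    s1[gapped] <- "-"
    s2[loop] <- vapply(seq_along(loop), function(i) {
      c1 <- s1[loop[i]]
      if (c1 == "-") sample(aa, 1) else sample(setdiff(aa, c1), 1)
    }, "")
  })
  seq_alignment(
    c(Kv1.2_synthetic = paste(s1, collapse = ""),
      Kv7.1_synthetic = paste(s2, collapse = "")),
    regions = list("VSD" = c(1, n_vsd),
                   "S2-S3 loop" = c(min(loop), max(loop)),
                   "PD" = c(n_vsd + 1, len)))
}
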