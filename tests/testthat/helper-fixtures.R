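# Fixture builders shared across test files. Everything is generated in code;
# no binary fixtures on disk.

# Minimal topology: one Arg, one Lys, one PIP with three phosphate oxygens.
toy_topology <- function() {
  topology(data.frame(
    name = c("NE", "NH1", "NH2", "NZ", "O1P", "O1P", "O1P"),
    residue_number = c(249, 249, 249, 358, 1001, 1001, 1001),
    residue_name = c("ARG", "ARG", "ARG", "LYS", "PIP", "PIP", "PIP"),
    subunit = c("A", "A", "A", "A", "A", "A", "A"),
    stringsAsFactors = FALSE))
}

# Place two single-bead groups (one donor residue, one acceptor lipid) at an
# exact separation d inside a cubic box, over nf frames.
pair_at_distance <- function(d, nf = 1, box = 50) {
  topo <- topology(data.frame(
    name = c("NZ", "O1P"),
    residue_number = c(358, 1001),
    residue_name = c("LYS", "PIP"),
    subunit = "A", stringsAsFactors = FALSE))
  topo <- add_selection(topo, "basic_nitrogens", 1L)
  topo <- add_selection(topo, "pip2_phosphate_oxygens", 2L)
  coords <- array(0, c(nf, 2, 3))
  coords[, 2, 3] <- d
  list(topo = topo,
       traj = trajectory(coords, times = seq_len(nf) - 1, box = rep(box, 3)))
}

# Exhaustive double-loop oracle for the minimum group distance under the
# minimum-image convention.
brute_min_distance <- function(coords, box, donors, acceptors) {
  best <- Inf
  for (i in donors) for (j in acceptors) {
    dx <- coords[i, ] - coords[j, ]
    for (k in 1:3) if (!is.na(box[k])) dx[k] <- dx[k] - box[k] * round(dx[k] / box[k])
    best <- min(best, sqrt(sum(dx^2)))
  }
  best
}

# Exhaustive pairwise oracle for switched LJ + Coulomb group energies.
brute_group_energy <- function(coords, box, topo, ga, gb, scheme) {
  a <- topo$atoms
  sw <- function(r) {
    s <- scheme$switch_on; cc <- scheme$cutoff
    if (r <= s) 1 else if (r >= cc) 0 else
      (cc^2 - r^2)^2 * (cc^2 + 2 * r^2 - 3 * s^2) / (cc^2 - s^2)^3
  }
  ev <- 0; ee <- 0
  for (i in ga) for (j in gb) {
    dx <- coords[i, ] - coords[j, ]
    for (k in 1:3) if (!is.na(box[k])) dx[k] <- dx[k] - box[k] * round(dx[k] / box[k])
    r <- sqrt(sum(dx^2))
    s <- sw(r)
    eps <- sqrt(a$lj_epsilon[i] * a$lj_epsilon[j])
    rmin <- a$lj_rmin_half[i] + a$lj_rmin_half[j]
    ev <- ev + s * eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
    ee <- ee + s * 332.0636 * a$charge[i] * a$charge[j] / (scheme$dielectric * r)
  }
  c(e_vdw = ev, e_elec = ee, e_total = ev + ee)
}

# Random charged-bead topology + single frame for oracle tests.
random_system <- function(n_atoms, box = 40, seed = 1) {
  set.seed(seed)
  topo <- topology(data.frame(
    name = "X",
    residue_number = seq_len(n_atoms),
    residue_name = "UNK",
    subunit = "A",
    charge = runif(n_atoms, -1, 1),
    lj_epsilon = runif(n_atoms, 0.05, 0.3),
    lj_rmin_half = runif(n_atoms, 1.5, 2.2),
    stringsAsFactors = FALSE))
  coords <- matrix(runif(n_atoms * 3, 0, box), n_atoms, 3)
  list(topo = topo, coords = coords, box = rep(box, 3))
}

# Build a contact_series directly from an occupancy array.
make_cs <- function(occ, residues, lipids, cutoff = 3.2) {
  structure(list(occupancy = occ, residues = residues, lipids = lipids,
                 times = seq_len(dim(occ)[1]) - 1, cutoff = cutoff),
            class = "contact_series")
}

# Build a probability_table directly.
make_ptab <- function(keys, p, sd = 0) {
  out <- data.frame(residue_key = keys, probability = p,
                    sd = rep_len(sd, length(keys)), n_runs = 1,
                    n_frames_total = 100, single_run = TRUE,
                    stringsAsFactors = FALSE)
  class(out) <- c("probability_table", "data.frame")
  out
}
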