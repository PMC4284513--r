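#' Nonbonded interaction scheme (switched Lennard-Jones + Coulomb)
#'
#' Defines the pairwise potential used for all interaction-energy analyses:
#' short-range electrostatics cut at 11 Angstrom with a CHARMM switching
#' function applied between 8 and 11 Angstrom that brings energies smoothly
#' to zero at the outer cutoff. Per-residue decompositions are only
#' well-defined for a pairwise form, so a switched-cutoff Coulomb term stands
#' in for the (non-pairwise-assignable) reciprocal part of Ewald
#' electrostatics; switching of the Coulomb term can be disabled with
#' `switch_electrostatics = FALSE`.
#'
#' @param cutoff outer cutoff (Angstrom).
#' @param switch_on switching onset (Angstrom), `0 < switch_on < cutoff`.
#' @param dielectric relative dielectric constant.
#' @param switch_electrostatics apply the switching factor to the Coulomb
#'   term as well as the LJ term.
#' @return object of class `"nonbonded_scheme"`.
#' @export
nonbonded_scheme <- function(cutoff = 11, switch_on = 8, dielectric = 1,
                             switch_electrostatics = TRUE) {
  if (!(switch_on > 0 && switch_on < cutoff))
    stop("need 0 < switch_on < cutoff")
  if (dielectric <= 0) stop("dielectric must be > 0")
  structure(list(cutoff = cutoff, switch_on = switch_on,
                 dielectric = dielectric,
                 coulomb_constant = .COULOMB_KCAL,
                 switch_electrostatics = switch_electrostatics),
            class = "nonbonded_scheme")
}

#' CHARMM switching factor
#'
#' `sw(r) = 1` for `r <= switch_on`, `0` for `r >= cutoff`, and
#' `(c^2 - r^2)^2 (c^2 + 2 r^2 - 3 s^2) / (c^2 - s^2)^3` in between
#' (`s = switch_on`, `c = cutoff`). Continuous with continuous first
#' derivative at both knots.
#'
#' @param r distance(s), Angstrom, `>= 0`.
#' @param scheme a [nonbonded_scheme()].
#' @return switching factor(s) in `[0, 1]`.
#' @export
switching_factor <- function(r, scheme = nonbonded_scheme()) {
  s <- scheme$switch_on; cc <- scheme$cutoff
  r2 <- r^2; s2 <- s^2; c2 <- cc^2
  sw <- (c2 - r2)^2 * (c2 + 2 * r2 - 3 * s2) / (c2 - s2)^3
  out <- ifelse(r <= s, 1, ifelse(r >= cc, 0, sw))
  out
}

#' Pairwise nonbonded energy of one atom pair
#'
#' `e_vdw = sw(r) * eps_ij * ((rmin_ij/r)^12 - 2 (rmin_ij/r)^6)` and
#' `e_elec = sw(r) * C * qi * qj / (dielectric * r)` with
#' `C = 332.0636 kcal A / (mol e^2)`. Combination rules:
#' `eps_ij = sqrt(eps_i eps_j)`, `rmin_ij = rmin_half_i + rmin_half_j`.
#'
#' @param r distance(s), Angstrom, `> 0`.
#' @param qi,qj partial charges (e).
#' @param eps_ij combined LJ well depth (kcal/mol, magnitude).
#' @param rmin_ij combined LJ minimum position (Angstrom).
#' @param scheme a [nonbonded_scheme()].
#' @return list with numeric `e_vdw` and `e_elec` (kcal/mol).
#' @export
pair_energy <- function(r, qi, qj, eps_ij, rmin_ij,
                        scheme = nonbonded_scheme()) {
  if (any(r <= 0)) stop("overlapping atoms: r must be > 0")
  sw <- switching_factor(r, scheme)
  sr6 <- (rmin_ij / r)^6
  e_vdw <- sw * eps_ij * (sr6^2 - 2 * sr6)
  e_el <- scheme$coulomb_constant * qi * qj / (scheme$dielectric * r)
  e_elec <- if (scheme$switch_electrostatics) sw * e_el
            else ifelse(r >= scheme$cutoff, 0, e_el)
  list(e_vdw = e_vdw, e_elec = e_elec)
}

## Atom indices of a region given as residue-number range (closed interval),
## optionally restricted to one subunit. Errors on unparameterized atoms when
## require_params is TRUE.
region_atoms <- function(topo, region, subunit = NULL, require_params = TRUE) {
  a <- topo$atoms
  idx <- which(a$residue_number >= region[1] & a$residue_number <= region[2])
  if (!is.null(subunit)) idx <- idx[a$subunit[idx] %in% subunit]
  if (!length(idx))
    stop("no atoms in residue range ", region[1], "-", region[2])
  if (require_params) {
    bad <- idx[is.na(a$charge[idx]) | is.na(a$lj_epsilon[idx]) |
               is.na(a$lj_rmin_half[idx])]
    if (length(bad))
      stop("unparameterized atom: ", a$residue_name[bad[1]],
           a$residue_number[bad[1]], "/", a$name[bad[1]],
           " (subunit ", a$subunit[bad[1]], ")")
  }
  idx
}

## Pairwise energy matrices between two atom sets in one frame.
## Returns list(e_vdw, e_elec) of |A| x |B| matrices.
frame_pair_matrices <- function(coords, box, topo, ia, ib, scheme) {
  a <- topo$atoms
  d2 <- dist2_pbc(matrix(coords[ia, ], length(ia), 3),
                  matrix(coords[ib, ], length(ib), 3), box)
  if (any(d2 == 0)) stop("overlapping atoms: r must be > 0")
  r <- sqrt(d2)
  sw <- switching_factor(r, scheme)
  eps <- outer(sqrt(a$lj_epsilon[ia]), sqrt(a$lj_epsilon[ib]))
  rmin <- outer(a$lj_rmin_half[ia], a$lj_rmin_half[ib], "+")
  qq <- outer(a$charge[ia], a$charge[ib])
  sr6 <- (rmin / r)^6
  e_vdw <- sw * eps * (sr6^2 - 2 * sr6)
  e_el <- scheme$coulomb_constant * qq / (scheme$dielectric * r)
  e_elec <- if (scheme$switch_electrostatics) sw * e_el
            else e_el * (r < scheme$cutoff)
  list(e_vdw = e_vdw, e_elec = e_elec)
}

#' Nonbonded interaction energy between two atom groups in one frame
#'
#' Sum of [pair_energy()] over all cross pairs with minimum-image distances;
#' no intra-group terms. The groups must be disjoint and fully
#' parameterized.
#'
#' @param coords `n_atoms x 3` frame coordinates (Angstrom).
#' @param box length-3 box (Angstrom); `NA` disables imaging.
#' @param topo a [topology()] with charges and LJ parameters assigned.
#' @param groupA,groupB disjoint atom index vectors.
#' @param scheme a [nonbonded_scheme()].
#' @return named numeric: `e_vdw`, `e_elec`, `e_total` (kcal/mol).
#' @export
group_energy <- function(coords, box, topo, groupA, groupB,
                         scheme = nonbonded_scheme()) {
  if (length(intersect(groupA, groupB)))
    stop("groups overlap: group energies need disjoint atom sets")
  a <- topo$atoms
  for (idx in list(groupA, groupB)) {
    bad <- idx[is.na(a$charge[idx]) | is.na(a$lj_epsilon[idx]) |
               is.na(a$lj_rmin_half[idx])]
    if (length(bad))
      stop("unparameterized atom: ", a$residue_name[bad[1]],
           a$residue_number[bad[1]], "/", a$name[bad[1]])
  }
  m <- frame_pair_matrices(coords, box, topo, groupA, groupB, scheme)
  ev <- sum(m$e_vdw); ee <- sum(m$e_elec)
  c(e_vdw = ev, e_elec = ee, e_total = ev + ee)
}

#' Per-residue decomposition of the S4-S5/S6 nonbonded interaction energy
#'
#' For every residue of region A (default 247-260, the S4-S5 linker), the
#' time-averaged nonbonded energy of its interaction with the *entire*
#' region B (default 323-358, the S6 helix), and vice versa. Each atom pair
#' is counted once, so the per-residue values of either direction sum to the
#' same group total. Errors are block-averaged standard deviations over
#' `n_blocks` consecutive time intervals ([block_error()]).
#'
#' The two regions share no chemical bonds, so all cross pairs are genuinely
#' nonbonded; this is asserted at run time by requiring the residue ranges to
#' be disjoint.
#'
#' @param traj a [trajectory()] (already restricted to the analysis window).
#' @param topo a [topology()] with parameters assigned.
#' @param regionA,regionB length-2 closed residue-number ranges.
#' @param scheme a [nonbonded_scheme()].
#' @param subunit optional subunit label(s) to restrict both regions to.
#' @param frames optional frame subset (e.g. from [exclude_bridge_frames()]).
#' @param n_blocks blocks for the error estimate.
#' @return list of class `"energy_profile"`: data.frames `profile_a` and
#'   `profile_b` (`residue_key`, `e_vdw`, `e_elec`, `e_total`, `se`), the
#'   `group` totals with SEs, and `per_frame_total` (kcal/mol per frame).
#' @export
per_residue_decomposition <- function(traj, topo, regionA = c(247, 260),
                                      regionB = c(323, 358),
                                      scheme = nonbonded_scheme(),
                                      subunit = NULL, frames = NULL,
                                      n_blocks = 5) {
  check_traj_topo(traj, topo)
  if (max(regionA[1], regionB[1]) <= min(regionA[2], regionB[2]))
    stop("regions overlap: per-residue decomposition needs disjoint ranges")
  ia <- region_atoms(topo, regionA, subunit)
  ib <- region_atoms(topo, regionB, subunit)
  if (is.null(frames)) frames <- seq_len(traj$n_frames)
  if (!length(frames)) stop("empty frame window")
  a <- topo$atoms
  keyA <- paste0(a$subunit[ia], ":", a$residue_number[ia])
  keyB <- paste0(a$subunit[ib], ":", a$residue_number[ib])
  resA <- unique(keyA); resB <- unique(keyB)
  IA <- outer(resA, keyA, "==") * 1
  IB <- outer(keyB, resB, "==") * 1
  nf <- length(frames)
  accA <- matrix(0, length(resA), 2)  # vdw, elec sums over frames
  accB <- matrix(0, length(resB), 2)
  serA <- array(0, c(nf, length(resA)))
  serB <- array(0, c(nf, length(resB)))
  tot <- numeric(nf)
  for (i in seq_len(nf)) {
    f <- frames[i]
    m <- frame_pair_matrices(traj$coords[f, , ], traj$box[f, ], topo,
                             ia, ib, scheme)
    etot_mat <- m$e_vdw + m$e_elec
    va <- IA %*% m$e_vdw %*% rep(1, length(ib))
    ea <- IA %*% m$e_elec %*% rep(1, length(ib))
    vb <- t(rep(1, length(ia))) %*% m$e_vdw %*% IB
    eb <- t(rep(1, length(ia))) %*% m$e_elec %*% IB
    accA <- accA + cbind(va, ea)
    accB <- accB + cbind(as.vector(vb), as.vector(eb))
    serA[i, ] <- va + ea
    serB[i, ] <- as.vector(vb) + as.vector(eb)
    tot[i] <- sum(etot_mat)
  }
  mk_profile <- function(keys, acc, ser) {
    data.frame(residue_key = keys,
               e_vdw = acc[, 1] / nf, e_elec = acc[, 2] / nf,
               e_total = (acc[, 1] + acc[, 2]) / nf,
               se = apply(ser, 2, function(x)
                 if (nf >= n_blocks) block_error(x, n_blocks) else NA_real_),
               stringsAsFactors = FALSE)
  }
  g_vdw <- sum(accA[, 1]) / nf
  g_elec <- sum(accA[, 2]) / nf
  structure(list(
    profile_a = mk_profile(resA, accA, serA),
    profile_b = mk_profile(resB, accB, serB),
    group = c(e_vdw = g_vdw, e_elec = g_elec, e_total = g_vdw + g_elec,
              se = if (nf >= n_blocks) block_error(tot, n_blocks) else NA_real_),
    per_frame_total = tot, frames = frames, n_blocks = n_blocks),
    class = "energy_profile")
}

#' @export
print.energy_profile <- function(x, ...) {
  g <- x$group
  cat(sprintf(
    "S4-S5/S6 style decomposition over %d frames\n  vdW %.3f  El %.3f  Tot %.3f +/- %.3f kcal/mol\n",
    length(x$frames), g["e_vdw"], g["e_elec"], g["e_total"], g["se"]))
  invisible(x)
}

#' Block-averaged error of a time series
#'
#' Splits the series into `n_blocks` consecutive, near-equal blocks and
#' returns the standard deviation between the block means (population SD,
#' dividing by the number of blocks) -- the error bar convention for
#' time-averaged energies over the last part of a trajectory.
#'
#' @param x numeric per-frame series.
#' @param n_blocks number of consecutive blocks (default 5).
#' @return SE (same units as `x`).
#' @export
block_error <- function(x, n_blocks = 5) {
  n <- length(x)
  if (n < n_blocks) stop("fewer frames (", n, ") than blocks (", n_blocks, ")")
  sizes <- rep(n %/% n_blocks, n_blocks)
  extra <- n %% n_blocks
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  idx <- rep(seq_len(n_blocks), sizes)
  means <- tapply(x, idx, mean)
  sqrt(sum((means - mean(means))^2) / n_blocks)
}

#' Frames free of a given inter-residue salt bridge
#'
#' Charge-reversal mutants can form an artificial salt bridge between the
#' mutated residue pair (e.g. R249E-K358); frames where that bridge is formed
#' are excluded from energy analyses. The bridge criterion mirrors the
#' protein-lipid one: minimum-image distance between the acid-side
#' carboxylate oxygens (OE1/OE2 or OD1/OD2) and the basic-side
#' guanidinium/ammonium nitrogens (NE/NH1/NH2 or NZ) strictly below `cutoff`.
#'
#' @param traj a [trajectory()].
#' @param topo a [topology()].
#' @param residue_a,residue_b `"subunit:resno"` keys (or bare residue
#'   numbers) of the two residues; one must be basic (ARG/LYS) and the other
#'   acidic (GLU/ASP).
#' @param cutoff Angstrom, strict `<`.
#' @return integer vector of frames where the bridge is absent.
#' @export
exclude_bridge_frames <- function(traj, topo, residue_a, residue_b,
                                  cutoff = 3.2) {
  occ <- residue_pair_occupancy(traj, topo, residue_a, residue_b, cutoff)
  which(!occ)
}

#' Per-frame salt-bridge occupancy between two protein residues
#' @inheritParams exclude_bridge_frames
#' @return logical vector, one value per frame (TRUE = bridge formed).
#' @export
residue_pair_occupancy <- function(traj, topo, residue_a, residue_b,
                                   cutoff = 3.2) {
  check_traj_topo(traj, topo)
  basic_names <- c(ARG = "NE NH1 NH2", LYS = "NZ", HSP = "ND1 NE2")
  acid_names <- c(GLU = "OE1 OE2", ASP = "OD1 OD2")
  find_group <- function(keyspec) {
    a <- topo$atoms
    if (grepl(":", keyspec)) {
      parts <- strsplit(keyspec, ":")[[1]]
      sel <- a$subunit == parts[1] & a$residue_number == as.integer(parts[2])
    } else sel <- a$residue_number == as.integer(keyspec)
    idx <- which(sel)
    if (!length(idx)) stop("residue not found: ", keyspec)
    rn <- unique(a$residue_name[idx])[1]
    nm <- if (rn %in% names(basic_names)) basic_names[[rn]]
          else if (rn %in% names(acid_names)) acid_names[[rn]]
          else stop("residue ", keyspec, " (", rn,
                    ") has no recognizable charged group")
    grp <- idx[a$name[idx] %in% strsplit(nm, " ")[[1]]]
    if (!length(grp))
      stop("no charged-group atoms found for residue ", keyspec)
    list(idx = grp, kind = if (rn %in% names(basic_names)) "basic" else "acid")
  }
  ga <- find_group(residue_a)
  gb <- find_group(residue_b)
  if (ga$kind == gb$kind)
    stop("need one basic and one acidic residue to define the bridge")
  vapply(seq_len(traj$n_frames), function(f)
    min_group_distance(traj$coords[f, , ], traj$box[f, ],
                       ga$idx, gb$idx) < cutoff, logical(1))
}
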