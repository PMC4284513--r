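#' Backbone RMSD series versus a reference frame
#'
#' Root-mean-square deviation of the backbone (N, CA, C, O) from a reference
#' frame after optimal rigid-body superposition (least-squares rotation +
#' translation, via [bio3d::rmsd()] with `fit = TRUE`). The plateau of this
#' series is what declares a trajectory equilibrated.
#'
#' @param traj a [trajectory()].
#' @param topo a [topology()]; the backbone is the stored `"backbone"`
#'   selection if present, else atoms named N/CA/C/O.
#' @param reference_frame frame index used as the reference (default 1).
#' @param fit superpose before computing the RMSD (default TRUE).
#' @return data.frame of class `"rmsd_series"` with `times` (ns) and
#'   `rmsd` (Angstrom).
#' @export
backbone_rmsd <- function(traj, topo, reference_frame = 1L, fit = TRUE) {
  check_traj_topo(traj, topo)
  bb <- topo$selections[["backbone"]]
  if (is.null(bb)) bb <- which(topo$atoms$name %in% c("N", "CA", "C", "O"))
  if (length(bb) < 3)
    stop("backbone selection has fewer than 3 atoms: superposition underdetermined")
  nf <- traj$n_frames
  xyz <- matrix(0, nf, 3L * length(bb))
  for (f in seq_len(nf))
    xyz[f, ] <- as.vector(t(matrix(traj$coords[f, bb, ], length(bb), 3)))
  r <- bio3d::rmsd(a = xyz[reference_frame, ], b = xyz, fit = fit)
  out <- data.frame(times = traj$times, rmsd = as.numeric(r))
  class(out) <- c("rmsd_series", "data.frame")
  out
}

#' Detect the start of the equilibrated segment of an RMSD series
#'
#' Operationalizes the visual "RMSD reached a plateau" call: the earliest
#' time `t` such that within the window `[t, t + window]` the RMSD spread
#' (max - min) stays within `tol`. Returns `NA` ("not equilibrated") when no
#' window qualifies.
#'
#' @param series an `rmsd_series` (or data.frame with `times`, `rmsd`).
#' @param window window length in ns (default 20).
#' @param tol maximum allowed RMSD spread in the window (Angstrom, default 1).
#' @return earliest equilibrated time (ns), or `NA_real_`.
#' @export
equilibration_start <- function(series, window = 20, tol = 1.0) {
  if (tol <= 0) stop("tol must be > 0")
  t <- series$times; r <- series$rmsd
  span <- t[length(t)] - t[1]
  if (span < 2 * window)
    stop("series span (", span, " ns) must be at least twice the window")
  for (i in seq_along(t)) {
    if (t[i] + window > t[length(t)] + 1e-9) break
    inw <- which(t >= t[i] & t <= t[i] + window)
    if (max(r[inw]) - min(r[inw]) <= tol) return(t[i])
  }
  NA_real_
}

#' Convergence check between analysis time-windows
#'
#' Compares salt-bridge probability tables computed on successive
#' time-windows (e.g. 50-100, 100-120 and 120-140 ns) and reports the
#' largest per-residue pairwise probability difference. The run is declared
#' converged when the global maximum stays at or below `threshold`.
#'
#' @param tables list (>= 2) of `probability_table` objects sharing keys.
#' @param threshold convergence threshold on `|delta p|` (default 0.15).
#' @return list with `per_residue` (data.frame `residue_key`, `max_delta`),
#'   `max_delta` (global), `converged`, `threshold`.
#' @export
window_convergence <- function(tables, threshold = 0.15) {
  if (length(tables) < 2) stop("need at least two window tables")
  keys <- tables[[1]]$residue_key
  for (tb in tables) if (!identical(sort(tb$residue_key), sort(keys)))
    stop("window tables have mismatched residue keys")
  P <- sapply(tables, function(tb) tb$probability[match(keys, tb$residue_key)])
  P <- matrix(P, nrow = length(keys))
  per_res <- apply(P, 1, function(p) max(dist(p)))
  out <- data.frame(residue_key = keys, max_delta = per_res,
                    stringsAsFactors = FALSE)
  list(per_residue = out, max_delta = max(per_res),
       converged = max(per_res) <= threshold, threshold = threshold)
}

#' Per-frame lipid headgroup positions (P1/P4/P5 centroid)
#'
#' The headgroup position of each lipid is the centroid of its P1, P4 and P5
#' phosphorus atoms, tracked per frame.
#'
#' @param traj a [trajectory()].
#' @param topo a [topology()]; lipid phosphorus atoms are selected with
#'   `p_selection` and grouped into lipids by (residue name, subunit,
#'   residue number).
#' @param p_selection selection expression for the marker atoms.
#' @param condition condition label stored with the result (e.g. `"WT-A/O"`).
#' @return object of class `"headgroup_positions"`: array
#'   `[frame, lipid, 3]` with lipid keys in dimnames, plus attributes.
#' @export
headgroup_positions <- function(traj, topo, p_selection = "name P1 P4 P5",
                                condition = NA_character_) {
  check_traj_topo(traj, topo)
  idx <- select(topo, p_selection)
  if (!length(idx)) stop("no headgroup marker atoms selected")
  a <- topo$atoms
  lkey <- paste(a$residue_name[idx], a$subunit[idx], a$residue_number[idx],
                sep = ":")
  lipids <- unique(lkey)
  nf <- traj$n_frames
  pos <- array(0, c(nf, length(lipids), 3),
               dimnames = list(NULL, lipids, c("x", "y", "z")))
  for (l in seq_along(lipids)) {
    sub <- idx[lkey == lipids[l]]
    for (k in 1:3)
      pos[, l, k] <- rowMeans(matrix(traj$coords[, sub, k], nf, length(sub)))
  }
  structure(pos, class = "headgroup_positions", condition = condition,
            times = traj$times)
}

#' Lipid headgroup shift between two conditions along a landmark axis
#'
#' Projects the change in mean headgroup position (condition b minus
#' condition a) onto the unit vector from an S4 landmark centroid to an S6
#' landmark centroid; positive values mean the lipid moved toward S6 (the
#' displacement seen when gain-of-function mutations shift PIP2 toward the
#' gate). Both ensembles must be imaged consistently relative to the protein.
#'
#' @param pos_a,pos_b `headgroup_positions` ensembles with matching lipids.
#' @param axis_from,axis_to length-3 landmark centroids (e.g. S4 and S6
#'   selection centroids); the axis points from `axis_from` to `axis_to`.
#' @return list with `per_lipid` signed displacements (Angstrom, named by
#'   lipid) and their `mean`.
#' @export
headgroup_shift <- function(pos_a, pos_b, axis_from, axis_to) {
  if (!identical(dimnames(pos_a)[[2]], dimnames(pos_b)[[2]]))
    stop("ensembles track different lipids")
  u <- as.numeric(axis_to) - as.numeric(axis_from)
  nu <- sqrt(sum(u^2))
  if (nu < 1e-9) stop("degenerate axis: landmark centroids coincide")
  u <- u / nu
  mean_a <- apply(pos_a, c(2, 3), mean)
  mean_b <- apply(pos_b, c(2, 3), mean)
  d <- (mean_b - mean_a) %*% u
  per_lipid <- setNames(as.numeric(d), dimnames(pos_a)[[2]])
  list(per_lipid = per_lipid, mean = mean(per_lipid))
}

#' Centroid of a selection in one frame
#' @param traj a [trajectory()].
#' @param topo a [topology()].
#' @param expression selection string ([select()]).
#' @param frame frame index (default 1) or `"mean"` for the all-frame mean.
#' @return length-3 centroid (Angstrom).
#' @export
selection_centroid <- function(traj, topo, expression, frame = 1L) {
  idx <- select(topo, expression)
  if (!length(idx)) stop("selection matched no atoms")
  if (identical(frame, "mean")) {
    apply(traj$coords[, idx, , drop = FALSE], 3, mean)
  } else {
    colMeans(matrix(traj$coords[frame, idx, ], length(idx), 3))
  }
}
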