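#' Build a molecular topology
#'
#' A topology holds per-atom identity (name, residue number and name, subunit,
#' partial charge, Lennard-Jones parameters) plus named atom selections. It is
#' the static companion of a [trajectory()]: every frame of a trajectory must
#' carry one coordinate triplet per topology atom.
#'
#' Residue numbering follows the author (structure-file) numbering verbatim;
#' all residue ranges elsewhere in the package are closed intervals. Charges
#' are in elementary charge units; `lj_epsilon` is the well depth magnitude in
#' kcal/mol (stored non-negative) and `lj_rmin_half` is Rmin/2 in Angstrom.
#'
#' @param atoms data.frame with columns `name`, `residue_number`,
#'   `residue_name`, `subunit`, and optionally `charge`, `lj_epsilon`,
#'   `lj_rmin_half` (missing parameter columns are filled with `NA` and can be
#'   assigned later with [assign_parameters()]).
#' @param selections named list of integer atom-index vectors (1-based).
#' @return object of class `"topology"`.
#' @seealso [select()], [read_structure()], [assign_parameters()]
#' @export
topology <- function(atoms, selections = list()) {
  stopifnot(is.data.frame(atoms))
  need <- c("name", "residue_number", "residue_name", "subunit")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("topology atoms missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("charge", "lj_epsilon", "lj_rmin_half"))
    if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  atoms$name <- as.character(atoms$name)
  atoms$residue_name <- as.character(atoms$residue_name)
  atoms$subunit <- as.character(atoms$subunit)
  atoms$residue_number <- as.integer(atoms$residue_number)
  ## 0-based index mirrors the on-disk atom serial order; unique and contiguous
  atoms$index <- seq_len(nrow(atoms)) - 1L
  rownames(atoms) <- NULL
  topo <- structure(list(atoms = atoms, selections = list()),
                    class = "topology")
  for (nm in names(selections)) topo <- add_selection(topo, nm, selections[[nm]])
  validate_topology(topo)
  topo
}

validate_topology <- function(topo) {
  a <- topo$atoms
  if (anyDuplicated(a$index) || !identical(a$index, seq_len(nrow(a)) - 1L))
    stop("topology atom indices must be unique and contiguous")
  bad <- !is.na(a$lj_rmin_half) & a$lj_rmin_half <= 0
  if (any(bad))
    stop("lj_rmin_half must be > 0 where present (atom ",
         a$index[which(bad)[1]], ")")
  for (nm in names(topo$selections)) {
    idx <- topo$selections[[nm]]
    if (length(idx) && (min(idx) < 1L || max(idx) > nrow(a)))
      stop("selection '", nm, "' references atoms outside the topology")
  }
  invisible(topo)
}

#' @export
print.topology <- function(x, ...) {
  a <- x$atoms
  cat("Topology:", nrow(a), "atoms,",
      length(unique(paste(a$subunit, a$residue_number))), "residues,",
      length(unique(a$subunit)), "subunit(s)\n")
  if (length(x$selections))
    cat("Selections:", paste(sprintf("%s[%d]", names(x$selections),
                                     vapply(x$selections, length, 1L)),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Register a named atom selection on a topology
#'
#' @param topo a [topology()].
#' @param name selection name, e.g. `"basic_nitrogens"`.
#' @param what either an integer vector of 1-based atom indices or a selection
#'   expression string understood by [select()].
#' @return the topology with the selection stored.
#' @export
add_selection <- function(topo, name, what) {
  idx <- if (is.character(what) && length(what) == 1L)
    select(topo, what) else sort(unique(as.integer(what)))
  if (length(idx) && (min(idx) < 1L || max(idx) > nrow(topo$atoms)))
    stop("selection '", name, "' references atoms outside the topology")
  topo$selections[[name]] <- idx
  topo
}

#' Residue keys ("subunit:residue_number") for a set of atoms
#' @param topo a [topology()].
#' @param idx atom indices (1-based); default all atoms.
#' @return character vector, one key per atom.
#' @export
residue_keys <- function(topo, idx = seq_len(nrow(topo$atoms))) {
  a <- topo$atoms
  paste0(a$subunit[idx], ":", a$residue_number[idx])
}

#' Build a coordinate trajectory
#'
#' Ordered frames of Cartesian coordinates with frame times and an
#' orthorhombic periodic box per frame. Coordinates are in Angstrom, times in
#' nanoseconds.
#'
#' @param coords numeric array `[n_frames, n_atoms, 3]`, or a single
#'   `n_atoms x 3` matrix for a one-frame trajectory.
#' @param times numeric vector of frame times (ns), strictly increasing.
#' @param box numeric `n_frames x 3` matrix of box edge lengths (Angstrom), or
#'   a length-3 vector recycled to every frame. `NA` is allowed (e.g. a bare
#'   PDB without CRYST1); operations that need periodicity will refuse to run.
#' @return object of class `"trajectory"`.
#' @export
trajectory <- function(coords, times = NULL, box = NA_real_) {
  if (is.matrix(coords)) coords <- array(coords, c(1L, nrow(coords), 3L))
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  nf <- dim(coords)[1]
  if (is.null(times)) times <- seq_len(nf) - 1
  if (length(times) != nf) stop("times length must equal frame count")
  if (nf > 1 && any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (is.null(dim(box))) box <- matrix(rep(box, length.out = 3L * nf), nf, 3L,
                                       byrow = TRUE)
  if (!all(dim(box) == c(nf, 3L))) stop("box must be n_frames x 3")
  if (any(!is.na(box) & box <= 0)) stop("box lengths must be > 0")
  structure(list(coords = coords, times = as.numeric(times), box = box,
                 n_frames = nf, n_atoms = dim(coords)[2]),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory:", x$n_frames, "frame(s) x", x$n_atoms, "atoms, t =",
      x$times[1], "..", x$times[x$n_frames], "ns\n")
  invisible(x)
}

#' Extract a frame or frame window from a trajectory
#' @param traj a [trajectory()].
#' @param frames integer vector of frame indices (1-based).
#' @return a [trajectory()] restricted to `frames`.
#' @export
subset_frames <- function(traj, frames) {
  frames <- as.integer(frames)
  if (any(frames < 1L | frames > traj$n_frames))
    stop("frame index out of range")
  trajectory(traj$coords[frames, , , drop = FALSE], traj$times[frames],
             traj$box[frames, , drop = FALSE])
}

#' Select frames whose times fall in a closed window
#' @param traj a [trajectory()].
#' @param start,end window bounds in ns (closed interval).
#' @return a [trajectory()] restricted to the window.
#' @export
time_window <- function(traj, start, end) {
  keep <- which(traj$times >= start & traj$times <= end)
  if (!length(keep)) stop("no frames in window [", start, ", ", end, "] ns")
  subset_frames(traj, keep)
}

check_traj_topo <- function(traj, topo) {
  if (traj$n_atoms != nrow(topo$atoms))
    stop("trajectory has ", traj$n_atoms, " atoms but topology has ",
         nrow(topo$atoms))
  invisible(TRUE)
}
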