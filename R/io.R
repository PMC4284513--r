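#' Read a PDB structure
#'
#' Parses a PDB v3 file into a [topology()] (atom identities, author residue
#' numbering preserved, chains mapped to subunit labels) and a single-frame
#' [trajectory()]. Charges and Lennard-Jones parameters are *not* taken from
#' the PDB; merge them afterwards with [read_parameters()] +
#' [assign_parameters()].
#'
#' @param path PDB file.
#' @return list with elements `topology` and `trajectory` (one frame; box from
#'   CRYST1 when present, `NA` otherwise).
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grep("^(ATOM  |HETATM)", lines)
  if (!length(rec)) stop("no ATOM/HETATM records in ", path)
  for (i in rec) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed ATOM/HETATM record (missing coordinates) at line ", i,
           " of ", path)
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz))
      stop("malformed ATOM/HETATM record (unparseable coordinates) at line ",
           i, " of ", path)
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  chain <- ifelse(is.na(a$chain) | a$chain == "", "A", a$chain)
  topo <- topology(data.frame(
    name = a$elety, residue_number = a$resno, residue_name = a$resid,
    subunit = chain, stringsAsFactors = FALSE))
  box <- rep(NA_real_, 3)
  cry <- grep("^CRYST1", lines, value = TRUE)
  if (length(cry)) {
    b <- suppressWarnings(as.numeric(c(substr(cry[1], 7, 15),
                                       substr(cry[1], 16, 24),
                                       substr(cry[1], 25, 33))))
    if (!anyNA(b) && all(b > 0)) box <- b
  }
  coords <- cbind(a$x, a$y, a$z)
  list(topology = topo,
       trajectory = trajectory(coords, times = 0, box = box))
}

#' Write a topology + frame as PDB
#'
#' @param topo a [topology()].
#' @param traj a [trajectory()]; its first frame (or `frame`) is written.
#' @param path output file.
#' @param frame frame index to write.
#' @return `path`, invisibly.
#' @export
write_structure <- function(topo, traj, path, frame = 1L) {
  check_traj_topo(traj, topo)
  a <- topo$atoms
  xyz <- as.vector(t(traj$coords[frame, , ]))
  bio3d::write.pdb(file = path, xyz = xyz, resno = a$residue_number,
                   resid = a$residue_name, chain = a$subunit, elety = a$name)
  if (!anyNA(traj$box[frame, ])) {
    cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     traj$box[frame, 1], traj$box[frame, 2], traj$box[frame, 3],
                     90, 90, 90)
    writeLines(c(cryst, readLines(path, warn = FALSE)), path)
  }
  invisible(path)
}

#' Read a multi-frame trajectory
#'
#' Dispatches on `format` (or the file extension for `"auto"`): CHARMM/NAMD
#' DCD via [bio3d::read.dcd()] (big or little endian), or the plain-text
#' `xyz_frames` dialect written by [write_trajectory()]. Frame times come from
#' the file where the format stores them (`xyz_frames`) or from `dt`/`t0`
#' (DCD, whose header timestep is not reliably in ns).
#'
#' @param path trajectory file.
#' @param topology optional [topology()]; when given, the atom count is
#'   checked and a mismatch is an error stating both counts.
#' @param format `"auto"`, `"dcd"` or `"xyz_frames"`.
#' @param dt frame interval in ns (used when the format has no times).
#' @param t0 time of the first frame (ns).
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, topology = NULL,
                            format = c("auto", "dcd", "xyz_frames"),
                            dt = 1, t0 = 0) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd"
              else "xyz_frames"
  traj <- if (format == "dcd") read_dcd_file(path, dt = dt, t0 = t0)
          else read_xyz_frames(path)
  if (!is.null(topology) && traj$n_atoms != nrow(topology$atoms))
    stop("trajectory has ", traj$n_atoms, " atoms but topology has ",
         nrow(topology$atoms))
  traj
}

#' Write a trajectory
#'
#' @param traj a [trajectory()].
#' @param path output file.
#' @param topo optional [topology()] supplying atom names for `xyz_frames`.
#' @param format `"xyz_frames"` (plain text, documented below) or `"dcd"`.
#' @param digits decimal digits for `xyz_frames` coordinates.
#'
#' @details The `xyz_frames` dialect is an XYZ-like multi-frame text format:
#' per frame, a line with the atom count, a comment line
#' `t= <ns> box= <lx> <ly> <lz>`, then one `name x y z` line per atom
#' (Angstrom). It round-trips through [read_trajectory()] to the written
#' precision.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, topo = NULL,
                             format = c("xyz_frames", "dcd"), digits = 6) {
  format <- match.arg(format)
  if (format == "dcd") return(write_dcd_file(traj, path))
  nm <- if (!is.null(topo)) topo$atoms$name else rep("X", traj$n_atoms)
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- paste0("%s %.", digits, "f %.", digits, "f %.", digits, "f")
  for (f in seq_len(traj$n_frames)) {
    writeLines(as.character(traj$n_atoms), con)
    writeLines(sprintf("t= %.6f box= %.6f %.6f %.6f", traj$times[f],
                       traj$box[f, 1], traj$box[f, 2], traj$box[f, 3]), con)
    writeLines(sprintf(fmt, nm, traj$coords[f, , 1], traj$coords[f, , 2],
                       traj$coords[f, , 3]), con)
  }
  invisible(path)
}

read_xyz_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(length(lines))]
  if (!length(lines) || all(!nzchar(trimws(lines))))
    stop("empty trajectory file: ", path)
  pos <- 1L; frame <- 0L
  coords <- list(); times <- numeric(0); boxes <- list(); na_ref <- NULL
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    frame <- frame + 1L
    na <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(na) || na <= 0)
      stop("bad atom-count line at frame ", frame, " of ", path)
    if (pos + 1L + na > length(lines))
      stop("truncated final frame (frame ", frame, ") in ", path)
    hdr <- lines[pos + 1L]
    m <- regmatches(hdr, regexec(
      "t=\\s*([-0-9.eE+]+)\\s+box=\\s*([-0-9.eE+]+)\\s+([-0-9.eE+]+)\\s+([-0-9.eE+]+)",
      hdr))[[1]]
    if (length(m) != 5)
      stop("bad frame header at frame ", frame, " of ", path)
    times <- c(times, as.numeric(m[2]))
    boxes[[frame]] <- as.numeric(m[3:5])
    body <- lines[(pos + 2L):(pos + 1L + na)]
    parts <- strsplit(trimws(body), "[[:space:]]+")
    if (any(vapply(parts, length, 1L) < 4))
      stop("truncated atom line in frame ", frame, " of ", path)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (anyNA(xyz)) stop("unparseable coordinates in frame ", frame, " of ", path)
    if (is.null(na_ref)) na_ref <- na
    else if (na != na_ref)
      stop("frame ", frame, " has ", na, " atoms but frame 1 has ", na_ref)
    coords[[frame]] <- xyz
    pos <- pos + 2L + na
  }
  arr <- array(0, c(frame, na_ref, 3L))
  for (f in seq_len(frame)) arr[f, , ] <- coords[[f]]
  trajectory(arr, times = times, box = do.call(rbind, boxes))
}

read_dcd_file <- function(path, dt = 1, t0 = 0) {
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  cell <- tryCatch(suppressWarnings(bio3d::read.dcd(path, cell = TRUE,
                                                    verbose = FALSE)),
                   error = function(e) NULL)
  nf <- nrow(xyz); na <- ncol(xyz) / 3L
  coords <- array(0, c(nf, na, 3L))
  for (d in 1:3) coords[, , d] <- xyz[, seq(d, by = 3L, length.out = na)]
  box <- if (!is.null(cell)) cell[, 1:3, drop = FALSE]
         else matrix(NA_real_, nf, 3)
  trajectory(coords, times = t0 + dt * (seq_len(nf) - 1L), box = box)
}

## CHARMM-style DCD writer (32-bit record markers, native endianness, unit
## cell block per frame with cosine angle convention). No installed R package
## writes DCD; reading back goes through bio3d::read.dcd.
write_dcd_file <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- traj$n_frames; na <- traj$n_atoms
  writeBin(84L, con, size = 4)
  writeChar("CORD", con, 4, eos = NULL)
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L
  icntrl[11] <- 1L   # unit-cell blocks present
  icntrl[20] <- 24L  # CHARMM version stamp
  writeBin(icntrl, con, size = 4)
  writeBin(84L, con, size = 4)
  writeBin(84L, con, size = 4)
  writeBin(1L, con, size = 4)
  writeChar(sprintf("%-80s", "written by kvcoupling"), con, 80, eos = NULL)
  writeBin(84L, con, size = 4)
  writeBin(4L, con, size = 4)
  writeBin(as.integer(na), con, size = 4)
  writeBin(4L, con, size = 4)
  for (f in seq_len(nf)) {
    writeBin(48L, con, size = 4)
    b <- traj$box[f, ]
    if (anyNA(b)) b <- c(0, 0, 0)
    ## a, cos(gamma), b, cos(beta), cos(alpha), c
    writeBin(as.double(c(b[1], 0, b[2], 0, 0, b[3])), con, size = 8)
    writeBin(48L, con, size = 4)
    for (d in 1:3) {
      writeBin(as.integer(4L * na), con, size = 4)
      writeBin(as.numeric(traj$coords[f, , d]), con, size = 4)
      writeBin(as.integer(4L * na), con, size = 4)
    }
  }
  invisible(path)
}

#' Read a per-atom nonbonded parameter table
#'
#' Expects a delimited file with header
#' `residue_name,atom_name,charge_e,lj_epsilon_kcal,lj_rmin_half_A`
#' (comma or tab separated). Keys are `(residue_name, atom_name)` pairs;
#' duplicates and non-numeric fields are errors.
#'
#' @param path CSV/TSV file.
#' @return data.frame of class `"nb_parameters"`.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 colClasses = "character")
  need <- c("residue_name", "atom_name", "charge_e", "lj_epsilon_kcal",
            "lj_rmin_half_A")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("parameter table missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("charge_e", "lj_epsilon_kcal", "lj_rmin_half_A")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v))
      stop("non-numeric value in column '", col, "' (row ",
           which(is.na(v))[1], ") of ", path)
    df[[col]] <- v
  }
  key <- paste(df$residue_name, df$atom_name)
  if (anyDuplicated(key))
    stop("duplicate parameter key: ", key[which(duplicated(key))[1]])
  class(df) <- c("nb_parameters", "data.frame")
  df
}

#' Write a parameter table (round-trips through [read_parameters()])
#' @param params data.frame with the [read_parameters()] columns.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  df <- as.data.frame(params)
  df$charge_e <- sprintf("%.10g", df$charge_e)
  df$lj_epsilon_kcal <- sprintf("%.10g", df$lj_epsilon_kcal)
  df$lj_rmin_half_A <- sprintf("%.10g", df$lj_rmin_half_A)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Merge nonbonded parameters into a topology
#'
#' Matches atoms on `(residue_name, name)` against the table from
#' [read_parameters()]. Unmatched atoms keep `NA` parameters and are reported
#' in the `"unmatched"` attribute; energy routines refuse to run on them.
#'
#' @param topo a [topology()].
#' @param params an `nb_parameters` table.
#' @param warn warn when atoms stay unmatched.
#' @return the topology with `charge`, `lj_epsilon`, `lj_rmin_half` filled.
#' @export
assign_parameters <- function(topo, params, warn = TRUE) {
  a <- topo$atoms
  key <- paste(a$residue_name, a$name)
  pkey <- paste(params$residue_name, params$atom_name)
  hit <- match(key, pkey)
  a$charge <- params$charge_e[hit]
  a$lj_epsilon <- abs(params$lj_epsilon_kcal[hit])
  a$lj_rmin_half <- params$lj_rmin_half_A[hit]
  topo$atoms <- a
  un <- a[is.na(hit), c("index", "name", "residue_number", "residue_name",
                        "subunit")]
  attr(topo, "unmatched") <- un
  if (warn && nrow(un))
    warning(nrow(un), " atom(s) without parameters, e.g. ",
            paste(head(paste0(un$residue_name, "/", un$name), 3),
                  collapse = ", "))
  validate_topology(topo)
  topo
}
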