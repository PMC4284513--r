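## Squared minimum-image distances between two coordinate sets under an
## orthorhombic box. D: nd x 3, A: na x 3, box: length-3. Returns nd x na.
dist2_pbc <- function(D, A, box) {
  d2 <- 0
  for (k in 1:3) {
    dx <- outer(D[, k], A[, k], "-")
    if (!is.na(box[k])) dx <- dx - box[k] * round(dx / box[k])
    d2 <- d2 + dx * dx
  }
  d2
}

#' Minimum distance between two atom groups (minimum image)
#'
#' The minimum over all donor-acceptor pairs of the minimum-image distance
#' under the frame's orthorhombic box, as used for the salt-bridge criterion
#' (minimal N...O distance between basic side-chain nitrogens and lipid
#' phosphate oxygens).
#'
#' @param coords `n_atoms x 3` coordinate matrix of one frame (Angstrom).
#' @param box length-3 box edge lengths (Angstrom); `NA` disables imaging.
#' @param donors,acceptors atom index vectors (1-based), non-empty.
#' @return minimum distance in Angstrom.
#' @export
min_group_distance <- function(coords, box, donors, acceptors) {
  if (!length(donors) || !length(acceptors))
    stop("donor and acceptor sets must be non-empty")
  sqrt(min(dist2_pbc(coords[donors, , drop = FALSE],
                     coords[acceptors, , drop = FALSE], box)))
}

#' Detect protein-lipid salt bridges along a trajectory
#'
#' A bridge between a basic residue and a lipid is formed in a frame when the
#' minimum-image distance between any of the residue's charged-group nitrogens
#' and any of the lipid's phosphate oxygens is strictly less than `cutoff`
#' (default 3.2 Angstrom; a pair at exactly 3.2 is *not* counted). Donor atoms
#' are grouped into residues by (subunit, residue number), acceptor atoms into
#' lipids by (residue name, subunit, residue number).
#'
#' @param traj a [trajectory()].
#' @param topo a [topology()] carrying the selections named by
#'   `donor_selection` / `acceptor_selection`.
#' @param cutoff bridge distance criterion (Angstrom, strict `<`).
#' @param donor_selection,acceptor_selection names of stored selections.
#' @return object of class `"contact_series"`: list with logical `occupancy`
#'   array `[frame, residue, lipid]`, `residues` ("subunit:resno" keys),
#'   `lipids` keys, and `times`.
#' @export
detect_bridges <- function(traj, topo, cutoff = 3.2,
                           donor_selection = "basic_nitrogens",
                           acceptor_selection = "pip2_phosphate_oxygens") {
  check_traj_topo(traj, topo)
  for (nm in c(donor_selection, acceptor_selection))
    if (is.null(topo$selections[[nm]]))
      stop("topology has no selection named '", nm, "'")
  don <- topo$selections[[donor_selection]]
  acc <- topo$selections[[acceptor_selection]]
  if (!length(don) || !length(acc))
    stop("donor/acceptor selections must be non-empty")
  if (any(!is.na(traj$box) & traj$box < 2 * cutoff))
    stop("box smaller than twice the cutoff: minimum image invalid")
  a <- topo$atoms
  rkey <- paste0(a$subunit[don], ":", a$residue_number[don])
  lkey <- paste(a$residue_name[acc], a$subunit[acc], a$residue_number[acc],
                sep = ":")
  residues <- unique(rkey)
  lipids <- unique(lkey)
  Rind <- outer(residues, rkey, "==") * 1        # nres x ndon
  Lind <- outer(lkey, lipids, "==") * 1          # nacc x nlip
  nf <- traj$n_frames
  occ <- array(FALSE, c(nf, length(residues), length(lipids)),
               dimnames = list(NULL, residues, lipids))
  c2 <- cutoff^2
  for (f in seq_len(nf)) {
    d2 <- dist2_pbc(matrix(traj$coords[f, don, ], length(don), 3),
                    matrix(traj$coords[f, acc, ], length(acc), 3),
                    traj$box[f, ])
    occ[f, , ] <- (Rind %*% (d2 < c2) %*% Lind) > 0
  }
  structure(list(occupancy = occ, residues = residues, lipids = lipids,
                 times = traj$times, cutoff = cutoff),
            class = "contact_series")
}

#' @export
print.contact_series <- function(x, ...) {
  cat("ContactSeries:", dim(x$occupancy)[1], "frames x",
      length(x$residues), "residues x", length(x$lipids), "lipids (cutoff",
      x$cutoff, "A)\n")
  invisible(x)
}

#' Per-lipid average salt-bridge counts
#'
#' For each lipid, the mean over frames of the number of residues it bridges
#' simultaneously, plus the set of partner residues (bridged in at least one
#' frame). Used to single out strongly bound lipids: a lipid whose average
#' approaches the size of its partner set is engaged persistently.
#'
#' @param cs a `contact_series` from [detect_bridges()].
#' @param region_map optional named map residue -> region label (names are
#'   either full `"subunit:resno"` keys or bare residue numbers) used to fill
#'   `regions_touched`.
#' @return data.frame of class `"lipid_bridge_summary"` with one row per
#'   lipid: `lipid_key`, `mean_bridges_per_frame`, `n_partners`,
#'   `same_subunit`, list-columns `partners` and `regions_touched`.
#' @export
per_lipid_average <- function(cs, region_map = NULL) {
  occ <- cs$occupancy
  nf <- dim(occ)[1]
  res <- lapply(seq_along(cs$lipids), function(l) {
    m <- matrix(occ[, , l], nf, length(cs$residues))
    partners <- cs$residues[colSums(m) > 0]
    regions <- if (is.null(region_map)) character(0) else
      unique(unname(map_regions(partners, region_map, strict = FALSE)))
    sub <- sub(":.*$", "", partners)
    list(mean = mean(rowSums(m)), partners = partners, regions = regions,
         same = length(partners) > 0 && length(unique(sub)) == 1)
  })
  out <- data.frame(
    lipid_key = cs$lipids,
    mean_bridges_per_frame = vapply(res, `[[`, 1, "mean"),
    n_partners = vapply(res, function(r) length(r$partners), 1L),
    same_subunit = vapply(res, `[[`, TRUE, "same"),
    stringsAsFactors = FALSE)
  out$partners <- I(lapply(res, `[[`, "partners"))
  out$regions_touched <- I(lapply(res, `[[`, "regions"))
  class(out) <- c("lipid_bridge_summary", "data.frame")
  out
}

## Map residue keys to region labels. region_map names may be full keys
## ("A:249") or bare residue numbers ("249").
map_regions <- function(keys, region_map, strict = TRUE) {
  resno <- sub("^.*:", "", keys)
  hit <- ifelse(keys %in% names(region_map), region_map[keys],
                region_map[resno])
  if (strict && anyNA(hit))
    stop("residue(s) not covered by region map: ",
         paste(keys[is.na(hit)], collapse = ", "))
  setNames(hit, keys)
}

#' Classify lipid binding poses as intrasubunit
#'
#' A lipid is labelled `"intrasubunit"` when its partner residues span at
#' least two distinct regions among S2-S3, S4-S5 and S6 *and* all partners
#' belong to one subunit -- the binding pose in which one PIP2 headgroup
#' simultaneously coordinates the S2-S3 loop, the S4-S5 linker and/or the S6
#' terminus of the same subunit. Everything else is `"other"`.
#'
#' @param summary a [per_lipid_average()] result.
#' @param region_map named map residue -> region label (must cover all
#'   partner residues; `"S2-S3"`, `"S4-S5"`, `"S6"` are the site regions).
#' @return character vector of labels, named by lipid key.
#' @export
classify_intrasubunit <- function(summary, region_map) {
  site_regions <- c("S2-S3", "S4-S5", "S6")
  labs <- vapply(seq_len(nrow(summary)), function(i) {
    partners <- summary$partners[[i]]
    if (!length(partners)) return("other")
    regions <- map_regions(partners, region_map, strict = TRUE)
    hits <- unique(regions[regions %in% site_regions])
    if (length(hits) >= 2 && summary$same_subunit[i]) "intrasubunit" else "other"
  }, character(1))
  setNames(labs, summary$lipid_key)
}

#' Salt-bridge formation probabilities with across-run error bars
#'
#' For each residue the probability is the pooled fraction of frames (over
#' all runs) in which the residue bridges *any* lipid (logical OR over
#' lipids). With `pool_subunits = TRUE` the four subunit copies are treated as
#' exchangeable samples: occupancy columns of residues sharing a residue
#' number are concatenated and keyed by residue number alone. The error bar
#' is the standard deviation of per-run probabilities; following the
#' descriptive-error-bar convention it divides by the number of runs
#' (population SD) by default, switchable to the sample SD.
#'
#' @param runs a single `contact_series` or a list of them (one per MD run).
#' @param pool_subunits pool subunit copies by residue number.
#' @param sd_convention `"population"` (divide by n_runs) or `"sample"`.
#' @return data.frame of class `"probability_table"` with columns
#'   `residue_key`, `probability`, `sd`, `n_runs`, `n_frames_total`,
#'   `single_run`.
#' @export
formation_probability <- function(runs, pool_subunits = TRUE,
                                  sd_convention = c("population", "sample")) {
  sd_convention <- match.arg(sd_convention)
  if (inherits(runs, "contact_series")) runs <- list(runs)
  if (!length(runs)) stop("at least one run is required")
  per_run <- lapply(runs, function(cs) {
    occ <- cs$occupancy
    if (dim(occ)[1] == 0) stop("contact series with zero frames")
    ## residue-level occupancy: OR over lipids
    d <- dim(occ)
    m <- matrix(FALSE, d[1], d[2], dimnames = list(NULL, cs$residues))
    for (l in seq_len(d[3])) m <- m | matrix(occ[, , l], d[1], d[2])
    if (pool_subunits) {
      resno <- sub("^.*:", "", cs$residues)
      groups <- split(seq_along(cs$residues), resno)
      pooled <- lapply(groups, function(j) as.vector(m[, j]))
      list(keys = names(groups),
           formed = vapply(pooled, sum, 1),
           total = vapply(pooled, length, 1))
    } else {
      list(keys = cs$residues, formed = colSums(m),
           total = rep(nrow(m), ncol(m)))
    }
  })
  keys <- per_run[[1]]$keys
  for (r in per_run) if (!identical(sort(r$keys), sort(keys)))
    stop("runs have mismatched residue keys")
  formed <- sapply(per_run, function(r) r$formed[match(keys, r$keys)])
  total <- sapply(per_run, function(r) r$total[match(keys, r$keys)])
  formed <- matrix(formed, nrow = length(keys))
  total <- matrix(total, nrow = length(keys))
  n_runs <- length(per_run)
  p_run <- formed / total
  pooled <- rowSums(formed) / rowSums(total)
  sdv <- if (n_runs == 1) rep(0, length(keys)) else {
    dev2 <- rowSums((p_run - rowMeans(p_run))^2)
    denom <- if (sd_convention == "population") n_runs else n_runs - 1
    sqrt(dev2 / denom)
  }
  out <- data.frame(residue_key = keys, probability = pooled, sd = sdv,
                    n_runs = n_runs, n_frames_total = rowSums(total),
                    single_run = n_runs == 1, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("probability_table", "data.frame")
  out
}

#' Categorize a contact probability
#'
#' Bins used when describing how often a residue engages the lipid:
#' `"frequent"` (p > 0.75), `"moderate"` (0.25 <= p <= 0.50),
#' `"intermittent"` (0 < p < 0.25 or 0.50 < p <= 0.75) and `"none"` (p = 0).
#'
#' @param p probability vector in `[0, 1]`.
#' @return character vector of categories.
#' @export
categorize <- function(p) {
  if (any(p < 0 | p > 1)) stop("probability out of [0, 1]")
  ifelse(p > 0.75, "frequent",
    ifelse(p >= 0.25 & p <= 0.50, "moderate",
      ifelse(p == 0, "none", "intermittent")))
}

#' Compare two probability tables (e.g. WT vs mutant)
#'
#' Per-residue probability change `delta = p_b - p_a`, flagged significant
#' when `|delta|` exceeds the first table's error bar -- the working rule for
#' declaring that a mutation changed a contact probability beyond the WT
#' run-to-run spread.
#'
#' @param a,b `probability_table` objects sharing residue keys.
#' @return data.frame with `residue_key`, `p_a`, `sd_a`, `p_b`, `delta`,
#'   `significant`.
#' @export
compare_probability_tables <- function(a, b) {
  common <- intersect(a$residue_key, b$residue_key)
  if (!length(common)) stop("tables share no residue keys")
  ia <- match(common, a$residue_key)
  ib <- match(common, b$residue_key)
  out <- data.frame(residue_key = common,
                    p_a = a$probability[ia], sd_a = a$sd[ia],
                    p_b = b$probability[ib],
                    stringsAsFactors = FALSE)
  out$delta <- out$p_b - out$p_a
  out$significant <- abs(out$delta) > out$sd_a
  out
}
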