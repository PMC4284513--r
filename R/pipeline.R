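## Allowed configuration schema: stage -> key -> validator (NULL = any).
pipeline_schema <- function() {
  num1 <- function(x) is.numeric(x) && length(x) == 1
  pos1 <- function(x) num1(x) && x > 0
  int1 <- function(x) num1(x) && x == round(x)
  bool1 <- function(x) is.logical(x) && length(x) == 1
  chr1 <- function(x) is.character(x) && length(x) == 1
  num3 <- function(x) is.numeric(x) && length(x) == 3
  num2 <- function(x) is.numeric(x) && length(x) == 2
  list(
    seed = list(. = int1),
    outdir = list(. = chr1),
    simulate = list(
      n_subunits = int1, n_frames = int1, frame_dt = pos1,
      dwell_frames = pos1, displacement = num1, delta_p = is.list,
      axis = num3),
    saltbridge = list(
      cutoff = pos1, pool_subunits = bool1, window = num2,
      runs = is.character, structure = chr1, parameters = chr1,
      donors = chr1, acceptors = chr1),
    energy = list(
      regionA = num2, regionB = num2, cutoff = pos1, switch_on = pos1,
      blocks = int1, n_frames = int1, dielectric = pos1,
      exclude_bridge = is.character),
    statecmp = list(threshold = pos1, window_ns = pos1, tol_A = pos1),
    gating = list(
      v_half_a = num1, v_half_b = num1, z = pos1, noise_sd = num1,
      voltages = is.numeric, temperature = pos1,
      cycle = function(x) is.numeric(x) && length(x) == 3,
      cycle_se = function(x) is.numeric(x) && length(x) == 3))
}

#' Validate a pipeline configuration
#'
#' Schema-validates a run configuration (YAML file or list): unknown keys
#' are rejected, typed fields are checked, and all problems are reported at
#' once with paths into the document.
#'
#' @param config path to a YAML file, or a named list.
#' @return `TRUE` when valid; otherwise a character vector of error
#'   messages, invisibly printed via attribute-free return (check with
#'   `isTRUE`).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  schema <- pipeline_schema()
  errs <- character(0)
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown))
    errs <- c(errs, paste0("unknown key: ", unknown))
  for (top in intersect(names(config), names(schema))) {
    val <- config[[top]]
    sch <- schema[[top]]
    if (!is.null(sch$.)) {
      if (!sch$.(val)) errs <- c(errs, paste0("invalid value at ", top))
      next
    }
    if (!is.list(val)) { errs <- c(errs, paste0(top, " must be a mapping")); next }
    bad <- setdiff(names(val), names(sch))
    if (length(bad)) errs <- c(errs, paste0("unknown key: ", top, ".", bad))
    for (k in intersect(names(val), names(sch)))
      if (!sch[[k]](val[[k]]))
        errs <- c(errs, paste0("invalid value at ", top, ".", k))
  }
  ## cross-field checks
  en <- config$energy
  if (is.list(en) && !is.null(en$cutoff) && !is.null(en$switch_on) &&
      is.numeric(en$cutoff) && is.numeric(en$switch_on) &&
      en$switch_on >= en$cutoff)
    errs <- c(errs, "invalid value at energy.switch_on: must be < energy.cutoff")
  sb <- config$saltbridge
  if (is.list(sb) && !is.null(sb$cutoff) && is.numeric(sb$cutoff) &&
      sb$cutoff <= 0)
    errs <- c(errs, "invalid value at saltbridge.cutoff")
  if (length(errs)) unique(errs) else TRUE
}

default_config <- function() {
  list(seed = 1, outdir = "kvcoupling_run",
       simulate = list(n_subunits = 4, n_frames = 250,
                       delta_p = list(`354` = 0.34, `358` = 0.3),
                       displacement = 2),
       saltbridge = list(cutoff = 3.2, pool_subunits = TRUE),
       energy = list(regionA = c(247, 260), regionB = c(323, 358),
                     cutoff = 11, switch_on = 8, blocks = 5, n_frames = 50),
       statecmp = list(threshold = 0.15),
       gating = list(v_half_a = -20, v_half_b = -50, z = 2, noise_sd = 0.02,
                     cycle = c(0.56, 0.68, 2.60),
                     cycle_se = c(0.14, 0.07, 0.13)))
}

write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  df <- df[, !vapply(df, is.list, TRUE), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the stages simulate -> saltbridge -> energy -> statecmp ->
#' gating from one configuration, writing deterministic outputs and a
#' manifest with content hashes into the output directory. Re-running with
#' the same config and seed reproduces identical hashes. When
#' `saltbridge$runs` lists external trajectory files, those (plus
#' `structure` and `parameters`) are analyzed instead of the simulated
#' system; missing input files fail pre-flight before any stage runs.
#'
#' @param config path to a YAML config, a named list, or `NULL` for the
#'   built-in demo configuration.
#' @param outdir output directory (overrides the config).
#' @return manifest data.frame (`file`, `md5`), invisibly; written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = NULL, outdir = NULL) {
  if (is.null(config)) config <- default_config()
  if (is.character(config)) config <- yaml::read_yaml(config)
  ok <- validate_config(config)
  if (!isTRUE(ok)) stop("invalid configuration:\n  ", paste(ok, collapse = "\n  "))
  cfg <- utils::modifyList(default_config(), config)
  if (!is.null(outdir)) cfg$outdir <- outdir
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  ## pre-flight: every referenced input must exist before any stage runs
  ext <- as.character(c(cfg$saltbridge$runs, cfg$saltbridge$structure,
                        cfg$saltbridge$parameters))
  missing <- if (length(ext)) ext[!file.exists(ext)] else character(0)
  if (length(missing))
    stop("pre-flight failure: missing input file(s): ",
         paste(missing, collapse = ", "))
  files <- character(0)
  logf <- file.path(cfg$outdir, "run.log")
  cat(sprintf("start seed=%d\n", cfg$seed), file = logf)
  note <- function(stage, msg) cat(sprintf("%s %s\n", stage, msg),
                                   file = logf, append = TRUE)
  out <- function(name) { p <- file.path(cfg$outdir, name); files <<- c(files, p); p }
  stage <- "simulate"
  res <- tryCatch({
    ## --- simulate -------------------------------------------------------
    note(stage, "begin")
    sim <- cfg$simulate
    spec_a <- toy_system_spec(n_subunits = sim$n_subunits,
                              n_frames = sim$n_frames,
                              frame_dt = if (is.null(sim$frame_dt)) 0.2 else sim$frame_dt,
                              dwell_frames = sim$dwell_frames,
                              seed = cfg$seed)
    dp <- unlist(sim$delta_p)
    pair <- gen_two_condition_system(spec_a, delta_p = dp,
                                     displacement = sim$displacement,
                                     axis = if (is.null(sim$axis)) c(0, 0, 1) else sim$axis)
    sys_a <- pair$system_a; sys_b <- pair$system_b
    write_structure(sys_a$topology, sys_a$trajectory, out("system_a.pdb"))
    write_trajectory(sys_a$trajectory, out("system_a.xyz"), sys_a$topology)
    write_trajectory(sys_b$trajectory, out("system_b.xyz"), sys_b$topology)
    write_parameters(sys_a$parameters, out("parameters.csv"))
    jsonlite::write_json(
      list(p_star_a = sys_a$p_star, p_star_b = sys_b$p_star,
           truth = pair$truth),
      out("ground_truth.json"), digits = NA, pretty = TRUE)
    note(stage, "end")
    ## --- saltbridge -----------------------------------------------------
    stage <- "saltbridge"
    note(stage, "begin")
    sb <- cfg$saltbridge
    if (!is.null(sb$runs)) {
      st <- read_structure(sb$structure)
      topo <- st$topology
      if (!is.null(sb$parameters))
        topo <- assign_parameters(topo, read_parameters(sb$parameters),
                                  warn = FALSE)
      topo <- add_selection(topo, "basic_nitrogens",
                            if (is.null(sb$donors))
                              "resname ARG and name NE NH1 NH2 or resname LYS and name NZ"
                            else sb$donors)
      topo <- add_selection(topo, "pip2_phosphate_oxygens",
                            if (is.null(sb$acceptors))
                              "resname PIP and name O1P O2P O3P O4P O5P"
                            else sb$acceptors)
      runs <- lapply(sb$runs, function(p) {
        tr <- read_trajectory(p, topology = topo)
        if (!is.null(sb$window)) tr <- time_window(tr, sb$window[1], sb$window[2])
        detect_bridges(tr, topo, cutoff = sb$cutoff)
      })
      tab_a <- formation_probability(runs, pool_subunits = sb$pool_subunits)
      cs_a <- runs[[1]]
      tab_b <- NULL
    } else {
      tr_a <- sys_a$trajectory; tr_b <- sys_b$trajectory
      if (!is.null(sb$window)) {
        tr_a <- time_window(tr_a, sb$window[1], sb$window[2])
        tr_b <- time_window(tr_b, sb$window[1], sb$window[2])
      }
      cs_a <- detect_bridges(tr_a, sys_a$topology, cutoff = sb$cutoff)
      cs_b <- detect_bridges(tr_b, sys_b$topology, cutoff = sb$cutoff)
      tab_a <- formation_probability(cs_a, pool_subunits = sb$pool_subunits)
      tab_b <- formation_probability(cs_b, pool_subunits = sb$pool_subunits)
    }
    tab_a$category <- categorize(tab_a$probability)
    write_tsv(tab_a, out("probability_a.tsv"))
    summ <- per_lipid_average(cs_a, region_map = sys_a$region_map)
    summ$site <- classify_intrasubunit(summ, sys_a$region_map)
    summ$partners_list <- vapply(summ$partners, paste, "", collapse = ",")
    write_tsv(summ, out("per_lipid_a.tsv"))
    if (!is.null(tab_b)) {
      tab_b$category <- categorize(tab_b$probability)
      write_tsv(tab_b, out("probability_b.tsv"))
      write_tsv(compare_probability_tables(tab_a, tab_b),
                out("probability_compare.tsv"))
    }
    note(stage, "end")
    ## --- energy ---------------------------------------------------------
    stage <- "energy"
    note(stage, "begin")
    en <- cfg$energy
    scheme <- nonbonded_scheme(cutoff = en$cutoff, switch_on = en$switch_on,
                               dielectric = if (is.null(en$dielectric)) 1
                                            else en$dielectric)
    esys <- gen_region_system(n_frames = en$n_frames, seed = cfg$seed + 17)
    dec <- per_residue_decomposition(esys$trajectory, esys$topology,
                                     regionA = en$regionA,
                                     regionB = en$regionB, scheme = scheme,
                                     n_blocks = en$blocks)
    write_tsv(dec$profile_a, out("energy_profile_s4s5.tsv"))
    write_tsv(dec$profile_b, out("energy_profile_s6.tsv"))
    jsonlite::write_json(as.list(dec$group), out("energy_totals.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
    note(stage, "end")
    ## --- statecmp -------------------------------------------------------
    stage <- "statecmp"
    note(stage, "begin")
    sc <- cfg$statecmp
    nf <- dim(cs_a$occupancy)[1]
    half <- nf %/% 2
    w1 <- structure(list(occupancy = cs_a$occupancy[1:half, , , drop = FALSE],
                         residues = cs_a$residues, lipids = cs_a$lipids,
                         times = cs_a$times[1:half], cutoff = cs_a$cutoff),
                    class = "contact_series")
    w2 <- structure(list(occupancy = cs_a$occupancy[(half + 1):nf, , , drop = FALSE],
                         residues = cs_a$residues, lipids = cs_a$lipids,
                         times = cs_a$times[(half + 1):nf], cutoff = cs_a$cutoff),
                    class = "contact_series")
    conv <- window_convergence(list(formation_probability(w1),
                                    formation_probability(w2)),
                               threshold = sc$threshold)
    write_tsv(conv$per_residue, out("window_convergence.tsv"))
    shift <- if (exists("sys_b") && !is.null(tab_b)) {
      pa <- headgroup_positions(sys_a$trajectory, sys_a$topology,
                                "name P1 P4 P5", condition = "a")
      pb <- headgroup_positions(sys_b$trajectory, sys_b$topology,
                                "name P1 P4 P5", condition = "b")
      headgroup_shift(pa, pb, pair$truth$axis_from, pair$truth$axis_to)
    } else NULL
    jsonlite::write_json(
      list(converged = conv$converged, max_delta = conv$max_delta,
           threshold = conv$threshold,
           headgroup_shift_A = if (is.null(shift)) NULL else shift$mean),
      out("statecmp.json"), digits = NA, auto_unbox = TRUE, pretty = TRUE)
    note(stage, "end")
    ## --- gating ---------------------------------------------------------
    stage <- "gating"
    note(stage, "begin")
    ga <- cfg$gating
    volts <- if (is.null(ga$voltages)) seq(-75, 35, by = 10) else ga$voltages
    temp <- if (is.null(ga$temperature)) 293.15 else ga$temperature
    ca <- gen_gating_curve(ga$v_half_a, ga$z, volts, ga$noise_sd,
                           temperature = temp, seed = cfg$seed + 101)
    cb <- gen_gating_curve(ga$v_half_b, ga$z, volts, ga$noise_sd,
                           temperature = temp, seed = cfg$seed + 102)
    fa <- fit_boltzmann(ca$curve, temperature = temp)
    fb <- fit_boltzmann(cb$curve, temperature = temp)
    sh <- curve_shift(fa, fb)
    cyc <- mutant_cycle(ga$cycle[1], ga$cycle[2], ga$cycle[3],
                        ga$cycle_se[1], ga$cycle_se[2], ga$cycle_se[3])
    jsonlite::write_json(
      list(fit_a = list(v_half = fa$v_half, z = fa$z,
                        dg_kcal = as.numeric(apparent_dg(fa))),
           fit_b = list(v_half = fb$v_half, z = fb$z,
                        dg_kcal = as.numeric(apparent_dg(fb))),
           shift_mV = sh$delta_v_half, shift_se = sh$se,
           cycle = unclass(cyc)),
      out("gating.json"), digits = NA, auto_unbox = TRUE, pretty = TRUE)
    note(stage, "end")
    TRUE
  }, error = function(e) e)
  ## manifest (written even on stage failure, listing files produced so far)
  manifest <- data.frame(file = basename(c(files, logf)),
                         md5 = unname(md5sum(c(files, logf))),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       digits = NA, pretty = TRUE)
  if (inherits(res, "error"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(res))
  invisible(manifest)
}
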