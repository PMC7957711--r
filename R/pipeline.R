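# Workflow orchestration: NMR-ensemble screening, site-region pose filtering,
# and the full per-complex analysis that reproduces the study-style summary
# table (total score, RRCS aggregates, interface metrics, per-key-residue
# %BSA) and contact lists.

#' Analysis configuration
#'
#' Bundles region definitions (binding-site region, S4-style subregion,
#' glycans, key residues for per-residue %BSA), scoring/search/contact/
#' surface parameters and the output directory.
#'
#' @param site_region RegionSpec for the binding-site filter (e.g. site 3)
#' @param s4_region RegionSpec for the voltage-sensor S4 subregion aggregate
#' @param glycan_region RegionSpec selecting glycan residues
#' @param key_residues data.frame(chain, resno) whose percent_BSA is reported
#' @param scoring ScoringParams
#' @param search SearchConfig or NULL (rescore-only workflows)
#' @param contacts ContactParams
#' @param probe,n_points surface parameters
#' @param out_dir output directory for report files
#' @return AnalysisConfig object
#' @export
analysis_config <- function(site_region = NULL, s4_region = NULL,
                            glycan_region = region_spec("glycans",
                                                        resnames = glycan_residue_names()),
                            key_residues = NULL,
                            scoring = scoring_params(), search = NULL,
                            contacts = contact_params(),
                            probe = 1.4, n_points = 960L,
                            out_dir = ".") {
  structure(list(site_region = site_region, s4_region = s4_region,
                 glycan_region = glycan_region, key_residues = key_residues,
                 scoring = scoring, search = search, contacts = contacts,
                 probe = probe, n_points = as.integer(n_points),
                 out_dir = out_dir),
            class = "AnalysisConfig")
}

#' Read an analysis configuration from JSON
#'
#' The JSON mirrors \code{\link{analysis_config}}: regions are objects with
#' \code{name} plus \code{members} (records with chain/resno) and/or
#' \code{resnames}; \code{scoring}, \code{search} and \code{contacts}
#' override individual defaults. A default channel-style configuration
#' (site-3 region, S4 arginines, key residues Glu1255/Arg1265/Arg1268,
#' NAG glycans) ships in \code{inst/extdata/navpas_site3_config.json}.
#'
#' @param path JSON file path
#' @return AnalysisConfig
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  parse_region <- function(x, name) {
    if (is.null(x)) return(NULL)
    region_spec(if (!is.null(x$name)) x$name else name,
                members = x$members, resnames = x$resnames)
  }
  need <- function(field) {
    if (is.null(j[[field]])) stop("config missing required key: ", field)
    j[[field]]
  }
  sc <- scoring_params()
  if (!is.null(j$scoring)) {
    w <- sc$weights
    if (!is.null(j$scoring$weights)) w[names(j$scoring$weights)] <- unlist(j$scoring$weights)
    sc <- scoring_params(weights = w,
                         cutoff = if (!is.null(j$scoring$cutoff)) j$scoring$cutoff else sc$cutoff)
  }
  ct <- contact_params()
  if (!is.null(j$contacts)) {
    ct <- do.call(contact_params, utils::modifyList(unclass(ct), as.list(j$contacts)))
  }
  srch <- NULL
  if (!is.null(j$search)) {
    srch <- search_config(
      box_center = unlist(need("search")$box_center),
      box_half = unlist(j$search$box_half),
      n_restarts = if (!is.null(j$search$n_restarts)) j$search$n_restarts else 16L,
      steps = if (!is.null(j$search$steps)) j$search$steps else 500L,
      seed = if (!is.null(j$search$seed)) j$search$seed else 1L,
      keep_top = if (!is.null(j$search$keep_top)) j$search$keep_top else 20L,
      dedup_rmsd = if (!is.null(j$search$dedup_rmsd)) j$search$dedup_rmsd else 2.0
    )
  }
  analysis_config(
    site_region = parse_region(j$site_region, "site"),
    s4_region = parse_region(j$s4_region, "S4"),
    glycan_region = if (is.null(j$glycan_region))
      region_spec("glycans", resnames = glycan_residue_names())
    else parse_region(j$glycan_region, "glycans"),
    key_residues = j$key_residues,
    scoring = sc, search = srch, contacts = ct,
    probe = if (!is.null(j$probe)) j$probe else 1.4,
    n_points = if (!is.null(j$n_points)) j$n_points else 960L,
    out_dir = if (!is.null(j$out_dir)) j$out_dir else "."
  )
}

#' Screen a conformational ensemble by docking every model
#'
#' Runs one rigid docking per ensemble model (seed derived as
#' \code{cfg$seed + model index}), records each model's best total and
#' reports best/worst/population-SD over models plus the best model's id --
#' the screening step used to pick which NMR conformer to carry forward.
#'
#' @param receptor typed Structure
#' @param models list of typed ligand Structures with identical topology
#' @param cfg SearchConfig (its seed is the base seed)
#' @param params ScoringParams
#' @return EnsembleScreenResult: list(per_model data.frame(model, best_total),
#'   best, worst, sd, selected_model, results of the selected model)
#' @export
screen_ensemble <- function(receptor, models, cfg, params = scoring_params()) {
  stopifnot(length(models) >= 1)
  ref <- models[[1]]$atoms$name
  for (m in models) {
    if (!identical(m$atoms$name, ref)) {
      stop("screen_ensemble: models differ in atom topology")
    }
  }
  runs <- vector("list", length(models))
  for (i in seq_along(models)) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i
    runs[[i]] <- dock_rigid(receptor, models[[i]], cfg_i, params)
  }
  best_totals <- vapply(runs, function(r) r[[1]]$breakdown$total, numeric(1))
  sel <- which.min(best_totals)
  structure(list(
    per_model = data.frame(model = seq_along(models), best_total = best_totals),
    best = min(best_totals), worst = max(best_totals),
    sd = if (length(models) > 1) {
      stats::sd(best_totals) * sqrt((length(models) - 1) / length(models))
    } else 0,
    selected_model = sel,
    selected_results = runs[[sel]]
  ), class = "EnsembleScreenResult")
}

#' @export
print.EnsembleScreenResult <- function(x, ...) {
  cat(sprintf(
    "EnsembleScreenResult: %d models; best %.3f (model %d), worst %.3f, sd %.3f\n",
    nrow(x$per_model), x$best, x$selected_model, x$worst, x$sd))
  invisible(x)
}

#' Filter docking poses by contact with a receptor region
#'
#' Keeps poses with at least one heavy-atom pair within \code{cutoff} of any
#' residue of the region (a contact-based notion of "localised in the site").
#' Ranking order is preserved; output is a subset of the input.
#'
#' @param results ranked list from \code{\link{dock_rigid}} (or a bare list
#'   of poses carrying cached coords)
#' @param receptor typed Structure
#' @param region RegionSpec (must resolve to at least one residue)
#' @param cutoff contact distance, Angstrom
#' @return filtered list, original order
#' @export
filter_poses_by_region <- function(results, receptor, region, cutoff = 4.5) {
  sel <- select_region(receptor, region)
  if (!nrow(sel)) stop("filter_poses_by_region: region resolves to no residues")
  if (!length(results)) return(results)
  mask <- region_atom_mask(receptor, region) & !receptor$atoms$is_hydrogen
  reg_xyz <- as.matrix(receptor$atoms[mask, c("x", "y", "z")])
  keep <- vapply(results, function(r) {
    p <- if (!is.null(r$pose)) r$pose else r
    if (is.null(p$coords)) stop("filter_poses_by_region: pose lacks cached coords")
    min(cross_dist2(p$coords, reg_xyz)) <= cutoff^2
  }, logical(1))
  results[keep]
}

#' Full interaction analysis of one receptor-ligand complex
#'
#' Computes every summary-table analogue for a placed ligand: total empirical
#' score with per-term and per-residue decomposition, RRCS matrix with
#' amino-acid/glycan/region aggregates, interface report with the four
#' percentage metrics, per-key-residue percent_BSA, and all contact lists.
#'
#' @param receptor,ligand_pose typed Structures (ligand already placed)
#' @param cfg AnalysisConfig
#' @return ComplexReport: list with \code{score} (ScoreBreakdown),
#'   \code{decomposition}, \code{rrcs} (RRCSMatrix), \code{rrcs_total_AA},
#'   \code{rrcs_total_glycan}, \code{rrcs_region} (S4-style aggregate or NA),
#'   \code{interface} (InterfaceReport incl. summary), \code{key_residue_bsa},
#'   \code{contacts} (list per kind)
#' @export
analyze_complex <- function(receptor, ligand_pose, cfg = analysis_config()) {
  require_typed(receptor, "analyze_complex")
  require_typed(ligand_pose, "analyze_complex")
  stopifnot(inherits(cfg, "AnalysisConfig"))
  score <- score_complex(receptor, ligand_pose, cfg$scoring)
  rrcs <- rrcs_matrix(ligand_pose, receptor)
  rep0 <- residue_bsa(ligand_pose, receptor, probe = cfg$probe,
                      n_points = cfg$n_points)
  interface <- interface_metrics(ligand_pose, receptor, rep0)
  key_bsa <- NULL
  if (!is.null(cfg$key_residues) && NROW(cfg$key_residues)) {
    kr <- as.data.frame(cfg$key_residues)
    res <- interface$residues
    rows <- lapply(seq_len(nrow(kr)), function(i) {
      rt <- residue_table(receptor)
      hit <- rt$resno == kr$resno[i]
      if (!is.null(kr$chain) && !is.na(kr$chain[i])) {
        hit <- hit & rt$chain == kr$chain[i]
      }
      key <- rt$key[hit]
      pb <- res$percent_BSA[res$molecule == "receptor" & res$key %in% key]
      data.frame(chain = if (!is.null(kr$chain)) kr$chain[i] else NA,
                 resno = kr$resno[i],
                 percent_BSA = if (length(pb)) pb[1] else NA_real_)
    })
    key_bsa <- do.call(rbind, rows)
  }
  structure(list(
    score = score,
    decomposition = decompose_by_residue(score),
    rrcs = rrcs,
    rrcs_total_AA = rrcs_aggregate(rrcs, partition = "AA"),
    rrcs_total_glycan = rrcs_aggregate(rrcs, partition = "glycan"),
    rrcs_region = if (!is.null(cfg$s4_region))
      rrcs_aggregate(rrcs, receptor_region = cfg$s4_region) else NA_real_,
    interface = interface,
    key_residue_bsa = key_bsa,
    contacts = detect_all_contacts(ligand_pose, receptor, cfg$contacts)
  ), class = "ComplexReport")
}

#' @export
print.ComplexReport <- function(x, ...) {
  s <- x$interface$summary
  cat("ComplexReport\n")
  cat(sprintf("  total score (kcal/mol): %.3f\n", x$score$total))
  cat(sprintf("  Total RRCS (AA): %.2f   RRCS (glycan): %.2f   RRCS (region): %s\n",
              x$rrcs_total_AA, x$rrcs_total_glycan,
              ifelse(is.na(x$rrcs_region), "-", sprintf("%.2f", x$rrcs_region))))
  cat(sprintf("  ASA_TI: %.1f%%  ASA_NavI: %.1f%%  toxin AA in interface: %.1f%%  glycan atoms in interface: %.1f%%\n",
              s$ASA_TI_percent, s$ASA_NavI_percent,
              s$toxin_AA_in_interface_percent, s$NAG_atoms_in_interface_percent))
  cat(sprintf("  contacts: %d hbond, %d salt bridge, %d pi-cation, %d hydrophobic, %d close\n",
              nrow(x$contacts$hbond), nrow(x$contacts$salt_bridge),
              nrow(x$contacts$pi_cation), nrow(x$contacts$hydrophobic),
              nrow(x$contacts$close_contacts)))
  invisible(x)
}

# Serialise a ComplexReport to a plain list for JSON output
report_to_list <- function(rep) {
  list(
    total_score = rep$score$total,
    per_term = as.list(rep$score$per_term),
    rrcs_total_AA = rep$rrcs_total_AA,
    rrcs_total_glycan = rep$rrcs_total_glycan,
    rrcs_region = rep$rrcs_region,
    interface = rep$interface$summary,
    key_residue_bsa = rep$key_residue_bsa,
    n_contacts = lapply(rep$contacts, nrow)
  )
}

#' Run the full workflow from input files
#'
#' In \code{"rescore"} mode the ligand file holds an already-placed pose and
#' the pipeline types both molecules and runs \code{\link{analyze_complex}}.
#' In \code{"full"} mode each ligand model is docked
#' (\code{\link{screen_ensemble}}), the selected model's poses are filtered
#' by the configured site region, and the best surviving pose is analysed.
#' All stages log to stderr; outputs (JSON report, TSV tables, pose PDB) are
#' written under the config's output directory.
#'
#' @param receptor_path receptor PDB
#' @param ligand_path ligand PDB (single model or NMR ensemble)
#' @param config AnalysisConfig or path to a JSON config
#' @param mode "rescore" or "full"
#' @param strip optional chain id or RegionSpec removed from the receptor
#'   before analysis (e.g. a co-crystallised ligand)
#' @return ComplexReport (invisibly); files written as side effect
#' @export
run_full <- function(receptor_path, ligand_path, config = analysis_config(),
                     mode = c("rescore", "full"), strip = NULL) {
  mode <- match.arg(mode)
  if (is.character(config)) config <- read_analysis_config(config)
  stage <- function(...) message("[toxdock] ", sprintf(...))

  stage("reading receptor %s", receptor_path)
  receptor <- read_pdb(receptor_path, model_index = 1L)
  if (!is.null(strip)) {
    stage("stripping selector from receptor")
    receptor <- strip_residues(receptor, strip)
  }
  receptor <- assign_atom_types(receptor)

  stage("reading ligand %s", ligand_path)
  models <- read_pdb(ligand_path)
  if (inherits(models, "Structure")) models <- list(models)
  models <- lapply(models, assign_atom_types)

  if (mode == "rescore") {
    ligand <- models[[1]]
  } else {
    if (is.null(config$search)) stop("run_full: full mode needs a search config")
    stage("screening %d ensemble model(s), base seed %d", length(models),
          config$search$seed)
    scr <- screen_ensemble(receptor, models, config$search, config$scoring)
    stage("selected model %d (best %.3f)", scr$selected_model, scr$best)
    results <- scr$selected_results
    if (!is.null(config$site_region)) {
      results <- filter_poses_by_region(results, receptor, config$site_region)
      stage("%d pose(s) pass the site-region filter", length(results))
      if (!length(results)) stop("run_full: no pose passes the region filter")
    }
    ligand <- apply_pose(models[[scr$selected_model]], results[[1]]$pose)
  }

  stage("analysing complex")
  rep <- analyze_complex(receptor, ligand, config)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  jsonlite::write_json(report_to_list(rep), out("report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_contacts_tsv(rep$contacts, out("contacts.tsv"))
  write_interface_tsv(rep$interface, out("interface.tsv"))
  utils::write.table(rep$rrcs$entries, out("rrcs.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_pdb(ligand, out("ligand_pose.pdb"))
  stage("reports written to %s", config$out_dir)
  invisible(rep)
}
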