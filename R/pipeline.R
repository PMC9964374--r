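# Pipeline orchestration: screen -> motifs -> physchem -> localization
# -> regulation -> (optional) structure QC, producing a merged candidate
# report with the column layout of the study-style summary table
# (id, family, regulation, GRAVY, predicted localization).

#' Run the full screening pipeline
#'
#' Reads the inputs, applies the screening funnel, profiles the retained
#' candidates, and joins localization and regulation evidence into a
#' merged candidate table. Optional inputs may be `NULL`: the
#' corresponding columns are left empty with a warning and the run still
#' succeeds. All outputs are TSV files under `out`, plus a plain-text
#' log recording every threshold actually used.
#'
#' @param fasta Path to the protein FASTA file.
#' @param annotations Path to the annotation TSV (`id`, `description`,
#'   `domain`, `evalue`, `best_function`).
#' @param out Output directory (created if needed).
#' @param predictors Optional predictor TSV path.
#' @param lipid_sites Optional lipid-site TSV path (`id`, `type`,
#'   `position`).
#' @param regulation Optional regulation TSV path (`gene`, `dataset`,
#'   `timepoint`, `log2fc`).
#' @param structures Optional character vector of PDB paths.
#' @param config A [screen_config()].
#' @param threshold_log2 Candidate-selection threshold (default 2).
#' @param mito_cutoff Mitochondrial-score cutoff (default 0.85).
#' @return Invisibly, a list with the merged `candidates` table, the
#'   `screen` result, `profiles`, `localization`, `regulation` and
#'   `structure_qc` components.
#' @export
run_pipeline <- function(fasta, annotations, out,
                         predictors = NULL, lipid_sites = NULL,
                         regulation = NULL, structures = NULL,
                         config = screen_config(), threshold_log2 = 2,
                         mito_cutoff = 0.85) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(
    sprintf("lipscreen pipeline run %s", format(Sys.time())),
    sprintf("evalue_threshold = %g", config$evalue_threshold),
    sprintf("keywords = %s", paste(config$keywords, collapse = ", ")),
    sprintf("nterm_fraction = %g", config$nterm_fraction),
    sprintf("threshold_log2 = %g", threshold_log2),
    sprintf("mito_cutoff = %g", mito_cutoff))

  records <- read_fasta(fasta)
  ann <- read_table(annotations,
                    required_columns = c("id", "description", "domain",
                                         "evalue", "best_function"),
                    numeric_columns = "evalue")
  screen <- run_screen(records, ann, config)
  write_table(screen$audit, file.path(out, "screen_audit.tsv"))
  write_table(data.frame(stage = names(screen$stage_counts),
                         retained = as.integer(screen$stage_counts)),
              file.path(out, "screen_stage_counts.tsv"))

  kept <- records[records$id %in% screen$retained, , drop = FALSE]
  profiles <- physchem_profile_all(kept)
  write_table(profiles, file.path(out, "physchem_profiles.tsv"))

  penta <- do.call(rbind, lapply(seq_len(nrow(kept)), function(i) {
    scan_pentapeptide(kept[i, ])
  }))
  if (is.null(penta)) penta <- empty_hits()
  write_table(penta, file.path(out, "pentapeptide_hits.tsv"))

  targeting <- do.call(rbind, lapply(seq_len(nrow(kept)), function(i) {
    scan_targeting_signals(kept[i, ])
  }))
  if (is.null(targeting)) targeting <- empty_hits()

  loc <- NULL
  if (!is.null(predictors)) {
    pred <- read_table(predictors,
                       required_columns = c("id", "plastid_positive",
                                            "mito_score", "signal_peptide",
                                            "tm_count"),
                       numeric_columns = c("plastid_positive", "mito_score",
                                           "signal_peptide", "tm_count"))
    loc <- localize_all(pred, targeting, mito_cutoff)
    write_table(loc, file.path(out, "localization_calls.tsv"))
    write_table(summarize_localization(loc),
                file.path(out, "localization_summary.tsv"))
  } else {
    warning("no predictor table supplied; localization columns empty")
  }

  lipids <- NULL
  if (!is.null(lipid_sites)) {
    sites <- read_table(lipid_sites,
                        required_columns = c("id", "type", "position"),
                        numeric_columns = "position")
    lipids <- summarize_lipid_sites(sites)
    write_table(lipids$per_protein, file.path(out, "lipid_site_counts.tsv"))
  }

  reg <- NULL
  if (!is.null(regulation)) {
    obs <- read_table(regulation,
                      required_columns = c("gene", "dataset", "timepoint",
                                           "log2fc"),
                      numeric_columns = "log2fc")
    reg <- max_regulation(obs)
    write_table(reg, file.path(out, "regulation_summary.tsv"))
    write_table(select_candidates(reg, threshold_log2),
                file.path(out, "regulation_candidates.tsv"))
  } else {
    warning("no regulation table supplied; regulation columns empty")
  }

  sqc <- NULL
  if (!is.null(structures)) {
    sqc <- lapply(structures, function(p) {
      st <- read_structure(p)
      rama <- ramachandran_classify(backbone_dihedrals(st))
      pl <- plddt_summary(st)
      data.frame(structure = basename(p),
                 highly_favored = rama$percent[["highly_favored"]],
                 favored = rama$percent[["favored"]],
                 questionable = rama$percent[["questionable"]],
                 mean_plddt = pl$mean, stringsAsFactors = FALSE)
    })
    sqc <- do.call(rbind, sqc)
    write_table(sqc, file.path(out, "structure_qc.tsv"))
  }

  candidates <- data.frame(
    id = screen$retained,
    family = screen$families[screen$retained],
    regulation = if (is.null(reg)) NA_real_ else
      reg$max_signed_log2[match(screen$retained, reg$gene)],
    gravy = profiles$gravy[match(screen$retained, profiles$id)],
    localization = if (is.null(loc)) NA_character_ else
      loc$compartment[match(screen$retained, loc$id)],
    stringsAsFactors = FALSE)
  candidates <- candidates[order(-abs(ifelse(is.na(candidates$regulation),
                                             -Inf, candidates$regulation)),
                                 candidates$id), , drop = FALSE]
  rownames(candidates) <- NULL
  write_table(candidates, file.path(out, "candidates.tsv"))

  writeLines(log_lines, file.path(out, "pipeline.log"))
  invisible(list(candidates = candidates, screen = screen,
                 profiles = profiles, localization = loc,
                 lipid_sites = lipids, regulation = reg,
                 structure_qc = sqc))
}

#' Write a complete synthetic input bundle
#'
#' Generates a coherent set of pipeline inputs with planted ground truth
#' (screen set, predictor table, regulation table, one ideal-helix PDB)
#' and writes them, plus a manifest recording the seed and the plants,
#' under `dir`.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param ... Passed to [generate_screen_set()].
#' @return Invisibly, a list with the file paths and the truth tables.
#' @export
simulate_bundle <- function(dir, seed = 1, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scr <- generate_screen_set(seed = seed, ...)
  fasta <- file.path(dir, "proteins.fasta")
  write_fasta(scr$records, fasta)
  ann <- file.path(dir, "annotations.tsv")
  write_table(scr$annotations, ann)
  kept <- scr$truth$id[scr$truth$expected_stage == "retained"]
  plants <- data.frame(id = kept, compartment = "cytosol",
                       stringsAsFactors = FALSE)
  predgen <- generate_predictor_table(plants, noise = 0, seed = seed + 1)
  pred <- file.path(dir, "predictors.tsv")
  write_table(predgen$predictors, pred)
  effects <- stats::setNames(stats::runif(length(kept), -2, 2), kept)
  reggen <- generate_regulation_table(effects, seed = seed + 2)
  regp <- file.path(dir, "regulation.tsv")
  write_table(reggen$observations, regp)
  pdb <- file.path(dir, "model1.pdb")
  generate_helix_pdb(30, pdb)
  manifest <- file.path(dir, "manifest.tsv")
  write_table(data.frame(key = c("seed"), value = c(seed)), manifest)
  write_table(scr$truth, file.path(dir, "truth_screen.tsv"))
  write_table(reggen$truth, file.path(dir, "truth_regulation.tsv"))
  invisible(list(fasta = fasta, annotations = ann, predictors = pred,
                 regulation = regp, pdb = pdb,
                 truth = list(screen = scr$truth,
                              regulation = reggen$truth)))
}

#' Command-line entry point
#'
#' Subcommand dispatcher used by the `inst/cli/lipscreen` script:
#' `simulate` writes a synthetic bundle, `run` executes the full
#' pipeline. Flags mirror [run_pipeline()] arguments.
#'
#' @param args Character vector of command-line arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status, invisibly (0 on success).
#' @export
lipscreen_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    message("usage: lipscreen <simulate|run> [--key value ...]")
    return(invisible(1L))
  }
  cmd <- args[1]
  kv <- list()
  rest <- args[-1]
  i <- 1L
  while (i <= length(rest)) {
    if (startsWith(rest[i], "--")) {
      kv[[substring(rest[i], 3)]] <- rest[i + 1L]
      i <- i + 2L
    } else i <- i + 1L
  }
  get <- function(key, default = NULL) {
    if (!is.null(kv[[key]])) kv[[key]] else default
  }
  if (cmd == "simulate") {
    simulate_bundle(get("out", "lipscreen_bundle"),
                    seed = as.integer(get("seed", "1")))
  } else if (cmd == "run") {
    run_pipeline(fasta = get("fasta"), annotations = get("annotations"),
                 out = get("out", "lipscreen_out"),
                 predictors = get("predictors"),
                 lipid_sites = get("lipid-sites"),
                 regulation = get("regulation"),
                 config = screen_config(
                   evalue_threshold = as.numeric(get("evalue", "1e-5"))),
                 threshold_log2 = as.numeric(get("threshold-log2", "2")))
  } else {
    message("unknown subcommand: ", cmd)
    return(invisible(1L))
  }
  invisible(0L)
}
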