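# Rule-based subcellular localization from external-predictor outputs
# plus targeting-signal motifs, and lipid-modification summaries.
#
# The predictor table carries one row per protein with columns:
#   id, plastid_positive (0/1), mito_score ([0,1]), signal_peptide (0/1,
#   or several sp_* columns combined by majority, ties positive),
#   tm_count (integer >= 0).

COMPARTMENTS <- c("cytosol", "ER/cytosol", "ER", "chloroplast",
                  "mitochondria", "mitochondria/peroxisome", "peroxisome")

# Resolve possibly-multiple signal-peptide predictor columns by majority
# vote; ties count as positive.
signal_peptide_call <- function(row) {
  sp_cols <- grep("^sp_", names(row), value = TRUE)
  if (length(sp_cols) == 0L) return(as.logical(row[["signal_peptide"]]))
  votes <- as.numeric(row[sp_cols])
  mean(votes >= 0.5) >= 0.5
}

#' Decide the subcellular compartment of one protein
#'
#' Applies a fixed rule precedence (plastid > mitochondrion > secretory
#' > membrane > peroxisome > cytosol):
#' \enumerate{
#'   \item plastid-positive call -> chloroplast;
#'   \item mitochondrial score >= `mito_cutoff` -> mitochondria, or
#'     mitochondria/peroxisome when a PTS motif also fires;
#'   \item signal peptide -> ER (an ER-retention motif reinforces the
#'     call; a di-leucine motif additionally sets `vacuole_candidate`);
#'   \item no signal peptide but >= 1 transmembrane segment ->
#'     ER/cytosol;
#'   \item a PTS motif alone -> peroxisome;
#'   \item otherwise cytosol.
#' }
#' The vacuole is never emitted as a compartment: possible vacuolar
#' (lipophagy) lipases are flagged via `vacuole_candidate`, which
#' requires both a signal peptide and a di-leucine sorting motif.
#'
#' @param predictor_row One-row data.frame (or named list) of predictor
#'   outputs for the protein.
#' @param motif_hits Targeting-signal hits for the protein (from
#'   [scan_targeting_signals()]).
#' @param mito_cutoff Mitochondrial-score threshold (default 0.85).
#' @return List: `id`, `compartment`, `evidence` (character vector of
#'   fired rules), `vacuole_candidate`.
#' @export
decide_localization <- function(predictor_row, motif_hits,
                                mito_cutoff = 0.85) {
  if (is.null(predictor_row) || length(predictor_row) == 0L) {
    stop("missing predictor row")
  }
  id <- predictor_row[["id"]]
  has <- function(m) any(motif_hits$motif == m)
  pts <- has("pts1") || has("pts2")
  evid <- character()
  vac <- FALSE
  if (isTRUE(as.logical(predictor_row[["plastid_positive"]]))) {
    comp <- "chloroplast"
    evid <- "plastid_positive"
  } else if (!is.na(predictor_row[["mito_score"]]) &&
             predictor_row[["mito_score"]] >= mito_cutoff) {
    evid <- "mito_score"
    if (pts) {
      comp <- "mitochondria/peroxisome"
      evid <- c(evid, "pts_motif")
    } else comp <- "mitochondria"
  } else if (isTRUE(signal_peptide_call(predictor_row))) {
    comp <- "ER"
    evid <- "signal_peptide"
    if (has("er_retention")) evid <- c(evid, "er_retention_motif")
    if (has("dileucine")) {
      vac <- TRUE
      evid <- c(evid, "dileucine_motif")
    }
  } else if (!is.na(predictor_row[["tm_count"]]) &&
             predictor_row[["tm_count"]] >= 1) {
    comp <- "ER/cytosol"
    evid <- "tm_count"
  } else if (pts) {
    comp <- "peroxisome"
    evid <- "pts_motif"
  } else {
    comp <- "cytosol"
    evid <- "default"
  }
  list(id = id, compartment = comp, evidence = evid,
       vacuole_candidate = vac)
}

#' Localization calls for a whole predictor table
#'
#' @param predictors Predictor table (one row per protein).
#' @param targeting_hits Targeting-signal hits for all proteins (column
#'   `id` used to subset).
#' @param mito_cutoff Passed to [decide_localization()].
#' @return Data frame: `id`, `compartment`, `vacuole_candidate`,
#'   `evidence` (collapsed with `;`).
#' @export
localize_all <- function(predictors, targeting_hits = empty_hits(),
                         mito_cutoff = 0.85) {
  out <- lapply(seq_len(nrow(predictors)), function(i) {
    row <- predictors[i, , drop = FALSE]
    hits <- targeting_hits[targeting_hits$id == row$id, , drop = FALSE]
    call <- decide_localization(row, hits, mito_cutoff)
    data.frame(id = call$id, compartment = call$compartment,
               vacuole_candidate = call$vacuole_candidate,
               evidence = paste(call$evidence, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compartment counts and percentages
#'
#' @param calls Output of [localize_all()].
#' @return Data frame: `compartment`, `count`, `percent` (rounded to
#'   integer percent); counts sum to the number of calls.
#' @export
summarize_localization <- function(calls) {
  stopifnot(nrow(calls) >= 1L)
  counts <- table(factor(calls$compartment, levels = COMPARTMENTS))
  data.frame(compartment = names(counts),
             count = as.integer(counts),
             percent = as.integer(round(100 * as.integer(counts) /
                                          nrow(calls))),
             stringsAsFactors = FALSE)
}

#' Summarize predicted lipid-modification sites
#'
#' @param sites Lipid-site table: columns `id`, `type` (e.g.
#'   `"S-palmitoylation"`, `"N-myristoylation"`, `"prenylation"`),
#'   `position`.
#' @return List: `type_proportions` (over all sites, sums to 1),
#'   `per_protein` (data.frame `id`, `n_sites`, sorted by count
#'   descending), `n_with_site`.
#' @export
summarize_lipid_sites <- function(sites) {
  if (nrow(sites) == 0L) {
    return(list(type_proportions = numeric(),
                per_protein = data.frame(id = character(),
                                         n_sites = integer()),
                n_with_site = 0L))
  }
  props <- c(table(sites$type) / nrow(sites))
  per <- as.data.frame(table(sites$id), stringsAsFactors = FALSE)
  names(per) <- c("id", "n_sites")
  per <- per[order(-per$n_sites, per$id), , drop = FALSE]
  rownames(per) <- NULL
  list(type_proportions = props, per_protein = per,
       n_with_site = nrow(per))
}

#' Ids of possible vacuolar (lipophagy) lipases
#'
#' Proteins whose call carries `vacuole_candidate` (signal peptide plus
#' di-leucine sorting motif), sorted.
#'
#' @param calls Output of [localize_all()].
#' @return Sorted character vector of ids.
#' @export
flag_vacuolar_candidates <- function(calls) {
  sort(calls$id[calls$vacuole_candidate])
}
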