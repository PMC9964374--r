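# Candidate-retention funnel: keyword query -> annotation significance ->
# motif requirement -> functional-homology exclusion -> family assignment
# -> inactive-motif exclusion, with a per-protein audit trail.

#' Screening configuration
#'
#' @param keywords Query strings matched case-insensitively against the
#'   annotation description (default the lipase/phospholipase/alpha-beta
#'   hydrolase triple).
#' @param evalue_threshold Domain-hit significance cutoff; a hit is
#'   significant iff its E-value is strictly below this (default 1e-5).
#' @param excluded_functions Best-homolog function strings that disqualify
#'   a candidate (precise non-lipase activities).
#' @param forced_include Protein ids retained at the keyword stage
#'   regardless of description (candidates known from previous studies).
#' @param nterm_fraction N-terminal window for the GDSL motif.
#' @param family_rules Named character vector mapping a
#'   description/domain keyword (lower case) to a family label; applied
#'   in order, first match wins.
#' @return A `screen_config` list.
#' @export
screen_config <- function(keywords = c("lipase", "phospholipase",
                                       "alpha/beta hydrolase"),
                          evalue_threshold = EVALUE_THRESHOLD,
                          excluded_functions = c("proline iminopeptidase",
                                                 "pheophytinase"),
                          forced_include = character(),
                          nterm_fraction = 0.25,
                          family_rules = c(
                            "gdsl" = "GDSL lipase",
                            "patatin" = "patatin-like phospholipase",
                            "lipase_3" = "class 3 lipase",
                            "class 3" = "class 3 lipase",
                            "abhydrolase" = "α/β hydrolase",
                            "alpha/beta hydrolase" = "α/β hydrolase"
                          )) {
  stopifnot(length(keywords) > 0L, evalue_threshold > 0)
  structure(list(keywords = keywords,
                 evalue_threshold = evalue_threshold,
                 excluded_functions = excluded_functions,
                 forced_include = forced_include,
                 nterm_fraction = nterm_fraction,
                 family_rules = family_rules),
            class = "screen_config")
}

FAMILY_LEVELS <- c("α/β hydrolase", "class 3 lipase",
                   "GDSL lipase", "patatin-like phospholipase")

# Annotation tables carry one row per (id, domain hit); columns:
# id, description, domain, evalue, best_function. A protein with no
# domain hit has one row with empty domain and NA evalue.

#' Keyword filter (funnel stage 1)
#'
#' A protein is retained iff any configured keyword occurs
#' case-insensitively in its annotation description, or its id is on the
#' forced-include list.
#'
#' @param annotations Annotation table (columns `id`, `description`).
#' @param config A [screen_config()].
#' @return List with `retained` ids and `forced` ids (subset of retained).
#' @export
keyword_filter <- function(annotations, config) {
  ids <- unique(annotations$id)
  desc <- tolower(annotations$description[match(ids, annotations$id)])
  hit <- Reduce(`|`, lapply(tolower(config$keywords), function(k) {
    grepl(k, desc, fixed = TRUE)
  }))
  forced <- intersect(config$forced_include, ids)
  list(retained = union(ids[hit], forced),
       forced = setdiff(forced, ids[hit]))
}

#' Annotation-significance filter (funnel stage 2)
#'
#' Retained iff the minimum domain-hit E-value is strictly below the
#' threshold. Proteins with no domain hit are excluded with reason
#' "no annotation".
#'
#' @param annotations Annotation table (columns `id`, `evalue`).
#' @param ids Ids entering this stage.
#' @param config A [screen_config()].
#' @return Character vector of retained ids.
#' @export
significance_filter <- function(annotations, ids, config) {
  keep <- vapply(ids, function(i) {
    ev <- annotations$evalue[annotations$id == i]
    ev <- ev[!is.na(ev)]
    length(ev) > 0L && min(ev) < config$evalue_threshold
  }, logical(1))
  ids[keep]
}

# Family hint from annotation text, used to exempt GDSL candidates from
# the pentapeptide requirement. Returns NA when no rule matches.
family_hint <- function(annotations, id, config) {
  rows <- annotations[annotations$id == id, , drop = FALSE]
  text <- tolower(paste(c(rows$description, rows$domain), collapse = " "))
  for (k in names(config$family_rules)) {
    if (grepl(k, text, fixed = TRUE)) return(config$family_rules[[k]])
  }
  NA_character_
}

#' Catalytic-motif requirement filter (funnel stage 3)
#'
#' Non-GDSL candidates must contain at least one G-X-S-X-G pentapeptide;
#' GDSL candidates are exempt from the pentapeptide but must contain a
#' GDS motif (an inactive GDE variant, lacking the catalytic serine,
#' fails). Returns retained ids and per-id exclusion reasons.
#'
#' @param records Protein-record table.
#' @param ids Ids entering this stage.
#' @param hints Named character vector of family hints (NA allowed).
#' @param config A [screen_config()].
#' @return List with `retained` ids and named `reason` vector for
#'   exclusions (`"no pentapeptide motif"` or
#'   `"missing catalytic serine"`).
#' @export
motif_requirement_filter <- function(records, ids, hints, config) {
  reason <- character(0)
  keep <- logical(length(ids))
  for (k in seq_along(ids)) {
    rec <- records[records$id == ids[k], ]
    is_gdsl <- !is.na(hints[ids[k]]) && hints[ids[k]] == "GDSL lipase"
    if (is_gdsl) {
      hits <- scan_gdsl(rec, config$nterm_fraction)
      if (nrow(hits) > 0L) keep[k] <- TRUE
      else reason[ids[k]] <- "missing catalytic serine"
    } else {
      hits <- scan_pentapeptide(rec)
      if (nrow(hits) > 0L) keep[k] <- TRUE
      else reason[ids[k]] <- "no pentapeptide motif"
    }
  }
  list(retained = ids[keep], reason = reason)
}

#' Functional-homology exclusion filter (funnel stage 4)
#'
#' Excluded iff the best-homolog function matches (case-insensitively)
#' one of the configured non-lipase functions. An empty best-homolog
#' function retains the protein with a warning (absence of evidence).
#'
#' @param annotations Annotation table (columns `id`, `best_function`).
#' @param ids Ids entering this stage.
#' @param config A [screen_config()].
#' @return Character vector of retained ids.
#' @export
function_exclusion_filter <- function(annotations, ids, config) {
  best <- vapply(ids, function(i) {
    v <- annotations$best_function[annotations$id == i]
    v <- v[nzchar(v) & !is.na(v)]
    if (length(v) == 0L) "" else v[1]
  }, character(1))
  empty <- ids[!nzchar(best)]
  if (length(empty) > 0L) {
    warning("no best-homolog function for: ", paste(empty, collapse = ", "),
            " (retained)")
  }
  excl <- tolower(best) %in% tolower(config$excluded_functions)
  ids[!excl]
}

#' Assign a lipase family to a retained candidate
#'
#' Family chosen by the first matching family rule over the protein's
#' description and domain names; proteins matching no rule default to
#' the alpha/beta hydrolase family with a warning.
#'
#' @param annotations Annotation table.
#' @param id Protein id.
#' @param config A [screen_config()].
#' @return Family label.
#' @export
assign_family <- function(annotations, id, config) {
  fam <- family_hint(annotations, id, config)
  if (is.na(fam)) {
    warning("no family rule matched for ", id,
            "; defaulting to α/β hydrolase")
    fam <- FAMILY_LEVELS[1]
  }
  fam
}

#' Run the full screening funnel
#'
#' Applies the stages in order — keyword query, annotation significance,
#' catalytic-motif requirement, functional-homology exclusion, family
#' assignment, inactive-motif (GDE) exclusion — and emits a complete
#' per-protein audit trail plus per-stage retained counts.
#'
#' @param records Protein-record table (every annotated id must exist).
#' @param annotations Annotation table: columns `id`, `description`,
#'   `domain`, `evalue`, `best_function` (one row per domain hit).
#' @param config A [screen_config()].
#' @return A `screen_result` list: `audit` (data.frame with `id`,
#'   `stage_reached`, `family`, `exclusion_reason`), `stage_counts`
#'   (named vector of ids retained after each stage), `retained`
#'   (final ids).
#' @export
run_screen <- function(records, annotations, config = screen_config()) {
  ids <- unique(annotations$id)
  missing <- setdiff(ids, records$id)
  if (length(missing) > 0L) {
    stop("annotated id(s) absent from sequence set: ",
         paste(missing, collapse = ", "))
  }
  audit <- data.frame(id = ids, stage_reached = "input",
                      family = NA_character_,
                      exclusion_reason = NA_character_,
                      note = NA_character_,
                      stringsAsFactors = FALSE)
  set_reason <- function(audit, excluded, stage, reason) {
    sel <- audit$id %in% excluded
    audit$stage_reached[sel] <- stage
    audit$exclusion_reason[sel] <- if (length(reason) == 1L) reason else
      reason[audit$id[sel]]
    audit
  }

  kw <- keyword_filter(annotations, config)
  audit <- set_reason(audit, setdiff(ids, kw$retained), "keyword",
                      "no keyword")
  audit$note[audit$id %in% kw$forced] <- "manual inclusion"
  stage1 <- kw$retained

  stage2 <- significance_filter(annotations, stage1, config)
  audit <- set_reason(audit, setdiff(stage1, stage2), "significance",
                      "no significant annotation")

  hints <- vapply(stage2, function(i) family_hint(annotations, i, config),
                  character(1))
  names(hints) <- stage2
  mf <- motif_requirement_filter(records, stage2, hints, config)
  audit <- set_reason(audit, setdiff(stage2, mf$retained), "motif",
                      mf$reason)
  stage3 <- mf$retained

  stage4 <- function_exclusion_filter(annotations, stage3, config)
  audit <- set_reason(audit, setdiff(stage3, stage4), "function",
                      "excluded function")

  fams <- vapply(stage4, function(i) {
    suppressWarnings(assign_family(annotations, i, config))
  }, character(1))
  audit$family[match(stage4, audit$id)] <- fams
  audit$stage_reached[audit$id %in% stage4] <- "retained"

  counts <- c(input = length(ids), keyword = length(stage1),
              significance = length(stage2), motif = length(stage3),
              `function` = length(stage4), retained = length(stage4))
  structure(list(audit = audit, stage_counts = counts, retained = stage4,
                 families = fams),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("screen_result:", x$stage_counts["input"], "in ->",
      x$stage_counts["retained"], "retained\n")
  print(x$stage_counts)
  invisible(x)
}

#' Flag pentapeptide motifs lying outside a stated domain interval
#'
#' Structure inspection can reveal that a candidate's pentapeptide lies
#' outside its hydrolase-fold domain (so the protein is likely not a
#' lipase). This helper only flags such cases against a user-provided
#' domain interval; it never auto-excludes.
#'
#' @param hits Pentapeptide hits for one protein.
#' @param domain_start,domain_end 1-based domain interval.
#' @return Logical vector: TRUE where the hit lies outside the interval.
#' @export
flag_motif_outside_domain <- function(hits, domain_start, domain_end) {
  hits$start < domain_start | (hits$start + nchar(hits$match) - 1L) > domain_end
}
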