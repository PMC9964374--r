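# Motif detection: catalytic pentapeptide, GDSL N-terminal motif and
# targeting signals. All grammars are exact residue-class patterns; the
# wildcard positions ("X") match only the 20 standard residues, never
# ambiguity letters, since catalytic-context positions must be real
# residues.

AA_CLASS <- paste0("[", paste(AA_STANDARD, collapse = ""), "]")

empty_hits <- function() {
  data.frame(id = character(), motif = character(), start = integer(),
             match = character(), x1 = character(), x2 = character(),
             stringsAsFactors = FALSE)
}

hit_row <- function(id, motif, start, match, x1 = "", x2 = "") {
  data.frame(id = id, motif = motif, start = as.integer(start),
             match = match, x1 = x1, x2 = x2, stringsAsFactors = FALSE)
}

# All (overlapping) starts where a regex of fixed width matches.
overlapping_starts <- function(sequence, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), sequence, perl = TRUE)[[1]]
  if (m[1] == -1L) integer() else as.integer(m)
}

#' Scan a sequence for the catalytic G-X-S-X-G pentapeptide
#'
#' Reports every 5-residue window matching G-X-S-X-G, where X is any of
#' the 20 standard residues. Overlapping windows are all reported,
#' ordered by start; downstream stages keep the first hit per protein.
#' The variable residues are extracted as `x1` (position 2) and `x2`
#' (position 4). The most common active pentapeptide in class 3 lipases
#' is GHSLG; X2 is typically hydrophobic (I, L, M, V, A) because it also
#' contributes to the oxyanion hole.
#'
#' @param record One row of a protein-record table (or a list with `id`
#'   and `sequence`).
#' @return A data.frame of hits: `id`, `motif` (`"pentapeptide"`),
#'   `start` (1-based), `match`, `x1`, `x2`.
#' @export
scan_pentapeptide <- function(record) {
  s <- record$sequence
  if (nchar(s) < 5L) return(empty_hits())
  pat <- paste0("G", AA_CLASS, "S", AA_CLASS, "G")
  starts <- overlapping_starts(s, pat)
  if (length(starts) == 0L) return(empty_hits())
  match <- substring(s, starts, starts + 4L)
  hit_row(record$id, "pentapeptide", starts, match,
          x1 = substring(match, 2, 2), x2 = substring(match, 4, 4))
}

#' Scan a sequence for the GDSL-family GDS motif
#'
#' Reports every GDS tri-residue match, annotated with whether the match
#' begins within the N-terminal window (`start <= nterm_fraction *
#' length`) and whether it is L-extended (position 4 is L, the canonical
#' GDS(L) form). A GDE variant lacks the catalytic serine and never
#' matches.
#'
#' @param record Protein record (needs `id`, `sequence`).
#' @param nterm_fraction Fraction of the sequence counted as N-terminal
#'   (default 0.25).
#' @return Hits data.frame with extra logical columns `nterm` and
#'   `l_extended`.
#' @export
scan_gdsl <- function(record, nterm_fraction = 0.25) {
  s <- record$sequence
  if (nchar(s) < 3L) return(cbind(empty_hits(), nterm = logical(),
                                  l_extended = logical()))
  starts <- overlapping_starts(s, "GDS")
  if (length(starts) == 0L) {
    return(cbind(empty_hits(), nterm = logical(), l_extended = logical()))
  }
  hits <- hit_row(record$id, "gdsl", starts, substring(s, starts, starts + 2L))
  hits$nterm <- starts <= nterm_fraction * nchar(s)
  hits$l_extended <- substring(s, starts + 3L, starts + 3L) == "L"
  hits
}

#' Scan a sequence for subcellular targeting-signal motifs
#'
#' Four signal grammars are searched:
#' \itemize{
#'   \item di-leucine vacuolar/endosomal sorting motifs, either
#'     `[D/E]-X-X-X-L-[L/I]` or `D-X-X-L-L`, anywhere in the sequence;
#'   \item the ER-retention signal `[K/D]-[D/E]-E-L`, only as the last
#'     four residues;
#'   \item peroxisomal targeting signal 1, `[S/A/C]-[K/R/H]-[L/M]`, only
#'     as the last three residues;
#'   \item peroxisomal targeting signal 2, `S-S-L`, anchored at the
#'     C terminus by default (`pts2_anchor = "C"`); PTS2 is biologically
#'     usually N-terminal, so `pts2_anchor = "N"` searches the first
#'     `pts2_window` residues instead.
#' }
#' Anchored motifs never report internal matches. A di-leucine motif by
#' itself does not imply vacuolar localization; the localization rules
#' additionally require a secretory-pathway (signal-peptide) prediction.
#'
#' @param record Protein record.
#' @param pts2_anchor `"C"` (default) or `"N"`.
#' @param pts2_window Window length for N-terminal PTS2 search.
#' @return Hits data.frame (`motif` one of `"dileucine"`,
#'   `"er_retention"`, `"pts1"`, `"pts2"`).
#' @export
scan_targeting_signals <- function(record, pts2_anchor = c("C", "N"),
                                   pts2_window = 30L) {
  pts2_anchor <- match.arg(pts2_anchor)
  s <- record$sequence
  n <- nchar(s)
  if (n == 0L) stop("empty sequence for ", record$id)
  out <- list()
  # di-leucine, anywhere
  for (pat in c(paste0("[DE]", AA_CLASS, AA_CLASS, AA_CLASS, "L[LI]"),
                paste0("D", AA_CLASS, AA_CLASS, "LL"))) {
    starts <- overlapping_starts(s, pat)
    w <- if (grepl("\\[LI\\]", pat)) 6L else 5L
    if (length(starts) > 0L) {
      out[[length(out) + 1L]] <-
        hit_row(record$id, "dileucine", starts, substring(s, starts, starts + w - 1L))
    }
  }
  # ER retention: last 4 residues
  if (n >= 4L) {
    tail4 <- substring(s, n - 3L, n)
    if (grepl("^[KD][DE]EL$", tail4)) {
      out[[length(out) + 1L]] <- hit_row(record$id, "er_retention", n - 3L, tail4)
    }
  }
  # PTS1: last 3 residues
  if (n >= 3L) {
    tail3 <- substring(s, n - 2L, n)
    if (grepl("^[SAC][KRH][LM]$", tail3)) {
      out[[length(out) + 1L]] <- hit_row(record$id, "pts1", n - 2L, tail3)
    }
  }
  # PTS2: S-S-L, anchored
  if (n >= 3L) {
    if (pts2_anchor == "C") {
      tail3 <- substring(s, n - 2L, n)
      if (tail3 == "SSL") {
        out[[length(out) + 1L]] <- hit_row(record$id, "pts2", n - 2L, "SSL")
      }
    } else {
      head_region <- substring(s, 1L, min(pts2_window, n))
      starts <- overlapping_starts(head_region, "SSL")
      if (length(starts) > 0L) {
        out[[length(out) + 1L]] <- hit_row(record$id, "pts2", starts, "SSL")
      }
    }
  }
  if (length(out) == 0L) return(empty_hits())
  hits <- do.call(rbind, out)
  hits[order(hits$start, hits$motif), , drop = FALSE]
}

#' Summarize pentapeptide variable residues over a protein set
#'
#' Takes pentapeptide hits (one retained hit per protein: the first by
#' position) and tabulates the frequencies of the variable residues X1
#' and X2, plus the fraction of hydrophobic X2 (I, L, M, V, A).
#'
#' @param hits Pentapeptide hits data.frame.
#' @return List with `x1_freq`, `x2_freq` (named proportions summing to
#'   1) and `hydrophobic_x2_fraction`.
#' @export
summarize_pentapeptide_variants <- function(hits) {
  if (nrow(hits) == 0L) {
    return(list(x1_freq = numeric(), x2_freq = numeric(),
                hydrophobic_x2_fraction = NA_real_))
  }
  hits <- hits[hits$motif == "pentapeptide", , drop = FALSE]
  # first hit per protein
  hits <- hits[order(hits$id, hits$start), , drop = FALSE]
  hits <- hits[!duplicated(hits$id), , drop = FALSE]
  x1 <- table(hits$x1) / nrow(hits)
  x2 <- table(hits$x2) / nrow(hits)
  hydro <- mean(hits$x2 %in% c("I", "L", "M", "V", "A"))
  list(x1_freq = c(x1), x2_freq = c(x2), hydrophobic_x2_fraction = hydro)
}
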