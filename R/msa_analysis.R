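# Family-alignment analysis: per-column conservation, mapping of motif
# hits into alignment columns, catalytic-partner candidates and
# oxyanion-hole type classification. All reported positions are 1-based
# alignment columns (i.e. they include gaps).

alignment_matrix <- function(alignment) {
  do.call(rbind, strsplit(alignment$sequences, "", fixed = TRUE))
}

#' Per-column conservation of an alignment
#'
#' For each column, the modal residue and the fraction of sequences
#' carrying it. Gaps are excluded from the denominator by default
#' (`denominator = "nongap"`); `denominator = "all"` divides by the
#' number of rows instead. A column is highlighted iff its fraction is
#' strictly greater than the threshold (default 0.8, "conserved in more
#' than 80% of the sequences").
#'
#' @param alignment An `aa_alignment`.
#' @param threshold Conservation threshold (strict `>`).
#' @param denominator `"nongap"` (default) or `"all"`.
#' @return Data frame: `column`, `modal_residue`, `fraction`,
#'   `gap_fraction`, `highlighted`.
#' @export
column_conservation <- function(alignment, threshold = CONSERVATION_THRESHOLD,
                                denominator = c("nongap", "all")) {
  denominator <- match.arg(denominator)
  m <- alignment_matrix(alignment)
  nrow_m <- nrow(m)
  out <- lapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    nongap <- col[col != "-"]
    gap_fraction <- 1 - length(nongap) / nrow_m
    if (length(nongap) == 0L) {
      return(data.frame(column = j, modal_residue = NA_character_,
                        fraction = 0, gap_fraction = 1, highlighted = FALSE,
                        stringsAsFactors = FALSE))
    }
    tab <- sort(table(nongap), decreasing = TRUE)
    denom <- if (denominator == "nongap") length(nongap) else nrow_m
    frac <- unname(tab[1]) / denom
    data.frame(column = j, modal_residue = names(tab)[1], fraction = frac,
               gap_fraction = gap_fraction,
               highlighted = frac > threshold, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Map ungapped motif positions to alignment columns
#'
#' Lifts 1-based positions in the ungapped sequence of one alignment row
#' to 1-based alignment-column indices.
#'
#' @param alignment An `aa_alignment`.
#' @param id Row identifier.
#' @param positions Integer vector of ungapped positions.
#' @return Integer vector of alignment columns (same length).
#' @export
map_to_columns <- function(alignment, id, positions) {
  row <- match(id, alignment$ids)
  if (is.na(row)) stop("id not in alignment: ", id)
  chars <- strsplit(alignment$sequences[row], "", fixed = TRUE)[[1]]
  nongap_cols <- which(chars != "-")
  if (any(positions < 1L | positions > length(nongap_cols))) {
    stop("position beyond ungapped sequence length for ", id)
  }
  nongap_cols[positions]
}

#' Map alignment columns back to ungapped positions
#'
#' Inverse of [map_to_columns()]; errors if a requested column is a gap
#' in that row.
#'
#' @param alignment An `aa_alignment`.
#' @param id Row identifier.
#' @param columns Integer vector of alignment columns.
#' @return Integer vector of ungapped positions.
#' @export
map_to_positions <- function(alignment, id, columns) {
  row <- match(id, alignment$ids)
  if (is.na(row)) stop("id not in alignment: ", id)
  chars <- strsplit(alignment$sequences[row], "", fixed = TRUE)[[1]]
  nongap <- chars != "-"
  if (any(!nongap[columns])) stop("column is a gap in ", id)
  cumsum(nongap)[columns]
}

#' Candidate catalytic partners downstream of the serine
#'
#' The catalytic machinery of these lipase families is a serine, an
#' acidic residue (D/E) and, except in patatin-like dyads, a histidine,
#' the partners lying C-terminal to the serine at conserved but isolated
#' positions. This lists every column downstream of the serine column
#' whose modal residue is D/E (acidic candidates) or H (histidine
#' candidates), with its conservation, so weakly conserved cases remain
#' visible; no single "the triad" choice is made. Empty candidate lists
#' are valid (patatin-like centers need only serine + acid).
#'
#' @param alignment An `aa_alignment`.
#' @param serine_column Alignment column of the catalytic serine.
#' @param threshold Conservation threshold for the `conserved` flag.
#' @return List with data.frames `acidic` and `histidine` (columns:
#'   `column`, `residue`, `conservation`, `conserved`).
#' @export
find_catalytic_partners <- function(alignment, serine_column,
                                    threshold = CONSERVATION_THRESHOLD) {
  cons <- column_conservation(alignment, threshold)
  down <- cons[cons$column > serine_column & !is.na(cons$modal_residue), ,
               drop = FALSE]
  pick <- function(residues) {
    sel <- down[down$modal_residue %in% residues, , drop = FALSE]
    data.frame(column = sel$column, residue = sel$modal_residue,
               conservation = sel$fraction,
               conserved = sel$fraction > threshold,
               stringsAsFactors = FALSE)
  }
  list(acidic = pick(c("D", "E")), histidine = pick("H"))
}

#' Classify the oxyanion-hole type
#'
#' GDSL-family sequences form a distinct oxyanion hole around the
#' catalytic serine and are returned as `"GDSL-type"` directly. For the
#' other families the region N-terminal to the catalytic serine is
#' searched for a conserved G-G-G-X run (`"GGGX"`), else a conserved
#' G-X pair (`"GX"`); when no conserved glycine-led pair exists the
#' result is `"unknown"` (this also covers the tyrosine-based "Y" class,
#' for which no sequence rule is implemented). The X residue is reported
#' (in class 3 lipases X is mainly T).
#'
#' @param alignment An `aa_alignment`.
#' @param serine_column Alignment column of the catalytic serine.
#' @param family Family label; `"GDSL lipase"` short-circuits.
#' @param threshold Conservation threshold for "conserved".
#' @param window Number of columns upstream of the serine searched
#'   (default 300).
#' @return List with `type` (one of `"GX"`, `"GGGX"`, `"GDSL-type"`,
#'   `"unknown"`), `x_residue` and `column` (of the leading G; NA when
#'   not applicable).
#' @export
classify_oxyanion <- function(alignment, serine_column, family,
                              threshold = CONSERVATION_THRESHOLD,
                              window = 300L) {
  if (!is.na(family) && family == "GDSL lipase") {
    return(list(type = "GDSL-type", x_residue = NA_character_,
                column = NA_integer_))
  }
  cons <- column_conservation(alignment, threshold)
  lo <- max(1L, serine_column - window)
  region <- cons[cons$column >= lo & cons$column < serine_column, ,
                 drop = FALSE]
  conserved <- !is.na(region$modal_residue) & region$fraction > threshold
  res <- region$modal_residue
  n <- nrow(region)
  # conserved G-G-G-X run first
  if (n >= 4L) {
    for (i in seq_len(n - 3L)) {
      if (all(conserved[i:(i + 3L)]) &&
          all(res[i:(i + 2L)] == "G") && res[i + 3L] != "G") {
        return(list(type = "GGGX", x_residue = res[i + 3L],
                    column = region$column[i]))
      }
    }
  }
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      if (conserved[i] && conserved[i + 1L] &&
          res[i] == "G" && res[i + 1L] != "G") {
        return(list(type = "GX", x_residue = res[i + 1L],
                    column = region$column[i]))
      }
    }
  }
  list(type = "unknown", x_residue = NA_character_, column = NA_integer_)
}
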