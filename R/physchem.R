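# ProtParam-style physico-chemical descriptors. Constant tables live in
# constants.R and follow the ProtParam conventions (average masses,
# Bjellqvist pKa set, Kyte-Doolittle hydropathy, Guruprasad DIWV,
# Gill - von Hippel extinction coefficients, N-end-rule half-life).

# Split into residue vector, handling ambiguity letters per mode.
# mode "lenient": drop X/B/Z/U with a warning; "strict": error.
residues_of <- function(sequence, mode = c("lenient", "strict"),
                        what = "descriptor") {
  mode <- match.arg(mode)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  amb <- chars %in% AA_AMBIGUOUS
  if (any(amb)) {
    if (mode == "strict") {
      stop("ambiguity letter '", chars[which(amb)[1]], "' in sequence (",
           what, ", strict mode)")
    }
    warning(sum(amb), " ambiguity letter(s) excluded from ", what)
    chars <- chars[!amb]
  }
  bad <- !chars %in% AA_STANDARD
  if (any(bad)) stop("invalid residue '", chars[which(bad)[1]], "'")
  chars
}

#' Molecular weight of a protein (average masses)
#'
#' Sum of average free amino-acid masses minus one water per peptide
#' bond, i.e. `sum(mass) - (n - 1) * 18.0153` Da.
#'
#' @param sequence Amino-acid sequence string.
#' @param mode `"lenient"` (ambiguity letters dropped, with warning) or
#'   `"strict"` (error).
#' @return Molecular weight in Dalton.
#' @export
molecular_weight <- function(sequence, mode = "lenient") {
  chars <- residues_of(sequence, mode, "molecular weight")
  if (length(chars) == 0L) stop("empty sequence")
  sum(AA_WEIGHT[chars]) - (length(chars) - 1L) * MASS_WATER
}

#' Counts of charged residues
#'
#' ProtParam convention: negative = D + E, positive = R + K (histidine is
#' not counted).
#'
#' @param sequence Amino-acid sequence string.
#' @return Named integer vector `c(n_negative, n_positive)`.
#' @export
charge_counts <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  c(n_negative = sum(chars %in% c("D", "E")),
    n_positive = sum(chars %in% c("R", "K")))
}

#' Molar extinction coefficient at 280 nm
#'
#' Gill - von Hippel coefficients: 5500 per Trp, 1490 per Tyr; the
#' cystine form adds 125 per disulfide pair (`floor(nC / 2)`).
#'
#' @param sequence Amino-acid sequence string.
#' @return Named vector `c(reduced, cystine)` in M^-1 cm^-1.
#' @export
extinction_coefficient_280 <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  reduced <- EXT_TRP * sum(chars == "W") + EXT_TYR * sum(chars == "Y")
  c(reduced = reduced,
    cystine = reduced + EXT_CYSTINE * (sum(chars == "C") %/% 2L))
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the termini and the D, E, C, Y, H, K,
#' R side chains with the Bjellqvist pKa set. Strictly decreasing in pH;
#' its unique zero is the isoelectric point.
#'
#' @param sequence Amino-acid sequence string.
#' @param ph pH value.
#' @param mode Ambiguity handling, see [molecular_weight()].
#' @return Net charge in elementary-charge units.
#' @export
net_charge <- function(sequence, ph, mode = "lenient") {
  chars <- residues_of(sequence, mode, "net charge")
  if (length(chars) == 0L) stop("empty sequence")
  first <- chars[1]; last <- chars[length(chars)]
  pos_frac <- function(pka) 1 / (1 + 10^(ph - pka))
  neg_frac <- function(pka) -1 / (1 + 10^(pka - ph))
  nterm_pka <- if (first %in% names(PKA_NTERM_BY_RESIDUE)) {
    PKA_NTERM_BY_RESIDUE[[first]]
  } else PKA_POSITIVE[["Nterm"]]
  cterm_pka <- if (last %in% names(PKA_CTERM_BY_RESIDUE)) {
    PKA_CTERM_BY_RESIDUE[[last]]
  } else PKA_NEGATIVE[["Cterm"]]
  q <- pos_frac(nterm_pka) + neg_frac(cterm_pka)
  for (res in c("K", "R", "H")) {
    q <- q + sum(chars == res) * pos_frac(PKA_POSITIVE[[res]])
  }
  for (res in c("D", "E", "C", "Y")) {
    q <- q + sum(chars == res) * neg_frac(PKA_NEGATIVE[[res]])
  }
  q
}

#' Isoelectric point
#'
#' pH at which the Henderson-Hasselbalch net charge (termini plus D, E,
#' C, Y, H, K, R side chains, Bjellqvist pKa set) crosses zero, found by
#' bisection on [0, 14]. The net charge is strictly decreasing in pH, so
#' the root is unique.
#'
#' @param sequence Amino-acid sequence string.
#' @param tolerance Bisection tolerance in pH units (default 1e-3).
#' @param mode Ambiguity handling, see [molecular_weight()].
#' @return Isoelectric point in pH units.
#' @export
isoelectric_point <- function(sequence, tolerance = 1e-3, mode = "lenient") {
  lo <- 0; hi <- 14
  while (hi - lo > tolerance) {
    mid <- (lo + hi) / 2
    if (net_charge(sequence, mid, mode) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Instability index (Guruprasad)
#'
#' `II = (10 / L) * sum(DIWV(i, i+1))` over consecutive dipeptides, with
#' the published dipeptide weight values. Proteins with II > 40 are
#' classed unstable (in vivo half-life under ~5 h).
#'
#' @param sequence Amino-acid sequence string (length >= 2 after
#'   ambiguity handling).
#' @param mode Ambiguity handling.
#' @return List with `value` and logical `unstable`.
#' @export
instability_index <- function(sequence, mode = "lenient") {
  chars <- residues_of(sequence, mode, "instability index")
  n <- length(chars)
  if (n < 2L) stop("instability index undefined for length < 2")
  idx <- cbind(match(chars[-n], AA_STANDARD), match(chars[-1], AA_STANDARD))
  value <- (10 / n) * sum(DIWV[idx])
  list(value = value, unstable = value > INSTABILITY_THRESHOLD)
}

#' Aliphatic index (Ikai)
#'
#' `AI = X(Ala) + 2.9 X(Val) + 3.9 (X(Ile) + X(Leu))` with X in mole
#' percent. Values above 80 indicate likely thermostability.
#'
#' @param sequence Amino-acid sequence string.
#' @param mode Ambiguity handling.
#' @return List with `value` and logical `thermostable`.
#' @export
aliphatic_index <- function(sequence, mode = "lenient") {
  chars <- residues_of(sequence, mode, "aliphatic index")
  if (length(chars) == 0L) stop("empty sequence")
  mp <- function(res) 100 * mean(chars == res)
  value <- mp("A") + 2.9 * mp("V") + 3.9 * (mp("I") + mp("L"))
  list(value = value, thermostable = value > ALIPHATIC_THRESHOLD)
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over all residues; positive values
#' indicate hydrophobic proteins.
#'
#' @param sequence Amino-acid sequence string.
#' @param mode Ambiguity handling.
#' @return GRAVY value in [-4.5, 4.5].
#' @export
gravy <- function(sequence, mode = "lenient") {
  chars <- residues_of(sequence, mode, "GRAVY")
  if (length(chars) == 0L) stop("empty sequence")
  mean(KYTE_DOOLITTLE[chars])
}

#' Estimated half-life class (N-end rule)
#'
#' N-terminal-residue lookup in the ProtParam N-end-rule table for the
#' requested expression system.
#'
#' @param sequence Amino-acid sequence string.
#' @param organism One of `"mammalian"`, `"yeast"`, `"bacterial"`.
#' @return Half-life label, e.g. `"30 h"`, or `NA` if not tabulated.
#' @export
half_life_class <- function(sequence,
                            organism = c("mammalian", "yeast", "bacterial")) {
  organism <- match.arg(organism)
  first <- toupper(substring(sequence, 1, 1))
  if (!first %in% rownames(HALF_LIFE)) return(NA_character_)
  HALF_LIFE[first, organism]
}

#' Full physico-chemical profile of a protein
#'
#' Computes the complete descriptor panel: length, molecular weight,
#' charged-residue counts, extinction coefficients, pI, instability
#' index (stable/unstable at 40), aliphatic index (thermostable flag at
#' 80), GRAVY and half-life class.
#'
#' @param record Protein record (needs `id`, `sequence`).
#' @param organism Expression system for the half-life lookup.
#' @param mode Ambiguity handling.
#' @return One-row data.frame with all descriptor columns.
#' @export
physchem_profile <- function(record, organism = "mammalian",
                             mode = "lenient") {
  s <- record$sequence
  cc <- charge_counts(s)
  ext <- extinction_coefficient_280(s)
  ii <- if (nchar(s) >= 2L) instability_index(s, mode) else
    list(value = NA_real_, unstable = NA)
  ai <- aliphatic_index(s, mode)
  data.frame(
    id = record$id,
    length = nchar(s),
    molecular_weight = round(molecular_weight(s, mode), 2),
    n_negative = unname(cc["n_negative"]),
    n_positive = unname(cc["n_positive"]),
    extinction_reduced = unname(ext["reduced"]),
    extinction_cystine = unname(ext["cystine"]),
    isoelectric_point = round(isoelectric_point(s, mode = mode), 2),
    half_life = half_life_class(s, organism),
    instability_index = ii$value,
    unstable = ii$unstable,
    aliphatic_index = ai$value,
    thermostable = ai$thermostable,
    gravy = round(gravy(s, mode), 3),
    stringsAsFactors = FALSE
  )
}

#' Physico-chemical profiles for a protein set
#'
#' @param records Protein-record table.
#' @param ... Passed to [physchem_profile()].
#' @return Data frame, one row per protein.
#' @export
physchem_profile_all <- function(records, ...) {
  do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    physchem_profile(records[i, ], ...)
  }))
}
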