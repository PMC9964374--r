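# Transcript-regulation ranking: merge multi-dataset stress time-course
# log2 fold changes, take each gene's signed maximal regulation, classify
# at absolute-log2 thresholds 1 and 2, and rank candidates.

#' Signed maximal regulation per gene
#'
#' For each gene, returns the observation whose absolute log2 fold
#' change is maximal across all datasets and timepoints, sign preserved.
#' An exact tie in absolute value between opposite signs is flagged
#' ambiguous and resolved toward the lexicographically earliest dataset
#' label. Genes present in only some datasets are summarized over their
#' available observations. The per-gene min and max signed values are
#' also reported as a dispersion diagnostic (conflicting datasets or
#' merged gene-model halves stay visible).
#'
#' @param observations Data frame: `gene`, `dataset`, `timepoint`,
#'   `log2fc` (finite).
#' @return Data frame, one row per gene: `gene`, `max_signed_log2`,
#'   `dataset`, `timepoint`, `direction` (`"up"`/`"down"`), `band`
#'   (`"|log2|<=1"`, `"1<|log2|<=2"`, `"|log2|>2"`), `ambiguous`,
#'   `min_signed`, `max_signed`.
#' @export
max_regulation <- function(observations) {
  stopifnot(all(is.finite(observations$log2fc)))
  key <- paste(observations$gene, observations$dataset,
               observations$timepoint)
  if (anyDuplicated(key)) stop("duplicate (gene, dataset, timepoint) rows")
  genes <- unique(observations$gene)
  out <- lapply(genes, function(g) {
    obs <- observations[observations$gene == g, , drop = FALSE]
    obs <- obs[order(obs$dataset, obs$timepoint), , drop = FALSE]
    amax <- max(abs(obs$log2fc))
    at <- obs[abs(obs$log2fc) == amax, , drop = FALSE]
    ambiguous <- length(unique(sign(at$log2fc))) > 1L
    best <- at[1L, ]  # earliest dataset label lexicographically
    v <- best$log2fc
    band <- if (abs(v) > 2) "|log2|>2" else
      if (abs(v) > 1) "1<|log2|<=2" else "|log2|<=1"
    data.frame(gene = g, max_signed_log2 = v, dataset = best$dataset,
               timepoint = best$timepoint,
               direction = ifelse(v >= 0, "up", "down"),
               band = band, ambiguous = ambiguous,
               min_signed = min(obs$log2fc), max_signed = max(obs$log2fc),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Direction and band counts over regulation summaries
#'
#' Both thresholds are strict: a gene is counted above a threshold only
#' if its absolute maximal log2 exceeds it.
#'
#' @param summaries Output of [max_regulation()].
#' @return List: `direction` (named counts up/down), `band` (named
#'   counts for the three bands), `above1` (named up/down counts with
#'   `|log2| > 1`), `above2` (idem at 2).
#' @export
classify_regulation <- function(summaries) {
  dir_tab <- table(factor(summaries$direction, levels = c("up", "down")))
  bands <- table(factor(summaries$band,
                        levels = c("|log2|<=1", "1<|log2|<=2", "|log2|>2")))
  above <- function(th) {
    sel <- abs(summaries$max_signed_log2) > th
    table(factor(summaries$direction[sel], levels = c("up", "down")))
  }
  list(direction = c(dir_tab), band = c(bands),
       above1 = c(above(1)), above2 = c(above(2)))
}

#' Select the most regulated candidates
#'
#' Genes whose absolute maximal log2 strictly exceeds the threshold,
#' sorted by descending absolute value, ties broken by gene id.
#'
#' @param summaries Output of [max_regulation()].
#' @param threshold Absolute-log2 cutoff (default 2).
#' @return Data frame subset of `summaries`, ranked.
#' @export
select_candidates <- function(summaries, threshold = 2) {
  sel <- summaries[abs(summaries$max_signed_log2) > threshold, ,
                   drop = FALSE]
  sel <- sel[order(-abs(sel$max_signed_log2), sel$gene), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}
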