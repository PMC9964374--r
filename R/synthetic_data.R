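# Synthetic-data generators: every input the pipeline consumes, with
# planted ground truth, so all stages are testable offline. Backgrounds
# for motif-planting draw from an alphabet without G and S where chance
# pentapeptide / GDS matches must be impossible.

#' Generate a random protein sequence
#'
#' @param length Sequence length (>= 1).
#' @param weights Named composition weights over the 20 standard
#'   residues (default uniform). Missing residues get weight 0.
#' @param id Record identifier.
#' @param seed Optional integer seed (local to this call).
#' @return One-row protein-record data.frame.
#' @export
generate_protein <- function(length, weights = NULL, id = "synth1",
                             seed = NULL) {
  if (length < 1L) stop("length must be >= 1")
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1, 20), AA_STANDARD)
  }
  if (any(weights < 0) || sum(weights) <= 0) stop("invalid weights")
  unknown <- setdiff(names(weights), AA_STANDARD)
  if (length(unknown) > 0L) stop("invalid residue in weights: ",
                                 paste(unknown, collapse = ", "))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  seq <- paste(sample(names(weights), length, replace = TRUE,
                      prob = weights / sum(weights)), collapse = "")
  data.frame(id = id, description = "synthetic protein", sequence = seq,
             stringsAsFactors = FALSE)
}

# Background alphabet that cannot produce chance GXSXG or GDS matches.
MOTIF_FREE_WEIGHTS <- stats::setNames(
  rep(1, 18), setdiff(AA_STANDARD, c("G", "S")))

#' Plant exact motif strings into a sequence
#'
#' Substitutes the given motif strings at the stated 1-based positions;
#' positions must be in range and non-overlapping. The remainder of the
#' sequence is unchanged.
#'
#' @param record Protein record.
#' @param plants Data frame: `motif` (string to insert), `position`.
#' @return List: `record` (modified), `truth` (the plants with an
#'   `end` column).
#' @export
plant_motifs <- function(record, plants) {
  s <- record$sequence
  n <- nchar(s)
  plants$end <- plants$position + nchar(plants$motif) - 1L
  if (any(plants$position < 1L | plants$end > n)) {
    stop("motif plant out of range")
  }
  o <- order(plants$position)
  plants <- plants[o, , drop = FALSE]
  if (nrow(plants) > 1L &&
      any(plants$position[-1L] <= plants$end[-nrow(plants)])) {
    stop("overlapping motif plants")
  }
  for (i in seq_len(nrow(plants))) {
    substr(s, plants$position[i], plants$end[i]) <- plants$motif[i]
  }
  record$sequence <- s
  list(record = record, truth = plants)
}

#' Generate a screening-funnel input set with planted outcomes
#'
#' Emits a protein set and matching annotation table in which every
#' protein has a planted, recorded funnel outcome: retained (per
#' family), excluded for missing keyword, for insignificant annotation,
#' for a missing pentapeptide, for a precise non-lipase function, or for
#' an inactive GDE variant of the GDSL motif.
#'
#' @param n_keep Named integer vector of retained proteins per family
#'   (names from the four family labels).
#' @param n_no_keyword,n_insignificant,n_motifless,n_function_excluded,
#'   n_gde Counts for each planted exclusion class.
#' @param seed Integer seed.
#' @param length Sequence length of each synthetic protein.
#' @return List: `records`, `annotations`, `truth` (data.frame: `id`,
#'   `category`, `family`, `expected_stage`, `expected_reason`).
#' @export
generate_screen_set <- function(n_keep = c("α/β hydrolase" = 2,
                                           "class 3 lipase" = 2,
                                           "GDSL lipase" = 2,
                                           "patatin-like phospholipase" = 2),
                                n_no_keyword = 5, n_insignificant = 3,
                                n_motifless = 2, n_function_excluded = 1,
                                n_gde = 1, seed = 1, length = 120L) {
  set.seed(seed)
  recs <- list(); anns <- list(); truth <- list(); k <- 0L
  fam_desc <- c("α/β hydrolase" = "alpha/beta hydrolase, putative",
                "class 3 lipase" = "triacylglycerol lipase, class 3",
                "GDSL lipase" = "GDSL esterase/lipase",
                "patatin-like phospholipase" = "patatin-like phospholipase")
  fam_domain <- c("α/β hydrolase" = "Abhydrolase_1",
                  "class 3 lipase" = "Lipase_3",
                  "GDSL lipase" = "GDSL_lipase",
                  "patatin-like phospholipase" = "Patatin")
  add <- function(desc, domain, evalue, best_function, sequence,
                  category, family, stage, reason) {
    k <<- k + 1L
    id <- sprintf("SYN%03d", k)
    recs[[k]] <<- data.frame(id = id, description = desc,
                             sequence = sequence, stringsAsFactors = FALSE)
    anns[[k]] <<- data.frame(id = id, description = desc, domain = domain,
                             evalue = evalue, best_function = best_function,
                             stringsAsFactors = FALSE)
    truth[[k]] <<- data.frame(id = id, category = category,
                              family = family, expected_stage = stage,
                              expected_reason = reason,
                              stringsAsFactors = FALSE)
  }
  background <- function() {
    paste(sample(names(MOTIF_FREE_WEIGHTS), length, replace = TRUE),
          collapse = "")
  }
  with_motif <- function(motif, position) {
    s <- background()
    substr(s, position, position + nchar(motif) - 1L) <- motif
    s
  }
  sig <- function() 10^stats::runif(1, -30, -6)    # strictly below 1e-5
  insig <- function() 10^stats::runif(1, -4, -1)   # strictly above 1e-5

  for (fam in names(n_keep)) {
    for (i in seq_len(n_keep[[fam]])) {
      motif <- if (fam == "GDSL lipase") "GDSL" else "GHSLG"
      pos <- if (fam == "GDSL lipase") sample(5:20, 1) else
        sample(40:80, 1)
      add(fam_desc[[fam]], fam_domain[[fam]], sig(),
          "triacylglycerol lipase", with_motif(motif, pos),
          "keep", fam, "retained", NA_character_)
    }
  }
  for (i in seq_len(n_no_keyword)) {
    add("protein kinase, putative", "Pkinase", sig(), "protein kinase",
        background(), "no_keyword", NA, "keyword", "no keyword")
  }
  for (i in seq_len(n_insignificant)) {
    add("lipase family protein", "Abhydrolase_1", insig(), "",
        with_motif("GHSLG", 50), "insignificant", NA,
        "significance", "no significant annotation")
  }
  for (i in seq_len(n_motifless)) {
    add("triacylglycerol lipase, putative", "Lipase_3", sig(), "lipase",
        background(), "motifless", NA, "motif", "no pentapeptide motif")
  }
  for (i in seq_len(n_function_excluded)) {
    add("alpha/beta hydrolase fold protein", "Abhydrolase_1", sig(),
        "proline iminopeptidase", with_motif("GHSLG", 50),
        "function_excluded", NA, "function", "excluded function")
  }
  for (i in seq_len(n_gde)) {
    add("GDSL esterase/lipase", "GDSL_lipase", sig(), "",
        with_motif("GDEL", 10), "gde", "GDSL lipase", "motif",
        "missing catalytic serine")
  }
  list(records = do.call(rbind, recs),
       annotations = do.call(rbind, anns),
       truth = do.call(rbind, truth))
}

#' Generate a predictor table with planted compartments
#'
#' Each planted compartment is encoded by exactly the evidence that the
#' localization rules require (e.g. plastid call for chloroplast, signal
#' peptide plus di-leucine motif for an ER-routed vacuole candidate).
#' With `noise = 0`, [localize_all()] recovers every plant. Each noisy
#' row has one evidence column flipped at random.
#'
#' @param plants Data frame: `id`, `compartment` (one of the seven
#'   classes), optional logical `vacuole` (only meaningful for ER).
#' @param noise Probability a row is corrupted (in [0, 1)).
#' @param seed Integer seed.
#' @return List: `predictors` (data.frame), `targeting_hits` (motif-hit
#'   data.frame), `truth` (the plants, with a `noisy` flag).
#' @export
generate_predictor_table <- function(plants, noise = 0, seed = 1) {
  stopifnot(noise >= 0, noise < 1)
  set.seed(seed)
  if (is.null(plants$vacuole)) plants$vacuole <- FALSE
  bad <- setdiff(plants$compartment, COMPARTMENTS)
  if (length(bad) > 0L) stop("unknown compartment: ",
                             paste(unique(bad), collapse = ", "))
  n <- nrow(plants)
  pred <- data.frame(id = plants$id, plastid_positive = 0L,
                     mito_score = 0, signal_peptide = 0L, tm_count = 0L,
                     stringsAsFactors = FALSE)
  hits <- list()
  for (i in seq_len(n)) {
    comp <- plants$compartment[i]
    id <- plants$id[i]
    if (comp == "chloroplast") pred$plastid_positive[i] <- 1L
    if (comp %in% c("mitochondria", "mitochondria/peroxisome")) {
      pred$mito_score[i] <- stats::runif(1, 0.9, 0.99)
    }
    if (comp == "mitochondria/peroxisome" || comp == "peroxisome") {
      hits[[length(hits) + 1L]] <- hit_row(id, "pts1", 101L, "SKL")
    }
    if (comp == "ER") {
      pred$signal_peptide[i] <- 1L
      if (isTRUE(plants$vacuole[i])) {
        hits[[length(hits) + 1L]] <- hit_row(id, "dileucine", 30L, "ETTTLL")
      }
    }
    if (comp == "ER/cytosol") pred$tm_count[i] <- sample(1:3, 1)
  }
  noisy <- stats::runif(n) < noise
  for (i in which(noisy)) {
    col <- sample(c("plastid_positive", "mito_score", "signal_peptide",
                    "tm_count"), 1)
    pred[[col]][i] <- if (pred[[col]][i] > 0) 0 else
      if (col == "mito_score") 0.95 else 1
  }
  plants$noisy <- noisy
  targeting <- if (length(hits) > 0L) do.call(rbind, hits) else empty_hits()
  list(predictors = pred, targeting_hits = targeting, truth = plants)
}

#' Generate a multi-dataset regulation table with planted maxima
#'
#' For each gene the intended signed maximum is planted at one
#' (dataset, timepoint) cell; all other observations are drawn strictly
#' smaller in absolute value. Gaussian noise of standard deviation
#' `noise_sd` is added to the non-maximal cells only, truncated so the
#' planted cell stays the unique absolute maximum; at `noise_sd = 0`
#' the recovered maxima are exact.
#'
#' @param effects Named numeric vector: gene -> intended signed maximal
#'   log2 fold change.
#' @param datasets Dataset labels (default three studies).
#' @param timepoints Timepoint labels per dataset.
#' @param noise_sd Noise standard deviation.
#' @param seed Integer seed.
#' @return List: `observations` (data.frame: gene, dataset, timepoint,
#'   log2fc), `truth` (data.frame: gene, planted_max).
#' @export
generate_regulation_table <- function(effects,
                                      datasets = c("dsA", "dsB", "dsC"),
                                      timepoints = c("t1", "t2", "t3"),
                                      noise_sd = 0, seed = 1) {
  stopifnot(length(datasets) >= 1L)
  set.seed(seed)
  genes <- names(effects)
  obs <- list()
  for (g in genes) {
    target <- effects[[g]]
    cells <- expand.grid(dataset = datasets, timepoint = timepoints,
                         stringsAsFactors = FALSE)
    peak <- sample(nrow(cells), 1)
    amax <- abs(target)
    for (r in seq_len(nrow(cells))) {
      v <- if (r == peak) target else {
        base <- stats::runif(1, -0.7, 0.7) * amax
        v2 <- base + stats::rnorm(1, 0, noise_sd)
        # keep the planted cell the unique absolute maximum
        if (amax > 0) sign(v2) * min(abs(v2), 0.95 * amax) else 0
      }
      obs[[length(obs) + 1L]] <- data.frame(
        gene = g, dataset = cells$dataset[r],
        timepoint = cells$timepoint[r], log2fc = v,
        stringsAsFactors = FALSE)
    }
  }
  list(observations = do.call(rbind, obs),
       truth = data.frame(gene = genes, planted_max = unname(effects),
                          stringsAsFactors = FALSE))
}

# Internal-coordinate (NeRF) placement of atom D bonded to C, with bond
# length r, bond angle theta at C (B-C-D) and torsion chi (A-B-C-D).
nerf_place <- function(a, b, c_, r, theta, chi) {
  th <- theta * pi / 180; ch <- chi * pi / 180
  bc <- c_ - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a; ab <- ab / sqrt(sum(ab^2))
  n <- cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- c(-r * cos(th), r * sin(th) * cos(ch), -r * sin(th) * sin(ch))
  c_ + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Fixed backbone internal coordinates for synthetic chain construction.
GEOM <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
             a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
             omega = 180)

#' Build an ideal-geometry backbone with prescribed dihedrals
#'
#' Constructs an n-residue poly-alanine backbone chain by sequential
#' internal-coordinate placement (fixed bond lengths and angles, omega =
#' 180 degrees) such that the measured phi/psi dihedrals equal the
#' requested values. The per-residue confidence plan is stored as the
#' pLDDT-style confidence.
#'
#' @param n Number of residues (>= 3).
#' @param phi,psi Backbone dihedrals in degrees (scalar or vector;
#'   default ideal alpha helix, phi = -57, psi = -47).
#' @param confidence Per-residue confidence values in [0, 100] (scalar
#'   or vector of length n).
#' @return A `pdb_backbone` object.
#' @export
generate_helix_structure <- function(n, phi = -57, psi = -47,
                                     confidence = 90) {
  if (n < 3L) stop("n must be >= 3")
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  confidence <- rep_len(confidence, n)
  co <- array(NA_real_, dim = c(n, 3, 3),
              dimnames = list(NULL, c("N", "CA", "C"), c("x", "y", "z")))
  co[1, "N", ] <- c(0, 0, 0)
  co[1, "CA", ] <- c(GEOM$b_n_ca, 0, 0)
  ang <- GEOM$a_n_ca_c * pi / 180
  co[1, "C", ] <- co[1, "CA", ] +
    GEOM$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n - 1L)) {
    co[i + 1L, "N", ] <- nerf_place(co[i, "N", ], co[i, "CA", ], co[i, "C", ],
                                    GEOM$b_c_n, GEOM$a_ca_c_n, psi[i])
    co[i + 1L, "CA", ] <- nerf_place(co[i, "CA", ], co[i, "C", ],
                                     co[i + 1L, "N", ],
                                     GEOM$b_n_ca, GEOM$a_c_n_ca, GEOM$omega)
    co[i + 1L, "C", ] <- nerf_place(co[i, "C", ], co[i + 1L, "N", ],
                                    co[i + 1L, "CA", ],
                                    GEOM$b_ca_c, GEOM$a_n_ca_c, phi[i + 1L])
  }
  res <- data.frame(chain = "A", resno = seq_len(n), resname = "ALA",
                    confidence = confidence, complete = TRUE,
                    stringsAsFactors = FALSE)
  structure(list(residues = res, coords = co), class = "pdb_backbone")
}

#' Write an ideal-geometry backbone to a PDB file
#'
#' Convenience wrapper: [generate_helix_structure()] then [write_pdb()].
#' Note the PDB fixed-column format stores coordinates to 0.001 A, so
#' dihedrals re-measured from the file agree with the build values to
#' about 0.1 degree; the in-memory structure is exact.
#'
#' @inheritParams generate_helix_structure
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
generate_helix_pdb <- function(n, path, phi = -57, psi = -47,
                               confidence = 90) {
  s <- generate_helix_structure(n, phi, psi, confidence)
  write_pdb(s, path)
}
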