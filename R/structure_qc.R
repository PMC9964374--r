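# Predicted-structure quality control: backbone dihedrals, Ramachandran
# region fractions, per-residue confidence (pLDDT) summaries and rolling
# smoothing of per-residue score series.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Signed dihedral (degrees, IUPAC convention) of four points.
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Backbone phi/psi dihedrals of a structure
#'
#' phi(i) is the C(i-1)-N(i)-CA(i)-C(i) torsion, psi(i) the
#' N(i)-CA(i)-C(i)-N(i+1) torsion, in degrees with the standard sign
#' convention. Angles are undefined (NA) at chain termini and wherever a
#' participating residue is missing a backbone atom.
#'
#' @param structure A `pdb_backbone` (see [read_structure()]).
#' @return Data frame: `resno`, `chain`, `phi`, `psi`, `complete`.
#' @export
backbone_dihedrals <- function(structure) {
  res <- structure$residues
  co <- structure$coords
  n <- nrow(res)
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!res$complete[i]) next
    same_chain <- function(j) j >= 1L && j <= n &&
      res$chain[j] == res$chain[i] && res$complete[j]
    if (same_chain(i - 1L)) {
      phi[i] <- dihedral_angle(co[i - 1L, "C", ], co[i, "N", ],
                               co[i, "CA", ], co[i, "C", ])
    }
    if (same_chain(i + 1L)) {
      psi[i] <- dihedral_angle(co[i, "N", ], co[i, "CA", ],
                               co[i, "C", ], co[i + 1L, "N", ])
    }
  }
  data.frame(resno = res$resno, chain = res$chain, phi = phi, psi = psi,
             complete = res$complete, stringsAsFactors = FALSE)
}

#' Default Ramachandran region map
#'
#' A coarse-grained 10 x 10 degree lookup over the (phi, psi) torus with
#' three classes: "highly_favored" (the canonical alpha and beta/PPII
#' basins), "favored" (a surrounding halo plus the left-handed alpha
#' region) and "questionable" (everything else, including unmapped
#' cells). The map is deliberately simple and pluggable: any matrix of
#' the same shape (36 x 36, rows = phi bins from -180, cols = psi bins
#' from -180, values in the three class labels) can be passed to
#' [ramachandran_classify()], e.g. one loaded from a TSV census.
#'
#' @return A 36 x 36 character matrix of class labels.
#' @export
default_rama_map <- function() {
  centers <- seq(-175, 175, by = 10)
  m <- matrix("questionable", 36, 36,
              dimnames = list(phi = centers, psi = centers))
  in_box <- function(v, lo, hi) v > lo & v < hi
  for (i in seq_len(36)) {
    for (j in seq_len(36)) {
      phi <- centers[i]; psi <- centers[j]
      # favored halos first, then highly favored cores overwrite
      if ((in_box(phi, -180, -20) && in_box(psi, -90, 40)) ||
          (in_box(phi, -180, -40) && (psi > 90 || psi < -160)) ||
          (in_box(phi, 30, 100) && in_box(psi, -10, 90))) {
        m[i, j] <- "favored"
      }
      if ((in_box(phi, -110, -35) && in_box(psi, -75, -5)) ||
          (in_box(phi, -165, -55) && in_box(psi, 105, 180))) {
        m[i, j] <- "highly_favored"
      }
    }
  }
  m
}

#' Classify residues into Ramachandran regions
#'
#' Each residue with both angles defined is assigned exactly one of the
#' three stereochemical-quality classes via a 10-degree grid lookup;
#' fractions are reported over the counted residues and sum to 1.
#'
#' @param dihedrals Output of [backbone_dihedrals()].
#' @param region_map Class-label matrix (default [default_rama_map()]).
#' @return List: `fractions` (named, the three classes), `percent`
#'   (rounded to 1 decimal), `counted`, `per_residue` (data.frame with
#'   `resno` and `region`).
#' @export
ramachandran_classify <- function(dihedrals, region_map = default_rama_map()) {
  ok <- !is.na(dihedrals$phi) & !is.na(dihedrals$psi)
  d <- dihedrals[ok, , drop = FALSE]
  classes <- c("highly_favored", "favored", "questionable")
  if (nrow(d) == 0L) {
    fr <- stats::setNames(rep(NA_real_, 3), classes)
    return(list(fractions = fr, percent = fr, counted = 0L,
                per_residue = data.frame(resno = integer(),
                                         region = character())))
  }
  bin <- function(a) {
    # map (-180, 180] to bins 1..36; 180 wraps to the -180 bin
    a <- ifelse(a == 180, -180, a)
    pmin(pmax(floor((a + 180) / 10) + 1L, 1L), 36L)
  }
  region <- region_map[cbind(bin(d$phi), bin(d$psi))]
  fr <- vapply(classes, function(cl) mean(region == cl), numeric(1))
  list(fractions = fr, percent = round(100 * fr, 1), counted = nrow(d),
       per_residue = data.frame(resno = d$resno, region = region,
                                stringsAsFactors = FALSE))
}

#' Per-residue confidence (pLDDT) summary
#'
#' Summarizes the per-residue confidence read from the B-factor field
#' (the predicted-structure convention, 0-100): mean, series, and
#' fractions in the bands <50 (random/disordered), 50-70, 70-90
#' (confident) and >90 (very confident).
#'
#' @param structure A `pdb_backbone`.
#' @return List: `mean`, `series`, `band_fractions` (named, sums to 1).
#' @export
plddt_summary <- function(structure) {
  v <- structure$residues$confidence
  bad <- which(is.na(v) | v < 0 | v > 100)
  if (length(bad) > 0L) {
    stop("confidence value out of [0, 100] at residue ",
         structure$residues$resno[bad[1]])
  }
  bands <- c("<50" = mean(v < 50),
             "50-70" = mean(v >= 50 & v < 70),
             "70-90" = mean(v >= 70 & v < 90),
             ">90" = mean(v >= 90))
  list(mean = mean(v), series = v, band_fractions = bands)
}

#' Centered rolling mean of a per-residue series
#'
#' Centered moving average with shrunken windows at the edges; the
#' output has the same length as the input. With an even window the
#' extra point is taken on the left (standard convention).
#'
#' @param series Numeric vector.
#' @param window Window size in residues (default 40).
#' @return Smoothed numeric vector.
#' @export
rolling_mean <- function(series, window = 40L) {
  n <- length(series)
  if (window < 1L || window > n) stop("window must be in [1, length]")
  lo_off <- ceiling((window - 1) / 2)
  hi_off <- floor((window - 1) / 2)
  vapply(seq_len(n), function(i) {
    mean(series[max(1L, i - lo_off):min(n, i + hi_off)])
  }, numeric(1))
}
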