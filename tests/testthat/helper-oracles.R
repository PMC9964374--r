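# Independent brute-force oracles used across the suite. These stay
# deliberately naive (explicit window loops, full scans) so they never
# share code paths with the implementation they check.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_seq <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Every 1-based start of a G-X-S-X-G window (X = standard residue),
# checked character by character.
oracle_pentapeptide <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  starts <- integer()
  if (n < 5L) return(starts)
  for (i in 1:(n - 4L)) {
    w <- chars[i:(i + 4L)]
    if (w[1] == "G" && w[3] == "S" && w[5] == "G" &&
        w[2] %in% AA20 && w[4] %in% AA20) {
      starts <- c(starts, i)
    }
  }
  starts
}

# Signed value of maximal absolute log2fc, full scan; ties toward the
# earliest dataset label then timepoint.
oracle_max_regulation <- function(obs) {
  obs <- obs[order(obs$dataset, obs$timepoint), , drop = FALSE]
  obs$log2fc[which.max(abs(obs$log2fc))]
}

# Toy gapped alignment builder.
toy_alignment <- function(...) {
  seqs <- c(...)
  aa_alignment(paste0("s", seq_along(seqs)), seqs)
}

# Random rigid motion of a backbone structure (rotation + translation).
rigid_motion <- function(structure) {
  th <- stats::runif(3, 0, 2 * pi)
  rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0),
              c(-sin(th[2]), 0, cos(th[2])))
  rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
              c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  rot <- rx %*% ry %*% rz
  shift <- stats::runif(3, -50, 50)
  co <- structure$coords
  for (i in seq_len(dim(co)[1])) {
    for (a in 1:3) co[i, a, ] <- as.numeric(rot %*% co[i, a, ]) + shift
  }
  structure$coords <- co
  structure
}
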