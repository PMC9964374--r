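# Embedded physico-chemical constant tables (ProtParam conventions).
# All tables are keyed by one-letter amino-acid code over the 20 standard
# residues; ambiguity letters (X/B/Z/U) are handled by the callers.

AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_AMBIGUOUS <- c("X", "B", "Z", "U")

# Average molecular weights of the free amino acids (Da). A peptide of n
# residues weighs sum(weights) - (n - 1) * MASS_WATER.
AA_WEIGHT <- c(
  A = 89.0932, C = 121.1582, D = 133.1027, E = 147.1293, F = 165.1891,
  G = 75.0666, H = 155.1546, I = 131.1729, K = 146.1876, L = 131.1729,
  M = 149.2113, N = 132.1179, P = 115.1305, Q = 146.1445, R = 174.2010,
  S = 105.0926, T = 119.1192, V = 117.1463, W = 204.2252, Y = 181.1885
)

MASS_WATER <- 18.0153

# Kyte-Doolittle hydropathy values.
KYTE_DOOLITTLE <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8,
  G = -0.4, H = -3.2, I = 4.5, K = -3.9, L = 3.8,
  M = 1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3
)

# Guruprasad dipeptide instability weight values (DIWV). Rows index the
# first residue of the dipeptide, columns the second.
DIWV <- local({
  m <- matrix(c(
    # A     C      D      E      F      G      H      I      K      L      M      N      P      Q      R      S      T      V      W      Y
    1.00, 44.94, -7.49,  1.00,  1.00,  1.00, -7.49,  1.00,  1.00,  1.00,  1.00,  1.00, 20.26,  1.00,  1.00,  1.00,  1.00,  1.00,  1.00,  1.00,   # A
    1.00,  1.00, 20.26,  1.00,  1.00,  1.00, 33.60,  1.00,  1.00, 20.26, 33.60,  1.00, 20.26, -6.54,  1.00,  1.00, 33.60, -6.54, 24.68,  1.00,   # C
    1.00,  1.00,  1.00,  1.00, -6.54,  1.00,  1.00,  1.00, -7.49,  1.00,  1.00,  1.00,  1.00,  1.00, -6.54, 20.26, -14.03,  1.00,  1.00,  1.00,  # D
    1.00, 44.94, 20.26, 33.60,  1.00,  1.00, -6.54, 20.26,  1.00,  1.00,  1.00,  1.00, 20.26, 20.26,  1.00, 20.26,  1.00,  1.00, -14.03,  1.00,  # E
    1.00,  1.00, 13.34,  1.00,  1.00,  1.00,  1.00,  1.00, -14.03,  1.00,  1.00,  1.00, 20.26,  1.00,  1.00,  1.00,  1.00,  1.00,  1.00, 33.601, # F
   -7.49,  1.00,  1.00, -6.54,  1.00, 13.34,  1.00, -7.49, -7.49,  1.00,  1.00, -7.49,  1.00,  1.00,  1.00,  1.00, -7.49,  1.00, 13.34, -7.49,   # G
    1.00,  1.00,  1.00,  1.00, -9.37, -9.37,  1.00, 44.94, 24.68,  1.00,  1.00, 24.68, -1.88,  1.00,  1.00,  1.00, -6.54,  1.00, -1.88, 44.94,   # H
    1.00,  1.00,  1.00, 44.94,  1.00,  1.00, 13.34,  1.00, -7.49, 20.26,  1.00,  1.00, -1.88,  1.00,  1.00,  1.00,  1.00, -7.49,  1.00,  1.00,   # I
    1.00,  1.00,  1.00,  1.00,  1.00, -7.49,  1.00, -7.49,  1.00, -7.49, 33.60,  1.00, -6.54, 24.64, 33.60,  1.00,  1.00, -7.49,  1.00,  1.00,   # K
    1.00,  1.00,  1.00,  1.00,  1.00,  1.00,  1.00,  1.00, -7.49,  1.00,  1.00,  1.00, 20.26, 33.60, 20.26,  1.00,  1.00,  1.00, 24.68,  1.00,   # L
   13.34,  1.00,  1.00,  1.00,  1.00,  1.00, 58.28,  1.00,  1.00,  1.00, -1.88,  1.00, 44.94, -6.54, -6.54, 44.94, -1.88,  1.00,  1.00, 24.68,   # M
    1.00, -1.88,  1.00,  1.00, -14.03, -14.03,  1.00, 44.94, 24.68,  1.00,  1.00,  1.00, -1.88, -6.54,  1.00,  1.00, -7.49,  1.00, -9.37,  1.00,  # N
   20.26, -6.54, -6.54, 18.38, 20.26,  1.00,  1.00,  1.00,  1.00,  1.00, -6.54,  1.00, 20.26, 20.26, -6.54, 20.26,  1.00, 20.26, -1.88,  1.00,   # P
    1.00, -6.54, 20.26, 20.26, -6.54,  1.00,  1.00,  1.00,  1.00,  1.00,  1.00,  1.00, 20.26, 20.26,  1.00, 44.94,  1.00, -6.54,  1.00, -6.54,   # Q
    1.00,  1.00,  1.00,  1.00,  1.00, -7.49, 20.26,  1.00,  1.00,  1.00,  1.00, 13.34, 20.26, 20.26, 58.28, 44.94,  1.00,  1.00, 58.28, -6.54,   # R
    1.00, 33.60,  1.00, 20.26,  1.00,  1.00,  1.00,  1.00,  1.00,  1.00,  1.00,  1.00, 44.94, 20.26, 20.26, 20.26,  1.00,  1.00,  1.00,  1.00,   # S
    1.00,  1.00,  1.00, 20.26, 13.34, -7.49,  1.00,  1.00,  1.00,  1.00,  1.00, -14.03,  1.00, -6.54,  1.00,  1.00,  1.00,  1.00, -14.03,  1.00, # T
    1.00,  1.00, -14.03,  1.00,  1.00, -7.49,  1.00,  1.00, -1.88,  1.00,  1.00,  1.00, 20.26,  1.00,  1.00,  1.00, -7.49,  1.00,  1.00, -6.54,  # V
  -14.03,  1.00,  1.00,  1.00,  1.00, -9.37, 24.68,  1.00,  1.00, 13.34, 24.68, 13.34,  1.00,  1.00,  1.00,  1.00, -14.03, -7.49,  1.00,  1.00,  # W
   24.68,  1.00, 24.68, -6.54,  1.00, -7.49, 13.34,  1.00,  1.00,  1.00, 44.94,  1.00, 13.34,  1.00, -15.91,  1.00, -7.49,  1.00, -9.37, 13.34   # Y
  ), nrow = 20, byrow = TRUE, dimnames = list(AA_STANDARD, AA_STANDARD))
  m
})

# Bjellqvist pKa set as used for ProtParam isoelectric points. The
# N-terminal pKa depends on the first residue; the C-terminal on the last.
PKA_POSITIVE <- c(Nterm = 7.50, K = 10.00, R = 12.00, H = 5.98)
PKA_NEGATIVE <- c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.00, Y = 10.00)
PKA_NTERM_BY_RESIDUE <- c(A = 7.59, M = 7.00, S = 6.93, P = 8.36,
                          T = 6.82, V = 7.44, E = 7.70)
PKA_CTERM_BY_RESIDUE <- c(D = 4.55, E = 4.75)

# Gill - von Hippel molar extinction coefficients at 280 nm (M^-1 cm^-1).
EXT_TRP <- 5500
EXT_TYR <- 1490
EXT_CYSTINE <- 125

# N-end-rule half-life lookup by N-terminal residue (ProtParam table):
# mammalian reticulocytes in vitro, yeast in vivo, E. coli in vivo.
HALF_LIFE <- local({
  tab <- rbind(
    A = c("4.4 h",  ">20 h",  ">10 h"),
    R = c("1 h",    "2 min",  "2 min"),
    N = c("1.4 h",  "3 min",  ">10 h"),
    D = c("1.1 h",  "3 min",  ">10 h"),
    C = c("1.2 h",  ">20 h",  ">10 h"),
    Q = c("0.8 h",  "10 min", ">10 h"),
    E = c("1 h",    "30 min", ">10 h"),
    G = c("30 h",   ">20 h",  ">10 h"),
    H = c("3.5 h",  "10 min", ">10 h"),
    I = c("20 h",   "30 min", ">10 h"),
    L = c("5.5 h",  "3 min",  "2 min"),
    K = c("1.3 h",  "3 min",  "2 min"),
    M = c("30 h",   ">20 h",  ">10 h"),
    F = c("1.1 h",  "3 min",  "2 min"),
    P = c(">20 h",  ">20 h",  NA),
    S = c("1.9 h",  ">20 h",  ">10 h"),
    T = c("7.2 h",  ">20 h",  ">10 h"),
    W = c("2.8 h",  "3 min",  "2 min"),
    Y = c("2.8 h",  "10 min", "2 min"),
    V = c("100 h",  ">20 h",  ">10 h")
  )
  colnames(tab) <- c("mammalian", "yeast", "bacterial")
  tab
})

# Thresholds used across the pipeline.
INSTABILITY_THRESHOLD <- 40
ALIPHATIC_THRESHOLD <- 80
CONSERVATION_THRESHOLD <- 0.8
EVALUE_THRESHOLD <- 1e-5
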