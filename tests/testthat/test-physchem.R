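test_that("molecular weight follows the average-mass convention", {
  expect_equal(molecular_weight("G"), 75.07, tolerance = 1e-4)
  expect_equal(molecular_weight("GG"), 132.12, tolerance = 1e-4)
  expect_error(molecular_weight(""), "empty")
  # additivity: MW(a+b) = MW(a) + MW(b) - water
  set.seed(7)
  for (i in 1:20) {
    a <- random_seq(sample(1:50, 1)); b <- random_seq(sample(1:50, 1))
    expect_equal(molecular_weight(paste0(a, b)),
                 molecular_weight(a) + molecular_weight(b) - 18.0153,
                 tolerance = 1e-9)
  }
})

test_that("charge counts and extinction coefficients", {
  expect_equal(unname(charge_counts("DEKR")), c(2, 2))
  expect_equal(unname(charge_counts("HHHH")), c(0, 0))
  expect_equal(unname(charge_counts("GGGG")), c(0, 0))
  expect_equal(unname(extinction_coefficient_280("W")), c(5500, 5500))
  expect_equal(unname(extinction_coefficient_280("YY")), c(2980, 2980))
  expect_equal(unname(extinction_coefficient_280("CC")), c(0, 125))
  expect_equal(unname(extinction_coefficient_280("CCC")), c(0, 125))
})

test_that("isoelectric point satisfies its defining property", {
  set.seed(11)
  for (i in 1:30) {
    s <- random_seq(sample(5:120, 1))
    pi_ <- isoelectric_point(s)
    expect_lt(abs(net_charge(s, pi_)), 1e-2)
  }
  expect_lt(isoelectric_point("DDDDDD"), 4.5)
  expect_gt(isoelectric_point("KKKKKK"), 9.5)
})

test_that("pI is monotone under charged-residue composition", {
  # tolerance 0.02 pH: appending a residue also swaps the
  # residue-specific C-terminal pKa (Bjellqvist set), which can shift
  # the root by ~0.01 against the side-chain effect
  set.seed(13)
  for (i in 1:15) {
    s <- random_seq(sample(5:60, 1))
    expect_gte(isoelectric_point(paste0(s, "K")) + 0.02,
               isoelectric_point(s))
    expect_lte(isoelectric_point(paste0(s, "D")) - 0.02,
               isoelectric_point(s))
  }
})

test_that("physchem descriptors match an independent reference", {
  # frozen from the ProtParam implementation in Biopython 1.88
  s1 <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRVGDGTQDNLSGAEKAVQ"
  s2 <- "GHSLGWYRDEKKCCPMNV"
  expect_equal(molecular_weight(s1), 6244.06, tolerance = 1e-5)
  expect_equal(isoelectric_point(s1, tolerance = 1e-4), 9.3950,
               tolerance = 1e-3)
  expect_equal(gravy(s1), -0.3910714, tolerance = 1e-6)
  expect_equal(instability_index(s1)$value, 43.5250, tolerance = 1e-4)
  expect_true(instability_index(s1)$unstable)
  expect_equal(molecular_weight(s2), 2123.44, tolerance = 1e-5)
  expect_equal(isoelectric_point(s2, tolerance = 1e-4), 8.0429,
               tolerance = 1e-3)
  expect_equal(gravy(s2), -0.916667, tolerance = 1e-6)
  expect_equal(instability_index(s2)$value, 13.4167, tolerance = 1e-4)
})

test_that("instability index uses the dipeptide table", {
  # DIWV(G, G) = 13.34 -> II("GG") = (10/2) * 13.34
  expect_equal(instability_index("GG")$value, 66.7)
  expect_true(instability_index("GG")$unstable)
  expect_error(instability_index("G"), "length")
  # order enters only through dipeptides
  expect_equal(instability_index("GAG")$value,
               (10 / 3) * (instability_index("GA")$value / 5 +
                           instability_index("AG")$value / 5))
})

test_that("aliphatic index closed forms", {
  expect_equal(aliphatic_index("AAAA")$value, 100)
  expect_equal(aliphatic_index("VVVV")$value, 290)
  expect_equal(aliphatic_index("GGGG")$value, 0)
  expect_true(aliphatic_index("VVVV")$thermostable)
  expect_false(aliphatic_index("GGGG")$thermostable)
})

test_that("GRAVY of homopolymers equals the hydropathy value, all residues", {
  kd <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
          H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
          P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7, V = 4.2,
          W = -0.9, Y = -1.3)
  for (aa in names(kd)) {
    expect_equal(gravy(strrep(aa, 5)), unname(kd[aa]), info = aa)
  }
})

test_that("half-life lookup is organism-keyed", {
  expect_equal(half_life_class("MKKK", "mammalian"), "30 h")
  expect_equal(half_life_class("RKKK", "yeast"), "2 min")
  expect_false(identical(half_life_class("LKKK", "mammalian"),
                         half_life_class("LKKK", "yeast")))
})

test_that("ambiguity letters: lenient warns and excludes, strict errors", {
  expect_warning(g <- gravy("AAXAA"), "ambiguity")
  expect_equal(g, 1.8)
  expect_error(gravy("AAXAA", mode = "strict"), "strict")
})

test_that("descriptors except II/half-life are permutation-invariant", {
  set.seed(17)
  s <- random_seq(60)
  chars <- strsplit(s, "")[[1]]
  # keep the termini fixed: the terminal pKa values are residue-specific
  perm <- paste(c(chars[1], sample(chars[2:59]), chars[60]), collapse = "")
  expect_equal(molecular_weight(s), molecular_weight(perm))
  expect_equal(gravy(s), gravy(perm))
  expect_equal(aliphatic_index(s)$value, aliphatic_index(perm)$value)
  expect_equal(isoelectric_point(s), isoelectric_point(perm),
               tolerance = 2e-3)
})

test_that("profile composes the individual descriptors", {
  r <- list(id = "p1", sequence = "GHSLGWYRDEKKCCPMNV")
  p <- physchem_profile(r)
  expect_equal(p$molecular_weight, round(molecular_weight(r$sequence), 2))
  expect_equal(p$gravy, round(gravy(r$sequence), 3))
  expect_equal(p$n_negative, 2)
  expect_equal(p$aliphatic_index, aliphatic_index(r$sequence)$value)
  # length-1 edge: instability undefined but profile still returned
  p1 <- physchem_profile(list(id = "x", sequence = "G"))
  expect_true(is.na(p1$instability_index))
  expect_equal(p1$length, 1)
})
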