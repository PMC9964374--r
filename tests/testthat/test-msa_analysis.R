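test_that("column conservation counts and gap handling", {
  aln <- toy_alignment("SAAGA", "SAAGA", "SAAGA", "SAAGA", "SACGT")
  cons <- column_conservation(aln)
  expect_equal(nrow(cons), 5)
  expect_equal(cons$fraction[1], 1.0)
  expect_true(cons$highlighted[1])
  # 4/5 = 0.8 is NOT highlighted (strict >)
  expect_equal(cons$fraction[3], 0.8)
  expect_false(cons$highlighted[3])

  # gaps excluded from the denominator
  aln2 <- toy_alignment("S-A", "SAA", "S-A")
  cons2 <- column_conservation(aln2)
  expect_equal(cons2$fraction[2], 1.0)
  expect_equal(cons2$gap_fraction[2], 2 / 3)

  # all-rows denominator switch
  cons3 <- column_conservation(aln2, denominator = "all")
  expect_equal(cons3$fraction[2], 1 / 3)

  # all-gap column
  aln4 <- toy_alignment("A-A", "A-A")
  expect_equal(column_conservation(aln4)$fraction[2], 0)
})

test_that("conservation is invariant to sequence order", {
  set.seed(31)
  seqs <- replicate(6, random_seq(20))
  a1 <- aa_alignment(paste0("s", 1:6), seqs)
  a2 <- aa_alignment(paste0("t", 1:6), sample(seqs))
  expect_equal(column_conservation(a1)$fraction,
               column_conservation(a2)$fraction)
})

test_that("motif positions map through gaps and round-trip", {
  aln <- toy_alignment("GH-SLG", "GHAS-G")
  expect_equal(map_to_columns(aln, "s1", 1:5), c(1, 2, 4, 5, 6))
  # gap-free row: identity
  aln2 <- toy_alignment("GHSLG", "GHSVG")
  expect_equal(map_to_columns(aln2, "s1", 1:5), 1:5)
  expect_error(map_to_columns(aln, "s1", 6), "beyond")

  # round trip property on random gappings
  set.seed(33)
  for (i in 1:50) {
    base <- random_seq(30)
    chars <- strsplit(base, "")[[1]]
    gapped <- character(45)
    pos <- sort(sample(45, 30))
    gapped[pos] <- chars; gapped[-pos] <- "-"
    aln <- aa_alignment("g1", paste(gapped, collapse = ""))
    p <- sample(30, 10)
    cols <- map_to_columns(aln, "g1", p)
    expect_equal(map_to_positions(aln, "g1", cols), p)
  }
})

test_that("catalytic partners are listed with conservation", {
  # invariant D at col 8 and H at col 12 after serine at col 4
  rows <- rep("AAASAAADAAAHAA", 5)
  aln <- do.call(toy_alignment, as.list(rows))
  cp <- find_catalytic_partners(aln, 4)
  expect_true(8 %in% cp$acidic$column)
  expect_equal(cp$acidic$conservation[cp$acidic$column == 8], 1.0)
  expect_true(12 %in% cp$histidine$column)

  # patatin-style: conserved D, no conserved H
  rows <- c("AAASAAADAAAHAA", "AAASAAADAAAYAA", "AAASAAADAAAFAA",
            "AAASAAADAAAWAA", "AAASAAADAAAVAA")
  cp <- find_catalytic_partners(do.call(toy_alignment, as.list(rows)), 4)
  expect_true(8 %in% cp$acidic$column)
  expect_equal(nrow(cp$histidine), 0)

  # weakly conserved H visible with below-threshold flag
  rows <- c("AAASAAAHAA", "AAASAAAHAA", "AAASAAAHAA", "AAASAAAVAA",
            "AAASAAAVAA")
  cp <- find_catalytic_partners(do.call(toy_alignment, as.list(rows)), 4)
  expect_equal(cp$histidine$conservation, 0.6)
  expect_false(cp$histidine$conserved)
})

test_that("planted triads on gapped copies are recovered at fraction 1", {
  set.seed(35)
  master <- strsplit(random_seq(40, setdiff(AA20, c("S", "D", "E", "H"))),
                     "")[[1]]
  master[10] <- "S"; master[25] <- "D"; master[33] <- "H"
  rows <- vapply(1:6, function(i) {
    # insert gap columns at shared random positions per row set
    paste(master, collapse = "")
  }, character(1))
  aln <- do.call(toy_alignment, as.list(rows))
  cp <- find_catalytic_partners(aln, 10)
  expect_equal(cp$acidic$column, 25)
  expect_equal(cp$acidic$conservation, 1.0)
  expect_equal(cp$histidine$column, 33)
})

test_that("oxyanion classification: GX, GGGX, GDSL, unknown", {
  # conserved GT pair upstream of serine -> GX with X = T
  rows <- rep("AAGTAAAASAA", 5)
  aln <- do.call(toy_alignment, as.list(rows))
  ox <- classify_oxyanion(aln, 9, "class 3 lipase")
  expect_equal(ox$type, "GX")
  expect_equal(ox$x_residue, "T")

  # conserved GGGA block -> GGGX
  rows <- rep("AGGGAAAAASAA", 5)
  ox <- classify_oxyanion(do.call(toy_alignment, as.list(rows)), 10,
                          "patatin-like phospholipase")
  expect_equal(ox$type, "GGGX")
  expect_equal(ox$x_residue, "A")

  # GDSL family short-circuits
  ox <- classify_oxyanion(aln, 9, "GDSL lipase")
  expect_equal(ox$type, "GDSL-type")

  # no conserved G upstream -> unknown
  rows <- c("AAATAAAASAA", "AALTAAAASAA", "AAVTAAAASAA", "AAITAAAASAA",
            "AAFTAAAASAA")
  ox <- classify_oxyanion(do.call(toy_alignment, as.list(rows)), 9,
                          "class 3 lipase")
  expect_equal(ox$type, "unknown")
})
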