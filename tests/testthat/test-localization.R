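pred_row <- function(id = "p", plastid = 0, mito = 0, sp = 0, tm = 0) {
  data.frame(id = id, plastid_positive = plastid, mito_score = mito,
             signal_peptide = sp, tm_count = tm, stringsAsFactors = FALSE)
}

no_hits <- data.frame(id = character(), motif = character(),
                      start = integer(), match = character(),
                      x1 = character(), x2 = character())

test_that("rule precedence assigns the seven compartments", {
  expect_equal(decide_localization(pred_row(plastid = 1), no_hits)$compartment,
               "chloroplast")
  expect_equal(decide_localization(pred_row(mito = 0.95), no_hits)$compartment,
               "mitochondria")
  pts <- data.frame(id = "p", motif = "pts1", start = 100L, match = "SKL",
                    x1 = "", x2 = "")
  expect_equal(decide_localization(pred_row(mito = 0.95), pts)$compartment,
               "mitochondria/peroxisome")
  expect_equal(decide_localization(pred_row(sp = 1), no_hits)$compartment,
               "ER")
  expect_equal(decide_localization(pred_row(tm = 1), no_hits)$compartment,
               "ER/cytosol")
  expect_equal(decide_localization(pred_row(), pts)$compartment,
               "peroxisome")
  expect_equal(decide_localization(pred_row(), no_hits)$compartment,
               "cytosol")
  # plastid call wins over everything
  expect_equal(decide_localization(pred_row(plastid = 1, mito = 0.99,
                                            sp = 1, tm = 3),
                                   pts)$compartment, "chloroplast")
})

test_that("vacuole candidacy needs signal peptide AND di-leucine", {
  dil <- data.frame(id = "p", motif = "dileucine", start = 3L,
                    match = "ETTTLL", x1 = "", x2 = "")
  call <- decide_localization(pred_row(sp = 1), dil)
  expect_equal(call$compartment, "ER")
  expect_true(call$vacuole_candidate)
  expect_false(decide_localization(pred_row(), dil)$vacuole_candidate)
  expect_false(decide_localization(pred_row(sp = 1),
                                   no_hits)$vacuole_candidate)
})

test_that("majority vote over multiple signal-peptide columns, ties positive", {
  row <- data.frame(id = "p", plastid_positive = 0, mito_score = 0,
                    sp_a = 1, sp_b = 0, sp_c = 1, tm_count = 0)
  expect_equal(decide_localization(row, no_hits)$compartment, "ER")
  row2 <- transform(row, sp_c = 0)
  expect_equal(decide_localization(row2, no_hits)$compartment, "cytosol")
  row3 <- data.frame(id = "p", plastid_positive = 0, mito_score = 0,
                     sp_a = 1, sp_b = 0, tm_count = 0)  # tie -> positive
  expect_equal(decide_localization(row3, no_hits)$compartment, "ER")
})

test_that("missing predictor row errors; summary partitions the set", {
  expect_error(decide_localization(NULL, no_hits), "missing")
  calls <- data.frame(id = c("a", "b", "c"),
                      compartment = c("cytosol", "cytosol", "ER"),
                      vacuole_candidate = FALSE)
  s <- summarize_localization(calls)
  expect_equal(sum(s$count), 3)
  expect_equal(s$percent[s$compartment == "cytosol"], 67L)
  s1 <- summarize_localization(calls[3, , drop = FALSE])
  expect_equal(s1$percent[s1$compartment == "ER"], 100L)
})

test_that("planted compartments recover exactly at zero noise", {
  set.seed(41)
  comps <- sample(c("cytosol", "ER/cytosol", "ER", "chloroplast",
                    "mitochondria", "mitochondria/peroxisome",
                    "peroxisome"), 60, replace = TRUE)
  plants <- data.frame(id = sprintf("q%02d", 1:60), compartment = comps)
  g <- generate_predictor_table(plants, noise = 0, seed = 43)
  calls <- localize_all(g$predictors, g$targeting_hits)
  expect_equal(calls$compartment, comps)
  # permuting row order never changes any call
  perm <- sample(nrow(g$predictors))
  calls2 <- localize_all(g$predictors[perm, ], g$targeting_hits)
  expect_equal(calls2$compartment[order(calls2$id)],
               calls$compartment[order(calls$id)])
})

test_that("recovery degrades with noise but beats random", {
  plants <- data.frame(id = sprintf("n%03d", 1:400),
                       compartment = rep(c("cytosol", "chloroplast",
                                           "mitochondria", "ER"), 100))
  g0 <- generate_predictor_table(plants, noise = 0, seed = 47)
  g5 <- generate_predictor_table(plants, noise = 0.5, seed = 47)
  rec0 <- mean(localize_all(g0$predictors, g0$targeting_hits)$compartment ==
                 plants$compartment)
  rec5 <- mean(localize_all(g5$predictors, g5$targeting_hits)$compartment ==
                 plants$compartment)
  expect_equal(rec0, 1)
  expect_lt(rec5, 1)
  expect_gt(rec5, 1 / 7)  # random over seven compartments
})

test_that("lipid-site summary proportions and per-protein counts", {
  sites <- data.frame(
    id = c(rep("a", 7), rep("b", 3)),
    type = c(rep("S-palmitoylation", 7), rep("prenylation", 3)),
    position = 1:10)
  s <- summarize_lipid_sites(sites)
  expect_equal(unname(s$type_proportions[["S-palmitoylation"]]), 0.7)
  expect_equal(sum(s$type_proportions), 1)
  expect_equal(s$n_with_site, 2)
  expect_equal(s$per_protein$id[1], "a")
  expect_equal(s$per_protein$n_sites[1], 7)

  empty <- summarize_lipid_sites(sites[0, ])
  expect_equal(empty$n_with_site, 0)
  expect_length(empty$type_proportions, 0)
})

test_that("vacuolar flag collects exactly the signal+dileucine proteins", {
  plants <- data.frame(id = c("v1", "v2", "v3", "e1", "c1"),
                       compartment = c("ER", "ER", "ER", "ER", "cytosol"),
                       vacuole = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  g <- generate_predictor_table(plants, noise = 0, seed = 51)
  calls <- localize_all(g$predictors, g$targeting_hits)
  expect_equal(flag_vacuolar_candidates(calls), c("v1", "v2", "v3"))
})
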