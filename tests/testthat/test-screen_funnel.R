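ann_row <- function(id, desc, domain = "Abhydrolase_1", evalue = 1e-12,
                    best = "") {
  data.frame(id = id, description = desc, domain = domain, evalue = evalue,
              best_function = best, stringsAsFactors = FALSE)
}

test_that("keyword filter matches case-insensitively and honors forcing", {
  ann <- rbind(ann_row("a", "Triacylglycerol LIPASE, putative"),
               ann_row("b", "protein kinase"),
               ann_row("c", "hypothetical protein"))
  cfg <- screen_config(forced_include = "c")
  kw <- keyword_filter(ann, cfg)
  expect_setequal(kw$retained, c("a", "c"))
  expect_equal(kw$forced, "c")
})

test_that("significance filter uses strict < at the threshold", {
  ann <- rbind(ann_row("a", "lipase", evalue = 1e-12),
               ann_row("b", "lipase", evalue = 1e-3),
               ann_row("c", "lipase", evalue = 1e-5),  # boundary
               ann_row("d", "lipase", evalue = NA))
  cfg <- screen_config()
  expect_equal(significance_filter(ann, c("a", "b", "c", "d"), cfg), "a")
  # min over multiple hits decides
  ann2 <- rbind(ann_row("e", "lipase", evalue = 1e-3),
                ann_row("e", "lipase", domain = "Lipase_3", evalue = 1e-9))
  expect_equal(significance_filter(ann2, "e", cfg), "e")
})

test_that("motif requirement distinguishes GDSL from pentapeptide families", {
  recs <- rbind(
    data.frame(id = "ab1", description = "", sequence = "MAAGVSHGAAA"),
    data.frame(id = "ab2", description = "", sequence = "MAAAAAAAAAA"),
    data.frame(id = "gd1", description = "", sequence = "MAGDSLAAAAA"),
    data.frame(id = "gd2", description = "", sequence = "MAGDELAAAAA"))
  hints <- c(ab1 = NA, ab2 = NA, gd1 = "GDSL lipase", gd2 = "GDSL lipase")
  mf <- motif_requirement_filter(recs, recs$id, hints, screen_config())
  expect_setequal(mf$retained, c("ab1", "gd1"))
  expect_equal(unname(mf$reason["ab2"]), "no pentapeptide motif")
  expect_equal(unname(mf$reason["gd2"]), "missing catalytic serine")
})

test_that("function exclusion matches the configured list; empty retains", {
  ann <- rbind(ann_row("a", "lipase", best = "proline iminopeptidase"),
               ann_row("b", "lipase", best = "triacylglycerol lipase"),
               ann_row("c", "lipase", best = ""))
  cfg <- screen_config()
  expect_warning(keep <- function_exclusion_filter(ann, c("a", "b", "c"), cfg),
                 "retained")
  expect_setequal(keep, c("b", "c"))
})

test_that("family assignment is rule-table driven with a warned default", {
  cfg <- screen_config()
  expect_equal(assign_family(ann_row("x", "lipase", domain = "Lipase_3"),
                             "x", cfg), "class 3 lipase")
  expect_equal(assign_family(ann_row("x", "lipase", domain = "Patatin"),
                             "x", cfg), "patatin-like phospholipase")
  expect_equal(assign_family(ann_row("x", "GDSL esterase/lipase"),
                             "x", cfg), "GDSL lipase")
  expect_warning(fam <- assign_family(ann_row("x", "lipase", domain = "Foo"),
                                      "x", cfg), "defaulting")
  expect_equal(fam, "α/β hydrolase")
})

test_that("run_screen recovers every planted outcome", {
  g <- generate_screen_set(seed = 9)
  res <- suppressWarnings(run_screen(g$records, g$annotations))
  merged <- merge(res$audit, g$truth, by = "id")
  expect_equal(merged$stage_reached, merged$expected_stage)
  expect_equal(merged$exclusion_reason, merged$expected_reason)
  expect_equal(length(res$retained),
               sum(g$truth$expected_stage == "retained"))
  # family recovery for retained proteins
  kept <- merged[merged$expected_stage == "retained", ]
  expect_equal(kept$family.x, kept$family.y)
})

test_that("funnel invariants: partition, monotonicity, determinism", {
  for (seed in c(1, 5, 23)) {
    g <- generate_screen_set(seed = seed,
                             n_no_keyword = 4, n_insignificant = 2,
                             n_motifless = 3, n_function_excluded = 2,
                             n_gde = 2)
    res <- suppressWarnings(run_screen(g$records, g$annotations))
    counts <- res$stage_counts
    expect_true(all(diff(counts[-1]) <= 0))
    # every protein appears exactly once in the audit
    expect_equal(sort(res$audit$id), sort(unique(g$annotations$id)))
    # excluded + retained partitions the input
    expect_equal(sum(!is.na(res$audit$exclusion_reason)) +
                   counts[["retained"]], counts[["input"]])
    # determinism: byte-identical audit on rerun
    res2 <- suppressWarnings(run_screen(g$records, g$annotations))
    expect_identical(res$audit, res2$audit)
  }
})

test_that("degenerate funnels behave", {
  g <- generate_screen_set(seed = 2, n_no_keyword = 0, n_insignificant = 0,
                           n_motifless = 0, n_function_excluded = 0,
                           n_gde = 0)
  res <- suppressWarnings(run_screen(g$records, g$annotations))
  expect_equal(unname(res$stage_counts[["retained"]]),
               unname(res$stage_counts[["input"]]))

  # annotation id missing from records is fatal
  ann <- ann_row("ghost", "lipase")
  recs <- data.frame(id = "real", description = "", sequence = "GHSLG")
  expect_error(run_screen(recs, ann), "ghost")
})

test_that("motifs outside a stated domain interval are flagged only", {
  hits <- scan_pentapeptide(list(id = "p", sequence = "GHSLGAAAAAGVSHG"))
  out <- flag_motif_outside_domain(hits, 8, 15)
  expect_equal(out, c(TRUE, FALSE))
})
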