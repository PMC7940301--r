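write_toy_table <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- paste("Protein IDs", "Gene names", "Ratio H/M normalized",
                  "Intensity", "Peptides", sep = "\t")
  writeLines(c(header, rows), path)
  path
}

test_that("ratio table parsing drops decoys/contaminants and reports them", {
  path <- write_toy_table(c(
    "P1\tGeneA\t0.75\t1000\t5",
    "CON__P2\tKeratin\t1.1\t99999\t12",
    "P3\tGeneB\tNaN\t500\t2"))
  rec <- parse_ratio_table(path)
  expect_equal(nrow(rec), 2L)
  expect_equal(attr(rec, "parse_report")$dropped_contaminant, 1L)
  expect_true(is.na(rec$ratio_hm_raw[rec$gene_id == "GeneB"]))
  expect_equal(rec$ratio_hm_raw[rec$gene_id == "GeneA"], 0.75)
})

test_that("parsing rejects missing mapped columns and empty files", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("Protein IDs\tGene names\tIntensity", "P1\tG1\t10"), path)
  expect_error(parse_ratio_table(path), "Ratio H/M normalized")
  empty <- tempfile(fileext = ".tsv")
  writeLines("Protein IDs\tGene names\tRatio H/M normalized\tIntensity", empty)
  expect_error(parse_ratio_table(empty), "empty")
})

test_that("duplicate gene entries collapse to the highest-intensity record", {
  path <- write_toy_table(c(
    "P1\tGeneA\t0.70\t100\t3",
    "P2\tGeneA\t0.90\t9000\t8",
    "P3\tGeneB\t1.00\t50\t1"))
  rec <- parse_ratio_table(path)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$ratio_hm_raw[rec$gene_id == "GeneA"], 0.90)
  expect_equal(attr(rec, "parse_report")$dropped_duplicate_gene, 1L)
})

test_that("median-log normalization centers the log ratios at zero", {
  df <- data.frame(gene_id = letters[1:3], ratio_hm_raw = c(0.5, 1.0, 2.0))
  expect_equal(normalize_ratios(df)$ratio_hm_norm, c(0.5, 1.0, 2.0))

  df2 <- data.frame(gene_id = letters[1:3], ratio_hm_raw = c(1.0, 2.0, 4.0))
  expect_equal(normalize_ratios(df2)$ratio_hm_norm, c(0.5, 1.0, 2.0))

  df3 <- data.frame(gene_id = "a", ratio_hm_raw = 0.8)
  expect_equal(normalize_ratios(df3)$ratio_hm_norm, 1.0)

  # property: median of log normalized ratios is 0 to machine precision
  set.seed(7)
  df4 <- data.frame(gene_id = paste0("g", 1:101),
                    ratio_hm_raw = rlnorm(101, 0.3, 0.5))
  out <- normalize_ratios(df4)
  expect_lt(abs(median(log(out$ratio_hm_norm))), 1e-12)

  # missing ratios pass through; "none" copies raw
  df5 <- data.frame(gene_id = c("a", "b"), ratio_hm_raw = c(NA, 2))
  expect_true(is.na(normalize_ratios(df5)$ratio_hm_norm[1]))
  expect_equal(normalize_ratios(df5, "none")$ratio_hm_norm, c(NA, 2))
  expect_error(normalize_ratios(data.frame(ratio_hm_raw = NA_real_)),
               "no usable")
})

test_that("cut-off derivation is the one-decimal ceiling of the control ratio", {
  expect_equal(as.numeric(derive_cutoff(0.773)), 0.8)
  expect_equal(as.numeric(derive_cutoff(0.8)), 0.8)
  expect_equal(as.numeric(derive_cutoff(0.701)), 0.8)
  expect_equal(as.numeric(derive_cutoff(0.05)), 0.1)
  expect_error(derive_cutoff(1.02), "not downregulated")
  expect_error(derive_cutoff(-0.1), "positive")
  expect_equal(attr(derive_cutoff(0.773), "provenance"), "derived")

  # idempotent on its own outputs
  for (r in c(0.773, 0.31, 0.65, 0.999)) {
    c1 <- as.numeric(derive_cutoff(r))
    if (c1 < 1) expect_equal(as.numeric(derive_cutoff(c1)), c1)
  }
})

test_that("screen classifies the hand-worked 5-gene toy correctly", {
  toy <- toy_screen_inputs()
  sites <- fake_sites(toy$complete_sites)
  cand <- screen_targets(toy$records, sites, screen_config(cutoff = 0.8))
  cls <- setNames(cand$classification, cand$gene_id)
  expect_equal(cls[["g1"]], "direct")
  expect_equal(cls[["g2"]], "indirect")
  expect_equal(cls[["g3"]], "unchanged")   # 0.81 > 0.8 despite 2 sites
  expect_equal(cls[["g4"]], "unchanged")
  expect_equal(cls[["g5"]], "indirect")

  counts <- attr(cand, "class_counts")
  expect_equal(unname(counts["n_quantified"]), 5L)
  expect_equal(unname(counts["n_downregulated"]), 3L)
  expect_equal(unname(counts["n_direct"]), 1L)
  expect_equal(unname(counts["n_indirect"]), 2L)
})

test_that("an IRS-1-like control (ratio 0.773, with site) is declared direct", {
  rec <- data.frame(gene_id = "Irs1", ratio_hm_norm = 0.773, intensity = 1e6)
  cand <- screen_targets(rec, fake_sites(c(Irs1 = 1L)),
                         screen_config(cutoff = 0.8))
  expect_equal(cand$classification, "direct")
})

test_that("missing ratios and missing UTRs are flagged, not dropped", {
  rec <- data.frame(gene_id = c("a", "b"),
                    ratio_hm_norm = c(NA, 0.5), intensity = c(1, 2))
  cand <- screen_targets(rec, fake_sites(c(b = 1L)),
                         screen_config(), utr_genes = "b")
  expect_equal(nrow(cand), 2L)
  expect_true(cand$missing_ratio[cand$gene_id == "a"])
  expect_equal(cand$classification[cand$gene_id == "a"], "unchanged")
  expect_true(cand$no_utr[cand$gene_id == "a"])
  expect_equal(cand$max_match_len[cand$gene_id == "a"], 0L)
})

test_that("direct set grows with the cut-off and shrinks with min_match", {
  set.seed(123)
  n <- 200
  rec <- data.frame(gene_id = sprintf("g%03d", 1:n),
                    ratio_hm_norm = rlnorm(n, -0.1, 0.25),
                    intensity = rlnorm(n, 10, 1))
  counts <- setNames(sample(0:2, n, TRUE), rec$gene_id)
  sites <- fake_sites(counts)
  directs <- function(cfg) {
    cand <- screen_targets(rec, sites, cfg)
    cand$gene_id[cand$classification == "direct"]
  }
  d6 <- directs(screen_config(cutoff = 0.6))
  d8 <- directs(screen_config(cutoff = 0.8))
  d10 <- directs(screen_config(cutoff = 1.0))
  expect_true(all(d6 %in% d8))
  expect_true(all(d8 %in% d10))

  # partial-only sites: min_match 7 direct set is a subset of min_match 6
  sites6 <- sites
  half <- sites6$gene_id %in% rec$gene_id[1:100]
  sites6$length[half] <- 6L
  sites6$site_class[half] <- "partial6_5p"
  dm6 <- screen_targets(rec, sites6, screen_config(min_match = 6L))
  dm7 <- screen_targets(rec, sites6, screen_config(min_match = 7L))
  g6 <- dm6$gene_id[dm6$classification == "direct"]
  g7 <- dm7$gene_id[dm7$classification == "direct"]
  expect_true(all(g7 %in% g6))
  expect_gt(length(g6), length(g7))

  # the three classes always partition the records
  for (cand in list(dm6, dm7)) {
    cc <- attr(cand, "class_counts")
    expect_equal(unname(cc["n_direct"] + cc["n_indirect"]),
                 unname(cc["n_downregulated"]))
    expect_equal(unname(cc["n_direct"] + cc["n_indirect"] +
                        cc["n_unchanged"]), n)
  }
})

test_that("ranking orders by intensity, then deeper downregulation, then name", {
  d <- data.frame(gene_id = c("a", "b", "c"),
                  ratio_hm_norm = c(0.5, 0.5, 0.5),
                  intensity = c(10, 100, 50),
                  classification = "direct")
  expect_equal(rank_candidates(d)$rank, c(3L, 1L, 2L))

  tie <- data.frame(gene_id = c("x", "y"),
                    ratio_hm_norm = c(0.7, 0.6),
                    intensity = c(5, 5), classification = "direct")
  r <- rank_candidates(tie)
  expect_equal(r$rank[r$gene_id == "y"], 1L)   # more downregulated wins

  expect_equal(nrow(rank_candidates(d[0, ])), 0L)
  expect_error(rank_candidates(transform(d, classification = "bogus")),
               "classification")

  # ranks are a permutation of 1..n_direct
  toy <- toy_screen_inputs()
  cand <- screen_targets(toy$records, fake_sites(c(g1 = 1L, g3 = 1L, g5 = 1L)),
                         screen_config())
  rk <- sort(cand$rank[cand$classification == "direct"])
  expect_equal(rk, seq_along(rk))
})

test_that("screen report counts reconcile and round-trip through JSON", {
  toy <- toy_screen_inputs()
  cand <- screen_targets(toy$records, fake_sites(toy$complete_sites),
                         screen_config(cutoff = 0.8))
  rep <- screen_report(cand)
  expect_equal(rep$n_quantified, 5L)
  expect_equal(rep$n_downregulated, 3L)
  expect_equal(rep$n_direct, 1L)
  expect_equal(rep$n_indirect, 2L)
  expect_equal(rep$cutoff, 0.8)

  path <- tempfile(fileext = ".json")
  write_screen_report(rep, path)
  back <- read_screen_report(path)
  expect_equal(back[setdiff(names(back), "control_gene")],
               rep[setdiff(names(rep), "control_gene")],
               ignore_attr = TRUE)

  # empty screen: all counts zero
  e <- screen_targets(data.frame(gene_id = character(),
                                 ratio_hm_norm = numeric(),
                                 intensity = numeric()),
                      fake_sites(integer(0)), screen_config())
  er <- screen_report(e)
  expect_equal(er$n_quantified, 0L)
  expect_equal(er$n_direct, 0L)
})
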