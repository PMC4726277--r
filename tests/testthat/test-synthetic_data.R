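small_cfg <- function(...) {
  simulation_config(n_transcripts = 60, n_venom = 6, seed = 7, ...)
}

test_that("simulation_config validates fields by name", {
  expect_error(simulation_config(n_transcripts = 0), "n_transcripts")
  expect_error(simulation_config(n_transcripts = 10, n_venom = 11),
               "n_venom")
  expect_error(simulation_config(dispersion = -1), "dispersion")
  expect_error(simulation_config(sp_fraction_background = 1.5),
               "sp_fraction_background")
  expect_error(simulation_config(n_venom = 10,
                                 venn_design = c(1, 1, 1, 1)),
               "venn_design")
  # default design partitions n_venom
  expect_equal(sum(simulation_config(n_venom = 33)$venn_design), 33L)
})

test_that("generate_transcriptome is deterministic and seed-sensitive", {
  cfg <- simulation_config(n_transcripts = 200, n_venom = 20, seed = 7)
  a <- generate_transcriptome(cfg)
  b <- generate_transcriptome(cfg)
  expect_identical(a, b)
  expect_equal(length(a$transcripts), 200L)
  c <- generate_transcriptome(simulation_config(n_transcripts = 200,
                                                n_venom = 20, seed = 8))
  expect_false(identical(digest_strings(a$transcripts),
                         digest_strings(c$transcripts)))
})

test_that("written inputs are byte-identical across reruns", {
  cfg <- small_cfg()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_inputs(cfg, d1)
  simulate_inputs(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
})

test_that("ground truth invariants hold and n_venom = 0 degenerates", {
  tg <- generate_transcriptome(small_cfg())
  truth <- tg$truth
  expect_true(all(truth$venom_ids %in% truth$sp_ids))
  expect_true(all(truth$venom_ids %in% truth$psm_supported_ids))
  expect_setequal(names(truth$venn_labels), truth$venom_ids)
  # planted proteins are what six-frame translation recovers
  for (id in truth$venom_ids) {
    rec <- transcript_record(id, tg$transcripts[[id]])
    expect_identical(predict_orf(rec), truth$proteins[[id]])
  }
  tg0 <- generate_transcriptome(simulation_config(n_transcripts = 30,
                                                  n_venom = 0, seed = 1))
  expect_length(tg0$truth$venom_ids, 0L)
})

test_that("counts are non-negative integers from the planted model", {
  cfg <- small_cfg()
  tg <- generate_transcriptome(cfg)
  counts <- generate_counts(cfg, tg$truth)
  expect_true(all(counts$count_vg >= 0 & counts$count_carcass >= 0))
  expect_true(all(counts$count_vg == round(counts$count_vg)))
  expect_equal(attr(counts, "libsize_vg"), sum(counts$count_vg))
})

test_that("dispersion 0 gives rounded expectations at the configured fold", {
  cfg <- simulation_config(n_transcripts = 300, n_venom = 30,
                           dispersion = 0, seed = 11)
  tg <- generate_transcriptome(cfg)
  counts <- generate_counts(cfg, tg$truth)
  rerun <- generate_counts(cfg, tg$truth)
  expect_identical(counts, rerun)
  is_venom <- counts$id %in% tg$truth$venom_ids
  ratio <- counts$count_vg[is_venom] / counts$count_carcass[is_venom]
  # rounding perturbs each gene slightly; the mean ratio is the fold change
  expect_equal(mean(ratio), cfg$fold_change_venom *
                 cfg$library_size_vg / cfg$library_size_carcass,
               tolerance = 0.02)
  bg_ratio <- counts$count_vg[!is_venom] / counts$count_carcass[!is_venom]
  expect_equal(stats::median(bg_ratio, na.rm = TRUE),
               cfg$library_size_vg / cfg$library_size_carcass,
               tolerance = 0.02)
})

test_that("a unit fold change is statistically invisible to the DE test", {
  cfg <- simulation_config(n_transcripts = 250, n_venom = 125,
                           fold_change_venom = 1, dispersion = 1e-6,
                           seed = 12)
  tg <- generate_transcriptome(cfg)
  counts <- generate_counts(cfg, tg$truth)
  expr <- expression_table(counts)
  is_venom <- expr$id %in% tg$truth$venom_ids
  # rejection rate at alpha = 0.05 is near alpha for both groups
  expect_lte(abs(mean(expr$p_value[is_venom] < 0.05) -
                   mean(expr$p_value[!is_venom] < 0.05)), 0.08)
  expect_lte(mean(expr$p_value < 0.01), 0.05)
})

test_that("PSM table construction guarantees hold", {
  cfg <- simulation_config(n_transcripts = 120, n_venom = 20,
                           psm_depth = 3, seed = 13)
  tg <- generate_transcriptome(cfg)
  psms <- generate_psm_table(cfg, tg$truth)
  passing <- filter_psms(psms)
  expect_gte(nrow(passing), 20L)
  # every passing peptide is a substring of its source venom protein
  venom_prots <- tg$truth$proteins[tg$truth$psm_supported_ids]
  expect_true(all(vapply(passing$peptide, function(p) {
    any(grepl(p, venom_prots, fixed = TRUE))
  }, logical(1))))
  # per-protein floor: at least one passing tryptic peptide each
  ev <- map_peptides(passing$peptide, tg$truth$proteins)
  expect_true(all(tg$truth$psm_supported_ids %in% ev$transcript_id))
  # decoys pinned to delta_cn 0.05 never survive
  decoys <- psms[psms$delta_cn < 0.1, ]
  decoys$delta_cn <- 0.05
  expect_equal(nrow(filter_psms(decoys)), 0L)
})

test_that("homology tables realize the planted Venn design", {
  cfg <- simulation_config(n_transcripts = 40, n_venom = 10,
                           venn_design = c(2, 3, 1, 4), seed = 14)
  tg <- generate_transcriptome(cfg)
  hom <- generate_homology_tables(cfg, tg$truth)
  paired <- paired_scores(names(tg$truth$venn_labels),
                          hom$pp_vs_nv, hom$pp_vs_oep)
  vp <- venn_partition(paired)
  expect_equal(unname(vp$counts), c(2L, 3L, 1L, 4L))
  got <- vp$assignments$label
  names(got) <- vp$assignments$protein_id
  expect_identical(got[names(tg$truth$venn_labels)],
                   tg$truth$venn_labels)
  # all-unique design: no row passes the cutoffs
  cfg2 <- simulation_config(n_transcripts = 40, n_venom = 10,
                            venn_design = c(10, 0, 0, 0), seed = 15)
  tg2 <- generate_transcriptome(cfg2)
  hom2 <- generate_homology_tables(cfg2, tg2$truth)
  for (tab in hom2[c("pp_vs_nv", "pp_vs_oep")]) {
    if (nrow(tab) > 0) {
      expect_false(any(homology_call(tab$evalue, tab$bitscore)))
    }
  }
})

test_that("outfmt6 files round-trip through the reader", {
  cfg <- small_cfg()
  d <- withr::local_tempdir()
  x <- simulate_inputs(cfg, d)
  back <- read_outfmt6(file.path(d, "pp_vs_nv.tsv"))
  expect_equal(names(back), c("qseqid", "sseqid", "pident", "length",
                              "mismatch", "gapopen", "qstart", "qend",
                              "sstart", "send", "evalue", "bitscore"))
  expect_equal(nrow(back), nrow(x$homology$pp_vs_nv))
  expect_equal(back$bitscore, x$homology$pp_vs_nv$bitscore)
})
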