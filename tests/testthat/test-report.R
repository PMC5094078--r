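mk_call <- function(id, gg, family, completeness, membrane = FALSE, wap = FALSE,
                    kind = if (family %in% c("CniFL", "MASP", "SRCR", "CTLD"))
                      "accessory" else "candidate") {
  list(transcript_id = id, gene_group_id = gg, family = family, kind = kind,
       completeness = completeness, note = "", n_lrr = 0L, n_ank = 0L, n_ig = 0L,
       death_fold_type = "none", n_tmd = as.integer(membrane),
       membrane_bound = membrane, tmd_n_terminal_clustered = membrane,
       has_wap = wap, evidence = "")
}
calls_df <- function(...) cnidimmune:::family_calls_df(list(...))

test_that("gene counts follow the complete-only vs total table semantics", {
  calls <- calls_df(
    mk_call("g1_i1", "g1", "NLR", "complete"), mk_call("g1_i2", "g1", "NLR", "partial"),
    mk_call("g2_i1", "g2", "NLR", "complete"),
    mk_call("g3_i1", "g3", "NLR", "partial"), mk_call("g4_i1", "g4", "NLR", "partial"),
    mk_call("g5_i1", "g5", "NLR", "partial"))
  rep <- build_counts(calls, species_label = "sp")
  nlr <- rep$families[rep$families$family == "NLR", ]
  expect_equal(nlr$n_complete_genes, 2L)
  expect_equal(nlr$n_total_genes, 5L)
  expect_equal(nlr$n_partial, 3L)
})

test_that("one gene with three complete isoforms counts once as a gene, thrice as isoforms", {
  calls <- calls_df(mk_call("g1_i1", "g1", "TLR", "complete"),
                    mk_call("g1_i2", "g1", "TLR", "complete"),
                    mk_call("g1_i3", "g1", "TLR", "complete"))
  rep <- build_counts(calls, species_label = "sp")
  tlr <- rep$families[rep$families$family == "TLR", ]
  expect_equal(tlr$n_complete_genes, 1L)
  expect_equal(tlr$n_isoforms, 3L)
})

test_that("a conservative species row reproduces the published row shape", {
  # 1 TLR, 1 MyD88, 1 NF-kB, 2 NLR, 3 IL-1R-like complete genes
  calls <- calls_df(
    mk_call("t1_i1", "t1", "TLR", "complete"),
    mk_call("m1_i1", "m1", "MyD88", "complete"),
    mk_call("n1_i1", "n1", "NFKB", "complete"),
    mk_call("l1_i1", "l1", "NLR", "complete"), mk_call("l2_i1", "l2", "NLR", "complete"),
    mk_call("i1_i1", "i1", "IL1R_like", "complete"),
    mk_call("i2_i1", "i2", "IL1R_like", "complete"),
    mk_call("i3_i1", "i3", "IL1R_like", "complete"))
  rep <- build_counts(calls, species_label = "A_tenebrosa_1")
  f <- rep$families
  got <- f$n_complete_genes[match(c("TLR", "MyD88", "NFKB", "NLR", "IL1R_like"),
                                  f$family)]
  expect_equal(got, c(1L, 1L, 1L, 2L, 3L))
})

test_that("calls without a gene group are rejected", {
  calls <- calls_df(mk_call("x_i1", "", "TLR", "complete"))
  expect_error(build_counts(calls), "gene group")
})

test_that("species merging zero-fills, keeps order, rejects duplicates", {
  r1 <- build_counts(calls_df(mk_call("a_i1", "a", "TLR", "complete")), species_label = "s1")
  r2 <- build_counts(calls_df(mk_call("b_i1", "b", "NLR", "partial")), species_label = "s2")
  m <- merge_species(list(r1, r2))
  expect_equal(nrow(m), 2L)
  expect_equal(m$species, c("s1", "s2"))
  expect_equal(m$CniFL_total, c(0L, 0L))
  expect_equal(m$NLR_total, c(0L, 1L))
  expect_equal(m$NLR_complete, c(0L, 0L))
  expect_error(merge_species(list(r1, r1)), "duplicate")

  reps <- lapply(1:13, function(i)
    build_counts(calls_df(mk_call("a_i1", "a", "TLR", "complete")),
                 species_label = paste0("sp", i)))
  m13 <- merge_species(reps)
  expect_equal(nrow(m13), 13L)
  expect_equal(sum(m13$TLR_complete), 13L)
})

test_that("column sums over a noise-free fixture equal planted gene counts", {
  cfg <- fixture_config(fraction_partial = 0, fraction_missing_homology = 0)
  fx <- generate_fixture(cfg, seed = 12)
  prof <- profile_immunome(fx$catalog, masp_reference_ids = fx$masp_reference_ids)
  f <- prof$counts$families
  for (fam in setdiff(names(cfg$genes_per_family), "NFKB")) {
    expect_equal(f$n_total_genes[f$family == fam],
                 unname(cfg$genes_per_family[fam]), label = fam)
  }
  expect_equal(f$n_total_genes[f$family == "NFKB"],
               unname(cfg$genes_per_family["NFKB"] + cfg$decoys["RHD_only"]))
  # RHD-only decoys add partial-only NFKB genes on top of the planted ones
  expect_equal(f$n_total_genes[f$family == "NFKB"] - f$n_complete_genes[f$family == "NFKB"],
               unname(cfg$decoys["RHD_only"]))
})

test_that("deleting all partial calls leaves the complete count invariant", {
  fx <- generate_fixture(fixture_config(), seed = 14)
  prof <- profile_immunome(fx$catalog, masp_reference_ids = fx$masp_reference_ids)
  calls <- prof$family_calls
  full <- build_counts(calls, prof$novelty_calls, "sp")
  trimmed <- build_counts(calls[calls$completeness == "complete", ],
                          prof$novelty_calls, "sp")
  expect_equal(trimmed$families$n_complete_genes, full$families$n_complete_genes)
  expect_equal(trimmed$families$n_total_genes, trimmed$families$n_complete_genes)
  expect_true(all(full$families$n_complete_genes <= full$families$n_total_genes))
})
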