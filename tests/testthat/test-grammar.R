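rules <- family_rules()

test_that("candidate rules recover the canonical receptor/adaptor architectures", {
  tlr <- classify_candidate(fix_ann(c(rep("LRR", 12), "TIR"), tmds = list(c(300, 321))), rules)
  expect_equal(tlr$family, "TLR")
  expect_equal(tlr$completeness, "complete")

  expect_null(classify_candidate(fix_ann(character(0)), rules))

  nlr <- classify_candidate(fix_ann(c("CARD", "NACHT", rep("LRR", 5))), rules)
  expect_equal(nlr$family, "NLR")
  expect_equal(nlr$death_fold_type, "CARD")

  il1r <- classify_candidate(fix_ann(c("Ig", "Ig", "TIR")), rules)
  expect_equal(il1r$family, "IL1R_like")

  myd <- classify_candidate(fix_ann(c("DD", "TIR")), rules)
  expect_equal(myd$family, "MyD88")

  nfkb <- classify_candidate(fix_ann(c("RHD", "Ank", "Ank", "Ank")), rules)
  expect_equal(nfkb$family, "NFKB")
  expect_equal(nfkb$completeness, "complete")
})

test_that("a Rel homology domain without ankyrin repeats is only ever a partial call", {
  call <- classify_candidate(fix_ann("RHD"), rules)
  expect_equal(call$family, "NFKB")
  expect_equal(call$completeness, "partial")
  expect_equal(call$note, "RHD-only")
  # even a full-length, annotated ORF cannot rescue it
  call2 <- classify_candidate(fix_ann("RHD", has_start = TRUE, has_stop = TRUE,
                                      n_homology = 2), rules)
  expect_equal(call2$completeness, "partial")
})

test_that("TIR transcripts with novelty-indicative extras are routed away from candidates", {
  expect_null(classify_candidate(fix_ann(c("Pkinase", "DD", "TIR_2")), rules))
  expect_null(classify_candidate(fix_ann(c("LRR", "Miro", "Ras", "TIR_2")), rules))
  # the same architecture minus the extras is MyD88
  expect_equal(classify_candidate(fix_ann(c("DD", "TIR_2")), rules)$family, "MyD88")
})

test_that("completeness requires start, stop, and a peptide-level homology hit", {
  base <- c("DD", "TIR")
  expect_equal(classify_candidate(fix_ann(base), rules)$completeness, "complete")
  expect_equal(classify_candidate(fix_ann(base, has_stop = FALSE), rules)$completeness,
               "partial")
  expect_equal(classify_candidate(fix_ann(base, has_start = FALSE), rules)$completeness,
               "partial")
  expect_equal(classify_candidate(fix_ann(base, n_homology = 0), rules)$completeness,
               "partial")
  # a nucleotide-level hit alone is not enough
  nuc <- fix_ann(base, homology = fix_homology(n = 1, query_level = "nucleotide"))
  expect_equal(classify_candidate(nuc, rules)$completeness, "partial")
})

test_that("TMD subtyping flags membrane binding and N-terminal clustering", {
  nlr <- classify_candidate(fix_ann(c("NACHT", rep("LRR", 4))), rules)
  up <- detect_tmd_subtype(nlr, fix_tmds(list(c(40, 60), c(70, 92), c(100, 122),
                                              c(150, 172))),
                           peptide_length = 1000, n_terminal_fraction = 0.30)
  expect_true(up$membrane_bound)
  expect_true(up$tmd_n_terminal_clustered)
  expect_equal(up$n_tmd, 4L)

  none <- detect_tmd_subtype(nlr, fix_tmds(NULL), peptide_length = 1000)
  expect_false(none$membrane_bound)
  expect_false(none$tmd_n_terminal_clustered)

  cterm <- detect_tmd_subtype(nlr, fix_tmds(list(c(790, 810))), peptide_length = 1000)
  expect_true(cterm$membrane_bound)
  expect_false(cterm$tmd_n_terminal_clustered)   # midpoint at 80% of length
})

test_that("accessory lectin families are called from their domain sets", {
  cni <- classify_other_immune(fix_ann(c("Collagen", "Ig", "Ig", "Ig", "Fibrinogen"),
                                       tmds = list(c(5, 26))), rules = rules)
  expect_equal(length(cni), 1L)
  expect_equal(cni[[1]]$family, "CniFL")
  expect_equal(cni[[1]]$n_ig, 3L)
  expect_false(cni[[1]]$has_wap)

  wap <- classify_other_immune(fix_ann(c("Collagen", "Ig", "Ig", "Ig", "WAP",
                                         "Fibrinogen")), rules = rules)
  expect_true(wap[[1]]$has_wap)

  expect_equal(length(classify_other_immune(fix_ann(c("Collagen", "Fibrinogen")),
                                            rules = rules)), 0L)

  srcr <- classify_other_immune(fix_ann("SRCR"), rules = rules)
  expect_equal(srcr[[1]]$family, "SRCR")

  masp_dom <- c("CUB", "EGF_CA", "CUB", "Sushi", "Sushi", "Trypsin")
  ref <- "sp|MASPR1|MASP1_Nematostella_vectensis"
  no_ref <- classify_other_immune(fix_ann(masp_dom), rules = rules)
  expect_equal(length(no_ref), 0L)   # needs homology to the reference MASP
  with_ref <- classify_other_immune(fix_ann(masp_dom, homology = fix_homology(subject = ref)),
                                    masp_reference_ids = ref, rules = rules)
  expect_equal(with_ref[[1]]$family, "MASP")
})

test_that("complement presence is called from homology name patterns", {
  h <- fix_homology(subject = "sp|P01024|Complement_C3_Homo_sapiens")
  flags <- presence_flags(h)
  expect_equal(unname(flags["C3"]), "present")
  expect_equal(unname(flags["C6"]), "absent")
  empty <- presence_flags(fix_homology(n = 0))
  expect_true(all(empty == "absent"))
})

test_that("topology validation warns on unexpected membrane architecture only", {
  tlr <- classify_candidate(fix_ann(c("LRR", "TIR")), rules)
  tlr <- detect_tmd_subtype(tlr, fix_tmds(NULL), 600)
  myd <- classify_candidate(fix_ann(c("DD", "TIR"), id = "tx2"), rules)
  myd <- detect_tmd_subtype(myd, fix_tmds(NULL, id = "tx2"), 600)
  nfkb <- classify_candidate(fix_ann(c("RHD", "Ank"), id = "tx3"), rules)
  nfkb <- detect_tmd_subtype(nfkb, fix_tmds(list(c(10, 30)), id = "tx3"), 600)
  calls <- cnidimmune:::family_calls_df(list(tlr, myd, nfkb))
  w <- validate_topology(calls)
  expect_length(w, 2L)
  expect_match(w[1], "TLR without a TMD")
  expect_match(w[2], "NFKB with 1 TMD")
})

test_that("domain subsequences are clipped to envelope coordinates in order", {
  pep <- paste(sample(c("A", "G", "L", "S"), 400, replace = TRUE), collapse = "")
  ann <- fix_ann(character(0), peptide = pep)
  ann$domains <- data.frame(transcript_id = "tx1", domain_name = "NACHT",
                            family_accession = "PF05729", clan_accession = "CL0023",
                            aa_start = c(320L, 120L), aa_end = c(380L, 310L),
                            e_value = 1e-10, stringsAsFactors = FALSE)
  ss <- extract_domain_subsequence(ann, "NACHT")
  expect_equal(nrow(ss), 2L)
  expect_equal(ss$aa_start, c(120L, 320L))     # coordinate order
  expect_equal(nchar(ss$subsequence[1]), 191L)
  expect_equal(ss$subsequence[1], substr(pep, 120, 310))
  expect_equal(nrow(extract_domain_subsequence(ann, "PF00554")), 0L)
})

test_that("every call's evidence contains its rule's required domains (grammar soundness)", {
  fx <- generate_fixture(fixture_config(), seed = 21)
  calls <- classify_catalog(fx$catalog, rules,
                            masp_reference_ids = fx$masp_reference_ids)
  for (i in seq_len(nrow(calls))) {
    if (calls$note[i] == "RHD-only") next
    ann <- transcript_annotation(fx$catalog, calls$transcript_id[i])
    rule <- rules$families[[calls$family[i]]]
    for (p in rule$required)
      expect_true(cnidimmune:::predicate_satisfied(ann$domains, p),
                  label = sprintf("%s/%s", calls$transcript_id[i], calls$family[i]))
  }
})

test_that("classification matches an independent brute-force matcher on small catalogs", {
  cfg <- fixture_config(genes_per_family = c(TLR = 1L, NLR = 1L, MyD88 = 1L,
                                             NFKB = 1L, IL1R_like = 1L),
                        n_membrane_nlr = 0L, isoform_range = c(1L, 1L),
                        decoys = c(RHD_only = 1L, TIR_only = 1L, NG1 = 1L,
                                   NG2 = 1L, NG3 = 1L, unmatched_novel = 1L))
  for (seed in c(3, 17, 29)) {
    fx <- generate_fixture(cfg, seed = seed)
    expect_lte(nrow(fx$catalog$orfs), 20L)
    for (id in fx$catalog$orfs$transcript_id) {
      ann <- transcript_annotation(fx$catalog, id)
      got <- classify_candidate(ann, rules)
      want <- oracle_classify(ann$domains)
      if (is.na(want)) expect_null(got, label = id)
      else expect_equal(got$family, want, label = id)
    }
  }
})

test_that("classification is invariant under catalog row permutation", {
  fx <- generate_fixture(fixture_config(), seed = 9)
  cat1 <- fx$catalog
  set.seed(2)
  cat2 <- cat1
  cat2$orfs <- cat2$orfs[sample(nrow(cat2$orfs)), ]
  cat2$domains <- cat2$domains[sample(nrow(cat2$domains)), ]
  cat2$homology <- cat2$homology[sample(nrow(cat2$homology)), ]
  a <- classify_catalog(cat1, rules, fx$masp_reference_ids)
  b <- classify_catalog(cat2, rules, fx$masp_reference_ids)
  key <- function(d) {
    d <- d[order(d$transcript_id, d$family), ]
    rownames(d) <- NULL
    d[names(d) != "evidence"]   # evidence string order follows hit order
  }
  expect_equal(key(a), key(b))
})

test_that("removing stop codons never increases the complete count (conservativeness)", {
  fx <- generate_fixture(fixture_config(fraction_partial = 0), seed = 13)
  calls <- classify_catalog(fx$catalog, rules, fx$masp_reference_ids)
  n_complete <- sum(calls$completeness == "complete")
  cat2 <- fx$catalog
  cat2$orfs$has_stop_codon <- FALSE
  calls2 <- classify_catalog(cat2, rules, fx$masp_reference_ids)
  expect_equal(nrow(calls2), nrow(calls))
  expect_equal(sum(calls2$completeness == "complete"), 0L)
  expect_lte(sum(calls2$completeness == "complete"), n_complete)
})
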