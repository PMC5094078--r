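test_that("stop stripping removes terminal stops and rejects frame problems", {
  aln <- strip_stops_and_validate(c(a = "ATGAAATAA", b = "ATGAAGTAA"))
  expect_equal(aln$seqs, c("ATGAAA", "ATGAAG"))
  expect_equal(aln$n_codons, 2L)
  expect_error(strip_stops_and_validate(c(a = "ATGTAAAAA")), "internal stop")
  expect_error(strip_stops_and_validate(c(a = "ATGAA")), "whole number of codons")
  expect_error(strip_stops_and_validate(c(a = "ATGAAATAA", b = "ATGTAA")),
               "codon count")
})

test_that("identical sequences give zero differences and zero rates", {
  aln <- strip_stops_and_validate(c(a = "ATGAAACCCGGG", b = "ATGAAACCCGGG"))
  p <- pairwise_dnds(aln)
  expect_equal(p$Nd, 0); expect_equal(p$Sd, 0)
  expect_equal(p$dN, 0); expect_equal(p$dS, 0)
})

test_that("single-codon synonymous and nonsynonymous pairs behave as expected", {
  syn <- pairwise_dnds(strip_stops_and_validate(c(a = "TTT", b = "TTC")))
  expect_equal(syn$Nd, 0); expect_equal(syn$Sd, 1)
  expect_equal(syn$dN, 0)
  # one synonymous difference on a single codon saturates the correction
  # (pS = 1 / (1/3) > 3/4); with more synonymous sites dS is positive
  expect_true(syn$saturated)
  long <- strip_stops_and_validate(c(a = paste0(strrep("GGA", 9), "TTT"),
                                     b = paste0(strrep("GGA", 9), "TTC")))
  psyn <- pairwise_dnds(long)
  expect_equal(psyn$Nd, 0); expect_equal(psyn$Sd, 1)
  expect_equal(psyn$dN, 0); expect_gt(psyn$dS, 0)

  non <- pairwise_dnds(strip_stops_and_validate(c(a = "ATGAAA", b = "ATGAGA")))
  expect_equal(non$Sd, 0); expect_equal(non$Nd, 1)
  expect_equal(non$dS, 0); expect_gt(non$dN, 0)
  expect_equal(non$omega, Inf)
})

test_that("site counts match brute-force mutant enumeration (TTT: S=1/3, N=8/3)", {
  code <- Biostrings::getGeneticCode("1")
  tt <- cnidimmune:::codon_sites("TTT", code)
  expect_equal(tt[["S"]], 1 / 3, tolerance = 1e-12)
  expect_equal(tt[["N"]], 8 / 3, tolerance = 1e-12)
  for (codon in c("ATG", "TGG", "CTC", "AGA", "GGG", "TAT")) {
    got <- cnidimmune:::codon_sites(codon, code)
    want <- oracle_sites(codon)
    expect_equal(got[["S"]], want[["S"]], tolerance = 1e-12, label = codon)
    expect_equal(got[["N"]] + got[["S"]], 3, tolerance = 1e-12, label = codon)
  }
})

test_that("pathway averaging matches the brute-force oracle on multi-difference codons", {
  code <- Biostrings::getGeneticCode("1")
  pairs <- list(c("TTT", "GAT"), c("ATG", "CGC"), c("AAA", "GGG"),
                c("TGT", "AGG"), c("CCT", "CAG"), c("TCA", "ACT"))
  for (p in pairs) {
    got <- cnidimmune:::codon_diffs(p[1], p[2], code)
    want <- oracle_diffs(p[1], p[2])
    expect_equal(got[["Sd"]], want[["Sd"]], tolerance = 1e-9,
                 label = paste(p, collapse = "/"))
    expect_equal(got[["Nd"]], want[["Nd"]], tolerance = 1e-9,
                 label = paste(p, collapse = "/"))
    expect_equal(got[["Sd"]] + got[["Nd"]], sum(want), tolerance = 1e-9)
  }
})

test_that("pairwise estimates are symmetric and conserve sites", {
  set.seed(42)
  gp <- generate_codon_pair(0.5, 120, seed = 5)
  a <- strip_stops_and_validate(gp$seqs)
  b <- strip_stops_and_validate(rev(gp$seqs))
  pa <- pairwise_dnds(a); pb <- pairwise_dnds(b)
  expect_equal(pa$dN, pb$dN); expect_equal(pa$dS, pb$dS)
  expect_equal(pa$N + pa$S, 3 * pa$n_codons, tolerance = 1e-9)
  py <- pairwise_dnds(a, method = "YN00")
  expect_equal(py$N + py$S, 3 * py$n_codons, tolerance = 1e-9)
})

test_that("corrected distances converge to raw proportions at low divergence", {
  gp <- generate_codon_pair(1, 400, n_events = 8, seed = 3)
  p <- pairwise_dnds(strip_stops_and_validate(gp$seqs))
  if (p$pS > 0) expect_equal(p$dS / p$pS, 1, tolerance = 0.05)
  if (p$pN > 0) expect_equal(p$dN / p$pN, 1, tolerance = 0.05)
})

test_that("gene averaging is the ratio of mean rates, not the mean ratio", {
  pairs <- data.frame(id_a = c("a", "a"), id_b = c("b", "c"), n_codons = 100L,
                      N = 220, S = 80, Nd = 10, Sd = 20, pN = NA, pS = NA,
                      dN = c(0.1, 0.3), dS = c(0.5, 1.5),
                      se_dN = c(0.01, 0.02), se_dS = c(0.05, 0.1),
                      omega = c(0.2, 0.2), saturated = FALSE)
  class(pairs) <- c("pairwise_dnds", "data.frame")
  g <- gene_average(pairs, "toy")
  expect_equal(g$mean_dN, 0.2)
  expect_equal(g$mean_dS, 1.0)
  expect_equal(g$omega, 0.2)
  expect_equal(g$regime, "purifying")
  expect_equal(g$mean_se_dN, 0.015)

  one <- gene_average(pairs[1, ], "single")
  expect_equal(one$mean_dN, 0.1)
  expect_equal(one$omega, 0.2)

  pairs$saturated <- c(FALSE, TRUE)
  expect_warning(g2 <- gene_average(pairs, "sat"), "saturated")
  expect_equal(g2$n_pairs, 1L)
})

test_that("a planted 4-sequence alignment averages to the oracle's per-pair values", {
  first <- generate_codon_pair(0.25, 150, seed = 81)
  anc <- first$seqs[["ancestor"]]
  seqs <- c(s1 = anc, s2 = first$seqs[["derived"]],
            s3 = generate_codon_pair(0.25, 150, seed = 82,
                                     ancestor = anc)$seqs[["derived"]],
            s4 = generate_codon_pair(0.25, 150, seed = 83,
                                     ancestor = anc)$seqs[["derived"]])
  aln <- strip_stops_and_validate(seqs)
  pw <- pairwise_dnds(aln)
  expect_equal(nrow(pw), 6L)
  g <- gene_average(pw, "plant")
  # independent recomputation: oracle per pair, then hand averaging
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  odn <- ods <- numeric(0)
  ids <- aln$ids
  for (i in 1:3) for (j in (i + 1):4) {
    o <- oracle_ng86(aln$seqs[[i]], aln$seqs[[j]])
    odn <- c(odn, jc(o$Nd / o$N)); ods <- c(ods, jc(o$Sd / o$S))
  }
  expect_equal(g$mean_dN, mean(odn), tolerance = 1e-9)
  expect_equal(g$mean_dS, mean(ods), tolerance = 1e-9)
  expect_equal(g$omega, mean(odn) / mean(ods), tolerance = 1e-9)
})

test_that("selection regimes split at omega = 1 with a neutrality band", {
  expect_equal(classify_regime(0.23), "purifying")
  expect_equal(classify_regime(1.0), "neutral")
  expect_equal(classify_regime(0.96), "neutral")
  expect_equal(classify_regime(1.4), "positive")
  expect_error(classify_regime(Inf))
})

test_that("codon alignments round-trip through FASTA and sequential PHYLIP", {
  gp <- generate_codon_pair(0.5, 60, seed = 10)
  fa <- withr::local_tempfile(lines = c(">ancestor", gp$seqs[["ancestor"]],
                                        ">derived", gp$seqs[["derived"]]))
  a1 <- read_codon_alignment(fa)
  expect_equal(a1$ids, c("ancestor", "derived"))
  ph <- withr::local_tempfile(lines = c(" 2 180",
                                        paste("ancestor", gp$seqs[["ancestor"]]),
                                        paste("derived", gp$seqs[["derived"]])))
  a2 <- read_codon_alignment(ph)
  expect_equal(a1$seqs, a2$seqs)
})
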