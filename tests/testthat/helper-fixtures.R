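# Compact builders for single-transcript annotations used by the grammar
# unit tests.  Accessions/clans are stated directly here so the fixtures do
# not depend on the generator under test.

FIX_DOMAINS <- list(
  TIR = c("TIR", "PF01582", "CL0173", 135),
  TIR_2 = c("TIR_2", "PF13676", "CL0173", 120),
  LRR = c("LRR_8", "PF13855", "CL0022", 24),
  Ig = c("I-set", "PF07679", "CL0011", 70),
  RHD = c("RHD_DNA_bind", "PF00554", "", 170),
  Ank = c("Ank", "PF00023", "CL0465", 33),
  NACHT = c("NACHT", "PF05729", "CL0023", 160),
  CARD = c("CARD", "PF00619", "CL0041", 90),
  DD = c("Death", "PF00531", "CL0041", 85),
  Collagen = c("Collagen", "PF01391", "", 60),
  Fibrinogen = c("Fibrinogen_C", "PF00147", "", 220),
  WAP = c("WAP", "PF00095", "", 45),
  SRCR = c("SRCR", "PF00530", "", 100),
  CTLD = c("Lectin_C", "PF00059", "", 110),
  CUB = c("CUB", "PF00431", "CL0164", 110),
  EGF_CA = c("EGF_CA", "PF07645", "", 40),
  Sushi = c("Sushi", "PF00084", "", 60),
  Trypsin = c("Trypsin", "PF00089", "CL0124", 220),
  Pkinase = c("Pkinase", "PF00069", "CL0016", 250),
  Pkinase_Tyr = c("Pkinase_Tyr", "PF07714", "CL0016", 250),
  Ras = c("Ras", "PF00071", "CL0023", 160),
  Miro = c("Miro", "PF08477", "CL0023", 170),
  COR = c("COR", "PF16095", "", 120),
  SH3 = c("SH3_1", "PF00018", "CL0010", 55),
  SAM = c("SAM_1", "PF00536", "CL0003", 65),
  BTK = c("BTK", "PF00779", "", 30),
  DUF1863 = c("DUF1863", "", "", 140)
)

# domain table from a vector of labels, laid out left to right
fix_domains <- function(labels, id = "tx1", gap = 10L) {
  pos <- 1L
  rows <- lapply(labels, function(L) {
    d <- FIX_DOMAINS[[L]]
    len <- as.integer(d[[4]])
    r <- data.frame(transcript_id = id, domain_name = d[[1]],
                    family_accession = d[[2]], clan_accession = d[[3]],
                    aa_start = pos + gap, aa_end = pos + gap + len - 1L,
                    e_value = 1e-20, stringsAsFactors = FALSE)
    pos <<- pos + gap + len
    r
  })
  do.call(rbind, rows)
}

fix_homology <- function(id = "tx1", n = 1L, species = "Mus musculus",
                         subject = "sp|P00001|HIT_Mus_musculus",
                         query_level = "peptide") {
  if (n == 0L) {
    return(data.frame(transcript_id = character(0), database_label = character(0),
                      subject_id = character(0), subject_species = character(0),
                      e_value = double(0), query_level = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(transcript_id = id, database_label = "swissprot",
             subject_id = subject, subject_species = species,
             e_value = 1e-30, query_level = query_level, stringsAsFactors = FALSE)
}

fix_tmds <- function(segs, id = "tx1") {
  if (is.null(segs)) {
    return(data.frame(transcript_id = character(0), aa_start = integer(0),
                      aa_end = integer(0), stringsAsFactors = FALSE))
  }
  data.frame(transcript_id = id, aa_start = vapply(segs, `[[`, numeric(1), 1),
             aa_end = vapply(segs, `[[`, numeric(1), 2), stringsAsFactors = FALSE)
}

# a free-standing transcript annotation (the unit classify_candidate consumes)
fix_ann <- function(labels = character(0), id = "tx1", tmds = NULL,
                    n_homology = 1L, has_start = TRUE, has_stop = TRUE,
                    peptide = NULL, homology = NULL, plen = NULL) {
  doms <- if (length(labels)) fix_domains(labels, id) else
    data.frame(transcript_id = character(0), domain_name = character(0),
               family_accession = character(0), clan_accession = character(0),
               aa_start = integer(0), aa_end = integer(0), e_value = double(0),
               stringsAsFactors = FALSE)
  plen <- plen %||% max(c(600L, doms$aa_end + 20L))
  peptide <- peptide %||% paste(rep("A", plen), collapse = "")
  list(transcript_id = id, gene_group_id = sub("_i\\d+$", "", id),
       species_label = "test",
       orf = data.frame(transcript_id = id, orf_id = paste0(id, ".p1"),
                        peptide_length = nchar(peptide), has_start_codon = has_start,
                        has_stop_codon = has_stop, peptide = peptide,
                        coding_sequence = "", stringsAsFactors = FALSE),
       domains = doms, tmds = fix_tmds(tmds, id),
       homology = homology %||% fix_homology(id, n_homology))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
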