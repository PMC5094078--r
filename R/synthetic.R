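# Domain block definitions used by the fixture generator: canonical label ->
# (reported domain name, Pfam family accession, clan accession, typical
# envelope length in residues).  "TMD" is a pseudo-block that becomes a
# transmembrane segment rather than a domain hit.
DOMAIN_BLOCKS <- list(
  TIR = list(name = "TIR", acc = "PF01582", clan = "CL0173", len = 135L),
  TIR_2 = list(name = "TIR_2", acc = "PF13676", clan = "CL0173", len = 120L),
  LRR = list(name = "LRR_8", acc = "PF13855", clan = "CL0022", len = 24L),
  Ig = list(name = "I-set", acc = "PF07679", clan = "CL0011", len = 70L),
  RHD = list(name = "RHD_DNA_bind", acc = "PF00554", clan = "", len = 170L),
  Ank = list(name = "Ank", acc = "PF00023", clan = "CL0465", len = 33L),
  NACHT = list(name = "NACHT", acc = "PF05729", clan = "CL0023", len = 160L),
  CARD = list(name = "CARD", acc = "PF00619", clan = "CL0041", len = 90L),
  PYD = list(name = "PYD", acc = "PF02758", clan = "CL0041", len = 90L),
  DD = list(name = "Death", acc = "PF00531", clan = "CL0041", len = 85L),
  DED = list(name = "DED", acc = "PF01335", clan = "CL0041", len = 85L),
  Collagen = list(name = "Collagen", acc = "PF01391", clan = "", len = 60L),
  Fibrinogen = list(name = "Fibrinogen_C", acc = "PF00147", clan = "", len = 220L),
  WAP = list(name = "WAP", acc = "PF00095", clan = "", len = 45L),
  SRCR = list(name = "SRCR", acc = "PF00530", clan = "", len = 100L),
  CTLD = list(name = "Lectin_C", acc = "PF00059", clan = "", len = 110L),
  CUB = list(name = "CUB", acc = "PF00431", clan = "CL0164", len = 110L),
  EGF_CA = list(name = "EGF_CA", acc = "PF07645", clan = "", len = 40L),
  Sushi = list(name = "Sushi", acc = "PF00084", clan = "", len = 60L),
  Trypsin = list(name = "Trypsin", acc = "PF00089", clan = "CL0124", len = 220L),
  Pkinase = list(name = "Pkinase", acc = "PF00069", clan = "CL0016", len = 250L),
  Pkinase_Tyr = list(name = "Pkinase_Tyr", acc = "PF07714", clan = "CL0016", len = 250L),
  Ras = list(name = "Ras", acc = "PF00071", clan = "CL0023", len = 160L),
  Miro = list(name = "Miro", acc = "PF08477", clan = "CL0023", len = 170L),
  Roc = list(name = "Roc", acc = "PF08699", clan = "CL0023", len = 120L),
  COR = list(name = "COR", acc = "PF16095", clan = "", len = 120L),
  SH3 = list(name = "SH3_1", acc = "PF00018", clan = "CL0010", len = 55L),
  SAM = list(name = "SAM_1", acc = "PF00536", clan = "CL0003", len = 65L),
  BTK = list(name = "BTK", acc = "PF00779", clan = "", len = 30L),
  DUF1863 = list(name = "DUF1863", acc = "", clan = "", len = 140L)
)

MASP_REFERENCE_ID <- "sp|MASPR1|MASP1_Nematostella_vectensis"

#' Configuration for the synthetic fixture generator
#'
#' Defaults emulate the statistical structure of an annotated actiniarian
#' transcriptome at desk scale: nine immune families with three genes each,
#' one to two isoforms per gene, 30% of transcripts with partial ORFs
#' (missing start and/or stop codon), 10% of annotated transcripts lacking
#' homology hits, one membrane-bound NLR gene carrying 3-5 N-terminal
#' transmembrane helices (the remaining NLRs cytosolic), and ten decoy
#' transcripts covering the RHD-only pseudo-NF-kB case, the TIR-only class,
#' and the named novel genes NG1-NG3.  Complement presence defaults mirror
#' the published presence/absence pattern (C3 and Factor B present, C6 and
#' Factor I absent).
#'
#' @param genes_per_family Named integer vector of planted gene counts.
#' @param n_membrane_nlr Number of NLR genes given the membrane subtype.
#' @param isoform_range Inclusive range isoform counts are drawn from.
#' @param fraction_partial Probability a transcript's ORF is partial.
#' @param fraction_missing_homology Probability an otherwise annotated
#'   transcript gets no homology hits.
#' @param decoys Named integer vector of decoy transcript counts
#'   (`RHD_only`, `TIR_only`, `NG1`, `NG2`, `NG3`, `unmatched_novel`).
#' @param complement_present Named logical vector over C3/Bf/C6/If.
#' @param species_label Species label for the catalog.
#' @param with_cds Also generate coding sequences (reverse-translated).
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(genes_per_family = c(TLR = 3L, NLR = 3L, MyD88 = 3L,
                                                NFKB = 3L, IL1R_like = 3L,
                                                CniFL = 3L, MASP = 3L,
                                                SRCR = 3L, CTLD = 3L),
                           n_membrane_nlr = 1L,
                           isoform_range = c(1L, 2L),
                           fraction_partial = 0.30,
                           fraction_missing_homology = 0.10,
                           decoys = c(RHD_only = 2L, TIR_only = 2L, NG1 = 2L,
                                      NG2 = 2L, NG3 = 2L, unmatched_novel = 0L),
                           complement_present = c(C3 = TRUE, Bf = TRUE,
                                                  C6 = FALSE, If = FALSE),
                           species_label = "A_tenebrosa_syn",
                           with_cds = TRUE) {
  stopifnot(all(genes_per_family >= 0), all(decoys >= 0),
            fraction_partial >= 0, fraction_partial <= 1,
            fraction_missing_homology >= 0, fraction_missing_homology <= 1)
  n_nlr <- if ("NLR" %in% names(genes_per_family)) genes_per_family[["NLR"]] else 0L
  stopifnot(n_membrane_nlr <= n_nlr || n_membrane_nlr == 0L)
  structure(list(genes_per_family = genes_per_family,
                 n_membrane_nlr = n_membrane_nlr,
                 isoform_range = isoform_range,
                 fraction_partial = fraction_partial,
                 fraction_missing_homology = fraction_missing_homology,
                 decoys = decoys, complement_present = complement_present,
                 species_label = species_label, with_cds = with_cds),
            class = "fixture_config")
}

AA20 <- strsplit("ACDEFGHIKLNPQRSTVWY", "")[[1]]     # no M: starts are explicit
HYDROPHOBIC <- strsplit("AILVFGWC", "")[[1]]

rand_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# architecture template (vector of block labels) for one gene of a family
family_template <- function(label, membrane = FALSE) {
  switch(label,
    TLR = c(rep("LRR", sample(4:10, 1)), "TMD", "TIR"),
    NLR = c(if (membrane) rep("TMD", sample(3:5, 1)),
            if (runif(1) < 0.5) sample(c("CARD", "PYD", "DD", "DED"), 1),
            "NACHT", rep("LRR", sample(if (membrane) 5:10 else 3:8, 1))),
    MyD88 = c("DD", "TIR"),
    NFKB = c("RHD", rep("Ank", sample(3:6, 1))),
    IL1R_like = c(rep("Ig", sample(2:3, 1)), "TMD", "TIR"),
    CniFL = c("TMD", "Collagen", rep("Ig", 3),
              if (runif(1) < 1 / 3) "WAP", "Fibrinogen"),
    MASP = c("CUB", "EGF_CA", "CUB", "Sushi", "Sushi", "Trypsin"),
    SRCR = rep("SRCR", sample(1:3, 1)),
    CTLD = "CTLD",
    RHD_only = "RHD",
    TIR_only = sample(c("TIR", "TIR_2", "DUF1863"), 1),
    NG1 = c(rep("LRR", sample(2:4, 1)), "Miro", "Ras", "TIR_2", "COR"),
    NG2 = c(rep("TIR_2", sample(1:2, 1)), "BTK"),
    NG3 = c("Pkinase_Tyr", if (runif(1) < 0.5) "SH3", "DD", "TIR"),
    unmatched_novel = c("TIR_2", "SAM"),
    stop(sprintf("no template for '%s'", label))
  )
}

# lay blocks onto a peptide; returns peptide string + domain/tmd coordinate rows
build_peptide <- function(blocks, has_start) {
  parts <- if (has_start) "M" else sample(setdiff(AA20, "M"), 1)
  doms <- list(); tmds <- list()
  pos <- 1L
  for (b in blocks) {
    # helices sit close together so N-terminal TMD clusters stay within the
    # first third of the peptide, as in the membrane NLR topology
    link <- if (b == "TMD") sample(2:4, 1) else sample(3:12, 1)
    parts <- c(parts, rand_aa(link))
    pos <- pos + link
    if (b == "TMD") {
      len <- 21L
      parts <- c(parts, paste(sample(HYDROPHOBIC, len, replace = TRUE), collapse = ""))
      tmds[[length(tmds) + 1L]] <- c(pos + 1L, pos + len)
      pos <- pos + len
    } else {
      blk <- DOMAIN_BLOCKS[[b]]
      parts <- c(parts, rand_aa(blk$len))
      doms[[length(doms) + 1L]] <- list(label = b, name = blk$name, acc = blk$acc,
                                        clan = blk$clan, start = pos + 1L,
                                        end = pos + blk$len)
      pos <- pos + blk$len
    }
  }
  parts <- c(parts, rand_aa(sample(5:20, 1)))
  list(peptide = paste(parts, collapse = ""), domains = doms, tmds = tmds)
}

reverse_translate <- function(pep, code) {
  by_aa <- split(names(code), unname(code))
  paste(vapply(strsplit(pep, "")[[1]],
               function(a) sample(by_aa[[a]], 1), character(1)),
        collapse = "")
}

#' Generate an annotated synthetic transcript catalog with ground truth
#'
#' Plants complete and partial isoforms of each configured family, the
#' membrane-bound NLR subtype, decoy/novel architectures and
#' complement-homology background transcripts, and returns the merged
#' catalog together with a truth table covering every emitted transcript.
#' Planted peptides are concatenations of per-domain placeholder blocks
#' whose coordinates drive the domain table directly (the pipeline consumes
#' annotations; no homology search is simulated).  Output is fully
#' determined by `(config, seed)`.
#'
#' @param config A [fixture_config()].
#' @param seed Integer seed; every random choice derives from it.
#' @param dir Optional output directory; when given, the catalog is also
#'   written in the exact dialects the ingest functions read (`pep.fa`,
#'   `cds.fa`, `domains.tsv`, `tmhmm.txt`, `blast_swissprot.tsv`,
#'   `blast_trembl.tsv`, `truth.tsv`).
#' @return List with `catalog` (a `transcript_catalog`), `truth` (data frame
#'   `transcript_id`, `gene_group_id`, `label`, `completeness`, `membrane`),
#'   `masp_reference_ids`, `config`, and `files` (named paths or `NULL`).
#' @export
generate_fixture <- function(config = fixture_config(), seed = 42L, dir = NULL) {
  stopifnot(inherits(config, "fixture_config"))
  set.seed(seed)
  code <- genetic_code(1L)
  orf_rows <- list(); dom_rows <- list(); tmd_rows <- list()
  hom_rows <- list(); truth_rows <- list()
  gene_counter <- 0L; subj_counter <- 0L

  add_transcript <- function(label, template, gene_group, iso, truth_label,
                             homology_mode, membrane) {
    tid <- sprintf("%s_i%d", gene_group, iso)
    partial_type <- if (runif(1) < config$fraction_partial)
      sample(c("5prime_partial", "3prime_partial", "internal"), 1) else "complete"
    if (homology_mode %in% c("no_hits", "nvectensis_only"))
      partial_type <- "complete"   # novel calls rest on architecture, keep ORFs clean
    has_start <- partial_type %in% c("complete", "3prime_partial")
    has_stop <- partial_type %in% c("complete", "5prime_partial")
    bp <- build_peptide(template, has_start)
    plen <- nchar(bp$peptide)
    cds <- if (config$with_cds)
      paste0(reverse_translate(bp$peptide, code), if (has_stop) "TAA" else "") else ""

    missing_hom <- homology_mode == "annotated" &&
      runif(1) < config$fraction_missing_homology
    hom <- list()
    if (homology_mode == "annotated" && !missing_hom) {
      subj_counter <<- subj_counter + 1L
      hom[[1]] <- list(transcript_id = tid, database_label = "swissprot",
                       subject_id = sprintf("sp|P%05d|%s_Mus_musculus",
                                            subj_counter, toupper(label)),
                       e_value = 10^-runif(1, 10, 60), query_level = "peptide")
      if (runif(1) < 0.5) {
        subj_counter <<- subj_counter + 1L
        hom[[2]] <- list(transcript_id = tid, database_label = "trembl",
                         subject_id = sprintf("tr|Q%05d|%s_Danio_rerio",
                                              subj_counter, toupper(label)),
                         e_value = 10^-runif(1, 6, 40), query_level = "peptide")
      }
    }
    if (label == "MASP") {
      # the reference-MASP comparison is a configured input of the MASP rule,
      # always present regardless of the missing-homology noise
      hom[[length(hom) + 1L]] <- list(transcript_id = tid,
                                      database_label = "swissprot",
                                      subject_id = MASP_REFERENCE_ID,
                                      e_value = 10^-runif(1, 20, 80),
                                      query_level = "peptide")
    }
    if (homology_mode == "nvectensis_only") {
      subj_counter <<- subj_counter + 1L
      hom[[1]] <- list(transcript_id = tid, database_label = "trembl",
                       subject_id = sprintf("tr|N%05d|PREDICTED_Nematostella_vectensis",
                                            subj_counter),
                       e_value = 10^-runif(1, 6, 20), query_level = "peptide")
    }

    truth_complete <- if (label == "RHD_only") "partial"
    else if (truth_label %in% c(CANDIDATE_FAMILIES, ACCESSORY_FAMILIES)) {
      if (has_start && has_stop && length(hom) > 0) "complete" else "partial"
    } else NA_character_

    orf_rows[[length(orf_rows) + 1L]] <<- list(
      transcript_id = tid, orf_id = paste0(tid, ".p1"), peptide_length = plen,
      has_start_codon = has_start, has_stop_codon = has_stop,
      peptide = bp$peptide, coding_sequence = cds, partial_type = partial_type)
    for (d in bp$domains)
      dom_rows[[length(dom_rows) + 1L]] <<- list(
        transcript_id = tid, domain_name = d$name, family_accession = d$acc,
        clan_accession = d$clan, aa_start = d$start, aa_end = d$end,
        e_value = 10^-runif(1, 6, 40))
    for (tm in bp$tmds)
      tmd_rows[[length(tmd_rows) + 1L]] <<- list(transcript_id = tid,
                                                 aa_start = tm[[1]], aa_end = tm[[2]])
    hom_rows <<- c(hom_rows, hom)
    truth_rows[[length(truth_rows) + 1L]] <<- list(
      transcript_id = tid, gene_group_id = gene_group, label = truth_label,
      completeness = truth_complete, membrane = membrane)
  }

  # planted families
  for (fam in names(config$genes_per_family)) {
    n_genes <- config$genes_per_family[[fam]]
    for (g in seq_len(n_genes)) {
      gene_counter <- gene_counter + 1L
      gg <- sprintf("DN%04d_c0_g1", gene_counter)
      membrane_gene <- fam == "NLR" && g <= config$n_membrane_nlr
      template <- family_template(fam, membrane = membrane_gene)
      n_iso <- sample(seq(config$isoform_range[[1]], config$isoform_range[[2]]), 1)
      for (iso in seq_len(n_iso))
        add_transcript(fam, template, gg, iso, fam, "annotated",
                       membrane = membrane_gene ||
                         fam %in% c("TLR", "IL1R_like", "CniFL"))
    }
  }
  # decoys and novel architectures
  for (dk in names(config$decoys)) {
    for (g in seq_len(config$decoys[[dk]])) {
      gene_counter <- gene_counter + 1L
      gg <- sprintf("DN%04d_c0_g1", gene_counter)
      template <- family_template(dk)
      mode <- if (dk == "RHD_only") "annotated" else
        sample(c("no_hits", "nvectensis_only"), 1)
      truth_label <- if (dk == "RHD_only") "NFKB" else dk
      add_transcript(dk, template, gg, 1L, truth_label, mode, membrane = FALSE)
    }
  }
  # complement-homology background transcripts (no domains)
  comp_subjects <- c(C3 = "sp|P01024|Complement_C3_Homo_sapiens",
                     Bf = "sp|P00751|Complement_factor_B_Homo_sapiens",
                     C6 = "sp|P13671|Complement_C6_Homo_sapiens",
                     If = "sp|P05156|Complement_factor_I_Homo_sapiens")
  for (cf in names(config$complement_present)) {
    if (!isTRUE(config$complement_present[[cf]])) next
    gene_counter <- gene_counter + 1L
    gg <- sprintf("DN%04d_c0_g1", gene_counter)
    tid <- paste0(gg, "_i1")
    pep <- paste0("M", rand_aa(sample(150:400, 1)))
    orf_rows[[length(orf_rows) + 1L]] <- list(
      transcript_id = tid, orf_id = paste0(tid, ".p1"), peptide_length = nchar(pep),
      has_start_codon = TRUE, has_stop_codon = TRUE, peptide = pep,
      coding_sequence = if (config$with_cds)
        paste0(reverse_translate(pep, code), "TAA") else "",
      partial_type = "complete")
    hom_rows[[length(hom_rows) + 1L]] <- list(
      transcript_id = tid, database_label = "swissprot",
      subject_id = comp_subjects[[cf]], e_value = 10^-runif(1, 20, 80),
      query_level = "peptide")
    truth_rows[[length(truth_rows) + 1L]] <- list(
      transcript_id = tid, gene_group_id = gg, label = "none",
      completeness = NA_character_, membrane = FALSE)
  }

  orfs <- if (length(orf_rows))
    do.call(rbind.data.frame, c(orf_rows, list(stringsAsFactors = FALSE)))
  else empty_df(c(ORF_COLS, partial_type = "character"))
  domains <- if (length(dom_rows))
    do.call(rbind.data.frame, c(dom_rows, list(stringsAsFactors = FALSE)))
  else empty_df(DOMAIN_COLS)
  tmds <- if (length(tmd_rows))
    do.call(rbind.data.frame, c(tmd_rows, list(stringsAsFactors = FALSE)))
  else empty_df(TMD_COLS)
  homology <- if (length(hom_rows)) {
    h <- do.call(rbind.data.frame, c(hom_rows, list(stringsAsFactors = FALSE)))
    h$subject_species <- vapply(h$subject_id, function(s) {
      m <- regmatches(s, regexec("_([A-Z][A-Za-z]*_[a-z]+)$", s))[[1]]
      if (length(m) >= 2) gsub("_", " ", m[[2]]) else ""
    }, character(1), USE.NAMES = FALSE)
    h <- h[order(match(h$database_label, c("swissprot", "trembl")),
                 match(h$transcript_id, orfs$transcript_id), h$e_value), ,
           drop = FALSE]
    rownames(h) <- NULL
    h[c("transcript_id", "database_label", "subject_id", "subject_species",
        "e_value", "query_level")]
  } else empty_df(HOMOLOGY_COLS)
  truth <- if (length(truth_rows))
    do.call(rbind.data.frame, c(truth_rows, list(stringsAsFactors = FALSE)))
  else empty_df(c(transcript_id = "character", gene_group_id = "character",
                  label = "character", completeness = "character",
                  membrane = "logical"))

  catalog <- assemble_annotations(orfs[names(orfs) != "partial_type"],
                                  domains, tmds, homology,
                                  species_label = config$species_label)
  files <- NULL
  if (!is.null(dir)) files <- write_fixture_files(dir, orfs, domains, tmds,
                                                  homology, truth, config)
  invisible(list(catalog = catalog, truth = truth,
                 masp_reference_ids = MASP_REFERENCE_ID, config = config,
                 files = files))
}

write_fixture_files <- function(dir, orfs, domains, tmds, homology, truth, config) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  pep_lines <- as.vector(rbind(sprintf(">%s type:%s", orfs$orf_id, orfs$partial_type),
                               orfs$peptide))
  writeLines(pep_lines, p("pep.fa"))
  files <- c(pep = p("pep.fa"))
  if (config$with_cds) {
    cds_lines <- as.vector(rbind(sprintf(">%s", orfs$orf_id), orfs$coding_sequence))
    writeLines(cds_lines, p("cds.fa"))
    files["cds"] <- p("cds.fa")
  }
  dom <- domains
  dom$e_value <- format(dom$e_value, digits = 6, scientific = TRUE, trim = TRUE)
  write.table(dom, p("domains.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  files["domains"] <- p("domains.tsv")

  # TMHMM short format, one line per transcript
  tm_lines <- vapply(seq_len(nrow(orfs)), function(i) {
    tid <- orfs$transcript_id[[i]]
    seg <- tmds[tmds$transcript_id == tid, , drop = FALSE]
    topo <- if (nrow(seg)) paste0("o", paste(sprintf("%d-%d", seg$aa_start, seg$aa_end),
                                             collapse = "i"), "i") else "o"
    sprintf("%s\tlen=%d\tExpAA=%.2f\tFirst60=0.00\tPredHel=%d\tTopology=%s",
            tid, orfs$peptide_length[[i]], 21.0 * nrow(seg), nrow(seg), topo)
  }, character(1))
  writeLines(tm_lines, p("tmhmm.txt"))
  files["tmhmm"] <- p("tmhmm.txt")

  for (db in c("swissprot", "trembl")) {
    h <- homology[homology$database_label == db, , drop = FALSE]
    out <- p(sprintf("blast_%s.tsv", db))
    if (nrow(h)) {
      tab <- data.frame(q = h$transcript_id, s = h$subject_id, pid = 90.0, len = 100L,
                        mm = 10L, go = 0L, qs = 1L, qe = 100L, ss = 1L, se = 100L,
                        ev = format(h$e_value, digits = 6, scientific = TRUE, trim = TRUE),
                        bit = 200.0, stringsAsFactors = FALSE)
      write.table(tab, out, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
    } else {
      writeLines(character(0), out)
    }
    files[paste0("blast_", db)] <- out
  }
  write.table(truth, p("truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  files["truth"] <- p("truth.tsv")
  files
}

#' Load a fixture written by [generate_fixture()] through the ingest readers
#'
#' Convenience round-trip: reads `pep.fa`/`cds.fa`/`domains.tsv`/`tmhmm.txt`
#' and the two BLAST tables back into a `transcript_catalog`.
#'
#' @param dir Fixture directory.
#' @param species_label Species label for the catalog.
#' @return A `transcript_catalog`.
#' @export
read_fixture <- function(dir, species_label = "A_tenebrosa_syn") {
  cds <- file.path(dir, "cds.fa")
  orfs <- read_orfs(file.path(dir, "pep.fa"),
                    if (file.exists(cds)) cds else NULL)
  assemble_annotations(
    orfs,
    read_domain_hits(file.path(dir, "domains.tsv"), dialect = "tsv"),
    read_tmd_calls(file.path(dir, "tmhmm.txt")),
    list(read_homology(file.path(dir, "blast_swissprot.tsv"), "swissprot"),
         read_homology(file.path(dir, "blast_trembl.tsv"), "trembl")),
    species_label = species_label)
}

SENSE_CODONS <- setdiff(apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                          c("T", "C", "A", "G")), 1, paste, collapse = ""),
                        STOP_CODONS)

#' Simulate a codon pair under a controlled dN/dS
#'
#' Draws an ancestral sequence uniformly over sense codons and applies
#' point-substitution events to one lineage: each event proposes a random
#' single-base change (transitions weighted by `kappa`), rejects changes
#' creating a stop codon, and accepts synonymous changes with probability 1
#' and nonsynonymous changes with probability `omega_target` — so the
#' realised nonsynonymous/synonymous rate ratio per site equals
#' `omega_target`.  True accepted substitution counts are recorded.
#'
#' @param omega_target Target dN/dS (> 0 and <= 1 for this acceptance
#'   scheme; values > 1 are handled by inverting the acceptance weights).
#' @param n_codons Number of codons (>= 1).
#' @param kappa Transition/transversion proposal weight (default 2).
#' @param n_events Number of proposal events (default `0.45 * n_codons`,
#'   which keeps divergence far from saturation).
#' @param seed Optional seed set before simulation.
#' @param ancestor Optional ancestral coding sequence (sense codons only);
#'   lets several lineages be evolved from one ancestor.
#' @return List with `seqs` (named character vector `ancestor`/`derived`),
#'   `true_Nd`, `true_Sd`, `omega_target`.
#' @export
generate_codon_pair <- function(omega_target, n_codons, kappa = 2,
                                n_events = round(0.45 * n_codons), seed = NULL,
                                ancestor = NULL) {
  stopifnot(omega_target > 0, n_codons >= 1)
  if (!is.null(seed)) set.seed(seed)
  code <- genetic_code(1L)
  acc_syn <- min(1, 1 / omega_target)   # scale so max acceptance prob is 1
  acc_non <- min(1, omega_target)
  anc <- if (is.null(ancestor)) sample(SENSE_CODONS, n_codons, replace = TRUE)
  else {
    stopifnot(nchar(ancestor) == 3L * n_codons)
    split_codons(toupper(ancestor))
  }
  der <- anc
  true_Sd <- 0L; true_Nd <- 0L
  bases <- c("A", "C", "G", "T")
  for (ev in seq_len(max(0L, n_events))) {
    i <- sample.int(n_codons, 1L)
    pos <- sample.int(3L, 1L)
    b <- substr(der[[i]], pos, pos)
    alts <- setdiff(bases, b)
    w <- ifelse(is_transition(b, alts), kappa, 1)
    nb <- sample(alts, 1L, prob = w)
    cand <- der[[i]]; substr(cand, pos, pos) <- nb
    if (cand %in% STOP_CODONS) next
    syn <- code[[cand]] == code[[der[[i]]]]
    p_acc <- if (syn) acc_syn else acc_non
    if (runif(1) < p_acc) {
      der[[i]] <- cand
      if (syn) true_Sd <- true_Sd + 1L else true_Nd <- true_Nd + 1L
    }
  }
  list(seqs = c(ancestor = paste(anc, collapse = ""),
                derived = paste(der, collapse = "")),
       true_Nd = true_Nd, true_Sd = true_Sd, omega_target = omega_target)
}

#' Precision and recall of recovered labels against planted truth
#'
#' Standard one-vs-rest confusion counts per truth label (the background
#' label `"none"` is scored only as a source of false positives).  A
#' transcript present in `calls` but absent from `truth` is an error.
#'
#' @param truth Truth table from [generate_fixture()] (columns
#'   `transcript_id`, `label`).
#' @param calls Data frame with `transcript_id` and `label` (e.g. from
#'   [profile_labels()]).
#' @return Data frame with `label`, `tp`, `fp`, `fn`, `precision`, `recall`;
#'   precision is `NA` when nothing was called for a label.
#' @export
score_recovery <- function(truth, calls) {
  if (!all(calls$transcript_id %in% truth$transcript_id))
    stop("calls contain transcripts absent from the truth table", call. = FALSE)
  call_label <- setNames(calls$label, calls$transcript_id)
  labels <- setdiff(unique(truth$label), "none")
  rows <- lapply(labels, function(L) {
    truth_ids <- truth$transcript_id[truth$label == L]
    called_ids <- calls$transcript_id[calls$label == L]
    tp <- sum(called_ids %in% truth_ids)
    fp <- sum(!called_ids %in% truth_ids)
    fn <- sum(!truth_ids %in% called_ids)
    list(label = L, tp = tp, fp = fp, fn = fn,
         precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
         recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
  })
  do.call(rbind.data.frame, c(rows, list(stringsAsFactors = FALSE)))
}
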