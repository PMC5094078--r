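CANDIDATE_FAMILIES <- c("TLR", "NLR", "MyD88", "NFKB", "IL1R_like")
ACCESSORY_FAMILIES <- c("CniFL", "MASP", "SRCR", "CTLD")

new_family_call <- function(ann, family, kind, completeness = "partial",
                            note = "", evidence_hits = NULL) {
  ev <- evidence_hits %||% ann$domains
  lab <- label_domains(ev)
  list(transcript_id = ann$transcript_id,
       gene_group_id = ann$gene_group_id,
       family = family, kind = kind, completeness = completeness, note = note,
       n_lrr = sum(lab == "LRR"), n_ank = sum(lab == "Ank"),
       n_ig = sum(lab == "Ig"),
       death_fold_type = "none",
       n_tmd = 0L, membrane_bound = FALSE, tmd_n_terminal_clustered = FALSE,
       has_wap = FALSE,
       evidence = if (nrow(ev)) paste(sprintf("%s:%d-%d:%s", lab, ev$aa_start,
                                              ev$aa_end, ev$family_accession),
                                      collapse = ";") else "")
}

#' Classify a transcript into a candidate innate-immune family
#'
#' Applies the candidate-gene identification rules over a transcript's domain
#' hits: TLR = TIR (PF01582, or the bacterial-type TIR_2, PF13676) plus at
#' least one leucine-rich repeat (clan CL0022); MyD88 = TIR plus a death
#' domain; IL-1R-like = TIR plus at least one immunoglobulin domain (clan
#' CL0011); NF-kB = Rel homology domain (PF00554) plus at least one ankyrin
#' repeat (PF00023); NLR = NACHT plus at least one LRR, with an optional
#' N-terminal death-fold domain (CARD PF00619, PYD PF02758, DD PF00531,
#' DED PF01335) recorded as the subtype.
#'
#' Two special cases: (i) a TIR-bearing transcript that also carries
#' novelty-indicative domains (kinase, Ras/Roc/COR/Miro GTPase, SH3, SAM,
#' BTK, CBM) is returned as `NULL` and left to the novelty detector — this
#' is what separates e.g. the kinase-bearing novel gene class from MyD88;
#' (ii) a Rel homology domain without ankyrin repeats is reported as a
#' partial NF-kB call with note `"RHD-only"` (such transcripts are never
#' complete).  When several rules match, the most specific co-domain wins:
#' NLR > TLR > IL-1R-like > MyD88 > NF-kB.
#'
#' @param ann A transcript annotation from [transcript_annotation()].
#' @param rules Rule set from [family_rules()].
#' @return A family-call list, or `NULL` when no rule matches.
#' @export
classify_candidate <- function(ann, rules = family_rules()) {
  hits <- ann$domains
  if (!nrow(hits)) return(NULL)
  if (tir_bearing(hits, rules) && has_novelty_extras(hits, rules)) return(NULL)
  prec <- rules$candidate_precedence %||% CANDIDATE_FAMILIES
  for (fam in prec) {
    rule <- rules$families[[fam]]
    if (is.null(rule) || !identical(rule$kind, "candidate")) next
    if (all(vapply(rule$required, function(p) predicate_satisfied(hits, p), logical(1)))) {
      call <- new_family_call(ann, fam, "candidate")
      if (fam == "NLR") call$death_fold_type <- death_fold_type(hits)
      call$completeness <- assess_completeness(ann, call, rules)
      return(call)
    }
  }
  # RHD without ankyrin repeats: reported, but never a full-length NF-kB
  rhd <- rules$families$NFKB$required[[1]]
  if (predicate_satisfied(hits, rhd)) {
    call <- new_family_call(ann, "NFKB", "candidate", completeness = "partial",
                            note = "RHD-only")
    return(call)
  }
  NULL
}

# N-terminal-most death-fold domain, by envelope start
death_fold_type <- function(hits) {
  df_acc <- c(PF00619 = "CARD", PF02758 = "PYD", PF00531 = "DD", PF01335 = "DED")
  i <- which(hits$family_accession %in% names(df_acc))
  if (!length(i)) return("none")
  i <- i[which.min(hits$aa_start[i])]
  unname(df_acc[hits$family_accession[[i]]])
}

#' Assess completeness of a family call
#'
#' A call is `"complete"` only when the underlying ORF is full length (start
#' and stop codon present), the peptide received at least one peptide-level
#' homology hit, and all canonical required domains of the family are
#' present.  Anything else — and any call carrying the `"RHD-only"` note —
#' is `"partial"`.
#'
#' @param ann Transcript annotation.
#' @param call Family call produced by [classify_candidate()] or
#'   [classify_other_immune()].
#' @param rules Rule set.
#' @return `"complete"` or `"partial"`.
#' @export
assess_completeness <- function(ann, call, rules = family_rules()) {
  if (identical(call$note, "RHD-only")) return("partial")
  orf <- ann$orf
  if (!isTRUE(orf$has_start_codon) || !isTRUE(orf$has_stop_codon)) return("partial")
  if (!any(ann$homology$query_level == "peptide")) return("partial")
  rule <- rules$families[[call$family]]
  ok <- all(vapply(rule$required, function(p) predicate_satisfied(ann$domains, p),
                   logical(1)))
  if (ok) "complete" else "partial"
}

#' Annotate membrane topology of a family call
#'
#' Sets the transmembrane-segment count, the membrane-bound flag
#' (`n_tmd >= 1`), and whether all predicted helices are clustered at the
#' N-terminus — the hallmark of the membrane-bound NLR subtype, which
#' carries 3-5 helices in the N-terminal region.  A helix counts as
#' N-terminal when its midpoint lies within the first
#' `n_terminal_fraction` of the peptide.
#'
#' @param call Family call.
#' @param tmds TMD segment data frame for the transcript.
#' @param peptide_length Length of the translated ORF.
#' @param n_terminal_fraction Fraction of the peptide counted as N-terminal
#'   (default 0.30).
#' @return The updated call.
#' @export
detect_tmd_subtype <- function(call, tmds, peptide_length,
                               n_terminal_fraction = 0.30) {
  stopifnot(peptide_length > 0, n_terminal_fraction > 0, n_terminal_fraction <= 1)
  n <- nrow(tmds)
  call$n_tmd <- n
  call$membrane_bound <- n >= 1L
  call$tmd_n_terminal_clustered <- n >= 1L &&
    all((tmds$aa_start + tmds$aa_end) / 2 <= n_terminal_fraction * peptide_length)
  call
}

#' Classify accessory immune families
#'
#' Calls the lectin/complement-pathway families from domain content:
#' CniFL (Cnidarian Ficolin-like: Collagen PF01391 + immunoglobulin domains
#' + Fibrinogen PF00147, with an optional WAP domain and usually one TMD),
#' MASP (CUB x2, EGF-like calcium-binding, Sushi x2 and a Peptidase S1
#' domain, plus homology to a supplied reference MASP), SRCR (PF00530) and
#' C-type lectin (Lectin_C, PF00059).  A transcript may receive several
#' accessory calls.
#'
#' @param ann Transcript annotation.
#' @param masp_reference_ids Subject ids accepted as reference MASP homologs;
#'   a MASP call additionally requires a homology hit to one of these.
#' @param rules Rule set.
#' @param relax_masp If `TRUE`, require only 4 of the 6 MASP domain slots.
#' @return List of family calls (possibly empty).
#' @export
classify_other_immune <- function(ann, masp_reference_ids = character(),
                                  rules = family_rules(), relax_masp = FALSE) {
  hits <- ann$domains
  out <- list()
  for (fam in ACCESSORY_FAMILIES) {
    rule <- rules$families[[fam]]
    if (is.null(rule)) next
    sat <- vapply(rule$required, function(p) predicate_satisfied(hits, p), logical(1))
    n_slots <- vapply(rule$required, function(p) min(sum(predicate_matches(hits, p)),
                                                     p$min %||% 1L), numeric(1))
    ok <- if (fam == "MASP" && relax_masp) sum(n_slots) >= 4 else all(sat)
    if (!ok) next
    if (isTRUE(rule$requires_reference_homology) &&
        !any(ann$homology$subject_id %in% masp_reference_ids)) next
    call <- new_family_call(ann, fam, "accessory")
    if (fam == "CniFL") {
      wap <- rule$optional[[1]]
      call$has_wap <- sum(predicate_matches(hits, wap)) >= 1
    }
    call$completeness <- assess_completeness(ann, call, rules)
    out[[length(out) + 1L]] <- call
  }
  out
}

#' Complement-family presence flags
#'
#' The complement components (C3, Factor B, C6, Factor I) have no domain
#' rule: presence is called from homology alone, by matching subject
#' identifiers against per-family name patterns (case-insensitive regex).
#'
#' @param homology Homology table (or a `transcript_catalog`).
#' @param patterns Named character vector of regexes, one per family.
#' @return Named character vector, `"present"`/`"absent"` per family.
#' @export
presence_flags <- function(homology,
                           patterns = c(C3 = "complement[_ ]?c3",
                                        Bf = "factor[_ ]?b|complement[_ ]?bf",
                                        C6 = "complement[_ ]?c6|complement[_ ]component[_ ]?6",
                                        If = "factor[_ ]?i\\b|complement[_ ]?if")) {
  if (inherits(homology, "transcript_catalog")) homology <- homology$homology
  subj <- homology$subject_id
  vapply(patterns, function(p)
    if (any(grepl(p, subj, ignore.case = TRUE))) "present" else "absent",
    character(1))
}

#' Check family calls against expected membrane topology
#'
#' TLR and IL-1R-like receptors are expected to carry a transmembrane
#' segment, while the cytosolic adaptors/transcription factors MyD88 and
#' NF-kB are expected to carry none.  Deviations produce warnings; calls are
#' never altered.
#'
#' @param calls Family-call data frame (see [classify_catalog()]).
#' @return Character vector of warning messages (empty when all consistent).
#' @export
validate_topology <- function(calls) {
  out <- character(0)
  if (!nrow(calls)) return(out)
  for (i in seq_len(nrow(calls))) {
    fam <- calls$family[[i]]; n <- calls$n_tmd[[i]]; id <- calls$transcript_id[[i]]
    if (fam %in% c("TLR", "IL1R_like") && n == 0L)
      out <- c(out, sprintf("%s: %s without a TMD (membrane receptor expected)", id, fam))
    if (fam %in% c("MyD88", "NFKB") && n > 0L)
      out <- c(out, sprintf("%s: %s with %d TMD(s) (cytosolic protein expected)", id, fam, n))
  }
  out
}

#' Extract domain subsequences from a peptide
#'
#' Clips the peptide to the envelope coordinates of every hit matching the
#' given accession (or domain name) — e.g. trimming NLRs to the conserved
#' NACHT domain before phylogenetic alignment.  Subsequences are returned in
#' coordinate order.
#'
#' @param ann Transcript annotation (peptide must be available).
#' @param accession Pfam accession or domain name to extract.
#' @return Data frame with `transcript_id`, `accession`, `aa_start`,
#'   `aa_end`, `subsequence`; zero rows when the domain is absent.
#' @export
extract_domain_subsequence <- function(ann, accession) {
  hits <- ann$domains
  i <- which(hits$family_accession == accession | hits$domain_name == accession)
  pep <- ann$orf$peptide
  if (!length(i) || !nzchar(pep))
    return(data.frame(transcript_id = character(0), accession = character(0),
                      aa_start = integer(0), aa_end = integer(0),
                      subsequence = character(0), stringsAsFactors = FALSE))
  i <- i[order(hits$aa_start[i])]
  data.frame(transcript_id = ann$transcript_id, accession = accession,
             aa_start = hits$aa_start[i], aa_end = hits$aa_end[i],
             subsequence = substring(pep, hits$aa_start[i], hits$aa_end[i]),
             stringsAsFactors = FALSE)
}

#' Write domain subsequences as FASTA
#'
#' @param subseqs Output of [extract_domain_subsequence()] (rows may come
#'   from several transcripts).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_subsequences_fasta <- function(subseqs, path) {
  ss <- Biostrings::AAStringSet(subseqs$subsequence)
  names(ss) <- sprintf("%s/%d-%d %s", subseqs$transcript_id, subseqs$aa_start,
                       subseqs$aa_end, subseqs$accession)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

family_calls_df <- function(calls) {
  cols <- c(transcript_id = "character", gene_group_id = "character",
            family = "character", kind = "character", completeness = "character",
            note = "character", n_lrr = "integer", n_ank = "integer",
            n_ig = "integer", death_fold_type = "character", n_tmd = "integer",
            membrane_bound = "logical", tmd_n_terminal_clustered = "logical",
            has_wap = "logical", evidence = "character")
  if (!length(calls)) return(empty_df(cols))
  do.call(rbind.data.frame,
          c(lapply(calls, function(x) x[names(cols)]),
            list(stringsAsFactors = FALSE)))
}

#' Classify every transcript in a catalog
#'
#' Runs [classify_candidate()], [classify_other_immune()] and
#' [detect_tmd_subtype()] over all transcripts.  Transcript order does not
#' affect the result (rows are emitted in catalog order).
#'
#' @param catalog A `transcript_catalog`.
#' @param rules Rule set.
#' @param masp_reference_ids Passed to [classify_other_immune()].
#' @param n_terminal_fraction Passed to [detect_tmd_subtype()].
#' @return Data frame of family calls, one row per call.
#' @export
classify_catalog <- function(catalog, rules = family_rules(),
                             masp_reference_ids = character(),
                             n_terminal_fraction = 0.30) {
  calls <- list()
  for (id in catalog$orfs$transcript_id) {
    ann <- transcript_annotation(catalog, id)
    plen <- ann$orf$peptide_length
    cand <- classify_candidate(ann, rules)
    acc <- classify_other_immune(ann, masp_reference_ids, rules)
    for (call in c(if (!is.null(cand)) list(cand), acc)) {
      if (plen > 0) call <- detect_tmd_subtype(call, ann$tmds, plen, n_terminal_fraction)
      calls[[length(calls) + 1L]] <- call
    }
  }
  family_calls_df(calls)
}
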