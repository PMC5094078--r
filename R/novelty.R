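NOVELTY_PATTERNS <- c("NG1", "NG2", "NG3", "TIR_only", "unmatched_novel")

#' Build a transcript's domain-architecture signature
#'
#' Orders domain hits N- to C-terminal by envelope start and collapses
#' overlapping same-clan hits: when two hits share a clan and their
#' envelopes overlap by more than half the shorter envelope, only the hit
#' with the lower E-value is kept (e.g. `Pkinase` and `Pkinase_Tyr` calls on
#' the same kinase domain, which always overlap).  Labels follow
#' [label_domains()].
#'
#' @param ann Transcript annotation.
#' @param collapse Collapse overlapping same-clan hits (default `TRUE`).
#' @return Character vector of ordered domain labels with attribute
#'   `transcript_id`.
#' @export
architecture_signature <- function(ann, collapse = TRUE) {
  hits <- ann$domains
  if (!nrow(hits)) return(structure(character(0), transcript_id = ann$transcript_id))
  hits <- hits[order(hits$aa_start, hits$aa_end, hits$e_value), , drop = FALSE]
  if (collapse && nrow(hits) > 1L) {
    drop <- rep(FALSE, nrow(hits))
    for (i in seq_len(nrow(hits) - 1L)) {
      if (drop[[i]]) next
      for (j in seq.int(i + 1L, nrow(hits))) {
        if (drop[[j]]) next
        ov <- min(hits$aa_end[[i]], hits$aa_end[[j]]) -
          max(hits$aa_start[[i]], hits$aa_start[[j]]) + 1L
        shorter <- min(hits$aa_end[[i]] - hits$aa_start[[i]],
                       hits$aa_end[[j]] - hits$aa_start[[j]]) + 1L
        same_clan <- nzchar(hits$clan_accession[[i]]) &&
          hits$clan_accession[[i]] == hits$clan_accession[[j]]
        if (same_clan && ov > shorter / 2) {
          if (hits$e_value[[j]] >= hits$e_value[[i]]) drop[[j]] <- TRUE else drop[[i]] <- TRUE
        }
      }
    }
    hits <- hits[!drop, , drop = FALSE]
  }
  structure(label_domains(hits), transcript_id = ann$transcript_id)
}

annotation_status <- function(ann) {
  h <- ann$homology
  if (!nrow(h)) return("no_hits")
  nv <- grepl("nematostella", h$subject_species, ignore.case = TRUE) |
    grepl("nematostella", h$subject_id, ignore.case = TRUE)
  if (all(nv)) "nvectensis_only" else "annotated"
}

#' Select candidate novel transcripts
#'
#' The novelty screen considers TIR/TIR_2-bearing transcripts that either
#' received no homology annotation at all, or whose only hits are against
#' *Nematostella vectensis* predicted proteins.  Everything with a hit to
#' any other species is treated as annotated and excluded.
#'
#' @param catalog A `transcript_catalog`.
#' @param rules Rule set (for the TIR-equivalence set).
#' @return Data frame with `transcript_id` and `annotation_status`
#'   (`"no_hits"` or `"nvectensis_only"`).
#' @export
candidate_novel_set <- function(catalog, rules = family_rules()) {
  ids <- character(0); status <- character(0)
  for (id in catalog$orfs$transcript_id) {
    ann <- transcript_annotation(catalog, id)
    if (!tir_like_bearing(ann$domains, rules)) next
    st <- annotation_status(ann)
    if (st %in% c("no_hits", "nvectensis_only")) {
      ids <- c(ids, id); status <- c(status, st)
    }
  }
  data.frame(transcript_id = ids, annotation_status = status,
             stringsAsFactors = FALSE)
}

#' Match a signature against the named novel-gene patterns
#'
#' The named classes of novel TIR-domain architectures are: NG1 — LRR plus
#' at least one GTPase-family domain (Miro, Ras or Roc) plus TIR_2 (a
#' low-threshold COR domain is often present downstream and is recorded but
#' not required); NG2 — one or two TIR_2 domains upstream of a BTK
#' (Bruton's tyrosine-kinase-type zinc-finger) motif; NG3 — a kinase domain
#' (Pkinase or Pkinase_Tyr), a death domain and a TIR (or TIR_2) domain,
#' with SH3/Roc/COR optional; TIR-only — no immune-relevant domain beyond
#' TIR/TIR_2 (or the TIR-like DUF1863 in its place).  Anything else is
#' `unmatched_novel`.  The label is a pure function of the signature.
#'
#' @param signature Ordered label vector from [architecture_signature()].
#' @return One of `"NG1"`, `"NG2"`, `"NG3"`, `"TIR_only"`,
#'   `"unmatched_novel"`.
#' @export
match_named_pattern <- function(signature) {
  s <- as.character(signature)
  if (!length(s)) return("unmatched_novel")
  gtpase <- c("Miro", "Ras", "Roc")
  if ("LRR" %in% s && any(gtpase %in% s) && "TIR_2" %in% s) return("NG1")
  n_tir2 <- sum(s == "TIR_2")
  if (n_tir2 >= 1 && n_tir2 <= 2 && "BTK" %in% s &&
      max(which(s == "TIR_2")) < min(which(s == "BTK"))) return("NG2")
  if (any(c("Pkinase", "Pkinase_Tyr") %in% s) && "DD" %in% s &&
      any(c("TIR", "TIR_2") %in% s)) return("NG3")
  if (all(s %in% c("TIR", "TIR_2", "DUF1863", "TIR_like"))) return("TIR_only")
  "unmatched_novel"
}

#' Load the known-architecture catalog
#'
#' A local, versioned replacement for a live domain-architecture database
#' query: a table of architecture signatures considered already known, with
#' provenance.  The shipped asset is a synthetic compilation of widely
#' documented TIR-domain architectures.
#'
#' @param path Optional path to an alternative catalog TSV
#'   (columns `signature`, `provenance`; signatures comma-separated labels).
#' @return Object of class `known_architectures` (data frame).
#' @export
known_architectures <- function(path = NULL) {
  path <- path %||% system.file("extdata", "known_architectures.tsv",
                                package = "cnidimmune")
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (anyDuplicated(df$signature)) stop("duplicate signatures in catalog", call. = FALSE)
  structure(df, class = c("known_architectures", "data.frame"))
}

#' Screen a signature against the known-architecture catalog
#'
#' @param signature Ordered label vector.
#' @param catalog A `known_architectures` table.
#' @param order_sensitive Match the signature as an ordered sequence
#'   (default) or as an unordered multiset.
#' @return `"known"` or `"novel"`.
#' @export
screen_against_catalog <- function(signature, catalog = known_architectures(),
                                   order_sensitive = TRUE) {
  if (!nrow(catalog)) {
    warning("empty known-architecture catalog: everything is novel", call. = FALSE)
    return("novel")
  }
  sig <- paste(as.character(signature), collapse = ",")
  known <- if (order_sensitive) {
    sig %in% catalog$signature
  } else {
    key <- paste(sort(as.character(signature)), collapse = ",")
    key %in% vapply(strsplit(catalog$signature, ","),
                    function(x) paste(sort(x), collapse = ","), character(1))
  }
  if (known) "known" else "novel"
}

#' Detect novel TIR-domain architectures in a catalog
#'
#' Runs the novelty screen: candidate transcripts from
#' [candidate_novel_set()] that did not receive a candidate family call are
#' matched against the named patterns and screened against the
#' known-architecture catalog.  Routing is exclusive — a transcript never
#' carries both a family call and a novelty call.
#'
#' @param catalog A `transcript_catalog`.
#' @param family_calls Family-call data frame from [classify_catalog()]
#'   (computed if missing).
#' @param rules Rule set.
#' @param known Known-architecture catalog.
#' @return Data frame of novelty calls: `transcript_id`, `gene_group_id`,
#'   `pattern`, `annotation_status`, `catalog_status`, `signature`.
#' @export
detect_novel <- function(catalog, family_calls = NULL, rules = family_rules(),
                         known = known_architectures()) {
  family_calls <- family_calls %||% classify_catalog(catalog, rules)
  cand <- candidate_novel_set(catalog, rules)
  called <- family_calls$transcript_id[family_calls$kind == "candidate"]
  cand <- cand[!cand$transcript_id %in% called, , drop = FALSE]
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    ann <- transcript_annotation(catalog, cand$transcript_id[[i]])
    sig <- architecture_signature(ann)
    list(transcript_id = ann$transcript_id, gene_group_id = ann$gene_group_id,
         pattern = match_named_pattern(sig),
         annotation_status = cand$annotation_status[[i]],
         catalog_status = screen_against_catalog(sig, known),
         signature = paste(sig, collapse = ","))
  })
  cols <- c(transcript_id = "character", gene_group_id = "character",
            pattern = "character", annotation_status = "character",
            catalog_status = "character", signature = "character")
  if (!length(rows)) return(empty_df(cols))
  do.call(rbind.data.frame, c(rows, list(stringsAsFactors = FALSE)))
}
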