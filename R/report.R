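COMPLEMENT_FAMILIES <- c("C3", "Bf", "C6", "If")

#' Build a per-species immune gene count report
#'
#' Aggregates family and novelty calls into the twin count semantics used
#' for the published tables: a *conservative* count (gene groups with at
#' least one complete-ORF call — the "genes with a complete ORF only"
#' convention) and a *total* count (gene groups with at least one call of
#' any completeness, i.e. contigs the assembler identified as different
#' genes, including partial ORFs).  Candidate receptor/adaptor families are
#' reported both ways; accessory lectin/complement families are counted
#' non-conservatively (total genes); complement components are reported as
#' presence/absence flags only.  Per-family subtype tallies record
#' membrane-bound NLR genes (including partials) and WAP-bearing CniFL
#' genes.
#'
#' @param calls Family-call data frame from [classify_catalog()].
#' @param novelty_calls Novelty-call data frame from [detect_novel()]
#'   (or `NULL`).
#' @param species_label Species label for the report row.
#' @param presence Named presence/absence vector from [presence_flags()]
#'   (or `NULL` for all-absent).
#' @return Object of class `counts_report`.
#' @export
build_counts <- function(calls, novelty_calls = NULL, species_label = "unknown",
                         presence = NULL) {
  novelty_calls <- novelty_calls %||%
    empty_df(c(transcript_id = "character", gene_group_id = "character",
               pattern = "character", annotation_status = "character",
               catalog_status = "character", signature = "character"))
  if (nrow(calls) && (is.null(calls$gene_group_id) || anyNA(calls$gene_group_id) ||
                      any(!nzchar(calls$gene_group_id))))
    stop("family call without a gene group", call. = FALSE)
  if (nrow(novelty_calls) && any(!nzchar(novelty_calls$gene_group_id)))
    stop("novelty call without a gene group", call. = FALSE)

  fam_vocab <- c(CANDIDATE_FAMILIES, ACCESSORY_FAMILIES)
  fam_rows <- lapply(fam_vocab, function(fam) {
    sub <- calls[calls$family == fam, , drop = FALSE]
    complete_genes <- unique(sub$gene_group_id[sub$completeness == "complete"])
    total_genes <- unique(sub$gene_group_id)
    list(family = fam,
         kind = if (fam %in% CANDIDATE_FAMILIES) "candidate" else "accessory",
         n_complete_genes = length(complete_genes),
         n_total_genes = length(total_genes),
         n_partial = length(total_genes) - length(complete_genes),
         n_isoforms = length(unique(sub$transcript_id)))
  })
  families <- do.call(rbind.data.frame, c(fam_rows, list(stringsAsFactors = FALSE)))

  nov_rows <- lapply(NOVELTY_PATTERNS, function(p) {
    sub <- novelty_calls[novelty_calls$pattern == p, , drop = FALSE]
    list(pattern = p, n_genes = length(unique(sub$gene_group_id)),
         n_isoforms = length(unique(sub$transcript_id)))
  })
  novelty <- do.call(rbind.data.frame, c(nov_rows, list(stringsAsFactors = FALSE)))

  nlr <- calls[calls$family == "NLR" & calls$membrane_bound, , drop = FALSE]
  cni <- calls[calls$family == "CniFL" & calls$has_wap, , drop = FALSE]
  pres <- setNames(rep("absent", length(COMPLEMENT_FAMILIES)), COMPLEMENT_FAMILIES)
  if (!is.null(presence)) pres[names(presence)] <- presence

  structure(list(species_label = species_label, families = families,
                 novelty = novelty, presence = pres,
                 n_membrane_NLR = length(unique(nlr$gene_group_id)),
                 n_CniFL_with_WAP = length(unique(cni$gene_group_id))),
            class = "counts_report")
}

#' @export
print.counts_report <- function(x, ...) {
  cat(sprintf("Immune gene counts for %s\n", x$species_label))
  cat("  (conservative = gene groups with >=1 complete-ORF call; total includes partials)\n")
  print(x$families, row.names = FALSE)
  cat(sprintf("  membrane-bound NLR genes: %d; WAP-bearing CniFL genes: %d\n",
              x$n_membrane_NLR, x$n_CniFL_with_WAP))
  cat("  complement: ", paste(sprintf("%s=%s", names(x$presence),
                                      ifelse(x$presence == "present", "+", "-")),
                              collapse = " "), "\n", sep = "")
  if (any(x$novelty$n_genes > 0)) {
    cat("  novel TIR-domain genes:\n")
    print(x$novelty[x$novelty$n_genes > 0, ], row.names = FALSE)
  }
  invisible(x)
}

#' Merge per-species count reports into a species-by-family matrix
#'
#' One row per species, in input order; families absent from a report are
#' zero-filled; complement flags become `"+"`/`"-"` glyph columns.
#'
#' @param reports List of `counts_report` objects.
#' @return Data frame, one row per species.
#' @export
merge_species <- function(reports) {
  stopifnot(length(reports) > 0, all(vapply(reports, inherits, logical(1), "counts_report")))
  labels <- vapply(reports, `[[`, character(1), "species_label")
  if (anyDuplicated(labels)) stop("duplicate species label", call. = FALSE)
  rows <- lapply(reports, function(r) {
    f <- r$families
    row <- list(species = r$species_label)
    for (i in seq_len(nrow(f))) {
      fam <- f$family[[i]]
      if (f$kind[[i]] == "candidate")
        row[[paste0(fam, "_complete")]] <- f$n_complete_genes[[i]]
      row[[paste0(fam, "_total")]] <- f$n_total_genes[[i]]
    }
    for (p in r$novelty$pattern)
      row[[p]] <- r$novelty$n_genes[r$novelty$pattern == p]
    row$membrane_NLR <- r$n_membrane_NLR
    for (cf in names(r$presence))
      row[[cf]] <- if (r$presence[[cf]] == "present") "+" else "-"
    row
  })
  do.call(rbind.data.frame, c(rows, list(stringsAsFactors = FALSE)))
}

#' Write the merged counts matrix and presence flags as TSV
#'
#' @param matrix Data frame from [merge_species()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(matrix, path) {
  write.table(matrix, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Profile the immunome of an annotated transcript catalog
#'
#' The end-to-end grammar pipeline: candidate and accessory family
#' classification with completeness assessment and TMD subtyping, the
#' novelty screen for TIR-domain architectures, complement presence flags,
#' topology consistency warnings, and the per-species count report.
#'
#' @param catalog A `transcript_catalog`.
#' @param rules Rule set from [family_rules()].
#' @param masp_reference_ids Reference MASP subject ids (see
#'   [classify_other_immune()]).
#' @param n_terminal_fraction N-terminal window for TMD clustering.
#' @param known Known-architecture catalog for the novelty screen.
#' @return Object of class `immunome_profile` with elements `family_calls`,
#'   `novelty_calls`, `presence`, `topology_warnings`, `counts`.
#' @export
profile_immunome <- function(catalog, rules = family_rules(),
                             masp_reference_ids = character(),
                             n_terminal_fraction = 0.30,
                             known = known_architectures()) {
  fc <- classify_catalog(catalog, rules, masp_reference_ids, n_terminal_fraction)
  nc <- detect_novel(catalog, fc, rules, known)
  pres <- presence_flags(catalog)
  counts <- build_counts(fc, nc, catalog$species_label, pres)
  structure(list(species_label = catalog$species_label, family_calls = fc,
                 novelty_calls = nc, presence = pres,
                 topology_warnings = validate_topology(fc), counts = counts),
            class = "immunome_profile")
}

#' @export
print.immunome_profile <- function(x, ...) {
  cat(sprintf("immunome_profile: %s\n", x$species_label))
  cat(sprintf("  %d family calls (%d complete), %d novelty calls, %d topology warnings\n",
              nrow(x$family_calls),
              sum(x$family_calls$completeness == "complete"),
              nrow(x$novelty_calls), length(x$topology_warnings)))
  invisible(x)
}

#' @export
summary.immunome_profile <- function(object, ...) {
  print(object$counts)
  if (length(object$topology_warnings)) {
    cat("topology warnings:\n")
    for (w in object$topology_warnings) cat("  -", w, "\n")
  }
  invisible(object$counts)
}

#' One label per transcript from a profile
#'
#' Combines family and novelty calls into a single transcript -> label table
#' (candidate family, accessory family, or novelty pattern), the form
#' consumed by [score_recovery()].  Transcripts with several accessory calls
#' contribute one row per call.
#'
#' @param profile An `immunome_profile`.
#' @return Data frame with `transcript_id`, `label`, `completeness`.
#' @export
profile_labels <- function(profile) {
  f <- profile$family_calls
  n <- profile$novelty_calls
  rbind(
    data.frame(transcript_id = f$transcript_id, label = f$family,
               completeness = f$completeness, stringsAsFactors = FALSE),
    data.frame(transcript_id = n$transcript_id, label = n$pattern,
               completeness = NA_character_, stringsAsFactors = FALSE)
  )
}
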