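#' Read protein domain hits
#'
#' Parses per-residue protein domain annotations into a normalised hit table.
#' Two dialects are supported: a 7-column TSV
#' (`transcript_id, domain_name, family_accession, clan_accession, aa_start,
#' aa_end, e_value`) and HMMER's `domtblout` format (as written by
#' `hmmscan --domtblout`, where the target is the Pfam model and the query is
#' the translated ORF; envelope coordinates and the independent E-value are
#' used).  Coordinates are 1-based inclusive amino-acid envelope coordinates
#' throughout the package.
#'
#' `domtblout` carries no clan column, so clan accessions are filled from a
#' family-to-clan map (see [default_clan_map()]); unmapped families get an
#' empty clan.
#'
#' @param path Path to the hit table.
#' @param e_value_max Retain only hits with `e_value <= e_value_max`
#'   (default `1e-5`).
#' @param dialect `"tsv"` or `"domtblout"`.
#' @param clan_map Named character vector mapping Pfam family accessions to
#'   clan accessions, used for the `domtblout` dialect and to backfill empty
#'   clan fields in TSV input.
#' @return A data frame with columns `transcript_id`, `domain_name`,
#'   `family_accession`, `clan_accession`, `aa_start`, `aa_end`, `e_value`,
#'   in file order.
#' @export
read_domain_hits <- function(path, e_value_max = 1e-5,
                             dialect = c("tsv", "domtblout"),
                             clan_map = default_clan_map()) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln)) || startsWith(ln, "#")) next
    # tab-delimited rows may contain empty fields (e.g. no clan): split on
    # tabs exactly; whitespace-aligned rows use "-" for empty fields
    f <- if (grepl("\t", ln, fixed = TRUE)) strsplit(ln, "\t", fixed = TRUE)[[1]]
         else strsplit(trimws(ln), " +")[[1]]
    if (dialect == "tsv") {
      if (i == 1L && length(f) >= 7 && is.na(suppressWarnings(as.numeric(f[[5]]))))
        next  # header line
      if (length(f) < 7) stop_line(path, i, "expected 7 columns in domain TSV")
      row <- list(transcript_id = f[[1]], domain_name = f[[2]],
                  family_accession = f[[3]], clan_accession = f[[4]],
                  aa_start = suppressWarnings(as.integer(f[[5]])),
                  aa_end = suppressWarnings(as.integer(f[[6]])),
                  e_value = suppressWarnings(as.numeric(f[[7]])))
    } else {
      if (length(f) < 22) stop_line(path, i, "expected >= 22 columns in domtblout")
      row <- list(transcript_id = f[[4]], domain_name = f[[1]],
                  family_accession = sub("\\.\\d+$", "", f[[2]]),
                  clan_accession = "",
                  aa_start = suppressWarnings(as.integer(f[[20]])),
                  aa_end = suppressWarnings(as.integer(f[[21]])),
                  e_value = suppressWarnings(as.numeric(f[[13]])))
    }
    if (is.na(row$aa_start) || is.na(row$aa_end) || is.na(row$e_value))
      stop_line(path, i, "non-numeric coordinate or E-value")
    if (row$aa_start < 1L || row$aa_start > row$aa_end)
      stop_line(path, i, "invalid envelope coordinates (need 1 <= start <= end)")
    if (row$e_value < 0) stop_line(path, i, "negative E-value")
    if (nzchar(row$family_accession) && row$family_accession != "-" &&
        !grepl("^PF\\d{5}$", row$family_accession))
      stop_line(path, i, sprintf("malformed family accession '%s'", row$family_accession))
    if (row$family_accession == "-") row$family_accession <- ""
    if (row$clan_accession %in% c("-", "NA")) row$clan_accession <- ""
    if (nzchar(row$clan_accession) && !grepl("^CL\\d{4}$", row$clan_accession))
      stop_line(path, i, sprintf("malformed clan accession '%s'", row$clan_accession))
    rows[[i]] <- row
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_df(DOMAIN_COLS))
  df <- do.call(rbind.data.frame, c(rows, list(stringsAsFactors = FALSE)))
  # backfill clans from the family->clan map
  fill <- !nzchar(df$clan_accession) & df$family_accession %in% names(clan_map)
  df$clan_accession[fill] <- unname(clan_map[df$family_accession[fill]])
  df <- df[df$e_value <= e_value_max, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Default Pfam family-to-clan map
#'
#' A small map covering the families the architecture grammar cites, shipped
#' as `extdata/family_clans.tsv`.  Used to backfill clan accessions when the
#' input dialect (e.g. `domtblout`) does not carry them.
#'
#' @param path Optional path to a two-column TSV (`family_accession`,
#'   `clan_accession`); defaults to the shipped asset.
#' @return Named character vector, family accession -> clan accession.
#' @export
default_clan_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "family_clans.tsv", package = "cnidimmune")
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE, comment.char = "#")
  setNames(df$clan_accession, df$family_accession)
}

#' Read transmembrane-helix calls
#'
#' Accepts the one-line-per-protein TMHMM "short" format (segments taken from
#' the `Topology=` string when `PredHel > 0`), the TMHMM long format (rows
#' whose third column is `TMhelix`), or a plain 3-column TSV
#' (`transcript_id, aa_start, aa_end`).  Only transmembrane helix rows become
#' segments; per transcript, segments are sorted by start coordinate.
#' Overlapping segments on one transcript trigger a warning but are kept.
#'
#' @param path Path to the TMD call file.
#' @return A data frame with columns `transcript_id`, `aa_start`, `aa_end`.
#' @export
read_tmd_calls <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "[ \t]+")[[1]]
    if (any(grepl("^PredHel=", f))) {
      id <- f[[1]]
      nh <- as.integer(sub("^PredHel=", "", grep("^PredHel=", f, value = TRUE)[[1]]))
      if (nh == 0L) next
      topo <- sub("^Topology=", "", grep("^Topology=", f, value = TRUE)[[1]])
      m <- gregexpr("(\\d+)-(\\d+)", topo)[[1]]
      segs <- regmatches(topo, gregexpr("\\d+-\\d+", topo))[[1]]
      for (s in segs) {
        ab <- as.integer(strsplit(s, "-")[[1]])
        rows[[length(rows) + 1L]] <- list(transcript_id = id,
                                          aa_start = ab[[1]], aa_end = ab[[2]])
      }
    } else if (length(f) >= 5 && f[[3]] == "TMhelix") {
      rows[[length(rows) + 1L]] <- list(transcript_id = f[[1]],
                                        aa_start = as.integer(f[[4]]),
                                        aa_end = as.integer(f[[5]]))
    } else if (length(f) >= 3 && !is.na(suppressWarnings(as.integer(f[[2]])))) {
      rows[[length(rows) + 1L]] <- list(transcript_id = f[[1]],
                                        aa_start = as.integer(f[[2]]),
                                        aa_end = as.integer(f[[3]]))
    } else if (i == 1L) {
      next  # header of a TSV
    } else {
      stop_line(path, i, "unrecognised TMD row")
    }
  }
  if (!length(rows)) return(empty_df(TMD_COLS))
  df <- do.call(rbind.data.frame, c(rows, list(stringsAsFactors = FALSE)))
  if (any(df$aa_start > df$aa_end)) stop("TMD segment with start > end", call. = FALSE)
  df <- df[order(match(df$transcript_id, unique(df$transcript_id)), df$aa_start), ,
           drop = FALSE]
  rownames(df) <- NULL
  # overlap check per transcript
  for (id in unique(df$transcript_id)) {
    seg <- df[df$transcript_id == id, , drop = FALSE]
    if (nrow(seg) > 1L && any(seg$aa_start[-1L] <= seg$aa_end[-nrow(seg)]))
      warning(sprintf("overlapping TMD segments on '%s' kept as-is", id), call. = FALSE)
  }
  df
}

#' Read tabular homology hits (BLAST outfmt 6)
#'
#' Reads a 12-column BLAST tabular file (qseqid, sseqid, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore).  An
#' optional 13th column is taken as the subject species; otherwise the
#' species is captured from the subject identifier with `species_regex`
#' (underscores become spaces).  Hits above the E-value threshold are
#' dropped; remaining hits are ordered best-first (ascending E-value) within
#' each transcript, transcripts in order of first appearance.
#'
#' @param path Path to the tabular file; an empty file yields an empty table.
#' @param database_label Label recorded for every hit, e.g. `"swissprot"`.
#' @param e_value_max E-value threshold for retained hits (default `1e-5`).
#' @param query_level `"peptide"` (BLASTp-style) or `"nucleotide"`
#'   (BLASTx-style); the completeness rule requires a peptide-level hit.
#' @param species_regex Regex with one capture group applied to `sseqid`.
#' @return Data frame with columns `transcript_id`, `database_label`,
#'   `subject_id`, `subject_species`, `e_value`, `query_level`.
#' @export
read_homology <- function(path, database_label,
                          e_value_max = 1e-5,
                          query_level = c("peptide", "nucleotide"),
                          species_regex = "_([A-Z][A-Za-z]*_[a-z]+)$") {
  query_level <- match.arg(query_level)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) return(empty_df(HOMOLOGY_COLS))
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[[i]]), "\t| +")[[1]]
    if (length(f) < 12) stop_line(path, i, "expected >= 12 tabular columns")
    sp <- if (length(f) >= 13) gsub("_", " ", f[[13]]) else {
      m <- regmatches(f[[2]], regexec(species_regex, f[[2]]))[[1]]
      if (length(m) >= 2) gsub("_", " ", m[[2]]) else ""
    }
    ev <- suppressWarnings(as.numeric(f[[11]]))
    if (is.na(ev) || ev < 0) stop_line(path, i, "bad E-value")
    rows[[i]] <- list(transcript_id = f[[1]], database_label = database_label,
                      subject_id = f[[2]], subject_species = sp,
                      e_value = ev, query_level = query_level)
  }
  df <- do.call(rbind.data.frame, c(rows, list(stringsAsFactors = FALSE)))
  df <- df[df$e_value <= e_value_max, , drop = FALSE]
  df <- df[order(match(df$transcript_id, unique(df$transcript_id)), df$e_value), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read ORF records from peptide (and optional CDS) FASTA
#'
#' Headers may carry a TransDecoder-style completeness tag
#' (`type:complete`, `type:5prime_partial`, `type:3prime_partial`,
#' `type:internal`), which maps onto start/stop codon flags.  When no tag is
#' present, completeness is inferred from the peptide: a leading `M` implies
#' a start codon and a trailing `*` a stop codon.  A trailing `*` is stripped
#' from the stored peptide.  The ORF id is the first header token; the
#' transcript id is the ORF id with any trailing `.p<digits>` removed.
#'
#' @param pep_path Peptide FASTA path.
#' @param cds_path Optional coding-sequence FASTA with matching ids; each CDS
#'   must be `3 * peptide_length` long, or that plus a terminal stop codon.
#' @return Data frame with one row per ORF: `transcript_id`, `orf_id`,
#'   `peptide_length`, `has_start_codon`, `has_stop_codon`, `peptide`,
#'   `coding_sequence` (empty string when no CDS given).
#' @export
read_orfs <- function(pep_path, cds_path = NULL) {
  pep <- Biostrings::readAAStringSet(pep_path)
  heads <- names(pep)
  seqs <- as.character(pep)
  ids <- vapply(strsplit(heads, "[ \t]+"), `[[`, character(1), 1L)
  type <- rep(NA_character_, length(ids))
  m <- regmatches(heads, regexec("type:(complete|5prime_partial|3prime_partial|internal)", heads))
  for (i in seq_along(m)) if (length(m[[i]]) >= 2) type[[i]] <- m[[i]][[2]]
  has_stop_marker <- endsWith(seqs, "*")
  seqs <- sub("\\*$", "", seqs)
  has_start <- ifelse(is.na(type), startsWith(seqs, "M"),
                      type %in% c("complete", "3prime_partial"))
  has_stop <- ifelse(is.na(type), has_stop_marker,
                     type %in% c("complete", "5prime_partial"))
  cds <- setNames(rep("", length(ids)), ids)
  if (!is.null(cds_path)) {
    cs <- Biostrings::readDNAStringSet(cds_path)
    cids <- vapply(strsplit(names(cs), "[ \t]+"), `[[`, character(1), 1L)
    hit <- intersect(cids, ids)
    cds[hit] <- as.character(cs)[match(hit, cids)]
    bad <- hit[!(nchar(cds[hit]) == 3L * nchar(seqs[match(hit, ids)]) |
                 nchar(cds[hit]) == 3L * nchar(seqs[match(hit, ids)]) + 3L)]
    if (length(bad))
      stop(sprintf("CDS length inconsistent with peptide for: %s",
                   paste(head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(transcript_id = sub("\\.p\\d+$", "", ids), orf_id = ids,
                    peptide_length = unname(nchar(seqs)),
                    has_start_codon = unname(has_start),
                    has_stop_codon = unname(has_stop), peptide = unname(seqs),
                    coding_sequence = unname(cds), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Assemble a per-transcript annotation catalog
#'
#' Merges ORF records with domain hits, transmembrane segments and homology
#' hits into a `transcript_catalog`, the unit consumed by the architecture
#' grammar.  Every ORF yields exactly one annotated transcript; domain, TMD
#' or homology rows whose transcript has no ORF are dropped with one warning
#' reporting the orphan count.  Transcripts are grouped into genes by
#' stripping an assembler-style isoform suffix (default: a trailing
#' `_i<digits>`, the Trinity convention); transcripts that do not match the
#' pattern form their own gene group.
#'
#' @param orfs ORF table from [read_orfs()].
#' @param domains Domain-hit table from [read_domain_hits()] (or `NULL`).
#' @param tmds TMD table from [read_tmd_calls()] (or `NULL`).
#' @param homology A homology table from [read_homology()], or a list of such
#'   tables (one per database), or `NULL`.
#' @param species_label Species label stored in the catalog.
#' @param gene_group_regex Regex removed from `transcript_id` to obtain the
#'   gene group id.
#' @return An object of class `transcript_catalog`: a list with elements
#'   `species_label`, `orfs` (with an added `gene_group_id` column),
#'   `domains`, `tmds`, `homology`.
#' @export
assemble_annotations <- function(orfs, domains = NULL, tmds = NULL,
                                 homology = NULL, species_label = "unknown",
                                 gene_group_regex = "_i\\d+$") {
  stopifnot(is.data.frame(orfs), nrow(orfs) == 0 || all(nzchar(orfs$transcript_id)))
  if (anyDuplicated(orfs$orf_id))
    stop("duplicate orf_id in ORF table", call. = FALSE)
  if (anyDuplicated(orfs$transcript_id))
    stop("multiple ORFs per transcript are not supported; keep the primary ORF",
         call. = FALSE)
  orfs$gene_group_id <- sub(gene_group_regex, "", orfs$transcript_id)
  domains <- domains %||% empty_df(DOMAIN_COLS)
  tmds <- tmds %||% empty_df(TMD_COLS)
  if (is.list(homology) && !is.data.frame(homology))
    homology <- do.call(rbind, homology)
  homology <- homology %||% empty_df(HOMOLOGY_COLS)
  rownames(homology) <- NULL

  n_orphan <- 0L
  keep <- function(df) {
    ok <- df$transcript_id %in% orfs$transcript_id
    n_orphan <<- n_orphan + sum(!ok)
    df[ok, , drop = FALSE]
  }
  domains <- keep(domains); tmds <- keep(tmds); homology <- keep(homology)
  if (n_orphan > 0L)
    warning(sprintf("%d annotation rows without a matching ORF dropped", n_orphan),
            call. = FALSE)
  structure(list(species_label = species_label, orfs = orfs,
                 domains = domains, tmds = tmds, homology = homology),
            class = "transcript_catalog")
}

#' Extract one transcript's merged annotation
#'
#' @param catalog A `transcript_catalog`.
#' @param transcript_id Transcript to extract.
#' @return A list with `transcript_id`, `gene_group_id`, `species_label`,
#'   `orf` (one-row data frame), `domains`, `tmds`, `homology`.
#' @export
transcript_annotation <- function(catalog, transcript_id) {
  stopifnot(inherits(catalog, "transcript_catalog"))
  i <- match(transcript_id, catalog$orfs$transcript_id)
  if (is.na(i)) stop(sprintf("no ORF for transcript '%s'", transcript_id), call. = FALSE)
  list(transcript_id = transcript_id,
       gene_group_id = catalog$orfs$gene_group_id[[i]],
       species_label = catalog$species_label,
       orf = catalog$orfs[i, , drop = FALSE],
       domains = catalog$domains[catalog$domains$transcript_id == transcript_id, , drop = FALSE],
       tmds = catalog$tmds[catalog$tmds$transcript_id == transcript_id, , drop = FALSE],
       homology = catalog$homology[catalog$homology$transcript_id == transcript_id, , drop = FALSE])
}

#' @export
print.transcript_catalog <- function(x, ...) {
  cat(sprintf("transcript_catalog: %s\n", x$species_label))
  cat(sprintf("  %d transcripts (%d gene groups), %d domain hits, %d TMD segments, %d homology hits\n",
              nrow(x$orfs), length(unique(x$orfs$gene_group_id)),
              nrow(x$domains), nrow(x$tmds), nrow(x$homology)))
  invisible(x)
}

#' Write / read the canonical merged catalog
#'
#' The catalog round-trips through four TSV files plus a JSON metadata file
#' (`orfs.tsv`, `domains.tsv`, `tmds.tsv`, `homology.tsv`, `meta.json`).
#' Domain and TMD coordinates are written as 1-based inclusive amino-acid
#' positions.
#'
#' @param catalog A `transcript_catalog`.
#' @param dir Output (or input) directory.
#' @return `write_catalog` returns `dir` invisibly; `read_catalog` returns a
#'   `transcript_catalog`.
#' @export
write_catalog <- function(catalog, dir) {
  stopifnot(inherits(catalog, "transcript_catalog"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) write.table(df, file.path(dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  wr(catalog$orfs, "orfs.tsv"); wr(catalog$domains, "domains.tsv")
  wr(catalog$tmds, "tmds.tsv"); wr(catalog$homology, "homology.tsv")
  jsonlite::write_json(list(species_label = catalog$species_label),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(dir) {
  rd <- function(f, spec) {
    cls <- ifelse(spec == "double", "numeric", spec)
    df <- read.delim(file.path(dir, f), stringsAsFactors = FALSE,
                     colClasses = unname(cls))
    if (!nrow(df)) return(empty_df(spec))
    for (nm in names(df)) if (is.character(df[[nm]])) df[[nm]][is.na(df[[nm]])] <- ""
    df
  }
  orfs <- read.delim(file.path(dir, "orfs.tsv"), stringsAsFactors = FALSE,
                     colClasses = c("character", "character", "integer", "logical",
                                    "logical", "character", "character", "character"))
  orfs$coding_sequence[is.na(orfs$coding_sequence)] <- ""
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  assemble_annotations(orfs[names(orfs) != "gene_group_id"],
                       rd("domains.tsv", DOMAIN_COLS),
                       rd("tmds.tsv", TMD_COLS),
                       rd("homology.tsv", HOMOLOGY_COLS),
                       species_label = meta$species_label)
}
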