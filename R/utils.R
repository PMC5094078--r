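`%||%` <- function(a, b) if (is.null(a)) b else a

stop_line <- function(path, line, msg) {
  stop(sprintf("%s: line %d: %s", path, line, msg), call. = FALSE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

#' @importFrom utils read.delim write.table head tail
#' @importFrom stats setNames runif rbinom
NULL

empty_df <- function(spec) {
  # spec: named character vector of column modes
  as.data.frame(lapply(spec, function(m) vector(m, 0L)), stringsAsFactors = FALSE)
}

DOMAIN_COLS <- c(transcript_id = "character", domain_name = "character",
                 family_accession = "character", clan_accession = "character",
                 aa_start = "integer", aa_end = "integer", e_value = "double")

TMD_COLS <- c(transcript_id = "character", aa_start = "integer", aa_end = "integer")

HOMOLOGY_COLS <- c(transcript_id = "character", database_label = "character",
                   subject_id = "character", subject_species = "character",
                   e_value = "double", query_level = "character")

ORF_COLS <- c(transcript_id = "character", orf_id = "character",
              peptide_length = "integer", has_start_codon = "logical",
              has_stop_codon = "logical", peptide = "character",
              coding_sequence = "character")
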