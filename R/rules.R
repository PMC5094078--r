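#' Load the architecture-grammar rule set
#'
#' The grammar is data-driven: families, their required and optional domain
#' predicates, the TIR-equivalence set, candidate precedence and the
#' novelty-indicative domain list are read from a versioned YAML file.  The
#' shipped default (`extdata/family_rules.yaml`) encodes the published
#' identification rules for TLR, MyD88, IL-1R-like, NF-kB and NLR plus the
#' accessory lectin/complement families (CniFL, MASP, SRCR, C-type lectin).
#'
#' @param path Optional path to an alternative YAML rule file.
#' @return A list of class `family_rules`.
#' @export
family_rules <- function(path = NULL) {
  path <- path %||% system.file("extdata", "family_rules.yaml", package = "cnidimmune")
  r <- yaml::read_yaml(path)
  stopifnot(is.list(r$families), length(r$families) > 0)
  for (fam in names(r$families))
    if (!length(r$families[[fam]]$required))
      stop(sprintf("family '%s' has no required domains", fam), call. = FALSE)
  structure(r, class = "family_rules")
}

# logical vector: which hit rows satisfy a predicate
predicate_matches <- function(hits, pred) {
  if (!nrow(hits)) return(logical(0))
  hits$family_accession %in% (pred$accessions %||% character(0)) |
    hits$clan_accession %in% (pred$clans %||% character(0)) |
    hits$domain_name %in% (pred$names %||% character(0))
}

predicate_satisfied <- function(hits, pred) {
  sum(predicate_matches(hits, pred)) >= (pred$min %||% 1L)
}

# canonical accession -> display label for architecture signatures
DOMAIN_LABELS <- c(PF01582 = "TIR", PF13676 = "TIR_2", PF00531 = "DD",
                   PF00619 = "CARD", PF02758 = "PYD", PF01335 = "DED",
                   PF05729 = "NACHT", PF00554 = "RHD", PF00023 = "Ank",
                   PF12796 = "Ank", PF00069 = "Pkinase", PF07714 = "Pkinase_Tyr",
                   PF00071 = "Ras", PF08477 = "Miro", PF08699 = "Roc",
                   PF16095 = "COR", PF00018 = "SH3", PF00536 = "SAM",
                   PF00779 = "BTK", PF01391 = "Collagen", PF00147 = "Fibrinogen",
                   PF00095 = "WAP", PF00530 = "SRCR", PF00059 = "CTLD",
                   PF00431 = "CUB", PF07645 = "EGF_CA", PF00084 = "Sushi",
                   PF00089 = "Trypsin")

#' Canonical display labels for domain hits
#'
#' Maps each hit to the label used in architecture signatures and the known
#' architecture catalog: by family accession where the accession is one the
#' grammar knows, by clan for LRR (CL0022) and Ig (CL0011) repeats, else by
#' the reported domain name.
#'
#' @param hits Domain-hit data frame.
#' @return Character vector of labels, one per row.
#' @export
label_domains <- function(hits) {
  if (!nrow(hits)) return(character(0))
  lab <- unname(DOMAIN_LABELS[hits$family_accession])
  lab[is.na(lab) & hits$clan_accession == "CL0022"] <- "LRR"
  lab[is.na(lab) & hits$clan_accession == "CL0011"] <- "Ig"
  lab[is.na(lab)] <- hits$domain_name[is.na(lab)]
  lab[grepl("^LRR", lab)] <- "LRR"
  lab
}

tir_bearing <- function(hits, rules) {
  any(hits$family_accession %in% rules$tir_equivalence |
        hits$domain_name %in% c("TIR", "TIR_2"))
}

# the novelty screen also admits the TIR-like DUF1863, which stands in for
# TIR in the TIR-only class
tir_like_bearing <- function(hits, rules) {
  tir_bearing(hits, rules) || any(hits$domain_name %in% c("DUF1863", "TIR_like"))
}

has_novelty_extras <- function(hits, rules) {
  ni <- rules$novelty_indicative
  any(hits$family_accession %in% (ni$accessions %||% character(0)) |
        hits$domain_name %in% (ni$names %||% character(0)))
}
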