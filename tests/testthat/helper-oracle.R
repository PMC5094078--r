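# Independent brute-force oracles, deliberately implemented with different
# machinery than the package internals.

ORACLE_CODE <- as.list(Biostrings::GENETIC_CODE)
ORACLE_STOPS <- names(ORACLE_CODE)[unlist(ORACLE_CODE) == "*"]

oracle_is_ts <- function(x, y) {
  paste0(sort(c(x, y)), collapse = "") %in% c("AG", "CT")
}

# site counts for one codon: enumerate all 9 single-base mutants; a mutation
# is synonymous iff it preserves the amino acid and does not create a stop
oracle_sites <- function(codon) {
  b <- strsplit(codon, "")[[1]]
  syn <- 0
  for (pos in 1:3) {
    for (nb in setdiff(c("A", "C", "G", "T"), b[pos])) {
      mb <- b; mb[pos] <- nb
      mc <- paste(mb, collapse = "")
      if (!(mc %in% ORACLE_STOPS) && ORACLE_CODE[[mc]] == ORACLE_CODE[[codon]])
        syn <- syn + 1
    }
  }
  c(S = syn / 3, N = 3 - syn / 3)
}

# all orderings of a set of positions, by recursive enumeration
oracle_orderings <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in oracle_orderings(v[-i]))
      out <- c(out, list(c(v[i], rest)))
  out
}

# average syn/nonsyn differences over minimal pathways between two codons,
# excluding pathways that pass through a stop codon
oracle_diffs <- function(c1, c2) {
  b1 <- strsplit(c1, "")[[1]]; b2 <- strsplit(c2, "")[[1]]
  pos <- which(b1 != b2)
  if (!length(pos)) return(c(Sd = 0, Nd = 0))
  paths <- oracle_orderings(pos)
  tallies <- list()
  for (ord in paths) {
    cur <- b1; sd <- 0; nd <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur; nxt[p] <- b2[p]
      ccur <- paste(cur, collapse = ""); cnxt <- paste(nxt, collapse = "")
      if (cnxt %in% ORACLE_STOPS) { blocked <- TRUE; break }
      if (ORACLE_CODE[[cnxt]] == ORACLE_CODE[[ccur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (!blocked) tallies[[length(tallies) + 1]] <- c(sd, nd)
  }
  if (!length(tallies)) return(NULL)  # degenerate; not exercised by oracle tests
  m <- do.call(rbind, tallies)
  c(Sd = mean(m[, 1]), Nd = mean(m[, 2]))
}

# full NG86 quantities for an ungapped pair of equal-length coding sequences
oracle_ng86 <- function(s1, s2) {
  cod1 <- substring(s1, seq(1, nchar(s1), 3), seq(3, nchar(s1), 3))
  cod2 <- substring(s2, seq(1, nchar(s2), 3), seq(3, nchar(s2), 3))
  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  for (k in seq_along(cod1)) {
    st1 <- oracle_sites(cod1[k]); st2 <- oracle_sites(cod2[k])
    S <- S + (st1[["S"]] + st2[["S"]]) / 2
    N <- N + (st1[["N"]] + st2[["N"]]) / 2
    d <- oracle_diffs(cod1[k], cod2[k])
    Sd <- Sd + d[["Sd"]]; Nd <- Nd + d[["Nd"]]
  }
  list(S = S, N = N, Sd = Sd, Nd = Nd)
}

# independent rule matcher: tests every candidate rule against a transcript's
# domain multiset with hand-written conditions (used only on tiny catalogs)
oracle_classify <- function(doms) {
  acc <- doms$family_accession; clan <- doms$clan_accession; nm <- doms$domain_name
  tir <- any(acc %in% c("PF01582", "PF13676"))
  lrr <- any(clan == "CL0022" | nm == "LRR")
  ig <- any(clan == "CL0011")
  nacht <- any(nm == "NACHT" | acc == "PF05729")
  dd <- any(acc == "PF00531" | clan == "CL0041")
  rhd <- any(acc == "PF00554")
  ank <- any(acc %in% c("PF00023", "PF12796"))
  extras <- any(acc %in% c("PF00069", "PF07714", "PF00071", "PF08699", "PF16095",
                           "PF08477", "PF00018", "PF00536", "PF00779") |
                  nm %in% c("Pkinase", "Pkinase_Tyr", "Ras", "Roc", "COR", "Miro",
                            "SH3", "SAM", "BTK", "CBM"))
  if (tir && extras) return(NA_character_)
  if (nacht && lrr) return("NLR")
  if (tir && lrr) return("TLR")
  if (tir && ig) return("IL1R_like")
  if (tir && dd) return("MyD88")
  if (rhd && ank) return("NFKB")
  if (rhd) return("NFKB")   # RHD-only, reported as a partial call
  NA_character_
}
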