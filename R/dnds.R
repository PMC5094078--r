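STOP_CODONS <- c("TAA", "TAG", "TGA")

genetic_code <- function(code_id = 1L) {
  Biostrings::getGeneticCode(as.character(code_id))
}

split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Strip terminal stop codons and validate a codon alignment
#'
#' Prepares coding sequences for pairwise substitution-rate estimation:
#' sequences are uppercased, a terminal stop codon (TAA/TAG/TGA) is removed
#' from each, and the result is validated — every sequence must be a whole
#' number of codons, all sequences must have equal length, and internal stop
#' codons are an error (they signal a reading-frame problem, not data to be
#' patched).  Alignment gaps (`-`) are tolerated and the affected codons are
#' skipped downstream.
#'
#' @param seqs Named character vector of nucleotide sequences (or a
#'   `DNAStringSet`).
#' @param code_id NCBI genetic code table id (default 1, the standard code).
#' @return Object of class `codon_alignment`: list with `ids`, `seqs`
#'   (codon-trimmed strings), `n_codons`, `code_id`.
#' @export
strip_stops_and_validate <- function(seqs, code_id = 1L) {
  if (inherits(seqs, "DNAStringSet")) seqs <- setNames(as.character(seqs), names(seqs))
  stopifnot(length(seqs) >= 1)
  ids <- names(seqs) %||% paste0("seq", seq_along(seqs))
  seqs <- toupper(unname(seqs))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  for (i in seq_along(seqs)) {
    if (nchar(seqs[[i]]) %% 3L != 0L)
      stop(sprintf("'%s': length %d is not a whole number of codons",
                   ids[[i]], nchar(seqs[[i]])), call. = FALSE)
    cod <- split_codons(seqs[[i]])
    if (length(cod) && cod[[length(cod)]] %in% STOP_CODONS)
      cod <- cod[-length(cod)]
    internal <- which(cod %in% STOP_CODONS)
    if (length(internal))
      stop(sprintf("'%s': internal stop codon at codon %d (check the reading frame)",
                   ids[[i]], internal[[1]]), call. = FALSE)
    seqs[[i]] <- paste(cod, collapse = "")
  }
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences differ in codon count after stop stripping; align them first",
         call. = FALSE)
  structure(list(ids = ids, seqs = seqs, n_codons = nchar(seqs[[1]]) %/% 3L,
                 code_id = code_id),
            class = "codon_alignment")
}

#' Read a codon alignment from FASTA or sequential PHYLIP
#'
#' @param path Alignment file.
#' @param format `"auto"` (by extension/first byte), `"fasta"` or
#'   `"phylip"` (sequential).
#' @param code_id Genetic code table id.
#' @return A `codon_alignment` (stop-stripped and validated).
#' @export
read_codon_alignment <- function(path, format = c("auto", "fasta", "phylip"),
                                 code_id = 1L) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- substr(readLines(path, n = 1L), 1L, 1L)
    format <- if (first == ">") "fasta" else "phylip"
  }
  seqs <- if (format == "fasta") {
    x <- Biostrings::readBStringSet(path)
    setNames(as.character(x), sub("[ \t].*$", "", names(x)))
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    hdr <- as.integer(strsplit(trimws(lines[[1]]), "[ \t]+")[[1]])
    body <- lines[-1L]
    ids <- character(hdr[[1]]); out <- character(hdr[[1]])
    for (i in seq_len(hdr[[1]])) {
      f <- strsplit(trimws(body[[i]]), "[ \t]+")[[1]]
      ids[[i]] <- f[[1]]
      out[[i]] <- paste(f[-1L], collapse = "")
    }
    setNames(out, ids)
  }
  strip_stops_and_validate(seqs, code_id)
}

# per-codon NG86 site counts; weight transitions by kappa (kappa = 1 -> NG86).
# Changes creating a stop codon count as nonsynonymous, so every codon
# contributes exactly 3 sites.
codon_sites <- function(codon, code, kappa = 1) {
  bases <- c("A", "C", "G", "T")
  aa <- code[[codon]]
  s <- 0
  for (pos in 1:3) {
    b <- substr(codon, pos, pos)
    alts <- setdiff(bases, b)
    w <- ifelse(is_transition(b, alts), kappa, 1)
    syn <- vapply(alts, function(nb) {
      nc <- codon; substr(nc, pos, pos) <- nb
      !(nc %in% STOP_CODONS) && code[[nc]] == aa
    }, logical(1))
    s <- s + sum(w[syn]) / sum(w)
  }
  c(S = s, N = 3 - s)
}

is_transition <- function(a, b) {
  pur <- c("A", "G")
  (a %in% pur) == (b %in% pur)
}

PERMS <- list(`1` = list(1L),
              `2` = list(c(1L, 2L), c(2L, 1L)),
              `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                         c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

# average synonymous/nonsynonymous difference counts between two codons,
# averaging over minimal substitution pathways; pathways through stop codons
# are excluded (all pathways used if every one is blocked).  Pathways are
# weighted by kappa^(transitional steps) when kappa != 1.
codon_diffs <- function(c1, c2, code, kappa = 1) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(pos)
  if (nd == 0L) return(c(Sd = 0, Nd = 0))
  paths <- PERMS[[as.character(nd)]]
  res <- matrix(NA_real_, length(paths), 3L)  # sd, nd, weight
  for (k in seq_along(paths)) {
    cur <- c1; sd <- 0; ndf <- 0; w <- 1; ok <- TRUE
    for (p in pos[paths[[k]]]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (nxt %in% STOP_CODONS) { ok <- FALSE; break }
      if (is_transition(substr(cur, p, p), substr(nxt, p, p))) w <- w * kappa
      if (code[[nxt]] == code[[cur]]) sd <- sd + 1 else ndf <- ndf + 1
      cur <- nxt
    }
    if (ok) res[k, ] <- c(sd, ndf, w)
  }
  valid <- !is.na(res[, 1L])
  if (!any(valid)) {  # degenerate: every pathway passes through a stop
    return(codon_diffs_all_paths(c1, c2, code, kappa))
  }
  res <- res[valid, , drop = FALSE]
  w <- res[, 3L] / sum(res[, 3L])
  c(Sd = sum(res[, 1L] * w), Nd = sum(res[, 2L] * w))
}

codon_diffs_all_paths <- function(c1, c2, code, kappa) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  paths <- PERMS[[as.character(length(pos))]]
  acc <- matrix(0, length(paths), 3L)
  for (k in seq_along(paths)) {
    cur <- c1; sd <- 0; ndf <- 0; w <- 1
    for (p in pos[paths[[k]]]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (is_transition(substr(cur, p, p), substr(nxt, p, p))) w <- w * kappa
      syn <- !(cur %in% STOP_CODONS) && !(nxt %in% STOP_CODONS) &&
        code[[nxt]] == code[[cur]]
      if (syn) sd <- sd + 1 else ndf <- ndf + 1
      cur <- nxt
    }
    acc[k, ] <- c(sd, ndf, w)
  }
  w <- acc[, 3L] / sum(acc[, 3L])
  c(Sd = sum(acc[, 1L] * w), Nd = sum(acc[, 2L] * w))
}

jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

# delta-method SE of the Jukes-Cantor corrected proportion
jc_se <- function(p, n_sites) {
  if (is.na(p) || p >= 0.75 || n_sites <= 0) return(NA_real_)
  sqrt(p * (1 - p) / n_sites) / (1 - 4 * p / 3)
}

# K80 transition/transversion rate ratio from aligned nucleotide columns
estimate_kappa <- function(s1, s2) {
  b1 <- strsplit(s1, "")[[1]]; b2 <- strsplit(s2, "")[[1]]
  ok <- b1 %in% c("A", "C", "G", "T") & b2 %in% c("A", "C", "G", "T")
  b1 <- b1[ok]; b2 <- b2[ok]
  n <- length(b1)
  if (!n) return(2)
  diff <- b1 != b2
  P <- sum(diff & is_transition(b1, b2)) / n
  Q <- sum(diff & !is_transition(b1, b2)) / n
  a1 <- 1 - 2 * P - Q; a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0 || Q == 0) return(2)
  alpha <- -0.5 * log(a1) + 0.25 * log(a2)
  beta <- -0.25 * log(a2)
  k <- alpha / beta
  if (!is.finite(k) || k <= 0) 2 else k
}

#' Pairwise dN/dS over a codon alignment
#'
#' For every sequence pair, counts synonymous (S) and nonsynonymous (N)
#' sites by averaging per-codon site counts over the two sequences, and
#' synonymous (Sd) and nonsynonymous (Nd) differences by averaging over all
#' minimal substitution pathways between differing codons (pathways through
#' stop codons excluded).  Proportions are corrected for multiple hits with
#' the Jukes-Cantor-style formula `d = -3/4 log(1 - 4p/3)`; standard errors
#' come from the delta method.  Codons containing a gap or ambiguity in
#' either member of a pair are skipped.
#'
#' `method = "NG86"` is the unweighted estimator of Nei and Gojobori (1986).
#' `method = "YN00"` is a transition-bias-weighted approximation in the
#' spirit of Yang and Nielsen (2000): a kappa (transition/transversion rate
#' ratio) is estimated for each pair from the aligned nucleotides with K80
#' formulas, and both site counting and pathway weighting are
#' kappa-weighted.  Codon-frequency weighting is not implemented.
#'
#' @param aln A `codon_alignment` (>= 2 sequences).
#' @param method `"NG86"` or `"YN00"`.
#' @return Data frame of class `pairwise_dnds`, one row per unordered pair:
#'   `id_a`, `id_b`, `n_codons`, `N`, `S`, `Nd`, `Sd`, `pN`, `pS`, `dN`,
#'   `dS`, `se_dN`, `se_dS`, `omega`, `saturated`, plus attributes `method`
#'   and `kappa` (per pair, 1 for NG86).
#' @export
pairwise_dnds <- function(aln, method = c("NG86", "YN00")) {
  method <- match.arg(method)
  stopifnot(inherits(aln, "codon_alignment"))
  if (length(aln$seqs) < 2) stop("need at least two sequences", call. = FALSE)
  code <- genetic_code(aln$code_id)
  site_cache <- new.env(parent = emptyenv())
  rows <- list(); kappas <- numeric(0)
  n <- length(aln$seqs)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    kappa <- if (method == "YN00") estimate_kappa(aln$seqs[[i]], aln$seqs[[j]]) else 1
    key_suffix <- sprintf("|%.6f", kappa)
    cod1 <- split_codons(aln$seqs[[i]]); cod2 <- split_codons(aln$seqs[[j]])
    S <- 0; N <- 0; Sd <- 0; Nd <- 0; ncmp <- 0L
    for (k in seq_along(cod1)) {
      c1 <- cod1[[k]]; c2 <- cod2[[k]]
      if (grepl("[^ACGT]", c1) || grepl("[^ACGT]", c2)) next
      ncmp <- ncmp + 1L
      for (cd in c(c1, c2)) {
        key <- paste0(cd, key_suffix)
        if (is.null(site_cache[[key]])) site_cache[[key]] <- codon_sites(cd, code, kappa)
        sc <- site_cache[[key]]
        S <- S + sc[["S"]] / 2; N <- N + sc[["N"]] / 2
      }
      d <- codon_diffs(c1, c2, code, kappa)
      Sd <- Sd + d[["Sd"]]; Nd <- Nd + d[["Nd"]]
    }
    pS <- if (S > 0) Sd / S else NA_real_
    pN <- if (N > 0) Nd / N else NA_real_
    dS <- jc_correct(pS); dN <- jc_correct(pN)
    saturated <- (!is.na(pS) && pS >= 0.75) || (!is.na(pN) && pN >= 0.75)
    omega <- if (!is.na(dN) && !is.na(dS)) {
      if (dS > 0) dN / dS else if (dN > 0) Inf else NA_real_
    } else NA_real_
    rows[[length(rows) + 1L]] <- list(
      id_a = aln$ids[[i]], id_b = aln$ids[[j]], n_codons = ncmp,
      N = N, S = S, Nd = Nd, Sd = Sd, pN = pN, pS = pS,
      dN = dN, dS = dS, se_dN = jc_se(pN, N), se_dS = jc_se(pS, S),
      omega = omega, saturated = saturated)
    kappas <- c(kappas, kappa)
  }
  out <- do.call(rbind.data.frame, c(rows, list(stringsAsFactors = FALSE)))
  attr(out, "method") <- method
  attr(out, "kappa") <- kappas
  class(out) <- c("pairwise_dnds", "data.frame")
  out
}

#' Average pairwise rates into a per-gene dN/dS
#'
#' Averages dN, dS and their standard errors arithmetically over all
#' pairwise comparisons of a gene, and reports omega as the ratio of the
#' mean rates (`mean(dN) / mean(dS)`), *not* the mean of per-pair ratios —
#' and without propagating the standard errors into the ratio.  Pairs with
#' a saturated (undefined) correction are excluded with a warning.  When the
#' mean dS is zero while the mean dN is positive, omega is `Inf` and the
#' regime `"undefined"`; when both are zero omega is undefined.
#'
#' @param pairs A `pairwise_dnds` table.
#' @param gene_label Label stored in the result.
#' @param tol Neutrality tolerance passed to [classify_regime()].
#' @return Object of class `gene_dnds`: list with `gene_label`, `n_pairs`,
#'   `mean_dN`, `mean_dS`, `mean_se_dN`, `mean_se_dS`, `omega`, `regime`,
#'   `method`.
#' @export
gene_average <- function(pairs, gene_label = "gene", tol = 0.05) {
  stopifnot(nrow(pairs) >= 1)
  usable <- !pairs$saturated & !is.na(pairs$dN) & !is.na(pairs$dS)
  if (any(!usable))
    warning(sprintf("%d saturated/undefined pair(s) excluded from the average",
                    sum(!usable)), call. = FALSE)
  if (!any(usable))
    return(structure(list(gene_label = gene_label, n_pairs = 0L,
                          mean_dN = NA_real_, mean_dS = NA_real_,
                          mean_se_dN = NA_real_, mean_se_dS = NA_real_,
                          omega = NA_real_, regime = "undefined",
                          method = attr(pairs, "method") %||% "NG86"),
                     class = "gene_dnds"))
  p <- pairs[usable, , drop = FALSE]
  mean_dN <- mean(p$dN); mean_dS <- mean(p$dS)
  omega <- if (mean_dS > 0) mean_dN / mean_dS else if (mean_dN > 0) Inf else NA_real_
  regime <- if (is.finite(omega)) classify_regime(omega, tol) else "undefined"
  structure(list(gene_label = gene_label, n_pairs = nrow(p),
                 mean_dN = mean_dN, mean_dS = mean_dS,
                 mean_se_dN = mean(p$se_dN, na.rm = TRUE),
                 mean_se_dS = mean(p$se_dS, na.rm = TRUE),
                 omega = omega, regime = regime,
                 method = attr(pairs, "method") %||% "NG86"),
            class = "gene_dnds")
}

#' @export
print.gene_dnds <- function(x, ...) {
  cat(sprintf("%s (%s, %d pairs)\n", x$gene_label, x$method, x$n_pairs))
  cat(sprintf("  dN (+/-SE): %.4f (+/- %.4f)   dS (+/-SE): %.4f (+/- %.4f)\n",
              x$mean_dN, x$mean_se_dN, x$mean_dS, x$mean_se_dS))
  cat(sprintf("  dN/dS: %.4f  [%s]\n", x$omega, x$regime))
  invisible(x)
}

#' Classify the selection regime from omega
#'
#' Purifying selection when `omega < 1 - tol`, neutral when
#' `|omega - 1| <= tol`, positive when `omega > 1 + tol`.
#'
#' @param omega dN/dS ratio (finite).
#' @param tol Neutrality tolerance (default 0.05).
#' @return `"purifying"`, `"neutral"` or `"positive"`.
#' @export
classify_regime <- function(omega, tol = 0.05) {
  stopifnot(is.finite(omega), omega >= 0)
  if (omega < 1 - tol) "purifying"
  else if (omega > 1 + tol) "positive"
  else "neutral"
}

#' One-call per-gene dN/dS from an alignment
#'
#' Convenience wrapper: [pairwise_dnds()] then [gene_average()].
#'
#' @inheritParams pairwise_dnds
#' @inheritParams gene_average
#' @return A `gene_dnds`.
#' @export
dnds <- function(aln, method = c("NG86", "YN00"), gene_label = "gene", tol = 0.05) {
  gene_average(pairwise_dnds(aln, method), gene_label, tol)
}
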