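---
title: "Profiling actiniarian innate immune gene families: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling actiniarian innate immune gene families: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnidimmune)
```

## The problem

Anthozoans lack an adaptive immune system; their defence rests on innate
immune gene families whose members are recognised not by overall sequence
similarity but by *domain architecture* — the ordered combination of Pfam
domains along the peptide. In a de novo transcriptome this recognition is
complicated by isoform redundancy, truncated ORFs, annotation gaps, and
lineage-restricted genes with architectures absent from reference
databases. `cnidimmune` treats the problem in four stages: a
domain-architecture grammar, a novelty screen, table aggregation, and a
codon-level selection analysis. This vignette explains each stage's model
and assumptions, the parameters that matter, the numerical choices, and
what the synthetic validation does and does not demonstrate.

## The annotation catalog

The unit of analysis is a transcript with its merged evidence: one ORF
(peptide, optional CDS, start/stop flags), Pfam-style domain hits with
1-based inclusive amino-acid envelope coordinates, predicted
transmembrane helices, and homology hits labelled by database. Isoforms
are grouped into genes by stripping a trailing Trinity-style `_i<digits>`
suffix (configurable regex; unmatched ids form singleton groups). Gene
groups, not transcripts, are the units counted in the reports, because
published family counts refer to assembler genes while isoforms are
listed separately.

Two thresholds govern ingestion, both defaulting to `1e-5`: the homology
E-value cutoff (the conventional BLAST annotation threshold) and the
domain E-value cutoff. Domain significance thresholds are rarely reported
with annotation tables, so the domain cutoff mirrors the homology one and
is exposed as an argument. Clan accessions, which HMMER tabular output
does not carry, are backfilled from a small family→clan map shipped with
the package (`extdata/family_clans.tsv`).

## The architecture grammar

Each family rule is a set of domain predicates (match by Pfam family
accession, clan accession, or domain name; each with a minimum count),
stored in a versioned YAML file (`extdata/family_rules.yaml`) so the
grammar is data, not code. The candidate rules are:

| family | required | notes |
|---|---|---|
| NLR | NACHT + ≥1 LRR (CL0022) | N-terminal death-fold (CARD PF00619, PYD PF02758, DD PF00531, DED PF01335) recorded as subtype |
| TLR | TIR (PF01582 or TIR_2 PF13676) + ≥1 LRR | |
| IL-1R-like | TIR + ≥1 Ig (CL0011) | |
| MyD88 | TIR + death domain | DD matched by PF00531, with clan CL0041 as fallback since the source rule names no accession |
| NF-κB | RHD (PF00554) + ≥1 ankyrin (PF00023) | RHD without ankyrin ⇒ partial call, note `RHD-only`, never complete |

TIR and TIR_2 are interchangeable everywhere a rule says "TIR", but the
observed accession is kept in the evidence. When several rules match one
transcript the most specific co-domain wins: NLR > TLR > IL-1R-like >
MyD88 > NF-κB. This precedence is a design decision — the source rules
are silent on conflicts — chosen so that a NACHT+LRR+TIR transcript is an
NLR rather than a TLR, and a TIR+LRR+Ig transcript a TLR rather than an
IL-1R-like; conflicts of that kind do not arise in the synthetic
conditions and are rare in practice because the co-domains are distinct.

**Completeness.** A call is *complete* iff the ORF has both start and
stop codons, the peptide received at least one peptide-level homology
hit, and all the rule's required domains are present. Everything else is
*partial*. This makes the conservative counts robust to assembly
truncation at the cost of undercounting genuinely complete but
unannotatable genes.

**Membrane topology.** `detect_tmd_subtype()` marks a call
membrane-bound when ≥1 helix is predicted, and *N-terminally clustered*
when every helix midpoint lies within the first `n_terminal_fraction` of
the peptide. The default fraction is 0.30: the source description of
membrane NLRs says only "clustered at the N-terminus", and 3–5 helices
plus inter-helix loops occupy roughly the first quarter to third of a
typical ~450–600 aa NLR, so 0.30 accepts that layout while rejecting
C-terminal or dispersed helices. Expected topologies (TLR and IL-1R-like
membrane-bound; MyD88 and NF-κB cytosolic) are checked by
`validate_topology()`, which warns and never alters calls, since the
expectation is an empirical regularity, not part of the identification
rule.

**Accessory families.** CniFL requires Collagen (PF01391) + Ig +
Fibrinogen (PF00147), recording the Ig count, an optional WAP domain and
membrane binding. MASP requires the six-domain set CUB ×2, EGF-like
calcium-binding, Sushi ×2, Peptidase S1 *and* homology to a supplied
reference MASP; a `relax_masp` switch lowers the requirement to four of
the six slots because the source wording does not state a tolerance.
SRCR (PF00530) and C-type lectin (PF00059) are single-domain calls.
Complement components (C3, Factor B, C6, Factor I) have no domain rule
and are reported as presence/absence from homology subject-name patterns.

## The novelty screen

The screen asks a different question from the grammar: not "which known
family?" but "is this TIR-domain architecture known at all?". Candidates
are transcripts bearing TIR/TIR_2 (or the TIR-like DUF1863) whose
annotation status is `no_hits` or `nvectensis_only` — hits exclusively to
*N. vectensis* predicted proteins do not count as annotation because they
are themselves unvalidated predictions. Routing between grammar and
screen is exclusive and resolved by domain content: a TIR transcript
carrying novelty-indicative extras (Pkinase/Pkinase_Tyr, Ras/Roc/Miro
GTPase domains, COR, SH3, SAM, BTK, CBM) never receives a candidate call.
This is precisely what separates NG3 (kinase + DD + TIR) from MyD88
(DD + TIR), and NG1 (LRR + GTPase + TIR_2) from TLR (LRR + TIR).

Architecture signatures are the domain labels ordered by envelope start.
Overlapping hits that share a clan and overlap by more than half the
shorter envelope are collapsed to the lower E-value hit — motivated by
kinase domains, where Pkinase and Pkinase_Tyr models routinely fire on
the same region. Named patterns are then pure functions of the signature:
NG1 (LRR + ≥1 of Miro/Ras/Roc + TIR_2; COR recorded, not required, as its
reported position tolerance is unspecified), NG2 (1–2 TIR_2 strictly
upstream of a BTK motif, matched by name since no accession is given),
NG3 (kinase + DD + TIR/TIR_2), TIR-only (nothing immune-relevant beyond
TIR/TIR_2/DUF1863), else `unmatched_novel`. Finally each signature is
screened against a local known-architecture catalog
(`extdata/known_architectures.tsv`, a synthetic compilation standing in
for a live architecture-database query); matching is order-sensitive by
default because architectures are ordered, with an order-insensitive
option.

## Count tables

`build_counts()` implements the twin semantics of published family
tables: `n_complete_genes` counts gene groups with ≥1 complete call
(conservative), `n_total_genes` counts gene groups with ≥1 call of any
completeness (non-conservative, the assembler-gene count), and
`n_isoforms` counts transcripts. Candidate families are reported both
ways; accessory families are counted non-conservatively, matching how
the corresponding tables were built; complement families appear only as
flags. Deleting every partial transcript must leave `n_complete_genes`
unchanged and collapse totals onto it — an invariant the acceptance suite
checks over randomized configurations.

## Pairwise dN/dS

Codon alignments are validated before estimation: terminal stop codons
are stripped, and an *internal* stop is an error rather than data,
because it signals a frame problem that would corrupt every downstream
codon. Gapped or ambiguous codons are skipped pairwise.

The primary estimator is Nei–Gojobori (1986). Synonymous sites per codon
are the fraction of the nine single-base mutations that preserve the
amino acid, summed per position, so each codon contributes exactly three
sites; mutations that create a stop codon count as nonsynonymous, which
keeps that identity exact. Differences between codons are averaged over
all minimal substitution pathways (1, 2 or 6 orderings), excluding
pathways through stop codons with uniform weight on the remainder; in
the degenerate case where every pathway is blocked, all pathways are
used. Proportions are corrected with d = −(3/4)·ln(1 − 4p/3); p ≥ 3/4 is
flagged saturated and excluded from gene averages with a warning.
Standard errors use the delta method,
se(d) = sqrt(p(1−p)/L)/(1 − 4p/3).

Per-gene summaries average dN, dS and their SEs arithmetically over all
pairwise comparisons and report ω = mean dN / mean dS — the ratio of
means, not the mean of per-pair ratios, and without error propagation
into the ratio, matching the convention of the tables this mirrors. When
mean dS = 0 with mean dN > 0, ω is +Inf and the regime `undefined`; both
zero gives an undefined ω. The regime classifier uses a neutrality band
of ±0.05 around ω = 1 (configurable): point estimates essentially at 1
should not be labelled positive or purifying on noise alone.

The `YN00` method option approximates the Yang–Nielsen (2000) estimator
by weighting both site counting and pathway probabilities with a
transition/transversion ratio κ estimated per pair from K80 formulas.
Codon-frequency weighting and iterative κ estimation are not
implemented; the published analyses this mirrors used yn00 proper, and
the NG86 baseline is the method the package's own validation is anchored
to (it admits an exact brute-force oracle). The method used is recorded
in the output.

## The synthetic generator

`fixture_config()` defaults encode the study conditions the validation
runs under: nine families × three genes, 1–2 isoforms per gene, 30%
partial ORFs, 10% missing homology, one membrane NLR with 3–5 N-terminal
helices, ten decoys (2 × RHD-only, TIR-only, NG1, NG2, NG3), and
complement presence C3/Bf present, C6/If absent. Planted peptides are
concatenations of per-domain placeholder blocks whose coordinates drive
the domain table directly; inter-domain linkers are 3–12 residues
(2–4 within transmembrane clusters so that planted N-terminal helices
genuinely satisfy the 0.30 clustering window). Every byte of output is a
deterministic function of `(config, seed)`.

The codon-pair simulator draws a uniform sense-codon ancestor and applies
proposal events (transitions weighted κ = 2): synonymous changes are
accepted with probability 1 and nonsynonymous ones with probability ω,
so the realised rate ratio per site equals the target; stop-creating
proposals are rejected. The default 0.45 proposals per codon yields
dS ≈ 0.15–0.25, far from saturation. Validation at ω ∈ {0.1, 1.0}, 500
codons, 50 replicates recovers the mean ω within 25% relative error;
the residual downward bias at ω = 1 (≈ 0.83) is the textbook NG86
behaviour under transition bias, not a defect of the simulation.

**What passing these tests shows — and does not.** The generator
emulates the *annotation structure* of real data (architectures,
isoforms, partial ORFs, annotation gaps, decoys), not its sequence
statistics: placeholder peptides carry no real domain sequence, E-values
are synthetic, and domain callers' errors (missed repeats, split hits,
envelope slippage) are absent. Perfect recovery on fixtures therefore
demonstrates that the grammar, routing, counting and estimation logic
are correct under clean annotations; on real transcriptomes accuracy is
bounded by the upstream annotation quality, and published table numbers
additionally depend on database snapshots, so they are not reproduction
targets at desk scale.

## Problem sizes and runtime

The shipped validation uses the default fixture (~55 transcripts), 20
randomized table-semantics configurations, 10 membrane-NLR runs, 100
routing fixtures, 136 single-mutant codon pairs for the oracle check,
and 2 × 50 simulated 500-codon pairs — sizes chosen so the full suite
and the acceptance script each run in well under a minute on one CPU
while still exercising every rule and invariant.

## Known limitations

* One ORF per transcript; supply the primary TransDecoder ORF.
* The grammar does not model domain order within candidate families
  (order matters only in novelty signatures), nor repeat-count subtypes
  beyond what the rules state.
* MASP identification needs a user-supplied reference id set; without it
  no MASP is ever called.
* yn00's codon-frequency machinery, ML codon models, and tree-aware
  dN/dS are out of scope; alignments are inputs, not computed.
* The known-architecture catalog is a small local stand-in; real novelty
  claims should re-screen against a current architecture database.
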