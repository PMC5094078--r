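# Domain-architecture grammar for actiniarian innate immune gene families.
# A requirement is satisfied when at least `min` retained domain hits match
# any of its accessions, clans, or domain names.
version: 1
tir_equivalence: [PF01582, PF13676]
candidate_precedence: [NLR, TLR, IL1R_like, MyD88, NFKB]
novelty_indicative:
  names: [Pkinase, Pkinase_Tyr, Ras, Roc, COR, Miro, SH3, SAM, BTK, CBM]
  accessions: [PF00069, PF07714, PF00071, PF08699, PF16095, PF08477, PF00018, PF00536, PF00779]
families:
  NLR:
    kind: candidate
    required:
      - label: NACHT
        names: [NACHT]
        accessions: [PF05729]
        min: 1
      - label: LRR
        clans: [CL0022]
        names: [LRR]
        min: 1
    optional:
      - label: death_fold
        accessions: [PF00619, PF02758, PF00531, PF01335]
        min: 0
  TLR:
    kind: candidate
    required:
      - label: TIR
        accessions: [PF01582, PF13676]
        min: 1
      - label: LRR
        clans: [CL0022]
        names: [LRR]
        min: 1
  IL1R_like:
    kind: candidate
    required:
      - label: TIR
        accessions: [PF01582, PF13676]
        min: 1
      - label: Ig
        clans: [CL0011]
        names: [Ig, ig, I-set, V-set]
        min: 1
  MyD88:
    kind: candidate
    required:
      - label: TIR
        accessions: [PF01582, PF13676]
        min: 1
      - label: DD
        accessions: [PF00531]
        clans: [CL0041]
        names: [Death, DD]
        min: 1
  NFKB:
    kind: candidate
    required:
      - label: RHD
        accessions: [PF00554]
        names: [RHD, RHD_DNA_bind]
        min: 1
      - label: Ank
        accessions: [PF00023, PF12796]
        names: [Ank, Ankyrin]
        min: 1
  CniFL:
    kind: accessory
    required:
      - label: Collagen
        accessions: [PF01391]
        names: [Collagen]
        min: 1
      - label: Ig
        clans: [CL0011]
        names: [Ig, ig, I-set]
        min: 1
      - label: Fibrinogen
        accessions: [PF00147]
        names: [Fibrinogen_C]
        min: 1
    optional:
      - label: WAP
        accessions: [PF00095]
        names: [WAP]
        min: 0
  MASP:
    kind: accessory
    requires_reference_homology: true
    required:
      - label: CUB
        accessions: [PF00431]
        names: [CUB]
        min: 2
      - label: EGF_CA
        accessions: [PF07645]
        names: [EGF_CA, EGF-CA]
        min: 1
      - label: Sushi
        accessions: [PF00084]
        names: [Sushi]
        min: 2
      - label: Trypsin
        accessions: [PF00089]
        names: [Trypsin, Peptidase_S1]
        min: 1
  SRCR:
    kind: accessory
    required:
      - label: SRCR
        accessions: [PF00530]
        names: [SRCR]
        min: 1
  CTLD:
    kind: accessory
    required:
      - label: CTLD
        accessions: [PF00059]
        names: [Lectin_C, CTLD]
        min: 1
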