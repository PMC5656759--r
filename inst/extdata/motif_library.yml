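# Default motif library: consensus-style position patterns for the
# picorna-like non-structural domain triad (superfamily III helicase,
# 3C-like chymotrypsin-related protease, superfamily I RdRp).
# Patterns use regular-expression semantics over the 20-letter amino-acid
# alphabet; X never matches a character class. Curated patterns can
# replace these defaults without code changes: patterns are data.
#
# Hel-A/B/C are the Walker A / Walker B / C motifs of the SF3 helicase.
# Pro-cat is the chymotrypsin-like catalytic-site tetrapeptide G-x-[C/S]-G;
# Pro-H and Pro-D are the upstream catalytic-triad members, located by a
# windowed search rather than by these single-residue patterns.
# RdRp-I..VIII are the eight conserved polymerase motifs; motif VI (often
# called motif C) is the magnesium-coordinating [G/A/S]DD locus.
motifs:
  - motif_id: Hel-A
    domain: Hel
    pattern: "G..G.GK[ST]"
    required: true
  - motif_id: Hel-B
    domain: Hel
    pattern: "[ILMFV]{3}DD"
    required: true
  - motif_id: Hel-C
    domain: Hel
    pattern: "[ILMV]..N..[ST]"
    required: true
  - motif_id: Pro-H
    domain: Pro
    pattern: "H"
    required: false
  - motif_id: Pro-D
    domain: Pro
    pattern: "D"
    required: false
  - motif_id: Pro-cat
    domain: Pro
    pattern: "G.[CS]G"
    required: true
  - motif_id: RdRp-I
    domain: RdRp
    pattern: "K.[LIVM]..E"
    required: false
  - motif_id: RdRp-II
    domain: RdRp
    pattern: "[ST]G..[AG]T"
    required: false
  - motif_id: RdRp-III
    domain: RdRp
    pattern: "[DE]..DF..F"
    required: false
  - motif_id: RdRp-IV
    domain: RdRp
    pattern: "D.{4}D"
    required: true
  - motif_id: RdRp-V
    domain: RdRp
    pattern: "G.{3}[ST].{3}N"
    required: true
  - motif_id: RdRp-VI
    domain: RdRp
    pattern: "[A-Z]DD"
    required: true
  - motif_id: RdRp-VII
    domain: RdRp
    pattern: "FLK[RK]"
    required: false
  - motif_id: RdRp-VIII
    domain: RdRp
    pattern: "[DE][FY]{2}..[FW]"
    required: false
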