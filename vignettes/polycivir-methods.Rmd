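---
title: "Methods: annotating and classifying polycistronic picorna-like virus genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating and classifying polycistronic picorna-like virus genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polycivir)
```

## The biological problem

Polycipiviruses are polyadenylated, positive-sense RNA viruses of roughly
11–12 kb with a genome organization unlike any other characterized
picorna-like virus. The structural module is not a single polyprotein ORF
but four consecutive, closely spaced and often overlapping ORFs in the 5'
third of the genome (ORF1–ORF4, three of them encoding jelly-roll capsid
domains). An intergenic region of several hundred nucleotides follows,
then one long 3' ORF (ORF5) spanning roughly two thirds of the genome and
encoding the non-structural polyprotein: a superfamily III helicase (Hel),
a 3C-like chymotrypsin-related protease (Pro) and a superfamily I
RNA-dependent RNA polymerase (RdRp), in that order. Ant-associated members
carry an extra short gene, ORF2b, overlapping the 5' end of ORF2 in the +1
frame and encoding a small protein with a central transmembrane helix.

`polycivir` turns that description into a tested, reusable pipeline:

1. **Layout inference** (`find_orfs()`, `infer_layout()`,
   `detect_orf2b()`, `layout_stats()`) reconstructs the five-ORF
   architecture and its UTR/IGR statistics from a bare nucleotide
   sequence.
2. **Motif scanning** (`scan_motifs()`, `call_triad_variant()`,
   `call_motif6_variant()`, `hydropathy_profile()`/`predict_tm()`)
   verifies the Hel/Pro/RdRp complement on the ORF5 polypeptide and calls
   the protease-triad (GxSG vs GxCG) and RdRp motif-VI (GDD/ADD/SDD)
   variants.
3. **Homology and discovery** (`local_align()`, `search_panel()`,
   `rbh_filter()`) reimplements the reciprocal-best-hit retention rule
   used to mine transcriptome assemblies for new family members.
4. **Phylogenetics** (`pdistance_matrix()`, `nj_tree()`,
   `midpoint_root()`, `is_monophyletic()`) supports the clade-structure
   claims (family monophyly, genus clusters) at desk scale.
5. **Classification** (`assess_family()`, `assign_genus()`,
   `build_report()`) applies the family-membership criteria and the
   three-genus decision rules.
6. **Variant analysis** (`filter_snps()`, `classify_snp()`,
   `aggregate_counts()`, `coverage_windows()`) summarizes read-mapping
   pileups into coverage profiles and per-ORF synonymous/nonsynonymous
   tallies.
7. **Synthetic data** (`genome_spec()`, `generate_genome()`,
   `evolve_family()`, `generate_decoys()`, `simulate_pileup()`) produces
   seeded genomes, families, decoys and pileups with known ground truth so
   every other module is testable offline.

One coordinate convention holds everywhere: positions are 1-based and
inclusive, and every ORF includes its stop codon, matching the published
annotation table. RNA input (`U`) is silently normalized to the DNA
alphabet on read; missing table cells are represented as absent values,
never as zero.

## Layout inference

`find_orfs()` enumerates ATG-initiated, stop-terminated spans on the
forward strand (the family is positive-sense; reverse-complement deposits
are expected to be normalized at ingest). For each (frame, stop codon)
pair only the 5'-most ATG is kept, so nested same-frame starts collapse
onto the longest ORF. The default minimum length of 150 nt sits below the
smallest annotated gene in the family (the 210 nt ORF3a).

`infer_layout()` then proceeds in two steps:

* **ORF5** is the longest candidate whose polypeptide contains the Hel,
  Pro and RdRp motifs in order. If no candidate qualifies, the longest
  ORF is used and the layout is flagged (`orf5_motifs_found = FALSE`).
* **ORF1–ORF4** are chosen among the candidates upstream of ORF5 as the
  four-ORF chain maximizing total coding length, subject to every
  junction gap lying in `[-max_overlap, +max_gap]`. "Closely spaced" is
  quantified as gap ≤ 60 nt and overlap ≤ 20 nt, which covers every
  junction in the family's published table (the deepest printed overlap
  is 14 nt) while leaving room for unusual members; both bounds are
  arguments. One junction may exceed `max_gap` when a short ORF bridges
  it with compliant gaps on both sides — this reproduces the extra ORF3a
  observed between ORF2 and ORF3 in one assembly — and the bridge is
  reported with an `a` suffix. The chain search is a small dynamic
  program over the candidate list with deterministic tie-breaking
  (largest total length, then leftmost), so results are reproducible.

When no compliant chain exists the function does not throw: it returns a
layout with status `"not_polycipivirus_like"` carrying the partial
evidence, because "this genome is not a polycipivirus" is a result, not
an error. Reading-frame offsets are reported relative to ORF5 using the
display convention of the family's genome maps: `(start − ORF5.start)
mod 3` mapped to `{0 → 0, 1 → +1, 2 → −1}` (the published figures define
the labels but not the arithmetic; this mapping reproduces them).

The layout statistics apply the table arithmetic verbatim
(`utr5 = ORF1.start − 1`, `igr = ORF5.start − ORF4.end − 1`,
`utr3 = seq_len − ORF5.end`), and `infer_layout()` strips the poly(A)
tail internally so its output is invariant to the tail's presence or
length. A genuinely negative intergenic region (ORF4/ORF5 overlap) is an
error: it never occurs in the family and almost always indicates a
mis-specified ORF5 start.

`detect_orf2b()` encodes the observed geometry of the overlapping gene:
start within 120 nt of the ORF2 start (printed offsets range from 4 to
52 nt), `+1` frame relative to ORF2 (`(start − ORF2.start) mod 3 == 1`),
length at least 200 nt, ending within 60 nt of the ORF2 end, and a
predicted central transmembrane helix. The TM predictor is a
Kyte–Doolittle sliding window (width 19, threshold 1.6 — the standard
defaults), with "central" quantified as the window center falling in the
middle half (25–75%) of the peptide. This is a deliberate, transparent
hydropathy criterion standing in for an HMM-based topology predictor; it
is exactly reproducible and sufficient for the family's strongly
hydrophobic ORF2b cores, but it is not a general-purpose TM topology
model.

## Motif scanning

The motif library is data, not logic: a YAML file of
`motif_id / domain / pattern / required` records
(`inst/extdata/motif_library.yml`), so curated patterns can replace the
defaults without code changes. The shipped defaults encode
consensus-style patterns for the picorna-like complement: Walker A
(`G..G.GK[ST]`), Walker B (hydrophobic run + `DD`), an N-containing
helicase C motif, the protease catalytic site `G.[CS]G`, and the eight
polymerase motifs with the magnesium-coordinating motif VI as `[A-Z]DD`.
Patterns use regular-expression semantics over amino-acid classes; `X`
and gap characters never match any class (conservative on partial
translations), implemented by masking unknowns and compiling `.` into
`[A-Z]`.

Because several of these patterns are short, a naive "leftmost match"
rule would bind motif VI to any chance acidic pair. `scan_motifs()`
therefore assigns loci left to right: helicase motifs by leftmost match,
the protease site as the first occurrence downstream of the helicase
region, the required polymerase motifs left to right downstream of the
protease site, and motif VI downstream of motif V specifically.
`ordered_ok` is `TRUE` exactly when this assignment succeeds — which is
also the domain-order criterion (Hel < Pro < RdRp) used by the family
assessment. The triad call searches `G.[CS]G` in the inter-domain
interval when both flanks were found (whole peptide otherwise) and
reports the upstream catalytic H and D within a configurable 200-residue
window; the window is a default flagged in the output, because the exact
triad spacing is not conserved across the order.

## Homology and the discovery filter

Pairwise alignment uses affine-gap Smith–Waterman / Needleman–Wunsch
optima under BLOSUM62 with gap open 11 / extend 1 (protein-BLAST
defaults; a gap of length L costs `11 + L`). Percent identity divides
identities by **all** alignment columns, gaps included; this convention
is stated in the result object because published identity values rarely
say which denominator they used — the package attaches a tolerance to
any comparison against printed identities rather than pretending the
convention is known.

The E-value is the Karlin–Altschul closed form `K·m·n·exp(−λ·score)`
with fixed gapped-BLOSUM62 constants (λ = 0.267, K = 0.041). It is a
thresholding device for the discovery filter, not a calibrated
statistic, and is documented as such.

`rbh_filter()` reimplements the retention rule used on transcriptome
contigs: candidates shorter than 10 kb are dropped (`too_short`); the
candidate's longest-ORF peptide is searched against a user-supplied
panel, and a best hit outside the reference set discards the candidate
(`wrong_best_target` — the fate of contigs matching iflavirus or
dicistrovirus entries); the forward hit must clear E-value ≤ 1e-6 and
≥ 300 nt of aligned coding sequence; finally the best panel member
searches back against the candidates plus the rest of the panel, and the
candidate is retained only when every entry ranked above it is a
reference. The panel is always an explicit input — the original search
target was a public database whose composition changes over time, so
nothing is downloaded implicitly. Ranking uses score-only alignments
(with the full alignment computed for the best hit), which keeps the
filter fast without changing any verdict.

## Phylogenetics at desk scale

Bayesian MCMC inference is the field's standard for publishable virus
trees. The claim this package exercises is clade structure — the family
is monophyletic against outgroups, and the genera form clades — and for
that purpose a deterministic distance method is sufficient and
reproducible byte-for-byte. `pdistance_matrix()` computes raw p-distances
(`1 − identity/100`) from global alignments, with no Poisson or Gamma
correction (documented; correction hooks can be added by transforming
the matrix before `nj_tree()`). An optional residue window restricts the
comparison to a conserved region — the monophyly tests use a window
around the polymerase motifs, the analogue of aligning the "core RdRp"
region rather than full polyproteins. Neighbor joining, midpoint rooting
and monophyly testing follow the standard algorithms; negative NJ branch
lengths are clamped to zero with the deficit recorded as an attribute.
Posterior probabilities and bootstrap support are out of scope.

## Classification

`assess_family()` requires (a) the ORF1–ORF5 chain with compliant
junctions, (b) the ordered Hel/Pro/RdRp complement on ORF5, and (c) an
ORF5 spanning at least half the genome (a conservative quantification of
"a single long ORF covering the 3' two thirds"). Partial genomes fail
with evidence naming the untestable criteria.

`assign_genus()` is a decision tree distilled from the genus
descriptions: ORF2b present → Sopolycivirus; otherwise motif VI = ADD →
Chipolycivirus; otherwise Hupolycivirus. The published delineation is
ultimately phylogenetic, so a rooted tree with labelled reference clades
can be supplied for cross-checking — a conflict is flagged in the
evidence but the rule verdict stands, keeping classification runnable
without a tree. `classify_table_rows()` applies the same rules to the
curated annotation table, where family membership is curated fact and
the motif variants come from a packaged transcription; `build_report()`
emits the table-shaped per-genome report (sequences are counted
individually; a species column carries the two-sequences-one-species
case).

## Variant analysis

Read mapping itself is out of scope: the pileup TSV
(`genome_id, pos, depth, countA..countT`) is the contract, produced by
`simulate_pileup()` or converted from any mapper. `filter_snps()` applies
a strict threshold (alternative fraction **greater than** 0.10 by
default, matching a "present in more than 10% of reads" rule).
`classify_snp()` reads the affected codon in each containing main ORF's
frame; a SNP inside an ORF–ORF overlap yields one call per ORF, because
per-ORF tallies imply per-ORF accounting. Stop gains and losses are
labelled `stop_affecting` rather than folded into nonsynonymous. Calls
against the double-coding accessory genes (ORF2b/ORF3a) are tallied
separately and never enter the main per-ORF totals, since it is unstated
whether published tallies included them. `coverage_windows()` is a
centered 1000-nt sliding mean truncated at the genome ends;
`mean_coverage()` divides total mapped depth by genome length.

## The synthetic-data generator

The generator exists so that every claim above is testable with no
downloads, against ground truth known by construction. Its defaults are
the family's published conditions: 5' UTR 130–370 nt, IGR 336–768 nt,
3' UTR 385–479 nt, ORF lengths and junction gaps drawn from the span of
the curated table, ORF2b offsets 4–52 nt, a 30 nt poly(A) tail, and the
`UUU` + AU-rich 5'-completeness signature.

Construction is codon-wise with rejection, never free sampling followed
by hope:

* **Overlap junctions** are solved first as isolated constraint windows:
  a handful of bases is rejection-sampled so the upstream frame reads
  sense codons then its stop while the downstream frame reads ATG then
  sense codons. Windows of different junctions never touch (overlaps are
  tens of nt, ORFs hundreds), so each is solved independently and locked.
* **ORF5** is assembled from a blueprint: filler spacers around planted
  motif instances at known residue offsets, with the spec'd triad and
  motif-VI variants. Spacer residues are drawn from a 16-letter alphabet
  excluding D, N, C and S — every required motif pattern needs at least
  one of those residues, so the planted instances are provably the only
  required-motif matches and the scan anchors land on them
  deterministically. This makes the spacers compositionally artificial;
  the package documents it rather than hiding it, and it is one of the
  listed ways synthetic data differ from real polyproteins.
* **ORF2b** is written into ORF2 in the +1 frame with per-codon
  rejection keeping ORF2's frame stop-free, and a 21-residue core drawn
  from {I, L, V, F} (window-19 Kyte–Doolittle mean ≥ 2.8, safely above
  the 1.6 threshold) — or from charged residues when the spec asks for a
  scrambled-core negative control.
* **Guard stop codons** are planted a few nt upstream of every ORF start
  in that ORF's frame (resampling flanking codons of another gene's body
  where necessary, preserving that frame), so no upstream in-frame ATG
  can extend a planted ORF and `find_orfs()` recovers every planted
  start exactly. The genome never ends in `A`, so the appended poly(A)
  tail is exactly recoverable.
* **Post-hoc verification with bounded rerolls**: the built sequence is
  checked with the independently tested primitives (`find_orfs()`,
  `scan_motifs()`, `hydropathy_profile()`) — planted coordinates present
  exactly, no unplanned ORF as long as the shortest planted main ORF,
  variants and anchors at the planted offsets, signature flag honored.
  On failure the genome is rebuilt from the continuing seeded stream (up
  to 60 attempts). The verification deliberately does **not** call
  `infer_layout()` or `detect_orf2b()`: those are the functions whose
  round-trip behaviour the generator exists to test, and using them here
  would make the round-trip tests circular.

`evolve_family()` applies Poisson numbers of substitutions along the
edges of a random (or given) tree, rejecting proposals that would create
an in-frame stop or touch a locked feature (start/stop codons, motif
blocks, ORF2b, the signature), so every leaf retains the planted
architecture. `generate_decoys()` builds dicistrovirus-style two-ORF
genomes whose motif blocks are *different instances of the same
patterns* — a decoy shares the family's generic motif complement but not
its exact sequences, as a real out-of-family virus would — plus
mononucleotide shuffles and uniform-random sequences.
`simulate_pileup()` is Poisson depth with Binomial alternative counts at
planted SNP positions and no read-error model. All generators are pure
functions of (spec, seed).

### What passing tests do and do not show

Synthetic genomes have uniform-random codon usage, spacers over a reduced
alphabet, substitution-only evolution (no indels, no rate heterogeneity,
no recombination), and pileups without sequencing error or strand bias.
Tests passing on them demonstrate that the algorithms implement their
stated rules exactly (coordinate recovery, variant calls, filter
verdicts, clade recovery), not that the pipeline is robust to assembly
artifacts, frameshift errors, or deeply diverged real sequences — on
real data the configurable thresholds (`max_gap`, `max_overlap`, motif
patterns, TM threshold) are the knobs a user should revisit.

## Numerical and design choices

* Deterministic tie-breaking everywhere: chain selection prefers larger
  total coding length then leftmost starts; panel ranking orders by
  score, then identity, then subject id; NJ and the generators are pure
  functions of their seeds.
* ORFs are ATG-initiated (the published coordinates are consistent with
  ATG starts); stop-to-stop enumeration is not used.
* The motif-VI locus is anchored on the motif-V hit (first `[A-Z]DD`
  downstream of it) rather than "rightmost overall", because anchoring
  is what keeps a 3-residue pattern off chance acidic pairs; when motif
  V is absent the rightmost helicase-downstream occurrence is used.
* Degenerate inputs return empty results or flagged layouts rather than
  errors wherever "absence" is a scientific answer (no ORFs, no motifs,
  not family-like); errors are reserved for contract violations
  (counts above depth, alt equal to ref, non-symmetric matrices,
  malformed files).
* Problem sizes in the shipped tests — 100 seeded specs per genus for
  the round-trip property, 50 seeds for the discovery filter, 100
  12-leaf families against 3 outgroups for monophyly, 50 additive
  matrices of 4–12 taxa, the exhaustive 576-case codon oracle — were
  chosen to exercise the stated properties at the family's own genome
  scale while keeping a full run on one CPU in the tens of minutes.

## A worked example

```{r example, eval = FALSE}
library(polycivir)

# a seeded family-like genome with known ground truth
g <- generate_genome(sample_genome_spec(1, "Sopolycivirus"))
out <- classify_genome(g$record)
out$layout
out$classification

# the curated family table
rows <- read_layout_table()
layout_stats(rows[["SINV-2"]])

# coverage and SNPs from a simulated pileup
sim <- simulate_pileup(strip_polya(g$record), mean_depth = 500,
                       snps = data.frame(pos = 5000L, alt = "A",
                                         freq = 0.25),
                       seed = 2)
snps <- filter_snps(sim$pileup, strip_polya(g$record))
aggregate_counts(classify_snps(snps, out$layout, strip_polya(g$record)$seq))
```

## Known limitations

* Negative-strand genes, splicing, frameshifts and circular genomes are
  out of scope; the layout model is strictly forward-strand and linear.
* The hydropathy TM criterion is not a topology model; borderline ORF2b
  candidates in real data deserve a dedicated predictor.
* The E-value is uncalibrated; use it only as the discovery filter's
  threshold, with the defaults that mirror the original procedure.
* p-distances saturate for deeply diverged proteins; the NJ stand-in is
  for clade-structure checks, not for publishable phylogenies.
* Peptides containing `X` are handled conservatively (never matching a
  motif class), which can under-call motifs on partial translations.
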