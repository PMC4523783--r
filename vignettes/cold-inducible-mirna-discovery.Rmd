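---
title: "Discovering cold-inducible miRNAs from two small RNA libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering cold-inducible miRNAs from two small RNA libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldmiR)
```

## The analysis this package implements

`coldmiR` re-implements, as a tested and reusable workflow, the classic
replicate-free two-library design used to find cold-inducible microRNAs in
grapevine: one small-RNA library from control plantlets (NCT, 25°C) and one
from cold-treated plantlets (CT, 4°C for 4 h) are deep-sequenced, and every
inference — which miRNAs exist, which respond to cold, and what they cleave —
is drawn from the comparison of these two read sets. The chain is:

1. **Tag processing** — adapter trimming, quality and length filtering
   (18–30 nt), and collapsing of clean reads into unique tags with
   per-library counts.
2. **Annotation triage** — exact-match mapping to the genome on both strands
   and classification into rRNA/tRNA/snRNA/snoRNA/scRNA, repeat, exonic,
   intronic, miRNA-candidate and unannotated classes; ncRNA matches are
   excluded from all miRNA analyses.
3. **Known miRNA identification** — matching candidate tags against a mature
   miRNA reference with at most two mismatches, with family-level read
   aggregation.
4. **Novel miRNA discovery** — excision of precursor windows around
   unannotated tag clusters, RNA secondary-structure folding, location of the
   miRNA/miRNA\* duplex, and a ten-rule plant-miRNA precursor check.
5. **Differential expression** — TPM normalisation, zero-count substitution,
   a low-expression filter, log2 fold-change and an exact two-library count
   test; classification into up/down/unchanged.
6. **Targets** — plant-style complementarity scoring over transcripts,
   summarisation of 5'-RACE cleavage clones, and Pearson anti-correlation of
   miRNA and target expression time series.

A synthetic-data module generates a toy genome with planted miRNA hairpins,
ncRNA contaminants and two simulated libraries with full ground truth, so
that every stage can be validated by parameter recovery.

## Statistical model for two libraries without replicates

With a single library per condition there is no biological dispersion
estimate; the test is on the counts themselves. For a miRNA with `x` reads
among `N1` clean reads in NCT and `y` among `N2` in CT, the count in the
second library conditional on the first follows

$$p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
\frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}},$$

i.e. $y \mid x \sim \mathrm{NegBin}(x+1,\ N_1/(N_1+N_2))$, the exact
two-library test of Audic and Claverie. Tails are evaluated in log space
through the negative-binomial CDF, so library-scale counts never overflow.

**Two-sided rule.** The package doubles the smaller of the two *directional
enrichment* tails, each under its own conditioning:
$p = \min\{1,\ 2\min(P(Y \ge y \mid x),\ P(X \ge x \mid y))\}$.
Doubling the lower/upper tails of a single conditional is not invariant
under exchanging the libraries (conditioning on `x` and on `y` give
different laws); the directional form restores exact exchange symmetry,
which we regard as a requirement for a test whose two libraries have no
privileged order. A two-proportion z-test is available as an alternative
(`method = "two-proportion"`).

**Expression thresholds.** TPM = count / clean reads × 10⁶. A zero count is
substituted by exactly 0.01 TPM so that fold-changes of library-exclusive
miRNAs are finite; miRNAs below 10 TPM in *both* libraries are neglected
(`filtered_low`). Fold-change is log₂(CT/NCT); a miRNA is up (down) if
FC > 1 (< −1) with p ≤ 0.001. Classification always uses unrounded
fold-changes: several published borderline rows (printed FC −1.00) pass the
strict threshold only on the unrounded value, and reproducing the published
up/down tally (11 and 33 after expanding fused family labels) depends on it.
No multiple-testing correction enters classification, matching the original
design; a Benjamini–Hochberg column is emitted for reference.

**A note on the bundled reference table.** The published DEM table shipped in
`inst/extdata/` contains one internally inconsistent row: `novel_mir_27`'s
printed fold-change (−13.89) corresponds to twice its printed NCT-TPM. The
row is retained for classification (its recomputed FC is −12.89, still
below −1) but excluded from fold-change agreement summaries.

## The ten-rule precursor check

Novel miRNAs are accepted only if the excised, folded precursor satisfies
all of: mature length 18–25 nt (1) and 20–23 nt on the reference (2); at
most 20 genomic copies (3); MFE ≤ −18 kcal/mol (4); ≤ 30 nt between miRNA
and miRNA\* (5); ≥ 16 duplex base pairs (6); largest bulge ≤ 4 (7); duplex
asymmetry ≤ 4 (8); 20-nt precursor flanks (9); and ≥ 50 reads on the
precursor in at least one library (10).

Design interpretations, where the rule set under-specifies:

* Rules (1) and (2) are both length rules whose distinction ("miRNA
  sequence" vs "miRNA reference sequence") is ambiguous; both are checked as
  written, which makes 20–23 nt the effective band.
* Rule (10) is stated both as "more than 50" and as "less than 50 …
  neglected"; the package reconciles these as ≥ 50, configurable.
* The duplex bulge is the longest run of consecutive unpaired bases on
  either strand of the duplex; asymmetry is the absolute difference of the
  two strands' unpaired counts. The miRNA\* is the segment pairing the
  mature in the dot-bracket structure, reported with the canonical 2-nt 3'
  overhang.
* Candidate windows are excised with 20-nt flanks around the tag cluster,
  once with the tag as 5' arm and once as 3' arm; overlapping accepted
  windows merge, keeping the lowest-MFE candidate. Clusters carrying fewer
  than 50 reads in total are screened out before folding — they can never
  satisfy rule (10), so this is purely a speedup.

**Folding backends.** Folding is a pluggable contract
(sequences → dot-bracket + energy). The default backend shells out to the
thermodynamic RNAfold program when it is on the PATH. A bundled pure-R
Nussinov-style maximum-pairing backend with a stacking-weighted energy
surrogate (GC 3, AU 2, GU 1; energy −0.9 per unit) is provided for
environments without it; it reproduces hairpin topology but its energies are
not thermodynamic, and MFE-based claims in the test suite are made with the
thermodynamic backend. The criteria logic is backend-independent by
construction: identical (structure, MFE) inputs give identical reports.

## Tag processing and matching conventions

* "Low quality" is pinned to mean Phred < 20 or any N call — the original
  protocol does not define it; both cutoffs are configurable.
* Adapter search is a deterministic exact match: the leftmost occurrence of
  a ≥ 6-nt prefix of the 3' adapter. Untrimmed reads within 18–30 nt are
  kept, as they may be full-length inserts.
* Genome mapping is exact (zero mismatches) on both strands, the
  conservative equivalent of `soap -v 0`; ncRNA exclusion is exact substring
  matching rather than BLAST, for determinism.
* Category priority is fixed as rRNA > tRNA > snRNA > snoRNA > scRNA >
  miRNA candidate > repeat > exon_sense > exon_antisense > intron_sense >
  intron_antisense > unannotated; the original category list names no
  precedence, and ncRNA-first follows its exclusion rule. Tags above the
  20-copy cap are flagged repeat-like and barred from candidacy.
* Known matching allows ≤ 2 mismatches over an ungapped alignment with ≤ 2 nt
  of end overhang or truncation (end offsets are capped but not counted as
  mismatches) — short-word BLAST behaves essentially this way at these
  lengths. Ties resolve to the fewest mismatches; residual ties are kept as
  *shared* assignments, mirroring fused labels such as `vvi-miR398b/c`.
  Family totals count each tag once per family. Only tags identical to an
  annotated mature feed differential expression; end/sequence variants
  (isomiRs) are listed separately.
* The TPM denominator is the library's total clean reads (the alternative,
  mapped reads, is configurable); published candidate-miRNA TPMs are
  consistent with library-scale totals.

## Target scoring and cleavage summaries

Complementarity scoring uses the plant penalty scheme: match 0, G:U 0.5,
mismatch 1, gap 2, doubled at miRNA positions 2–13; sites at or below score
3.0 (the psRNATarget-era default expectation) are reported over CDS and UTR
alike. The scanner is an exhaustive ungapped sliding window; gapped duplexes
(at most one gap) are scored when given as explicit alignments, e.g. when
reproducing published duplex diagrams. The expected cleavage position is the
transcript nucleotide opposite miRNA position 10; RACE clone 5' ends are
summarised as fractions by miRNA-relative offset. miRNA–target
anti-correlation uses the Pearson coefficient with a two-sided t-based
p-value on the shared timepoint grid (0, 2, 4, 8, 24, 48 h, all series
normalised to 1 at 0 h).

The qPCR validation patterns are formalised as four rule-based groups
applied in the order II, III, IV, I (most to least specific): II = above
control at 2 h, lower by 8 h, mean stress-period expression < 1;
III = early peak at 2–4 h above control, declining afterwards with stress
mean > 1; IV = repressed through 8 h but ≥ 2-fold induced at 48 h;
I = minimum at 4 or 8 h with stress mean < 1. Flat series are
`unclassified`. These boundaries are this package's formalisation of a
verbal description and are configurable in spirit: the classifier is a
single pure function.

## What the synthetic generator emulates — and what it does not

`build_genome()` plants, into a random background genome, (i) known-family
hairpins whose matures are emitted as the known-miRNA reference, (ii) novel
hairpins, and (iii) rRNA/tRNA/snRNA/snoRNA/repeat loci. Every novel hairpin
is verified *in situ*: the discovery-shaped window around the planted mature
is excised, folded and required to pass all ten criteria, with failing draws
redrawn — planted novel loci are positive controls by construction.
`simulate_library()` draws Poisson counts per locus around the planted
abundance of the selected library, generates isomiR end variants from a
truncated-geometric offset model, appends the 3' adapter (TruSeq small-RNA
sequence by default), and adds ncRNA fragments (24-nt modal length, giving
the leaf-typical 21/24-nt bimodal tag profile), genomic background reads,
sequencing errors (10⁻³ per base), N calls and low-quality reads at small
fractions. The two libraries are drawn independently — there is no shared
dispersion — mirroring the replicate-free design.

Default scales are chosen for desk-scale validation, not realism: genomes of
~10⁵ bases, tens of loci, libraries of 2×10⁴–2×10⁵ reads. What the
generator does **not** emulate: realistic Illumina error and quality
profiles, repeat-associated siRNA biogenesis, multi-locus families sharing a
precursor, expression dispersion beyond Poisson, and genome-scale repeat
structure. Consequently, passing recovery tests demonstrate the
*correctness of the inference chain* under its own assumptions; they do not
certify performance on real libraries, where overdispersion and annotation
incompleteness dominate.

## Problem sizes and numerical choices in the test suite

The shipped tests validate on: a 120-kb two-chromosome genome with 5 known,
3 novel and 10 ncRNA loci and paired 20–30k-read libraries for end-to-end
recovery; and a 400-kb genome with 40 known loci (30 null, 10 with planted
4-fold changes, 5 up and 5 down) and paired 200k-read libraries across 20
seeds for parameter recovery, requiring ≥ 95% DEM recovery and at most one
false call per seed among the nulls. Oracle tests compare exact-match
mapping with naive string scans (1000 tags), mismatch matching with
exhaustive Hamming search, window scanning with per-window rescoring, and
the log-space exact test with direct summation of the conditional mass to
10⁻¹². Determinism is asserted byte-for-byte: a seed fully determines the
genome, the truth table and the simulated FASTQ.

## Known limitations

* Exact-substring ncRNA exclusion is stricter than the original BLAST
  screen; borderline contaminants with sequencing errors can surface as
  unannotated tags (they are then removed by the read-support rule).
* The Nussinov fallback backend over-pairs long random sequences; criteria
  rule (4) is only meaningful with the thermodynamic backend.
* The duplex parser requires the mature to pair exclusively into one arm; a
  mature spanning the terminal loop is rejected rather than re-anchored.
* Shared (fused-label) counting assigns tied tags to each tied mature and
  counts them once per family; per-mature columns are therefore not
  additive across matures of a family with shared tags.
* Group I–IV time-series rules are a formalisation of a verbal description;
  series matching several verbal patterns are resolved by rule order.
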