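---
title: "Ambiguity-site analysis of heterogeneous amplicon consensus sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ambiguity-site analysis of heterogeneous amplicon consensus sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ambigscan)
```

## The model

A Sanger amplicon consensus of a locus that exists in several divergent
copies within one genome superimposes those copies. Where the copies
agree the consensus shows a plain base; where they disagree the
chromatogram shows stacked peaks and the consensus records an IUPAC
ambiguity code. `ambigscan` treats such a consensus as a compact
description of a *haplotype space*: at each position the code's
expansion lists the bases present among the copies, and any sequence
drawn site-wise from these expansions is a possible copy (resolution).

Everything downstream follows from that reading:

- **Site census.** A position is variable when its expansion (or, in an
  aligned cohort, the union of the per-sequence expansions) holds more
  than one base. Two alternating bases form an SND (single nucleotide
  dimorphism), three an SNT, four an SNP; SND pairs are typed as
  transitions ({A,G}, {C,T}) or transversions. These conservation laws
  are enforced structurally: `n_variable = n_SND + n_SNT + n_SNP` and
  `n_SND = n_transitions + n_transversions` on every input.
- **Haplotype space.** The number of resolutions is the product of the
  per-site expansion sizes (2^k for an SND-only consensus with k
  ambiguous sites). Since each ambiguous site can differ between two
  resolutions independently, the maximum pairwise divergence is exactly
  `k / L` with `L` the non-gap length; the largest per-site expansion
  lower-bounds the number of alleles actually present. The bound is a
  genuine lower bound only: dosage (how many physical copies carry each
  allele) is never inferred.
- **OTU splitting.** With similarity defined as 1 − p-distance (no
  evolutionary correction, matching how metabarcoding thresholds are
  applied), a genome's own copies split across OTUs at threshold *t*
  exactly when `1 − k/L < t`.
- **Codon effects.** A variable site at segment position *p* of a
  coding segment whose first residue is the `orf_start`-th nucleotide of
  the ORF lies in codon `ceiling((orf_start + p − 1)/3)` at codon
  position `((orf_start + p − 2) mod 3) + 1`. A codon with ambiguity is
  synonymous when all its resolutions translate identically, otherwise
  nonsynonymous. Two tallies are kept, because a cohort can be pooled in
  two ways: *per-sequence* (a codon counts when nonsynonymous within at
  least one isolate's own consensus) and *union* (all isolates'
  alternatives pooled onto one reference, the way variant summaries are
  usually drawn). The union tally is the headline one.
- **Structure context.** Secondary structure is consumed as dot-bracket
  input — folding is someone else's job — and each variable site is
  labelled loop or paired. A paired site is wobble-neutral when every
  base in its expansion still forms a legal pair (Watson–Crick or G·U)
  with the partner. The default contract is existential on the partner
  side (any partner base suffices); a stricter all-pairs variant is
  reported alongside, since the biological argument ("substitutions in
  helices are tolerated because wobble pairing absorbs them") is
  qualitative and both readings are defensible.
- **Fingerprints.** RAPD/RFLP band patterns arrive as binary matrices.
  Distances use Dice by default (the common choice for dominant
  markers), with Jaccard and simple matching available; UPGMA joins the
  closest pair at half its distance with size-weighted updates, and
  ultrametricity of the result is tested to 1e-9. Identical rows are
  grouped into patterns, with the undistinguishable pairs listed
  explicitly.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `max_gap` | 10 nt | maximum spacing between consecutive sites inside one variability block |
| `min_block_sites` | 2 | smallest run reported as a block |
| `cap` | 2^20 | largest resolution set listed explicitly; counts and bounds stay exact above it |
| `threshold` | 0.97 | OTU similarity threshold |
| `orf_start` | — | 1-based ORF position of the segment's first residue |
| `code_table` | `"standard"` | genetic code; `"alt_yeast"` (NCBI 12, CTG→Ser) for CUG-Ser clade yeasts |
| `h` | 0.3 | minor-peak calling threshold of the consensus caller |
| `coefficient` | `"dice"` | band similarity coefficient |
| `min_band_size` | 0 | bands at or below this size (bp) are dropped, strictly by default |

Block detection deserves a note: there is no canonical definition of a
"variability block" in this literature, so the run rule (`max_gap`,
`min_block_sites`) is exposed rather than asserted — block counts are a
description of the input under stated parameters, not a reproducible
constant of the data. Similarly, which genetic code a given study's ORF
translator used is often unstated; both codes are supported and neither
is hard-wired into the analysis.

Percentages are carried at full precision in machine output; headline
figures are additionally rounded half-away-from-zero to integer percent
(`pct_variable_headline`), because that is how such numbers are quoted.
The percentage denominator excludes indel columns, which are counted
separately (a maximal gap run within one sequence is one indel event) —
ambiguity and indels are different phenomena and are never conflated.

## The simulator: what it emulates, what it does not

`simulate_chimera()` plants an exact or binomial number of substitution
sites between alleles of a random ancestor, transition-biased
(default 0.7, reflecting the transition dominance typical of these
dimorphic sites), optionally confined to intervals or to an explicit
position set. `call_consensus()` then emulates the majority-peak rule of
chromatogram reading: the consensus shows an ambiguity code over the
majority base and every minority base whose weight reaches `h`;
minority bases below `h` are suppressed and the position flagged
`majority_called`. The flag exists because a plain FASTA record cannot
reveal suppressed minor variants — the scanner treats only explicit
codes as variable, and the simulator keeps the ground truth for
sensitivity analysis. One definitional choice: with more than two bases
at a site, "minority reaches the threshold" could mean the summed or the
per-base minority weight; the per-base rule is implemented (displayed
set = majority base plus every base with weight ≥ `h`) because it is the
only one that defines *which* bases appear in the code, and the two
rules coincide in the dimorphic regime that dominates real data.

`evolve_repeat_array()` contrasts the two hypotheses for rRNA repeat
evolution as per-generation event probabilities: gene conversion
(`homogenise`: conversion 0.5, no birth/death) versus duplication and
deletion without conversion (`birth_death`: 0.05 each). No rates for the
real process are known; the presets are illustrative, and every claim
made about the regimes is comparative (birth-and-death arrays accumulate
more consensus ambiguity than homogenised ones at matched mutation rate
and time), tested one-sided at α = 0.01 over 100 replicates of 2 × 300 nt
arrays, 50 generations, mutation 2e-3 — sizes chosen so the contrast is
decisive at desk scale.

`simulate_pul4_like()` builds a cohort shaped like a published nuclear-
gene amplicon survey: 37 strains, two alleles each, a 380 nt segment
anchored at ORF position 754, a union of exactly 70 dimorphic sites of
which 14 codons are amino-acid-changing, transition-biased, with each
strain heterozygous at a random ~30% subset of the site pool (every site
carried by at least one strain). Sites occupy distinct codons: silent
sites sit at third positions (NNC/NNT transitions, always synonymous, or
A/T transversions in fourfold-degenerate contexts), nonsynonymous ones
are first/second-position substitutions from stop-free templates. The
sequences themselves are random — this is a synthetic stand-in with the
real survey's summary statistics, not its data.

What the simulator does *not* emulate: phylogenetically realistic
substitution processes (no GTR, no rate heterogeneity), indels in coding
fixtures, chromatogram noise, PCR drift or recombination between loci.
Passing tests therefore demonstrate that the analyses recover planted
truth under the stated generative model, not that they are robust to
every artefact of real amplicon data.

## Numerical and degenerate-input choices

- Enumeration above `cap` returns counts and closed-form bounds with the
  explicit list omitted and flagged; nothing silently truncates.
- UPGMA tie-breaking is deterministic: ids are sorted lexicographically
  at the start and the tied pair with the lowest (row, column) index
  merges first, so identical inputs give byte-identical Newick strings
  without any seed.
- Jaccard/Dice distance between two all-empty band patterns is defined
  as 0 with a warning (the limit of "no shared, no union" is
  indeterminate; two empty patterns are operationally identical).
- Gap-containing codons are reported unresolvable and excluded from all
  codon denominators; codons only partially inside the segment likewise,
  and both exclusions are listed.
- An empty site set gives `NA` fractions flagged by `n_sites = 0`, not a
  silent 0.
- Pseudoknots are not parsed (single bracket tier); hairpin-stem loops
  need none.
- All simulator randomness derives from explicit integer seeds;
  identical seed and parameters give byte-identical output.

## Problem sizes used by the test suite

The suite runs entirely from generated data: 200 seeded two-allele
recoveries at 1–30 planted sites on 200 nt sequences; 60 brute-force
divergence checks with resolution spaces kept below ~4 × 10³; exhaustive
codon-effect checks for all single-ambiguity codons plus 10⁴ random
ambiguity codons against an independent enumerate-and-translate oracle;
100 random ultrametric trees of up to 16 leaves recovered exactly from
their cophenetic matrices; and 2 × 100 repeat-array replicates for the
regime contrast. These sizes make every exact claim exhaustive or
near-exhaustive over its stated domain while the whole suite stays in
the low minutes.

## Known limitations

- Majority-called (suppressed-minority) positions cannot be recovered
  from FASTA input; sensitivity to the calling threshold can only be
  studied on simulated data where the truth is recorded.
- The allele-count bound is tight only when alleles differ at a shared
  site; two alleles identical across the amplified segment are invisible.
- Divergence bounds assume ambiguity codes are exact (every listed base
  truly present); sequencing artefacts that inflate codes inflate the
  bounds.
- UPGMA assumes a clock-like (ultrametric) signal; for band data this is
  a descriptive clustering, not a phylogeny.
- The 380 nt worked-example segment is not a whole number of codons; the
  two trailing residues sit in an excluded partial codon, which is why
  codon percentages use the complete-codon denominator (126) and are
  reported alongside raw counts.
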