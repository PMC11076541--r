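# ambigscan

Analysis of intragenomic sequence diversity recorded as IUPAC ambiguity
codes in amplicon consensus sequences.

## The problem

When a genome carries several divergent copies of a locus — an
unhomogenised rRNA repeat array, or two alleles of a nuclear gene brought
together by hybridisation — direct Sanger sequencing of the amplified
locus superimposes the copies. Positions where the copies disagree appear
as double peaks and are written as IUPAC ambiguity codes: a site where
exactly two bases alternate is a **single nucleotide dimorphism (SND**,
e.g. `Y` = C/T), three alternating bases an **SNT**, four an **SNP**.
Some yeasts, notably *Metschnikowia pulcherrima*, show so much of this
intragenomic variation in their barcode loci (ITS, LSU D1/D2) that the
within-genome differences exceed the similarity thresholds (e.g. 97%)
used to delimit species-like OTUs in metabarcoding — one genome's own
repeat variants would be called different species.

`ambigscan` is for people who work with such sequences: it censuses the
ambiguous sites of single consensus sequences or pre-aligned cohorts,
locates variability blocks, enumerates the haplotype space implied by a
consensus, bounds the number of alleles in the genome, tests OTU
threshold splitting, classifies dimorphic codons as synonymous or
amino-acid-changing, places variable sites into secondary-structure
context (stem vs loop, wobble-neutral or not), and clusters binary
RAPD/RFLP fingerprints by UPGMA. A seeded simulator generates chimeric
genomes, repeat arrays evolving under homogenisation vs birth-and-death
dynamics, majority-peak consensus calls and strain-structured band
matrices, providing exact ground truth for every analysis.

## Core quantities

For a consensus with ambiguous sites at *k* of *L* non-gap positions:

- the haplotype space is the Cartesian product of the per-site
  expansions, with ∏ sizes members (2^k for an SND-only sequence);
- the maximum pairwise divergence between resolutions is *k/L*, so the
  minimum similarity between copies of the same genome is 1 − *k/L*; a
  genome **splits** at an OTU similarity threshold *t* when
  1 − *k/L* < *t*;
- the minimum allele count is the largest per-site expansion (an
  SND-only sequence implies at least two alleles);
- a dimorphic codon is synonymous when all its resolutions translate to
  one residue, nonsynonymous otherwise;
- SND pairs are transitions ({A,G}, {C,T}) or transversions (the other
  four pairs);
- UPGMA joins the closest clusters at half their distance with
  size-weighted distance updates, giving an ultrametric dendrogram.

## Worked example

```r
library(ambigscan)

census <- scan_sequence("ACGYACGTARGTWCGT")
census
#> Variability census over 1 sequence(s), 16 positions
#>   variable sites: 3 (18.75%, headline 19%, denominator 16)
#>   SND/SNT/SNP: 3/0/0   ti/tv: 2:1
#>   indel columns: 0 (0 events)
census$sites
#>   position observed code morphism substitution is_indel_column majority_called
#> 1        4      C/T    Y      SND   transition           FALSE              NA
#> 2       10      A/G    R      SND   transition           FALSE              NA
#> 3       13      A/T    W      SND transversion           FALSE              NA

enumerate_haplotypes("ACGYACGTARGTWCGT")
#> haplotype_space of 'seq1' (16 nt)
#>   ambiguous sites: 3;  resolutions: 8
#>   max pairwise divergence: 0.1875 (denominator 16 non-gap sites)
#>   minimum allele count: 2
```

Three SND sites (two transitions, one transversion) imply 2³ = 8 possible
haplotypes, at least two alleles in the genome, and copies of this locus
that can be as little as 81.25% identical — far below a 97% OTU
threshold, so this single genome would split into multiple OTUs.

On a whole synthetic cohort (37 strains, two alleles each, 380 nt coding
segment anchored at ORF position 754):

```r
fix <- simulate_pul4_like(seed = 1)
scan_alignment(fix$consensus)
#> Variability census over 37 sequence(s), 380 positions
#>   variable sites: 70 (18.42%, headline 18%, denominator 380)
#>   SND/SNT/SNP: 70/0/0   ti/tv: 62:8
#>   indel columns: 0 (0 events)
summarize_coding(fix$consensus, fix$frame)
#> codon effect table: 126 complete codons
#>   nonsynonymous (union of isolates): 14 (11.1%)
#>   nonsynonymous (within >=1 isolate): 14
#>   variable sites at third codon positions: 80.0%
```

The union of the strains' dimorphic sites covers 70 of 380 positions
(18%), all SNDs — so every strain carries exactly two alleles — and
pooling all alternatives onto the reference marks 14 codons as
amino-acid-changing, with most variable sites in silent third codon
positions.

The same analyses are available from a shell through the installed
script (`inst/cli/ambigscan`) with subcommands `scan`, `haplo`, `codons`,
`structure`, `cluster`, `simulate` and `run`, or in R through
`run_pipeline()` with a YAML configuration.

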