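---
title: "Mapping EMS-induced recessive mutations with mutmapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping EMS-induced recessive mutations with mutmapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutmapr)
```

## The mapping problem

An EMS-mutagenised line of a selfing crop shows a stable recessive
phenotype. Crossing the mutant back to its progenitor and selfing the F1
gives an F2 in which the phenotype segregates; pooling DNA from
mutant-phenotype F2 plants and sequencing the pool (bulked segregant
analysis, the MutMap design) turns linkage into allele frequency. At a
mutant-origin SNP unlinked to the causal lesion, a mutant-phenotype F2
plant carries the mutant allele with frequency 1/2, so the fraction of
pool reads carrying it — the **SNP index** — is centred on 0.5. At the
causal site itself every selected plant is homozygous, the index is 1, and
it decays towards 0.5 with map distance. The causal region is therefore
the window where the index approaches 1.

`mutmapr` implements this analysis from the point where variant calls
exist: three libraries (wild-type progenitor, mutant, F2 mutant-phenotype
bulk) in a VCF with per-sample allele depths, plus gene models (GFF3) and
the reference sequence (FASTA) for effect annotation. Everything upstream
(alignment, raw variant calling) and downstream of the candidate list
(enrichment, wet-lab validation) is out of scope.

## The pipeline

`mutmap_pipeline()` fixes the stage order:

1. **Homozygous parental differences** (`homozygous_differences()`): keep
   sites where the mutant library is homozygous-alternate and the
   wild-type library homozygous-reference. Sites where the progenitor
   itself differs from the reference genome are background introduced by
   the assembly, not EMS candidates.
2. **Effect annotation** (`annotate_effect()`): strand-aware codon
   translation classifies coding SNPs as synonymous / nonsynonymous /
   stop gain / stop loss; intronic SNPs within `splice_margin` of an exon
   boundary are `splicing`. The default margin of 2 bp is the canonical
   donor/acceptor dinucleotide; published candidate tables label such
   variants "splicing" without stating a margin.
3. **Large-effect preselection**: the SNP index is computed at
   nonsynonymous / stop / splice sites — the set at which an index is worth
   reporting, mirroring how published MutMap candidate tables are built.
4. **Low-index filter** (`filter_low_index()`): "index < 0.3 filtered out"
   is applied exactly as worded — the boundary 0.3 is *kept*. Zero-depth
   (undefined-index) sites are dropped with a logged count, never silently.
5. **Sliding-window scan** (`sliding_window_scan()`): 1 Mb windows every
   10 kb by default. Windows are anchored at position 1 of each
   chromosome (no anchoring convention is standard; this one is stated so
   results are reproducible). Terminal windows are shortened at the
   chromosome end. An empty window reports an *undefined* mean, not 0 —
   zero would fabricate evidence of absence.
6. **Candidate cascade** (`candidate_screen()`): retain index = 1; filter
   non-EMS-typical changes; retain large-effect classes. Retention counts
   are recorded per stage and are monotone non-increasing by construction.

### The "SNP index = 1" tolerance

At finite depth "index = 1" needs a convention. `index_mode = "exact"`
takes it literally. The default `index_mode = "tolerant"` retains loci
within **one read of fixation**, `index >= 1 - 1/depth`. The reasoning: at
depth *d* with per-read error rate *e*, a truly fixed locus shows at least
one non-alternate read with probability about *d·e* (≈ 10% at 21× and
*e* = 0.005), so an exact screen ejects the causal site in a tangible
fraction of experiments; and any tolerance smaller than one read is
vacuous at integer counts, because the next attainable index below 1 is
(d−1)/d. One read is also the smallest tolerance that changes anything, so
it rejects any locus genuinely two or more reads away from fixation. Both
modes are exposed; the worked examples in the candidate tables of MutMap
studies (all candidates printed at index 1 at ~21×) are consistent with
either.

### The EMS-typicality filter

EMS alkylates guanine, so the canonical lesions are G→A and C→T
transitions. `ems_filter = "strict"` drops everything else. Published
candidate lists, however, sometimes retain a transversion despite
describing such a filter (e.g. a G→T among otherwise canonical
candidates), so the stage is configurable: `"permissive"` keeps atypical
changes but flags them, `"off"` skips the stage. The discrepancy is a
property of practice, not something this package resolves.

## Segregation genetics

`chi_square_segregation()` tests observed phenotype counts against a
Mendelian ratio. For two classes the **Yates continuity correction** is on
by default, with the `|O−E|−0.5` term clamped at zero for perfect fits.
The choice matters at the second decimal: for an F2 of 1225 : 401 against
3:1 the corrected statistic is 0.08 and the plain Pearson 0.10; for a
backcross of 264 : 272 against 1:1 they are 0.09 and 0.12. Published
tables in this literature print the corrected values, so that is the
default, with `yates = FALSE` available; the Pearson form is verified
against `stats::chisq.test` in the test suite. `segregation_ratio()`
reports the "r : 1" summary, and `cosegregation_check()` performs the
KASP-style confirmation: a marker co-segregates when no mutant-phenotype
individual lacks homozygosity for the mutant allele.

## Expression utilities

`ddct()` implements 2^−ΔΔCt relative quantification (technical-replicate
Ct values are averaged before ΔCt — the usual aggregation, stated because
protocols rarely do). `deg_filter()` applies the common |log2FC| ≥ 1 and
p < 0.05 rule; fold-change boundaries are kept (the rule's "≥"), the
p boundary is not ("<"). P-values are accepted as input because real
pipelines compute them internally; `deg_test()` offers a plain Welch
t-test for synthetic data only. No claim is made of reproducing any
published DEG count, which depends on external data and the upstream
pipeline's internal test.

## The synthetic data generator

`simulate_mutmap()` emulates the *post-variant-calling* state of a MutMap
experiment so that every stage is testable without external data:

* **Genome**: uniform-random chromosome sequences with non-overlapping
  multi-exon gene models; one gene always spans the causal locus, with the
  causal site at a known codon phase inside an exon and the reference
  codon set to TCT so the forced C→T lesion is the nonsynonymous S→F
  change — the annotation path is exercised end to end.
* **Mutations**: counts are Binomial(length, `ems_rate`) per chromosome; a
  fraction `ems_spectrum` (default 0.99) are canonical G→A/C→T transitions
  placed on G/C sites; the rest are non-canonical changes. All are
  homozygous in the mutant line.
* **Meiosis**: the F1 is uniformly heterozygous; gametes get
  Poisson(`recomb_rate`) crossovers at uniform positions — the Haldane
  map, i.e. no interference, the simplest model consistent with silence on
  recombination in this literature. Physical position maps linearly to
  Morgans. Individuals are rejected until `bulk_size` plants homozygous at
  the causal locus are collected (fully penetrant monogenic recessive, the
  model the segregation data support).
* **Sequencing**: per site, depth ~ Poisson(`depth_mean`); each read draws
  a random bulk individual and one of its alleles, then flips to the other
  allele with probability `error_rate` (a biallelic miscall model: the
  expected reference-read fraction at a fixed site equals the error rate).
  Zero-depth sites are kept and flagged. Parental libraries are emitted as
  hard genotype calls: the pipeline uses only their homozygous-difference
  status.
* **Determinism**: all stages derive their RNG streams from the config
  seed (genome: seed; mutations: seed+1; bulk: seed+2; depths: seed+3, in
  documented draw order), so identical configs give identical output, and
  each stage is independently reproducible.

Defaults mirror the experimental design this kind of study uses: a bulk of
**15** F2 plants at about **21×** with a **0.99** canonical-transition
fraction and 0.5% read error. The genome scale — 2 chromosomes × 2 Mb,
1 Morgan per chromosome, `ems_rate` 2 × 10⁻⁵, 40 genes/Mb — is the
package's own desk-scale choice: it yields a few dozen mutant-origin loci
per chromosome, the same order of sparsity per megabase as real candidate
sets, while keeping a full pipeline replicate to a few seconds. The test
suite runs 50 such replicates for the causal-recovery property and 500
small bulks for the allele-frequency calibration against the exhaustive
two-locus oracle.

### What the generator does not emulate

Uniform base composition and gene spacing; context-dependent or
non-uniform sequencing error; indels and structural variants (the scan is
SNP-only, though `translate_cds(truncate_at_stop = TRUE)` supports
reasoning about premature-stop alleles); residual heterozygosity or
natural variation between progenitor and reference (the simulated
wild type *is* the reference); mapping artefacts from paralogy;
incomplete penetrance or polygenic phenotypes. Passing tests therefore
demonstrate correctness of the analysis on data satisfying the MutMap
assumptions, not robustness to violations of them.

## Numerical and degenerate-input conventions

Coordinates are 1-based inclusive at every interface (VCF/GFF
convention); the BED window track written by `write_report()` is 0-based
half-open with the conversion documented and round-trip tested. Undefined
SNP indices (zero depth) propagate as NA and are counted when dropped.
`sliding_window_scan()` refuses unsorted input rather than sorting
silently. Multi-allelic records and indels are skipped with logged counts
at read time. `translate_cds()` errors on internal stops unless truncation
is requested. Negative depths, zero expected chi-square counts, unknown
co-segregation alleles and malformed genotypes are errors, not warnings.

## Known limitations

Single-transcript gene models (no isoforms); biallelic SNPs only; no
ΔSNP-index two-bulk statistic or confidence bands (not needed for this
design); the scan reports the global maximum window but no significance
claim — confirmation belongs to co-segregation genotyping, as in
`cosegregation_check()`.
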