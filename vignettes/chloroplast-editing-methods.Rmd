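---
title: "Methods: calling and comparing chloroplast C-to-U RNA editing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling and comparing chloroplast C-to-U RNA editing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chloroedit)
```

## The problem

Chloroplast transcripts in land plants undergo C-to-U RNA editing:
specific cytidines are deaminated to uridine after transcription, so the
mRNA sequence differs from the genome at 20–60 positions per plastome.
Editing sites are recognised by nuclear-encoded factors (PPR proteins,
ORRM proteins and other editosome components); losing one factor changes
editing at many sites at once. The computational task this package covers
is the comparison that reveals such a defect: given DNA resequencing and
strand-specific RNA-seq from the same material, find the positions where
the RNA disagrees with the DNA in a C-to-U pattern, quantify how often
each site is edited, annotate what the edit does to the protein, and
compare wild-type and mutant editotypes. Around this core sit the small
pieces of genetics and physiology arithmetic such a study needs: a 3:1
segregation test, fine-mapping interval delimitation, chlorophyll
equations and qPCR normalization.

## Editing model and the caller

Sequencing reads at a genomic position are summarised as a *pileup
column*: counts of A, C, G and T on the reference strand, summing to the
column depth. An editing site on a plus-strand gene shows T reads at a
reference C; on a minus-strand gene the transcript's C-to-U change
appears on the reference strand as A reads at a reference G. Both
orientations are scanned; only the C-to-U pattern is considered, since it
is essentially the only editing type in plastid mRNAs.

`discover_sites()` calls a position a candidate when three predicates
hold:

1. **Depth** — DNA and RNA columns both reach `min_depth` (default 20
   reads). The filter applies to total column depth; `depth_mode = "cu"`
   switches it to the C-role + U-role counts only.
2. **DNA homozygosity** — the DNA column's non-reference fraction is at
   most `dna_max_alt_fraction` (default 0.02). A heterozygous or variant
   genomic position would masquerade as editing; the fraction threshold
   is the pileup-level analogue of a homozygous SNP call. With typical
   DNA depths of 50–500× and sub-percent sequencing error, a true
   heterozygote (≈ 50% alternate) is separated from this threshold by a
   wide margin.
3. **Edited-base fraction** — the RNA column's edited-base fraction
   reaches `min_rna_edit_fraction` (default 0.05). SNP-caller based
   pipelines implicitly impose such a floor; it is exposed here as an
   explicit, conservative parameter.

Efficiency is the field's standard statistic, Editing (%) =
U/(C + U) × 100, with U the edited-base and C the genomic-base count.
Reads that are neither base (sequencing errors to the other two
nucleotides) are excluded from the denominator, mirroring the two-allele
form of the statistic. When C + U = 0 the efficiency is undefined (`NA`),
which is distinct from 0%.

`quantify_known_sites()` bypasses predicate 3 (and reports rather than
enforces 1–2) so that sites known from other species or experiments can
be quantified even when they would not be discovered — e.g. a site edited
at 1%. `pool_replicates()` sums C- and U-role counts across biological
replicates and recomputes efficiency from the pooled counts, which
weights replicates by depth and maximises the effective coverage;
per-replicate means are easily computed from the per-replicate tables if
wanted.

## Coordinates and codon annotation

Positions are 1-based and inclusive throughout. A site is named by its
transcript position counted from the first base of the initiation codon.
For genes with introns the coding-site position refers to the *spliced*
transcript — the convention under which published multi-exon gene
positions fall inside the spliced CDS — while intronic sites are located
on the unspliced pre-mRNA from the same origin. The codon site is
`((pos − 1) mod 3) + 1` and the conversion is rendered as
`X(abc)→Y(abd)`: RNA alphabet, edited base uppercased on both sides,
single-letter amino acids, and the literal token `stop codon` when the
edited codon terminates translation. The genetic-code table is written
out explicitly in the package and cross-checked in the tests against an
independent implementation.

`conversion_string()` accepts an edited base of `c` (→ `u`) and also `g`
(→ `a`). The latter covers the rare non-C-to-U conversions that published
organelle editotypes occasionally contain — the bundled soybean catalogue
has exactly one such row (ndhB-9, `W(ugG)→stop codon (ugA)`).

The package ships a transcription of a published catalogue of 45 editing
sites in soybean chloroplast transcripts (`soybean_editing_sites()`): 43
coding-region sites with codon annotations and 2 intronic sites
(rps12-554 and rps16-499). One printed coding row (psbE-214) is
internally inconsistent in the source: the position implies codon site 1,
while the printed codon site and conversion mark the codon's second base
(transcript position 215). The fixture preserves the printed values
verbatim rather than silently correcting either column, and the test
suite documents the discrepancy; the other 42 coding rows satisfy the
positional formula exactly.

Annotation reports every overlapping matching-strand gene (no arbitrary
primary-gene choice); a call whose orientation conflicts with all
overlapping genes is flagged rather than dropped, and calls outside every
gene are labelled intergenic.

## Differential classification

Genotype comparison is done on replicate-pooled efficiencies. Classes:

- **abolished** — mutant efficiency below `zero_floor` (1 point) while
  the wild type is edited at ≥ `wt_min_for_abolished` (10 points).
  Requiring "< 1 point" rather than exactly 0 acknowledges sequencing
  error; the wild-type floor prevents labelling noise-level sites.
- **decreased / increased** — change of at least `alter_threshold`
  (10 percentage points of efficiency). Percentage *points* is the
  default reading; a relative-change mode exists but is not default.
- **unchanged** — everything else with both efficiencies defined.
- **undetermined** — either efficiency undefined (depth failure).

The partition is exhaustive and antisymmetric (swapping genotypes swaps
decreased and increased). Per-transcript summaries count altered sites
(abolished + decreased + increased) over all surveyed sites of the gene;
the overall alteration rate is reported to the nearest whole percent.
No per-site statistical test is applied — with two pooled replicates per
genotype and a 10-point threshold the decision is deliberately a fixed
effect-size rule, not an inference procedure.

## The synthetic-data generator

`make_genome()` builds a seeded random plastid-like genome: non-
overlapping genes on both strands, CDS lengths divisible by 3, no
internal stops, start codons ATG or ACG (the ACG class models genes such
as psbL whose initiation codon is created by editing), and at least one
intron-containing gene. Genes never span the circular origin, which
avoids coordinate-wrap complexity that is irrelevant to the method.
`plant_sites()` selects editable sense-strand Cs inside spliced CDS and
assigns each genotype an efficiency; `simulate_pileups()` then draws each
column from a multinomial in which a read is edited with probability
`eff` and misread with probability `error_rate` (spread uniformly over
the other three bases). Counts are reported on the reference strand.
Every output sample has its own RNG stream derived from the master seed
and the sample label, so replicates differ but reruns are byte-identical.

Defaults are chosen once to emulate a small-organelle resequencing
design: DNA 100×, RNA 200× per replicate, two biological replicates per
genotype, two genotypes (wild type and mutant), base error 10⁻³. The
planted class mixture follows the proportions typical of an editing-
factor mutant survey (3 abolished : 14 decreased : 2 increased : 26
unchanged). Class efficiency ranges keep planted effects at least 20
points away from the 10-point decision threshold and mutant efficiencies
at least 5 points above the abolished floor; at the depths used in the
recovery tests (500× per replicate, pooled to 1000×) the binomial
standard error of an efficiency estimate is at most ~1.6 points, so a
20-point margin is > 4 standard errors and truth labels are recoverable
essentially surely. These margins are part of the generator's definition
of a "clear" effect, not a tuning of the tests.

What the simulator does *not* model: read-level error profiles and
quality scores, indels, mapping and strand bias, rRNA contamination,
variable depth along the genome, and mitochondrial editing. Passing
recovery tests therefore demonstrate correctness of the counting,
filtering and classification logic under ideal mapping — not robustness
to alignment artefacts, which an aligner-level pipeline must handle
before the pileup stage.

## Genetics and phenotype arithmetic

**Segregation.** `chi_square_segregation()` tests counts against an
expected ratio with E·= total·ratio/Σratio. The default applies the Yates
continuity correction, χ² = Σ max(|O−E| − 0.5, 0)²/E, with the correction
clamped at zero when |O−E| ≤ 0.5 — on a near-perfect 3:1 fit the
statistic is exactly 0 rather than slightly negative-biased. The
corrected form is the default because published 3:1 tables of this kind
are reproduced by it and not by the uncorrected Pearson statistic; the
uncorrected form remains available and is cross-checked against
`stats::chisq.test()` in the tests. P-values are exact chi-square tail
probabilities; the classic table-interval label (e.g. `0.50~0.25`) is a
formatting layer only.

**Fine mapping.** For a recessive-class F2 panel, `delimit_interval()`
finds the markers where every mutant individual is homozygous for the
mutant-parent allele and returns the innermost flanking markers showing
at least one recombinant. This zero-recombinant delimitation is the
standard endpoint of fine mapping; centimorgan estimation is deliberately
out of scope, with `est_recomb_fraction()` provided only as the
approximate recessive-class estimator r̂ = (H + 2B)/(2n).
`simulate_f2_mutant_markers()` draws marker genotypes per individual with
recombination probabilities from the Haldane map function, independently
per marker; interference between markers is not modelled, which is
adequate for validating the delimitation logic but not for simulating
joint recombination patterns.

**Pigments and expression.** `chlorophyll()` applies the 95%-ethanol
extract equations for absorbances at 665 and 649 nm and reports a
physically impossible negative pigment value as a flag rather than
clamping it. `relative_expression()` implements 2^−ΔCt; with several
reference genes the reference Ct is their arithmetic mean, the simplest
defensible combination when no weighting is published.

## Numerical choices and degenerate inputs

- Efficiency with C + U = 0 is `NA`, never 0; classification maps any
  `NA` to `undetermined`.
- Discovery on mismatched references errors; positions present in only
  one pileup are skipped with a warning.
- The capacity check in `make_genome()` (genes + minimum gaps must fit)
  raises a typed error rather than looping forever on impossible
  packings; `plant_sites()` errors when more sites are requested than
  editable Cs exist.
- Multinomial sampling is implemented by sequential conditional
  binomials, which is vectorised over positions and exactly equivalent in
  distribution; degenerate probabilities (error rate 0) are handled by
  clamping the conditional probabilities into [0, 1].
- Tie-breaks: none are needed in classification (the class rules are
  evaluated in fixed order: undetermined, abolished, decreased,
  increased, unchanged).

## Problem sizes in the test suite

The packaged tests run on genomes of 3–26 kb with 1–8 genes: property
checks (brute-force equivalence, strand symmetry, monotonicity) use 4–5 kb
genomes across dozens of seeds, and the recovery benchmark plants 200
sites in a 26-kb genome at 500× depth with error-free reads. These sizes
were chosen as the smallest at which every structural feature (both
strands, introns, all four differential classes, pooled replicates) is
exercised with comfortable statistical margins.

## Known limitations

- Two genotypes per comparison; multi-genotype designs require pairwise
  runs.
- Depth is constant along the simulated genome; depth-dependent caller
  behaviour under realistic coverage variation is untested.
- The caller assumes pileups are already strand-resolved and
  duplicate-free; it performs no alignment-level corrections.
- Trans-spliced genes (rps12-type) are not modelled by the gene
  representation: exons of one transcript must lie in one contiguous
  orientation block.
- No per-site significance testing; the 10-point rule is an effect-size
  convention.
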