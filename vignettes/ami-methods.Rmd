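---
title: "Detecting admixture-source-derived variants with the ancestry-marker index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting admixture-source-derived variants with the ancestry-marker index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(amitools)
```

## The setting

Consider an admixed population formed when a lineage that had been isolated
for a long time (call it *source 1*; the motivating case is the Jomon people
of the Japanese archipelago) received a large influx of migrants from its
diverged sister lineage (*source 2*, continental East Asians), leaving a
modern population that carries a minority fraction α of source-1 ancestry.
No large modern panel of source-1 genomes exists, so source-1 haplotypes can
only be studied through their traces in the admixed genomes.

The entry point is the set of **target-specific variants**: alleles observed
in the admixed sample but in none of the reference panels. Three processes
create them:

1. **type 1** — mutations that arose on the source-1 lineage (or in the
   common ancestor and survived only there): the signal of interest;
2. **type 2** — mutations that arose on the source-2 lineage, crossed into
   the admixed population with the migrants, and were subsequently lost from
   the sampled source-2 reference;
3. **type 3** — mutations younger than the admixture.

Because a type-1 variant entered on a long source-1 haplotype together with
many other type-1 variants, it tends to be in linkage disequilibrium with
many *other* specific variants; types 2 and 3 do not. The
**ancestry-marker index** of specific variant *i* is

$$AMI_i = \frac{\#\{j \ne i : r^2(i,j) > c,\ |pos_i - pos_j| \le W\}}{\text{specific-variant density of the chromosome (per kb)}}$$

with defaults $c = 0.01$ and $W = 1$ Mb, $r^2$ computed between the specific
alleles on phased haplotypes. The per-chromosome density denominator makes
the partner count comparable across chromosomes with different
specific-variant loads. Variants with AMI above a threshold are called
**ancestry markers**.

## The validation simulator

`demography_model()` + `simulate_panels()` implement the study history with
msprime: two populations of constant diploid size Ne split `split_gen`
generations ago; the admixed population is the continuation of the source-1
lineage and receives one-way migration from source 2 during
`[adm_end_gen, adm_start_gen]`. The migration rate per generation is the
closed-form solution of $(1-m)^G = \alpha$, so the *expected* residual
source-1 ancestry equals α exactly; the realized fraction per replicate is
checked (and is unbiased) in the test suite. Defaults: split 1,200
generations ago, admixture 120–80 generations ago, α = 0.12, Ne = 5,000,
μ = 1.2e-8 and ρ = 1.3e-8 per bp per generation, 1 Mb contigs, and 200
sampled haplotypes from each of four groups (modern admixed, modern
source 2, and both sources at the admixture onset).

Two pieces of ground truth are recorded. **Ancestry tracts**: a census is
placed just older than the admixture onset and every modern admixed
haplotype segment is mapped to its census ancestor, whose population label
(still-source-1 vs migrated-to-source-2) is exact — no coalescence-time
heuristic is involved. **Mutation origins**: each mutation's carrying
lineage is traced through the recorded migrations to the population it
occupied at the mutation's time. Typing then follows the definitions above;
mutations older than the split, or on the source-1 lineage before the
admixture onset, are type 1; mutations in the admixed population younger
than the admixture onset are type 3. (Mutations arising *during* the
migration window in the admixed population are counted as type 3 — they are
younger than the onset of admixture; the alternative convention, cutting at
the end of the window, moves a negligible number of variants.)

What the simulator deliberately does **not** emulate: genotyping and phasing
error, imputation, variable mutation/recombination rate along the genome,
population growth, selection, and more than two admixture sources. Passing
tests therefore demonstrate the statistical behavior of the method under a
clean two-source history, not robustness to data-quality artifacts — on real
data the low-density masking in `density_profile()` (below) is the only
artifact guard.

## Parameters that matter

* `r2_cut = 0.01` (unitless, exclusive). At 0 every pair is "in LD" and
  discrimination collapses to chance; the simulated AUC is flat for cutoffs
  in [0.01, 0.2] and decays beyond 0.2, because high cutoffs discard the
  moderate-LD pairs that carry most of the signal. Both behaviors are
  asserted in the acceptance tests.
* `ld_window_bp = 1e6`. Pairing uses a symmetric 1 Mb radius by default; a
  fixed non-overlapping 1 Mb bin variant (`pairing = "bin"`) is provided
  because windowed implementations differ in this respect. The radius form
  is the default as it has no boundary artifacts.
* Density masking (`density_profile`): bins of 1 Mb whose specific-variant
  density falls below mean − 1 sd of their chromosome are excluded from
  marker calling, flagging regions whose apparent specific variants are
  likely sequencing artifacts. The sd is the population (n-denominator)
  standard deviation by default; `sd_type = "sample"` switches conventions.
  The bin width follows the LD window scale.
* Calling threshold. `roc_analysis()` sweeps "AMI ≥ t" over all observed
  scores, reports the trapezoidal AUC, and selects the Youden threshold
  (max TPR − FPR, smallest threshold on ties, so the choice is
  deterministic). The threshold is realization-dependent: users calling
  markers on real data should regenerate it from simulations matched to
  their own demography, or set it by their false-positive tolerance. Marker
  calling uses the strict inequality AMI > threshold, so call sets are
  nested and shrink monotonically as the threshold rises.
* `flank_bp = 1e4` for haplotype classification: a haplotype is classified
  source-1 at a focal SNP iff it carries a marker allele within the closed
  window ±10 kb. The window is symmetric; a haplotype whose nearest marker
  sits just outside the window is classified source-2 even if it shares the
  LD block — the literal presence/absence rule, not an HMM.
* Marker threshold per task. For *estimation* tasks (ancestral frequencies,
  individual ranking by JAS) the package defaults to the strict threshold
  100 rather than the Youden point: false-positive markers directly
  contaminate the source-1 haplotype class, and the strict set keeps the
  false-positive fraction near zero at the cost of coverage.

## Downstream statistics

**JAS.** For an individual with marker-allele dosages $d_k$ over usable
(non-missing) markers, $JAS = \sum_k d_k / (2 n_{\text{usable}})$. The
denominator counts the markers usable *in that individual*, which handles
missing genotypes (e.g. low-coverage ancient samples) without biasing the
score. `ld_prune()` (greedy sliding window, earlier position wins on a
high-r² pair) thins redundant markers first.

**Ancestral allele frequencies.** At each focal SNP with MAF above
`maf_min = 0.01`, haplotypes are partitioned by the ±10 kb marker rule and
the allele frequency of each class is reported together with the class
sizes `n_hap_src1` / `n_hap_src2`. An empty class yields `NA`, never 0. The
class sizes matter: a frequency estimated from a handful of haplotypes is a
noisy binomial draw, and the simulation-based recovery checks in the test
suite evaluate sites with at least 10 supporting haplotypes (of 200) for
that reason. The exact mixture identity
$f_{sample} = (n_1 f_1 + n_2 f_2) / (n_1 + n_2)$ holds whenever both
classes are non-empty and is asserted as an invariant.

**mean 2βf and D.** For a trait with GWAS effects $\beta_i$ and
effect-allele frequencies $f_i$ over n independent (LD-clumped) SNPs,
$\text{mean }2\beta f = \sum_i 2\beta_i f_i / n$ is the population's
expected polygenic contribution. The divergence statistic is

$$D = \frac{(\text{mean }2\beta f)_{src1} - (\text{mean }2\beta f)_{src2}}
{P_{97.5} - P_{2.5}\ \text{of the permutation null}},$$

where the null draws each SNP's frequency independently from its two
ancestral values with probability ½ and recomputes mean 2βf once per
replicate (1,000 by default). The null is built on the *unordered* frequency
pair per SNP, which makes it exactly invariant under exchanging the two
ancestry labels — so D flips sign exactly, with an unchanged null width,
under a label swap at the same seed. A permuted-difference null is available
via `null = "difference"` for users who prefer a null on the contrast
itself. When the null has zero width (identical frequency vectors) D is 0 if
the numerator is 0 and flagged `NA` otherwise. Effect alleles are harmonized
to the frequency table's alternate allele; strand-ambiguous (A/T, C/G) SNPs
are dropped because their orientation cannot be verified.

**Outgroup f3.** $f3(O; A, B) = \overline{(f_O - f_A)(f_O - f_B)}$ over
sites with all three frequencies defined. Point estimates only: no
block-jackknife standard errors and no small-sample bias correction are
implemented, which is the main extension point of this module. Frequencies
of single diploid genomes enter as dosage/2.

**S\*.** The chain score over an individual's reference-absent variants:
pair score $5000 + d$ for dosage-matched sites at distance $d \ge 10$ bp,
$-10000$ per unit dosage difference otherwise, maximized over chains by
dynamic programming, per 50 kb window. These constants follow the original
genotype formulation of the statistic and are configurable
(`sstar_config()`). `sstar_scenario_contrast()` reproduces the
negative-control experiment: under an archaic-scale history (split 40,000
generations ago, 4% source-1 ancestry) windowed S\* separates individuals
carrying source-1-derived haplotypes almost perfectly, while under the
recent-divergence history (1,200 generations, 12%) the distributions
overlap — which is precisely why the AMI exists.

## Numerical and design choices

* Coordinates are 1-based inclusive in every user-facing table (VCF
  convention); ancestry-tract files are 0-based half-open (BED convention).
* r² is computed on phased haplotypes (`cor()^2` of allele indicators,
  algebraically identical to the textbook haplotype formula); monomorphic
  sites give `NA` and the pair is skipped. Genotype-EM r² is not
  implemented, so unphased panels are rejected by LD operations with an
  error naming the operation; dosage-only operations (JAS, S\*) accept them.
* Specificity against a reference panel treats a position absent from the
  panel's site list as "no alternate allele there" only when the position
  lies inside the panel's observed range on that contig; otherwise the
  variant is excluded (conservative) and counted in a message.
* Every stochastic function takes an explicit seed; replicate seeds are
  drawn from a base seed by R's RNG, and identical `(model, seed)` pairs
  give byte-identical simulator output.
* Problem sizes in the test suite: the validation experiment pools 300 × 1
  Mb replicates (the published experiment used 3,000; at 300 the pooled AUC
  is stable to well under the tolerance asserted), reduced-scale models
  (100 kb, 40 haplotypes) back the unit tests, and the S\* contrast uses 10
  replicates per scenario as in the original experiment.

## Known limitations

* The simulator's admixture is continuous migration over the window; a
  pulse model would concentrate tract lengths differently, though the
  residual-ancestry calibration is exact either way.
* AMI assumes a single diverged minority source; multi-way admixture or
  very recent divergence compresses the AMI contrast between type 1 and
  type 2/3 (the Youden threshold, and even the attainable AUC, are
  demography-dependent).
* Ancestral-frequency estimates inherit the marker set's blind spots:
  regions more than 10 kb from any strict marker produce empty source-1
  classes (`NA`), and small classes produce noisy estimates — filter on
  `n_hap_src1`.
* The S\* module is a comparator, not an introgression caller: no match
  rates to an archaic reference, no posterior tract inference.
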