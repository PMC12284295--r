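---
title: "Methods: diversity and mutation dynamics in fissiparous clonal lineages"
author: "clonediv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity and mutation dynamics in fissiparous clonal lineages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonediv)
```

## The system and the questions

Asexual planarians of the *Schmidtea mediterranea* CIW4 strain reproduce
exclusively by transverse self-bisection (fission): the body rips into a
large anterior head offspring and a smaller posterior tail offspring, each of
which regenerates into a complete worm.  There is no single-cell stage.
Heritable genetic information therefore travels between generations as a
multicellular propagule, and any mutation that arises in an adult pluripotent
stem cell (a neoblast) is carried by only a fraction of the body's cells — a
mosaic clone.  Whether such a mutation reaches the next generation depends on
whether cells of that clone end up in the offspring piece.

`clonediv` implements the analysis stages needed to quantify this process
from whole-genome sequencing of individually tracked worms:

1. **Variant filtering** (`read_vcf()`, `apply_site_filters()`,
   `genotype_confident_subset()`): the downstream site filters applied to a
   quality-filtered multi-sample VCF — per-sample depth between 0.5 and 2
   times that sample's mean depth, pooled alternate-allele frequency at most
   0.5 (removing variants fixed across all individuals), removal of repeat
   overlaps, and an optional GQ > 20 subset for genotype-sensitive analyses.
2. **Substrain structure** (`ld_prune()`, `pca_genotypes()`, `fst_site()`,
   `pi_site()`, `windowed_pi()`): LD pruning with a 50-SNP window, 10-SNP
   step and r² threshold 0.1, PCA of dosages, per-site Weir–Cockerham FST
   averaged in non-overlapping 10-kb windows, and windowed nucleotide
   diversity with between-group differences.
3. **Runs of homozygosity** (`detect_roh()`, `lineage_consensus()`,
   `substrain_specific_roh()`, `gc_content()`): direct detection of runs at
   least 50 kb long with at least 25 supporting SNPs and inter-SNP gaps of at
   most 50 kb, merged across individuals into lineage-consensus intervals and
   contrasted between substrains; GC content inside versus outside runs.
4. **Somatic allelic imbalance** (`allele_frequency()`,
   `classify_specificity()`, `imbalance_summary()`): read-level allele
   frequencies (AD_alt over total AD, requiring at least 10 supporting
   reads), classification of sites as shared between or specific to the FS
   and PH substrains, and per-class AF summaries.  A diploid heterozygote
   present in all cells is expected at AF 0.5; a variant present in a cell
   fraction $f$ is expected at AF $f/2$.
5. **Newly detected mutations** (`call_newly_detected()`,
   `false_negative_rate()`, `transmission_fraction()`, `mutation_rate()`):
   pedigree-aware calling across consecutive head generations, calibrated by
   the parent-to-offspring loss rate of full hets, the fraction of calls
   detected again in the next generation, and the per-generation rate
   arithmetic `n_new / (2 x callable_bp)`.
6. **Reproduction dynamics** (`waiting_times()`, `aggregate_events()`,
   `death_rates()`): waiting times from birth to next division,
   classification of reproductive events into fissions and fragmentations
   (consecutive divisions less than 6 days apart, aggregated into one event
   with `n_middles = n_divisions - 1`), and death rates per offspring type.

A forward simulator (`sim_config()`, `simulate_cohort()`, `emit_vcf()`)
generates all of the package's inputs with known ground truth, so that every
stage can be validated quantitatively.

## The fission-bottleneck model behind the simulator

The simulator embodies the head-line experimental design: each lineage
starts from a founder; at every generation the current worm acquires
`Poisson(mu)` new somatic variants, each present in a cell fraction
`init_cell_fraction` (f0), and then bisects.  The head offspring is archived
(sequenced) and the tail continues the line.  Founder variants are
heterozygous in every cell of every worm (population allele frequency 0.5);
somatic variants reach the tail in one of two modes:

* **direct** — each somatic variant is transmitted independently with
  probability `p_transmit`; its cell fraction is unchanged.  This is the
  minimal parameterisation of fission acting as a genetic bottleneck.
* **spatial** — each variant occupies a 1-D patch on the body axis (centre
  uniform, width `clone_width`); it is transmitted iff its patch intersects
  the tail segment `[fission_plane, 1]`, and the regenerated cell fraction is
  the parental fraction scaled by the overlap length relative to the tail
  length, capped at 1.  After regeneration the patch is rescaled into the new
  body's coordinates.  No quantitative clone-geometry model exists for
  planarians; this linear overlap rule is documented as one admissible
  instantiation of spatially segregated neoblast clones, not as an empirical
  claim.  Patch geometry after repeated regeneration is likewise an
  approximation (clones are kept local rather than re-dispersed).

Read data are generated per site and sample: depth is negative binomial with
mean `mean_depth` and dispersion `depth_dispersion` (variance
$\mu + \phi\mu^2$; 0 degenerates to Poisson), alternate reads are
`Binomial(DP, f/2)` for a het carrier at cell fraction $f$,
`Binomial(DP, 1 - error_rate)` for hom-alt, and `Binomial(DP, error_rate)`
otherwise.  Because the upstream genotype caller is out of scope, the
emitter states its own explicit rule: a call is het iff at least
`min_alt_reads` (2) alternate reads are observed and the read AF lies in
`[0.1, 0.9]`, hom-alt above 0.9, missing at zero depth; a true het call is
missed with probability `dropout_rate` (its reads are drawn as reference),
which is what the false-negative calibration measures.  GQ is emitted as 99
for calls with depth at least 8, else 10 — deliberately simple, since only
the GQ > 20 threshold semantics matter downstream.

### Default parameters (the simulated study conditions)

| parameter | default | meaning |
|---|---|---|
| `lineages` | F, S (FS); P, H (PH) | four lineages in two substrains |
| `n_generations` | 4 | consecutive archived heads per lineage |
| `founder_het_sites` | 3,000 | all-cell heterozygous founder variants |
| `mu` | 111 | expected new somatic mutations per generation |
| `init_cell_fraction` | 0.32 | so specific-variant AF is ~0.16 |
| `p_transmit` | 0.092 | tail-transmission probability per variant |
| `mean_depth` | 60 | sequencing depth |
| `depth_dispersion` | 0.02 | depth CV ~0.19, mild overdispersion |
| `dropout_rate` | 0.008 | false-negative rate of het calls |
| genome | 4 scaffolds x 3 Mb | 12 Mb model genome |

`mu`, `p_transmit`, `init_cell_fraction`, `mean_depth` and `dropout_rate`
mirror the study-scale estimates they emulate; the genome and founder-site
count are scaled down about 60-fold so a full cohort simulates and analyses
in seconds while every per-site statistic still has hundreds to thousands of
informative sites.  The substrain preset `sim_config_substrains()` adds
1,000 substrain-fixed variants per substrain and a 1.3-Mb ancestral
loss-of-heterozygosity block (each founder het inside it resolved to hom-ref
or hom-alt by one coin flip shared by all FS samples); the head-line default
leaves these at zero because the mutation-rate lineages all belong to a
single substrain.

The reproduction log is simulated as a separate individual-tracking process:
waiting times are log-normal (median 14 days, sdlog 0.6), a division is a
fragmentation with probability 0.3 with 1–3 middle pieces (probabilities
0.75/0.20/0.05, gaps 1–5 days), and death probabilities are 0.05 for heads
and middles and 0.22 for tails.  These magnitudes reproduce the qualitative
structure of individually cultured CIW4 lineages (tails die at >20% and wait
longer); they are not fitted values.  The log encodes a fragmentation chain
under the dividing body's worm id: the first bisection sheds the tail,
subsequent ones shed middles, and the head is emitted at the final division,
so every piece appears exactly once as an offspring row.

## Statistical and numerical choices

* **Weir–Cockerham FST** is computed per site from the two populations'
  genotype counts via the variance components $a$ (among populations), $b$
  (among individuals within populations, using observed heterozygosity) and
  $c$ (within individuals), as $a/(a+b+c)$.  Missing genotypes are dropped
  per population; the estimate is `NA` when a population is empty, both
  populations are single individuals, or the site is monomorphic overall.
  Negative estimates are retained (finite-sample behaviour).  Windowed FST
  is the arithmetic mean of per-site estimates in 10-kb tiles anchored at
  position 0 (half-open); reciprocally fixed populations give exactly 1 and
  all-het populations exactly 0.
* **Nucleotide diversity** per site is $n_\mathrm{ref} n_\mathrm{alt} /
  \binom{n}{2}$ over called alleles; windowed diversity divides the
  per-window sum by the window length, with unobserved positions
  contributing zero (the convention of standard VCF diversity tools).
* **LD pruning** keeps the earlier site of a violating pair, the common
  convention; correlations of constant-dosage sites are undefined and
  treated as 0.  Missing dosages are pairwise-deleted in r² and imputed to
  the site mean for PCA (which preserves centring).
* **ROH detection** implements the three stated criteria directly rather
  than a windowed heuristic scan: the criteria are exactly testable, and the
  direct scan is validated against an exhaustive chain search.  Missing
  genotypes neither support nor break a chain but count toward gap distance
  (a conservative choice, stated explicitly because the data format is
  silent).  Bookended intervals merge during consensus construction.
* **Pooled allele-frequency filter** follows the strict `> 0.5` rule, which
  retains a site that is heterozygous in every individual (pooled AF exactly
  0.5).  The depth band uses per-sample mean depths frozen at table
  construction, which makes the filter idempotent under subsetting.
* **Specificity classification** counts any non-hom-ref called genotype as a
  carrier (hom-alt included), with a `carriers = "het"` switch; imbalance
  summaries pool carrier (site, sample) records with defined AF, matching
  the per-SNP-datapoint testing design.  Whether a carrier definition should
  include hom-alt calls is genuinely open; "any non-reference evidence" is
  the default because classification is done from genotype calls while
  imbalance is measured separately from allele depths.
* **Newly detected mutations**: the descendant exemption is transitive, so a
  genuine new mutation transmitted onwards cannot veto itself; the 150-bp
  cluster rule removes *both* members of any close pair, after all
  membership filters; "covered by all libraries" means depth within the
  0.5–2x band in every library.  The false-negative AF band
  operationalising "heterozygous in all cells" is `[0.4, 0.6]` — a declared
  choice, as no band is stated.  The transmission SD is the sample (n-1)
  standard deviation across lineages.
* **Group comparisons** (Wilcoxon, Kruskal–Wallis, Fisher, Poisson and
  quasibinomial GLMs) are delegated to base R; the package produces the
  exact tables and record vectors those tests consume
  (`imbalance_summary()$records`, `repro_summary()`,
  `diversity_vs_depth_table()` with `fit_diversity_glm()`).

## What the synthetic data do and do not show

The simulator reproduces the statistical structure the analyses assume:
binomial read sampling around cell-fraction-determined allele frequencies,
overdispersed depth, genotype dropout, pedigree structure, fission
transmission, substrain-fixed differences, an LOH block, and a reproduction
log with the <6-day fragmentation semantics.  Passing recovery tests on it
therefore shows that the pipeline's estimators are consistent under the
stated model at realistic sample sizes.

It deliberately does not emulate several features of real data: mapping
artefacts and repeat-driven spurious heterozygosity (the repeat BED is empty
by default), indels and multiallelic sites (the reader handles them; the
generator emits SNPs), selection among neoblast clones, clone geometry
beyond one dimension, library-specific contamination, or reference bias.
Real-data quantities that depend on those features — for example the
depressed mean AF (~0.44) of shared variants caused by repeat-region SNPs —
are not reproduced: simulated shared variants sit at 0.50.

## Problem sizes

Unit tests run on tables of tens to a few hundred sites.  The end-to-end
recovery analyses simulate the full default cohort (20 samples, ~5,000–9,000
sites, three seeds for the head-line recovery) and complete in well under
two minutes; oracle-equivalence checks use 100 random instances per
operation with up to a few hundred sites each, sizes at which the
brute-force references are exact and fast.

## Known limitations

* The per-site FST "ratio of sums" windowed variant is not implemented;
  windowed FST is the mean of per-site estimates (with per-scaffold means
  available through `windowed_mean()` on scaffold-sized windows).
* `read_vcf()` loads the full table into memory; it is intended for
  cohort-scale VCFs (tens of samples, up to a few million records), not
  population biobanks.
* The genotype-caller emulation is a thresholded binomial caller; it does
  not model GATK's likelihoods, so GQ values are schematic.
* Reproduction-log analyses assume day-resolution integer dates.
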