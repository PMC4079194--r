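---
title: "Methods: cross-population haplotype selection scans and their simulation-based calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-population haplotype selection scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A recent, strong episode of positive selection drags a haplotype to high
frequency faster than recombination can break it apart. Relative to a
population that did not experience the selection, the swept population shows
unusually *extended haplotype homozygosity* (EHH) around the selected locus,
locally reduced nucleotide diversity, and long runs of homozygosity (ROH) in
its individuals. `haploscan` implements this whole inference chain for two
populations of phased diploid genotypes — a selected candidate (population
A, e.g. an intensively bred dairy line) and a reference (population B) —
together with a two-population simulator used to probe how the scan behaves
under explicit demographic and selection models.

## The statistics

**EHH.** For a core SNP and a marker at distance $x$, EHH is the probability
that two haplotypes drawn without replacement are identical at every site
from the core through the marker:

$$\mathrm{EHH}(x) = \sum_g \binom{e_g}{2} \Big/ \binom{n}{2},$$

where the $e_g$ are the sizes of the haplotype identity classes over that
interval. `compute_ehh()` uses the site-pooled form (both core alleles
together), the definition entering the cross-population ratio; EHH at the
core itself is 1 and the decay is computed separately left and right.

**iHH and XP-EHH.** `compute_ihh()` integrates the decay trapezoidally
against physical distance (bp), left plus right, truncated where the
*pooled-sample* EHH falls below a cutoff (default 0.05;
`truncation_boundary()`). The same boundary is used for both populations so
the ratio compares like with like. The per-SNP statistic is

$$\mathrm{XP\text{-}EHH} = \ln\left(\mathrm{iHH}_A / \mathrm{iHH}_B\right),$$

standardized to mean 0 and variance 1 over all defined sites. Extreme
positive scores indicate a sweep toward fixation in A; extreme negative in
B. Standardization uses the population variance (denominator $n$): "variance
1" is a property of the realized score set, and it makes pooled sets of
standardized scans exactly variance-1 as well.

Two numerical conventions matter here. Sites where either iHH is zero
(pooled EHH already below the cutoff at the first flanking marker) are
flagged undefined and excluded from standardization. And if raw scores are
exactly constant — e.g. population B is a literal copy of A — the
standardized scores are set to 0 with a warning rather than left 0/0.

**Windows and empirical P.** `make_windows()` splits each chromosome into
nonoverlapping 50-kb windows anchored at coordinate 0 and summarizes each
occupied window by its maximum score. Window arithmetic is 0-based
half-open throughout; 1-based VCF/matrix positions are converted (`pos - 1`)
at the boundary, the only place a ±1 appears. Because SNP-dense windows
have more chances to contain an extreme maximum, windows are binned by SNP
count in increments of 200 (1–200, 201–400, 401–599, and a combined bin for
everything ≥ 600 — a window with exactly 600 SNPs joins the combined bin)
and ranked within bins: the empirical P of window $i$ is the fraction of
bin members whose statistic strictly exceeds window $i$'s. Windows with
P < 0.01 are called significant. Consequences of the strict-inequality
definition: ties share a P, and each bin's best window has P = 0 exactly; a
`(k+1)/(N+1)` convention is available behind the `convention` argument for
users who need nonzero minima, without changing the default. Bins with
fewer than 50 windows are merged into the adjacent lower bin (with a
message) so every P rests on a meaningful reference set.

`empirical_p()` can also rank against an external `reference` window set
instead of the windows' own pool. This is how the simulation study scores
scenario replicates: each replicate is one short region, and ranking it
against itself would make one window per replicate "significant" by
construction. Ranking against pooled neutral-scenario windows mirrors the
real-data situation, where the genome-wide window set — overwhelmingly
neutral — is the empirical null.

**Diversity and ROH.** `window_pi()` computes windowed nucleotide diversity
$\pi = \sum_{\text{sites}} 2p(1-p)\,n/(n-1) \,/\, L$ with $L$ the full
window length (per-site diversity on a fixed grid, so monomorphic windows
report 0, and the trailing partial window is normalized by its actual
width). `detect_roh()` finds maximal runs of consecutive homozygous calls
per sample, allowing a configurable number of heterozygous calls inside a
run (default 0), and keeps runs of at least 50 kb. Run boundaries are the
first and last homozygous call (not midpoints to the flanking
heterozygotes — the simplest defensible convention); detection is greedy
left-to-right so reported segments never overlap; missing calls neither
break a run nor count against the tolerance, and are counted in an
attribute. Raising the length filter can only remove segments.

**Variant hard filters.** `hard_filter()` removes a site iff QUAL < 30, or
(MQ0 > 4 and QD < 5) jointly, or FS > 200. A missing annotation fails its
comparison conservatively — the filter exists to remove possible false
positives, so a site that cannot prove it passes is removed, and the count
of such decisions is reported.

## The simulator

`sim_config()` bundles one scenario. Defaults are the two-breed cattle
design the calibration study emulates:

| parameter | default | meaning |
|---|---|---|
| `theta` | 0.0012 | 4 N~e~ µ per site (used when `fixed_s = NULL`) |
| `n_e` | 300 | effective diploid size |
| `gen_years` | 5 | years per generation |
| `n_hap_a`, `n_hap_b` | 20, 22 | sampled chromosomes per population |
| `split_gen` | 1,200 | divergence time (≈ 6 ka at 5 y/gen) |
| `fixed_s` | 100 | condition on exactly S segregating sites |
| `region_bp` | 10^6^ | region length |
| `recomb_rate` | 10^-8^/bp/gen | crossovers in the forward sweep phase (1 cM/Mb) |

θ = 0.0012 is read as a per-site rate — it is exactly 4 × 300 × 10^-6^, a
standard mammalian per-site mutation rate at this N~e~ — and the default
region of 1 Mb gives a locus-wide θ of 1,200. With `fixed_s` set, mutations
are placed on the coalescent tree with probability proportional to branch
length, conditioning every replicate on exactly S sites (the `-s`
convention of classic coalescent simulators); positions are distinct
uniform integers over the region, so every emitted site is polymorphic and
strictly ordered. In fixed-S mode the coalescent itself runs without
intra-locus recombination, matching that convention; θ-mode obeys
E[S] = θ·L·Σ 1/i, which the test suite checks against the closed form.

**Demography.** The backward-in-time engine is a two-deme Hudson
coalescent: demes merge at `split_gen`, and an optional bottleneck
multiplies population size by `intensity` between two times. The default
bottleneck scenario (8,000–7,200 generations ago, intensity 0.01 — i.e.
40–36 ka at 5 y/gen) predates the split, so it acts on the ancestral
lineage; the configuration is written generally enough that a post-split
interval would act on deme A instead. Internal time is in units of 2 N~e~
generations with coalescence rate $\binom{k}{2}/x$ for relative size $x$ —
equivalent to the familiar 4 N~e~ scaling with rate $k(k-1)$, and chosen so
the mutation intensity is simply θ/2 per unit branch length.

**Sweeps.** A structured coalescent with selection is out of proportion to
a 10-generation selection episode, so `simulate_sweep()` uses a hybrid:
the neutral coalescent generates the *entire* standing variation of
population A (2 N~e~ = 600 founder haplotypes) plus the B sample, and A then
evolves forward under discrete Wright–Fisher reproduction for
`onset_gen` generations. Selection acts on one core site with additive
fitness 1, 1+s, 1+2s for 0/1/2 copies (the favoured homozygote twice the
heterozygote advantage); the scaled strength α = 2 N~e~ s follows the
convention of selection-capable coalescent software, so α = 100 and 500
give s ≈ 0.17 and 0.83. Gametes recombine with Poisson crossovers. The
core site is the segregating site nearest the region midpoint with founder
frequency in [0.1, 0.9]: a 10-generation episode acting on a breed trait is
selection on standing variation, and conditioning on an intermediate
starting frequency keeps the favoured allele's fate driven by selection
rather than by immediate drift loss. Replicates that lose the allele
anyway — in the population or in the final 20-chromosome sample — are
retried (up to 100 times, counted in an attribute), the implicit
conditioning-on-survival of selection simulators. Mutation is ignored
during the 10-generation forward phase; sites driven monomorphic in the
emitted combined sample by drift are dropped, so sweep replicates can carry
fewer than `fixed_s` sites. No migration connects A and B.

The deterministic limit of the forward phase,
$p' = p(1+s+sp)/(1+2sp)$, is exposed as
`deterministic_sweep_trajectory()` and verified in the tests against an
independently coded genotype-frequency recursion.

## Scoring simulated scenarios: two scales

`run_scenarios()` simulates each configured scenario, scans every
replicate, and reports scores on two scales:

* `std` — each replicate standardized internally. On this scale the
  scenario distributions are expected to *closely match* regardless of
  demography or even selection: a 1-Mb replicate that is swept end to end
  is its own standardization reference, so the region-wide shift cancels.
  This is the scale on which the robustness claim about demographic
  misspecification lives.
* `std_null` — every raw log-ratio standardized by the pooled moments of
  the *neutral* scenario. This is the analogue of genome-wide
  standardization on real data, where the reference is overwhelmingly
  neutral background; scenario differences (and planted sweeps) are visible
  here. Quantiles and Kolmogorov–Smirnov distances are reported on this
  scale when a neutral scenario is present.

The calibration study in the test suite runs the four default scenarios
(neutral; ancestral bottleneck; weak sweep α = 100; strong sweep α = 500) at
200 replicates each — enough for the rates and distances being asserted
while keeping the suite's runtime in minutes — builds the empirical null
from the pooled neutral windows, and checks that neutral and bottleneck
replicates flag a fixed window at approximately the nominal 1% rate, that
demography perturbs the score distribution far less than strong selection
does, and that the strong sweep's upper quantile exceeds the weak sweep's.

## What the generator does and does not emulate

The generator reproduces the *design* of the study it calibrates: sample
sizes, split time, fixed segregating-site count, bottleneck and selection
parameters. It does not emulate several features of real resequencing
data: genome-scale SNP density (a 1-Mb region with 100 sites, against
millions genome-wide), intra-locus recombination in the neutral history
(fixed-S convention), genotyping and phasing error, ascertainment, or
migration/admixture between the populations. Passing the simulation-based
tests therefore demonstrates that the statistics and the outlier machinery
behave as designed under the stated model — not that the scan has any
particular power or false-discovery rate on real genomes.

## Known limitations

* **Power in the simulated regime is intrinsically modest.** A
  10-generation sweep from standing variation at intermediate frequency
  fixes a *clade*, not a single haplotype: the A sample typically retains
  several distinct haplotypes, so iHH~A~ is elevated but not maximal.
  Meanwhile, without intra-locus recombination a neutral replicate is one
  unbroken haplotype block, which makes the neutral window-maximum
  distribution fat-tailed. Both effects compress the separation between
  swept and neutral replicates — visibly consistent with the observation
  that the scenario score distributions closely match — and the test suite
  reports the resulting core-window detection rate honestly rather than
  tuning the generator to inflate it.
* The coalescent engine supports two demes with one split and one
  piecewise size change; it is not a general demography description
  language.
* ROH detection with a nonzero heterozygote tolerance is greedy
  left-to-right; it reports non-overlapping segments, not every maximal
  tolerant window.
* `read_phased_vcf()` expects a single chromosome per file and fully
  phased, complete genotypes; these are preconditions of haplotype
  statistics, not parser limitations to be relaxed.
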