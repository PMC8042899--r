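---
title: "Models and methods behind popflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind popflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

popflow is built around a recurring study design in domestication genomics:
a wild population, a domesticated population derived from it, a diverged
sister lineage (here modelled on Southeast/South-Asian village ducks), and a
distant outgroup for allele polarization. The questions the package answers
are the classic trio: where has gene flow occurred between the diverged
lineages, where has selection reshaped the domesticated genome, and which
demographic gene-flow scenario best explains the data as a whole. This
vignette explains each model, its assumptions, the tunable parameters, and
the design decisions that were genuinely open.

## The variant substrate

All statistics run on a `variant_tbl`: a tibble of biallelic SNPs (one row
per site) with diploid genotypes coded 0/1/2 and missing calls as `NA`.
Multi-allelic and indel records are dropped at read time. Coordinates are
1-based inclusive internally (the VCF convention); BED output converts to
0-based half-open. No imputation is ever performed: every statistic uses
per-site non-missing counts. Chromosome lengths come from VCF `##contig`
headers when present, else `max(pos)`, so window truncation is
deterministic.

Sliding windows are anchored at position 1, `[k*step + 1, k*step + size]`,
truncated at the chromosome end. A trailing truncated window is emitted
while at least half of it lies on the chromosome; when `step == size`
additional truncated windows are emitted as needed so that windows tile the
chromosome exactly and every SNP falls in exactly one window. Windows
below the minimum SNP count are flagged `excluded` but still emitted, so
downstream joins stay aligned.

## Diversity and divergence statistics

Per site with derived/alternate frequency $p$ over $n$ called haplotypes:

* nucleotide diversity $\pi_{site} = 2p(1-p)\,n/(n-1)$; a window's
  $\theta_\pi$ is $\sum \pi_{site}$ divided by the window length in bp
  (non-variant positions count as monomorphic, matching the windowed-scan
  tools used in this field);
* absolute divergence $d_{xy,site} = p_A(1-p_B) + p_B(1-p_A)$, summed and
  divided by window length; symmetric by construction, and
  $d_{xy}(A,A) = \theta_\pi(A)\,(n-1)/n$ exactly;
* Tajima's D follows the 1989 constants, computed per window from the
  segregating-site count and the $\pi$ sum. The constants use the window's
  modal non-missing haplotype count; sites with a different count still
  contribute their own frequencies. A window with $S = 0$ is undefined
  (`NA`), never 0. In the ABC summary vector, undefined values are imputed
  as 0 so vectors stay finite for PLS; the imputation is the one deviation
  from `NA` semantics and is confined to that layer.

FST offers two estimators. The default is Weir & Cockerham (1984) variance
components with the windowed value computed as a ratio of sums
$\sum a / \sum (a+b+c)$ — the "weighted" convention of VCFtools — and
negative windowed values are reported as computed, because the sweep scan
Z-transforms the distribution and clamping would distort it. The
alternative `"hudson"` estimator is the plain frequency form
$\sum (p_1-p_2)^2 / \sum [p_1(1-p_2) + p_2(1-p_1)]$ without a finite-sample
correction; it exists to anchor the invariant suite (identical frequency
vectors give exactly 0, fixed differences exactly 1) and is not the
default precisely because it is biased upward in small samples.

LD decay uses composite (genotype-correlation) $r^2$ on unphased data, the
same quantity PopLDdecay computes from unphased VCFs, and
haplotype-frequency $r^2 = D^2/(p_A(1-p_A)p_B(1-p_B))$ when haplotypes are
supplied. Pairs are binned by physical distance; monomorphic members of a
pair are skipped.

## Gene-flow statistics

Sites are polarized by a designated outgroup: the ancestral allele is the
one fixed among the outgroup's non-missing calls, and sites where the
outgroup is polymorphic or entirely missing are excluded from polarized
statistics rather than guessed. This exclusion rule is a documented choice;
the alternative (using the major outgroup allele) is deliberately not
offered as a default because it biases ABBA/BABA counts near fixation.

For the four-population arrangement (((P1, P2), P3), O), frequency-based
pattern masses are `abba = (1-p1) p2 p3` and `baba = p1 (1-p2) p3`
(the outgroup's derived frequency is 0 after polarization), and

$$D = \frac{\sum (abba - baba)}{\sum (abba + baba)}.$$

Standard errors come from a delete-one block jackknife over non-overlapping
2-Mb coordinate blocks, and `|Z| > 3` is the conventional evidence
threshold. Two weighting schemes are provided, and the choice matters more
than is usually acknowledged:

* `"informative"` (default) weights each block by its informative mass
  $\sum(abba+baba)$, the Busing-style weighted jackknife. This is right for
  contiguous genomic blocks, where a block is a bundle of many
  weakly-correlated genealogies and the variance of its summed excess is
  roughly proportional to its mass.
* `"uniform"` is the classic unweighted delete-one jackknife. When each
  block is a single independent locus — as in simulation studies where
  loci are placed on separate blocks — all sites in a block share one
  genealogy, the block's ABBA-BABA excess scales with its whole mass
  (variance proportional to mass squared), and mass weighting then
  underestimates the standard error by a noticeable margin. The package's
  own null-calibration experiments use uniform weights for exactly this
  reason, and the difference is visible: with mass weights the null rate
  of |Z| > 3 is a few percent, with uniform weights it is at the nominal
  level.

The f3 three-population test uses the unbiased per-site form
$t = (p_A-p_B)(p_A-p_C) - h_A/n_A$ with
$h_A = p_A(1-p_A)n_A/(n_A-1)$, averaged over sites, with the same block
jackknife (site counts as weights). No heterozygosity scaling is applied:
only the sign and Z enter the inference this package supports, and the
reference implementation's normalization is not described precisely enough
to copy. Significantly negative values (`Z <= -2` by convention) indicate
the target is admixed.

The fd window scan (Martin et al.'s modification of the admixture-fraction
estimator) replaces P2 and P3 by the per-site donor proxy
$p_D = \max(p_2, p_3)$ in the denominator. Windows default to 100 kb at
20-kb steps with at least 100 usable polarized SNPs. Windows with a
non-positive numerator get `fd = 0` rather than `NA` so that region calling
is well defined (a switch restores `NA` semantics); a zero denominator with
positive numerator is flagged undefined. Candidate regions are maximal
runs of overlapping or bookended windows with `fd >= 0.5`, and merged
spans shorter than 200 kb are dropped — both constants are arguments, with
these defaults.

Verification distinguishes introgression from incomplete lineage sorting:
recent gene flow makes recipient haplotypes coalesce with donor haplotypes
after the split, reducing $d_{xy}$ locally, whereas shared ancestral
polymorphism does not reduce $d_{xy}$ at all. `verify_region()` therefore
contrasts the region's recipient-donor $d_{xy}$ and FST against a
background built from all windows of the region's size, reporting z-scores
against the background mean and SD. The package's ILS control (a tenfold
larger ancestral population and no gene flow) shows no localized reduction,
while planted tracts show clear negative z-scores.

## The sweep scan

The wild/domestic contrast runs in 40-kb windows at 10-kb steps. For each
usable window the scan reports $\log_2(\theta_{\pi,wild}/\theta_{\pi,dom})$
and the Z-transformed FST over included windows. Outliers must exceed the
empirical upper 5% quantile of both scores jointly; the thresholds are
always recomputed from the data at hand, because published cutoff values
are properties of a particular dataset, not of the method. Windows where
the domestic group has zero diversity cannot enter a log ratio; they are
flagged `fixed_dom` and set aside rather than pseudo-counted, because a
pseudo-count would distort the upper quantile that defines the outlier set.
Outlier comparisons are strict (`>`), so a degenerate scan in which every
window is identical flags nothing. Tajima's D is computed alongside for
both groups but is not part of the outlier rule. Overlapping outlier
windows merge into regions; genes overlap a region with 1 bp of
intersection.

## The coalescent simulator

`simulate_dataset()` is an event-driven structured coalescent over
independent loci: per-deme coalescence at rate $k(k-1)/(4N_e)$ per
generation (continuous-time approximation), per-lineage backward migration
at rate $m$, deme joins and size changes at fixed times, and
infinite-sites mutations placed as Poisson($\mu L \times$ branch length)
uniformly on branches. The core is ~200 lines of C++ driven by R's RNG, so
`set.seed()` gives bit-identical output. Independent loci (no intra-locus
recombination) match the multilocus summary-statistic workflow the ABC
layer emulates; they are *not* suitable for LD studies, which is why a
dedicated single-locus mode assembles haplotypes by jumping between
independent genealogies at Poisson crossover points — an explicit
approximation to recombination that produces the expected monotone decay of
$r^2$ with distance, used only for LD validation.

Scaled migration is specified as $4N_e m$ per edge (symmetric by default)
and converted internally using the backward deme's size. Times are
generations internally; years appear only at reporting via the generation
time (1 year by default, the conventional value for ducks, with mutation
rate 1.91e-9 per bp per generation).

Neutral checks are part of the test suite: a constant-size deme reproduces
$E[\pi] = 4N_e\mu$ and $E[S] = \theta a_1 L$ within three Monte-Carlo
standard errors over 2000 loci, and mean Tajima's D is statistically
indistinguishable from 0.

## The eight-model ABC layer

The model space holds the topology fixed — domestic and the
Southeast/South-Asian lineage merge at `t1`, their ancestor meets wild at
`t0` — and varies which symmetric migration edges are active: none (M1),
each single pair (M2-M4), two pairs (M5, M6), all three pairs continuously
(M7), or all three only in the most recent `t1/2` generations (M8). This
composition spans the natural lattice of gene-flow hypotheses on a fixed
tree; the registry is deliberately plain data, so a different model set
and priors can be substituted wholesale when a specific published
comparison must be matched. Priors:
log-uniform diploid sizes on [1e3, 1e6]; `t0` uniform [1000, 10000] and
`t1` uniform [100, t0) by rejection; founding-bottleneck fractions
log-uniform [0.01, 1] applied over the oldest fifth of each derived deme's
existence; `4Nm` uniform [0, 20] per active edge.

Each simulated or observed dataset is summarized by 37 statistics: per
population S, derived singletons, private segregating sites, $\theta_\pi$,
Tajima's D and expected heterozygosity (18); the same four pooled over
populations (4); and per pair FST, $d_{xy}$, net divergence
$d_a = d_{xy} - (\pi_1+\pi_2)/2$, shared polymorphic sites and fixed
differences (15). This composition is one defensible choice at this
dimensionality (the arlsumstat-style multilocus workflow it emulates
computes a comparable set) and can be subset or replaced; statistics are
computed by the same code path for simulated and empirical data (simulated
haplotypes are paired into pseudo-diploids first).

The statistics are compressed by PLS-DA — NIPALS partial least squares
with one-hot model labels as the response, on standardized statistics —
into 9 components by default. The transformer is a fixed linear map
fitted once on the reference table and applied identically to observed
data. The in-package NIPALS implementation exists because the reduction
must be a reusable, exactly-reproducible transform; the test suite
cross-checks its components against mixOmics on constructed data.

Model choice offers two estimators:

* *rejection*: the posterior is proportional to each model's share of the
  globally nearest `retain_fraction` of simulations (Euclidean distance in
  PLS space);
* *glm* (the Leuenberger-Wegmann construction, default): per model, the
  nearest `retain_fraction` of that model's own simulations are retained, a
  linear-Gaussian regression of PLS statistics on the model's parameters is
  fitted (ridge 1e-8 on the normal equations; a floor on the retained
  count guarantees enough degrees of freedom for the residual covariance),
  and the marginal density of the observed statistics — the fitted Gaussian
  averaged over retained parameter draws — is combined with an equal model
  prior. Densities are accumulated in log space and normalized by the
  maximum, so posteriors remain proper when all densities underflow.

`validate_model_choice()` closes the loop: pseudo-observed datasets drawn
from each model's own prior are classified against the reference tables,
and the diagonal of the confusion matrix measures self-recovery. At the
package's validation scale (2000 simulations and 50 pseudo-observed
datasets per model, 50 loci of 2 kb, 20 haplotypes per deme) mean diagonal
recovery is around 0.35 against a chance level of 0.125 — the models
overlap heavily by construction, since single-edge and multi-edge scenarios
nest, so perfect recovery is not expected and not claimed.

## The synthetic fixture

`generate_fixture()` emulates the three-group duck design: 19 wild + 25
domestic + 21 Southeast/South-Asian + 4 outgroup diploids, two 5-Mb
chromosomes tiled from 5-kb independent loci, split times 1700 and 3500
generations, outgroup join at 500k generations, mutation rate 1.91e-9, and
founding bottlenecks in the derived demes (fractions 0.05 and 0.03). The
bottlenecks matter: they push within-population diversity below
between-population divergence, which is the regime in which $d_{xy}$-based
introgression verification can work at all; split times this recent
relative to $N_e$ would otherwise leave differentiation almost entirely
ancestral. The bottleneck severity was chosen once, from demographic
evidence that village-duck lineages passed through severe founding
bottlenecks, to place donor diversity at roughly half of background
divergence.

Planted truths are haplotype-level edits after simulation: an introgressed
tract copies randomly paired donor haplotypes into a configured fraction of
recipient haplotypes over a contiguous interval (default 400 kb at
fraction 0.5); a sweep replaces all target-deme haplotypes in an interval
by one founder plus Poisson new singletons. Both truths are recorded as
BED intervals so scans can be scored against them. What the fixture does
*not* emulate: genotyping error, missing data structure, intra-locus
recombination (LD at locus boundaries drops to baseline), variable mutation
rate, and linked selection. Passing recovery tests therefore demonstrates
that the estimators see the signals they are defined to see under clean
conditions — not that real data will be as kind.

In the fd recovery experiments the wild group serves as P1 (the unadmixed
reference), the recipient domestic group as P2 and the donor as P3. Because
P2 and P3 are sisters in this topology, genome-wide D is positive even
without the planted tract; the scan localizes the tract against that
baseline, matching standard practice of choosing an unadmixed reference
as P1. For the null calibration of D,
where E[D] = 0 must hold exactly, P1 and P2 are instead two halves of the
domestic sample — exchangeable by construction.

## Numerical choices and problem sizes

Degenerate inputs are handled by rule, not by accident: zero jackknife
variance reports SE 0 with an infinite Z flag; an all-uninformative D is an
error; a fully missing population at a site is skipped by every statistic;
`fd` windows below the SNP floor are excluded from calling but still
reported. The acceptance experiments run at sizes chosen to make their
statistical claims testable on one CPU in minutes: 200 null replicates of
100 loci x 5 kb for D calibration; 20 fixtures of one 5-Mb chromosome for
each recovery rate; 2000 loci for simulator neutrality; 2000 simulations
and 50 pseudo-observed datasets per model for ABC validation. These sizes
are the package's own validation conditions and are stated here so that
anyone re-running them knows what was actually measured.

## Known limitations

The simulator's continuous-time approximation slightly distorts
coalescence when sample sizes approach deme sizes; priors allowing
$N_e = 10^3$ with 20 sampled haplotypes sit within the usual tolerance of
this approximation. The GLM density model assumes local linearity of
statistics in parameters over the retained neighborhood; with very small
retained sets it degrades toward the rejection answer. Region calling
merges bookended windows only — a single excluded window splits a region,
which is the conservative behavior. The package deliberately does not
estimate admixture proportions (f4-ratio), paint local ancestry, or infer
continuous Ne trajectories; those sit outside its scope.
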