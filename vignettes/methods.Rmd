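---
title: "Methods: models, estimators and design choices in popgensweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in popgensweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

popgensweep re-implements, as tested and reusable building blocks, the
self-contained computations of a resequencing-based domestication study of a
perennial outcrossing tree: site filtering from VCF, sliding-window
diversity, an FST + reduction-of-diversity (ROD) selective-sweep caller, LD
decay, four-population ABBA-BABA tests, and p-distance neighbour-joining.
Because the original data volume (hundreds of genomes) is not reproducible
at desk scale, every estimator is validated instead against a bundled
forward Wright-Fisher simulator with known truth.  This vignette documents
the models, the parameter conventions, and the places where the design was
genuinely open.

## Genotype model and site filters

Genotypes are diploid alternate-allele dosages (0/1/2, `NA` for missing) in
a sites-by-samples matrix; phase is ignored by every statistic, although
the simulator carries haplotypes so that phased operations (sweep
injection, phased VCF output) remain possible.  Site retention uses four
rules applied with *strict* inequalities, matching the printed operators of
the protocol it follows: biallelic; QUAL > 30; missing rate < 0.25; MAF >
0.05 computed over non-missing calls only.  A site failing several rules is
attributed to the first failing rule in that fixed order, so the filter
report always reconciles with the input count.  The missing rate is the
fraction of samples with a missing GT call (per-sample fraction); whether
the original pipeline used per-sample or per-allele missingness is not
stated, and this choice is declared rather than guessed.

## Windowed diversity

Windows start at 1, 1 + step, ... per chromosome (defaults 10 kb / 5 kb for
diversity, 100 kb / 10 kb for the selection scan); the terminal window is
truncated and normalised by its true length.  Per window:

* theta-pi is the sum of per-site unbiased heterozygosities
  `(n/(n-1)) 2p(1-p)` divided by the window length in bp.  Unlisted
  positions are treated as invariant (no accessibility mask): diversities
  of order 1e-3 are conventionally reported on that denominator and the
  upstream protocol provides no mask.
* theta-w sums `1/a1(n_i)` over segregating sites, with the harmonic
  number evaluated at each site's effective allele count, again per bp.
* Tajima's D uses the 1989 constants at a single haplotype count per
  window (the rounded mean effective allele count over segregating sites;
  the variance formula admits only one n).  Windows with S < 2 or n < 4
  yield `NA` rather than 0, and windows whose allele counts vary more than
  two-fold are flagged.

## Selection scan

FST is the Weir & Cockerham (1984) estimator in its allele-frequency
(haploid) form without the within-individual component, aggregated per
window as a ratio of sums -- the windowed weighting used by the standard
VCF tooling the protocol ran.  Negative per-window values are retained so
the top-decile rule operates on the estimator's native scale.  ROD is
`1 - pi_dom / pi_wild` (undefined where `pi_wild = 0`); the raw ratio
`pi_wild / pi_dom` is emitted alongside because the source figure legend
prints the ratio form, while the caller thresholds the `1 -` form.  A
window is called when FST > 0.15, FST is at or above the 90th percentile
of defined window FSTs (type-1 quantile, so the cutoff is an observed
value and the boundary is closed), and ROD > 0.2; qualifying windows that
overlap or touch are merged, since 100-kb windows on a 10-kb step overlap
by construction.  Genes are annotated into regions on >= 1 bp overlap
(1-based inclusive; BED input is converted on import) -- whether the
original gene lists required full containment is unstated, and partial
overlap is the declared choice.

## LD decay

r-squared is the squared Pearson correlation of dosage vectors over
samples non-missing at both sites.  All intra-chromosomal pairs within
200 kb (the protocol's bound) are binned by distance; the half-decay
distance is where the lightly smoothed bin-mean curve first falls to half
of its *maximum bin mean*, linearly interpolated between the bracketing
bins.  Measuring from the maximum rather than from distance zero is
deliberate: r-squared at zero distance is unobservable.  "~50%" is
implemented as exactly 50%.  Above a pair cap (default 5e6) pairs are
uniformly subsampled under the run seed, and the cap and seed are recorded
in the output.  The binning and interpolation conventions are explicit
substitutes for choices the upstream protocol does not state.

## Gene flow

The D statistic is frequency-based,
`D = sum((w-x)(y-z)) / sum((w+x-2wx)(y+z-2yz))` over informative sites,
with Z the outgroup; sites where the outgroup frequency is more than 0.01
from 0 or 1 are excluded so the outgroup orients the ancestral state.  For
haploid populations this reduces to pattern counting with positive values
indicating excess W-Y (or X-Z) sharing -- exactly the published verbal
convention that positive Z scores mean gene flow between W and Y or
between X and Z, negative between W and Z or X and Y, significant when
|Z| > 3.  (The source's own lettering is internally inconsistent, naming
the outgroup "X" in one sentence; this implementation fixes Z as the
outgroup and reports the published interpretation strings verbatim.)
Standard errors come from a delete-one block jackknife over contiguous
genomic blocks (default 5 Mb, or total span / 20 on short simulated
genomes -- no block size is published); identical leave-one-out values are
reported as a degenerate z = +/-Inf flag rather than an error.  Wright's
`Nm = (1 - FST) / (4 FST)` is exposed as a direct transform, undefined for
FST <= 0.

In the bundled four-population scenario `(((W,X),Y),Z)` the admixture
pulse flows from Y into X, so D for the quartet ordered (W, X, Y, Z) is
expected *negative*; the simulation truth records that sign and the power
experiment checks it.

## Phylogeny

The p-distance between unphased diploids is the allele-difference fraction
`sum |d_a - d_b| / (2 n_shared)`, a phase-free convention that reduces to
the standard p-distance for haploids (how the original pipeline scored
heterozygous calls is unstated).  Neighbour-joining is the Saitou-Nei
algorithm with the O(n^3) Studier-Keppler update, deterministic smallest
(i, j) tie-breaking, and negative branch lengths clamped to zero with a
flag; on additive matrices it reproduces the generating tree's topology
and branch lengths to 1e-9.  Outgroup rooting places the root at the
midpoint of the outgroup's pendant edge, which preserves all leaf-to-leaf
path lengths and is idempotent.

## The simulator: what it emulates and what it does not

The generator is a discrete-generation forward Wright-Fisher model:
per-gamete parent choice (selfing allowed at rate 1/N), Poisson
recombination with uniform breakpoints, infinite-sites mutation on integer
positions with collision re-draw (keeping every site biallelic, matching
the filter model), per-gamete migration, and events (resize, deme split,
one-generation admixture pulse).  All randomness flows through R's RNG, so
a fixed seed reproduces output byte-identically across platforms.
Chromosomes are independent replicates of the same demography, which is
exact for every neutral statistic computed here.  Fixed differences are
purged (they carry no information under infinite sites), and only sites
segregating in the final sample are emitted.

Stated-world defaults, chosen once:

* **Equilibrium calibration** uses N = 100 diploids, 4Nmu = 0.005/bp over
  ~1 Mb (201 overlapping 10-kb windows) after a 10N-generation burn-in;
  theta-pi and theta-w then sit within a few percent of 4Nmu and mean
  Tajima's D near 0.
* **Two-deme island model.** Wright's `FST = 1/(1+4Nm)` is an
  infinite-island result.  For two demes, the pairwise FST a two-population
  estimator measures is `(T_b - T_w)/T_b = 1/(1 + 8 N m_raw)` (within-deme
  coalescence time 4N; between-deme excess `1/(2 m_raw)`), so the
  constructor sets `m_raw = Nm/(2N)`, making the realized FST target
  Wright's curve.  Because a structured population relaxes on the
  between-deme timescale `4N + 1/(2 m_raw)`, the burn-in is at least six
  such times rather than the generic 10N.
* **Domestication scenario.** The domesticated deme splits from the wild
  deme and is held at 80% of its size for 10 generations -- a mild
  perennial domestication losing roughly 10% of diversity, consistent with
  the few-percent pi reduction the motivating study reports (its only
  stated effect size); background FST (~0.08) stays below the sweep
  thresholds.  Sweeps are injected post hoc by replacing haplotypes inside
  a 200-kb interval with draws from k founder haplotypes (k = 2 for the
  recovery experiments); forward-simulated selection dynamics are out of
  scope.  The synthetic genome (2.4 Mb) is chosen large enough that the
  geometric overhang of qualifying 100-kb windows around a true sweep
  stays in proportion to real chromosomes; on much shorter genomes the
  overhang alone would dominate the false-positive accounting.
* **LD scenarios.** LD depends on the scaled rates 4N*rec and 4N*mu, so
  target per-bp recombination rates of 1e-8 to 1e-7 (natural-population
  scale) are emulated at N = 100 by multiplying rec by an effective-size
  factor (default 20).  Half-decay distances then land at 1-30 kb, the
  range the 100-bp (experiments: 500-bp) bins are designed to resolve.
  The bottleneck contrast holds a split deme at 10% size for 80
  generations; a bottleneck curve that never decays to half its maximum
  within the examined span counts as "longer LD" provided the ancestral
  curve's half-distance is defined.

What the simulator does *not* emulate: realistic chromosome counts and
lengths, accessibility masks, genotyping error and QUAL variation (all
simulated sites carry QUAL 60 and no missingness), gene conversion,
overlapping generations, and selection simulated forward in time.  A green
recovery test therefore establishes that the estimators measure what they
claim on data satisfying their own model assumptions -- not that the
original study's numbers are reproduced.

## Numerical and interface choices

* Coordinates are 1-based inclusive throughout; BED output converts to
  0-based half-open at the boundary only.
* Multiallelic records are read as-is and dropped (not split) by the
  biallelic rule.
* Pipeline configuration is JSON (the environment provides no YAML
  parser); every run writes a manifest with the config, its md5 hash, the
  package version and the seed, sufficient to reproduce any output.
* Experiment replicate counts in the acceptance suite are scaled down
  (25 sweep replicates, 60 per D-statistic arm) to fit single-CPU runtime
  budgets; the thresholded rates are unchanged and the scaling is noted
  where it happens.

## Known limitations

* The forward simulator is O(generations x haplotypes x polymorphism) and
  is meant for 1e5-1e6 bp genomes with tens to hundreds of diploids, not
  chromosome-scale data.
* Tajima's D with heavy, unevenly distributed missingness uses one
  haplotype count per window; the `n_varies` flag marks windows where that
  approximation is doubtful.
* The jackknife assumes blocks are exchangeable; on genomes shorter than
  ~10 blocks the D test refuses to report a Z score rather than
  fabricating one.
* `nm_from_fst` inherits every caveat of Wright's island-model identity;
  it is a reporting transform, not an estimator of contemporary migration.
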