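---
title: "Detecting mosaic allelic imbalances from SNP-array BAF tracks"
author: "mosaicseg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mosaic allelic imbalances from SNP-array BAF tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicseg)
```

## The signal model

A SNP array reports, per probe, the B-allele frequency (BAF) — the fraction
of hybridisation signal attributable to the B allele — and the log R ratio
(LRR), a log2 proxy for total copy number. In a homogeneous diploid sample
heterozygous probes cluster at BAF 0.5 and homozygous probes at 0 and 1.
When only a fraction $p$ of cells carries a chromosomal alteration, the
heterozygous cluster splits into twin bands displaced symmetrically from
0.5 by an amount that depends on the event type:

| event        | upper band position | band offset $b$      |
|--------------|---------------------|----------------------|
| copy-neutral (UPD) | $(1+p)/2$     | $p/2$                |
| deletion     | $1/(2-p)$           | $p/(2(2-p))$         |
| duplication / trisomy | $(1+p)/(2+p)$ | $p/(2(2+p))$    |

These follow from counting B-allele copies over the cell mixture: for a
duplication, for instance, the affected cells carry 3 copies of which 2 are
B at an upper-band probe, so BAF $=((1-p)+2p)/(2(1-p)+3p)=(1+p)/(2+p)$.
Inverting these band positions is what [estimate_cell_fraction()] does:
$p = 2b$ (UPD), $p = 2b/(0.5+b)$ (deletion), $p = 2b/(0.5-b)$
(duplication), clipped to $[0,1]$. Because LRR shifts are tiny at low $p$,
BAF carries essentially all of the detection signal; LRR is used only
afterwards, to classify a called region.

## From BAF to a segmentation signal

Each probe's **b-deviation** is the absolute deviation of its BAF from the
expected cluster, $b_{dev} = |BAF - e|$, with $e \in \{0, 0.5, 1\}$ taken
from the genotype call when available and otherwise from the nearest
cluster (ties at 0.25/0.75 resolve toward 0.5, which favours sensitivity to
allelic imbalance). The b-deviation is compressed against its floor at 0,
so before segmentation it is spread by a clamped probit,
$\Phi^{-1}(\mathrm{clamp}(b_{dev}, \varepsilon, 1-\varepsilon))$ with
$\varepsilon = 10^{-4}$ (floor value $\approx -3.72$). The transform is
strictly monotone, keeps the null signal in a bounded band, and stretches
exactly the near-zero region where the mosaic signal lives.

A caveat we verified by simulation: the clamped probit does **not** make
the per-probe null distribution normal — at noise SD 0.03 the transformed
null has skewness about $-0.9$, and values within a shifted band (offset
0.05) about $-1.4$. The package does not rely on per-probe normality:
every test statistic is a mean over at least `min_seg_len` probes (300 by
default), where the central limit theorem applies comfortably.

Segmentation runs over **all probes with usable BAF** by default.
Homozygous probes contribute near-floor values regardless of mosaic state
and so dilute the per-probe effect size, but keeping them makes
`min_seg_len` count array probes, which is what ties the parameter to
physical span: 300 probes on a 1M-probe, 3,000-Mb array is 0.9 Mb. The
`informative_only` option restricts the signal to heterozygous probes
(genotype `AB`, or BAF inside `het_window = (0.1, 0.9)` without
genotypes) for callers who prefer the denser per-probe signal and are
willing to rescale `min_seg_len` themselves.

## Segmentation: sparse candidates plus backward elimination

Detection is a changepoint problem: find contiguous probe runs whose mean
transformed b-deviation exceeds the background. The search has two stages.

**Candidate generation** (`sbl_candidates()`): the signal is scanned at
dyadic window sizes $w = 4, 8, \dots$ for boundaries where the flanking
$w$-probe means differ by more than a threshold number of noise SDs; local
maxima of the window statistic become candidates. The threshold decreases
linearly in the sparseness prior $a$ (`4.2 - 3a`, floored at 1.5), so
$a = 0.8$ admits many candidates (sensitive, more false leads for the next
stage to prune) and $a = 0.2$ few. Any boundary whose flanking windows
differ by at least 4 noise SDs exceeds every threshold in the supported
range of $a$ already at the smallest scale, which gives a guaranteed-recall
floor that the test suite exercises. Candidates are then polished by
coordinate-descent relocation (`refine_breakpoints()`): each breakpoint
moves to the exact maximum-likelihood changepoint within the span bounded
by its neighbours, a step that monotonically reduces the residual sum of
squares of the piecewise-constant fit, so the sweep loop terminates
cleanly (relative RSS tolerance `1e-4`, at most `max_iter = 10` sweeps).

**Backward elimination** (`backward_eliminate()`): with noise scale
$\hat\sigma$ estimated robustly from successive differences
($\mathrm{median}|\Delta y| / (\sqrt{2}\cdot 0.6745)$ — insensitive to the
very level shifts being sought), each boundary between adjacent segments
$L, R$ carries
$t = (\bar y_R - \bar y_L) / (\hat\sigma\sqrt{1/n_L + 1/n_R})$.
The weakest boundary is removed and its neighbours' statistics recomputed,
until every surviving boundary has $|t| \ge T$. Since a run at a higher
threshold simply continues the elimination sequence of a lower one, the
surviving set is nested in $T$ — thresholds can be swept cheaply and the
ranking reused. After elimination, segments shorter than `min_seg_len`
merge into the neighbour with the closer mean (ties merge left), surviving
boundaries are relocated once more within their now-clean spans, and the
minimum length is re-enforced.

**Emission**: b-deviation rises under every event type, so altered segments
are those standing out *above* background. The background level is the
10%-trimmed mean of the transformed signal — pooled across chromosomes in
[call_mosaics()], so that a wholly altered chromosome (mosaic trisomy) is
still visible against the rest of the genome. A segment is emitted when its
mean exceeds background with
$t_{seg} = (\bar y_i - \bar y_{bg})\sqrt{n_i}/\hat\sigma \ge T$; this is
the same $T$ that drives elimination, and it is what makes the FDR
estimator below the matching bound for the emitted calls. Each call gets a
two-sided p-value from the $t_{n_i-1}$ tail (a documented switch uses the
normal tail for segments above 200 probes).

## Genome-wide FDR control

The number of opportunities for a false call on an $N$-probe array is
bounded by the count of disjoint minimum-length windows, $N/\texttt{min\_seg\_len}$;
each exceeds $T$ under the null with probability
$P(|t_\nu| > T)$, $\nu = \texttt{min\_seg\_len} - 1$. Hence

$$\widehat{\mathrm{FDR}} = \min\left(1,\;
  \frac{(N/\texttt{min\_seg\_len})\, P(|t_\nu| > T)}{\max(n_{called}, 1)}\right),$$

reported as 0 when nothing is called (the expected false count is still
recorded so parameter scans stay well defined). The estimator is
deliberately conservative — windows overlap in reality, and elimination
makes calls rarer than windows — and the benchmark suite verifies by
simulation that it upper-bounds the realized false-discovery fraction
across noise levels, mosaic fractions and thresholds, while both fall as
$T$ grows. At the default profile ($T = 8$, `min_seg_len = 300`,
$N = 10^6$) the bound is below $10^{-4}$. `recommend_settings()` picks the
smallest $T$ on the grid $\{2, 2.5, \dots, 5, 8\}$ meeting a target FDR,
with the window scaled proportionally to array size
(`300 * N / 1e6`).

## Classification and cell fraction

LRR thresholds are applied *relative* to the sample's diploid baseline: the
mean LRR over autosomal probes outside every call (X and Y are excluded;
a constant intensity offset therefore cannot change any classification).
Calls with relative mean LRR below $-0.10$ are deletions, above $+0.10$
duplications, and inside the closed band $[-0.10, 0.10]$ copy-neutral
(UPD). A copy-number call covering more than 95% of its chromosome's probes
is promoted to a whole-chromosome event — trisomy for gains and, by
symmetry, monosomy for losses (the monosomy label is this package's
addition; whole-chromosome losses would otherwise be reported as giant
deletions). Low-fraction gains sit inside the UPD band by construction
(a 10% duplication shifts LRR by only $\log_2(2.1/2) \approx 0.07$), and
genuine duplications cannot always be separated from constitutional ones —
both limitations are inherent to the thresholds, not to the
implementation.

The affected cell fraction is estimated from the **median** per-probe
b-deviation of heterozygous probes inside the call (median, because the
twin bands make the per-probe distribution bimodal-tailed; heterozygous
only, because homozygous probes carry no dosage information on the
original scale), inverted through the event-specific band formula above.

## The simulator

`simulate_track()` reproduces the statistical design used throughout the
validation experiments, and its defaults *are* those study conditions:
20,000 probes per chromosome at uniform 3-kb spacing; genotypes AA/AB/BB
drawn at 0.25/0.50/0.25; heterozygous BAF $\sim N(0.5, \sigma)$ with
$\sigma = 0.03$ (good quality) or $0.1$ (noisy); homozygous BAF anchored
at 0 and 1 with a skewed, log-normal-shaped deviation of SD $\sigma$
(mode $\approx 0.17\sigma$, i.e. $\approx 0.005$ at good quality) — a
literal normal at the anchors would leave $[0,1]$ half the time, so a
boundary-respecting skewed law is the realisable reading of the design;
altered blocks of 1,000 (small) or 10,000 (large) probes whose
heterozygous probes split evenly at random between the twin bands
$0.5 \pm b$ (bands 0.55/0.60 correspond to 10%/20% affected cells under
the copy-neutral mapping). LRR is simulated from the event's dosage
(0 for UPD, $\log_2((2-p)/2)$ for deletions, $\log_2((2+p)/2)$ for
gains) plus $N(0, 0.15)$ probe noise, so that classification and
cell-fraction recovery are testable end to end.

What the simulator does **not** emulate: GC waves and regional LRR drift,
probe-specific bias and outlier probes, genotyping-error clusters,
non-uniform probe spacing, and linkage between neighbouring genotypes.
Passing the simulated benchmarks therefore demonstrates the statistical
machinery under the designed noise model, not robustness to
platform artefacts; on real arrays the conservative profile and the
relative-LRR classification absorb some, but not all, of these effects.

`simulate_study_grid()` enumerates the eight validation scenarios
({10%, 20%} cells x {small, large} block x {good, noisy}), and
`simulate_proportion_series()` the low-fraction sensitivity design (a
1,000-probe block at proportions 0, 0.01, ..., 0.15, 200 replicates
each, copy-neutral shift $p/2$). All replicate seeds derive
deterministically from one master seed.

## Benchmarks and the sizes they run at

* `sensitivity_curve()` — detection rate (a call covering at least 50% of
  the simulated block) per proportion, with the trapezoid area over
  $[0, 0.15]$ and its normalisation by the perfect curve. At the reference
  operating point ($a = 0.5$, $T = 2$, `min_seg_len = 900`) the package
  reproduces a sensitivity of ~1.0 at proportion 0.15 and a normalized
  area of ~0.75.
* `roc_experiment()` — probe-level TPR/FPR over the $(a, T)$ grid
  ($a \in \{0.2, 0.8\}$, $T \in \{2.5, \dots, 5\}$); probe-level rates are
  used because they are insensitive to how a region is split into calls
  (a segment-level notion is available through [detection_success()]).
* `fdr_calibration()` — estimated versus realized FDR per scenario and
  threshold, with a call counted false when it is completely disjoint
  from the simulated block.

The shipped test suite runs these at reduced replicate counts chosen as a
package default for a routine check — 200 replicates for the single-point
sensitivity and null-FDR checks, 20 per curve point (1/10 of the reference
design, with correspondingly widened tolerances), 8 per ROC/FDR cell — and
`scripts/acceptance.R` re-runs the sensitivity experiment at the full
16 x 200 design. `cmd_bench(..., fast = TRUE)` gives the same 1/10
scaling from the command line.

## Numerical and design choices

* **Ties and determinism.** Elimination removes the first of tied weakest
  boundaries; short-segment merging takes the shortest segment first and
  merges left on ties; the nearest-cluster rule sends 0.25/0.75 to 0.5.
  Everything downstream of the simulator's RNG is deterministic, and every
  stochastic experiment takes an explicit master seed.
* **Degenerate inputs.** Tracks with fewer than `2 * min_seg_len` usable
  probes are skipped with a warning; all-missing BAF is an error; duplicate
  positions keep the first probe (warning); BAF outside $[0,1]$ is an
  error naming the probe. Missing BAF/LRR values are excluded, never
  imputed — imputation would bias the b-deviation toward 0.
* **Whole-signal alterations.** A single track processed alone compares
  segments against its own trimmed mean, so an alteration spanning the
  entire track is undetectable by construction; genome-wide calling pools
  the background across chromosomes precisely to expose such events.
* **The candidate generator is a contract, not a canon.** Any generator
  that (i) produces more candidates as $a$ grows and (ii) never misses a
  4-SD boundary can replace the multiscale scan without touching the
  elimination, FDR, or classification stages; the test suite pins the
  contract, not the generator's internals.
* **Known limitations.** Runs of homozygosity by descent are
  indistinguishable from high-fraction mosaic UPD without pedigree or
  population data; constitutional duplications overlap mosaic gains in
  LRR; sensitivity below ~3% affected cells is limited at good quality
  (and worse at $\sigma = 0.1$); `min_seg_len` trades resolution against
  false calls and should be rescaled for sparser arrays.

## A worked call

```{r example, eval = FALSE}
params <- seg_params(a = 0.8, T = 8, min_seg_len = 300)
sim <- simulate_track(sim_scenario(event = "UPD", proportion = 0.2,
                                   block_len = 10000, seed = 42))
res <- call_mosaics(sim$track, params)
res
```

The call reports one copy-neutral segment spanning the simulated block,
with an estimated cell fraction within a percentage point of the simulated
0.20 and a genome-wide FDR estimate far below $10^{-4}$.
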