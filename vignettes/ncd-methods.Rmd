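---
title: "Detecting long-term balancing selection with ncdscan: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting long-term balancing selection with ncdscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncdscan)
```

## The statistic

Long-term balancing selection (LTBS) holds one or more alleles at an
intermediate equilibrium frequency for time scales long enough that linked
neutral variation equilibrates around it. Two signatures follow: the folded
site frequency spectrum (SFS) of a linked window piles up near the
equilibrium frequency, and the ratio of polymorphism to divergence against an
outgroup rises, because much of the window's genealogy coalesces only at the
deep split between the two balanced allelic classes.

Given a window's informative sites with minor allele frequencies
$p_1,\dots,p_n$ and a target frequency $tf$,

$$NCD(tf) = \sqrt{\frac{1}{n}\sum_{i=1}^{n} (p_i - tf)^2}.$$

It is a standard deviation computed around a hypothesized frequency rather
than around the sample mean. We stress the square root: the statistic lives
on the allele-frequency scale, ranges over $[0,\ \max(tf, 0.5 - tf)]$, and is
zero exactly when every site sits at $tf$. $tf$ is not estimated from the
data; it is the frequency one is testing for, and the scan simply runs the
statistic at $tf \in \{0.3, 0.4, 0.5\}$.

*NCD1* restricts the sum to SNPs. *NCD2* also counts each fixed difference
(FD: a site monomorphic in the sample whose allele differs from the
outgroup) as an informative site with $p_i = 0$. An FD contributes the
maximal deviation $(0 - tf)^2$, so divergence-rich windows — the typical
neutral case — score high, and adding an FD to a window whose NCD2 is below
$tf$ strictly increases it. The divisor is $n$, not $n-1$: the deviations
are taken from a fixed reference point, so no degree of freedom is spent on
a mean.

Sites are folded ($p \in [0, 0.5]$) because with balanced alleles there is
no prior on whether the ancestral or derived allele is held at high
frequency. Minor allele frequencies are computed over called chromosomes;
sites with a call rate below 0.9 (tunable) are excluded, and multiallelic
records are dropped entirely — they count toward no category.

## The scan

The genome is tiled with 3-kb windows advancing by 1.5 kb, defined in
physical distance (not IS count) because SNP density is itself part of the
signature. Windows with fewer than 10 informative sites, or with fewer than
500 bp of callable outgroup orthology, are excluded (both boundaries
inclusive: 10 IS and 500 bp pass); exclusions are tallied by reason.

Significance is calibrated by neutral simulation, matched on the number of
informative sites because the sampling variance of any SFS statistic grows
as windows get site-poor. For each IS count the null holds (nominally)
10,000 NCD2 values; a window is **significant** when its observed NCD2 lies
strictly below *all* of them ($P < 10^{-4}$). Because an observed IS count
may be rare among simulations, bins with fewer than `min_count` values
(default 1000) absorb their nearest IS neighbors, expanding symmetrically
until filled; the merge radius is recorded. A window whose IS count cannot
be matched at all is flagged untestable rather than dropped.

For ranking, each window gets
$$Z_{tf\text{-}IS} = \frac{NCD2_{tf} - \overline{NCD2}_{tf\text{-}IS}}{sd_{tf\text{-}IS}},$$
the distance in null standard deviations from the null mean of its IS bin.
The **empirical P** is the window's rank in the $Z$ ordering divided by the
number of scanned windows (rank 1 = most negative $Z$); ties are ordered by
(Z, IS descending, chromosome, start) so that rank/N is reproducible.
**Outlier windows** are the $\lceil 0.0005 \cdot N\rceil$ most extreme ranks
— the 0.05% lower tail; at $N = 1{,}657{,}989$ scanned windows this is
exactly 829 windows, and the minimum attainable empirical P is
$1/N = 6.03\times10^{-7}$. The ceiling (rather than floor) convention is
deliberate: the boundary window's $p = 829/N$ exceeds the cutoff by
$3\times10^{-9}$ only because $0.0005\,N$ is fractional, and the intended
set is "the 0.05% most extreme windows". Windows identified at several $tf$
values receive an **assigned tf**, the one minimizing their empirical P
(ties: most negative $Z$, then smallest $tf$).

Candidate windows are merged (union of overlapping or book-ended
intervals) before SNP-level annotation counting, so each SNP is counted
once; `resampling_enrichment()` then compares a category's SNP proportion in
candidates against draws of equally many windows from the scanned
background, $p = (1 + \#\{\text{resamples} \ge \text{observed}\})/(R+1)$.

## Simulators

### Neutral

`simulate_neutral()` is an ancestral-recombination-graph (ARG) coalescent:
lineages carry their ancestral material as segments with per-segment
descendant sets; coalescence, recombination (rate $\rho$ per bp per
generation across a lineage's span) and piecewise-constant population sizes
are handled in continuous time, and mutations are dropped as a Poisson
process on total ancestral length between events — a mutation simply
inherits the descendant set of the segment it lands on, so no marginal
trees are built. One outgroup lineage runs in its own population until the
human–chimp split (6.5 Ma) and then joins the ancestral population, which
generates fixed differences (including ancestral-polymorphism noise) under
the same classification rule the VCF reader applies: sample-polymorphic
$\to$ SNP; sample-monomorphic and different from the outgroup $\to$ FD;
otherwise invisible.

Default parameters are the human settings used throughout: mutation rate
$2.5\times10^{-8}$ and recombination rate $1\times10^{-8}$ per bp per
generation, generation time 25 y, sample 100 chromosomes, $L = 3$ kb. The
shipped demographies follow the Gravel et al. (2011) human models
(ancestral $N_e$ 7,310; African expansion to 14,474 at 148 kya; for Europe
a 1,861 bottleneck at 51 kya, then 1,032 at 23 kya growing at 0.38% per
generation). Two simplifications are documented rather than modeled:
continental migration is omitted (the scan and the power surface are
per-population), and exponential-growth epochs are discretized into 24
piecewise-constant steps.

### Balancing selection

`simulate_balancing()` layers an overdominant polymorphism at the sequence
midpoint. Genotype fitnesses are $1 - s_{AA}$, $1$, $1 - s_{aa}$, so the
deterministic equilibrium is $f_{eq} = s_{aa}/(s_{AA}+s_{aa})$; the
`selection_model()` helper derives the costs from a requested $f_{eq}$ and a
total cost $s_{AA} + s_{aa}$, default 0.01. The default is a one-time
choice: it puts $N_e s$ well above 1 (so the polymorphism survives the 5-Ma
onset times studied, with HLA-like coefficients) while the downstream
genealogy depends on the trajectory almost solely through $x \approx
f_{eq}$, making results insensitive to the exact magnitude.

The allele's frequency path is simulated *forward* from one copy at the
onset time, conditioned on the polymorphism segregating at sampling (lost
or fixed paths are redrawn and counted). Forward simulation is rescaled
(default factor 10: sizes and times divided, coefficients multiplied) —
the standard diffusion-preserving speedup.

Linked variation is then generated *backward* on the structured genealogy
implied by the trajectory: within the selected phase, lineages belong to
the derived or ancestral allelic class with sizes $2Nx(t)$ and $2N(1-x(t))$
(the trajectory enters as 200 piecewise-constant chunks); coalescence is
only possible within a class; and a recombination breakpoint that separates
a lineage's material from the selected site moves it to a class drawn with
probability $x(t)$ — the Hudson–Kaplan background-switching rate
$r \cdot d$ for material at distance $d$, emerging naturally because
recombination spans include the distance to the selected site. At the
onset, all derived-class lineages coalesce into the single originating
chromosome; earlier than that the process is the plain neutral ARG with
the outgroup lineage. The balanced site itself enters the sample as a
binomial draw at the final trajectory frequency. This construction
reproduces the two LTBS signatures jointly — deep two-class genealogies
near the selected site (intermediate-frequency SNPs, depressed divergence)
decaying with distance at rate $r d$ — without re-implementing a
coalescent-with-selection machinery; with both costs zero it reduces
exactly to the neutral simulator.

## Power evaluation

`tpr_at_fpr()` sets the detection threshold at the empirical
$fpr$-quantile of the neutral statistic distribution — the order statistic
of rank $\lceil fpr \cdot n \rceil$, lower tail for NCD, upper for
Tajima's D and HKA — and reports the fraction of selected replicates
strictly beyond it (ties do not count: a conservative convention).
`power_grid()` drives the simulators end-to-end over conditions
(population × onset × $f_{eq}$ × $L$), computing each statistic on the
whole replicate as one window. The HKA comparator is a one-window 2×2
chi-square of (SNPs, FDs) against the neutral genome background, signed by
the polymorphism-excess direction; it stands in for a full multi-locus HKA
fit, which the power comparison does not require.

At the reference conditions (African demography, onset 5 Ma, 3 kb, 100
chromosomes, $tf = f_{eq}$), the acceptance suite requires NCD2 power at
FPR 0.05 within ±0.05 of 0.96 / 0.93 / 0.93 for $f_{eq}$ = 0.5 / 0.4 /
0.3, NCD1(0.5) within ±0.05 of 0.93, NCD2 ≥ NCD1, and matched-$tf$ power
≥ mismatched-$tf$ power (orderings with a 0.025 allowance, two binomial
standard errors at 500 replicates per arm — the problem size used
throughout the heavy checks, alongside 2,000 replicates for the simulator
calibrations and an 800-replicate null for the scan calibration).

## What the synthetic data does and does not emulate

The generators reproduce the coalescent-scale features the statistic
responds to: demography-shaped SFS, outgroup divergence with ancestral
polymorphism, recombination decay of the selection signature, and
IS-count heterogeneity across windows. They do not emulate sequencing or
alignment artifacts (call-rate variation, mapping error), mutation-rate or
recombination-map heterogeneity along the genome, gene conversion, archaic
introgression, or continental migration. Passing the calibration and power
suites therefore validates the method's statistical behavior under the
stated model, not robustness to those data pathologies — which is what the
mappability/duplication masks and the orthology filter are for on real
data.

## Numerical choices and degenerate inputs

* $tf$ outside $(0, 0.5]$ is rejected, not folded; frequencies outside
  $[0, 0.5]$ are errors, not clamped.
* An empty window is an `ncd_insufficient_data` error; NCD1 on an FD-only
  window raises the same class with a distinct message (it is not an empty
  window).
* Tajima's D with zero segregating sites returns `NA` (a typed undefined
  marker) so window tables stay rectangular; $n < 4$ has zero variance
  constants and is the caller's responsibility.
* Null bins must retain positive variance; a zero-variance bin aborts
  `build_null` rather than yielding infinite Z.
* ms-format fractional positions are scaled to $[0, L)$ and rounded;
  collisions nudge to the next free integer position (wrapping downward at
  the boundary). The writer emits a non-standard `outgroup:` row; the
  reader accepts files without one, taking the outgroup as ancestral.
* All randomness flows through explicit seeds; both simulators are
  bit-reproducible for a fixed seed, and `power_grid` derives per-condition
  substreams from its root seed.

## Known limitations

* The European growth epoch is a 24-step staircase, and single-population
  models omit migration; absolute power under the European model may
  differ slightly from a full multi-population simulation.
* The structured-coalescent phase conditions on chunk-averaged
  trajectories; sub-chunk frequency fluctuations are smoothed out. This
  matters only near the onset, where the forced coalescence of the derived
  class dominates anyway.
* The scan assumes biallelic SNPs; multiallelic balanced systems (e.g.,
  some MHC loci) are visible only through their biallelic projections.
* `hka_chi2` is a single-window screening statistic, not the full HKA
  likelihood test.
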