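# ncdscan

Genome scans for long-term balancing selection (LTBS) with the
**Non-Central Deviation** statistics *NCD1* and *NCD2*.

## The problem and the statistic

Long-term balancing selection — heterozygote advantage, negative
frequency dependence — maintains alleles at intermediate frequency for
millions of years. Linked neutral variation then shows two signatures
relative to neutrality: an excess of polymorphism over divergence to an
outgroup species, and a folded site frequency spectrum concentrated near
the equilibrium frequency of the balanced allele.

The NCD statistic quantifies both at once. For a genomic window with
*n* informative sites with minor allele frequencies *p₁ … pₙ* and a
*target frequency* *tf* (the hypothesized frequency of the balanced
allele),

```
NCD(tf) = sqrt( Σᵢ (pᵢ − tf)² / n )
```

a standard-deviation-type dispersion measure around *tf* rather than
around the mean. Note the square root: NCD is on the allele-frequency
scale and is bounded by `max(tf, 0.5 − tf)`. Low values support LTBS.

* **NCD1** uses polymorphic sites only (no outgroup needed).
* **NCD2** additionally counts fixed differences (FDs) to an outgroup as
  informative sites with MAF = 0, so divergence-rich windows are pushed
  away from the LTBS signature. NCD2 has the higher power.

The package implements, for human-scale population data:

* readers for VCF genotypes, reference-aligned outgroup FASTA (or
  per-site allele tables), BED masks, and ms-format simulation output;
* the sliding-window scan (3-kb windows, 1.5-kb step): window filtering
  (≥ 10 informative sites, ≥ 500 bp outgroup orthology), significance
  against neutral simulations matched on informative-site count,
  Z-standardization, empirical-P ranking, outlier calling
  (empirical P ≤ 0.0005) and per-window assigned *tf*;
* coalescent simulators: neutral (piecewise demography, recombination,
  outgroup lineage at the 6.5-Ma split) and balancing-selection
  (forward Wright–Fisher overdominance trajectory + structured
  coalescent conditioned on it);
* a power harness (TPR at fixed FPR, ROC curves) including Tajima's D
  and an HKA-type polymorphism/divergence chi-square as comparators.

## Worked example

Compute NCD on a window, then measure the power of NCD2 on simulated
data under the African demographic model:

```r
library(ncdscan)

# one window: three SNPs near frequency 0.5 plus one fixed difference
w <- window_sites(data.frame(pos = c(10, 20, 30, 40),
                             kind = c("SNP", "SNP", "SNP", "FD"),
                             maf  = c(0.48, 0.50, 0.41, 0)))
ncd2(w, tf = 0.5)
#> NCD2(tf = 0.5) = 0.25421  [4 informative sites]
ncd1(w, tf = 0.5)
#> NCD1(tf = 0.5) = 0.05323  [3 informative sites]
```

The FD (a site at frequency 0 relative to the target 0.5) pulls NCD2 up,
weakening the balancing-selection signal; the SNPs alone sit close to
0.5, giving a very low NCD1.

```r
model <- demographic_model("african")
neutral <- simulate_neutral(model, n = 100, L = 3000, n_reps = 200, seed = 1)
sel <- simulate_balancing(model, selection_model(f_eq = 0.5, tbs_ma = 5),
                          n = 100, L = 3000, n_reps = 200, seed = 2)
tpr_at_fpr(vapply(neutral, replicate_ncd2, 0, tf = 0.5),
           vapply(sel,     replicate_ncd2, 0, tf = 0.5),
           fpr = 0.05, direction = "lower")
#> <power_result> TPR = 0.945 at FPR = 0.05 (threshold 0.4542, 200/200 reps)
```

Of 200 regions simulated with a balanced polymorphism maintained for
5 Ma at equilibrium frequency 0.5, 94.5% fall below the 5%-false-positive
threshold set by the neutral replicates.

A thin command-line front end over the same functions ships in
`inst/cli/ncd.R` (subcommands `scan`, `simulate`, `null-build`, `power`,
`fixtures`).

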