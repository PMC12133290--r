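---
title: "Reconstructing beacon datasets from summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing beacon datasets from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beaconrecon)
```

## The attack surface

A genomic data-sharing beacon answers the question "does any participant in
this dataset carry allele X at locus Y?" with yes/no, and optionally with
the in-dataset allele frequency. The interface looks harmless: no genotypes
ever leave the server, only one summary statistic per query. This package
implements, end to end, the demonstration that the interface is *not*
harmless: an attacker who takes a full snapshot of the responses over a SNP
panel, and who has two pieces of public side information — population
allele frequencies and pairwise SNP co-carriage correlations from any
reference panel — can reconstruct a substantial fraction of every
participant's carrier genotypes, and then feed the reconstructions into a
downstream membership-inference attack against other beacons.

Throughout, a dataset of `N` individuals over a target SNP set `M'` is a
binary carrier matrix `B` (entry 1 when the individual carries at least one
copy of the minor allele); the beacon response vector is `b`, the public
population frequencies are `m`, and the reference co-carriage matrix is
`C`, with `C[j,k]` the fraction of reference individuals carrying both SNP
`j` and SNP `k`. Carrier status, not allelic dosage, is the resolution of
the problem: the beacon protocol cannot distinguish heterozygous from
homozygous carriers, so nothing finer is recoverable from it.

## The two attacks

**Greedy baseline** (`baseline_reconstruct()`). For each SNP answered
"yes", infer the carrier count — `b[j] * N` when frequencies are reported,
`m[j] * N` (rounded half-up, clamped into `[1, N]`) when only yes/no is —
and assign that many carriers to uniformly random rows, independently per
SNP. Column sums are exact by construction; everything about *which* rows
carry *which* SNPs is noise, because the baseline treats SNPs as
independent.

**Alternating gradient attack** (`reconstruct_beacon()`). SNPs are not
independent: alleles at nearby loci are co-inherited (linkage
disequilibrium), and `C` summarizes exactly that. The attack relaxes the
binary matrix to `R` in `[0,1]^(N x M')`, initializes it with the baseline,
and alternates two Adam-driven descent blocks:

* `e1` steps on the squared correlation loss `|| t(R) R / N - C ||_F^2`,
  pulling the reconstruction's co-carriage toward the public `C`;
* `e2` steps on the frequency loss `mean_j (f[j] - colmean_j(R))^2`, where
  `f` is the beacon-reported frequency (or its population proxy under
  binary responses, overridden to 0 by a "no" and floored at `1/N` by a
  "yes").

After each alternation the iterate is binarized at 0.5 and the number of
flipped entries is counted; the attack stops when fewer than
`flip_threshold` entries change, or after `max_iter` alternations.

Rows answered "no" certify zero carriers and stay frozen at zero. If the
attacker already owns some participants' genomes (say, from a previous
breach), those rows are frozen bit-exactly and the remaining carrier mass
is redistributed over the unknown rows at initialization.

## Defaults and why

| parameter | default | meaning |
|---|---|---|
| `eta` | 0.001 | Adam learning rate for both blocks |
| `e1` / `e2` | 1000 / 500 | steps per correlation / frequency block |
| `max_iter` | 3000 | cap on outer alternations |
| `flip_threshold` | 10 | stop when fewer entries flip per alternation |
| `binarize_threshold` | 0.5 | relaxed-to-binary cut, ties map to 1 |

These are the attack's published operating point and we keep them as-is.
One consequence worth knowing: the flip-count rule is calibrated for
matrices with thousands of entries. On very small instances (tens of
entries) "fewer than 10 flips" is satisfied almost immediately, so the
attack effectively performs a single alternation there.

## Numerical choices

* **Box relaxation.** Adam cannot step a binary matrix, so the iterate
  lives in the box `[0,1]` and is clipped after every update; binarization
  happens only for flip counting and the final output. Binary fixed points
  of the relaxed losses coincide with zero-gradient points, which is the
  property that matters. A logit parametrization was considered and
  rejected: clipping is simpler and the box boundary is exactly where
  genotypes live.
* **Squared norm in the gradient, plain norm in the report.** The descent
  uses `||.||_F^2` (smooth at zero, gradient `4/N R (t(R)R/N - C)`); the
  history reports the unsquared norm, evaluated on the *binarized* iterate,
  which is the quantity a reader of the loss trace cares about.
* **Fresh Adam moments per block.** The two losses have different geometry;
  moment estimates from one are stale for the other.
* **Ties at 0.5 binarize to 1**, deterministically, so flip counts cannot
  chatter on exact ties.
* **Carrier counts round half away from zero** (`floor(x + 0.5)`): base R's
  round-half-even is the wrong convention for "how many of 5 people carry
  this allele".
* **Frequency estimates are never exactly 0 or 1 inside the LRT**: they are
  clamped away from the boundary before logs are taken. A reference-panel
  estimate of 0 for a SNP the beacon answers "yes" on is an estimation
  artifact, and the clamp bounds its influence.

The correlation matrix itself is the dot-product form `s_j . s_k / Np`
(fraction of the reference panel carrying *both* alleles; diagonal = single
SNP carrier frequency). The classical Sokal-Michener similarity, which also
counts 0-0 matches, is available via `compute_correlation_matrix(...,
method = "sokal-michener")` for sensitivity analysis; the attack's loss is
defined on the dot-product form, which is therefore the default.

## The synthetic population

Real evaluations of this attack use consortium genotype panels. For a
self-contained, network-free package we generate populations with the one
statistical feature the attack exploits — block-wise LD — and nothing else:

* SNPs are partitioned into blocks (default 10 SNPs each, the low end of
  typical human haploblock sizes);
* each block has a small haplotype pool (default 4), with Dirichlet
  frequencies; every individual draws one haplotype per block
  independently;
* per-SNP target carrier frequencies are uniform in `maf_range` (default
  0.05–0.5); a per-entry mutation flip (default 0.01) adds noise, and
  turning it up toward 0.5 is the knob that erases LD — and with it the
  gradient attack's advantage.

Member, correlation-reference, frequency-reference and control cohorts are
disjoint row subsets of one generated super-population (`split_cohorts()`),
mirroring a left-out-sample design: `C` is estimated from 100 reference
individuals and `m` from 64 others, so both carry realistic estimation
noise rather than being the beacon's own statistics.

What the generator does **not** emulate: diploid phase and dosage,
recombination gradients within blocks, long-range population structure,
relatedness between individuals, and genotyping error of real
community-sourced panels. Passing tests on this generator demonstrate that
the machinery exploits pairwise LD exactly as designed; they do not certify
attack performance on any particular real dataset.

## Study sizes used by the tests and the acceptance script

Property checks run at the scale where the mechanism is visible and a
laptop is sufficient, chosen once: beacons of `N = 10` over a
block-structured 50-SNP panel (10 seeds, paired across response modes and
known-subset fractions); exhaustive-enumeration checks at `N = 3`, 5 SNPs,
where all carrier placements can be enumerated; the membership-inference
chain on a 300-SNP panel, whose rare-allele content gives the LRT
meaningful evidence while keeping each replicate in seconds. The panel is
block-structured end to end because every property under test is about
exploiting LD; a panel of mostly-independent SNPs would reduce those
checks to coin flips.

## Design choices where the design was open

* **Row anonymity in scoring.** The attacker outputs genomes, not names.
  `evaluate_reconstruction()` therefore pairs reconstructed rows with true
  individuals by minimum-total-Hamming assignment before computing
  micro-averaged precision/recall/F1 (`match = "identity"` exists for the
  frozen-known-rows case where row identity is real).
* **Known-subset initialization.** With known rows frozen, the baseline
  initialization distributes only the *remaining* inferred carriers over
  the unknown rows, keeping the initialization consistent with the beacon's
  frequencies instead of over-assigning.
* **Membership decisions.** `infer_membership()` is sequential —
  rarest-allele first, threshold recalibrated on the controls' same-length
  query prefixes, stop at first exceedance — which makes "how many queries
  were needed" well-defined. The chain experiment (`run_mi_chain()`)
  instead defaults to the one-shot rule (full-query statistic against a
  threshold calibrated once), because repeated sequential looks inflate the
  false-positive rate well above its nominal level, and FPR control is the
  point of calibration. The threshold is the `floor(fpr * (n_controls +
  1))`-th largest control statistic: by order-statistics of exchangeable
  draws, a fresh non-member exceeds it with probability at most `fpr`
  (with 20 controls at 5%, the threshold is the maximum and the
  out-of-sample FPR is 1/21).
* **Mismatch rate `delta`** (the chance the attacker's copy of a genome
  disagrees with the beacon's copy at a queried allele) defaults to 1e-6,
  the genotyping-error scale of the classical attack. It is a swappable
  constant in `mi_config()`.

## Known limitations

* **The correlation objective can be overfit.** A small beacon cannot
  realize population co-carriage exactly, and `C` itself is estimated, so
  the optimizer routinely reaches a correlation loss *below* the truth's
  own — extra degrees of freedom absorb reference noise. One measurable
  consequence, which the acceptance script quantifies: freezing known true
  rows does not improve (and can slightly degrade) the reconstruction of
  the remaining rows at these scales, because the free rows then absorb
  the full reference mismatch. Nothing in the published procedure
  regularizes against this; we report it rather than patch it.
* **Membership-inference power is panel-limited.** With maf ≥ 0.05 and a
  ten-person beacon, most SNPs are present regardless of any one victim,
  so evidence concentrates in a handful of rare alleles; per-seed power is
  volatile and grows with panel size.
* Binary-mode reconstruction inherits every bias of the proxy frequencies;
  with badly mismatched proxies (a different population), performance
  degrades sharply — reproduced qualitatively by the experiment grid.

## A minimal run

```{r example, eval = FALSE}
model <- population_model(n_snps = 50, seed = 42)
setting <- simulate_attack_setting(model, n = 10, m_prime = 50,
                                   mode = "af", seed = 42)
inputs <- attack_inputs(setting$response, setting$panel,
                        setting$correlation, seed = 42)
recon <- reconstruct_beacon(inputs, optimizer_config(seed = 42))
glance(evaluate_reconstruction(setting$truth, recon$genotypes))
autoplot(recon)
```

`run_experiment()` sweeps beacon sizes, panel sizes, response modes and
known fractions into a tidy tibble (one row per cell, seed and method), and
`run_mi_chain()` executes the full reconstruction-to-membership-inference
chain. `scripts/acceptance.R` at the repository root re-runs the package's
headline computations from scratch and writes them as JSON.
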