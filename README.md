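# beaconrecon

Genome reconstruction and membership-inference attacks against genomic
data-sharing beacons, for privacy researchers and beacon operators who want
to quantify what the "harmless" summary-statistic interface actually leaks.

A beacon exposes a dataset of `N` genomes only through per-SNP summary
statistics: "yes/no, someone here carries allele j" or, optionally, the
in-dataset allele frequency. Writing the dataset as a binary carrier matrix
`B` (N individuals × |M′| SNPs), the attacker observes the response vector
`b` over a chosen SNP panel M′ and has two pieces of *public* side
information: population allele frequencies `m`, and a pairwise co-carriage
matrix `C` estimated from any reference panel,
`C[j,k] = s_j · s_k / N_p` (the fraction of reference individuals carrying
both SNPs). The package implements:

- a **greedy baseline**: for each "yes"-SNP place
  `max(1, round(b_j · N))` carriers (or `m_j · N` under binary responses)
  on random rows — exact frequencies, no structure;
- the **alternating gradient attack**: relax `B′` to `R ∈ [0,1]^{N×|M′|}`,
  initialize with the baseline, then alternate `e1` Adam steps on the
  correlation loss `L_corr = ‖RᵀR/N − C‖_F` with `e2` steps on the
  frequency loss `L_MSE = Σ_j (f_j − f′_j)²/|M′|`, binarize at 0.5, and
  stop when fewer than 10 entries flip per alternation (defaults
  `η = 0.001`, `e1 = 1000`, `e2 = 500`, `max_iter = 3000`);
- the **known-subset variant** (attacker already owns a fraction `p` of
  the genomes: those rows are frozen bit-exactly);
- **evaluation** under row anonymity (minimum-Hamming assignment, then
  micro precision/recall/F1 and the Frobenius gap `‖B − B′‖_F`);
- a **haplotype-block population generator** (block-wise LD, tunable
  mutation knob) so member/reference/control cohorts exist without any
  download, plus `run_experiment()` grids over `N`, `|M′|`, response mode,
  `p` and seeds;
- the downstream **membership-inference chain**: reconstruct a "safe"
  Beacon A, then use each reconstructed genome in a rare-allele-first
  likelihood-ratio test against a sensitive beacon, thresholded on a
  control group at 5% false-positive rate (`run_mi_chain()`,
  `infer_membership()`).

## Worked example

Simulate a 10-person beacon over a 50-SNP LD-block panel, attack it with
both methods, and score against the (normally unknown) truth:

```r
library(beaconrecon)

model   <- population_model(n_snps = 50, seed = 4)
setting <- simulate_attack_setting(model, n = 10, m_prime = 50,
                                   mode = "af", seed = 4)
inputs  <- attack_inputs(setting$response, setting$panel,
                         setting$correlation, seed = 4)

baseline <- baseline_reconstruct(inputs)
recon    <- reconstruct_beacon(inputs, optimizer_config(seed = 4))
recon
#> <beacon_reconstruction> 10 x 50, af mode, 3 iteration(s), converged
#>   final l_corr = 3.3827, l_mse = 0.002400

glance(evaluate_reconstruction(setting$truth, baseline))
#> # A tibble: 1 × 9
#>   precision recall    f1 frobenius_gap    tp    fp    fn    tn match
#>       <dbl>  <dbl> <dbl>         <dbl> <int> <int> <int> <int> <chr>
#> 1     0.812  0.812 0.812          7.87   134    31    31   304 optimal

glance(evaluate_reconstruction(setting$truth, recon$genotypes))
#> # A tibble: 1 × 9
#>   precision recall    f1 frobenius_gap    tp    fp    fn    tn match
#>       <dbl>  <dbl> <dbl>         <dbl> <int> <int> <int> <int> <chr>
#> 1     0.925  0.903 0.914          5.29   149    12    16   323 optimal
```

The frequency-only baseline gets each SNP's carrier *count* right but
scatters the carriers (F1 0.81 here); pulling the reconstruction's
co-carriage toward the public correlation matrix recovers much of the
row structure (F1 0.91, balanced precision/recall). `tidy(recon)` exposes
the per-alternation loss/flip trace and `autoplot(recon)` plots it:

```r
tidy(recon)
#> # A tibble: 3 × 4
#>    iter l_corr  l_mse flips
#>   <int>  <dbl>  <dbl> <dbl>
#> 1     1   4.01 0.003     31
#> 2     2   3.58 0.003     20
#> 3     3   3.38 0.0024     5
```

A thin CLI wraps the same functions
(`system.file("cli", "beaconrecon", package = "beaconrecon")`):
`simulate`, `beacon`, `correlate`, `attack-baseline`, `attack-opt`,
`evaluate`, `mi-attack`, `experiment`.

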