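# fixtures are generated in code; no data files

rand_geno <- function(n, m, p = 0.3, seed = 1) {
  set.seed(seed)
  genotype_matrix(matrix(rbinom(n * m, 1L, p), n, m))
}

# a tiny fully-wired attack setting over a block-LD panel
tiny_setting <- function(seed = 1, n = 5, m_prime = 20, mode = "af",
                         n_snps = 20) {
  simulate_attack_setting(population_model(n_snps = n_snps, seed = seed),
                          n = n, m_prime = m_prime, mode = mode,
                          n_reference = 30, n_freq_reference = 20,
                          seed = seed)
}

fast_config <- function(seed = 1, e1 = 100, e2 = 50, max_iter = 60, ...) {
  optimizer_config(e1 = e1, e2 = e2, max_iter = max_iter, seed = seed, ...)
}

# hand-assembled attack inputs from raw response values
make_inputs <- function(values, mode, n, m = NULL, seed = 1,
                        correlation = NULL) {
  ids <- sprintf("s%02d", seq_along(values))
  counts <- if (mode == "af") as.integer(round(values * n)) else
    rep(NA_integer_, length(values))
  resp <- beaconrecon:::new_beacon_response(ids, mode, values, counts, n)
  if (is.null(m)) m <- rep(0.2, length(values))
  pan <- snp_panel(ids, m)
  attack_inputs(resp, pan, correlation, seed = seed)
}
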