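# independent loss definitions used by the finite-difference oracles
sq_corr_loss <- function(R, C, n = nrow(R)) sum((t(R) %*% R / n - C)^2)
mse_loss <- function(R, f) mean((f - colMeans(R))^2)

fd_grad <- function(fn, R, h = 1e-5) {
  G <- R * 0
  for (i in seq_along(R)) {
    up <- R; up[i] <- up[i] + h
    dn <- R; dn[i] <- dn[i] - h
    G[i] <- (fn(up) - fn(dn)) / (2 * h)
  }
  G
}

test_that("analytic gradients match central finite differences", {
  for (seed in 1:3) {
    set.seed(seed)
    R <- matrix(runif(12, 0.1, 0.9), 4, 3)
    C <- reconstruction_correlation(matrix(runif(12, 0.1, 0.9), 4, 3))
    f <- runif(3)
    ga <- beaconrecon:::grad_corr(R, C)
    gn <- fd_grad(function(x) sq_corr_loss(x, C), R)
    expect_lt(max(abs(ga - gn)) / max(abs(gn)), 1e-4)

    ga2 <- beaconrecon:::grad_freq(R, f)
    gn2 <- fd_grad(function(x) mse_loss(x, f), R)
    expect_lt(max(abs(ga2 - gn2)) / max(abs(gn2)), 1e-4)
  }
})

test_that("compiled Adam blocks agree with the pure-R reference", {
  set.seed(5)
  R <- matrix(runif(20, 0.2, 0.8), 5, 4)
  C <- reconstruction_correlation(matrix(runif(20), 5, 4))
  f <- runif(4)
  cfg <- optimizer_config(e1 = 7, e2 = 7)
  free <- matrix(1, 5, 4); free[2, ] <- 0
  frozen <- R

  cpp <- beaconrecon:::.adam_block_corr(R, unclass(C), 7L, cfg$eta,
                                        cfg$adam_beta1, cfg$adam_beta2,
                                        cfg$adam_eps, free, frozen)
  ref <- beaconrecon:::adam_block_r(R, 7, function(x)
    beaconrecon:::grad_corr(x, C), cfg, free, frozen)
  expect_equal(cpp, ref, tolerance = 1e-12)

  cpp2 <- beaconrecon:::.adam_block_freq(R, f, 7L, cfg$eta,
                                         cfg$adam_beta1, cfg$adam_beta2,
                                         cfg$adam_eps, free, frozen)
  ref2 <- beaconrecon:::adam_block_r(R, 7, function(x)
    beaconrecon:::grad_freq(x, f), cfg, free, frozen)
  expect_equal(cpp2, ref2, tolerance = 1e-12)
  # frozen rows untouched by both
  expect_identical(cpp[2, ], R[2, ])
})

test_that("both steps are fixed points at their respective optima", {
  g <- rand_geno(4, 3, seed = 6)
  R <- unname(unclass(g) * 1.0)
  C <- correlation_matrix(reconstruction_correlation(R),
                          snp_ids = snp_ids(g), n_reference = 4)
  st <- beaconrecon:::new_recon_state(R, optimizer_config(e1 = 25, e2 = 25),
                                      integer(0), integer(0), R * 0)
  out <- correlation_step(st, C, st$config)
  expect_equal(out$relaxed, R)

  f <- colMeans(R)
  out2 <- frequency_step(st, f, st$config)
  expect_equal(out2$relaxed, R)
})

test_that("frequency pressure moves a column monotonically toward its target", {
  st <- beaconrecon:::new_recon_state(matrix(0.5, 2, 1),
                                      optimizer_config(e2 = 1),
                                      integer(0), integer(0),
                                      matrix(0, 2, 1))
  vals <- numeric(12)
  for (k in 1:12) {
    st <- frequency_step(st, 1, st$config)
    vals[k] <- mean(st$relaxed)
  }
  expect_true(all(diff(c(0.5, vals)) > 0))
  expect_true(all(vals <= 1))
})

test_that("a single free entry cannot do worse than before and approaches the 1-D optimum", {
  set.seed(9)
  R <- matrix(runif(12, 0.2, 0.8), 4, 3)
  C <- reconstruction_correlation(matrix(runif(12, 0.1, 0.9), 4, 3))
  free <- matrix(0, 4, 3); free[2, 2] <- 1
  st <- beaconrecon:::new_recon_state(R, optimizer_config(e1 = 3000),
                                      integer(0), integer(0), R)
  st$free_mask <- free
  before <- sq_corr_loss(R, C)
  out <- correlation_step(st, C, st$config)
  after <- sq_corr_loss(out$relaxed, C)
  expect_lte(after, before)
  # 1-D grid-search oracle over the free entry
  grid <- seq(0, 1, by = 1e-3)
  oracle <- min(vapply(grid, function(v) {
    Rv <- R; Rv[2, 2] <- v; sq_corr_loss(Rv, C)
  }, numeric(1)))
  expect_lt(after - oracle, 1e-4)
})

test_that("degenerate configurations reduce to known results", {
  st <- tiny_setting(seed = 2)
  inputs <- attack_inputs(st$response, st$panel, st$correlation, seed = 2)

  # e1 = e2 = 0 leaves the baseline initialization untouched
  cfg0 <- optimizer_config(e1 = 0, e2 = 0, seed = 77)
  r0 <- reconstruct_beacon(inputs, cfg0)
  base_inputs <- inputs; base_inputs$seed <- 77L
  expect_identical(unclass(r0$genotypes),
                   unclass(baseline_reconstruct(base_inputs)))
  expect_true(r0$converged)

  # flip_threshold = 0 with max_iter = 1 runs exactly one alternation
  cfg1 <- fast_config(flip_threshold = 0, max_iter = 1)
  r1 <- reconstruct_beacon(inputs, cfg1)
  expect_identical(nrow(r1$history), 1L)
  expect_false(r1$converged)

  # an all-'no' beacon is reconstructed as the zero matrix immediately
  ids <- sprintf("z%d", 1:4)
  resp <- beaconrecon:::new_beacon_response(ids, "af", rep(0, 4),
                                            rep(0L, 4), 5)
  pan <- snp_panel(ids, rep(0.3, 4))
  Cz <- correlation_matrix(diag(0.3, 4), snp_ids = ids, n_reference = 10)
  rz <- reconstruct_beacon(attack_inputs(resp, pan, Cz), fast_config())
  expect_true(all(unclass(rz$genotypes) == 0L))
  expect_true(rz$converged)
  expect_identical(rz$history$flips[1], 0)
})

test_that("frequency targets honor the response semantics", {
  i_af <- make_inputs(c(0.25, 0, 0.75), "af", n = 4)
  expect_equal(frequency_target(i_af), c(0.25, 0, 0.75))

  i_bin <- make_inputs(c(0, 1, 1), "binary", n = 10, m = c(0.3, 0.2, 0))
  # 'no' overrides m; 'yes' with m = 0 implies at least one carrier
  expect_equal(frequency_target(i_bin), c(0, 0.2, 0.1))
})

test_that("known genomes stay bit-exact and zero-columns stay frozen", {
  st <- tiny_setting(seed = 4, n = 6)
  inputs <- attack_inputs(st$response, st$panel, st$correlation, seed = 4)
  truth <- st$truth

  # all rows known: output equals the known genomes regardless of config
  all_known <- reconstruct_beacon(inputs, fast_config(), known = truth,
                                  known_rows = 1:6)
  expect_identical(unname(unclass(all_known$genotypes)),
                   unname(unclass(truth)))

  known <- genotype_matrix(unclass(truth)[1:2, , drop = FALSE],
                           individual_ids = individual_ids(truth)[1:2],
                           snp_ids = snp_ids(truth))
  r <- reconstruct_beacon(inputs, fast_config(), known = known,
                          known_rows = 1:2)
  expect_identical(unname(unclass(r$genotypes)[1:2, ]),
                   unname(unclass(known)))
  expect_identical(unname(r$relaxed[1:2, ]), unname(unclass(known) * 1.0))
  zero_cols <- which(st$response$values == 0)
  if (length(zero_cols)) {
    expect_true(all(unclass(r$genotypes)[, zero_cols] == 0L))
    expect_true(all(r$relaxed[, zero_cols] == 0))
  }
})

test_that("convergence bookkeeping is consistent", {
  st <- tiny_setting(seed = 6)
  inputs <- attack_inputs(st$response, st$panel, st$correlation, seed = 6)
  cfg <- fast_config(seed = 6)
  r <- reconstruct_beacon(inputs, cfg)
  expect_lte(nrow(r$history), cfg$max_iter)
  expect_identical(r$iterations, nrow(r$history))
  if (r$converged) {
    expect_lt(dplyr::last(r$history$flips), cfg$flip_threshold)
  }
  # losses recorded on the binarized iterate are reproducible
  f <- frequency_target(inputs)
  expect_equal(dplyr::last(r$history$l_corr),
               loss_corr(unclass(r$genotypes), st$correlation))
  expect_equal(dplyr::last(r$history$l_mse),
               loss_freq(unclass(r$genotypes), f))
})
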