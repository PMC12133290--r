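test_that("the LRT statistic equals the closed form, term by term", {
  m <- c(0.1, 0.2, 0.3)
  n <- 5; delta <- 1e-6
  ids <- c("r1", "r2", "r3")
  pan <- snp_panel(ids, m)
  resp <- beaconrecon:::new_beacon_response(ids, "binary", c(1, 1, 0),
                                            rep(NA_integer_, 3), n)
  victim <- c(1L, 1L, 1L)
  lam <- lrt_statistic(victim, resp, pan, n, delta = delta)

  # independent scalar evaluation of the three terms
  oracle <- 0
  x <- c(1, 1, 0)
  for (j in 1:3) {
    dn <- (1 - m[j])^(2 * n)
    dn1 <- (1 - m[j])^(2 * (n - 1))
    p1m <- 1 - delta * dn1
    p1n <- 1 - dn
    oracle <- oracle + x[j] * log(p1m / p1n) +
      (1 - x[j]) * log((1 - p1m) / (1 - p1n))
  }
  expect_equal(as.numeric(lam), oracle)
  expect_identical(attr(lam, "n_queries"), 3L)

  # all-yes responses with delta = 0 accumulate positive evidence
  resp_yes <- beaconrecon:::new_beacon_response(ids, "binary", c(1, 1, 1),
                                               rep(NA_integer_, 3), n)
  l1 <- as.numeric(lrt_statistic(c(1L, 0L, 0L), resp_yes, pan, n, delta = 0))
  l2 <- as.numeric(lrt_statistic(c(1L, 1L, 0L), resp_yes, pan, n, delta = 0))
  l3 <- as.numeric(lrt_statistic(c(1L, 1L, 1L), resp_yes, pan, n, delta = 0))
  expect_true(l1 > 0 && l2 > l1 && l3 > l2)

  # a victim with no panel alleles is flagged uninformative
  expect_warning(l0 <- lrt_statistic(c(0L, 0L, 0L), resp, pan, n), "no panel")
  expect_identical(as.numeric(l0), 0)
  expect_true(attr(l0, "flagged"))
})

test_that("queries run rarest-first and max_queries truncates additively", {
  ids <- sprintf("q%d", 1:4)
  pan <- snp_panel(ids, c(0.4, 0.05, 0.3, 0.1))
  resp <- beaconrecon:::new_beacon_response(ids, "binary", c(1, 1, 1, 1),
                                            rep(NA_integer_, 4), 8)
  victim <- rep(1L, 4)
  full <- as.numeric(lrt_statistic(victim, resp, pan, 8))
  # rarest two SNPs are q2 (0.05) and q4 (0.1)
  two <- as.numeric(lrt_statistic(victim, resp, pan, 8, max_queries = 2))
  only24 <- as.numeric(lrt_statistic(c(0L, 1L, 0L, 1L), resp, pan, 8))
  expect_equal(two, only24)
  # additivity over the disjoint remainder
  rest <- as.numeric(lrt_statistic(c(1L, 0L, 1L, 0L), resp, pan, 8))
  expect_equal(full, two + rest)
})

test_that("threshold calibration controls the out-of-sample FPR", {
  # 20 controls at 5%: threshold is the maximum, no control is flagged
  lam <- c(1:19, 100) / 10
  thr <- beaconrecon:::threshold_from_controls(lam, 0.05)
  expect_identical(thr, 10)
  expect_lte(sum(lam > thr), 1L)

  # identical controls: common value, zero flagged under the strict rule
  same <- rep(2.5, 20)
  thr2 <- beaconrecon:::threshold_from_controls(same, 0.05)
  expect_identical(thr2, 2.5)
  expect_identical(sum(same > thr2), 0L)

  g <- rand_geno(1, 4, seed = 1)
  pan <- snp_panel(snp_ids(g), rep(0.2, 4))
  resp <- beaconrecon:::new_beacon_response(snp_ids(g), "binary",
                                            rep(1, 4), rep(NA_integer_, 4), 5)
  expect_error(calibrate_threshold(g, resp, pan, 5), "2 control")
})

test_that("empirical FPR on fresh non-members stays near the target", {
  model <- population_model(n_snps = 100, seed = 1)
  pop <- generate_population(model, 10 + 20 + 200)
  co <- split_cohorts(pop, c(10, 20, 200), seed = 5)
  members <- co[[1]]; controls <- co[[2]]; fresh <- co[[3]]
  pan <- population_af(fresh)  # frequency source independent of the beacon
  resp <- beacon_respond(beacon(members), pan, "binary")
  cfg <- mi_config()
  thr <- calibrate_threshold(controls, resp, pan, 10, cfg)
  lam <- vapply(seq_len(200), function(i) {
    as.numeric(lrt_statistic(unclass(fresh)[i, ], resp, pan, 10,
                             delta = cfg$delta))
  }, numeric(1))
  fpr <- mean(lam > thr)
  expect_gte(fpr, 0)
  expect_lte(fpr, 0.12)
})

test_that("sequential inference detects a strongly-exposed member", {
  # beacon whose members carry rare alleles: strong per-query evidence
  set.seed(17)
  m <- 50; n <- 10
  af <- rep(0.03, m)
  others <- matrix(rbinom((n - 1) * m, 1L, 0.03), n - 1, m)
  victim <- as.integer(runif(m) < 0.4)  # carries ~20 rare alleles
  bcn <- genotype_matrix(unname(rbind(others, victim)))
  pan <- snp_panel(snp_ids(bcn), af)
  resp <- beacon_respond(beacon(bcn), pan, "binary")
  controls <- genotype_matrix(matrix(rbinom(20 * m, 1L, 0.03), 20, m),
                              snp_ids = snp_ids(bcn))
  res <- infer_membership(victim, resp, pan, n, controls, mi_config())
  expect_identical(res$decision, "member")
  expect_lte(res$n_queries, m)

  # empty query set: immediate non-member with zero queries
  res0 <- infer_membership(rep(0L, m), resp, pan, n, controls, mi_config())
  expect_identical(res0$decision, "non-member")
  expect_identical(res0$n_queries, 0L)

  # victims from an unrelated population are mostly rejected
  unrelated <- matrix(rbinom(20 * m, 1L, 0.03), 20, m)
  calls <- vapply(seq_len(20), function(i) {
    infer_membership(unrelated[i, ], resp, pan, n, controls,
                     mi_config())$decision
  }, character(1))
  expect_gte(mean(calls == "non-member"), 0.8)
})
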