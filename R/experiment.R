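#' Simulate one complete attack setting
#'
#' Generates a super-population from `model`, carves disjoint member,
#' correlation-reference and frequency-reference cohorts out of it, picks a
#' nested SNP subset of size `m_prime`, and wires up the beacon, the public
#' frequency panel and the correlation matrix. The SNP subset of size `m`
#' is always a prefix of the subset of size `m' > m` drawn under the same
#' seed, so subsets are nested across grid cells.
#'
#' @param model a [population_model()].
#' @param n beacon size.
#' @param m_prime number of target SNPs.
#' @param mode `"af"`, `"binary"`, or `"binary-mismatched"` (binary
#'   responses with proxy frequencies from a different population).
#' @param n_reference size of the correlation-reference cohort.
#' @param n_freq_reference size of the frequency-reference cohort.
#' @param mismatch_model a [population_model()] for the mismatched
#'   frequency source; defaults to `model` with a shifted frequency band
#'   and a different seed.
#' @param n_extra additional disjoint individuals to return (e.g. control
#'   or non-member cohorts for membership inference).
#' @param seed master seed of the setting.
#' @return A list with `truth` (the beacon's genotype matrix over the
#'   target SNPs), `beacon`, `panel`, `correlation`, `response`, `extra`
#'   (genotype matrix of `n_extra` disjoint individuals, aligned), and
#'   `snp_subset`.
#' @export
simulate_attack_setting <- function(model, n, m_prime,
                                    mode = c("af", "binary", "binary-mismatched"),
                                    n_reference = 100, n_freq_reference = 64,
                                    mismatch_model = NULL, n_extra = 0,
                                    seed = 1) {
  mode <- match.arg(mode)
  if (m_prime > model$n_snps) {
    stop_config(sprintf("m_prime (%d) exceeds the model's n_snps (%d)",
                        m_prime, model$n_snps))
  }
  model <- utils::modifyList(model, list(seed = derive_seed(seed, 11)))
  class(model) <- "population_model"
  total <- n + n_reference + n_freq_reference + n_extra
  pop <- generate_population(model, total)
  cohorts <- split_cohorts(pop, c(n, n_reference, n_freq_reference, n_extra),
                           seed = derive_seed(seed, 12))
  subset_ids <- local_seed(derive_seed(seed, 13), {
    snp_ids(pop)[sample.int(model$n_snps)][seq_len(m_prime)]
  })
  order_panel <- snp_panel(subset_ids, rep(0, m_prime)) # order carrier only
  truth <- align_to_panel(cohorts[[1L]], order_panel)
  corr_ref <- align_to_panel(cohorts[[2L]], order_panel)
  freq_ref <- align_to_panel(cohorts[[3L]], order_panel)
  extra <- if (n_extra > 0) align_to_panel(cohorts[[4L]], order_panel)

  panel <- if (mode == "binary-mismatched") {
    mm <- mismatch_model %||% {
      lo <- min(0.4, model$maf_range[1] + 0.2)
      hi <- min(0.9, model$maf_range[2] + 0.4)
      utils::modifyList(model, list(maf_range = c(lo, hi)))
    }
    mm <- utils::modifyList(mm, list(seed = derive_seed(seed, 17)))
    class(mm) <- "population_model"
    mpop <- generate_population(mm, n_freq_reference)
    mpanel <- population_af(mpop)
    # mismatched population measured over the same loci, realigned by position
    snp_panel(subset_ids, mpanel$af[match(subset_ids, mpanel$snp_id)])
  } else {
    population_af(freq_ref)
  }

  bcn <- beacon(truth)
  response_mode <- if (mode == "af") "af" else "binary"
  response <- beacon_respond(bcn, panel, response_mode)
  list(truth = truth, beacon = bcn, panel = panel,
       correlation = compute_correlation_matrix(corr_ref),
       response = response, extra = extra, snp_subset = subset_ids,
       mode = mode, seed = seed)
}

#' Run a grid of reconstruction experiments
#'
#' For every combination of beacon size `n`, SNP-set size `m_prime`,
#' response `mode`, known fraction `p` and seed, simulates an attack
#' setting, runs both the greedy baseline and the gradient attack, and
#' scores them against the true beacon. When `p > 0` the first
#' `round(p * n)` participants' genomes are given to the attacker (frozen
#' rows) and scores are computed over the remaining, unknown rows only
#' (optimal assignment among them); with `p = 0` scores cover all rows.
#'
#' @param n,m_prime,mode,p,seeds vectors defining the grid.
#' @param model the [population_model()] shared by all cells.
#' @param config an [optimizer_config()] for the gradient attack.
#' @param n_reference,n_freq_reference reference cohort sizes.
#' @param mismatch_model optional model for `"binary-mismatched"` cells.
#' @return A tibble of class `becn_experiment`, one row per
#'   (cell, seed, method), with columns `n`, `m_prime`, `mode`, `p`,
#'   `seed`, `method`, `precision`, `recall`, `f1`, `l_corr`, `l_mse`,
#'   `converged`, `iters`. Deterministic given `seeds`.
#' @export
#' @examples
#' \donttest{
#' res <- run_experiment(n = 5, m_prime = 20, seeds = 1,
#'                       model = population_model(n_snps = 40, seed = 1),
#'                       config = optimizer_config(e1 = 50, e2 = 25,
#'                                                 max_iter = 50))
#' }
run_experiment <- function(n = 10, m_prime = 50, mode = "af", p = 0,
                           seeds = 1:3,
                           model = population_model(),
                           config = optimizer_config(),
                           n_reference = 100, n_freq_reference = 64,
                           mismatch_model = NULL) {
  mode <- match.arg(mode, c("af", "binary", "binary-mismatched"),
                    several.ok = TRUE)
  if (any(m_prime > model$n_snps)) {
    stop_config("every m_prime must be <= model$n_snps")
  }
  if (any(p < 0 | p >= 1)) stop_config("known fraction p must lie in [0, 1)")
  if (any(n < 1)) stop_config("beacon sizes must be >= 1")

  grid <- expand.grid(seed = seeds, p = p, mode = mode, m_prime = m_prime,
                      n = n, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    cell <- grid[k, ]
    setting <- simulate_attack_setting(
      model, n = cell$n, m_prime = cell$m_prime, mode = cell$mode,
      n_reference = n_reference, n_freq_reference = n_freq_reference,
      mismatch_model = mismatch_model, seed = cell$seed
    )
    inputs <- attack_inputs(setting$response, setting$panel,
                            setting$correlation,
                            seed = derive_seed(cell$seed, 21))
    n_known <- round_half_up(cell$p * cell$n)
    known <- if (n_known > 0) {
      genotype_matrix(unclass(setting$truth)[seq_len(n_known), , drop = FALSE],
                      individual_ids = rownames(setting$truth)[seq_len(n_known)],
                      snp_ids = snp_ids(setting$truth))
    }
    cfg <- utils::modifyList(config, list(seed = derive_seed(cell$seed, 22)))
    class(cfg) <- "optimizer_config"

    base <- baseline_reconstruct(inputs)
    if (!is.null(known)) {
      bm <- unclass(base)
      bm[seq_len(n_known), ] <- unclass(known)
      base <- genotype_matrix(bm, individual_ids = rownames(base),
                              snp_ids = colnames(base))
    }
    opt <- reconstruct_beacon(inputs, cfg, known = known,
                              known_rows = if (!is.null(known)) seq_len(n_known))

    score <- function(recon) {
      if (n_known > 0) {
        keep <- setdiff(seq_len(cell$n), seq_len(n_known))
        tr <- genotype_matrix(unclass(setting$truth)[keep, , drop = FALSE],
                              snp_ids = snp_ids(setting$truth))
        rc <- genotype_matrix(unclass(recon)[keep, , drop = FALSE],
                              snp_ids = snp_ids(setting$truth))
        evaluate_reconstruction(tr, rc, match = "optimal")
      } else {
        evaluate_reconstruction(setting$truth, recon, match = "optimal")
      }
    }
    f <- frequency_target(inputs)
    ev_b <- score(base)
    ev_o <- score(opt$genotypes)
    last <- utils::tail(opt$history, 1L)
    tibble::tibble(
      n = rep(cell$n, 2), m_prime = rep(cell$m_prime, 2),
      mode = rep(cell$mode, 2), p = rep(cell$p, 2),
      seed = rep(cell$seed, 2),
      method = c("baseline", "optimization"),
      precision = c(ev_b$precision, ev_o$precision),
      recall = c(ev_b$recall, ev_o$recall),
      f1 = c(ev_b$f1, ev_o$f1),
      l_corr = c(loss_corr(unclass(base), setting$correlation), last$l_corr),
      l_mse = c(loss_freq(unclass(base), f), last$l_mse),
      converged = c(NA, opt$converged),
      iters = c(NA_integer_, opt$iterations)
    )
  })
  structure(dplyr::bind_rows(rows),
            class = c("becn_experiment", class(tibble::tibble())))
}

#' Membership-inference chain experiment
#'
#' The downstream use of reconstructions: attack a "safe" Beacon A with the
#' gradient reconstruction, then use each reconstructed genome as the
#' victim's genome in a likelihood-ratio membership-inference attack
#' against sensitive beacons B_i, each consisting of `n_beacon - 1` fresh
#' individuals plus the true genome of member i. Power (true-positive rate
#' at the calibrated false-positive rate) is compared against victims
#' replaced by frequency-matched random genotypes; false-positive control
#' is measured on fresh non-member genomes if `n_fpr > 0`.
#'
#' @param model a [population_model()].
#' @param n_beacon size of Beacon A (and of every B_i).
#' @param m_prime number of target SNPs.
#' @param n_reference,n_freq_reference reference cohort sizes.
#' @param config an [optimizer_config()] for the reconstruction step.
#' @param mi an [mi_config()].
#' @param n_fpr number of fresh non-members used to measure the empirical
#'   false-positive rate (0 to skip).
#' @param rule decision rule: `"fixed"` (default) compares the full-query
#'   statistic against a threshold calibrated once on the controls' full
#'   query sets — the rule whose false-positive rate the calibration
#'   actually controls; `"sequential"` recalibrates per query prefix and
#'   stops at the first exceedance ([infer_membership()]), which reports
#'   how few queries suffice but inflates the false-positive rate through
#'   repeated testing.
#' @param seed master seed.
#' @return A list with `results` (tibble: one row per victim and genome
#'   source), `tpr_reconstructed`, `tpr_random`, `fpr_empirical`,
#'   `recon_f1`, `seed`.
#' @export
run_mi_chain <- function(model = population_model(), n_beacon = 10,
                         m_prime = 50, n_reference = 100,
                         n_freq_reference = 64,
                         config = optimizer_config(),
                         mi = mi_config(), n_fpr = 0,
                         rule = c("fixed", "sequential"), seed = 1) {
  rule <- match.arg(rule)
  n_extra <- n_beacon - 1 + mi$n_controls + n_fpr
  setting <- simulate_attack_setting(model, n = n_beacon, m_prime = m_prime,
                                     mode = "af", n_reference = n_reference,
                                     n_freq_reference = n_freq_reference,
                                     n_extra = n_extra, seed = seed)
  inputs <- attack_inputs(setting$response, setting$panel,
                          setting$correlation, seed = derive_seed(seed, 21))
  cfg <- utils::modifyList(config, list(seed = derive_seed(seed, 22)))
  class(cfg) <- "optimizer_config"
  recon <- reconstruct_beacon(inputs, cfg)
  # pair anonymous reconstructed rows with the true members they best match
  perm <- match_rows(setting$truth, recon$genotypes)
  recon_f1 <- evaluate_reconstruction(setting$truth, recon$genotypes)$f1

  extra <- unclass(setting$extra)
  others <- extra[seq_len(n_beacon - 1), , drop = FALSE]
  controls <- genotype_matrix(
    extra[n_beacon - 1 + seq_len(mi$n_controls), , drop = FALSE],
    snp_ids = snp_ids(setting$truth)
  )
  af <- panel_af(setting$panel)
  truth <- unclass(setting$truth)

  decide <- function(victim_genome, resp) {
    if (rule == "sequential") {
      return(infer_membership(victim_genome, resp, setting$panel, n_beacon,
                              controls, mi))
    }
    lam <- lrt_statistic(victim_genome, resp, setting$panel, n_beacon,
                         delta = mi$delta, max_queries = mi$max_queries)
    thr <- calibrate_threshold(controls, resp, setting$panel, n_beacon, mi)
    list(decision = if (as.numeric(lam) > thr) "member" else "non-member",
         lambda = as.numeric(lam), threshold = thr,
         n_queries = attr(lam, "n_queries"))
  }

  attack_one <- function(victim_genome, target_row) {
    bi <- beacon(genotype_matrix(rbind(others, truth[target_row, , drop = FALSE]),
                                 snp_ids = snp_ids(setting$truth)))
    resp <- beacon_respond(bi, setting$panel, "binary")
    decide(victim_genome, resp)
  }

  rec_mat <- unclass(recon$genotypes)
  rand_mat <- local_seed(derive_seed(seed, 23), {
    matrix(rbinom(n_beacon * m_prime, 1L, rep(af, each = n_beacon)),
           nrow = n_beacon)
  })
  rows <- lapply(seq_len(n_beacon), function(i) {
    # reconstructed row assigned to true member i
    ri <- which(perm == i)
    res_rec <- attack_one(rec_mat[ri, ], i)
    res_rnd <- attack_one(rand_mat[i, ], i)
    tibble::tibble(victim = rep(i, 2),
                   source = c("reconstructed", "random"),
                   decision = c(res_rec$decision, res_rnd$decision),
                   lambda = c(res_rec$lambda, res_rnd$lambda),
                   n_queries = c(res_rec$n_queries, res_rnd$n_queries))
  })
  results <- dplyr::bind_rows(rows)

  fpr <- NA_real_
  if (n_fpr > 0) {
    non_members <- extra[n_beacon - 1 + mi$n_controls + seq_len(n_fpr), ,
                         drop = FALSE]
    bi <- beacon(genotype_matrix(rbind(others, truth[1L, , drop = FALSE]),
                                 snp_ids = snp_ids(setting$truth)))
    resp <- beacon_respond(bi, setting$panel, "binary")
    calls <- vapply(seq_len(n_fpr), function(i) {
      decide(non_members[i, ], resp)$decision == "member"
    }, logical(1))
    fpr <- mean(calls)
  }

  list(results = results,
       tpr_reconstructed = mean(results$decision[results$source == "reconstructed"] == "member"),
       tpr_random = mean(results$decision[results$source == "random"] == "member"),
       fpr_empirical = fpr,
       recon_f1 = recon_f1,
       seed = seed)
}
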