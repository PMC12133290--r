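#' Membership-inference configuration
#'
#' @param fpr_target target false-positive rate for threshold calibration
#'   (default 0.05).
#' @param n_controls number of non-member control genomes used to calibrate
#'   the decision threshold (default 20, >= 2).
#' @param max_queries optional cap on the number of beacon queries per
#'   victim (a fixed query budget); `NULL` means query every carried SNP.
#' @param delta attacker-side mismatch rate between their copy of the
#'   victim's genome and the beacon's copy; enters the member likelihood as
#'   the probability that a truly-carried allele is absent from the beacon.
#' @param seed RNG seed.
#' @return A list of class `mi_config`.
#' @export
mi_config <- function(fpr_target = 0.05, n_controls = 20, max_queries = NULL,
                      delta = 1e-6, seed = 1) {
  if (fpr_target <= 0 || fpr_target >= 1) stop_config("fpr_target must lie in (0, 1)")
  if (n_controls < 2) stop_config("n_controls must be >= 2")
  if (delta < 0 || delta >= 1) stop_config("delta must lie in [0, 1)")
  structure(list(fpr_target = fpr_target, n_controls = as.integer(n_controls),
                 max_queries = max_queries, delta = delta,
                 seed = as.integer(seed)),
            class = "mi_config")
}

# ascending-population-frequency order of the SNPs a genome carries:
# rare alleles are queried first because they carry the most evidence
query_order <- function(victim, panel) {
  carried <- which(victim == 1L)
  carried[order(panel_af(panel)[carried], carried)]
}

# per-query log-likelihood-ratio terms of the optimal LRT attack.
# D_n(j) = (1 - m_j)^(2n) is the probability that none of n diploid
# non-members carries allele j; under H0 (victim not in the beacon of N)
# P(x_j = 1) = 1 - D_N, under H1 (victim in, carrying j) the response is
# "yes" unless the attacker's copy is wrong (rate delta) and none of the
# other N-1 carries it: P(x_j = 1) = 1 - delta * D_{N-1}.
lrt_terms <- function(x, m, n, delta) {
  m <- pmin(pmax(m, 1e-9), 1 - 1e-9)
  dn <- (1 - m)^(2 * n)
  dn1 <- (1 - m)^(2 * (n - 1))
  p1_mem <- pmin(pmax(1 - delta * dn1, 1e-12), 1 - 1e-12)
  p1_non <- pmin(pmax(1 - dn, 1e-12), 1 - 1e-12)
  x * log(p1_mem / p1_non) + (1 - x) * log((1 - p1_mem) / (1 - p1_non))
}

#' Log-likelihood-ratio membership statistic
#'
#' The optimal-attack LRT: the attacker queries the beacon at the SNPs the
#' victim's genome carries, rarest first, and accumulates per-response
#' log-likelihood ratios of member vs non-member. Positive values favour
#' membership. A victim carrying no panel allele yields 0 with attribute
#' `flagged = TRUE` (no evidence either way).
#'
#' @param victim binary vector (or 1-row [genotype_matrix()]) aligned to
#'   `panel`.
#' @param responses a binary-mode `beacon_response` over `panel`.
#' @param panel a [snp_panel()] of population frequencies.
#' @param n_individuals the (public) beacon size N.
#' @param delta attacker/beacon genome mismatch rate.
#' @param max_queries optional cap: only the first `max_queries` rarest
#'   carried SNPs contribute.
#' @return Scalar statistic with attributes `n_queries` and `flagged`.
#' @export
lrt_statistic <- function(victim, responses, panel, n_individuals,
                          delta = 1e-6, max_queries = NULL) {
  victim <- as.integer(as.vector(unclass(as.matrix(victim))))
  if (length(victim) != nrow(panel)) {
    stop_validation("victim genome and panel lengths differ")
  }
  if (responses$mode != "binary") {
    stop_validation("membership inference expects binary beacon responses")
  }
  qs <- query_order(victim, panel)
  if (!is.null(max_queries)) qs <- utils::head(qs, max_queries)
  if (length(qs) == 0L) {
    warn("victim carries no panel allele; membership statistic is uninformative")
    return(structure(0, n_queries = 0L, flagged = TRUE))
  }
  x <- responses$values[qs]
  m <- panel_af(panel)[qs]
  lam <- sum(lrt_terms(x, m, n_individuals, delta))
  structure(lam, n_queries = length(qs), flagged = FALSE)
}

# statistics for every control genome, each over its own first `budget`
# rarest carried SNPs (comparable query effort across genomes)
control_statistics <- function(controls, responses, panel, n_individuals,
                               delta, budget = NULL) {
  vapply(seq_len(nrow(controls)), function(i) {
    as.numeric(lrt_statistic(unclass(controls)[i, ], responses, panel,
                             n_individuals, delta, max_queries = budget))
  }, numeric(1))
}

#' Calibrate the membership decision threshold on a control group
#'
#' Computes the LRT statistic for every control (a known non-member of the
#' beacon) and returns the smallest threshold such that the fraction of
#' controls with a statistic strictly above it is at most `fpr_target`.
#' With 20 controls and a 5% target, at most one control may exceed the
#' threshold. Decisions use "member iff statistic > threshold".
#'
#' @param controls a [genotype_matrix()] of non-member genomes over `panel`.
#' @param responses,panel,n_individuals as in [lrt_statistic()].
#' @param config an [mi_config()].
#' @return Scalar threshold.
#' @export
calibrate_threshold <- function(controls, responses, panel, n_individuals,
                                config = mi_config()) {
  if (nrow(controls) < 2L) stop_validation("need at least 2 control genomes")
  lam <- control_statistics(controls, responses, panel, n_individuals,
                            config$delta, config$max_queries)
  threshold_from_controls(lam, config$fpr_target)
}

# k-th largest control statistic with k = floor(fpr * (n + 1)): a fresh
# non-member exceeds it with probability k / (n + 1) <= fpr_target (order
# statistics of exchangeable draws), so the *out-of-sample* FPR is
# controlled, not just the in-sample fraction. With 20 controls at 5% this
# is the maximum: no control is called a member, and a fresh non-member is
# flagged with probability 1/21.
threshold_from_controls <- function(lam, fpr_target) {
  k <- max(1L, floor(fpr_target * (length(lam) + 1L)))
  sort(lam, decreasing = TRUE)[k]
}

#' Sequential membership-inference attack
#'
#' Queries the beacon at the victim's carried SNPs in ascending population
#' frequency. After each query the victim's LRT statistic over the prefix
#' is compared with a threshold recalibrated on the controls' statistics
#' over their own same-length prefixes; "member" is declared at the first
#' query where the statistic exceeds the threshold, otherwise "non-member"
#' after the last query (or after `config$max_queries`). The sequential
#' design makes "number of queries needed" well-defined.
#'
#' @param victim binary genome vector over `panel`.
#' @param responses binary `beacon_response` of the attacked beacon.
#' @param panel a [snp_panel()].
#' @param n_individuals beacon size N.
#' @param controls [genotype_matrix()] of non-members for calibration.
#' @param config an [mi_config()].
#' @return A list of class `mi_result`: `decision` ("member"/"non-member"),
#'   `lambda`, `threshold`, `n_queries`, `flagged`.
#' @export
infer_membership <- function(victim, responses, panel, n_individuals,
                             controls, config = mi_config()) {
  victim <- as.integer(as.vector(unclass(as.matrix(victim))))
  qs <- query_order(victim, panel)
  if (!is.null(config$max_queries)) qs <- utils::head(qs, config$max_queries)
  if (length(qs) == 0L) {
    return(structure(list(decision = "non-member", lambda = 0,
                          threshold = NA_real_, n_queries = 0L,
                          flagged = TRUE), class = "mi_result"))
  }
  m_all <- panel_af(panel)
  ctrl_orders <- lapply(seq_len(nrow(controls)), function(i) {
    query_order(unclass(controls)[i, ], panel)
  })
  terms_v <- lrt_terms(responses$values[qs], m_all[qs], n_individuals,
                       config$delta)
  lam_v <- cumsum(terms_v)
  ctrl_terms <- lapply(ctrl_orders, function(o) {
    if (length(o) == 0L) return(numeric(0))
    cumsum(lrt_terms(responses$values[o], m_all[o], n_individuals,
                     config$delta))
  })
  decision <- "non-member"
  lam_t <- NA_real_; thr_t <- NA_real_; t_used <- length(qs)
  for (t in seq_along(qs)) {
    lam_c <- vapply(ctrl_terms, function(cs) {
      if (length(cs) == 0L) 0 else cs[min(t, length(cs))]
    }, numeric(1))
    thr <- threshold_from_controls(lam_c, config$fpr_target)
    if (lam_v[t] > thr) {
      decision <- "member"
      lam_t <- lam_v[t]; thr_t <- thr; t_used <- t
      break
    }
    lam_t <- lam_v[t]; thr_t <- thr
  }
  structure(list(decision = decision, lambda = lam_t, threshold = thr_t,
                 n_queries = as.integer(t_used), flagged = FALSE),
            class = "mi_result")
}

#' @export
print.mi_result <- function(x, ...) {
  cat(sprintf("<mi_result> %s (lambda %.3f vs threshold %.3f after %d queries)\n",
              x$decision, x$lambda, x$threshold, x$n_queries))
  invisible(x)
}
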