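#' Bundle of everything the attacker observes
#'
#' The argument tuple of the reconstruction attacks: the beacon snapshot
#' `b`, the public frequency panel `m`, and (for the gradient attack) the
#' correlation matrix `C`. All three must cover exactly the same SNPs in
#' exactly the same order.
#'
#' @param response a `beacon_response` (see [beacon_respond()]).
#' @param panel a [snp_panel()] of public population frequencies.
#' @param correlation optionally a [correlation_matrix()]; not used by the
#'   baseline, required by [reconstruct_beacon()].
#' @param seed RNG seed for the (randomized) baseline assignment.
#' @return A list of class `attack_inputs`.
#' @export
attack_inputs <- function(response, panel, correlation = NULL, seed = 1) {
  stopifnot(inherits(response, "beacon_response"))
  ids <- panel_snp_ids(panel)
  if (!identical(response$snp_ids, ids)) {
    stop_validation("response and panel SNP ids must be identical and identically ordered")
  }
  if (!is.null(correlation) && !identical(colnames(correlation), ids)) {
    stop_validation("correlation matrix SNP ids must match the panel")
  }
  structure(
    list(response = response, panel = panel, correlation = correlation,
         seed = as.integer(seed)),
    class = "attack_inputs"
  )
}

#' Inferred number of carriers per SNP
#'
#' The greedy attack's per-SNP carrier count: a "no" (`b_j = 0`) certifies
#' zero carriers; otherwise the count is `b_j * N` in frequency mode, or the
#' public-population proxy `m_j * N` in binary mode, rounded half-up and
#' clamped into `[1, N]` (a "yes" implies at least one carrier). In
#' frequency mode with exact beacon responses `b_j * N` is already integral,
#' so rounding only matters for external or mismatched frequency sources.
#'
#' @param inputs an [attack_inputs()].
#' @return Integer vector over the panel SNPs.
#' @export
carriers_per_snp <- function(inputs) {
  r <- inputs$response
  n <- r$n_individuals
  x <- if (r$mode == "af") r$values else panel_af(inputs$panel)
  k <- pmin(n, pmax(1, round_half_up(x * n)))
  k[r$values == 0] <- 0
  as.integer(k)
}

#' Greedy baseline reconstruction
#'
#' The frequency-matching baseline attack: start from a zero matrix and,
#' for each SNP answered "yes", assign its inferred carrier count to a
#' uniformly random subset of the `N` rows, independently per SNP. The
#' column sums of the result equal [carriers_per_snp()] exactly; all
#' correlation structure between SNPs is ignored (each SNP is treated as
#' independent), which is precisely the weakness the gradient attack fixes.
#' Also used as the initialization of [reconstruct_beacon()].
#'
#' @param inputs an [attack_inputs()]; randomness flows from `inputs$seed`.
#' @return A [genotype_matrix()] with synthetic row ids `recon_0001`, ...
#' @export
#' @examples
#' g <- genotype_matrix(matrix(c(1, 0, 1, 0, 1, 1), 2, 3))
#' pan <- population_af(g)
#' resp <- beacon_respond(beacon(g), pan, "af")
#' baseline_reconstruct(attack_inputs(resp, pan, seed = 3))
baseline_reconstruct <- function(inputs) {
  stopifnot(inherits(inputs, "attack_inputs"))
  n <- inputs$response$n_individuals
  counts <- carriers_per_snp(inputs)
  m <- length(counts)
  data <- matrix(0L, n, m)
  local_seed(inputs$seed, {
    for (j in seq_len(m)) {
      if (counts[j] > 0L) data[sample.int(n, counts[j]), j] <- 1L
    }
  })
  genotype_matrix(data,
                  individual_ids = sprintf("recon_%04d", seq_len(n)),
                  snp_ids = inputs$response$snp_ids)
}
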