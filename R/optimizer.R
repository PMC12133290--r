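#' Configuration of the gradient reconstruction attack
#'
#' Defaults follow the attack's published operating point: Adam with
#' learning rate `eta = 0.001`, `e1 = 1000` epochs per correlation block,
#' `e2 = 500` epochs per frequency block, at most `max_iter = 3000` outer
#' alternations, and convergence declared when fewer than `flip_threshold =
#' 10` entries of the binarized reconstruction change across one outer
#' alternation.
#'
#' @param eta Adam learning rate (> 0).
#' @param e1 Adam steps per correlation-loss block (>= 0).
#' @param e2 Adam steps per frequency-loss block (>= 0).
#' @param max_iter maximum outer alternations (>= 1).
#' @param flip_threshold convergence threshold on the per-alternation flip
#'   count (>= 0).
#' @param adam_beta1,adam_beta2,adam_eps Adam moment/stability constants.
#' @param binarize_threshold relaxed entries at or above this map to 1.
#' @param seed master seed of the attack run (drives the baseline init).
#' @return A list of class `optimizer_config`.
#' @export
optimizer_config <- function(eta = 0.001, e1 = 1000, e2 = 500,
                             max_iter = 3000, flip_threshold = 10,
                             adam_beta1 = 0.9, adam_beta2 = 0.999,
                             adam_eps = 1e-8, binarize_threshold = 0.5,
                             seed = 1) {
  if (!is_scalar_number(eta) || eta <= 0) stop_config("eta must be > 0")
  if (e1 < 0 || e2 < 0) stop_config("e1 and e2 must be >= 0")
  if (max_iter < 1) stop_config("max_iter must be >= 1")
  if (flip_threshold < 0) stop_config("flip_threshold must be >= 0")
  if (binarize_threshold <= 0 || binarize_threshold >= 1) {
    stop_config("binarize_threshold must lie in (0, 1)")
  }
  structure(
    list(eta = eta, e1 = as.integer(e1), e2 = as.integer(e2),
         max_iter = as.integer(max_iter),
         flip_threshold = as.integer(flip_threshold),
         adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
         adam_eps = adam_eps, binarize_threshold = binarize_threshold,
         seed = as.integer(seed)),
    class = "optimizer_config"
  )
}

#' Target frequency vector of the frequency-adjustment step
#'
#' `f = b` when the beacon reports frequencies. With binary responses the
#' public population frequency `m` stands in, overridden by the response
#' where the response is informative: a "no" forces `f_j = 0` (zero carriers
#' certified) and a "yes" at a SNP with `m_j = 0` forces `f_j = 1/N` (at
#' least one carrier certified).
#'
#' @param inputs an [attack_inputs()].
#' @return Numeric vector over the panel SNPs.
#' @export
frequency_target <- function(inputs) {
  r <- inputs$response
  if (r$mode == "af") return(r$values)
  f <- panel_af(inputs$panel)
  f[r$values == 0] <- 0
  f[r$values == 1 & f == 0] <- 1 / r$n_individuals
  f
}

# --- losses and analytic gradients (reference forms; the hot loops live in
# --- src/adam.cpp and are cross-checked against these in the test suite)

#' Attack losses
#'
#' `loss_corr()` is the correlation loss: the (unsquared) Frobenius norm
#' `|| C_B' - C ||_F` where `C_B'` is [reconstruction_correlation()] of the
#' iterate. `loss_freq()` is the frequency loss: the mean over SNPs of the
#' squared gap between target and reconstructed carrier frequency. The
#' optimizer descends the *squared* Frobenius norm (same minimizers, smooth
#' at zero); losses are reported unsquared to match the loss definitions.
#'
#' @param R numeric matrix in `[0,1]` (relaxed or binary reconstruction).
#' @param C a [correlation_matrix()] (or plain matrix) over the same SNPs.
#' @param f target frequency vector (see [frequency_target()]).
#' @return A non-negative scalar.
#' @export
loss_corr <- function(R, C) {
  sqrt(sum((reconstruction_correlation(R) - unclass(C))^2))
}

#' @rdname loss_corr
#' @export
loss_freq <- function(R, f) {
  mean((f - colMeans(unclass(as.matrix(R))))^2)
}

grad_corr <- function(R, C) {
  n <- nrow(R)
  (4 / n) * R %*% (crossprod(R) / n - unclass(C))
}

grad_freq <- function(R, f) {
  n <- nrow(R)
  m <- ncol(R)
  g <- 2 * (colMeans(R) - f) / (n * m)
  matrix(g, nrow = n, ncol = m, byrow = TRUE)
}

# pure-R Adam block, kept as the slow reference for the compiled kernels
adam_block_r <- function(R, steps, grad_fn, config, free_mask, frozen_vals) {
  m <- v <- matrix(0, nrow(R), ncol(R))
  b1 <- config$adam_beta1; b2 <- config$adam_beta2
  b1t <- b2t <- 1
  for (t in seq_len(steps)) {
    g <- grad_fn(R)
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    b1t <- b1t * b1; b2t <- b2t * b2
    R <- R - config$eta * (m / (1 - b1t)) / (sqrt(v / (1 - b2t)) + config$adam_eps)
    R <- pmin(pmax(R, 0), 1)
    R <- free_mask * R + (1 - free_mask) * frozen_vals
  }
  R
}

new_recon_state <- function(relaxed, config, frozen_cols, frozen_rows,
                            frozen_vals) {
  free <- matrix(1, nrow(relaxed), ncol(relaxed))
  free[, frozen_cols] <- 0
  free[frozen_rows, ] <- 0
  list(relaxed = relaxed,
       free_mask = free,
       frozen_vals = frozen_vals,
       config = config)
}

binarize <- function(R, threshold) {
  # ties at the threshold map to 1 (deterministic, keeps flip counts stable)
  (unclass(as.matrix(R)) >= threshold) * 1L
}

#' One correlation / frequency block of the alternating attack
#'
#' `correlation_step()` runs `e1` Adam updates of the relaxed iterate on the
#' squared correlation loss; `frequency_step()` runs `e2` updates on the
#' frequency loss. After every single update the iterate is clipped into
#' `[0,1]` and frozen entries (zero-certified columns, known rows) are
#' restored. Exposed mainly for inspection and testing; [reconstruct_beacon()]
#' alternates them.
#'
#' @param state internal reconstruction state (see [reconstruct_beacon()]).
#' @param C correlation matrix aligned to the state's SNPs.
#' @param f target frequency vector.
#' @param config an [optimizer_config()].
#' @return The state with an updated `relaxed` matrix.
#' @keywords internal
#' @export
correlation_step <- function(state, C, config = state$config) {
  if (config$e1 == 0L) return(state)
  state$relaxed <- .adam_block_corr(
    state$relaxed, unclass(C), config$e1, config$eta,
    config$adam_beta1, config$adam_beta2, config$adam_eps,
    state$free_mask, state$frozen_vals
  )
  state
}

#' @rdname correlation_step
#' @export
frequency_step <- function(state, f, config = state$config) {
  if (config$e2 == 0L) return(state)
  state$relaxed <- .adam_block_freq(
    state$relaxed, f, config$e2, config$eta,
    config$adam_beta1, config$adam_beta2, config$adam_eps,
    state$free_mask, state$frozen_vals
  )
  state
}

#' Gradient-based beacon reconstruction attack
#'
#' The two-objective alternating attack. The reconstruction is initialized
#' with [baseline_reconstruct()] and relaxed to a continuous matrix in
#' `[0,1]^(N x M')`. Each outer alternation runs `e1` Adam steps on the
#' correlation loss (match the reconstruction's co-carriage matrix to the
#' public `C`), then `e2` Adam steps on the frequency loss (match per-SNP
#' carrier frequencies to the beacon-reported or proxy target). After each
#' alternation the iterate is binarized at `binarize_threshold` and the
#' number of flipped entries relative to the previous alternation is
#' counted; the attack stops when the flip count drops below
#' `flip_threshold`, or after `max_iter` alternations (returning
#' `converged = FALSE`, never raising).
#'
#' Columns answered "no" by the beacon are frozen at zero throughout (a
#' "no" certifies zero carriers). If the attacker already possesses some
#' participants' genomes, pass them via `known`: those rows are fixed
#' bit-exactly and only the remaining rows are reconstructed.
#'
#' @param inputs an [attack_inputs()] carrying response, panel and
#'   correlation matrix.
#' @param config an [optimizer_config()]; `config$seed` drives the baseline
#'   initialization.
#' @param known optionally a [genotype_matrix()] of known participant
#'   genomes over the same SNP panel.
#' @param known_rows integer row indices (in `1..N`) that `known` occupies;
#'   defaults to the first `nrow(known)` rows.
#' @return An object of class `beacon_reconstruction`: list with
#'   `genotypes` (the binary reconstruction), `relaxed`, `history` (tibble
#'   with columns `iter`, `l_corr`, `l_mse`, `flips`, losses evaluated on
#'   the binarized iterate), `converged`, `iterations`, `config`, `known_rows`.
#' @export
#' @seealso [baseline_reconstruct()] for the initialization,
#'   [evaluate_reconstruction()] for scoring against ground truth.
reconstruct_beacon <- function(inputs, config = optimizer_config(),
                               known = NULL, known_rows = NULL) {
  stopifnot(inherits(inputs, "attack_inputs"))
  if (is.null(inputs$correlation)) {
    stop_validation("gradient attack requires a correlation matrix in attack_inputs()")
  }
  n <- inputs$response$n_individuals
  ids <- inputs$response$snp_ids
  m <- length(ids)

  init_inputs <- inputs
  init_inputs$seed <- config$seed
  frozen_cols <- which(inputs$response$values == 0)
  frozen_rows <- integer(0)
  if (is.null(known)) {
    b0 <- baseline_reconstruct(init_inputs)
    relaxed <- unclass(b0) * 1.0
    row_ids <- rownames(b0)
  } else {
    if (!identical(snp_ids(known), ids)) {
      stop_validation("known genomes must cover the attack SNP panel in order")
    }
    known_rows <- known_rows %||% seq_len(nrow(known))
    if (length(known_rows) != nrow(known) || any(known_rows < 1 | known_rows > n)) {
      stop_validation("known_rows must index rows of the beacon (1..N)")
    }
    if (any(unclass(known)[, frozen_cols, drop = FALSE] == 1L)) {
      stop_validation("known genomes carry alleles at SNPs the beacon answered 'no'")
    }
    # conditioned baseline init: the known rows already account for part of
    # each SNP's inferred carrier count, so only the remainder is spread at
    # random over the unknown rows
    counts <- carriers_per_snp(inputs)
    remaining <- pmax(0L, counts - as.integer(colSums(unclass(known))))
    free_rows <- setdiff(seq_len(n), known_rows)
    remaining <- pmin(remaining, length(free_rows))
    relaxed <- matrix(0, n, m)
    local_seed(config$seed, {
      for (j in seq_len(m)) {
        if (remaining[j] > 0L && length(free_rows)) {
          relaxed[free_rows[sample.int(length(free_rows), remaining[j])], j] <- 1
        }
      }
    })
    row_ids <- sprintf("recon_%04d", seq_len(n))
    relaxed[known_rows, ] <- unclass(known) * 1.0
    row_ids[known_rows] <- rownames(known)
    frozen_rows <- as.integer(known_rows)
  }
  frozen_vals <- matrix(0, n, m)
  if (length(frozen_rows)) frozen_vals[frozen_rows, ] <- unclass(known) * 1.0

  state <- new_recon_state(relaxed, config, frozen_cols, frozen_rows,
                           frozen_vals)
  f <- frequency_target(inputs)
  C <- inputs$correlation

  prev_bin <- binarize(state$relaxed, config$binarize_threshold)
  hist_iter <- integer(0); hist_lc <- hist_lm <- hist_fl <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < config$max_iter) {
    it <- it + 1L
    state <- tryCatch(
      frequency_step(correlation_step(state, C, config), f, config),
      error = function(e) stop_numeric(sprintf(
        "optimizer failed at outer iteration %d: %s", it, conditionMessage(e)))
    )
    bin <- binarize(state$relaxed, config$binarize_threshold)
    flips <- sum(bin != prev_bin)
    hist_iter <- c(hist_iter, it)
    hist_lc <- c(hist_lc, loss_corr(bin, C))
    hist_lm <- c(hist_lm, loss_freq(bin, f))
    hist_fl <- c(hist_fl, flips)
    prev_bin <- bin
    if (flips < config$flip_threshold) {
      converged <- TRUE
      break
    }
  }

  genotypes <- genotype_matrix(prev_bin, individual_ids = row_ids,
                               snp_ids = ids)
  structure(
    list(genotypes = genotypes,
         relaxed = state$relaxed,
         history = tibble::tibble(iter = hist_iter, l_corr = hist_lc,
                                  l_mse = hist_lm, flips = hist_fl),
         converged = converged,
         iterations = it,
         mode = inputs$response$mode,
         config = config,
         known_rows = frozen_rows),
    class = "beacon_reconstruction"
  )
}

#' @export
print.beacon_reconstruction <- function(x, ...) {
  cat(sprintf(
    "<beacon_reconstruction> %d x %d, %s mode, %d iteration(s), %s\n",
    nrow(x$genotypes), ncol(x$genotypes), x$mode, x$iterations,
    if (x$converged) "converged" else "max_iter reached"
  ))
  cat(sprintf("  final l_corr = %.4f, l_mse = %.6f\n",
              utils::tail(x$history$l_corr, 1),
              utils::tail(x$history$l_mse, 1)))
  invisible(x)
}
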