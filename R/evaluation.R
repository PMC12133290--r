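#' Optimal row assignment between reconstruction and truth
#'
#' A reconstruction's rows are anonymous: the attacker recovers genomes, not
#' identities. Before scoring, reconstructed rows are paired with true
#' individuals by the bijection minimizing total Hamming distance (solved as
#' a linear sum assignment problem).
#'
#' @param truth,recon [genotype_matrix()] objects of identical shape with
#'   the same SNP order.
#' @return Integer permutation `p` with `p[i]` the truth row assigned to
#'   reconstructed row `i`.
#' @export
match_rows <- function(truth, recon) {
  check_same_shape(truth, recon)
  cost <- hamming_cost(truth, recon)
  as.integer(clue::solve_LSAP(cost))
}

check_same_shape <- function(truth, recon) {
  if (!all(dim(truth) == dim(recon))) {
    stop_validation(sprintf("shape mismatch: truth %dx%d vs reconstruction %dx%d",
                            nrow(truth), ncol(truth), nrow(recon), ncol(recon)))
  }
  if (!identical(colnames(truth), colnames(recon))) {
    stop_validation("truth and reconstruction must share the same SNP order")
  }
}

# rows of the cost matrix = reconstructed rows, columns = true rows;
# Hamming(a, b) = a.(1-b) + (1-a).b computed by two matrix products
hamming_cost <- function(truth, recon) {
  A <- unclass(recon) * 1.0
  B <- unclass(truth) * 1.0
  A %*% t(1 - B) + (1 - A) %*% t(B)
}

#' Score a reconstruction against ground truth
#'
#' After pairing rows ([match_rows()] by default, or identity pairing when
#' row identity is meaningful, e.g. with frozen known rows), computes
#' micro-averaged precision, recall and F1 over all cells with carrier
#' status (1) as the positive class, a per-individual F1 vector, and the
#' Frobenius gap `|| B - B' ||_F`. For binary matrices the squared
#' Frobenius gap equals the number of disagreeing cells, i.e. FP + FN.
#'
#' @param truth the true [genotype_matrix()] of the beacon.
#' @param recon the reconstructed [genotype_matrix()].
#' @param match `"optimal"` (default) or `"identity"`.
#' @return An object of class `recon_evaluation`: list with `precision`,
#'   `recall`, `f1`, `row_assignment`, `per_individual_f1`,
#'   `frobenius_gap`, and the confusion counts `tp`, `fp`, `fn`, `tn`.
#' @export
#' @examples
#' g <- genotype_matrix(matrix(rbinom(30, 1, 0.3), 5, 6))
#' ev <- evaluate_reconstruction(g, g)
#' ev$f1 # 1
evaluate_reconstruction <- function(truth, recon,
                                    match = c("optimal", "identity")) {
  match <- match.arg(match)
  check_same_shape(truth, recon)
  perm <- if (match == "optimal") match_rows(truth, recon) else seq_len(nrow(truth))
  A <- unclass(recon)
  B <- unclass(truth)[perm, , drop = FALSE]
  tp <- sum(A == 1L & B == 1L)
  fp <- sum(A == 1L & B == 0L)
  fn <- sum(A == 0L & B == 1L)
  tn <- sum(A == 0L & B == 0L)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  per_ind <- vapply(seq_len(nrow(A)), function(i) {
    tpi <- sum(A[i, ] == 1L & B[i, ] == 1L)
    fpi <- sum(A[i, ] == 1L & B[i, ] == 0L)
    fni <- sum(A[i, ] == 0L & B[i, ] == 1L)
    if (2 * tpi + fpi + fni > 0) 2 * tpi / (2 * tpi + fpi + fni) else 0
  }, numeric(1))
  structure(
    list(precision = precision, recall = recall, f1 = f1,
         row_assignment = perm, per_individual_f1 = per_ind,
         frobenius_gap = sqrt(fp + fn),
         tp = tp, fp = fp, fn = fn, tn = tn, match = match),
    class = "recon_evaluation"
  )
}

#' @export
print.recon_evaluation <- function(x, ...) {
  cat(sprintf(
    "<recon_evaluation> precision %.3f, recall %.3f, F1 %.3f (%s matching)\n",
    x$precision, x$recall, x$f1, x$match
  ))
  invisible(x)
}
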