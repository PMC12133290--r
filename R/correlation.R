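#' Pairwise SNP co-carriage correlation matrix
#'
#' The public side-information the gradient attack exploits: for SNPs `j`
#' and `k` with binary carrier vectors `s_j`, `s_k` over a reference panel of
#' `Np` individuals, the entry is `(s_j . s_k) / Np` — the fraction of the
#' panel carrying *both* alleles. The diagonal is therefore the per-SNP
#' carrier frequency in the panel. This dot-product form (counting only 1-1
#' matches) is the default because the attack's correlation loss is defined
#' on it; the textbook Sokal-Michener similarity, which also counts 0-0
#' matches, is available as `method = "sokal-michener"` for sensitivity
#' analysis.
#'
#' @param reference a [genotype_matrix()] of `Np >= 1` reference individuals
#'   whose columns are ordered as the target panel.
#' @param method `"dotproduct"` (default) or `"sokal-michener"`.
#' @return A symmetric matrix of class `correlation_matrix` with entries in
#'   `[0, 1]`, SNP ids on both dimnames, and attribute `n_reference = Np`.
#' @export
#' @examples
#' ref <- genotype_matrix(matrix(c(1, 1, 0, 0, 1, 0, 1, 0), 4, 2),
#'                        snp_ids = c("rs1", "rs2"))
#' compute_correlation_matrix(ref)["rs1", "rs2"] # 0.25
compute_correlation_matrix <- function(reference,
                                       method = c("dotproduct", "sokal-michener")) {
  method <- match.arg(method)
  if (nrow(reference) == 0L) {
    stop_validation("reference panel is empty; cannot estimate correlations")
  }
  x <- unclass(reference)
  storage.mode(x) <- "double"
  np <- nrow(x)
  values <- crossprod(x) / np
  if (method == "sokal-michener") {
    values <- values + crossprod(1 - x) / np
  }
  correlation_matrix(values, snp_ids = colnames(x), n_reference = np)
}

#' @rdname compute_correlation_matrix
#' @param values symmetric numeric matrix in `[0, 1]`.
#' @param snp_ids SNP ids aligned to rows/columns.
#' @param n_reference the reference-panel size the matrix was estimated from.
#' @export
correlation_matrix <- function(values, snp_ids = colnames(values), n_reference) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop_validation("correlation matrix must be square")
  if (max(abs(values - t(values))) > 1e-12) {
    stop_validation("correlation matrix must be symmetric (tolerance 1e-12)")
  }
  if (anyNA(values) || any(values < 0 | values > 1)) {
    stop_validation("correlation entries must lie in [0, 1]")
  }
  if (is.null(snp_ids)) snp_ids <- sprintf("snp_%04d", seq_len(ncol(values)))
  dimnames(values) <- list(snp_ids, snp_ids)
  structure(values, n_reference = as.integer(n_reference),
            class = c("correlation_matrix", "matrix", "array"))
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %d SNPs, estimated from %d individuals\n",
              ncol(x), attr(x, "n_reference")))
  invisible(x)
}

#' Co-carriage matrix of a (possibly relaxed) reconstruction
#'
#' The differentiable extension of [compute_correlation_matrix()] to the
#' continuous relaxation `R` in `[0,1]^{N x M}` used by the optimizer:
#' `t(R) %*% R / N`. On a binary matrix it coincides bit-exactly with
#' [compute_correlation_matrix()] applied with `Np = N`.
#'
#' @param R numeric matrix with entries in `[0, 1]` (rows = individuals).
#' @return A plain `M x M` numeric matrix.
#' @export
reconstruction_correlation <- function(R) {
  R <- unclass(as.matrix(R))
  storage.mode(R) <- "double"
  if (anyNA(R) || any(R < 0 | R > 1)) {
    stop_validation("relaxed reconstruction entries must lie in [0, 1]")
  }
  crossprod(R) / nrow(R)
}

#' Read / write a correlation matrix as TSV
#'
#' Header row and first column carry the SNP ids.
#'
#' @param path file path.
#' @return `read_correlation_tsv()` returns a [correlation_matrix()].
#' @export
read_correlation_tsv <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  hdr <- readLines(path, n = 1L)
  has_meta <- startsWith(hdr, "#")
  np <- if (has_meta) {
    as.integer(sub("^#n_reference=(\\d+).*$", "\\1", hdr))
  } else {
    NA_integer_
  }
  tab <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    row.names = 1L, skip = as.integer(has_meta))
  correlation_matrix(as.matrix(tab), snp_ids = colnames(tab),
                     n_reference = np)
}

#' @rdname read_correlation_tsv
#' @param C a [correlation_matrix()].
#' @export
write_correlation_tsv <- function(C, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#n_reference=%d", attr(C, "n_reference")), con)
  tab <- data.frame(snp_id = rownames(C), unclass(C), check.names = FALSE)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
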