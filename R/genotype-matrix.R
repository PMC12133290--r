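#' Binary carrier genotype matrix
#'
#' The central container of the package: an `N x M` binary matrix whose
#' entry `(i, j)` is 1 if and only if individual `i` carries at least one
#' copy of the minor/alternate allele at SNP `j`. Both the beacon dataset
#' under attack and the attacker's reconstruction are objects of this class.
#' Genotypes are deliberately collapsed to carrier status (0/1), not allele
#' counts: a beacon answers presence-of-allele queries, so carrier status is
#' the resolution at which its responses constrain the data.
#'
#' @param data numeric or integer matrix containing only 0 and 1.
#' @param individual_ids character vector of unique row identifiers; defaults
#'   to existing rownames, or `ind_###`.
#' @param snp_ids character vector of unique column identifiers; defaults to
#'   existing colnames, or `snp_###`.
#'
#' @return An integer matrix of class `genotype_matrix` with individual ids
#'   as rownames and SNP ids as colnames.
#' @export
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 1, 0), 2, 2),
#'                      individual_ids = c("a", "b"),
#'                      snp_ids = c("rs1", "rs2"))
#' carrier_counts(g)
genotype_matrix <- function(data, individual_ids = NULL, snp_ids = NULL) {
  if (!is.matrix(data)) data <- as.matrix(data)
  individual_ids <- individual_ids %||% rownames(data) %||%
    sprintf("ind_%04d", seq_len(nrow(data)))
  snp_ids <- snp_ids %||% colnames(data) %||%
    sprintf("snp_%04d", seq_len(ncol(data)))
  storage.mode(data) <- "integer"
  dimnames(data) <- list(as.character(individual_ids), as.character(snp_ids))
  g <- structure(data, class = c("genotype_matrix", "matrix", "array"))
  validate_genotype_matrix(g)
  g
}

validate_genotype_matrix <- function(g) {
  if (anyNA(g)) stop_validation("genotype matrix contains missing values")
  if (nrow(g) && ncol(g) && !all(g == 0L | g == 1L)) {
    bad <- which(!(g == 0L | g == 1L), arr.ind = TRUE)[1L, ]
    stop_format(sprintf(
      "non-binary genotype at individual '%s', SNP '%s'",
      rownames(g)[bad[1L]], colnames(g)[bad[2L]]
    ))
  }
  if (anyDuplicated(rownames(g))) {
    stop_validation("duplicate individual ids in genotype matrix")
  }
  if (anyDuplicated(colnames(g))) {
    stop_validation("duplicate SNP ids in genotype matrix")
  }
  invisible(g)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d individuals x %d SNPs (%.1f%% carriers)\n",
    nrow(x), ncol(x), if (length(x)) 100 * mean(x) else 0
  ))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param g a `genotype_matrix`.
#' @export
individual_ids <- function(g) rownames(g)

#' @rdname genotype_matrix
#' @export
snp_ids <- function(g) colnames(g)

#' @rdname genotype_matrix
#' @export
carrier_counts <- function(g) colSums(unclass(g))

#' Read a genotype matrix from a tab-separated file
#'
#' Expects a header row of SNP ids, one row per individual, first column the
#' individual id, remaining cells 0 or 1.
#'
#' @param path path to a TSV file.
#' @return A [genotype_matrix()].
#' @export
read_genotype_tsv <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  tab <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character")
  if (ncol(tab) < 2L) stop_format("genotype TSV needs an id column and at least one SNP column")
  ids <- tab[[1L]]
  snps <- colnames(tab)[-1L]
  cells <- as.matrix(tab[, -1L, drop = FALSE])
  ok <- cells == "0" | cells == "1"
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    stop_format(sprintf(
      "non-binary cell '%s' at individual '%s', SNP '%s'",
      cells[bad[1L], bad[2L]], ids[bad[1L]], snps[bad[2L]]
    ))
  }
  data <- matrix(as.integer(cells), nrow = nrow(cells), ncol = ncol(cells))
  genotype_matrix(data, individual_ids = ids, snp_ids = snps)
}

#' Write a genotype matrix to a tab-separated file
#'
#' Inverse of [read_genotype_tsv()]: `read_genotype_tsv(write_genotype_tsv(g))`
#' reproduces `g` exactly, preserving row and column order.
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(g, path) {
  validate_genotype_matrix(g)
  tab <- data.frame(individual_id = rownames(g), unclass(g),
                    check.names = FALSE)
  ok <- tryCatch({
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_io(sprintf("cannot write '%s': %s", path, conditionMessage(ok)))
  invisible(path)
}

#' Read genotypes from a VCF and collapse to carrier status
#'
#' Each sample/record pair maps to 1 if the GT field contains any
#' non-reference allele (so `0/1`, `1/1`, `0|2` all collapse to 1), and 0 for
#' homozygous reference. Missing genotypes (`./.` or `.`) are treated as
#' non-carrier — a beacon cannot answer "yes" from missing data — and the
#' number of missing calls is reported as a message.
#'
#' @param path path to a VCF 4.x file (plain text).
#' @return A [genotype_matrix()] with individuals as rows. SNP ids come from
#'   the ID column, falling back to `CHROM:POS` where ID is ".".
#' @export
read_genotype_vcf <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(vcf@gt) < 2L || !all(grepl("GT", vcf@gt[, "FORMAT"]))) {
    stop_format("VCF has no GT field; cannot derive carrier genotypes")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ids <- vcf@fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(vcf@fix[noid, "CHROM"], ":", vcf@fix[noid, "POS"])
  missing <- is.na(gt) | gt %in% c(".", "./.", ".|.")
  if (any(missing)) {
    inform(sprintf("%d missing genotype(s) set to non-carrier", sum(missing)))
  }
  carrier <- !missing & grepl("[1-9]", gt)
  # gt is variants x samples; the package convention is individuals x SNPs
  data <- t(carrier) * 1L
  genotype_matrix(data, individual_ids = colnames(gt), snp_ids = ids)
}

#' Restrict and reorder a genotype matrix to a SNP panel
#'
#' @param g a [genotype_matrix()].
#' @param panel a [snp_panel()] (or anything with a `snp_id` column).
#' @return `g` with columns subset/reordered to `panel$snp_id`.
#' @export
align_to_panel <- function(g, panel) {
  want <- panel_snp_ids(panel)
  missing <- setdiff(want, snp_ids(g))
  if (length(missing)) {
    stop_validation(sprintf(
      "SNP id(s) absent from genotype matrix: %s",
      paste(missing, collapse = ", ")
    ))
  }
  sub <- unclass(g)[, want, drop = FALSE]
  genotype_matrix(sub, individual_ids = rownames(g), snp_ids = want)
}
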