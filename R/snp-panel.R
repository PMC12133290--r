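#' SNP panel with public population allele frequencies
#'
#' The target SNP set of an attack together with the publicly known
#' population carrier frequency of each SNP. Stored as a tibble with columns
#' `snp_id` and `af` so it pipes naturally through dplyr; the row order *is*
#' the panel order and every aligned object (responses, correlation matrices,
#' reconstructions) follows it.
#'
#' @param snp_ids character vector of unique SNP ids.
#' @param pop_af numeric vector in `[0, 1]`, same length as `snp_ids`.
#' @return A tibble of class `snp_panel` with columns `snp_id`, `af`.
#' @export
#' @examples
#' snp_panel(c("rs1", "rs2"), c(0.1, 0.35))
snp_panel <- function(snp_ids, pop_af) {
  snp_ids <- as.character(snp_ids)
  pop_af <- as.numeric(pop_af)
  if (length(snp_ids) != length(pop_af)) {
    stop_validation("snp_ids and pop_af must have the same length")
  }
  if (anyDuplicated(snp_ids)) stop_validation("duplicate SNP ids in panel")
  if (anyNA(pop_af) || any(pop_af < 0 | pop_af > 1)) {
    stop_validation("allele frequencies must lie in [0, 1]")
  }
  structure(
    tibble::tibble(snp_id = snp_ids, af = pop_af),
    class = c("snp_panel", class(tibble::tibble()))
  )
}

panel_snp_ids <- function(panel) {
  if (is.data.frame(panel)) as.character(panel$snp_id) else as.character(panel)
}

panel_af <- function(panel) as.numeric(panel$af)

#' Estimate population allele frequencies from a cohort
#'
#' The per-SNP carrier fraction (column mean) of a genotype matrix, used as
#' the public frequency vector `m` when the cohort is a left-out reference
#' sample from the same population as the beacon.
#'
#' @param g a [genotype_matrix()] with at least one individual.
#' @return A [snp_panel()] over `g`'s SNPs.
#' @export
population_af <- function(g) {
  if (nrow(g) == 0L || ncol(g) == 0L) {
    stop_validation("cannot estimate frequencies from an empty cohort")
  }
  snp_panel(snp_ids(g), colMeans(unclass(g)))
}

#' Read / write a frequency table
#'
#' Plain TSV with columns `snp_id` and `af`.
#'
#' @param path file path.
#' @return `read_af_tsv()` returns a [snp_panel()]; `write_af_tsv()` returns
#'   `path` invisibly.
#' @export
read_af_tsv <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  tab <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  if (!all(c("snp_id", "af") %in% colnames(tab))) {
    stop_format("frequency TSV must have columns 'snp_id' and 'af'")
  }
  snp_panel(tab$snp_id, tab$af)
}

#' @rdname read_af_tsv
#' @param panel a [snp_panel()].
#' @export
write_af_tsv <- function(panel, path) {
  write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
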