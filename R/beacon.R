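#' A simulated genomic data-sharing beacon
#'
#' Wraps a [genotype_matrix()] behind the query interface of the beacon
#' protocol: per-SNP summary statistics only, either presence/absence
#' (`binary`) or the in-dataset carrier frequency (`af`). The number of
#' participants `N` is treated as public. A query counter is kept (the
#' protocol is authenticated and logs queries) but no budget is imposed —
#' the threat model grants the attacker unlimited queries.
#'
#' @param g a [genotype_matrix()] of the beacon participants.
#' @return An object of class `beacon`.
#' @export
#' @examples
#' b <- beacon(genotype_matrix(matrix(c(1, 0, 1, 0), 2, 2)))
#' beacon_respond(b, snp_ids(b$genotypes), mode = "af")
beacon <- function(g) {
  validate_genotype_matrix(g)
  counter <- new.env(parent = emptyenv())
  counter$queries <- 0L
  structure(list(genotypes = g, n_individuals = nrow(g), counter = counter),
            class = "beacon")
}

#' @export
print.beacon <- function(x, ...) {
  cat(sprintf("<beacon> %d participants, %d SNPs, %d queries served\n",
              x$n_individuals, ncol(x$genotypes), query_count(x)))
  invisible(x)
}

#' @rdname beacon
#' @param b a `beacon`.
#' @export
query_count <- function(b) b$counter$queries

#' Query a beacon over a SNP panel
#'
#' In `af` mode the response for SNP `j` is `(number of carriers) / N`,
#' computed as an integer count then divided so `value * N` is always an
#' exact carrier count; in `binary` mode it is 1 iff at least one
#' participant carries the allele. Unknown SNP ids raise an error (a live
#' beacon would answer "no"; the simulator is strict to surface harness
#' bugs). The beacon's query counter advances by the panel size.
#'
#' @param b a [beacon()].
#' @param panel a [snp_panel()] or character vector of SNP ids.
#' @param mode `"af"` or `"binary"`.
#' @return An object of class `beacon_response`: list with `snp_ids`,
#'   `mode`, `values`, `n_carriers` (exact integer counts) and
#'   `n_individuals`.
#' @export
beacon_respond <- function(b, panel, mode = c("af", "binary")) {
  mode <- match.arg(mode)
  ids <- panel_snp_ids(panel)
  unknown <- setdiff(ids, snp_ids(b$genotypes))
  if (length(unknown)) {
    stop_validation(sprintf("beacon does not index SNP(s): %s",
                            paste(unknown, collapse = ", ")))
  }
  counts <- as.integer(colSums(unclass(b$genotypes)[, ids, drop = FALSE]))
  b$counter$queries <- b$counter$queries + length(ids)
  values <- if (mode == "af") counts / b$n_individuals else as.numeric(counts > 0L)
  new_beacon_response(ids, mode, values, counts, b$n_individuals)
}

new_beacon_response <- function(snp_ids, mode, values, n_carriers, n_individuals) {
  structure(
    list(snp_ids = as.character(snp_ids), mode = mode,
         values = as.numeric(values), n_carriers = as.integer(n_carriers),
         n_individuals = as.integer(n_individuals)),
    class = "beacon_response"
  )
}

#' @export
print.beacon_response <- function(x, ...) {
  cat(sprintf("<beacon_response> %s mode, %d SNPs, N = %d (%d yes)\n",
              x$mode, length(x$snp_ids), x$n_individuals,
              sum(x$values > 0)))
  invisible(x)
}

#' @rdname generics-tidiers
#' @export
tidy.beacon_response <- function(x, ...) {
  tibble::tibble(snp_id = x$snp_ids, value = x$values, mode = x$mode)
}

#' Save / load a beacon snapshot
#'
#' The attacker's full capture of a beacon's responses over the target SNP
#' set, as JSON: `{mode, n_individuals, responses: [{snp_id, value}, ...]}`.
#' `read_snapshot(write_snapshot(x))` is the identity.
#'
#' @param response a `beacon_response`.
#' @param path JSON file path.
#' @return `write_snapshot()` returns `path` invisibly; `read_snapshot()`
#'   returns a `beacon_response`.
#' @export
write_snapshot <- function(response, path) {
  stopifnot(inherits(response, "beacon_response"))
  obj <- list(
    mode = response$mode,
    n_individuals = response$n_individuals,
    responses = data.frame(snp_id = response$snp_ids, value = response$values)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("mode", "n_individuals", "responses") %in% names(obj))) {
    stop_format("snapshot JSON missing required fields")
  }
  values <- as.numeric(obj$responses$value)
  counts <- as.integer(round(values * obj$n_individuals))
  if (obj$mode == "binary") counts <- rep(NA_integer_, length(values))
  new_beacon_response(obj$responses$snp_id, obj$mode, values, counts,
                      obj$n_individuals)
}
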