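#' Haplotype-block population model
#'
#' Synthetic populations are generated as a mosaic of linkage-disequilibrium
#' blocks: within a block every individual carries one of a small pool of
#' haplotypes, so SNPs inside a block are strongly co-carried, while blocks
#' are sampled independently so cross-block correlation is weak. This
#' reproduces the one statistical feature the reconstruction attack exploits
#' — pairwise co-carriage structure — without simulating recombination or
#' demography. Typical human haploblocks span roughly 10-50 SNPs, hence the
#' default block size of 10.
#'
#' @param n_snps total number of SNPs.
#' @param block_size SNPs per LD block (last block may be shorter).
#' @param haplotypes_per_block size of the haplotype pool per block (>= 2).
#' @param haplotype_weight_concentration symmetric Dirichlet concentration
#'   for the haplotype frequencies within each block; 1 = uniform simplex.
#' @param maf_range length-2 numeric, the band from which each SNP's target
#'   carrier frequency is drawn uniformly.
#' @param mutation_rate per-entry flip probability in `[0, 0.5)`; the knob
#'   that degrades LD — at 0.5 all block structure is gone.
#' @param seed RNG seed making generation deterministic.
#' @return A list of class `population_model`.
#' @export
#' @examples
#' m <- population_model(n_snps = 40, block_size = 10, seed = 7)
#' g <- generate_population(m, 30)
population_model <- function(n_snps = 1000, block_size = 10,
                             haplotypes_per_block = 4,
                             haplotype_weight_concentration = 1,
                             maf_range = c(0.05, 0.5),
                             mutation_rate = 0.01, seed = 1) {
  if (!is_scalar_number(n_snps) || n_snps < 1) stop_config("n_snps must be >= 1")
  if (!is_scalar_number(block_size) || block_size < 1) stop_config("block_size must be >= 1")
  if (!is_scalar_number(haplotypes_per_block) || haplotypes_per_block < 2) {
    stop_config("haplotypes_per_block must be >= 2")
  }
  if (!is_scalar_number(haplotype_weight_concentration) ||
      haplotype_weight_concentration <= 0) {
    stop_config("haplotype_weight_concentration must be > 0")
  }
  if (length(maf_range) != 2L || maf_range[1] >= maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] >= 1) {
    stop_config("maf_range must be (low, high) with 0 < low < high < 1")
  }
  if (!is_scalar_number(mutation_rate) || mutation_rate < 0 || mutation_rate >= 0.5) {
    stop_config("mutation_rate must lie in [0, 0.5)")
  }
  structure(
    list(n_snps = as.integer(n_snps), block_size = as.integer(block_size),
         haplotypes_per_block = as.integer(haplotypes_per_block),
         haplotype_weight_concentration = haplotype_weight_concentration,
         maf_range = as.numeric(maf_range), mutation_rate = mutation_rate,
         seed = as.integer(seed)),
    class = "population_model"
  )
}

#' @rdname population_model
#' @param path YAML file whose keys map 1:1 to `population_model()` arguments.
#' @export
read_population_model <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  do.call(population_model, yaml::read_yaml(path))
}

block_index <- function(model) {
  blocks <- ceiling(seq_len(model$n_snps) / model$block_size)
  split(seq_len(model$n_snps), blocks)
}

#' Generate a synthetic population
#'
#' For every block, a pool of `haplotypes_per_block` binary haplotypes is
#' drawn (entry `j` Bernoulli with a per-SNP probability uniform in
#' `maf_range`), haplotype frequencies are drawn from a symmetric Dirichlet,
#' each individual independently samples one haplotype per block, and
#' finally every entry flips with probability `mutation_rate`.
#'
#' @param model a [population_model()].
#' @param n_individuals number of rows to generate (>= 1).
#' @return A [genotype_matrix()] of size `n_individuals x n_snps`,
#'   deterministic given `model$seed`.
#' @export
generate_population <- function(model, n_individuals) {
  stopifnot(inherits(model, "population_model"))
  if (!is_scalar_number(n_individuals) || n_individuals < 1) {
    stop_config("n_individuals must be >= 1")
  }
  n <- as.integer(n_individuals)
  local_seed(model$seed, {
    data <- matrix(0L, n, model$n_snps)
    for (cols in block_index(model)) {
      bs <- length(cols)
      h <- model$haplotypes_per_block
      p_snp <- runif(bs, model$maf_range[1], model$maf_range[2])
      haplos <- matrix(rbinom(h * bs, 1L, rep(p_snp, each = h)), nrow = h)
      w <- rgamma(h, shape = model$haplotype_weight_concentration)
      w <- w / sum(w)
      pick <- sample.int(h, n, replace = TRUE, prob = w)
      data[, cols] <- haplos[pick, , drop = FALSE]
    }
    if (model$mutation_rate > 0) {
      flips <- matrix(rbinom(length(data), 1L, model$mutation_rate),
                      nrow = n)
      data <- abs(data - flips)
    }
    genotype_matrix(data)
  })
}

#' Split a population into disjoint cohorts
#'
#' Samples disjoint row subsets without replacement — the device used to
#' carve member, correlation-reference, frequency-reference and control
#' cohorts out of one super-population, mirroring a left-out-sample design.
#'
#' @param g a [genotype_matrix()].
#' @param sizes integer vector of cohort sizes, `sum(sizes) <= nrow(g)`.
#' @param seed RNG seed.
#' @return A list of [genotype_matrix()] cohorts with disjoint individuals.
#' @export
split_cohorts <- function(g, sizes, seed = 1) {
  sizes <- as.integer(sizes)
  if (any(sizes < 0)) stop_config("cohort sizes must be non-negative")
  if (sum(sizes) > nrow(g)) {
    stop_config(sprintf("cohort sizes sum to %d but population has %d individuals",
                        sum(sizes), nrow(g)))
  }
  local_seed(seed, {
    perm <- sample.int(nrow(g), sum(sizes))
    ends <- cumsum(sizes)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    lapply(seq_along(sizes), function(k) {
      rows <- perm[seq.int(starts[k], length.out = sizes[k])]
      genotype_matrix(unclass(g)[rows, , drop = FALSE],
                      individual_ids = rownames(g)[rows],
                      snp_ids = colnames(g))
    })
  })
}
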