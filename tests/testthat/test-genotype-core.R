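test_that("genotype matrices validate shape, binariness and id uniqueness", {
  g <- genotype_matrix(matrix(0L, 2, 3))
  expect_s3_class(g, "genotype_matrix")
  expect_identical(dim(g), c(2L, 3L))
  expect_true(all(g == 0L))

  expect_error(genotype_matrix(matrix(c(0, 2, 1, 0), 2, 2),
                               individual_ids = c("ind1", "a"),
                               snp_ids = c("rs3", "rs4")),
               "a.*rs3")
  expect_error(genotype_matrix(matrix(0L, 2, 2),
                               individual_ids = c("a", "a"),
                               snp_ids = c("s1", "s2")),
               "duplicate individual")
  expect_error(genotype_matrix(matrix(0L, 2, 2),
                               individual_ids = c("a", "b"),
                               snp_ids = c("s", "s")),
               "duplicate SNP")
})

test_that("TSV write/read round-trips exactly and flags bad cells", {
  for (seed in 1:3) {
    g <- rand_geno(4, 6, seed = seed)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_genotype_tsv(g, path)
    g2 <- read_genotype_tsv(path)
    expect_identical(unclass(g2), unclass(g))
    expect_identical(snp_ids(g2), snp_ids(g))
    expect_identical(individual_ids(g2), individual_ids(g))
  }

  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("individual_id\trs1\trs2\trs3",
               "ind0\t0\t1\t0",
               "ind1\t0\t0\t2"), path)
  expect_error(read_genotype_tsv(path), "ind1.*rs3|rs3.*ind1")
  expect_error(read_genotype_tsv(file.path(tempdir(), "nope.tsv")),
               class = "becn_error_io")
})

test_that("VCF genotypes collapse to carrier status with missing as 0", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT",
          "0|0", "./.", "0/0", sep = "\t"),
    paste("1", "300", ".", "G", "A,C", ".", "PASS", ".", "GT",
          "0/2", "0/0", "1|0", sep = "\t"),
    paste("1", "400", "rs4", "T", "C", ".", "PASS", ".", "GT",
          "1/1", "0/0", "./.", sep = "\t")
  ), path)
  expect_message(g <- read_genotype_vcf(path), "2 missing")
  # hand-enumerated carrier truth: rows s1..s3, multi-allelic 0/2 is carrier
  truth <- matrix(c(0L, 1L, 1L,   # rs1
                    0L, 0L, 0L,   # rs2 (missing -> 0)
                    1L, 0L, 1L,   # 1:300
                    1L, 0L, 0L),  # rs4 (missing -> 0)
                  nrow = 3)
  expect_identical(unname(unclass(g)), truth)
  expect_identical(individual_ids(g), c("s1", "s2", "s3"))
  expect_identical(snp_ids(g), c("rs1", "rs2", "1:300", "rs4"))

  # VCF-derived matrices round-trip through the TSV format
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_tsv(g, tsv)
  expect_identical(unclass(read_genotype_tsv(tsv)), unclass(g))
})

test_that("align_to_panel permutes/subsets columns and preserves row content", {
  g <- rand_geno(5, 8, seed = 2)
  self <- snp_panel(snp_ids(g), rep(0, 8))
  expect_identical(unclass(align_to_panel(g, self)), unclass(g))

  rev_panel <- snp_panel(rev(snp_ids(g)), rep(0, 8))
  flipped <- align_to_panel(g, rev_panel)
  expect_identical(unclass(flipped), unclass(g)[, 8:1])
  expect_identical(rowSums(unclass(flipped)), rowSums(unclass(g)))

  sub <- snp_panel(snp_ids(g)[c(3, 1)], c(0, 0))
  expect_identical(snp_ids(align_to_panel(g, sub)), snp_ids(g)[c(3, 1)])

  expect_error(align_to_panel(g, snp_panel("rsX", 0)), "rsX")
})

test_that("snp_panel and population_af validate and compute column means", {
  expect_error(snp_panel(c("a", "a"), c(0.1, 0.2)), "duplicate")
  expect_error(snp_panel("a", 1.5), "\\[0, 1\\]")

  g <- genotype_matrix(cbind(c(1L, 1L, 1L, 1L), c(1L, 0L, 1L, 0L)),
                       snp_ids = c("s1", "s2"))
  p <- population_af(g)
  expect_equal(p$af, c(1, 0.5))

  # brute-force per-column count oracle on a random fixture
  g2 <- rand_geno(7, 5, seed = 9)
  oracle <- vapply(seq_len(5), function(j) sum(unclass(g2)[, j]) / 7,
                   numeric(1))
  expect_equal(population_af(g2)$af, oracle)
})
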