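test_that("read_vcf maps GT fields to dosages and preserves metadata", {
  path <- write_tiny_vcf(withr::local_tempfile(fileext = ".vcf"))
  gm <- read_vcf(path)

  expect_s3_class(gm, "genotype_matrix")
  expect_equal(gm$samples, c("sampleA", "sampleB", "sampleC"))
  expect_equal(n_sites(gm), 3)
  # 0/0 0/1 ./. -> 0, 1, NA
  expect_equal(unname(gm$dosages[1, ]), c(0L, 1L, NA))
  # 1/1 1|0 0/0 -> 2, 1, 0 (phase ignored)
  expect_equal(unname(gm$dosages[2, ]), c(2L, 1L, 0L))
  # multiallelic 1/2 retained with both alts, dosage = alt-allele count
  expect_equal(unname(gm$dosages[3, ]), c(2L, 0L, 1L))
  expect_equal(gm$alt[[3]], c("A", "G"))
  expect_equal(gm$qual, c(50, 45, 20))
  expect_equal(gm$chrom_lengths, c(chr1 = 5000))
})

test_that("read_vcf honours sample subsets and rejects unknown samples", {
  path <- write_tiny_vcf(withr::local_tempfile(fileext = ".vcf"))
  gm <- read_vcf(path, sample_subset = c("sampleC", "sampleA"))
  expect_equal(gm$samples, c("sampleC", "sampleA"))
  expect_equal(unname(gm$dosages[1, ]), c(NA, 0L))
  expect_error(read_vcf(path, sample_subset = "nope"), "not in VCF")
})

test_that("VCF with no records yields an empty matrix without error", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=5000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", sep = "\t")), path)
  gm <- read_vcf(path)
  expect_equal(n_sites(gm), 0)
  expect_equal(gm$samples, "s1")
})

test_that("non-diploid genotypes are rejected naming sample and site", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=5000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", sep = "\t"),
    paste("chr1", "10", ".", "A", "T", "50", ".", ".", "GT",
          "0/0", "0/1/1", sep = "\t")), path)
  expect_error(read_vcf(path), "non-diploid.*s2.*chr1:10")
})

test_that("simulator VCF round-trips to the identical dosage matrix", {
  sim <- fix_single_deme()
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim$gm, path)
  back <- read_vcf(path)
  expect_equal(back$samples, sim$gm$samples)
  expect_equal(back$pos, sim$gm$pos)
  expect_equal(back$chrom, sim$gm$chrom)
  expect_equal(unname(back$dosages), unname(sim$gm$dosages))
  expect_equal(back$qual, sim$gm$qual)
  expect_equal(back$chrom_lengths, sim$gm$chrom_lengths)
  expect_equal(vapply(back$alt, paste, "", collapse = ","),
               vapply(sim$gm$alt, paste, "", collapse = ","))
})

test_that("population map IO round-trips and validates labels", {
  pm <- pop_map(c(a = "wild", b = "wild", c = "cultivar"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pop_map(pm, path)
  back <- read_pop_map(path)
  expect_equal(back$assignment, pm$assignment)
  expect_equal(back$groups, c("wild", "cultivar"))
  expect_error(group_samples(pm, "landrace"), "unknown group")
  expect_error(pop_map(c("wild", "wild")), "named")
})

test_that("group_allele_freq matches brute-force allele counting", {
  # spec arithmetic cases
  gm <- random_dosage_matrix(1, 3)
  gm$dosages[1, ] <- c(0L, 1L, 2L)
  pm <- pop_map(setNames(rep("g", 3), gm$samples))
  af <- group_allele_freq(gm, pm, "g")
  expect_equal(af$freq, 0.5)
  expect_equal(af$n, 6)

  gm2 <- random_dosage_matrix(1, 2)
  gm2$dosages[1, ] <- c(2L, NA)
  pm2 <- pop_map(setNames(rep("g", 2), gm2$samples))
  af2 <- group_allele_freq(gm2, pm2, "g")
  expect_equal(af2$freq, 1)
  expect_equal(af2$n, 2)

  # brute-force oracle on random matrices with missingness
  set.seed(11)
  for (rep in 1:10) {
    gm3 <- random_dosage_matrix(20, 6, miss = 0.2)
    pm3 <- pop_map(setNames(rep("g", 6), gm3$samples))
    af3 <- group_allele_freq(gm3, pm3, "g")
    for (s in seq_len(20)) {
      al <- dosage_to_alleles(gm3$dosages[s, ])
      if (length(al) == 0) {
        expect_true(is.na(af3$freq[s]))
      } else {
        expect_equal(af3$freq[s], mean(al))
        expect_equal(af3$n[s], length(al))
      }
    }
    ok <- !is.na(af3$freq)
    expect_true(all(af3$freq[ok] >= 0 & af3$freq[ok] <= 1))
  }
})

test_that("genotype_matrix enforces its invariants", {
  expect_error(
    genotype_matrix(samples = "s1", chrom = c("chr1", "chr1"),
                    pos = c(5L, 5L), ref = c("A", "A"),
                    alt = list("T", "T"), qual = c(1, 1),
                    dosages = matrix(0L, 2, 1),
                    chrom_lengths = c(chr1 = 10)),
    "duplicate")
  expect_error(
    genotype_matrix(samples = "s1", chrom = "chr2", pos = 1L, ref = "A",
                    alt = list("T"), qual = 1,
                    dosages = matrix(0L, 1, 1),
                    chrom_lengths = c(chr1 = 10)),
    "absent from chrom_lengths")
  expect_error(
    genotype_matrix(samples = "s1", chrom = "chr1", pos = 1L, ref = "A",
                    alt = list("T"), qual = 1,
                    dosages = matrix(5L, 1, 1),
                    chrom_lengths = c(chr1 = 10)),
    "dosages outside")
})
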