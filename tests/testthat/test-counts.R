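test_that("frequency-only tables reconstruct counts with default_n", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("rsid\tfreq", "rs1\t0.25"), tf)
  ct <- read_frequency_table(tf, "KOR", default_n = 400)
  expect_equal(ct$eac, 100L)
  expect_equal(ct$tac, 400L)
  expect_match(ct$flags, "counts_reconstructed")

  writeLines(c("rsid\tfreq\tan", "rs1\t0.25\t200"), tf)
  ct <- read_frequency_table(tf, "KOR", default_n = 400)
  expect_equal(ct$eac, 50L)
  expect_equal(ct$tac, 200L)
  expect_equal(ct$flags, "")

  writeLines(c("rsid\tfreq", "rs1\t1.3"), tf)
  expect_error(read_frequency_table(tf, "KOR", default_n = 400),
               "outside \\[0, 1\\]")
})

test_that("VCF counting follows GT fields, missingness and allele flips", {
  map <- tibble::tibble(sample = c("S1", "S2"), population = "POP1")
  model <- make_model(c(1.2, 1.2, 1.2, 1.2),
                      rsid = paste0("rs", 1:4),
                      allele = c("G", "G", "A", "T"),
                      chrom = rep("1", 4), pos = c(100L, 200L, 300L, 400L))
  vcf <- write_vcf_fixture(c("S1", "S2"), c(
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/1",   # ALT effect: 3/4
    "1\t200\trs2\tA\tG\t.\tPASS\t.\tGT\t0/1\t./.",   # missing excluded: 1/2
    "1\t300\trs3\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1",   # REF effect: 3/4
    "1\t400\trs4\tA\tG\t.\tPASS\t.\tGT\t1/1\t1/1"))  # effect T absent: 0/4
  ct <- read_vcf_counts(vcf, map, model)
  get <- function(id) unlist(ct[ct$rsid == id, c("eac", "tac")])
  expect_equal(get("rs1"), c(eac = 3L, tac = 4L))
  expect_equal(get("rs2"), c(eac = 1L, tac = 2L))
  expect_equal(get("rs3"), c(eac = 3L, tac = 4L))
  expect_equal(get("rs4"), c(eac = 0L, tac = 4L))
  expect_match(ct$flags[ct$rsid == "rs4"], "effect_allele_not_in_ref_alt")
})

test_that("VCF counting trusts ploidy, flags ambiguity, reports missing SNPs", {
  map <- tibble::tibble(sample = c("S1", "S2", "S3"),
                        population = c("POP1", "POP1", "POP2"))
  model <- make_model(c(1, 1), rsid = c("rs1", "rs9"),
                      allele = c("T", "C"), chrom = c("X", "1"),
                      pos = c(100L, 900L))
  vcf <- write_vcf_fixture(c("S1", "S2", "S3"),
    "X\t100\trs1\tA\tT\t.\tPASS\t.\tGT\t1\t0/1\t1")  # male X: haploid calls
  ct <- read_vcf_counts(vcf, map, model)
  expect_equal(unlist(ct[ct$population == "POP1", c("eac", "tac")]),
               c(eac = 2L, tac = 3L))
  expect_equal(unlist(ct[ct$population == "POP2", c("eac", "tac")]),
               c(eac = 1L, tac = 1L))
  expect_match(ct$flags[1], "strand_ambiguous")  # A/T site
  expect_equal(attr(ct, "missing_rsids"), "rs9")
  # totals can never exceed 2 haplotypes per mapped diploid sample
  expect_true(all(ct$tac <= 2 * c(2, 1)))
})

test_that("unmapped VCF samples are dropped with a warning or rejected", {
  map <- tibble::tibble(sample = "S1", population = "POP1")
  model <- make_model(1, allele = "G", chrom = "1", pos = 100L)
  vcf <- write_vcf_fixture(c("S1", "S2"),
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/1")
  expect_warning(ct <- read_vcf_counts(vcf, map, model), "dropped")
  expect_equal(ct$tac, 2L)  # only S1 counted
  expect_error(read_vcf_counts(vcf, map, model, unmapped = "error"),
               "absent from sample map")
})

test_that("frequencies distinguish missing SNPs from zero totals", {
  ct <- make_counts(c("P1", "P1", "P2"), c("rs1", "rs2", "rs1"),
                    c(3L, 0L, 0L), c(4L, 200L, 0L))
  expect_equal(effect_allele_frequency(ct, "rs1", "P1"), 0.75)
  expect_equal(effect_allele_frequency(ct, "rs2", "P1"), 0)
  expect_error(effect_allele_frequency(ct, "rs3", "P1"), "missing")
  expect_error(effect_allele_frequency(ct, "rs1", "P2"), "zero called")
  expect_error(effect_allele_frequency(ct, "rs1"), "several populations")
})

test_that("an EAS-like fixated SNP reports frequency exactly 1", {
  ct <- make_counts("EASLIKE", "rs5919393", 1008L, 1008L)
  expect_equal(effect_allele_frequency(ct, "rs5919393", "EASLIKE"), 1.0)
})

test_that("pooling sums counts and behaves like a commutative monoid", {
  ct <- make_counts(c("P1", "P2", "P2"), c("rs1", "rs1", "rs2"),
                    c(3L, 5L, 2L), c(4L, 16L, 10L))
  pooled <- pool_counts(ct)
  expect_equal(pooled$eac[pooled$rsid == "rs1"], 8L)
  expect_equal(pooled$tac[pooled$rsid == "rs1"], 20L)
  # SNP missing from P1 contributes 0/0
  expect_equal(pooled$tac[pooled$rsid == "rs2"], 10L)
  # single population pooled is unchanged
  p1 <- pool_counts(ct, "P1", code = "P1")
  expect_equal(as.data.frame(p1[, c("rsid", "eac", "tac")]),
               as.data.frame(ct[ct$population == "P1",
                                c("rsid", "eac", "tac")]))
  # commutativity/associativity over population subsets
  ct3 <- dplyr::bind_rows(ct, make_counts("P3", "rs1", 1L, 8L))
  ab_c <- pool_counts(dplyr::bind_rows(pool_counts(ct3, c("P1", "P2")),
                                       ct3[ct3$population == "P3", ]))
  a_bc <- pool_counts(dplyr::bind_rows(ct3[ct3$population == "P1", ],
                                       pool_counts(ct3, c("P2", "P3"))))
  expect_equal(as.data.frame(ab_c[, c("rsid", "eac", "tac")]),
               as.data.frame(a_bc[, c("rsid", "eac", "tac")]))
  # pooled frequency = count-weighted mean of member frequencies
  w <- c(4, 16)
  f <- c(3 / 4, 5 / 16)
  expect_equal(effect_allele_frequency(pooled, "rs1", "ALL"),
               sum(w * f) / sum(w))
})

test_that("count tables validate their invariants", {
  expect_error(pop_counts(tibble::tibble(population = "P", rsid = "rs1",
                                         eac = 5L, tac = 4L)),
               "0 <= eac <= tac")
  expect_error(pop_counts(tibble::tibble(population = "P", rsid = "rs1",
                                         eac = 1L)),
               "missing column")
})
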