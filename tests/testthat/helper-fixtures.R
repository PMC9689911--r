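# Shared fixtures and independent oracles.

# Brute-force two-sided Fisher p: enumerate every table with the observed
# margins via explicit binomial coefficients (lchoose), sum the probabilities
# of tables no more probable than the observed one. Kept deliberately
# independent of the package's dhyper/log-sum-exp path.
naive_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  k <- a + c
  xs <- max(0, k - r2):min(r1, k)
  pr <- exp(lchoose(r1, xs) + lchoose(r2, k - xs) - lchoose(r1 + r2, k))
  sum(pr[pr <= pr[xs == a] * (1 + 1e-7)])
}

make_model <- function(beta,
                       rsid = paste0("rs", seq_along(beta)),
                       allele = rep("A", length(beta)),
                       chrom = rep("1", length(beta)),
                       pos = rep(NA_integer_, length(beta))) {
  m <- tibble::tibble(rsid = rsid, chrom = chrom, pos = as.integer(pos),
                      effect_allele = allele, beta_i = beta,
                      n_studies = 1L, flags = "")
  class(m) <- c("risk_model", class(m))
  m
}

make_counts <- function(population, rsid, eac, tac) {
  pop_counts(tibble::tibble(population = population, rsid = rsid,
                            eac = eac, tac = tac))
}

make_assoc <- function(rsid, effect_size, kind = "odds_ratio",
                       allele = "A", accession = "GCST1") {
  a <- tibble::tibble(rsid = rsid, chrom = NA_character_, pos = NA_integer_,
                      effect_allele = allele, effect_size_kind = kind,
                      effect_size = effect_size, study_accession = accession,
                      trait = "Prostate carcinoma")
  class(a) <- c("snp_associations", class(a))
  a
}

catalog_header <- paste("SNPS", "STRONGEST SNP-RISK ALLELE", "OR or BETA",
                        "MAPPED_TRAIT", "STUDY ACCESSION", sep = "\t")

write_catalog_fixture <- function(rows, header = catalog_header,
                                  path = tempfile(fileext = ".tsv")) {
  writeLines(c(header, rows), path)
  path
}

write_vcf_fixture <- function(samples, rows,
                              path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    rows), path)
  path
}

# a minimal enrichment_matrix object for filter/order tests
make_em <- function(scores) {
  structure(list(scores = scores, p = 10^(-abs(scores)),
                 rsids = rownames(scores), populations = colnames(scores),
                 meta = list()),
            class = "enrichment_matrix")
}
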