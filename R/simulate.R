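#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. All generators are
#' pure functions of (config, seed): the same config yields byte-identical
#' outputs. The default population preset is "1000GP-like": five
#' superpopulation codes with unequal sample sizes matching the phase-3
#' panel and divergence parameters F chosen to resemble continental FST
#' (illustrative, clearly synthetic — real risk-SNP frequency differences
#' also reflect discovery-cohort ascertainment, which a symmetric
#' Balding-Nichols draw does not produce).
#'
#' Epidemiology is generated as a linear function of the true expected PRS
#' plus Gaussian noise, on the scale of age-adjusted rates per 100,000:
#' around a typical expected PRS of 0.5 the defaults center incidence near
#' 100 and mortality near 30 per 100,000, with hormone (DHT:T) and vitamin-D
#' covariates coupled to the PRS more weakly (and vitamin D negatively).
#'
#' @param n_snps Number of risk SNPs.
#' @param populations Tibble with columns `code`, `fst` (in (0,1)) and
#'   `n_samples` per population.
#' @param or_log_sd SD of log odds ratios: `OR = exp(N(0, or_log_sd))`.
#' @param dup_fraction Fraction of SNPs that receive a duplicate catalog row
#'   (a second study of the same SNP).
#' @param beta_fraction Fraction of catalog rows reported on the beta (log)
#'   scale instead of as an OR.
#' @param epi_intercept,epi_slope,epi_noise_sd Incidence model:
#'   `intercept + slope * E[PRS] + N(0, sd)`, floored at 0.
#' @param mort_intercept,mort_slope,mort_noise_sd Mortality model, same form.
#' @param dht_slope,dht_noise_sd,vitd_slope,vitd_noise_sd Covariate
#'   couplings around baselines 0.07 (DHT:T) and 70 nmol/L (vitamin D).
#' @param seed Integer seed; every generator derives its stream from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 200,
                       populations = tibble::tibble(
                         code = c("AFR", "AMR", "EAS", "EUR", "SAS"),
                         fst = c(0.15, 0.11, 0.10, 0.08, 0.09),
                         n_samples = c(661L, 347L, 504L, 503L, 489L)),
                       or_log_sd = 0.1,
                       dup_fraction = 0.05,
                       beta_fraction = 0.05,
                       epi_intercept = -650, epi_slope = 1500,
                       epi_noise_sd = 2,
                       mort_intercept = -170, mort_slope = 400,
                       mort_noise_sd = 1,
                       dht_slope = 0.4, dht_noise_sd = 0.01,
                       vitd_slope = -60, vitd_noise_sd = 4,
                       seed = 1) {
  stopifnot(is_count(n_snps), n_snps >= 1,
            all(c("code", "fst", "n_samples") %in% names(populations)),
            all(populations$fst > 0 & populations$fst < 1),
            all(populations$n_samples >= 1),
            or_log_sd >= 0, epi_noise_sd >= 0, mort_noise_sd >= 0,
            dup_fraction >= 0, beta_fraction >= 0,
            is.numeric(seed), length(seed) == 1)
  structure(list(n_snps = as.integer(n_snps), populations = populations,
                 or_log_sd = or_log_sd, dup_fraction = dup_fraction,
                 beta_fraction = beta_fraction,
                 epi_intercept = epi_intercept, epi_slope = epi_slope,
                 epi_noise_sd = epi_noise_sd,
                 mort_intercept = mort_intercept, mort_slope = mort_slope,
                 mort_noise_sd = mort_noise_sd,
                 dht_slope = dht_slope, dht_noise_sd = dht_noise_sd,
                 vitd_slope = vitd_slope, vitd_noise_sd = vitd_noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

sim_rsids <- function(n) paste0("rs", 1000000 + seq_len(n))

#' Simulate a GWAS-catalog-style association file
#'
#' Generates `n_snps` base rows (rsIDs rs1000001...) with random effect
#' alleles and odds ratios `exp(N(0, or_log_sd))`, plus a configurable
#' fraction of duplicate-rsID rows (second studies) and beta-scale rows, to
#' exercise harmonization. The file carries NHGRI-EBI-style headers plus an
#' `EFFECT_KIND` column labelling each row's effect scale.
#'
#' @param cfg A [sim_config()].
#' @param path Optional output TSV path; written when given.
#' @return The association tibble (invisibly when `path` given); attribute
#'   `truth` holds the per-SNP ground truth (rsid, effect allele, all ORs).
#' @export
simulate_catalog <- function(cfg, path = NULL) {
  tab <- withr::with_seed(cfg$seed, {
    n <- cfg$n_snps
    rsid <- sim_rsids(n)
    allele <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    or <- exp(rnorm(n, 0, cfg$or_log_sd))
    chrom <- as.character(sample(1:22, n, replace = TRUE))
    pos <- 10000L + seq_len(n) * 100L
    base <- tibble::tibble(
      SNPS = rsid,
      `STRONGEST SNP-RISK ALLELE` = paste0(rsid, "-", allele),
      `OR or BETA` = or,
      EFFECT_KIND = "OR",
      MAPPED_TRAIT = "Prostate carcinoma",
      `STUDY ACCESSION` = sprintf("GCST%06d", seq_len(n)),
      CHR_ID = chrom,
      CHR_POS = pos)
    n_beta <- round(cfg$beta_fraction * n)
    if (n_beta > 0) {
      bi <- sample(n, n_beta)
      base$`OR or BETA`[bi] <- log(base$`OR or BETA`[bi])
      base$EFFECT_KIND[bi] <- "BETA"
    }
    n_dup <- round(cfg$dup_fraction * n)
    if (n_dup > 0) {
      di <- sample(n, n_dup)
      dup <- base[di, ]
      dup$`OR or BETA` <- exp(rnorm(n_dup, 0, cfg$or_log_sd))
      dup$EFFECT_KIND <- "OR"
      dup$`STUDY ACCESSION` <- sprintf("GCST9%05d", seq_len(n_dup))
      base <- dplyr::bind_rows(base, dup)
    }
    attr(base, "truth") <- tibble::tibble(rsid = rsid, effect_allele = allele)
    base
  })
  if (!is.null(path)) {
    readr::write_tsv(tab, path, progress = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Simulate diverged population allele frequencies (Balding-Nichols)
#'
#' Each SNP gets an ancestral effect-allele frequency `p ~ Uniform(0.05,
#' 0.95)`; each population draws its frequency from
#' `Beta(p (1 - F) / F, (1 - p) (1 - F) / F)` with its own divergence
#' parameter F, so that `Var(f) = F p (1 - p)` — the standard minimal model
#' of FST-controlled drift.
#'
#' @param cfg A [sim_config()].
#' @param rsids SNP identifiers; defaults to the ids [simulate_catalog()]
#'   uses for the same config.
#' @param dir Optional directory: per-population frequency TSVs
#'   (`freq_<POP>.tsv` with columns rsid, freq, an) and the ancestral truth
#'   (`ancestral.tsv`) are written there.
#' @return List with `freqs` (long tibble: population, rsid, freq, an) and
#'   `ancestral` (tibble: rsid, freq).
#' @export
simulate_frequencies <- function(cfg, rsids = NULL, dir = NULL) {
  rsids <- rsids %||% sim_rsids(cfg$n_snps)
  n <- length(rsids)
  res <- withr::with_seed(cfg$seed + 1L, {
    p <- runif(n, 0.05, 0.95)
    freqs <- lapply(seq_len(nrow(cfg$populations)), function(j) {
      f_st <- cfg$populations$fst[j]
      shape1 <- p * (1 - f_st) / f_st
      shape2 <- (1 - p) * (1 - f_st) / f_st
      tibble::tibble(population = cfg$populations$code[j],
                     rsid = rsids,
                     freq = rbeta(n, shape1, shape2),
                     an = 2L * cfg$populations$n_samples[j])
    })
    list(freqs = dplyr::bind_rows(freqs),
         ancestral = tibble::tibble(rsid = rsids, freq = p))
  })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (pop in unique(res$freqs$population)) {
      readr::write_tsv(res$freqs[res$freqs$population == pop,
                                 c("rsid", "freq", "an")],
                       file.path(dir, paste0("freq_", pop, ".tsv")),
                       progress = FALSE)
    }
    readr::write_tsv(res$ancestral, file.path(dir, "ancestral.tsv"),
                     progress = FALSE)
  }
  res
}

#' Turn a simulated frequency table into allele counts
#'
#' @param freqs Long tibble with columns `population`, `rsid`, `freq`, `an`.
#' @return A `pop_counts` tibble with `eac = round(freq * an)`.
#' @export
counts_from_frequencies <- function(freqs) {
  pop_counts(tibble::tibble(
    population = freqs$population,
    rsid = freqs$rsid,
    eac = as.integer(round(freqs$freq * freqs$an)),
    tac = as.integer(freqs$an),
    flags = ""))
}

#' Simulate a diploid genotype panel and write it as VCF + sample map
#'
#' Genotype dosages are Hardy-Weinberg draws `Binomial(2, f)` from the given
#' per-population frequencies. The VCF encodes the effect allele as ALT for
#' most SNPs and as REF for a configurable fraction (exercising the
#' allele-flip path in [read_vcf_counts()]).
#'
#' @param model A `risk_model` supplying rsid, chrom, pos and effect allele.
#' @param freqs Long frequency tibble (population, rsid, freq), e.g. from
#'   [simulate_frequencies()].
#' @param n_samples Named integer vector of diploid sample counts per
#'   population (names = population codes), or one number for all.
#' @param seed Integer seed.
#' @param dir Output directory for `genotypes.vcf` and `samples.tsv`.
#' @param prop_effect_ref Fraction of SNPs whose REF is the effect allele.
#' @param missing_rate Per-genotype probability of a `./.` missing call.
#' @return List: `vcf`, `sample_map` (paths), `samples` (tibble) and
#'   `dosages` (list of per-population matrices, individuals x SNPs).
#' @export
simulate_genotypes <- function(model, freqs, n_samples, seed,
                               dir = tempfile("panel"),
                               prop_effect_ref = 0.2, missing_rate = 0) {
  stopifnot(all(freqs$freq >= 0 & freqs$freq <= 1))
  pops <- unique(freqs$population)
  if (is.null(names(n_samples))) {
    n_samples <- setNames(rep(as.integer(n_samples), length(pops))[seq_along(pops)],
                          pops)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bases <- c("A", "C", "G", "T")

  out <- withr::with_seed(seed, {
    n_snp <- nrow(model)
    eff <- model$effect_allele
    eff[is.na(eff)] <- "A"  # unknown allele: emit something countable
    other <- vapply(eff, function(e) sample(setdiff(bases, e), 1), "")
    eff_is_ref <- runif(n_snp) < prop_effect_ref
    ref <- ifelse(eff_is_ref, eff, other)
    alt <- ifelse(eff_is_ref, other, eff)
    chrom <- ifelse(is.na(model$chrom), "1", model$chrom)
    pos <- ifelse(is.na(model$pos), 10000L + seq_len(n_snp) * 100L, model$pos)

    samples <- dplyr::bind_rows(lapply(pops, function(p) {
      tibble::tibble(sample = sprintf("%s_%04d", p, seq_len(n_samples[[p]])),
                     population = p)
    }))

    dosages <- list()
    gt_cols <- list()
    gt_code <- list(alt_eff = c("0/0", "0/1", "1/1"),
                    ref_eff = c("1/1", "0/1", "0/0"))
    for (p in pops) {
      fp <- freqs[freqs$population == p, ]
      f <- fp$freq[match(model$rsid, fp$rsid)]
      if (anyNA(f)) {
        stop("population ", p, " lacks a frequency for some model SNP",
             call. = FALSE)
      }
      n <- n_samples[[p]]
      d <- matrix(rbinom(n * n_snp, 2, rep(f, each = n)), nrow = n)
      colnames(d) <- model$rsid
      dosages[[p]] <- d
      g <- matrix("", nrow = n_snp, ncol = n)
      for (i in seq_len(n_snp)) {
        codes <- if (eff_is_ref[i]) gt_code$ref_eff else gt_code$alt_eff
        g[i, ] <- codes[d[, i] + 1L]
      }
      if (missing_rate > 0) {
        drop <- matrix(runif(n_snp * n) < missing_rate, nrow = n_snp)
        g[drop] <- "./."
      }
      gt_cols[[p]] <- g
    }
    gt <- do.call(cbind, gt_cols)

    vcf_path <- file.path(dir, "genotypes.vcf")
    header <- c("##fileformat=VCFv4.2",
                "##source=prscape_simulate_genotypes",
                '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", samples$sample),
                      collapse = "\t"))
    body <- vapply(seq_len(n_snp), function(i) {
      paste(c(chrom[i], pos[i], model$rsid[i], ref[i], alt[i], ".",
              "PASS", ".", "GT", gt[i, ]), collapse = "\t")
    }, "")
    writeLines(c(header, body), vcf_path)
    map_path <- file.path(dir, "samples.tsv")
    readr::write_tsv(samples, map_path, progress = FALSE)
    list(vcf = vcf_path, sample_map = map_path, samples = samples,
         dosages = dosages)
  })
  out
}

#' Simulate a population epidemiology table from expected scores
#'
#' Incidence and mortality are linear in the expected PRS plus Gaussian
#' noise, floored at 0; the DHT:T ratio and vitamin-D covariates are coupled
#' to the PRS more weakly (vitamin D negatively), so a downstream predictor
#' comparison should rank the PRS first when the generating signal is
#' strong.
#'
#' @param pop_prs Tibble with columns `population`, `prs` (e.g. from
#'   [population_expected_prs()]).
#' @param cfg A [sim_config()].
#' @param path Optional output TSV path.
#' @return Tibble: `population`, `incidence`, `mortality`, `dht_t_ratio`,
#'   `vit_d`.
#' @export
simulate_epidemiology <- function(pop_prs, cfg, path = NULL) {
  if (nrow(pop_prs) < 3) {
    stop("need at least 3 populations", call. = FALSE)
  }
  epi <- withr::with_seed(cfg$seed + 3L, {
    n <- nrow(pop_prs)
    tibble::tibble(
      population = pop_prs$population,
      incidence = pmax(0, cfg$epi_intercept + cfg$epi_slope * pop_prs$prs +
                         rnorm(n, 0, cfg$epi_noise_sd)),
      mortality = pmax(0, cfg$mort_intercept + cfg$mort_slope * pop_prs$prs +
                         rnorm(n, 0, cfg$mort_noise_sd)),
      dht_t_ratio = pmax(0.01, 0.07 + cfg$dht_slope * (pop_prs$prs - 0.5) +
                           rnorm(n, 0, cfg$dht_noise_sd)),
      vit_d = pmax(1, 70 + cfg$vitd_slope * (pop_prs$prs - 0.5) +
                     rnorm(n, 0, cfg$vitd_noise_sd)))
  })
  if (!is.null(path)) readr::write_tsv(epi, path, progress = FALSE)
  epi
}

#' Generate a complete synthetic study in one call
#'
#' Writes every input the pipeline consumes — catalog TSV, per-population
#' frequency TSVs, a genotype VCF with sample map, an epidemiology TSV —
#' plus `truth.json` recording the generating parameters.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory.
#' @param genotypes Also write the (larger) VCF panel? Default `TRUE`.
#' @return Named list of the paths written.
#' @export
simulate_study <- function(cfg, dir, genotypes = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  catalog_path <- file.path(dir, "catalog.tsv")
  simulate_catalog(cfg, path = catalog_path)

  assoc <- parse_gwas_catalog(catalog_path, kind_column = "EFFECT_KIND")
  model <- harmonize_risk_model(assoc)
  sim <- simulate_frequencies(cfg, rsids = model$rsid, dir = dir)

  paths <- list(catalog = catalog_path,
                frequencies = file.path(dir, paste0("freq_",
                                                    cfg$populations$code,
                                                    ".tsv")))
  if (genotypes) {
    panel <- simulate_genotypes(
      model, sim$freqs,
      n_samples = setNames(cfg$populations$n_samples, cfg$populations$code),
      seed = cfg$seed + 2L, dir = dir)
    paths$vcf <- panel$vcf
    paths$sample_map <- panel$sample_map
  }

  prs <- population_expected_prs(model, counts_from_frequencies(sim$freqs))
  epi_path <- file.path(dir, "epidemiology.tsv")
  simulate_epidemiology(prs, cfg, path = epi_path)
  paths$epidemiology <- epi_path

  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(config = cfg[setdiff(names(cfg), "populations")],
         populations = cfg$populations,
         expected_prs = prs),
    truth_path, auto_unbox = TRUE, digits = NA)
  paths$truth <- truth_path
  paths
}
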