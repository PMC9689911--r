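#' Construct or validate a per-population allele-count table
#'
#' The package stores allele-frequency observations as counts: for each
#' population and SNP, the number of observed effect alleles (`eac`) out of
#' the number of called haplotypes (`tac`). Keeping integer counts (rather
#' than frequencies) is what makes exact tests downstream well defined.
#'
#' @param df A data frame with columns `population`, `rsid`, `eac`, `tac`
#'   and optionally `flags`.
#' @return A tibble of class `pop_counts`.
#' @export
pop_counts <- function(df) {
  need <- c("population", "rsid", "eac", "tac")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("count table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"flags" %in% names(df)) df$flags <- ""
  df <- tibble::as_tibble(df)
  if (any(df$eac < 0 | df$tac < 0 | df$eac > df$tac)) {
    stop("invalid counts: need 0 <= eac <= tac", call. = FALSE)
  }
  if (any(df$eac != round(df$eac) | df$tac != round(df$tac))) {
    stop("allele counts must be integers", call. = FALSE)
  }
  class(df) <- unique(c("pop_counts", class(df)))
  df
}

#' Read a sample-to-population map
#'
#' @param path Two-column TSV with header `sample` and `population`.
#' @return A tibble with those columns; duplicated samples are an error.
#' @export
read_sample_map <- function(path) {
  map <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("sample", "population") %in% names(map))) {
    stop("sample map needs columns 'sample' and 'population'", call. = FALSE)
  }
  if (anyDuplicated(map$sample)) {
    stop("sample map assigns a sample to more than one population",
         call. = FALSE)
  }
  map
}

#' Count effect alleles per population from a genotype VCF
#'
#' Locates each model SNP in the VCF (by ID, falling back to chrom:pos) and,
#' for every population in the sample map, counts haplotypes carrying the
#' effect allele among called haplotypes. Missing allele calls (`.`) are
#' excluded from numerator and denominator; haploid genotypes (e.g. male X)
#' contribute one haplotype, diploid two — the VCF's ploidy encoding is
#' trusted. At multiallelic sites only the allele equal to the effect allele
#' counts as "effect"; everything else is non-effect. If the effect allele
#' matches neither REF nor any ALT (or is unknown), the SNP is counted as
#' `0/total` and flagged. Biallelic A/T and C/G sites are flagged
#' `strand_ambiguous` for the user's attention but counted normally.
#'
#' @param vcf Path to a VCF file (plain or gzipped).
#' @param sample_map A tibble from [read_sample_map()] or a path to one.
#' @param model A `risk_model`.
#' @param unmapped What to do with VCF samples absent from the map:
#'   `"drop"` (default, with a warning) or `"error"`.
#' @return A `pop_counts` tibble; attribute `missing_rsids` lists model SNPs
#'   not found in the VCF (they are simply absent from the table).
#' @export
read_vcf_counts <- function(vcf, sample_map, model,
                            unmapped = c("drop", "error")) {
  unmapped <- match.arg(unmapped)
  if (is.character(sample_map) && length(sample_map) == 1) {
    sample_map <- read_sample_map(sample_map)
  }
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- t(fx)  # single-variant VCF comes back as a vector
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  samples <- colnames(gt)

  pop_of <- sample_map$population[match(samples, sample_map$sample)]
  if (anyNA(pop_of)) {
    if (unmapped == "error") {
      stop("VCF sample(s) absent from sample map: ",
           paste(utils::head(samples[is.na(pop_of)], 5), collapse = ", "),
           call. = FALSE)
    }
    warning(sum(is.na(pop_of)),
            " VCF sample(s) absent from sample map; dropped", call. = FALSE)
    keep <- !is.na(pop_of)
    gt <- gt[, keep, drop = FALSE]
    pop_of <- pop_of[keep]
  }

  hit <- match(model$rsid, fix$ID)
  if ("pos" %in% names(model)) {
    k_fix <- paste(fix$CHROM, fix$POS)
    k_mod <- paste(model$chrom, model$pos)
    alt <- match(k_mod, k_fix)
    hit[is.na(hit)] <- alt[is.na(hit)]
  }
  pops <- sort(unique(pop_of))

  rows <- list()
  for (i in which(!is.na(hit))) {
    vi <- hit[i]
    alleles <- c(fix$REF[vi], strsplit(fix$ALT[vi], ",", fixed = TRUE)[[1]])
    eff_idx <- match(model$effect_allele[i], alleles) - 1L
    flags <- character(0)
    if (is.na(eff_idx)) {
      flags <- c(flags,
                 if (is.na(model$effect_allele[i])) "unknown_effect_allele"
                 else "effect_allele_not_in_ref_alt")
    }
    if (length(alleles) == 2 &&
        paste(sort(alleles), collapse = "") %in% c("AT", "CG")) {
      flags <- c(flags, "strand_ambiguous")
    }
    toks <- strsplit(as.character(gt[vi, ]), "[/|]")
    for (p in pops) {
      tk <- unlist(toks[pop_of == p], use.names = FALSE)
      tk <- tk[!is.na(tk) & tk != "."]
      tac <- length(tk)
      eac <- if (is.na(eff_idx)) 0L else sum(tk == as.character(eff_idx))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        population = p, rsid = model$rsid[i],
        eac = as.integer(eac), tac = as.integer(tac),
        flags = join_flags(flags))
    }
  }
  out <- pop_counts(dplyr::bind_rows(rows))
  attr(out, "missing_rsids") <- model$rsid[is.na(hit)]
  out
}

#' Read a pre-aggregated allele-frequency table as counts
#'
#' For frequency-only resources (KRGDB-style tables) the integer counts are
#' reconstructed as `round(freq * n) / n`, using the table's allele-number
#' column when present and `default_n` otherwise. Reconstructed rows carry
#' the flag `counts_reconstructed` so the approximation stays auditable.
#'
#' @param path TSV with columns `rsid`, `freq` (effect-allele frequency in
#'   \[0, 1\]) and optionally `an` (allele number).
#' @param population Population code to assign to all rows.
#' @param default_n Allele number assumed when the table has none.
#' @param rsid_column,freq_column,an_column Column names in the file.
#' @return A `pop_counts` tibble.
#' @export
read_frequency_table <- function(path, population, default_n = 1000,
                                 rsid_column = "rsid", freq_column = "freq",
                                 an_column = "an") {
  stopifnot(is_count(default_n), default_n > 0)
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  for (col in c(rsid_column, freq_column)) {
    if (!col %in% names(tab)) {
      stop("frequency table missing column: '", col, "'", call. = FALSE)
    }
  }
  freq <- as.numeric(tab[[freq_column]])
  if (any(is.na(freq) | freq < 0 | freq > 1)) {
    stop("effect-allele frequency outside [0, 1] in ", path, call. = FALSE)
  }
  an <- if (an_column %in% names(tab)) as.numeric(tab[[an_column]]) else
    rep(NA_real_, nrow(tab))
  reconstructed <- is.na(an)
  an[reconstructed] <- default_n
  pop_counts(tibble::tibble(
    population = population,
    rsid = tab[[rsid_column]],
    eac = as.integer(round(freq * an)),
    tac = as.integer(an),
    flags = ifelse(reconstructed, "counts_reconstructed", "")
  ))
}

#' Effect-allele frequency of one SNP in one population
#'
#' @param counts A `pop_counts` tibble.
#' @param rsid SNP identifier.
#' @param population Population code; may be omitted when `counts` holds a
#'   single population.
#' @return `eac / tac`, a fraction in \[0, 1\]. A SNP absent from the table
#'   and a SNP with zero called haplotypes raise distinct errors.
#' @export
effect_allele_frequency <- function(counts, rsid, population = NULL) {
  sel <- counts$rsid == rsid
  if (!is.null(population)) {
    sel <- sel & counts$population == population
  } else if (length(unique(counts$population)) > 1) {
    stop("counts hold several populations; supply `population`",
         call. = FALSE)
  }
  if (!any(sel)) {
    stop("SNP missing from count table: ", rsid, call. = FALSE)
  }
  eac <- sum(counts$eac[sel])
  tac <- sum(counts$tac[sel])
  if (tac == 0) {
    stop("zero called haplotypes for ", rsid, call. = FALSE)
  }
  eac / tac
}

#' Pool allele counts across populations
#'
#' Sums numerators and denominators per SNP over the selected populations
#' (outer union of SNPs: a population lacking a SNP contributes 0/0). Pooling
#' is associative and commutative, and the pooled frequency equals the
#' count-weighted mean of member frequencies.
#'
#' @param counts A `pop_counts` tibble.
#' @param populations Populations to pool; default all.
#' @param code Population code of the pooled result.
#' @return A single-population `pop_counts` tibble.
#' @export
pool_counts <- function(counts, populations = NULL, code = "ALL") {
  if (!is.null(populations)) {
    counts <- counts[counts$population %in% populations, ]
  }
  out <- counts |>
    dplyr::group_by(.data$rsid) |>
    dplyr::summarise(eac = sum(.data$eac), tac = sum(.data$tac),
                     .groups = "drop") |>
    dplyr::mutate(population = code, flags = "") |>
    dplyr::select("population", "rsid", "eac", "tac", "flags")
  pop_counts(out)
}

#' Write a count table to TSV
#' @param counts A `pop_counts` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(tibble::as_tibble(counts), path, progress = FALSE)
  invisible(path)
}
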