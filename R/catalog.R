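#' Parse a GWAS-catalog-style association table
#'
#' Reads a tab-separated association file whose headers follow the NHGRI-EBI
#' GWAS catalog download format and returns one tidy association per usable
#' row. Risk-allele strings of the form `"rs12345-G"` are split into an rsID
#' and an effect allele; `"?"` or any non-ACGT allele is recorded as unknown
#' (`NA`). Rows without a well-formed rsID (`rs` followed by digits) are
#' dropped and counted in the `n_dropped` attribute.
#'
#' The catalog's `OR or BETA` column does not say which scale a value is on.
#' If `kind_column` names a column whose values contain `"beta"`
#' (case-insensitively) for log-scale effects, that column decides; otherwise
#' positive values are taken as odds ratios and non-positive values as betas
#' (an OR can never be <= 0, a reported beta usually is small or negative).
#'
#' @param path Path to the tab-separated association file.
#' @param trait_filter Optional character vector of trait labels; rows whose
#'   trait matches one of them case-insensitively are kept. `NULL` keeps all.
#' @param columns Named list overriding default column names. Recognized
#'   names: `rsid`, `risk_allele`, `effect`, `trait`, `accession`, `chrom`,
#'   `pos`. Defaults match the NHGRI-EBI download headers (`SNPS`,
#'   `STRONGEST SNP-RISK ALLELE`, `OR or BETA`, `MAPPED_TRAIT`,
#'   `STUDY ACCESSION`, `CHR_ID`, `CHR_POS`).
#' @param kind_column Optional name of a column labelling each row's effect
#'   scale (values containing "beta" are treated as log-scale).
#'
#' @return A tibble of class `snp_associations` with columns `rsid`, `chrom`,
#'   `pos`, `effect_allele`, `effect_size_kind` (`"odds_ratio"`, `"beta"` or
#'   `"missing"`), `effect_size`, `study_accession`, `trait`; attribute
#'   `n_dropped` counts malformed rows.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "SNPS\tSTRONGEST SNP-RISK ALLELE\tOR or BETA\tMAPPED_TRAIT\tSTUDY ACCESSION",
#'   "rs10486567\trs10486567-G\t1.3\tProstate carcinoma\tGCST000001"), f)
#' parse_gwas_catalog(f)
parse_gwas_catalog <- function(path, trait_filter = NULL, columns = list(),
                               kind_column = NULL) {
  defaults <- list(rsid = "SNPS",
                   risk_allele = "STRONGEST SNP-RISK ALLELE",
                   effect = "OR or BETA",
                   trait = "MAPPED_TRAIT",
                   accession = "STUDY ACCESSION",
                   chrom = "CHR_ID",
                   pos = "CHR_POS")
  columns <- utils::modifyList(defaults, columns)
  if (!file.exists(path)) {
    stop("association file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, name_repair = "minimal")
  for (key in c("rsid", "risk_allele", "effect", "trait")) {
    if (!columns[[key]] %in% names(raw)) {
      stop("mandatory column missing from association file: '",
           columns[[key]], "'", call. = FALSE)
    }
  }

  ra <- raw[[columns$risk_allele]]
  has_ra <- !is.na(ra) & grepl("^rs[0-9]+-", ra)
  rsid <- ifelse(has_ra, sub("-.*$", "", ra), raw[[columns$rsid]])
  allele <- ifelse(has_ra, toupper(sub("^rs[0-9]+-", "", ra)), NA_character_)
  allele[!allele %in% c("A", "C", "G", "T")] <- NA_character_

  effect_size <- suppressWarnings(as.numeric(raw[[columns$effect]]))
  if (!is.null(kind_column)) {
    if (!kind_column %in% names(raw)) {
      stop("kind column missing from association file: '", kind_column, "'",
           call. = FALSE)
    }
    kind <- ifelse(grepl("beta", raw[[kind_column]], ignore.case = TRUE),
                   "beta", "odds_ratio")
  } else {
    kind <- ifelse(effect_size > 0, "odds_ratio", "beta")
  }
  kind[is.na(effect_size)] <- "missing"

  out <- tibble::tibble(
    rsid = rsid,
    chrom = if (columns$chrom %in% names(raw)) raw[[columns$chrom]] else NA_character_,
    pos = if (columns$pos %in% names(raw)) {
      suppressWarnings(as.integer(raw[[columns$pos]]))
    } else NA_integer_,
    effect_allele = allele,
    effect_size_kind = kind,
    effect_size = effect_size,
    study_accession = if (columns$accession %in% names(raw)) {
      raw[[columns$accession]]
    } else NA_character_,
    trait = raw[[columns$trait]]
  )

  ok <- !is.na(out$rsid) & grepl("^rs[0-9]+$", out$rsid)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message(n_dropped, " row(s) dropped: missing or malformed rsID")
  }
  out <- out[ok, ]

  if (!is.null(trait_filter)) {
    out <- out[tolower(out$trait) %in% tolower(trait_filter), ]
  }
  if (nrow(out) == 0) {
    stop("no usable associations after parsing/filtering", call. = FALSE)
  }
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("snp_associations", class(out))
  out
}

#' Harmonize associations into a deduplicated per-SNP risk model
#'
#' Groups associations by rsID and produces one entry per SNP with weight
#' `beta_i` equal to the arithmetic mean of the group's odds ratios. Effects
#' reported as betas are brought onto the OR scale by `exp(beta)` when
#' `beta_to_or = TRUE` (the default, keeping all weights on one scale) and
#' dropped otherwise. SNPs with no usable effect size receive the neutral
#' weight 1 and the flag `no_effect_size`.
#'
#' When studies disagree on the effect allele, the allele from the study with
#' the largest odds-ratio magnitude (largest `|log OR|`) is kept and the
#' entry is flagged `allele_conflict`. Entries whose effect allele is unknown
#' are retained with flag `unknown_allele` unless `strict_alleles = TRUE`,
#' in which case they are dropped.
#'
#' @param assocs A `snp_associations` tibble from [parse_gwas_catalog()].
#' @param beta_to_or Convert beta-scale effects to ORs via `exp()`? Default
#'   `TRUE`; if `FALSE`, beta-scale rows contribute no weight.
#' @param strict_alleles Drop SNPs whose effect allele is unknown? Default
#'   `FALSE` (retain and flag).
#'
#' @return A tibble of class `risk_model` with columns `rsid`, `chrom`,
#'   `pos`, `effect_allele`, `beta_i`, `n_studies`, `flags`; the number of
#'   SNPs is `nrow()`.
#' @export
harmonize_risk_model <- function(assocs, beta_to_or = TRUE,
                                 strict_alleles = FALSE) {
  if (is.null(assocs) || nrow(assocs) == 0) {
    stop("no associations to harmonize", call. = FALSE)
  }

  # OR-scale weight per row, NA when unusable
  or <- rep(NA_real_, nrow(assocs))
  is_or <- assocs$effect_size_kind == "odds_ratio"
  or[is_or] <- assocs$effect_size[is_or]
  or[is_or & !is.na(or) & or <= 0] <- NA_real_  # an OR must be positive
  if (beta_to_or) {
    is_b <- assocs$effect_size_kind == "beta"
    or[is_b] <- exp(assocs$effect_size[is_b])
  }

  rsids <- unique(assocs$rsid)  # first-appearance order
  rows <- lapply(rsids, function(id) {
    g <- which(assocs$rsid == id)
    flags <- character(0)
    usable <- or[g][!is.na(or[g])]
    if (length(usable) > 0) {
      beta_i <- mean(usable)
    } else {
      beta_i <- 1.0
      flags <- c(flags, "no_effect_size")
    }
    alleles <- assocs$effect_allele[g]
    known <- unique(alleles[!is.na(alleles)])
    if (length(known) == 0) {
      allele <- NA_character_
      flags <- c(flags, "unknown_allele")
    } else if (length(known) == 1) {
      allele <- known
    } else {
      # conflicting alleles: keep the one from the strongest-effect study
      cand <- g[!is.na(alleles)]
      mag <- abs(log(or[cand]))
      mag[is.na(mag)] <- -Inf
      allele <- assocs$effect_allele[cand[which.max(mag)]]
      flags <- c(flags, "allele_conflict")
    }
    chrom <- assocs$chrom[g]
    pos <- assocs$pos[g]
    tibble::tibble(
      rsid = id,
      chrom = if (any(!is.na(chrom))) chrom[!is.na(chrom)][1] else NA_character_,
      pos = if (any(!is.na(pos))) pos[!is.na(pos)][1] else NA_integer_,
      effect_allele = allele,
      beta_i = beta_i,
      n_studies = length(g),
      flags = join_flags(flags)
    )
  })
  model <- dplyr::bind_rows(rows)
  if (strict_alleles) {
    model <- model[!is.na(model$effect_allele), ]
    if (nrow(model) == 0) {
      stop("no SNPs left after dropping unknown effect alleles", call. = FALSE)
    }
  }
  class(model) <- c("risk_model", class(model))
  model
}

#' Restrict a risk model to SNPs available in a genotype panel
#'
#' @param model A `risk_model`.
#' @param available_rsids Character vector of rsIDs present in the panel.
#' @return The sub-model in original order; attribute `n_dropped` holds the
#'   number of SNPs removed. Empty intersection is an error.
#' @export
intersect_with_panel <- function(model, available_rsids) {
  keep <- model$rsid %in% available_rsids
  if (!any(keep)) {
    stop("no model SNP is present in the panel", call. = FALSE)
  }
  if (any(!keep)) {
    message(sum(!keep), " model SNP(s) absent from the panel; dropped")
  }
  out <- model[keep, ]
  attr(out, "n_dropped") <- sum(!keep)
  class(out) <- unique(c("risk_model", class(out)))
  out
}

#' @export
print.risk_model <- function(x, ...) {
  cat("<risk_model> ", nrow(x), " SNPs; mean weight ",
      signif(mean(x$beta_i), 4), "\n", sep = "")
  flagged <- sum(nzchar(x$flags))
  if (flagged > 0) cat("  ", flagged, " flagged entr",
                       if (flagged == 1) "y" else "ies", "\n", sep = "")
  NextMethod()
}

#' Write a harmonized risk model to TSV
#'
#' @param model A `risk_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_risk_model <- function(model, path) {
  readr::write_tsv(tibble::as_tibble(model), path, progress = FALSE)
  invisible(path)
}
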