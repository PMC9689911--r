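#' Normalized polygenic risk score for one individual
#'
#' The score is the weighted dosage sum scaled into \[0, 1\]:
#' \deqn{PRS = \frac{\sum_i \beta_i X_i}{2 \sum_i \beta_i}}
#' where \eqn{X_i \in \{0, 1, 2\}} counts copies of the effect allele at SNP
#' i and \eqn{\beta_i > 0} is its averaged odds-ratio weight. This
#' normalization makes three calibration points hold for *any* positive
#' weights: a carrier of two effect alleles everywhere scores exactly 1, a
#' carrier of none scores exactly 0, and dosages drawn uniformly from
#' \{0, 1, 2\} give expectation 0.5. `literal_denominator = TRUE` divides by
#' `2 * I` (twice the SNP count) instead — the unweighted-denominator
#' convention, equivalent only when all weights are 1 and then no longer
#' confined to \[0, 1\].
#'
#' Missing dosages are excluded from numerator and denominator
#' (renormalization over the observed SNPs) rather than imputed.
#'
#' @param model A `risk_model`.
#' @param dosage Numeric vector of effect-allele copies, one per model SNP
#'   in model order (0, 1, 2 or `NA`). For X-linked SNPs in males, pass the
#'   haploid call through `haploid` below rather than a raw 0/1.
#' @param literal_denominator Use `2 * n_used` instead of `2 * sum(beta)`.
#' @param haploid Optional logical vector marking hemizygous SNPs whose
#'   dosage was called on one haplotype (values 0/1).
#' @param haploid_dosage How a hemizygous call enters the score:
#'   `"double"` (default; 0/1 becomes 0/2, preserving the \[0, 1\] range) or
#'   `"as_is"` (contributes 0/1).
#' @return List of class `prs_value`: `value`, `n_used`, `n_missing`.
#' @export
#' @examples
#' m <- tibble::tibble(rsid = c("rs1", "rs2"), chrom = "1", pos = NA_integer_,
#'                     effect_allele = "A", beta_i = c(1.2, 1.8),
#'                     n_studies = 1L, flags = "")
#' class(m) <- c("risk_model", class(m))
#' individual_prs(m, c(1, 2))$value  # (1.2 + 3.6) / (2 * 3) = 0.8
individual_prs <- function(model, dosage, literal_denominator = FALSE,
                           haploid = NULL, haploid_dosage = c("double", "as_is")) {
  haploid_dosage <- match.arg(haploid_dosage)
  if (length(dosage) != nrow(model)) {
    stop("dosage vector length (", length(dosage),
         ") != number of model SNPs (", nrow(model), ")", call. = FALSE)
  }
  if (!is.null(haploid)) {
    stopifnot(length(haploid) == length(dosage))
    if (any(!is.na(dosage[haploid]) & dosage[haploid] > 1)) {
      stop("hemizygous dosage must be 0 or 1", call. = FALSE)
    }
    if (haploid_dosage == "double") {
      dosage[haploid] <- 2 * dosage[haploid]
    }
  }
  used <- !is.na(dosage)
  if (!all(dosage[used] %in% c(0, 1, 2))) {
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  }
  if (!any(used)) {
    stop("all dosages missing; PRS undefined", call. = FALSE)
  }
  beta <- model$beta_i[used]
  num <- sum(beta * dosage[used])
  den <- if (literal_denominator) 2 * sum(used) else 2 * sum(beta)
  structure(list(value = num / den,
                 n_used = sum(used),
                 n_missing = sum(!used)),
            class = "prs_value")
}

#' @export
print.prs_value <- function(x, ...) {
  cat("<prs_value> ", signif(x$value, 6), " (", x$n_used, " SNPs used, ",
      x$n_missing, " missing)\n", sep = "")
  invisible(x)
}

#' Expected polygenic risk score of each population
#'
#' Under Hardy-Weinberg equilibrium the expected dosage at frequency
#' \eqn{f_i} is \eqn{2 f_i}, so the population expectation of the
#' normalized score reduces to
#' \deqn{E[PRS] = \frac{\sum_i \beta_i f_i}{\sum_i \beta_i}.}
#' SNPs without a frequency in a population are excluded from both sums and
#' counted as missing.
#'
#' @param model A `risk_model`.
#' @param counts A `pop_counts` tibble (one or more populations).
#' @return Tibble with one row per population: `population`, `prs`,
#'   `n_used`, `n_missing`. A population sharing no SNP with the model is an
#'   error.
#' @export
population_expected_prs <- function(model, counts) {
  pops <- sort(unique(counts$population))
  rows <- lapply(pops, function(pop) {
    sub <- counts[counts$population == pop & counts$tac > 0, ]
    idx <- match(model$rsid, sub$rsid)
    used <- !is.na(idx)
    if (!any(used)) {
      stop("population ", pop, " shares no scoreable SNP with the model",
           call. = FALSE)
    }
    f <- sub$eac[idx[used]] / sub$tac[idx[used]]
    beta <- model$beta_i[used]
    tibble::tibble(population = pop,
                   prs = sum(beta * f) / sum(beta),
                   n_used = sum(used),
                   n_missing = sum(!used))
  })
  dplyr::bind_rows(rows)
}

#' Mean individual score over a genotype panel
#'
#' @param model A `risk_model`.
#' @param dosages Matrix of dosages, individuals in rows, model SNPs in
#'   columns (model order); `NA` allowed.
#' @param ... Passed on to [individual_prs()].
#' @return Arithmetic mean of the individual scores.
#' @export
panel_mean_prs <- function(model, dosages, ...) {
  if (is.null(dim(dosages))) dosages <- matrix(dosages, nrow = 1)
  if (nrow(dosages) < 1) stop("empty panel", call. = FALSE)
  if (!anyNA(dosages) && length(list(...)) == 0) {
    # fast path: no missingness, default normalization
    if (!all(dosages %in% c(0, 1, 2))) {
      stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
    }
    vals <- as.vector(dosages %*% model$beta_i) / (2 * sum(model$beta_i))
    return(mean(vals))
  }
  mean(apply(dosages, 1, function(x) individual_prs(model, x, ...)$value))
}

#' Bar chart of expected population scores
#'
#' @param prs_tbl Output of [population_expected_prs()].
#' @return A ggplot object.
#' @export
plot_population_prs <- function(prs_tbl) {
  ggplot2::ggplot(prs_tbl,
                  ggplot2::aes(x = stats::reorder(.data$population, -.data$prs),
                               y = .data$prs)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "population", y = "expected PRS") +
    ggplot2::theme_minimal()
}
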