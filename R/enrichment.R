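#' Build a 2x2 contingency table for one SNP
#'
#' Cell layout: `a` = effect alleles in the focal population, `b` = its
#' non-effect alleles, `c` and `d` = the same for the comparison pool. The
#' comparison pool must exclude the focal population: a valid exact test
#' needs disjoint groups, and including the focal alleles in the "global"
#' side would double-count them.
#'
#' @param focal Single-population `pop_counts` for the focal population.
#' @param rest Single-population `pop_counts` for the pooled remainder.
#' @param rsid SNP identifier.
#' @return Named integer vector `c(a, b, c, d)`, or `NULL` when the SNP is
#'   untestable (absent from either side, or zero total on either side).
#' @export
contingency_table <- function(focal, rest, rsid) {
  fi <- which(focal$rsid == rsid)
  ri <- which(rest$rsid == rsid)
  if (length(fi) != 1 || length(ri) != 1) return(NULL)
  ft <- focal$tac[fi]
  rt <- rest$tac[ri]
  if (ft == 0 || rt == 0) return(NULL)
  c(a = as.integer(focal$eac[fi]), b = as.integer(ft - focal$eac[fi]),
    c = as.integer(rest$eac[ri]), d = as.integer(rt - rest$eac[ri]))
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Probability-ordering definition: with all four margins fixed, the p-value
#' is the sum of hypergeometric probabilities of every table whose
#' probability does not exceed that of the observed table (up to a 1e-7
#' relative tolerance guarding against ties lost to rounding). The
#' enumeration runs on log probabilities and sums by log-sum-exp, so it
#' remains stable for large allele counts.
#'
#' @param a,b,c,d Non-negative integer cells: focal effect, focal
#'   non-effect, comparison effect, comparison non-effect.
#' @return The p-value in (0, 1].
#' @export
#' @examples
#' fisher_exact_p(5, 5, 50, 50)  # equal proportions: 1
fisher_exact_p <- function(a, b, c, d) {
  stopifnot(is_count(a), is_count(b), is_count(c), is_count(d))
  r1 <- a + b
  r2 <- c + d
  if (r1 == 0 || r2 == 0) {
    stop("untestable table: a row margin is zero", call. = FALSE)
  }
  k <- a + c                      # effect-allele column margin
  lo <- max(0, k - r2)
  hi <- min(r1, k)
  sup <- lo:hi
  lp <- dhyper(sup, m = r1, n = r2, k = k, log = TRUE)
  lp_obs <- lp[sup == a]
  keep <- lp <= lp_obs + 1e-7
  # log-sum-exp over the retained tables
  mx <- max(lp[keep])
  p <- exp(mx + log(sum(exp(lp[keep] - mx))))
  min(p, 1)
}

#' Signed -log10 enrichment score for a 2x2 table
#'
#' The magnitude is `-log10(p)` of the two-sided exact test; the sign is
#' positive when the focal effect-allele frequency exceeds the comparison
#' pool's (enrichment) and negative when it falls below (depletion). Equal
#' proportions score exactly 0. The p-value is floored at 1e-300 before the
#' log, capping scores at 300.
#'
#' @inheritParams fisher_exact_p
#' @return A real score; attributes `p` (raw p-value) carried along.
#' @export
signed_score <- function(a, b, c, d) {
  f_focal <- a / (a + b)
  f_rest <- c / (c + d)
  p <- fisher_exact_p(a, b, c, d)
  s <- if (f_focal == f_rest) 0 else -log10(max(p, 1e-300)) * sign(f_focal - f_rest)
  structure(s, p = p)
}

#' Score effect-allele enrichment for every SNP and population
#'
#' For each population the comparison group is the pooled counts of all
#' *other* populations; each testable (SNP, population) cell gets the signed
#' score of [signed_score()]. Untestable cells (SNP absent, or zero total on
#' either side) are `NA`.
#'
#' @param model A `risk_model` (defines the SNP rows).
#' @param counts A multi-population `pop_counts` tibble.
#' @return An object of class `enrichment_matrix`: list with `scores` and
#'   `p` (SNP x population matrices), `rsids`, `populations`, and `meta`
#'   recording the sign convention and that the comparison pool excludes the
#'   focal population.
#' @export
build_enrichment_matrix <- function(model, counts) {
  pops <- sort(unique(counts$population))
  if (length(pops) < 2) {
    stop("need at least 2 populations to score enrichment", call. = FALSE)
  }
  rsids <- model$rsid[model$rsid %in% counts$rsid]
  scores <- p <- matrix(NA_real_, nrow = length(rsids), ncol = length(pops),
                        dimnames = list(rsids, pops))
  by_pop <- split(tibble::as_tibble(counts), counts$population)
  for (pop in pops) {
    focal <- by_pop[[pop]]
    rest <- pool_counts(counts, setdiff(pops, pop), code = "REST")
    for (id in rsids) {
      tab <- contingency_table(focal, rest, id)
      if (is.null(tab)) next
      s <- signed_score(tab["a"], tab["b"], tab["c"], tab["d"])
      scores[id, pop] <- as.numeric(s)
      p[id, pop] <- attr(s, "p")
    }
  }
  structure(list(scores = scores, p = p, rsids = rsids, populations = pops,
                 meta = list(comparison = "pooled counts of all other populations (focal excluded)",
                             sign = "+ = effect allele enriched in focal population",
                             p_floor = 1e-300)),
            class = "enrichment_matrix")
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat("<enrichment_matrix> ", nrow(x$scores), " SNPs x ",
      ncol(x$scores), " populations; ", sum(is.na(x$scores)),
      " untestable cell(s)\n", sep = "")
  cat("  comparison: ", x$meta$comparison, "\n", sep = "")
  invisible(x)
}

#' Long-format view of an enrichment matrix
#'
#' @param em An `enrichment_matrix`.
#' @return Tibble with `rsid`, `population`, `score`, `p` and a Bonferroni
#'   column (`p_bonferroni`, emitted for reference; no filtering in the
#'   package uses it).
#' @export
enrichment_long <- function(em) {
  n_tests <- sum(!is.na(em$p))
  tibble::tibble(
    rsid = rep(rownames(em$scores), times = ncol(em$scores)),
    population = rep(colnames(em$scores), each = nrow(em$scores)),
    score = as.vector(em$scores),
    p = as.vector(em$p),
    p_bonferroni = pmin(as.vector(em$p) * n_tests, 1)
  )
}

#' Select SNPs by combined divergence in two populations
#'
#' Keeps SNPs whose absolute scores in two chosen populations sum to
#' strictly more than `cutoff` — the device used to pull out variants most
#' differentiated between the most diverged population pair (e.g. AFR vs
#' EAS, with cutoff 60 for downstream gene lists and 100 for display).
#' Cells that are `NA` in either population disqualify the SNP.
#'
#' @param em An `enrichment_matrix`.
#' @param pop_a,pop_b Population codes.
#' @param cutoff Positive threshold; strict inequality.
#' @return Character vector of retained rsIDs.
#' @export
divergence_filter <- function(em, pop_a = "AFR", pop_b = "EAS", cutoff = 60) {
  for (p in c(pop_a, pop_b)) {
    if (!p %in% colnames(em$scores)) {
      stop("population not in matrix: ", p, call. = FALSE)
    }
  }
  stopifnot(cutoff >= 0)
  total <- abs(em$scores[, pop_a]) + abs(em$scores[, pop_b])
  rownames(em$scores)[!is.na(total) & total > cutoff]
}

#' Hierarchical-clustering leaf orders for rendering the matrix
#'
#' Agglomerative clustering (complete linkage, Euclidean distance) of rows
#' and of columns, with `NA` cells imputed as 0 for ordering only. Fewer
#' than two rows (or columns) yields the identity order.
#'
#' @param em An `enrichment_matrix`.
#' @return List with integer vectors `rows` and `cols` (leaf orders).
#' @export
cluster_order <- function(em) {
  m <- em$scores
  m[is.na(m)] <- 0
  ord <- function(x) {
    if (nrow(x) < 2) return(seq_len(nrow(x)))
    stats::hclust(stats::dist(x), method = "complete")$order
  }
  list(rows = ord(m), cols = ord(t(m)))
}

#' Render the enrichment heatmap
#'
#' Red = effect allele enriched in the population, blue = depleted, matching
#' the sign convention of [signed_score()]. Rows and columns are ordered by
#' complete-linkage Euclidean clustering.
#'
#' @param em An `enrichment_matrix`.
#' @param file Optional output path (png); `NULL` draws to the active device.
#' @param cutoff Optional divergence cutoff: when given together with
#'   `pop_a`/`pop_b`, only SNPs passing [divergence_filter()] are drawn.
#' @param pop_a,pop_b Populations for the optional cutoff.
#' @return The `pheatmap` object, invisibly.
#' @export
plot_enrichment_heatmap <- function(em, file = NULL, cutoff = NULL,
                                    pop_a = "AFR", pop_b = "EAS") {
  m <- em$scores
  if (!is.null(cutoff)) {
    keep <- divergence_filter(em, pop_a, pop_b, cutoff)
    m <- m[rownames(m) %in% keep, , drop = FALSE]
  }
  m[is.na(m)] <- 0
  lim <- max(abs(m), 1e-6)
  ph <- pheatmap::pheatmap(
    m,
    clustering_method = "complete",
    color = grDevices::colorRampPalette(c("blue", "white", "red"))(101),
    breaks = seq(-lim, lim, length.out = 102),
    filename = file %||% NA,
    silent = !is.null(file),
    show_rownames = nrow(m) <= 60
  )
  invisible(ph)
}
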