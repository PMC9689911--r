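#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a plain list. All problems are collected and
#' reported together, not first-failure. Recognized keys:
#'
#' - `catalog`: association TSV (required)
#' - `vcf` + `sample_map`, and/or `frequency_tables` (named map population
#'   -> TSV path); at least one genotype/frequency source is required
#' - `epidemiology`: optional TSV; when absent the regression stage is
#'   skipped
#' - `out_dir` (required), `seed` (default 1)
#' - `trait_filter` (optional), `kind_column` (optional)
#' - `cutoff` (default 60, must be > 0), `comparison` (two population
#'   codes, default AFR and EAS)
#' - `default_n`: allele number assumed for frequency tables lacking one
#'
#' @param x Path to a YAML file, or a list.
#' @return A validated config list of class `prscape_config`; invalid
#'   configs raise one error listing every problem.
#' @export
validate_config <- function(x) {
  cfg <- if (is.character(x) && length(x) == 1) yaml::read_yaml(x) else x
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)
  errs <- character(0)
  need_file <- function(path, what) {
    if (is.null(path)) return(paste0("missing required entry: ", what))
    if (!file.exists(path)) return(paste0(what, " does not exist: ", path))
    NULL
  }
  errs <- c(errs, need_file(cfg$catalog, "catalog"))
  has_vcf <- !is.null(cfg$vcf)
  has_freq <- !is.null(cfg$frequency_tables)
  if (!has_vcf && !has_freq) {
    errs <- c(errs, "need a genotype source: 'vcf' (+ 'sample_map') or 'frequency_tables'")
  }
  if (has_vcf) {
    errs <- c(errs, need_file(cfg$vcf, "vcf"),
              need_file(cfg$sample_map, "sample_map"))
  }
  if (has_freq) {
    for (pop in names(cfg$frequency_tables)) {
      errs <- c(errs, need_file(cfg$frequency_tables[[pop]],
                                paste0("frequency_tables[", pop, "]")))
    }
  }
  if (!is.null(cfg$epidemiology)) {
    errs <- c(errs, need_file(cfg$epidemiology, "epidemiology"))
  }
  if (is.null(cfg$out_dir)) errs <- c(errs, "missing required entry: out_dir")
  cfg$cutoff <- cfg$cutoff %||% 60
  if (!is.numeric(cfg$cutoff) || cfg$cutoff <= 0) {
    errs <- c(errs, "cutoff must be a positive number")
  }
  cfg$comparison <- unlist(cfg$comparison %||% c("AFR", "EAS"))
  if (length(cfg$comparison) != 2) {
    errs <- c(errs, "comparison must name exactly two populations")
  }
  cfg$seed <- cfg$seed %||% 1
  if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed)) {
    errs <- c(errs, "seed must be an integer")
  }
  cfg$default_n <- cfg$default_n %||% 1000
  errs <- errs[!vapply(errs, is.null, TRUE)]
  if (length(errs) > 0) {
    stop("invalid config:\n", paste0("  - ", errs, collapse = "\n"),
         call. = FALSE)
  }
  class(cfg) <- c("prscape_config", class(cfg))
  cfg
}

run_stage <- function(name, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(c(paste0("stage: ", name),
                 paste0("error: ", conditionMessage(e))),
               file.path(out_dir, "FAILED"))
    stop("[stage:", name, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes ingest -> allele counts -> enrichment matrix (heatmap +
#' divergence-filtered SNP list) -> per-population expected PRS (bar chart)
#' -> regressions (scatter plots), writing every intermediate as TSV plus a
#' JSON manifest recording the config, seed, package version and the
#' analysis conventions in force. With a fixed config the tabular outputs
#' are bit-identical across runs. A stage failure aborts with the stage
#' name; partial outputs stay on disk next to a `FAILED` marker. A missing
#' epidemiology table skips the regression stage with a notice instead of
#' failing.
#'
#' @param config A YAML path, list, or validated `prscape_config`.
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "prscape_config")) config else
    validate_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(out, "FAILED"))

  model <- run_stage("ingest", out, {
    assoc <- parse_gwas_catalog(cfg$catalog, trait_filter = cfg$trait_filter,
                                kind_column = cfg$kind_column)
    harmonize_risk_model(assoc)
  })

  counts <- run_stage("counts", out, {
    parts <- list()
    if (!is.null(cfg$vcf)) {
      parts$vcf <- read_vcf_counts(cfg$vcf, cfg$sample_map, model)
    }
    for (pop in names(cfg$frequency_tables)) {
      parts[[pop]] <- read_frequency_table(cfg$frequency_tables[[pop]],
                                           population = pop,
                                           default_n = cfg$default_n)
    }
    pop_counts(dplyr::bind_rows(parts))
  })
  model <- run_stage("intersect", out,
                     intersect_with_panel(model, unique(counts$rsid)))
  write_risk_model(model, file.path(out, "risk_model.tsv"))
  write_counts(counts, file.path(out, "allele_counts.tsv"))

  em <- run_stage("enrichment", out, {
    em <- build_enrichment_matrix(model, counts)
    readr::write_tsv(
      tibble::as_tibble(em$scores, rownames = "rsid"),
      file.path(out, "enrichment_scores.tsv"), progress = FALSE)
    readr::write_tsv(enrichment_long(em),
                     file.path(out, "enrichment_long.tsv"), progress = FALSE)
    cmp <- intersect(cfg$comparison, em$populations)
    if (length(cmp) == 2) {
      divergent <- divergence_filter(em, cmp[1], cmp[2], cfg$cutoff)
      readr::write_tsv(tibble::tibble(rsid = divergent),
                       file.path(out, "divergent_snps.tsv"), progress = FALSE)
      plot_enrichment_heatmap(em, file = file.path(out, "heatmap.png"))
    } else {
      message("comparison populations not both present; divergence filter skipped")
    }
    em
  })

  prs <- run_stage("prs", out, {
    prs <- population_expected_prs(model, counts)
    readr::write_tsv(prs, file.path(out, "population_prs.tsv"),
                     progress = FALSE)
    ggplot2::ggsave(file.path(out, "population_prs.png"),
                    plot_population_prs(prs), width = 5, height = 4,
                    dpi = 150)
    prs
  })

  if (!is.null(cfg$epidemiology)) {
    run_stage("regression", out, {
      epi <- read_epidemiology(cfg$epidemiology)
      report <- covariate_report(epi, prs)
      readr::write_tsv(report, file.path(out, "regression_report.tsv"),
                       progress = FALSE)
      dat <- dplyr::inner_join(epi, prs, by = "population")
      for (resp in c("incidence", "mortality")) {
        fit <- fit_linear(dat$prs, dat[[resp]], labels = dat$population)
        ggplot2::ggsave(
          file.path(out, paste0("prs_vs_", resp, ".png")),
          plot_fit(fit, dat$prs, dat[[resp]], labels = dat$population,
                   ylab = paste(resp, "per 100,000")),
          width = 5, height = 4, dpi = 150)
      }
      report
    })
  } else {
    message("no epidemiology table configured; regression stage skipped")
  }

  manifest <- list(
    package = "prscape",
    version = as.character(utils::packageVersion("prscape")),
    seed = cfg$seed,
    config = unclass(cfg),
    config_hash = rlang::hash(unclass(cfg)),
    conventions = list(
      comparison_pool = "pooled counts of all other populations (focal excluded)",
      prs_denominator = "2 * sum(beta_i), renormalized over non-missing SNPs",
      fisher = "two-sided, probability ordering, p floored at 1e-300",
      clustering = "complete linkage, Euclidean distance, NA imputed as 0 for ordering",
      multiple_testing = "raw p used throughout; Bonferroni column emitted for reference"
    ))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
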