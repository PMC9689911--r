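#' Ordinary least-squares fit of a population rate on a predictor
#'
#' Ecological regression: each point is one population, equally weighted.
#' With a handful of populations the fit is descriptive — R-squared on four
#' or five points is fragile, and the printed report says so.
#'
#' @param x Predictor values (e.g. expected PRS per population).
#' @param y Response values (e.g. age-adjusted incidence per 100,000).
#' @param labels Optional point labels (population codes) for residuals.
#' @return Object of class `epi_fit`: `slope`, `intercept`, `r_squared`,
#'   `n`, `residuals` (named when labels given), and the underlying `lm`
#'   fit. Fewer than 3 complete pairs, a constant predictor, or a constant
#'   response are errors.
#' @export
fit_linear <- function(x, y, labels = NULL) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (!is.null(labels)) labels <- labels[ok]
  if (length(x) < 3) {
    stop("need at least 3 populations with both values", call. = FALSE)
  }
  if (sd(x) == 0) stop("degenerate predictor: x is constant", call. = FALSE)
  if (sd(y) == 0) {
    stop("degenerate response: y is constant (SS_tot = 0)", call. = FALSE)
  }
  fit <- lm(y ~ x)
  res <- stats::residuals(fit)
  if (!is.null(labels)) names(res) <- labels
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = min(max(1 - sum(res^2) / sum((y - mean(y))^2),
                                     0), 1),
                 n = length(x),
                 residuals = res,
                 lm = fit),
            class = "epi_fit")
}

#' @export
print.epi_fit <- function(x, ...) {
  cat("<epi_fit> y = ", signif(x$intercept, 5), " + ", signif(x$slope, 5),
      " * x; R^2 = ", signif(x$r_squared, 4), " (n = ", x$n,
      " populations; ecological fit, interpret with care)\n", sep = "")
  invisible(x)
}

#' Predict a rate for a new population from a fitted line
#'
#' Places a held-out population (e.g. one whose frequencies come from a
#' separate reference panel) on the fitted line so its predicted rate can be
#' compared with the observed one.
#'
#' @param fit An `epi_fit`.
#' @param x_new Predictor value(s).
#' @return `intercept + slope * x_new`.
#' @export
predict_rate <- function(fit, x_new) {
  fit$intercept + fit$slope * x_new
}

#' Compare predictors of incidence and mortality across populations
#'
#' Fits every available predictor (expected PRS, DHT:T ratio, vitamin D)
#' against incidence and against mortality, one OLS fit each, and ranks
#' predictors by R-squared within each response. A covariate observed in
#' fewer than 3 populations is skipped with a note.
#'
#' @param epi Tibble with columns `population`, `incidence`, `mortality`,
#'   and optionally `dht_t_ratio`, `vit_d`.
#' @param prs_tbl Output of [population_expected_prs()].
#' @return Tibble: `predictor`, `response`, `slope`, `intercept`,
#'   `r_squared`, `n`, ordered by response then decreasing R-squared.
#' @export
covariate_report <- function(epi, prs_tbl) {
  dat <- dplyr::inner_join(epi, prs_tbl[, c("population", "prs")],
                           by = "population")
  if (nrow(dat) < 3) {
    stop("need at least 3 populations shared by epidemiology and PRS tables",
         call. = FALSE)
  }
  predictors <- c(PRS = "prs", `DHT:T` = "dht_t_ratio", VitD = "vit_d")
  rows <- list()
  for (resp in c("incidence", "mortality")) {
    for (i in seq_along(predictors)) {
      col <- predictors[[i]]
      if (!col %in% names(dat) || sum(!is.na(dat[[col]]) & !is.na(dat[[resp]])) < 3) {
        if (col != "prs") {
          message("covariate '", names(predictors)[i],
                  "' observed in < 3 populations; skipped for ", resp)
        }
        next
      }
      f <- fit_linear(dat[[col]], dat[[resp]], labels = dat$population)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        predictor = names(predictors)[i], response = resp,
        slope = f$slope, intercept = f$intercept,
        r_squared = f$r_squared, n = f$n)
    }
  }
  dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$response, dplyr::desc(.data$r_squared))
}

#' Read an epidemiology table
#'
#' @param path TSV with columns `population`, `incidence`, `mortality` and
#'   optionally `dht_t_ratio`, `vit_d`. Rates are age-adjusted per 100,000
#'   and must be non-negative.
#' @return A tibble.
#' @export
read_epidemiology <- function(path) {
  epi <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  need <- c("population", "incidence", "mortality")
  miss <- setdiff(need, names(epi))
  if (length(miss) > 0) {
    stop("epidemiology table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(epi$incidence < 0 | epi$mortality < 0, na.rm = TRUE)) {
    stop("rates must be non-negative", call. = FALSE)
  }
  epi
}

#' Scatter plot of a fitted population-level regression
#'
#' Observed populations as solid points with the OLS line dashed gray;
#' optional extra populations (e.g. a reference-panel prediction) drawn as
#' open diamonds beside their observed value.
#'
#' @param fit An `epi_fit`.
#' @param x,y The fitted data (same vectors given to [fit_linear()]).
#' @param labels Point labels.
#' @param xlab,ylab Axis titles.
#' @param extra Optional tibble with columns `x`, `y`, `label` of held-out
#'   points to overlay as open diamonds.
#' @return A ggplot object.
#' @export
plot_fit <- function(fit, x, y, labels = NULL, xlab = "expected PRS",
                     ylab = "rate per 100,000", extra = NULL) {
  dat <- tibble::tibble(x = x, y = y,
                        label = labels %||% rep("", length(x)))
  gg <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                         linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = xlab, y = ylab,
                  subtitle = paste0("R² = ", signif(fit$r_squared, 3),
                                    " (n = ", fit$n, ")")) +
    ggplot2::theme_minimal()
  if (!is.null(extra) && nrow(extra) > 0) {
    gg <- gg +
      ggplot2::geom_point(data = extra, shape = 5, size = 3,
                          colour = "blue") +
      ggplot2::geom_text(data = extra, ggplot2::aes(label = .data$label),
                         vjust = -0.8, size = 3, colour = "blue")
  }
  gg
}
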