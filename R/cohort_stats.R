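# Cohort statistics: partial Pearson correlation with covariates, FDR,
# ANCOVA with post hoc t tests, Fisher r-to-z comparison, linear/quadratic
# age trends, and KS normality — the battery applied to the subject x
# region metric table.

#' Assign lifespan age groups
#'
#' Young <= 34 years, middle 35-54, older >= 55.
#'
#' @param age numeric vector of ages in years.
#' @return Factor with levels `young`, `middle`, `older`.
#' @export
age_group <- function(age) {
  cut(age, breaks = c(-Inf, 34.5, 54.5, Inf),
      labels = c("young", "middle", "older"))
}

#' Partial Pearson correlation
#'
#' Pearson correlation of the OLS residuals of `x` and `y` on the
#' covariates; with no covariates this is the plain Pearson correlation.
#' The two-sided p-value uses `t = r sqrt((n - 2 - k)/(1 - r^2))` on
#' `n - 2 - k` degrees of freedom, k the number of covariates.
#'
#' @param x,y numeric vectors.
#' @param covariates optional numeric vector, matrix or data frame of
#'   covariates (e.g. sex coded 0/1, a free-water fraction column).
#' @return One-row tibble of class `correlation_result`: `r`, `p`, `n`,
#'   `n_covariates`.
#' @export
partial_pearson <- function(x, y, covariates = NULL) {
  ok <- is.finite(x) & is.finite(y)
  if (!is.null(covariates)) {
    covariates <- as.matrix(as.data.frame(covariates))
    ok <- ok & apply(is.finite(covariates), 1, all)
    covariates <- covariates[ok, , drop = FALSE]
  }
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  if (n <= k + 2) stop("need n > number of covariates + 2")
  if (is.null(covariates)) {
    rx <- x - mean(x); ry <- y - mean(y)
  } else {
    Z <- cbind(1, covariates)
    rx <- stats::lm.fit(Z, x)$residuals
    ry <- stats::lm.fit(Z, y)$residuals
  }
  if (stats::sd(rx) < 1e-12 * (abs(mean(x)) + 1) ||
      stats::sd(ry) < 1e-12 * (abs(mean(y)) + 1)) {
    stop("zero residual variance: input constant or collinear with covariates")
  }
  r <- stats::cor(rx, ry)
  df <- n - 2 - k
  t <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(t), df)
  out <- tibble::tibble(r = r, p = p, n = n, n_covariates = k)
  class(out) <- c("correlation_result", class(out))
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone and clipped at 1.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
fdr_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' ANCOVA group comparison with post hoc t tests
#'
#' Compares a metric among the three age groups adjusting for sex: an
#' F-test of the full linear model (group + sex) against the reduced model
#' (sex only), followed by pairwise unpaired Student t tests with FDR
#' adjustment over the three pairs.
#'
#' @param table data frame with one row per subject (for one region)
#'   containing the metric column, `group` (factor) and `sex`.
#' @param metric name of the metric column.
#' @param welch use Welch's t instead of Student's for the post hoc tests.
#' @return List of class `sandi_group_comparison` with `ancova` (one-row
#'   tibble: `F`, `df1`, `df2`, `p`) and `posthoc` (three rows: `group1`,
#'   `group2`, `t`, `df`, `p`, `fdr_p`).
#' @export
compare_groups_ancova <- function(table, metric, welch = FALSE) {
  y <- table[[metric]]
  g <- droplevels(as.factor(table$group))
  sex <- as.numeric(as.factor(table$sex))
  if (any(tabulate(g) < 2) || nlevels(g) < 2) {
    stop("each group needs at least 2 subjects")
  }
  full <- stats::lm(y ~ sex + g)
  red <- stats::lm(y ~ sex)
  rss_f <- sum(stats::residuals(full)^2)
  rss_r <- sum(stats::residuals(red)^2)
  df1 <- nlevels(g) - 1
  df2 <- length(y) - nlevels(g) - 1
  Fst <- ((rss_r - rss_f) / df1) / (rss_f / df2)
  p <- stats::pf(Fst, df1, df2, lower.tail = FALSE)
  pairs <- utils::combn(levels(g), 2)
  ph <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- y[g == pairs[1, i]]; b <- y[g == pairs[2, i]]
    tt <- stats::t.test(a, b, var.equal = !welch)
    tibble::tibble(group1 = pairs[1, i], group2 = pairs[2, i],
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value)
  })
  ph <- dplyr::bind_rows(ph)
  ph$fdr_p <- fdr_adjust(ph$p)
  structure(list(
    ancova = tibble::tibble(F = Fst, df1 = df1, df2 = df2, p = p),
    posthoc = ph, metric = metric),
    class = "sandi_group_comparison")
}

#' @export
print.sandi_group_comparison <- function(x, ...) {
  cat(sprintf("<sandi_group_comparison> %s: F(%d, %d) = %.3f, p = %.3g\n",
              x$metric, x$ancova$df1, x$ancova$df2, x$ancova$F, x$ancova$p))
  print(x$posthoc)
  invisible(x)
}

#' Fisher r-to-z comparison of two correlation magnitudes
#'
#' \eqn{z = (\mathrm{atanh}|r_1| - \mathrm{atanh}|r_2|) /
#' \sqrt{1/(n_1-3) + 1/(n_2-3)}} with a two-sided normal p-value; the sign
#' of z states whether the first correlation is the stronger one. The
#' independent-samples formula is used (set `dependent = TRUE` for the
#' Steiger-style variant when the two correlations share a variable and
#' their overlap correlation `r12` is known).
#'
#' @param r1,r2 correlation coefficients, `|r| < 1`.
#' @param n1,n2 sample sizes (> 3).
#' @param dependent use the dependent-correlations variant.
#' @param r12 correlation between the two correlated variables (required
#'   when `dependent = TRUE`; both samples must then share `n1`).
#' @return One-row tibble: `z`, `p`.
#' @export
fisher_z_compare <- function(r1, n1, r2, n2, dependent = FALSE, r12 = NULL) {
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1")
  if (n1 <= 3 || n2 <= 3) stop("n must be > 3")
  if (!dependent) {
    z <- (atanh(abs(r1)) - atanh(abs(r2))) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  } else {
    if (is.null(r12)) stop("r12 is required for the dependent variant")
    n <- n1
    a1 <- abs(r1); a2 <- abs(r2)
    rbar2 <- ((a1 + a2) / 2)^2
    cov_term <- r12 * (1 - 2 * rbar2) - 0.5 * rbar2 * (1 - 2 * rbar2 - r12^2)
    s <- cov_term / (1 - rbar2)^2
    z <- (atanh(a1) - atanh(a2)) * sqrt((n - 3) / (2 * (1 - s)))
  }
  tibble::tibble(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Linear and quadratic age-trend fit
#'
#' OLS fits of a metric on age (degree 1) and on age + age^2 (degree 2)
#' with their R-squared. For a concave quadratic (beta2 < 0) the peak age
#' `-beta1 / (2 beta2)` is reported when it falls inside the observed age
#' range.
#'
#' @param table data frame with `age` and the metric column.
#' @param metric name of the metric column.
#' @param degree 1 or 2 — the fit reported as `coefficients`/`r_squared`;
#'   both fits are always available in the result.
#' @return List of class `sandi_age_trend` with `linear`, `quadratic`
#'   (each: `coefficients`, `r_squared`), `degree`, `peak_age` (`NA` when
#'   not applicable), `concave`, `n`, `age_range`.
#' @export
polynomial_age_fit <- function(table, metric, degree = 2) {
  if (!degree %in% 1:2) stop("degree must be 1 or 2")
  ok <- is.finite(table$age) & is.finite(table[[metric]])
  age <- table$age[ok]; y <- table[[metric]][ok]
  if (length(age) < degree + 2) stop("too few observations")
  if (stats::sd(age) == 0) stop("degenerate design: all ages equal")
  r2 <- function(fit, y) 1 - sum(stats::residuals(fit)^2) /
    sum((y - mean(y))^2)
  lin <- stats::lm(y ~ age)
  quad <- stats::lm(y ~ age + I(age^2))
  b <- stats::coef(quad)
  concave <- is.finite(b[3]) && b[3] < 0
  peak <- if (concave) unname(-b[2] / (2 * b[3])) else NA_real_
  if (!is.na(peak) && (peak < min(age) || peak > max(age))) peak <- NA_real_
  structure(list(
    linear = list(coefficients = stats::coef(lin), r_squared = r2(lin, y)),
    quadratic = list(coefficients = stats::coef(quad), r_squared = r2(quad, y)),
    degree = degree, peak_age = peak, concave = concave,
    n = length(y), age_range = range(age), metric = metric),
    class = "sandi_age_trend")
}

#' @export
print.sandi_age_trend <- function(x, ...) {
  cat(sprintf(
    "<sandi_age_trend> %s: R^2 linear %.3f, quadratic %.3f%s\n",
    x$metric, x$linear$r_squared, x$quadratic$r_squared,
    if (!is.na(x$peak_age)) sprintf(", peak age %.1f y", x$peak_age) else ""))
  invisible(x)
}

#' Kolmogorov-Smirnov normality test
#'
#' Sup-distance between the empirical CDF and a normal distribution with
#' the sample mean and SD (no Lilliefors correction; the p-value is
#' therefore conservative with estimated parameters, which is flagged in
#' the output).
#'
#' @param values numeric vector, n >= 5.
#' @return One-row tibble: `D`, `p`, `n`, `parameters_estimated = TRUE`.
#' @export
ks_normality <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 5) stop("need at least 5 observations")
  if (stats::sd(values) == 0) stop("zero variance")
  kt <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), stats::sd(values)))
  tibble::tibble(D = unname(kt$statistic), p = kt$p.value,
                 n = length(values), parameters_estimated = TRUE)
}

#' Pooled mean and SD from per-group summaries
#'
#' Combines group sizes, means and SDs into the overall mean and SD —
#' the standard check that a demographics table's group rows reproduce its
#' total row.
#'
#' @param n,mean,sd numeric vectors of per-group sizes, means, SDs.
#' @return One-row tibble: `n`, `mean`, `sd`.
#' @export
pooled_moments <- function(n, mean, sd) {
  N <- sum(n)
  M <- sum(n * mean) / N
  V <- (sum((n - 1) * sd^2) + sum(n * (mean - M)^2)) / (N - 1)
  tibble::tibble(n = N, mean = M, sd = sqrt(V))
}

#' Correlation results table (metrics x regions x targets)
#'
#' For every metric x region x target combination, the partial Pearson
#' correlation controlling for sex (coded 0/1; any consistent binary
#' coding gives the same r) and optionally for a free-water fraction
#' column, with Benjamini-Hochberg FDR applied within each target family
#' (one metric set x region set x target = one family).
#'
#' @param table cohort tibble: one row per subject x region with columns
#'   `subject`, `age`, `sex`, `region`, `normalized_volume`, the metric
#'   columns, and optionally `f_iso`.
#' @param metrics character vector of metric column names.
#' @param targets subset of `c("age", "normalized_volume")`.
#' @param covariates covariate column names; `"sex"` is coded 0/1
#'   automatically, any other name must be numeric in `table`.
#' @return Tibble of class `sandi_results_table`: `metric`, `region`,
#'   `target`, `r`, `p`, `fdr_p`, `n`.
#' @export
build_results_table <- function(table,
                                metrics = sandi_metric_names(),
                                targets = c("age", "normalized_volume"),
                                covariates = "sex") {
  if (!all(targets %in% c("age", "normalized_volume"))) {
    stop("targets must be among 'age', 'normalized_volume'")
  }
  missing_cols <- setdiff(c(metrics, "region", "age", covariates), names(table))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  covmat <- function(df) {
    if (length(covariates) == 0) return(NULL)
    as.data.frame(lapply(stats::setNames(covariates, covariates), function(cv) {
      v <- df[[cv]]
      if (cv == "sex") as.numeric(as.factor(v)) - 1 else as.numeric(v)
    }))
  }
  out <- list()
  for (tg in targets) {
    for (rg in unique(table$region)) {
      df <- table[table$region == rg, ]
      for (m in metrics) {
        cr <- partial_pearson(df[[m]], df[[tg]], covariates = covmat(df))
        out[[length(out) + 1]] <- tibble::tibble(
          metric = m, region = rg, target = tg,
          r = cr$r, p = cr$p, n = cr$n)
      }
    }
  }
  res <- dplyr::bind_rows(out)
  res <- dplyr::group_by(res, .data$target)
  res <- dplyr::mutate(res, fdr_p = fdr_adjust(.data$p))
  res <- dplyr::ungroup(res)
  res <- res[, c("metric", "region", "target", "r", "p", "fdr_p", "n")]
  class(res) <- c("sandi_results_table", class(res))
  res
}
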