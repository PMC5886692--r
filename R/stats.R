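# Statistics layer: median tract summaries, contingency tests, and
# Lea-Coulson fluctuation-rate estimation.

#' Median hetDNA length summary
#'
#' Medians are used rather than means because many tracts extend to the
#' border of homology. Events without hetDNA are excluded; each summary
#' reports the number of contributing events.
#'
#' @param length_table Per-event length table from [hetdna_length_table()]
#'   (columns `upstream_bp`, `downstream_bp`, `total_bp`, `has_hetdna`).
#' @return Tibble with `quantity` (`upstream`, `downstream`, `total`,
#'   `side_sum`), `median_bp`, `n`. `side_sum` is the sum of the per-side
#'   medians, reported alongside the median of per-event totals.
#' @export
median_summary <- function(length_table) {
  lt <- filter(length_table, .data$has_hetdna)
  if (nrow(lt) == 0) stop("no events with hetDNA after exclusion", call. = FALSE)
  up <- lt$upstream_bp[lt$upstream_bp > 0]
  dn <- lt$downstream_bp[lt$downstream_bp > 0]
  tot <- lt$total_bp[!is.na(lt$total_bp)]
  tibble(
    quantity = c("upstream", "downstream", "total", "side_sum"),
    median_bp = c(median(up), median(dn), median(tot), median(up) + median(dn)),
    n = c(length(up), length(dn), length(tot), NA_integer_)
  )
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Two-sided p-value by summing hypergeometric probabilities less than or
#' equal to that of the observed table (the standard exact formulation).
#'
#' @param table 2x2 matrix (or coercible) of non-negative integer counts.
#' @return List with `p_value` and the odds-ratio estimate.
#' @export
fisher_2x2 <- function(table) {
  tab <- as.matrix(table)
  stopifnot(all(dim(tab) == c(2, 2)))
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  ft <- fisher.test(tab, alternative = "two.sided")
  list(p_value = unname(ft$p.value), odds_ratio = unname(ft$estimate))
}

#' Chi-square goodness-of-fit test
#'
#' Pearson statistic (no continuity correction by default) against expected
#' proportions, with k-1 degrees of freedom.
#'
#' @param observed Vector of observed counts.
#' @param expected_prop Expected proportions (default uniform); must be
#'   positive.
#' @param correct Apply the Yates continuity correction (two cells only).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chisq_gof <- function(observed, expected_prop = NULL, correct = FALSE) {
  k <- length(observed)
  p <- expected_prop %||% rep(1 / k, k)
  if (any(p <= 0)) stop("expected proportions must be positive", call. = FALSE)
  p <- p / sum(p)
  expected <- sum(observed) * p
  adj <- if (correct && k == 2) pmin(abs(observed - expected), 0.5) else 0
  stat <- sum((abs(observed - expected) - adj)^2 / expected)
  list(statistic = stat, df = k - 1, p_value = pchisq(stat, k - 1, lower.tail = FALSE))
}

#' Mann-Whitney U test for two length distributions
#'
#' Exact distribution when the smaller sample has at most `exact_max`
#' observations and there are no ties; otherwise the normal approximation
#' with tie and continuity corrections.
#'
#' @param a,b Numeric vectors (e.g. hetDNA lengths).
#' @param exact_max Largest small-sample size for the exact test.
#' @return List with `U`, `p_value`.
#' @export
mann_whitney <- function(a, b, exact_max = 8) {
  if (length(a) == 0 || length(b) == 0) stop("empty sample", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- min(length(a), length(b)) <= exact_max && !ties
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE, alternative = "two.sided")
  )
  list(U = unname(wt$statistic), p_value = wt$p.value)
}

# Lea-Coulson median-method equation: the expected median satisfies
# r/m - ln(m) = 1.24.
lea_coulson_root <- function(r_med) {
  f <- function(m) r_med / m - log(m) - 1.24
  lo <- 1e-8
  hi <- max(10, r_med * 10)
  while (f(hi) > 0) hi <- hi * 10
  uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Lea-Coulson (method of the median) mutation-rate estimate
#'
#' Solves `r_med / m - ln(m) = 1.24` for the expected mutations per culture
#' `m` from the median mutant count, and divides by the viable cells per
#' culture to obtain the rate. The 95% confidence interval is computed on
#' `ln(m)` with the Stewart-type dispersion `sigma = 1.225 * m^-0.315 /
#' sqrt(C)` and exponentiated back.
#'
#' When the median count is zero but some cultures carry mutants, the
#' zero-fraction (P0) estimator `m = -ln(P0)` is used and flagged. When all
#' cultures are zero, only an upper bound is reported: the largest `m`
#' consistent (at the 5% level) with observing no mutants in any of the `C`
#' cultures, `m_up = -ln(0.05) / C`.
#'
#' @param experiment A `fluctuation_experiment` tibble (columns `culture`,
#'   `mutant_count`; attribute `n_total_cells`), or a numeric vector of
#'   mutant counts.
#' @param n_total_cells Mean viable cells per culture (required when
#'   `experiment` is a bare vector).
#' @return Object of class `rate_estimate`: list with `rate`, `m_hat`,
#'   `ci95` (on the rate scale), `method`, `flagged`, `n_cultures`,
#'   `n_total_cells`, `median_count`.
#' @export
lea_coulson_rate <- function(experiment, n_total_cells = NULL) {
  if (inherits(experiment, "fluctuation_experiment") || is.data.frame(experiment)) {
    counts <- experiment$mutant_count
    n_total_cells <- n_total_cells %||% attr(experiment, "n_total_cells")
  } else {
    counts <- experiment
  }
  if (is.null(n_total_cells) || n_total_cells <= 0) {
    stop("n_total_cells must be supplied and positive", call. = FALSE)
  }
  if (length(counts) < 2) stop("need at least 2 cultures", call. = FALSE)
  C <- length(counts)
  r_med <- median(counts)

  if (all(counts == 0)) {
    m_up <- -log(0.05) / C
    est <- list(
      rate = NA_real_, m_hat = NA_real_,
      ci95 = c(0, m_up / n_total_cells),
      method = "all-zero upper bound", flagged = TRUE,
      n_cultures = C, n_total_cells = n_total_cells, median_count = r_med
    )
    return(structure(est, class = "rate_estimate"))
  }

  if (r_med < 1) {
    p0 <- mean(counts == 0)
    m_hat <- -log(p0)
    method <- "p0"
    flagged <- TRUE
  } else {
    m_hat <- lea_coulson_root(r_med)
    method <- "median"
    flagged <- FALSE
  }
  sigma <- 1.225 * m_hat^(-0.315) / sqrt(C)
  ci_m <- exp(log(m_hat) + c(-1.96, 1.96) * sigma)
  est <- list(
    rate = m_hat / n_total_cells, m_hat = m_hat,
    ci95 = ci_m / n_total_cells,
    method = method, flagged = flagged,
    n_cultures = C, n_total_cells = n_total_cells, median_count = r_med
  )
  structure(est, class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  if (is.na(x$rate)) {
    cat(sprintf(
      "<rate_estimate> all-zero cultures: rate < %.3g (95%% upper bound, C = %d)\n",
      x$ci95[2], x$n_cultures
    ))
  } else {
    cat(sprintf(
      "<rate_estimate> rate %.3g [%.3g, %.3g] (m = %.3g, %s method, C = %d)\n",
      x$rate, x$ci95[1], x$ci95[2], x$m_hat, x$method, x$n_cultures
    ))
  }
  invisible(x)
}

#' Tidy a rate estimate
#'
#' @param x A `rate_estimate`.
#' @param ... Unused.
#' @return One-row tibble with `estimate`, `m_hat`, `conf.low`,
#'   `conf.high`, `method`, `flagged`.
#' @export
#' @importFrom generics tidy
tidy.rate_estimate <- function(x, ...) {
  tibble(
    estimate = x$rate, m_hat = x$m_hat,
    conf.low = x$ci95[1], conf.high = x$ci95[2],
    method = x$method, flagged = x$flagged
  )
}

#' Glance at a rate estimate
#'
#' @param x A `rate_estimate`.
#' @param ... Unused.
#' @return One-row tibble with experiment-level summaries.
#' @export
#' @importFrom generics glance
glance.rate_estimate <- function(x, ...) {
  tibble(
    n_cultures = x$n_cultures, n_total_cells = x$n_total_cells,
    median_count = x$median_count, estimate = x$rate
  )
}
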