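#' Statistical comparison of eGFR equations
#'
#' Paired comparisons between equations on the same patients: Wilcoxon
#' signed-rank for median bias, McNemar for the Pxx accuracy and
#' correct-staging indicators, and a paired bootstrap for the IQR precision.
#' All p-values from one analysis run form a single family for
#' Benjamini-Hochberg adjustment unless configured otherwise.
#'
#' @name stat_tests
#' @keywords internal
NULL

#' Statistical-test configuration
#'
#' @param n_boot Bootstrap replicates (default 1000).
#' @param ci_level Confidence level for bootstrap intervals.
#' @param seed Integer seed governing all bootstrap draws in a run.
#' @param alpha Significance threshold applied to adjusted p-values.
#' @param bh_scope `"run"` treats every p-value of an analysis run as one
#'   Benjamini-Hochberg family; `"per_kpi"` adjusts within each KPI.
#' @return A list of class `stat_config`.
#' @export
stat_config <- function(n_boot = 1000L, ci_level = 0.95, seed = 1L,
                        alpha = 0.05, bh_scope = c("run", "per_kpi")) {
  stopifnot(n_boot >= 1, ci_level > 0 && ci_level < 1)
  structure(list(n_boot = as.integer(n_boot), ci_level = ci_level,
                 seed = as.integer(seed), alpha = alpha,
                 bh_scope = match.arg(bh_scope)), class = "stat_config")
}

# percentile interval whose endpoints are order statistics of the replicates
percentile_ci <- function(reps, level = 0.95) {
  reps <- reps[!is.na(reps)]
  alpha <- (1 - level) / 2
  unname(stats::quantile(reps, c(alpha, 1 - alpha), type = 1))
}

#' Percentile-bootstrap confidence interval
#'
#' Resamples patient rows (or vector elements) with replacement, keeping
#' paired columns together, and returns the percentile interval of the
#' replicate statistics. Reproducible under the configured seed.
#'
#' @param statistic Function of one resampled data set returning a scalar.
#' @param data A vector or data frame to resample.
#' @param config A [stat_config()].
#' @return Named numeric vector `c(lo, hi)` with the replicate vector in
#'   attribute `"replicates"`.
#' @export
bootstrap_ci <- function(statistic, data, config = stat_config()) {
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  if (n == 0L) stop("data must be non-empty", call. = FALSE)
  reps <- withr::with_seed(config$seed, {
    vapply(seq_len(config$n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      s <- if (is.data.frame(data)) data[i, , drop = FALSE] else data[i]
      as.numeric(statistic(s))
    }, numeric(1))
  })
  if (length(unique(reps)) == 1L) {
    warning("statistic is degenerate on all resamples; interval collapsed",
            call. = FALSE)
  }
  ci <- percentile_ci(reps, config$ci_level)
  structure(c(lo = ci[1L], hi = ci[2L]), replicates = reps)
}

#' Compare median bias of two equations (Wilcoxon signed-rank)
#'
#' Two-sided signed-rank test on the per-patient differences
#' `errors_a - errors_b`; zero differences are dropped (classic Wilcoxon
#' convention).
#'
#' @param errors_a,errors_b Paired per-patient errors (eGFR - mGFR) of the
#'   two equations on the same patients.
#' @return Two-sided p-value.
#' @export
compare_bias <- function(errors_a, errors_b) {
  stopifnot(length(errors_a) == length(errors_b))
  d <- errors_a - errors_b
  d <- d[!is.na(d)]
  if (all(d == 0)) {
    warning("all paired differences are zero; no signal", call. = FALSE)
    return(1)
  }
  suppressWarnings(stats::wilcox.test(d, exact = FALSE, correct = TRUE))$p.value
}

#' Compare paired proportions (McNemar)
#'
#' For the within-tolerance indicators of two equations on the same
#' patients. Uses the continuity-corrected chi-square statistic
#' `(|b - c| - 1)^2 / (b + c)` when there are at least 25 discordant pairs,
#' and the exact binomial test otherwise.
#'
#' @param within_a,within_b Paired logical indicators (e.g. within 30% of
#'   mGFR) for equations A and B.
#' @return Two-sided p-value.
#' @export
compare_accuracy <- function(within_a, within_b) {
  stopifnot(length(within_a) == length(within_b),
            is.logical(within_a), is.logical(within_b))
  ok <- !is.na(within_a) & !is.na(within_b)
  b <- sum(within_a[ok] & !within_b[ok])
  cc <- sum(!within_a[ok] & within_b[ok])
  if (b + cc == 0L) {
    warning("no discordant pairs; McNemar test has no information",
            call. = FALSE)
    return(1)
  }
  if (b + cc < 25L) {
    stats::binom.test(b, b + cc, p = 0.5)$p.value
  } else {
    stats::pchisq((abs(b - cc) - 1)^2 / (b + cc), df = 1, lower.tail = FALSE)
  }
}

#' Compare correct-staging indicators of two equations
#'
#' [compare_accuracy()] applied to the correct/incorrect CKD-staging
#' indicators.
#'
#' @param correct_a,correct_b Paired logical correct-staging indicators.
#' @return Two-sided p-value.
#' @export
compare_staging <- function(correct_a, correct_b) {
  compare_accuracy(correct_a, correct_b)
}

#' Compare IQR precision of two equations (paired bootstrap)
#'
#' Bootstraps patients jointly for both equations and computes the
#' difference of IQRs on each resample; the two-sided p-value is
#' `2 * min(P(delta <= 0), P(delta >= 0))`, capped at 1 and floored at
#' `1 / (n_boot + 1)` so a bootstrap p-value is never exactly zero.
#'
#' @param errors_a,errors_b Paired per-patient errors of the two equations.
#' @param config A [stat_config()].
#' @return Two-sided bootstrap p-value.
#' @export
compare_iqr <- function(errors_a, errors_b, config = stat_config()) {
  stopifnot(length(errors_a) == length(errors_b))
  ok <- !is.na(errors_a) & !is.na(errors_b)
  a <- errors_a[ok]
  b <- errors_b[ok]
  n <- length(a)
  if (n < 4L) stop("compare_iqr needs at least 4 paired errors", call. = FALSE)
  delta <- withr::with_seed(config$seed, {
    vapply(seq_len(config$n_boot), function(r) {
      i <- sample.int(n, n, replace = TRUE)
      stats::IQR(a[i], type = 7) - stats::IQR(b[i], type = 7)
    }, numeric(1))
  })
  p <- 2 * min(mean(delta <= 0), mean(delta >= 0))
  min(max(p, 1 / (config$n_boot + 1)), 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment producing q-values, returned in
#' the input order.
#'
#' @param pvals Vector of p-values in \[0, 1\].
#' @return Vector of q-values, componentwise >= the p-values.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Pairwise comparison grid
#'
#' Runs every pairwise comparison of the given equations, per KPI and
#' subgroup: Wilcoxon signed-rank for bias, paired bootstrap for IQR,
#' McNemar for each Pxx accuracy and for correct CKD staging; then adjusts
#' the whole family by Benjamini-Hochberg.
#'
#' @param cohort Cohort tibble with `mgfr` and `egfr_<name>` columns.
#' @param equations Character vector of equation names (>= 2).
#' @param subgroups Named list of logical row masks; default one `overall`
#'   group.
#' @param kpi_cfg A [kpi_config()].
#' @param config A [stat_config()].
#' @param reference Optional single equation name: only pairs involving it
#'   are tested (the typical new-equation-versus-incumbents design).
#' @return Tibble: `subgroup`, `kpi`, `equation_a`, `equation_b`, `p`, `q`,
#'   `significant`.
#' @export
pairwise_comparisons <- function(cohort, equations,
                                 subgroups = NULL,
                                 kpi_cfg = kpi_config(),
                                 config = stat_config(),
                                 reference = NULL) {
  stopifnot(length(equations) >= 2L)
  cohort <- tibble::as_tibble(cohort)
  if (is.null(subgroups)) {
    subgroups <- list(overall = rep(TRUE, nrow(cohort)))
  }
  pairs <- utils::combn(equations, 2L, simplify = FALSE)
  if (!is.null(reference)) {
    pairs <- Filter(function(pr) reference %in% pr, pairs)
  }
  stage_tab <- kdigo_stages()
  rows <- list()
  for (sg in names(subgroups)) {
    mask <- subgroups[[sg]] & !is.na(cohort$mgfr)
    slice <- cohort[mask, , drop = FALSE]
    if (nrow(slice) < 4L) next
    mg <- slice$mgfr
    stage_m <- ckd_stage(mg, stage_tab)
    for (pr in pairs) {
      ea <- slice[[paste0("egfr_", pr[1L])]]
      eb <- slice[[paste0("egfr_", pr[2L])]]
      add <- function(kpi, p) {
        rows[[length(rows) + 1L]] <<- tibble::tibble(
          subgroup = sg, kpi = kpi, equation_a = pr[1L],
          equation_b = pr[2L], p = p)
      }
      suppressWarnings({
        add("bias", compare_bias(ea - mg, eb - mg))
        add("precision_iqr", compare_iqr(ea - mg, eb - mg, config))
        for (tol in kpi_cfg$tolerances) {
          add(paste0("P", round(100 * tol)),
              compare_accuracy(abs(ea - mg) <= tol * mg,
                               abs(eb - mg) <= tol * mg))
        }
        add("staging",
            compare_staging(ckd_stage(ea, stage_tab) == stage_m,
                            ckd_stage(eb, stage_tab) == stage_m))
      })
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) return(out)
  if (config$bh_scope == "per_kpi") {
    out$q <- stats::ave(out$p, out$kpi, FUN = bh_adjust)
  } else {
    out$q <- bh_adjust(out$p)
  }
  out$significant <- out$q < config$alpha
  out
}
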