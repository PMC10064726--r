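#' Key performance indicators for eGFR equations
#'
#' The KPIs follow standard GFR method-comparison practice: *bias* is the
#' median of the per-patient differences eGFR - mGFR (positive values mean
#' GFR is overestimated); *precision* is the interquartile range of those
#' differences; *Pxx accuracy* is the percentage of patients whose eGFR lies
#' within xx% of mGFR (boundary inclusive). Confidence intervals are
#' percentile-bootstrap over patient rows, keeping all equations' errors
#' paired within a resample.
#'
#' @name kpi_eval
#' @keywords internal
NULL

#' KPI configuration
#'
#' @param tolerances Relative accuracy tolerances (fractions) defining the
#'   Pxx KPIs; defaults to P10/P15/P20/P30.
#' @param ci_level Bootstrap confidence level.
#' @param n_boot Number of bootstrap resamples.
#' @return A list of class `kpi_config`.
#' @export
kpi_config <- function(tolerances = c(0.10, 0.15, 0.20, 0.30),
                       ci_level = 0.95, n_boot = 1000L) {
  stopifnot(all(tolerances > 0 & tolerances < 1),
            ci_level > 0 && ci_level < 1, n_boot >= 1)
  structure(list(tolerances = sort(tolerances), ci_level = ci_level,
                 n_boot = as.integer(n_boot)), class = "kpi_config")
}

#' Median bias of estimation errors
#'
#' @param errors Per-patient differences eGFR - mGFR, ml/min/1.73 m2.
#' @return The median difference; positive = overestimation of GFR.
#' @export
median_bias <- function(errors) {
  if (length(errors) == 0L || all(is.na(errors))) {
    stop("median_bias needs at least one error", call. = FALSE)
  }
  stats::median(errors, na.rm = TRUE)
}

#' Precision as interquartile range of errors
#'
#' Uses linear-interpolation quantiles (R type 7).
#'
#' @param errors Per-patient differences eGFR - mGFR.
#' @return Q3 - Q1 of the differences, ml/min/1.73 m2.
#' @export
precision_iqr <- function(errors) {
  errors <- errors[!is.na(errors)]
  if (length(errors) < 2L) {
    stop("precision_iqr needs at least two errors", call. = FALSE)
  }
  stats::IQR(errors, type = 7)
}

#' Pxx accuracy
#'
#' @param egfr,mgfr Paired GFR vectors (mgfr > 0).
#' @param tol Relative tolerance as a fraction (0.30 for P30).
#' @return Percentage of patients with `|eGFR - mGFR| <= tol * mGFR`
#'   (boundary inclusive), in 0--100.
#' @export
p_accuracy <- function(egfr, mgfr, tol) {
  if (length(egfr) != length(mgfr)) {
    stop("egfr and mgfr must be paired vectors of equal length",
         call. = FALSE)
  }
  if (any(mgfr <= 0, na.rm = TRUE)) {
    stop("mgfr must be strictly positive", call. = FALSE)
  }
  100 * mean(abs(egfr - mgfr) <= tol * mgfr, na.rm = TRUE)
}

#' Between-stratum disparity of a KPI
#'
#' The difference in a KPI between preserved (PLF) and reduced (RLF) liver
#' function, computed as PLF - RLF. A creatinine equation that overestimates
#' GFR in reduced liver function therefore shows a *negative* bias
#' disparity.
#'
#' @param kpi_plf,kpi_rlf KPI values in the preserved and reduced strata.
#' @return `kpi_plf - kpi_rlf`.
#' @export
kpi_disparity <- function(kpi_plf, kpi_rlf) {
  kpi_plf - kpi_rlf
}

kpi_names <- function(config) {
  c("bias", "precision_iqr", paste0("P", round(100 * config$tolerances)))
}

# point values of every KPI for one equation on one cohort slice
kpi_points <- function(egfr, mgfr, config) {
  e <- egfr - mgfr
  iqr <- if (sum(!is.na(e)) >= 2L) precision_iqr(e) else NA_real_
  vals <- c(median_bias(e), iqr,
            vapply(config$tolerances, function(tol) {
              p_accuracy(egfr, mgfr, tol)
            }, numeric(1)))
  names(vals) <- kpi_names(config)
  vals
}

#' Evaluate a KPI grid over equations and subgroups
#'
#' Computes every KPI for every equation in every subgroup, with
#' percentile-bootstrap confidence intervals. The resampling unit is the
#' patient row within the subgroup, so all equations' errors stay paired
#' inside each resample; one seed makes the whole grid reproducible.
#' Subgroups with fewer than two members are flagged and reported without a
#' confidence interval.
#'
#' @param cohort Cohort tibble with `mgfr` and either precomputed
#'   `egfr_<name>` columns or the biomarker columns needed by
#'   [egfr_panel()].
#' @param equations Character vector of equation names.
#' @param subgroups Named list of logical row masks; defaults to a single
#'   `overall` subgroup.
#' @param config A [kpi_config()].
#' @param seed Integer seed for the bootstrap.
#' @return A tibble with columns `equation`, `subgroup`, `kpi`, `value`,
#'   `ci_lo`, `ci_hi`, `n`.
#' @export
evaluate_equations <- function(cohort, equations = ckdepi_equation_names(),
                               subgroups = NULL, config = kpi_config(),
                               seed = 1L) {
  cohort <- tibble::as_tibble(cohort)
  cols <- paste0("egfr_", equations)
  if (!all(cols %in% names(cohort))) {
    cohort <- egfr_panel(cohort, equations)
  }
  if (is.null(subgroups)) {
    subgroups <- list(overall = rep(TRUE, nrow(cohort)))
  }
  out <- withr::with_seed(seed, {
    dplyr::bind_rows(lapply(names(subgroups), function(sg) {
      mask <- subgroups[[sg]] & !is.na(cohort$mgfr)
      slice <- cohort[mask, , drop = FALSE]
      n <- nrow(slice)
      if (n == 0L) return(NULL)
      if (n < 2L) {
        warning("subgroup '", sg, "' has fewer than 2 members; ",
                "confidence intervals omitted", call. = FALSE)
        reps <- NULL
      } else {
        idx <- matrix(sample.int(n, n * config$n_boot, replace = TRUE),
                      nrow = config$n_boot)
        reps <- lapply(stats::setNames(equations, equations), function(eq) {
          eg <- slice[[paste0("egfr_", eq)]]
          mg <- slice$mgfr
          t(apply(idx, 1L, function(i) kpi_points(eg[i], mg[i], config)))
        })
      }
      alpha <- 1 - config$ci_level
      dplyr::bind_rows(lapply(equations, function(eq) {
        eg <- slice[[paste0("egfr_", eq)]]
        pts <- kpi_points(eg, slice$mgfr, config)
        ci <- if (is.null(reps)) {
          matrix(NA_real_, nrow = length(pts), ncol = 2L)
        } else {
          t(apply(reps[[eq]], 2L, percentile_ci, level = config$ci_level))
        }
        tibble::tibble(equation = eq, subgroup = sg, kpi = names(pts),
                       value = unname(pts), ci_lo = ci[, 1L],
                       ci_hi = ci[, 2L], n = n)
      }))
    }))
  })
  out
}
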