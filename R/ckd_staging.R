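#' KDIGO CKD staging and concordance with measured GFR
#'
#' GFR categories G1 (>= 90) through G5 (< 15 ml/min/1.73 m2), with lower
#' boundaries inclusive (a GFR of exactly 60 is G2). Staging concordance
#' compares the stage an equation assigns with the stage measured GFR
#' assigns: assigning a *milder* stage than mGFR underestimates CKD severity
#' (i.e. overestimates GFR), a *more severe* stage overestimates it.
#'
#' @name ckd_staging
#' @keywords internal
NULL

#' KDIGO GFR stage table
#'
#' @param path Optional path to an alternate JSON stage table; the shipped
#'   default holds the G1--G5 KDIGO categories. Stages must be ordered from
#'   best to worst kidney function with strictly decreasing inclusive lower
#'   bounds partitioning (0, Inf).
#' @return A tibble with columns `stage` and `lower`, classed `stage_table`.
#' @export
kdigo_stages <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "kdigo_stages.json",
                        package = "gfrbench", mustWork = TRUE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  tab <- tibble::as_tibble(raw$stages)
  stopifnot(all(c("stage", "lower") %in% names(tab)),
            !is.unsorted(rev(tab$lower), strictly = TRUE),
            tab$lower[nrow(tab)] == 0)
  class(tab) <- c("stage_table", class(tab))
  tab
}

#' Assign a CKD stage to a GFR value
#'
#' @param gfr GFR in ml/min/1.73 m2, strictly positive; applied to unrounded
#'   values.
#' @param table A [kdigo_stages()] stage table.
#' @return Factor of stage labels, levels ordered best to worst.
#' @examples
#' ckd_stage(c(95, 60, 59.9, 14.9))   # G1 G2 G3a G5
#' @export
ckd_stage <- function(gfr, table = kdigo_stages()) {
  if (any(gfr <= 0, na.rm = TRUE)) {
    stop("gfr must be strictly positive", call. = FALSE)
  }
  # stages are ordered by decreasing lower bound; first bound not exceeding
  # the value wins, so lower boundaries are inclusive
  idx <- vapply(gfr, function(g) {
    if (is.na(g)) NA_integer_ else which(g >= table$lower)[1L]
  }, integer(1))
  factor(table$stage[idx], levels = table$stage)
}

#' Classify staging concordance for one patient
#'
#' @param stage_egfr,stage_mgfr Stage labels (factors from [ckd_stage()] or
#'   characters matching the stage table).
#' @param table Stage table defining the severity order.
#' @return Factor in `correct` / `under_severity` / `over_severity`:
#'   `under_severity` means the equation assigned a milder CKD stage than
#'   mGFR (GFR overestimated), `over_severity` a more severe stage.
#' @export
concordance_class <- function(stage_egfr, stage_mgfr, table = kdigo_stages()) {
  ie <- stage_index(stage_egfr, table)
  im <- stage_index(stage_mgfr, table)
  out <- dplyr::case_when(
    ie == im ~ "correct",
    ie < im ~ "under_severity",
    TRUE ~ "over_severity"
  )
  factor(out, levels = c("correct", "under_severity", "over_severity"))
}

stage_index <- function(stage, table) {
  idx <- match(as.character(stage), table$stage)
  if (anyNA(idx)) stop("invalid stage label", call. = FALSE)
  idx
}

#' Summarize staging concordance over a cohort
#'
#' @param stage_egfr,stage_mgfr Paired stage labels, or alternatively pass
#'   `classes`, a precomputed vector from [concordance_class()].
#' @param classes Optional precomputed concordance classes.
#' @param table Stage table.
#' @return A one-row tibble: `n_total`, `n_correct`, `n_under_severity`,
#'   `n_over_severity` and the corresponding percentages of `n_total`
#'   (`pct_correct`, `pct_under_severity`, `pct_over_severity`, unrounded).
#' @export
concordance_summary <- function(stage_egfr = NULL, stage_mgfr = NULL,
                                classes = NULL, table = kdigo_stages()) {
  if (is.null(classes)) {
    classes <- concordance_class(stage_egfr, stage_mgfr, table)
  }
  classes <- classes[!is.na(classes)]
  if (length(classes) == 0L) {
    stop("no staging pairs to summarize", call. = FALSE)
  }
  n <- length(classes)
  n_c <- sum(classes == "correct")
  n_u <- sum(classes == "under_severity")
  n_o <- sum(classes == "over_severity")
  tibble::tibble(
    n_total = n,
    n_correct = n_c,
    n_under_severity = n_u,
    n_over_severity = n_o,
    pct_correct = 100 * n_c / n,
    pct_under_severity = 100 * n_u / n,
    pct_over_severity = 100 * n_o / n
  )
}
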