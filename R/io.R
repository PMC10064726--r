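#' Cohort schema, input/output and the evaluation pipeline
#'
#' The canonical cohort file is a comma-separated, UTF-8, header-first CSV
#' with "." as decimal separator and empty cells for missing values; parsing
#' is locale-independent. [run_evaluation()] ties the whole pipeline
#' together: equation panel, Child-Pugh scoring and stratification, MELD,
#' KPI grid with bootstrap intervals, staging concordance and pairwise
#' statistical comparisons.
#'
#' @name cli_io
#' @keywords internal
NULL

#' Canonical cohort column schema
#'
#' @return A tibble with columns `column`, `type` and `required` describing
#'   the cohort CSV schema.
#' @export
cohort_schema <- function() {
  tibble::tribble(
    ~column, ~type, ~required,
    "id", "character", TRUE,
    "center", "character", FALSE,
    "age", "numeric", TRUE,
    "sex", "factor:female|male", TRUE,
    "race_black", "logical", TRUE,
    "scr_mgdl", "numeric", TRUE,
    "scys_mgl", "numeric", FALSE,
    "mgfr", "numeric", TRUE,
    "bilirubin_mgdl", "numeric", FALSE,
    "albumin_gdl", "numeric", FALSE,
    "inr", "numeric", FALSE,
    "ascites", "factor:absent|present", FALSE,
    "encephalopathy", "factor:absent|present", FALSE
  )
}

#' Read a cohort CSV
#'
#' Validates the header against [cohort_schema()] and each row's values;
#' rows failing validation are dropped with a message (or abort the read
#' with `strict = TRUE`). Missing values are empty cells.
#'
#' @param path Path to the cohort CSV.
#' @param strict Upgrade row-level problems to errors.
#' @return A validated cohort tibble; the per-row validation report is in
#'   attribute `"validation"`.
#' @export
read_cohort <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), fileEncoding = "UTF-8")
  schema <- cohort_schema()
  missing_cols <- setdiff(schema$column[schema$required], names(raw))
  if (length(missing_cols) > 0L) {
    stop("cohort file ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- tibble::as_tibble(raw)
  if ("race_black" %in% names(raw)) {
    raw$race_black <- as.logical(raw$race_black)
  }
  problems <- character(0)
  bad <- rep(FALSE, nrow(raw))
  check <- function(cond, msg) {
    cond[is.na(cond)] <- FALSE
    if (any(cond)) {
      problems <<- c(problems,
                     paste0("row ", which(cond), ": ", msg))
      bad <<- bad | cond
    }
  }
  check(raw$scr_mgdl <= 0, "non-positive creatinine")
  check(raw$mgfr <= 0, "non-positive mGFR")
  check(!raw$sex %in% c("female", "male"), "invalid sex")
  if ("scys_mgl" %in% names(raw)) check(raw$scys_mgl <= 0,
                                        "non-positive cystatin C")
  if ("ascites" %in% names(raw)) {
    check(!is.na(raw$ascites) & !raw$ascites %in% c("absent", "present"),
          "invalid ascites code")
  }
  if (length(problems) > 0L) {
    if (strict) {
      stop("cohort validation failed:\n  ",
           paste(problems, collapse = "\n  "), call. = FALSE)
    }
    message("dropping ", sum(bad), " invalid row(s):\n  ",
            paste(problems, collapse = "\n  "))
  }
  out <- raw[!bad, , drop = FALSE]
  attr(out, "validation") <- problems
  out
}

#' Write a cohort CSV
#'
#' @param cohort Cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' Score a cohort for liver function
#'
#' Adds Child-Pugh points/class/stratum and (where the inputs exist) the
#' MELD score and dysfunction flags to the cohort.
#'
#' @param cohort Cohort tibble following [cohort_schema()].
#' @param thresholds A [cp_thresholds()] table.
#' @return The cohort with scoring columns appended.
#' @export
score_cohort <- function(cohort, thresholds = cp_thresholds()) {
  cohort <- tibble::as_tibble(cohort)
  need <- function(col) {
    if (col %in% names(cohort)) cohort[[col]] else rep(NA, nrow(cohort))
  }
  cp <- child_pugh(need("bilirubin_mgdl"), need("albumin_gdl"), need("inr"),
                   need("ascites"), need("encephalopathy"),
                   thresholds = thresholds)
  cohort$cp_total <- cp$cp_total
  cohort$cp_class <- cp$cp_class
  cohort$n_missing_cp <- cp$n_missing
  cohort$stratum <- cp$stratum
  if (all(c("bilirubin_mgdl", "inr") %in% names(cohort))) {
    cohort$meld <- suppressWarnings(
      meld(cohort$scr_mgdl, cohort$bilirubin_mgdl, cohort$inr))
    flags <- dysfunction_flags(cohort$meld, cohort$mgfr)
    cohort$hepatic_dysfunction <- flags$hepatic
    cohort$renal_dysfunction <- flags$renal
  }
  cohort
}

# the analysis subgroups: overall plus liver-function strata, MELD, ascites
# and renal-function splits (unscorable records stay in 'overall' only)
build_subgroups <- function(cohort) {
  sg <- list(overall = rep(TRUE, nrow(cohort)))
  if ("stratum" %in% names(cohort)) {
    sg$preserved <- cohort$stratum == "preserved"
    sg$reduced <- cohort$stratum == "reduced"
  }
  if ("meld" %in% names(cohort)) {
    sg$meld_le15 <- !is.na(cohort$meld) & cohort$meld <= 15
    sg$meld_gt15 <- !is.na(cohort$meld) & cohort$meld > 15
  }
  if ("ascites" %in% names(cohort)) {
    sg$ascites_absent <- !is.na(cohort$ascites) & cohort$ascites == "absent"
    sg$ascites_present <- !is.na(cohort$ascites) & cohort$ascites == "present"
  }
  sg$mgfr_ge60 <- cohort$mgfr >= 60
  sg$mgfr_lt60 <- cohort$mgfr < 60
  sg
}

# bootstrap CI for the preserved-minus-reduced KPI disparity: the two strata
# are resampled independently within each replicate
disparity_grid <- function(cohort, equations, config, seed) {
  plf <- cohort[cohort$stratum == "preserved", , drop = FALSE]
  rlf <- cohort[cohort$stratum == "reduced", , drop = FALSE]
  if (nrow(plf) < 2L || nrow(rlf) < 2L) return(NULL)
  withr::with_seed(seed, {
    dplyr::bind_rows(lapply(equations, function(eq) {
      ep <- plf[[paste0("egfr_", eq)]]
      er <- rlf[[paste0("egfr_", eq)]]
      pt <- kpi_points(ep, plf$mgfr, config) - kpi_points(er, rlf$mgfr, config)
      reps <- vapply(seq_len(config$n_boot), function(b) {
        ip <- sample.int(nrow(plf), replace = TRUE)
        ir <- sample.int(nrow(rlf), replace = TRUE)
        kpi_points(ep[ip], plf$mgfr[ip], config) -
          kpi_points(er[ir], rlf$mgfr[ir], config)
      }, numeric(length(pt)))
      ci <- t(apply(reps, 1L, percentile_ci, level = config$ci_level))
      tibble::tibble(equation = eq, subgroup = "disparity_plf_minus_rlf",
                     kpi = names(pt), value = unname(pt),
                     ci_lo = ci[, 1L], ci_hi = ci[, 2L],
                     n = nrow(plf) + nrow(rlf))
    }))
  })
}

#' Run the full evaluation pipeline
#'
#' Scores the cohort (Child-Pugh, stratum, MELD), evaluates the equation
#' panel, computes the KPI grid with bootstrap intervals for the overall
#' cohort and every subgroup, the preserved-minus-reduced KPI disparity,
#' per-subgroup staging concordance, and the pairwise statistical
#' comparisons with Benjamini-Hochberg q-values. Records with an unscorable
#' Child-Pugh score are excluded from liver-function strata but retained in
#' the overall analyses.
#'
#' @param cohort Cohort tibble following [cohort_schema()].
#' @param equations Character vector of equation names.
#' @param kpi_cfg A [kpi_config()].
#' @param stat_cfg A [stat_config()]; its seed governs every bootstrap.
#' @param reference Optional equation name restricting pairwise tests to
#'   pairs involving it.
#' @param outdir Optional directory: writes `kpi_grid.csv`,
#'   `concordance.csv`, `comparisons.csv`, `kpi_table.txt` and
#'   `metadata.json` (no timestamps, so equal-seed runs are byte-identical).
#' @return A list with elements `cohort` (scored, with eGFR columns),
#'   `kpi_grid`, `concordance`, `comparisons`, `metadata`.
#' @export
run_evaluation <- function(cohort,
                           equations = ckdepi_equation_names(),
                           kpi_cfg = kpi_config(),
                           stat_cfg = stat_config(),
                           reference = NULL,
                           outdir = NULL) {
  cohort <- score_cohort(tibble::as_tibble(cohort))
  cohort <- egfr_panel(cohort, equations)
  subgroups <- build_subgroups(cohort)

  kpi_grid <- suppressWarnings(
    evaluate_equations(cohort, equations, subgroups, kpi_cfg,
                       seed = stat_cfg$seed))
  disp <- disparity_grid(cohort, equations, kpi_cfg, seed = stat_cfg$seed)
  kpi_grid <- dplyr::bind_rows(kpi_grid, disp)

  stage_tab <- kdigo_stages()
  stage_m <- ckd_stage(cohort$mgfr, stage_tab)
  concordance <- dplyr::bind_rows(lapply(names(subgroups), function(sg) {
    mask <- subgroups[[sg]]
    if (sum(mask) == 0L) return(NULL)
    dplyr::bind_rows(lapply(equations, function(eq) {
      se <- ckd_stage(cohort[[paste0("egfr_", eq)]][mask], stage_tab)
      dplyr::bind_cols(
        tibble::tibble(subgroup = sg, equation = eq),
        concordance_summary(se, stage_m[mask], table = stage_tab))
    }))
  }))

  comparisons <- if (length(equations) >= 2L) {
    pairwise_comparisons(
      cohort, equations,
      subgroups = subgroups[intersect(c("overall", "preserved", "reduced"),
                                      names(subgroups))],
      kpi_cfg = kpi_cfg, config = stat_cfg, reference = reference)
  } else {
    tibble::tibble(subgroup = character(0), kpi = character(0),
                   equation_a = character(0), equation_b = character(0),
                   p = numeric(0), q = numeric(0), significant = logical(0))
  }

  metadata <- list(
    package = "gfrbench",
    version = as.character(utils::packageVersion("gfrbench")),
    seed = stat_cfg$seed,
    n_boot = stat_cfg$n_boot,
    ci_level = stat_cfg$ci_level,
    bh_scope = stat_cfg$bh_scope,
    bootstrap_method = "percentile",
    wilcoxon_zeros = "dropped",
    equations = equations,
    n_overall = nrow(cohort),
    n_preserved = sum(cohort$stratum == "preserved"),
    n_reduced = sum(cohort$stratum == "reduced"),
    n_unscored = sum(cohort$stratum == "unscored"),
    config_hash = config_hash(list(equations, kpi_cfg, stat_cfg))
  )

  result <- list(cohort = cohort, kpi_grid = kpi_grid,
                 concordance = concordance, comparisons = comparisons,
                 metadata = metadata)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(kpi_grid, file.path(outdir, "kpi_grid.csv"),
                     row.names = FALSE)
    utils::write.csv(concordance, file.path(outdir, "concordance.csv"),
                     row.names = FALSE)
    utils::write.csv(comparisons, file.path(outdir, "comparisons.csv"),
                     row.names = FALSE)
    writeLines(format_kpi_table(kpi_grid),
               file.path(outdir, "kpi_table.txt"))
    jsonlite::write_json(metadata, file.path(outdir, "metadata.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  result
}

# structural hash of the run configuration (polynomial rolling hash over the
# deparsed config); identifies runs, not cryptographic
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Render a KPI grid as an aligned text table
#'
#' One row per equation x subgroup, KPIs as `value [lo-hi]` with values
#' rounded to one decimal for presentation (internal values are never
#' rounded).
#'
#' @param kpi_grid Tibble from [evaluate_equations()] / [run_evaluation()].
#' @return Character vector of table lines.
#' @export
format_kpi_table <- function(kpi_grid) {
  fmt <- function(v, lo, hi) {
    ifelse(is.na(lo), sprintf("%.1f", v),
           sprintf("%.1f [%.1f-%.1f]", v, lo, hi))
  }
  kpi_grid$cell <- fmt(kpi_grid$value, kpi_grid$ci_lo, kpi_grid$ci_hi)
  wide <- stats::reshape(
    as.data.frame(kpi_grid[, c("subgroup", "equation", "kpi", "cell")]),
    idvar = c("subgroup", "equation"), timevar = "kpi",
    direction = "wide")
  names(wide) <- sub("^cell\\.", "", names(wide))
  utils::capture.output(print(wide, row.names = FALSE))
}
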