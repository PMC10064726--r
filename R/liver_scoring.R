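#' Child-Pugh and MELD liver scoring
#'
#' Child-Pugh scoring as harmonized for retrospective multicenter cohorts:
#' ascites and hepatic encephalopathy are binary (1 point absent, 2 points
#' present -- severity grades pooled, so 3 points are never awarded for these
#' two components); laboratory components (bilirubin, albumin, INR) score
#' 1-3 against an editable threshold table. Exactly one missing component is
#' tolerated and scores 1 point; records missing two or more components are
#' unscorable and are excluded from liver-function strata while remaining in
#' the overall analyses.
#'
#' @name liver_scoring
#' @keywords internal
NULL

#' Child-Pugh laboratory threshold table
#'
#' Default thresholds: bilirubin <2 / 2-3 / >3 mg/dL, albumin >3.5 / 2.8-3.5 /
#' <2.8 g/dL, INR <1.7 / 1.7-2.3 / >2.3 scoring 1/2/3 points; boundary values
#' score the middle category.
#'
#' @param path Optional path to an alternate JSON threshold table with the
#'   same schema as the shipped default.
#' @return A list of class `cp_thresholds`.
#' @export
cp_thresholds <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cp_thresholds.json",
                        package = "gfrbench", mustWork = TRUE)
  }
  tab <- jsonlite::read_json(path, simplifyVector = FALSE)
  stopifnot(identical(as.integer(tab$schema_version), 1L),
            all(c("bilirubin", "albumin", "inr") %in% names(tab$components)))
  structure(tab, class = "cp_thresholds")
}

# 1/2/3 points for one lab value; NA passes through
score_lab <- function(x, comp) {
  lo <- comp$cut_low
  hi <- comp$cut_high
  if (identical(comp$direction, "higher_worse")) {
    ifelse(is.na(x), NA_integer_,
           ifelse(x < lo, 1L, ifelse(x <= hi, 2L, 3L)))
  } else {
    ifelse(is.na(x), NA_integer_,
           ifelse(x > hi, 1L, ifelse(x >= lo, 2L, 3L)))
  }
}

# "absent"/"present"/NA (or logical) -> 1/2/NA points
score_flag <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), NA_integer_, 1L + x))
  x <- tolower(as.character(x))
  x[x %in% c("", "na", "missing")] <- NA
  ok <- is.na(x) | x %in% c("absent", "present")
  if (!all(ok)) {
    stop("ascites/encephalopathy must be 'absent', 'present' or missing",
         call. = FALSE)
  }
  ifelse(is.na(x), NA_integer_, ifelse(x == "present", 2L, 1L))
}

#' Compute harmonized Child-Pugh scores
#'
#' Vectorised over patients. A single missing component (lab or flag alike)
#' is imputed at 1 point; with two or more missing components the record is
#' unscorable (`cp_class = "unscorable"`, `stratum = "unscored"`).
#'
#' @param bilirubin Total bilirubin, mg/dL (NA allowed).
#' @param albumin Serum albumin, g/dL (NA allowed).
#' @param inr International normalized ratio (NA allowed).
#' @param ascites,encephalopathy `"absent"`/`"present"`/NA, or logical.
#' @param thresholds A [cp_thresholds()] table.
#' @return A tibble with per-component points (`pts_bilirubin`,
#'   `pts_albumin`, `pts_inr`, `pts_ascites`, `pts_encephalopathy`),
#'   `n_missing`, `cp_total`, `cp_class` (`A`/`B`/`C`/`unscorable`) and
#'   `stratum` (`preserved`/`reduced`/`unscored`).
#' @examples
#' child_pugh(1.0, 4.0, 1.0, "absent", "absent")   # total 5, class A
#' @export
child_pugh <- function(bilirubin, albumin, inr, ascites, encephalopathy,
                       thresholds = cp_thresholds()) {
  labs <- list(bilirubin = bilirubin, albumin = albumin, inr = inr)
  for (nm in names(labs)) {
    if (any(labs[[nm]] <= 0, na.rm = TRUE)) {
      stop(nm, " must be strictly positive", call. = FALSE)
    }
  }
  n <- max(lengths(labs), length(ascites), length(encephalopathy))
  pts <- tibble::tibble(
    pts_bilirubin = rep_len(score_lab(bilirubin, thresholds$components$bilirubin), n),
    pts_albumin   = rep_len(score_lab(albumin, thresholds$components$albumin), n),
    pts_inr       = rep_len(score_lab(inr, thresholds$components$inr), n),
    pts_ascites   = rep_len(score_flag(ascites), n),
    pts_encephalopathy = rep_len(score_flag(encephalopathy), n)
  )
  pmat <- as.matrix(pts)
  n_missing <- rowSums(is.na(pmat))
  # one missing component scores 1 point; >= 2 missing is unscorable
  imputed <- pmat
  imputed[is.na(imputed)] <- 1L
  total <- as.integer(rowSums(imputed))
  scorable <- n_missing <= 1L
  total[!scorable] <- NA_integer_
  cp_class <- dplyr::case_when(
    !scorable ~ "unscorable",
    total <= 6L ~ "A",
    total <= 9L ~ "B",
    TRUE ~ "C"
  )
  asc_flag <- rep_len(score_flag(ascites), n) == 2L
  pts$n_missing <- as.integer(n_missing)
  pts$cp_total <- total
  pts$cp_class <- cp_class
  pts$stratum <- stratify(cp_class, asc_flag)
  pts
}

#' Liver-function stratification
#'
#' Preserved liver function is Child-Pugh class A without ascites; reduced
#' liver function is class A with ascites, or class B or C regardless of
#' ascites; unscorable records are `"unscored"`.
#'
#' @param cp_class Character vector in `A`/`B`/`C`/`unscorable`.
#' @param ascites Logical (present), or `"absent"`/`"present"`/NA.
#' @return Character vector in `preserved`/`reduced`/`unscored`.
#' @export
stratify <- function(cp_class, ascites) {
  if (!is.logical(ascites)) ascites <- score_flag(ascites) == 2L
  stopifnot(all(cp_class %in% c("A", "B", "C", "unscorable")))
  dplyr::case_when(
    cp_class == "unscorable" ~ "unscored",
    cp_class == "A" & !is.na(ascites) & ascites ~ "reduced",
    cp_class == "A" ~ "preserved",
    TRUE ~ "reduced"
  )
}

#' MELD score
#'
#' `9.57 ln(creatinine) + 3.78 ln(bilirubin) + 11.2 ln(INR) + 6.43` with the
#' UNOS clamping conventions: each input floored at 1.0, creatinine capped at
#' 4.0 mg/dL, and creatinine set to 4.0 for patients on dialysis. Returned
#' unrounded; set `round_classic = TRUE` for the classical integer score.
#'
#' @param creatinine Serum creatinine, mg/dL.
#' @param bilirubin Total bilirubin, mg/dL.
#' @param inr International normalized ratio.
#' @param dialysis Logical; at least two dialysis sessions in the prior week.
#' @param round_classic Round to the nearest integer (presentation option).
#' @return Numeric MELD scores; NA where any input is NA.
#' @export
meld <- function(creatinine, bilirubin, inr, dialysis = FALSE,
                 round_classic = FALSE) {
  for (v in list(creatinine, bilirubin, inr)) {
    if (any(v <= 0, na.rm = TRUE)) {
      stop("MELD inputs must be strictly positive", call. = FALSE)
    }
  }
  n <- max(length(creatinine), length(bilirubin), length(inr),
           length(dialysis))
  creatinine <- rep_len(as.numeric(creatinine), n)
  dialysis <- rep_len(as.logical(dialysis), n)
  creatinine[!is.na(dialysis) & dialysis] <- 4.0
  cr <- pmin(pmax(creatinine, 1.0), 4.0)
  bi <- pmax(rep_len(as.numeric(bilirubin), n), 1.0)
  ir <- pmax(rep_len(as.numeric(inr), n), 1.0)
  out <- 9.57 * log(cr) + 3.78 * log(bi) + 11.2 * log(ir) + 6.43
  if (round_classic) round(out) else out
}

#' Hepatic and renal dysfunction flags
#'
#' Strict thresholds: hepatic dysfunction is MELD > 15, renal dysfunction is
#' mGFR < 60 ml/min/1.73 m2 (boundary values are *not* dysfunctional).
#'
#' @param meld_score Numeric MELD scores.
#' @param mgfr Measured GFR, ml/min/1.73 m2.
#' @return A tibble with logical columns `hepatic` and `renal`.
#' @export
dysfunction_flags <- function(meld_score, mgfr) {
  n <- max(length(meld_score), length(mgfr))
  tibble::tibble(
    hepatic = rep_len(meld_score, n) > 15,
    renal = rep_len(mgfr, n) < 60
  )
}
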