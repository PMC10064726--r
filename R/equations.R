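#' GFR-estimating equations
#'
#' The CKD-EPI equations are piecewise power laws in the serum biomarkers:
#' each marker term is `min(x / kappa, 1)^a * max(x / kappa, 1)^b`, i.e. a
#' two-slope spline (on the log scale) with a knot at `kappa`; the product of
#' the marker terms is scaled by a constant, an exponential age decay
#' (`age_base^age`), a sex factor, and -- for the pre-2021 equations -- a
#' race factor. `gfrbench` ships the four CKD-EPI coefficient sets as
#' versioned JSON data files and evaluates any equation of this family, built
#' in or user supplied, through a single code path.
#'
#' @name equations
#' @keywords internal
NULL

#' Built-in equation names
#'
#' @return Character vector of the names accepted by [egfr_equation()]:
#'   the 2009 creatinine equation (`ckdepi_2009_cr`), the 2012
#'   creatinine--cystatin C equation (`ckdepi_2012_crcys`), their 2021
#'   race-free refits, and a clearly labelled synthetic multimarker stand-in
#'   (`multimarker_synthetic`) demonstrating the pluggable-coefficient slot.
#' @export
egfr_equation_names <- function() {
  c("ckdepi_2009_cr", "ckdepi_2021_cr",
    "ckdepi_2012_crcys", "ckdepi_2021_crcys",
    "multimarker_synthetic")
}

#' The four CKD-EPI equations evaluated by default
#' @return Character vector of equation names.
#' @export
ckdepi_equation_names <- function() {
  c("ckdepi_2009_cr", "ckdepi_2021_cr",
    "ckdepi_2012_crcys", "ckdepi_2021_crcys")
}

#' Load an eGFR equation specification
#'
#' Built-in equations are loaded from the JSON coefficient files shipped
#' under `inst/extdata/equations/`; any other path is read as a user-supplied
#' coefficient file with the same schema (see [read_equation_spec()]).
#'
#' @param name One of [egfr_equation_names()], or a path to a coefficient
#'   JSON file.
#' @return An object of class `egfr_spec`.
#' @examples
#' spec <- egfr_equation("ckdepi_2021_cr")
#' egfr(spec, scr = 1.0, age = 60, sex = "male")
#' @export
egfr_equation <- function(name) {
  if (inherits(name, "egfr_spec")) return(name)
  stopifnot(is.character(name), length(name) == 1L)
  if (name %in% egfr_equation_names()) {
    path <- system.file("extdata", "equations", paste0(name, ".json"),
                        package = "gfrbench", mustWork = TRUE)
  } else if (file.exists(name)) {
    path <- name
  } else {
    stop("unknown equation '", name, "'; expected one of ",
         paste(egfr_equation_names(), collapse = ", "),
         " or a path to a coefficient JSON file", call. = FALSE)
  }
  read_equation_spec(path)
}

#' Read and validate an equation coefficient file
#'
#' Coefficient files are JSON documents with a `schema_version` field, a
#' positive `constant`, a list of marker `terms` (each with `marker`, `knot`,
#' `min_exponent`, `max_exponent`; knots and exponents may be scalars or
#' `{"female": .., "male": ..}` objects), an `age_base` in (0, 1], a
#' `female_factor` and an optional `black_factor` (defaults to 1, i.e. a
#' race-free equation).
#'
#' @param path Path to a JSON coefficient file.
#' @return An `egfr_spec` object.
#' @export
read_equation_spec <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = FALSE)
  validate_equation_spec(spec, where = path)
}

#' @rdname read_equation_spec
#' @param spec A list with the fields described above (an already-parsed
#'   coefficient document).
#' @param where Label used in error messages.
#' @export
validate_equation_spec <- function(spec, where = "coefficient list") {
  required <- c("schema_version", "name", "constant", "terms",
                "age_base", "female_factor")
  missing <- setdiff(required, names(spec))
  if (length(missing) > 0L) {
    stop("invalid equation coefficients in ", where,
         ": missing field(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!identical(as.integer(spec$schema_version), 1L)) {
    stop("unsupported equation schema_version in ", where, call. = FALSE)
  }
  if (!is.numeric(spec$constant) || spec$constant <= 0) {
    stop("equation constant must be > 0 in ", where, call. = FALSE)
  }
  if (!is.numeric(spec$age_base) || spec$age_base <= 0 || spec$age_base > 1) {
    stop("age_base must lie in (0, 1] in ", where, call. = FALSE)
  }
  if (length(spec$terms) == 0L) {
    stop("invalid equation coefficients in ", where,
         ": 'terms' must contain at least one marker term", call. = FALSE)
  }
  spec$terms <- lapply(spec$terms, function(term) {
    tmiss <- setdiff(c("marker", "knot", "min_exponent", "max_exponent"),
                     names(term))
    if (length(tmiss) > 0L) {
      stop("invalid marker term in ", where, ": missing ",
           paste(tmiss, collapse = ", "), call. = FALSE)
    }
    for (f in c("knot", "min_exponent", "max_exponent")) {
      term[[f]] <- as_by_sex(term[[f]], f, where)
    }
    if (any(term$knot <= 0)) {
      stop("marker knots must be > 0 in ", where, call. = FALSE)
    }
    term
  })
  if (is.null(spec$black_factor)) spec$black_factor <- 1.0
  spec$markers <- vapply(spec$terms, `[[`, character(1), "marker")
  structure(spec, class = "egfr_spec")
}

# normalise scalar / {"female","male"} coefficient to a named length-2 vector
as_by_sex <- function(x, field, where) {
  if (is.list(x)) {
    if (!all(c("female", "male") %in% names(x))) {
      stop("by-sex field '", field, "' needs both 'female' and 'male' in ",
           where, call. = FALSE)
    }
    c(female = as.numeric(x$female), male = as.numeric(x$male))
  } else if (is.numeric(x) && length(x) == 1L) {
    c(female = x, male = x)
  } else {
    stop("field '", field, "' must be a scalar or a {female, male} object in ",
         where, call. = FALSE)
  }
}

#' @export
print.egfr_spec <- function(x, ...) {
  cat("<egfr_spec> ", x$name,
      if (!is.null(x$label)) paste0(" [", x$label, "]"), "\n", sep = "")
  cat("  constant ", x$constant, ", markers: ",
      paste(x$markers, collapse = ", "), "\n", sep = "")
  if (!is.null(x$note)) cat("  note: ", substr(x$note, 1, 70), "...\n", sep = "")
  invisible(x)
}

#' Evaluate an eGFR equation
#'
#' Computes estimated GFR in ml/min/1.73 m2 of body-surface area for one or
#' more patients. All arguments are vectorised and recycled to a common
#' length. Units are fixed: creatinine in mg/dL, cystatin C in mg/L; no unit
#' auto-detection is attempted.
#'
#' @param spec An `egfr_spec` (see [egfr_equation()]) or an equation name.
#' @param scr Serum creatinine, mg/dL (> 0).
#' @param age Age in years; values outside 18--120 trigger a warning (the
#'   equations were developed in adults).
#' @param sex `"female"` or `"male"`.
#' @param scys Serum cystatin C, mg/L; required when the equation has a
#'   cystatin term.
#' @param race_black Logical, self-declared Black race; only multiplies
#'   through the `black_factor` of race-aware equations (1 for the race-free
#'   refits).
#' @param markers Named list of additional marker vectors (e.g.
#'   `myo_inositol`, `valine`) for multimarker equations.
#' @return Numeric vector of eGFR values, unrounded.
#' @export
egfr <- function(spec, scr, age, sex, scys = NULL, race_black = FALSE,
                 markers = list()) {
  spec <- egfr_equation(spec)
  sex <- match_sex(sex)
  n <- max(length(scr), length(age), length(sex), length(race_black),
           length(scys))
  scr <- rep_len(as.numeric(scr), n)
  age <- rep_len(as.numeric(age), n)
  sex <- rep_len(sex, n)
  race_black <- rep_len(as.logical(race_black), n)
  if (!is.null(scys)) scys <- rep_len(as.numeric(scys), n)

  marker_values <- c(list(scr = scr, scys = scys), markers)
  for (m in spec$markers) {
    v <- marker_values[[m]]
    if (is.null(v)) {
      stop("equation '", spec$name, "' requires marker '", m, "'",
           call. = FALSE)
    }
    v <- rep_len(as.numeric(v), n)
    if (anyNA(v)) {
      warning("marker '", m, "' missing for ", sum(is.na(v)),
              " record(s); returning NA eGFR there", call. = FALSE)
    }
    if (any(v <= 0, na.rm = TRUE)) {
      stop("marker '", m, "' must be strictly positive", call. = FALSE)
    }
    marker_values[[m]] <- v
  }
  if (any(age <= 0)) stop("age must be positive", call. = FALSE)
  if (any(age < 18 | age > 120)) {
    warning("age outside 18-120 years: adult eGFR equations extrapolate",
            call. = FALSE)
  }

  out <- rep_len(spec$constant, n)
  for (term in spec$terms) {
    x <- marker_values[[term$marker]]
    kappa <- unname(term$knot[sex])
    a <- unname(term$min_exponent[sex])
    b <- unname(term$max_exponent[sex])
    r <- x / kappa
    out <- out * pmin(r, 1)^a * pmax(r, 1)^b
  }
  out <- out * spec$age_base^age
  out <- out * ifelse(sex == "female", spec$female_factor, 1)
  out <- out * ifelse(race_black, spec$black_factor, 1)
  out
}

match_sex <- function(sex) {
  if (is.factor(sex)) sex <- as.character(sex)
  sex <- tolower(as.character(sex))
  ok <- sex %in% c("female", "male")
  if (!all(ok)) stop("sex must be 'female' or 'male'", call. = FALSE)
  sex
}

#' Evaluate a panel of eGFR equations over a cohort
#'
#' Adds one `egfr_<name>` column per equation to the cohort table. Cohort
#' columns follow the canonical schema (see [cohort_schema()]): `scr_mgdl`,
#' `scys_mgl`, `age`, `sex`, `race_black`, plus any extra marker columns a
#' custom equation needs.
#'
#' @param cohort A data frame following [cohort_schema()].
#' @param equations Character vector of equation names or list of
#'   `egfr_spec` objects; defaults to the four CKD-EPI equations.
#' @return The cohort with the eGFR columns appended (a tibble).
#' @export
egfr_panel <- function(cohort, equations = ckdepi_equation_names()) {
  cohort <- tibble::as_tibble(cohort)
  specs <- lapply(equations, egfr_equation)
  extra <- setdiff(unique(unlist(lapply(specs, `[[`, "markers"))),
                   c("scr", "scys"))
  markers <- lapply(extra, function(m) {
    if (!m %in% names(cohort)) {
      stop("cohort lacks marker column '", m, "'", call. = FALSE)
    }
    cohort[[m]]
  })
  names(markers) <- extra
  for (spec in specs) {
    cohort[[paste0("egfr_", spec$name)]] <- egfr(
      spec,
      scr = cohort$scr_mgdl, age = cohort$age, sex = cohort$sex,
      scys = if ("scys_mgl" %in% names(cohort)) cohort$scys_mgl,
      race_black = cohort$race_black, markers = markers
    )
  }
  cohort
}
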