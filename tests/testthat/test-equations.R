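test_that("creatinine at the knot reduces the equation to its demographic part", {
  # both piecewise creatinine terms equal 1 at scr = kappa
  expect_equal(egfr("ckdepi_2021_cr", scr = 0.9, age = 60, sex = "male"),
               142 * 0.9938^60)
  expect_equal(egfr("ckdepi_2021_cr", scr = 0.7, age = 45, sex = "female"),
               142 * 0.9938^45 * 1.012)
})

test_that("race flag acts as a pure multiplicative factor", {
  base <- egfr("ckdepi_2009_cr", 1.1, 50, "male", race_black = FALSE)
  black <- egfr("ckdepi_2009_cr", 1.1, 50, "male", race_black = TRUE)
  expect_equal(black / base, 1.159)
  # race-free refit is insensitive to the flag
  expect_equal(egfr("ckdepi_2021_cr", 1.1, 50, "male", race_black = TRUE),
               egfr("ckdepi_2021_cr", 1.1, 50, "male", race_black = FALSE))
})

test_that("reference patient reproduces frozen oracle values", {
  # scr 1.36 mg/dL, scys 1.60 mg/L, age 58, female, non-black; expected
  # values computed once with the independently transcribed closed forms
  expect_equal(egfr("ckdepi_2009_cr", 1.36, 58, "female"),
               42.7856657002, tolerance = 1e-9)
  expect_equal(egfr("ckdepi_2021_cr", 1.36, 58, "female"),
               45.1524556386, tolerance = 1e-9)
  expect_equal(egfr("ckdepi_2012_crcys", 1.36, 58, "female", scys = 1.60),
               40.0876815699, tolerance = 1e-9)
  expect_equal(egfr("ckdepi_2021_crcys", 1.36, 58, "female", scys = 1.60),
               42.1131194660, tolerance = 1e-9)
})

test_that("all four equations match the independent oracle on a grid", {
  grid <- oracle_grid()
  expect_gte(nrow(grid), 100)
  for (eq in ckdepi_equation_names()) {
    got <- egfr(eq, scr = grid$scr, age = grid$age,
                sex = ifelse(grid$female, "female", "male"),
                scys = grid$scys, race_black = grid$black)
    want <- vapply(seq_len(nrow(grid)), function(i) {
      oracle_panel(grid$scr[i], grid$scys[i], grid$age[i],
                   grid$female[i], grid$black[i])[[eq]]
    }, numeric(1))
    expect_equal(got, want, tolerance = 1e-6, info = eq)
    expect_true(all(got > 0 & is.finite(got)))
  }
})

test_that("eGFR is strictly decreasing in creatinine, cystatin C and age", {
  set.seed(41)
  for (rep in 1:25) {
    scr <- runif(1, 0.4, 4)
    scys <- runif(1, 0.5, 3)
    age <- runif(1, 20, 90)
    sex <- sample(c("female", "male"), 1)
    for (eq in ckdepi_equation_names()) {
      f <- function(s, c2 = scys, a = age) {
        egfr(eq, s, a, sex, scys = c2)
      }
      expect_lt(f(scr * 1.05), f(scr))
      if (grepl("crcys", eq)) {
        expect_lt(f(scr, c2 = scys * 1.05), f(scr))
      }
      expect_lt(f(scr, a = age + 1), f(scr))
    }
  }
})

test_that("equations are continuous at the piecewise knots", {
  eps <- 1e-9
  for (eq in ckdepi_equation_names()) {
    for (sex in c("female", "male")) {
      kappa <- if (sex == "female") 0.7 else 0.9
      at <- egfr(eq, kappa, 50, sex, scys = 0.8)
      below <- egfr(eq, kappa * (1 - eps), 50, sex, scys = 0.8)
      above <- egfr(eq, kappa * (1 + eps), 50, sex, scys = 0.8)
      expect_equal(below / at, 1, tolerance = 1e-8)
      expect_equal(above / at, 1, tolerance = 1e-8)
      # cystatin knot
      at <- egfr(eq, 1.2, 50, sex, scys = 0.8)
      below <- egfr(eq, 1.2, 50, sex, scys = 0.8 * (1 - eps))
      above <- egfr(eq, 1.2, 50, sex, scys = 0.8 * (1 + eps))
      expect_equal(below / at, 1, tolerance = 1e-8)
      expect_equal(above / at, 1, tolerance = 1e-8)
    }
  }
})

test_that("a user coefficient file encoding a built-in spec is bit-identical", {
  src <- system.file("extdata", "equations", "ckdepi_2021_cr.json",
                     package = "gfrbench")
  tmp <- withr::local_tempfile(fileext = ".json")
  doc <- jsonlite::read_json(src)
  doc$name <- "user_copy_2021_cr"
  jsonlite::write_json(doc, tmp, auto_unbox = TRUE, digits = NA)
  user <- read_equation_spec(tmp)
  grid <- oracle_grid()
  expect_identical(
    egfr(user, grid$scr, grid$age, ifelse(grid$female, "female", "male")),
    egfr("ckdepi_2021_cr", grid$scr, grid$age,
         ifelse(grid$female, "female", "male")))
})

test_that("incomplete or empty coefficient files fail validation with a listing", {
  tmp <- withr::local_tempfile(fileext = ".json")
  writeLines("{}", tmp)
  expect_error(read_equation_spec(tmp), "missing field")
  writeLines('{"schema_version": 1, "name": "x", "constant": 100,
              "age_base": 0.99, "female_factor": 1,
              "terms": [{"marker": "scr", "knot": 0.9}]}', tmp)
  expect_error(read_equation_spec(tmp), "min_exponent")
})

test_that("the synthetic multimarker stand-in yields a finite positive smoke value", {
  v <- egfr("multimarker_synthetic", scr = 1.2, age = 60, sex = "male",
            scys = 1.4, markers = list(myo_inositol = 35, valine = 220))
  expect_equal(v, 61.9332862393, tolerance = 1e-9)  # frozen from first run
  expect_true(is.finite(v) && v > 0)
})

test_that("domain errors and warnings fire as contracted", {
  expect_error(egfr("ckdepi_2009_cr", -1, 50, "male"), "positive")
  expect_error(egfr("ckdepi_2012_crcys", 1.0, 50, "male"), "scys")
  expect_error(egfr("ckdepi_2009_cr", 1.0, 50, "other"), "sex")
  expect_warning(egfr("ckdepi_2009_cr", 1.0, 14, "male"), "18-120")
})
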