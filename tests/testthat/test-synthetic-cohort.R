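test_that("generation is deterministic under a fixed seed", {
  p <- cohort_params(n = 120, seed = 42)
  c1 <- generate_cohort(p)
  c2 <- generate_cohort(p)
  attr(c1, "params") <- attr(c2, "params") <- NULL
  expect_identical(c1, c2)
  expect_false(identical(c1, {
    c3 <- generate_cohort(cohort_params(n = 120, seed = 43))
    attr(c3, "params") <- NULL
    c3
  }))
})

test_that("generated records round-trip through Child-Pugh scoring", {
  co <- generate_cohort(cohort_params(n = 400, seed = 5))
  sc <- score_cohort(co)
  expect_identical(sc$stratum, co$stratum)
  expect_true(all(sc$cp_class %in% c("A", "B", "C")))
  # preserved records are class A without ascites by construction
  expect_true(all(sc$ascites[sc$stratum == "preserved"] == "absent"))
  expect_true(all(sc$cp_class[sc$stratum == "preserved"] == "A"))
})

test_that("the deterministic fixture reproduces the pinned composition", {
  fx <- table1_fixture()
  expect_equal(nrow(fx), 203)
  sc <- score_cohort(fx)
  expect_identical(sc$stratum, fx$stratum)
  # (class, ascites) joint counts
  expect_equal(sum(sc$cp_class == "A" & sc$ascites == "absent"), 143)
  expect_equal(sum(sc$cp_class == "A" & sc$ascites == "present"), 6)
  expect_equal(sum(sc$cp_class == "B"), 45)
  expect_equal(sum(sc$cp_class == "C"), 9)
  expect_equal(sum(sc$ascites == "present"), 42)
  # stratification: 143 preserved / 60 reduced
  expect_equal(sum(sc$stratum == "preserved"), 143)
  expect_equal(sum(sc$stratum == "reduced"), 60)
  # ascites prevalence and class B share within reduced liver function
  red <- sc[sc$stratum == "reduced", ]
  expect_equal(sum(red$ascites == "present"), 42)
  expect_equal(sum(red$cp_class == "B"), 45)
  # schema-valid and rerun-identical
  expect_true(all(cohort_schema()$column %in% names(fx)))
  expect_identical(fx, table1_fixture())
})

test_that("zero creatinine deficit leaves the creatinine equation unbiased across strata", {
  co <- generate_cohort(cohort_params(n = 500, creatinine_deficit_delta = 0,
                                      seed = 101))
  co <- egfr_panel(co, "ckdepi_2021_cr")
  e <- co$egfr_ckdepi_2021_cr - co$mgfr
  disp <- median_bias(e[co$stratum == "preserved"]) -
    median_bias(e[co$stratum == "reduced"])
  expect_lt(abs(disp), 2)
})

test_that("a positive creatinine deficit biases creatinine equations upward in reduced liver function", {
  co <- generate_cohort(cohort_params(n = 500, creatinine_deficit_delta = 0.25,
                                      seed = 102))
  co <- egfr_panel(co)
  red <- co$stratum == "reduced"
  bias_cr_red <- median_bias(co$egfr_ckdepi_2021_cr[red] - co$mgfr[red])
  bias_cr_pre <- median_bias(co$egfr_ckdepi_2021_cr[!red] - co$mgfr[!red])
  expect_gt(bias_cr_red, 0)
  expect_gt(bias_cr_red, bias_cr_pre)
  disp_cr <- kpi_disparity(bias_cr_pre, bias_cr_red)
  expect_lt(disp_cr, 0)
  # the combined creatinine-cystatin equation moves much less
  bias_cc_red <- median_bias(co$egfr_ckdepi_2021_crcys[red] - co$mgfr[red])
  bias_cc_pre <- median_bias(co$egfr_ckdepi_2021_crcys[!red] - co$mgfr[!red])
  expect_lt(abs(kpi_disparity(bias_cc_pre, bias_cc_red)), abs(disp_cr))
})

test_that("the creatinine deficit is recoverable from generated cohorts", {
  for (delta in c(0, 0.25)) {
    co <- generate_cohort(cohort_params(n = 2000,
                                        creatinine_deficit_delta = delta,
                                        seed = 300 + round(100 * delta)))
    expect_lt(abs(recover_delta(co) - delta), 0.05)
  }
  # invariant to relabeling patient ids
  co <- generate_cohort(cohort_params(n = 500, seed = 9))
  shuffled <- co
  shuffled$id <- rev(shuffled$id)
  expect_equal(recover_delta(shuffled), recover_delta(co))
  expect_error(recover_delta(co[co$stratum == "preserved", ]), "both")
})

test_that("cystatin C is stratum-independent conditional on mGFR", {
  rejections <- 0L
  for (i in 1:10) {
    co <- generate_cohort(cohort_params(n = 1000, seed = 500 + i))
    female <- co$sex == "female"
    resid <- log(co$scys_mgl) -
      log(gfrbench:::scys_baseline(co$mgfr, co$age, female))
    p <- wilcox.test(resid[co$stratum == "preserved"],
                     resid[co$stratum == "reduced"])$p.value
    rejections <- rejections + (p < 0.01)
  }
  expect_lte(rejections, 1L)
})

test_that("increasing the deficit strictly lowers reduced-stratum creatinine at fixed seed", {
  mk <- function(delta) {
    generate_cohort(cohort_params(n = 400, creatinine_deficit_delta = delta,
                                  seed = 77))
  }
  deltas <- c(0, 0.1, 0.2, 0.4)
  means <- vapply(deltas, function(d) {
    co <- mk(d)
    mean(co$scr_mgdl[co$stratum == "reduced"])
  }, numeric(1))
  expect_true(all(diff(means) < 0))
  # preserved stratum untouched by the knob
  expect_identical(mk(0)$scr_mgdl[mk(0)$stratum == "preserved"],
                   mk(0.4)$scr_mgdl[mk(0.4)$stratum == "preserved"])
})
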