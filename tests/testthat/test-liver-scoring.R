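test_that("Child-Pugh worked examples score as expected", {
  # all-minimum case
  r <- child_pugh(1.0, 4.0, 1.0, "absent", "absent")
  expect_equal(r$cp_total, 5L)
  expect_equal(r$cp_class, "A")
  expect_equal(r$stratum, "preserved")

  # same labs with ascites: class A but reduced liver function
  r <- child_pugh(1.0, 4.0, 1.0, "present", "absent")
  expect_equal(r$cp_total, 6L)
  expect_equal(r$cp_class, "A")
  expect_equal(r$stratum, "reduced")

  # one missing parameter scores one point
  r <- child_pugh(1.0, 4.0, NA, "absent", "absent")
  expect_equal(r$n_missing, 1L)
  expect_equal(r$cp_total, 5L)
  expect_equal(r$cp_class, "A")

  # two missing parameters: unscorable, excluded from strata
  r <- child_pugh(NA, 4.0, NA, "absent", "absent")
  expect_equal(r$cp_class, "unscorable")
  expect_equal(r$stratum, "unscored")
  expect_true(is.na(r$cp_total))

  # hand-scored mid-range case: 2+2+2 labs + ascites 2 + HE 1 = 9, class B
  r <- child_pugh(2.5, 3.0, 1.9, "present", "absent")
  expect_equal(unname(unlist(r[1, 1:5])), c(2L, 2L, 2L, 2L, 1L))
  expect_equal(r$cp_total, 9L)
  expect_equal(r$cp_class, "B")
  expect_equal(r$stratum, "reduced")
})

test_that("boundary lab values score the middle category", {
  expect_equal(child_pugh(2.0, 4.0, 1.0, "absent", "absent")$pts_bilirubin, 2L)
  expect_equal(child_pugh(3.0, 4.0, 1.0, "absent", "absent")$pts_bilirubin, 2L)
  expect_equal(child_pugh(1.0, 3.5, 1.0, "absent", "absent")$pts_albumin, 2L)
  expect_equal(child_pugh(1.0, 2.8, 1.0, "absent", "absent")$pts_albumin, 2L)
  expect_equal(child_pugh(1.0, 4.0, 1.7, "absent", "absent")$pts_inr, 2L)
  expect_equal(child_pugh(1.0, 4.0, 2.3, "absent", "absent")$pts_inr, 2L)
})

test_that("component points and totals respect their ranges; ascites shifts class-A strata", {
  set.seed(7)
  bili <- runif(60, 0.3, 10)
  alb <- runif(60, 1.5, 5)
  inr <- runif(60, 0.8, 4)
  asc <- sample(c("absent", "present"), 60, replace = TRUE)
  he <- sample(c("absent", "present"), 60, replace = TRUE)
  r <- child_pugh(bili, alb, inr, asc, he)
  pts <- as.matrix(r[, 1:5])
  expect_true(all(pts >= 1 & pts <= 3))
  expect_true(all(r$cp_total >= 5 & r$cp_total <= 15))
  expect_equal(r$cp_total, as.integer(rowSums(pts)))
  # trichotomy: every record maps to exactly one stratum
  expect_true(all(r$stratum %in% c("preserved", "reduced", "unscored")))

  # adding ascites to a class-A record: +1 point, preserved -> reduced
  base <- child_pugh(bili, alb, inr, "absent", "absent")
  with_asc <- child_pugh(bili, alb, inr, "present", "absent")
  isA <- base$cp_class == "A"
  expect_equal(with_asc$cp_total[isA], base$cp_total[isA] + 1L)
  expect_true(all(base$stratum[isA] == "preserved"))
  expect_true(all(with_asc$stratum[isA] == "reduced"))
})

test_that("stratify implements the liver-function trichotomy", {
  expect_equal(stratify("A", "absent"), "preserved")
  expect_equal(stratify("A", "present"), "reduced")
  expect_equal(stratify("B", "absent"), "reduced")
  expect_equal(stratify("C", "absent"), "reduced")
  expect_equal(stratify("unscorable", "absent"), "unscored")
})

test_that("MELD clamps inputs and matches the frozen hand evaluation", {
  expect_equal(meld(1, 1, 1), 6.43)
  # sub-unity inputs all floored at 1
  expect_equal(meld(0.6, 0.8, 0.9), 6.43)
  # frozen value of 9.57 ln(1.2) + 3.78 ln(2) + 11.2 ln(1.5) + 6.43
  expect_equal(meld(1.2, 2.0, 1.5), 15.3361228518, tolerance = 1e-9)
  # creatinine cap and dialysis rule coincide
  expect_equal(meld(9, 2, 1.5), meld(4, 2, 1.5))
  expect_equal(meld(1.2, 2, 1.5, dialysis = TRUE), meld(4, 2, 1.5))
  expect_equal(meld(1.2, 2.0, 1.5, round_classic = TRUE), 15)
  expect_error(meld(-1, 1, 1), "positive")
})

test_that("MELD is monotone non-decreasing in each clamped input", {
  set.seed(11)
  for (i in 1:20) {
    cr <- runif(1, 0.5, 5)
    bi <- runif(1, 0.5, 10)
    ir <- runif(1, 0.8, 4)
    expect_gte(meld(cr * 1.2, bi, ir), meld(cr, bi, ir))
    expect_gte(meld(cr, bi * 1.2, ir), meld(cr, bi, ir))
    expect_gte(meld(cr, bi, ir * 1.2), meld(cr, bi, ir))
  }
})

test_that("dysfunction flags use strict inequalities", {
  f <- dysfunction_flags(c(15.0, 19.4), c(60.0, 59.9))
  expect_equal(f$hepatic, c(FALSE, TRUE))
  expect_equal(f$renal, c(FALSE, TRUE))
})
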