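# Independent oracles used across the suite. The eGFR oracles are scalar
# closed-form transcriptions of the published CKD-EPI coefficient tables,
# typed separately from the package's spec-driven evaluator (anti-typo
# defense for the shipped coefficient files).

oracle_2009_cr <- function(scr, age, female, black) {
  k <- if (female) 0.7 else 0.9
  a <- if (female) -0.329 else -0.411
  141 * min(scr / k, 1)^a * max(scr / k, 1)^-1.209 * 0.993^age *
    (if (female) 1.018 else 1) * (if (black) 1.159 else 1)
}

oracle_2021_cr <- function(scr, age, female) {
  k <- if (female) 0.7 else 0.9
  a <- if (female) -0.241 else -0.302
  142 * min(scr / k, 1)^a * max(scr / k, 1)^-1.200 * 0.9938^age *
    (if (female) 1.012 else 1)
}

oracle_2012_crcys <- function(scr, scys, age, female, black) {
  k <- if (female) 0.7 else 0.9
  a <- if (female) -0.248 else -0.207
  135 * min(scr / k, 1)^a * max(scr / k, 1)^-0.601 *
    min(scys / 0.8, 1)^-0.375 * max(scys / 0.8, 1)^-0.711 *
    0.995^age * (if (female) 0.969 else 1) * (if (black) 1.08 else 1)
}

oracle_2021_crcys <- function(scr, scys, age, female) {
  k <- if (female) 0.7 else 0.9
  a <- if (female) -0.219 else -0.144
  135 * min(scr / k, 1)^a * max(scr / k, 1)^-0.544 *
    min(scys / 0.8, 1)^-0.323 * max(scys / 0.8, 1)^-0.778 *
    0.9961^age * (if (female) 0.963 else 1)
}

# evaluate all four oracles on one input
oracle_panel <- function(scr, scys, age, female, black) {
  c(ckdepi_2009_cr = oracle_2009_cr(scr, age, female, black),
    ckdepi_2021_cr = oracle_2021_cr(scr, age, female),
    ckdepi_2012_crcys = oracle_2012_crcys(scr, scys, age, female, black),
    ckdepi_2021_crcys = oracle_2021_crcys(scr, scys, age, female))
}

# brute-force O(m^2) Benjamini-Hochberg from the step-up definition:
# q_(i) = min over j >= i of p_(j) * m / j, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(vapply(i:m, function(j) p[ord][j] * m / j, numeric(1))))
  }, numeric(1))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# grid of biomarker inputs covering both sides of every knot
oracle_grid <- function() {
  expand.grid(
    scr = c(0.4, 0.7, 0.8, 0.9, 1.1, 1.36, 2.2, 4.5),
    scys = c(0.5, 0.8, 1.1, 1.9, 3.0),
    age = c(22, 58, 81),
    female = c(TRUE, FALSE),
    black = c(TRUE, FALSE)
  )
}
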