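line_tbl <- function(...) {
  dplyr::bind_rows(...)
}

one_line <- function(pid, role, start, end, type) {
  tibble::tibble(patient_id = pid, line_role = role,
                 start_date = as.Date(start),
                 event_date = as.Date(end), event_type = type)
}

test_that("PFS converts day spans into 30.4375-day months", {
  l <- one_line("P1", "pre_mtb_last", "2020-01-01", "2020-03-02", "progression")
  pfs <- compute_pfs(l)
  expect_equal(pfs$pfs_months, 61 / 30.4375, tolerance = 1e-12)
  expect_equal(pfs$event, "progression")

  # death is PFS-defining
  d <- one_line("P2", "pre_mtb_last", "2020-01-01", "2020-02-01", "death")
  expect_equal(compute_pfs(d)$event, "death")

  # no event by cutoff: censored at the cutoff
  c1 <- one_line("P3", "recommended_first", "2020-01-01", NA, "censored")
  pfs3 <- compute_pfs(c1, cutoff_date = "2020-07-01")
  expect_equal(pfs3$pfs_months, 182 / 30.4375)
  expect_error(compute_pfs(c1), class = "cupcompass_input_error")

  bad <- one_line("P4", "pre_mtb_last", "2020-01-01", "2020-01-01", "progression")
  expect_error(compute_pfs(bad), class = "cupcompass_input_error")
})

test_that("PFS ratios follow the progression-on-prior rule and strict benefit cut", {
  pfs <- tibble::tibble(
    patient_id = c("P1", "P1", "P2", "P2", "P3", "P3", "P4"),
    line_role = c("pre_mtb_last", "recommended_first",
                  "pre_mtb_last", "recommended_first",
                  "pre_mtb_last", "recommended_first",
                  "recommended_first"),
    pfs_months = c(2, 5, 4, 4, 3, 9, 6),
    event = c("progression", "progression", "censored", "progression",
              "progression", "censored", "progression"))
  r <- pfs_ratio(pfs)
  r1 <- r[r$patient_id == "P1", ]
  expect_equal(r1$pfsr, 2.5)
  expect_true(r1$benefit)
  # prior line censored: ratio undefined, PFS2 retained
  r2 <- r[r$patient_id == "P2", ]
  expect_true(is.na(r2$pfsr))
  expect_equal(r2$pfs2, 4)
  expect_equal(r2$undefined_reason, "no_progression_on_prior")
  # no prior line at all
  r4 <- r[r$patient_id == "P4", ]
  expect_equal(r4$undefined_reason, "missing_prior")
  # exactly 1.3 is not benefit (strict >)
  border <- tibble::tibble(
    patient_id = c("B", "B"),
    line_role = c("pre_mtb_last", "recommended_first"),
    pfs_months = c(10, 13), event = c("progression", "progression"))
  expect_false(pfs_ratio(border)$benefit)
})

test_that("PFS ratios are scale invariant", {
  cl <- sim_clinical_cohort(tiny_config(seed = 9))
  pfs <- compute_pfs(cl$therapy_lines)
  r1 <- pfs_ratio(pfs)
  scaled <- dplyr::mutate(pfs, pfs_months = pfs_months * 7.3)
  r2 <- pfs_ratio(scaled)
  expect_equal(r1$pfsr, r2$pfsr, tolerance = 1e-12)
})

test_that("the modified ratio applies floor and cap, or nothing at all", {
  r <- tibble::tibble(patient_id = "P1", pfs1 = 1, pfs2 = 6, pfsr = 6,
                      benefit = TRUE, undefined_reason = NA_character_)
  expect_equal(modified_pfs_ratio(r)$mpfsr, 6)                 # empty rule
  expect_equal(modified_pfs_ratio(r, mpfsr_rule(pfs1_floor_months = 2))$mpfsr, 3)
  big <- tibble::tibble(patient_id = "P2", pfs1 = 1, pfs2 = 16.4, pfsr = 16.4,
                        benefit = TRUE, undefined_reason = NA_character_)
  expect_equal(modified_pfs_ratio(big, mpfsr_rule(ratio_cap = 12))$mpfsr, 12)
  und <- tibble::tibble(patient_id = "P3", pfs1 = NA_real_, pfs2 = 4,
                        pfsr = NA_real_, benefit = NA,
                        undefined_reason = "no_progression_on_prior")
  expect_true(is.na(modified_pfs_ratio(und, mpfsr_rule(2, 12))$mpfsr))
})

test_that("the product-limit estimator matches hand computation", {
  km <- km_estimate(c(1, 3), c(TRUE, TRUE))
  expect_equal(km$steps$surv, c(0.5, 0))
  expect_equal(km$median, 1)

  # all censored: flat curve, undefined median
  flat <- km_estimate(c(2, 4, 6), c(FALSE, FALSE, FALSE))
  expect_true(all(flat$steps$surv == 1))
  expect_true(is.na(flat$median))

  expect_error(km_estimate(c(0, 1), c(TRUE, TRUE)),
               class = "cupcompass_input_error")
  expect_error(km_estimate(numeric(), logical()),
               class = "cupcompass_input_error")
})

test_that("without censoring the KM curve equals the empirical survival function", {
  set.seed(21)
  t <- round(rexp(40, 0.3), 3)
  km <- km_estimate(t, rep(TRUE, 40))
  emp <- vapply(km$steps$time, function(u) mean(t > u), numeric(1))
  expect_equal(km$steps$surv, emp, tolerance = 1e-12)
})

test_that("log-rank is null on identical groups and symmetric in labels", {
  t <- c(1, 2, 3, 4, 5)
  ev <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  same <- logrank_test(c(t, t), c(ev, ev), rep(c("a", "b"), each = 5))
  expect_lt(same$statistic, 1e-10)
  expect_gt(same$p_value, 0.99)

  set.seed(2)
  t2 <- c(rexp(20, 0.2), rexp(20, 0.5))
  g <- rep(c("x", "y"), each = 20)
  l1 <- logrank_test(t2, rep(TRUE, 40), g)
  l2 <- logrank_test(t2, rep(TRUE, 40), rev(g))
  expect_equal(l1$statistic,
               logrank_test(t2, rep(TRUE, 40),
                            ifelse(g == "x", "y", "x"))$statistic)

  # no events anywhere: chi-square 0, p 1
  none <- logrank_test(t2, rep(FALSE, 40), g)
  expect_equal(none$statistic, 0)
  expect_equal(none$p_value, 1)
})

test_that("log-rank matches a by-hand observed-versus-expected table", {
  # group A events at 1, 2; group B events at 4, 5:
  # O_A = 2, E_A = 1/2 + 1/3 = 5/6, V = 1/4 + 2/9 = 17/36,
  # chi-square = (2 - 5/6)^2 / (17/36) = 49/17
  res <- logrank_test(c(1, 2, 4, 5), rep(TRUE, 4), c("A", "A", "B", "B"))
  expect_equal(res$statistic, 49 / 17, tolerance = 1e-10)
})

test_that("cohort summaries keep undefined-ratio patients in PFS2 only", {
  r <- tibble::tibble(
    patient_id = sprintf("P%d", 1:5),
    pfs1 = c(2, 4, NA, 3, 2.9),
    pfs2 = c(5, 2, 6, 9, 7.8),
    pfsr = c(2.5, 0.5, NA, 3, 7.8 / 2.9),
    benefit = c(TRUE, FALSE, NA, TRUE, TRUE),
    undefined_reason = c(NA, NA, "no_progression_on_prior", NA, NA))
  s <- cohort_summary(modified_pfs_ratio(r))
  expect_equal(s$n[s$measure == "pfsr"], 4)
  expect_equal(s$n[s$measure == "pfs2"], 5)
  expect_equal(s$n[s$measure == "pfs1"], 4)
  expect_equal(s$mean[s$measure == "benefit"], 0.75)
  expect_equal(s$max[s$measure == "benefit"], 3)

  one <- cohort_summary(tibble::tibble(
    patient_id = "P1", pfs1 = 2.9, pfs2 = 7.8, pfsr = 7.8 / 2.9,
    benefit = TRUE, undefined_reason = NA_character_))
  expect_equal(one$median[one$measure == "pfs1"], 2.9)
  expect_equal(one$median[one$measure == "pfs2"], 7.8)
  expect_equal(one$median[one$measure == "pfsr"], 7.8 / 2.9, tolerance = 1e-12)

  empty <- cohort_summary(tibble::tibble())
  expect_equal(nrow(empty), 0)
})
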