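test_that("trial_ledger validates structure and the death/recurrence rule", {
  ok <- data.frame(animal_id = "a1", group_id = 1, resection = "cold_knife",
                   treatment = "none", perioperative_death = FALSE,
                   recurrence = TRUE, time_to_event_days = 45)
  expect_s3_class(trial_ledger(ok), "trial_ledger")
  bad <- ok; bad$perioperative_death <- TRUE  # dead but recurrence recorded
  expect_error(trial_ledger(bad), class = "pdtbedkit_validation_error")
  bad2 <- ok; bad2$time_to_event_days <- 120
  expect_error(trial_ledger(bad2), class = "pdtbedkit_validation_error")
  bad3 <- ok[, -3]
  expect_error(trial_ledger(bad3), class = "pdtbedkit_validation_error")
})

test_that("summarize_groups applies the evaluable-denominator policy", {
  mk <- function(gid, resection, treatment, enrolled, deaths, recurrent) {
    data.frame(
      animal_id = sprintf("g%d_%d", gid, seq_len(enrolled)), group_id = gid,
      resection = resection, treatment = treatment,
      perioperative_death = seq_len(enrolled) <= deaths,
      recurrence = c(rep(NA, deaths), rep(TRUE, recurrent),
                     rep(FALSE, enrolled - deaths - recurrent)),
      time_to_event_days = NA_real_)
  }
  led <- trial_ledger(rbind(
    mk(10, "cold_knife", "none", 13, 1, 11),     # 11/12 = 91.7 -> 92
    mk(5, "laser_scalpel", "none", 11, 0, 0),    # 0/11 = 0
    mk(9, "cold_knife", "pdt_405", 11, 1, 7)))   # 7/10 = 70
  s <- summarize_groups(led)
  s10 <- s[s$group_id == 10, ]
  expect_equal(s10$n_evaluable, 12)
  expect_equal(s10$rate_percent, 100 * 11 / 12, tolerance = 1e-12)
  expect_equal(s10$rate_percent_reported, 92)
  s5 <- s[s$group_id == 5, ]
  expect_equal(s5$rate_percent, 0)
  expect_equal(s5$ci95_low, 0)
  s9 <- s[s$group_id == 9, ]
  expect_equal(s9$rate_percent, 70)
  expect_true(s9$ci95_low < 70 && s9$ci95_high > 70)
  # denominator audit
  expect_true(all(s$n_evaluable + s$n_perioperative_deaths == s$n_enrolled))
})

test_that("reported rates are round-half-up of exact rates", {
  expect_equal(pdtbedkit:::round_half_up(91.6667), 92)
  expect_equal(pdtbedkit:::round_half_up(45.4545), 45)
  expect_equal(pdtbedkit:::round_half_up(0.5), 1)  # half goes up, not to even
  expect_equal(pdtbedkit:::round_half_up(1.5), 2)
  expect_equal(pdtbedkit:::round_half_up(2.5), 3)
})

test_that("exact_binomial_ci matches the tail-inversion oracle", {
  expect_equal(unname(exact_binomial_ci(0, 11)[1]), 0)
  expect_equal(unname(exact_binomial_ci(11, 11)[2]), 1)
  for (case in list(c(7, 10), c(0, 11), c(11, 12), c(3, 10), c(5, 11),
                    c(1, 13), c(9, 10))) {
    k <- case[1]; n <- case[2]
    got <- unname(exact_binomial_ci(k, n))
    want <- cp_oracle(k, n)
    expect_equal(got, want, tolerance = 1e-8,
                 label = sprintf("CI for k=%d n=%d", k, n))
  }
  expect_error(exact_binomial_ci(5, 0), class = "pdtbedkit_validation_error")
  expect_error(exact_binomial_ci(-1, 5), class = "pdtbedkit_validation_error")
})

test_that("Clopper-Pearson coverage is conservative at p = 0.3, n = 10", {
  set.seed(2024)
  draws <- rbinom(2000, 10, 0.3)
  covered <- vapply(draws, function(k) {
    ci <- exact_binomial_ci(k, 10)
    ci[1] <= 0.3 && 0.3 <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.95)
})

test_that("fisher_exact agrees with the independent reference on a table grid", {
  tables <- list(c(1, 1, 1, 1), c(11, 1, 0, 11), c(5, 5, 2, 8),
                 c(3, 7, 6, 4), c(0, 10, 5, 5), c(2, 0, 1, 3),
                 c(7, 3, 11, 1), c(4, 6, 4, 6), c(9, 1, 2, 8),
                 c(1, 12, 3, 7))
  for (tb in tables) {
    got <- fisher_exact(tb[1], tb[2], tb[3], tb[4])
    ref <- stats::fisher.test(matrix(tb, 2, 2, byrow = TRUE))
    expect_equal(got$fisher_p_two_sided, ref$p.value, tolerance = 1e-9,
                 label = paste("p for table", paste(tb, collapse = ",")))
    if (is.finite(got$odds_ratio) && got$odds_ratio > 0)
      expect_equal(got$odds_ratio, unname(ref$estimate), tolerance = 1e-4,
                   label = paste("OR for table", paste(tb, collapse = ",")))
  }
})

test_that("fisher_exact symmetry, boundaries and validation", {
  expect_equal(fisher_exact(1, 1, 1, 1)$fisher_p_two_sided, 1)
  # row swap leaves the two-sided p unchanged
  a <- fisher_exact(9, 1, 2, 8); b <- fisher_exact(2, 8, 9, 1)
  expect_equal(a$fisher_p_two_sided, b$fisher_p_two_sided, tolerance = 1e-12)
  # zero margin cells flag the odds ratio as 0 / Inf
  expect_equal(fisher_exact(0, 10, 5, 5)$odds_ratio, 0)
  expect_true(is.infinite(fisher_exact(11, 1, 0, 11)$odds_ratio))
  expect_error(fisher_exact(0, 0, 0, 0), class = "pdtbedkit_validation_error")
  expect_error(fisher_exact(1.5, 1, 1, 1), class = "pdtbedkit_validation_error")
})

test_that("recurrence_report writes table, markdown and chart", {
  led <- generate_ledger(trial_gen_spec(), mode = "expected")
  s <- summarize_groups(led)
  out <- tempfile("report_")
  cmp <- list(fisher_exact(11, 1, 0, 11, group_a = "G10", group_b = "G5"))
  paths <- recurrence_report(s, cmp, out_dir = out)
  expect_true(file.exists(paths$csv))
  expect_true(file.exists(paths$markdown))
  expect_true(file.exists(paths$chart))
  md <- readLines(paths$markdown)
  expect_true(any(grepl("92%", md)))
  expect_true(any(grepl("G10 vs G5", md)))
  back <- read.csv(paths$csv)
  expect_equal(nrow(back), 10)
  unlink(out, recursive = TRUE)
})
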