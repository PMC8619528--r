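mk_ledger <- function(df) { class(df) <- c("survival_ledger", "data.frame"); df }

test_that("Kaplan-Meier matches the hand product oracle", {
  led <- mk_ledger(data.frame(group = 0, cage = "c1", day = c(1, 2),
                              n_at_risk = c(10, 8), deaths = c(2, 1),
                              censored = 0))
  km <- kaplan_meier(led)
  expect_equal(km$s_hat, c(1, 0.8, 0.8 * 7 / 8))

  none <- mk_ledger(data.frame(group = 0, cage = "c1", day = 1:5,
                               n_at_risk = 50, deaths = 0, censored = 0))
  expect_true(all(kaplan_meier(none)$s_hat == 1))

  all_die <- mk_ledger(data.frame(group = 0, cage = "c1", day = 1,
                                  n_at_risk = 20, deaths = 20, censored = 0))
  expect_equal(tail(kaplan_meier(all_die)$s_hat, 1), 0)

  bad <- data.frame(group = 0, cage = "c1", day = 1, n_at_risk = 5,
                    deaths = 6, censored = 0)
  expect_error(kaplan_meier(mk_ledger(bad)), "exceed n_at_risk")
})

test_that("KM agrees with the survival package on a censored cohort", {
  skip_if_not_installed("survival")
  cfg <- synth_config(seed = 17, doses_ppb = c(0, 0.1), cages_per_group = 2,
                      bees_per_cage = 60)
  led <- generate_survival(cfg)
  for (g in c(0, 0.1)) {
    sub <- led[led$group == g, ]
    km <- kaplan_meier(sub)
    subj <- ledger_to_subjects(sub)
    fit <- survival::survfit(survival::Surv(time, status) ~ 1, data = subj)
    s_ref <- summary(fit, times = km$day[km$day > 0])$surv
    expect_equal(km$s_hat[km$day > 0], s_ref, tolerance = 1e-12)
  }
})

test_that("without censoring KM equals the empirical survival function", {
  set.seed(23)
  deaths <- c(rmultinom(1, 60, rep(1 / 8, 8)))
  led <- mk_ledger(data.frame(group = 0, cage = "c1", day = 1:8,
                              n_at_risk = 100 - c(0, cumsum(deaths)[-8]),
                              deaths = deaths, censored = 0))
  km <- kaplan_meier(led)
  expect_equal(km$s_hat[-1], (100 - cumsum(deaths)) / 100, tolerance = 1e-12)
})

test_that("KM is invariant to splitting a day's deaths across cages", {
  one <- mk_ledger(data.frame(group = 0, cage = "c1", day = c(1, 2),
                              n_at_risk = c(40, 30), deaths = c(10, 6),
                              censored = 0))
  split2 <- mk_ledger(data.frame(group = 0, cage = c("a", "b", "a", "b"),
                                 day = c(1, 1, 2, 2),
                                 n_at_risk = c(25, 15, 18, 12),
                                 deaths = c(7, 3, 4, 2), censored = 0))
  expect_equal(kaplan_meier(one)$s_hat, kaplan_meier(split2)$s_hat)
})

test_that("median survival follows the curve and the geometric analytic value", {
  led <- mk_ledger(data.frame(group = 0, cage = "c1", day = c(5, 9),
                              n_at_risk = c(100, 60), deaths = c(40, 20),
                              censored = 0))
  expect_equal(median_survival(kaplan_meier(led)), 9)  # 1 -> .6 -> .4

  high <- mk_ledger(data.frame(group = 0, cage = "c1", day = 1:3,
                               n_at_risk = c(100, 99, 98), deaths = 1,
                               censored = 0))
  expect_true(is.na(median_survival(kaplan_meier(high))))

  # constant hazard 0.05/day at 1000 bees: analytic median ln2/-ln(0.95) = 13.5
  cfg <- synth_config(seed = 29, doses_ppb = 0, cages_per_group = 5,
                      bees_per_cage = 200, sampling_days = integer(0),
                      hazard = c(`0` = 0.05, `0.1` = 0.05, `1` = 0.05, `10` = 0.05))
  med <- median_survival(kaplan_meier(generate_survival(cfg), 0))
  expect_lte(abs(med - log(2) / -log(0.95)), 1)
})

test_that("log-rank: null identity, symmetry, power, and oracle agreement", {
  cfg <- synth_config(seed = 31, doses_ppb = c(0, 10), cages_per_group = 3,
                      bees_per_cage = 100)
  led <- generate_survival(cfg)
  dup <- led[led$group == 0, ]
  dup2 <- dup; dup2$group <- 99
  same <- logrank(rbind(dup, dup2), 0, 99)
  expect_lt(same$chi2, 1e-10)
  expect_gt(same$p, 0.999)

  ab <- logrank(led, 0, 10)
  ba <- logrank(led, 10, 0)
  expect_equal(ab$chi2, ba$chi2, tolerance = 1e-12)

  skip_if_not_installed("survival")
  subj <- rbind(cbind(ledger_to_subjects(led[led$group == 0, ]), grp = "a"),
                cbind(ledger_to_subjects(led[led$group == 10, ]), grp = "b"))
  ref <- survival::survdiff(survival::Surv(time, status) ~ grp, data = subj)
  expect_equal(ab$chi2, unname(ref$chisq), tolerance = 1e-8)

  # power: hazards 0.02 vs 0.10, 500 bees each, 28 days
  hits <- 0L
  for (s in 1:20) {
    cfgp <- synth_config(seed = 500 + s, doses_ppb = c(0, 0.1),
                         cages_per_group = 5, bees_per_cage = 100,
                         sampling_days = integer(0),
                         hazard = c(`0` = 0.02, `0.1` = 0.10, `1` = 0, `10` = 0))
    lr <- logrank(generate_survival(cfgp), 0, 0.1)
    if (lr$p < 0.001) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("feeding rate implements the mean-alive denominator", {
  led <- data.frame(group = 0, cage = "c1", day = 1, syrup_consumed = 9.75,
                    alive_prev = 200, alive_now = 190)
  expect_equal(feeding_rate(led)$per_bee_consumption, 0.05)

  zero <- led; zero$syrup_consumed <- 0
  expect_equal(feeding_rate(zero)$per_bee_consumption, 0)

  dead <- data.frame(group = 0, cage = "c1", day = 2, syrup_consumed = 0,
                     alive_prev = 0, alive_now = 0)
  expect_warning(out <- feeding_rate(rbind(led, dead)), "no living bees")
  expect_equal(nrow(out), 1L)
})

test_that("feeding comparisons rank the 1 ppb group highest by design", {
  cfg <- synth_config(seed = 37, feeding_noise_sd = 0.05)
  rates <- feeding_rate(generate_feeding(cfg, generate_survival(cfg)))
  means <- tapply(rates$per_bee_consumption, rates$group, mean)
  expect_equal(names(which.max(means)), "1")
  cmp <- feeding_comparisons(rates)
  expect_equal(nrow(cmp$vs_control), 3L)
  expect_lt(cmp$vs_control$p[cmp$vs_control$group == 1], 0.001)
  paired <- feeding_comparisons(rates, paired_by_day = TRUE)
  expect_true(all(paired$vs_control$p >= 0 & paired$vs_control$p <= 1))
  expect_true(all(cmp$per_day$p >= 0))
})
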