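test_that("the design grid matches the study layout and is deterministic", {
  cfg <- synth_config(seed = 3)
  d <- generate_design(cfg)
  expect_equal(nrow(d), 120L)  # 3 sections x 4 doses x 5 cages x 2 replicates
  expect_equal(length(unique(d$cage)), 20L)
  expect_true(all(d$timepoint_day == 7L))
  expect_equal(nrow(unique(d[, c("gut_section", "dose_ppb")])), 12L)

  small <- synth_config(seed = 3, cages_per_group = 1, replicates_per_cage = 1)
  expect_equal(nrow(generate_design(small)), 12L)

  expect_identical(d, generate_design(synth_config(seed = 3)))
})

test_that("activity generation is deterministic and carries full lineages", {
  cfg <- synth_config(seed = 11)
  d <- generate_design(cfg)
  t1 <- generate_activity(d, cfg)
  t2 <- generate_activity(d, synth_config(seed = 11))
  expect_identical(unclass(t1), unclass(t2))
  lin <- synth_lineages(t1)
  expect_setequal(lin$asv_id, colnames(t1))
  expect_true(all(unclass(t1) >= 0))
  expect_true(all(unclass(t1) == round(unclass(t1))))
})

test_that("a planted strong positive pair shows up in the sample rank correlation", {
  hits <- 0L
  for (s in 1:10) {
    cfg <- synth_config(
      seed = s, sections = "midgut", doses_ppb = 0,
      planted_edges = data.frame(genus_a = "Lactobacillus",
                                 genus_b = "Bifidobacterium", rho = 0.95,
                                 doses = "all", sections = "all",
                                 stringsAsFactors = FALSE))
    d <- generate_design(cfg)
    tab <- generate_activity(d, cfg)
    gt <- aggregate_genus(tab, synth_lineages(tab))
    rel <- relative_activity(gt)
    rho <- cor(rel[, "Lactobacillus"], rel[, "Bifidobacterium"],
               method = "spearman")
    if (rho > 0.4) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("a planted negative dose effect lowers mean relative activity at scale", {
  # law-of-large-numbers check: 100 cages x 2 replicates = 200 samples/condition
  cfg <- synth_config(seed = 5, sections = "midgut", cages_per_group = 100)
  d <- generate_design(cfg)
  tab <- generate_activity(d, cfg)
  gt <- aggregate_genus(tab, synth_lineages(tab))
  rel <- relative_activity(gt)
  fri <- tapply(rel[, "Frischella"], d$dose_ppb[match(rownames(rel), d$sample_id)],
                mean)
  expect_true(all(fri[c("0.1", "1", "10")] < fri[["0"]]))
})

test_that("rare genera stay rare: sparse occurrence and trace activity", {
  cfg <- synth_config(seed = 9)
  d <- generate_design(cfg)
  tab <- generate_activity(d, cfg)
  lin <- synth_lineages(tab)
  gt <- aggregate_genus(tab, lin)
  m <- unclass(as.matrix(gt))
  for (s in unique(d$gut_section)) for (dose in unique(d$dose_ppb)) {
    ids <- d$sample_id[d$gut_section == s & d$dose_ppb == dose]
    sub <- m[ids, , drop = FALSE]
    for (g in cfg$rare_genera) {
      expect_lte(sum(sub[, g] > 0), 2L)
      expect_lt(sum(sub[, g]) / sum(sub), 1e-4)
    }
  }
})

test_that("the survival cohort matches the design and the hazard model", {
  cfg <- synth_config(seed = 2)
  led <- generate_survival(cfg)
  expect_equal(sum(led$n_at_risk[led$day == 1]), 4000L)  # 200 x 5 x 4
  expect_true(all(led$deaths + led$censored <= led$n_at_risk))

  # zero hazard: no deaths, survival identically 1
  cfg0 <- synth_config(seed = 2, hazard = c(`0` = 0, `0.1` = 0, `1` = 0, `10` = 0))
  led0 <- generate_survival(cfg0)
  expect_equal(sum(led0$deaths), 0L)
  expect_true(all(kaplan_meier(led0, 0.1)$s_hat == 1))

  # independent oracle re-draw with the same generator state
  cfg1 <- synth_config(seed = 7, doses_ppb = 0, cages_per_group = 1,
                       horizon_days = 3, sampling_days = integer(0),
                       hazard = c(`0` = 0.05, `0.1` = 0.05, `1` = 0.05, `10` = 0.05))
  led1 <- generate_survival(cfg1)
  set.seed(gutnetdys:::stage_seed(7, 2L))
  alive <- 200L; expected <- integer(3)
  for (day in 1:3) {
    expected[day] <- rbinom(1L, alive, 0.05)
    alive <- alive - expected[day]
  }
  expect_equal(led1$deaths, expected)
  expect_equal(led1$n_at_risk, 200L - c(0L, cumsum(expected)[1:2]))
})

test_that("feeding ledger follows the intake model and inverts exactly", {
  # formula case: 0.05 g/bee/day, 200 -> 190 alive, no noise
  led <- data.frame(group = 0, cage = "c", day = 1, n_at_risk = 200,
                    deaths = 10, censored = 0)
  class(led) <- c("survival_ledger", "data.frame")
  cfg <- synth_config(seed = 1, feeding_noise_sd = 0,
                      intake_g = c(`0` = 0.05, `0.1` = 0.05, `1` = 0.05, `10` = 0.05))
  fl <- generate_feeding(cfg, led)
  expect_equal(fl$syrup_consumed, 0.05 * 195)

  # all bees dead: zero mass
  dead <- led; dead$n_at_risk <- 0; dead$deaths <- 0
  class(dead) <- c("survival_ledger", "data.frame")
  expect_equal(generate_feeding(cfg, dead)$syrup_consumed, 0)

  # noiseless round trip: feeding_rate recovers configured intakes exactly
  cfg2 <- synth_config(seed = 4, feeding_noise_sd = 0)
  surv <- generate_survival(cfg2)
  rates <- feeding_rate(generate_feeding(cfg2, surv))
  configured <- cfg2$intake_g[gutnetdys:::dose_label(rates$group)]
  expect_true(all(abs(rates$per_bee_consumption - configured) < 1e-12))
})

test_that("an unrepairable planted correlation matrix is rejected with advice", {
  # a tight frustrated triangle cannot be made positive definite within tolerance
  cfg <- synth_config(
    seed = 1, sections = "midgut", doses_ppb = 0,
    planted_edges = data.frame(
      genus_a = c("Lactobacillus", "Lactobacillus", "Bifidobacterium"),
      genus_b = c("Bifidobacterium", "Gilliamella", "Gilliamella"),
      rho = c(0.95, 0.95, -0.95), doses = "all", sections = "all",
      stringsAsFactors = FALSE))
  d <- generate_design(cfg)
  expect_error(generate_activity(d, cfg), "weaker rho_targets")
})
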