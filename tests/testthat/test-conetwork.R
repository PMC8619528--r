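test_that("genus aggregation sums ASVs and buckets above-genus assignments", {
  m <- sample_matrix(c(10, 5, 3,
                       2, 1, 4), c("s1", "s2"), c("a1", "a2", "a3"))
  lin <- data.frame(
    asv_id = c("a1", "a2", "a3"),
    superkingdom = "Bacteria", phylum = "Firmicutes", class = "Bacilli",
    order = "Lactobacillales", family = "Lactobacillaceae",
    genus = c("Lactobacillus", "Lactobacillus", ""), species = "",
    stringsAsFactors = FALSE)
  g <- aggregate_genus(activity_table(m), lin)
  expect_equal(unname(unclass(g)["s1", "Lactobacillus"]), 15)
  expect_true("unassigned_family_Lactobacillaceae" %in% colnames(g))
  expect_false(ncol(g) != 2L)

  # one genus per ASV: identity up to relabeling, descending-total order
  lin2 <- lin; lin2$genus <- c("Ga", "Gb", "Gc")
  g2 <- aggregate_genus(activity_table(m), lin2)
  expect_equal(colnames(g2), c("Ga", "Gc", "Gb"))  # totals 12, 7, 6
  expect_equal(sort(unname(colSums(g2))), sort(unname(colSums(m))))

  # fully unassigned ASVs fall into the plain "unassigned" bucket
  lin3 <- lin; lin3[1, 2:8] <- ""
  g3 <- aggregate_genus(activity_table(m), lin3)
  expect_true("unassigned" %in% colnames(g3))
})

test_that("occurrence filter keeps 8/10, drops 7/10, generalizes strictly", {
  m <- matrix(1, nrow = 10, ncol = 3,
              dimnames = list(sprintf("s%02d", 1:10), c("g8", "g7", "gAll")))
  m[1:2, "g8"] <- 0   # present 8 of 10
  m[1:3, "g7"] <- 0   # present 7 of 10
  kept <- occurrence_filter(m)
  expect_true("g8" %in% kept)
  expect_false("g7" %in% kept)
  expect_true("gAll" %in% kept)

  expect_error(occurrence_filter(m[1:3, ]), "fewer than 4 samples")
  # N = 7: threshold > 4.9, i.e. present in at least 5
  m7 <- m[1:7, ]; m7[, "g7"] <- 1; m7[1:2, "g7"] <- 0   # 5 of 7
  expect_true("g7" %in% occurrence_filter(m7))
  m7[3, "g7"] <- 0                                       # 4 of 7
  expect_false("g7" %in% occurrence_filter(m7))
})

test_that("spearman screen handles degenerate and constant inputs", {
  x <- 1:10
  m <- cbind(gA = x, gB = 2 * x + 3, gC = 30 - x, gD = rep(5, 10))
  rownames(m) <- sprintf("s%02d", 1:10)
  scr <- spearman_screen(m, relative = FALSE)
  expect_equal(attr(scr, "dropped_constant"), "gD")
  expect_equal(attr(scr, "m_family"), 3L)  # pairs among gA, gB, gC only
  ab <- scr[scr$genus_a == "gA" & scr$genus_b == "gB", ]
  expect_equal(ab$rho, 1); expect_equal(ab$p_raw, 0)
  ac <- scr[scr$genus_a == "gA" & scr$genus_b == "gC", ]
  expect_equal(ac$rho, -1); expect_equal(ac$p_raw, 0)
  # Bonferroni bookkeeping: p_bonf = min(1, m * p_raw)
  expect_equal(scr$p_bonf, pmin(1, attr(scr, "m_family") * scr$p_raw))
  expect_error(spearman_screen(m[1:3, ]), "at least 4 samples")
})

test_that("rho and p match independent oracles on a seeded 10x3 table", {
  set.seed(19)
  m <- matrix(rlnorm(30, 3, 1), nrow = 10,
              dimnames = list(sprintf("s%02d", 1:10), c("g1", "g2", "g3")))
  m[, 2] <- m[, 1] * exp(rnorm(10, 0, 0.4))  # a correlated pair
  scr_t <- spearman_screen(m, relative = FALSE)
  # rho against direct rank-Pearson
  for (k in seq_len(nrow(scr_t))) {
    direct <- cor(rank(m[, scr_t$genus_a[k]]), rank(m[, scr_t$genus_b[k]]))
    expect_equal(scr_t$rho[k], direct, tolerance = 1e-12)
  }
  # permutation mode against an independent permutation oracle
  set.seed(77)
  scr_p <- spearman_screen(m, relative = FALSE, p_method = "permutation",
                           n_perm = 20000)
  set.seed(78)
  for (k in seq_len(nrow(scr_p))) {
    p_o <- oracle_spearman_perm(m[, scr_p$genus_a[k]], m[, scr_p$genus_b[k]],
                                20000)
    se <- sqrt(scr_p$p_raw[k] * (1 - scr_p$p_raw[k]) / 20000 +
                 p_o * (1 - p_o) / 20000)
    expect_lt(abs(scr_p$p_raw[k] - p_o), 3 * se + 1e-4)
  }
})

test_that("the edge rule enforces all three clauses", {
  screen <- data.frame(
    genus_a = c("A", "A", "B"), genus_b = c("B", "C", "C"),
    rho = c(0.95, 0.39, 0.80),
    p_raw = c(1e-5, 1e-7, 1e-3),
    p_bh = c(1e-4, 1e-6, 0.01),
    p_bonf = c(1e-3, 1e-6, 0.20), stringsAsFactors = FALSE)
  class(screen) <- c("correlation_screen", "data.frame")
  nodes <- data.frame(genus = c("A", "B", "C"), total_activity = 1,
                      occurrence = 10L, class = "core", stringsAsFactors = FALSE)
  net <- build_network(screen, nodes, "midgut", 0.1)
  expect_equal(nrow(net$edges), 1L)          # only the first pair survives
  expect_equal(net$edges$source, "A")
  expect_equal(net$edges$sign, "+")
  expect_equal(nrow(net$nodes), 3L)          # C stays as a degree-0 node
  # relaxing the Bonferroni clause admits the (0.8, p_bh 0.01) pair
  net_bh <- build_network(screen, nodes, "midgut", 0.1,
                          require_bonferroni = FALSE)
  expect_equal(nrow(net_bh$edges), 2L)
})

test_that("full design yields 12 networks; subsets and gaps behave", {
  cfg <- synth_config(seed = 21)
  d <- generate_design(cfg)
  tab <- generate_activity(d, cfg)
  gt <- aggregate_genus(tab, synth_lineages(tab))
  nets <- run_all_conditions(gt, d)
  expect_length(nets, 12L)
  expect_s3_class(nets[[1]], "taxon_network")
  summ <- network_summary(nets)
  expect_equal(nrow(summ), 12L)
  expect_true(all(summ$nodes > 0))

  one <- run_all_conditions(gt, d[d$gut_section == "ileum", ],
                            sections = "ileum")
  expect_length(one, 4L)

  expect_error(run_all_conditions(gt, d[d$gut_section != "rectum", ]),
               "rectum/0 ppb")
})

test_that("edge sets are invariant to depth rescaling and genus relabeling", {
  cfg <- synth_config(seed = 23, sections = "midgut", doses_ppb = 0)
  d <- generate_design(cfg)
  tab <- generate_activity(d, cfg)
  gt <- aggregate_genus(tab, synth_lineages(tab))
  m <- unclass(as.matrix(gt))

  edge_key <- function(net) {
    if (!nrow(net$edges)) return(character(0))
    sort(paste(pmin(net$edges$source, net$edges$target),
               pmax(net$edges$source, net$edges$target), net$edges$sign))
  }
  base <- condition_network(activity_table(m), d, "midgut", 0)

  scale <- m * matrix(runif(nrow(m), 0.5, 8), nrow(m), ncol(m))
  scaled <- condition_network(activity_table(scale), d, "midgut", 0)
  expect_equal(edge_key(scaled), edge_key(base))

  perm <- sample(ncol(m))
  relab <- m[, perm]
  colnames(relab) <- colnames(m)[perm]
  permed <- condition_network(activity_table(relab), d, "midgut", 0)
  expect_equal(edge_key(permed), edge_key(base))
})
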