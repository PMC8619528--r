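lin_lact_apis <- lineage("Bacteria", "Firmicutes", "Bacilli", "Lactobacillales",
                         "Lactobacillaceae", "Lactobacillus", "Lactobacillus apis")
lin_lact_kimb <- lineage("Bacteria", "Firmicutes", "Bacilli", "Lactobacillales",
                         "Lactobacillaceae", "Lactobacillus", "Lactobacillus kimbladii")
lin_snod <- lineage("Bacteria", "Proteobacteria", "Betaproteobacteria",
                    "Neisseriales", "Neisseriaceae", "Snodgrassella",
                    "Snodgrassella alvi")

test_that("lineages fill gaps top-down and expose their deepest rank", {
  l <- lineage(superkingdom = "Bacteria", phylum = "Firmicutes", class = "Bacilli",
               order = "Lactobacillales", genus = "Lactobacillus")
  expect_equal(unname(l[["family"]]), "unclassified_Lactobacillales")
  expect_equal(assigned_rank(l), "genus")
  expect_true(is_unassigned(unassigned_lineage()))
  expect_true(is.na(assigned_rank(unassigned_lineage())))
})

test_that("lca walks ranks and truncates at the first disagreement", {
  expect_equal(unclass(lca(list(lin_lact_apis, lin_lact_apis))),
               unclass(lin_lact_apis))
  g <- lca(list(lin_lact_apis, lin_lact_kimb))
  expect_equal(assigned_rank(g), "genus")
  expect_equal(unname(g[["genus"]]), "Lactobacillus")
  expect_equal(unname(g[["species"]]), "")
  k <- lca(list(lin_lact_apis, lin_snod))
  expect_equal(assigned_rank(k), "superkingdom")
  expect_equal(unname(k[["superkingdom"]]), "Bacteria")
  expect_error(lca(list()), "empty")
})

test_that("lca is commutative, associative and monotone non-deepening", {
  pool <- list(lin_lact_apis, lin_lact_kimb, lin_snod, unassigned_lineage(),
               lineage("Bacteria", "Firmicutes", "Bacilli"))
  set.seed(42)
  rank_depth <- function(l) {
    r <- assigned_rank(l)
    if (is.na(r)) 0L else match(r, gutnetdys:::LINEAGE_RANKS)
  }
  for (i in 1:25) {
    pick <- sample(seq_along(pool), sample(2:4, 1), replace = TRUE)
    a <- lca(pool[pick])
    b <- lca(pool[rev(pick)])
    expect_equal(unclass(a), unclass(b))                       # commutative
    expect_equal(unclass(a), oracle_lca(pool[pick]))           # oracle
    extra <- lca(c(pool[pick], pool[sample(seq_along(pool), 1)]))
    expect_lte(rank_depth(extra), rank_depth(a))               # non-deepening
    nest <- lca(list(lca(pool[pick[1:2]]), pool[[pick[length(pick)]]]))
    flat <- lca(pool[c(pick[1:2], pick[length(pick)])])
    expect_equal(unclass(nest), unclass(flat))                 # associative
  }
})

lookup <- data.frame(
  taxid = c("101", "102", "201"),
  superkingdom = "Bacteria",
  phylum = c("Firmicutes", "Firmicutes", "Proteobacteria"),
  class = c("Bacilli", "Bacilli", "Gammaproteobacteria"),
  order = c("Lactobacillales", "Lactobacillales", "Orbales"),
  family = c("Lactobacillaceae", "Lactobacillaceae", "Orbaceae"),
  genus = c("Lactobacillus", "Lactobacillus", "Gilliamella"),
  species = c("Lactobacillus apis", "Lactobacillus kimbladii",
              "Gilliamella apicola"),
  stringsAsFactors = FALSE)

hit <- function(q, taxid, pid, bits) {
  data.frame(query_id = q, subject_taxid = taxid, percent_identity = pid,
             bitscore = bits, stringsAsFactors = FALSE)
}

test_that("assignment uses the >98% top hit or the top-50 LCA fallback", {
  best <- assign_taxon(hit("a", "201", 99.1, 500), lookup)
  expect_equal(unname(best[["species"]]), "Gilliamella apicola")
  expect_equal(assigned_rank(best), "species")

  # below threshold: LCA of the hits, genus level here
  two <- rbind(hit("a", "101", 95, 480), hit("a", "102", 94, 470))
  fall <- assign_taxon(two, lookup)
  expect_equal(assigned_rank(fall), "genus")
  expect_equal(unname(fall[["genus"]]), "Lactobacillus")

  # exactly 98 is not "above 98"
  border <- assign_taxon(rbind(hit("a", "101", 98, 480), hit("a", "102", 97, 470)),
                         lookup)
  expect_equal(assigned_rank(border), "genus")

  expect_true(is_unassigned(assign_taxon(hit("a", "101", 99, 500)[0, ], lookup)))

  # unknown taxids are dropped with a warning; nothing left -> unassigned
  expect_warning(res <- assign_taxon(hit("a", "999", 99.9, 500), lookup),
                 "absent from the lineage lookup")
  expect_true(is_unassigned(res))
})

test_that("threshold 0 reduces to top-hit and threshold 101 to pure LCA", {
  hits <- rbind(hit("a", "101", 95, 480), hit("a", "201", 94, 470))
  top <- assign_taxon(hits, lookup, identity_threshold = 0)
  expect_equal(unname(top[["species"]]), "Lactobacillus apis")
  pure <- assign_taxon(hits, lookup, identity_threshold = 101)
  expect_equal(assigned_rank(pure), "superkingdom")
  # top_n binds the LCA family: with top_n = 1 pure LCA is the best hit
  one <- assign_taxon(hits, lookup, identity_threshold = 101, top_n = 1)
  expect_equal(unname(one[["species"]]), "Lactobacillus apis")
})

test_that("BLAST tabular hits parse and assign per query", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(
    "asv1\tref1\t99.3\t250\t1\t0\t1\t250\t1\t250\t1e-120\t500\t201",
    "asv2\tref2\t95.0\t250\t9\t1\t1\t250\t1\t250\t1e-90\t480\t101",
    "asv2\tref3\t94.0\t250\t11\t1\t1\t250\t1\t250\t1e-85\t470\t102"), f)
  hits <- read_blast_hits(f)
  expect_equal(nrow(hits), 3L)
  res <- assign_all_taxa(hits, lookup)
  expect_equal(res$species[res$asv_id == "asv1"], "Gilliamella apicola")
  expect_equal(res$assigned_rank[res$asv_id == "asv2"], "genus")
})
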