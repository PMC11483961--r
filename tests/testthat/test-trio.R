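# independent Mendelian oracle: enumerate every gamete choice explicitly
oracle_compatible <- function(p1, p2, f) {
  al <- list(`0` = c("a", "a"), `1` = c("a", "b"), `2` = c("b", "b"))
  fa <- sort(al[[as.character(f)]])
  for (x in al[[as.character(p1)]]) for (y in al[[as.character(p2)]])
    if (identical(sort(c(x, y)), fa)) return(TRUE)
  FALSE
}

test_that("the compatibility table equals exhaustive Mendelian enumeration", {
  tab <- build_compatibility_table()
  expect_equal(nrow(tab), 27L)
  for (i in seq_len(nrow(tab)))
    expect_equal(tab$compatible[i],
                 oracle_compatible(tab$p1[i], tab$p2[i], tab$f[i]),
                 info = tab$label[i])
  expect_equal(sum(tab$compatible), 15L)
  expect_equal(sum(!tab$compatible), 12L)
})

test_that("the table reproduces the published compatible and incompatible lists", {
  compatible <- c("aaxaa->aa", "aaxab->aa", "aaxab->ab", "aaxbb->ab",
                  "abxaa->aa", "abxaa->ab", "abxab->aa", "abxab->ab",
                  "abxab->bb", "abxbb->ab", "abxbb->bb", "bbxaa->ab",
                  "bbxab->ab", "bbxab->bb", "bbxbb->bb")
  incompatible <- c("aaxaa->ab", "aaxaa->bb", "aaxab->bb", "aaxbb->aa",
                    "aaxbb->bb", "abxaa->bb", "abxbb->aa", "bbxaa->aa",
                    "bbxaa->bb", "bbxab->aa", "bbxbb->aa", "bbxbb->ab")
  tab <- build_compatibility_table()
  expect_setequal(tab$label[tab$compatible], compatible)
  expect_setequal(tab$label[!tab$compatible], incompatible)
})

test_that("the table is symmetric under swapping the parents", {
  tab <- build_compatibility_table()
  lk <- attr(tab, "lookup")
  for (i in seq_len(nrow(tab)))
    expect_equal(lk[9 * tab$p1[i] + 3 * tab$p2[i] + tab$f[i] + 1],
                 lk[9 * tab$p2[i] + 3 * tab$p1[i] + tab$f[i] + 1])
})

test_that("an error-free genuine trio has exactly zero Mendelian errors and is accepted", {
  sim <- small_sim(101, het_to_hom_rate = 0, hom_to_het_rate = 0,
                   genotype_missing_rate = 0)
  ws <- build_windows(sim$genome)
  rep <- test_trio(sim$genotypes, ws, "FndA1", "FndA2", "Quart1")
  expect_equal(rep$n_mendelian_errors, 0L)
  expect_equal(rep$error_rate, 0)
  expect_equal(rep$verdict, "accepted")
})

test_that("swapping the parents changes neither counts nor verdicts", {
  sim <- small_sim(111)
  ws <- build_windows(sim$genome)
  r1 <- test_trio(sim$genotypes, ws, "FndA1", "FndA2", "Quart2")
  r2 <- test_trio(sim$genotypes, ws, "FndA2", "FndA1", "Quart2")
  expect_equal(r2$n_informative, r1$n_informative)
  expect_equal(r2$n_mendelian_errors, r1$n_mendelian_errors)
  expect_equal(r2$verdict, r1$verdict)
  r3 <- test_trio(sim$genotypes, ws, "ParXSib", "FndB5", "Off8")
  r4 <- test_trio(sim$genotypes, ws, "FndB5", "ParXSib", "Off8")
  expect_equal(r4$verdict, r3$verdict)
  expect_error(test_trio(sim$genotypes, ws, "FndA1", "FndA1", "Quart1"),
               "distinct")
})

test_that("a trio with no informative sites is undetermined", {
  calls <- cbind(a = c(NA, 0L), b = c(1L, NA), c = c(2L, 2L))
  gm <- make_gm(calls, ids = c("a", "b", "c"))
  ws <- build_windows(toy_genome(1e6), 1e6)
  rep <- test_trio(gm, ws, "a", "b", "c")
  expect_equal(rep$verdict, "undetermined")
  expect_equal(rep$n_informative, 0L)
})

test_that("substituting a parent by its full sibling produces clustered errors", {
  sim <- small_sim(121)
  ws <- build_windows(sim$genome)
  true_rep <- test_trio(sim$genotypes, ws, "ParX", "FndB5", "Off8")
  false_rep <- test_trio(sim$genotypes, ws, "ParXSib", "FndB5", "Off8")
  expect_equal(true_rep$verdict, "accepted")
  expect_equal(false_rep$verdict, "rejected_clustered")
  expect_gt(false_rep$error_rate, true_rep$error_rate)
  expect_gt(nrow(false_rep$flagged_runs), 0)
})

test_that("incompatible regions merge flagged runs and report genome fractions", {
  sim <- small_sim(121)
  ws <- build_windows(sim$genome)
  acc <- test_trio(sim$genotypes, ws, "ParX", "FndB5", "Off8")
  reg0 <- incompatible_regions(acc, ws)
  expect_equal(nrow(reg0$intervals), 0L)
  expect_equal(reg0$total_fraction, 0)
  bad <- test_trio(sim$genotypes, ws, "ParXSib", "FndB5", "Off8")
  reg <- incompatible_regions(bad, ws)
  expect_equal(nrow(reg$intervals), nrow(bad$flagged_runs))
  expect_equal(reg$total_fraction, sum(reg$intervals$fraction))
  expect_gt(reg$total_fraction, 0)
  expect_lt(reg$total_fraction, 1)
  # fractions are additive over runs and measured in non-repetitive bp
  i <- 1
  w <- bad$flagged_runs$first_window[i]:bad$flagged_runs$last_window[i]
  expect_equal(reg$intervals$nonrep_bp[i], sum(ws$nonrep_span[w]))
})

test_that("trio search recovers the planted pedigree, full sibs and nothing else", {
  # full study-scale genome: trio exclusion needs genome-wide power
  sim <- simulate_pedigree_data(sim_config(seed = 131))
  ws <- build_windows(sim$genome)
  pairs <- ibd_all_pairs(sim$genotypes, ws)
  res <- search_trios(sim$genotypes, ws, pairs)
  acc <- res$accepted
  cp1 <- canon_clones(acc$p1, sim$truth$clones)
  cp2 <- canon_clones(acc$p2, sim$truth$clones)
  tr <- sim$truth$trios
  expect_setequal(trio_key(cp1, cp2, acc$f), trio_key(tr$p1, tr$p2, tr$f))
  # the quartet yields its 6 full-sib pairs, plus the two planted sib pairs
  fs <- sim$truth$full_sibs
  expect_setequal(pair_key(res$full_sibs$a, res$full_sibs$b),
                  pair_key(fs$a, fs$b))
  quart <- res$full_sibs[grepl("^Quart", res$full_sibs$a) &
                         grepl("^Quart", res$full_sibs$b), ]
  expect_equal(nrow(quart), choose(4, 2))
  # the clone was collapsed to a single representative
  expect_true(length(res$clone_rep) >= 1)
})

test_that("an accession with a single partner is never tested as offspring", {
  pairs <- data.frame(a = c("P", "P"), b = c("F", "Q"),
                      call = c("parent_offspring", "other"))
  gm <- make_gm(matrix(0L, 2, 3), ids = c("P", "F", "Q"))
  ws <- build_windows(toy_genome(1e6), 1e6)
  res <- search_trios(gm, ws, pairs)
  expect_equal(nrow(res$trios), 0L)
})

test_that("exhaustive re-testing rejects all combinations of a false-pedigree triangle", {
  sim <- small_sim(141)
  ws <- build_windows(sim$genome)
  # ParX has parent-offspring links to FndB3, FndB4 and Off8; only the
  # (FndB3, FndB4) combination is its true parent pair
  cand <- data.frame(p1 = c("FndB3", "FndB4"), p2 = c("Off8", "Off8"),
                     f = "ParX")
  res <- search_trios(sim$genotypes, ws,
                      data.frame(a = character(0), b = character(0),
                                 call = character(0)),
                      extra_candidates = cand)
  expect_equal(nrow(res$trios), 2L)
  expect_true(all(res$trios$verdict != "accepted"))
})
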