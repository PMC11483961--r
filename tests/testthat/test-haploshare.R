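test_that("reference homozygosity verification applies its threshold", {
  gm <- make_gm(cbind(ref = rep(0L, 100)), pos = seq(1000L, 100000L, 1000L),
                ids = "ref")
  chk <- verify_reference_homozygosity(gm, "ref", "chr1", 0, 2e5)
  expect_equal(chk$fraction_homozygous, 1)
  expect_true(chk$pass)
  calls <- rep(0L, 100); calls[1:5] <- 1L # 5% heterozygous
  gm2 <- make_gm(cbind(ref = calls), pos = seq(1000L, 100000L, 1000L),
                 ids = "ref")
  chk2 <- verify_reference_homozygosity(gm2, "ref", "chr1", 0, 2e5)
  expect_equal(chk2$fraction_homozygous, 0.95)
  expect_false(chk2$pass)
  chk3 <- verify_reference_homozygosity(gm, "ref", "chr1", 5e5, 6e5)
  expect_false(chk3$pass)
  expect_equal(chk3$n_sites, 0L)
  expect_error(verify_reference_homozygosity(gm, "ghost", "chr1", 0, 1e5),
               "unknown accession")
})

test_that("a clone of the reference shares two haplotypes in every window", {
  set.seed(5)
  ref <- sample(c(0L, 2L), 400, TRUE)
  gm <- make_gm(cbind(ref = ref, clone = ref, other = 2L - ref),
                pos = seq(2000L, 800000L, 2000L),
                ids = c("ref", "clone", "other"))
  gen <- toy_genome(8e5)
  scan <- sharing_scan(gm, gen, "ref", "chr1", n_windows = 4,
                       verify = c(0, 8e5))
  expect_true(all(scan$states["clone", ] == "shares_two"))
  expect_true(all(scan$states["ref", ] == "shares_two"))
  expect_true(all(scan$states["other", ] == "shares_none"))
  dos <- call_dosage(scan, 0, 8e5)
  expect_equal(dos[["ref"]], 2L)
  expect_equal(dos[["clone"]], 2L)
  expect_equal(dos[["other"]], 0L)
})

test_that("a failed reference check stops the scan", {
  gm <- make_gm(cbind(ref = rep(1L, 50), x = rep(0L, 50)),
                pos = seq(1000L, 50000L, 1000L), ids = c("ref", "x"))
  expect_error(sharing_scan(gm, toy_genome(1e5), "ref", "chr1",
                            n_windows = 2, verify = c(0, 1e5)),
               "homozygosity check")
})

test_that("dosage is monotone in window sharing states", {
  scan <- structure(list(
    windows = data.frame(chrom = "chr1", start = c(0, 100), end = c(100, 200)),
    states = matrix(c("shares_one_or_two", "shares_one_or_two"), 1, 2,
                    dimnames = list("x", NULL)),
    ref_id = "r", chrom = "chr1"), class = "sharing_scan")
  expect_equal(call_dosage(scan, 0, 200)[["x"]], 1L)
  scan$states[1, 2] <- "shares_none"
  expect_equal(call_dosage(scan, 0, 200)[["x"]], 0L)
  scan$states[1, ] <- "shares_two"
  expect_equal(call_dosage(scan, 0, 200)[["x"]], 2L)
  scan$states[1, ] <- "uninformative"
  expect_true(is.na(call_dosage(scan, 0, 200)[["x"]]))
})

test_that("population frequencies follow the dosage arithmetic", {
  dos <- setNames(rep(2L, 10), paste0("a", 1:10))
  pops <- data.frame(id = paste0("a", 1:10), population = "p")
  expect_equal(population_frequencies(dos, pops)$frequency, 1)
  dos2 <- setNames(c(rep(1L, 10), rep(0L, 10)), paste0("b", 1:20))
  pops2 <- data.frame(id = paste0("b", 1:20), population = "q")
  expect_equal(population_frequencies(dos2, pops2)$frequency, 10 / 40)
  # undetermined dosages leave the denominator, with the count reported
  dos3 <- setNames(c(2L, NA, 0L), c("c1", "c2", "c3"))
  pops3 <- data.frame(id = c("c1", "c2", "c3", "c4"),
                      population = c("r", "r", "r", "empty"))
  pf <- population_frequencies(dos3, pops3)
  r <- pf[pf$population == "r", ]
  expect_equal(r$n_called, 2L)
  expect_equal(r$n_undetermined, 1L)
  expect_equal(r$frequency, 2 / 4)
  expect_true(is.na(pf$frequency[pf$population == "empty"]))
  expect_error(population_frequencies(dos3,
    data.frame(id = c("c1", "c1"), population = c("r", "s"))),
    "more than one population")
})

test_that("planted haplotype dosage and frequency are recovered from the scan", {
  sim <- simulate_pedigree_data(wild_panel_config(seed = 17, frequency = 0.25))
  scan <- sharing_scan(sim$genotypes, sim$genome, "RefCarrier", "chr2",
                       n_windows = 50, verify = c(6e6, 1e7))
  dos <- call_dosage(scan, 6e6, 1e7)
  truth <- sim$truth$dosage
  agree <- mean(dos[names(truth)] == truth, na.rm = TRUE)
  expect_gte(agree, 0.95)
  expect_equal(dos[["RefCarrier"]], 2L)
  pf <- population_frequencies(dos,
    data.frame(id = grep("^Wld", names(truth), value = TRUE),
               population = "wild"))
  expect_lt(abs(pf$frequency - 0.25), 0.05)
})

test_that("ancestry-group assignment follows the strict majority rule", {
  q <- rbind(A = c(1, 0, 0),
             B = c(0.5, 0.3, 0.2),
             C = c(0.85, 0.15, 0),
             D = c(0.86, 0.14, 0))
  colnames(q) <- c("k1", "k2", "k3")
  grp <- assign_ancestry_groups(q)
  expect_equal(unname(grp["A"]), "k1")
  expect_equal(unname(grp["B"]), "admixed")
  expect_equal(unname(grp["C"]), "admixed") # exactly at threshold: admixed
  expect_equal(unname(grp["D"]), "k1")
  bad <- rbind(E = c(0.5, 0.2, 0.2))
  expect_error(assign_ancestry_groups(bad), "E")
})
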