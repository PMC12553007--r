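test_that("harmonisation aligns alleles, flips swapped outcomes and drops mismatches", {
  exp <- make_sumstats("E", "metabolite", beta = c(0.1, 0.2, 0.3),
                       se = rep(0.01, 3), ea = c("A", "A", "A"),
                       oa = c("G", "G", "G"), eaf = c(0.2, 0.3, 0.4))
  # same alleles / swapped alleles / incompatible alleles
  out <- make_sumstats("O", "disease", beta = c(1, 1, 1), se = rep(0.1, 3),
                       ea = c("A", "G", "C"), oa = c("G", "A", "T"),
                       eaf = c(0.2, 0.7, 0.5))
  h <- harmonise(exp, out)
  expect_equal(h$variants$variant_id, c("rs001", "rs002"))
  expect_equal(h$variants$by, c(1, -1))
  expect_equal(h$log$reason[h$log$variant_id == "rs003"], "allele_mismatch")
  # exposure-side quantities are untouched
  expect_equal(h$variants$bx, c(0.1, 0.2))
})

test_that("harmonisation of disjoint sets yields an empty result with a log entry", {
  a <- make_sumstats("E", "metabolite", beta = 0.1, se = 0.01, ids = "rsA")
  b <- make_sumstats("O", "disease", beta = 0.1, se = 0.01, ids = "rsB")
  h <- harmonise(a, b)
  expect_equal(nrow(h$variants), 0)
  expect_true("no_overlap" %in% h$log$reason)
})

test_that("harmonisation is invariant to the outcome's allele labelling", {
  exp <- make_sumstats("E", "metabolite", beta = c(0.1, -0.2), se = rep(0.01, 2))
  out1 <- make_sumstats("O", "disease", beta = c(0.5, 0.4), se = rep(0.1, 2),
                        eaf = c(0.3, 0.3))
  # relabel: swap alleles and negate beta, reflect eaf -> same harmonised by
  out2 <- out1
  out2$records$effect_allele <- out1$records$other_allele
  out2$records$other_allele <- out1$records$effect_allele
  out2$records$beta <- -out1$records$beta
  out2$records$eaf <- 1 - out1$records$eaf
  expect_equal(harmonise(exp, out1)$variants$by, harmonise(exp, out2)$variants$by)
})

test_that("palindromic variants are kept and logged for audit", {
  exp <- make_sumstats("E", "metabolite", beta = 0.1, se = 0.01,
                       ea = "A", oa = "T")
  out <- make_sumstats("O", "disease", beta = 0.3, se = 0.1, ea = "A", oa = "T")
  h <- harmonise(exp, out)
  expect_equal(nrow(h$variants), 1)
  expect_true("palindromic_kept" %in% h$log$reason)
})

test_that("the F-statistic is the squared Wald ratio", {
  expect_equal(f_statistic(0.1, 0.02), 25)
  expect_equal(f_statistic(0, 0.1), 0)
  expect_error(f_statistic(0.1, 0), "se")
  expect_equal(f_statistic(c(0.1, 0.2), c(0.02, 0.02)), c(25, 100))
})

test_that("the cis window is closed on both ends and chromosome-aware", {
  prot <- make_sumstats("P", "protein",
                        beta = rep(0.1, 4), se = rep(0.01, 4),
                        chrom = c("1", "1", "1", "2"),
                        pos = c(900, 202000, 202001, 1500),
                        locus = list(chrom = "1", start = 1000, end = 2000))
  kept <- cis_window(prot, 200000)$records
  expect_setequal(kept$variant_id, c("rs001", "rs002"))  # 202001 is 1 bp out
  nolocus <- make_sumstats("P2", "metabolite", beta = 0.1, se = 0.01)
  expect_error(cis_window(nolocus), class = "mrtriad_missing_locus")
})

test_that("greedy clumping retains the best variant per LD clique", {
  v1 <- data.frame(variant_id = "rsA", pval = 0.01)
  expect_equal(clump_variants(v1, identity_ld("rsA")), "rsA")
  ld <- matrix(c(1, 0.6, 0.6, 1), 2, dimnames = list(c("rsA", "rsB"), c("rsA", "rsB")))
  v2 <- data.frame(variant_id = c("rsA", "rsB"), pval = c(0.05, 0.001))
  expect_equal(clump_variants(v2, ld, 0.30), "rsB")   # r2 = 0.36 > 0.30
  expect_equal(clump_variants(v2, ld, 0.40), c("rsB", "rsA"))
  expect_error(clump_variants(data.frame(variant_id = "rsZ", pval = 0.1), ld),
               class = "mrtriad_missing_ld")
})

test_that("clumping matches an exhaustive greedy oracle on random instances", {
  for (i in 1:20) {
    set.seed(i)
    m <- sample(4:10, 1)
    ids <- sprintf("rs%02d", seq_len(m))
    A <- matrix(rnorm(m * m), m)
    C <- cov2cor(crossprod(A) + diag(m))
    dimnames(C) <- list(ids, ids)
    v <- data.frame(variant_id = ids, pval = runif(m))
    expect_equal(clump_variants(v, C, 0.3), clump_oracle(ids, v$pval, C, 0.3))
    # invariant to input ordering given distinct p-values
    perm <- sample(m)
    expect_equal(clump_variants(v[perm, ], C, 0.3), clump_variants(v, C, 0.3))
  }
})

test_that("clumping ties on p-value break by ascending variant id", {
  ids <- c("rsB", "rsA")
  ld <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(ids, ids))
  v <- data.frame(variant_id = ids, pval = c(0.01, 0.01))
  expect_equal(clump_variants(v, ld, 0.3), "rsA")
})

test_that("instrument selection applies cis, MAF, F and clump filters with a log", {
  ids <- sprintf("rs%02d", 1:5)
  prot <- make_sumstats("P", "protein",
                        beta = c(0.1, 0.1, 0.005, 0.1, 0.1),
                        se = c(0.01, 0.01, 0.001, 0.0224, 0.01),
                        ids = ids, eaf = c(0.3, 0.005, 0.3, 0.3, 0.3),
                        pos = c(1e6, 1e6 + 1, 1e6 + 2, 1e6 + 3, 5e6),
                        locus = list(chrom = "1", start = 1e6, end = 1.02e6))
  out <- make_sumstats("O", "disease", beta = rep(0.05, 5), se = rep(0.01, 5),
                       ids = ids, pos = prot$records$pos)
  instr <- select_instruments(prot, out, identity_ld(ids))
  log <- instr$exclusion_log
  expect_equal(log$reason[log$variant_id == "rs02"], "maf")    # eaf 0.005
  expect_equal(log$reason[log$variant_id == "rs04"], "weak")   # F ~ 19.9
  expect_equal(log$reason[log$variant_id == "rs05"], "outside_cis")
  expect_setequal(instr$variants$variant_id, c("rs01", "rs03"))
  # a variant exactly at the F threshold is retained ("at least")
  prot24 <- make_sumstats("P", "protein", beta = 0.05, se = 0.01,
                          locus = list(chrom = "1", start = 1e6, end = 1.02e6))
  out24 <- make_sumstats("O", "disease", beta = 0.01, se = 0.01)
  i24 <- select_instruments(prot24, out24, identity_ld("rs001"), f_min = 25)
  expect_equal(nrow(i24$variants), 1)   # F = (0.05/0.01)^2 = 25 exactly
  i25 <- select_instruments(prot24, out24, identity_ld("rs001"), f_min = 25.0001)
  expect_equal(nrow(i25$variants), 0)
})

test_that("retained instrument count is monotone in the F and MAF thresholds", {
  set.seed(99)
  m <- 12
  ids <- sprintf("rs%02d", seq_len(m))
  prot <- make_sumstats("P", "metabolite", beta = runif(m, 0, 0.2),
                        se = rep(0.01, m), ids = ids,
                        eaf = runif(m, 0.005, 0.5))
  out <- make_sumstats("O", "disease", beta = rnorm(m, 0, 0.02),
                       se = rep(0.01, m), ids = ids)
  ld <- identity_ld(ids)
  n_at <- function(f_min, maf_min)
    nrow(select_instruments(prot, out, ld, f_min = f_min, maf_min = maf_min)$variants)
  counts_f <- vapply(c(0, 10, 24, 100, 400), n_at, numeric(1), maf_min = 0.01)
  expect_true(all(diff(counts_f) <= 0))
  counts_maf <- vapply(c(0.001, 0.01, 0.05, 0.2), n_at, numeric(1), f_min = 0)
  expect_true(all(diff(counts_maf) <= 0))
})
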