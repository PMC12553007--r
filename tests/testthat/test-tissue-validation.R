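test_that("the PVI association recovers the generating slope", {
  tab <- simulate_plaque_table(60, c(G = 2), noise_sd = 0, seed = 1)
  res <- suppressWarnings(pvi_association(tab, "G"))  # exact fit warns in summary.lm
  expect_equal(res$beta, 2, tolerance = 1e-10)
  expect_lt(res$pval, 1e-200)
  # closed-form OLS oracle on a 12-sample table
  tab12 <- simulate_plaque_table(12, c(G = 1.3), noise_sd = 0.8, seed = 2)
  x <- tab12$samples$pvi
  y <- tab12$values[, "G"]
  slope_oracle <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(pvi_association(tab12, "G")$beta, slope_oracle, tolerance = 1e-12)
  # equivariance: scaling the PVI by c scales the slope by 1/c
  tab2 <- tab12
  tab2$samples$pvi <- 4 * tab12$samples$pvi
  expect_equal(pvi_association(tab2, "G")$beta, slope_oracle / 4,
               tolerance = 1e-12)
  # constant features are flagged, not fitted
  tabc <- tab12
  tabc$values[, "G"] <- 7
  expect_equal(pvi_association(tabc, "G")$status, "not_detected")
})

test_that("the null rejection rate of the PVI association is near the nominal level", {
  tab <- simulate_plaque_table(80, c(DUMMY = 0), noise_sd = 1, seed = 10,
                               n_null_features = 400)
  res <- pvi_association_table(tab, fdr = 0.1)
  rate <- mean(res$pval[res$status == "ok"] < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("BH adjustment matches the brute-force step-up procedure", {
  a <- bh_adjust(c(0.01, 0.02, 0.03, 0.04), fdr = 0.1)
  expect_true(all(a$significant))                 # k = 4: 0.04 <= 4*0.1/4
  expect_false(any(bh_adjust(rep(1, 5), 0.1)$significant))
  one <- bh_adjust(0.05, 0.1)
  expect_equal(one$qval, 0.05)
  expect_true(one$significant)
  expect_equal(nrow(bh_adjust(numeric(0))), 0)
  for (i in 1:20) {
    set.seed(300 + i)
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    fdr <- sample(c(0.05, 0.1, 0.2), 1)
    a <- bh_adjust(p, fdr)
    expect_equal(a$significant, bh_oracle_reject(p, fdr))
    expect_true(all(a$qval >= a$pval - 1e-12))
  }
  # discoveries never shrink as the FDR threshold grows
  set.seed(77)
  p <- runif(30)^2
  n_disc <- vapply(c(0.01, 0.05, 0.1, 0.2, 0.5),
                   function(f) sum(bh_adjust(p, f)$significant), numeric(1))
  expect_true(all(diff(n_disc) >= 0))
})

test_that("subgroup fits and interaction tests behave under signal and null", {
  # distinct slopes by sex with low noise: interaction detected
  tab <- simulate_plaque_table(200, c(G = 0), noise_sd = 0.1, seed = 4,
                               sex_interaction = c(G = 2))
  res <- subgroup_and_interaction(tab, "G", "sex")
  expect_lt(res$interaction_p, 1e-6)
  expect_equal(nrow(res$subgroups), 2)
  bM <- res$subgroups$beta[res$subgroups$level == "M"]
  bF <- res$subgroups$beta[res$subgroups$level == "F"]
  expect_gt(bM, 1.5)
  expect_lt(abs(bF), 0.5)
  # null interaction: rejection near the nominal level
  rej <- vapply(1:150, function(i) {
    t0 <- simulate_plaque_table(60, c(G = 1), noise_sd = 1, seed = 5000 + i)
    subgroup_and_interaction(t0, "G", "diabetes")$interaction_p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.005)
  expect_lt(mean(rej), 0.12)
  # age is dichotomised at 65
  res_age <- subgroup_and_interaction(tab, "G", "age65")
  expect_setequal(res_age$subgroups$level, c("<65", ">=65"))
  # a single stratum is an error
  tab1 <- tab
  tab1$samples$sex <- "M"
  expect_error(subgroup_and_interaction(tab1, "G", "sex"),
               class = "mrtriad_single_stratum")
})

test_that("one-vs-rest Wilcoxon matches exact enumeration and handles ties", {
  cells <- structure(list(
    counts = matrix(c(1, 2, 3, 10, 11, 12), ncol = 1,
                    dimnames = list(sprintf("c%d", 1:6), "G")),
    cells = data.frame(cell_id = sprintf("c%d", 1:6),
                       cell_type = rep(c("SMCs", "T-cells"), each = 3),
                       cluster = rep(c("structural", "adaptive_immune"), each = 3))),
    class = "cell_matrix")
  exact <- wilcoxon_one_vs_rest(cells, "G", "SMCs", method = "exact")
  expect_equal(exact$pval, 0.1, tolerance = 1e-12)
  expect_equal(exact$direction, "lower")
  # all-tied expression: p = 1, undefined direction
  cells$counts[, 1] <- 5
  tied <- wilcoxon_one_vs_rest(cells, "G", "SMCs")
  expect_equal(tied$pval, 1)
  expect_true(is.na(tied$direction))
  # normal approximation with continuity correction near exact p; the 0.02
  # bound holds for every dataset once both groups have >= 5 members (at
  # sizes 3-4 the worst-case deviation grows to ~0.037, checked below)
  set.seed(9)
  for (i in 1:25) {
    n1 <- sample(5:8, 1)
    n2 <- sample(5:8, 1)
    x <- rnorm(n1)
    y <- rnorm(n2, sample(c(0, 1), 1))
    cm <- structure(list(
      counts = matrix(c(x, y), ncol = 1,
                      dimnames = list(sprintf("c%d", 1:(n1 + n2)), "G")),
      cells = data.frame(cell_id = sprintf("c%d", 1:(n1 + n2)),
                         cell_type = c(rep("SMCs", n1), rep("T-cells", n2)),
                         cluster = c(rep("structural", n1),
                                     rep("adaptive_immune", n2)))),
      class = "cell_matrix")
    p_norm <- wilcoxon_one_vs_rest(cm, "G", "SMCs")$pval
    expect_lt(abs(p_norm - wilcox_exact_oracle(x, y)), 0.02)
  }
  # exhaustive bound over every attainable rank-sum statistic, sizes 3-8
  worst <- 0
  for (n1 in 3:8) for (n2 in n1:8) for (W in 0:(n1 * n2)) {
    p_exact <- min(1, 2 * min(stats::pwilcox(W, n1, n2),
                              1 - stats::pwilcox(W - 1, n1, n2)))
    mu <- n1 * n2 / 2
    z <- if (W == mu) 0 else
      (W - mu - sign(W - mu) * 0.5) / sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
    worst <- max(worst, abs(2 * stats::pnorm(-abs(z)) - p_exact))
  }
  expect_lt(worst, 0.04)
})

test_that("a gene expressed in one type is flagged higher only in that type", {
  sc <- simulate_single_cell(1500, enriched = c(MARKER = "SMCs"), fold = 12,
                             n_background_genes = 2, seed = 6)
  de <- wilcoxon_all_types(sc, "MARKER")
  types <- de[de$level == "cell_type", ]
  hits <- types$group[types$significant & types$direction == "higher"]
  expect_equal(hits, "SMCs")
  # the broad structural cluster inherits the signal
  clust <- de[de$level == "cluster" & de$group == "structural", ]
  expect_true(clust$significant && clust$direction == "higher")
})

test_that("the prioritised-protein matrix assembles and is deterministic", {
  tri <- data.frame(protein_id = c("P1", "P2"), metabolite_id = c("M1", "M2"),
                    theta_pm = c(0.2, -0.1), theta_mc = c(0.1, 0.2),
                    theta_pc = c(0.02, -0.02), p_pm = 1e-9, p_mc = 1e-9,
                    p_pc = 1e-9, concordant = c(TRUE, TRUE),
                    source_gwas = "S", stringsAsFactors = FALSE)
  prot_tab <- data.frame(feature_id = "P1", beta = 1.5, se = 0.2, pval = 1e-5,
                         n = 50, status = "ok", qval = 1e-4, significant = TRUE,
                         stringsAsFactors = FALSE)
  sc <- simulate_single_cell(300, enriched = c(P1 = "SMCs"), fold = 10,
                             n_background_genes = 0, seed = 7)
  de <- wilcoxon_all_types(sc, "P1")
  drugs <- classify_druggability(c("P1", "P2"),
                                 data.frame(protein_id = "P1", status = "drugged",
                                            drugs = "aspirin",
                                            cardiac_indication = TRUE,
                                            cardiac_side_effect = FALSE))
  m1 <- enrichment_matrix(de, prot_tab, NULL, tri, drugs)
  m2 <- enrichment_matrix(de, prot_tab, NULL, tri, drugs)
  expect_identical(m1, m2)
  expect_equal(colnames(m1), c("P1", "P2"))
  expect_equal(m1["chd_effect", ], c(P1 = "increasing", P2 = "decreasing"))
  expect_equal(m1["protein_pvi", "P1"], "up")
  expect_equal(m1["druggability", "P2"], "not_yet_druggable")
  # protein without single-cell data gets NA cell-type rows
  expect_true(all(is.na(m1["SMCs", "P2"])))
  expect_equal(m1["SMCs", "P1"], "enriched")
})
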