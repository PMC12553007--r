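test_that("GLS-IVW reduces to the textbook weighted-ratio estimator under identity LD", {
  set.seed(11)
  bx <- runif(5, 0.05, 0.2)
  by <- 0.5 * bx
  instr <- make_instruments(bx, by, se_y = rep(0.01, 5))
  fit <- gls_fit(instr, "ivw")
  expect_equal(fit$slope, 0.5, tolerance = 1e-12)
  expect_lt(fit$Q, 1e-20)
  by2 <- 0.5 * bx + rnorm(5, 0, 0.01)
  se2 <- runif(5, 0.005, 0.02)
  fit2 <- gls_fit(make_instruments(bx, by2, se_y = se2), "ivw")
  expect_equal(fit2$slope, closed_form_ivw(bx, by2, se2), tolerance = 1e-12)
})

test_that("GLS fits match a brute-force matrix-inverse oracle under block LD", {
  for (i in 1:25) {
    set.seed(100 + i)
    m <- sample(3:6, 1)
    bx <- runif(m, 0.05, 0.2) * sample(c(-1, 1), m, TRUE)
    by <- 0.3 * bx + rnorm(m, 0, 0.02)
    se_y <- runif(m, 0.01, 0.03)
    C <- simulate_ld_matrix(m, m, 0.3)
    ids <- sprintf("rs%02d", seq_len(m))
    dimnames(C) <- list(ids, ids)
    instr <- make_instruments(bx, by, se_y, ld = C, ids = ids)
    for (model in c("ivw", "egger")) {
      if (model == "egger" && m < 3) next
      fit <- gls_fit(instr, model)
      ora <- gls_oracle(bx, by, se_y, C, egger = model == "egger")
      expect_equal(fit$slope, ora$slope, tolerance = 1e-8)
      expect_equal(fit$slope_se_fixed, ora$se_fixed, tolerance = 1e-8)
      expect_equal(fit$Q, ora$Q, tolerance = 1e-8)
      expect_equal(unname(fit$leverage), ora$leverage, tolerance = 1e-8)
      if (model == "egger") expect_equal(fit$intercept, ora$intercept,
                                         tolerance = 1e-8)
      # chi-square contributions decompose Q
      expect_equal(sum(fit$std_residual_sq), fit$Q, tolerance = 1e-10)
    }
  }
})

test_that("slope equivariance and orientation conventions hold", {
  set.seed(21)
  m <- 8
  bx <- runif(m, 0.05, 0.2)
  by <- 0.4 * bx + rnorm(m, 0, 0.01)
  se_y <- rep(0.01, m)
  C <- simulate_ld_matrix(m, c(4, 4), 0.25)
  dimnames(C) <- list(sprintf("rs%02d", 1:m), sprintf("rs%02d", 1:m))
  i1 <- make_instruments(bx, by, se_y, ld = C, ids = rownames(C))
  i2 <- make_instruments(-bx, by, se_y, ld = C, ids = rownames(C))
  expect_equal(gls_fit(i2, "ivw")$slope, -gls_fit(i1, "ivw")$slope,
               tolerance = 1e-12)
  # Egger result is invariant to per-variant allele relabelling
  flip <- sample(c(-1, 1), m, TRUE)
  Cf <- C * tcrossprod(flip)
  dimnames(Cf) <- dimnames(C)
  i3 <- make_instruments(flip * bx, flip * by, se_y, ld = Cf, ids = rownames(C))
  e1 <- gls_fit(i1, "egger")
  e3 <- gls_fit(i3, "egger")
  expect_equal(e3$slope, e1$slope, tolerance = 1e-12)
  expect_equal(e3$intercept, e1$intercept, tolerance = 1e-12)
  # Q is invariant to variant ordering
  perm <- sample(m)
  i4 <- make_instruments(bx[perm], by[perm], se_y[perm],
                         ld = C[perm, perm], ids = rownames(C)[perm])
  expect_equal(gls_fit(i4, "ivw")$Q, gls_fit(i1, "ivw")$Q, tolerance = 1e-12)
})

test_that("exact-duplicate instruments are repaired by LD shrinkage", {
  ids <- c("rsA", "rsB", "rsC")
  C <- matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3, dimnames = list(ids, ids))
  instr <- make_instruments(c(0.1, 0.1, 0.12), c(0.05, 0.05, 0.06),
                            rep(0.01, 3), ld = C, ids = ids)
  fit <- gls_fit(instr, "ivw")
  expect_gt(fit$ld_lambda, 0)
  expect_true(is.finite(fit$slope))
})

test_that("leverage and outlier pruning follows the stated rules", {
  set.seed(31)
  m <- 10
  bx <- runif(m, 0.05, 0.2)
  se_y <- rep(0.01, m)
  # perfectly proportional: no residual, no outlier exclusions
  instr0 <- make_instruments(bx, 0.3 * bx, se_y)
  fit0 <- gls_fit(instr0, "ivw")
  expect_equal(nrow(prune_flags(fit0)), 0)
  # balanced design: every leverage equals the mean -> no leverage exclusion
  instr_b <- make_instruments(rep(0.1, m), 0.3 * rep(0.1, m) + rnorm(m, 0, 0.005),
                              rep(0.01, m))
  fit_b <- gls_fit(instr_b, "ivw")
  h <- fit_b$leverage
  expect_true(all(abs(h - mean(h)) < 1e-12))
  expect_false(any(prune_flags(fit_b)$reason == "leverage"))
  # a variant whose chi-square contribution exceeds 10.83 is excluded as outlier
  by <- 0.3 * bx
  by[4] <- by[4] + sqrt(20) * se_y[4]
  instr1 <- make_instruments(bx, by, se_y)
  fit1 <- gls_fit(instr1, "ivw")
  expect_gt(fit1$std_residual_sq[["rs004"]], 10.83)
  pr <- leverage_outlier_prune(fit1, instr1)
  expect_true("rs004" %in% pr$excluded$variant_id)
  expect_equal(pr$fit$n_variants_used, m - nrow(pr$excluded))
  # pruning below the model's minimum signals insufficient_instruments
  instr_small <- make_instruments(c(0.1, 0.1), c(0.03, 0.5), rep(0.01, 2))
  fit_small <- gls_fit(instr_small, "ivw")
  expect_error(leverage_outlier_prune(fit_small, instr_small),
               class = "mrtriad_insufficient_instruments")
})

test_that("model selection prefers parsimony unless Egger clearly fits better", {
  f_i <- fake_fit("E", "O", 0.3, 0.01)
  f_i$Q <- 20; f_i$model <- "IVW"
  f_e <- fake_fit("E", "O", 0.2, 0.05)
  f_e$Q <- 20; f_e$model <- "Egger"
  expect_equal(select_model(f_i, f_e)$model, "IVW")       # equal Q -> parsimony
  f_e$Q <- 10
  sel <- select_model(f_i, f_e)                            # dQ = 10 > 3.841
  expect_equal(sel$model, "Egger")
  expect_equal(sel$selection$critical, qchisq(0.95, 1))
  f_e$Q <- 16.2                                            # dQ = 3.8 < 3.841
  expect_equal(select_model(f_i, f_e)$model, "IVW")
  noegger <- select_model(f_i, NULL)
  expect_equal(noegger$model, "IVW")
  expect_true(noegger$selection$egger_unfit)
})

test_that("run_mr enforces the six-variant rule and reports odds ratios", {
  mk <- function(m, ids = sprintf("rs%03d", seq_len(m))) {
    bx <- runif(m, 0.06, 0.2)
    prot <- make_sumstats("P", "protein", beta = bx, se = rep(0.01, m),
                          ids = ids, locus = list(chrom = "1", start = 1e6,
                                                  end = 1.02e6))
    out <- make_sumstats("O", "disease",
                         beta = 0.2 * bx + rnorm(m, 0, 0.001),
                         se = rep(0.005, m), ids = ids)
    list(p = prot, o = out, ld = identity_ld(ids))
  }
  set.seed(7)
  five <- mk(5)
  r5 <- run_mr(five$p, five$o, five$ld)
  expect_true(is_discarded(r5))
  expect_equal(r5$reason, "fewer_than_six")
  six <- mk(6)
  r6 <- run_mr(six$p, six$o, six$ld)
  expect_false(is_discarded(r6))
  expect_equal(r6$n_variants_used, 6)
  expect_equal(r6$or, exp(r6$slope))
  # disjoint variant sets are discarded as no_overlap
  other <- make_sumstats("O", "disease", beta = rep(0.1, 6), se = rep(0.01, 6),
                         ids = sprintf("zz%03d", 1:6))
  r0 <- run_mr(six$p, other, identity_ld(c(sprintf("rs%03d", 1:6),
                                           sprintf("zz%03d", 1:6))))
  expect_true(is_discarded(r0))
  expect_equal(r0$reason, "no_overlap")
})

test_that("MR results serialise to a one-row-per-pair table", {
  set.seed(8)
  ids <- sprintf("rs%03d", 1:8)
  bx <- runif(8, 0.06, 0.2)
  prot <- make_sumstats("P", "protein", beta = bx, se = rep(0.01, 8),
                        ids = ids, locus = list(chrom = "1", start = 1e6, end = 1.02e6))
  out <- make_sumstats("O", "disease", beta = 0.2 * bx + rnorm(8, 0, 0.002),
                       se = rep(0.005, 8), ids = ids)
  fit <- run_mr(prot, out, identity_ld(ids))
  d <- withr::local_tempdir()
  tab <- write_mr_results(list(fit, mr_discard("X", "O", "fewer_than_six", 3L)),
                          file.path(d, "mr.tsv"))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$discard_reason, c(NA, "fewer_than_six"))
  expect_true(file.exists(file.path(d, "mr.tsv")))
})
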