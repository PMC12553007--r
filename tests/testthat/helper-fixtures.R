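# Small construction helpers shared across test files.  All fixtures are
# built in code; nothing is read from disk except the shipped annotation
# table.

# a sumstat_set from minimal per-variant vectors
make_sumstats <- function(trait_id = "X", trait_class = "metabolite",
                          beta, se, ids = NULL, eaf = NULL,
                          ea = NULL, oa = NULL, chrom = "1", pos = NULL,
                          n = 10000, pval = NULL, locus = NULL) {
  m <- length(beta)
  ids <- ids %||% sprintf("rs%03d", seq_len(m))
  eaf <- eaf %||% rep(0.3, m)
  ea <- ea %||% rep("A", m)
  oa <- oa %||% rep("G", m)
  pos <- pos %||% seq(1e6, by = 1000, length.out = m)
  pval <- pval %||% pmax(2 * stats::pnorm(-abs(beta / se)), 1e-300)
  sumstat_set(trait_id, trait_class,
              data.frame(variant_id = ids, chrom = chrom, pos = pos,
                         effect_allele = ea, other_allele = oa, eaf = eaf,
                         beta = beta, se = se, pval = pval, n = n,
                         stringsAsFactors = FALSE),
              locus = locus)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# identity LD over given ids
identity_ld <- function(ids) {
  diag(length(ids)) |> (\(m) {
    dimnames(m) <- list(ids, ids)
    m
  })()
}

# an instrument_set straight from vectors (already harmonised)
make_instruments <- function(bx, by, se_y, ld = NULL, se_x = NULL,
                             ids = NULL) {
  m <- length(bx)
  ids <- ids %||% sprintf("rs%03d", seq_len(m))
  ld <- ld %||% identity_ld(ids)
  if (is.null(dimnames(ld)[[1]])) dimnames(ld) <- list(ids, ids)
  instrument_set("EXP", "OUT",
                 data.frame(variant_id = ids, bx = bx,
                            se_x = se_x %||% rep(0.01, m), by = by,
                            se_y = se_y, eaf = rep(0.3, m),
                            pval_x = rep(1e-10, m), pval_y = rep(0.5, m),
                            stringsAsFactors = FALSE),
                 ld)
}

# a minimal stand-in MR fit for screening/triangulation plumbing tests
fake_fit <- function(exposure_id, outcome_id, slope, pval) {
  structure(list(exposure_id = exposure_id, outcome_id = outcome_id,
                 model = "IVW", slope = slope, pval = pval),
            class = "mr_fit")
}

# textbook inverse-variance-weighted slope through the origin
closed_form_ivw <- function(bx, by, se_y) {
  sum(bx * by / se_y^2) / sum(bx^2 / se_y^2)
}

# brute-force GLS oracle: explicit matrix inverses, no whitening
gls_oracle <- function(bx, by, se_y, C, egger = FALSE) {
  if (egger) {
    flip <- ifelse(bx < 0, -1, 1)
    bx <- flip * bx
    by <- flip * by
    C <- C * tcrossprod(flip)
  }
  X <- if (egger) cbind(1, bx) else cbind(bx)
  Omega <- diag(se_y) %*% C %*% diag(se_y)
  Oi <- solve(Omega)
  A <- solve(t(X) %*% Oi %*% X)
  coefs <- A %*% t(X) %*% Oi %*% by
  resid <- by - X %*% coefs
  list(slope = unname(coefs[nrow(coefs), 1]),
       intercept = if (egger) unname(coefs[1, 1]) else NA_real_,
       se_fixed = unname(sqrt(diag(A))[length(coefs)]),
       Q = drop(t(resid) %*% Oi %*% resid),
       leverage = unname(diag(X %*% A %*% t(X) %*% Oi)))
}

# independent greedy clumping oracle (plain loop over a matrix of r2)
clump_oracle <- function(ids, pvals, ld, r2_max) {
  ord <- order(pvals, ids)
  pool <- ids[ord]
  kept <- character(0)
  while (length(pool) > 0) {
    lead <- pool[1]
    kept <- c(kept, lead)
    keep <- vapply(pool, function(v) ld[lead, v]^2 <= r2_max, logical(1))
    pool <- setdiff(pool[keep], lead)
  }
  kept
}

# exact two-sided rank-sum p by enumeration of all group assignments
wilcox_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  W_obs <- sum(rank(pooled)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  Ws <- apply(combs, 2, function(idx) {
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2
  })
  mu <- n1 * (length(y)) / 2
  mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-9)
}

# brute-force BH step-up: largest k with p_(k) <= k * fdr / m
bh_oracle_reject <- function(p, fdr) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- max(c(0, which(ps <= seq_len(m) * fdr / m)))
  rej <- rep(FALSE, m)
  if (k > 0) rej[o[seq_len(k)]] <- TRUE
  rej
}

# exact hypergeometric upper tail by combinatorial sum
hyper_tail_oracle <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}
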