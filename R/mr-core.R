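#' Tuning parameters of the MR pipeline
#'
#' Collects every threshold of the estimation cascade.  Defaults are the
#' analysis settings of the triangulation design: instrument F-statistic
#' at least 24, minor allele frequency at least 0.01, LD clumping at
#' r-squared 0.30, at least six variants per reported fit, leverage
#' exclusion above three times the mean leverage, outlier exclusion above
#' a chi-square of 10.83 (the 1-df critical value at two-sided p = 0.001),
#' and IVW-versus-Egger selection at alpha = 0.05.
#'
#' @param f_min,maf_min,r2_max Instrument filters (see
#'   [select_instruments()]).
#' @param min_variants Minimum variants for a reported fit (default 6).
#' @param leverage_mult Leverage exclusion multiplier (default 3).
#' @param chisq_cut Outlier chi-square cut-off (default 10.83).
#' @param alpha Model-selection significance level (default 0.05).
#' @param prune_passes Number of prune-and-refit passes (default 1).
#' @param window_bp Cis window in base pairs (default 200 kb).
#' @param kappa_max Condition-number bound above which the LD correlation
#'   is shrunk towards the identity before inversion.
#' @return List of class `mr_config`.
#' @export
mr_config <- function(f_min = 24, maf_min = 0.01, r2_max = 0.30,
                      min_variants = 6L, leverage_mult = 3, chisq_cut = 10.83,
                      alpha = 0.05, prune_passes = 1L, window_bp = 200000L,
                      kappa_max = 1e8) {
  structure(list(f_min = f_min, maf_min = maf_min, r2_max = r2_max,
                 min_variants = as.integer(min_variants),
                 leverage_mult = leverage_mult, chisq_cut = chisq_cut,
                 alpha = alpha, prune_passes = as.integer(prune_passes),
                 window_bp = window_bp, kappa_max = kappa_max),
            class = "mr_config")
}

# Shrink a correlation matrix towards the identity by the minimal lambda
# that brings its condition number below kappa_max.  Returns the matrix
# with attribute "lambda" (0 when untouched).
.regularise_corr <- function(C, kappa_max = 1e8) {
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  emax <- max(ev)
  emin <- min(ev)
  lambda <- 0
  if (emin <= 0 || emax / emin > kappa_max) {
    lambda <- (emax - kappa_max * emin) / (emax - 1 + kappa_max * (1 - emin))
    lambda <- min(max(lambda, 0), 1)
    C <- (1 - lambda) * C + diag(lambda, nrow(C))
  }
  attr(C, "lambda") <- lambda
  C
}

#' GLS inverse-variance-weighted or MR-Egger fit on an instrument set
#'
#' Fits the variant-level model `by = X beta + e`, `X = bx` (IVW, slope
#' through the origin) or `X = [1, bx]` (Egger, free intercept capturing
#' directional pleiotropy), by generalised least squares with working
#' covariance `Omega = S C S`, where `S = diag(se_y)` and `C` is the LD
#' correlation among the instruments.  Coefficients are
#' `(X' Omega^-1 X)^-1 X' Omega^-1 by`; the heterogeneity statistic `Q`
#' is the weighted residual sum of squares; per-variant leverage is the
#' diagonal of `X (X' Omega^-1 X)^-1 X' Omega^-1` and the per-variant
#' chi-square contribution is the squared whitened residual (they sum to
#' `Q`).  For Egger the conventional orientation is applied first: all
#' variants are flipped so `bx >= 0` (LD correlations flip accordingly).
#'
#' The reported standard error is the fixed-effect GLS standard error
#' inflated by `sqrt(max(1, Q / Q_df))` (multiplicative random effects);
#' the uninflated value is stored as `slope_se_fixed`.  Two-sided
#' p-values use the normal approximation and `ci95 = slope +/- 1.96 se`.
#' Near-singular LD is shrunk towards the identity (see [mr_config()]);
#' the applied shrinkage is recorded in `ld_lambda`.
#'
#' @param instr An [instrument_set].
#' @param model `"ivw"` or `"egger"`.
#' @param config An [mr_config] (only `kappa_max` is used here).
#' @return Object of class `mr_fit`.
#' @export
gls_fit <- function(instr, model = c("ivw", "egger"), config = mr_config()) {
  model <- match.arg(model)
  v <- instr$variants
  n <- nrow(v)
  p <- if (model == "ivw") 1L else 2L
  mrt_assert(n >= p + 1L || (model == "ivw" && n >= 2L),
             sprintf("%s requires at least %d variants", model, p + 1L),
             "mrtriad_too_few_variants")
  bx <- v$bx
  by <- v$by
  se_y <- v$se_y
  C <- instr$ld
  if (model == "egger") {
    flip <- ifelse(bx < 0, -1, 1)
    bx <- flip * bx
    by <- flip * by
    C <- C * tcrossprod(flip)
  }
  C <- .regularise_corr(C, config$kappa_max)
  lambda <- attr(C, "lambda")
  U <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(U)) {
    dup <- which(abs(C) > 0.999 & row(C) < col(C), arr.ind = TRUE)
    pairs <- if (nrow(dup) > 0)
      paste(v$variant_id[dup[, 1]], v$variant_id[dup[, 2]], sep = "~", collapse = ", ")
    else "unknown"
    mrt_stop(paste("singular LD covariance; near-duplicate variants:", pairs),
             "mrtriad_singular_ld")
  }
  X <- if (model == "ivw") cbind(bx = bx) else cbind(intercept = 1, bx = bx)
  # whiten: z = L^-1 (y / se), cov(z) = I, with C = L L'
  L <- t(U)
  yw <- forwardsolve(L, by / se_y)
  Xw <- forwardsolve(L, X / se_y)
  XtX <- crossprod(Xw)
  A <- solve(XtX)                       # (X' Omega^-1 X)^-1
  coefs <- setNames(drop(A %*% crossprod(Xw, yw)), colnames(X))
  resid_w <- yw - drop(Xw %*% coefs)
  Q <- sum(resid_w^2)
  Q_df <- n - p
  # leverage: diag of X (X'Omega^-1 X)^-1 X' Omega^-1
  Cinv <- chol2inv(U)
  Oinv_X <- (Cinv %*% (X / se_y)) / se_y
  h <- rowSums((X %*% A) * Oinv_X)
  infl <- if (Q_df > 0) sqrt(max(1, Q / Q_df)) else 1
  se_fixed <- sqrt(diag(A))
  se_rep <- se_fixed * infl
  slope <- coefs[["bx"]]
  slope_se <- se_rep[[which(colnames(X) == "bx")]]
  pval <- 2 * pnorm(-abs(slope / slope_se))
  fit <- list(
    exposure_id = instr$exposure_id, outcome_id = instr$outcome_id,
    model = if (model == "ivw") "IVW" else "Egger",
    slope = slope, slope_se = slope_se,
    slope_se_fixed = se_fixed[[which(colnames(X) == "bx")]],
    ci95 = c(lo = slope - 1.96 * slope_se, hi = slope + 1.96 * slope_se),
    pval = pval,
    intercept = if (model == "egger") coefs[["intercept"]] else NA_real_,
    intercept_se = if (model == "egger") se_rep[[1]] else NA_real_,
    intercept_p = if (model == "egger")
      2 * pnorm(-abs(coefs[["intercept"]] / se_rep[[1]])) else NA_real_,
    Q = Q, Q_df = Q_df, n_variants_used = n,
    excluded = data.frame(variant_id = character(0), reason = character(0),
                          stringsAsFactors = FALSE),
    leverage = setNames(h, v$variant_id),
    std_residual_sq = setNames(resid_w^2, v$variant_id),
    ld_lambda = lambda
  )
  class(fit) <- "mr_fit"
  fit
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("<mr_fit> %s -> %s [%s]: slope %.4f (se %.4f), p = %.3g, Q = %.2f (df %d), %d variants\n",
              x$exposure_id, x$outcome_id, x$model, x$slope, x$slope_se,
              x$pval, x$Q, x$Q_df, x$n_variants_used))
  invisible(x)
}

#' Exclude high-leverage and outlying variants and refit once
#'
#' Flags variants whose leverage exceeds `leverage_mult` times the mean
#' leverage and/or whose chi-square contribution to `Q` exceeds
#' `chisq_cut`, removes them, and refits the same model on the reduced
#' set.  A single pass (flag once, refit once) is performed per call.
#'
#' @param fit An [gls_fit()] result on `instr`.
#' @param instr The [instrument_set] the fit was computed on.
#' @param leverage_mult Leverage multiplier (default 3).
#' @param chisq_cut Outlier chi-square cut-off (default 10.83).
#' @param config An [mr_config] passed to the refit.
#' @return List with `instruments` (pruned set), `fit` (refit) and
#'   `excluded` (data frame `variant_id`, `reason`).  Signals an error of
#'   class `mrtriad_insufficient_instruments` when pruning leaves fewer
#'   variants than the model needs.
#' @export
leverage_outlier_prune <- function(fit, instr, leverage_mult = 3,
                                   chisq_cut = 10.83, config = mr_config()) {
  flags <- prune_flags(fit, leverage_mult, chisq_cut)
  if (nrow(flags) == 0) {
    return(list(instruments = instr, fit = fit, excluded = flags))
  }
  keep <- !(instr$variants$variant_id %in% flags$variant_id)
  p_need <- if (fit$model == "IVW") 2L else 3L
  if (sum(keep) < p_need) {
    mrt_stop("insufficient_instruments after leverage/outlier pruning",
             "mrtriad_insufficient_instruments")
  }
  pruned <- instrument_set(
    instr$exposure_id, instr$outcome_id,
    instr$variants[keep, , drop = FALSE], instr$ld,
    rbind(instr$exclusion_log,
          data.frame(variant_id = flags$variant_id, stage = "prune",
                     reason = flags$reason, stringsAsFactors = FALSE))
  )
  refit <- gls_fit(pruned, tolower(fit$model), config)
  refit$excluded <- flags
  list(instruments = pruned, fit = refit, excluded = flags)
}

#' Variants flagged by the leverage/outlier rules of a fit
#'
#' @inheritParams leverage_outlier_prune
#' @return Data frame `variant_id`, `reason` (`"leverage"` takes
#'   precedence when a variant trips both rules).
#' @export
prune_flags <- function(fit, leverage_mult = 3, chisq_cut = 10.83) {
  h <- fit$leverage
  lev <- h > leverage_mult * mean(h)
  out <- fit$std_residual_sq > chisq_cut
  flagged <- lev | out
  data.frame(variant_id = names(h)[flagged],
             reason = ifelse(lev[flagged], "leverage", "outlier"),
             stringsAsFactors = FALSE)
}

#' Choose between the IVW and Egger fits of the same instrument set
#'
#' Goodness-of-fit versus parsimony: Egger is selected if and only if the
#' drop in heterogeneity, `Q_ivw - Q_egger`, exceeds the chi-square
#' critical value with 1 degree of freedom at level `alpha`; otherwise
#' the more parsimonious IVW model is kept.  The decision statistic and
#' both Q values are recorded on the returned fit (`$selection`).
#'
#' @param fit_ivw,fit_egger Fits on the same (pruned) variant set;
#'   `fit_egger` may be `NULL` when too few variants were available, in
#'   which case IVW is returned flagged with `egger_unfit = TRUE`.
#' @param alpha Significance level (default 0.05).
#' @return The selected [gls_fit()] object with a `$selection` record.
#' @export
select_model <- function(fit_ivw, fit_egger, alpha = 0.05) {
  if (is.null(fit_egger)) {
    fit_ivw$selection <- list(chosen = "IVW", egger_unfit = TRUE,
                              dQ = NA_real_, critical = NA_real_,
                              Q_ivw = fit_ivw$Q, Q_egger = NA_real_)
    return(fit_ivw)
  }
  dQ <- fit_ivw$Q - fit_egger$Q
  crit <- qchisq(1 - alpha, df = 1)
  chosen <- if (dQ > crit) fit_egger else fit_ivw
  chosen$selection <- list(chosen = chosen$model, egger_unfit = FALSE,
                           dQ = dQ, critical = crit,
                           Q_ivw = fit_ivw$Q, Q_egger = fit_egger$Q)
  chosen
}

#' Full MR cascade for one exposure-outcome pair
#'
#' Instrument selection, initial IVW and Egger fits, one joint
#' leverage/outlier pruning pass (the union of variants flagged by either
#' initial fit is removed so both models are refit on the same set),
#' refit, and IVW-versus-Egger model selection.  Whenever fewer than
#' `min_variants` variants remain at any fitting stage, a discard marker
#' (class `mr_discard`) is returned instead of a fit.
#'
#' @param exposure,outcome [sumstat_set]s.
#' @param ld LD correlation matrix covering the exposure's variants.
#' @param config An [mr_config].
#' @return An `mr_fit` (with `$instruments`, `$fit_ivw`, `$fit_egger`
#'   attached) or an `mr_discard` list with `reason` and counts.
#' @export
run_mr <- function(exposure, outcome, ld, config = mr_config()) {
  instr <- select_instruments(exposure, outcome, ld,
                              f_min = config$f_min, maf_min = config$maf_min,
                              r2_max = config$r2_max, window_bp = config$window_bp)
  n0 <- nrow(instr$variants)
  if (n0 == 0 && any(instr$exclusion_log$reason == "no_overlap")) {
    return(mr_discard(exposure$trait_id, outcome$trait_id, "no_overlap", 0L, instr))
  }
  if (n0 < config$min_variants) {
    return(mr_discard(exposure$trait_id, outcome$trait_id, "fewer_than_six", n0, instr))
  }
  egger_or_null <- function(ins) {
    if (nrow(ins$variants) < 3) return(NULL)
    # a degenerate design (constant bx) leaves the intercept and slope
    # unidentifiable; treat Egger as unfit rather than failing the cascade
    tryCatch(gls_fit(ins, "egger", config), error = function(e) NULL)
  }
  fit_i <- gls_fit(instr, "ivw", config)
  fit_e <- egger_or_null(instr)
  flags <- prune_flags(fit_i, config$leverage_mult, config$chisq_cut)
  if (!is.null(fit_e)) {
    flags_e <- prune_flags(fit_e, config$leverage_mult, config$chisq_cut)
    flags <- rbind(flags, flags_e[!(flags_e$variant_id %in% flags$variant_id), ,
                                  drop = FALSE])
  }
  passes <- config$prune_passes
  if (passes > 0 && nrow(flags) > 0) {
    keep <- !(instr$variants$variant_id %in% flags$variant_id)
    if (sum(keep) < config$min_variants) {
      return(mr_discard(exposure$trait_id, outcome$trait_id, "fewer_than_six",
                        sum(keep), instr, excluded = flags))
    }
    instr <- instrument_set(
      instr$exposure_id, instr$outcome_id,
      instr$variants[keep, , drop = FALSE], instr$ld,
      rbind(instr$exclusion_log,
            data.frame(variant_id = flags$variant_id, stage = "prune",
                       reason = flags$reason, stringsAsFactors = FALSE)))
    fit_i <- gls_fit(instr, "ivw", config)
    fit_e <- egger_or_null(instr)
  }
  sel <- select_model(fit_i, fit_e, config$alpha)
  sel$excluded <- flags
  if (outcome$trait_class == "disease") {
    sel$or <- exp(sel$slope)
    sel$or_ci95 <- exp(sel$ci95)
  }
  sel$instruments <- instr
  sel$fit_ivw <- fit_i
  sel$fit_egger <- fit_e
  sel
}

#' Discard marker for analyses that fail the minimum-variant rule
#'
#' @param exposure_id,outcome_id Trait identifiers.
#' @param reason `"fewer_than_six"` or `"no_overlap"`.
#' @param n_variants Variants remaining when the analysis was discarded.
#' @param instruments The instrument set at discard time (may be empty).
#' @param excluded Optional data frame of pruning exclusions.
#' @return List of class `mr_discard`.
#' @export
mr_discard <- function(exposure_id, outcome_id, reason, n_variants,
                       instruments = NULL, excluded = NULL) {
  structure(list(exposure_id = exposure_id, outcome_id = outcome_id,
                 discarded = TRUE, reason = reason,
                 n_variants = n_variants, instruments = instruments,
                 excluded = excluded),
            class = "mr_discard")
}

#' @export
print.mr_discard <- function(x, ...) {
  cat(sprintf("<mr_discard> %s -> %s: %s (%d variants)\n",
              x$exposure_id, x$outcome_id, x$reason, x$n_variants))
  invisible(x)
}

#' Is an MR result a discard marker?
#'
#' @param x Result of [run_mr()].
#' @return Logical scalar.
#' @export
is_discarded <- function(x) inherits(x, "mr_discard")

#' Write MR results (fits and discards) as a TSV table
#'
#' One row per exposure-outcome pair with model, slope, standard error,
#' odds ratio (disease outcomes), confidence interval, p-value, Q
#' statistic, variant counts, exclusion counts and discard reason.
#'
#' @param fits List of [run_mr()] results.
#' @param path File path.
#' @return The assembled data frame, invisibly.
#' @export
write_mr_results <- function(fits, path) {
  rows <- lapply(fits, function(f) {
    if (is_discarded(f)) {
      data.frame(exposure_id = f$exposure_id, outcome_id = f$outcome_id,
                 model = NA_character_, slope = NA_real_, se = NA_real_,
                 or = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                 pval = NA_real_, Q = NA_real_, Q_df = NA_integer_,
                 n_variants = f$n_variants, n_excluded_leverage = NA_integer_,
                 n_excluded_outlier = NA_integer_, discard_reason = f$reason,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(exposure_id = f$exposure_id, outcome_id = f$outcome_id,
                 model = f$model, slope = f$slope, se = f$slope_se,
                 or = if (!is.null(f$or)) f$or else NA_real_,
                 ci_lo = f$ci95[["lo"]], ci_hi = f$ci95[["hi"]],
                 pval = f$pval, Q = f$Q, Q_df = f$Q_df,
                 n_variants = f$n_variants_used,
                 n_excluded_leverage = sum(f$excluded$reason == "leverage"),
                 n_excluded_outlier = sum(f$excluded$reason == "outlier"),
                 discard_reason = NA_character_, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
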