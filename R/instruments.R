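#' Instrument F-statistic
#'
#' Squared Wald ratio `(beta / se)^2`, the per-variant instrument-strength
#' statistic the weak-instrument filter is applied to.  Vectorised.
#'
#' @param beta Effect estimate(s).
#' @param se Standard error(s), all `> 0`.
#' @return Numeric F-statistics.
#' @export
f_statistic <- function(beta, se) {
  mrt_assert(all(se > 0), "se must be > 0")
  (beta / se)^2
}

#' Restrict a protein's summary statistics to its cis window
#'
#' Keeps variants on the encoding gene's chromosome whose position lies in
#' the closed interval `[start - window_bp, end + window_bp]`.
#'
#' @param protein A [sumstat_set] of class `"protein"` with a locus.
#' @param window_bp Window in base pairs around and within the gene
#'   (default 200 kb).
#' @return The filtered [sumstat_set].
#' @export
cis_window <- function(protein, window_bp = 200000L) {
  mrt_assert(!is.null(protein$locus), "cis_window requires a protein locus",
             "mrtriad_missing_locus")
  r <- protein$records
  keep <- r$chrom == protein$locus$chrom &
    r$pos >= protein$locus$start - window_bp &
    r$pos <= protein$locus$end + window_bp
  protein$records <- r[keep, , drop = FALSE]
  protein
}

#' Align outcome summary statistics to the exposure's effect alleles
#'
#' Variants are matched on `variant_id`.  When the outcome's effect/other
#' alleles are swapped relative to the exposure, the outcome beta is
#' negated and its allele frequency reflected; variants with incompatible
#' allele pairs are dropped and logged.  Palindromic (A/T, C/G) variants
#' are aligned by allele labels only, without frequency-based flipping;
#' each is noted in the log so the decision can be audited.
#'
#' @param exposure,outcome [sumstat_set]s.
#' @return List with `variants` (data frame: `variant_id`, `bx`, `se_x`,
#'   `by`, `se_y`, `eaf`, `pval_x`, `pval_y`) and `log` (data frame:
#'   `variant_id`, `stage`, `reason`).  An empty variant intersection
#'   yields an empty result with a log entry, not an error.
#' @export
harmonise <- function(exposure, outcome) {
  mrt_assert(nrow(exposure$records) > 0 && nrow(outcome$records) > 0,
             "both summary-statistic sets must be non-empty")
  ex <- exposure$records
  ou <- outcome$records
  common <- intersect(ex$variant_id, ou$variant_id)
  empty_log <- data.frame(variant_id = character(0), stage = character(0),
                          reason = character(0), stringsAsFactors = FALSE)
  if (length(common) == 0) {
    return(list(
      variants = data.frame(variant_id = character(0), bx = numeric(0),
                            se_x = numeric(0), by = numeric(0), se_y = numeric(0),
                            eaf = numeric(0), pval_x = numeric(0), pval_y = numeric(0)),
      log = data.frame(variant_id = "*", stage = "harmonise",
                       reason = "no_overlap", stringsAsFactors = FALSE)
    ))
  }
  ex <- ex[match(common, ex$variant_id), ]
  ou <- ou[match(common, ou$variant_id), ]
  same <- ex$effect_allele == ou$effect_allele & ex$other_allele == ou$other_allele
  swapped <- ex$effect_allele == ou$other_allele & ex$other_allele == ou$effect_allele
  mismatch <- !(same | swapped)
  by <- ifelse(swapped, -ou$beta, ou$beta)
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  palin <- ex$other_allele == comp[ex$effect_allele]
  log <- empty_log
  if (any(mismatch)) {
    log <- rbind(log, data.frame(variant_id = common[mismatch], stage = "harmonise",
                                 reason = "allele_mismatch", stringsAsFactors = FALSE))
  }
  keep_palin <- palin & !mismatch
  if (any(keep_palin)) {
    log <- rbind(log, data.frame(variant_id = common[keep_palin], stage = "harmonise",
                                 reason = "palindromic_kept", stringsAsFactors = FALSE))
  }
  keep <- !mismatch
  list(
    variants = data.frame(variant_id = common[keep], bx = ex$beta[keep],
                          se_x = ex$se[keep], by = by[keep], se_y = ou$se[keep],
                          eaf = ex$eaf[keep], pval_x = ex$pval[keep],
                          pval_y = ou$pval[keep], stringsAsFactors = FALSE),
    log = log
  )
}

#' Greedy LD clumping at an r-squared bound
#'
#' Greedy by ascending exposure p-value (ties broken by ascending
#' `variant_id`): the best remaining variant is retained and every other
#' remaining variant with `r^2 > r2_max` against it is removed; repeat.
#' Every retained pair therefore satisfies `r^2 <= r2_max`.
#'
#' @param variants Data frame with at least `variant_id` and `pval`.
#' @param ld LD correlation matrix covering all variants.
#' @param r2_max Maximum allowed pairwise r-squared (default 0.30).
#' @return Character vector of retained variant ids, in retention order.
#' @export
clump_variants <- function(variants, ld, r2_max = 0.30) {
  ids <- variants$variant_id
  mrt_assert(all(ids %in% rownames(ld)), "variant missing from LD matrix",
             "mrtriad_missing_ld")
  ord <- order(variants$pval, variants$variant_id)
  remaining <- ids[ord]
  retained <- character(0)
  while (length(remaining) > 0) {
    top <- remaining[1]
    retained <- c(retained, top)
    r2 <- ld[top, remaining]^2
    remaining <- remaining[r2 <= r2_max & remaining != top]
  }
  retained
}

#' Bundle harmonised variants, their LD and the exclusion log
#'
#' @param exposure_id,outcome_id Trait identifiers.
#' @param variants Data frame of harmonised quadruples (see [harmonise()]).
#' @param ld LD correlation matrix restricted to (and ordered like) the
#'   retained variants.
#' @param exclusion_log Data frame `variant_id`, `stage`, `reason`.
#' @return Object of class `instrument_set`.
#' @export
instrument_set <- function(exposure_id, outcome_id, variants, ld,
                           exclusion_log = NULL) {
  mrt_assert(all(variants$variant_id %in% rownames(ld)),
             "ld must cover all retained variants")
  ld <- ld[variants$variant_id, variants$variant_id, drop = FALSE]
  structure(list(exposure_id = exposure_id, outcome_id = outcome_id,
                 variants = variants, ld = ld,
                 exclusion_log = exclusion_log %||% data.frame(
                   variant_id = character(0), stage = character(0),
                   reason = character(0), stringsAsFactors = FALSE)),
            class = "instrument_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %s -> %s: %d variants (%d exclusions logged)\n",
              x$exposure_id, x$outcome_id, nrow(x$variants), nrow(x$exclusion_log)))
  invisible(x)
}

#' Select and harmonise MR instruments for one exposure-outcome pair
#'
#' Applies, in order: cis restriction (protein exposures only), minor
#' allele frequency filter on `min(eaf, 1 - eaf)`, F-statistic filter
#' (`(beta/se)^2 >= f_min`, boundary retained), greedy LD clumping, and
#' allele harmonisation against the outcome.  All removals are logged
#' with a stage and reason.  An empty set is returned rather than an
#' error; the minimum-variant rule is enforced downstream.
#'
#' @param exposure,outcome [sumstat_set]s.
#' @param ld LD correlation matrix covering the exposure's variants.
#' @param f_min Minimum F-statistic (default 24).
#' @param maf_min Minimum minor allele frequency (default 0.01).
#' @param r2_max Clumping r-squared bound (default 0.30).
#' @param cis Apply the cis window?  Defaults to `TRUE` for protein
#'   exposures with a locus, otherwise `FALSE` (genome-wide selection
#'   uses identical filters without the cis restriction).
#' @param window_bp Cis window size in base pairs.
#' @return An [instrument_set].
#' @export
select_instruments <- function(exposure, outcome, ld, f_min = 24,
                               maf_min = 0.01, r2_max = 0.30, cis = NULL,
                               window_bp = 200000L) {
  if (is.null(cis)) cis <- exposure$trait_class == "protein" && !is.null(exposure$locus)
  log <- data.frame(variant_id = character(0), stage = character(0),
                    reason = character(0), stringsAsFactors = FALSE)
  add_log <- function(ids, stage, reason) {
    if (length(ids) > 0)
      log <<- rbind(log, data.frame(variant_id = ids, stage = stage,
                                    reason = reason, stringsAsFactors = FALSE))
  }
  work <- exposure
  if (cis) {
    before <- work$records$variant_id
    work <- cis_window(work, window_bp)
    add_log(setdiff(before, work$records$variant_id), "cis_window", "outside_cis")
  }
  r <- work$records
  maf <- pmin(r$eaf, 1 - r$eaf)
  add_log(r$variant_id[maf < maf_min], "maf_filter", "maf")
  r <- r[maf >= maf_min, , drop = FALSE]
  if (nrow(r) > 0) {
    f <- f_statistic(r$beta, r$se)
    add_log(r$variant_id[f < f_min], "f_filter", "weak")
    r <- r[f >= f_min, , drop = FALSE]
  }
  if (nrow(r) > 0) {
    kept <- clump_variants(r, ld, r2_max)
    add_log(setdiff(r$variant_id, kept), "clump", "ld_clump")
    r <- r[match(kept, r$variant_id), , drop = FALSE]
  }
  work$records <- r
  if (nrow(r) > 0) {
    h <- harmonise(work, outcome)
    log <- rbind(log, h$log[h$log$reason != "palindromic_kept", , drop = FALSE],
                 h$log[h$log$reason == "palindromic_kept", , drop = FALSE])
    missing <- setdiff(r$variant_id,
                       c(h$variants$variant_id,
                         h$log$variant_id[h$log$reason == "allele_mismatch"]))
    add_log(missing, "harmonise", "missing_outcome")
    v <- h$variants
  } else {
    v <- data.frame(variant_id = character(0), bx = numeric(0), se_x = numeric(0),
                    by = numeric(0), se_y = numeric(0), eaf = numeric(0),
                    pval_x = numeric(0), pval_y = numeric(0))
  }
  if (nrow(v) > 0) {
    instrument_set(exposure$trait_id, outcome$trait_id, v, ld, log)
  } else {
    empty_ld <- matrix(numeric(0), 0, 0, dimnames = list(character(0), character(0)))
    structure(list(exposure_id = exposure$trait_id, outcome_id = outcome$trait_id,
                   variants = v, ld = empty_ld, exclusion_log = log),
              class = "instrument_set")
  }
}

#' Write an exclusion log as TSV
#'
#' @param log Data frame with `variant_id`, `stage`, `reason`.
#' @param path File path.
#' @export
write_exclusion_log <- function(log, path) {
  write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
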