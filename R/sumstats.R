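#' Construct a set of per-variant summary associations for one trait
#'
#' A `sumstat_set` holds the GWAS summary statistics of a single trait:
#' one row per variant with alleles, effect-allele frequency, effect size,
#' standard error, p-value and sample size.  Protein traits additionally
#' carry the encoding gene's locus so cis windows can be applied.
#'
#' @param trait_id Character scalar identifying the trait (e.g. a protein
#'   or metabolite name, or `"CHD"`).
#' @param trait_class One of `"metabolite"`, `"protein"`, `"disease"`.
#' @param records Data frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#'   Effect sizes are per effect-allele copy, on the standard-deviation
#'   scale for quantitative traits and the log-odds scale for disease.
#' @param locus Optional list with elements `chrom`, `start`, `end` giving
#'   the encoding gene's coordinates (1-based, closed).  Required when
#'   `trait_class = "protein"`.
#' @param study_id Optional character scalar naming the source study; used
#'   when the same protein was measured by several GWAS.
#' @return An object of class `sumstat_set`.
#' @export
sumstat_set <- function(trait_id, trait_class, records, locus = NULL,
                        study_id = NA_character_) {
  trait_class <- match.arg(trait_class, c("metabolite", "protein", "disease"))
  needed <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
              "eaf", "beta", "se", "pval", "n")
  mrt_assert(is.data.frame(records) && all(needed %in% names(records)),
             paste("records must contain columns:", paste(needed, collapse = ", ")))
  records <- as.data.frame(records)[, needed]
  rownames(records) <- NULL
  records$variant_id <- as.character(records$variant_id)
  records$chrom <- as.character(records$chrom)
  mrt_assert(!anyDuplicated(records$variant_id), "duplicate variant_id in records")
  mrt_assert(all(records$se > 0), "all standard errors must be > 0")
  mrt_assert(all(records$eaf > 0 & records$eaf < 1), "eaf must lie in (0,1)")
  mrt_assert(all(records$effect_allele != records$other_allele),
             "effect and other allele must differ")
  if (trait_class == "protein") {
    mrt_assert(is.list(locus) && all(c("chrom", "start", "end") %in% names(locus)),
               "protein traits require locus = list(chrom, start, end)")
  }
  structure(
    list(trait_id = trait_id, trait_class = trait_class,
         records = records, locus = locus, study_id = study_id),
    class = "sumstat_set"
  )
}

#' @export
print.sumstat_set <- function(x, ...) {
  cat(sprintf("<sumstat_set> %s (%s), %d variants\n",
              x$trait_id, x$trait_class, nrow(x$records)))
  if (!is.null(x$locus)) {
    cat(sprintf("  locus: chr%s:%d-%d\n", x$locus$chrom,
                as.integer(x$locus$start), as.integer(x$locus$end)))
  }
  invisible(x)
}

#' Read / write the tab-delimited summary-statistic dialect
#'
#' Files carry one header line with the columns `variant_id`, `chrom`,
#' `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`,
#' `n`, tab-separated.
#'
#' @param path File path.
#' @inheritParams sumstat_set
#' @return `read_sumstats()` returns a [sumstat_set]; `write_sumstats()`
#'   returns `path` invisibly.
#' @export
read_sumstats <- function(path, trait_id, trait_class, locus = NULL,
                          study_id = NA_character_) {
  rec <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = c(variant_id = "character", chrom = "character"))
  sumstat_set(trait_id, trait_class, rec, locus = locus, study_id = study_id)
}

#' @rdname read_sumstats
#' @param x A [sumstat_set].
#' @export
write_sumstats <- function(x, path) {
  mrt_assert(inherits(x, "sumstat_set"), "x must be a sumstat_set")
  write.table(x$records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an LD correlation matrix as a square TSV
#'
#' The on-disk form is a square tab-delimited matrix whose header line and
#' first column repeat the variant ids; entries are pairwise correlations
#' `r` (not r-squared) with unit diagonal.
#'
#' @param path File path.
#' @return `read_ld_matrix()` returns a validated symmetric matrix with
#'   variant-id dimnames.
#' @export
read_ld_matrix <- function(path) {
  m <- as.matrix(read.delim(path, header = TRUE, sep = "\t",
                            row.names = 1, check.names = FALSE))
  validate_ld_matrix(m)
}

#' @rdname read_ld_matrix
#' @param m Symmetric correlation matrix with variant-id dimnames.
#' @export
write_ld_matrix <- function(m, path) {
  m <- validate_ld_matrix(m)
  df <- data.frame(variant_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate an LD correlation matrix
#'
#' Checks squareness, symmetry (to numerical tolerance), unit diagonal and
#' `|r| <= 1`; symmetrises exactly before returning.
#'
#' @param m Matrix of pairwise correlations with variant-id dimnames.
#' @return The validated (exactly symmetric) matrix.
#' @export
validate_ld_matrix <- function(m) {
  mrt_assert(is.matrix(m) && nrow(m) == ncol(m), "LD matrix must be square")
  mrt_assert(!is.null(rownames(m)) || !is.null(colnames(m)),
             "LD matrix needs variant-id dimnames")
  if (is.null(rownames(m))) rownames(m) <- colnames(m)
  if (is.null(colnames(m))) colnames(m) <- rownames(m)
  mrt_assert(all(abs(m - t(m)) < 1e-8), "LD matrix must be symmetric")
  mrt_assert(all(abs(diag(m) - 1) < 1e-8), "LD matrix must have unit diagonal")
  mrt_assert(all(abs(m) <= 1 + 1e-8), "LD entries must satisfy |r| <= 1")
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}
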