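#' Effective number of tests from principal components
#'
#' The smallest `k` such that the top-`k` eigenvalues of the trait
#' correlation matrix account for at least `variance_target` of the total
#' variance.  Accepts either a traits x observations matrix (rows are
#' traits) or a ready-made trait correlation matrix (square, symmetric,
#' unit diagonal).
#'
#' @param values Traits x observations matrix, or a trait correlation
#'   matrix.
#' @param variance_target Fraction of variance to explain (default 0.90).
#' @return Integer count of effective tests.
#' @export
effective_tests_pca <- function(values, variance_target = 0.90) {
  mrt_assert(all(is.finite(values)), "values must be finite")
  m <- as.matrix(values)
  is_corr <- nrow(m) == ncol(m) && all(abs(m - t(m)) < 1e-8) &&
    all(abs(diag(m) - 1) < 1e-8)
  R <- if (is_corr) m else cor(t(m))
  mrt_assert(nrow(R) >= 2, "need at least 2 traits")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  cum <- cumsum(ev) / sum(ev)
  as.integer(which(cum >= variance_target - 1e-12)[1])
}

#' Bonferroni threshold for a given effective test count
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_effective Number of (effective) tests, >= 1.
#' @return `alpha / n_effective`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_effective) {
  mrt_assert(n_effective >= 1, "n_effective must be >= 1")
  alpha / n_effective
}

#' Multiplicity plan for one MR layer
#'
#' @param layer `"metabolite_chd"`, `"protein_metabolite"` or
#'   `"protein_chd"`.
#' @param method `"bonferroni_pca"` (effective tests from principal
#'   components) or `"bonferroni_count"` (raw test count).
#' @param n_effective Effective number of tests.
#' @param alpha Family-wise error rate (default 0.05).
#' @return List of class `multiplicity_plan` with the derived `threshold`.
#' @export
multiplicity_plan <- function(layer = c("metabolite_chd", "protein_metabolite",
                                        "protein_chd"),
                              method = c("bonferroni_pca", "bonferroni_count"),
                              n_effective, alpha = 0.05) {
  layer <- match.arg(layer)
  method <- match.arg(method)
  structure(list(layer = layer, method = method,
                 n_effective = as.integer(n_effective), alpha = alpha,
                 threshold = bonferroni_threshold(alpha, n_effective)),
            class = "multiplicity_plan")
}

#' Screen one MR layer at its multiplicity threshold
#'
#' Retains fits with selected-model `p` strictly below the plan's
#' threshold; discarded markers and fits at or above the threshold are
#' logged.
#'
#' @param fits List of [run_mr()] results.
#' @param plan A [multiplicity_plan].
#' @return List with `surviving` (fits) and `dropped` (data frame:
#'   `exposure_id`, `outcome_id`, `pval`, `threshold`, `reason`).
#' @export
screen_layer <- function(fits, plan) {
  surviving <- list()
  dropped <- data.frame(exposure_id = character(0), outcome_id = character(0),
                        pval = numeric(0), threshold = numeric(0),
                        reason = character(0), stringsAsFactors = FALSE)
  for (f in fits) {
    if (is_discarded(f)) {
      dropped <- rbind(dropped, data.frame(
        exposure_id = f$exposure_id, outcome_id = f$outcome_id,
        pval = NA_real_, threshold = plan$threshold, reason = f$reason,
        stringsAsFactors = FALSE))
    } else if (f$pval < plan$threshold) {
      surviving <- c(surviving, list(f))
    } else {
      dropped <- rbind(dropped, data.frame(
        exposure_id = f$exposure_id, outcome_id = f$outcome_id,
        pval = f$pval, threshold = plan$threshold, reason = "above_threshold",
        stringsAsFactors = FALSE))
    }
  }
  list(surviving = surviving, dropped = dropped)
}

#' Directional concordance of a protein-metabolite-CHD sign triple
#'
#' A protein's effects are directionally concordant when the sign of its
#' effect on the disease equals the product of the signs of its effect on
#' the metabolite and the metabolite's effect on the disease: for
#' example, if a higher metabolite value lowers disease risk and the
#' protein raises the metabolite, concordance requires that higher
#' protein values lower disease risk.  Vectorised; any zero effect is
#' indeterminate and yields `NA`.
#'
#' @param theta_pm Protein -> metabolite effect(s).
#' @param theta_mc Metabolite -> disease effect(s).
#' @param theta_pc Protein -> disease effect(s).
#' @return Logical vector (`NA` where any effect is zero).
#' @export
concordance <- function(theta_pm, theta_mc, theta_pc) {
  out <- sign(theta_pm) * sign(theta_mc) == sign(theta_pc)
  out[theta_pm == 0 | theta_mc == 0 | theta_pc == 0] <- NA
  out
}

#' Assemble protein-metabolite-CHD triangles from the three screened layers
#'
#' For every protein -> metabolite fit surviving its layer whose
#' metabolite survived the metabolite -> CHD layer and whose protein
#' survived the protein -> CHD layer, one record is emitted carrying the
#' three selected-model slopes, their p-values and the concordance flag.
#'
#' @param pm_fits Surviving protein -> metabolite fits.
#' @param mc_fits Surviving metabolite -> CHD fits.
#' @param pc_fits Surviving protein -> CHD fits.
#' @param source_gwas Optional named character mapping protein id to the
#'   study its fit came from.
#' @return Data frame of class `triangle_table` (one row per
#'   protein-metabolite pair) with attribute `n_unique_proteins`:
#'   concordant proteins are counted once even when concordant via
#'   several metabolites.
#' @export
triangulate <- function(pm_fits, mc_fits, pc_fits, source_gwas = NULL) {
  mc_by_met <- setNames(mc_fits, vapply(mc_fits, `[[`, "", "exposure_id"))
  pc_by_prot <- setNames(pc_fits, vapply(pc_fits, `[[`, "", "exposure_id"))
  rows <- list()
  for (f in pm_fits) {
    prot <- f$exposure_id
    met <- f$outcome_id
    if (!met %in% names(mc_by_met) || !prot %in% names(pc_by_prot)) next
    mc <- mc_by_met[[met]]
    pc <- pc_by_prot[[prot]]
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = prot, metabolite_id = met,
      theta_pm = f$slope, theta_mc = mc$slope, theta_pc = pc$slope,
      p_pm = f$pval, p_mc = mc$pval, p_pc = pc$pval,
      concordant = concordance(f$slope, mc$slope, pc$slope),
      source_gwas = if (!is.null(source_gwas) && prot %in% names(source_gwas))
        source_gwas[[prot]] else NA_character_,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(protein_id = character(0), metabolite_id = character(0),
               theta_pm = numeric(0), theta_mc = numeric(0), theta_pc = numeric(0),
               p_pm = numeric(0), p_mc = numeric(0), p_pc = numeric(0),
               concordant = logical(0), source_gwas = character(0),
               stringsAsFactors = FALSE)
  attr(out, "n_unique_proteins") <-
    length(unique(out$protein_id[out$concordant %in% TRUE]))
  class(out) <- c("triangle_table", class(out))
  out
}

#' Cross-study replication flags for protein-CHD effects
#'
#' For each primary protein fit, looks up the protein in a secondary
#' study and flags: `nominal` replication (secondary `p <= 0.05` with
#' matching effect direction) and `strict` replication (secondary
#' `p <= 0.05 / n_overlap` with matching direction), where `n_overlap`
#' is the number of proteins measured in more than one study (supplied,
#' not hard-coded).
#'
#' @param primary Named list (by protein id) of primary [run_mr()] fits.
#' @param secondary Named list (by protein id) of secondary fits.
#' @param overlap_proteins Character vector of proteins measured in more
#'   than one study; its length sets the strict Bonferroni denominator.
#' @return Data frame: `protein_id`, `nominal`, `strict`,
#'   `direction_agrees`, `secondary_p`, `strict_threshold`, `status`.
#' @export
mr_replicate <- function(primary, secondary, overlap_proteins) {
  n_overlap <- length(overlap_proteins)
  mrt_assert(n_overlap >= 1, "need at least one overlapping protein")
  thr <- 0.05 / n_overlap
  rows <- lapply(names(primary), function(prot) {
    pf <- primary[[prot]]
    sf <- secondary[[prot]]
    if (is.null(sf) || is_discarded(sf)) {
      return(data.frame(protein_id = prot, nominal = NA, strict = NA,
                        direction_agrees = NA, secondary_p = NA_real_,
                        strict_threshold = thr, status = "not_testable",
                        stringsAsFactors = FALSE))
    }
    agree <- sign(pf$slope) == sign(sf$slope)
    data.frame(protein_id = prot,
               nominal = sf$pval <= 0.05 && agree,
               strict = sf$pval <= thr && agree,
               direction_agrees = agree, secondary_p = sf$pval,
               strict_threshold = thr, status = "tested",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pick the largest-sample GWAS for a protein measured in several studies
#'
#' Ties on sample size are broken by the lexicographically smallest study
#' id (a documented, deterministic rule).
#'
#' @param protein_id Protein identifier (carried through to the result).
#' @param studies Data frame with columns `study_id` and `n`.
#' @return The chosen `study_id` (character scalar) with attribute
#'   `"tie"` indicating whether the tie-break fired.
#' @export
choose_largest_gwas <- function(protein_id, studies) {
  mrt_assert(is.data.frame(studies) && nrow(studies) >= 1,
             "studies must be a non-empty data frame")
  best_n <- max(studies$n)
  cand <- sort(studies$study_id[studies$n == best_n])
  structure(cand[1], tie = length(cand) > 1)
}

#' Write a triangle table as TSV
#'
#' @param triangles A [triangulate()] result.
#' @param path File path.
#' @export
write_triangles <- function(triangles, path) {
  write.table(as.data.frame(triangles), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
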