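#' Association of one feature's expression with the plaque vulnerability index
#'
#' Ordinary least squares of expression on the plaque vulnerability index
#' (PVI): the slope is the mean difference in normalised count per unit
#' increase in the PVI, with a two-sided t-test p-value.  The primary
#' model is unadjusted; residual-versus-fitted summaries are attached as
#' a linearity diagnostic.
#'
#' @param table A `plaque_table` (see [simulate_plaque_table()] or
#'   [read_plaque_table()]).
#' @param feature_id Feature (gene/protein) column of `table$values`.
#' @return One-row data frame: `feature_id`, `beta`, `se`, `pval`, `n`,
#'   `status` (`"ok"` or `"not_detected"` for constant features, in which
#'   case the estimates are `NA`).  Attribute `"diagnostics"` carries the
#'   residual-vs-fitted summary.
#' @export
pvi_association <- function(table, feature_id) {
  mrt_assert(feature_id %in% colnames(table$values), "unknown feature_id")
  y <- table$values[, feature_id]
  x <- table$samples$pvi
  ok <- is.finite(y) & is.finite(x)
  y <- y[ok]
  x <- x[ok]
  mrt_assert(length(y) >= 10, "need >= 10 samples with non-missing feature and pvi")
  if (var(y) == 0) {
    out <- data.frame(feature_id = feature_id, beta = NA_real_, se = NA_real_,
                      pval = NA_real_, n = length(y), status = "not_detected",
                      stringsAsFactors = FALSE)
    return(out)
  }
  fit <- lm(y ~ x)
  cf <- summary(fit)$coefficients
  out <- data.frame(feature_id = feature_id, beta = cf["x", "Estimate"],
                    se = cf["x", "Std. Error"], pval = cf["x", "Pr(>|t|)"],
                    n = length(y), status = "ok", stringsAsFactors = FALSE)
  res <- residuals(fit)
  ftd <- fitted(fit)
  attr(out, "diagnostics") <- list(
    resid_mean = mean(res),
    resid_fitted_cor = if (sd(ftd) > 0 && sd(res) > 0) cor(ftd, res) else NA_real_,
    resid_sd = sd(res))
  out
}

#' Benjamini-Hochberg adjustment with significance flags
#'
#' Step-up false discovery rate control; monotone q-values via the
#' standard cumulative-minimum enforcement.  A feature is flagged
#' significant when its q-value is at or below `fdr`.
#'
#' @param pvals Numeric p-values in `(0, 1]`.
#' @param fdr False discovery rate threshold (default 0.1).
#' @return Data frame `pval`, `qval`, `significant` (empty input gives an
#'   empty frame).
#' @export
bh_adjust <- function(pvals, fdr = 0.1) {
  if (length(pvals) == 0) {
    return(data.frame(pval = numeric(0), qval = numeric(0), significant = logical(0)))
  }
  mrt_assert(all(pvals > 0 & pvals <= 1), "p-values must lie in (0,1]")
  q <- p.adjust(pvals, method = "BH")
  data.frame(pval = pvals, qval = q, significant = q <= fdr)
}

#' PVI associations for a family of features with BH correction
#'
#' Runs [pvi_association()] per feature and adjusts the detected
#' features' p-values by Benjamini-Hochberg within this family (the
#' protein-expression and mRNA-expression families are adjusted
#' separately by calling this once per family).
#'
#' @param table A `plaque_table`.
#' @param features Features to test (default: all columns).
#' @param fdr False discovery rate threshold (default 0.1).
#' @return Data frame with one row per feature: estimates, `qval` and
#'   `significant` (NA for undetected features).
#' @export
pvi_association_table <- function(table, features = colnames(table$values),
                                  fdr = 0.1) {
  res <- do.call(rbind, lapply(features, function(f) pvi_association(table, f)))
  res$qval <- NA_real_
  res$significant <- NA
  ok <- res$status == "ok"
  if (any(ok)) {
    adj <- bh_adjust(res$pval[ok], fdr)
    res$qval[ok] <- adj$qval
    res$significant[ok] <- adj$significant
  }
  res
}

#' Subgroup and interaction analysis of a PVI association
#'
#' Stratum-wise OLS fits of expression on the PVI plus a pooled model
#' with a PVI-by-group interaction term; the interaction p-value comes
#' from the interaction coefficient's t-test.  Age is dichotomised at 65
#' years (`< 65` versus `>= 65`).
#'
#' @param table A `plaque_table`.
#' @param feature_id Feature to analyse.
#' @param group_var `"sex"`, `"age65"` or `"diabetes"`.
#' @param min_stratum Minimum samples per stratum (default 5); a smaller
#'   stratum is flagged but the interaction is still attempted when
#'   estimable.
#' @return List with `subgroups` (data frame: `group`, `level`, `beta`,
#'   `se`, `pval`, `n`, `flag`) and `interaction_p`.  Signals an error of
#'   class `mrtriad_single_stratum` when all samples fall in one stratum.
#' @export
subgroup_and_interaction <- function(table, feature_id,
                                     group_var = c("sex", "age65", "diabetes"),
                                     min_stratum = 5L) {
  group_var <- match.arg(group_var)
  y <- table$values[, feature_id]
  x <- table$samples$pvi
  g <- switch(group_var,
              sex = table$samples$sex,
              age65 = ifelse(table$samples$age >= 65, ">=65", "<65"),
              diabetes = table$samples$diabetes)
  g <- factor(g)
  if (nlevels(droplevels(g)) < 2) {
    mrt_stop("single_stratum: all samples fall in one level of the grouping variable",
             "mrtriad_single_stratum")
  }
  sub <- do.call(rbind, lapply(levels(g), function(lv) {
    sel <- g == lv
    n <- sum(sel)
    if (n < 3 || var(y[sel]) == 0 || var(x[sel]) == 0) {
      return(data.frame(group = group_var, level = lv, beta = NA_real_,
                        se = NA_real_, pval = NA_real_, n = n,
                        flag = "too_small", stringsAsFactors = FALSE))
    }
    cf <- summary(lm(y[sel] ~ x[sel]))$coefficients
    data.frame(group = group_var, level = lv, beta = cf[2, "Estimate"],
               se = cf[2, "Std. Error"], pval = cf[2, "Pr(>|t|)"], n = n,
               flag = if (n < min_stratum) "below_min" else "ok",
               stringsAsFactors = FALSE)
  }))
  pooled <- lm(y ~ x * g)
  cf <- summary(pooled)$coefficients
  int_rows <- grep("^x:g", rownames(cf))
  interaction_p <- if (length(int_rows) > 0) cf[int_rows[1], "Pr(>|t|)"] else NA_real_
  list(subgroups = sub, interaction_p = interaction_p)
}

#' One-versus-rest Wilcoxon rank-sum test for a gene in one cell group
#'
#' Compares expression of `gene_id` in cells of one cell type (or broad
#' cluster) against all remaining cells.  The default is the two-sided
#' rank-sum test with mid-ranks for ties, a tie-corrected normal
#' approximation and continuity correction; `method = "exact"` uses the
#' exact distribution (tie-free data only) for validation at small group
#' sizes.  Direction is `"higher"` when the group's mean rank exceeds the
#' complement's.
#'
#' @param cells A `cell_matrix` (see [simulate_single_cell()]).
#' @param gene_id Gene column of `cells$counts`.
#' @param group Cell-type or cluster label to contrast against the rest.
#' @param level `"cell_type"` or `"cluster"`.
#' @param method `"normal"` (default) or `"exact"`.
#' @param alpha Nominal significance level (default 0.05).
#' @return One-row data frame: `gene_id`, `group`, `level`, `statistic`
#'   (rank-sum W), `pval`, `direction`, `significant`.
#' @export
wilcoxon_one_vs_rest <- function(cells, gene_id, group,
                                 level = c("cell_type", "cluster"),
                                 method = c("normal", "exact"), alpha = 0.05) {
  level <- match.arg(level)
  method <- match.arg(method)
  mrt_assert(gene_id %in% colnames(cells$counts), "unknown gene_id")
  lab <- cells$cells[[level]]
  mrt_assert(group %in% lab, sprintf("no cells labelled '%s'", group))
  in_g <- lab == group
  x <- cells$counts[in_g, gene_id]
  y <- cells$counts[!in_g, gene_id]
  mrt_assert(length(x) >= 3 && length(y) >= 3,
             "group and complement each need >= 3 cells")
  if (length(unique(c(x, y))) == 1) {
    return(data.frame(gene_id = gene_id, group = group, level = level,
                      statistic = NA_real_, pval = 1, direction = NA_character_,
                      significant = FALSE, stringsAsFactors = FALSE))
  }
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided",
                exact = (method == "exact"), correct = TRUE))
  r <- rank(c(x, y))
  dir <- if (mean(r[seq_along(x)]) > mean(r[-seq_along(x)])) "higher" else "lower"
  data.frame(gene_id = gene_id, group = group, level = level,
             statistic = unname(wt$statistic), pval = wt$p.value,
             direction = dir, significant = wt$p.value < alpha,
             stringsAsFactors = FALSE)
}

#' One-versus-rest tests for genes across all cell types and clusters
#'
#' @param cells A `cell_matrix`.
#' @param genes Genes to test (default all).
#' @param alpha Nominal significance level (default 0.05).
#' @return Data frame stacking [wilcoxon_one_vs_rest()] rows over every
#'   gene x cell-type and gene x cluster combination with enough cells.
#' @export
wilcoxon_all_types <- function(cells, genes = colnames(cells$counts),
                               alpha = 0.05) {
  out <- list()
  for (level in c("cell_type", "cluster")) {
    groups <- unique(cells$cells[[level]])
    groups <- groups[vapply(groups, function(g) {
      n <- sum(cells$cells[[level]] == g)
      n >= 3 && (nrow(cells$cells) - n) >= 3
    }, logical(1))]
    for (g in groups) {
      for (gene in genes) {
        out[[length(out) + 1L]] <-
          wilcoxon_one_vs_rest(cells, gene, g, level, alpha = alpha)
      }
    }
  }
  do.call(rbind, out)
}

#' Prioritised-protein summary matrix
#'
#' One column per prioritised protein; rows give the CHD effect
#' direction, the plaque protein- and mRNA-PVI associations, per
#' cell-type enrichment flags and druggability status.  Inputs are joined
#' on shared protein/gene identifiers; identifier mismatches yield `NA`
#' cells and are logged in the `"mismatches"` attribute, not fatal.
#' Re-generating the matrix from the same inputs is deterministic
#' (columns sorted by protein id).
#'
#' @param de_results [wilcoxon_all_types()] output (or `NULL`).
#' @param protein_pvi,mrna_pvi [pvi_association_table()] outputs keyed by
#'   `feature_id` (either may be `NULL`).
#' @param triangles A [triangulate()] result.
#' @param drug_annotations [classify_druggability()] output (or `NULL`).
#' @return Character matrix (rows = annotation, columns = proteins).
#' @export
enrichment_matrix <- function(de_results, protein_pvi, mrna_pvi, triangles,
                              drug_annotations = NULL) {
  prots <- sort(unique(triangles$protein_id))
  mismatches <- character(0)
  cell_groups <- if (!is.null(de_results))
    sort(unique(de_results$group[de_results$level == "cell_type"])) else character(0)
  rows <- c("chd_effect", "protein_pvi", "mrna_pvi", cell_groups, "druggability")
  m <- matrix(NA_character_, nrow = length(rows), ncol = length(prots),
              dimnames = list(rows, prots))
  assoc_cell <- function(tab, prot) {
    if (is.null(tab) || !prot %in% tab$feature_id) return(NA_character_)
    r <- tab[tab$feature_id == prot, ][1, ]
    if (is.na(r$significant)) "not_detected"
    else if (!r$significant) "ns"
    else if (r$beta > 0) "up" else "down"
  }
  for (prot in prots) {
    tri <- triangles[triangles$protein_id == prot, ][1, ]
    m["chd_effect", prot] <- if (tri$theta_pc > 0) "increasing" else "decreasing"
    m["protein_pvi", prot] <- assoc_cell(protein_pvi, prot)
    m["mrna_pvi", prot] <- assoc_cell(mrna_pvi, prot)
    if (!is.null(protein_pvi) && !prot %in% protein_pvi$feature_id)
      mismatches <- c(mismatches, paste0(prot, ":protein_pvi"))
    for (g in cell_groups) {
      d <- de_results[de_results$level == "cell_type" & de_results$group == g &
                        de_results$gene_id == prot, ]
      m[g, prot] <- if (nrow(d) == 0) NA_character_
      else if (d$significant[1] && identical(d$direction[1], "higher")) "enriched"
      else "ns"
    }
    if (!is.null(drug_annotations)) {
      i <- match(prot, drug_annotations$protein_id)
      m["druggability", prot] <- if (is.na(i)) NA_character_
      else drug_annotations$status[i]
    }
  }
  attr(m, "mismatches") <- mismatches
  m
}

#' Read a plaque expression table and its covariate sidecar
#'
#' `values_path` is a samples x features TSV with a `sample_id` first
#' column; `samples_path` is a TSV with `sample_id`, `pvi`, `sex`, `age`,
#' `diabetes`.
#'
#' @param values_path,samples_path File paths.
#' @return A `plaque_table`.
#' @export
read_plaque_table <- function(values_path, samples_path) {
  vals <- read.delim(values_path, header = TRUE, sep = "\t", row.names = 1,
                     check.names = FALSE)
  samples <- read.delim(samples_path, header = TRUE, sep = "\t",
                        colClasses = c(sample_id = "character"))
  mrt_assert(all(samples$sample_id == rownames(vals)),
             "sample ids of values and sidecar must match")
  mrt_assert(!anyNA(samples$pvi), "missing pvi for analysed samples")
  structure(list(values = as.matrix(vals), samples = samples),
            class = "plaque_table")
}

#' Write a plaque expression table (values + covariate sidecar)
#'
#' @param table A `plaque_table`.
#' @param values_path,samples_path File paths.
#' @export
write_plaque_table <- function(table, values_path, samples_path) {
  df <- data.frame(sample_id = rownames(table$values), table$values,
                   check.names = FALSE)
  write.table(df, values_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(table$samples, samples_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(values_path)
}

#' Read a cell matrix and its annotation sidecar
#'
#' `counts_path` is a cells x genes TSV with a `cell_id` first column;
#' `cells_path` maps each cell to its type (clusters are re-derived from
#' [plaque_cell_types()] when absent).
#'
#' @param counts_path,cells_path File paths.
#' @return A `cell_matrix`.
#' @export
read_cell_matrix <- function(counts_path, cells_path) {
  counts <- as.matrix(read.delim(counts_path, header = TRUE, sep = "\t",
                                 row.names = 1, check.names = FALSE))
  cells <- read.delim(cells_path, header = TRUE, sep = "\t",
                      colClasses = c(cell_id = "character"))
  mrt_assert(all(cells$cell_id == rownames(counts)),
             "cell ids of counts and annotation must match")
  if (!"cluster" %in% names(cells)) {
    map <- plaque_cell_types()
    cells$cluster <- map$cluster[match(cells$cell_type, map$cell_type)]
  }
  mrt_assert(!anyNA(cells$cluster), "every cell needs a type with a known cluster")
  structure(list(counts = counts, cells = cells), class = "cell_matrix")
}

#' Write a cell matrix (counts + annotation sidecar)
#'
#' @param cells A `cell_matrix`.
#' @param counts_path,cells_path File paths.
#' @export
write_cell_matrix <- function(cells, counts_path, cells_path) {
  df <- data.frame(cell_id = rownames(cells$counts), cells$counts,
                   check.names = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cells$cells, cells_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(counts_path)
}
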