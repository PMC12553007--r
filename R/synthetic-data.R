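#' Configuration for the summary-statistic chain simulator
#'
#' Bundles every parameter of the synthetic protein -> metabolite -> CHD
#' generating model.  Traits are simulated on the unit-variance scale; the
#' disease outcome is on the log-odds scale.  Summary statistics are
#' generated directly at the summary level (no individual genotypes):
#' per-variant standard errors follow `1 / sqrt(2 * eaf * (1 - eaf) * n)`,
#' which reproduces the F-statistic / sample-size relationship the
#' instrument filters depend on.
#'
#' @param n_variants_per_locus Number of cis variants at the protein locus.
#' @param block_size Variants per LD block at the cis locus.
#' @param ld_block_correlation Within-block correlation `r` in `[0, 1)`.
#' @param n_gw_variants Number of genome-wide metabolite instruments
#'   (independent of the protein locus).
#' @param gw_block_size Variants per LD block among genome-wide instruments.
#' @param maf_range Length-2 numeric; effect-allele frequencies are drawn
#'   uniformly from this interval (both ends in `(0, 0.5]` up to reflection).
#' @param n_exposure_samples Protein GWAS sample size.
#' @param n_metabolite_samples Metabolite GWAS sample size.
#' @param n_outcome_samples Effective disease GWAS sample size.
#' @param theta_pm True protein -> metabolite effect (SD per SD).
#' @param theta_mc True metabolite -> CHD effect (log-odds per SD).
#' @param theta_pc True direct protein -> CHD effect (log-odds per SD),
#'   i.e. the path not mediated by the metabolite.
#' @param pleiotropy_mode `"none"`, `"balanced"` (zero-mean per-variant
#'   direct effects) or `"directional"` (nonzero-mean direct effects, which
#'   should push model selection towards MR-Egger downstream).
#' @param pleiotropy_sd Scale of the per-variant direct effects; under
#'   `"directional"` it is also used as their mean.
#' @param protein_id,metabolite_id,outcome_id,study_id Identifiers stamped
#'   onto the emitted [sumstat_set]s.
#' @param seed Integer seed; the same seed reproduces identical output.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_variants_per_locus = 20,
                              block_size = 5,
                              ld_block_correlation = 0.3,
                              n_gw_variants = 30,
                              gw_block_size = 5,
                              maf_range = c(0.05, 0.45),
                              n_exposure_samples = 35559,
                              n_metabolite_samples = 5023,
                              n_outcome_samples = 500000,
                              theta_pm = 0.4,
                              theta_mc = 0.3,
                              theta_pc = 0,
                              pleiotropy_mode = c("none", "balanced", "directional"),
                              pleiotropy_sd = 0,
                              protein_id = "PROT1",
                              metabolite_id = "MET1",
                              outcome_id = "CHD",
                              study_id = "study_A",
                              seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  cfg <- list(
    n_variants_per_locus = as.integer(n_variants_per_locus),
    block_size = as.integer(block_size),
    ld_block_correlation = ld_block_correlation,
    n_gw_variants = as.integer(n_gw_variants),
    gw_block_size = as.integer(gw_block_size),
    maf_range = maf_range,
    n_exposure_samples = as.integer(n_exposure_samples),
    n_metabolite_samples = as.integer(n_metabolite_samples),
    n_outcome_samples = as.integer(n_outcome_samples),
    theta_pm = theta_pm, theta_mc = theta_mc, theta_pc = theta_pc,
    pleiotropy_mode = pleiotropy_mode, pleiotropy_sd = pleiotropy_sd,
    protein_id = protein_id, metabolite_id = metabolite_id,
    outcome_id = outcome_id, study_id = study_id,
    seed = as.integer(seed)
  )
  mrt_assert(cfg$n_variants_per_locus >= 1 && cfg$n_gw_variants >= 0 &&
               cfg$n_exposure_samples >= 1 && cfg$n_metabolite_samples >= 1 &&
               cfg$n_outcome_samples >= 1, "all counts must be >= 1")
  mrt_assert(abs(cfg$ld_block_correlation) < 1, "|ld_block_correlation| must be < 1")
  mrt_assert(cfg$pleiotropy_sd >= 0, "pleiotropy_sd must be >= 0")
  mrt_assert(length(maf_range) == 2 && all(maf_range > 0) && all(maf_range < 1) &&
               maf_range[1] <= maf_range[2], "maf_range must be an increasing pair in (0,1)")
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate a block-structured LD correlation matrix
#'
#' Builds a block-diagonal compound-symmetry correlation matrix: unit
#' diagonal, constant correlation `within_block_r` inside each block, zero
#' between blocks.  The construction is deterministic; `seed` is accepted
#' for interface symmetry with the other simulators.  If the requested
#' correlation makes the matrix indefinite (possible for negative `r`),
#' the minimal diagonal inflation restoring positive semi-definiteness is
#' applied and recorded in the `"inflation"` attribute.
#'
#' @param n_variants Total number of variants.
#' @param block_sizes Integer vector summing to `n_variants`.
#' @param within_block_r Within-block correlation, `|r| < 1`.
#' @param seed Ignored (deterministic); kept so callers can treat all
#'   simulators uniformly.
#' @param variant_ids Optional character vector of dimnames.
#' @return Symmetric positive semi-definite correlation matrix.
#' @export
simulate_ld_matrix <- function(n_variants, block_sizes = n_variants,
                               within_block_r = 0, seed = NULL,
                               variant_ids = NULL) {
  mrt_assert(n_variants >= 1, "n_variants must be positive")
  mrt_assert(abs(within_block_r) < 1, "|within_block_r| must be < 1")
  mrt_assert(sum(block_sizes) == n_variants, "block sizes must sum to n_variants")
  blocks <- lapply(block_sizes, function(m) {
    b <- matrix(within_block_r, m, m)
    diag(b) <- 1
    b
  })
  C <- matrix(0, n_variants, n_variants)
  at <- 1L
  for (b in blocks) {
    m <- nrow(b)
    C[at:(at + m - 1L), at:(at + m - 1L)] <- b
    at <- at + m
  }
  inflation <- 0
  ev_min <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 0) {
    inflation <- -ev_min + 1e-10
    C <- (C + diag(inflation, n_variants)) / (1 + inflation)
  }
  if (is.null(variant_ids)) variant_ids <- paste0("v", seq_len(n_variants))
  dimnames(C) <- list(variant_ids, variant_ids)
  attr(C, "inflation") <- inflation
  C
}

# split n into blocks of size k (last block possibly smaller)
.block_sizes <- function(n, k) {
  if (n == 0L) return(integer(0))
  sizes <- rep(k, n %/% k)
  if (n %% k) sizes <- c(sizes, n %% k)
  sizes
}

# Draw summary-level estimation noise with covariance S C S,
# S = diag(se), C the LD correlation (U'U = C with U upper-triangular).
.gwas_noise <- function(U, se) {
  unname(se * drop(t(U) %*% rnorm(length(se))))
}

.per_variant_pleiotropy <- function(n, mode, sd) {
  switch(mode,
         none = rep(0, n),
         balanced = rnorm(n, 0, sd),
         directional = rnorm(n, mean = sd, sd = sd / 2))
}

#' Simulate the three GWAS layers of a protein-metabolite-CHD chain
#'
#' Generates marginal summary statistics with known ground truth for one
#' causal chain.  Two variant groups are produced:
#'
#' * **cis variants** at the protein locus: true protein effects are drawn
#'   oriented to the protein-increasing allele; the metabolite inherits
#'   `theta_pm` times the protein effect (plus optional per-variant
#'   pleiotropy) and the disease inherits `theta_mc` times the metabolite
#'   effect plus the direct path `theta_pc` times the protein effect.
#' * **genome-wide metabolite instruments** on a separate chromosome: true
#'   metabolite effects with random sign; the disease inherits `theta_mc`
#'   times the metabolite effect.
#'
#' Estimation noise is multivariate normal with covariance `S C S` (`S` the
#' per-variant standard errors, `C` the LD correlation), matching the
#' working covariance of the downstream GLS estimators; exposure-side and
#' outcome-side noise are independent, as in two-sample MR.
#'
#' @param config A [simulation_config].
#' @return List of class `gwas_chain_sim` with elements `protein`,
#'   `metabolite`, `outcome` ([sumstat_set]s), `ld` (joint LD matrix over
#'   all variants) and `truth` (all generating quantities).
#' @export
simulate_gwas_chain <- function(config = simulation_config()) {
  mrt_assert(inherits(config, "simulation_config"), "config must be a simulation_config")
  set.seed(config$seed)
  cis_ids <- sprintf("rs%s_c%02d", config$protein_id, seq_len(config$n_variants_per_locus))
  gw_ids <- if (config$n_gw_variants > 0)
    sprintf("rs%s_g%02d", config$metabolite_id, seq_len(config$n_gw_variants)) else character(0)

  C_cis <- simulate_ld_matrix(config$n_variants_per_locus,
                              .block_sizes(config$n_variants_per_locus, config$block_size),
                              config$ld_block_correlation, variant_ids = cis_ids)
  C_gw <- if (config$n_gw_variants > 0)
    simulate_ld_matrix(config$n_gw_variants,
                       .block_sizes(config$n_gw_variants, config$gw_block_size),
                       config$ld_block_correlation, variant_ids = gw_ids) else NULL
  U_cis <- chol(C_cis)
  U_gw <- if (!is.null(C_gw)) chol(C_gw) else NULL

  n_cis <- config$n_variants_per_locus
  n_gw <- config$n_gw_variants
  alleles <- c("A", "C", "G", "T")
  draw_alleles <- function(n) {
    ea <- sample(alleles, n, replace = TRUE)
    oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1L), character(1))
    list(ea = ea, oa = unname(oa))
  }

  # --- cis locus (gene body 1.0-1.02 Mb, variants within gene +/- 150 kb)
  locus <- list(chrom = "1", start = 1000000L, end = 1020000L)
  pos_cis <- sort(sample(seq(locus$start - 150000L, locus$end + 150000L), n_cis))
  eaf_cis <- runif(n_cis, config$maf_range[1], config$maf_range[2])
  al_cis <- draw_alleles(n_cis)
  se_p <- 1 / sqrt(2 * eaf_cis * (1 - eaf_cis) * config$n_exposure_samples)
  se_m_cis <- 1 / sqrt(2 * eaf_cis * (1 - eaf_cis) * config$n_metabolite_samples)
  se_c_cis <- 1 / sqrt(2 * eaf_cis * (1 - eaf_cis) * config$n_outcome_samples)

  bp_true <- runif(n_cis, 0.05, 0.15) # oriented to protein-increasing allele
  if (all(bp_true == 0)) warning("degenerate chain: all protein effects are zero")
  alpha_m <- .per_variant_pleiotropy(n_cis, config$pleiotropy_mode, config$pleiotropy_sd)
  alpha_c <- .per_variant_pleiotropy(n_cis, config$pleiotropy_mode, config$pleiotropy_sd)
  bm_cis_true <- config$theta_pm * bp_true + alpha_m
  bc_cis_true <- config$theta_mc * bm_cis_true + config$theta_pc * bp_true + alpha_c

  bp_hat <- bp_true + .gwas_noise(U_cis, se_p)
  bm_cis_hat <- bm_cis_true + .gwas_noise(U_cis, se_m_cis)
  bc_cis_hat <- bc_cis_true + .gwas_noise(U_cis, se_c_cis)

  # --- genome-wide metabolite instruments (chromosome 2)
  if (n_gw > 0) {
    pos_gw <- sort(sample(seq(5e6L, 9e6L), n_gw))
    eaf_gw <- runif(n_gw, config$maf_range[1], config$maf_range[2])
    al_gw <- draw_alleles(n_gw)
    se_m_gw <- 1 / sqrt(2 * eaf_gw * (1 - eaf_gw) * config$n_metabolite_samples)
    se_c_gw <- 1 / sqrt(2 * eaf_gw * (1 - eaf_gw) * config$n_outcome_samples)
    bm_gw_true <- sample(c(-1, 1), n_gw, replace = TRUE) * runif(n_gw, 0.15, 0.30)
    alpha_gw <- .per_variant_pleiotropy(n_gw, config$pleiotropy_mode, config$pleiotropy_sd)
    bc_gw_true <- config$theta_mc * bm_gw_true + alpha_gw
    bm_gw_hat <- bm_gw_true + .gwas_noise(U_gw, se_m_gw)
    bc_gw_hat <- bc_gw_true + .gwas_noise(U_gw, se_c_gw)
  }

  wald_p <- function(b, se) 2 * pnorm(-abs(b / se))
  rec <- function(ids, chrom, pos, al, eaf, b, se, n) {
    data.frame(variant_id = ids, chrom = chrom, pos = pos,
               effect_allele = al$ea, other_allele = al$oa, eaf = eaf,
               beta = b, se = se, pval = pmax(wald_p(b, se), 1e-300), n = n,
               stringsAsFactors = FALSE)
  }

  protein <- sumstat_set(config$protein_id, "protein",
                         rec(cis_ids, locus$chrom, pos_cis, al_cis, eaf_cis,
                             bp_hat, se_p, config$n_exposure_samples),
                         locus = locus, study_id = config$study_id)
  met_rec <- rec(cis_ids, locus$chrom, pos_cis, al_cis, eaf_cis,
                 bm_cis_hat, se_m_cis, config$n_metabolite_samples)
  out_rec <- rec(cis_ids, locus$chrom, pos_cis, al_cis, eaf_cis,
                 bc_cis_hat, se_c_cis, config$n_outcome_samples)
  if (n_gw > 0) {
    met_rec <- rbind(met_rec, rec(gw_ids, "2", pos_gw, al_gw, eaf_gw,
                                  bm_gw_hat, se_m_gw, config$n_metabolite_samples))
    out_rec <- rbind(out_rec, rec(gw_ids, "2", pos_gw, al_gw, eaf_gw,
                                  bc_gw_hat, se_c_gw, config$n_outcome_samples))
  }
  metabolite <- sumstat_set(config$metabolite_id, "metabolite", met_rec)
  outcome <- sumstat_set(config$outcome_id, "disease", out_rec)

  all_ids <- c(cis_ids, gw_ids)
  ld <- matrix(0, length(all_ids), length(all_ids), dimnames = list(all_ids, all_ids))
  ld[cis_ids, cis_ids] <- C_cis
  if (n_gw > 0) ld[gw_ids, gw_ids] <- C_gw

  truth <- list(config = config, bp_true = bp_true, bm_cis_true = bm_cis_true,
                bc_cis_true = bc_cis_true, alpha_m = alpha_m, alpha_c = alpha_c,
                bm_gw_true = if (n_gw > 0) bm_gw_true else numeric(0),
                theta_pm = config$theta_pm, theta_mc = config$theta_mc,
                theta_pc = config$theta_pc,
                theta_pc_total = config$theta_pm * config$theta_mc + config$theta_pc)
  structure(list(protein = protein, metabolite = metabolite, outcome = outcome,
                 ld = ld, truth = truth),
            class = "gwas_chain_sim")
}

#' Write a TruthRecord as a flat key-value text file
#'
#' @param truth The `truth` element of a [simulate_gwas_chain] result.
#' @param path File path.
#' @export
write_truth_record <- function(truth, path) {
  scal <- vapply(truth, function(x) is.atomic(x) && length(x) == 1, logical(1))
  kv <- c(
    vapply(truth[scal], function(x) format(x, digits = 15), character(1)),
    vapply(truth[!scal & !vapply(truth, is.list, logical(1))],
           function(x) paste(format(x, digits = 15), collapse = ","), character(1))
  )
  writeLines(paste(names(kv), kv, sep = "\t"), path)
  invisible(path)
}

#' Simulate a plaque expression table with a vulnerability index
#'
#' Per-sample plaque vulnerability index (PVI) is drawn uniformly on
#' `[0, 4]`, mimicking a composite histology score; expression is linear
#' in the PVI with Gaussian noise.  Covariates are generated with the
#' prevalences of a carotid endarterectomy cohort: 75% male, age
#' `N(69, 8.7)` years, 22% diabetes.
#'
#' @param n_samples Number of plaque samples (>= 10).
#' @param feature_effects Named numeric: expression slope per unit PVI for
#'   each named feature (features absent from the map get slope 0).
#' @param noise_sd Residual standard deviation (>= 0).
#' @param seed Integer seed.
#' @param n_null_features Extra unnamed null features appended with slope 0.
#' @param sex_interaction Optional named numeric: additional PVI slope in
#'   males, for exercising interaction tests.
#' @return List of class `plaque_table` with elements `values`
#'   (samples x features matrix), `samples` (data frame with `sample_id`,
#'   `pvi`, `sex`, `age`, `diabetes`).
#' @export
simulate_plaque_table <- function(n_samples = 194, feature_effects = c(GENE1 = 2),
                                  noise_sd = 1, seed = 1L, n_null_features = 0,
                                  sex_interaction = NULL) {
  mrt_assert(n_samples >= 10, "n_samples must be >= 10")
  mrt_assert(noise_sd >= 0, "noise_sd must be >= 0")
  set.seed(seed)
  features <- names(feature_effects)
  if (n_null_features > 0) {
    nulls <- sprintf("NULL%03d", seq_len(n_null_features))
    feature_effects <- c(feature_effects, setNames(rep(0, n_null_features), nulls))
    features <- names(feature_effects)
  }
  pvi <- runif(n_samples, 0, 4)
  sex <- ifelse(rbinom(n_samples, 1, 0.75) == 1, "M", "F")
  age <- rnorm(n_samples, 69, 8.7)
  diabetes <- ifelse(rbinom(n_samples, 1, 0.22) == 1, "yes", "no")
  male <- as.numeric(sex == "M")
  vals <- vapply(features, function(f) {
    slope <- feature_effects[[f]]
    inter <- if (!is.null(sex_interaction) && f %in% names(sex_interaction))
      sex_interaction[[f]] else 0
    5 + slope * pvi + inter * pvi * male + rnorm(n_samples, 0, noise_sd)
  }, numeric(n_samples))
  rownames(vals) <- sprintf("S%04d", seq_len(n_samples))
  structure(list(
    values = vals,
    samples = data.frame(sample_id = rownames(vals), pvi = pvi, sex = sex,
                         age = age, diabetes = diabetes, stringsAsFactors = FALSE)
  ), class = "plaque_table")
}

#' The thirteen plaque cell types and their broad clusters
#'
#' Maps each cell type observed in carotid plaque single-cell data to one
#' of three broad clusters: structural, innate immune or adaptive immune.
#' The mapping is an editable convention, not computed from data.
#'
#' @return Data frame with columns `cell_type` and `cluster`.
#' @export
plaque_cell_types <- function() {
  data.frame(
    cell_type = c("dendritic cells", "endothelial cells I", "endothelial cells II",
                  "foam cells", "inflammatory macrophages", "mast cells",
                  "memory B-cells", "monocytes", "NK-cells", "plasma B-cells",
                  "resident macrophages", "SMCs", "T-cells"),
    cluster = c("innate_immune", "structural", "structural",
                "innate_immune", "innate_immune", "innate_immune",
                "adaptive_immune", "innate_immune", "innate_immune",
                "adaptive_immune", "innate_immune", "structural", "adaptive_immune"),
    stringsAsFactors = FALSE
  )
}

# default composition of a plaque cell mixture (proportions sum to 1)
.default_cell_props <- function() {
  c("SMCs" = 0.18, "endothelial cells I" = 0.08, "endothelial cells II" = 0.05,
    "dendritic cells" = 0.03, "foam cells" = 0.08,
    "inflammatory macrophages" = 0.12, "mast cells" = 0.02,
    "memory B-cells" = 0.05, "monocytes" = 0.06, "NK-cells" = 0.07,
    "plasma B-cells" = 0.02, "resident macrophages" = 0.09, "T-cells" = 0.15)
}

#' Simulate a labelled single-cell count matrix
#'
#' Negative-binomial counts with a common baseline mean; genes listed in
#' `enriched` have their mean multiplied by `fold` in the target cell
#' type.  Cells are labelled with one of the thirteen plaque cell types
#' and the corresponding broad cluster (see [plaque_cell_types()]).
#'
#' @param n_cells Number of cells.
#' @param cell_type_props Named numeric proportions over cell types,
#'   summing to 1.  Defaults to a plausible plaque mixture.
#' @param enriched Named character: `gene -> cell type` enrichment targets.
#' @param fold Fold-change (> 1) applied to enriched genes in their type.
#' @param n_background_genes Unenriched genes added alongside.
#' @param base_mu Baseline negative-binomial mean.
#' @param dispersion Negative-binomial size parameter.
#' @param seed Integer seed.
#' @return List of class `cell_matrix` with `counts` (cells x genes) and
#'   `cells` (data frame: `cell_id`, `cell_type`, `cluster`).
#' @export
simulate_single_cell <- function(n_cells = 4948,
                                 cell_type_props = .default_cell_props(),
                                 enriched = c(GENE1 = "SMCs"), fold = 10,
                                 n_background_genes = 20, base_mu = 2,
                                 dispersion = 2, seed = 1L) {
  mrt_assert(abs(sum(cell_type_props) - 1) < 1e-8, "cell_type_props must sum to 1")
  types <- plaque_cell_types()
  mrt_assert(all(names(cell_type_props) %in% types$cell_type),
             "unknown cell type in cell_type_props")
  mrt_assert(all(enriched %in% types$cell_type), "unknown cell type in enriched map")
  if (length(enriched) > 0) mrt_assert(fold > 1, "fold must be > 1 for enriched genes")
  set.seed(seed)
  cell_type <- sample(names(cell_type_props), n_cells, replace = TRUE,
                      prob = cell_type_props)
  cluster <- types$cluster[match(cell_type, types$cell_type)]
  genes <- unique(c(names(enriched),
                    if (n_background_genes > 0) sprintf("BG%03d", seq_len(n_background_genes))))
  counts <- vapply(genes, function(g) {
    mu <- rep(base_mu, n_cells)
    if (g %in% names(enriched)) mu[cell_type == enriched[[g]]] <- base_mu * fold
    rnbinom(n_cells, mu = mu, size = dispersion)
  }, numeric(n_cells))
  rownames(counts) <- sprintf("cell%05d", seq_len(n_cells))
  structure(list(
    counts = counts,
    cells = data.frame(cell_id = rownames(counts), cell_type = cell_type,
                       cluster = cluster, stringsAsFactors = FALSE)
  ), class = "cell_matrix")
}
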