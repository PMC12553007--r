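#' Default end-to-end run configuration
#'
#' Returns the full configuration of a synthetic-data pipeline run: the
#' analysis thresholds (instrument F >= 24, MAF >= 0.01, clumping
#' r-squared 0.30, at least six variants, leverage multiplier 3, outlier
#' chi-square 10.83, model-selection alpha 0.05, 90% PCA variance target,
#' plaque FDR 0.1, pathway FDR 0.05, single-cell alpha 0.05) and a
#' simulation block planting three protein-metabolite-CHD chains: one
#' directionally concordant, one discordant (the direct protein effect
#' opposes the mediated path), and one whose metabolite-CHD effect is too
#' weak to pass the first layer's screen.
#'
#' @param seed Integer master seed; every stage derives its own seed from
#'   it deterministically.
#' @param out_dir Output directory (created if missing).
#' @return Nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L, out_dir = tempfile("mrtriad_run_")) {
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    thresholds = list(
      f_min = 24, maf_min = 0.01, clump_r2 = 0.30, min_variants = 6L,
      leverage_mult = 3, chisq_cut = 10.83, alpha = 0.05,
      variance_target = 0.90, layer2_n_eff = 1562L * 29L,
      layer3_n_eff = NULL, plaque_fdr = 0.1, ora_fdr = 0.05, sc_alpha = 0.05),
    simulate = list(
      chains = list(
        list(protein_id = "PROT_CONC", metabolite_id = "MET_CONC",
             theta_pm = 0.6, theta_mc = 0.3, theta_pc = 0),
        list(protein_id = "PROT_DISC", metabolite_id = "MET_DISC",
             theta_pm = -0.6, theta_mc = 0.3, theta_pc = 0.48),
        list(protein_id = "PROT_SUB", metabolite_id = "MET_SUB",
             theta_pm = 0.6, theta_mc = 5e-4, theta_pc = 0)),
      base = list(),                       # overrides for simulation_config()
      metabolite_panel = list(n_metabolites = 60L, n_obs = 300L,
                              block_size = 4L, within_r = 0.5),
      replication = list(n_samples = 10708L, study_id = "study_B"),
      plaque = list(protein_samples = 194L, mrna_samples = 632L,
                    effect = 1.5, noise_sd = 1, n_null_features = 10L),
      single_cell = list(n_cells = 1500L, fold = 8, target_type = "SMCs",
                         n_background_genes = 20L),
      enrichment = list(n_universe = 200L, n_sets = 5L, set_size = 10L)),
    ingest = NULL
  )
  class(cfg) <- "run_config"
  cfg
}

#' Validate a run configuration
#'
#' Checks threshold ranges, the mutual exclusivity of the `simulate` and
#' `ingest` blocks, and (for ingest) file existence.  Errors are
#' aggregated into a character vector rather than thrown one by one.
#'
#' @param config A `run_config`.
#' @return Character vector of problems; `character(0)` when valid.
#' @export
validate_config <- function(config) {
  errs <- character(0)
  add <- function(msg) errs <<- c(errs, msg)
  th <- config$thresholds
  if (is.null(th)) {
    add("missing thresholds block")
    return(errs)
  }
  if (!is.null(th$clump_r2) && (th$clump_r2 < 0 || th$clump_r2 > 1))
    add("clump_r2 out of range [0,1]")
  if (!is.null(th$alpha) && (th$alpha <= 0 || th$alpha >= 1))
    add("alpha out of range (0,1)")
  for (nm in c("plaque_fdr", "ora_fdr", "sc_alpha")) {
    if (!is.null(th[[nm]]) && (th[[nm]] <= 0 || th[[nm]] >= 1))
      add(sprintf("%s out of range (0,1)", nm))
  }
  if (!is.null(th$variance_target) &&
      (th$variance_target <= 0 || th$variance_target > 1))
    add("variance_target out of range (0,1]")
  if (!is.null(th$f_min) && th$f_min < 0) add("f_min must be >= 0")
  if (!is.null(th$min_variants) && th$min_variants < 2)
    add("min_variants must be >= 2")
  has_sim <- !is.null(config$simulate)
  has_ing <- !is.null(config$ingest)
  if (has_sim && has_ing) add("simulate and ingest blocks are mutually exclusive")
  if (!has_sim && !has_ing) add("one of simulate or ingest is required")
  if (has_ing) {
    flat <- unlist(config$ingest)
    for (p in flat[grepl("path$", names(flat))]) {
      if (!file.exists(p)) add(sprintf("missing input file: %s", p))
    }
  }
  if (is.null(config$seed)) add("missing seed")
  errs
}

# simulate a traits x observations metabolite panel with block correlation,
# used to derive the PCA-based effective test count for layer 1
.simulate_metabolite_panel <- function(n_metabolites, n_obs, block_size,
                                       within_r, seed) {
  set.seed(seed)
  C <- simulate_ld_matrix(n_metabolites, .block_sizes(n_metabolites, block_size),
                          within_r)
  U <- chol(C)
  Z <- matrix(rnorm(n_obs * n_metabolites), n_obs, n_metabolites)
  t(Z %*% U)   # traits x observations
}

#' Re-measure a simulated protein GWAS in a second study
#'
#' Redraws the protein-layer summary statistics of an existing
#' [simulate_gwas_chain()] result with fresh estimation noise at a new
#' sample size, emulating the same protein measured by an independent
#' proteomics GWAS.
#'
#' @param sim A `gwas_chain_sim`.
#' @param n_samples Secondary study sample size.
#' @param study_id Secondary study identifier.
#' @param seed Integer seed.
#' @return A [sumstat_set] for the protein in the secondary study.
#' @export
resimulate_protein_study <- function(sim, n_samples, study_id, seed) {
  set.seed(seed)
  rec <- sim$protein$records
  C <- sim$ld[rec$variant_id, rec$variant_id, drop = FALSE]
  se2 <- 1 / sqrt(2 * rec$eaf * (1 - rec$eaf) * n_samples)
  rec$beta <- sim$truth$bp_true + .gwas_noise(chol(C), se2)
  rec$se <- se2
  rec$pval <- pmax(2 * pnorm(-abs(rec$beta / rec$se)), 1e-300)
  rec$n <- n_samples
  sumstat_set(sim$protein$trait_id, "protein", rec, locus = sim$protein$locus,
              study_id = study_id)
}

# merge outcome sumstat sets from several chains (disjoint variants)
.merge_outcomes <- function(sims, outcome_id = "CHD") {
  rec <- do.call(rbind, lapply(sims, function(s) s$outcome$records))
  sumstat_set(outcome_id, "disease", rec)
}

# block-diagonal union of per-chain LD matrices (chains are independent loci)
.merge_ld <- function(sims) {
  ids <- unlist(lapply(sims, function(s) rownames(s$ld)))
  L <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (s in sims) L[rownames(s$ld), rownames(s$ld)] <- s$ld
  L
}

#' Run the full triangulation pipeline
#'
#' Executes, in order: input simulation (or ingest), the three MR layers
#' (metabolite -> CHD, protein -> metabolite, protein -> CHD), the
#' layer-wise multiplicity screens, triangle assembly, cross-study
#' replication, plaque vulnerability association (protein and mRNA
#' families, BH-adjusted separately) with subgroup/interaction follow-up,
#' single-cell one-versus-rest enrichment, pathway over-representation,
#' druggability classification, the prioritised-protein summary matrix
#' and a run manifest.  Each stage's outputs are written to
#' `config$out_dir` before the next stage starts; re-running with the
#' same configuration and seed reproduces identical outputs.
#'
#' @param config A `run_config` (see [default_run_config()]).
#' @return Invisible list with all stage results (`mr_layers`, `screens`,
#'   `triangles`, `replication`, `plaque`, `single_cell`, `ora`,
#'   `druggability`, `matrix`, `manifest`).
#' @export
run_pipeline <- function(config = default_run_config()) {
  errs <- validate_config(config)
  mrt_assert(length(errs) == 0,
             paste("invalid config:", paste(errs, collapse = "; ")),
             "mrtriad_config_error")
  th <- config$thresholds
  mrc <- mr_config(f_min = th$f_min, maf_min = th$maf_min, r2_max = th$clump_r2,
                   min_variants = th$min_variants,
                   leverage_mult = th$leverage_mult, chisq_cut = th$chisq_cut,
                   alpha = th$alpha)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "inputs"), showWarnings = FALSE)
  manifest <- list(seed = config$seed,
                   version = as.character(utils::packageVersion("mrtriad")))
  counts <- list()

  # ---- stage 1: inputs ------------------------------------------------
  if (!is.null(config$simulate)) {
    inp <- .stage_simulate(config)
  } else {
    inp <- .stage_ingest(config)
  }
  for (nm in names(inp$proteins))
    write_sumstats(inp$proteins[[nm]], file.path(out_dir, "inputs",
                                                 paste0("protein_", nm, ".tsv")))
  for (nm in names(inp$metabolites))
    write_sumstats(inp$metabolites[[nm]], file.path(out_dir, "inputs",
                                                    paste0("metabolite_", nm, ".tsv")))
  write_sumstats(inp$outcome, file.path(out_dir, "inputs", "outcome.tsv"))
  write_ld_matrix(inp$ld, file.path(out_dir, "inputs", "ld.tsv"))
  counts$n_proteins <- length(inp$proteins)
  counts$n_metabolites <- length(inp$metabolites)
  counts$n_variants <- nrow(inp$ld)

  # ---- stage 2: three MR layers --------------------------------------
  layer1 <- lapply(inp$metabolites, function(m)
    run_mr(m, inp$outcome, inp$ld, mrc))
  layer3 <- lapply(inp$proteins, function(p)
    run_mr(p, inp$outcome, inp$ld, mrc))
  layer2 <- list()
  for (p in inp$proteins) {
    for (m in inp$metabolites) {
      if (!any(p$records$variant_id %in% m$records$variant_id)) next
      layer2[[paste(p$trait_id, m$trait_id, sep = "~")]] <-
        run_mr(p, m, inp$ld, mrc)
    }
  }
  write_mr_results(layer1, file.path(out_dir, "mr_metabolite_chd.tsv"))
  write_mr_results(layer2, file.path(out_dir, "mr_protein_metabolite.tsv"))
  write_mr_results(layer3, file.path(out_dir, "mr_protein_chd.tsv"))
  counts$n_layer1_fits <- sum(!vapply(layer1, is_discarded, logical(1)))
  counts$n_layer2_fits <- sum(!vapply(layer2, is_discarded, logical(1)))
  counts$n_layer3_fits <- sum(!vapply(layer3, is_discarded, logical(1)))

  # ---- stage 3: multiplicity screens ---------------------------------
  n_eff1 <- if (!is.null(inp$metabolite_panel))
    effective_tests_pca(inp$metabolite_panel, th$variance_target)
  else length(inp$metabolites)
  plan1 <- multiplicity_plan("metabolite_chd", "bonferroni_pca", n_eff1, th$alpha)
  plan2 <- multiplicity_plan("protein_metabolite", "bonferroni_count",
                             th$layer2_n_eff, th$alpha)
  n_eff3 <- th$layer3_n_eff %||% counts$n_layer3_fits
  plan3 <- multiplicity_plan("protein_chd", "bonferroni_count",
                             max(n_eff3, 1L), th$alpha)
  s1 <- screen_layer(layer1, plan1)
  s2 <- screen_layer(layer2, plan2)
  s3 <- screen_layer(layer3, plan3)
  counts$n_layer1_survivors <- length(s1$surviving)
  counts$n_layer2_survivors <- length(s2$surviving)
  counts$n_layer3_survivors <- length(s3$surviving)

  # ---- stage 4: triangulation ----------------------------------------
  source_gwas <- vapply(inp$proteins, function(p)
    p$study_id %||% NA_character_, character(1))
  triangles <- triangulate(s2$surviving, s1$surviving, s3$surviving,
                           source_gwas = source_gwas)
  write_triangles(triangles, file.path(out_dir, "triangles.tsv"))
  counts$n_triangles <- nrow(triangles)
  counts$n_concordant <- sum(triangles$concordant %in% TRUE)

  # ---- stage 5: replication ------------------------------------------
  replication <- NULL
  if (!is.null(inp$secondary_proteins) && length(inp$secondary_proteins) > 0) {
    primary_by_prot <- setNames(
      lapply(s3$surviving, identity),
      vapply(s3$surviving, `[[`, "", "exposure_id"))
    secondary_fits <- lapply(inp$secondary_proteins, function(p)
      run_mr(p, inp$outcome, inp$ld, mrc))
    overlap <- intersect(names(primary_by_prot), names(secondary_fits))
    if (length(overlap) > 0) {
      replication <- mr_replicate(primary_by_prot[overlap],
                                  secondary_fits[overlap], overlap)
      write.table(replication, file.path(out_dir, "replication.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  # ---- stage 6: plaque vulnerability ---------------------------------
  plaque <- NULL
  if (!is.null(inp$plaque_protein)) {
    prot_tab <- pvi_association_table(inp$plaque_protein, fdr = th$plaque_fdr)
    mrna_tab <- if (!is.null(inp$plaque_mrna))
      pvi_association_table(inp$plaque_mrna, fdr = th$plaque_fdr) else NULL
    sig <- prot_tab$feature_id[prot_tab$significant %in% TRUE]
    subgroups <- lapply(setNames(sig, sig), function(f) {
      lapply(c(sex = "sex", age65 = "age65", diabetes = "diabetes"), function(gv)
        tryCatch(subgroup_and_interaction(inp$plaque_protein, f, gv),
                 mrtriad_single_stratum = function(e) NULL))
    })
    write.table(prot_tab, file.path(out_dir, "plaque_protein_pvi.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(mrna_tab))
      write.table(mrna_tab, file.path(out_dir, "plaque_mrna_pvi.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    plaque <- list(protein = prot_tab, mrna = mrna_tab, subgroups = subgroups)
    counts$n_plaque_protein_hits <- sum(prot_tab$significant %in% TRUE)
    counts$n_plaque_mrna_hits <- if (!is.null(mrna_tab))
      sum(mrna_tab$significant %in% TRUE) else 0L
  }

  # ---- stage 7: single-cell enrichment -------------------------------
  sc <- NULL
  if (!is.null(inp$cells)) {
    genes <- intersect(unique(triangles$protein_id), colnames(inp$cells$counts))
    if (length(genes) > 0) {
      sc <- wilcoxon_all_types(inp$cells, genes, alpha = th$sc_alpha)
      write.table(sc, file.path(out_dir, "single_cell_de.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      counts$n_sc_tests <- nrow(sc)
    }
  }

  # ---- stage 8: enrichment and druggability --------------------------
  ora <- NULL
  drugs <- NULL
  conc_prots <- unique(triangles$protein_id[triangles$concordant %in% TRUE])
  if (!is.null(inp$collection) && length(conc_prots) > 0) {
    ora <- ora_collection(conc_prots, inp$collection, fdr = th$ora_fdr)
    write.table(ora, file.path(out_dir, "ora.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(inp$drug_table)) {
    drugs <- classify_druggability(unique(triangles$protein_id), inp$drug_table)
    write.table(drugs, file.path(out_dir, "druggability.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  # ---- stage 9: summary matrix and manifest --------------------------
  summary_matrix <- NULL
  if (nrow(triangles) > 0) {
    summary_matrix <- enrichment_matrix(
      sc, if (!is.null(plaque)) plaque$protein else NULL,
      if (!is.null(plaque)) plaque$mrna else NULL, triangles, drugs)
    write.table(data.frame(annotation = rownames(summary_matrix), summary_matrix,
                           check.names = FALSE),
                file.path(out_dir, "protein_matrix.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  cfg_file <- file.path(out_dir, "config.txt")
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), cfg_file)
  manifest$config_md5 <- unname(md5sum(cfg_file))
  manifest$threshold_layer1 <- plan1$threshold
  manifest$threshold_layer2 <- plan2$threshold
  manifest$threshold_layer3 <- plan3$threshold
  manifest$n_effective_layer1 <- plan1$n_effective
  manifest <- c(manifest, counts)
  writeLines(paste(names(manifest),
                   vapply(manifest, function(x) format(x, digits = 15), ""),
                   sep = "\t"),
             file.path(out_dir, "manifest.tsv"))

  invisible(list(
    inputs = inp,
    mr_layers = list(metabolite_chd = layer1, protein_metabolite = layer2,
                     protein_chd = layer3),
    plans = list(plan1, plan2, plan3),
    screens = list(layer1 = s1, layer2 = s2, layer3 = s3),
    triangles = triangles, replication = replication, plaque = plaque,
    single_cell = sc, ora = ora, druggability = drugs,
    matrix = summary_matrix, manifest = manifest))
}

# build all pipeline inputs from the simulation block
.stage_simulate <- function(config) {
  sb <- config$simulate
  seed <- config$seed
  sims <- list()
  proteins <- list()
  metabolites <- list()
  secondary <- list()
  for (i in seq_along(sb$chains)) {
    ch <- sb$chains[[i]]
    args <- modifyList(
      list(theta_pm = ch$theta_pm, theta_mc = ch$theta_mc,
           theta_pc = ch$theta_pc, protein_id = ch$protein_id,
           metabolite_id = ch$metabolite_id, seed = seed + 1000L + i),
      sb$base %||% list())
    sim <- simulate_gwas_chain(do.call(simulation_config, args))
    sims[[i]] <- sim
    proteins[[ch$protein_id]] <- sim$protein
    metabolites[[ch$metabolite_id]] <- sim$metabolite
    if (!is.null(sb$replication)) {
      secondary[[ch$protein_id]] <- resimulate_protein_study(
        sim, sb$replication$n_samples, sb$replication$study_id,
        seed + 5000L + i)
    }
  }
  panel <- if (!is.null(sb$metabolite_panel)) {
    mp <- sb$metabolite_panel
    .simulate_metabolite_panel(mp$n_metabolites, mp$n_obs, mp$block_size,
                               mp$within_r, seed + 2000L)
  }
  conc_ids <- vapply(sb$chains, `[[`, "", "protein_id")
  plaque_effects <- setNames(rep(0, length(conc_ids)), conc_ids)
  if (!is.null(sb$plaque)) {
    plaque_effects[conc_ids[1]] <- sb$plaque$effect
    plaque_protein <- simulate_plaque_table(
      sb$plaque$protein_samples, plaque_effects, sb$plaque$noise_sd,
      seed + 3000L, n_null_features = sb$plaque$n_null_features)
    plaque_mrna <- simulate_plaque_table(
      sb$plaque$mrna_samples, plaque_effects, sb$plaque$noise_sd,
      seed + 3001L, n_null_features = sb$plaque$n_null_features)
  } else plaque_protein <- plaque_mrna <- NULL
  cells <- if (!is.null(sb$single_cell)) {
    sc <- sb$single_cell
    simulate_single_cell(
      n_cells = sc$n_cells,
      enriched = setNames(sc$target_type, conc_ids[1]),
      fold = sc$fold, n_background_genes = sc$n_background_genes,
      seed = seed + 4000L)
  }
  collection <- if (!is.null(sb$enrichment)) {
    en <- sb$enrichment
    set.seed(seed + 6000L)
    universe <- unique(c(conc_ids, sprintf("U%03d", seq_len(en$n_universe))))
    sets <- list(planted_set = unique(c(
      conc_ids[1], sample(universe, en$set_size - 1L))))
    for (j in seq_len(en$n_sets - 1L)) {
      sets[[sprintf("random_set_%02d", j)]] <- sample(universe, en$set_size)
    }
    gene_set_collection(sets, universe)
  }
  drug_table <- data.frame(
    protein_id = conc_ids,
    status = c("drugged", rep("not_yet_druggable", length(conc_ids) - 1L)),
    drugs = c("syntharol", rep("", length(conc_ids) - 1L)),
    cardiac_indication = c(TRUE, rep(FALSE, length(conc_ids) - 1L)),
    cardiac_side_effect = FALSE, stringsAsFactors = FALSE)
  list(proteins = proteins, metabolites = metabolites,
       outcome = .merge_outcomes(sims), ld = .merge_ld(sims), sims = sims,
       metabolite_panel = panel, secondary_proteins = secondary,
       plaque_protein = plaque_protein, plaque_mrna = plaque_mrna,
       cells = cells, collection = collection, drug_table = drug_table)
}

# read all pipeline inputs from the ingest block
.stage_ingest <- function(config) {
  ig <- config$ingest
  proteins <- list()
  for (p in ig$proteins %||% list()) {
    proteins[[p$trait_id]] <- read_sumstats(p$path, p$trait_id, "protein",
                                            locus = p$locus,
                                            study_id = p$study_id %||% NA_character_)
  }
  metabolites <- list()
  for (m in ig$metabolites %||% list()) {
    metabolites[[m$trait_id]] <- read_sumstats(m$path, m$trait_id, "metabolite")
  }
  outcome <- read_sumstats(ig$outcome$path, ig$outcome$trait_id %||% "CHD",
                           "disease")
  ld <- read_ld_matrix(ig$ld_path)
  panel <- if (!is.null(ig$metabolite_corr_path))
    validate_ld_matrix(as.matrix(read.delim(ig$metabolite_corr_path, sep = "\t",
                                            row.names = 1, check.names = FALSE)))
  plaque_protein <- if (!is.null(ig$plaque_protein))
    read_plaque_table(ig$plaque_protein$values_path, ig$plaque_protein$samples_path)
  plaque_mrna <- if (!is.null(ig$plaque_mrna))
    read_plaque_table(ig$plaque_mrna$values_path, ig$plaque_mrna$samples_path)
  cells <- if (!is.null(ig$cells))
    read_cell_matrix(ig$cells$counts_path, ig$cells$cells_path)
  collection <- if (!is.null(ig$gmt_path)) read_gmt(ig$gmt_path, ig$universe)
  drug_table <- if (!is.null(ig$drug_table_path)) ig$drug_table_path
  list(proteins = proteins, metabolites = metabolites, outcome = outcome,
       ld = ld, sims = NULL, metabolite_panel = panel,
       secondary_proteins = NULL, plaque_protein = plaque_protein,
       plaque_mrna = plaque_mrna, cells = cells, collection = collection,
       drug_table = drug_table)
}
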