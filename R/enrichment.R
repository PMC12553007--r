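#' Exact hypergeometric over-representation test
#'
#' Upper-tail probability `P(X >= k)` of observing at least `k` hits in a
#' gene set, where `N` is the background universe size, `K` the set size
#' after intersection with the universe, `n` the number of hits, and `k`
#' the hit-set overlap.  No mid-p correction is applied, so disjoint sets
#' (`k = 0`) give `p = 1`.
#'
#' @param hits Character vector of prioritised identifiers.
#' @param geneset Character vector of set members.
#' @param universe Character vector: the background all identifiers are
#'   intersected with.
#' @return One-row data frame: `overlap_k`, `set_size_K`, `hits_n`,
#'   `universe_N`, `pval`.
#' @export
ora_test <- function(hits, geneset, universe) {
  mrt_assert(length(universe) > 0, "universe must be non-empty")
  universe <- unique(universe)
  hits <- intersect(unique(hits), universe)
  geneset <- intersect(unique(geneset), universe)
  N <- length(universe)
  K <- length(geneset)
  n <- length(hits)
  k <- length(intersect(hits, geneset))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(overlap_k = k, set_size_K = K, hits_n = n, universe_N = N,
             pval = p)
}

#' A gene-set collection over a fixed background universe
#'
#' @param sets Named list of character vectors (set name -> members).
#' @param universe Background identifiers used for every test.
#' @return List of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe) {
  mrt_assert(is.list(sets) && !is.null(names(sets)) && all(nzchar(names(sets))),
             "sets must be a named list")
  structure(list(sets = sets, universe = unique(universe)),
            class = "gene_set_collection")
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated as
#' `name<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path GMT file path.
#' @param universe Background identifiers (defaults to the union of all
#'   set members).
#' @return A [gene_set_collection].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  if (is.null(universe)) universe <- unique(unlist(sets))
  gene_set_collection(sets, universe)
}

#' Over-representation analysis across a collection with BH correction
#'
#' Runs [ora_test()] per set (empty sets are skipped and logged),
#' adjusts p-values by Benjamini-Hochberg across the tested sets, and
#' sorts by q-value then p-value.
#'
#' @param hits Prioritised identifiers.
#' @param collection A [gene_set_collection].
#' @param fdr False discovery rate threshold (default 0.05).
#' @return Data frame with one row per tested set: `set_name`, counts,
#'   `pval`, `qval`, `significant`.  Attribute `"skipped"` lists empty
#'   sets.
#' @export
ora_collection <- function(hits, collection, fdr = 0.05) {
  mrt_assert(inherits(collection, "gene_set_collection"),
             "collection must be a gene_set_collection")
  nonempty <- vapply(collection$sets, function(s)
    length(intersect(s, collection$universe)) > 0, logical(1))
  skipped <- names(collection$sets)[!nonempty]
  sets <- collection$sets[nonempty]
  rows <- lapply(names(sets), function(nm) {
    r <- ora_test(hits, sets[[nm]], collection$universe)
    cbind(data.frame(set_name = nm, stringsAsFactors = FALSE), r)
  })
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(set_name = character(0), overlap_k = integer(0),
               set_size_K = integer(0), hits_n = integer(0),
               universe_N = integer(0), pval = numeric(0))
  if (nrow(out) > 0) {
    adj <- bh_adjust(out$pval, fdr)
    out$qval <- adj$qval
    out$significant <- adj$significant
    out <- out[order(out$qval, out$pval, out$set_name), ]
    rownames(out) <- NULL
  } else {
    out$qval <- numeric(0)
    out$significant <- logical(0)
  }
  attr(out, "skipped") <- skipped
  out
}

#' Classify proteins by druggability from a static annotation table
#'
#' Joins the protein list against an annotation table (as shipped in
#' `inst/extdata` or supplied by the user).  Proteins absent from the
#' table are classified `not_yet_druggable`; duplicate rows for one
#' protein are merged with the union of their drugs, keeping the most
#' advanced status (`drugged` > `druggable` > `not_yet_druggable`).
#'
#' @param proteins Character vector of protein identifiers.
#' @param table Data frame with columns `protein_id`, `status`, `drugs`
#'   (comma-separated, may be empty), `cardiac_indication`,
#'   `cardiac_side_effect` — or a path to such a TSV.
#' @return Data frame with one row per input protein (same order) and the
#'   five annotation columns.
#' @export
classify_druggability <- function(proteins, table) {
  if (is.character(table) && length(table) == 1) {
    table <- read.delim(table, header = TRUE, sep = "\t",
                        colClasses = "character")
    table$cardiac_indication <- table$cardiac_indication %in% c("TRUE", "yes", "Yes")
    table$cardiac_side_effect <- table$cardiac_side_effect %in% c("TRUE", "yes", "Yes")
  }
  rank <- c(drugged = 1L, druggable = 2L, not_yet_druggable = 3L)
  mrt_assert(all(table$status %in% names(rank)),
             "status must be drugged/druggable/not_yet_druggable")
  if (anyDuplicated(table$protein_id)) {
    table <- do.call(rbind, lapply(split(table, table$protein_id), function(d) {
      drugs <- unique(unlist(strsplit(d$drugs, ",", fixed = TRUE)))
      drugs <- drugs[nzchar(trimws(drugs))]
      data.frame(protein_id = d$protein_id[1],
                 status = names(rank)[min(rank[d$status])],
                 drugs = paste(trimws(drugs), collapse = ","),
                 cardiac_indication = any(d$cardiac_indication),
                 cardiac_side_effect = any(d$cardiac_side_effect),
                 stringsAsFactors = FALSE)
    }))
  }
  bad <- table$status == "drugged" & !nzchar(table$drugs)
  mrt_assert(!any(bad), "a drugged protein must list at least one approved drug")
  i <- match(proteins, table$protein_id)
  out <- data.frame(
    protein_id = proteins,
    status = ifelse(is.na(i), "not_yet_druggable", table$status[i]),
    drugs = ifelse(is.na(i), "", table$drugs[i]),
    cardiac_indication = ifelse(is.na(i), FALSE, table$cardiac_indication[i]),
    cardiac_side_effect = ifelse(is.na(i), FALSE, table$cardiac_side_effect[i]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Status counts of a druggability classification
#'
#' @param annotations [classify_druggability()] output.
#' @return Named integer vector `(drugged, druggable, not_yet_druggable)`.
#' @export
druggability_counts <- function(annotations) {
  c(drugged = sum(annotations$status == "drugged"),
    druggable = sum(annotations$status == "druggable"),
    not_yet_druggable = sum(annotations$status == "not_yet_druggable"))
}
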