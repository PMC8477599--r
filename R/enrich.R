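# Gene-proximity annotation and gene-score-resampling (GSR) enrichment
# over GO terms, with a simplified multifunctionality diagnostic.

#' Find genes near loci
#'
#' Reports every gene whose annotated interval overlaps the closed window
#' `[position - window, position + window]` around each locus, on the
#' same scaffold.  A locus may hit several genes and vice versa.
#'
#' @param loci Data frame with `locus_id`, `scaffold`, `position`.
#' @param annotations Path to a GFF file, or a `GRanges` of gene
#'   features.  When a path is given, features are read with
#'   `rtracklayer::import()` and filtered to `type == feature_type`; gene
#'   ids come from the `ID` attribute (fallback `gene_id`, then `Name`).
#' @param window Flanking window in bp (default 5000).
#' @param feature_type GFF feature type to use (default `"gene"`).
#' @return List with `hits` (data frame `locus_id, gene_id`) and
#'   `n_no_gene` (loci with no gene in range, including scaffold
#'   mismatches).
#' @export
genes_near_loci <- function(loci, annotations, window = 5000L,
                            feature_type = "gene") {
  if (is.character(annotations)) {
    gr <- rtracklayer::import(annotations)
    gr <- gr[gr$type == feature_type]
    ids <- gr$ID
    if (is.null(ids)) ids <- gr$gene_id
    if (is.null(ids)) ids <- gr$Name
    if (is.null(ids)) stop("no ID/gene_id/Name attribute in GFF genes")
    gr$gene_id <- ids
  } else {
    gr <- annotations
    if (is.null(gr$gene_id)) stop("annotations GRanges needs a gene_id")
  }
  qry <- GenomicRanges::GRanges(
    seqnames = loci$scaffold,
    ranges = IRanges::IRanges(start = pmax(loci$position - window, 1L),
                              end = loci$position + window))
  ov <- suppressWarnings(GenomicRanges::findOverlaps(qry, gr))
  hits <- data.frame(
    locus_id = loci$locus_id[S4Vectors::queryHits(ov)],
    gene_id = as.character(gr$gene_id[S4Vectors::subjectHits(ov)]),
    stringsAsFactors = FALSE)
  hits <- unique(hits)
  list(hits = hits,
       n_no_gene = sum(!(loci$locus_id %in% hits$locus_id)))
}

#' Per-gene significance scores from locus p-values
#'
#' A gene's score for an effect is the best (minimum) p-value among its
#' nearby loci.
#'
#' @param hits `locus_id`/`gene_id` pairs from [genes_near_loci()].
#' @param pvalues Data frame with `locus_id` and a p-value column.
#' @param p_col Name of the p-value column.
#' @return Named numeric vector of per-gene p-values.
#' @export
gene_scores <- function(hits, pvalues, p_col) {
  p <- pvalues[[p_col]][match(hits$locus_id, pvalues$locus_id)]
  ok <- !is.na(p)
  res <- tapply(p[ok], hits$gene_id[ok], min)
  stats::setNames(as.numeric(res), names(res))
}

#' Gene score resampling enrichment
#'
#' Scores each gene as `-log10(p)`, aggregates each GO term as the mean
#' score of its member genes, and compares it to a null distribution of
#' mean scores over random gene sets of the same size drawn without
#' replacement from all scored genes.  The empirical p-value is
#' `(1 + #{null >= observed}) / (n_resamples + 1)`.  Terms sharing a
#' member count share one null distribution (the draws depend only on set
#' size), so results are reproducible per seed and identical-membership
#' terms get identical results.
#'
#' @param scores Named vector of per-gene p-values (the gene universe).
#' @param go_map Data frame `gene_id, go_id` (one pair per row).
#' @param n_resamples Number of random sets per set size (default 10000).
#' @param min_members Minimum scored genes per tested term (default 2).
#' @param seed Optional integer seed.
#' @return Data frame per tested term: `go_id, n_genes, score, p_value`;
#'   skipped terms are recorded in the `skipped` attribute.
#' @export
gene_score_resampling <- function(scores, go_map, n_resamples = 10000L,
                                  min_members = 2L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- -log10(scores)
  genes <- names(s)
  members <- split(go_map$gene_id, go_map$go_id)
  members <- lapply(members, function(g) unique(intersect(g, genes)))
  n_mem <- lengths(members)
  skipped <- names(members)[n_mem < min_members]
  members <- members[n_mem >= min_members]
  sizes <- sort(unique(lengths(members)))
  null_by_size <- lapply(sizes, function(k) {
    vapply(seq_len(n_resamples),
           function(i) mean(s[sample.int(length(s), k)]), numeric(1))
  })
  names(null_by_size) <- as.character(sizes)
  obs <- vapply(members, function(g) mean(s[g]), numeric(1))
  pval <- vapply(seq_along(members), function(i) {
    null <- null_by_size[[as.character(length(members[[i]]))]]
    (1 + sum(null >= obs[i])) / (n_resamples + 1)
  }, numeric(1))
  out <- data.frame(go_id = names(members), n_genes = lengths(members),
                    score = unname(obs), p_value = pval,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Simplified multifunctionality scores
#'
#' Gene multifunctionality (MF) is the normalized mid-rank of its number
#' of GO memberships, scaled to `[0, 1]` (`(rank - 1) / (n - 1)`; all-tied
#' genes get 0.5).  Term MF is the mean MF of member genes.  A diagnostic
#' annotation only — a membership-count rank, not the optimization-based
#' score of dedicated enrichment tools.
#'
#' @param go_map Data frame `gene_id, go_id`.
#' @return List with `gene_mf` (named vector) and `term_mf` (named
#'   vector).
#' @export
multifunctionality_scores <- function(go_map) {
  counts <- table(unique(go_map)$gene_id)
  n <- length(counts)
  mf <- if (n == 1L) stats::setNames(0.5, names(counts)) else {
    r <- rank(as.numeric(counts), ties.method = "average")
    stats::setNames((r - 1) / (n - 1), names(counts))
  }
  members <- split(go_map$gene_id, go_map$go_id)
  term_mf <- vapply(members, function(g) mean(mf[unique(g)]), numeric(1))
  list(gene_mf = mf, term_mf = term_mf)
}

#' Full enrichment analysis for one effect
#'
#' Convenience wrapper: gene scores from locus p-values, GSR empirical
#' p-values, and multifunctionality annotation, assembled into one table
#' sorted by empirical p.
#'
#' @inheritParams gene_score_resampling
#' @param hits Locus-to-gene table from [genes_near_loci()].
#' @param pvalues,p_col Locus p-values and the column to use.
#' @param go_names Optional named character vector mapping GO ids to
#'   names.
#' @return Data frame `go_id, name, n_genes, score, p_value, mf`.
#' @export
enrichment_analysis <- function(hits, pvalues, p_col, go_map,
                                n_resamples = 10000L, min_members = 2L,
                                seed = NULL, go_names = NULL) {
  scores <- gene_scores(hits, pvalues, p_col)
  res <- gene_score_resampling(scores, go_map, n_resamples, min_members,
                               seed)
  mf <- multifunctionality_scores(
    go_map[go_map$gene_id %in% names(scores), , drop = FALSE])
  res$mf <- unname(mf$term_mf[res$go_id])
  res$name <- if (is.null(go_names)) NA_character_ else
    unname(go_names[res$go_id])
  res <- res[order(res$p_value), c("go_id", "name", "n_genes", "score",
                                   "p_value", "mf")]
  rownames(res) <- NULL
  res
}
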