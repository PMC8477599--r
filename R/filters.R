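# Locus-retention cascade: depth -> biallelic -> one SNP per tag ->
# replicate presence -> minor-allele frequency.  Filters only change
# membership / missingness, never surviving counts.

#' Mask cells outside the depth retention window
#'
#' Cells (sample x locus) whose total read depth lies outside
#' `[min_depth, max_depth]` are set missing (all four counts `NA`); loci
#' missing in every sample are dropped.  Masking rather than dropping
#' keeps [replicate_presence_filter()] the sole arbiter of testability.
#'
#' @param counts A count table.
#' @param min_depth,max_depth Inclusive retention bounds (defaults 50 and
#'   1000).
#' @return A count table with an `audit` attribute recording loci removed.
#' @export
depth_filter <- function(counts, min_depth = 50L, max_depth = 1000L) {
  if (min_depth >= max_depth) stop("min_depth must be < max_depth")
  audit <- attr(counts, "audit")
  counts <- as_count_table(counts)
  depth <- rowSums(counts[, COUNT_COLS])
  bad <- !is.na(depth) & (depth < min_depth | depth > max_depth)
  counts[bad, COUNT_COLS] <- NA_integer_
  alive <- !is.na(counts$countA)
  dead_loci <- setdiff(unique(counts$locus_id),
                       unique(counts$locus_id[alive]))
  out <- counts[!(counts$locus_id %in% dead_loci), , drop = FALSE]
  rownames(out) <- NULL
  add_audit(out, "depth_filter", length(dead_loci), audit)
}

add_audit <- function(x, name, removed, prev = NULL) {
  attr(x, "audit") <- c(prev, stats::setNames(list(removed), name))
  x
}

#' Drop loci with more than two observed alleles
#'
#' An allele is "observed" when its read count summed over all non-missing
#' samples reaches `min_allele_reads`.  Loci with more than two observed
#' nucleotides are dropped; two-allele loci get their allele identities
#' recorded (orientation is assigned later, at panel construction).
#'
#' @param counts A count table.
#' @param min_allele_reads Minimum summed reads for a nucleotide to count
#'   as an observed allele (default 1: a single stray read creates a
#'   third allele).
#' @return A count table; its `alleles` attribute maps retained loci to
#'   observed nucleotides.
#' @export
biallelic_filter <- function(counts, min_allele_reads = 1L) {
  audit <- attr(counts, "audit")
  counts <- as_count_table(counts)
  tot <- rowsum(as.matrix(counts[, COUNT_COLS]), counts$locus_id,
                na.rm = TRUE)
  n_alleles <- rowSums(tot >= min_allele_reads)
  drop <- rownames(tot)[n_alleles > 2]
  out <- counts[!(counts$locus_id %in% drop), , drop = FALSE]
  rownames(out) <- NULL
  keep_tot <- tot[setdiff(rownames(tot), drop), , drop = FALSE]
  nts <- c("A", "C", "G", "T")
  alleles <- apply(keep_tot, 1L, function(r) nts[r >= min_allele_reads],
                   simplify = FALSE)
  out <- add_audit(out, "biallelic_filter", length(drop), audit)
  attr(out, "alleles") <- alleles
  out
}

#' Build a SNP panel from biallelic-filtered counts
#'
#' Collects per-locus (allele1, allele2) read counts into loci x samples
#' matrices.  Monomorphic loci (fewer than two observed alleles) are
#' dropped here.  Allele 2 is fixed as the minor allele at baseline:
#' frequency computed from day-2 samples of both groups combined,
#' read-count weighted (falling back to all samples when a locus has no
#' day-2 reads); the orientation is then held constant so frequency
#' trajectories stay comparable.  Ties (exactly 0.5) keep the
#' alphabetically later nucleotide as allele 2.
#'
#' @param counts Output of [biallelic_filter()].
#' @return An object of class `snp_panel`: list with `loci` (locus
#'   metadata + alleles), `samples` (sample metadata), `c1`/`c2` (count
#'   matrices, allele 1 = baseline major), and `audit`.
#' @export
snp_panel <- function(counts) {
  alleles <- attr(counts, "alleles")
  audit <- attr(counts, "audit")
  counts <- as_count_table(counts)
  if (is.null(alleles))
    stop("counts must come from biallelic_filter() (no alleles attribute)")
  mono <- names(alleles)[lengths(alleles) < 2L]
  keep <- setdiff(names(alleles), mono)
  counts2 <- counts[counts$locus_id %in% keep, , drop = FALSE]

  loci_meta <- unique(counts2[, c("locus_id", "scaffold", "tag_start",
                                  "position")])
  loci_meta <- loci_meta[order(loci_meta$scaffold, loci_meta$tag_start,
                               loci_meta$position), ]
  rownames(loci_meta) <- NULL
  samples <- unique(counts2[, c("sample_id", "group", "stage", "treatment",
                                "replicate")])
  rownames(samples) <- NULL
  li <- match(counts2$locus_id, loci_meta$locus_id)
  si <- match(counts2$sample_id, samples$sample_id)
  nl <- nrow(loci_meta); ns <- nrow(samples)
  cA <- matrix(NA_real_, nl, ns,
               dimnames = list(loci_meta$locus_id, samples$sample_id))
  cB <- cA
  nts <- c("A", "C", "G", "T")
  a1 <- vapply(alleles[loci_meta$locus_id], `[`, "", 1L)
  a2 <- vapply(alleles[loci_meta$locus_id], `[`, "", 2L)
  cnt <- as.matrix(counts2[, COUNT_COLS])
  colnames(cnt) <- nts
  cA[cbind(li, si)] <- cnt[cbind(seq_len(nrow(cnt)), match(a1[li], nts))]
  cB[cbind(li, si)] <- cnt[cbind(seq_len(nrow(cnt)), match(a2[li], nts))]

  # baseline (day-2, both groups, count-weighted) orientation
  base_cols <- samples$stage == "day2"
  sumA_base <- rowSums(cA[, base_cols, drop = FALSE], na.rm = TRUE)
  sumB_base <- rowSums(cB[, base_cols, drop = FALSE], na.rm = TRUE)
  no_base <- (sumA_base + sumB_base) == 0
  sumA_base[no_base] <- rowSums(cA[no_base, , drop = FALSE], na.rm = TRUE)
  sumB_base[no_base] <- rowSums(cB[no_base, , drop = FALSE], na.rm = TRUE)
  fB <- sumB_base / pmax(sumA_base + sumB_base, 1)
  swap <- fB > 0.5 | (fB == 0.5 & a1 > a2)
  allele1 <- ifelse(swap, a2, a1)
  allele2 <- ifelse(swap, a1, a2)
  c1 <- cA; c2 <- cB
  c1[swap, ] <- cB[swap, , drop = FALSE]
  c2[swap, ] <- cA[swap, , drop = FALSE]

  loci_meta$allele1 <- allele1
  loci_meta$allele2 <- allele2
  structure(list(loci = loci_meta, samples = samples, c1 = c1, c2 = c2,
                 audit = c(audit, list(monomorphic = length(mono)))),
            class = "snp_panel")
}

#' @export
print.snp_panel <- function(x, ...) {
  cat("snp_panel:", nrow(x$loci), "loci x", nrow(x$samples), "samples\n")
  if (length(x$audit)) {
    cat("audit (loci removed):\n")
    for (nm in names(x$audit)) cat("  ", nm, ":", x$audit[[nm]], "\n")
  }
  invisible(x)
}

subset_panel <- function(panel, keep, filter_name) {
  removed <- nrow(panel$loci) - sum(keep)
  panel$loci <- panel$loci[keep, , drop = FALSE]
  rownames(panel$loci) <- NULL
  panel$c1 <- panel$c1[keep, , drop = FALSE]
  panel$c2 <- panel$c2[keep, , drop = FALSE]
  panel$audit <- c(panel$audit, stats::setNames(list(removed), filter_name))
  panel
}

#' Keep one SNP per 36-bp restriction tag
#'
#' Within each (scaffold, tag_start) group, keeps the SNP with the highest
#' total read depth across all samples; ties resolve to the smallest
#' position.  Limits artifacts from ambiguous read mapping that can fake
#' multiple nearby polymorphisms.
#'
#' @param panel A `snp_panel`.
#' @return The filtered panel.
#' @export
one_snp_per_tag <- function(panel) {
  stopifnot(inherits(panel, "snp_panel"))
  depth <- rowSums(panel$c1 + panel$c2, na.rm = TRUE)
  tag <- paste(panel$loci$scaffold, panel$loci$tag_start)
  ord <- order(tag, -depth, panel$loci$position)
  keep_ids <- panel$loci$locus_id[ord][!duplicated(tag[ord])]
  subset_panel(panel, panel$loci$locus_id %in% keep_ids, "one_snp_per_tag")
}

#' Require replicate presence in every design cell
#'
#' Retains loci with at least `min_reps` non-missing replicate pools in
#' every stage x treatment cell of each group under analysis.
#'
#' @param panel A `snp_panel`.
#' @param min_reps Minimum replicates per cell (default 3).
#' @param groups Groups that must each satisfy the predicate (default:
#'   all groups in the panel; pass a single group for a per-group panel).
#' @return The filtered panel.
#' @export
replicate_presence_filter <- function(panel, min_reps = 3L,
                                      groups = unique(panel$samples$group)) {
  stopifnot(inherits(panel, "snp_panel"))
  s <- panel$samples
  ok <- rep(TRUE, nrow(panel$loci))
  for (g in groups) for (st in unique(s$stage[s$group == g]))
    for (tr in unique(s$treatment[s$group == g])) {
      cols <- s$group == g & s$stage == st & s$treatment == tr
      n_present <- rowSums(!is.na(panel$c1[, cols, drop = FALSE]))
      ok <- ok & n_present >= min_reps
    }
  subset_panel(panel, ok, "replicate_presence_filter")
}

# Baseline (day-2, both treatments, count-weighted) minor-allele frequency
# per group.  Returns a loci x groups matrix of MAF in [0, 0.5].
baseline_maf <- function(panel, groups = unique(panel$samples$group)) {
  s <- panel$samples
  out <- sapply(groups, function(g) {
    cols <- s$group == g & s$stage == "day2"
    tot1 <- rowSums(panel$c1[, cols, drop = FALSE], na.rm = TRUE)
    tot2 <- rowSums(panel$c2[, cols, drop = FALSE], na.rm = TRUE)
    f <- ifelse(tot1 + tot2 > 0, tot2 / (tot1 + tot2), NA_real_)
    pmin(f, 1 - f)
  })
  matrix(out, nrow = nrow(panel$loci), dimnames = list(panel$loci$locus_id,
                                                       groups))
}

#' Filter on starting minor-allele frequency
#'
#' Retains loci whose baseline (day-2, treatments pooled, read-count
#' weighted) minor-allele frequency strictly exceeds `min_maf` in at least
#' one group.
#'
#' @param panel A `snp_panel`.
#' @param min_maf Strict lower bound on the starting MAF (default 0.01).
#' @return The filtered panel; baseline MAFs are stored in
#'   `panel$loci$maf_<group>` columns.
#' @export
maf_filter <- function(panel, min_maf = 0.01) {
  stopifnot(inherits(panel, "snp_panel"))
  maf <- baseline_maf(panel)
  keep <- rowSums(maf > min_maf, na.rm = TRUE) >= 1L
  for (g in colnames(maf))
    panel$loci[[paste0("maf_", g)]] <- maf[, g]
  subset_panel(panel, keep, "maf_filter")
}

#' Run the full locus-retention cascade
#'
#' Applies, in order: [depth_filter()], [biallelic_filter()],
#' [snp_panel()] construction, [one_snp_per_tag()],
#' [replicate_presence_filter()] and [maf_filter()], accumulating the
#' audit trail.
#'
#' @param counts A raw merged count table.
#' @param min_depth,max_depth,min_allele_reads,min_reps,min_maf Thresholds
#'   passed to the individual filters.
#' @param groups Groups required testable by the presence filter (default
#'   all).
#' @return A filtered `snp_panel`.
#' @export
filter_pipeline <- function(counts, min_depth = 50L, max_depth = 1000L,
                            min_allele_reads = 1L, min_reps = 3L,
                            min_maf = 0.01, groups = NULL) {
  x <- depth_filter(counts, min_depth, max_depth)
  x <- biallelic_filter(x, min_allele_reads)
  panel <- snp_panel(x)
  panel <- one_snp_per_tag(panel)
  if (is.null(groups)) groups <- unique(panel$samples$group)
  panel <- replicate_presence_filter(panel, min_reps, groups)
  maf_filter(panel, min_maf)
}
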