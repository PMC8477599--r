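# Linkage-map bridging: SNPs inherit the linkage-group / cM position of
# markers sharing their genomic scaffold.

#' Read a linkage map table
#'
#' TSV with columns `marker_id, scaffold, position, linkage_group, cM`.
#'
#' @param path File path.
#' @return Validated data frame.
#' @export
read_linkage_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_linkage_map(map)
}

validate_linkage_map <- function(map) {
  need <- c("marker_id", "scaffold", "position", "linkage_group", "cM")
  miss <- setdiff(need, names(map))
  if (length(miss))
    stop("linkage map missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(map$marker_id)) stop("duplicate marker ids")
  if (any(map$cM < 0)) stop("negative cM positions")
  map
}

#' Assign SNPs to linkage positions via shared scaffolds
#'
#' For each SNP: a scaffold carrying exactly one mapped marker passes its
#' position to all its SNPs (`one_to_one` when the scaffold has a single
#' SNP, `many_to_one` otherwise); a scaffold with several markers on one
#' linkage group assigns each SNP the bp-nearest marker
#' (`nearest_of_many`; equidistant ties go to the lower-bp marker); SNPs
#' on scaffolds absent from the map (`omitted_no_marker`) or whose
#' markers span multiple linkage groups (`omitted_multi_LG`) are omitted
#' with the reason recorded.  Every input locus appears exactly once.
#'
#' @param loci Data frame with `locus_id`, `scaffold`, `position`.
#' @param map Linkage map (see [read_linkage_map()]).
#' @return Data frame: `locus_id, scaffold, position, linkage_group, cM,
#'   marker_id, rule`; assignment columns are `NA` for omitted loci.
#' @export
assign_linkage_positions <- function(loci, map) {
  map <- validate_linkage_map(map)
  out <- data.frame(locus_id = loci$locus_id, scaffold = loci$scaffold,
                    position = loci$position,
                    linkage_group = NA_character_, cM = NA_real_,
                    marker_id = NA_character_, rule = "omitted_no_marker",
                    stringsAsFactors = FALSE)
  snps_per_scaf <- table(loci$scaffold)
  for (scaf in intersect(unique(loci$scaffold), unique(map$scaffold))) {
    mk <- map[map$scaffold == scaf, , drop = FALSE]
    rows <- which(out$scaffold == scaf)
    if (length(unique(mk$linkage_group)) > 1L) {
      out$rule[rows] <- "omitted_multi_LG"
      next
    }
    if (nrow(mk) == 1L) {
      out$linkage_group[rows] <- as.character(mk$linkage_group)
      out$cM[rows] <- mk$cM
      out$marker_id[rows] <- mk$marker_id
      out$rule[rows] <- if (snps_per_scaf[[scaf]] == 1L) "one_to_one"
                        else "many_to_one"
    } else {
      mk <- mk[order(mk$position), , drop = FALSE]  # ties -> lower bp
      for (r in rows) {
        d <- abs(mk$position - out$position[r])
        j <- which.min(d)
        out$linkage_group[r] <- as.character(mk$linkage_group[j])
        out$cM[r] <- mk$cM[j]
        out$marker_id[r] <- mk$marker_id[j]
        out$rule[r] <- "nearest_of_many"
      }
    }
  }
  out
}

#' Manhattan-style significance table for mapped SNPs
#'
#' Joins bridged loci with per-locus p-values, sorts by (linkage group,
#' cM, bp) and reports `-log10(p)` per effect plus, per effect, the
#' Benjamini-Hochberg threshold line: the largest raw p-value called
#' significant at each FDR level (`NA` when nothing is).  Loci sharing a
#' linkage position are flagged `co_located`.
#'
#' @param bridged Output of [assign_linkage_positions()]; omitted loci
#'   are excluded.
#' @param pvalues Data frame with `locus_id` and one or more p-value
#'   columns (e.g. `p_stage`, `p_trt`).
#' @param fdr_levels FDR levels for the threshold lines (default 0.05 and
#'   0.01).
#' @return List with `table` (sorted plotting table) and `thresholds`
#'   (effect x level matrix of raw-p cutoffs).
#' @export
manhattan_table <- function(bridged, pvalues, fdr_levels = c(0.05, 0.01)) {
  b <- bridged[!startsWith(bridged$rule, "omitted"), , drop = FALSE]
  m <- match(b$locus_id, pvalues$locus_id)
  if (anyNA(m)) stop("p-values missing for some mapped loci")
  pcols <- setdiff(names(pvalues), "locus_id")
  tab <- b[, c("locus_id", "scaffold", "position", "linkage_group", "cM")]
  thresholds <- matrix(NA_real_, length(pcols), length(fdr_levels),
                       dimnames = list(pcols, paste0("fdr_", fdr_levels)))
  for (pc in pcols) {
    p <- pvalues[[pc]][m]
    tab[[paste0("neglog10_", pc)]] <- -log10(p)
    for (k in seq_along(fdr_levels)) {
      q <- stats::p.adjust(p, "BH")
      sig <- !is.na(q) & q <= fdr_levels[k]
      if (any(sig)) thresholds[pc, k] <- max(p[sig], na.rm = TRUE)
    }
  }
  ord <- order(tab$linkage_group, tab$cM, tab$position)
  tab <- tab[ord, , drop = FALSE]
  pos_key <- paste(tab$linkage_group, tab$cM)
  tab$co_located <- pos_key %in% pos_key[duplicated(pos_key)]
  rownames(tab) <- NULL
  list(table = tab, thresholds = thresholds)
}
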