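# Pool-adapted diversity and differentiation statistics: allele
# frequencies, nucleotide diversity, pairwise FST, bootstrap CIs, folded
# spectrum comparison, replicate PCA.

#' Allele-2 frequency matrices from a SNP panel
#'
#' Frequencies are for allele 2 (the baseline minor allele).  Aggregation
#' above the replicate level pools read counts (read-count weighting), it
#' does not average per-replicate frequencies.
#'
#' @param panel A `snp_panel`.
#' @param level `"replicate"` (one column per sample), `"cell"` (per
#'   group x stage x treatment), or `"group"`.
#' @return List of class `freq_matrix` with `f` (frequencies), `depth`
#'   (read depths) and `samples` (column metadata).
#' @export
allele_frequencies <- function(panel,
                               level = c("replicate", "cell", "group")) {
  stopifnot(inherits(panel, "snp_panel"))
  level <- match.arg(level)
  s <- panel$samples
  key <- switch(level,
                replicate = s$sample_id,
                cell = paste(s$group, s$stage, s$treatment, sep = "_"),
                group = s$group)
  groups <- unique(key)
  c1 <- sapply(groups, function(k)
    rowSums(panel$c1[, key == k, drop = FALSE], na.rm = TRUE))
  c2 <- sapply(groups, function(k)
    rowSums(panel$c2[, key == k, drop = FALSE], na.rm = TRUE))
  c1 <- matrix(c1, nrow = nrow(panel$loci),
               dimnames = list(panel$loci$locus_id, groups))
  c2 <- matrix(c2, nrow = nrow(panel$loci),
               dimnames = list(panel$loci$locus_id, groups))
  if (level == "replicate") {  # keep genuine missingness at replicate level
    c1 <- panel$c1
    c2 <- panel$c2
  }
  depth <- c1 + c2
  f <- ifelse(!is.na(depth) & depth > 0, c2 / depth, NA_real_)
  meta <- if (level == "replicate") s else
    unique(data.frame(key = key,
                      group = s$group)[, c("key", "group"), drop = FALSE])
  structure(list(f = f, depth = depth, level = level, samples = meta),
            class = "freq_matrix")
}

#' Pooled nucleotide diversity
#'
#' Per locus and sample, `pi = (D / (D - 1)) * 2 * f * (1 - f)` with `D`
#' the read depth and `f` the allele-2 frequency: the expected
#' heterozygosity of two reads drawn without replacement, a pool-seq
#' finite-depth correction.  Cells with `D < 2` are excluded.  The
#' per-locus value averages samples in scope; the mean averages loci.
#'
#' @param panel A `snp_panel`.
#' @param samples Optional character vector of sample ids to restrict the
#'   scope (e.g. day-2 ambient pools of one group).
#' @param correction If `FALSE`, report raw `2 f (1 - f)` without the
#'   `D/(D-1)` factor.
#' @return List with `per_locus` (named vector) and `mean`.
#' @export
nucleotide_diversity <- function(panel, samples = NULL, correction = TRUE) {
  stopifnot(inherits(panel, "snp_panel"))
  cols <- if (is.null(samples)) panel$samples$sample_id else samples
  c1 <- panel$c1[, cols, drop = FALSE]
  c2 <- panel$c2[, cols, drop = FALSE]
  D <- c1 + c2
  f <- c2 / D
  pi_mat <- 2 * f * (1 - f)
  if (correction) pi_mat <- pi_mat * D / (D - 1)
  pi_mat[!is.na(D) & D < 2] <- NA_real_
  per_locus <- rowMeans(pi_mat, na.rm = TRUE)
  per_locus[is.nan(per_locus)] <- NA_real_
  list(per_locus = per_locus, mean = mean(per_locus, na.rm = TRUE))
}

#' Pairwise FST between two sets of pools
#'
#' Hudson/Wright heterozygosity form on pooled per-group frequencies:
#' `HS = 2 f (1 - f)` within each group, `HT = 2 fbar (1 - fbar)` with
#' `fbar` the unweighted mean of the two group frequencies, and
#' `FST = (HT - mean(HS)) / HT`.  SNPs with `HT = 0` are `NA` and excluded
#' from the mean; negative per-SNP values are retained, not clamped.
#'
#' @param panel A `snp_panel`.
#' @param samplesA,samplesB Character vectors of sample ids defining the
#'   two groups (read counts are pooled within each).
#' @return List with `per_snp` (named vector) and `mean`.
#' @export
pairwise_fst <- function(panel, samplesA, samplesB) {
  stopifnot(inherits(panel, "snp_panel"))
  if (!length(samplesA) || !length(samplesB))
    stop("both sample sets must be non-empty")
  pool_f <- function(cols) {
    t1 <- rowSums(panel$c1[, cols, drop = FALSE], na.rm = TRUE)
    t2 <- rowSums(panel$c2[, cols, drop = FALSE], na.rm = TRUE)
    ifelse(t1 + t2 > 0, t2 / (t1 + t2), NA_real_)
  }
  fA <- pool_f(samplesA)
  fB <- pool_f(samplesB)
  hs <- (2 * fA * (1 - fA) + 2 * fB * (1 - fB)) / 2
  fbar <- (fA + fB) / 2
  ht <- 2 * fbar * (1 - fbar)
  fst <- ifelse(!is.na(ht) & ht > 0, (ht - hs) / ht, NA_real_)
  names(fst) <- panel$loci$locus_id
  list(per_snp = fst, mean = mean(fst, na.rm = TRUE))
}

#' Percentile bootstrap CI for a mean over loci
#'
#' Resamples loci with replacement `n_boot` times and returns the
#' percentile interval of the resampled means.
#'
#' @param x Numeric vector of per-locus statistics (`NA`s dropped).
#' @param n_boot Number of resamples (default 1000).
#' @param ci Interval mass (default 0.95).
#' @param seed Optional integer seed.
#' @return Named vector `c(lower, upper)`.
#' @export
bootstrap_ci <- function(x, n_boot = 1000L, ci = 0.95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) return(c(lower = NA_real_, upper = NA_real_))
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  means <- colMeans(matrix(x[idx], nrow = n))
  q <- stats::quantile(means, c((1 - ci) / 2, 1 - (1 - ci) / 2),
                       names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

#' Compare folded allele-frequency spectra
#'
#' Folds both frequency vectors to minor-allele frequencies
#' (`pmin(f, 1 - f)`) and runs a two-sample Kolmogorov-Smirnov test.
#'
#' @param freqsA,freqsB Numeric vectors of allele frequencies.
#' @return List with `statistic` and `p_value`.
#' @export
sfs_compare <- function(freqsA, freqsB) {
  a <- pmin(freqsA, 1 - freqsA)
  b <- pmin(freqsB, 1 - freqsB)
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  kt <- suppressWarnings(stats::ks.test(a, b))
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}

#' PCA of replicate pool allele frequencies
#'
#' Samples are observations, loci variables; frequencies are centered per
#' locus but not scaled.  Missing cells are mean-imputed per locus before
#' decomposition (the number imputed is reported).
#'
#' @param fm A `freq_matrix` at replicate level (see
#'   [allele_frequencies()]).
#' @return List with `scores` (samples x PCs), `explained` (variance
#'   fractions summing to 1), `n_imputed` and the `prcomp` fit.
#' @export
replicate_pca <- function(fm) {
  stopifnot(inherits(fm, "freq_matrix"))
  f <- fm$f
  n_imputed <- sum(is.na(f))
  if (n_imputed) {
    mu <- rowMeans(f, na.rm = TRUE)
    idx <- which(is.na(f), arr.ind = TRUE)
    f[idx] <- mu[idx[, 1]]
    f[is.na(f)] <- 0  # loci missing everywhere
  }
  fit <- stats::prcomp(t(f), center = TRUE, scale. = FALSE)
  tot <- sum(fit$sdev^2)
  expl <- if (tot > 0) fit$sdev^2 / tot else rep(NA_real_,
                                                 length(fit$sdev))
  list(scores = fit$x, explained = expl, n_imputed = n_imputed, fit = fit)
}
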