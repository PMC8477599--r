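# Per-locus binomial GLM with type III likelihood-ratio tests,
# Benjamini-Hochberg adjustment, exclusive effect classification, and
# category cross-tabulation.

#' Fit the per-locus binomial GLM and type III tests
#'
#' Models allele-2 successes out of total reads per replicate pool with a
#' logit-link binomial GLM, full model `~ stage + trt + stage:trt` under
#' sum-to-zero coding (day2/ambient = -1, day22/high = +1).  Each term's
#' type III p-value is the likelihood-ratio test of the full model against
#' the model with only that term's column removed, so main effects are
#' tested with the interaction retained.
#'
#' @param c1,c2 Integer vectors of allele-1 / allele-2 read counts per
#'   replicate pool (`NA` cells dropped).
#' @param stage,trt Factors or character vectors with two levels each
#'   (`day2`/`day22`, `ambient`/`high`), parallel to the counts.
#' @return List with `beta` (named `stage`, `trt`, `int`, full-model
#'   estimates on the logit scale), `p` (named type III p-values),
#'   `deviance` (full-model deviance), `lr` (named LR statistics) and
#'   `converged`.  Degenerate loci (no reads, or all reads on one allele)
#'   return `NA` p-values with `converged = FALSE`.
#' @export
fit_locus_glm <- function(c1, c2, stage, trt) {
  ok <- !is.na(c1) & !is.na(c2) & (c1 + c2) >= 1
  c1 <- c1[ok]; c2 <- c2[ok]
  s <- ifelse(stage[ok] == "day22", 1, -1)
  t_ <- ifelse(trt[ok] == "high", 1, -1)
  bad <- list(beta = c(stage = NA_real_, trt = NA_real_, int = NA_real_),
              p = c(stage = NA_real_, trt = NA_real_, int = NA_real_),
              deviance = NA_real_,
              lr = c(stage = NA_real_, trt = NA_real_, int = NA_real_),
              converged = FALSE)
  if (length(c1) < 4L || length(unique(paste(s, t_))) < 4L) return(bad)
  if (sum(c2) == 0 || sum(c1) == 0) return(bad)
  m <- c1 + c2
  X <- cbind("(Intercept)" = 1, stage = s, trt = t_, int = s * t_)
  fit_dev <- function(cols) {
    f <- suppressWarnings(
      stats::glm.fit(X[, cols, drop = FALSE], c2 / m, weights = m,
                     family = stats::binomial()))
    list(dev = f$deviance, coef = f$coefficients, conv = f$converged)
  }
  full <- fit_dev(1:4)
  if (!full$conv || !is.finite(full$dev)) return(bad)
  terms <- c(stage = 2L, trt = 3L, int = 4L)
  lr <- p <- stats::setNames(rep(NA_real_, 3L), names(terms))
  conv <- TRUE
  for (nm in names(terms)) {
    red <- fit_dev(setdiff(1:4, terms[[nm]]))
    if (!red$conv || !is.finite(red$dev)) { conv <- FALSE; next }
    lr[nm] <- max(red$dev - full$dev, 0)
    p[nm] <- stats::pchisq(lr[nm], df = 1L, lower.tail = FALSE)
  }
  list(beta = c(stage = unname(full$coef["stage"]),
                trt = unname(full$coef["trt"]),
                int = unname(full$coef["int"])),
       p = p, deviance = full$dev, lr = lr, converged = conv)
}

#' Fit the GLM across all loci of one group
#'
#' @param panel A `snp_panel`.
#' @param group Group label to analyze (a value of
#'   `panel$samples$group`).
#' @return Data frame with one row per locus: coefficient estimates, type
#'   III p-values and a convergence flag.
#' @export
fit_effects <- function(panel, group) {
  stopifnot(inherits(panel, "snp_panel"))
  cols <- panel$samples$group == group
  if (!any(cols)) stop("no samples in group '", group, "'")
  s <- panel$samples$stage[cols]
  tr <- panel$samples$treatment[cols]
  c1 <- panel$c1[, cols, drop = FALSE]
  c2 <- panel$c2[, cols, drop = FALSE]
  n <- nrow(panel$loci)
  out <- data.frame(locus_id = panel$loci$locus_id,
                    beta_stage = NA_real_, beta_trt = NA_real_,
                    beta_int = NA_real_, p_stage = NA_real_,
                    p_trt = NA_real_, p_int = NA_real_,
                    converged = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    f <- fit_locus_glm(c1[i, ], c2[i, ], s, tr)
    out$beta_stage[i] <- f$beta[["stage"]]
    out$beta_trt[i] <- f$beta[["trt"]]
    out$beta_int[i] <- f$beta[["int"]]
    out$p_stage[i] <- f$p[["stage"]]
    out$p_trt[i] <- f$p[["trt"]]
    out$p_int[i] <- f$p[["int"]]
    out$converged[i] <- f$converged
  }
  out
}

CATEGORY_LEVELS <- c("None", "Stage", "Trt", "Stage+Trt", "Stage*Trt")

#' Classify loci into exclusive effect categories
#'
#' Applies Benjamini-Hochberg adjustment per term across loci (three
#' families per group by default) and assigns each locus to exactly one
#' category: `Stage*Trt` when the interaction q-value clears `alpha`
#' (regardless of main effects), else `Stage+Trt` when both mains do,
#' else `Stage` or `Trt` when exactly one does, else `None`.
#' Non-converged loci are excluded from the BH families and classified
#' `None` with `NA` q-values.
#'
#' @param fits Output of [fit_effects()].
#' @param alpha FDR threshold (default 0.05).
#' @param family `"per_term"` (default) adjusts each term across loci
#'   separately; `"pooled"` adjusts all three terms in one family.
#' @return `fits` augmented with `q_stage`, `q_trt`, `q_int`, `category`
#'   and `int_sign` (sign of the interaction estimate, only for
#'   `Stage*Trt` loci).
#' @export
classify_effects <- function(fits, alpha = 0.05,
                             family = c("per_term", "pooled")) {
  family <- match.arg(family)
  ok <- fits$converged & !is.na(fits$p_stage) & !is.na(fits$p_trt) &
    !is.na(fits$p_int)
  q_stage <- q_trt <- q_int <- rep(NA_real_, nrow(fits))
  if (family == "per_term") {
    q_stage[ok] <- stats::p.adjust(fits$p_stage[ok], "BH")
    q_trt[ok] <- stats::p.adjust(fits$p_trt[ok], "BH")
    q_int[ok] <- stats::p.adjust(fits$p_int[ok], "BH")
  } else {
    pq <- stats::p.adjust(c(fits$p_stage[ok], fits$p_trt[ok],
                            fits$p_int[ok]), "BH")
    k <- sum(ok)
    q_stage[ok] <- pq[seq_len(k)]
    q_trt[ok] <- pq[k + seq_len(k)]
    q_int[ok] <- pq[2 * k + seq_len(k)]
  }
  sig_s <- !is.na(q_stage) & q_stage < alpha
  sig_t <- !is.na(q_trt) & q_trt < alpha
  sig_i <- !is.na(q_int) & q_int < alpha
  category <- rep("None", nrow(fits))
  category[sig_s & !sig_t] <- "Stage"
  category[sig_t & !sig_s] <- "Trt"
  category[sig_s & sig_t] <- "Stage+Trt"
  category[sig_i] <- "Stage*Trt"
  fits$q_stage <- q_stage
  fits$q_trt <- q_trt
  fits$q_int <- q_int
  fits$category <- factor(category, levels = CATEGORY_LEVELS)
  fits$int_sign <- ifelse(category == "Stage*Trt",
                          ifelse(fits$beta_int < 0, "-", "+"),
                          NA_character_)
  fits
}

#' Cross-tabulate effect categories between two groups
#'
#' @param effectsA,effectsB Classified effect tables
#'   ([classify_effects()]) for the two groups over the same loci.
#' @param labels Length-2 character, row/column group labels.
#' @param collapse Collapsing used for the chi-square comparison of
#'   category distributions: `"sig_vs_not"` (default) tests the 2x2 table
#'   of significant-vs-not counts by group; `"full"` tests the two 5-level
#'   category margins against each other.
#' @return List with `crosstab` (5x5 matrix, rows = group A), `margins`,
#'   `chisq` (statistic, df, p_value) and `n_loci`.
#' @export
crosstab_categories <- function(effectsA, effectsB,
                                labels = c("MBP", "wild"),
                                collapse = c("sig_vs_not", "full")) {
  collapse <- match.arg(collapse)
  if (!setequal(effectsA$locus_id, effectsB$locus_id))
    stop("the two effect tables must cover the same loci")
  m <- match(effectsA$locus_id, effectsB$locus_id)
  a <- factor(effectsA$category, levels = CATEGORY_LEVELS)
  b <- factor(effectsB$category[m], levels = CATEGORY_LEVELS)
  tab <- table(a, b)
  dimnames(tab) <- stats::setNames(dimnames(tab), labels)
  margins <- list(rowSums(tab), colSums(tab))
  names(margins) <- labels
  if (collapse == "sig_vs_not") {
    sigA <- sum(tab[-1, ]); sigB <- sum(tab[, -1])
    n <- sum(tab)
    cmp <- rbind(c(sigA, n - sigA), c(sigB, n - sigB))
    dimnames(cmp) <- list(labels, c("significant", "not"))
  } else {
    cmp <- rbind(margins[[1]], margins[[2]])
    rownames(cmp) <- labels
  }
  ct <- suppressWarnings(stats::chisq.test(cmp, correct = FALSE))
  list(crosstab = unclass(tab), margins = margins,
       chisq = list(statistic = unname(ct$statistic),
                    df = unname(ct$parameter), p_value = ct$p.value,
                    collapse = collapse),
       n_loci = sum(tab))
}

#' Summarize a category cross-tabulation
#'
#' Derives the headline quantities from a 5x5 category cross-tabulation
#' (rows = first group, columns = second, categories `None`, `Stage`,
#' `Trt`, `Stage+Trt`, `Stage*Trt`): per-group significant totals,
#' treatment-affected counts (`Trt + Stage+Trt + Stage*Trt`), the percent
#' excess of significant loci in the second group, the percent deficit of
#' `Stage` loci in the first, and the ratio of treatment-affected counts.
#'
#' @param crosstab 5x5 numeric matrix (margins excluded), rows group A,
#'   columns group B, category order as above.
#' @param labels Length-2 group labels (row group first).
#' @return Named list of derived quantities.
#' @export
category_summary <- function(crosstab, labels = c("MBP", "wild")) {
  crosstab <- as.matrix(crosstab)
  stopifnot(all(dim(crosstab) == c(5L, 5L)))
  n <- sum(crosstab)
  margA <- rowSums(crosstab)
  margB <- colSums(crosstab)
  names(margA) <- names(margB) <- CATEGORY_LEVELS
  sigA <- n - margA[["None"]]
  sigB <- n - margB[["None"]]
  trtA <- margA[["Trt"]] + margA[["Stage+Trt"]] + margA[["Stage*Trt"]]
  trtB <- margB[["Trt"]] + margB[["Stage+Trt"]] + margB[["Stage*Trt"]]
  out <- list(n_loci = n, margins = list(margA, margB),
              sig_total = stats::setNames(c(sigA, sigB), labels),
              trt_affected = stats::setNames(c(trtA, trtB), labels),
              stage_only = stats::setNames(
                c(margA[["Stage"]], margB[["Stage"]]), labels),
              pct_sig = stats::setNames(
                100 * c(sigA, sigB) / n, labels),
              pct_more_sig_B = 100 * (sigB - sigA) / sigA,
              pct_fewer_stage_A = 100 *
                (margB[["Stage"]] - margA[["Stage"]]) / margB[["Stage"]],
              trt_ratio_A_over_B = trtA / trtB,
              unchanged_both = crosstab[1, 1])
  names(out$margins) <- labels
  out
}

#' Read a category cross-tabulation from TSV
#'
#' First column: row-group categories; remaining columns: counts per
#' column-group category.  Category order must be `None, Stage, Trt,
#' Stage+Trt, Stage*Trt`.  An example table ships in
#' `system.file("extdata", "published_category_crosstab.tsv",
#' package = "poolfactor")`.
#'
#' @param path File path.
#' @return A 5x5 numeric matrix suitable for [category_summary()].
#' @export
read_crosstab <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (!identical(rownames(m), CATEGORY_LEVELS) ||
      !identical(colnames(m), CATEGORY_LEVELS))
    stop("crosstab categories must be: ",
         paste(CATEGORY_LEVELS, collapse = ", "))
  m
}

#' Fraction of interaction loci with negative interaction estimates
#'
#' @param effects A classified effect table.
#' @return Fraction of `Stage*Trt` loci whose interaction coefficient
#'   (allele-2 orientation fixed at baseline) is negative; `NA` when the
#'   category is empty.
#' @export
interaction_sign_summary <- function(effects) {
  i <- !is.na(effects$category) & effects$category == "Stage*Trt"
  if (!any(i)) return(NA_real_)
  mean(effects$beta_int[i] < 0)
}
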