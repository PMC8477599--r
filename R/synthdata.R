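# Synthetic pooled-sequencing experiment generator.
#
# The generator emulates the design of a replicated factorial larval
# experiment: 2 broodstock groups x 2 developmental stages x 2 seawater
# treatments x n_reps replicate pools, with per-locus biallelic read counts
# and a ground-truth table of generating effect categories.

#' Simulation parameters for a pooled factorial experiment
#'
#' Assembles and validates the parameter set consumed by
#' [simulate_experiment()].  Defaults describe the study design the package
#' targets: five replicate pools per group x treatment, read depths
#' truncated to the retention window 50--1000, founder minor-allele
#' frequencies from a Beta(2, 8) distribution, and a majority of loci with
#' no true effect.
#'
#' @param n_loci Number of loci to simulate.
#' @param n_reps Replicate pools per group x stage x treatment cell
#'   (default 5).
#' @param prop_category Named numeric vector over the categories
#'   `none`, `stage`, `trt`, `additive`, `interaction`; must sum to 1.
#' @param effect_logit Named numeric vector of logit-scale shift magnitudes
#'   per non-null category.  For `additive`, both main shifts have this
#'   magnitude; for `interaction`, the interaction term does.
#' @param founder_maf_dist Numeric `c(shape1, shape2)` of the Beta
#'   distribution from which founder minor-allele frequencies are drawn
#'   (rejection-sampled into (0, 0.5]).
#' @param depth_dist List with `meanlog`, `sdlog`, `lo`, `hi`: log-normal
#'   read-depth distribution truncated to `[lo, hi]`.
#' @param pool_size Individuals per replicate pool; allele copies are
#'   drawn binomially from 2 * pool_size before read sampling (drift
#'   layer).  `Inf` disables drift (pure binomial read sampling).
#' @param seed Integer seed; the simulation is bit-reproducible for a
#'   fixed seed.
#'
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_loci,
                       n_reps = 5L,
                       prop_category = c(none = 0.66, stage = 0.12,
                                         trt = 0.06, additive = 0.06,
                                         interaction = 0.10),
                       effect_logit = c(stage = 1.5, trt = 1.5,
                                        additive = 1.5, interaction = 1.5),
                       founder_maf_dist = c(2, 8),
                       depth_dist = list(meanlog = log(200), sdlog = 0.5,
                                         lo = 50, hi = 1000),
                       pool_size = 200,
                       seed = 1L) {
  stopifnot(is.numeric(n_loci), length(n_loci) == 1L, n_loci >= 1,
            is.numeric(n_reps), length(n_reps) == 1L, n_reps >= 1)
  cats <- c("none", "stage", "trt", "additive", "interaction")
  if (!setequal(names(prop_category), cats))
    stop("prop_category must be named over: ", paste(cats, collapse = ", "))
  prop_category <- prop_category[cats]
  if (abs(sum(prop_category) - 1) > 1e-9)
    stop("prop_category must sum to 1 (got ", sum(prop_category), ")")
  if (any(prop_category < 0)) stop("prop_category must be non-negative")
  if (!all(c("stage", "trt", "additive", "interaction") %in%
           names(effect_logit)))
    stop("effect_logit must name stage, trt, additive, interaction")
  stopifnot(length(founder_maf_dist) == 2L, all(founder_maf_dist > 0))
  d <- depth_dist
  stopifnot(is.list(d), all(c("meanlog", "sdlog", "lo", "hi") %in% names(d)))
  if (!(50 <= d$lo && d$lo < d$hi && d$hi <= 1000))
    stop("depth bounds must satisfy 50 <= lo < hi <= 1000")
  if (!(is.infinite(pool_size) || pool_size >= 1))
    stop("pool_size must be >= 1 or Inf")
  structure(list(n_loci = as.integer(n_loci), n_reps = as.integer(n_reps),
                 prop_category = prop_category, effect_logit = effect_logit,
                 founder_maf_dist = founder_maf_dist, depth_dist = d,
                 pool_size = pool_size, seed = as.integer(seed)),
            class = "sim_params")
}

# Truncated log-normal depths via inverse-CDF; sdlog = 0 degenerates to a
# constant depth at exp(meanlog).
rdepth <- function(n, d) {
  if (d$sdlog == 0) return(rep(as.integer(round(exp(d$meanlog))), n))
  plo <- stats::plnorm(d$lo, d$meanlog, d$sdlog)
  phi <- stats::plnorm(d$hi, d$meanlog, d$sdlog)
  u <- stats::runif(n, plo, phi)
  pmin(pmax(as.integer(round(stats::qlnorm(u, d$meanlog, d$sdlog))),
            as.integer(d$lo)), as.integer(d$hi))
}

# Founder MAFs: Beta(a, b) rejection-sampled into (0, 0.5].
rfounder <- function(n, ab) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rbeta(2L * (n - length(out)) + 16L, ab[1], ab[2])
    x <- x[x > 0 & x <= 0.5]
    out <- c(out, x)
  }
  out[seq_len(n)]
}

#' Simulate a pooled factorial sequencing experiment
#'
#' Draws a ground truth (category and logit-scale shifts per locus), then
#' per-pool allele counts in two layers: a finite-pool binomial draw of
#' allele copies (drift) followed by binomial read sampling at a depth
#' drawn from a truncated log-normal.  The true pool frequency in each
#' design cell is
#' `plogis(qlogis(f0) + d_stage*I(day22) + d_trt*I(high) + d_int*I(day22)*I(high))`.
#'
#' Both broodstock groups share founder frequencies and shifts; replicate
#' pools are independent.  The simulated minor allele always carries the
#' founder MAF; its nucleotide identity is randomized per locus and the
#' analysis pipeline re-derives its own minor-allele orientation.
#'
#' @param params A [sim_params()] object.
#' @return List with `counts` (a count table, see [read_counts()] for the
#'   schema), `truth` (ground-truth data frame with per-locus category,
#'   founder MAF, shifts and interaction sign) and `params`.
#' @export
simulate_experiment <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n <- params$n_loci
  cats <- names(params$prop_category)
  category <- sample(cats, n, replace = TRUE, prob = params$prop_category)
  f0 <- rfounder(n, params$founder_maf_dist)
  el <- params$effect_logit
  sgn <- function(k) sample(c(-1, 1), k, replace = TRUE)
  d_stage <- d_trt <- d_int <- numeric(n)
  i <- category == "stage"
  d_stage[i] <- sgn(sum(i)) * el[["stage"]]
  i <- category == "trt"
  d_trt[i] <- sgn(sum(i)) * el[["trt"]]
  i <- category == "additive"
  d_stage[i] <- sgn(sum(i)) * el[["additive"]]
  d_trt[i] <- sgn(sum(i)) * el[["additive"]]
  i <- category == "interaction"
  d_int[i] <- sgn(sum(i)) * el[["interaction"]]

  loci_per_scaf <- 10L
  scaffold <- sprintf("scaffold_%05d", (seq_len(n) - 1L) %/% loci_per_scaf + 1L)
  within <- (seq_len(n) - 1L) %% loci_per_scaf
  position <- within * 500L + 100L
  truth <- data.frame(
    locus_id = sprintf("L%06d", seq_len(n)),
    scaffold = scaffold, position = position,
    category = category, founder_maf = f0,
    delta_stage = d_stage, delta_trt = d_trt, delta_int = d_int,
    int_sign = ifelse(category == "interaction",
                      ifelse(d_int < 0, "-", "+"), NA_character_),
    stringsAsFactors = FALSE)

  # biallelic nucleotide identities per locus (minor first)
  nts <- c("A", "C", "G", "T")
  nt_minor <- sample(nts, n, replace = TRUE)
  nt_major <- vapply(nt_minor, function(b) sample(setdiff(nts, b), 1L), "")

  design <- expand.grid(replicate = seq_len(params$n_reps),
                        treatment = c("ambient", "high"),
                        stage = c("day2", "day22"),
                        group = c("MBP", "wild"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[, c("group", "stage", "treatment", "replicate")]
  n_samp <- nrow(design)
  lg0 <- stats::qlogis(f0)

  blocks <- vector("list", n_samp)
  for (s in seq_len(n_samp)) {
    is22 <- design$stage[s] == "day22"
    ishi <- design$treatment[s] == "high"
    p_true <- stats::plogis(lg0 + d_stage * is22 + d_trt * ishi +
                              d_int * is22 * ishi)
    if (is.finite(params$pool_size)) {
      ncop <- 2L * params$pool_size
      f_pool <- stats::rbinom(n, ncop, p_true) / ncop
    } else {
      f_pool <- p_true
    }
    depth <- rdepth(n, params$depth_dist)
    c_minor <- stats::rbinom(n, depth, f_pool)
    c_major <- depth - c_minor
    cnt <- matrix(0L, n, 4L, dimnames = list(NULL, nts))
    cnt[cbind(seq_len(n), match(nt_minor, nts))] <- c_minor
    cnt[cbind(seq_len(n), match(nt_major, nts))] <-
      cnt[cbind(seq_len(n), match(nt_major, nts))] + c_major
    sid <- sprintf("%s_%s_%s_r%d", design$group[s], design$stage[s],
                   design$treatment[s], design$replicate[s])
    blocks[[s]] <- data.frame(
      sample_id = sid, group = design$group[s], stage = design$stage[s],
      treatment = design$treatment[s], replicate = design$replicate[s],
      locus_id = truth$locus_id, scaffold = scaffold, position = position,
      countA = cnt[, "A"], countC = cnt[, "C"], countG = cnt[, "G"],
      countT = cnt[, "T"], tag_start = pmax(position - 17L, 1L),
      stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, blocks)
  rownames(counts) <- NULL
  class(counts) <- c("count_table", "data.frame")
  list(counts = counts, truth = truth, params = params)
}

#' Score effect classifications against simulation ground truth
#'
#' @param truth Truth table from [simulate_experiment()].
#' @param effects Effect table from [classify_effects()] with columns
#'   `locus_id` and `category` (values `None`, `Stage`, `Trt`,
#'   `Stage+Trt`, `Stage*Trt`).
#' @return List with `confusion` (truth x called matrix), `power` (named
#'   per-category fraction classified exactly right; `NA` where a category
#'   has no truth loci), and `fdr` (false discoveries / max(1, discoveries),
#'   a discovery being any locus called non-`None`).
#' @export
evaluate_recovery <- function(truth, effects) {
  if (!setequal(truth$locus_id, effects$locus_id))
    stop("locus sets of truth and effects differ")
  m <- match(truth$locus_id, effects$locus_id)
  called <- effects$category[m]
  truth_lab <- c(none = "None", stage = "Stage", trt = "Trt",
                 additive = "Stage+Trt", interaction = "Stage*Trt")
  tcat <- factor(truth_lab[truth$category], levels = unname(truth_lab))
  ccat <- factor(called, levels = unname(truth_lab))
  confusion <- table(truth = tcat, called = ccat)
  diagp <- diag(confusion) / rowSums(confusion)
  power <- ifelse(rowSums(confusion) == 0, NA_real_, diagp)
  names(power) <- rownames(confusion)
  disc <- !is.na(called) & called != "None"
  false_disc <- disc & truth$category == "none"
  fdr <- sum(false_disc) / max(1L, sum(disc))
  list(confusion = confusion, power = power, fdr = fdr)
}

#' Generate a small synthetic FASTQ fixture
#'
#' Minimal read generator for exercising the read quality filter: random
#' bases, per-base phred qualities drawn i.i.d. from a supplied integer
#' distribution.
#'
#' @param path Output FASTQ path.
#' @param n_reads Number of reads.
#' @param read_len Read length in bp.
#' @param quality_levels Integer vector of phred scores to sample from.
#' @param quality_probs Sampling probabilities (recycled uniform if NULL).
#' @param seed Integer seed.
#' @return `path`, invisibly.
#' @export
simulate_fastq <- function(path, n_reads = 100L, read_len = 50L,
                           quality_levels = c(15L, 25L, 38L),
                           quality_probs = NULL, seed = 1L) {
  set.seed(seed)
  nts <- c("A", "C", "G", "T")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_reads)) {
    seqs <- paste(sample(nts, read_len, replace = TRUE), collapse = "")
    q <- sample(quality_levels, read_len, replace = TRUE,
                prob = quality_probs)
    qual <- rawToChar(as.raw(q + 33L))
    writeLines(c(paste0("@read_", i), seqs, "+", qual), con)
  }
  invisible(path)
}
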