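# Fixture: a small factorial count table with controllable depths/alleles.
two_allele_cnt <- function(n_loci, depth, f2) {
  cbind(A = as.integer(round(depth * (1 - f2))),
        C = as.integer(round(depth * f2)), G = 0L, T = 0L)
}

cellkey_of <- function(panel)
  paste(panel$samples$group, panel$samples$stage, panel$samples$treatment)

test_that("depth filter masks cells at the stated closed bounds", {
  loci <- data.frame(locus_id = paste0("L", 1:4), scaffold = "s1",
                     position = c(10L, 50L, 90L, 130L))
  samples <- make_samples("MBP", n_reps = 1L)  # 4 samples
  # per-locus depth in sample 1; depth 100 elsewhere (L4 bad everywhere)
  d1 <- c(49L, 50L, 1000L, 1001L)
  cnt <- lapply(seq_len(4), function(si)
    two_allele_cnt(4, if (si == 1) d1 else c(100L, 100L, 100L, 1001L),
                   0.2))
  x <- make_counts(loci, samples, cnt)
  out <- depth_filter(x)
  d <- rowSums(out[, c("countA", "countC", "countG", "countT")])
  by_locus <- split(d, out$locus_id)
  expect_true(is.na(by_locus$L1[1]))          # 49 -> missing
  expect_true(all(!is.na(by_locus$L1[-1])))
  expect_true(all(!is.na(by_locus$L2)))       # 50 -> retained
  expect_true(!is.na(by_locus$L3[1]))         # 1000 -> retained
  expect_true(is.null(by_locus$L4))           # 1001 everywhere -> dropped
  expect_equal(attr(out, "audit")$depth_filter, 1L)
  expect_error(depth_filter(x, 100, 100), "min_depth")
})

test_that("depth filter is the identity within bounds and matches a scan", {
  sim <- simulate_experiment(sim_params(n_loci = 200, seed = 21))
  out <- depth_filter(sim$counts)
  expect_equal(as.data.frame(out)[, names(sim$counts)],
               as.data.frame(sim$counts))  # generator truncates to bounds
  # brute-force oracle on perturbed bounds
  out2 <- depth_filter(sim$counts, 150, 400)
  d <- rowSums(sim$counts[, c("countA", "countC", "countG", "countT")])
  expect_equal(sum(!is.na(out2$countA)),
               sum(d >= 150 & d <= 400))
})

test_that("biallelic filter drops >2 observed alleles, even one stray read", {
  loci <- data.frame(locus_id = paste0("L", 1:3), scaffold = "s1",
                     position = c(10L, 50L, 90L))
  samples <- make_samples("MBP", n_reps = 1L)
  base <- rbind(c(60L, 0L, 40L, 0L),    # A/G biallelic
                c(60L, 0L, 40L, 0L),
                c(100L, 0L, 0L, 0L))    # monomorphic
  stray <- base
  stray[2, 2] <- 1L                     # one stray C read, sample 1 only
  cnt <- c(list(stray), rep(list(base), 3))
  x <- make_counts(loci, samples, cnt)
  out <- biallelic_filter(x)
  expect_setequal(unique(out$locus_id), c("L1", "L3"))
  expect_equal(attr(out, "audit")$biallelic_filter, 1L)
  expect_equal(attr(out, "alleles")$L1, c("A", "G"))
  # min_allele_reads = 2 tolerates the stray read
  out2 <- biallelic_filter(x, min_allele_reads = 2L)
  expect_setequal(unique(out2$locus_id), c("L1", "L2", "L3"))
  # monomorphic loci drop at panel construction
  panel <- snp_panel(out)
  expect_equal(panel$loci$locus_id, "L1")
  expect_equal(panel$audit$monomorphic, 1L)
})

test_that("simulated tri-allelic loci are counted against truth", {
  sim <- simulate_experiment(sim_params(n_loci = 300, seed = 13))
  cnt <- sim$counts
  # inject a third allele into 25 known loci (one stray read in one sample)
  bad <- sample(unique(cnt$locus_id), 25)
  for (l in bad) {
    i <- which(cnt$locus_id == l)[1]
    cols <- c("countA", "countC", "countG", "countT")
    zero <- cols[which(cnt[i, cols] == 0)][1]
    cnt[i, zero] <- 1L
  }
  out <- biallelic_filter(cnt)
  expect_equal(attr(out, "audit")$biallelic_filter, length(bad))
  expect_true(!any(bad %in% out$locus_id))
})

test_that("minor-allele orientation is fixed at day-2 baseline", {
  # allele2 frequency rises above 0.5 by day 22; orientation must not flip
  samples <- make_samples("MBP", n_reps = 2L)  # 8 samples
  f2 <- ifelse(samples$stage == "day2", 0.3, 0.7)
  cnt <- lapply(seq_len(nrow(samples)), function(si)
    two_allele_cnt(1, 100L, f2[si]))
  loci <- data.frame(locus_id = "L1", scaffold = "s1", position = 10L)
  panel <- snp_panel(biallelic_filter(make_counts(loci, samples, cnt)))
  expect_equal(panel$loci$allele2, "C")  # minor at day 2
  f <- allele_frequencies(panel, "replicate")$f
  expect_true(all(f[, samples$stage == "day22"] > 0.5))
})

test_that("one SNP per tag keeps highest depth, then smallest position", {
  samples <- make_samples("MBP", n_reps = 1L)
  loci <- data.frame(locus_id = paste0("L", 1:5),
                     scaffold = c("s1", "s1", "s2", "s2", "s3"),
                     tag_start = c(1L, 1L, 7L, 7L, 1L),
                     position = c(5L, 20L, 10L, 30L, 3L))
  depth_per_locus <- c(900L, 400L, 250L, 250L, 100L)
  cnt <- lapply(seq_len(4), function(si)
    two_allele_cnt(5, depth_per_locus %/% 4L, 0.25))
  panel <- snp_panel(biallelic_filter(make_counts(loci, samples, cnt)))
  out <- one_snp_per_tag(panel)
  # s1: depth 900 beats 400; s2: tie -> position 10; s3: singleton
  expect_setequal(out$loci$locus_id, c("L1", "L3", "L5"))
  expect_equal(out$audit$one_snp_per_tag, 2L)
})

test_that("replicate presence filter applies the >=3-per-cell predicate", {
  sim <- simulate_experiment(sim_params(n_loci = 150, seed = 17))
  panel <- snp_panel(biallelic_filter(depth_filter(sim$counts)))
  # knock out random cells
  set.seed(5)
  nmask <- 2500
  idx <- cbind(sample(nrow(panel$c1), nmask, TRUE),
               sample(ncol(panel$c1), nmask, TRUE))
  panel$c1[idx] <- NA
  panel$c2[idx] <- NA
  out <- replicate_presence_filter(panel, min_reps = 3L)
  # oracle: brute-force evaluation of the predicate
  s <- panel$samples
  cellkey <- paste(s$group, s$stage, s$treatment)
  keep_oracle <- vapply(seq_len(nrow(panel$loci)), function(i) {
    pres <- tapply(!is.na(panel$c1[i, ]), cellkey, sum)
    all(pres >= 3)
  }, logical(1))
  expect_setequal(out$loci$locus_id, panel$loci$locus_id[keep_oracle])
  # 5/5 everywhere is retained; 2 in one cell is dropped
  full <- snp_panel(biallelic_filter(depth_filter(
    simulate_experiment(sim_params(n_loci = 5, seed = 2))$counts)))
  expect_equal(nrow(replicate_presence_filter(full)$loci), 5L)
  crip <- full
  cols <- which(cellkey_of(crip) == "MBP day2 ambient")[1:3]
  crip$c1[1, cols] <- NA
  crip$c2[1, cols] <- NA
  expect_false("L000001" %in%
                 replicate_presence_filter(crip)$loci$locus_id)
})

test_that("MAF filter is strict and uses the better group", {
  samples <- make_samples(c("MBP", "wild"), n_reps = 1L)
  # L1: MAF 0.05 in wild day2, 0 in MBP -> retained
  # L2: MAF exactly 0.01 in both -> dropped (strict >)
  f2 <- function(s, l) {
    if (l == 1) { if (s$group == "wild") 0.05 else 0 }
    else 0.01
  }
  cnt <- lapply(seq_len(nrow(samples)), function(si) {
    s <- samples[si, ]
    rbind(two_allele_cnt(1, 1000L, f2(s, 1)),
          two_allele_cnt(1, 1000L, f2(s, 2)))
  })
  loci <- data.frame(locus_id = c("L1", "L2"), scaffold = "s1",
                     position = c(10L, 50L))
  panel <- snp_panel(biallelic_filter(make_counts(loci, samples, cnt)))
  out <- maf_filter(panel)
  expect_equal(out$loci$locus_id, "L1")
  expect_equal(out$audit$maf_filter, 1L)
})

test_that("retained fraction under the MAF filter matches the Beta tail", {
  p <- sim_params(n_loci = 2000, pool_size = Inf, seed = 23,
                  prop_category = c(none = 1, stage = 0, trt = 0,
                                    additive = 0, interaction = 0),
                  depth_dist = list(meanlog = log(900), sdlog = 0,
                                    lo = 50, hi = 1000))
  sim <- simulate_experiment(p)
  panel <- filter_pipeline(sim$counts)
  # oracle: founder MAF ~ Beta(2,8) truncated to (0, 0.5]; retention is
  # (approximately, at high depth) P(f > 0.01 | f <= 0.5)
  p_tail <- (stats::pbeta(0.5, 2, 8) - stats::pbeta(0.01, 2, 8)) /
    stats::pbeta(0.5, 2, 8)
  frac <- nrow(panel$loci) / 2000
  se <- sqrt(p_tail * (1 - p_tail) / 2000)
  expect_lt(abs(frac - p_tail), 4 * se + 0.01)
})

test_that("the cascade audit trail accounts for every removed locus", {
  sim <- simulate_experiment(sim_params(n_loci = 400, seed = 31))
  cnt <- sim$counts
  # widen the generator's world: inject depth violations via doubling
  i <- cnt$locus_id %in% unique(cnt$locus_id)[1:10]
  cnt[i, c("countA", "countC", "countG", "countT")] <-
    cnt[i, c("countA", "countC", "countG", "countT")] * 25L
  panel <- filter_pipeline(cnt)
  removed <- sum(unlist(panel$audit))
  expect_equal(removed, 400L - nrow(panel$loci))
  expect_named(panel$audit, c("depth_filter", "biallelic_filter",
                              "monomorphic", "one_snp_per_tag",
                              "replicate_presence_filter", "maf_filter"))
})

test_that("filters never alter surviving counts", {
  sim <- simulate_experiment(sim_params(n_loci = 100, seed = 37))
  panel <- filter_pipeline(sim$counts)
  cnt <- sim$counts
  for (i in sample(nrow(panel$loci), 20)) {
    l <- panel$loci$locus_id[i]
    for (sj in sample(ncol(panel$c1), 3)) {
      s <- panel$samples$sample_id[sj]
      row <- cnt[cnt$locus_id == l & cnt$sample_id == s, ]
      a1 <- panel$loci$allele1[i]; a2 <- panel$loci$allele2[i]
      if (!is.na(panel$c1[i, sj])) {
        expect_equal(panel$c1[i, sj], row[[paste0("count", a1)]])
        expect_equal(panel$c2[i, sj], row[[paste0("count", a2)]])
      }
    }
  }
})
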