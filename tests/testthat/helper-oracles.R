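# Independent oracles and fixture builders shared across tests.

# --- brute-force IRLS for a binomial GLM (independent of stats::glm) ----
# y successes out of m trials, model matrix X; returns coefficients and
# deviance.  Used as the oracle for type III likelihood-ratio statistics.
irls_binom <- function(X, y, m, tol = 1e-12, maxit = 200L) {
  mu <- (y + 0.5) / (m + 1)
  eta <- log(mu / (1 - mu))
  beta <- rep(0, ncol(X))
  dev_old <- Inf
  for (it in seq_len(maxit)) {
    mu <- 1 / (1 + exp(-eta))
    W <- m * mu * (1 - mu)
    z <- eta + (y / m - mu) / (mu * (1 - mu))
    beta <- solve(crossprod(X, W * X), crossprod(X, W * z))[, 1]
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    dv <- function(a, b) ifelse(a == 0, 0, a * log(a / b))
    dev <- 2 * sum(dv(y, m * mu) + dv(m - y, m - m * mu))
    if (abs(dev - dev_old) < tol * (abs(dev) + 0.1)) break
    dev_old <- dev
  }
  list(beta = beta, deviance = dev)
}

# Type III LR statistics by explicit full-vs-reduced refits.
irls_type3 <- function(c1, c2, s, t_) {
  m <- c1 + c2
  X <- cbind(1, s, t_, s * t_)
  full <- irls_binom(X, c2, m)
  vapply(2:4, function(j) {
    red <- irls_binom(X[, -j, drop = FALSE], c2, m)
    red$deviance - full$deviance
  }, numeric(1))
}

# --- panel builder --------------------------------------------------------
# Builds a snp_panel directly from c1/c2 matrices (loci x samples) and a
# factorial sample sheet, bypassing the count-table constructor.
make_samples <- function(groups = c("MBP", "wild"), n_reps = 5L) {
  d <- expand.grid(replicate = seq_len(n_reps),
                   treatment = c("ambient", "high"),
                   stage = c("day2", "day22"), group = groups,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d <- d[, c("group", "stage", "treatment", "replicate")]
  d$sample_id <- sprintf("%s_%s_%s_r%d", d$group, d$stage, d$treatment,
                         d$replicate)
  d[, c("sample_id", "group", "stage", "treatment", "replicate")]
}

make_panel <- function(c1, c2, samples = NULL, loci = NULL) {
  n <- nrow(c1)
  if (is.null(samples)) samples <- make_samples()[seq_len(ncol(c1)), ]
  if (is.null(loci))
    loci <- data.frame(locus_id = sprintf("L%04d", seq_len(n)),
                       scaffold = sprintf("s%03d", seq_len(n)),
                       tag_start = 1L, position = 18L,
                       allele1 = "A", allele2 = "G",
                       stringsAsFactors = FALSE)
  dimnames(c1) <- dimnames(c2) <- list(loci$locus_id, samples$sample_id)
  structure(list(loci = loci, samples = samples, c1 = c1, c2 = c2,
                 audit = list()), class = "snp_panel")
}

# A panel where every sample has the same (c1, c2) pair per locus.
constant_panel <- function(f2, depth, samples = make_samples("MBP")) {
  n <- length(f2)
  c2 <- matrix(round(depth * f2), n, nrow(samples))
  c1 <- matrix(depth, n, nrow(samples)) - c2
  make_panel(c1, c2, samples)
}

# --- count-table builder --------------------------------------------------
make_counts <- function(loci, samples, cnt) {
  # cnt: list of per-sample 4-col matrices (A,C,G,T) or single matrix
  rows <- lapply(seq_len(nrow(samples)), function(si) {
    m <- if (is.list(cnt)) cnt[[si]] else cnt
    data.frame(sample_id = samples$sample_id[si],
               group = samples$group[si], stage = samples$stage[si],
               treatment = samples$treatment[si],
               replicate = samples$replicate[si],
               locus_id = loci$locus_id, scaffold = loci$scaffold,
               position = loci$position,
               countA = m[, 1], countC = m[, 2], countG = m[, 3],
               countT = m[, 4],
               tag_start = if (!is.null(loci$tag_start)) loci$tag_start
                           else loci$position,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# --- toy SAM writer -------------------------------------------------------
# records: data.frame(qname, flag, rname, pos, cigar, seq, md)
write_toy_sam <- function(records, path,
                          sq = c("ref1" = 10000L, "ref2" = 10000L)) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sq), sq))
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s\tMD:Z:%s",
                  records$qname, records$flag, records$rname, records$pos,
                  records$cigar, records$seq,
                  strrep("I", nchar(records$seq)), records$md)
  writeLines(c(hdr, body), path)
  path
}

# --- FDR helpers ----------------------------------------------------------
# Per-family false-discovery proportion of BH at level alpha on null p's.
bh_fdp_null <- function(p, alpha = 0.05) {
  q <- p.adjust(p[!is.na(p)], "BH")
  as.numeric(any(q < alpha))
}
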