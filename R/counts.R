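# Front end: FASTQ quality filtering, SAM -> nucleotide-count conversion,
# count-table I/O and merging.

COUNT_COLS <- c("countA", "countC", "countG", "countT")
TABLE_COLS <- c("sample_id", "group", "stage", "treatment", "replicate",
                "locus_id", "scaffold", "position", COUNT_COLS)

as_count_table <- function(df) {
  miss <- setdiff(TABLE_COLS, names(df))
  if (length(miss))
    stop("count table missing columns: ", paste(miss, collapse = ", "))
  if ("tag_start" %in% names(df)) {
    df <- df[, c(TABLE_COLS, "tag_start")]
  } else {
    df <- df[, TABLE_COLS]
    df$tag_start <- df$position
  }
  key <- paste(df$sample_id, df$locus_id)
  if (anyDuplicated(key)) stop("duplicate (sample_id, locus_id) rows")
  cnt <- as.matrix(df[, COUNT_COLS])
  if (any(cnt < 0, na.rm = TRUE)) stop("negative counts")
  if (any(df$position < 1)) stop("positions must be 1-based (>= 1)")
  class(df) <- c("count_table", "data.frame")
  df
}

#' Read / write the tab-delimited nucleotide-count table
#'
#' One row per locus per sample: `sample_id, group, stage, treatment,
#' replicate, locus_id, scaffold, position, countA, countC, countG, countT`
#' (plus a `tag_start` column locating the 36-bp restriction tag; it
#' defaults to `position` when absent).  Missing cells carry `NA` counts.
#' Gzip-compressed paths are handled transparently.
#'
#' @param path File path (TSV, optionally .gz).
#' @param x A count table.
#' @return `read_counts`: a `count_table` data frame. `write_counts`:
#'   `path`, invisibly.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_count_table(df)
}

#' @rdname read_counts
#' @export
write_counts <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Truncate and quality-filter short reads
#'
#' Reads are truncated to `trunc_len` bp (reads shorter than that are
#' discarded) and retained only when strictly fewer than `max_low_bases`
#' of the retained bases have phred quality below `phred_floor`.  Quality
#' is assessed after truncation: only the bases that survive matter.
#'
#' @param input FASTQ path (optionally gzipped).
#' @param output Optional path to write retained reads (FASTQ).
#' @param trunc_len Truncation length in bp (default 36).
#' @param max_low_bases Discard a read when it has `>= max_low_bases`
#'   positions below the floor (default 10, i.e. the rule is
#'   "fewer than 10 low-quality bases").
#' @param phred_floor Phred threshold defining a low-quality base
#'   (default 20).
#' @param offset Phred encoding offset, 33 (default) or 64.
#' @return List with `reads` (a `QualityScaledDNAStringSet` of retained,
#'   truncated reads) and `summary` (`n_input`, `retained`,
#'   `discarded_short`, `discarded_quality`).
#' @export
quality_filter_reads <- function(input, output = NULL, trunc_len = 36L,
                                 max_low_bases = 10L, phred_floor = 20L,
                                 offset = 33L) {
  stopifnot(offset %in% c(33L, 64L))
  scoring <- if (offset == 33L) "phred" else "illumina"
  lines <- readLines(input)
  while (length(lines) && lines[length(lines)] == "")
    lines <- lines[-length(lines)]
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ in '", input, "': truncated record ",
         length(lines) %/% 4L + 1L, call. = FALSE)
  i1 <- seq(1L, length(lines), 4L)
  bad <- which(!startsWith(lines[i1], "@") |
                 !startsWith(lines[i1 + 2L], "+") |
                 nchar(lines[i1 + 1L]) != nchar(lines[i1 + 3L]))
  if (length(bad))
    stop("malformed FASTQ in '", input, "': record ", bad[1],
         call. = FALSE)
  reads <- tryCatch(
    suppressWarnings(
      Biostrings::readQualityScaledDNAStringSet(input,
                                                quality.scoring = scoring)),
    error = function(e) stop("malformed FASTQ in '", input, "': ",
                             conditionMessage(e), call. = FALSE))
  n_input <- length(reads)
  long_enough <- Biostrings::width(reads) >= trunc_len
  reads <- reads[long_enough]
  discarded_short <- n_input - length(reads)
  if (length(reads)) {
    reads <- IRanges::narrow(reads, start = 1L, end = trunc_len)
    qmat <- as(Biostrings::quality(reads), "matrix")
    n_low <- rowSums(qmat < phred_floor)
    keep <- n_low < max_low_bases
  } else {
    keep <- logical(0)
  }
  discarded_quality <- sum(!keep)
  reads <- reads[keep]
  if (!is.null(output))
    Biostrings::writeQualityScaledXStringSet(reads, output)
  list(reads = reads,
       summary = list(n_input = n_input, retained = length(reads),
                      discarded_short = discarded_short,
                      discarded_quality = discarded_quality))
}

# Sum of the integer runs in an MD tag = number of reference-matching
# aligned bases (MD numbers are match-run lengths; letters are mismatches,
# ^-prefixed runs are deletions).
md_matched_bases <- function(md) {
  runs <- regmatches(md, gregexpr("[0-9]+", md))[[1]]
  sum(as.integer(runs))
}

# Walk one CIGAR, returning reference positions and the read base aligned
# to each (M/=/X ops only).  SAM SEQ is stored in reference orientation,
# so no strand complementing is needed here.
cigar_ref_bases <- function(cigar, pos, seq) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  len <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  op <- sub("^[0-9]+", "", ops)
  refpos <- integer(0)
  base <- character(0)
  rp <- pos
  qp <- 1L
  bases <- strsplit(seq, "")[[1]]
  for (k in seq_along(op)) {
    l <- len[k]
    o <- op[k]
    if (o %in% c("M", "=", "X")) {
      refpos <- c(refpos, rp:(rp + l - 1L))
      base <- c(base, bases[qp:(qp + l - 1L)])
      rp <- rp + l
      qp <- qp + l
    } else if (o %in% c("D", "N")) {
      rp <- rp + l
    } else if (o %in% c("I", "S")) {
      qp <- qp + l
    } # H, P consume nothing we track
  }
  list(refpos = refpos, base = base)
}

#' Convert alignments to per-position nucleotide counts
#'
#' Consumes a headered SAM (or BAM) file of pre-resolved single
#' alignments, drops unmapped and secondary records, and keeps only
#' alignments with at least `min_match` bases identical to the reference
#' (counted from the MD tag).  Retained alignments contribute one count of
#' the read base at every aligned reference position.  A locus is the
#' 36-bp tag anchored at the alignment reference start, so `locus_id` is
#' `scaffold:start` and rows are emitted per reference position within
#' the tag.
#'
#' @param sam Path to a SAM or BAM file.
#' @param sample_id,group,stage,treatment,replicate Sample labels attached
#'   to every output row.
#' @param min_match Minimum reference-matching bases (default 30).
#' @return List with `counts` (a `count_table`; here `locus_id` keys a
#'   tag *position*, i.e. `scaffold:tag_start:position`) and `summary`
#'   (`n_records`, `used`, `dropped_unmapped`, `dropped_secondary`,
#'   `dropped_min_match`, `skipped_no_cigar`, `skipped_no_md`).
#' @export
sam_to_counts <- function(sam, sample_id, group = NA_character_,
                          stage = NA_character_, treatment = NA_character_,
                          replicate = NA_integer_, min_match = 30L) {
  bam <- sam
  if (grepl("\\.sam$", sam, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(sam, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  }
  what <- c("flag", "rname", "pos", "cigar", "seq")
  res <- Rsamtools::scanBam(bam,
    param = Rsamtools::ScanBamParam(what = what, tag = "MD"))[[1]]
  n_records <- length(res$flag)
  flag <- res$flag
  unmapped <- bitwAnd(flag, 4L) != 0L
  secondary <- bitwAnd(flag, 256L) != 0L
  keep <- !unmapped & !secondary
  dropped_unmapped <- sum(unmapped)
  dropped_secondary <- sum(secondary & !unmapped)
  cigar <- res$cigar
  md <- res$tag$MD
  if (is.null(md)) md <- rep(NA_character_, n_records)
  no_cigar <- keep & (is.na(cigar) | cigar == "*")
  no_md <- keep & !no_cigar & is.na(md)
  if (any(no_cigar)) warning(sum(no_cigar), " records without CIGAR skipped")
  if (any(no_md)) warning(sum(no_md), " records without MD tag skipped")
  keep <- keep & !no_cigar & !no_md
  matched <- rep(NA_integer_, n_records)
  matched[keep] <- vapply(md[keep], md_matched_bases, 1L)
  low_match <- keep & matched < min_match
  keep <- keep & !low_match

  acc <- new.env(parent = emptyenv())
  seqs <- as.character(res$seq)
  rname <- as.character(res$rname)
  for (i in which(keep)) {
    w <- cigar_ref_bases(cigar[i], res$pos[i], seqs[i])
    tag0 <- res$pos[i]
    for (j in seq_along(w$refpos)) {
      key <- paste(rname[i], tag0, w$refpos[j], sep = ":")
      cur <- acc[[key]]
      if (is.null(cur)) cur <- c(A = 0L, C = 0L, G = 0L, T = 0L)
      b <- w$base[j]
      if (b %in% names(cur)) cur[[b]] <- cur[[b]] + 1L
      acc[[key]] <- cur
    }
  }
  keys <- ls(acc)
  if (length(keys)) {
    parts <- strsplit(keys, ":", fixed = TRUE)
    scaf <- vapply(parts, `[`, "", 1L)
    tstart <- as.integer(vapply(parts, `[`, "", 2L))
    rpos <- as.integer(vapply(parts, `[`, "", 3L))
    cnt <- t(vapply(keys, function(k) acc[[k]], integer(4)))
    ord <- order(scaf, tstart, rpos)
    df <- data.frame(sample_id = sample_id, group = group, stage = stage,
                     treatment = treatment, replicate = replicate,
                     locus_id = keys, scaffold = scaf, position = rpos,
                     countA = cnt[, "A"], countC = cnt[, "C"],
                     countG = cnt[, "G"], countT = cnt[, "T"],
                     tag_start = tstart, stringsAsFactors = FALSE)[ord, ]
    rownames(df) <- NULL
    df <- as_count_table(df)
  } else {
    df <- as_count_table(data.frame(
      sample_id = character(0), group = character(0), stage = character(0),
      treatment = character(0), replicate = integer(0),
      locus_id = character(0), scaffold = character(0),
      position = integer(0), countA = integer(0), countC = integer(0),
      countG = integer(0), countT = integer(0), tag_start = integer(0),
      stringsAsFactors = FALSE))
  }
  list(counts = df,
       summary = list(n_records = n_records, used = sum(keep),
                      dropped_unmapped = dropped_unmapped,
                      dropped_secondary = dropped_secondary,
                      dropped_min_match = sum(low_match),
                      skipped_no_cigar = sum(no_cigar),
                      skipped_no_md = sum(no_md)))
}

#' Merge per-sample count tables
#'
#' Row-binds count tables from disjoint samples; total count mass is
#' conserved.  Duplicate (sample_id, locus_id) keys are a hard error.
#'
#' @param tables List of count tables.
#' @return A merged `count_table`.
#' @export
merge_counts <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  tables <- lapply(tables, as_count_table)
  out <- do.call(rbind, lapply(tables, as.data.frame))
  rownames(out) <- NULL
  as_count_table(out)
}
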