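#' Load primary alignments from a SAM or BAM file
#'
#' Reads alignment records with `Rsamtools` (SAM input is converted to BAM in
#' a temporary file first). Secondary (0x100) and supplementary (0x800)
#' alignments are skipped so that each simulated read contributes exactly one
#' record, mirroring mappers run in primary-only mode.
#'
#' @param file Path to a `.sam` or `.bam` file.
#' @return data.frame with one row per primary record: `name`, `mate` (1/2),
#'   `mapped`, `chrom`, `pos`, `strand`, `mapq`.
#' @export
read_alignments <- function(file) {
  if (grepl("\\.sam$", file, ignore.case = TRUE))
    file <- Rsamtools::asBam(file, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "mapq"))
  b <- Rsamtools::scanBam(Rsamtools::BamFile(file), param = param)[[1]]
  flag <- b$flag
  primary <- bitwAnd(flag, 0x100L) == 0L & bitwAnd(flag, 0x800L) == 0L
  mapped <- bitwAnd(flag, 0x4L) == 0L
  mate <- ifelse(bitwAnd(flag, 0x80L) != 0L, 2L, 1L)
  df <- data.frame(
    name = b$qname,
    mate = mate,
    mapped = mapped,
    chrom = as.character(b$rname),
    pos = b$pos,
    strand = as.character(b$strand),
    mapq = as.integer(b$mapq),
    stringsAsFactors = FALSE
  )[primary, , drop = FALSE]
  df$chrom[!df$mapped] <- NA_character_
  df$pos[!df$mapped] <- NA_integer_
  df$strand[!df$mapped] <- NA_character_
  rownames(df) <- NULL
  df
}

#' Judge simulated alignments against their encoded origins
#'
#' Each record's read name is decoded back to the true placement of its
#' fragment; the mate index selects the mate-1 or mate-2 coordinates. A mapped
#' record is `correct` when contig and strand match the truth and the reported
#' leftmost position is within `tolerance` bases of the true one, `incorrect`
#' otherwise; records with the unmapped flag are `unmapped`. Indels of up to
#' 24 bp can legitimately shift leftmost coordinates, hence a default
#' tolerance of 20 bp rather than exact equality. A read name that fails to
#' decode aborts the evaluation (silent drops would bias the percentages).
#'
#' @param alns data.frame from [read_alignments()] (or of the same shape).
#' @param tolerance Maximum |reported - true| leftmost-position distance, in
#'   bp, for a mapped record to count as correct.
#' @param origins Optional origins table (from [read_origins()]) used as the
#'   truth channel instead of decoding read names; every alignment name must
#'   be present in it.
#' @return An `alignment_judgments` data.frame: `name`, `mate`, `verdict`
#'   (`correct`/`incorrect`/`unmapped`), `mapq`, `distance`.
#' @export
judge_alignments <- function(alns, tolerance = 20L, origins = NULL) {
  if (is.null(origins)) {
    origins <- decode_read_name(alns$name)
  } else {
    idx <- match(alns$name, origins$name)
    if (anyNA(idx))
      stop("read name absent from origins table: ",
           alns$name[which(is.na(idx))[1]], call. = FALSE)
    origins <- origins[idx, , drop = FALSE]
  }
  true_start <- ifelse(alns$mate == 1L, origins$start1, origins$start2)
  true_strand <- ifelse(alns$mate == 1L, origins$strand1, origins$strand2)
  if (anyNA(true_start[alns$mate == 2L]) && any(alns$mate == 2L))
    stop("mate-2 record for a single-end origin: ",
         alns$name[alns$mate == 2L & is.na(true_start)][1], call. = FALSE)
  distance <- ifelse(alns$mapped, abs(alns$pos - true_start), NA_integer_)
  verdict <- ifelse(!alns$mapped, "unmapped",
                    ifelse(alns$chrom == origins$chrom &
                             alns$strand == true_strand &
                             distance <= tolerance,
                           "correct", "incorrect"))
  structure(data.frame(name = alns$name, mate = alns$mate, verdict = verdict,
                       mapq = alns$mapq, distance = distance,
                       stringsAsFactors = FALSE),
            class = c("alignment_judgments", "data.frame"))
}

#' Summarize per-read verdicts into mapped/correct/incorrect/unmapped counts
#'
#' Both mates of a pair count as separate reads. Percentages are computed
#' against the total number of reads and reported to two decimals in printed
#' output. The identities `correct + incorrect == mapped` and
#' `mapped + unmapped == total` hold exactly.
#'
#' @param judgments An `alignment_judgments` data.frame.
#' @return An `alignment_summary` object (named list of counts and
#'   percentages).
#' @export
alignment_summary <- function(judgments) {
  key <- paste(judgments$name, judgments$mate)
  if (anyDuplicated(key))
    stop("duplicate read/mate records: ", key[anyDuplicated(key)], call. = FALSE)
  total <- nrow(judgments)
  n <- c(correct = sum(judgments$verdict == "correct"),
         incorrect = sum(judgments$verdict == "incorrect"),
         unmapped = sum(judgments$verdict == "unmapped"))
  mapped <- n[["correct"]] + n[["incorrect"]]
  pct <- function(x) if (total == 0L) 0 else 100 * x / total
  structure(list(total = total, mapped = mapped,
                 correct = n[["correct"]], incorrect = n[["incorrect"]],
                 unmapped = n[["unmapped"]],
                 mapped_pct = pct(mapped), correct_pct = pct(n[["correct"]]),
                 incorrect_pct = pct(n[["incorrect"]]),
                 unmapped_pct = pct(n[["unmapped"]])),
            class = "alignment_summary")
}

#' @export
print.alignment_summary <- function(x, ...) {
  cat(sprintf("reads: %d\n  mapped:    %d (%.2f%%)\n  correct:   %d (%.2f%%)\n  incorrect: %d (%.2f%%)\n  unmapped:  %d (%.2f%%)\n",
              x$total, x$mapped, x$mapped_pct, x$correct, x$correct_pct,
              x$incorrect, x$incorrect_pct, x$unmapped, x$unmapped_pct))
  invisible(x)
}

#' Mapping-quality ROC-like curve
#'
#' Sweeps a mapping-quality threshold from the highest observed value
#' downwards; the point at threshold `t` counts correctly and incorrectly
#' mapped reads with `mapq >= t` (ties share one point). Both cumulative
#' coordinates are non-decreasing and the final point equals the totals over
#' all mapped reads. Unmapped reads do not contribute.
#'
#' @param judgments An `alignment_judgments` data.frame.
#' @return data.frame with columns `threshold`, `cum_correct`,
#'   `cum_incorrect`.
#' @export
mapq_roc <- function(judgments) {
  m <- judgments[judgments$verdict != "unmapped", , drop = FALSE]
  if (nrow(m) == 0L)
    return(data.frame(threshold = numeric(0), cum_correct = integer(0),
                      cum_incorrect = integer(0)))
  o <- order(m$mapq, decreasing = TRUE)
  q <- m$mapq[o]
  corr <- m$verdict[o] == "correct"
  last <- !duplicated(q, fromLast = TRUE)
  data.frame(threshold = q[last],
             cum_correct = cumsum(corr)[last],
             cum_incorrect = cumsum(!corr)[last])
}

#' Mapping-quality calibration histogram for incorrectly mapped reads
#'
#' Each mapped read receives a mapping-quality percentile: its rank among all
#' mapped reads' MAPQ values (mean rank for ties), scaled to (0, 100].
#' Incorrectly mapped reads are then counted into `n_bins` equal-width
#' percentile bins (default ten: `[0,10), ..., [90,100]`). A well-calibrated
#' mapper concentrates its incorrect reads in the low-percentile bins.
#'
#' @param judgments An `alignment_judgments` data.frame.
#' @param n_bins Number of equal-width percentile bins.
#' @return data.frame with `bin_lo`, `bin_hi`, `incorrect` (counts summing to
#'   the total number of incorrect reads).
#' @export
mapq_calibration <- function(judgments, n_bins = 10L) {
  m <- judgments[judgments$verdict != "unmapped", , drop = FALSE]
  if (nrow(m) == 0L)
    stop("no mapped reads: calibration undefined", call. = FALSE)
  pct <- 100 * rank(m$mapq, ties.method = "average") / nrow(m)
  bin <- pmin(floor(pct / (100 / n_bins)), n_bins - 1L)
  inc <- bin[m$verdict == "incorrect"]
  counts <- tabulate(inc + 1L, nbins = n_bins)
  data.frame(bin_lo = (seq_len(n_bins) - 1L) * (100 / n_bins),
             bin_hi = seq_len(n_bins) * (100 / n_bins),
             incorrect = counts)
}

#' Write a truth-derived SAM file from read origins
#'
#' Produces the "perfect mapper" alignment: every mate is placed exactly at
#' its true origin with MAPQ 60. Useful for closed-loop validation (a
#' truth-derived SAM must score 100% correct) and as a fixture generator.
#'
#' @param origins Origins data.frame (from a `read_set` or
#'   [read_origins()]).
#' @param contigs Named integer vector of contig lengths.
#' @param path Output SAM path.
#' @param read_length Read length used for the CIGAR string.
#' @param mapq MAPQ value to assign.
#' @return `path`, invisibly.
#' @export
origins_to_sam <- function(origins, contigs, path, read_length = 100L,
                           mapq = 60L) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), as.integer(contigs)))
  cigar <- sprintf("%dM", read_length)
  paired <- !is.na(origins$start2)
  l1 <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t*\t*",
                origins$name, ifelse(paired, 99L, 0L), origins$chrom,
                origins$start1, mapq, cigar,
                ifelse(paired, "=", "*"),
                ifelse(paired, origins$start2, 0L))
  l2 <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t0\t*\t*",
                origins$name[paired], 147L, origins$chrom[paired],
                origins$start2[paired], mapq, cigar, origins$start1[paired])
  writeLines(c(hdr, l1, l2), path)
  invisible(path)
}
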