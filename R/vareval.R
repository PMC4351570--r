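#' Read a VCF call set into a normalized call table
#'
#' Parses a VCF 4.x file (optionally bgzipped) with `VariantAnnotation`,
#' decomposing multi-allelic sites into biallelic records. Genotypes are
#' mapped per decomposed alternate allele: a genotype carrying one copy of
#' the allele is `het`, two copies `hom-alt`; genotypes without the allele
#' (including hom-ref rows produced by decomposition) are dropped. Per-sample
#' depth (`DP`) is used when present, with site-level `INFO/DP` as fallback.
#' Records whose `FILTER` is neither `PASS` nor `.` are excluded unless
#' `include_filtered = TRUE`.
#'
#' @param path Path to a VCF file.
#' @param sample Sample index or name to take genotype/depth from (default:
#'   first sample; files without samples yield `NA` genotypes).
#' @param include_filtered Keep records failing FILTER.
#' @return data.frame of call records: `chrom`, `pos`, `ref`, `alt`,
#'   `genotype`, `quality`, `depth`, `vclass`, `filter`.
#' @export
read_calls <- function(path, sample = 1L, include_filtered = FALSE) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  n <- length(rr)
  if (n == 0L)
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      genotype = character(0), quality = numeric(0),
                      depth = integer(0), vclass = character(0),
                      filter = character(0), stringsAsFactors = FALSE))
  # expand() repeats each site once per ALT, in order; recover the ALT index
  # by grouping on locus + REF
  locus <- paste(as.character(GenomicRanges::seqnames(rr)),
                 GenomicRanges::start(rr), as.character(rr$REF), sep = ":")
  alt_index <- if (n > 0L) stats::ave(seq_len(n), locus, FUN = seq_along)
               else integer(0)

  gt <- rep(NA_character_, n)
  depth <- rep(NA_integer_, n)
  geno <- VariantAnnotation::geno(vcf)
  if ("GT" %in% names(geno) && ncol(geno$GT) >= 1L) {
    gts <- as.character(geno$GT[, sample])
    copies <- mapply(function(g, ai) {
      if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
      a <- suppressWarnings(as.integer(strsplit(g, "[/|]")[[1]]))
      if (all(is.na(a))) return(NA_integer_)
      sum(a == ai, na.rm = TRUE)
    }, gts, alt_index, USE.NAMES = FALSE)
    gt <- ifelse(is.na(copies), NA_character_,
                 ifelse(copies >= 2L, "hom-alt",
                        ifelse(copies == 1L, "het", "absent")))
  }
  if ("DP" %in% names(geno) && ncol(geno$DP) >= 1L) {
    depth <- suppressWarnings(as.integer(geno$DP[, sample]))
  }
  if (all(is.na(depth)) && "DP" %in% names(VariantAnnotation::info(vcf))) {
    depth <- suppressWarnings(as.integer(VariantAnnotation::info(vcf)$DP))
  }
  flt <- as.character(VariantAnnotation::fixed(vcf)$FILTER)
  qual <- as.numeric(VariantAnnotation::fixed(vcf)$QUAL)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = as.character(rr$ALT),
    genotype = gt,
    quality = qual,
    depth = depth,
    vclass = NA_character_,
    filter = flt,
    stringsAsFactors = FALSE
  )
  df <- df[is.na(df$genotype) | df$genotype != "absent", , drop = FALSE]
  df <- df[nzchar(df$alt) & df$alt != "*" & df$alt != "<NON_REF>", ,
           drop = FALSE]
  if (!include_filtered)
    df <- df[df$filter %in% c("PASS", "."), , drop = FALSE]
  df$vclass <- variant_class(df$ref, df$alt)
  df <- df[order(df$chrom, df$pos, df$ref, df$alt), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Normalize call records: trim shared bases and left-align indels
#'
#' Applies the standard variant normalization: repeatedly truncate a shared
#' rightmost base (extending leftwards with reference sequence whenever an
#' allele would become empty), then trim shared leading bases. The result is
#' the canonical leftmost, minimal representation, so equivalent indel
#' representations from different callers compare equal. The operation is
#' idempotent. Multi-allelic records must be decomposed first (as
#' [read_calls()] does).
#'
#' @param calls data.frame with at least `chrom`, `pos`, `ref`, `alt`.
#' @param ref A `reference` object, or a named character vector of contig
#'   sequences.
#' @return The normalized data.frame, sorted by `(chrom, pos, ref, alt)`.
#' @export
normalize_calls <- function(calls, ref) {
  seqs <- ref_sequences(ref)
  if (nrow(calls) == 0L) return(calls)
  for (i in seq_len(nrow(calls))) {
    ctg <- calls$chrom[i]
    if (!ctg %in% names(seqs))
      stop("no reference sequence for contig '", ctg, "'", call. = FALSE)
    refseq <- seqs[[ctg]]
    pos <- calls$pos[i]; r <- calls$ref[i]; a <- calls$alt[i]
    if (!nzchar(r) || !nzchar(a))
      stop("empty allele in record ", i, " (", ctg, ":", pos, ")", call. = FALSE)
    if (substr(refseq, pos, pos + nchar(r) - 1L) != r)
      stop(sprintf("REF allele mismatch at %s:%d (VCF '%s' vs reference '%s')",
                   ctg, pos, r, substr(refseq, pos, pos + nchar(r) - 1L)),
           call. = FALSE)
    repeat {
      lr <- nchar(r); la <- nchar(a)
      # trim a shared rightmost base; stop at pos 1 when an allele would
      # empty (no reference base left to extend with)
      if (substr(r, lr, lr) == substr(a, la, la) &&
          !(lr == 1L && la == 1L) &&
          (pos > 1L || (lr > 1L && la > 1L))) {
        r <- substr(r, 1L, lr - 1L)
        a <- substr(a, 1L, la - 1L)
        if (!nzchar(r) || !nzchar(a)) {
          pos <- pos - 1L
          b <- substr(refseq, pos, pos)
          r <- paste0(b, r)
          a <- paste0(b, a)
        }
      } else break
    }
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r))
      a <- substr(a, 2L, nchar(a))
      pos <- pos + 1L
    }
    calls$pos[i] <- pos; calls$ref[i] <- r; calls$alt[i] <- a
  }
  if ("vclass" %in% names(calls))
    calls$vclass <- variant_class(calls$ref, calls$alt)
  calls <- calls[order(calls$chrom, calls$pos, calls$ref, calls$alt), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  calls
}

ref_sequences <- function(ref) {
  if (inherits(ref, "reference")) {
    out <- stats::setNames(list(ref$sequence), ref$name)
  } else if (is.character(ref) && !is.null(names(ref))) {
    out <- as.list(ref)
  } else stop("'ref' must be a reference object or named character vector",
              call. = FALSE)
  out
}

#' Build the complex-region exclusion set from a truth call set
#'
#' Nearby indels and other variants ("complex variants") are represented
#' differently by different mappers and callers, so windows containing an
#' indel plus another truth variant are excluded from comparison. For every
#' truth indel, if any other truth variant starts within `window - 1` bases
#' of the indel's start, the interval spanning both variants' reference
#' footprints is excluded; overlapping exclusions are merged.
#'
#' @param truth Normalized, sorted truth data.frame (`chrom`, `pos`, `ref`,
#'   `alt`, `vclass`).
#' @param window Window size in bases (default 10).
#' @return A merged `GRanges` of excluded intervals (possibly empty).
#' @export
build_exclusions <- function(truth, window = 10L) {
  if (nrow(truth) == 0L)
    return(GenomicRanges::GRanges())
  start <- truth$pos
  end <- truth$pos + nchar(truth$ref) - 1L
  is_indel <- truth$vclass != "SNP"
  ex_chrom <- character(0); ex_start <- integer(0); ex_end <- integer(0)
  for (i in which(is_indel)) {
    near <- which(truth$chrom == truth$chrom[i] &
                    abs(start - start[i]) <= window - 1L)
    near <- setdiff(near, i)
    if (length(near) == 0L) next
    ex_chrom <- c(ex_chrom, truth$chrom[i])
    ex_start <- c(ex_start, min(start[c(i, near)]))
    ex_end <- c(ex_end, max(end[c(i, near)]))
  }
  if (length(ex_chrom) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::reduce(GenomicRanges::GRanges(
    ex_chrom, IRanges::IRanges(ex_start, ex_end)))
}

footprint_granges <- function(calls) {
  if (nrow(calls) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(calls$chrom,
                         IRanges::IRanges(calls$pos,
                                          calls$pos + nchar(calls$ref) - 1L))
}

#' Count true-negative bases over high-confidence regions
#'
#' Every base of the high-confidence regions not covered by the reference
#' footprint of a variant in either the truth or the test set counts as a
#' true negative. Because most confident bases are homozygous reference, this
#' is typically close to the total confident length, which is why specificity
#' saturates near 100% and precision is usually the more informative
#' statistic.
#'
#' @param regions `GRanges` of high-confidence regions (merged).
#' @param truth,test Call data.frames with `chrom`, `pos`, `ref`.
#' @return Number of true-negative bases.
#' @export
count_true_negatives <- function(regions, truth, test) {
  regions <- GenomicRanges::reduce(regions, ignore.strand = TRUE)
  total <- sum(GenomicRanges::width(regions))
  cov <- GenomicRanges::reduce(c(footprint_granges(truth),
                                 footprint_granges(test)),
                               ignore.strand = TRUE)
  covered <- sum(GenomicRanges::width(
    GenomicRanges::intersect(regions, cov, ignore.strand = TRUE)))
  total - covered
}

#' Compare a test call set to a truth set over high-confidence regions
#'
#' Calls and truth variants whose start positions fall outside the
#' high-confidence regions, or whose reference footprints overlap the
#' exclusion set, are excluded (they count as neither TP/FP nor FN). Among
#' evaluable records, a test call is a true positive when a truth record
#' matches it on `(chrom, pos, ref, alt)` — and on genotype when
#' `genotype_aware` (the default, since the truth asserts genotypes; an
#' allele match with the wrong zygosity then counts as one FP and one FN).
#' Matching is one-to-one: duplicate test representations of one truth
#' variant yield one TP and the rest FP. Unmatched test calls are FP,
#' unmatched truth variants FN, and true negatives are counted per base via
#' [count_true_negatives()].
#'
#' @param test Normalized call data.frame (from [read_calls()] /
#'   [normalize_calls()]).
#' @param truth Normalized truth data.frame.
#' @param regions `GRanges` of high-confidence regions.
#' @param exclusions `GRanges` exclusion set, or `NULL` to derive it from the
#'   truth set via [build_exclusions()].
#' @param genotype_aware Require matching zygosity for a TP.
#' @param window Exclusion window passed to [build_exclusions()] when
#'   `exclusions` is `NULL`.
#' @return A `variant_comparison` object: counts `tp`, `fp`, `fn`, `tn`
#'   (bases), `excluded_test`, `excluded_truth`, plus record tables
#'   `tp_records`, `fp_records`, `fn_records` retaining quality and depth.
#' @export
compare_calls <- function(test, truth, regions, exclusions = NULL,
                          genotype_aware = TRUE, window = 10L) {
  if (is.null(exclusions)) exclusions <- build_exclusions(truth, window)
  keep_eval <- function(df) {
    if (nrow(df) == 0L)
      return(list(eval = df, n_excluded = 0L))
    starts <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$pos, df$pos))
    in_reg <- IRanges::overlapsAny(starts, regions, ignore.strand = TRUE)
    in_exc <- IRanges::overlapsAny(footprint_granges(df), exclusions,
                                   ignore.strand = TRUE)
    ok <- in_reg & !in_exc
    list(eval = df[ok, , drop = FALSE], n_excluded = sum(!ok))
  }
  ts <- keep_eval(test)
  tr <- keep_eval(truth)
  test_eval <- ts$eval
  truth_eval <- tr$eval

  keyof <- function(df) {
    k <- paste(df$chrom, df$pos, df$ref, df$alt, sep = "\r")
    if (genotype_aware) k <- paste(k, df$genotype, sep = "\r")
    k
  }
  ti <- match(keyof(test_eval), keyof(truth_eval))
  # one-to-one: only the first test call matching a given truth row is TP
  ti[duplicated(ti, incomparables = NA)] <- NA
  is_tp <- !is.na(ti)
  matched_truth <- stats::na.omit(ti)

  tp_records <- test_eval[is_tp, , drop = FALSE]
  fp_records <- test_eval[!is_tp, , drop = FALSE]
  fn_records <- truth_eval[setdiff(seq_len(nrow(truth_eval)), matched_truth), ,
                           drop = FALSE]
  tn <- count_true_negatives(regions, truth_eval, test_eval)
  structure(list(tp = nrow(tp_records), fp = nrow(fp_records),
                 fn = nrow(fn_records), tn = tn,
                 excluded_test = ts$n_excluded, excluded_truth = tr$n_excluded,
                 tp_records = tp_records, fp_records = fp_records,
                 fn_records = fn_records,
                 genotype_aware = genotype_aware),
            class = "variant_comparison")
}

#' @export
print.variant_comparison <- function(x, ...) {
  m <- call_metrics(x)
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.2f%%", 100 * v)
  cat(sprintf(paste0("variant comparison (%s matching)\n",
                     "  TP %d  FP %d  FN %d  TN %d bases",
                     "  (excluded: %d test, %d truth)\n",
                     "  precision %s  sensitivity %s  specificity %s\n"),
              if (x$genotype_aware) "genotype-aware" else "allele",
              x$tp, x$fp, x$fn, x$tn, x$excluded_test, x$excluded_truth,
              fmt(m$precision), fmt(m$sensitivity), fmt(m$specificity)))
  invisible(x)
}

#' Precision, sensitivity and specificity of a variant comparison
#'
#' Precision = TP/(TP+FP), sensitivity = TP/(TP+FN), specificity =
#' TN/(TN+FP). Undefined ratios (0/0) are reported as `NA`, never as 0 or 1.
#' Specificity is near-saturated whenever the confident regions are large,
#' because almost every confident base is homozygous reference.
#'
#' @param comparison A `variant_comparison`, or a list/counts vector with
#'   `tp`, `fp`, `fn`, `tn`.
#' @return List with `precision`, `sensitivity`, `specificity` as fractions
#'   in `[0,1]` (or `NA`).
#' @export
call_metrics <- function(comparison) {
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(precision = ratio(comparison$tp, comparison$tp + comparison$fp),
       sensitivity = ratio(comparison$tp, comparison$tp + comparison$fn),
       specificity = ratio(comparison$tn, comparison$tn + comparison$fp))
}

#' Variant-quality ROC-like curve
#'
#' Sweeps a variant-quality threshold from the highest observed score
#' downwards. At threshold `t`, calls with quality >= `t` are positives
#' (matched calls TP, unmatched FP) and calls below `t` are negatives
#' (matched calls revert to FN, unmatched to TN), on top of the comparison's
#' baseline FN and TN. Calls without a quality score sit below every explicit
#' threshold; when any exist, a final `-Inf` point restores the unthresholded
#' totals, so the lowest point of the curve always reproduces the overall
#' metric set.
#'
#' @param comparison A `variant_comparison` whose TP/FP records carry
#'   `quality`.
#' @return data.frame with `threshold`, `tp`, `fp`, `fn`, `tn`, `tpr`, `fpr`.
#' @export
quality_roc <- function(comparison) {
  qt <- comparison$tp_records$quality
  qf <- comparison$fp_records$quality
  thr <- sort(unique(c(qt, qf)), decreasing = TRUE, na.last = NA)
  if (anyNA(qt) || anyNA(qf) || length(thr) == 0L) thr <- c(thr, -Inf)
  tp <- vapply(thr, function(t)
    if (t == -Inf) length(qt) else sum(!is.na(qt) & qt >= t), 0)
  fp <- vapply(thr, function(t)
    if (t == -Inf) length(qf) else sum(!is.na(qf) & qf >= t), 0)
  fn <- comparison$fn + (comparison$tp - tp)
  tn <- comparison$tn + (comparison$fp - fp)
  tpr <- ifelse(tp + fn == 0, NA_real_, tp / (tp + fn))
  fpr <- ifelse(fp + tn == 0, NA_real_, fp / (fp + tn))
  data.frame(threshold = thr, tp = tp, fp = fp, fn = fn, tn = tn,
             tpr = tpr, fpr = fpr)
}

#' Stratify calling precision by read depth
#'
#' Bins TP and FP records by their depth annotation into `[lo, hi)` bins
#' given by `bin_edges` and computes per-bin precision. Records without a
#' depth annotation are collected into an `"unknown"` stratum. FN records
#' carry no caller depth and are not binned.
#'
#' @param comparison A `variant_comparison`.
#' @param bin_edges Strictly increasing numeric vector of bin edges.
#' @return data.frame with `lo`, `hi`, `tp`, `fp`, `precision`; the last row
#'   is the `"unknown"` stratum (with `lo`/`hi` `NA`) when applicable.
#' @export
stratify_by_depth <- function(comparison,
                              bin_edges = c(0, 10, 20, 30, 40, 60, 100, Inf)) {
  if (length(bin_edges) < 2L || is.unsorted(bin_edges, strictly = TRUE))
    stop("'bin_edges' must be strictly increasing with >= 2 values",
         call. = FALSE)
  if (comparison$tp + comparison$fp == 0L)
    return(data.frame(lo = numeric(0), hi = numeric(0), tp = integer(0),
                      fp = integer(0), precision = numeric(0)))
  nb <- length(bin_edges) - 1L
  bin_of <- function(d) {
    b <- findInterval(d, bin_edges, rightmost.closed = FALSE)
    b[!is.na(d) & (d < bin_edges[1] | d >= bin_edges[length(bin_edges)])] <- NA
    b
  }
  bt <- bin_of(comparison$tp_records$depth)
  bf <- bin_of(comparison$fp_records$depth)
  tp <- tabulate(bt, nbins = nb)
  fp <- tabulate(bf, nbins = nb)
  out <- data.frame(lo = bin_edges[-length(bin_edges)], hi = bin_edges[-1],
                    tp = tp, fp = fp,
                    precision = ifelse(tp + fp == 0, NA_real_, tp / (tp + fp)))
  n_unk_tp <- sum(is.na(bt))
  n_unk_fp <- sum(is.na(bf))
  if (n_unk_tp + n_unk_fp > 0L)
    out <- rbind(out, data.frame(lo = NA_real_, hi = NA_real_, tp = n_unk_tp,
                                 fp = n_unk_fp,
                                 precision = n_unk_tp / (n_unk_tp + n_unk_fp)))
  out
}
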