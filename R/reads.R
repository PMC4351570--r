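#' Sequencing library model
#'
#' Parameters of the paired-end library used by [simulate_reads()]. Defaults
#' describe the emulated benchmark library: 100-bp reads, 500-bp fragments
#' (outer fragment length) with 50 bp standard deviation, 20x coverage. The
#' per-base substitution error rate is a configurable stand-in (default 1%),
#' with a flat base-quality string at the matching Phred score.
#'
#' @param read_length Read length in bp.
#' @param insert_mean Mean outer fragment length in bp.
#' @param insert_sd Standard deviation of fragment length in bp.
#' @param coverage Target mean fold coverage of the reference.
#' @param paired Simulate read pairs (`TRUE`) or single-end reads.
#' @param base_error_rate Per-base probability of a substitution sequencing
#'   error.
#' @return A `library_model` object.
#' @export
library_model <- function(read_length = 100L, insert_mean = 500, insert_sd = 50,
                          coverage = 20, paired = TRUE,
                          base_error_rate = 0.01) {
  read_length <- as.integer(read_length)
  if (is.na(read_length) || read_length < 1L)
    stop("'read_length' must be a positive integer", call. = FALSE)
  if (coverage <= 0) stop("'coverage' must be > 0", call. = FALSE)
  if (insert_sd < 0) stop("'insert_sd' must be >= 0", call. = FALSE)
  if (base_error_rate < 0 || base_error_rate > 1)
    stop("'base_error_rate' must be in [0,1]", call. = FALSE)
  structure(list(read_length = read_length, insert_mean = insert_mean,
                 insert_sd = insert_sd, coverage = coverage,
                 paired = isTRUE(paired), base_error_rate = base_error_rate),
            class = "library_model")
}

#' Encode a read origin into a FASTQ/SAM-safe read name
#'
#' The true placement of each simulated fragment travels losslessly in the
#' read name, colon-separated:
#' `vb:<chrom>:<start1>:<strand1>:<start2>:<strand2>:<hap>:<serial>`.
#' Single-end origins carry `*` for the mate-2 fields. Positions are 1-based
#' reference (unmutated) coordinates of each mate's leftmost base, matching
#' SAM `POS`. Decoding parses fixed fields from the right so contig names may
#' themselves contain colons.
#'
#' @param origin data.frame (one or more rows) with columns `chrom`, `start1`,
#'   `strand1` (`"+"`/`"-"`), `start2`, `strand2` (may be `NA` for
#'   single-end), `haplotype` (0/1) and `serial`.
#' @return Character vector of read names.
#' @export
encode_read_name <- function(origin) {
  stopifnot(all(c("chrom", "start1", "strand1", "start2", "strand2",
                  "haplotype", "serial") %in% names(origin)))
  if (any(grepl("[[:space:]@+]", origin$chrom)))
    stop("contig names must not contain whitespace, '@' or '+'", call. = FALSE)
  s2 <- ifelse(is.na(origin$start2), "*", as.character(origin$start2))
  st2 <- ifelse(is.na(origin$strand2), "*", as.character(origin$strand2))
  paste("vb", origin$chrom, origin$start1, origin$strand1, s2, st2,
        origin$haplotype, origin$serial, sep = ":")
}

#' @rdname encode_read_name
#' @param name Character vector of encoded read names.
#' @return For `decode_read_name()`, a data.frame of origins (one row per
#'   name). Malformed names raise an error identifying the offending field.
#' @export
decode_read_name <- function(name) {
  parts <- strsplit(name, ":", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 8L))
    stop("malformed read name (need 8+ ':' fields): ", name[which(nf < 8L)[1]],
         call. = FALSE)
  tail6 <- t(vapply(parts, function(p) p[(length(p) - 5L):length(p)],
                    character(6)))
  chrom <- vapply(parts, function(p)
    paste(p[2:(length(p) - 6L)], collapse = ":"), "")
  if (any(vapply(parts, `[`, "", 1L) != "vb"))
    stop("malformed read name (missing 'vb' prefix): ",
         name[which(vapply(parts, `[`, "", 1L) != "vb")[1]], call. = FALSE)
  num_or_stop <- function(x, field, allow_star = FALSE) {
    out <- suppressWarnings(as.integer(x))
    bad <- is.na(out) & !(allow_star & x == "*")
    if (any(bad))
      stop(sprintf("malformed read name field '%s': %s", field,
                   name[which(bad)[1]]), call. = FALSE)
    out
  }
  strand_or_stop <- function(x, field, allow_star = FALSE) {
    ok <- x %in% c("+", "-") | (allow_star & x == "*")
    if (!all(ok))
      stop(sprintf("malformed read name field '%s': %s", field,
                   name[which(!ok)[1]]), call. = FALSE)
    ifelse(x == "*", NA_character_, x)
  }
  data.frame(
    name = name,
    chrom = chrom,
    start1 = num_or_stop(tail6[, 1], "start1"),
    strand1 = strand_or_stop(tail6[, 2], "strand1"),
    start2 = num_or_stop(tail6[, 3], "start2", allow_star = TRUE),
    strand2 = strand_or_stop(tail6[, 4], "strand2", allow_star = TRUE),
    haplotype = num_or_stop(tail6[, 5], "haplotype"),
    serial = num_or_stop(tail6[, 6], "serial"),
    stringsAsFactors = FALSE
  )
}

# Map haplotype coordinates back to unmutated reference coordinates.
# Positions inside an inserted run map to the base following the anchor;
# results are clamped to [1, ref_length].
hap_to_ref <- function(hap_pos, variants, ref_length) {
  if (nrow(variants) == 0L) return(pmin(pmax(hap_pos, 1L), ref_length))
  delta <- nchar(variants$alt) - nchar(variants$ref)
  ref_end <- variants$pos + nchar(variants$ref) - 1L
  # haplotype coordinate of the last base of each alt allele
  hap_end <- variants$pos + c(0L, cumsum(delta)[-length(delta)]) +
    nchar(variants$alt) - 1L
  idx <- findInterval(hap_pos, hap_end + 1L)
  shift <- c(0L, hap_end - ref_end)[idx + 1L]
  pmin(pmax(hap_pos - shift, 1L), ref_length)
}

#' Simulate paired-end reads from a diploid genome
#'
#' Draws fragments uniformly from the two haplotypes (each chosen with
#' probability 0.5), with fragment (outer insert) lengths sampled from a
#' normal distribution and resampled until they fit within
#' `[read_length, haplotype length]`. Mate 1 reads the forward strand of the
#' fragment's left end; mate 2 is the reverse complement of its right end
#' (standard FR layout). The number of pairs is the closed form
#' `round(coverage * reference_length / (2 * read_length))`. Substitution
#' errors are injected per base at `base_error_rate` from an error random
#' stream seeded independently of the fragmentation stream (`seed + 1`), so
#' changing the error rate does not perturb fragment placement.
#'
#' @param genome A `diploid_genome` (from [mutate_diploid()]) or a plain
#'   `reference` (treated as an unmutated diploid).
#' @param lib A `library_model`.
#' @param seed Integer seed (fragmentation stream; `seed + 1` seeds the error
#'   stream).
#' @return A `read_set` object: list with `reads1`, `reads2` (character
#'   vectors; `reads2` is `NULL` for single-end), `qual1`, `qual2` (flat
#'   quality strings), and `origins`, a data.frame with one row per fragment
#'   (`name`, `chrom`, `start1`, `strand1`, `start2`, `strand2`, `haplotype`,
#'   `serial`, `frag_hap_len`).
#' @examples
#' ref <- generate_reference(10000, seed = 1)
#' rs <- simulate_reads(ref, library_model(coverage = 2), seed = 5)
#' length(rs$reads1)
#' @export
simulate_reads <- function(genome, lib = library_model(), seed = 1L) {
  if (inherits(genome, "reference"))
    genome <- structure(list(reference = genome,
                             haplotypes = c(genome$sequence, genome$sequence),
                             truth = empty_truth()),
                        class = "diploid_genome")
  stopifnot(inherits(genome, "diploid_genome"), inherits(lib, "library_model"))
  L <- genome$reference$length
  rl <- lib$read_length
  hap_len <- nchar(genome$haplotypes)
  if (rl > min(hap_len))
    stop("read_length exceeds haplotype length", call. = FALSE)

  n_pairs <- as.integer(round(lib$coverage * L /
                                ((if (lib$paired) 2 else 1) * rl)))
  set.seed(as.integer(seed))
  hap <- sample(0:1, n_pairs, replace = TRUE)
  min_frag <- if (lib$paired) rl else rl
  frag <- as.integer(round(stats::rnorm(n_pairs, lib$insert_mean, lib$insert_sd)))
  bad <- frag < min_frag | frag > hap_len[hap + 1L]
  while (any(bad)) {
    frag[bad] <- as.integer(round(stats::rnorm(sum(bad), lib$insert_mean,
                                               lib$insert_sd)))
    bad <- frag < min_frag | frag > hap_len[hap + 1L]
  }
  start_hap <- 1L + as.integer(floor(stats::runif(n_pairs) *
                                       (hap_len[hap + 1L] - frag + 1L)))

  reads1 <- substring(genome$haplotypes[hap + 1L], start_hap,
                      start_hap + rl - 1L)
  if (lib$paired) {
    r2_start <- start_hap + frag - rl
    reads2 <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(substring(genome$haplotypes[hap + 1L],
                                         r2_start, r2_start + rl - 1L))))
  } else {
    reads2 <- NULL
    r2_start <- rep(NA_integer_, n_pairs)
  }

  ref_start1 <- ref_start2 <- integer(n_pairs)
  for (h in 0:1) {
    sel <- hap == h
    v <- genome$truth[truth_on_hap(genome$truth, h), , drop = FALSE]
    ref_start1[sel] <- hap_to_ref(start_hap[sel], v, L)
    if (lib$paired) ref_start2[sel] <- hap_to_ref(r2_start[sel], v, L)
  }

  origins <- data.frame(
    chrom = genome$reference$name,
    start1 = ref_start1,
    strand1 = "+",
    start2 = if (lib$paired) ref_start2 else NA_integer_,
    strand2 = if (lib$paired) "-" else NA_character_,
    haplotype = hap,
    serial = seq_len(n_pairs) - 1L,
    frag_hap_len = frag,
    stringsAsFactors = FALSE
  )
  origins <- cbind(name = encode_read_name(origins), origins,
                   stringsAsFactors = FALSE)

  set.seed(as.integer(seed) + 1L)
  reads1 <- inject_errors(reads1, lib$base_error_rate)
  if (lib$paired) reads2 <- inject_errors(reads2, lib$base_error_rate)

  q <- flat_quality(rl, lib$base_error_rate)
  structure(list(reads1 = reads1, reads2 = reads2,
                 qual1 = rep(q, n_pairs),
                 qual2 = if (lib$paired) rep(q, n_pairs) else NULL,
                 origins = origins, lib = lib),
            class = "read_set")
}

# flat per-base quality string matching the simulated substitution rate,
# capped at Phred 40 when the rate is (near) zero
flat_quality <- function(read_length, error_rate) {
  phred <- if (error_rate <= 0) 40L else
    min(40L, as.integer(round(-10 * log10(error_rate))))
  strrep(rawToChar(as.raw(33L + phred)), read_length)
}

# substitute bases at a flat per-base rate; each error picks one of the
# three non-reference bases uniformly
inject_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  rl <- nchar(reads)
  n_err <- stats::rbinom(length(reads), rl, rate)
  hit <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    p <- sample.int(rl[i], n_err[i])
    r <- reads[i]
    for (j in p) {
      old <- substr(r, j, j)
      substr(r, j, j) <- sample(setdiff(bases, old), 1L)
    }
    reads[i] <- r
  }
  reads
}

#' Write a read set to gzip-compressed FASTQ (plus an origins sidecar)
#'
#' Mate files are named `<prefix>_1.fastq.gz` and `<prefix>_2.fastq.gz`
#' (single-end: `<prefix>.fastq.gz`); origins go to `<prefix>.origins.tsv`.
#'
#' @param rs A `read_set`.
#' @param prefix Output path prefix.
#' @return Character vector of the files written, invisibly.
#' @export
write_fastq <- function(rs, prefix) {
  stopifnot(inherits(rs, "read_set"))
  write_one <- function(reads, quals, path) {
    x <- Biostrings::DNAStringSet(reads)
    names(x) <- rs$origins$name
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals),
                                compress = TRUE)
    path
  }
  files <- character(0)
  if (is.null(rs$reads2)) {
    files <- write_one(rs$reads1, rs$qual1, paste0(prefix, ".fastq.gz"))
  } else {
    files <- c(write_one(rs$reads1, rs$qual1, paste0(prefix, "_1.fastq.gz")),
               write_one(rs$reads2, rs$qual2, paste0(prefix, "_2.fastq.gz")))
  }
  org <- paste0(prefix, ".origins.tsv")
  utils::write.table(rs$origins[, c("name", "chrom", "start1", "strand1",
                                    "start2", "strand2", "haplotype", "serial")],
                     org, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(files, org))
}

#' Read an origins sidecar TSV
#'
#' @param path Path to a `.origins.tsv` written by [write_fastq()].
#' @return data.frame of read origins.
#' @export
read_origins <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(strand2 = "character"))
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d %s, read length %d bp\n", length(x$reads1),
              if (is.null(x$reads2)) "single-end reads" else "read pairs",
              x$lib$read_length))
  invisible(x)
}
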