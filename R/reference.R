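#' Generate a seeded synthetic reference contig
#'
#' Draws an i.i.d. nucleotide sequence with a target GC content, standing in
#' for a real chromosome when no reference FASTA is supplied. Base
#' probabilities are `gc_content/2` for each of G and C and `(1-gc_content)/2`
#' for each of A and T, so the observed GC fraction of a long contig converges
#' to `gc_content` under binomial sampling.
#'
#' @param length Contig length in bases (minimum 1000).
#' @param gc_content Target GC fraction, strictly between 0 and 1.
#' @param seed Integer seed; the same seed and parameters always give the
#'   identical sequence.
#' @param name Contig name used in FASTA/VCF/BED output.
#' @return A `reference` object: list with `name`, `sequence` (uppercase
#'   A/C/G/T character scalar) and `length`.
#' @examples
#' ref <- generate_reference(2000, gc_content = 0.45, seed = 1)
#' ref$length
#' @export
generate_reference <- function(length, gc_content = 0.5, seed = 1L,
                               name = "synth1") {
  if (!is.numeric(length) || length(length) != 1L || is.na(length) ||
      length < 1000)
    stop("'length' must be a single number >= 1000", call. = FALSE)
  if (!is.numeric(gc_content) || gc_content <= 0 || gc_content >= 1)
    stop("'gc_content' must lie strictly between 0 and 1", call. = FALSE)
  length <- as.integer(length)
  set.seed(as.integer(seed))
  bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                  prob = c((1 - gc_content) / 2, gc_content / 2,
                           gc_content / 2, (1 - gc_content) / 2))
  new_reference(name, paste(bases, collapse = ""))
}

#' Construct a reference object from a sequence
#'
#' @param name Contig name.
#' @param sequence Uppercase A/C/G/T character scalar.
#' @return A `reference` object.
#' @export
new_reference <- function(name, sequence) {
  sequence <- toupper(as.character(sequence))
  if (grepl("[^ACGT]", sequence))
    stop("reference sequence may contain only A/C/G/T", call. = FALSE)
  structure(list(name = as.character(name), sequence = sequence,
                 length = nchar(sequence)),
            class = "reference")
}

#' Read the first contig of a FASTA file as a reference object
#'
#' @param path Path to a FASTA file.
#' @param which Index or name of the contig to load (default: first).
#' @return A `reference` object.
#' @export
read_reference <- function(path, which = 1L) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no sequences in ", path, call. = FALSE)
  s <- seqs[[which]]
  nm <- sub("\\s.*$", "", names(seqs)[if (is.character(which))
    match(which, sub("\\s.*$", "", names(seqs))) else which])
  new_reference(nm, as.character(s))
}

#' Write a reference object to FASTA
#'
#' @param ref A `reference` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  stopifnot(inherits(ref, "reference"))
  x <- Biostrings::DNAStringSet(ref$sequence)
  names(x) <- ref$name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @export
print.reference <- function(x, ...) {
  gc <- mean(strsplit(x$sequence, "", fixed = TRUE)[[1]] %in% c("G", "C"))
  cat(sprintf("reference contig '%s': %d bp, GC %.3f\n", x$name, x$length, gc))
  invisible(x)
}
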