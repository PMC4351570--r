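#' Write a truth variant set as VCF 4.2 plus a high-confidence BED
#'
#' Materializes the simulator's ground truth: a spec-conformant VCF with a
#' single `TRUTH` sample (`GT` `0/1` for heterozygous variants, `1/1` for
#' homozygous-alternate) and a BED of high-confidence regions (0-based
#' half-open). By default the confident region is the whole contig.
#'
#' @param truth Truth data.frame (see [mutate_diploid()]): columns `chrom`,
#'   `pos`, `ref`, `alt`, `genotype`; must be sorted by position per contig
#'   with non-overlapping footprints per haplotype.
#' @param contigs Named integer vector of contig lengths for the VCF header.
#' @param vcf_path Output VCF path.
#' @param bed_path Output BED path (`NULL` to skip).
#' @param regions A `GRanges` of confident regions, or `NULL` for whole
#'   contigs.
#' @return Character vector of files written, invisibly.
#' @export
write_truth <- function(truth, contigs, vcf_path, bed_path = NULL,
                        regions = NULL) {
  stopifnot(is.data.frame(truth), !is.null(names(contigs)))
  for (ctg in unique(truth$chrom)) {
    p <- truth$pos[truth$chrom == ctg]
    if (is.unsorted(p))
      stop("truth variants must be sorted by position within each contig",
           call. = FALSE)
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=varbench",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTRUTH"
  )
  lines <- hdr
  if (nrow(truth) > 0L) {
    gt <- ifelse(is.na(truth$genotype), "./.",
                 ifelse(truth$genotype == "het", "0/1", "1/1"))
    lines <- c(hdr, paste(truth$chrom, truth$pos, ".", truth$ref, truth$alt,
                          ".", "PASS", ".", "GT", gt, sep = "\t"))
  }
  writeLines(lines, vcf_path)
  files <- vcf_path
  if (!is.null(bed_path)) {
    if (is.null(regions))
      regions <- GenomicRanges::GRanges(
        names(contigs), IRanges::IRanges(1L, as.integer(contigs)))
    rtracklayer::export(regions, bed_path, format = "BED")
    files <- c(files, bed_path)
  }
  invisible(files)
}

#' Read a truth VCF back into a truth data.frame
#'
#' Parses a (single-sample) VCF with `VariantAnnotation`, decomposing
#' multi-allelic sites, and maps `GT` onto the `het` / `hom-alt` zygosity
#' labels used throughout the package.
#'
#' @param path Path to a VCF file.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`, `genotype`,
#'   `vclass`.
#' @export
read_truth_vcf <- function(path) {
  calls <- read_calls(path)
  truth <- calls[, c("chrom", "pos", "ref", "alt", "genotype", "vclass")]
  rownames(truth) <- NULL
  truth
}

#' Read high-confidence regions from a BED file
#'
#' @param path Path to a BED file (0-based half-open intervals).
#' @return A merged `GRanges` (1-based closed internally, as usual in R).
#' @export
read_regions <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  GenomicRanges::reduce(gr, ignore.strand = TRUE)
}
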