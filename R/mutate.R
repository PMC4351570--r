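#' Mutation model for diploid genome simulation
#'
#' Parameters of the per-base mutation process used by [mutate_diploid()].
#' Defaults follow the simulation conditions the toolkit emulates: a 0.1%
#' per-base chance of mutation, 10% of mutations being indels, small indels of
#' 1-10 bp and large indels of 10-24 bp. The large-indel mix and the zygosity
#' of simulated mutations are not pinned down by those conditions; the
#' defaults here (10% of indels large, 50% of mutations heterozygous) are
#' explicit, configurable stand-ins.
#'
#' @param mutation_rate Per-base probability that a site nucleates a mutation.
#' @param indel_fraction Fraction of mutations that are indels (the rest are
#'   SNPs).
#' @param small_indel_range Integer length range (inclusive) of small indels.
#' @param large_indel_range Integer length range (inclusive) of large indels.
#' @param large_indel_fraction Fraction of indels drawn from the large range.
#' @param het_probability Probability that a mutation is heterozygous (applied
#'   to one haplotype); otherwise it is homozygous-alternate (both).
#' @return A `mutation_model` object.
#' @export
mutation_model <- function(mutation_rate = 0.001, indel_fraction = 0.1,
                           small_indel_range = c(1L, 10L),
                           large_indel_range = c(10L, 24L),
                           large_indel_fraction = 0.1,
                           het_probability = 0.5) {
  probs <- c(mutation_rate = mutation_rate, indel_fraction = indel_fraction,
             large_indel_fraction = large_indel_fraction,
             het_probability = het_probability)
  bad <- probs < 0 | probs > 1 | is.na(probs)
  if (any(bad))
    stop("probabilities out of [0,1]: ", paste(names(probs)[bad], collapse = ", "),
         call. = FALSE)
  small_indel_range <- as.integer(small_indel_range)
  large_indel_range <- as.integer(large_indel_range)
  if (length(small_indel_range) != 2L || small_indel_range[1] > small_indel_range[2] ||
      small_indel_range[1] < 1L)
    stop("'small_indel_range' must be c(min, max) with 1 <= min <= max", call. = FALSE)
  if (length(large_indel_range) != 2L || large_indel_range[1] > large_indel_range[2])
    stop("'large_indel_range' must be c(min, max) with min <= max", call. = FALSE)
  structure(list(mutation_rate = mutation_rate,
                 indel_fraction = indel_fraction,
                 small_indel_range = small_indel_range,
                 large_indel_range = large_indel_range,
                 large_indel_fraction = large_indel_fraction,
                 het_probability = het_probability),
            class = "mutation_model")
}

# Classify ref/alt allele pair into SNP / insertion / deletion.
variant_class <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  ifelse(lr == la, "SNP", ifelse(la > lr, "insertion", "deletion"))
}

#' Mutate a reference into two haplotypes with an explicit truth set
#'
#' Scans the contig with an independent per-base mutation probability, assigns
#' each accepted mutation a class (SNP, insertion or deletion), a length for
#' indels, and a zygosity (heterozygous mutations land on one randomly chosen
#' haplotype, homozygous-alternate on both). Indels use the VCF anchor-base
#' convention: a deletion removes bases following the anchor, an insertion
#' inserts after the anchor. A proposed mutation whose reference footprint
#' would touch an already-accepted mutation on the same haplotype is rejected
#' (not resampled), so truth variants never overlap on a haplotype.
#'
#' @param ref A `reference` object.
#' @param model A `mutation_model`.
#' @param seed Integer seed for the mutation stage.
#' @return A `diploid_genome` object: list with `reference`, `haplotypes`
#'   (character vector of the two mutated sequences), and `truth`, a
#'   data.frame with columns `chrom`, `pos` (1-based anchor), `ref`, `alt`,
#'   `genotype` (`"het"`/`"hom-alt"`), `vclass`, and `hap` (0 or 1 for het
#'   variants, `NA` for homozygous ones).
#' @examples
#' ref <- generate_reference(5000, seed = 2)
#' g <- mutate_diploid(ref, mutation_model(), seed = 3)
#' nrow(g$truth)
#' @export
mutate_diploid <- function(ref, model = mutation_model(), seed = 1L) {
  stopifnot(inherits(ref, "reference"), inherits(model, "mutation_model"))
  set.seed(as.integer(seed))
  L <- ref$length
  seq <- ref$sequence

  pos <- which(stats::runif(L) < model$mutation_rate)
  n <- length(pos)
  if (n == 0L) {
    truth <- empty_truth(ref$name)
    return(structure(list(reference = ref,
                          haplotypes = c(seq, seq),
                          truth = truth),
                     class = "diploid_genome"))
  }

  is_indel <- stats::runif(n) < model$indel_fraction
  is_large <- stats::runif(n) < model$large_indel_fraction
  is_ins <- stats::runif(n) < 0.5
  len_small <- sample(seq(model$small_indel_range[1], model$small_indel_range[2]),
                      n, replace = TRUE)
  len_large <- sample(seq(model$large_indel_range[1], model$large_indel_range[2]),
                      n, replace = TRUE)
  indel_len <- ifelse(is_large, len_large, len_small)
  is_het <- stats::runif(n) < model$het_probability
  het_hap <- sample(0:1, n, replace = TRUE)
  # pre-drawn substitution targets / inserted sequences keep the stream stable
  snp_pick <- sample.int(3L, n, replace = TRUE)
  ins_seq <- vapply(indel_len, function(k)
    paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = ""), "")

  last_end <- c(0L, 0L)  # rightmost occupied ref position per haplotype
  keep <- logical(n)
  ref_allele <- alt_allele <- character(n)
  for (i in seq_len(n)) {
    p <- pos[i]
    haps <- if (is_het[i]) het_hap[i] + 1L else 1:2
    if (is_indel[i] && !is_ins[i]) {
      end <- p + indel_len[i]
      if (end > L) next
    } else end <- p
    if (any(p <= last_end[haps])) next
    anchor <- substr(seq, p, p)
    if (is_indel[i]) {
      if (is_ins[i]) {
        ref_allele[i] <- anchor
        alt_allele[i] <- paste0(anchor, ins_seq[i])
      } else {
        ref_allele[i] <- substr(seq, p, end)
        alt_allele[i] <- anchor
      }
    } else {
      ref_allele[i] <- anchor
      alt_allele[i] <- setdiff(c("A", "C", "G", "T"), anchor)[snp_pick[i]]
    }
    keep[i] <- TRUE
    last_end[haps] <- end
  }

  truth <- data.frame(
    chrom = ref$name,
    pos = pos[keep],
    ref = ref_allele[keep],
    alt = alt_allele[keep],
    genotype = ifelse(is_het[keep], "het", "hom-alt"),
    vclass = variant_class(ref_allele[keep], alt_allele[keep]),
    hap = ifelse(is_het[keep], het_hap[keep], NA_integer_),
    stringsAsFactors = FALSE
  )
  haps <- vapply(0:1, function(h)
    apply_variants(seq, truth[truth_on_hap(truth, h), , drop = FALSE]), "")
  structure(list(reference = ref, haplotypes = haps, truth = truth),
            class = "diploid_genome")
}

empty_truth <- function(chrom = character(0)) {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), genotype = character(0), vclass = character(0),
             hap = integer(0), stringsAsFactors = FALSE)
}

# logical index of truth rows applied to haplotype h (0 or 1)
truth_on_hap <- function(truth, h) {
  truth$genotype == "hom-alt" | (!is.na(truth$hap) & truth$hap == h)
}

#' Apply sorted, non-overlapping variants to a sequence
#'
#' Splices a set of variants (VCF anchor-base convention) into a reference
#' sequence by cutting it at each variant's reference footprint and pasting in
#' the alternate allele.
#'
#' @param seq Reference sequence (character scalar).
#' @param variants data.frame with `pos`, `ref`, `alt`, sorted by `pos` and
#'   non-overlapping.
#' @return The mutated sequence.
#' @export
apply_variants <- function(seq, variants) {
  if (nrow(variants) == 0L) return(seq)
  if (is.unsorted(variants$pos, strictly = TRUE))
    stop("variants must be sorted by position and non-overlapping", call. = FALSE)
  ref_end <- variants$pos + nchar(variants$ref) - 1L
  if (any(variants$pos[-1] <= ref_end[-length(ref_end)]))
    stop("variants overlap on the same haplotype", call. = FALSE)
  seg_start <- c(1L, ref_end + 1L)
  seg_end <- c(variants$pos - 1L, nchar(seq))
  segs <- substring(seq, seg_start, seg_end)
  out <- character(2L * nrow(variants) + 1L)
  out[seq(1L, length(out), by = 2L)] <- segs
  out[seq(2L, length(out), by = 2L)] <- variants$alt
  paste(out, collapse = "")
}

#' @export
print.diploid_genome <- function(x, ...) {
  cat(sprintf("diploid genome on '%s' (%d bp): %d truth variants (%d SNP, %d ins, %d del)\n",
              x$reference$name, x$reference$length, nrow(x$truth),
              sum(x$truth$vclass == "SNP"), sum(x$truth$vclass == "insertion"),
              sum(x$truth$vclass == "deletion")))
  invisible(x)
}
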