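# Independent brute-force oracles and small fixture builders. These must
# stay naive re-implementations of the contracts, not calls into the package.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# random small call/truth set over a given sequence: SNPs and short indels at
# distinct, well-separated positions
rand_calls <- function(refseq, n, chrom = "c1", p_indel = 0.3,
                       with_scores = FALSE, min_gap = 30L) {
  L <- nchar(refseq)
  pos <- sort(sample(seq(2L, L - 30L, by = min_gap), n))
  ref <- alt <- character(n)
  for (i in seq_len(n)) {
    b <- substr(refseq, pos[i], pos[i])
    if (runif(1) < p_indel) {
      k <- sample(1:5, 1)
      if (runif(1) < 0.5) {   # insertion
        ref[i] <- b
        alt[i] <- paste0(b, rand_seq(k))
      } else {                # deletion
        ref[i] <- substr(refseq, pos[i], pos[i] + k)
        alt[i] <- b
      }
    } else {
      ref[i] <- b
      alt[i] <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }
  }
  df <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                   genotype = sample(c("het", "hom-alt"), n, TRUE),
                   stringsAsFactors = FALSE)
  df$vclass <- ifelse(nchar(df$ref) == nchar(df$alt), "SNP",
                      ifelse(nchar(df$alt) > nchar(df$ref), "insertion",
                             "deletion"))
  if (with_scores) {
    df$quality <- round(runif(n, 0, 100), 1)
    df$depth <- sample(c(NA, 1:80), n, TRUE)
  }
  df
}

# canonical leftmost minimal representation of the single event turning
# refseq into mutseq, derived from whole-sequence comparison (independent of
# the package's per-allele trimming loop)
oracle_canonical <- function(refseq, mutseq) {
  Lr <- nchar(refseq); Lm <- nchar(mutseq)
  rs <- strsplit(refseq, "")[[1]]; ms <- strsplit(mutseq, "")[[1]]
  s <- 0L
  while (s < min(Lr, Lm) - 1L && rs[Lr - s] == ms[Lm - s]) s <- s + 1L
  rpart <- rs[seq_len(Lr - s)]; mpart <- ms[seq_len(Lm - s)]
  p <- 0L
  while (p < min(length(rpart), length(mpart)) &&
         rpart[p + 1L] == mpart[p + 1L]) p <- p + 1L
  if (p == length(rpart) || p == length(mpart)) {  # indel: keep anchor at p
    pos <- p
    r <- rpart[seq.int(p, length(rpart))]
    a <- mpart[seq.int(p, length(mpart))]
  } else {                                        # substitution block
    pos <- p + 1L
    r <- rpart[seq.int(p + 1L, length(rpart))]
    a <- mpart[seq.int(p + 1L, length(mpart))]
  }
  list(pos = pos, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

# per-read correctness rule, re-stated naively
oracle_judge <- function(mapped, chrom, pos, strand, true_chrom, true_pos,
                         true_strand, tol) {
  if (!mapped) return("unmapped")
  if (identical(chrom, true_chrom) && identical(strand, true_strand) &&
      abs(pos - true_pos) <= tol) "correct" else "incorrect"
}

# base set (integer positions, single contig) of a GRanges
granges_bases <- function(gr) {
  if (length(gr) == 0L) return(integer(0))
  unlist(lapply(seq_along(gr), function(i)
    seq(GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i])))
}

# pairwise exclusion rule: indel + other variant starting within window-1
# bases => exclude the span of both footprints (single contig)
oracle_exclusion_bases <- function(truth, window = 10L) {
  st <- truth$pos
  en <- truth$pos + nchar(truth$ref) - 1L
  out <- integer(0)
  for (i in seq_len(nrow(truth))) {
    if (truth$vclass[i] == "SNP") next
    for (j in seq_len(nrow(truth))) {
      if (j == i) next
      if (abs(st[j] - st[i]) <= window - 1L)
        out <- c(out, seq(min(st[i], st[j]), max(en[i], en[j])))
    }
  }
  sort(unique(out))
}

# per-site enumeration oracle for compare(): single contig, region and
# exclusion sets given as base vectors
oracle_compare <- function(test, truth, reg_bases, excl_bases,
                           genotype_aware = TRUE) {
  evaluable <- function(df) {
    if (nrow(df) == 0L) return(df)
    keep <- vapply(seq_len(nrow(df)), function(i) {
      fp <- seq(df$pos[i], df$pos[i] + nchar(df$ref[i]) - 1L)
      (df$pos[i] %in% reg_bases) && !any(fp %in% excl_bases)
    }, TRUE)
    df[keep, , drop = FALSE]
  }
  test <- evaluable(test); truth <- evaluable(truth)
  keyof <- function(df) {
    k <- paste(df$chrom, df$pos, df$ref, df$alt)
    if (genotype_aware) k <- paste(k, df$genotype)
    k
  }
  kt <- keyof(test); kr <- keyof(truth)
  used <- rep(FALSE, length(kr)); tp <- 0L
  for (i in seq_along(kt)) {
    j <- which(!used & kr == kt[i])
    if (length(j)) { used[j[1]] <- TRUE; tp <- tp + 1L }
  }
  cov <- unique(unlist(lapply(list(test, truth), function(df)
    if (nrow(df)) unlist(lapply(seq_len(nrow(df)), function(i)
      seq(df$pos[i], df$pos[i] + nchar(df$ref[i]) - 1L))) else integer(0))))
  list(tp = tp, fp = length(kt) - tp, fn = sum(!used),
       tn = sum(!(reg_bases %in% cov)))
}

# right-to-left splice patcher, independent of apply_variants()
oracle_patch <- function(seq, variants) {
  for (i in rev(seq_len(nrow(variants)))) {
    p <- variants$pos[i]
    lr <- nchar(variants$ref[i])
    seq <- paste0(substr(seq, 1L, p - 1L), variants$alt[i],
                  substr(seq, p + lr, nchar(seq)))
  }
  seq
}

# judgments table of a given shape without going through SAM
fake_judgments <- function(mapq, verdict) {
  n <- length(mapq)
  structure(data.frame(name = sprintf("r%d", seq_len(n)), mate = rep(1L, n),
                       verdict = verdict, mapq = mapq,
                       distance = rep(0L, n), stringsAsFactors = FALSE),
            class = c("alignment_judgments", "data.frame"))
}

# random variant_comparison with scored records
rand_comparison <- function(L = 3000L, n = 30L, missing_quality = FALSE) {
  refseq <- rand_seq(L)
  truth <- rand_calls(refseq, n, with_scores = TRUE, min_gap = 25L)
  test <- truth[runif(n) < 0.8, , drop = FALSE]
  extra <- rand_calls(rand_seq(L), sample(2:8, 1), with_scores = TRUE,
                      min_gap = 40L)
  extra$pos <- extra$pos + 3L
  extra <- extra[!extra$pos %in% truth$pos, , drop = FALSE]
  test <- rbind(test, extra)
  if (missing_quality) test$quality[runif(nrow(test)) < 0.3] <- NA
  compare_calls(test, truth,
                GenomicRanges::GRanges("c1", IRanges::IRanges(1, L)),
                exclusions = GenomicRanges::GRanges())
}

# shared larger simulation, built once per test run
.fixture_env <- new.env(parent = emptyenv())
shared_sim_1mb <- function() {
  if (is.null(.fixture_env$sim1mb)) {
    ref <- generate_reference(1e6, gc_content = 0.41, seed = 101)
    .fixture_env$sim1mb <- list(
      ref = ref,
      genome = mutate_diploid(ref, mutation_model(), seed = 102))
  }
  .fixture_env$sim1mb
}
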