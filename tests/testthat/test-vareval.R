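whole_region <- function(L, chrom = "c1")
  GenomicRanges::GRanges(chrom, IRanges::IRanges(1, L))

test_that("normalization trims shared bases and is idempotent", {
  refseq <- paste0(strrep("A", 99), "CTGGGGG", strrep("A", 50))
  ref <- c(c1 = refseq)
  calls <- data.frame(chrom = "c1", pos = 100L, ref = "CT", alt = "CA",
                      stringsAsFactors = FALSE)
  out <- normalize_calls(calls, ref)
  expect_identical(out$pos, 101L)
  expect_identical(out$ref, "T")
  expect_identical(out$alt, "A")
  snp <- data.frame(chrom = "c1", pos = 100L, ref = "C", alt = "G",
                    stringsAsFactors = FALSE)
  expect_identical(normalize_calls(snp, ref), snp)
  expect_identical(normalize_calls(out, ref), out)
  bad <- data.frame(chrom = "c1", pos = 100L, ref = "T", alt = "A",
                    stringsAsFactors = FALSE)
  expect_error(normalize_calls(bad, ref), "REF allele mismatch")
})

test_that("equivalent indel representations normalize to one canonical form", {
  set.seed(51)
  for (rep in 1:100) {
    refseq <- rand_seq(60)
    # one random indel event applied mid-sequence
    pos <- sample(10:40, 1)
    k <- sample(1:6, 1)
    if (runif(1) < 0.5) {
      ev <- data.frame(chrom = "c1", pos = pos,
                       ref = substr(refseq, pos, pos),
                       alt = paste0(substr(refseq, pos, pos), rand_seq(k)),
                       stringsAsFactors = FALSE)
    } else {
      ev <- data.frame(chrom = "c1", pos = pos,
                       ref = substr(refseq, pos, pos + k),
                       alt = substr(refseq, pos, pos),
                       stringsAsFactors = FALSE)
    }
    mutseq <- oracle_patch(refseq, ev)
    can <- oracle_canonical(refseq, mutseq)
    # equivalent padded representations of the same event
    reps <- lapply(0:4, function(pad) {
      lo <- max(1L, ev$pos - pad)
      hi <- min(nchar(refseq), ev$pos + nchar(ev$ref) - 1L + pad)
      data.frame(chrom = "c1", pos = lo,
                 ref = substr(refseq, lo, hi),
                 alt = paste0(substr(refseq, lo, ev$pos - 1L), ev$alt,
                              substr(refseq, ev$pos + nchar(ev$ref), hi)),
                 stringsAsFactors = FALSE)
    })
    for (r in reps) {
      out <- normalize_calls(r, c(c1 = refseq))
      expect_identical(out$pos, can$pos)
      expect_identical(out$ref, can$ref)
      expect_identical(out$alt, can$alt)
    }
  }
})

test_that("exclusion rule follows documented examples", {
  truth <- data.frame(chrom = "c1", pos = c(100L, 105L),
                      ref = c("CTTT", "A"), alt = c("C", "G"),
                      genotype = "het", vclass = c("deletion", "SNP"),
                      stringsAsFactors = FALSE)
  ex <- build_exclusions(truth, window = 10)
  expect_identical(length(ex), 1L)
  expect_identical(GenomicRanges::start(ex), 100L)
  expect_identical(GenomicRanges::end(ex), 105L)
  snps <- data.frame(chrom = "c1", pos = c(100L, 105L), ref = "A", alt = "G",
                     genotype = "het", vclass = "SNP", stringsAsFactors = FALSE)
  expect_identical(length(build_exclusions(snps, window = 10)), 0L)
  far <- truth; far$pos <- c(100L, 120L)
  expect_identical(length(build_exclusions(far, window = 10)), 0L)
})

test_that("exclusions match a pairwise brute-force oracle (>=200 cases)", {
  set.seed(52)
  for (rep in 1:200) {
    n <- sample(2:12, 1)
    refseq <- rand_seq(400)
    truth <- rand_calls(refseq, n, p_indel = 0.5, min_gap = sample(3:12, 1))
    ex <- build_exclusions(truth, window = 10)
    expect_identical(granges_bases(ex), oracle_exclusion_bases(truth, 10))
  }
})

test_that("true-negative base counting follows the definition", {
  reg <- whole_region(1000)
  none <- varbench:::empty_truth()
  expect_identical(count_true_negatives(reg, none, none), 1000L)
  one <- data.frame(chrom = "c1", pos = 500L, ref = "A", alt = "G",
                    stringsAsFactors = FALSE)
  expect_identical(count_true_negatives(reg, one, one), 999L)
  expect_identical(count_true_negatives(reg, one, none), 999L)
})

test_that("compare reproduces identity and dropout perturbations", {
  set.seed(53)
  refseq <- rand_seq(20000)
  truth <- rand_calls(refseq, 120, with_scores = TRUE)
  reg <- whole_region(20000)
  cmp <- compare_calls(truth, truth, reg, exclusions = GenomicRanges::GRanges())
  expect_identical(cmp$fp, 0L)
  expect_identical(cmp$fn, 0L)
  expect_identical(cmp$tp, 120L)
  m <- call_metrics(cmp)
  expect_equal(m$precision, 1)
  expect_equal(m$sensitivity, 1)
  drop <- sample(120, 10)
  cmp2 <- compare_calls(truth[-drop, ], truth, reg,
                        exclusions = GenomicRanges::GRanges())
  expect_identical(cmp2$fn, 10L)
  expect_identical(cmp2$tp, 110L)
  expect_identical(cmp2$fp, 0L)
})

test_that("genotype-aware matching splits a zygosity error into FP + FN", {
  truth <- data.frame(chrom = "c1", pos = 10L, ref = "A", alt = "G",
                      genotype = "het", vclass = "SNP", stringsAsFactors = FALSE)
  test <- truth; test$genotype <- "hom-alt"
  reg <- whole_region(100)
  cmp <- compare_calls(test, truth, reg, exclusions = GenomicRanges::GRanges())
  expect_identical(c(cmp$tp, cmp$fp, cmp$fn), c(0L, 1L, 1L))
  cmp2 <- compare_calls(test, truth, reg, exclusions = GenomicRanges::GRanges(),
                        genotype_aware = FALSE)
  expect_identical(c(cmp2$tp, cmp2$fp, cmp2$fn), c(1L, 0L, 0L))
})

test_that("compare matches the per-site enumeration oracle (>=200 cases)", {
  set.seed(54)
  for (rep in 1:200) {
    L <- 2000L
    refseq <- rand_seq(L)
    n_truth <- sample(3:15, 1)
    truth <- rand_calls(refseq, n_truth, min_gap = sample(10:40, 1))
    # test set: subset of truth + extra calls (some genotype-flipped)
    keep <- runif(n_truth) < 0.7
    test <- truth[keep, , drop = FALSE]
    flip <- runif(nrow(test)) < 0.2
    test$genotype[flip] <- ifelse(test$genotype[flip] == "het", "hom-alt", "het")
    extra <- rand_calls(rand_seq(L), sample(1:6, 1), min_gap = 25L)
    extra$pos <- extra$pos + 7L  # decouple from truth positions
    extra <- extra[!extra$pos %in% truth$pos, , drop = FALSE]
    test <- rbind(test, extra)
    reg_gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(
      c(1, 1001), c(sample(500:900, 1), sample(1500:2000, 1))))
    excl_gr <- build_exclusions(truth, 10)
    gta <- runif(1) < 0.5
    cmp <- compare_calls(test, truth, reg_gr, exclusions = excl_gr,
                         genotype_aware = gta)
    exp <- oracle_compare(test, truth, granges_bases(reg_gr),
                          granges_bases(excl_gr), genotype_aware = gta)
    expect_identical(cmp$tp, exp$tp)
    expect_identical(cmp$fp, exp$fp)
    expect_identical(cmp$fn, exp$fn)
    expect_identical(cmp$tn, exp$tn)
    # conservation identities
    expect_identical(cmp$tp + cmp$fn, nrow(truth) - cmp$excluded_truth)
    expect_identical(cmp$tp + cmp$fp, nrow(test) - cmp$excluded_test)
  }
})

test_that("enlarging the exclusion set never increases FP or FN", {
  set.seed(55)
  refseq <- rand_seq(5000)
  truth <- rand_calls(refseq, 40, p_indel = 0.5, min_gap = 8L)
  test <- truth[sample(40, 30), ]
  reg <- whole_region(5000)
  prev_fp <- Inf; prev_fn <- Inf
  for (w in c(0, 5, 10, 25, 60)) {
    ex <- if (w == 0) GenomicRanges::GRanges() else build_exclusions(truth, w)
    cmp <- compare_calls(test, truth, reg, exclusions = ex)
    expect_lte(cmp$fp, prev_fp)
    expect_lte(cmp$fn, prev_fn)
    prev_fp <- cmp$fp; prev_fn <- cmp$fn
  }
})

test_that("metric ratios follow the formulas, with 0/0 absent", {
  m <- call_metrics(list(tp = 9, fp = 1, fn = 1, tn = 990))
  expect_equal(m$precision, 0.9)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 990 / 991)
  m0 <- call_metrics(list(tp = 0, fp = 0, fn = 3, tn = 100))
  expect_true(is.na(m0$precision))
  expect_equal(m0$sensitivity, 0)
  set.seed(56)
  for (rep in 1:50) {
    k <- as.list(stats::setNames(sample(0:30, 4, TRUE), c("tp", "fp", "fn", "tn")))
    m <- call_metrics(k)
    expect_equal(m$precision,
                 if (k$tp + k$fp == 0) NA_real_ else k$tp / (k$tp + k$fp))
    expect_equal(m$sensitivity,
                 if (k$tp + k$fn == 0) NA_real_ else k$tp / (k$tp + k$fn))
    expect_equal(m$specificity,
                 if (k$tn + k$fp == 0) NA_real_ else k$tn / (k$tn + k$fp))
  }
})

test_that("quality ROC separates scores and reproduces overall metrics", {
  truth <- data.frame(chrom = "c1", pos = c(10L, 30L, 50L), ref = "A",
                      alt = "G", genotype = "het", vclass = "SNP",
                      stringsAsFactors = FALSE)
  test <- rbind(truth[1:2, ], within(truth[3, ], pos <- 70L))
  test$quality <- c(100, 100, 10)
  test$depth <- 20L
  cmp <- compare_calls(test, truth, whole_region(1000),
                       exclusions = GenomicRanges::GRanges())
  roc <- quality_roc(cmp)
  top <- roc[roc$threshold == 100, ]
  expect_equal(top$fp, 0)
  expect_equal(top$tpr, 2 / 3)
  expect_equal(top$fpr, 0)
  # lowest threshold reproduces the unthresholded comparison
  bottom <- roc[nrow(roc), ]
  expect_equal(c(bottom$tp, bottom$fp, bottom$fn, bottom$tn),
               c(cmp$tp, cmp$fp, cmp$fn, cmp$tn))
})

test_that("quality ROC matches a brute-force sweep (>=200 cases)", {
  set.seed(57)
  for (rep in 1:200) {
    cmp <- rand_comparison(missing_quality = runif(1) < 0.3)
    roc <- quality_roc(cmp)
    qt <- cmp$tp_records$quality
    qf <- cmp$fp_records$quality
    for (i in seq_len(nrow(roc))) {
      t <- roc$threshold[i]
      tp <- if (t == -Inf) length(qt) else sum(!is.na(qt) & qt >= t)
      fp <- if (t == -Inf) length(qf) else sum(!is.na(qf) & qf >= t)
      expect_equal(roc$tp[i], tp)
      expect_equal(roc$fp[i], fp)
      expect_equal(roc$fn[i], cmp$fn + (cmp$tp - tp))
      expect_equal(roc$tn[i], cmp$tn + (cmp$fp - fp))
      expect_equal(roc$tpr[i], tp / (tp + roc$fn[i]))
    }
    # lowest-threshold consistency and monotone cumulative counts
    expect_equal(roc$tp[nrow(roc)], cmp$tp)
    expect_equal(roc$fp[nrow(roc)], cmp$fp)
    expect_false(is.unsorted(roc$tp))
    expect_false(is.unsorted(roc$fp))
  }
})

test_that("depth stratification bins TP/FP and matches a naive oracle", {
  set.seed(58)
  cmp <- rand_comparison(n = 40)
  cmp$tp_records$depth <- 35L
  cmp$fp_records$depth <- 35L
  s <- stratify_by_depth(cmp, c(0, 10, 20, 30, 100))
  expect_identical(s$tp[4], cmp$tp)
  expect_identical(s$fp[4], cmp$fp)
  expect_equal(s$precision[4], call_metrics(cmp)$precision)
  expect_true(all(s$tp[-4] == 0L))

  for (rep in 1:30) {
    cmp <- rand_comparison()
    edges <- sort(sample(0:100, sample(3:6, 1)))
    s <- stratify_by_depth(cmp, edges)
    oracle_bin <- function(d) {
      found <- rep(NA_integer_, length(d))
      for (b in seq_len(length(edges) - 1))
        found[!is.na(d) & d >= edges[b] & d < edges[b + 1]] <- b
      found
    }
    bt <- oracle_bin(cmp$tp_records$depth)
    bf <- oracle_bin(cmp$fp_records$depth)
    known <- s[!is.na(s$lo), ]
    expect_identical(known$tp, tabulate(bt, length(edges) - 1))
    expect_identical(known$fp, tabulate(bf, length(edges) - 1))
    unk <- s[is.na(s$lo), ]
    if (nrow(unk))
      expect_identical(unk$tp + unk$fp, sum(is.na(bt)) + sum(is.na(bf)))
  }
  expect_error(stratify_by_depth(cmp, c(10, 10, 20)), "increasing")
  empty <- compare_calls(varbench:::empty_truth(), varbench:::empty_truth(),
                         whole_region(100),
                         exclusions = GenomicRanges::GRanges())
  expect_identical(nrow(stratify_by_depth(empty)), 0L)
})

test_that("simulated truth round-trips through VCF into a perfect comparison", {
  ref <- generate_reference(100000, seed = 61)
  g <- mutate_diploid(ref, mutation_model(), seed = 62)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_truth(g$truth, stats::setNames(ref$length, ref$name), vcf, bed)
  truth <- normalize_calls(read_truth_vcf(vcf), ref)
  cmp <- compare_calls(truth, truth, read_regions(bed))
  m <- call_metrics(cmp)
  expect_equal(m$precision, 1)
  expect_equal(m$sensitivity, 1)
  expect_identical(cmp$tp + cmp$excluded_truth, nrow(g$truth))
})
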