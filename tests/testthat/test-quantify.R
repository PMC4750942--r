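# helper: write a FASTQ from parallel read/quality strings
writeFastq <- function(reads, quals, path,
                       ids = sprintf("r%03d", seq_along(reads))) {
  writeLines(as.vector(rbind(paste0("@", ids), reads, "+", quals)), path)
  path
}

test_that("read QC applies masking, length, mismatch and multi-hit rules", {
  ref <- paste(rep(c("ACGT", "TGCA", "GGAT", "CCTA", "AACG", "TTGC",
                     "GATC", "CTAG", "AGGC", "TCCG"), 3), collapse = "")
  seqs <- Biostrings::DNAStringSet(c(f1 = ref))
  q40 <- strrep("I", 40)
  d <- withr::local_tempdir()
  # exact 40 nt substring, all Phred >= 20: one count
  f <- writeFastq(substr(ref, 11, 50), q40, file.path(d, "a.fastq"))
  out <- qcAndCountReads(c(media_1 = f), seqs)
  expect_equal(unname(counts(out$counts)["f1", ]), 1L)
  expect_equal(out$qc$total_valid_reads, 1L)
  # 24 nt read is below the 25 nt minimum: discarded
  f <- writeFastq(substr(ref, 1, 24), strrep("I", 24),
                  file.path(d, "b.fastq"))
  out <- qcAndCountReads(c(media_1 = f), seqs)
  expect_equal(out$qc$discarded_by_length, 1L)
  expect_equal(sum(counts(out$counts)), 0)
  # 3 masked bases against an otherwise exact match: 3 mismatches > 2
  qual <- paste0(strrep("#", 3), strrep("I", 37))  # '#' is Phred 2
  f <- writeFastq(substr(ref, 11, 50), qual, file.path(d, "c.fastq"))
  out <- qcAndCountReads(c(media_1 = f), seqs)
  expect_equal(sum(counts(out$counts)), 0)
  expect_equal(out$qc$unmatched, 1L)
  expect_gt(out$qc$masked_base_fraction, 0)
  # a read matching 11 features is discarded (> 10 hits)
  seqs11 <- Biostrings::DNAStringSet(
    setNames(rep(substr(ref, 1, 60), 11), paste0("g", 1:11)))
  f <- writeFastq(substr(ref, 5, 44), q40, file.path(d, "d.fastq"))
  out <- qcAndCountReads(c(media_1 = f), seqs11)
  expect_equal(out$qc$discarded_by_multihit, 1L)
  expect_equal(sum(counts(out$counts)), 0)
  # ... but 11 hits still count under max_hits = 11, once per feature
  out <- qcAndCountReads(c(media_1 = f), seqs11, max_hits = 11)
  expect_true(all(counts(out$counts) == 1))
  # and not at all under the unique-only convention
  out <- qcAndCountReads(c(media_1 = f), seqs11, max_hits = 11,
                         multihit = "unique")
  expect_equal(sum(counts(out$counts)), 0)
})

test_that("counter equals the brute-force matcher on random fixtures", {
  set.seed(31)
  bases <- c("A", "C", "G", "T")
  nfeat <- 20
  seq_chr <- vapply(sample(60:200, nfeat, replace = TRUE), function(n)
    paste(sample(bases, n, replace = TRUE), collapse = ""), "")
  names(seq_chr) <- sprintf("f%02d", seq_len(nfeat))
  seqs <- Biostrings::DNAStringSet(seq_chr)
  # reads: substrings with random errors, plus unrelated junk, with a
  # mixed-quality profile so masking matters
  n_reads <- 120
  reads <- character(n_reads); quals <- character(n_reads)
  for (i in seq_len(n_reads)) {
    if (i %% 5 == 0) {
      rd <- paste(sample(bases, 40, replace = TRUE), collapse = "")
    } else {
      s <- sample(nfeat, 1)
      off <- sample(nchar(seq_chr[s]) - 39, 1)
      rd <- substr(seq_chr[s], off, off + 39)
      ch <- strsplit(rd, "")[[1]]
      nerr <- sample(0:3, 1)
      if (nerr) {
        at <- sample(40, nerr)
        ch[at] <- sample(bases, nerr, replace = TRUE)
      }
      rd <- paste(ch, collapse = "")
    }
    q <- ifelse(runif(40) < 0.03, 2L, 38L)
    reads[i] <- rd
    quals[i] <- intToUtf8(q + 33L)
  }
  d <- withr::local_tempdir()
  f <- writeFastq(reads, quals, file.path(d, "x.fastq"))
  out <- qcAndCountReads(c(media_1 = f), seqs)
  oracle <- bruteMatchCounts(reads, quals, seq_chr)
  expect_equal(unname(counts(out$counts)[, 1]), unname(oracle$counts))
  expect_equal(out$qc$total_valid_reads, oracle$valid)
})

test_that("FPKM follows its closed form and scaling identities", {
  m <- matrix(c(100L, 0L), nrow = 2,
              dimnames = list(c("f1", "f2"), "media_1"))
  models <- GeneModels(
    genes = data.frame(gene_id = "G1", chrom = "c", strand = "+",
                       biotype = "mRNA", marker_class = "none"),
    features = data.frame(feature_id = c("f1", "f2"), gene_id = "G1",
                          kind = "exon", effective_length = 1000L))
  libs <- data.frame(library_id = "media_1", condition = "media",
                     cell_type = "x", timepoint_h = 1,
                     total_valid_reads = 26e6)
  fc <- fpkmNormalize(FeatureCounts(m, libs), models)
  expect_equal(fpkm(fc)["f1", 1], 100 * 1e9 / (1000 * 26e6))
  expect_equal(fpkm(fc)["f2", 1], 0)
  libs2 <- libs; libs2$total_valid_reads <- 52e6
  fc2 <- fpkmNormalize(FeatureCounts(m, libs2), models)
  expect_equal(fpkm(fc2)["f1", 1], fpkm(fc)["f1", 1] / 2)
  # linear in counts, inverse-linear in length, on random instances
  set.seed(7)
  for (i in 1:5) {
    cnt <- matrix(rpois(8, 50), nrow = 4,
                  dimnames = list(paste0("f", 1:4), c("media_1", "iron_1")))
    len <- sample(100:2000, 4)
    mods <- GeneModels(
      genes = data.frame(gene_id = "G1", chrom = "c", strand = "+",
                         biotype = "mRNA", marker_class = "none"),
      features = data.frame(feature_id = paste0("f", 1:4), gene_id = "G1",
                            kind = "exon", effective_length = len))
    fcr <- fpkmNormalize(makeTinyCounts(cnt, 1e6), mods)
    expect_equal(fpkm(fcr), cnt * 1e9 / (len %o% rep(1e6, 2)))
  }
  expect_error(fpkmNormalize(FeatureCounts(m[1, , drop = FALSE], libs),
                             makeOneGeneModels(1)),
               "absent from models")
})

test_that("species profile shares sum to one and handle empty libraries", {
  genes <- data.frame(gene_id = c("Gm", "Gr"), chrom = "c",
                      strand = "+", biotype = c("mRNA", "rRNA"),
                      marker_class = "none")
  feats <- data.frame(feature_id = c("fm", "fr"),
                      gene_id = c("Gm", "Gr"), kind = "exon",
                      effective_length = 1000L)
  models <- GeneModels(genes, feats)
  cnt <- matrix(c(50L, 50L, 0L, 0L), nrow = 2,
                dimnames = list(c("fm", "fr"), c("media_1", "iron_1")))
  fc <- fpkmNormalize(makeTinyCounts(cnt, 1e6), models)
  sp <- speciesProfile(fc, models)
  m1 <- sp[sp$library_id == "media_1", ]
  expect_equal(sort(m1$share), c(0.5, 0.5))   # equal FPKM mass
  expect_equal(sum(m1$share), 1)
  i1 <- sp[sp$library_id == "iron_1", ]
  expect_true(all(is.na(i1$share)))           # all-zero library
  expect_equal(sum(i1$fpkm_total), 0)
  # single-biotype universe: share exactly 1
  sp1 <- speciesProfile(fc[1, ], models)
  expect_equal(sp1$share[sp1$library_id == "media_1"], 1)
})

test_that("marker specificity flags and ratios behave at the limits", {
  genes <- data.frame(gene_id = c("E", "N"), chrom = "c", strand = "+",
                      biotype = "mRNA",
                      marker_class = c("endothelial", "non_endothelial"))
  feats <- data.frame(feature_id = c("fe", "fn"), gene_id = c("E", "N"),
                      kind = "exon", effective_length = 1000L)
  models <- GeneModels(genes, feats)
  cnt <- matrix(c(1000L, 10L), nrow = 2, ncol = 1,
                dimnames = list(c("fe", "fn"), "media_1"))
  libs <- makeLibraries(1e6)[1, ]
  fc <- fpkmNormalize(FeatureCounts(cnt, libs), models)
  ms <- markerSpecificity(fc, models)
  expect_equal(ms$ratio, 100)       # 100x by construction
  expect_true(ms$pass)
  cnt2 <- matrix(c(10L, 10L), nrow = 2, ncol = 1,
                 dimnames = list(c("fe", "fn"), "media_1"))
  ms2 <- markerSpecificity(fpkmNormalize(FeatureCounts(cnt2, libs),
                                         models), models)
  expect_equal(ms2$ratio, 1)
  expect_false(ms2$pass)
  cnt3 <- matrix(c(10L, 0L), nrow = 2, ncol = 1,
                 dimnames = list(c("fe", "fn"), "media_1"))
  ms3 <- markerSpecificity(fpkmNormalize(FeatureCounts(cnt3, libs),
                                         models), models)
  expect_equal(ms3$ratio, Inf)
  expect_true(ms3$pass)
  models_no <- GeneModels(transform(genes, marker_class = "none"), feats)
  expect_error(markerSpecificity(fc, models_no), "marker class")
})

test_that("error-free simulated reads recount to the exact matrix", {
  u <- simulateUniverse(10, dispersion = 0, seed = 21)
  fc <- simulateCounts(u$models, u$truth, makeLibraries(30000), seed = 22)
  rd <- simulateReads(u$models, fc, dir = withr::local_tempdir(),
                      seed = 23)
  rc <- qcAndCountReads(rd$fastq, rd$sequences)
  expect_identical(
    counts(rc$counts)[rownames(counts(fc)), colnames(counts(fc))],
    counts(fc))
  expect_equal(rc$qc$unmatched, c(0L, 0L))
})
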