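# Independent brute-force oracles. These deliberately avoid the code paths
# they check: direct PMF summation, exhaustive enumeration, and naive
# character-level matching.

# Upper-tail hypergeometric P(X >= k - 1) by direct PMF summation
bruteEaseP <- function(k, n, K, N) {
  if (k == 0) return(1)
  pmf <- function(i) choose(K, i) * choose(N - K, n - i) / choose(N, n)
  min(1, sum(vapply(max(0, k - 1):min(n, K), pmf, 0)))
}

# Benjamini-Hochberg step-up, written from the definition
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, m / i * p[o[i]])
    q[o[i]] <- prev
  }
  pmin(q, 1)
}

# Two-sided F p from numerical integration of the density (larger/smaller
# variance ratio with matching dfs)
bruteFP <- function(x, y) {
  vx <- var(x); vy <- var(y)
  if (vx >= vy) {
    f <- vx / vy; d1 <- length(x) - 1; d2 <- length(y) - 1
  } else {
    f <- vy / vx; d1 <- length(y) - 1; d2 <- length(x) - 1
  }
  up <- integrate(function(q) df(q, d1, d2), lower = f, upper = Inf,
                  rel.tol = 1e-10)$value
  min(1, 2 * up)
}

# Exact two-sided Mann-Whitney p by exhaustive enumeration over all
# choose(n1 + n2, n1) group assignments of the pooled sample
bruteMWp <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  rk <- rank(pooled)
  wObs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(length(pooled), n1)
  wAll <- apply(idx, 2, function(i) sum(rk[i]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(y) / 2
  p <- if (wObs > mu) mean(wAll >= wObs) else mean(wAll <= wObs)
  min(1, 2 * p)
}

# Naive character-level read counter mirroring the QC contract: mask low
# quality to N, drop short reads, hit = any offset with <= max_mm
# mismatches (N always mismatches), drop > max_hits
bruteMatchCounts <- function(reads, quals, seqs, phred_min = 20,
                             max_mm = 2, min_len = 25, max_hits = 10) {
  counts <- setNames(integer(length(seqs)), names(seqs))
  valid <- 0L
  for (r in seq_along(reads)) {
    rd <- strsplit(reads[r], "")[[1]]
    q <- utf8ToInt(quals[r]) - 33L
    rd[q < phred_min] <- "N"
    if (length(rd) < min_len) next
    valid <- valid + 1L
    hits <- integer(0)
    for (s in seq_along(seqs)) {
      sq <- strsplit(seqs[s], "")[[1]]
      hit <- FALSE
      if (length(sq) >= length(rd)) {
        for (off in 0:(length(sq) - length(rd))) {
          mm <- sum(rd != sq[off + seq_along(rd)])
          if (mm <= max_mm) { hit <- TRUE; break }
        }
      }
      if (hit) hits <- c(hits, s)
    }
    if (length(hits) >= 1 && length(hits) <= max_hits)
      counts[hits] <- counts[hits] + 1L
  }
  list(counts = counts, valid = valid)
}

# Tiny two-library FeatureCounts built directly from a count matrix
makeTinyCounts <- function(counts, depth = NULL) {
  if (is.null(depth)) depth <- max(1L, max(colSums(counts)))
  FeatureCounts(counts, data.frame(
    library_id = colnames(counts),
    condition = c("media", "iron")[seq_len(ncol(counts))],
    cell_type = "HUVEC", timepoint_h = 1,
    total_valid_reads = as.integer(depth), stringsAsFactors = FALSE))
}

# Hand-built gene with ne exons (+ ne - 1 junctions) for vector tests
makeOneGeneModels <- function(ne = 3, exon_len = 300L, junc_len = 40L,
                              gene_id = "G1", strand = "+") {
  feats <- data.frame(
    feature_id = c(sprintf("%s.e%d", gene_id, seq_len(ne)),
                   if (ne > 1) sprintf("%s.j%d", gene_id,
                                       seq_len(ne - 1))),
    gene_id = gene_id,
    kind = c(rep("exon", ne), rep("junction", max(0, ne - 1))),
    effective_length = c(rep(exon_len, ne),
                         rep(junc_len, max(0, ne - 1))),
    stringsAsFactors = FALSE)
  GeneModels(
    genes = data.frame(gene_id = gene_id, chrom = "chr1", strand = strand,
                       biotype = "mRNA", marker_class = "none",
                       stringsAsFactors = FALSE),
    features = feats)
}
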