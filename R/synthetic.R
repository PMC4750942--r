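#' Simulate a gene universe with known ground truth
#'
#' Builds a synthetic annotation emulating the structure the pipeline was
#' designed for: a mix of RNA biotypes, mRNA genes carrying exon features
#' plus one junction per adjacent exon pair (`n_exons - 1` junctions),
#' miRNA genes carrying a single stem-loop feature, and a balanced panel
#' of endothelial / non-endothelial marker genes whose true abundances
#' differ by a large, known factor. Alongside the models a truth table
#' records each gene's true abundance (FPKM), iron-vs-media fold change,
#' and negative-binomial dispersion, so downstream stages have
#' parameter-recovery tests.
#'
#' @param n_genes number of genes (>= 1).
#' @param feature_count list with `mean_exons` (Poisson mean above the
#'   minimum) and `min_exons` for mRNA genes.
#' @param biotype_mix named proportions over
#'   `mRNA, miRNA, rRNA, lincRNA, other`; must sum to 1.
#' @param n_marker_pairs number of endothelial/non-endothelial marker
#'   gene pairs (equal counts of each class).
#' @param de_fraction fraction of non-marker genes given a spiked fold
#'   change (`is_de` in the truth table).
#' @param de_fold fold change (iron vs media) applied to spiked genes;
#'   may be a vector, recycled over the spiked genes.
#' @param dispersion negative-binomial dispersion shared by all genes
#'   (0 gives Poisson counts).
#' @param base_fpkm_meanlog,base_fpkm_sdlog log-normal parameters of true
#'   gene abundance.
#' @param marker_fpkm_high,marker_fpkm_low fixed true FPKM for
#'   endothelial and non-endothelial marker genes (ratio 100 by default).
#' @param exon_length_range integer range (bp) of exon effective lengths.
#' @param junction_length effective length (bp) of junctions and
#'   stem-loops; defaults to the 40 nt read length.
#' @param seed integer seed; identical seeds give identical universes.
#' @return list with elements `models` ([GeneModels-class]) and `truth`
#'   (data.frame: `gene_id`, `base_fpkm`, `fold_change`, `dispersion`,
#'   `is_de`; the seed is kept in `attr(truth, "seed")`).
#' @export
simulateUniverse <- function(n_genes,
                             feature_count = list(mean_exons = 6,
                                                  min_exons = 2),
                             biotype_mix = c(mRNA = 0.55, miRNA = 0.15,
                                             rRNA = 0.05, lincRNA = 0.15,
                                             other = 0.10),
                             n_marker_pairs = 0,
                             de_fraction = 0,
                             de_fold = 4,
                             dispersion = 0.05,
                             base_fpkm_meanlog = log(10),
                             base_fpkm_sdlog = 1.2,
                             marker_fpkm_high = 200,
                             marker_fpkm_low = 2,
                             exon_length_range = c(120L, 1500L),
                             junction_length = 40L,
                             seed = 1L) {
  stopifnot(n_genes >= 1)
  if (any(biotype_mix < 0) || abs(sum(biotype_mix) - 1) > 1e-8 ||
      !all(names(biotype_mix) %in% .BIOTYPES))
    stop("biotype_mix must be nonnegative proportions over known biotypes summing to 1")
  if (2 * n_marker_pairs > n_genes)
    stop("need at least 2 * n_marker_pairs genes")
  set.seed(seed)
  gene_id <- sprintf("G%05d", seq_len(n_genes))
  biotype <- sample(names(biotype_mix), n_genes, replace = TRUE,
                    prob = biotype_mix)
  marker_class <- rep("none", n_genes)
  if (n_marker_pairs > 0) {
    marker_class[seq_len(n_marker_pairs)] <- "endothelial"
    marker_class[n_marker_pairs + seq_len(n_marker_pairs)] <- "non_endothelial"
  }
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  feats <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    bt <- biotype[i]
    if (bt == "mRNA") {
      ne <- feature_count$min_exons +
        stats::rpois(1, max(0, feature_count$mean_exons -
                              feature_count$min_exons))
      elen <- sample(seq(exon_length_range[1], exon_length_range[2]), ne,
                     replace = TRUE)
      fid <- c(sprintf("%s.e%02d", gene_id[i], seq_len(ne)),
               if (ne > 1) sprintf("%s.j%02d", gene_id[i], seq_len(ne - 1)))
      feats[[i]] <- data.frame(
        feature_id = fid, gene_id = gene_id[i],
        kind = c(rep("exon", ne), rep("junction", max(0, ne - 1))),
        effective_length = c(elen,
                             rep(junction_length, max(0, ne - 1))),
        stringsAsFactors = FALSE)
    } else if (bt == "miRNA") {
      feats[[i]] <- data.frame(
        feature_id = sprintf("%s.sl", gene_id[i]), gene_id = gene_id[i],
        kind = "stem_loop",
        effective_length = sample(60:120, 1),
        stringsAsFactors = FALSE)
    } else {
      ne <- sample(1:3, 1)
      feats[[i]] <- data.frame(
        feature_id = sprintf("%s.e%02d", gene_id[i], seq_len(ne)),
        gene_id = gene_id[i], kind = "exon",
        effective_length = sample(seq(exon_length_range[1],
                                      exon_length_range[2]), ne,
                                  replace = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  models <- GeneModels(
    genes = data.frame(gene_id = gene_id,
                       chrom = paste0("chr", 1 + (seq_len(n_genes) %% 22)),
                       strand = strand, biotype = biotype,
                       marker_class = marker_class,
                       stringsAsFactors = FALSE),
    features = do.call(rbind, feats))
  base_fpkm <- stats::rlnorm(n_genes, base_fpkm_meanlog, base_fpkm_sdlog)
  base_fpkm[marker_class == "endothelial"] <- marker_fpkm_high
  base_fpkm[marker_class == "non_endothelial"] <- marker_fpkm_low
  fold_change <- rep(1, n_genes)
  eligible <- which(marker_class == "none")
  n_de <- round(de_fraction * length(eligible))
  if (n_de > 0) {
    de_idx <- sample(eligible, n_de)
    fold_change[de_idx] <- rep_len(de_fold, n_de)
  }
  truth <- data.frame(gene_id = gene_id, base_fpkm = base_fpkm,
                      fold_change = fold_change, dispersion = dispersion,
                      is_de = fold_change != 1, stringsAsFactors = FALSE)
  attr(truth, "seed") <- seed
  list(models = models, truth = truth)
}

#' Default two-library study design
#'
#' One media and one iron library at a shared timepoint, mirroring a
#' single-library-per-condition design in which a gene's exon/junction
#' features, not libraries, are the replicates of the downstream test.
#'
#' @param depth total valid reads per library.
#' @param cell_type,timepoint_h library metadata.
#' @return data.frame of library metadata suitable for [FeatureCounts()].
#' @export
makeLibraries <- function(depth = 5e5, cell_type = "HDMEC",
                          timepoint_h = 1) {
  data.frame(library_id = c("media_1", "iron_1"),
             condition = c("media", "iron"), cell_type = cell_type,
             timepoint_h = timepoint_h,
             total_valid_reads = as.integer(depth),
             stringsAsFactors = FALSE)
}

#' Simulate feature counts from a truth table
#'
#' Inverts the FPKM definition to get each feature's expected count,
#' `mu = fpkm * effective_length/1e3 * total_valid_reads/1e6`, applying
#' the gene's fold change in iron libraries, then draws negative-binomial
#' counts with the gene's dispersion (Poisson when dispersion is 0).
#'
#' @param models A [GeneModels-class] object.
#' @param truth truth table from [simulateUniverse()].
#' @param libraries library metadata data.frame (see [makeLibraries()]).
#' @param seed integer seed.
#' @return A [FeatureCounts-class] object.
#' @export
simulateCounts <- function(models, truth, libraries, seed = 1L) {
  stopifnot(all(c("library_id", "condition",
                  "total_valid_reads") %in% names(libraries)))
  set.seed(seed)
  f <- featureTable(models)
  ti <- match(f$gene_id, truth$gene_id)
  if (anyNA(ti)) stop("truth table missing genes present in models")
  counts <- matrix(0L, nrow(f), nrow(libraries),
                   dimnames = list(f$feature_id, libraries$library_id))
  for (j in seq_len(nrow(libraries))) {
    fc <- if (libraries$condition[j] == "iron")
      truth$fold_change[ti] else 1
    mu <- truth$base_fpkm[ti] * fc * (f$effective_length / 1e3) *
      (libraries$total_valid_reads[j] / 1e6)
    if (any(mu > 2^31 - 1)) stop("expected count overflow (mu too large)")
    disp <- truth$dispersion[ti]
    x <- numeric(length(mu))
    pois <- disp == 0 | mu == 0
    x[pois] <- stats::rpois(sum(pois), mu[pois])
    if (any(!pois))
      x[!pois] <- stats::rnbinom(sum(!pois), mu = mu[!pois],
                                 size = 1 / disp[!pois])
    counts[, j] <- as.integer(x)
  }
  FeatureCounts(counts, libraries)
}

.PHRED33 <- function(q) intToUtf8(q + 33L, multiple = FALSE)

#' Simulate strand-specific reads as FASTQ
#'
#' Draws, for every count cell, that many fixed-length reads from a
#' random gene-strand sequence assigned to the feature, with optional
#' uniform base errors and a two-state (high/low) Phred quality profile
#' so the Phred-masking QC path is exercised. Reads are written per
#' library as Sanger Phred+33 FASTQ.
#'
#' @param models A [GeneModels-class] object.
#' @param fc A [FeatureCounts-class] object giving the per-feature read
#'   numbers to emit.
#' @param dir output directory for `<library_id>.fastq` files.
#' @param read_length read length in nt (default 40).
#' @param per_base_error probability a base is substituted.
#' @param quality_profile list: `p_low` per-base probability of the low
#'   state, `q_high`/`q_low` the two Phred scores.
#' @param seed integer seed; fixed seed gives byte-identical FASTQ.
#' @return list: `fastq` (named paths), `sequences`
#'   (a [Biostrings::DNAStringSet] of feature sequences, needed by
#'   [qcAndCountReads()]).
#' @importFrom Biostrings DNAStringSet BStringSet writeXStringSet
#' @export
simulateReads <- function(models, fc, dir = tempdir(), read_length = 40L,
                          per_base_error = 0,
                          quality_profile = list(p_low = 0, q_high = 38L,
                                                 q_low = 11L),
                          seed = 1L) {
  set.seed(seed)
  f <- featureTable(models)
  if (any(f$effective_length < read_length))
    stop("read_length exceeds some feature effective lengths")
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(f$effective_length, function(n)
    paste(sample(bases, n, replace = TRUE), collapse = ""), "")
  names(seqs) <- f$feature_id
  cnt <- counts(fc)
  paths <- character(0)
  for (lib in colnames(cnt)) {
    n_reads <- cnt[, lib]
    total <- sum(n_reads)
    reads <- character(total)
    quals <- character(total)
    ids <- character(total)
    pos <- 0L
    for (i in which(n_reads > 0)) {
      k <- n_reads[i]
      maxoff <- f$effective_length[i] - read_length
      offs <- if (maxoff > 0) sample.int(maxoff + 1L, k, replace = TRUE) - 1L
              else rep(0L, k)
      for (r in seq_len(k)) {
        s <- substr(seqs[i], offs[r] + 1L, offs[r] + read_length)
        if (per_base_error > 0) {
          hit <- which(stats::runif(read_length) < per_base_error)
          if (length(hit)) {
            ch <- strsplit(s, "")[[1]]
            ch[hit] <- sample(bases, length(hit), replace = TRUE)
            s <- paste(ch, collapse = "")
          }
        }
        q <- ifelse(stats::runif(read_length) < quality_profile$p_low,
                    quality_profile$q_low, quality_profile$q_high)
        reads[pos + r] <- s
        quals[pos + r] <- .PHRED33(as.integer(q))
        ids[pos + r] <- sprintf("%s:%s:%d", lib, f$feature_id[i], r)
      }
      pos <- pos + k
    }
    path <- file.path(dir, paste0(lib, ".fastq"))
    x <- DNAStringSet(reads)
    names(x) <- ids
    writeXStringSet(x, path, format = "fastq", qualities = BStringSet(quals))
    paths[lib] <- path
  }
  list(fastq = paths, sequences = DNAStringSet(seqs))
}

#' Simulate the qPCR / cellular-assay validation arm
#'
#' Ct values are tied log-linearly to true expression,
#' `ct = ct_intercept - ct_slope * log2(expression) + N(0, ct_noise_sd)`,
#' per replicate; expression in the iron sample is the gene's base
#' abundance times its fold change. Assay positives (comet tails,
#' pan-nuclear gamma-H2AX, DDR foci) are binomial draws with
#' group-specific rates.
#'
#' @param truth truth table from [simulateUniverse()].
#' @param genes target genes to assay (must include the two reference
#'   genes, which must have fold change 1).
#' @param reference_genes exactly 2 gene ids used downstream as the
#'   normalizer pair.
#' @param ct_intercept cycles at expression 1 (default 34).
#' @param ct_slope cycles lost per doubling of expression (default 1,
#'   i.e. amplification efficiency 2.0).
#' @param ct_noise_sd replicate Gaussian noise, cycles.
#' @param n_replicates technical replicates per well group (>= 2).
#' @param assay_rates named list per assay (`comet`, `pan_nuclear`,
#'   `ddr_foci`) of `c(media =, iron =)` positive-cell rates.
#' @param n_cells cells scored per group.
#' @param seed integer seed.
#' @return list: `plate` (data.frame `sample_id`, `gene_id`, `replicate`,
#'   `ct`) and `assays` (data.frame `assay`, `group`, `n_total`,
#'   `n_positive`).
#' @export
simulateValidationData <- function(truth, genes, reference_genes,
                                   ct_intercept = 34, ct_slope = 1,
                                   ct_noise_sd = 0.15, n_replicates = 2,
                                   assay_rates = list(
                                     comet = c(media = 0.08, iron = 0.25),
                                     pan_nuclear = c(media = 0.02,
                                                     iron = 0.10),
                                     ddr_foci = c(media = 0.10,
                                                  iron = 0.45)),
                                   n_cells = 300L, seed = 1L) {
  stopifnot(length(reference_genes) == 2, n_replicates >= 2)
  genes <- union(reference_genes, genes)
  ti <- match(genes, truth$gene_id)
  if (anyNA(ti)) stop("genes not in truth universe: ",
                      paste(genes[is.na(ti)], collapse = ", "))
  if (any(truth$fold_change[match(reference_genes, truth$gene_id)] != 1))
    stop("reference genes must have fold change 1")
  set.seed(seed)
  grid <- expand.grid(sample_id = c("media", "iron"), gene_id = genes,
                      replicate = seq_len(n_replicates),
                      stringsAsFactors = FALSE)
  gi <- match(grid$gene_id, truth$gene_id)
  expr <- truth$base_fpkm[gi] *
    ifelse(grid$sample_id == "iron", truth$fold_change[gi], 1)
  grid$ct <- ct_intercept - ct_slope * log2(expr) +
    stats::rnorm(nrow(grid), 0, ct_noise_sd)
  if (any(grid$ct <= 0 | grid$ct >= 45))
    stop("simulated Ct outside (0, 45); adjust intercept/slope")
  assays <- do.call(rbind, lapply(names(assay_rates), function(a)
    data.frame(assay = a, group = c("media", "iron"),
               n_total = as.integer(n_cells),
               n_positive = stats::rbinom(2, n_cells,
                                          assay_rates[[a]][c("media",
                                                             "iron")]),
               stringsAsFactors = FALSE)))
  list(plate = grid[order(grid$gene_id, grid$sample_id, grid$replicate), ],
       assays = assays)
}

#' Synthetic term-gene ontology
#'
#' Random term memberships over a gene universe, optionally with one
#' planted ("spiked") term containing a supplied gene set, for testing
#' enrichment and its random-set null control.
#'
#' @param gene_ids universe of gene ids.
#' @param n_terms number of random terms.
#' @param size_range integer range of term sizes.
#' @param spike_genes optional genes planted together as term `"SPIKED"`.
#' @param seed integer seed.
#' @return A [TermSets-class] object.
#' @export
makeSyntheticTermSets <- function(gene_ids, n_terms = 40,
                                  size_range = c(10L, 80L),
                                  spike_genes = NULL, seed = 1L) {
  set.seed(seed)
  sizes <- sample(seq(size_range[1], min(size_range[2], length(gene_ids))),
                  n_terms, replace = TRUE)
  sets <- lapply(sizes, function(k) sample(gene_ids, k))
  names(sets) <- sprintf("T%04d", seq_len(n_terms))
  desc <- stats::setNames(sprintf("random term %d", seq_len(n_terms)),
                          names(sets))
  if (!is.null(spike_genes)) {
    sets$SPIKED <- unique(spike_genes)
    desc["SPIKED"] <- "planted signal term"
  }
  TermSets(sets, desc)
}
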