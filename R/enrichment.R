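#' EASE-score hypergeometric tail probability
#'
#' The conservative one-tailed overrepresentation p used by DAVID-style
#' annotation scoring: the upper-tail hypergeometric probability
#' evaluated after removing one gene from the overlap (the "jackknifed"
#' Fisher p), i.e. `P(X >= k - 1)` for `X` hypergeometric with `n` draws
#' from `K` annotated among `N` universe genes. `k = 0` (and `k = 1`,
#' whose tail at 0 is the whole distribution) give p = 1.
#'
#' @param k overlap count (query genes annotated to the term).
#' @param n query list size.
#' @param K term size within the universe.
#' @param N universe size.
#' @return the EASE p-value (vectorized over its arguments).
#' @export
easeP <- function(k, n, K, N) {
  bad <- k < 0 | k > pmin(n, K) | n > N | K > N | n < 0 | K < 0
  if (any(bad)) stop("inconsistent counts for hypergeometric tail")
  p <- stats::phyper(k - 2, K, N - K, n, lower.tail = FALSE)
  p[k == 0] <- 1
  pmin(p, 1)
}

#' Multiple-testing adjustment for enrichment p-values
#'
#' Benjamini-Hochberg step-up q-values (monotone, capped at 1) or
#' Bonferroni `min(1, m * p)`, over the tested terms.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param method `"benjamini_hochberg"` or `"bonferroni"`.
#' @return adjusted p-values, same order as the input.
#' @export
adjustPvalues <- function(pvals,
                          method = c("benjamini_hochberg", "bonferroni")) {
  method <- match.arg(method)
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals,
                  method = switch(method, benjamini_hochberg = "BH",
                                  bonferroni = "bonferroni"))
}

#' Term enrichment of a gene list
#'
#' Scores every annotation term overlapping the query by its EASE p,
#' fold enrichment `(k/n) / (K/N)`, and both Benjamini-Hochberg and
#' Bonferroni adjustments computed over the tested (overlapping) terms.
#'
#' @param genes query gene ids (must be a subset of `universe`).
#' @param terms A [TermSets-class] object.
#' @param universe character vector of universe gene ids; term sets are
#'   intersected with it.
#' @return data.frame sorted by ascending `p_ease`: `term_id`, `name`,
#'   `k`, `n`, `K`, `N`, `fold_enrichment`, `p_ease`, `q_benjamini`,
#'   `p_bonferroni`. Empty when no term overlaps the query.
#' @export
enrichGeneList <- function(genes, terms, universe) {
  genes <- unique(genes)
  universe <- unique(universe)
  offenders <- setdiff(genes, universe)
  if (length(offenders))
    stop("query genes outside the universe: ",
         paste(utils::head(offenders, 5), collapse = ", "),
         if (length(offenders) > 5) " ...")
  if (length(terms) == 0) stop("empty annotation")
  sets <- lapply(termSets(terms), intersect, y = universe)
  Ks <- lengths(sets)
  ks <- vapply(sets, function(s) length(intersect(s, genes)), 0L)
  keep <- which(ks >= 1)
  n <- length(genes)
  N <- length(universe)
  if (length(keep) == 0)
    return(data.frame(term_id = character(0), name = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), fold_enrichment = numeric(0),
                      p_ease = numeric(0), q_benjamini = numeric(0),
                      p_bonferroni = numeric(0),
                      stringsAsFactors = FALSE))
  out <- data.frame(
    term_id = names(sets)[keep],
    name = unname(termDescription(terms)[keep]),
    k = unname(ks[keep]), n = n, K = unname(Ks[keep]), N = N,
    stringsAsFactors = FALSE)
  out$fold_enrichment <- (out$k / out$n) / (out$K / out$N)
  out$p_ease <- easeP(out$k, out$n, out$K, out$N)
  out$q_benjamini <- adjustPvalues(out$p_ease, "benjamini_hochberg")
  out$p_bonferroni <- adjustPvalues(out$p_ease, "bonferroni")
  out <- out[order(out$p_ease, out$term_id), ]
  rownames(out) <- NULL
  out
}

#' Cohen's kappa between two term membership vectors
#'
#' Agreement of two binary membership vectors beyond chance.
#' @param a,b logical vectors of equal length.
#' @return kappa in `[-1, 1]` (1 when either marginal is degenerate and
#'   the vectors agree everywhere; 0 when observed equals chance
#'   agreement).
#' @keywords internal
.cohenKappa <- function(a, b) {
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(!a) * mean(!b)
  if (pe == 1) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Kappa-based clustering of enriched terms
#'
#' Groups enriched terms whose gene memberships agree: pairwise Cohen's
#' kappa is computed on term-gene membership vectors restricted to the
#' query's genes, and terms with kappa at or above `kappa_threshold` to
#' at least one other member are merged by greedy single-linkage
#' agglomeration. Each cluster's enrichment score is the mean
#' `-log10(p_ease)` of its members; the representative term is the
#' member with the smallest EASE p. The cluster-level fold enrichment
#' is summarized as the member mean with an approximate t-based 95%
#' interval across member-term fold enrichments (NA for singletons).
#'
#' @param results enrichment table from [enrichGeneList()].
#' @param terms the [TermSets-class] used to build it.
#' @param genes the query gene list.
#' @param kappa_threshold linkage threshold (default 0.5).
#' @return data.frame, one row per cluster, sorted by descending
#'   enrichment score: `cluster`, `n_terms`, `members` (semicolon
#'   separated), `representative_term`, `enrichment_score`, `fold_mean`,
#'   `fold_ci_lo`, `fold_ci_hi`.
#' @export
clusterTerms <- function(results, terms, genes, kappa_threshold = 0.5) {
  if (nrow(results) == 0) stop("no enrichment results to cluster")
  genes <- unique(genes)
  ids <- results$term_id
  memb <- vapply(ids, function(t) genes %in% terms[[t]],
                 logical(length(genes)))
  memb <- matrix(memb, nrow = length(genes), ncol = length(ids),
                 dimnames = list(genes, ids))
  m <- length(ids)
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (m > 1) {
    for (i in seq_len(m - 1)) for (j in seq(i + 1, m)) {
      if (.cohenKappa(memb[, i], memb[, j]) >= kappa_threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(m), find, 0L)
  cl <- split(seq_len(m), roots)
  rows <- lapply(cl, function(idx) {
    sub <- results[idx, ]
    score <- mean(-log10(pmax(sub$p_ease, .Machine$double.xmin)))
    fe <- sub$fold_enrichment
    if (length(fe) >= 2 && stats::sd(fe) > 0) {
      half <- stats::qt(0.975, length(fe) - 1) * stats::sd(fe) /
        sqrt(length(fe))
      lo <- mean(fe) - half; hi <- mean(fe) + half
    } else if (length(fe) >= 2) {
      lo <- mean(fe); hi <- mean(fe)
    } else {
      lo <- NA_real_; hi <- NA_real_
    }
    data.frame(n_terms = nrow(sub),
               members = paste(sub$term_id, collapse = ";"),
               representative_term = sub$term_id[which.min(sub$p_ease)],
               enrichment_score = score, fold_mean = mean(fe),
               fold_ci_lo = lo, fold_ci_hi = hi,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$enrichment_score, out$representative_term), ]
  out <- data.frame(cluster = seq_len(nrow(out)), out,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Random-gene-set null control for enrichment
#'
#' Repeats the full enrichment run on gene sets of the query's size
#' sampled without replacement from a universe, summarizing the smallest
#' adjusted p over (optionally restricted) terms per replicate --
#' the negative control establishing that the query's enrichment does
#' not arise from list size alone.
#'
#' @param universe gene ids to sample from (the experiment's detected
#'   genes, or a RefSeq-scale background).
#' @param set_size genes per random set (the query size).
#' @param terms A [TermSets-class] object.
#' @param n_sets number of random sets (default 10).
#' @param adjust which adjusted p to summarize (`"benjamini_hochberg"`
#'   or `"bonferroni"`).
#' @param alpha significance level for the "any significant term" flag.
#' @param relevant_terms optional allow-list of term ids over which the
#'   per-replicate minimum is taken (default: all terms).
#' @param seed integer seed.
#' @return list: `replicates` (data.frame `replicate`, `min_adj_p`,
#'   `n_terms_tested`, `any_significant`) and `summary` (list `mean`,
#'   `sd`, `fraction_significant`, `n_sets`).
#' @export
randomSetControl <- function(universe, set_size, terms, n_sets = 10,
                             adjust = c("benjamini_hochberg",
                                        "bonferroni"),
                             alpha = 0.05, relevant_terms = NULL,
                             seed = 1L) {
  adjust <- match.arg(adjust)
  universe <- unique(universe)
  if (set_size > length(universe))
    stop("set_size exceeds universe size")
  set.seed(seed)
  col <- if (adjust == "benjamini_hochberg") "q_benjamini"
         else "p_bonferroni"
  reps <- lapply(seq_len(n_sets), function(r) {
    gs <- sample(universe, set_size)
    tab <- enrichGeneList(gs, terms, universe)
    if (!is.null(relevant_terms))
      tab <- tab[tab$term_id %in% relevant_terms, ]
    minp <- if (nrow(tab) == 0) 1 else min(tab[[col]])
    data.frame(replicate = r, min_adj_p = minp,
               n_terms_tested = nrow(tab),
               any_significant = minp < alpha)
  })
  reps <- do.call(rbind, reps)
  list(replicates = reps,
       summary = list(mean = mean(reps$min_adj_p),
                      sd = stats::sd(reps$min_adj_p),
                      fraction_significant = mean(reps$any_significant),
                      n_sets = n_sets))
}

#' Export term-gene network tables
#'
#' Writes node and edge TSVs (terms and query genes; edges are term
#' membership) consumable by any graph viewer.
#'
#' @param results enrichment table from [enrichGeneList()].
#' @param terms the [TermSets-class] used to build it.
#' @param genes the query gene list.
#' @param node_path,edge_path output TSV paths.
#' @return invisibly, a list with the two data.frames.
#' @export
writeNetworkTables <- function(results, terms, genes, node_path,
                               edge_path) {
  genes <- unique(genes)
  nodes <- rbind(
    data.frame(id = results$term_id, type = "term",
               label = results$name, p = results$p_ease,
               stringsAsFactors = FALSE),
    data.frame(id = genes, type = "gene", label = genes, p = NA_real_,
               stringsAsFactors = FALSE))
  edges <- do.call(rbind, lapply(results$term_id, function(t) {
    g <- intersect(terms[[t]], genes)
    if (length(g) == 0) return(NULL)
    data.frame(source = t, target = g, stringsAsFactors = FALSE)
  }))
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(nodes = nodes, edges = edges))
}
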