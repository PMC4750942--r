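#' Paired per-feature value vectors for one gene
#'
#' Extracts the gene's exon/junction values (FPKM by default, raw counts
#' on request) for the media and iron libraries, in the deterministic
#' feature order of the gene models, giving the two "samples" of the
#' per-gene test: with one library per condition, a gene's features act
#' as the replicates.
#'
#' @param fc A [FeatureCounts-class] (with an fpkm assay when
#'   `scale = "fpkm"`).
#' @param models A [GeneModels-class] object.
#' @param gene_id gene to extract.
#' @param library_media,library_iron library ids of the two conditions.
#' @param scale `"fpkm"` (default) or `"raw"`.
#' @return list: `media`, `iron` (numeric vectors, identical feature
#'   order), `feature_id`.
#' @export
geneFeatureVectors <- function(fc, models, gene_id, library_media,
                               library_iron,
                               scale = c("fpkm", "raw")) {
  scale <- match.arg(scale)
  f <- featureTable(models)
  fid <- f$feature_id[f$gene_id == gene_id]
  if (length(fid) == 0) stop("unknown gene: ", gene_id)
  m <- if (scale == "fpkm") fpkm(fc) else counts(fc)
  if (!all(fid %in% rownames(m)))
    stop("gene features missing from the count matrix")
  list(media = unname(m[fid, library_media]),
       iron = unname(m[fid, library_iron]),
       feature_id = fid)
}

#' Welch two-sample t-test (unequal variances)
#'
#' The two-sample t statistic without the equal-variance assumption,
#' with Welch-Satterthwaite degrees of freedom and a two-sided p from
#' the t distribution. Degenerate inputs (both variances zero) give
#' `t = 0, p = 1` when the means agree, and a flagged `p = 0` when they
#' differ (infinite evidence under the model).
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return list: `t`, `df`, `p`, `degenerate` (logical flag).
#' @export
welchTTest <- function(x, y) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 2, ny >= 2)
  vx <- stats::var(x); vy <- stats::var(y)
  mx <- mean(x); my <- mean(y)
  if (vx == 0 && vy == 0) {
    if (mx == my) return(list(t = 0, df = NA_real_, p = 1,
                              degenerate = TRUE))
    return(list(t = sign(mx - my) * Inf, df = NA_real_, p = 0,
                degenerate = TRUE))
  }
  se2 <- vx / nx + vy / ny
  t <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, degenerate = FALSE)
}

#' Variance-ratio F test
#'
#' Two-sided test of equal variances: `F` is the larger sample variance
#' over the smaller, with numerator/denominator degrees of freedom
#' ordered to match, and `p = min(1, 2 * P(F >= f))`. Two identical
#' zero-variance vectors are trivially equal-variance (`p = 1`, flagged).
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return list: `f`, `df1`, `df2`, `p`, `degenerate`.
#' @export
varianceFTest <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0)
    return(list(f = NA_real_, df1 = NA_real_, df2 = NA_real_, p = 1,
                degenerate = TRUE))
  if (vx >= vy) {
    f <- vx / vy; df1 <- length(x) - 1; df2 <- length(y) - 1
  } else {
    f <- vy / vx; df1 <- length(y) - 1; df2 <- length(x) - 1
  }
  p <- min(1, 2 * stats::pf(f, df1, df2, lower.tail = FALSE))
  list(f = f, df1 = df1, df2 = df2, p = p, degenerate = FALSE)
}

#' Per-gene differential expression between media and iron libraries
#'
#' For every detected gene (at least one read in either library) with at
#' least two features, runs [welchTTest()] on the paired per-feature
#' vectors and [varianceFTest()] as a variance filter: only genes whose
#' variances are not demonstrably unequal (`p_f > variance_filter_alpha`)
#' enter the ranked list, but filtered genes are still reported. Results
#' are sorted by ascending t-test p (ties broken by gene id) and counted
#' at each significance threshold, both over filter-passing genes and
#' over all tested genes.
#'
#' @param fc A [FeatureCounts-class] (run [fpkmNormalize()] first when
#'   `scale = "fpkm"`).
#' @param models A [GeneModels-class] object.
#' @param library_media,library_iron library ids; by default the single
#'   media and iron libraries present (an error if not exactly one each).
#' @param scale value scale fed to the test, `"fpkm"` (default; a
#'   per-feature length rescale of the counts) or `"raw"`.
#' @param thresholds significance thresholds to count genes at
#'   (default `c(0.05, 0.15)`).
#' @param variance_filter_alpha F-test alpha for the variance filter
#'   (default 0.05; genes with `p_f > alpha` pass).
#' @return list:
#'   `results` -- data.frame (one row per gene) with `gene_id`,
#'   `n_features`, `mean_media`, `mean_iron`, `t_stat`, `df`, `p_t`,
#'   `f_stat`, `p_f`, `passes_variance_filter`, `degenerate`, `tested`,
#'   `reason` (why a gene was not tested), `rank` (1..n over tested,
#'   filter-passing genes; NA otherwise);
#'   `threshold_counts` -- data.frame with per-threshold gene counts
#'   (`n_filtered` among filter-passing, `n_unfiltered` among all
#'   tested);
#'   `n_detected`, `n_tested`.
#' @export
runDifferentialExpression <- function(fc, models,
                                      library_media = NULL,
                                      library_iron = NULL,
                                      scale = c("fpkm", "raw"),
                                      thresholds = c(0.05, 0.15),
                                      variance_filter_alpha = 0.05) {
  scale <- match.arg(scale)
  li <- libraryInfo(fc)
  if (is.null(library_media)) {
    library_media <- li$library_id[li$condition == "media"]
    if (length(library_media) != 1)
      stop("need exactly one media library (or pass library_media)")
  }
  if (is.null(library_iron)) {
    library_iron <- li$library_id[li$condition == "iron"]
    if (length(library_iron) != 1)
      stop("need exactly one iron library (or pass library_iron)")
  }
  if (!all(c(library_media, library_iron) %in% li$library_id))
    stop("requested libraries not present")
  stopifnot(all(thresholds > 0 & thresholds < 1))
  f <- featureTable(models)
  raw <- counts(fc)
  gene_ids <- geneIds(models)
  rows <- vector("list", length(gene_ids))
  for (i in seq_along(gene_ids)) {
    g <- gene_ids[i]
    fid <- f$feature_id[f$gene_id == g]
    nfeat <- length(fid)
    detected <- sum(raw[fid, c(library_media, library_iron)]) > 0
    if (!detected || nfeat < 2) {
      rows[[i]] <- data.frame(
        gene_id = g, n_features = nfeat, mean_media = NA_real_,
        mean_iron = NA_real_, t_stat = NA_real_, df = NA_real_,
        p_t = NA_real_, f_stat = NA_real_, p_f = NA_real_,
        passes_variance_filter = NA, degenerate = NA, tested = FALSE,
        reason = if (!detected) "not_detected" else "single_feature",
        stringsAsFactors = FALSE)
      next
    }
    v <- geneFeatureVectors(fc, models, g, library_media, library_iron,
                            scale = scale)
    tt <- welchTTest(v$media, v$iron)
    ft <- varianceFTest(v$media, v$iron)
    rows[[i]] <- data.frame(
      gene_id = g, n_features = nfeat, mean_media = mean(v$media),
      mean_iron = mean(v$iron), t_stat = tt$t, df = tt$df, p_t = tt$p,
      f_stat = ft$f, p_f = ft$p,
      passes_variance_filter = ft$p > variance_filter_alpha,
      degenerate = tt$degenerate || ft$degenerate, tested = TRUE,
      reason = "", stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res <- res[order(!res$tested, res$p_t, res$gene_id), ]
  rownames(res) <- NULL
  res$rank <- NA_integer_
  ranked <- which(res$tested & res$passes_variance_filter)
  res$rank[ranked] <- seq_along(ranked)
  tc <- data.frame(
    threshold = thresholds,
    n_filtered = vapply(thresholds, function(a)
      sum(res$tested & res$passes_variance_filter & res$p_t < a,
          na.rm = TRUE), 0L),
    n_unfiltered = vapply(thresholds, function(a)
      sum(res$tested & res$p_t < a, na.rm = TRUE), 0L))
  list(results = res, threshold_counts = tc,
       n_detected = sum(res$tested | res$reason == "single_feature"),
       n_tested = sum(res$tested))
}
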