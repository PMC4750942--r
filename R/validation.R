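#' Relative expression from a qPCR plate (two-reference normalization)
#'
#' Replicate Ct values per (sample, gene) are pooled by their mean when
#' the replicate standard deviation confirms validity for pooling
#' (`sd <= pooling_sd_max`); otherwise the well group is flagged and
#' excluded. Each pooled Ct becomes a quantity `efficiency^(-Ct)`, the
#' geometric mean of the two reference-gene quantities serves as the
#' per-sample normalizing factor, and the normalized quantity is
#' rescaled so the calibrator sample's value is exactly 1 for every
#' gene.
#'
#' @param plate data.frame: `sample_id`, `gene_id`, `replicate`, `ct`
#'   (cycles, in (0, 45); >= 2 replicates per well group).
#' @param reference_genes exactly 2 reference gene ids (e.g. beta actin
#'   and GAPDH), present in every sample.
#' @param calibrator_sample sample whose relative quantity defines 1.
#' @param efficiency assumed amplification efficiency (default 2.0, a
#'   perfect doubling per cycle).
#' @param pooling_sd_max maximum replicate Ct SD for pooling
#'   (default 0.5 cycles).
#' @return data.frame: `sample_id`, `gene_id`, `ct_mean`, `ct_sd`,
#'   `pooled` (FALSE rows are excluded from quantification, `rq = NA`),
#'   `rq` (fold vs the calibrator sample).
#' @export
relativeExpression <- function(plate, reference_genes, calibrator_sample,
                               efficiency = 2.0, pooling_sd_max = 0.5) {
  stopifnot(length(reference_genes) == 2)
  need <- c("sample_id", "gene_id", "replicate", "ct")
  if (!all(need %in% names(plate)))
    stop("plate must have columns: ", paste(need, collapse = ", "))
  if (any(plate$ct <= 0 | plate$ct >= 45))
    stop("Ct values must lie in (0, 45)")
  key <- interaction(plate$sample_id, plate$gene_id, drop = TRUE)
  if (any(tapply(plate$ct, key, length) < 2))
    stop("need >= 2 Ct replicates per (sample, gene)")
  agg <- do.call(rbind, lapply(split(plate, key), function(d)
    data.frame(sample_id = d$sample_id[1], gene_id = d$gene_id[1],
               ct_mean = mean(d$ct), ct_sd = stats::sd(d$ct),
               stringsAsFactors = FALSE)))
  agg$pooled <- agg$ct_sd <= pooling_sd_max
  samples <- unique(agg$sample_id)
  for (s in samples) {
    refs <- agg[agg$sample_id == s & agg$gene_id %in% reference_genes &
                  agg$pooled, ]
    if (nrow(refs) < 2)
      stop("sample '", s, "' lacks a poolable measurement for both ",
           "reference genes")
  }
  if (!calibrator_sample %in% samples)
    stop("calibrator sample not on the plate")
  agg$quantity <- ifelse(agg$pooled, efficiency^(-agg$ct_mean), NA_real_)
  norm <- vapply(samples, function(s) {
    q <- agg$quantity[agg$sample_id == s &
                        agg$gene_id %in% reference_genes]
    exp(mean(log(q)))
  }, 0)
  names(norm) <- samples
  agg$rel <- agg$quantity / norm[agg$sample_id]
  cal <- agg[agg$sample_id == calibrator_sample, ]
  calv <- stats::setNames(cal$rel, cal$gene_id)
  agg$rq <- agg$rel / calv[agg$gene_id]
  agg$quantity <- NULL
  agg$rel <- NULL
  rownames(agg) <- NULL
  agg[order(agg$gene_id, agg$sample_id), ]
}

#' Sequencing / qPCR concordance regression
#'
#' Ordinary least squares of Ct on log-transformed alignment counts
#' (with a pseudocount). Because Ct falls as template rises, the slope
#' is expected negative; `r2` is invariant to the logarithm base.
#'
#' @param alignments nonnegative normalized alignment values, matched
#'   pairwise to `cts`.
#' @param cts Ct values.
#' @param pseudocount added before the log (default 0.5).
#' @param log_base base of the predictor transform (default 10).
#' @return list: `slope`, `intercept`, `r2`, `p` (two-sided, on the
#'   slope), `n`.
#' @export
concordanceRegression <- function(alignments, cts, pseudocount = 0.5,
                                  log_base = 10) {
  stopifnot(length(alignments) == length(cts))
  if (length(cts) < 3) stop("need at least 3 matched pairs")
  if (any(alignments < 0)) stop("alignments must be >= 0")
  x <- log(alignments + pseudocount, base = log_base)
  if (stats::var(cts) == 0)
    return(list(slope = 0, intercept = cts[1], r2 = 0, p = NA_real_,
                n = length(cts)))
  fit <- stats::lm(cts ~ x)
  # a noiseless (perfect-fit) relation is a legitimate input here
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  slope_p <- if (nrow(sm$coefficients) < 2 || is.na(sm$coefficients[2, 4]))
    NA_real_ else sm$coefficients[2, 4]
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = sm$r.squared, p = slope_p, n = length(cts))
}

#' Proportion with Wilson 95% confidence interval
#'
#' Reports a count proportion as a percentage to one decimal place with
#' a Wilson score interval. Percentages are rounded upward at the last
#' reported digit -- the conservative convention for adverse-event
#' proportions, which never understates a rate -- and the unrounded
#' proportion is returned alongside.
#'
#' @param n_positive,n_total nonnegative counts, `n_positive <= n_total`,
#'   `n_total >= 1`.
#' @param conf confidence level (default 0.95).
#' @return list: `n_positive`, `n_total`, `proportion`, `percent` (one
#'   decimal), `ci_low`, `ci_high`.
#' @export
proportionStat <- function(n_positive, n_total, conf = 0.95) {
  if (n_total < 1) stop("n_total must be >= 1")
  if (n_positive < 0 || n_positive > n_total)
    stop("need 0 <= n_positive <= n_total")
  p <- n_positive / n_total
  z <- stats::qnorm(1 - (1 - conf) / 2)
  denom <- 1 + z^2 / n_total
  center <- (p + z^2 / (2 * n_total)) / denom
  half <- z * sqrt(p * (1 - p) / n_total + z^2 / (4 * n_total^2)) / denom
  list(n_positive = n_positive, n_total = n_total, proportion = p,
       percent = ceiling(1000 * p - 1e-9) / 10,
       ci_low = max(0, center - half), ci_high = min(1, center + half))
}

#' Rank-based group comparisons
#'
#' Two-group design: two-sided Mann-Whitney (Wilcoxon rank-sum), exact
#' for small tie-free samples (both `n <= exact_max_n`), otherwise the
#' normal approximation with tie correction. Multi-group design:
#' Kruskal-Wallis omnibus test followed by Dunn's pairwise z tests (tie
#' corrected), with Bonferroni adjustment across pairs (raw pairwise p
#' also returned). Groups whose values are all identical yield p = 1
#' with a tie flag.
#'
#' @param groups named list of numeric vectors (each `n >= 1`).
#' @param design `"two_group"` (exactly 2 groups) or `"multi_group"`.
#' @param exact_max_n largest per-group n for the exact Mann-Whitney
#'   path (default 20).
#' @return For two groups: list `method`, `statistic` (W), `p`,
#'   `tie_flag`. For multi-group: list `method`, `statistic` (H),
#'   `df`, `p` (omnibus), `pairwise` (data.frame `group1`, `group2`,
#'   `z`, `p_raw`, `p_adjusted`), `tie_flag`.
#' @export
compareGroups <- function(groups, design = c("two_group", "multi_group"),
                          exact_max_n = 20) {
  design <- match.arg(design)
  stopifnot(is.list(groups), all(lengths(groups) >= 1))
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  vals <- unlist(groups, use.names = FALSE)
  all_identical <- length(unique(vals)) == 1
  if (design == "two_group") {
    if (length(groups) != 2) stop("two_group design needs exactly 2 groups")
    x <- groups[[1]]; y <- groups[[2]]
    if (all_identical)
      return(list(method = "mann_whitney", statistic = NA_real_, p = 1,
                  tie_flag = TRUE))
    ties <- anyDuplicated(c(x, y)) > 0
    exact <- !ties && length(x) <= exact_max_n && length(y) <= exact_max_n
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                              correct = !exact))
    list(method = if (exact) "mann_whitney_exact"
                  else "mann_whitney_normal_approx",
         statistic = unname(wt$statistic), p = wt$p.value,
         tie_flag = ties)
  } else {
    if (length(groups) < 2) stop("multi_group design needs >= 2 groups")
    if (all_identical)
      return(list(method = "kruskal_wallis_dunn", statistic = NA_real_,
                  df = length(groups) - 1, p = 1, pairwise = NULL,
                  tie_flag = TRUE))
    g <- factor(rep(names(groups), lengths(groups)),
                levels = names(groups))
    kw <- stats::kruskal.test(vals, g)
    pw <- .dunnTest(vals, g)
    list(method = "kruskal_wallis_dunn",
         statistic = unname(kw$statistic), df = unname(kw$parameter),
         p = kw$p.value, pairwise = pw,
         tie_flag = anyDuplicated(vals) > 0)
  }
}

#' Dunn's post-hoc pairwise z tests on joint ranks
#' @keywords internal
.dunnTest <- function(vals, g) {
  N <- length(vals)
  rk <- rank(vals)
  tie_tab <- table(rk)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  meanrk <- tapply(rk, g, mean)
  ns <- tapply(rk, g, length)
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(pc) {
    i <- pairs[1, pc]; j <- pairs[2, pc]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ns[[i]] + 1 / ns[[j]]))
    z <- (meanrk[[i]] - meanrk[[j]]) / se
    data.frame(group1 = i, group2 = j, z = z,
               p_raw = 2 * stats::pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, out$p_raw * nrow(out))
  rownames(out) <- NULL
  out
}

#' Fold-change summary across experiments
#'
#' Arithmetic mean with a t-based 95% confidence interval and the
#' minimum, for a set of per-experiment fold changes.
#'
#' @param ratios positive fold changes, one per experiment.
#' @param conf confidence level (default 0.95).
#' @return list: `mean`, `ci_low`, `ci_high` (NA when `n < 2`), `min`,
#'   `n`.
#' @export
foldChangeSummary <- function(ratios, conf = 0.95) {
  if (length(ratios) < 1) stop("need at least one ratio")
  if (any(ratios <= 0)) stop("fold changes must be > 0")
  n <- length(ratios)
  m <- mean(ratios)
  if (n < 2)
    return(list(mean = m, ci_low = NA_real_, ci_high = NA_real_,
                min = min(ratios), n = n))
  half <- stats::qt(1 - (1 - conf) / 2, n - 1) * stats::sd(ratios) / sqrt(n)
  list(mean = m, ci_low = m - half, ci_high = m + half,
       min = min(ratios), n = n)
}
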