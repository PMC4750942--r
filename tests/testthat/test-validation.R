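# build a plate from per-(sample, gene) mean Cts with exact replicates
flatPlate <- function(cts, n_rep = 2) {
  do.call(rbind, lapply(seq_len(nrow(cts)), function(i)
    data.frame(sample_id = cts$sample_id[i], gene_id = cts$gene_id[i],
               replicate = seq_len(n_rep), ct = cts$ct[i],
               stringsAsFactors = FALSE)))
}

test_that("relative quantification follows the efficiency^(-Ct) closed forms", {
  base <- expand.grid(sample_id = c("media", "iron"),
                      gene_id = c("ACTB", "GAPDH", "TGT"),
                      stringsAsFactors = FALSE)
  base$ct <- 25
  # all Cts identical: every rq is exactly 1
  rq <- relativeExpression(flatPlate(base), c("ACTB", "GAPDH"), "media")
  expect_true(all(rq$rq == 1))
  # target one cycle lower in iron, references unchanged: rq = 2^1
  b2 <- base; b2$ct[b2$sample_id == "iron" & b2$gene_id == "TGT"] <- 24
  rq2 <- relativeExpression(flatPlate(b2), c("ACTB", "GAPDH"), "media")
  expect_equal(rq2$rq[rq2$gene_id == "TGT" & rq2$sample_id == "iron"], 2)
  # both references one cycle lower in iron, target unchanged: rq = 0.5
  b3 <- base
  b3$ct[b3$sample_id == "iron" & b3$gene_id %in% c("ACTB", "GAPDH")] <- 24
  rq3 <- relativeExpression(flatPlate(b3), c("ACTB", "GAPDH"), "media")
  expect_equal(rq3$rq[rq3$gene_id == "TGT" & rq3$sample_id == "iron"],
               0.5)
  # efficiency other than 2 changes the scale accordingly (1 cycle, E=1.9)
  rq19 <- relativeExpression(flatPlate(b2), c("ACTB", "GAPDH"), "media",
                             efficiency = 1.9)
  expect_equal(rq19$rq[rq19$gene_id == "TGT" & rq19$sample_id == "iron"],
               1.9)
})

test_that("replicate pooling check excludes scattered wells", {
  base <- expand.grid(sample_id = c("media", "iron"),
                      gene_id = c("ACTB", "GAPDH", "TGT"),
                      stringsAsFactors = FALSE)
  base$ct <- 25
  plate <- flatPlate(base)
  # blow up the target replicates in iron: sd 2 > 0.5
  sel <- plate$sample_id == "iron" & plate$gene_id == "TGT"
  plate$ct[sel] <- c(23, 23 + 2 * sqrt(2))
  rq <- relativeExpression(plate, c("ACTB", "GAPDH"), "media")
  bad <- rq[rq$sample_id == "iron" & rq$gene_id == "TGT", ]
  expect_false(bad$pooled)
  expect_true(is.na(bad$rq))
  # a reference failing the pooling check is an error
  plate2 <- flatPlate(base)
  sel2 <- plate2$sample_id == "iron" & plate2$gene_id == "ACTB"
  plate2$ct[sel2] <- c(20, 30)
  expect_error(relativeExpression(plate2, c("ACTB", "GAPDH"), "media"),
               "reference genes")
  expect_error(relativeExpression(flatPlate(base), c("ACTB", "MISSING"),
                                  "media"), "reference")
  expect_error(relativeExpression(flatPlate(base)[-1, ],
                                  c("ACTB", "GAPDH"), "media"),
               ">= 2 Ct replicates")
})

test_that("relative quantification is invariant to per-sample Ct shifts", {
  set.seed(91)
  for (i in 1:5) {
    base <- expand.grid(sample_id = c("media", "iron"),
                        gene_id = c("R1", "R2", "A", "B"),
                        stringsAsFactors = FALSE)
    base$ct <- runif(nrow(base), 22, 30)
    plate <- flatPlate(base)
    rq1 <- relativeExpression(plate, c("R1", "R2"), "media")
    shifted <- plate
    shifted$ct[shifted$sample_id == "iron"] <-
      shifted$ct[shifted$sample_id == "iron"] + runif(1, -3, 3)
    rq2 <- relativeExpression(shifted, c("R1", "R2"), "media")
    expect_equal(rq1$rq, rq2$rq, tolerance = 1e-9)
  }
})

test_that("concordance regression r2 ignores the log base of the predictor", {
  set.seed(92)
  x <- rlnorm(20, 3, 1.5)
  ct <- 34 - log2(x) + rnorm(20, 0, 0.3)
  f10 <- concordanceRegression(x, ct)
  f2 <- concordanceRegression(x, ct, log_base = 2)
  fe <- concordanceRegression(x, ct, log_base = exp(1))
  expect_equal(f10$r2, f2$r2, tolerance = 1e-12)
  expect_equal(f10$r2, fe$r2, tolerance = 1e-12)
  expect_lt(f10$slope, 0)
  # noiseless relation: r2 exactly 1
  f0 <- concordanceRegression(x, 34 - log2(x), pseudocount = 0)
  expect_equal(f0$r2, 1)
  # constant response: slope 0, r2 0
  fcst <- concordanceRegression(x, rep(25, 20))
  expect_equal(fcst$slope, 0)
  expect_equal(fcst$r2, 0)
  expect_error(concordanceRegression(1:2, c(20, 21)), "3 matched pairs")
})

test_that("proportions report Wilson intervals and one-decimal percents", {
  p0 <- proportionStat(0, 10)
  expect_equal(p0$percent, 0)
  expect_equal(p0$ci_low, 0)
  expect_gt(p0$ci_high, 0)
  # Wilson interval cross-checked against prop.test without correction
  set.seed(93)
  for (i in 1:25) {
    n <- sample(5:500, 1)
    k <- sample(0:n, 1)
    ps <- proportionStat(k, n)
    ref <- prop.test(k, n, correct = FALSE)$conf.int
    expect_equal(ps$ci_low, ref[1], tolerance = 1e-9)
    expect_equal(ps$ci_high, ref[2], tolerance = 1e-9)
    expect_true(ps$ci_low <= ps$proportion & ps$proportion <= ps$ci_high)
  }
  expect_error(proportionStat(3, 0), "n_total")
  expect_error(proportionStat(5, 4), "n_positive")
})

test_that("two-group comparison takes the exact path and matches enumeration", {
  g <- compareGroups(list(a = c(1, 2, 3), b = c(101, 102, 103)))
  expect_equal(g$method, "mann_whitney_exact")
  expect_equal(g$p, 0.1)     # 2/20 rank assignments are as extreme
  ident <- compareGroups(list(a = c(2, 2), b = c(2, 2)))
  expect_equal(ident$p, 1)
  expect_true(ident$tie_flag)
  # exact path equals the permutation-enumeration oracle, sizes <= 7
  set.seed(94)
  for (i in 1:30) {
    x <- sample(1000, sample(2:7, 1))
    y <- sample(2000:3000, sample(2:7, 1))
    mine <- compareGroups(list(x = x, y = y))
    expect_equal(mine$method, "mann_whitney_exact")
    expect_equal(mine$p, bruteMWp(x, y), tolerance = 1e-12)
  }
  # ties push onto the corrected normal approximation
  gt <- compareGroups(list(a = c(1, 2, 2, 3), b = c(2, 4, 5, 6)))
  expect_equal(gt$method, "mann_whitney_normal_approx")
  expect_true(gt$tie_flag)
})

test_that("multi-group comparison runs Kruskal-Wallis with Dunn post hoc", {
  ident <- compareGroups(list(a = c(1, 1), b = c(1, 1), c = c(1, 1)),
                         design = "multi_group")
  expect_equal(ident$p, 1)
  expect_true(ident$tie_flag)
  k <- compareGroups(list(a = c(1, 2), b = c(3, 4), c = c(5, 6)),
                     design = "multi_group")
  expect_equal(unname(k$statistic),
               unname(kruskal.test(c(1:6),
                                   factor(rep(letters[1:3],
                                              each = 2)))$statistic))
  pw <- k$pairwise
  # hand-computed Dunn z for mean ranks 1.5/3.5/5.5, se = sqrt(3.5)
  expect_equal(pw$z[pw$group1 == "a" & pw$group2 == "b"],
               -2 / sqrt(3.5), tolerance = 1e-12)
  expect_equal(pw$z[pw$group1 == "a" & pw$group2 == "c"],
               -4 / sqrt(3.5), tolerance = 1e-12)
  expect_equal(pw$p_adjusted, pmin(1, pw$p_raw * 3))
})

test_that("fold-change summaries follow the t-interval arithmetic", {
  r <- foldChangeSummary(c(2, 2, 2))
  expect_equal(r$mean, 2)
  expect_equal(c(r$ci_low, r$ci_high), c(2, 2))
  expect_equal(r$min, 2)
  r2 <- foldChangeSummary(c(1, 3))
  expect_equal(r2$mean, 2)
  expect_equal(r2$min, 1)
  # frozen hand evaluation: mean 2.1, half-width qt(.975, 3) * sd / 2
  r3 <- foldChangeSummary(c(1.5, 2.0, 2.2, 2.7))
  expect_equal(r3$mean, 2.1)
  expect_equal(r3$ci_low, 1.309710, tolerance = 1e-6)
  expect_equal(r3$ci_high, 2.890290, tolerance = 1e-6)
  expect_equal(r3$min, 1.5)
  r1 <- foldChangeSummary(1.8)
  expect_true(is.na(r1$ci_low))
  expect_error(foldChangeSummary(c(1, -2)), "> 0")
})
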