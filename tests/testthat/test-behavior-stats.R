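test_that("outlier filtering removes extreme RTs and honors edge cases", {
  tr <- toyTrials(25)                       # identical RTs: SD = 0
  expect_equal(nrow(filterOutliers(tr)), nrow(tr))
  set.seed(1)
  tr2 <- toyTrials(25)
  tr2$rt_s <- rnorm(nrow(tr2), 0.5, 0.05)
  tr2$rt_s[7] <- 10
  out <- filterOutliers(tr2, k = 2)
  expect_false(7 %in% as.integer(rownames(out)))
  # direct check: removed exactly the trials outside mean +/- 2 SD
  m <- mean(tr2$rt_s); sdev <- sd(tr2$rt_s)
  expect_equal(nrow(out), sum(abs(tr2$rt_s - m) <= 2 * sdev))
  expect_identical(nrow(filterOutliers(tr2, k = Inf)), nrow(tr2))
})

test_that("subject-level exclusion flags extreme mean RTs", {
  set.seed(2)
  trs <- do.call(rbind, lapply(1:8, function(s) {
    tr <- toyTrials(20)
    tr$subject <- sprintf("sub%03d", s)
    tr$rt_s <- rnorm(nrow(tr), if (s == 8) 3.0 else 0.5, 0.05)
    tr
  }))
  out <- filterOutliers(trs, k = 2)
  flags <- attr(out, "subjectFlags")
  expect_true(flags$mean_rt_flag[flags$subject == "sub008"])
  expect_false(any(flags$mean_rt_flag[flags$subject != "sub008"]))
  dropped <- filterOutliers(trs, k = 2, dropFlagged = TRUE)
  expect_false("sub008" %in% dropped$subject)
})

test_that("condition summaries compute EP and correct-trial RT means", {
  tr <- toyTrials(10)
  s <- summarizeConditions(tr)
  expect_true(all(s$error_pct == 0))        # all correct
  tr$correct[tr$trial_type == "reference" &
               tr$switching == "switch"][1:2] <- 0L
  s2 <- summarizeConditions(tr)
  expect_equal(s2$error_pct[s2$condition == "switch-reference"], 20)
  # RT mean over correct trials only
  tr$rt_s[tr$correct == 0] <- 99
  s3 <- summarizeConditions(tr)
  expect_equal(s3$mean_rt_s[s3$condition == "switch-reference"], 0.5)
})

test_that("gating contrast follows its defining arithmetic and is linear", {
  cells <- c("switch-reference" = 1.0, "nonswitch-reference" = 0.9,
             "switch-comparison" = 1.2, "nonswitch-comparison" = 0.8)
  g <- gatingContrast(cells)
  expect_equal(g$opening, 0.1)
  expect_equal(g$closing, 0.4)
  eq <- gatingContrast(setNames(rep(2, 4), names(cells)))
  expect_equal(eq$opening, 0)
  expect_equal(eq$closing, 0)
  # linearity
  a <- 2.5; b <- -1
  cells2 <- setNames(runif(4), names(cells))
  gc1 <- gatingContrast(cells); gc2 <- gatingContrast(cells2)
  gc12 <- gatingContrast(a * cells + b * cells2)
  expect_equal(gc12$opening, a * gc1$opening + b * gc2$opening)
  expect_equal(gc12$closing, a * gc1$closing + b * gc2$closing)
  expect_error(gatingContrast(cells[-1]), "missing condition")
})

test_that("rmAnova agrees with the standard repeated-measures solver", {
  skip_if_not_installed("stats")
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(8:16, 1)
    cells <- matrix(rnorm(n * 4), n, 4)
    mine <- rmAnova(cells, c("A", "B"))
    df <- data.frame(y = as.vector(cells),
                     subj = factor(rep(seq_len(n), 4)),
                     A = factor(rep(rep(1:2, each = n), 2)),
                     B = factor(rep(1:2, each = 2 * n)))
    av <- summary(stats::aov(y ~ A * B + Error(subj / (A * B)), data = df))
    ref <- c(av[["Error: subj:A"]][[1]]["A", "F value"],
             av[["Error: subj:B"]][[1]]["B", "F value"],
             av[["Error: subj:A:B"]][[1]]["A:B", "F value"])
    expect_equal(mine$F, ref, tolerance = 1e-8)
  }
})

test_that("rmAnova handles 3 factors, zero contrasts and missing cells", {
  set.seed(3)
  cells <- matrix(rnorm(10 * 8), 10, 8)
  res <- rmAnova(cells, c("A", "B", "C"))
  expect_equal(nrow(res), 7)                # 3 main + 3 two-way + 1 three-way
  expect_true(all(res$eta_p2 >= 0 & res$eta_p2 < 1))
  # constant cells: all contrast scores zero
  res0 <- rmAnova(matrix(1, 8, 4), c("A", "B"))
  expect_true(all(res0$F == 0))
  expect_true(all(res0$eta_p2 == 0))
  cells[1, 2] <- NA
  expect_message(rmAnova(cells[, 1:4], c("A", "B")), "dropped")
})

test_that("rmAnova F equals squared paired t on the matching contrast", {
  set.seed(21)
  cells <- matrix(rnorm(12 * 4), 12, 4)
  res <- rmAnova(cells, c("A", "B"))
  # main effect A: (level1 - level2) averaged over B
  tA <- pairedT((cells[, 1] + cells[, 3]) / 2, (cells[, 2] + cells[, 4]) / 2)
  expect_equal(res$F[res$effect == "A"], tA$t^2, tolerance = 1e-10)
})

test_that("paired t and d_z reproduce printed statistic pairs", {
  x <- rnorm(10)
  same <- pairedT(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$d, 0)
  expect_equal(same$p, 1)
  # printed pairs are mutually consistent under d_z = t / sqrt(n)
  expect_equal(round(cohensDzFromT(6.93, 61), 3), 0.887)
  expect_equal(round(cohensDzFromT(3.340, 61), 3), 0.428)
  expect_equal(round(cohensDzFromT(14.70, 61), 3), 1.882)
  expect_equal(round(cohensDzFromT(6.78, 63), 2), 0.85)
})

test_that("partial eta squared matches printed worked examples", {
  expect_equal(round(etaSquaredFromF(210.98, 1, 60), 3), 0.779)
  expect_equal(round(etaSquaredFromF(317.29, 1, 60), 3), 0.841)
  expect_equal(round(etaSquaredFromF(93.42, 1, 60), 3), 0.609)
  expect_equal(etaSquaredFromF(0, 1, 60), 0)
  expect_error(etaSquaredFromF(-1, 1, 60), "nonnegative")
  # strictly increasing in F, bounded in [0, 1)
  Fs <- seq(0, 500, by = 10)
  es <- etaSquaredFromF(Fs, 1, 60)
  expect_true(all(diff(es) > 0))
  expect_true(all(es >= 0 & es < 1))
})
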