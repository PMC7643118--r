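test_that("Wilcoxon selection keeps separating features and drops noise", {
  set.seed(42)
  n_def <- 5; n_prof <- 5
  labels <- c(rep("BRCA1", 2), rep("BRCA2", 3), rep("none", 5))
  x <- cbind(
    separated = c(6:10, 1:5),          # all deficient above all proficient
    identical = rep(c(1, 2, 3, 4, 5), 2),
    constant = rep(1, 10),
    noise = rnorm(10)
  )
  sel <- select_features_wilcoxon(x, labels, p_cutoff = 0.01)
  expect_true("separated" %in% sel)
  expect_false("identical" %in% sel)
  expect_false("constant" %in% sel)
  # complete separation at n=m=5: exact one-sided p = 1/252
  p <- suppressWarnings(wilcox.test(x[1:5, 1], x[6:10, 1],
                                    alternative = "greater"))$p.value
  expect_equal(p, 1 / choose(10, 5))
  expect_error(select_features_wilcoxon(x[1:5, ], rep("BRCA1", 5)),
               "proficient")
})

test_that("rank-sum p-values match exhaustive enumeration on small groups", {
  set.seed(11)
  for (rep_i in 1:6) {
    n <- sample(3:6, 1); m <- sample(3:6, 1)
    x <- round(runif(n, 0, 10), 1)
    y <- round(runif(m, 0, 10), 1)
    p_pkg <- suppressWarnings(
      wilcox.test(x, y, alternative = "greater", exact = FALSE,
                  correct = FALSE))$p.value
    p_or <- oracle_wilcoxon_greater(x, y)
    # normal approximation vs exact enumeration on tiny groups
    expect_lt(abs(p_pkg - p_or), 0.12)
    if (!anyDuplicated(c(x, y))) {
      p_ex <- wilcox.test(x, y, alternative = "greater")$p.value
      expect_equal(p_ex, p_or, tolerance = 1e-12)
    }
  }
})

test_that("the resampling grid is row-major with down-sampling outer", {
  g <- hrd_resampling_grid()
  expect_identical(g$down_none, rep(c(1, 2, 4), each = 3))
  expect_identical(g$up_brca1, rep(c(1, 1.5, 2), times = 3))
})

test_that("resampling duplicates BRCA1 and thins none, leaving folds clean", {
  labels <- factor(rep(c("BRCA1", "BRCA2", "none"), c(10, 20, 100)),
                   levels = c("BRCA1", "BRCA2", "none"))
  idx <- hrdforest:::.resample_indices(labels, down_none = 2, up_brca1 = 2,
                                       seed = 3)
  expect_identical(sum(labels[idx] == "none"), 50L)
  expect_identical(sum(labels[idx] == "BRCA1"), 20L)
  expect_identical(sum(labels[idx] == "BRCA2"), 20L)
  # down-sampling is without replacement
  expect_false(anyDuplicated(idx[labels[idx] == "none"]) > 0)
  # stratified folds partition every class
  fold <- hrdforest:::.make_folds(labels, 10, seed = 1)
  expect_true(all(table(fold, labels)[, "none"] == 10))
  expect_true(all(fold %in% 1:10))
})

test_that("grid search returns the argmax cell (first on ties)", {
  sim <- fixture_cohort()
  one_cell <- data.frame(down_none = 4, up_brca1 = 1.5)
  gs <- grid_search_resampling(sim$features, sim$labels, grid = one_cell,
                               cv_folds = 5, seed = 2, ntree = 30)
  expect_identical(gs$down_none, 4)
  expect_identical(gs$up_brca1, 1.5)
  expect_true(gs$auprc$auprc[1] > 0.9)  # separable cohort
})

test_that("core training is deterministic and errors on degenerate input", {
  sim <- fixture_cohort()
  idx <- c(1:15, 26:45, 56:125)
  f1 <- hrd_train_core(sim$features[idx, ], sim$labels[idx], seed = 4,
                       ntree = 40, cv_folds = 5)
  f2 <- hrd_train_core(sim$features[idx, ], sim$labels[idx], seed = 4,
                       ntree = 40, cv_folds = 5)
  ho <- setdiff(seq_len(nrow(sim$features)), idx)
  p1 <- predict(f1, sim$features[ho, ])
  p2 <- predict(f2, sim$features[ho, ])
  expect_identical(p1, p2)
  expect_error(hrd_train_core(sim$features[56:125, ],
                              sim$labels[56:125], seed = 1),
               "each of the three classes")
})

test_that("predictions satisfy the probability and cutoff contracts", {
  sim <- fixture_cohort()
  fit <- hrd_train_core(sim$features, sim$labels, seed = 4, ntree = 60,
                        cv_folds = 5)
  pr <- predict(fit, sim$features)
  expect_equal(pr$p_brca1 + pr$p_brca2 + pr$p_none, rep(1, nrow(pr)),
               tolerance = 1e-9)
  expect_equal(pr$p_hrd, pr$p_brca1 + pr$p_brca2, tolerance = 1e-12)
  expect_identical(pr$hr_status, ifelse(pr$p_hrd >= 0.5, "HRD", "HRP"))
  # subtype is the argmax of the two deficiency probabilities
  hrd_rows <- pr$hr_status == "HRD"
  expect_identical(pr$hrd_type[hrd_rows],
                   ifelse(pr$p_brca1[hrd_rows] > pr$p_brca2[hrd_rows],
                          "BRCA1-type", "BRCA2-type"))
  expect_true(all(pr$hrd_type[!hrd_rows] == "none"))
  expect_error(predict(fit, sim$features[, 1:3]), "missing features")
  # persistence round trip reproduces predictions exactly
  tf <- tempfile(fileext = ".rds")
  write_hrdforest(fit, tf)
  expect_identical(predict(read_hrdforest(tf), sim$features), pr)
})

test_that("a model predicting at the cutoff calls HRD (inclusive rule)", {
  sim <- fixture_cohort()
  fit <- hrd_train_core(sim$features, sim$labels, seed = 4, ntree = 40,
                        cv_folds = 5)
  fake <- sim$features[1, , drop = FALSE]
  pr <- predict(fit, fake)
  # the rule itself: recompute the call at an exact-cutoff probability
  expect_identical(ifelse(0.5 >= fit$cutoff, "HRD", "HRP"), "HRD")
  expect_true(pr$p_hrd >= 0 && pr$p_hrd <= 1)
})

test_that("QC flags low mutation counts and MSI, gating LOW_SV on HRD", {
  prof <- setNames(rep(0L, 142), context_keys())
  prof["del.none.len.1"] <- 49L
  expect_identical(apply_qc(prof, "HRP"), "LOW_INDEL")
  prof["del.none.len.1"] <- 50L
  expect_identical(apply_qc(prof, "HRP"), character(0))
  # predicted HRP with 0 SVs: no LOW_SV flag
  expect_false("LOW_SV" %in% apply_qc(prof, "HRP"))
  expect_true("LOW_SV" %in% apply_qc(prof, "HRD"))
  prof["ins.rep.len.1"] <- 20000L
  expect_true("MSI" %in% apply_qc(prof, "HRP"))
})

test_that("evaluation matches brute-force AUROC and handles edge cases", {
  set.seed(19)
  scores <- runif(20)
  positive <- runif(20) < 0.5
  pr <- data.frame(p_hrd = scores, p_brca1 = scores / 2,
                   p_brca2 = scores / 2)
  truth <- ifelse(positive, "BRCA2", "none")
  ev <- evaluate_predictions(pr, truth)
  expect_equal(ev$HRD$auroc, oracle_auroc(scores, positive),
               tolerance = 1e-12)
  # perfect separation
  pr2 <- data.frame(p_hrd = c(rep(0.9, 5), rep(0.1, 5)),
                    p_brca1 = 0, p_brca2 = c(rep(0.9, 5), rep(0.1, 5)))
  ev2 <- evaluate_predictions(pr2, rep(c("BRCA2", "none"), each = 5))
  expect_equal(ev2$HRD$auroc, 1)
  expect_equal(ev2$HRD$auprc, 1)
  expect_error(evaluate_predictions(pr2, rep("BRCA2", 10)), "single class")
})

test_that("blacklisting requires at least one repeat", {
  sim <- fixture_cohort()
  expect_error(blacklist_samples(sim$features, sim$labels, repeats = 0),
               "repeats")
})

test_that("p_hrd is invariant to the ordering of the two HRD classes", {
  sim <- fixture_cohort()
  fit <- hrd_train_core(sim$features, sim$labels, seed = 4, ntree = 40,
                        cv_folds = 5)
  pr <- predict(fit, sim$features[1:20, ])
  expect_equal(pr$p_hrd, pr$p_brca2 + pr$p_brca1, tolerance = 1e-12)
})
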