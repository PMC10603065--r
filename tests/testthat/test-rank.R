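test_that("representative selection maximizes the statistic with deterministic ties", {
  m <- data.frame(clone_id = c("a", "b"), sequence_aa = c("ZZZ", "AAA"),
                  abundance = c(0.5, 0.05), enrichment = c(0.2, 8.0),
                  stringsAsFactors = FALSE)
  expect_equal(select_representative(m, "abundance"), "a")
  expect_equal(select_representative(m, "enrichment"), "b")
  m$abundance <- c(0.5, 0.5)
  # tie: lexicographically smallest full-length sequence wins
  expect_equal(select_representative(m, "abundance"), "b")
  expect_equal(select_representative(m[c(2, 1), ], "abundance"), "b")
})

test_that("liability alternatives list only strictly improved members", {
  m <- data.frame(clone_id = c("rep", "better", "equal", "alsobetter"),
                  sequence_aa = c("S1", "S2", "S3", "S4"),
                  abundance = c(10, 1, 1, 0.5),
                  liabilities = c(2L, 1L, 2L, 0L),
                  affinity_kd = c(1e-8, 1e-8 / 5.5, 1e-8, 2.5e-8),
                  stringsAsFactors = FALSE)
  alt <- liability_alternatives(m)
  expect_setequal(alt$clone_id, c("better", "alsobetter"))
  expect_equal(alt$delta_liabilities[alt$clone_id == "better"], -1L)
  # KD 5.5-fold lower than the representative: improved at both thresholds
  expect_equal(alt$affinity_class_2x[alt$clone_id == "better"], "improved")
  expect_equal(alt$affinity_class_5x[alt$clone_id == "better"], "improved")
  # 2.5-fold higher KD: worse at 2x, similar at 5x
  expect_equal(alt$affinity_class_2x[alt$clone_id == "alsobetter"], "worse")
  expect_equal(alt$affinity_class_5x[alt$clone_id == "alsobetter"], "similar")
})

test_that("bin concordance reports the share of single-bin clusters", {
  # 22 eligible clusters, 21 consistent
  cid <- rep(1:22, each = 2)
  bins <- rep("binA", 44)
  bins[2] <- "binB" # cluster 1 becomes inconsistent
  bc <- bin_concordance(cid, bins)
  expect_equal(bc$eligible, 22L)
  expect_equal(bc$consistent, 21L)
  expect_equal(bc$percent, 100 * 21 / 22)
  # all singletons: nothing eligible
  empty <- bin_concordance(1:5, rep("binA", 5))
  expect_true(is.na(empty$percent))
  expect_equal(empty$eligible, 0L)
  # fully consistent
  expect_equal(bin_concordance(rep(1:3, each = 3),
                               rep(c("a", "b", "c"), each = 3))$percent, 100)
})

test_that("bin concordance equals a brute-force group-by on random instances", {
  set.seed(37)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    cid <- sample(1:8, n, TRUE)
    bins <- sample(c("a", "b", "c", NA), n, TRUE)
    got <- bin_concordance(cid, bins, min_members = 2)
    keep <- !is.na(bins)
    df <- data.frame(cid = cid[keep], bins = bins[keep])
    sizes <- table(df$cid)
    elig <- names(sizes)[sizes >= 2]
    cons <- sum(vapply(elig, function(g) {
      length(unique(df$bins[df$cid == g])) == 1
    }, logical(1)))
    if (length(elig) == 0) {
      expect_true(is.na(got$percent))
    } else {
      expect_equal(got$consistent, cons)
      expect_equal(got$percent, 100 * cons / length(elig))
    }
  }
})

test_that("the binder abundance heuristic is inclusive at the threshold", {
  expect_true(binder_heuristic(0.005))
  expect_false(binder_heuristic(0.004))
  expect_true(all(binder_heuristic(c(0, 1e-9, 50), threshold = 0)))
})

test_that("population overlap reports Venn classes and conserves clusters", {
  cid <- c(1, 1, 2, 3, 3, 3)
  pop <- c("RBD", "S1", "S1", "RBD", "S1", "trimer")
  ov <- population_overlap(cid, pop)
  expect_equal(ov$pattern$pattern[ov$pattern$cluster_id == "1"], "RBD+S1")
  expect_equal(ov$pattern$pattern[ov$pattern$cluster_id == "2"], "S1")
  expect_equal(ov$pattern$pattern[ov$pattern$cluster_id == "3"],
               "RBD+S1+trimer")
  expect_equal(sum(ov$counts), length(unique(cid)))
})

test_that("picked clones are ranked by descending NGS frequency", {
  freqs <- setNames(c(50, 30, 15, 5), c("TOP", "MID", "LOW", "TINY"))
  res <- compare_picked_clones(c("TOP", "LOW", "GONE"), freqs)
  expect_equal(res$rank, c(1L, 3L, NA))
  expect_equal(res$found, c(TRUE, TRUE, FALSE))
  # ties break lexicographically, ranks strictly increase
  freqs2 <- setNames(c(10, 10, 5), c("BBB", "AAA", "CCC"))
  res2 <- compare_picked_clones(c("AAA", "BBB", "CCC"), freqs2)
  expect_equal(res2$rank, c(1L, 2L, 3L))
})

test_that("ROC and PR areas match brute-force oracles on small instances", {
  set.seed(53)
  for (i in 1:30) {
    n <- sample(6:20, 1)
    labels <- sample(0:1, n, TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- 0:1
    scores <- round(rnorm(n), 2) # ties likely
    expect_equal(abselect:::roc_auc(labels, scores),
                 roc_auc_oracle(labels, scores), tolerance = 1e-12)
    expect_equal(pr_auc(labels, scores),
                 pr_auc_oracle(labels, scores), tolerance = 1e-12)
  }
})

test_that("confusion metrics match direct counting", {
  labels <- c(1, 1, 1, 0, 0, 1)
  pred <- c(1, 0, 1, 0, 1, 1)
  cm <- abselect:::confusion_metrics(labels, pred)
  expect_equal(cm$confusion["1", "1"], 3)
  expect_equal(cm$confusion["0", "1"], 1)
  expect_equal(cm$precision, 3 / 4)
  expect_equal(cm$recall, 3 / 4)
})

test_that("feature tables are deterministic, complete and impute flagged gaps", {
  cl <- rbind(
    make_clones(c("AAAAAAKKKK", "FFFFFFPPPP"), "T1", "10nM", c(30L, 10L),
                sequence_aa = c("S1", "S2")),
    make_clones(c("AAAAAAKKKK", "FFFFFFPPPP", "HHHHHHGGGG"), "T1", "1nM",
                c(40L, 10L, 4L), sequence_aa = c("S1", "S2", "S3")))
  asg <- abscan_cluster(cl, abscan_config())
  ft <- build_features(cl, "T1", asg)
  expect_equal(nrow(ft), 3L)
  num <- ft[, !(names(ft) %in% c("clone_id", "imputed"))]
  expect_false(anyNA(num))
  # clone S3 is absent early: its features carry the corrected frequency
  expect_true(ft$imputed[ft$clone_id == "c3"] == FALSE) # corrected, not imputed
  enr <- fold_enrichment(cl, "T1", "HCDR3")
  expect_equal(ft$log10_rel_freq_early_HCDR3[ft$clone_id == "c3"],
               log10(enr$rel_freq_early[enr$roi_value == "HHHHHHGGGG"]))
  # identical inputs give identical rows
  cl2 <- rbind(cl, cl[cl$clone_id == "c2" & cl$concentration == "1nM", ])
  cl2$clone_id[nrow(cl2)] <- "c9"
  cl2$sequence_aa[nrow(cl2)] <- "S2" # same sequence, same stats
  ft2 <- build_features(cl2, "T1", abscan_cluster(cl2, abscan_config()))
  r1 <- ft2[ft2$clone_id == "c2", !(names(ft2) %in% "clone_id")]
  r2 <- ft2[ft2$clone_id == "c9", !(names(ft2) %in% "clone_id")]
  row.names(r1) <- row.names(r2) <- NULL
  expect_equal(r1, r2)
})

test_that("the classifier separates separable features and fails on one class", {
  set.seed(61)
  n <- 60
  x <- data.frame(f1 = c(rnorm(n / 2, -3), rnorm(n / 2, 3)),
                  f2 = rnorm(n))
  y <- rep(c(0, 1), each = n / 2)
  cfg <- model_config("classify", split = c(30L, 30L), bootstrap_reps = 5L,
                      seed = 2L, search_draws = 2L)
  fit <- train_eval(x, y, cfg)
  expect_equal(fit$metrics$auc, 1.0)
  expect_equal(fit$metrics$auprc, 1.0)
  expect_error(train_eval(x, rep(0, n), cfg), "single class")
  expect_error(train_eval(x[1:20, ], y[1:20], cfg), "smaller")
})

test_that("permuted labels give chance-level bootstrap discrimination", {
  set.seed(67)
  n <- 80
  x <- data.frame(f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n))
  y <- sample(rep(c(0, 1), each = n / 2))
  cfg <- model_config("classify", split = c(40L, 40L),
                      bootstrap_reps = 25L, seed = 3L, search_draws = 1L)
  fit <- train_eval(x, y, cfg)
  # with no signal the held-out ROC area hovers around 0.5
  expect_lt(abs(fit$metrics$auc - 0.5), 0.2)
  expect_gte(sum(!is.na(fit$bootstrap$auc)), 20L)
  expect_lt(abs(mean(fit$bootstrap$auc, na.rm = TRUE) - 0.5), 0.1)
})

test_that("regression on a label equal to one feature is read off almost perfectly", {
  # a tree ensemble quantizes predictions into leaves, so rank agreement
  # approaches but cannot exactly reach 1 on held-out points
  set.seed(71)
  n <- 240
  x <- data.frame(f1 = rnorm(n), f2 = rnorm(n))
  y <- x$f1
  cfg <- model_config("regress", split = c(120L, 120L), bootstrap_reps = 5L,
                      seed = 4L, search_draws = 4L)
  fit <- train_eval(x, y, cfg)
  expect_gt(fit$metrics$spearman, 0.98)
  expect_gt(fit$metrics$pearson, 0.98)
  expect_true(all(fit$importance$Feature[1] == "f1"))
})
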