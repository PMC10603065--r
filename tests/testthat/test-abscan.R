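test_that("pairwise Levenshtein distances match the DP oracle", {
  expect_equal(pairwise_distance_matrix(c("ARDYW", "ARDYW"))[1, 2], 0L)
  expect_equal(pairwise_distance_matrix(c("kitten", "sitting"))[1, 2], 3L)
  set.seed(31)
  seqs <- vapply(1:12, function(i) {
    paste(sample(letters[1:8], sample(4:12, 1), TRUE), collapse = "")
  }, "")
  d <- pairwise_distance_matrix(seqs)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  for (i in 1:11) {
    for (j in (i + 1):12) {
      expect_equal(d[i, j], lev_oracle(seqs[i], seqs[j]))
    }
  }
})

test_that("elbow epsilon finds the knee of the k-distance curve", {
  # 6 points pairwise at distance 1 plus one at distance 9 from all:
  # sorted 2-NN distances are 1,1,1,1,1,1,9 and the knee sits at the jump
  d <- matrix(1, 7, 7) - diag(7)
  d[7, ] <- 9; d[, 7] <- 9; d[7, 7] <- 0
  expect_equal(elbow_epsilon(d, k = 2), 1)
  # flat curve: all perpendicular distances tie, first index wins
  d4 <- matrix(2, 4, 4) - 2 * diag(4)
  expect_equal(elbow_epsilon(d4, k = 2), 2)
  # two points fall back to their distance
  expect_equal(elbow_epsilon(matrix(c(0, 3, 3, 0), 2), k = 2), 3)
  # fully degenerate input floors at the configured minimum
  expect_equal(elbow_epsilon(matrix(0, 5, 5), k = 2, min_eps = 1), 1)
  # result is floored at the smallest positive pairwise distance
  expect_gte(elbow_epsilon(d, k = 2), 1)
})

test_that("density_cluster handles the canonical small configurations", {
  # two groups of 3 identical points, far apart: 2 clusters, no noise
  d <- rbind(cbind(matrix(0, 3, 3), matrix(100, 3, 3)),
             cbind(matrix(100, 3, 3), matrix(0, 3, 3)))
  lab <- density_cluster(d, optics_params(2L, 1, 10, 0.01))
  expect_equal(canon_labels(as.integer(lab)), c(1L, 1L, 1L, 2L, 2L, 2L))
  # all identical: one cluster
  lab1 <- density_cluster(matrix(0, 5, 5), optics_params(2L, 1, 10, 0.01))
  expect_equal(unique(as.integer(lab1)), 1L)
  # an isolated point beyond max_eps is noise
  d2 <- matrix(c(0, 1, 50, 1, 0, 50, 50, 50, 0), 3)
  lab2 <- density_cluster(d2, optics_params(2L, 1, 10, 0.01))
  expect_equal(as.integer(lab2), c(1L, 1L, -1L))
})

test_that("density_cluster matches brute-force density-reachability on random instances", {
  set.seed(57)
  n_checked <- 0L
  for (rep in 1:120) {
    k <- sample(1:4, 1)
    sizes <- sample(1:4, k, replace = TRUE)
    while (sum(sizes) > 10) sizes <- sample(1:4, k, replace = TRUE)
    inst <- make_group_instance(k, sizes)
    d <- pairwise_distance_matrix(inst$seqs)
    params <- optics_params(2L, 1, max_eps = 5, xi = 0.01)
    for (extraction in c("xi", "eps_cut")) {
      lab <- as.integer(density_cluster(d, params, extraction))
      oracle <- density_reachability_oracle(d, 2L, 5)
      expect_equal(canon_labels(lab), canon_labels(oracle),
                   info = sprintf("rep %d (%s)", rep, extraction))
    }
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 100L)
})

test_that("density_cluster is deterministic for a fixed input order", {
  set.seed(91)
  inst <- make_group_instance(3, c(3, 3, 2))
  d <- pairwise_distance_matrix(inst$seqs)
  p <- optics_params(2L, 1, 8, 0.01)
  expect_identical(as.integer(density_cluster(d, p)),
                   as.integer(density_cluster(d, p)))
})

test_that("abscan groups near-identical families and covers all their values", {
  # 3 families, 2 members each at pseudo-distance <= 1, families far apart
  clones <- make_clones(
    hcdr3 = c("AAAAAAKKKK", "AAAAAAKKKR",   # K/R share a group: distance 0
              "FFFFFFPPPP", "FFFFFFPPPA",
              "HHHHHHGGGG", "HHHHHHGGGA"),
    population = "T1", concentration = "1nM",
    count = c(50L, 40L, 30L, 20L, 10L, 8L))
  asg <- abscan_cluster(clones, abscan_config())
  expect_equal(length(unique(asg$cluster_id)), 3L)
  expect_false(anyNA(asg$cluster_id))
  byfam <- split(asg$cluster_id, substr(asg$roi_value, 1, 6))
  for (ids in byfam) expect_equal(length(unique(ids)), 1L)
  # partition: every non-discarded value has exactly one id
  expect_equal(anyDuplicated(asg$roi_value), 0L)
})

test_that("abscan rescues abundant distinct singletons by count and discards true noise", {
  clones <- make_clones(
    hcdr3 = c("AAAAAAKKKK", "AAAAAAKKKR", "AAAAAAKKTR",
              "FFFFFFPPPPWWWW",            # distinct, count 2 -> rescue
              "CCCCGGGGHHHMMM"),           # distinct, count 1 -> noise
    population = "T1", concentration = "1nM",
    count = c(500L, 400L, 300L, 2L, 1L))
  asg <- abscan_cluster(clones, abscan_config())
  resc <- asg[asg$roi_value == "FFFFFFPPPPWWWW", ]
  expect_equal(resc$status, "rescued_count")
  expect_false(is.na(resc$cluster_id))
  noise <- asg[asg$roi_value == "CCCCGGGGHHHMMM", ]
  expect_equal(noise$status, "discarded_noise")
  expect_true(is.na(noise$cluster_id))
})

test_that("abscan noise with an equal-length >=90% identity partner joins its cluster", {
  # family: two units at pseudo-distance 1 anchor the elbow at 1; the odd
  # 20-mer sits at pseudo-distance 2 (beyond max_eps = 1) but matches the
  # dominant member at 18/20 = 90% amino-acid identity
  clones <- make_clones(
    hcdr3 = c("AAAAAAAAAAKKKKKKKKKK", "AAAAAAAAAAKKKKKKKKKR",
              "AAAAAAAAAASKKKKKKKKK", "AAAAAAAAAADDKKKKKKKK"),
    population = "T1", concentration = "1nM",
    count = c(500L, 400L, 300L, 1L))
  cfg <- abscan_config(max_eps_factor = 1) # tight radius forces noise
  asg <- abscan_cluster(clones, cfg)
  odd <- asg[asg$roi_value == "AAAAAAAAAADDKKKKKKKK", ]
  expect_equal(odd$status, "rescued_identity")
  expect_equal(odd$cluster_id,
               asg$cluster_id[asg$roi_value == "AAAAAAAAAAKKKKKKKKKK"])
})

test_that("abscan cluster ids are stable under input permutation", {
  set.seed(71)
  clones <- make_clones(
    hcdr3 = c("AAAAAAKKKK", "AAAAAAKKKR", "FFFFFFPPPP", "FFFFFFPPPA",
              "HHHHHHGGGG", "HHHHHHGGGA"),
    population = "T1", concentration = "1nM",
    count = c(50L, 40L, 30L, 20L, 10L, 8L))
  ref <- abscan_cluster(clones, abscan_config())
  for (i in 1:5) {
    perm <- clones[sample.int(nrow(clones)), ]
    out <- abscan_cluster(perm, abscan_config())
    expect_identical(out, ref)
  }
})

test_that("traditional clonotyping requires length, scaffold and identity", {
  # 8-mers differing at one position: 7/8 = 87.5% < 90%
  cl <- make_clones(c("ARDYWGQG", "ARDYWGQS"), "T1", "1nM", c(5L, 3L))
  ct <- traditional_clonotype(cl, "HCDR3", identity = 0.90)
  expect_equal(length(unique(ct$cluster_id)), 2L)
  # 10-mers differing at one position: 90% passes
  cl2 <- make_clones(c("ARDYWGQGTT", "ARDYWGQSTT"), "T1", "1nM", c(5L, 3L))
  ct2 <- traditional_clonotype(cl2, "HCDR3")
  expect_equal(length(unique(ct2$cluster_id)), 1L)
  # identical HCDR3 on different scaffolds stays apart
  cl3 <- make_clones(c("ARDYWGQGTT", "ARDYWGQGTT"), "T1", "1nM", c(5L, 3L),
                     scaffold = c("VH1::VL1", "VH2::VL2"))
  cl3$sequence_aa <- c("X1", "X2")
  ct3 <- traditional_clonotype(cl3, "HCDR3")
  expect_equal(length(unique(ct3$cluster_id)), 2L)
  # different lengths never join
  cl4 <- make_clones(c("ARDYWGQGT", "ARDYWGQGTT"), "T1", "1nM", c(5L, 3L))
  ct4 <- traditional_clonotype(cl4, "HCDR3")
  expect_equal(length(unique(ct4$cluster_id)), 2L)
})

test_that("clonotyping equals a brute-force pairwise graph on random instances", {
  set.seed(83)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    hc <- vapply(seq_len(n), function(i) {
      base <- c("ARDYWGQGTT", "SSSSYYYYPP")[sample(1:2, 1)]
      p <- sample(10, 1)
      substr(base, p, p) <- sample(abselect:::AA20, 1)
      base
    }, "")
    scaf <- sample(c("A", "B"), n, TRUE)
    cl <- make_clones(hc, "T1", "1nM", rep(1L, n), scaffold = scaf)
    cl$sequence_aa <- sprintf("S%02d", seq_len(n))
    got <- traditional_clonotype(cl, "HCDR3", 0.9)

    # brute force: connected components of the identity graph
    key <- paste(got$roi_value, got$scaffold)
    m <- nrow(got)
    adj <- matrix(FALSE, m, m)
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        a <- got$roi_value[i]; b <- got$roi_value[j]
        same_len <- nchar(a) == nchar(b)
        ident <- if (same_len) {
          mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
        } else 0
        adj[i, j] <- same_len && got$scaffold[i] == got$scaffold[j] &&
          ident >= 0.9
      }
    }
    comp <- rep(0L, m); c0 <- 0L
    for (i in seq_len(m)) {
      if (comp[i] > 0L) next
      c0 <- c0 + 1L
      queue <- i; comp[i] <- c0
      while (length(queue)) {
        p <- queue[1]; queue <- queue[-1]
        nb <- which(adj[p, ] & comp == 0L)
        comp[nb] <- c0; queue <- c(queue, nb)
      }
    }
    expect_equal(canon_labels(got$cluster_id), canon_labels(comp))
  }
})

test_that("identity clustering is one cluster per distinct ROI string", {
  cl <- make_clones(c("AAA", "BBB", "CCC", "DDD", "EEE"), "T1", "1nM",
                    rep(2L, 5))
  ic <- identity_cluster(cl, "HCDR3")
  expect_equal(nrow(ic), 5L)
  expect_equal(length(unique(ic$cluster_id)), 5L)
  # a string duplicated across populations collapses to one cluster
  cl2 <- make_clones(c("AAA", "AAA"), c("T1", "T2"), "1nM", c(2L, 3L))
  cl2$sequence_aa <- c("S1", "S1")
  ic2 <- identity_cluster(cl2, "HCDR3")
  expect_equal(nrow(ic2), 1L)
  expect_equal(ic2$count, 5L)
})

test_that("abscan equals identity clustering on mutually distant values with counts >= 2", {
  clones <- make_clones(
    hcdr3 = c(strrep("A", 12), strrep("F", 12), strrep("H", 12),
              strrep("P", 12)),
    population = "T1", concentration = "1nM",
    count = c(30L, 20L, 10L, 2L))
  # fixed epsilon keeps max_eps below the inter-value distances, so every
  # value is OPTICS noise and owes its singleton cluster to count rescue
  asg <- abscan_cluster(clones, abscan_config(eps_opt = 1))
  ic <- identity_cluster(clones, "HCDR3")
  expect_equal(length(unique(asg$cluster_id)),
               length(unique(ic$cluster_id)))
  expect_false(anyNA(asg$cluster_id))
  expect_true(all(asg$status == "rescued_count"))
})

test_that("method diversity is nested: identity >= clonotype >= abscan clusters", {
  cfg <- campaign_config(n_families = 20, n_targets = 1,
                         reads_per_population = 4000, seed = 99)
  sim <- simulate_campaign(cfg)
  dm <- demultiplex(quality_filter(sim$reads), sim$barcodes)
  ann <- annotate_reads(dm$assigned, sim$scaffolds)
  n_id <- length(unique(identity_cluster(ann$clones, "HCDR3")$cluster_id))
  n_ct <- length(unique(traditional_clonotype(ann$clones, "HCDR3")$cluster_id))
  asg <- abscan_cluster(ann$clones, abscan_config())
  n_ab <- length(unique(na.omit(asg$cluster_id)))
  expect_gte(n_id, n_ct)
  expect_gte(n_ct, n_ab)
})
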