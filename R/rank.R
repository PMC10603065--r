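#' Select the representative clone of a cluster
#'
#' Argmax of the chosen statistic; ties break to the lexicographically
#' smallest full-length sequence, so selection is deterministic.
#'
#' @param members data.frame of cluster members with columns `clone_id`,
#'   `sequence_aa` and the statistic named in `by`.
#' @param by `"abundance"` (most abundant) or `"enrichment"` (most
#'   enriched).
#' @return the representative's `clone_id`.
#' @export
select_representative <- function(members, by = c("abundance", "enrichment")) {
  by <- match.arg(by)
  stopifnot(nrow(members) >= 1L, by %in% names(members))
  ord <- order(-members[[by]], members$sequence_aa)
  members$clone_id[ord[1L]]
}

#' Liability-reduced alternatives within a cluster
#'
#' Lists cluster members whose liability count is strictly below that of
#' the abundance representative; when affinities are supplied, each
#' alternative is classed improved/similar/worse at a twofold and a
#' fivefold KD threshold relative to the representative.
#'
#' @param members data.frame with columns `clone_id`, `sequence_aa`,
#'   `abundance`, `liabilities` and optionally `affinity_kd` (molar).
#' @return data.frame: `clone_id`, `delta_liabilities`, and (when
#'   affinities are present) `affinity_class_2x`, `affinity_class_5x`.
#' @export
liability_alternatives <- function(members) {
  rep_id <- select_representative(members, "abundance")
  r <- members[members$clone_id == rep_id, , drop = FALSE][1L, ]
  alt <- members[members$liabilities < r$liabilities &
                   members$clone_id != rep_id, , drop = FALSE]
  out <- data.frame(clone_id = alt$clone_id,
                    delta_liabilities = alt$liabilities - r$liabilities,
                    stringsAsFactors = FALSE)
  if ("affinity_kd" %in% names(members) && !is.na(r$affinity_kd)) {
    classify <- function(kd, fold) {
      ifelse(is.na(kd), NA_character_,
             ifelse(kd <= r$affinity_kd / fold, "improved",
                    ifelse(kd >= r$affinity_kd * fold, "worse", "similar")))
    }
    out$affinity_class_2x <- classify(alt$affinity_kd, 2)
    out$affinity_class_5x <- classify(alt$affinity_kd, 5)
  }
  row.names(out) <- NULL
  out
}

#' Cluster / epitope-bin concordance
#'
#' A cluster with at least `min_members` characterized members is
#' consistent when all of them share one epitope bin. Returns the percent
#' of consistent clusters with the underlying counts.
#'
#' @param cluster_id cluster id per characterized clone.
#' @param epitope_bin bin label per characterized clone (NA = not
#'   binned; such clones are ignored).
#' @param min_members minimum characterized members per eligible
#'   cluster, default 2.
#' @return list: `percent`, `consistent`, `eligible` (`percent` is NA
#'   when no cluster is eligible).
#' @export
bin_concordance <- function(cluster_id, epitope_bin, min_members = 2L) {
  keep <- !is.na(cluster_id) & !is.na(epitope_bin)
  cluster_id <- cluster_id[keep]
  epitope_bin <- epitope_bin[keep]
  sizes <- table(cluster_id)
  eligible_ids <- names(sizes)[sizes >= min_members]
  if (!length(eligible_ids)) {
    return(list(percent = NA_real_, consistent = 0L, eligible = 0L))
  }
  consistent <- sum(vapply(eligible_ids, function(id) {
    length(unique(epitope_bin[cluster_id == id])) == 1L
  }, logical(1)))
  list(percent = 100 * consistent / length(eligible_ids),
       consistent = as.integer(consistent),
       eligible = length(eligible_ids))
}

#' Abundance heuristic for binder triage
#'
#' TRUE when the late-round relative frequency of the concatenated CDRs
#' reaches the threshold (inclusive). The default 0.005 percent is the
#' campaign-level cutoff that broadly separates binders from non-binders,
#' with the caveat that genuine binders also occur below it.
#'
#' @param rel_freq_late percent late-round relative frequency on the
#'   concatenated-CDRs ROI.
#' @param threshold percent, default 0.005.
#' @return logical vector.
#' @export
binder_heuristic <- function(rel_freq_late, threshold = 0.005) {
  rel_freq_late >= threshold
}

#' Cluster membership patterns across target arms
#'
#' For pooled clustering across selection arms, reports which arms
#' contain at least one member of each cluster (the Venn class of the
#' cluster) and the cluster counts per class.
#'
#' @param cluster_id cluster id per observation.
#' @param population target-arm label per observation.
#' @return list: `pattern` (data.frame cluster_id, pattern) and `counts`
#'   (table over patterns; sums to the number of clusters).
#' @export
population_overlap <- function(cluster_id, population) {
  keep <- !is.na(cluster_id)
  pat <- tapply(population[keep], cluster_id[keep], function(p) {
    paste(sort(unique(p)), collapse = "+")
  })
  pattern <- data.frame(cluster_id = names(pat), pattern = as.character(pat),
                        stringsAsFactors = FALSE, row.names = NULL)
  list(pattern = pattern, counts = table(pattern$pattern))
}

#' Rank picked (e.g. Sanger) clones within the NGS population
#'
#' @param picked character vector of picked ROI values (e.g. Sanger
#'   HCDR3s).
#' @param freqs named percent vector from [relative_frequency()].
#' @return data.frame: `roi_value`, `found`, `frequency`, `rank`
#'   (descending frequency, ties broken lexicographically; NA when
#'   absent).
#' @export
compare_picked_clones <- function(picked, freqs) {
  ord <- order(-freqs, names(freqs))
  rank_tab <- setNames(seq_along(ord), names(freqs)[ord])
  idx <- match(picked, names(freqs))
  data.frame(roi_value = picked,
             found = !is.na(idx),
             frequency = as.numeric(freqs[idx]),
             rank = as.integer(rank_tab[picked]),
             stringsAsFactors = FALSE)
}

#' NGS feature table for supervised ranking
#'
#' One row per unique full-length clone of a population: log10 early and
#' late relative frequency and log10 fold enrichment for each region of
#' interest, AbScan cluster size (unique full-length members), liability
#' count, and optionally one-hot encoded framework residues over a fixed
#' per-position vocabulary (20 residues + pad). Frequencies absent for a
#' clone are imputed with the smallest observed positive value of the
#' column and flagged.
#'
#' @param clones clone table.
#' @param population population label.
#' @param assignments AbScan assignment table used for cluster size,
#'   matched through `cluster_roi`.
#' @param rois regions contributing frequency/enrichment features.
#' @param cluster_roi ROI linking clones to `assignments`, default
#'   HCDR3.
#' @param policy [correction_policy()] used by the enrichment features.
#' @param include_framework_onehot add per-position framework dummies,
#'   default FALSE (the NGS-statistics-only feature set).
#' @return data.frame with `clone_id`, `imputed` flag and numeric
#'   feature columns (no missing values).
#' @export
build_features <- function(clones, population, assignments,
                           rois = c("HCDR3", "HCDR3+LCDR3", "CDRs", "FULL"),
                           cluster_roi = "HCDR3",
                           policy = correction_policy(),
                           include_framework_onehot = FALSE) {
  sel <- clones$population == population
  sub <- clones[sel, , drop = FALSE]
  uniq <- sub[!duplicated(sub$clone_id), , drop = FALSE]
  feat <- data.frame(clone_id = uniq$clone_id, stringsAsFactors = FALSE)
  imputed <- rep(FALSE, nrow(uniq))
  for (roi in rois) {
    enr <- fold_enrichment(clones, population, roi, policy)
    vals <- roi_string(uniq, roi)
    m <- match(vals, enr$roi_value)
    for (col in c("rel_freq_early", "rel_freq_late", "enrichment")) {
      x <- enr[[col]][m]
      if (anyNA(x)) {
        imputed <- imputed | is.na(x)
        x[is.na(x)] <- min(x[x > 0], na.rm = TRUE)
      }
      feat[[paste0("log10_", col, "_", gsub("[^A-Za-z0-9]", "", roi))]] <-
        log10(x)
    }
  }
  cvals <- roi_string(uniq, cluster_roi)
  cid <- assignments$cluster_id[match(cvals, assignments$roi_value)]
  all_cid <- assignments$cluster_id[
    match(roi_string(sub, cluster_roi), assignments$roi_value)]
  csize <- tapply(sub$sequence_aa, all_cid,
                  function(s) length(unique(s)))
  feat$cluster_size <- as.integer(csize[as.character(cid)])
  feat$cluster_size[is.na(feat$cluster_size)] <- 0L
  feat$liabilities <- uniq$liabilities
  feat$imputed <- imputed
  if (include_framework_onehot) {
    fr <- do.call(paste0, uniq[, paste0(fr_names, "_aa")])
    w <- max(nchar(fr))
    fr <- formatC(fr, width = w, flag = "-")
    fr <- gsub(" ", "-", fr)
    chars <- matrix(unlist(strsplit(fr, "")), ncol = w, byrow = TRUE)
    vocab <- c(sort(unique(names(default_reduced_alphabet()))), "-")
    for (j in seq_len(w)) {
      col <- factor(chars[, j], levels = vocab)
      mm <- diag(length(vocab))[as.integer(col), , drop = FALSE]
      keep <- colSums(mm) > 0 & colSums(mm) < nrow(mm)
      if (any(keep)) {
        block <- mm[, keep, drop = FALSE]
        colnames(block) <- paste0("fw_pos", j, "_", vocab[keep])
        feat <- cbind(feat, block)
      }
    }
  }
  feat
}

#' Model configuration for gradient-boosted ranking
#'
#' @param task `"classify"` (binder vs non-binder) or `"regress"`
#'   (log10 KD).
#' @param split train/test sizes, default c(100, 100).
#' @param bootstrap_reps bootstrap resamples of the training half used
#'   for metric distributions and hyperparameter scoring, default 100.
#' @param seed RNG seed.
#' @param search_draws random hyperparameter draws, default 25.
#' @return list of class `model_config`.
#' @export
model_config <- function(task = c("classify", "regress"),
                         split = c(100L, 100L), bootstrap_reps = 100L,
                         seed = 1L, search_draws = 25L) {
  task <- match.arg(task)
  stopifnot(length(split) == 2L, all(split >= 1L), bootstrap_reps >= 1L,
            search_draws >= 1L)
  structure(list(task = task, split = as.integer(split),
                 bootstrap_reps = as.integer(bootstrap_reps),
                 seed = as.integer(seed),
                 search_draws = as.integer(search_draws)),
            class = "model_config")
}

fit_xgb <- function(x, y, hp, task) {
  obj <- if (task == "classify") "binary:logistic" else "reg:squarederror"
  dm <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  xgboost::xgb.train(
    params = list(objective = obj, max_depth = hp$max_depth, eta = hp$eta,
                  subsample = hp$subsample,
                  colsample_bytree = hp$colsample_bytree, nthread = 1),
    data = dm, nrounds = hp$nrounds, verbose = 0)
}

predict_xgb <- function(model, x) {
  predict(model, xgboost::xgb.DMatrix(x, nthread = 1))
}

# out-of-bag bootstrap metric distribution for one hyperparameter draw;
# column 1 (auprc / spearman) is the model-selection score
boot_metric <- function(x, y, hp, task, reps) {
  n <- length(y)
  out <- t(vapply(seq_len(reps), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), unique(idx))
    if (length(oob) < 3L) return(c(NA_real_, NA_real_))
    if (task == "classify" && length(unique(y[idx])) < 2L) {
      return(c(NA_real_, NA_real_))
    }
    m <- fit_xgb(x[idx, , drop = FALSE], y[idx], hp, task)
    p <- predict_xgb(m, x[oob, , drop = FALSE])
    if (task == "classify") {
      c(pr_auc(y[oob], p), roc_auc(y[oob], p))
    } else {
      suppressWarnings(c(cor(p, y[oob], method = "spearman"),
                         cor(p, y[oob])))
    }
  }, numeric(2)))
  colnames(out) <- if (task == "classify") {
    c("auprc", "auc")
  } else {
    c("spearman", "pearson")
  }
  as.data.frame(out)
}

#' Train and evaluate a gradient-boosted binder model
#'
#' Partitions the data into a train/test split (default 100/100), selects
#' hyperparameters by seeded random search scored on bootstrap resamples
#' of the training half (mean out-of-bag precision-recall area for
#' classification, Spearman for regression), refits on the full training
#' half and reports held-out metrics: confusion matrix, precision,
#' recall, ROC and precision-recall areas (classification), or Pearson
#' and Spearman correlations of predicted vs measured log10 KD
#' (regression), plus the bootstrap metric distribution and the top-5
#' feature importances.
#'
#' @param features numeric feature data.frame or matrix (a `clone_id` or
#'   `imputed` column is dropped automatically).
#' @param labels 0/1 vector (classify) or numeric log10 KD (regress).
#' @param cfg a [model_config()].
#' @return list: `model`, `hp`, `metrics`, `bootstrap` (data.frame of
#'   per-rep out-of-bag metrics for the selected hyperparameters),
#'   `importance` (top 5), `split` (train/test indices).
#' @export
train_eval <- function(features, labels, cfg = model_config()) {
  x <- features
  if (is.data.frame(x)) {
    x <- x[, !(names(x) %in% c("clone_id", "imputed")), drop = FALSE]
    x <- as.matrix(x)
  }
  storage.mode(x) <- "double"
  n <- nrow(x)
  stopifnot(length(labels) == n)
  if (n < sum(cfg$split)) {
    stop("dataset smaller than the requested ", cfg$split[1], "/",
         cfg$split[2], " train/test split")
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  idx <- sample.int(n)
  train <- idx[seq_len(cfg$split[1])]
  test <- idx[cfg$split[1] + seq_len(cfg$split[2])]
  y_tr <- labels[train]; y_te <- labels[test]
  if (cfg$task == "classify" && length(unique(y_tr)) < 2L) {
    stop("training labels contain a single class")
  }
  draw_hp <- function() {
    list(max_depth = sample(2:6, 1), eta = runif(1, 0.05, 0.3),
         nrounds = sample(c(50L, 100L, 200L), 1),
         subsample = runif(1, 0.7, 1), colsample_bytree = runif(1, 0.7, 1))
  }
  best <- NULL; best_score <- -Inf; best_boot <- NULL
  for (s in seq_len(cfg$search_draws)) {
    hp <- draw_hp()
    bm <- boot_metric(x[train, , drop = FALSE], y_tr, hp, cfg$task,
                      cfg$bootstrap_reps)
    score <- mean(bm[[1L]], na.rm = TRUE)
    if (!is.na(score) && score > best_score) {
      best <- hp; best_score <- score; best_boot <- bm
    }
  }
  model <- fit_xgb(x[train, , drop = FALSE], y_tr, best, cfg$task)
  p <- predict_xgb(model, x[test, , drop = FALSE])
  if (cfg$task == "classify") {
    cm <- confusion_metrics(y_te, as.integer(p >= 0.5))
    metrics <- c(cm, list(auc = roc_auc(y_te, p), auprc = pr_auc(y_te, p),
                          class_balance_train = mean(y_tr)))
  } else {
    metrics <- list(pearson = cor(p, y_te),
                    spearman = cor(p, y_te, method = "spearman"),
                    rmse = sqrt(mean((p - y_te)^2)))
  }
  imp <- tryCatch(xgboost::xgb.importance(model = model),
                  error = function(e) NULL)
  list(model = model, hp = best, metrics = metrics,
       bootstrap = best_boot,
       importance = if (!is.null(imp)) utils::head(as.data.frame(imp), 5L),
       split = list(train = train, test = test),
       predictions = data.frame(index = test, predicted = p,
                                observed = y_te))
}
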