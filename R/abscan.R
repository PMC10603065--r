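#' Pairwise Levenshtein distance matrix
#'
#' @param seqs character vector of (pseudo-)sequences.
#' @return symmetric integer matrix of edit distances, zero diagonal.
#' @export
pairwise_distance_matrix <- function(seqs) {
  stopifnot(length(seqs) >= 1L)
  if (length(seqs) == 1L) return(matrix(0L, 1, 1))
  m <- as.matrix(Biostrings::stringDist(Biostrings::BStringSet(seqs),
                                        method = "levenshtein"))
  dimnames(m) <- NULL
  m
}

#' Density-based clustering of a precomputed distance matrix
#'
#' Runs the OPTICS ordering under `params$max_eps` and extracts flat
#' clusters from the reachability plot, either with the xi steep-area
#' method (default) or with an eps cut at `max_eps` (DBSCAN-equivalent).
#' Output is deterministic given the input order; callers should sort
#' points canonically (descending abundance, then lexicographically)
#' first.
#'
#' @param d symmetric distance matrix, zero diagonal.
#' @param params an [optics_params()].
#' @param extraction `"xi"` or `"eps_cut"`.
#' @return integer labels (1..k; -1 marks noise), with the ordering,
#'   reachability and core distances attached as attribute `"optics"`.
#' @export
density_cluster <- function(d, params, extraction = c("xi", "eps_cut")) {
  extraction <- match.arg(extraction)
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < params$min_pts) {
    labels <- rep(-1L, n)
    attr(labels, "optics") <- list(ordering = seq_len(n),
                                   reach = rep(Inf, n),
                                   core = rep(Inf, n))
    return(labels)
  }
  g <- optics_graph(d, params$min_pts, params$max_eps)
  if (extraction == "xi") {
    cl <- xi_clusters(g$reach[g$ordering], g$pred[g$ordering], g$ordering,
                      params$xi, params$min_pts)
    labels <- extract_xi_labels(g$ordering, cl)
    attr(labels, "xi_intervals") <- cl
  } else {
    labels <- extract_eps_cut(g, params$max_eps)
  }
  attr(labels, "optics") <- g
  labels
}

#' AbScan configuration
#'
#' @param roi region of interest, see [roi_string()].
#' @param seed_threshold percent relative abundance required of the first
#'   (seeding) clustering round, default 0.005.
#' @param iteration_schedule strictly decreasing percent thresholds, one
#'   per clustering round, starting at `seed_threshold` and ending at 0
#'   (everything). Default decade steps `c(0.005, 5e-4, 5e-5, 0)`.
#' @param rescue_min_count noise values whose reduced-space representation
#'   reaches this read count get a singleton cluster, default 2.
#' @param rescue_identity noise values matching an assigned value of equal
#'   length at at least this amino-acid identity join its cluster,
#'   default 0.90.
#' @param alphabet reduced alphabet, see [default_reduced_alphabet()].
#' @param min_pts,xi,max_eps_factor OPTICS controls; `max_eps` is
#'   `max_eps_factor` times the per-round elbow epsilon.
#' @param freeze_epsilon reuse the seeding round's elbow epsilon in all
#'   later rounds instead of recomputing, default FALSE.
#' @param eps_opt explicit epsilon overriding the elbow estimate,
#'   default NULL (data-driven).
#' @return list of class `abscan_config`.
#' @export
abscan_config <- function(roi = "HCDR3", seed_threshold = 0.005,
                          iteration_schedule = c(seed_threshold,
                                                 seed_threshold / 10,
                                                 seed_threshold / 100, 0),
                          rescue_min_count = 2L, rescue_identity = 0.90,
                          alphabet = default_reduced_alphabet(),
                          min_pts = 2L, xi = 0.01, max_eps_factor = 10,
                          freeze_epsilon = FALSE, eps_opt = NULL) {
  stopifnot(all(diff(iteration_schedule) < 0),
            iteration_schedule[length(iteration_schedule)] == 0,
            iteration_schedule[1] == seed_threshold,
            rescue_identity > 0, rescue_identity <= 1,
            rescue_min_count >= 1, min_pts >= 2, xi > 0, xi < 1,
            max_eps_factor >= 1)
  structure(list(roi = roi, seed_threshold = seed_threshold,
                 iteration_schedule = iteration_schedule,
                 rescue_min_count = as.integer(rescue_min_count),
                 rescue_identity = rescue_identity, alphabet = alphabet,
                 min_pts = as.integer(min_pts), xi = xi,
                 max_eps_factor = max_eps_factor,
                 freeze_epsilon = isTRUE(freeze_epsilon),
                 eps_opt = eps_opt),
            class = "abscan_config")
}

# identity between one string and a vector of equal-length strings
hamming_identity <- function(x, ys) {
  vapply(ys, function(y) aa_identity(x, y), numeric(1), USE.NAMES = FALSE)
}

#' AbScan clustering of region-of-interest values
#'
#' Implements abundance-seeded iterative density clustering: the first
#' round clusters all ROI values at or above `seed_threshold` percent
#' relative abundance on reduced-alphabet Levenshtein distances (OPTICS,
#' elbow-derived epsilon); each later round re-clusters the union of one
#' exemplar per existing cluster (its most abundant member) and the
#' still-unassigned values above the round's threshold. Values landing
#' with an exemplar inherit its cluster id; new groups found new ids.
#' After the last round (threshold 0), noise values are rescued by
#' reduced-space read count (singleton cluster) or by equal-length
#' amino-acid identity to an assigned value (joins its cluster); the
#' remainder is discarded as true noise.
#'
#' @param clones clone table (see [annotate_reads()]), pooled across
#'   populations, or a data.frame with columns `roi_value` and `count`.
#' @param cfg an [abscan_config()].
#' @return data.frame: `roi_value`, `pseudo` (reduced-space
#'   representation), `count`, `abundance` (percent), `cluster_id` (NA
#'   for discarded noise), `method`, `status` (core, member,
#'   rescued_count, rescued_identity, discarded_noise).
#' @details Distances are computed between the distinct reduced-space
#'   representations (amino-acid ROI values condensing onto one
#'   pseudo-sequence are clustered as a single point with pooled read
#'   count); every ROI value then carries its pseudo-sequence's cluster.
#' @export
abscan_cluster <- function(clones, cfg = abscan_config()) {
  tab <- roi_count_table(clones, cfg$roi)
  if (nrow(tab) == 0L) {
    return(data.frame(roi_value = character(), pseudo = character(),
                      count = integer(), abundance = numeric(),
                      cluster_id = integer(), method = character(),
                      status = character(), stringsAsFactors = FALSE))
  }
  total <- sum(tab$count)
  aa_pseudo <- reduce_alphabet(tab$roi_value, cfg$alphabet)

  # condense to reduced-space units with pooled counts
  ucount <- tapply(tab$count, aa_pseudo, sum)
  units <- names(ucount)
  ucount <- as.integer(ucount)
  uabund <- 100 * ucount / total
  ord <- order(-uabund, units)
  units <- units[ord]; ucount <- ucount[ord]; uabund <- uabund[ord]
  n <- length(units)

  cluster_id <- rep(NA_integer_, n)
  seen <- rep(FALSE, n)
  next_id <- 0L
  eps_frozen <- NULL

  for (thr in cfg$iteration_schedule) {
    seen <- seen | uabund >= thr
    active <- which(seen)
    if (length(active) < cfg$min_pts) next
    # exemplar per existing cluster: its most abundant member (canonical
    # order puts it first); exemplars anchor cluster ids across rounds
    exemplar_idx <- vapply(unique(cluster_id[!is.na(cluster_id)]),
                           function(id) which(cluster_id == id)[1L],
                           integer(1))
    d <- pairwise_distance_matrix(units[active])
    eps <- if (!is.null(cfg$eps_opt)) {
      cfg$eps_opt
    } else if (cfg$freeze_epsilon && !is.null(eps_frozen)) {
      eps_frozen
    } else {
      elbow_epsilon(d, k = cfg$min_pts)
    }
    if (is.null(eps_frozen)) eps_frozen <- eps
    params <- optics_params(min_pts = cfg$min_pts, eps_opt = eps,
                            max_eps = cfg$max_eps_factor * eps, xi = cfg$xi)
    lab <- density_cluster(d, params)
    is_ex <- active %in% exemplar_idx
    new_assign <- rep(NA_integer_, n)
    for (cl in setdiff(unique(lab), -1L)) {
      members <- which(lab == cl)
      ex_in <- members[is_ex[members]]
      id <- if (length(ex_in)) {
        # inherit from the most abundant exemplar in the group
        # (canonical order: lowest index)
        cluster_id[active[min(ex_in)]]
      } else {
        next_id <- next_id + 1L
        next_id
      }
      new_assign[active[members]] <- id
    }
    # values clustered in an earlier round but noise in this one keep
    # their id (adding points never justifies unassignment)
    keep <- is.na(new_assign) & !is.na(cluster_id)
    new_assign[keep] <- cluster_id[keep]
    cluster_id <- new_assign
  }

  ustatus <- rep(NA_character_, n)
  ustatus[!is.na(cluster_id)] <- "member"

  # rescue 1: noise units with sufficient pooled (reduced-space) count
  # get their own singleton cluster
  for (i in which(is.na(cluster_id))) {
    if (ucount[i] >= cfg$rescue_min_count) {
      next_id <- next_id + 1L
      cluster_id[i] <- next_id
      ustatus[i] <- "rescued_count"
    }
  }

  # rescue 2: noise units whose amino-acid value matches an assigned
  # value of equal length at >= rescue_identity join that cluster
  aa_unit <- match(aa_pseudo, units)
  aa_len <- nchar(tab$roi_value)
  assigned_aa <- which(!is.na(cluster_id[aa_unit]))
  for (i in which(is.na(cluster_id))) {
    vals_i <- which(aa_unit == i)
    hit_cluster <- NA_integer_; hit_ident <- -Inf
    for (v in vals_i) {
      cand <- assigned_aa[aa_len[assigned_aa] == aa_len[v]]
      if (!length(cand)) next
      ident <- hamming_identity(tab$roi_value[v], tab$roi_value[cand])
      ok <- ident >= cfg$rescue_identity
      if (any(ok) && max(ident[ok]) > hit_ident) {
        hit_ident <- max(ident[ok])
        j <- cand[ok][which.max(ident[ok])]
        hit_cluster <- cluster_id[aa_unit[j]]
      }
    }
    if (!is.na(hit_cluster)) {
      cluster_id[i] <- hit_cluster
      ustatus[i] <- "rescued_identity"
    } else {
      ustatus[i] <- "discarded_noise"
    }
  }

  # renumber ids by first appearance in canonical unit order
  ok <- !is.na(cluster_id)
  cluster_id[ok] <- match(cluster_id[ok], unique(cluster_id[ok]))

  # expand to amino-acid ROI values
  out <- data.frame(roi_value = tab$roi_value, pseudo = aa_pseudo,
                    count = tab$count,
                    abundance = 100 * tab$count / total,
                    cluster_id = cluster_id[aa_unit],
                    method = "abscan",
                    status = ustatus[aa_unit],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$abundance, out$roi_value), , drop = FALSE]
  row.names(out) <- NULL
  # the single most abundant member of each cluster is its core
  lead <- !is.na(out$cluster_id) & out$status == "member" &
    !duplicated(out$cluster_id)
  out$status[lead] <- "core"
  out
}

# Aggregate a clone table (or a roi_value/count data.frame) into unique
# ROI values with pooled read counts.
roi_count_table <- function(clones, roi) {
  if (all(c("roi_value", "count") %in% names(clones))) {
    vals <- clones$roi_value
    cnt <- clones$count
  } else {
    vals <- roi_string(clones, roi)
    cnt <- clones$consensus_count
  }
  agg <- tapply(cnt, vals, sum)
  data.frame(roi_value = names(agg), count = as.integer(agg),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Traditional clonotyping
#'
#' Groups (ROI value, scaffold) pairs into clonotypes: two values join
#' when they share the scaffold (the V/J surrogate), have equal length
#' and at least `identity` pairwise identity; clonotypes are the
#' connected components (single linkage). Ids are ordered by each
#' component's lexicographically smallest member.
#'
#' @param clones clone table.
#' @param roi region of interest, default HCDR3.
#' @param identity identity threshold on equal-length strings,
#'   default 0.90.
#' @return data.frame: `roi_value`, `scaffold`, `count`, `cluster_id`,
#'   `method`, `status`.
#' @export
traditional_clonotype <- function(clones, roi = "HCDR3", identity = 0.90) {
  vals <- roi_string(clones, roi)
  key <- paste(vals, clones$scaffold, sep = "\r")
  agg <- tapply(clones$consensus_count, key, sum)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  tab <- data.frame(roi_value = vapply(parts, `[`, "", 1L),
                    scaffold = vapply(parts, `[`, "", 2L),
                    count = as.integer(agg),
                    stringsAsFactors = FALSE, row.names = NULL)
  n <- nrow(tab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  grp <- split(seq_len(n),
               paste(tab$scaffold, nchar(tab$roi_value)))
  for (g in grp) {
    if (length(g) < 2L) next
    dm <- 1 - as.matrix(Biostrings::stringDist(
      Biostrings::BStringSet(tab$roi_value[g]),
      method = "hamming")) / nchar(tab$roi_value[g[1]])
    edges <- which(dm >= identity & upper.tri(dm), arr.ind = TRUE)
    for (e in seq_len(nrow(edges))) {
      ra <- find(g[edges[e, 1]]); rb <- find(g[edges[e, 2]])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  comp_min <- tapply(tab$roi_value, root, min)
  comp_rank <- rank(comp_min, ties.method = "first")
  tab$cluster_id <- as.integer(comp_rank[as.character(root)])
  tab$method <- "clonotype"
  tab$status <- "member"
  tab
}

#' 100 percent identity clustering
#'
#' One cluster per distinct ROI string, across populations. Ids follow
#' descending pooled count, then lexicographic order.
#'
#' @inheritParams traditional_clonotype
#' @return data.frame: `roi_value`, `count`, `cluster_id`, `method`,
#'   `status`.
#' @export
identity_cluster <- function(clones, roi = "HCDR3") {
  tab <- roi_count_table(clones, roi)
  ord <- order(-tab$count, tab$roi_value)
  tab <- tab[ord, , drop = FALSE]
  tab$cluster_id <- seq_len(nrow(tab))
  tab$method <- "identity"
  tab$status <- "member"
  row.names(tab) <- NULL
  tab
}
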