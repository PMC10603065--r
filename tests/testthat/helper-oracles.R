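# Independent oracles and fixture builders used across the suite.

# dynamic-programming Levenshtein distance (independent of the
# implementation path, which delegates to Biostrings)
lev_oracle <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  m <- matrix(0L, length(av) + 1L, length(bv) + 1L)
  m[, 1] <- 0:length(av)
  m[1, ] <- 0:length(bv)
  for (i in seq_along(av)) {
    for (j in seq_along(bv)) {
      m[i + 1, j + 1] <- min(m[i, j + 1] + 1L, m[i + 1, j] + 1L,
                             m[i, j] + (av[i] != bv[j]))
    }
  }
  m[length(av) + 1L, length(bv) + 1L]
}

# brute-force density-reachability components (DBSCAN semantics):
# core point = >= min_pts points within eps (self included); clusters =
# maximal density-connected sets; everything else is noise
density_reachability_oracle <- function(d, min_pts, eps) {
  n <- nrow(d)
  core <- vapply(seq_len(n), function(i) sum(d[i, ] <= eps) >= min_pts,
                 logical(1))
  labels <- rep(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != -1L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- i
    while (length(queue)) {
      p <- queue[1L]
      queue <- queue[-1L]
      nb <- which(d[p, ] <= eps & labels == -1L)
      labels[nb] <- cl
      queue <- c(queue, nb[core[nb]])
    }
  }
  labels
}

# canonical form of a labeling: clusters renamed by first appearance,
# noise kept as -1; partitions are equal iff canonical forms are equal
canon_labels <- function(labels) {
  out <- labels
  seen <- unique(labels[labels != -1L])
  out[labels != -1L] <- match(labels[labels != -1L], seen)
  out
}

# random instance with known density structure: groups built on disjoint
# letter blocks (inter-group distances far beyond max_eps) whose members
# are the center plus distinct single-edit variants, giving uniform
# intra-group density (all reachabilities 1, no duplicate points)
make_group_instance <- function(n_groups, sizes, letters_pool = letters[1:12]) {
  stopifnot(n_groups <= length(letters_pool))
  seqs <- character(0)
  truth <- integer(0)
  for (g in seq_len(n_groups)) {
    center <- strrep(letters_pool[g], 25)
    pos <- sample(25, sizes[g])
    for (s in seq_len(sizes[g])) {
      x <- center
      if (s > 1L) {
        substr(x, pos[s], pos[s]) <-
          sample(setdiff(letters_pool, letters_pool[g]), 1)
      }
      seqs <- c(seqs, x)
      truth <- c(truth, g)
    }
  }
  list(seqs = seqs, truth = truth)
}

# 0/1 classification oracles (independent of pROC / the package code)
roc_auc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

pr_auc_oracle <- function(labels, scores) {
  # walk thresholds from high to low, integrating precision over recall
  thr <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(labels == 1)
  prev_r <- 0
  area <- 0
  for (t in thr) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    r <- tp / npos
    p <- tp / sum(pred)
    area <- area + (r - prev_r) * p
    prev_r <- r
  }
  area
}

# all nucleotide strings at Hamming distance exactly m from an 8-mer
bc_neighbors <- function(b, m) {
  if (m == 0) return(b)
  out <- character(0)
  combs <- utils::combn(8, m)
  alt <- function(ch) setdiff(c("A", "C", "G", "T"), ch)
  for (ci in seq_len(ncol(combs))) {
    pos <- combs[, ci]
    grids <- expand.grid(lapply(pos, function(p) alt(substr(b, p, p))),
                         stringsAsFactors = FALSE)
    for (gi in seq_len(nrow(grids))) {
      x <- b
      for (k in seq_along(pos)) {
        substr(x, pos[k], pos[k]) <- grids[gi, k]
      }
      out <- c(out, x)
    }
  }
  out
}

# fixed two-scaffold reference used by annotation tests
test_scaffolds <- function() {
  list(
    scaffold_ref("VH1::VL1", c(
      fwl1 = "DIQMTQSPSSLSASVGDRVTITC", fwl2 = "WYQQKPGKAPKLLIY",
      fwl3 = "GVPSRFSGSGSGTDFTLTISSLQPEDFATYYC", fwl4 = "FGQGTKVEIK",
      fwh1 = "EVQLVESGGGLVQPGGSLRLSCAAS", fwh2 = "WVRQAPGKGLEWVS",
      fwh3 = "RFTISRDNSKNTLYLQMNSLRAEDTAVYYCAR", fwh4 = "WGQGTLVTVSS")),
    scaffold_ref("VH2::VL2", c(
      fwl1 = "EIVLTQSPATLSLSPGERATLSC", fwl2 = "WYQQKPGQAPRLLIY",
      fwl3 = "GIPARFSGSGSGTDFTLTISSLEPEDFAVYYC", fwl4 = "FGGGTKVEIK",
      fwh1 = "QVQLVQSGAEVKKPGASVKVSCKAS", fwh2 = "WVRQAPGQGLEWMG",
      fwh3 = "RVTMTRDTSTSTVYMELSSLRSEDTAVYYCAR", fwh4 = "WGQGTTVTVSS"))
  )
}

test_cdrs <- function(hcdr3 = "ARDYWGSSYFDY") {
  c(lcdr1 = "QSISSY", lcdr2 = "AASSLQS", lcdr3 = "QQSYSTPLT",
    hcdr1 = "GFTFSSYA", hcdr2 = "ISGSGGST", hcdr3 = hcdr3)
}

# nucleotide read for a clone, optionally barcoded
make_clone_read <- function(scaffold, cdrs, bc5 = NULL, bc3 = NULL) {
  aa <- abselect:::assemble_scfv(scaffold, cdrs)
  nt <- abselect:::reverse_translate(aa)
  if (!is.null(bc5)) {
    nt <- paste0(bc5, nt, abselect:::revcomp(bc3))
  }
  nt
}

# minimal clone-table row(s) for quantify/rank tests
make_clones <- function(hcdr3, population, concentration, count,
                        lcdr3 = "QQSYSTPLT", scaffold = "VH1::VL1",
                        sequence_aa = NULL) {
  n <- length(hcdr3)
  if (is.null(sequence_aa)) {
    sequence_aa <- paste0("SEQ", seq_len(n), "_", hcdr3)
  }
  data.frame(
    clone_id = paste0("c", seq_len(n)),
    sequence_aa = sequence_aa,
    scaffold = rep_len(scaffold, n),
    lcdr1_aa = "QSISSY", lcdr2_aa = "AAS", lcdr3_aa = rep_len(lcdr3, n),
    hcdr1_aa = "GFTFSSYA", hcdr2_aa = "ISGSGGST", hcdr3_aa = hcdr3,
    fwl1_aa = "DIQ", fwl2_aa = "WYQ", fwl3_aa = "GVP", fwl4_aa = "FGQ",
    fwh1_aa = "EVQ", fwh2_aa = "WVR", fwh3_aa = "RFT", fwh4_aa = "WGQ",
    fr_identity = 1,
    population = rep_len(population, n),
    concentration = rep_len(concentration, n),
    consensus_count = count,
    liabilities = 0L,
    stringsAsFactors = FALSE)
}

write_mini_fastq <- function(records, path) {
  writeLines(unlist(lapply(records, function(r) {
    c(paste0("@", r$id), r$seq, "+", r$qual)
  })), path)
  path
}
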