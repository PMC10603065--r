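AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")

# one codon per residue (highest-usage E. coli codon); used to build
# nucleotide reads from simulated amino-acid clones
codon_table <- c(A = "GCG", C = "TGC", D = "GAT", E = "GAA", F = "TTT",
                 G = "GGC", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
                 M = "ATG", N = "AAC", P = "CCG", Q = "CAG", R = "CGT",
                 S = "AGC", T = "ACC", V = "GTG", W = "TGG", Y = "TAT")

reverse_translate <- function(aa) {
  vapply(aa, function(s) {
    paste(codon_table[strsplit(s, "")[[1]]], collapse = "")
  }, "", USE.NAMES = FALSE)
}

random_aa <- function(n_len) paste(sample(AA20, n_len, replace = TRUE),
                                   collapse = "")

#' Campaign simulation configuration
#'
#' Defaults emulate the statistical structure of a two-round display
#' campaign: power-law (Zipf) clonal abundance over families built on a
#' handful of fixed scaffolds, two sort concentrations (early 10 nM,
#' late 1 nM) per target arm, substitution-type PCR/sequencing errors
#' inflating raw diversity, and a latent per-family affinity that is
#' uncoupled from late-round sampling unless `beta > 0`.
#'
#' @param n_scaffolds fixed scaffolds in the library, default 4.
#' @param n_families true clonal families, default 50.
#' @param zipf_exponent Zipf exponent of family abundance, default 1.5.
#' @param intra_family_edits maximum CDR substitutions of a variant from
#'   its family prototype, default 2.
#' @param mean_variants mean number of extra variants per family
#'   (Poisson), default 2.
#' @param nt_error_rate per-base substitution error rate, default 0.001.
#' @param reads_per_population reads per (target, concentration)
#'   population, default 50000.
#' @param n_targets selection arms sharing the family pool (each with its
#'   own Zipf rank order), default 3.
#' @param affinity_mean,affinity_sd latent log10 KD (molar) distribution.
#'   The defaults (-8.1, 2.4) are the normal quantile match to a
#'   selection output with 64% sub-nanomolar binders and 19% of clones
#'   at or above 1 uM.
#' @param beta coupling of affinity to late-round sampling weight
#'   (`late weight = early weight * exp(beta * (-log10 KD))`,
#'   renormalized); default 0, i.e. abundance uncoupled from affinity.
#' @param quality_low_fraction fraction of reads carrying one sub-40
#'   Phred base, default 0.02.
#' @param barcode_error_rate per-read probability of one barcode-base
#'   error, default 0.001.
#' @param n_bins epitope bins assigned at the family level, default 5.
#' @param n_characterized clones in the characterization table,
#'   default 200 (capped at the number of distinct clones).
#' @param seed RNG seed (mandatory).
#' @return list of class `campaign_config`.
#' @export
campaign_config <- function(n_scaffolds = 4L, n_families = 50L,
                            zipf_exponent = 1.5, intra_family_edits = 2L,
                            mean_variants = 2, nt_error_rate = 0.001,
                            reads_per_population = 50000L, n_targets = 3L,
                            affinity_mean = -8.1, affinity_sd = 2.4,
                            beta = 0, quality_low_fraction = 0.02,
                            barcode_error_rate = 0.001, n_bins = 5L,
                            n_characterized = 200L, seed) {
  stopifnot(n_families >= 2L, !missing(seed),
            nt_error_rate >= 0, nt_error_rate <= 1,
            quality_low_fraction >= 0, quality_low_fraction <= 1,
            barcode_error_rate >= 0, barcode_error_rate <= 1,
            n_targets >= 1L)
  structure(as.list(environment()), class = "campaign_config")
}

random_barcodes <- function(n, min_dist = 5L) {
  out <- character(0)
  while (length(out) < n) {
    cand <- paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE),
                  collapse = "")
    if (!length(out) ||
        min(hamming_to(out, cand)) >= min_dist) {
      out <- c(out, cand)
    }
  }
  out
}

simulate_scaffolds <- function(n) {
  fr_len <- c(fwl1 = 23L, fwl2 = 15L, fwl3 = 32L, fwl4 = 10L,
              fwh1 = 25L, fwh2 = 14L, fwh3 = 32L, fwh4 = 11L)
  lapply(seq_len(n), function(i) {
    frs <- vapply(fr_len, random_aa, "")
    scaffold_ref(sprintf("VH%d::VL%d", i, i), frs)
  })
}

mutate_aa <- function(seq, n_edits) {
  if (n_edits == 0L) return(seq)
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), min(n_edits, length(ch)))
  for (p in pos) ch[p] <- sample(setdiff(AA20, ch[p]), 1)
  paste(ch, collapse = "")
}

inject_substitutions <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  len <- nchar(seqs)
  n_err <- rbinom(length(seqs), len, rate)
  hit <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample(len[i], n_err[i])
    for (p in pos) {
      old <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(bases, old), 1)
    }
  }
  seqs
}

#' Simulate a selection campaign with known ground truth
#'
#' Generates scaffolds, clonal families (prototype CDRs, latent log10 KD,
#' epitope bin), per-family variants, and barcoded reads for every
#' (target arm, sort concentration) population: families are drawn with
#' Zipf weights in the early round and with affinity-tilted weights
#' (`beta`) in the late round; substitution errors, occasional barcode
#' errors and occasional sub-threshold quality bases are injected. All
#' output is deterministic for a fixed seed.
#'
#' @param cfg a [campaign_config()].
#' @param outdir optional directory; when given, writes one FASTQ per
#'   population plus `barcodes.tsv`, `scaffolds.json`, `truth_reads.tsv`,
#'   `truth_families.tsv` and `characterization.tsv`.
#' @return list: `reads` (pooled read table with barcodes attached),
#'   `barcodes` ([barcode_spec()]), `scaffolds`, `truth` (list
#'   `read_map`, `families`, `variants`, `weights`), `characterization`,
#'   and `files` when `outdir` was given.
#' @export
simulate_campaign <- function(cfg, outdir = NULL) {
  stopifnot(inherits(cfg, "campaign_config"))
  oldseed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, globalenv()))
  set.seed(cfg$seed)

  scaffolds <- simulate_scaffolds(cfg$n_scaffolds)
  scaffold_names <- vapply(scaffolds, function(s) s$name, "")

  cdr_len <- function() c(lcdr1 = sample(6:12, 1), lcdr2 = sample(3:7, 1),
                          lcdr3 = sample(8:11, 1), hcdr1 = 8L,
                          hcdr2 = sample(7:10, 1), hcdr3 = sample(10:18, 1))
  families <- data.frame(
    family_id = sprintf("F%03d", seq_len(cfg$n_families)),
    scaffold = scaffold_names[rep_len(seq_len(cfg$n_scaffolds),
                                      cfg$n_families)],
    log10_kd = rnorm(cfg$n_families, cfg$affinity_mean, cfg$affinity_sd),
    epitope_bin = paste0("bin", sample.int(cfg$n_bins, cfg$n_families,
                                           replace = TRUE)),
    stringsAsFactors = FALSE)
  proto <- lapply(seq_len(cfg$n_families), function(i) {
    vapply(cdr_len(), random_aa, "")
  })

  # per-family variants: prototype plus Poisson-many edited copies
  variants <- list()
  for (i in seq_len(cfg$n_families)) {
    n_var <- 1L + rpois(1, cfg$mean_variants)
    sc <- scaffolds[[match(families$scaffold[i], scaffold_names)]]
    for (v in seq_len(n_var)) {
      cdrs <- proto[[i]]
      if (v > 1L) {
        n_ed <- sample(seq_len(cfg$intra_family_edits), 1)
        slot <- sample(names(cdrs), 1)
        cdrs[slot] <- mutate_aa(cdrs[slot], n_ed)
      }
      aa <- assemble_scfv(sc, cdrs)
      variants[[length(variants) + 1L]] <- list(
        family = i, variant = v, cdrs = cdrs, aa = aa,
        weight = 0.2^(v - 1L),
        log10_kd = families$log10_kd[i] + rnorm(1, 0, 0.3))
    }
  }
  var_tab <- data.frame(
    family_id = families$family_id[vapply(variants, `[[`, 0L, "family")],
    variant = vapply(variants, `[[`, 0L, "variant"),
    sequence_aa = vapply(variants, `[[`, "", "aa"),
    log10_kd = vapply(variants, `[[`, 0, "log10_kd"),
    stringsAsFactors = FALSE)
  for (r in cdr_names) {
    var_tab[[paste0(r, "_aa")]] <-
      vapply(variants, function(v) v$cdrs[[r]], "")
  }
  var_tab$scaffold <- families$scaffold[match(var_tab$family_id,
                                              families$family_id)]
  var_tab$clone_id <- sprintf("V%04d", seq_len(nrow(var_tab)))
  var_nt <- reverse_translate(var_tab$sequence_aa)

  # within-family variant shares
  var_share <- unlist(lapply(split(vapply(variants, `[[`, 0, "weight"),
                                   var_tab$family_id),
                             function(w) w / sum(w)), use.names = FALSE)
  # split() reorders by family_id; realign
  var_share <- var_share[order(order(var_tab$family_id,
                                     var_tab$variant))]

  targets <- sprintf("T%d", seq_len(cfg$n_targets))
  concentrations <- c(early = "10nM", late = "1nM")
  pops <- expand.grid(population = targets,
                      concentration = unname(concentrations),
                      stringsAsFactors = FALSE)
  bc5 <- random_barcodes(nrow(pops))
  bc3 <- random_barcodes(nrow(pops))
  barcodes <- barcode_spec(pops$population, pops$concentration, bc5, bc3)

  zipf_w <- function(ranks, s) {
    w <- ranks^(-s)
    w / sum(w)
  }
  fam_rank <- lapply(targets, function(t) sample.int(cfg$n_families))
  names(fam_rank) <- targets

  reads_list <- list()
  truth_list <- list()
  weights <- list()
  for (pi in seq_len(nrow(pops))) {
    pop <- pops$population[pi]; conc <- pops$concentration[pi]
    we <- zipf_w(fam_rank[[pop]], cfg$zipf_exponent)
    w <- if (conc == concentrations[["late"]]) {
      wl <- we * exp(cfg$beta * (-families$log10_kd))
      wl / sum(wl)
    } else {
      we
    }
    pv <- w[match(var_tab$family_id, families$family_id)] * var_share
    counts <- as.vector(rmultinom(1, cfg$reads_per_population, pv))
    vi <- rep(seq_len(nrow(var_tab)), counts)
    vi <- vi[sample.int(length(vi))] # shuffle read order
    nt <- inject_substitutions(var_nt[vi], cfg$nt_error_rate)
    # attach barcodes (sense bc5, reverse-complement of bc3 at the tail)
    bc_tail <- revcomp(barcodes$bc3[pi])
    full <- paste0(barcodes$bc5[pi], nt, bc_tail)
    n_bc_err <- rbinom(length(full), 1, cfg$barcode_error_rate)
    for (i in which(n_bc_err > 0L)) {
      p <- sample(c(1:8, nchar(full[i]) - 0:7), 1)
      old <- substr(full[i], p, p)
      substr(full[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    }
    qual <- strrep("I", nchar(full))
    low <- which(runif(length(qual)) < cfg$quality_low_fraction)
    for (i in low) {
      p <- sample(nchar(qual[i]), 1)
      substr(qual[i], p, p) <- "5" # Phred 20
    }
    ids <- sprintf("%s_%s_r%06d", pop, conc, seq_along(full))
    reads_list[[pi]] <- data.frame(read_id = ids, nt_seq = full,
                                   qual = qual,
                                   population = NA_character_,
                                   stringsAsFactors = FALSE)
    truth_list[[pi]] <- data.frame(read_id = ids, population = pop,
                                   concentration = conc,
                                   family_id = var_tab$family_id[vi],
                                   clone_id = var_tab$clone_id[vi],
                                   stringsAsFactors = FALSE)
    weights[[paste(pop, conc, sep = "_")]] <-
      setNames(w, families$family_id)
  }
  reads <- do.call(rbind, reads_list)
  truth_reads <- do.call(rbind, truth_list)

  n_char <- min(cfg$n_characterized, nrow(var_tab))
  char_rows <- sort(sample.int(nrow(var_tab), n_char))
  characterization <- do.call(rbind, lapply(targets, function(t) {
    data.frame(clone_id = var_tab$clone_id[char_rows],
               sequence_aa = var_tab$sequence_aa[char_rows],
               family_id = var_tab$family_id[char_rows],
               target = t,
               kd_molar = 10^(var_tab$log10_kd[char_rows] +
                                rnorm(n_char, 0, 0.2)),
               epitope_bin = families$epitope_bin[
                 match(var_tab$family_id[char_rows], families$family_id)],
               stringsAsFactors = FALSE)
  }))

  out <- list(reads = reads, barcodes = barcodes, scaffolds = scaffolds,
              truth = list(read_map = truth_reads, families = families,
                           variants = var_tab, weights = weights),
              characterization = characterization)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    for (pi in seq_len(nrow(pops))) {
      f <- file.path(outdir, sprintf("%s_%s.fastq", pops$population[pi],
                                     pops$concentration[pi]))
      write_fastq(reads_list[[pi]], f)
      files <- c(files, f)
    }
    write_barcode_table(barcodes, file.path(outdir, "barcodes.tsv"))
    write_scaffolds(scaffolds, file.path(outdir, "scaffolds.json"))
    write.table(truth_reads, file.path(outdir, "truth_reads.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(families, file.path(outdir, "truth_families.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(characterization, file.path(outdir, "characterization.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    out$files <- c(files,
                   file.path(outdir, c("barcodes.tsv", "scaffolds.json",
                                       "truth_reads.tsv",
                                       "truth_families.tsv",
                                       "characterization.tsv")))
  }
  out
}

#' Ground-truth recovery metrics for a pipeline run
#'
#' Compares pipeline outputs on a simulated campaign against the
#' generator's ground truth: adjusted Rand index between cluster
#' assignments and true families (over unique ROI values, each attributed
#' to its majority family of origin), total-variation distance between
#' observed and configured family frequencies per population, and the
#' Spearman correlation between per-family fold enrichment and latent
#' affinity.
#'
#' @param assignments AbScan (or other) assignment table on the HCDR3
#'   ROI.
#' @param clones annotated clone table from the pipeline.
#' @param read_map pipeline read_id -> clone_id map
#'   ([annotate_reads()]).
#' @param truth the `truth` element of [simulate_campaign()].
#' @return list: `ari`, `freq_tvd` (worst population), `n_clusters`,
#'   `n_families_observed`, `enrich_affinity_spearman`.
#' @export
truth_metrics <- function(assignments, clones, read_map, truth) {
  if (!all(read_map$read_id %in% truth$read_map$read_id)) {
    stop("read ids in the pipeline output are missing from the ground truth")
  }
  tr <- truth$read_map[match(read_map$read_id, truth$read_map$read_id), ]
  uc <- clones[!duplicated(clones$clone_id), c("clone_id", "hcdr3_aa")]
  hcdr3 <- uc$hcdr3_aa[match(read_map$clone_id, uc$clone_id)]
  # majority family of origin per unique HCDR3
  maj <- vapply(split(tr$family_id, hcdr3), function(f) {
    names(sort(table(f), decreasing = TRUE))[1]
  }, "")
  m <- match(names(maj), assignments$roi_value)
  cl <- assignments$cluster_id[m]
  keep <- !is.na(cl)
  ari <- mclust::adjustedRandIndex(cl[keep], maj[keep])

  # family frequency recovery per population (early rounds carry the
  # configured Zipf weights; late rounds the tilted weights)
  tvd <- vapply(names(truth$weights), function(k) {
    parts <- strsplit(k, "_")[[1]]
    sel <- tr$population == parts[1] & tr$concentration == parts[2]
    if (!any(sel)) return(NA_real_)
    obs <- table(factor(tr$family_id[sel],
                        levels = names(truth$weights[[k]])))
    obs <- as.numeric(obs) / sum(obs)
    sum(abs(obs - truth$weights[[k]])) / 2
  }, numeric(1))

  # per-family enrichment vs latent affinity (pooled over arms)
  rho <- tryCatch({
    ec <- table(tr$family_id[tr$concentration == "10nM"])
    lc <- table(tr$family_id[tr$concentration == "1nM"])
    fams <- truth$families$family_id
    e <- as.numeric(ec[fams]); e[is.na(e)] <- 0
    l <- as.numeric(lc[fams]); l[is.na(l)] <- 0
    fold <- (l + 0.5) / (e + 0.5)
    suppressWarnings(cor(fold, -truth$families$log10_kd,
                         method = "spearman"))
  }, error = function(e) NA_real_)

  list(ari = ari, freq_tvd = max(tvd, na.rm = TRUE),
       n_clusters = length(unique(assignments$cluster_id[
         !is.na(assignments$cluster_id)])),
       n_families_observed = length(unique(tr$family_id)),
       enrich_affinity_spearman = rho)
}
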