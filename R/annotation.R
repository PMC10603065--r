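# Region layout of the scFv: VL - linker - VH, frameworks fixed per
# scaffold, CDR slots between consecutive frameworks of each chain.
fr_names <- c("fwl1", "fwl2", "fwl3", "fwl4", "fwh1", "fwh2", "fwh3", "fwh4")
cdr_names <- c("lcdr1", "lcdr2", "lcdr3", "hcdr1", "hcdr2", "hcdr3")

#' Build a scaffold reference
#'
#' A scaffold (a fixed VH/VL germline pair used to build the library)
#' is described by its eight framework amino-acid strings in scFv order
#' (VL frameworks 1-4, then VH frameworks 1-4; the inter-chain linker is
#' carried separately and sits between fwl4 and fwh1). CDRs are the
#' variable spans between consecutive frameworks of a chain.
#'
#' @param name scaffold (germline pair) label, e.g. "IGHV1-24::IGKV1-12".
#' @param frameworks named character vector with elements
#'   `fwl1..fwl4, fwh1..fwh4`.
#' @param linker inter-chain linker amino-acid string.
#' @return list of class `scaffold_ref`.
#' @export
scaffold_ref <- function(name, frameworks, linker = "GGGGSGGGGSGGGGS") {
  stopifnot(all(fr_names %in% names(frameworks)), all(nzchar(frameworks)))
  structure(list(name = name,
                 frameworks = vapply(frameworks[fr_names], toupper, ""),
                 linker = toupper(linker)),
            class = "scaffold_ref")
}

#' Read / write scaffold references (JSON)
#'
#' @param path JSON file path.
#' @return list of `scaffold_ref` (read); `path` invisibly (write).
#' @export
read_scaffolds <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(x, function(s) scaffold_ref(s$name, unlist(s$frameworks), s$linker))
}

#' @rdname read_scaffolds
#' @param scaffolds list of `scaffold_ref`.
#' @export
write_scaffolds <- function(scaffolds, path) {
  jsonlite::write_json(
    lapply(scaffolds, function(s)
      list(name = s$name, frameworks = as.list(s$frameworks), linker = s$linker)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# Assemble a full scFv amino-acid sequence from a scaffold and six CDRs.
# Used by the simulator and by round-trip tests.
assemble_scfv <- function(scaffold, cdrs) {
  f <- scaffold$frameworks
  paste0(f["fwl1"], cdrs["lcdr1"], f["fwl2"], cdrs["lcdr2"], f["fwl3"],
         cdrs["lcdr3"], f["fwl4"], scaffold$linker,
         f["fwh1"], cdrs["hcdr1"], f["fwh2"], cdrs["hcdr2"], f["fwh3"],
         cdrs["hcdr3"], f["fwh4"])
}

translate_frames <- function(nt_seq) {
  s <- Biostrings::DNAStringSet(nt_seq)
  lapply(0:2, function(off) {
    w <- Biostrings::width(s) - off
    w <- w - (w %% 3L)
    sub <- Biostrings::subseq(s, start = off + 1L, width = pmax(w, 0L))
    as.character(suppressWarnings(
      Biostrings::translate(sub, if.fuzzy.codon = "X")))
  })
}

# Exact positions of one framework string in a vector of aa sequences.
locate_fr_exact <- function(aa, pattern) {
  pos <- regexpr(pattern, aa, fixed = TRUE)
  ifelse(pos > 0L, as.integer(pos), NA_integer_)
}

# Fuzzy (substitution-only) position of `pattern` in a single sequence.
locate_fr_fuzzy <- function(aa1, pattern, max_sub = 2L) {
  m <- utils::aregexec(pattern, aa1, fixed = TRUE,
                       max.distance = list(sub = max_sub, ins = 0, del = 0))[[1]]
  if (m[1] > 0L) as.integer(m[1]) else NA_integer_
}

aa_identity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (!length(a)) return(numeric())
  w <- nchar(a[1])
  mean_per <- colSums(matrix(charToRaw(paste(a, collapse = "")), nrow = w) ==
                      matrix(charToRaw(paste(b, collapse = "")), nrow = w)) / w
  mean_per
}

# Anchor-extract the 16 regions of one scaffold from translated chains.
# Returns a data.frame (one row per sequence) with region columns,
# framework identity and an ok flag.
extract_regions <- function(aa, scaffold) {
  n <- length(aa)
  frs <- scaffold$frameworks
  pos <- matrix(NA_integer_, n, 8, dimnames = list(NULL, fr_names))
  for (f in fr_names) pos[, f] <- locate_fr_exact(aa, frs[[f]])
  # fuzzy rescue of missing anchors, but only for sequences that already
  # hit most anchors of this scaffold exactly (cheap rejection of reads
  # belonging to other scaffolds)
  n_exact <- rowSums(!is.na(pos))
  rescue <- which(n_exact >= 6L & n_exact < 8L)
  for (i in rescue) {
    for (f in fr_names[is.na(pos[i, ])]) {
      pos[i, f] <- locate_fr_fuzzy(aa[i], frs[[f]])
    }
  }
  flen <- nchar(frs)
  ends <- sweep(pos, 2, flen[fr_names], function(p, l) p + l - 1L)
  ok <- rowSums(is.na(pos)) == 0L
  # regions must appear in layout order with non-negative CDR widths
  ord_ok <- ok
  for (j in seq_len(7)) {
    gap_min <- if (j == 4L) nchar(scaffold$linker) else 1L
    ord_ok <- ord_ok & !is.na(pos[, j + 1]) & !is.na(ends[, j]) &
      (pos[, j + 1] - ends[, j] - 1L >= gap_min)
  }
  out <- data.frame(matrix(NA_character_, n, 14), stringsAsFactors = FALSE)
  names(out) <- c(paste0(fr_names, "_aa"), paste0(cdr_names, "_aa"))
  idx <- which(ord_ok)
  if (length(idx)) {
    for (j in seq_along(fr_names)) {
      out[idx, paste0(fr_names[j], "_aa")] <-
        substr(aa[idx], pos[idx, j], ends[idx, j])
    }
    cdr_after <- c(1L, 2L, 3L, 5L, 6L, 7L) # framework index preceding each CDR
    for (k in seq_along(cdr_names)) {
      j <- cdr_after[k]
      out[idx, paste0(cdr_names[k], "_aa")] <-
        substr(aa[idx], ends[idx, j] + 1L, pos[idx, j + 1] - 1L)
    }
    # linker occupies the fwl4 -> fwh1 gap; CDR slot 4 in layout is skipped
    fr_cat <- do.call(paste0, out[idx, paste0(fr_names, "_aa"), drop = FALSE])
    ref_cat <- paste(frs, collapse = "")
    ident <- vapply(fr_cat, function(x) {
      if (nchar(x) != nchar(ref_cat)) return(0)
      aa_identity(x, ref_cat)
    }, numeric(1), USE.NAMES = FALSE)
    out$fr_identity <- NA_real_
    out$fr_identity[idx] <- ident
  } else {
    out$fr_identity <- NA_real_
  }
  out$ok <- ord_ok & !is.na(out$fr_identity)
  out
}

#' Annotate reads against a set of scaffold references
#'
#' Translates each read (all three forward frames; first frame without
#' internal stop codons wins), assigns the scaffold whose concatenated
#' frameworks best match the translation, and extracts the six CDRs and
#' eight framework regions between located anchors. Reads failing
#' translation are rejected with reason `frameshift`; reads whose
#' framework identity falls below `identity_floor` (or whose anchors
#' cannot be located) are rejected with reason `no_scaffold`.
#'
#' @param reads demultiplexed read table (columns `read_id`, `nt_seq`,
#'   `population`, `concentration`).
#' @param scaffolds list of [scaffold_ref()].
#' @param identity_floor minimum framework identity, default 0.70.
#' @param liability_motifs motif set for [count_liabilities()], applied
#'   to the concatenated CDRs; default [default_liability_motifs()].
#' @return list with `clones` (one row per unique full-length amino-acid
#'   sequence per population/concentration, with `consensus_count`),
#'   `read_map` (read_id -> clone_id) and `rejects` (read_id, reason).
#' @export
annotate_reads <- function(reads, scaffolds, identity_floor = 0.70,
                           liability_motifs = default_liability_motifs()) {
  stopifnot(nrow(reads) > 0)
  uniq <- !duplicated(reads$nt_seq)
  unt <- reads$nt_seq[uniq]
  n <- length(unt)
  frames <- translate_frames(unt)
  has_stop <- vapply(frames, function(a) grepl("*", a, fixed = TRUE),
                     logical(n))
  has_stop <- matrix(has_stop, nrow = n)
  frame_pick <- apply(has_stop, 1, function(h) {
    w <- which(!h)
    if (length(w)) w[1] else NA_integer_
  })
  aa <- rep(NA_character_, n)
  for (f in 1:3) {
    sel <- which(!is.na(frame_pick) & frame_pick == f)
    if (length(sel)) aa[sel] <- frames[[f]][sel]
  }

  scaffold <- rep(NA_character_, n)
  fr_identity <- rep(NA_real_, n)
  regions <- data.frame(matrix(NA_character_, n, 14), stringsAsFactors = FALSE)
  names(regions) <- c(paste0(fr_names, "_aa"), paste0(cdr_names, "_aa"))
  todo <- which(!is.na(aa))
  # order scaffold attempts per read by identity of the fwl1-prefix
  for (s in scaffolds[order_scaffolds(scaffolds, aa, todo)]) {
    if (!length(todo)) break
    ex <- extract_regions(aa[todo], s)
    hit <- which(ex$ok & ex$fr_identity >= identity_floor)
    if (length(hit)) {
      gi <- todo[hit]
      scaffold[gi] <- s$name
      fr_identity[gi] <- ex$fr_identity[hit]
      regions[gi, ] <- ex[hit, names(regions)]
      todo <- setdiff(todo, gi)
    }
  }

  reason <- rep(NA_character_, n)
  reason[is.na(aa)] <- "frameshift"
  reason[!is.na(aa) & is.na(scaffold)] <- "no_scaffold"

  idx <- match(reads$nt_seq, unt)
  ok <- is.na(reason)[idx]
  rejects <- data.frame(read_id = reads$read_id[!ok],
                        reason = reason[idx][!ok],
                        stringsAsFactors = FALSE)

  kept <- reads[ok, , drop = FALSE]
  if (nrow(kept) == 0L) {
    empty <- make_clones_skeleton()
    return(list(clones = empty,
                read_map = data.frame(read_id = character(),
                                      clone_id = character(),
                                      population = character(),
                                      concentration = character(),
                                      stringsAsFactors = FALSE),
                rejects = rejects))
  }
  ui <- idx[ok]
  aa_full <- assemble_from_regions(regions[ui, , drop = FALSE],
                                   scaffolds, scaffold[ui])
  clone_key <- aa_full
  clone_id <- paste0("c", match(clone_key, unique(clone_key)))
  read_map <- data.frame(read_id = kept$read_id, clone_id = clone_id,
                         population = kept$population,
                         concentration = kept$concentration,
                         stringsAsFactors = FALSE)

  grp <- paste(clone_id, kept$population, kept$concentration, sep = "\r")
  first <- !duplicated(grp)
  counts <- as.vector(table(factor(grp, levels = grp[first])))
  clones <- data.frame(
    clone_id = clone_id[first],
    sequence_aa = aa_full[first],
    scaffold = scaffold[ui][first],
    regions[ui[first], c(paste0(cdr_names, "_aa"), paste0(fr_names, "_aa"))],
    fr_identity = fr_identity[ui][first],
    population = kept$population[first],
    concentration = kept$concentration[first],
    consensus_count = counts,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  cdr_cat <- do.call(paste0, clones[, paste0(cdr_names, "_aa")])
  clones$liabilities <- count_liabilities(cdr_cat, liability_motifs)
  list(clones = clones, read_map = read_map, rejects = rejects)
}

make_clones_skeleton <- function() {
  cols <- c("clone_id", "sequence_aa", "scaffold",
            paste0(cdr_names, "_aa"), paste0(fr_names, "_aa"),
            "fr_identity", "population", "concentration",
            "consensus_count", "liabilities")
  out <- as.data.frame(setNames(rep(list(character()), length(cols)), cols),
                       stringsAsFactors = FALSE)
  out$fr_identity <- numeric()
  out$consensus_count <- integer()
  out$liabilities <- integer()
  out
}

order_scaffolds <- function(scaffolds, aa, todo) {
  if (!length(todo) || length(scaffolds) == 1L) return(seq_along(scaffolds))
  probe <- aa[todo[1]]
  sc <- vapply(scaffolds, function(s) {
    p <- substr(s$frameworks[["fwl1"]], 1, 10)
    q <- substr(probe, 1, 10)
    if (nchar(q) < 10) return(0)
    aa_identity(q, p)
  }, numeric(1))
  order(sc, decreasing = TRUE)
}

assemble_from_regions <- function(regions, scaffolds, scaffold_name) {
  linkers <- setNames(vapply(scaffolds, function(s) s$linker, ""),
                      vapply(scaffolds, function(s) s$name, ""))
  paste0(regions$fwl1_aa, regions$lcdr1_aa, regions$fwl2_aa,
         regions$lcdr2_aa, regions$fwl3_aa, regions$lcdr3_aa,
         regions$fwl4_aa, linkers[scaffold_name],
         regions$fwh1_aa, regions$hcdr1_aa, regions$fwh2_aa,
         regions$hcdr2_aa, regions$fwh3_aa, regions$hcdr3_aa,
         regions$fwh4_aa)
}

#' Annotate a single nucleotide sequence
#'
#' Single-sequence convenience wrapper around [annotate_reads()].
#'
#' @inheritParams annotate_reads
#' @param nt_seq one nucleotide string.
#' @return one-row clone table, or an error with the rejection reason.
#' @export
annotate_clone <- function(nt_seq, scaffolds, identity_floor = 0.70) {
  r <- data.frame(read_id = "query", nt_seq = nt_seq,
                  qual = strrep("I", nchar(nt_seq)),
                  population = "query", concentration = "query",
                  stringsAsFactors = FALSE)
  out <- annotate_reads(r, scaffolds, identity_floor)
  if (nrow(out$rejects)) {
    stop("annotation rejected: ", out$rejects$reason[1], call. = FALSE)
  }
  out$clones
}

#' Region-of-interest string for clones
#'
#' Builds the string used for counting and clustering: a single CDR, a
#' fixed-order concatenation (light before heavy, CDR1 < CDR2 < CDR3,
#' joined by `sep`), or the full-length sequence.
#'
#' @param clones clone table.
#' @param roi one of `"HCDR3"`, `"HCDR3+LCDR3"`, `"CDRs"`, `"FULL"`.
#' @param sep separator used when concatenating, default `"|"`.
#' @return character vector, one ROI string per row of `clones`.
#' @export
roi_string <- function(clones, roi = c("HCDR3", "HCDR3+LCDR3", "CDRs", "FULL"),
                       sep = "|") {
  roi <- match.arg(roi)
  need <- switch(roi,
    "HCDR3" = "hcdr3_aa",
    "HCDR3+LCDR3" = c("lcdr3_aa", "hcdr3_aa"),
    "CDRs" = paste0(cdr_names, "_aa"),
    "FULL" = "sequence_aa")
  miss <- setdiff(need, names(clones))
  if (length(miss)) stop("clone table lacks region column(s): ",
                         paste(miss, collapse = ", "))
  vals <- clones[, need, drop = FALSE]
  if (anyNA(vals) || any(vals == "")) stop("missing region value in clone table")
  if (length(need) == 1L) return(vals[[1]])
  do.call(paste, c(vals, sep = sep))
}

#' Default 11-group physicochemical amino-acid alphabet
#'
#' Partition of the 20 standard residues into 11 physicochemical groups
#' (aliphatic LVIM; aromatic FYW; acidic DE; amide NQ; basic KR; hydroxyl
#' ST; and A, C, G, H, P as singleton groups), an 11-class refinement of
#' the Murphy-style reduced alphabets. Group characters are lower-case so
#' the pseudo-sequence space is disjoint from the amino-acid space. The
#' mapping is a plain named character vector and can be replaced wholesale
#' to reproduce any published grouping.
#'
#' @return named character vector: residue -> group character.
#' @export
default_reduced_alphabet <- function() {
  groups <- list(l = c("L", "V", "I", "M"), f = c("F", "Y", "W"),
                 d = c("D", "E"), n = c("N", "Q"), k = c("K", "R"),
                 s = c("S", "T"), a = "A", c = "C", g = "G", h = "H",
                 p = "P")
  out <- character()
  for (g in names(groups)) out[groups[[g]]] <- g
  out
}

#' Reduce an amino-acid sequence to a physicochemical pseudo-sequence
#'
#' Character-wise, length-preserving mapping onto the reduced alphabet.
#' Group characters already in pseudo space pass through unchanged, so
#' the mapping is idempotent. Unknown characters are an error.
#'
#' @param aa_seq character vector of amino-acid sequences.
#' @param alphabet named character vector as from
#'   [default_reduced_alphabet()].
#' @param passthrough characters copied through unchanged (region
#'   separators in concatenated ROI strings), default `"|"`.
#' @return character vector of pseudo-sequences.
#' @export
reduce_alphabet <- function(aa_seq, alphabet = default_reduced_alphabet(),
                            passthrough = "|") {
  from <- paste(names(alphabet), collapse = "")
  to <- paste(alphabet, collapse = "")
  known <- paste0("^[", gsub("([][\\^-])", "\\\\\\1", paste0(from, to, passthrough)),
                  "]*$")
  if (!all(grepl(known, aa_seq))) {
    bad <- aa_seq[!grepl(known, aa_seq)][1]
    stop("unknown residue character in sequence '", bad, "'", call. = FALSE)
  }
  chartr(from, to, aa_seq)
}

#' Default sequence-liability motifs
#'
#' Named POSIX/PCRE patterns for common developability risks in CDRs:
#' deamidation (NG, NS), isomerization (DG), N-glycosylation sequon
#' (N[^P][ST]), acid-labile DP, unpaired cysteine and methionine
#' oxidation (the last two are meaningful when scanning CDR regions,
#' where no scaffold cysteines occur). Fully user-overridable.
#'
#' @return named character vector of regular expressions.
#' @export
default_liability_motifs <- function() {
  c(deamidation_NG = "NG",
    deamidation_NS = "NS",
    isomerization_DG = "DG",
    glycosylation = "N[^P][ST]",
    dp_cleavage = "DP",
    unpaired_cys = "C",
    met_oxidation = "M")
}

#' Count sequence liability motifs
#'
#' Counts non-overlapping matches of each motif and sums over the motif
#' set. Different motifs are counted independently (an overlap between
#' two distinct motifs counts twice).
#'
#' @param aa_seq character vector of amino-acid strings (typically the
#'   concatenated CDRs of a clone).
#' @param motifs named character vector of regular expressions; empty
#'   set gives 0.
#' @return integer vector of total liability counts.
#' @export
count_liabilities <- function(aa_seq, motifs = default_liability_motifs()) {
  if (!length(motifs)) return(rep(0L, length(aa_seq)))
  total <- rep(0L, length(aa_seq))
  for (m in motifs) {
    hits <- gregexpr(m, aa_seq, perl = TRUE)
    total <- total + vapply(hits, function(h) sum(h > 0L), integer(1))
  }
  total
}
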