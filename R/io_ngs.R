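#' Decode Phred+33 quality strings
#'
#' @param qual character vector of FASTQ quality strings (Sanger/Phred+33).
#' @return list of integer vectors, one per element of `qual`.
#' @examples
#' phred_values("II5") # 40 40 20
#' @export
phred_values <- function(qual) {
  lapply(qual, function(q) as.integer(charToRaw(q)) - 33L)
}

#' Read a FASTQ file into a read table
#'
#' Reads Sanger-encoded (Phred+33) FASTQ into a data.frame with one row
#' per record, in file order. Quality strings are kept encoded; use
#' [phred_values()] to decode.
#'
#' @param path path to an uncompressed or gzipped FASTQ file.
#' @return data.frame with columns `read_id`, `nt_seq`, `qual`,
#'   `population` (NA until demultiplexed).
#' @export
read_fastq <- function(path) {
  stopifnot(file.exists(path))
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  if (length(x) == 0L) {
    return(data.frame(read_id = character(), nt_seq = character(),
                      qual = character(), population = character(),
                      stringsAsFactors = FALSE))
  }
  sw <- Biostrings::width(x)
  qual <- tryCatch(as.character(S4Vectors::mcols(x)$qualities),
                   error = function(e) NULL)
  if (is.null(qual) || any(nchar(qual) != sw)) {
    # diagnostic pass to name the offending record
    lines <- readLines(path)
    ids <- sub("^@", "", sub("\\s.*$", "", lines[seq(1, length(lines), 4)]))
    seqs <- lines[seq(2, length(lines), 4)]
    quals <- lines[seq(4, length(lines), 4)]
    bad <- ids[which(nchar(quals) != nchar(seqs))[1L]]
    stop("malformed FASTQ record '", bad,
         "': quality length differs from sequence length", call. = FALSE)
  }
  data.frame(
    read_id = names(x),
    nt_seq = as.character(x),
    qual = qual,
    population = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Write a read table to FASTQ
#'
#' @param reads data.frame as returned by [read_fastq()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "nt_seq", "qual") %in% names(reads)))
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads)) {
    writeLines(paste0("@", reads$read_id, "\n", reads$nt_seq, "\n+\n", reads$qual), con)
  }
  invisible(path)
}

#' Quality-filter reads on per-base Phred scores
#'
#' Retains a read when at least `fraction_required` of its bases have a
#' Phred score of at least `min_phred`. The defaults (all bases at Phred
#' >= 40) reproduce the strict filter used for long-read consensus
#' amplicons, where per-base accuracy is high and any low-quality base is
#' suspect.
#'
#' @param reads read table (see [read_fastq()]).
#' @param min_phred inclusive per-base threshold, default 40.
#' @param fraction_required fraction of bases that must meet `min_phred`,
#'   default 1.0 (every base).
#' @param verbose log retained counts, default FALSE.
#' @return the retained subset of `reads`, original order preserved.
#' @export
quality_filter <- function(reads, min_phred = 40L, fraction_required = 1.0,
                           verbose = FALSE) {
  stopifnot(fraction_required > 0, fraction_required <= 1)
  if (nrow(reads) == 0L) return(reads)
  thr <- as.raw(min_phred + 33L)
  frac_ok <- vapply(reads$qual, function(q) {
    r <- charToRaw(q)
    sum(r >= thr) / length(r)
  }, numeric(1), USE.NAMES = FALSE)
  keep <- frac_ok >= fraction_required
  if (verbose) {
    message(sprintf("quality_filter: retained %d/%d reads (min_phred=%d, fraction=%.2f)",
                    sum(keep), nrow(reads), min_phred, fraction_required))
  }
  reads[keep, , drop = FALSE]
}

#' Build a barcode specification table
#'
#' One row per demultiplexable population: a 5' and a 3' inline 8-mer
#' barcode, stored in sense orientation. A read is assigned when both
#' barcodes match with at most `max_mismatches` mismatches (the default,
#' 2 of 8, corresponds to >= 70% identity).
#'
#' @param population population labels (unique).
#' @param concentration sort-concentration labels (e.g. "10nM", "1nM");
#'   recycled if length 1.
#' @param bc5,bc3 8-mer nucleotide barcodes.
#' @param max_mismatches maximum Hamming mismatches per barcode, default 2.
#' @return data.frame of class `barcode_spec`.
#' @export
barcode_spec <- function(population, concentration, bc5, bc3, max_mismatches = 2L) {
  stopifnot(all(nchar(bc5) == 8L), all(nchar(bc3) == 8L))
  key <- paste(population, concentration)
  if (anyDuplicated(key)) {
    stop("duplicate population labels in barcode table: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  out <- data.frame(population = population,
                    concentration = rep_len(concentration, length(population)),
                    bc5 = toupper(bc5), bc3 = toupper(bc3),
                    stringsAsFactors = FALSE)
  attr(out, "max_mismatches") <- as.integer(max_mismatches)
  class(out) <- c("barcode_spec", "data.frame")
  out
}

#' Read / write a barcode table (TSV)
#'
#' Columns: population, concentration, bc5, bc3.
#'
#' @param path TSV path.
#' @param max_mismatches see [barcode_spec()].
#' @return a `barcode_spec`.
#' @export
read_barcode_table <- function(path, max_mismatches = 2L) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("population", "concentration", "bc5", "bc3")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("barcode table missing columns: ", paste(miss, collapse = ", "))
  barcode_spec(x$population, x$concentration, x$bc5, x$bc3, max_mismatches)
}

#' @rdname read_barcode_table
#' @param barcodes a `barcode_spec`.
#' @export
write_barcode_table <- function(barcodes, path) {
  write.table(as.data.frame(barcodes), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# Hamming mismatches between each element of `x` (equal-width strings)
# and a single pattern of the same width.
hamming_to <- function(x, pattern) {
  pb <- charToRaw(pattern)
  w <- length(pb)
  if (!length(x)) return(integer())
  m <- matrix(charToRaw(paste(x, collapse = "")), nrow = w)
  as.integer(colSums(m != pb))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Demultiplex reads by inline 5'/3' barcodes
#'
#' Compares the first 8 nt of each read against every `bc5` and the last
#' 8 nt (reverse-complemented, so the table stores both barcodes in sense
#' orientation) against every `bc3`. A read is assigned to the unique
#' population minimizing total mismatches among those with both barcodes
#' within `max_mismatches`; ties between populations leave the read
#' unassigned. Assigned reads have both barcodes trimmed (sequence and
#' quality).
#'
#' @param reads read table.
#' @param barcodes a [barcode_spec()].
#' @param bc3_as_given match the 3' barcode against the read tail as
#'   written instead of its reverse complement, default FALSE.
#' @param verbose log ambiguous reads, default FALSE.
#' @return list with elements `assigned` (reads with `population`,
#'   `concentration` set and barcodes trimmed) and `unassigned`.
#' @export
demultiplex <- function(reads, barcodes, bc3_as_given = FALSE, verbose = FALSE) {
  stopifnot(inherits(barcodes, "barcode_spec"))
  mm_max <- attr(barcodes, "max_mismatches")
  if (nrow(reads) == 0L) {
    return(list(assigned = cbind(reads, concentration = character(0)),
                unassigned = reads))
  }
  if (any(nchar(reads$nt_seq) < 17L)) {
    stop("reads shorter than two barcodes plus insert cannot be demultiplexed")
  }
  head8 <- substr(reads$nt_seq, 1L, 8L)
  len <- nchar(reads$nt_seq)
  tail8 <- substr(reads$nt_seq, len - 7L, len)
  if (!bc3_as_given) tail8 <- revcomp(tail8)

  npop <- nrow(barcodes)
  mm5 <- vapply(barcodes$bc5, function(b) hamming_to(head8, b),
                integer(length(head8)))
  mm3 <- vapply(barcodes$bc3, function(b) hamming_to(tail8, b),
                integer(length(tail8)))
  mm5 <- matrix(mm5, ncol = npop)
  mm3 <- matrix(mm3, ncol = npop)
  ok <- (mm5 <= mm_max) & (mm3 <= mm_max)
  total <- mm5 + mm3
  total[!ok] <- NA_integer_

  tot2 <- total
  tot2[is.na(tot2)] <- .Machine$integer.max
  mn <- do.call(pmin, as.data.frame(tot2))
  nties <- rowSums(tot2 == mn)
  best <- max.col(-tot2, ties.method = "first")
  best[mn == .Machine$integer.max | nties > 1L] <- NA_integer_
  if (verbose && any(nties > 1L & mn < .Machine$integer.max)) {
    for (i in which(nties > 1L & mn < .Machine$integer.max)) {
      w <- which(tot2[i, ] == mn[i])
      message(sprintf("demultiplex: read '%s' ambiguous between %s",
                      reads$read_id[i],
                      paste(barcodes$population[w], barcodes$concentration[w],
                            sep = ":", collapse = ", ")))
    }
  }

  hit <- !is.na(best)
  assigned <- reads[hit, , drop = FALSE]
  if (nrow(assigned)) {
    la <- nchar(assigned$nt_seq)
    assigned$nt_seq <- substr(assigned$nt_seq, 9L, la - 8L)
    assigned$qual <- substr(assigned$qual, 9L, la - 8L)
    assigned$population <- barcodes$population[best[hit]]
    assigned$concentration <- barcodes$concentration[best[hit]]
  } else {
    assigned$concentration <- character(0)
  }
  list(assigned = assigned, unassigned = reads[!hit, , drop = FALSE])
}

airr_columns <- c("clone_id", "sequence_aa", "scaffold",
                  "lcdr1_aa", "lcdr2_aa", "lcdr3_aa",
                  "hcdr1_aa", "hcdr2_aa", "hcdr3_aa",
                  "fwl1_aa", "fwl2_aa", "fwl3_aa", "fwl4_aa",
                  "fwh1_aa", "fwh2_aa", "fwh3_aa", "fwh4_aa",
                  "population", "concentration", "consensus_count",
                  "liabilities")

#' Write / read an annotated clone table (AIRR-style TSV)
#'
#' One row per unique full-length amino-acid sequence per (population,
#' concentration). Round trip is lossless.
#'
#' @param clones annotated clone table (see [annotate_reads()]).
#' @param path TSV path.
#' @return `path` invisibly (write); clone table (read).
#' @export
write_airr_table <- function(clones, path) {
  miss <- setdiff(airr_columns, names(clones))
  if (length(miss)) stop("clone table missing columns: ", paste(miss, collapse = ", "))
  key <- paste(clones$sequence_aa, clones$population, clones$concentration)
  if (anyDuplicated(key)) {
    stop("duplicated (full-length, population, concentration) rows in clone table")
  }
  write.table(clones[, airr_columns], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_airr_table
#' @export
read_airr_table <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  miss <- setdiff(airr_columns, names(x))
  if (length(miss)) stop("annotated table missing columns: ",
                         paste(miss, collapse = ", "))
  key <- paste(x$sequence_aa, x$population, x$concentration)
  if (anyDuplicated(key)) {
    stop("duplicated (full-length, population, concentration) rows in clone table")
  }
  x$consensus_count <- as.integer(x$consensus_count)
  x$liabilities <- as.integer(x$liabilities)
  x
}
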