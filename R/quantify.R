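#' Per-ROI relative frequencies within one sorted population
#'
#' Condenses all clones sharing the same ROI value (summing the read
#' counts of each unique full-length sequence) and returns each ROI's
#' percent share of the population:
#' `100 * count_i / sum(counts)`.
#'
#' @param clones clone table.
#' @param population population label to tabulate.
#' @param concentration sort-concentration label ("10nM" or "1nM").
#' @param roi region of interest.
#' @return named numeric vector (percent) over the present ROI values;
#'   sums to 100.
#' @export
relative_frequency <- function(clones, population, concentration,
                               roi = "HCDR3") {
  sel <- clones$population == population &
    clones$concentration == concentration
  if (!any(sel)) {
    stop("no clones for population '", population, "' at ", concentration)
  }
  sub <- clones[sel, , drop = FALSE]
  vals <- roi_string(sub, roi)
  cnt <- tapply(sub$consensus_count, vals, sum)
  c(100 * cnt / sum(cnt))
}

#' Correction policy for ROIs absent from one sort round
#'
#' When a ROI is present in only one of the two rounds, its missing-round
#' frequency is imputed from that round's minimum observed ROI count
#' divided by a penalty factor. Depletion (absent late) is penalized
#' more heavily than it benefits enrichment (absent early).
#'
#' @param factor_absent_early divisor for the early-round minimum count
#'   when a ROI appears only late, default 2.
#' @param factor_absent_late divisor for the late-round minimum count
#'   when a ROI appears only early, default 10.
#' @return list of class `correction_policy`.
#' @export
correction_policy <- function(factor_absent_early = 2,
                              factor_absent_late = 10) {
  stopifnot(factor_absent_early >= 1, factor_absent_late >= 1,
            factor_absent_late >= factor_absent_early)
  structure(list(factor_absent_early = factor_absent_early,
                 factor_absent_late = factor_absent_late),
            class = "correction_policy")
}

#' Early-to-late fold enrichment per ROI
#'
#' Computes, for every ROI observed in either sort round of a population,
#' the ratio of its late-round (1 nM) to early-round (10 nM) relative
#' frequency. ROIs absent from one round receive a pseudo-count per the
#' [correction_policy()]: the minimum observed ROI count of the missing
#' round divided by the penalty factor, converted to a frequency against
#' that round's observed-count total (observed frequencies of other ROIs
#' are untouched; set `pseudo_in_denominator = TRUE` to add the
#' pseudo-count to the denominator instead).
#'
#' @param clones clone table.
#' @param population population label.
#' @param roi region of interest.
#' @param policy a [correction_policy()].
#' @param early,late concentration labels of the two sort rounds.
#' @param percent_scale multiply the ratio by 100 (the percent form of
#'   the enrichment equation); default FALSE returns the plain fold
#'   ratio, the unit used by every downstream threshold (e.g. "tenfold",
#'   "< 0.01x").
#' @param pseudo_in_denominator see above, default FALSE.
#' @return data.frame: `roi_value`, `population`, `rel_freq_early`,
#'   `rel_freq_late` (percent), `corrected` ("none", "early", "late"),
#'   `enrichment`.
#' @export
fold_enrichment <- function(clones, population, roi = "HCDR3",
                            policy = correction_policy(),
                            early = "10nM", late = "1nM",
                            percent_scale = FALSE,
                            pseudo_in_denominator = FALSE) {
  fe <- relative_frequency(clones, population, early, roi)
  fl <- relative_frequency(clones, population, late, roi)
  sel_e <- clones$population == population & clones$concentration == early
  sel_l <- clones$population == population & clones$concentration == late
  cnt_e <- tapply(clones$consensus_count[sel_e],
                  roi_string(clones[sel_e, , drop = FALSE], roi), sum)
  cnt_l <- tapply(clones$consensus_count[sel_l],
                  roi_string(clones[sel_l, , drop = FALSE], roi), sum)
  all_vals <- sort(unique(c(names(fe), names(fl))))
  min_e <- min(cnt_e); sum_e <- sum(cnt_e)
  min_l <- min(cnt_l); sum_l <- sum(cnt_l)

  corrected <- rep("none", length(all_vals))
  freq_e <- as.numeric(fe[all_vals])
  freq_l <- as.numeric(fl[all_vals])
  absent_e <- is.na(freq_e)
  absent_l <- is.na(freq_l)
  pseudo_e <- min_e / policy$factor_absent_early
  pseudo_l <- min_l / policy$factor_absent_late
  if (pseudo_in_denominator && any(absent_e)) {
    freq_e <- 100 * as.numeric(cnt_e[all_vals]) / (sum_e + pseudo_e)
  }
  if (pseudo_in_denominator && any(absent_l)) {
    freq_l <- 100 * as.numeric(cnt_l[all_vals]) / (sum_l + pseudo_l)
  }
  den_e <- if (pseudo_in_denominator) sum_e + pseudo_e else sum_e
  den_l <- if (pseudo_in_denominator) sum_l + pseudo_l else sum_l
  freq_e[absent_e] <- 100 * pseudo_e / den_e
  freq_l[absent_l] <- 100 * pseudo_l / den_l
  corrected[absent_e] <- "early"
  corrected[absent_l] <- "late"

  enr <- freq_l / freq_e
  if (percent_scale) enr <- enr * 100
  data.frame(roi_value = all_vals, population = population,
             rel_freq_early = freq_e, rel_freq_late = freq_l,
             corrected = corrected, enrichment = enr,
             stringsAsFactors = FALSE)
}

#' Cumulative abundance curve
#'
#' Sorts frequencies in descending order and accumulates them; with
#' `assignments` given, keeps only the most abundant full-length clone
#' per cluster first (the per-cluster representative view of the curve).
#'
#' @param clones clone table.
#' @param population,concentration population to tabulate.
#' @param roi region used for condensing, default `"FULL"` (unique
#'   full-length clones).
#' @param assignments optional cluster assignment table (from
#'   [abscan_cluster()] on the same ROI as `representative_roi`) to
#'   reduce to per-cluster representatives.
#' @param representative_roi ROI linking clones to `assignments`,
#'   default `"HCDR3"`.
#' @return data.frame: `roi_value`, `frequency`, `cumulative` (percent),
#'   in descending frequency order (ties broken lexicographically).
#' @export
cumulative_abundance <- function(clones, population, concentration,
                                 roi = "FULL", assignments = NULL,
                                 representative_roi = "HCDR3") {
  f <- relative_frequency(clones, population, concentration, roi)
  out <- data.frame(roi_value = names(f), frequency = as.numeric(f),
                    stringsAsFactors = FALSE)
  if (!is.null(assignments)) {
    sel <- clones$population == population &
      clones$concentration == concentration
    sub <- clones[sel, , drop = FALSE]
    link <- data.frame(value = roi_string(sub, roi),
                       rep_value = roi_string(sub, representative_roi),
                       stringsAsFactors = FALSE)
    link <- link[!duplicated(link$value), ]
    out$cluster <- assignments$cluster_id[
      match(link$rep_value[match(out$roi_value, link$value)],
            assignments$roi_value)]
    out <- out[order(-out$frequency, out$roi_value), , drop = FALSE]
    out <- out[!is.na(out$cluster) & !duplicated(out$cluster), , drop = FALSE]
  }
  out <- out[order(-out$frequency, out$roi_value), , drop = FALSE]
  out$cumulative <- cumsum(out$frequency)
  row.names(out) <- NULL
  out
}
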