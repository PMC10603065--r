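#' Diversity accumulation by random subsampling
#'
#' For each sampling depth and replicate, shuffles the per-read unit
#' labels with a seeded generator, takes the first `depth` reads and
#' counts the distinct units observed (or applies `diversity_fun`, e.g.
#' a reclustering of the subsample). Bit-for-bit reproducible for a
#' fixed seed.
#'
#' @param labels character vector, one unit label per read: ROI values
#'   for sequence-level diversity, or cluster ids mapped onto reads for
#'   the fast cluster-level curve.
#' @param depths integer read numbers to sample; default 10 log-spaced
#'   depths from 100 (or the read count, if smaller) to the read count.
#' @param replicates shuffles per depth, default 5.
#' @param seed RNG seed (mandatory).
#' @param diversity_fun function from a label subsample to a diversity
#'   count; default counts distinct non-NA labels (reads mapping to no
#'   unit, e.g. discarded noise, add nothing). Pass a reclustering
#'   closure for exact cluster-unit curves.
#' @return data.frame: `reads`, `diversity`, `replicate`.
#' @export
accumulation_curve <- function(labels, depths = NULL, replicates = 5L,
                               seed, diversity_fun = NULL) {
  n <- length(labels)
  stopifnot(n >= 1L, replicates >= 1L)
  if (is.null(depths)) {
    lo <- min(100L, n)
    depths <- unique(round(exp(seq(log(lo), log(n), length.out = 10L))))
  }
  depths <- as.integer(depths)
  if (any(depths > n)) {
    stop("depth exceeds the ", n, " available reads")
  }
  if (any(depths < 1L)) stop("depths must be >= 1")
  if (is.null(diversity_fun)) {
    diversity_fun <- function(x) length(unique(x[!is.na(x)]))
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  out <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    perm <- sample.int(n)
    div <- vapply(depths, function(dep) {
      as.integer(diversity_fun(labels[perm[seq_len(dep)]]))
    }, integer(1))
    out[[r]] <- data.frame(reads = depths, diversity = div, replicate = r)
  }
  do.call(rbind, out)
}

#' Fit the power-law read-depth model
#'
#' Fits reads = C * diversity^k by nonlinear least squares (reads is the
#' response: the y-axis is the sampled read number, the x-axis the
#' diversity it yielded), initialized from the log-log linear regression.
#' If the nonlinear fit fails to converge the log-log estimate is
#' returned, flagged as a fallback.
#'
#' @param points data.frame with columns `reads` and `diversity`, as
#'   from [accumulation_curve()].
#' @return list of class `power_law_fit`: `C`, `k`, `converged`,
#'   `residual_sd`, `n_points`.
#' @export
fit_power <- function(points) {
  stopifnot(all(c("reads", "diversity") %in% names(points)))
  pts <- points[points$diversity > 0 & points$reads > 0, , drop = FALSE]
  if (length(unique(pts$diversity)) < 3L) {
    stop("need at least 3 distinct positive diversity values")
  }
  ll <- lm(log(reads) ~ log(diversity), data = pts)
  start <- list(C = exp(coef(ll)[[1]]), k = coef(ll)[[2]])
  fit <- tryCatch(
    minpack.lm::nlsLM(reads ~ C * diversity^k, data = pts, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- list(C = start$C, k = start$k, converged = FALSE,
                residual_sd = sd(log(pts$reads) -
                                   predict(ll)), n_points = nrow(pts))
  } else {
    cf <- coef(fit)
    out <- list(C = cf[["C"]], k = cf[["k"]], converged = TRUE,
                residual_sd = sd(residuals(fit)), n_points = nrow(pts))
  }
  if (out$C <= 0 || out$k <= 0) {
    warning("power-law fit returned non-positive constants")
  }
  class(out) <- "power_law_fit"
  out
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power-law read model: reads = %.4g * D^%.4g  (%s, n = %d)\n",
              x$C, x$k,
              if (x$converged) "nls converged" else "log-log fallback",
              x$n_points))
  invisible(x)
}

#' Reads required for a target diversity
#'
#' Inverts the fitted read-depth model at a desired diversity:
#' `ceiling(C * target^k)`.
#'
#' @param fit a [fit_power()] result.
#' @param target_diversity desired number of distinct units (>= 1).
#' @return predicted read count (integer-valued numeric).
#' @export
reads_required <- function(fit, target_diversity) {
  stopifnot(inherits(fit, "power_law_fit"), all(target_diversity >= 1))
  ceiling(fit$C * target_diversity^fit$k)
}
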