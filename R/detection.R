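# Threshold-based erroneous-kmer calls and wrong-prediction sweeps.
#
# A kmer is called erroneous when its statistic (estimated attempts T, or
# the observed count Y for the classical baseline) falls strictly below the
# threshold M. Against simulator truth, a false positive is a genome-present
# kmer called erroneous and a false negative an undetected erroneous kmer;
# WP = FP + FN is the figure of merit, swept over a threshold grid.

#' Flag kmers below a threshold
#'
#' Strict inequality: a kmer is called erroneous when its value is `< M`.
#'
#' @param x A data frame of per-kmer records (e.g. [tidy()] of a [run_em()]
#'   fit), or a plain numeric vector.
#' @param threshold Threshold `M`.
#' @param values Column holding the statistic to threshold (tidy-eval;
#'   default `attempts`). Ignored when `x` is a vector.
#' @return For a data frame, the same frame with a logical `called` column;
#'   for a vector, a logical vector.
#' @export
detect <- function(x, threshold, values = attempts) {
  if (is.data.frame(x)) {
    dplyr::mutate(x, called = {{ values }} < threshold)
  } else {
    x < threshold
  }
}

#' Attach kmer-level truth to a spectrum
#'
#' Joins true genomic occurrence counts onto the observed spectrum: an
#' observed kmer type is erroneous precisely when it never occurs in the
#' genome (`alpha = 0`), i.e. every one of its observations contains at
#' least one misread base.
#'
#' @param x A data frame with a `code` column (a `kmer_spectrum` or a tidied
#'   EM fit).
#' @param occurrences Output of [true_occurrences()] (columns `code`,
#'   `alpha`).
#' @return `x` with `alpha` (0 where absent from the genome) and logical
#'   `is_error` columns.
#' @export
kmer_truth <- function(x, occurrences) {
  stopifnot(is.data.frame(x), "code" %in% names(x))
  out <- dplyr::left_join(
    x, dplyr::select(occurrences, "code", "alpha"), by = "code"
  )
  out$alpha[is.na(out$alpha)] <- 0
  out$is_error <- out$alpha == 0
  out
}

#' Sweep detection thresholds against truth
#'
#' Computes FP, FN and WP = FP + FN for every threshold in the grid. FN
#' decreases and FP increases monotonically in `M`; plotted on a log scale
#' the WP curve is typically U-shaped.
#'
#' @param x A data frame of per-kmer records carrying the statistic and the
#'   truth flag.
#' @param thresholds Numeric grid; defaults to the integers
#'   `0..ceiling(max(values))`, comparable across Y- and T-thresholding.
#' @param values Column with the statistic (default `attempts`).
#' @param truth Column with the logical truth flag (default `is_error`).
#' @return A tibble of class `wp_curve` with columns `threshold`, `fp`,
#'   `fn`, `wp`.
#' @export
wp_curve <- function(x, thresholds = NULL, values = attempts, truth = is_error) {
  stopifnot(is.data.frame(x))
  v <- dplyr::pull(x, {{ values }})
  tr <- dplyr::pull(x, {{ truth }})
  if (length(v) != length(tr)) stop("value/truth length mismatch", call. = FALSE)
  if (anyNA(v) || anyNA(tr)) stop("values and truth must be complete", call. = FALSE)
  if (is.null(thresholds)) thresholds <- 0:ceiling(max(v))
  thresholds <- sort(thresholds)
  clean_sorted <- sort(v[!tr])
  err_sorted <- sort(v[tr])
  n_err <- length(err_sorted)
  # counts strictly below each threshold
  fp <- .count_lt(thresholds, clean_sorted)
  fn <- n_err - .count_lt(thresholds, err_sorted)
  out <- tibble::tibble(threshold = thresholds, fp = fp, fn = fn, wp = fp + fn)
  class(out) <- c("wp_curve", class(out))
  out
}

# number of elements of `sorted` strictly less than each x
.count_lt <- function(x, sorted) {
  if (length(sorted) == 0L) return(rep(0L, length(x)))
  findInterval(x, sorted, left.open = TRUE)
}

#' Minimum wrong predictions over a threshold sweep
#'
#' @param curve A [wp_curve()] result.
#' @return A one-row tibble with the minimizing `threshold` and its `fp`,
#'   `fn`, `wp`; ties are broken toward the smaller threshold.
#' @export
min_wp <- function(curve) {
  stopifnot(is.data.frame(curve), all(c("threshold", "wp") %in% names(curve)))
  curve <- dplyr::arrange(curve, .data$threshold)
  curve[which.min(curve$wp), c("threshold", "fp", "fn", "wp")]
}

#' Write a wrong-prediction curve as TSV
#'
#' @param curve A [wp_curve()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wp_curve <- function(curve, path) {
  readr::write_tsv(curve, path)
  invisible(path)
}
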