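# EM estimation of expected read attempts per kmer.
#
# Observed counts Y follow Multinomial(total windows, p) with
#   p_l proportional to sum over neighbors m of s_m * p_e(x_m -> x_l),
# where s_m is the (unknown) genomic occupancy of kmer x_m. On the attempt
# scale T_l = s_l * N(L - k + 1) the observed log likelihood is, up to an
# additive constant,
#   l(T | Y) = sum_l Y_l * log( sum_{m in N_l} T_m * p_e(x_m -> x_l) ).
# The E step splits each Y_l over its neighborhood proportionally to
# T_m * p_e(x_m -> x_l); the M step sums the pieces attributed to each
# source. Both leave sum(T) = sum(Y) invariant, and iteration from T = Y
# monotonically increases the likelihood. Everything is deterministic and
# runs in linear space (neighborhood sums are short and well scaled).

#' E step: expected misread attributions
#'
#' For each observed target kmer `x_l` and each neighbor source `x_m`,
#' computes `E[Y_lm] = Y_l * T_m * w_ml / sum_m' T_m' * w_m'l`. The
#' attributions over each target's neighborhood sum to `Y_l`.
#'
#' @param Y Observed counts, one per kmer (spectrum order).
#' @param T_cur Current attempt estimates, same length.
#' @param rows A [build_neighbor_rows()] result built from the spectrum.
#' @return A list with `pairs` (tibble `source`, `target`, `e_count`) and
#'   the per-target mixture mass `denom`.
#' @export
e_step <- function(Y, T_cur, rows) {
  stopifnot(inherits(rows, "neighbor_rows"))
  n <- length(rows$codes)
  stopifnot(length(Y) == n, length(T_cur) == n)
  denom <- as.vector(Matrix::crossprod(rows$W, T_cur))
  bad <- which(Y > 0 & denom <= 0)
  if (length(bad) > 0L) {
    stop("zero neighborhood mass for observed kmer ",
         decode_kmers(rows$codes[bad[1]], rows$k), call. = FALSE)
  }
  trip <- Matrix::summary(rows$W)
  e_count <- Y[trip$j] * T_cur[trip$i] * trip$x / denom[trip$j]
  list(
    pairs = tibble::tibble(source = trip$i, target = trip$j, e_count = e_count),
    denom = denom
  )
}

#' M step: attempt estimates from attributions
#'
#' Sums the expected attributions over targets for each source:
#' `T_m = sum_l E[Y_lm]`. Conserves `sum(T) = sum(Y)` exactly.
#'
#' @param responsibilities An [e_step()] result.
#' @param n Number of kmers (defaults to the largest index present).
#' @return The updated attempt vector.
#' @export
m_step <- function(responsibilities, n = NULL) {
  pairs <- responsibilities$pairs
  if (is.null(n)) n <- max(pairs$source, pairs$target)
  out <- numeric(n)
  agg <- rowsum(pairs$e_count, pairs$source)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Observed-data log likelihood (up to an additive constant)
#'
#' @inheritParams e_step
#' @return `sum_l Y_l * log(sum_m T_m * w_ml)`.
#' @export
log_likelihood <- function(Y, T_cur, rows) {
  denom <- as.vector(Matrix::crossprod(rows$W, T_cur))
  obs <- Y > 0
  if (any(denom[obs] <= 0)) {
    stop("non-positive mixture mass for an observed kmer", call. = FALSE)
  }
  sum(Y[obs] * log(denom[obs]))
}

#' Estimate expected read attempts per kmer by EM
#'
#' The core estimator: starting from `T = Y`, alternates the E and M steps
#' until the relative log-likelihood change drops below `tol` or `max_iter`
#' iterations are reached. Misread counts contributed by repeat-rich
#' neighbors are thereby re-attributed to their sources, so erroneous kmers
#' (zero genomic occurrence) end with attempt estimates near zero while
#' genuine kmers approach their true attempt counts.
#'
#' Kmers whose estimate reaches exactly zero stay at zero (absorbing under
#' these updates); detection treats `T = 0` as the strongest error evidence.
#'
#' @param spectrum A [build_spectrum()] result.
#' @param rows Neighborhoods from [build_neighbor_rows()] on `spectrum`.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @return An object of class `attempt_em`: list with `estimates` (tibble
#'   `kmer`, `code`, `count`, `attempts`), `loglik_trace`, `n_iter`,
#'   `converged`, `k`, `d_max`, `total_attempts`.
#' @examples
#' sp <- build_spectrum(c("ACGACG", "ACGACG"), k = 3)
#' rows <- build_neighbor_rows(sp, uniform_error_model(0.01), d_max = 1)
#' fit <- run_em(sp, rows)
#' tidy(fit)
#' @export
run_em <- function(spectrum, rows, tol = 1e-6, max_iter = 100) {
  stopifnot(inherits(spectrum, "kmer_spectrum"), inherits(rows, "neighbor_rows"))
  if (!identical(spectrum$code, rows$codes)) {
    stop("`rows` was not built from `spectrum`", call. = FALSE)
  }
  Y <- spectrum$count
  W <- rows$W
  T_cur <- Y
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    denom <- as.vector(Matrix::crossprod(W, T_cur))
    bad <- which(Y > 0 & denom <= 0)
    if (length(bad) > 0L) {
      stop("zero neighborhood mass for observed kmer ",
           decode_kmers(rows$codes[bad[1]], rows$k), call. = FALSE)
    }
    ll <- sum(Y * log(denom))
    if (!is.finite(ll)) {
      stop("non-finite log likelihood at iteration ", iter, call. = FALSE)
    }
    if (is.finite(ll_prev) && ll < ll_prev - 1e-9 * abs(ll_prev)) {
      warning("log likelihood decreased at iteration ", iter, call. = FALSE)
    }
    trace <- c(trace, ll)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) <= tol * (abs(ll_prev) + .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    # combined E + M step: T_m <- T_m * sum_l w_ml * Y_l / denom_l
    T_cur <- pmax(T_cur * as.vector(W %*% (Y / denom)), 0)
  }
  structure(
    list(
      estimates = tibble::tibble(
        kmer = spectrum$kmer, code = spectrum$code,
        count = Y, attempts = T_cur
      ),
      loglik_trace = trace,
      n_iter = iter,
      converged = converged,
      k = rows$k,
      d_max = rows$d_max,
      total_attempts = attr(spectrum, "total_attempts")
    ),
    class = "attempt_em"
  )
}

#' @export
print.attempt_em <- function(x, ...) {
  cat("Attempt-count EM fit: ", nrow(x$estimates), " kmers (k = ", x$k,
      ", d_max = ", x$d_max, ")\n", sep = "")
  cat("  iterations: ", x$n_iter, if (x$converged) " (converged)" else " (max_iter reached)",
      "\n  log likelihood: ", format(utils::tail(x$loglik_trace, 1)), "\n", sep = "")
  invisible(x)
}

#' Tidy per-kmer estimates from an EM fit
#'
#' @param x An `attempt_em` object.
#' @param ... Unused.
#' @return A tibble with one row per observed kmer: `kmer`, `code`,
#'   `count` (observed `Y_l`) and `attempts` (estimated `T_l`).
#' @export
tidy.attempt_em <- function(x, ...) x$estimates

#' One-row summary of an EM fit
#'
#' @inheritParams tidy.attempt_em
#' @return A one-row tibble: kmer count, iterations, final log likelihood,
#'   convergence flag, and the conservation total `sum(attempts)`.
#' @export
glance.attempt_em <- function(x, ...) {
  tibble::tibble(
    n_kmers = nrow(x$estimates),
    n_iter = x$n_iter,
    loglik = utils::tail(x$loglik_trace, 1),
    converged = x$converged,
    total_attempts = sum(x$estimates$attempts)
  )
}

#' Serialize attempt estimates as TSV
#'
#' @param fit An `attempt_em` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_attempts <- function(fit, path) {
  readr::write_tsv(
    dplyr::select(tidy(fit), "kmer", "count", "attempts"), path
  )
  invisible(path)
}
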