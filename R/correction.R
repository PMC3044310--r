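# Posterior-based correction of erroneous bases.
#
# For an observed kmer x_l, the probability that the true base at kmer
# position t was b (before any misread) is the neighborhood posterior
#   p_t(b | x_l) = sum_{m in N_l : x_m[t] = b} T_m p_e(x_m -> x_l)
#                  / sum_{m in N_l} T_m p_e(x_m -> x_l),
# with attempt estimates T_m standing in for the unknown genomic
# occupancies. Every read base is covered by up to k overlapping windows;
# their (non-independent) posteriors are averaged, and the base is
# rewritten to the argmax when it differs from the observed base. A single
# pass uses posteriors computed from the original read - corrections are
# not fed back into neighboring windows - and ties retain the observed
# base. Reads unlikely to contain errors are skipped via a liberal
# pre-filter on the minimum window attempt estimate.

# entries of column l of a dgCMatrix without densifying
.col_entries <- function(W, l) {
  p <- W@p
  sel <- seq.int(p[l] + 1L, length.out = p[l + 1L] - p[l])
  list(i = W@i[sel] + 1L, x = W@x[sel])
}

#' Posterior over the true base at one kmer position
#'
#' @param kmer An observed kmer (string, or code with attribute-free
#'   numeric; must be present in `rows`).
#' @param t Kmer position, 1..k (indexing matches the error-model tables).
#' @param fit An [run_em()] fit providing attempt estimates.
#' @param rows The [build_neighbor_rows()] object used for the fit.
#' @return A named probability 4-vector over A, C, G, T. When the
#'   neighborhood carries no attempt mass the posterior falls back to a
#'   point mass on the observed base.
#' @export
kmer_position_posterior <- function(kmer, t, fit, rows) {
  stopifnot(inherits(fit, "attempt_em"), inherits(rows, "neighbor_rows"))
  k <- rows$k
  stopifnot(t >= 1, t <= k)
  code <- if (is.character(kmer)) encode_kmers(kmer, k) else as.numeric(kmer)
  l <- .match_codes(code, rows$codes)
  if (is.na(l)) stop("kmer not present in the observed spectrum", call. = FALSE)
  col <- .col_entries(rows$W, l)
  u <- fit$estimates$attempts[col$i] * col$x
  b <- digit_at(rows$codes[col$i], t, k)
  num <- vapply(0:3, function(bb) sum(u[b == bb]), numeric(1))
  denom <- sum(num)
  if (denom <= 0) {
    out <- numeric(4)
    out[digit_at(code, t, k) + 1L] <- 1
  } else {
    out <- num / denom
  }
  names(out) <- .BASES
  out
}

#' Posterior over the true base at one read position
#'
#' Arithmetic mean of [kmer_position_posterior()] over every window of the
#' read covering the position (between 1 near the read ends and k in the
#' interior).
#'
#' @param read A read sequence (string) whose kmers are all observed.
#' @param i Read position, 0-based.
#' @inheritParams kmer_position_posterior
#' @return A named probability 4-vector over A, C, G, T.
#' @export
read_base_posterior <- function(read, i, fit, rows) {
  k <- rows$k
  L <- nchar(read)
  if (L < k) stop("read shorter than k", call. = FALSE)
  stopifnot(i >= 0, i < L)
  w_range <- max(0L, i - k + 1L):min(i, L - k)
  posts <- vapply(w_range, function(w) {
    kmer_position_posterior(substr(read, w + 1L, w + k), i - w + 1L, fit, rows)
  }, numeric(4))
  rowMeans(posts)
}

#' Correct one read
#'
#' @param read A read sequence (string) or one-row data frame with `id`
#'   and `seq`.
#' @inheritParams kmer_position_posterior
#' @return A list with `seq` (corrected sequence) and `records` (tibble
#'   `read_id`, `pos` 0-based, `from`, `to`).
#' @export
correct_read <- function(read, fit, rows) {
  df <- if (is.data.frame(read)) read else tibble::tibble(id = "read", seq = read)
  stopifnot(nrow(df) == 1L)
  out <- correct_reads(df, fit, rows, liberal_threshold = Inf)
  list(seq = out$seq[1], records = corrections(out))
}

#' Correct erroneous bases across a read set
#'
#' A read enters correction when at least one of its kmers has an attempt
#' estimate below the liberal threshold; all other reads pass through
#' unchanged (and identically to a full run restricted to them). Output
#' reads keep their ids and lengths; every base change is logged.
#'
#' @param reads A data frame with `id` and `seq` columns - the same reads
#'   the spectrum and EM fit were built from.
#' @param fit An [run_em()] fit.
#' @param rows The matching [build_neighbor_rows()] object.
#' @param liberal_threshold Liberal pre-filter threshold on attempt
#'   estimates (`0` corrects nothing, `Inf` processes every read).
#'   Defaults to `3 * threshold` when `threshold` is given.
#' @param threshold A detection threshold from which the liberal threshold
#'   is derived when `liberal_threshold` is missing.
#' @return A tibble of class `corrected_reads` with columns `id`, `seq`
#'   and a `corrections` attribute (tibble `read_id`, `pos`, `from`,
#'   `to`), retrievable with [corrections()].
#' @export
correct_reads <- function(reads, fit, rows,
                          liberal_threshold = NULL, threshold = NULL) {
  stopifnot(is.data.frame(reads), all(c("id", "seq") %in% names(reads)))
  stopifnot(inherits(fit, "attempt_em"), inherits(rows, "neighbor_rows"))
  if (is.null(liberal_threshold)) {
    if (is.null(threshold)) {
      stop("give `liberal_threshold` (or `threshold` to use 3x that value)",
           call. = FALSE)
    }
    liberal_threshold <- 3 * threshold
  }
  k <- rows$k
  T_est <- fit$estimates$attempts
  out_seq <- reads$seq
  rec_list <- list()
  groups <- split(seq_len(nrow(reads)), nchar(reads$seq))
  for (grp in groups) {
    L <- nchar(reads$seq[grp[1]])
    if (L < k) stop("read shorter than k", call. = FALSE)
    cm <- seq_code_matrix(reads$seq[grp])
    wc <- window_codes(cm, k)
    widx <- matrix(.match_codes(as.vector(wc), rows$codes), nrow = nrow(wc))
    if (anyNA(widx)) {
      stop("reads contain kmers absent from the spectrum the fit was built on",
           call. = FALSE)
    }
    # liberal pre-filter: smallest attempt estimate over the read's windows
    min_T <- T_est[widx[, 1]]
    n_win <- ncol(widx)
    for (w in seq_len(n_win)[-1]) min_T <- pmin(min_T, T_est[widx[, w]])
    eligible <- which(min_T < liberal_threshold)
    if (length(eligible) == 0L) next
    res <- .correct_group(cm[eligible, , drop = FALSE],
                          widx[eligible, , drop = FALSE],
                          reads$id[grp[eligible]], T_est, rows)
    out_seq[grp[eligible]] <- res$seq
    rec_list[[length(rec_list) + 1L]] <- res$records
  }
  out <- tibble::tibble(id = reads$id, seq = out_seq)
  recs <- if (length(rec_list) > 0L) {
    dplyr::bind_rows(rec_list)
  } else {
    tibble::tibble(read_id = character(0), pos = integer(0),
                   from = character(0), to = character(0))
  }
  attr(out, "corrections") <- recs
  class(out) <- c("corrected_reads", class(out))
  out
}

#' Retrieve the correction log
#'
#' @param x A [correct_reads()] result.
#' @return A tibble with one row per base change: `read_id`, `pos`
#'   (0-based), `from`, `to`.
#' @export
corrections <- function(x) attr(x, "corrections")

# vectorized correction engine for a block of equal-length reads
.correct_group <- function(cm, widx, ids, T_est, rows) {
  k <- rows$k
  m <- nrow(cm)
  L <- ncol(cm)
  n_win <- ncol(widx)
  need <- sort(unique(as.vector(widx)))
  cache <- .posterior_cache(T_est, rows, need)
  loc <- integer(length(rows$codes))
  loc[need] <- seq_along(need)
  # accumulate window posteriors per (read, position, base)
  A <- matrix(0, m, L * 4L)
  for (w in seq_len(n_win)) {
    prow <- loc[widx[, w]]
    for (t in seq_len(k)) {
      i <- w + t - 1L
      cols_to <- (i - 1L) * 4L + 1:4
      cols_from <- (t - 1L) * 4L + 1:4
      A[, cols_to] <- A[, cols_to] + cache$P[prow, cols_from, drop = FALSE]
    }
  }
  # argmax per position; ties keep the observed base
  new_cm <- cm
  for (i in seq_len(L)) {
    M4 <- A[, (i - 1L) * 4L + 1:4, drop = FALSE]
    obs <- cm[, i]
    obs_val <- M4[cbind(seq_len(m), obs + 1L)]
    best <- max.col(M4, ties.method = "first")
    best_val <- M4[cbind(seq_len(m), best)]
    change <- best_val > obs_val & (best - 1L) != obs
    new_cm[change, i] <- best[change] - 1L
  }
  diff_idx <- which(new_cm != cm, arr.ind = TRUE)
  records <- tibble::tibble(
    read_id = ids[diff_idx[, 1]],
    pos = as.integer(diff_idx[, 2] - 1L),
    from = .BASES[cm[diff_idx] + 1L],
    to = .BASES[new_cm[diff_idx] + 1L]
  )
  records <- dplyr::arrange(records, match(.data$read_id, ids), .data$pos)
  list(seq = code_matrix_to_seq(new_cm), records = records)
}

# per-kmer posterior matrices for the needed target kmers:
# P[local target, (t-1)*4 + b + 1] = p_t(b | x_l)
.posterior_cache <- function(T_est, rows, need) {
  W <- rows$W
  k <- rows$k
  n <- length(rows$codes)
  need_flag <- logical(n)
  need_flag[need] <- TRUE
  trip <- Matrix::summary(W)
  sel <- need_flag[trip$j]
  src <- trip$i[sel]
  tgt <- trip$j[sel]
  u <- T_est[src] * trip$x[sel]
  loc <- integer(n)
  loc[need] <- seq_along(need)
  jl <- loc[tgt]
  n_need <- length(need)
  P <- matrix(0, n_need, 4L * k)
  denom <- numeric(n_need)
  agg_d <- rowsum(u, jl)
  denom[as.integer(rownames(agg_d))] <- agg_d[, 1]
  src_codes <- rows$codes[src]
  for (t in seq_len(k)) {
    b <- digit_at(src_codes, t, k)
    grp <- (jl - 1L) * 4L + b + 1L
    agg <- rowsum(u, grp)
    P[cbind(((as.integer(rownames(agg)) - 1L) %/% 4L) + 1L,
            (t - 1L) * 4L + ((as.integer(rownames(agg)) - 1L) %% 4L) + 1L)] <- agg[, 1]
  }
  zero <- which(denom <= 0)
  if (length(zero) > 0L) {
    # no attempt mass anywhere in the neighborhood: point mass on own base
    message(length(zero), " kmer(s) had zero neighborhood mass; ",
            "kept their observed bases")
    for (z in zero) {
      for (t in seq_len(k)) {
        P[z, (t - 1L) * 4L + digit_at(rows$codes[need[z]], t, k) + 1L] <- 1
      }
    }
    denom[zero] <- 1
  }
  P <- P / denom
  list(P = P, denom = denom)
}
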