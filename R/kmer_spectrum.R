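# Kmer spectrum and misread neighborhoods.
#
# The spectrum of a read set is the multiset of all length-k read windows;
# only observed kmers are stored, with their counts Y_l. Neighborhoods link
# observed kmers within Hamming distance d_max, carrying misread weights
# p_e(x_m -> x_l) renormalized, per source kmer x_m, over the observed
# targets in its ball (unobserved kmers are ignored: their genomic
# occupancy must be negligible or they would have been observed).

#' Build the kmer spectrum of a read set
#'
#' Counts every length-`k` window of every read. The total number of
#' windows, `sum over reads of (len - k + 1)`, is the multinomial size of
#' the count model and is stored as the `total_attempts` attribute.
#'
#' @param reads A data frame with a `seq` column (e.g. from [read_fastq()]
#'   or [simulate_reads()]), or a character vector of read sequences.
#' @param k kmer length (1..26; codes are exact base-4 integers).
#' @return A tibble of class `kmer_spectrum` with columns `kmer`, `code`
#'   (base-4 integer encoding, sorted ascending) and `count`, plus
#'   attributes `k` and `total_attempts`.
#' @examples
#' build_spectrum(c("ACGT"), k = 3)  # ACG and CGT, one window each
#' @export
build_spectrum <- function(reads, k = 13) {
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  stopifnot(is.character(seqs), length(seqs) > 0L)
  k <- .check_k(k)
  lens <- nchar(seqs)
  if (min(lens) < k) stop("`k` exceeds the shortest read length", call. = FALSE)
  groups <- split(seqs, lens)
  codes <- unlist(lapply(groups, function(g) {
    as.vector(window_codes(seq_code_matrix(g), k))
  }), use.names = FALSE)
  dt <- data.table::data.table(code = codes)
  counts <- dt[, .N, by = "code"]
  data.table::setorderv(counts, "code")
  out <- tibble::tibble(
    kmer = decode_kmers(counts$code, k),
    code = counts$code,
    count = as.numeric(counts$N)
  )
  attr(out, "k") <- k
  attr(out, "total_attempts") <- sum(lens - k + 1)
  class(out) <- c("kmer_spectrum", class(out))
  out
}

#' Enumerate the Hamming ball around a kmer
#'
#' All kmers within Hamming distance `d_max` of the given kmer, including
#' the kmer itself: `sum_{d=0}^{d_max} choose(k, d) 3^d` sequences.
#'
#' @param kmer A kmer string, or a numeric code (supply `k` in that case).
#' @param d_max Maximum Hamming distance (small, typically 0-2).
#' @param k kmer length; inferred from a string `kmer`.
#' @return Sorted kmer strings if `kmer` was a string, else sorted codes.
#' @export
hamming_ball <- function(kmer, d_max, k = NULL) {
  as_string <- is.character(kmer)
  if (as_string) {
    k <- nchar(kmer)
    code <- encode_kmers(kmer, k)
  } else {
    stopifnot(!is.null(k))
    code <- as.numeric(kmer)
  }
  k <- .check_k(k)
  stopifnot(length(code) == 1L, d_max >= 0)
  ball <- .ball_codes(code, d_max, k)
  if (as_string) decode_kmers(ball, k) else ball
}

# codes within distance d_max of a single code (center included)
.ball_codes <- function(code, d_max, k) {
  out <- code
  frontier <- code
  for (d in seq_len(d_max)) {
    nxt <- unlist(lapply(frontier, function(cc) .mutations1(cc, k)), use.names = FALSE)
    nxt <- setdiff(nxt, out)
    out <- c(out, nxt)
    frontier <- nxt
  }
  sort(out)
}

# all 3k single-substitution variants of one code
.mutations1 <- function(code, k) {
  out <- numeric(3L * k)
  pos <- 0L
  for (t in seq_len(k)) {
    pw <- 4^(k - t)
    dt <- digit_at(code, t, k)
    for (b in 0:3) {
      if (b != dt) {
        pos <- pos + 1L
        out[pos] <- code + (b - dt) * pw
      }
    }
  }
  out
}

#' Build sparse misread neighborhoods among observed kmers
#'
#' For every ordered pair of observed kmers within Hamming distance `d_max`
#' (self-pairs included), the raw misread probability under `model` is
#' computed and then renormalized so that, for each source kmer, the weights
#' over all observed targets in its ball sum to one. The result is the
#' sparse misread matrix `P_e` restricted to the observed spectrum, stored
#' with rows indexed by source and columns by target.
#'
#' @param spectrum A [build_spectrum()] result.
#' @param model A [uniform_error_model()] or [positional_error_model()].
#' @param d_max Neighborhood radius (0, 1 or 2; 1 by default keeps each row
#'   at most `3k + 1` wide).
#' @return An object of class `neighbor_rows`: list with the normalized
#'   sparse matrix `W` (`dgCMatrix`, `W[m, l] = p_e(x_m -> x_l)` after
#'   renormalization), the kmer `codes`, `k` and `d_max`.
#' @export
build_neighbor_rows <- function(spectrum, model, d_max = 1) {
  stopifnot(inherits(spectrum, "kmer_spectrum"), nrow(spectrum) > 0L)
  stopifnot(d_max %in% 0:2)
  k <- attr(spectrum, "k")
  codes <- spectrum$code
  n <- length(codes)

  if (d_max == 0) {
    src <- seq_len(n); tgt <- seq_len(n)
  } else if (d_max == 1) {
    hits <- .observed_pairs_d1(codes, k)
    src <- c(seq_len(n), hits$src)
    tgt <- c(seq_len(n), hits$tgt)
  } else {
    # generic small-spectrum path: enumerate each kmer's ball
    src_l <- list(); tgt_l <- list()
    for (m in seq_len(n)) {
      ball <- .ball_codes(codes[m], d_max, k)
      pos <- .match_codes(ball, codes)
      hit <- which(!is.na(pos))
      src_l[[m]] <- rep.int(m, length(hit))
      tgt_l[[m]] <- pos[hit]
    }
    src <- unlist(src_l); tgt <- unlist(tgt_l)
  }

  w <- pair_misread_prob(model, codes[src], codes[tgt], k)
  rs <- numeric(n)
  agg <- rowsum(w, src)
  rs[as.integer(rownames(agg))] <- agg[, 1]
  if (any(rs[unique(src)] <= 0)) {
    stop("a source kmer has zero total misread weight over observed targets",
         call. = FALSE)
  }
  W <- Matrix::sparseMatrix(i = src, j = tgt, x = w / rs[src], dims = c(n, n))
  structure(
    list(W = W, codes = codes, k = k, d_max = d_max),
    class = "neighbor_rows"
  )
}

# positions of `x` in the sorted vector `table` (NA when absent)
.match_codes <- function(x, table) {
  pos <- findInterval(x, table)
  ok <- pos >= 1L & table[pmax(pos, 1L)] == x
  pos[!ok] <- NA_integer_
  pos
}

# all ordered (source, target) index pairs at Hamming distance exactly 1
# among sorted observed codes, vectorized one (position, base) at a time
.observed_pairs_d1 <- function(codes, k) {
  n <- length(codes)
  src_l <- vector("list", 4L * k)
  tgt_l <- vector("list", 4L * k)
  slot <- 0L
  for (t in seq_len(k)) {
    pw <- 4^(k - t)
    dt <- digit_at(codes, t, k)
    for (b in 0:3) {
      slot <- slot + 1L
      sel <- which(dt != b)
      cand <- codes[sel] + (b - dt[sel]) * pw
      pos <- .match_codes(cand, codes)
      hit <- which(!is.na(pos))
      src_l[[slot]] <- sel[hit]
      tgt_l[[slot]] <- pos[hit]
    }
  }
  list(src = unlist(src_l, use.names = FALSE),
       tgt = unlist(tgt_l, use.names = FALSE))
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat("# kmer spectrum: ", nrow(x), " distinct ", attr(x, "k"), "-mers, ",
      format(attr(x, "total_attempts"), big.mark = ","), " windows\n", sep = "")
  NextMethod()
}

#' Write / read a kmer spectrum as two-column TSV
#'
#' @param spectrum A `kmer_spectrum`.
#' @param path File path.
#' @return `path` invisibly (writer); a `kmer_spectrum` tibble (reader,
#'   which requires `total_attempts` to be recoverable as `sum(count)`).
#' @export
write_spectrum <- function(spectrum, path) {
  readr::write_tsv(tibble::tibble(kmer = spectrum$kmer, count = spectrum$count), path)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("kmer", "count") %in% names(tab)))
  k <- .check_k(unique(nchar(tab$kmer)))
  out <- tibble::tibble(
    kmer = tab$kmer,
    code = encode_kmers(tab$kmer, k),
    count = as.numeric(tab$count)
  )
  out <- dplyr::arrange(out, .data$code)
  attr(out, "k") <- k
  attr(out, "total_attempts") <- sum(out$count)
  class(out) <- c("kmer_spectrum", class(out))
  out
}
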