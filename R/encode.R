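# Nucleotide and kmer integer encodings.
#
# Bases map A=0, C=1, G=2, T=3 and a kmer is the base-4 integer with its
# first base as the most significant digit. Codes are stored as doubles,
# exact up to 2^53, so every code is representable for k <= 26.
# All coordinates in the package are 0-based, half-open.

.KMER_MAX_K <- 26L
.BASES <- c("A", "C", "G", "T")

.base_lookup <- local({
  m <- rep(NA_integer_, 256L)
  m[utf8ToInt("A")] <- 0L
  m[utf8ToInt("C")] <- 1L
  m[utf8ToInt("G")] <- 2L
  m[utf8ToInt("T")] <- 3L
  m
})

.check_k <- function(k) {
  if (length(k) != 1L || is.na(k) || k < 1 || k != floor(k)) {
    stop("`k` must be a single positive integer", call. = FALSE)
  }
  if (k > .KMER_MAX_K) {
    stop("`k` must be <= ", .KMER_MAX_K, " (exact integer encoding limit)",
         call. = FALSE)
  }
  as.integer(k)
}

# n x L matrix of base codes for equal-length ACGT sequences
seq_code_matrix <- function(seqs) {
  L <- unique(nchar(seqs))
  if (length(L) != 1L) {
    stop("sequences must share a common length", call. = FALSE)
  }
  v <- .base_lookup[utf8ToInt(paste(seqs, collapse = ""))]
  if (anyNA(v)) stop("sequences contain non-ACGT characters", call. = FALSE)
  matrix(v, nrow = length(seqs), ncol = L, byrow = TRUE)
}

code_matrix_to_seq <- function(mat) {
  cols <- lapply(seq_len(ncol(mat)), function(j) .BASES[mat[, j] + 1L])
  do.call(paste0, cols)
}

# kmer strings -> codes (vectorized, all strings length k)
encode_kmers <- function(kmers, k = NULL) {
  if (is.null(k)) k <- nchar(kmers[1])
  k <- .check_k(k)
  cm <- seq_code_matrix(kmers)
  if (ncol(cm) != k) stop("kmer length does not match `k`", call. = FALSE)
  as.vector(cm %*% 4^((k - 1L):0))
}

decode_kmers <- function(codes, k) {
  k <- .check_k(k)
  cols <- lapply(seq_len(k), function(t) .BASES[digit_at(codes, t, k) + 1L])
  do.call(paste0, cols)
}

# base code at kmer position t (1-based within the kmer)
digit_at <- function(codes, t, k) {
  floor(codes / 4^(k - t)) %% 4
}

# rolling kmer codes for every window of an n x L code matrix
window_codes <- function(cm, k) {
  L <- ncol(cm)
  n_win <- L - k + 1L
  pow <- 4^((k - 1L):0)
  out <- matrix(0, nrow = nrow(cm), ncol = n_win)
  out[, 1L] <- cm[, seq_len(k), drop = FALSE] %*% pow
  if (n_win > 1L) {
    top <- 4^(k - 1L)
    for (i in 2L:n_win) {
      out[, i] <- (out[, i - 1L] - cm[, i - 1L] * top) * 4 + cm[, i + k - 1L]
    }
  }
  out
}

# Hamming distance between paired kmer codes
hamming_codes <- function(a, b, k) {
  d <- numeric(length(a))
  for (t in seq_len(k)) {
    d <- d + (digit_at(a, t, k) != digit_at(b, t, k))
  }
  d
}
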