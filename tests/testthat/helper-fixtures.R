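# Shared fixture builders. All randomness is locally seeded so test order
# never matters.

random_seqs <- function(n, L, seed) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
  })
}

random_reads <- function(n, L, seed) {
  tibble::tibble(id = paste0("r", seq_len(n)), seq = random_seqs(n, L, seed))
}

# brute-force Hamming distance on kmer strings
str_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# enumerate all 4^k kmers as strings (k small)
all_kmers <- function(k) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                              stringsAsFactors = FALSE)[, k:1, drop = FALSE])
}

# dense source-normalized weight matrix computed the slow way, as an oracle
# for build_neighbor_rows
dense_neighbor_oracle <- function(spectrum, model, d_max) {
  k <- attr(spectrum, "k")
  n <- nrow(spectrum)
  raw <- matrix(0, n, n)
  for (m in seq_len(n)) {
    for (l in seq_len(n)) {
      if (str_hamming(spectrum$kmer[m], spectrum$kmer[l]) <= d_max) {
        raw[m, l] <- misread_prob(model, spectrum$kmer[m], spectrum$kmer[l])
      }
    }
  }
  raw / rowSums(raw)
}

# brute-force maximizer of the attempt likelihood over the simplex
# {T >= 0, sum(T) = sum(Y)} via a softmax parameterization; independent of
# the EM path
brute_force_attempts <- function(Y, W, n_starts = 5, seed = 1) {
  n <- length(Y)
  total <- sum(Y)
  negll <- function(theta) {
    T_vec <- total * exp(theta) / sum(exp(theta))
    denom <- as.vector(t(W) %*% T_vec)
    if (any(denom <= 0)) return(1e12)
    -sum(Y * log(denom))
  }
  best <- NULL
  withr::with_seed(seed, {
    for (s in seq_len(n_starts)) {
      theta0 <- if (s == 1) log(Y / total) else stats::rnorm(n)
      opt <- stats::optim(theta0, negll, method = "BFGS",
                          control = list(maxit = 2000, reltol = 1e-14))
      if (is.null(best) || opt$value < best$value) best <- opt
    }
  })
  total * exp(best$par) / sum(exp(best$par))
}

# a small spectrum + neighborhood + uniform model bundle on random reads
small_system <- function(n_reads = 30, L = 8, k = 5, p_e = 0.01, seed = 1,
                         d_max = 1) {
  sp <- build_spectrum(random_reads(n_reads, L, seed), k = k)
  model <- uniform_error_model(p_e)
  rows <- build_neighbor_rows(sp, model, d_max = d_max)
  list(spectrum = sp, model = model, rows = rows)
}
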