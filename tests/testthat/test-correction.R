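# a fit/rows pair over {AAA, AAC} with attempts pinned to chosen values
pinned_two_kmer_fit <- function(T_aaa = 500, T_aac = 1, p_e = 0.01) {
  sp <- build_spectrum(c(rep("AAA", 10), rep("AAC", 2)), k = 3)
  rows <- build_neighbor_rows(sp, uniform_error_model(p_e), d_max = 1)
  fit <- run_em(sp, rows)
  fit$estimates$attempts <- c(T_aaa, T_aac)  # spectrum order: AAA, AAC
  list(fit = fit, rows = rows)
}

test_that("self-only neighborhoods give a point mass on the observed base", {
  sp <- build_spectrum("AAAA", k = 3)
  rows <- build_neighbor_rows(sp, uniform_error_model(0.01), d_max = 0)
  fit <- run_em(sp, rows)
  for (t in 1:3) {
    expect_equal(kmer_position_posterior("AAA", t, fit, rows),
                 c(A = 1, C = 0, G = 0, T = 0))
  }
})

test_that("kmer position posterior matches two-term hand arithmetic", {
  ctx <- pinned_two_kmer_fit()
  W <- as.matrix(ctx$rows$W)
  # target AAC at position 3: sources AAA (base A) and AAC itself (base C)
  u_aaa <- 500 * W[1, 2]
  u_aac <- 1 * W[2, 2]
  expected <- c(A = u_aaa, C = u_aac, G = 0, T = 0) / (u_aaa + u_aac)
  got <- kmer_position_posterior("AAC", 3, ctx$fit, ctx$rows)
  expect_equal(got, expected, tolerance = 1e-12)
  expect_gt(got[["A"]], got[["C"]])  # the repeat source outweighs the observed base
  expect_equal(sum(got), 1, tolerance = 1e-12)
  # positions 1-2 agree on A across both sources
  expect_equal(kmer_position_posterior("AAC", 1, ctx$fit, ctx$rows)[["A"]], 1)
})

test_that("read base posterior averages the covering windows", {
  sys <- small_system(n_reads = 20, L = 7, k = 3, p_e = 0.02, seed = 31)
  fit <- run_em(sys$spectrum, sys$rows)
  read <- random_reads(20, 7, seed = 31)$seq[1]  # a read the spectrum saw
  L <- nchar(read)
  k <- 3
  for (i in c(0L, 3L, L - 1L)) {
    got <- read_base_posterior(read, i, fit, sys$rows)
    wins <- max(0L, i - k + 1L):min(i, L - k)
    manual <- rowMeans(vapply(wins, function(w) {
      kmer_position_posterior(substr(read, w + 1, w + k), i - w + 1,
                              fit, sys$rows)
    }, numeric(4)))
    expect_equal(got, manual, tolerance = 1e-12)
    expect_equal(sum(got), 1, tolerance = 1e-9)
    if (i == 0L || i == L - 1L) {
      expect_equal(length(wins), 1L)  # single covering window at read ends
    }
  }
  expect_error(read_base_posterior("AC", 0, fit, sys$rows), "shorter")
})

test_that("zero attempt mass falls back to the observed base", {
  ctx <- pinned_two_kmer_fit(T_aaa = 0, T_aac = 0)
  expect_message(
    out <- correct_reads(tibble::tibble(id = "r", seq = "AAAC"),
                         ctx$fit, ctx$rows, liberal_threshold = Inf),
    "zero neighborhood mass"
  )
  expect_equal(out$seq, "AAAC")
  expect_equal(nrow(corrections(out)), 0L)
})

test_that("error-free reads over unique kmers are left untouched", {
  reads <- tibble::tibble(id = "r1", seq = "ACGTTGCA")
  sp <- build_spectrum(reads, k = 4)
  rows <- build_neighbor_rows(sp, uniform_error_model(0.01), d_max = 1)
  fit <- run_em(sp, rows)
  res <- correct_read(reads, fit, rows)
  expect_equal(res$seq, reads$seq)
  expect_equal(nrow(res$records), 0L)
})

test_that("a planted substitution in a 500-copy repeat context is corrected", {
  unit <- random_seqs(1, 60, seed = 41)
  genome <- generate_genome(
    45000, repeats = tibble::tibble(unit_length = 60L, multiplicity = 500L),
    seed = 42
  )
  # replace the sampled unit with our fixed one for a self-contained check
  sim <- simulate_reads(genome, coverage = 30, read_length = 36,
                        model = uniform_error_model(0.004), seed = 43)
  # plant one substitution inside a read drawn from a repeat copy
  ann <- attr(genome, "repeats")
  inside <- which(sim$start >= ann$start[1] & sim$start + 36 <= ann$end[1] &
                    sim$seq == sim$true_seq)
  target <- inside[1]
  planted <- sim$seq[target]
  from <- substr(planted, 11, 11)
  to <- setdiff(c("A", "C", "G", "T"), from)[1]
  substr(planted, 11, 11) <- to
  sim$seq[target] <- planted
  sp <- build_spectrum(sim, k = 13)
  rows <- build_neighbor_rows(sp, uniform_error_model(0.004), d_max = 1)
  fit <- run_em(sp, rows)
  out <- correct_reads(sim, fit, rows, liberal_threshold = 10)
  expect_equal(out$seq[target], sim$true_seq[target])
  recs <- corrections(out)
  planted_rec <- recs[recs$read_id == sim$id[target] & recs$pos == 10L, ]
  expect_equal(planted_rec$from, to)
  expect_equal(planted_rec$to, from)
})

test_that("liberal pre-filter skips reads and matches the full run elsewhere", {
  sys <- small_system(n_reads = 80, L = 10, k = 5, p_e = 0.02, seed = 51)
  reads <- random_reads(80, 10, seed = 51)
  fit <- run_em(sys$spectrum, sys$rows)
  none <- correct_reads(reads, fit, sys$rows, liberal_threshold = 0)
  expect_equal(none$seq, reads$seq)
  expect_equal(nrow(corrections(none)), 0L)
  full <- correct_reads(reads, fit, sys$rows, liberal_threshold = Inf)
  M <- stats::median(fit$estimates$attempts)
  part <- correct_reads(reads, fit, sys$rows, liberal_threshold = M)
  # eligibility recomputed independently
  wc <- matrix(readem:::.match_codes(
    as.vector(readem:::window_codes(readem:::seq_code_matrix(reads$seq), 5)),
    sys$rows$codes
  ), nrow = 80)
  minT <- apply(matrix(fit$estimates$attempts[wc], nrow = 80), 1, min)
  eligible <- minT < M
  expect_equal(part$seq[eligible], full$seq[eligible])
  expect_equal(part$seq[!eligible], reads$seq[!eligible])
  # ids and lengths preserved, every change logged
  expect_equal(part$id, reads$id)
  expect_equal(nchar(part$seq), nchar(reads$seq))
  recs <- corrections(full)
  changed <- which(full$seq != reads$seq)
  expect_setequal(unique(recs$read_id), reads$id[changed])
  expect_true(all(recs$from != recs$to))
})

test_that("the vectorized engine agrees with the per-position posterior argmax", {
  sys <- small_system(n_reads = 50, L = 9, k = 4, p_e = 0.03, seed = 61)
  reads <- random_reads(50, 9, seed = 61)
  fit <- run_em(sys$spectrum, sys$rows)
  out <- correct_reads(reads, fit, sys$rows, liberal_threshold = Inf)
  for (r in c(1, 7, 25)) {
    manual <- reads$seq[r]
    for (i in 0:8) {
      post <- read_base_posterior(reads$seq[r], i, fit, sys$rows)
      obs <- substr(reads$seq[r], i + 1, i + 1)
      if (max(post) > post[[obs]]) {
        substr(manual, i + 1, i + 1) <- names(which.max(post))
      }
    }
    expect_equal(out$seq[r], manual)
  }
})
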