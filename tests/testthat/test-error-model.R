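test_that("uniform misread probability follows the distance formula", {
  m <- uniform_error_model(0.006)
  expect_equal(misread_prob(m, "AAA", "AAA"), 0.982107784, tolerance = 1e-9)
  expect_equal(misread_prob(m, "AAA", "AAC"), 0.001976072, tolerance = 1e-9)
  expect_equal(misread_prob(m, "AAC", "AAA"), misread_prob(m, "AAA", "AAC"))
  m0 <- uniform_error_model(0)
  expect_equal(misread_prob(m0, "ACG", "ACG"), 1)
  expect_equal(misread_prob(m0, "ACG", "ACT"), 0)
  expect_error(uniform_error_model(0.8))
})

test_that("positional misread probability is the per-position product", {
  q <- example_error_model("ecoli", k = 13)
  a <- strrep("A", 13)
  b <- paste0(strrep("A", 10), "C", "AA")  # substitution at kmer position 11
  expect_equal(misread_prob(q, a, b), 0.0063, tolerance = 1e-9)
  expect_equal(misread_prob(q, a, a), 0.9896, tolerance = 1e-9)
  # asymmetry: C misread as A is much rarer than A as C
  b2a <- paste0(strrep("A", 10), "C", "AA")
  expect_lt(misread_prob(q, b2a, a), misread_prob(q, a, b2a))

  # k = 2 hand product
  q2 <- array(0, dim = c(2, 4, 4))
  q2[1, , ] <- matrix(c(0.9, 0.05, 0.03, 0.02,
                        0.01, 0.97, 0.01, 0.01,
                        0.02, 0.02, 0.94, 0.02,
                        0.01, 0.01, 0.01, 0.97), 4, 4, byrow = TRUE)
  q2[2, , ] <- diag(4) * 0.96 + 0.01
  model2 <- positional_error_model(q2)
  expect_equal(misread_prob(model2, "AC", "CT"), 0.05 * 0.01, tolerance = 1e-12)
  expect_equal(misread_prob(model2, "GA", "GA"), 0.94 * 0.97, tolerance = 1e-12)
})

test_that("misread rows over all 4^k targets sum to one", {
  targets <- all_kmers(3)
  m <- uniform_error_model(0.02)
  for (src in c("AAA", "ACG", "TTT")) {
    expect_equal(sum(misread_prob(m, rep(src, 64), targets)), 1,
                 tolerance = 1e-12)
  }
  q <- withr::with_seed(5, {
    arr <- array(0, dim = c(3, 4, 4))
    for (i in 1:3) {
      tab <- matrix(stats::runif(16, 0, 0.05), 4, 4)
      diag(tab) <- 0
      diag(tab) <- 1 - rowSums(tab)
      arr[i, , ] <- tab
    }
    arr
  })
  model <- positional_error_model(q)
  expect_equal(sum(misread_prob(model, rep("CGT", 64), targets)), 1,
               tolerance = 1e-12)
})

test_that("uniform model equals the matched positional model", {
  p <- 0.013
  k <- 5
  q <- array(0, dim = c(k, 4, 4))
  for (i in seq_len(k)) {
    tab <- matrix(p / 3, 4, 4)
    diag(tab) <- 1 - p
    q[i, , ] <- tab
  }
  mu <- uniform_error_model(p)
  mq <- positional_error_model(q)
  pairs <- cbind(random_seqs(20, k, seed = 3), random_seqs(20, k, seed = 4))
  for (r in seq_len(nrow(pairs))) {
    expect_equal(misread_prob(mu, pairs[r, 1], pairs[r, 2]),
                 misread_prob(mq, pairs[r, 1], pairs[r, 2]),
                 tolerance = 1e-12)
  }
})

test_that("positional rate estimation matches hand counts", {
  aln <- tibble::tibble(ref = "AA", read = "AC")
  fit <- estimate_positional_rates(aln, k = 1)
  expect_equal(fit$q[1, 1, ], c(0.5, 0.5, 0, 0), ignore_attr = TRUE)
  # unseen true bases default to identity rows
  expect_equal(fit$q[1, 3, ], c(0, 0, 1, 0), ignore_attr = TRUE)

  clean <- tibble::tibble(ref = c("ACGT", "TTAA"), read = c("ACGT", "TTAA"))
  fit2 <- estimate_positional_rates(clean, k = 2)
  for (i in 1:2) expect_equal(fit2$q[i, , ], diag(4), ignore_attr = TRUE)
  expect_error(estimate_positional_rates(clean[0, ], k = 2), "empty")
})

test_that("read-profile estimation counts by read position", {
  ref <- strrep("A", 8)
  reads <- rep(ref, 10)
  substr(reads[1], 6, 6) <- "G"  # one substitution at 0-based position 5
  aln <- tibble::tibble(ref = rep(ref, 10), read = reads)
  prof <- estimate_read_profile(aln)
  expect_equal(prof$M[6, 1, ], c(0.9, 0, 0.1, 0), ignore_attr = TRUE)
  expect_equal(prof$M[5, 1, ], c(1, 0, 0, 0), ignore_attr = TRUE)
})

test_that("estimators recover a known profile from simulated alignments", {
  prof <- ramped_read_profile(20, 0.004, 0.02)
  g <- generate_genome(5000, repeats = NULL, seed = 21)
  sim <- simulate_reads(g, n_reads = 20000, read_length = 20,
                        model = prof, seed = 22)
  aln <- tibble::tibble(ref = sim$true_seq, read = sim$seq)
  est <- estimate_read_profile(aln)
  expect_lt(max(abs(est$M - prof$M)), 0.01)  # 4e5 sampled bases
  # kmer-position estimate approaches the window-averaged collapse
  estq <- estimate_positional_rates(aln, k = 7)
  collapse <- profile_to_kmer_model(prof, k = 7)
  expect_lt(max(abs(estq$q - collapse$q)), 0.005)
})

test_that("profile collapse window-averages the read-position tables", {
  M <- array(0, dim = c(3, 4, 4))
  for (j in 1:3) {
    tab <- matrix(0.01 * j, 4, 4)
    diag(tab) <- 1 - 3 * 0.01 * j
    M[j, , ] <- tab
  }
  prof <- read_error_profile(M)
  q <- profile_to_kmer_model(prof, k = 2)
  expect_equal(q$q[1, , ], (M[1, , ] + M[2, , ]) / 2, ignore_attr = TRUE)
  expect_equal(q$q[2, , ], (M[2, , ] + M[3, , ]) / 2, ignore_attr = TRUE)
  # identity in, identity out
  ident <- read_error_profile(array(rep(diag(4), each = 1),
                                    dim = c(1, 4, 4))[rep(1, 5), , , drop = FALSE])
  expect_equal(profile_to_kmer_model(ident, 3)$q[2, , ], diag(4),
               ignore_attr = TRUE)
})

test_that("error tables round trip through TSV", {
  q <- example_error_model("acinetobacter", k = 13)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_error_table(q, f)
  back <- read_error_table(f, type = "kmer")
  expect_equal(back$q, q$q, tolerance = 1e-12)
  expect_equal(back$q[11, 1, ], c(0.9618, 0.0253, 0.0019, 0.0110),
               ignore_attr = TRUE)
})

test_that("diagonal perturbation keeps rows stochastic and shifts diagonals", {
  q <- profile_to_kmer_model(ramped_read_profile(36), 13)
  qp <- perturb_error_model(q, 0.02)
  rs <- apply(qp$q, c(1, 2), sum)
  expect_equal(max(abs(rs - 1)), 0, tolerance = 1e-12)
  d_old <- vapply(1:13, function(i) qp$q[i, 1, 1] - q$q[i, 1, 1], numeric(1))
  expect_true(all(abs(d_old) > 0))          # every position moved
  expect_true(any(d_old > 0) && any(d_old < 0))  # alternating pattern
})
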