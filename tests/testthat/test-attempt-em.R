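test_that("E step attributes isolated kmers entirely to themselves", {
  # mutually isolated kmers: pairwise Hamming distance 3
  sp <- build_spectrum(c("AAA", "AAA", "CCC", "GGG", "GGG", "GGG", "TTT"), k = 3)
  m <- uniform_error_model(0.01)
  rows <- build_neighbor_rows(sp, m, d_max = 1)
  Y <- sp$count
  es <- e_step(Y, Y, rows)
  self <- es$pairs[es$pairs$source == es$pairs$target, ]
  expect_equal(self$e_count[order(self$target)], Y, tolerance = 1e-12)
  expect_equal(m_step(es, nrow(sp)), Y, tolerance = 1e-12)
})

test_that("E and M steps match the two-kmer closed form", {
  sp <- build_spectrum(c(rep("AAA", 100), rep("AAC", 10)), k = 3)
  m <- uniform_error_model(0.01)
  rows <- build_neighbor_rows(sp, m, d_max = 1)
  W <- as.matrix(rows$W)
  Y <- sp$count
  T0 <- Y
  es <- e_step(Y, T0, rows)
  # independent arithmetic: denom_l = sum_m T_m W[m, l]
  denom <- c(T0[1] * W[1, 1] + T0[2] * W[2, 1],
             T0[1] * W[1, 2] + T0[2] * W[2, 2])
  expect_equal(es$denom, denom, tolerance = 1e-12)
  expected <- tibble::tibble(
    source = c(1L, 2L, 1L, 2L),
    target = c(1L, 1L, 2L, 2L),
    e_count = c(Y[1] * T0[1] * W[1, 1] / denom[1],
                Y[1] * T0[2] * W[2, 1] / denom[1],
                Y[2] * T0[1] * W[1, 2] / denom[2],
                Y[2] * T0[2] * W[2, 2] / denom[2])
  )
  got <- dplyr::arrange(es$pairs, target, source)
  exp_sorted <- dplyr::arrange(expected, target, source)
  expect_equal(got$e_count, exp_sorted$e_count, tolerance = 1e-12)
  # responsibilities over each target's neighborhood sum to Y_l
  sums <- tapply(es$pairs$e_count, es$pairs$target, sum)
  expect_equal(as.numeric(sums), Y, tolerance = 1e-12)
  # M step totals and log likelihood against the same arithmetic
  expect_equal(sum(m_step(es, 2)), sum(Y), tolerance = 1e-12)
  expect_equal(log_likelihood(Y, T0, rows), sum(Y * log(denom)),
               tolerance = 1e-12)
})

test_that("E-step conservation holds on random fixtures", {
  for (seed in 1:4) {
    sys <- small_system(n_reads = 40, L = 9, k = 5, seed = seed)
    Y <- sys$spectrum$count
    es <- e_step(Y, Y, sys$rows)
    sums <- rep(0, length(Y))
    agg <- tapply(es$pairs$e_count, es$pairs$target, sum)
    sums[as.integer(names(agg))] <- as.numeric(agg)
    expect_equal(sums, Y, tolerance = 1e-10)
    expect_equal(sum(m_step(es, length(Y))), sum(Y), tolerance = 1e-8)
  }
})

test_that("degenerate zero-mass neighborhoods raise a named error", {
  sp <- build_spectrum("AAAA", k = 3)
  rows <- build_neighbor_rows(sp, uniform_error_model(0.01), d_max = 0)
  expect_error(e_step(sp$count, 0, rows), "AAA")
})

test_that("d_max = 0 fixes the estimates at the observed counts", {
  sys <- small_system(n_reads = 25, L = 9, k = 5, seed = 6, d_max = 0)
  fit <- run_em(sys$spectrum, sys$rows)
  expect_identical(fit$estimates$attempts, sys$spectrum$count)
  expect_true(fit$converged)
})

test_that("log likelihood is monotone and totals are conserved during EM", {
  for (seed in 1:4) {
    sys <- small_system(n_reads = 60, L = 10, k = 4, p_e = 0.02, seed = seed)
    fit <- run_em(sys$spectrum, sys$rows)
    expect_true(fit$converged)
    dll <- diff(fit$loglik_trace)
    expect_true(all(dll >= -1e-9 * abs(fit$loglik_trace[-1])))
    expect_equal(sum(fit$estimates$attempts), sum(sys$spectrum$count),
                 tolerance = 1e-6 * sum(sys$spectrum$count))
    expect_true(all(fit$estimates$attempts >= 0))
  }
})

test_that("EM matches brute-force likelihood maximization on small systems", {
  cases <- list(
    c(rep("AAA", 100), rep("AAC", 10)),
    c(rep("ACG", 50), rep("ACT", 7), rep("AAG", 20)),
    c(rep("TTT", 200), rep("TTA", 5), rep("TAT", 4), rep("ATT", 6))
  )
  for (reads in cases) {
    sp <- build_spectrum(reads, k = 3)
    rows <- build_neighbor_rows(sp, uniform_error_model(0.01), d_max = 1)
    fit <- run_em(sp, rows, tol = 1e-12, max_iter = 5000)
    oracle <- brute_force_attempts(sp$count, as.matrix(rows$W))
    ll_em <- log_likelihood(sp$count, fit$estimates$attempts, rows)
    ll_or <- log_likelihood(sp$count, oracle, rows)
    expect_gte(ll_em, ll_or - 1e-6 * abs(ll_or))
    expect_equal(fit$estimates$attempts, oracle,
                 tolerance = 1e-3, ignore_attr = TRUE)
  }
})

test_that("a low-count satellite of a strong repeat is drained to the ML value", {
  sp <- build_spectrum(c(rep("AAA", 500), rep("AAC", 6)), k = 3)
  rows <- build_neighbor_rows(sp, uniform_error_model(0.01), d_max = 1)
  fit <- run_em(sp, rows, tol = 1e-12, max_iter = 5000)
  # 1-D grid oracle over T_AAC with the conservation constraint
  W <- as.matrix(rows$W)
  Y <- sp$count
  grid <- seq(0, sum(Y), by = 1e-3)
  ll <- vapply(grid, function(t2) {
    T_vec <- c(sum(Y) - t2, t2)
    denom <- as.vector(t(W) %*% T_vec)
    if (any(denom <= 0)) return(-Inf)
    sum(Y * log(denom))
  }, numeric(1))
  t2_star <- grid[which.max(ll)]
  t2_em <- fit$estimates$attempts[sp$kmer == "AAC"]
  expect_equal(t2_em, t2_star, tolerance = 1e-2, ignore_attr = TRUE)
  expect_lt(t2_em, 6)  # below its observed count: misreads re-attributed
  expect_equal(sum(fit$estimates$attempts), 506, tolerance = 1e-6)
})

test_that("tidy and glance expose the fit in broom shape", {
  sys <- small_system(seed = 8)
  fit <- run_em(sys$spectrum, sys$rows)
  td <- tidy(fit)
  expect_named(td, c("kmer", "code", "count", "attempts"))
  gl <- glance(fit)
  expect_equal(gl$n_kmers, nrow(sys$spectrum))
  expect_equal(gl$total_attempts, sum(sys$spectrum$count), tolerance = 1e-8)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_attempts(fit, f)
  back <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(back$attempts, td$attempts, tolerance = 1e-9)
})
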