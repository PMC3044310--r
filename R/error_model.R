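# Misread probability models.
#
# Two parametric forms are supported. The uniform model assumes substitution
# errors strike every site independently at a constant rate p_e, giving the
# symmetric misread probability
#     p_e(x_m, x_l) = (p_e/3)^d * (1 - p_e)^(k - d),  d = Hamming distance.
# The positional model replaces the constant rate with one stochastic 4x4
# table per kmer position, q_i(true base, read base), so
#     p_e(x_m, x_l) = prod_i q_i(x_m[i], x_l[i]),
# which is no longer symmetric. A third container, the read error profile,
# holds one 4x4 table per READ position and drives the simulator.

#' Uniform substitution error model
#'
#' @param p_e Per-base substitution probability, `0 <= p_e < 0.75` (beyond
#'   0.75 a "read" base would be less informative than a uniform draw).
#' @return An object of class `uniform_error_model`.
#' @export
uniform_error_model <- function(p_e) {
  stopifnot(is.numeric(p_e), length(p_e) == 1L)
  if (is.na(p_e) || p_e < 0 || p_e >= 0.75) {
    stop("`p_e` must lie in [0, 0.75)", call. = FALSE)
  }
  structure(list(p_e = p_e), class = "uniform_error_model")
}

#' Position-specific substitution error model (kmer positions)
#'
#' @param q A numeric array of dimension `(k, 4, 4)`: `q[i, a, b]` is the
#'   probability that true base `a` (A,C,G,T order) at kmer position `i` is
#'   read as base `b`. Every row must sum to one and diagonals must exceed
#'   0.5 (sequencing is assumed mostly correct).
#' @return An object of class `positional_error_model`.
#' @export
positional_error_model <- function(q) {
  q <- .check_tables(q, diag_floor = 0.5)
  structure(list(k = dim(q)[1], q = q), class = "positional_error_model")
}

#' Per-read-position misread profile (simulator input)
#'
#' @param M A numeric array of dimension `(L, 4, 4)`: `M[j, a, b]` is the
#'   probability that true base `a` at read position `j` is read as `b`.
#' @return An object of class `read_error_profile`.
#' @export
read_error_profile <- function(M) {
  M <- .check_tables(M, diag_floor = NA)
  structure(list(L = dim(M)[1], M = M), class = "read_error_profile")
}

.check_tables <- function(q, diag_floor = NA) {
  if (!is.array(q) || length(dim(q)) != 3L || dim(q)[2] != 4L || dim(q)[3] != 4L) {
    stop("expected an array of dimension (positions, 4, 4)", call. = FALSE)
  }
  if (any(q < 0)) stop("misread probabilities must be non-negative", call. = FALSE)
  rs <- apply(q, c(1, 2), sum)
  if (any(abs(rs - 1) > 1e-9)) {
    stop("each (position, true base) row must sum to 1", call. = FALSE)
  }
  if (!is.na(diag_floor)) {
    diags <- vapply(seq_len(dim(q)[1]), function(i) min(diag(q[i, , ])), numeric(1))
    if (any(diags < diag_floor)) {
      warning("some diagonal entries fall below ", diag_floor,
              "; sequencing is usually mostly correct - check the tables",
              call. = FALSE)
    }
  }
  q
}

#' Misread probability between two kmers
#'
#' Probability that `source` is (mis)read as `target` under `model`.
#' Symmetric in its arguments under the uniform model only.
#'
#' @param model A [uniform_error_model()] or [positional_error_model()].
#' @param source,target kmer strings of equal length (the positional model
#'   additionally requires the length to equal `model$k`).
#' @return A numeric vector of probabilities (vectorized over pairs).
#' @examples
#' m <- uniform_error_model(0.006)
#' misread_prob(m, "AAA", "AAA")  # 0.994^3
#' misread_prob(m, "AAA", "AAC")  # (0.006/3) * 0.994^2
#' @export
misread_prob <- function(model, source, target) {
  k <- unique(nchar(c(source, target)))
  if (length(k) != 1L) stop("kmers must share a common length", call. = FALSE)
  k <- .check_k(k)
  if (inherits(model, "positional_error_model") && model$k != k) {
    stop("kmer length does not match the model's `k`", call. = FALSE)
  }
  pair_misread_prob(model, encode_kmers(source, k), encode_kmers(target, k), k)
}

# vectorized pair probabilities on kmer codes
pair_misread_prob <- function(model, src, tgt, k) {
  UseMethod("pair_misread_prob")
}

#' @export
pair_misread_prob.uniform_error_model <- function(model, src, tgt, k) {
  d <- hamming_codes(src, tgt, k)
  p <- model$p_e
  if (p == 0) return(as.numeric(d == 0))
  (p / 3)^d * (1 - p)^(k - d)
}

#' @export
pair_misread_prob.positional_error_model <- function(model, src, tgt, k) {
  stopifnot(k == model$k)
  out <- rep(1, length(src))
  q <- model$q
  for (t in seq_len(k)) {
    a <- digit_at(src, t, k)
    b <- digit_at(tgt, t, k)
    out <- out * q[cbind(t, a + 1L, b + 1L)]
  }
  out
}

# -- training from alignments -------------------------------------------------

# per-read-position 4x4 substitution count tables from an alignment table
.position_pair_counts <- function(alignments) {
  stopifnot(is.data.frame(alignments), all(c("ref", "read") %in% names(alignments)))
  if (nrow(alignments) == 0L) stop("empty alignment table", call. = FALSE)
  if (!all(nchar(alignments$ref) == nchar(alignments$read))) {
    stop("ref and read must have equal lengths (substitutions only)", call. = FALSE)
  }
  L <- unique(nchar(alignments$ref))
  if (length(L) != 1L) stop("alignments must share a common length", call. = FALSE)
  rm_ <- seq_code_matrix(alignments$ref)
  dm <- seq_code_matrix(alignments$read)
  counts <- array(0, dim = c(L, 4L, 4L))
  for (j in seq_len(L)) {
    idx <- rm_[, j] * 4L + dm[, j]  # 0..15
    counts[j, , ] <- matrix(tabulate(idx + 1L, nbins = 16L), 4L, 4L, byrow = TRUE)
  }
  counts
}

# normalize count tables row-wise; zero rows become identity; pseudocount is
# added to the diagonal (a prior toward correct sequencing)
.normalize_tables <- function(counts, pseudocount = 0) {
  P <- dim(counts)[1]
  for (j in seq_len(P)) {
    tab <- counts[j, , ]
    diag(tab) <- diag(tab) + pseudocount
    rs <- rowSums(tab)
    for (a in 1:4) {
      if (rs[a] > 0) {
        tab[a, ] <- tab[a, ] / rs[a]
      } else {
        tab[a, ] <- 0
        tab[a, a] <- 1
      }
    }
    counts[j, , ] <- tab
  }
  counts
}

#' Estimate kmer-position misread tables from aligned reads
#'
#' Each aligned read of length `L` is decomposed into its `L - k + 1` kmer
#' windows and substitutions are counted by *kmer* position: the maximum
#' likelihood estimate of `q_i(a, b)` is the number of times `a` is read as
#' `b` at kmer position `i` over all windows, divided by the number of times
#' `a` occurs at kmer position `i`. A single read base contributes to up to
#' `k` distinct windows. Rows with zero denominator default to the identity
#' row.
#'
#' @param alignments A data frame with character columns `ref` (reference
#'   substring) and `read` (read sequence), equal lengths, substitutions
#'   only. The plain-TSV export of the simulator truth has this shape.
#' @param k kmer length.
#' @param pseudocount Added to diagonal counts; default 0 (pure ML).
#' @return A [positional_error_model()].
#' @export
estimate_positional_rates <- function(alignments, k, pseudocount = 0) {
  k <- .check_k(k)
  counts <- .position_pair_counts(alignments)
  L <- dim(counts)[1]
  if (k > L) stop("`k` exceeds the aligned read length", call. = FALSE)
  qc <- array(0, dim = c(k, 4L, 4L))
  for (i in seq_len(k)) {
    # kmer position i maps to read positions i .. i + (L - k)
    for (j in i:(i + L - k)) qc[i, , ] <- qc[i, , ] + counts[j, , ]
  }
  positional_error_model(.normalize_tables(qc, pseudocount))
}

#' Estimate read-position misread matrices from aligned reads
#'
#' As [estimate_positional_rates()] but indexed by read position with no
#' kmer windowing; this is the profile the simulator consumes.
#'
#' @inheritParams estimate_positional_rates
#' @return A [read_error_profile()].
#' @export
estimate_read_profile <- function(alignments, pseudocount = 0) {
  counts <- .position_pair_counts(alignments)
  read_error_profile(.normalize_tables(counts, pseudocount))
}

#' Collapse a read-position profile to a kmer-position model
#'
#' Averages the per-read-position tables over the read positions each kmer
#' position can occupy (`i .. i + L - k`), assuming base composition is
#' stationary along the read. This is the model-matched way to run inference
#' when reads were generated from a read-position profile.
#'
#' @param profile A [read_error_profile()].
#' @param k kmer length.
#' @return A [positional_error_model()].
#' @export
profile_to_kmer_model <- function(profile, k) {
  stopifnot(inherits(profile, "read_error_profile"))
  k <- .check_k(k)
  L <- profile$L
  if (k > L) stop("`k` exceeds the profile's read length", call. = FALSE)
  q <- array(0, dim = c(k, 4L, 4L))
  for (i in seq_len(k)) {
    q[i, , ] <- apply(profile$M[i:(i + L - k), , , drop = FALSE], c(2, 3), mean)
  }
  positional_error_model(q)
}

# -- serialization ------------------------------------------------------------

#' Write an error model to a TSV table
#'
#' One row per (position, true base) with the four read-base probabilities.
#' Kmer-position models and read-position profiles share the format.
#'
#' @param model A [positional_error_model()] or [read_error_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_error_table <- function(model, path) {
  tabs <- if (inherits(model, "positional_error_model")) model$q else model$M
  P <- dim(tabs)[1]
  rows <- purrr::map_dfr(seq_len(P), function(i) {
    tibble::tibble(
      position = i, true_base = .BASES,
      A = tabs[i, , 1], C = tabs[i, , 2], G = tabs[i, , 3], T = tabs[i, , 4]
    )
  })
  readr::write_tsv(rows, path)
  invisible(path)
}

#' Read an error model from a TSV table
#'
#' @param path Path written by [write_error_table()] (columns `position`,
#'   `true_base`, `A`, `C`, `G`, `T`). Positions absent from the file are
#'   filled with identity rows, so tables known only at some positions (as
#'   published error profiles often are) can be used directly.
#' @param type `"kmer"` for a [positional_error_model()] or `"read"` for a
#'   [read_error_profile()].
#' @param positions Total number of positions (`k` or `L`); defaults to the
#'   largest position present in the file.
#' @return The reconstructed model object.
#' @export
read_error_table <- function(path, type = c("kmer", "read"), positions = NULL) {
  type <- match.arg(type)
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("position", "true_base", "A", "C", "G", "T") %in% names(tab)))
  P <- if (is.null(positions)) max(tab$position) else positions
  q <- array(0, dim = c(P, 4L, 4L))
  for (i in seq_len(P)) q[i, , ] <- diag(4)
  for (r in seq_len(nrow(tab))) {
    i <- tab$position[r]
    a <- match(tab$true_base[r], .BASES)
    q[i, a, ] <- as.numeric(tab[r, c("A", "C", "G", "T")])
  }
  if (type == "kmer") positional_error_model(q) else read_error_profile(q)
}

#' Published single-position error tables (illustrative)
#'
#' Loads one of the two bundled position-11 substitution tables estimated
#' from Illumina runs of *E. coli K-12* and *Acinetobacter sp. ADP1*,
#' expanded to a full kmer-position model with identity rows at the other
#' positions. Only position 11 of these profiles is published, so the
#' expansion is synthetic and intended for illustration and testing of the
#' positional machinery, not as a realistic full profile.
#'
#' @param which `"ecoli"` or `"acinetobacter"`.
#' @param k Number of kmer positions in the expanded model.
#' @return A [positional_error_model()].
#' @export
example_error_model <- function(which = c("ecoli", "acinetobacter"), k = 13) {
  which <- match.arg(which)
  f <- system.file("extdata", paste0("q11_", which, "_synthetic.tsv"),
                   package = "readem", mustWork = TRUE)
  read_error_table(f, type = "kmer", positions = k)
}

# -- built-in profiles for calibration studies --------------------------------

#' Illumina-like ramped read error profile
#'
#' Substitution rates increase linearly from the 5' to the 3' end of the
#' read, as typically seen on short-read platforms, with transitions
#' (A<->G, C<->T) twice as likely as either transversion.
#'
#' @param L Read length.
#' @param rate_5p,rate_3p Substitution rates at the first and last read
#'   position.
#' @return A [read_error_profile()].
#' @export
ramped_read_profile <- function(L, rate_5p = 0.002, rate_3p = 0.012) {
  stopifnot(L >= 1, rate_5p >= 0, rate_3p >= 0, max(rate_5p, rate_3p) < 0.75)
  rates <- seq(rate_5p, rate_3p, length.out = L)
  # substitution pattern per true base: transition weight 1/2, transversions 1/4
  pattern <- matrix(0, 4, 4)
  trans <- c(A = "G", C = "T", G = "A", T = "C")
  for (a in 1:4) {
    for (b in setdiff(1:4, a)) {
      pattern[a, b] <- if (.BASES[b] == trans[[.BASES[a]]]) 0.5 else 0.25
    }
  }
  M <- array(0, dim = c(L, 4L, 4L))
  for (j in seq_len(L)) {
    tab <- pattern * rates[j]
    diag(tab) <- 1 - rates[j]
    M[j, , ] <- tab
  }
  read_error_profile(M)
}

#' Perturb the diagonals of a kmer-position error model
#'
#' Emulates inference under a deliberately wrong error model: diagonal
#' entries are shifted by `delta` with alternating sign across kmer
#' positions (clamped to `[0.5 + 1e-6, 0.9995]`), and off-diagonals are
#' rescaled proportionally so each row still sums to one.
#'
#' @param model A [positional_error_model()].
#' @param delta Diagonal shift magnitude.
#' @return A [positional_error_model()] with perturbed tables.
#' @export
perturb_error_model <- function(model, delta = 0.02) {
  stopifnot(inherits(model, "positional_error_model"))
  q <- model$q
  for (i in seq_len(model$k)) {
    s <- if (i %% 2L == 1L) -1 else 1
    for (a in 1:4) {
      old <- q[i, a, a]
      new <- min(max(old + s * delta, 0.5 + 1e-6), 0.9995)
      off <- 1 - old
      q[i, a, ] <- if (off > 0) q[i, a, ] * (1 - new) / off else (1 - new) / 3
      q[i, a, a] <- new
    }
  }
  positional_error_model(q)
}
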