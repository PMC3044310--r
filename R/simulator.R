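# Repeat-structured genome and Illumina-like read simulator.
#
# Genomes are iid background sequence at a chosen base composition with
# repeat families (one random unit per family, copied `multiplicity` times)
# embedded at random non-overlapping locations; repeat units are drawn from
# the same base composition as the background. Reads are uniformly placed
# forward-strand substrings passed base-by-base through a substitution
# error model, and full ground truth (start coordinate and true sequence
# per read; genomic occurrence count per kmer) is emitted alongside.

#' Generate a synthetic genome with embedded repeats
#'
#' @param length Genome length in bases.
#' @param base_freqs Background base probabilities (A, C, G, T); the default
#'   matches a maize-like composition A 28% / C 23% / G 22% / T 27%.
#' @param repeats A data frame with columns `unit_length` and
#'   `multiplicity`, one row per repeat family, or `NULL` for a pure iid
#'   genome. Total repeat span must fit in `length`.
#' @param seed Optional integer seed; the same seed reproduces the genome
#'   bit-identically.
#' @return A tibble with columns `id`, `seq` and a `repeats` attribute
#'   (tibble `start`, `end`, `family`; 0-based half-open, pairwise
#'   disjoint).
#' @export
generate_genome <- function(length,
                            base_freqs = c(A = 0.28, C = 0.23, G = 0.22, T = 0.27),
                            repeats = NULL, seed = NULL) {
  stopifnot(length >= 1, length(base_freqs) == 4L, all(base_freqs >= 0))
  base_freqs <- base_freqs / sum(base_freqs)
  run <- function() .generate_genome_impl(length, base_freqs, repeats)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

.generate_genome_impl <- function(length, base_freqs, repeats) {
  ann <- tibble::tibble(start = integer(0), end = integer(0), family = integer(0))
  if (is.null(repeats) || nrow(repeats) == 0L) {
    seq <- .random_bases(length, base_freqs)
    out <- tibble::tibble(id = "genome", seq = seq)
    attr(out, "repeats") <- ann
    return(out)
  }
  stopifnot(all(c("unit_length", "multiplicity") %in% names(repeats)))
  span <- sum(repeats$unit_length * repeats$multiplicity)
  if (span > length) stop("repeat span exceeds genome length", call. = FALSE)
  units <- lapply(repeats$unit_length, .random_bases, freqs = base_freqs)
  fam <- rep(seq_len(nrow(repeats)), repeats$multiplicity)
  fam <- sample(fam)  # interleave family copies
  n_copies <- length(fam)
  background <- length - span
  # uniform placement of non-overlapping copies: split the background into
  # n_copies + 1 gaps at uniformly chosen cut points
  cuts <- sort(sample.int(background + 1L, n_copies, replace = TRUE) - 1L)
  gaps <- diff(c(0L, cuts, background))
  pieces <- character(2L * n_copies + 1L)
  starts <- integer(n_copies)
  pos <- 0L
  for (i in seq_len(n_copies)) {
    pieces[2L * i - 1L] <- .random_bases(gaps[i], base_freqs)
    pos <- pos + gaps[i]
    starts[i] <- pos
    pieces[2L * i] <- units[[fam[i]]]
    pos <- pos + nchar(units[[fam[i]]])
  }
  pieces[2L * n_copies + 1L] <- .random_bases(gaps[n_copies + 1L], base_freqs)
  ann <- tibble::tibble(
    start = starts,
    end = starts + repeats$unit_length[fam],
    family = fam
  )
  out <- tibble::tibble(id = "genome", seq = paste(pieces, collapse = ""))
  attr(out, "repeats") <- ann
  out
}

.random_bases <- function(n, freqs) {
  if (n == 0L) return("")
  paste(sample(.BASES, n, replace = TRUE, prob = freqs), collapse = "")
}

#' Simulate error-bearing reads with ground truth
#'
#' Read start positions are uniform on the forward strand; each base is
#' passed independently through the substitution model (a constant rate or
#' a per-read-position profile). Insertions and deletions are not modeled.
#'
#' @param genome A one-row data frame with a `seq` column (from
#'   [generate_genome()] or [read_fasta()]).
#' @param n_reads Number of reads; alternatively give `coverage` and the
#'   read count is `round(coverage * |G| / read_length)`.
#' @param read_length Read length L in bases.
#' @param model A [uniform_error_model()] or [read_error_profile()] with
#'   `L` positions.
#' @param coverage Target sequencing depth `C = n L / |G|` (used when
#'   `n_reads` is `NULL`).
#' @param seed Optional integer seed for bit-identical replay.
#' @return A tibble of class `sim_reads` with columns `id`, `seq`, `start`
#'   (0-based) and `true_seq` (the error-free genome substring); per-base
#'   error flags are `seq != true_seq` positionwise.
#' @export
simulate_reads <- function(genome, n_reads = NULL, read_length = 36,
                           model = uniform_error_model(0.006),
                           coverage = NULL, seed = NULL) {
  stopifnot(is.data.frame(genome), nrow(genome) == 1L)
  gseq <- genome$seq
  G_len <- nchar(gseq)
  L <- as.integer(read_length)
  stopifnot(L >= 1, L <= G_len)
  if (is.null(n_reads)) {
    if (is.null(coverage)) stop("give `n_reads` or `coverage`", call. = FALSE)
    n_reads <- as.integer(round(coverage * G_len / L))
  }
  run <- function() .simulate_reads_impl(gseq, G_len, n_reads, L, model)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

.simulate_reads_impl <- function(gseq, G_len, n_reads, L, model) {
  starts <- sample.int(G_len - L + 1L, n_reads, replace = TRUE) - 1L
  true_seq <- substring(gseq, starts + 1L, starts + L)
  cm <- seq_code_matrix(true_seq)
  if (inherits(model, "uniform_error_model")) {
    p <- model$p_e
    if (p > 0) {
      err <- matrix(stats::runif(n_reads * L) < p, n_reads, L)
      idx <- which(err)
      if (length(idx) > 0L) {
        cm[idx] <- (cm[idx] + sample.int(3L, length(idx), replace = TRUE)) %% 4L
      }
    }
  } else if (inherits(model, "read_error_profile")) {
    stopifnot(model$L == L)
    for (j in seq_len(L)) {
      u <- stats::runif(n_reads)
      newb <- integer(n_reads)
      for (a in 0:3) {
        sel <- cm[, j] == a
        if (any(sel)) {
          cum <- cumsum(model$M[j, a + 1L, ])[1:3]
          newb[sel] <- findInterval(u[sel], cum)
        }
      }
      cm[, j] <- newb
    }
  } else {
    stop("unsupported error model class", call. = FALSE)
  }
  out <- tibble::tibble(
    id = paste0("read", seq_len(n_reads)),
    seq = code_matrix_to_seq(cm),
    start = starts,
    true_seq = true_seq
  )
  class(out) <- c("sim_reads", class(out))
  out
}

#' True genomic occurrence count of every kmer
#'
#' Exhaustive window count over the genome; `sum(alpha)` over distinct
#' kmers equals `|G| - k + 1`.
#'
#' @param genome A one-row data frame with a `seq` column.
#' @param k kmer length.
#' @return A tibble with columns `kmer`, `code` (sorted) and `alpha`.
#' @export
true_occurrences <- function(genome, k) {
  stopifnot(is.data.frame(genome), nrow(genome) == 1L)
  k <- .check_k(k)
  codes <- as.vector(window_codes(seq_code_matrix(genome$seq), k))
  dt <- data.table::data.table(code = codes)
  counts <- dt[, .N, by = "code"]
  data.table::setorderv(counts, "code")
  tibble::tibble(
    kmer = decode_kmers(counts$code, k),
    code = counts$code,
    alpha = as.numeric(counts$N)
  )
}

#' Desk-scale simulation presets
#'
#' Scaled-down versions of the three synthetic repeat recipes used
#' throughout the package's calibration studies: 100 kb genomes at 80x
#' coverage of 36 bp reads with maize-like base composition, and repeat
#' spans of 20% / 50% / 80%. Relative to the full-size recipes (1 Mb
#' genomes with families such as (1000, 200) or (500, 400) x (1500, 200) x
#' (3000, 100)), unit lengths are scaled by 1/10 while multiplicities are
#' preserved, so per-kmer occupancy statistics - the quantity the
#' estimator operates on - match the full-scale setting at a tenth of the
#' problem size.
#'
#' @param name `"D1-small"` (20% repeats, one (100, 200) family),
#'   `"D2-small"` (50%, (50, 400) + (150, 200)) or `"D3-small"` (80%,
#'   (50, 400) + (150, 200) + (300, 100)).
#' @return A list with `genome_length`, `base_freqs`, `repeats`,
#'   `coverage`, `read_length` and the default uniform error rate `p_e`.
#' @export
sim_preset <- function(name = c("D1-small", "D2-small", "D3-small")) {
  name <- match.arg(name)
  fams <- switch(name,
    "D1-small" = tibble::tibble(unit_length = 100L, multiplicity = 200L),
    "D2-small" = tibble::tibble(unit_length = c(50L, 150L),
                                multiplicity = c(400L, 200L)),
    "D3-small" = tibble::tibble(unit_length = c(50L, 150L, 300L),
                                multiplicity = c(400L, 200L, 100L))
  )
  list(
    name = name,
    genome_length = 100000L,
    base_freqs = c(A = 0.28, C = 0.23, G = 0.22, T = 0.27),
    repeats = fams,
    coverage = 80,
    read_length = 36L,
    p_e = 0.006
  )
}

#' Write simulation truth files
#'
#' Truth TSV #1: per read `read_id`, `start` and the comma-separated
#' 0-based positions of misread bases. Truth TSV #2 (via
#' [true_occurrences()] + [readr::write_tsv()]): per kmer `alpha`.
#'
#' @param sim A [simulate_reads()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(sim, path) {
  flags <- .error_positions(sim$seq, sim$true_seq)
  readr::write_tsv(
    tibble::tibble(
      read_id = sim$id, start = sim$start,
      error_positions = vapply(flags, paste, character(1), collapse = ",")
    ),
    path
  )
  invisible(path)
}

# list of 0-based misread positions per read
.error_positions <- function(seq, true_seq) {
  cm <- seq_code_matrix(seq)
  tm <- seq_code_matrix(true_seq)
  diff <- cm != tm
  apply(diff, 1L, function(r) which(r) - 1L, simplify = FALSE)
}
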