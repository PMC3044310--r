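# Base-level correction metrics and end-to-end pipeline orchestration.

#' Base-level correction metrics
#'
#' Compares original and corrected reads against the true sequences. Per
#' base: a true positive is an erroneous base changed to the true base; a
#' false positive is a true base changed (necessarily wrongly); a true
#' negative is a true base left unchanged; a false negative is an erroneous
#' base that remains wrong - including an erroneous base changed to a
#' different wrong base, which harms no true base and therefore does not
#' count as a false positive. Sensitivity = TP/(TP+FN), specificity =
#' TN/(TN+FP), and gain = (TP-FP)/(TP+FN) is the net fraction of erroneous
#' bases removed from the data (never exceeding sensitivity).
#'
#' @param original Data frame of the uncorrected reads (`id`, `seq`).
#' @param corrected Data frame of corrected reads (`id`, `seq`), e.g. from
#'   [correct_reads()].
#' @param truth Data frame with `id` and the error-free sequence in
#'   `true_seq` (a [simulate_reads()] tibble works directly).
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `gain`.
#' @examples
#' correction_metrics(
#'   tibble::tibble(id = "r", seq = "AAAT"),
#'   tibble::tibble(id = "r", seq = "AAAA"),
#'   tibble::tibble(id = "r", true_seq = "AAAA")
#' )
#' @export
correction_metrics <- function(original, corrected, truth) {
  stopifnot(all(c("id", "seq") %in% names(original)),
            all(c("id", "seq") %in% names(corrected)),
            all(c("id", "true_seq") %in% names(truth)))
  if (!setequal(original$id, corrected$id) || !setequal(original$id, truth$id)) {
    stop("read ids do not align across inputs", call. = FALSE)
  }
  corrected <- corrected[match(original$id, corrected$id), ]
  truth <- truth[match(original$id, truth$id), ]
  tp <- fp <- tn <- fn <- 0
  groups <- split(seq_len(nrow(original)), nchar(original$seq))
  for (grp in groups) {
    o <- seq_code_matrix(original$seq[grp])
    cc <- seq_code_matrix(corrected$seq[grp])
    tt <- seq_code_matrix(truth$true_seq[grp])
    err <- o != tt
    changed <- cc != o
    right <- cc == tt
    tp <- tp + sum(err & right)
    fp <- fp + sum(!err & changed)
    tn <- tn + sum(!err & !changed)
    fn <- fn + sum(err & !right)
  }
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    gain = if (tp + fn > 0) (tp - fp) / (tp + fn) else NA_real_
  )
}

#' Run the full simulate-estimate-detect(-correct) pipeline
#'
#' Generates a repeat-structured genome and error-bearing reads, builds the
#' kmer spectrum and misread neighborhoods, runs the attempt EM, sweeps
#' integer detection thresholds on both the observed counts Y and the
#' estimated attempts T against kmer truth, and (optionally) corrects reads
#' and scores them at base level. The workhorse behind the calibration
#' studies and the command-line interface.
#'
#' @param preset A [sim_preset()] name or list.
#' @param seed Integer seed controlling every random draw.
#' @param k,d_max Spectrum and neighborhood parameters.
#' @param sim_model Error model used to simulate reads (a
#'   [uniform_error_model()] or [read_error_profile()]); defaults to the
#'   preset's uniform rate.
#' @param inference_model Error model used for the neighborhoods (a
#'   [uniform_error_model()] or [positional_error_model()]); defaults to
#'   `sim_model` when that is uniform, or to its window-averaged
#'   kmer-position collapse ([profile_to_kmer_model()]) otherwise.
#' @param correct Also run read correction and compute base-level metrics.
#' @param liberal_threshold Pre-filter threshold for correction; defaults
#'   to three times the T-optimal detection threshold.
#' @param tol,max_iter EM controls.
#' @return A list with the simulation (`genome`, `sim`), `spectrum`, EM
#'   `fit`, the truth-joined estimates `kmers`, both sweep curves
#'   (`curve_y`, `curve_t`), their minima (`min_y`, `min_t`), the percent
#'   `wp_reduction`, and - when `correct = TRUE` - `corrected` and
#'   `metrics`.
#' @export
run_pipeline <- function(preset = "D3-small", seed = 1, k = 13, d_max = 1,
                         sim_model = NULL, inference_model = NULL,
                         correct = FALSE, liberal_threshold = NULL,
                         tol = 1e-6, max_iter = 100) {
  if (is.character(preset)) preset <- sim_preset(preset)
  if (is.null(sim_model)) sim_model <- uniform_error_model(preset$p_e)
  if (is.null(inference_model)) {
    inference_model <- if (inherits(sim_model, "read_error_profile")) {
      profile_to_kmer_model(sim_model, k)
    } else {
      sim_model
    }
  }
  genome <- generate_genome(preset$genome_length, preset$base_freqs,
                            preset$repeats, seed = seed)
  sim <- simulate_reads(genome, coverage = preset$coverage,
                        read_length = preset$read_length,
                        model = sim_model, seed = seed + 1L)
  spectrum <- build_spectrum(sim, k = k)
  rows <- build_neighbor_rows(spectrum, inference_model, d_max = d_max)
  fit <- run_em(spectrum, rows, tol = tol, max_iter = max_iter)
  occ <- true_occurrences(genome, k)
  kmers <- kmer_truth(tidy(fit), occ)
  grid <- 0:ceiling(max(kmers$count))
  curve_y <- wp_curve(kmers, thresholds = grid, values = count)
  curve_t <- wp_curve(kmers, thresholds = grid, values = attempts)
  my <- min_wp(curve_y)
  mt <- min_wp(curve_t)
  out <- list(
    preset = preset, seed = seed, k = k, d_max = d_max,
    genome = genome, sim = sim, spectrum = spectrum, rows = rows, fit = fit,
    kmers = kmers, curve_y = curve_y, curve_t = curve_t,
    min_y = my, min_t = mt,
    wp_reduction = 100 * (my$wp - mt$wp) / my$wp
  )
  if (correct) {
    if (is.null(liberal_threshold)) liberal_threshold <- 3 * mt$threshold
    corrected <- correct_reads(sim, fit, rows,
                               liberal_threshold = liberal_threshold)
    out$corrected <- corrected
    out$metrics <- correction_metrics(sim, corrected, sim)
  }
  out
}
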