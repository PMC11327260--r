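# Seeded Monte-Carlo studies of the screening rule's operating
# characteristics, run through the full pipeline (synthesise spectra ->
# band metrics -> curve fits -> reference pooling -> offset scoring).

.curve_from_series <- function(series) {
  fit_grinding_curve(lapply(series, compute_band_metrics))
}

.ref_from_params <- function(p, n_replicates) {
  pool_reference(lapply(seq_len(n_replicates), function(r)
    .curve_from_series(synth_grinding_series(p, replicate = r))))
}

#' False-offset and detection rates of the screening rule
#'
#' For each Monte-Carlo repetition a fresh reference (default 5
#' replicate curves) is synthesised and pooled; a null test curve drawn
#' from the same parameters measures the false-offset rate, and a test
#' curve with an injected vertical offset of `offset_multiple` times the
#' dispersion scale used in scoring (the floored replicate spread of
#' that repetition's reference) measures detection power.
#'
#' @param n_reps number of Monte-Carlo repetitions.
#' @param seed master seed.
#' @param crystallinity reference crystallinity.
#' @param offset_multiple injected offset in units of the floored
#'   replicate spread (negative direction: increased order).
#' @param threshold,spread_floor passed to [assess_offset()].
#' @param n_replicates reference replicate curves per repetition.
#' @param ... further overrides for [synth_params()].
#' @return list with `false_offset_rate`, `detection_rate` (both in
#'   [0, 1]) and `n_reps`.
#' @export
screening_error_rates <- function(n_reps = 500, seed = 1,
                                  crystallinity = 0.86, offset_multiple = 4,
                                  threshold = 2.0, spread_floor = 0.5,
                                  n_replicates = 5, ...) {
  false_hit <- logical(n_reps); detected <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    p <- synth_params(crystallinity = crystallinity,
                      seed = .stream_seed(seed, i), ...)
    ref <- .ref_from_params(p, n_replicates)
    null_curve <- .curve_from_series(
      synth_grinding_series(p, replicate = n_replicates + 1L))
    a0 <- assess_offset(null_curve, ref, threshold = threshold,
                        spread_floor = spread_floor)
    false_hit[i] <- startsWith(a0$label, "offset")

    spread <- max(ref$replicate_spread, spread_floor)
    p_off <- p
    p_off$crystallinity <- crystallinity +
      shift_for_offset(p, -offset_multiple * spread)
    p_off$seed <- .stream_seed(seed, i, 2L)
    a1 <- assess_offset(.curve_from_series(synth_grinding_series(p_off)),
                        ref, threshold = threshold,
                        spread_floor = spread_floor)
    detected[i] <- startsWith(a1$label, "offset")
  }
  list(false_offset_rate = mean(false_hit),
       detection_rate = mean(detected), n_reps = n_reps)
}

#' Ranking fidelity of assemblage screening
#'
#' Synthesises assemblages of fossils with known injected offsets,
#' screens them against a freshly built reference, and scores how often
#' the ranking respects the truth: with `success = "set"`, the fossils
#' with non-zero offsets must occupy the bottom ranks; with
#' `success = "order"`, the ranking's |injected offset| sequence must be
#' non-decreasing.
#'
#' @inheritParams screening_error_rates
#' @param offsets injected vertical offsets (1/cm) of the fossils;
#'   zeros are well-preserved specimens.
#' @param success success rule, see above.
#' @return list with `success_rate` and `n_reps`.
#' @export
screening_rank_rate <- function(n_reps = 200, seed = 1, crystallinity = 0.82,
                                offsets = c(rep(0, 6), -6, -8, -10),
                                success = c("set", "order"),
                                threshold = 2.0, n_replicates = 5, ...) {
  success <- match.arg(success)
  ok <- logical(n_reps)
  heavy_ids <- sprintf("Fossil%02d", which(offsets != 0))
  for (i in seq_len(n_reps)) {
    p <- synth_params(crystallinity = crystallinity,
                      seed = .stream_seed(seed, i), ...)
    shifts <- vapply(offsets, function(o)
      if (o == 0) 0 else shift_for_offset(p, o), 0)
    asm <- synth_assemblage(p, n_reference_replicates = n_replicates,
                            fossils = shifts)
    ref <- pool_reference(lapply(asm$reference, .curve_from_series))
    tests <- lapply(asm$fossils, .curve_from_series)
    rep_tab <- screen_assemblage(tests, ref, threshold = threshold)
    ok[i] <- if (success == "set") {
      tail_ids <- utils::tail(rep_tab$sample, length(heavy_ids))
      setequal(tail_ids, heavy_ids)
    } else {
      mag <- abs(asm$truth$injected_offset[match(rep_tab$sample,
                                                 asm$truth$id)])
      !is.unsorted(mag)
    }
  }
  list(success_rate = mean(ok), n_reps = n_reps)
}
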