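#' Combined STR contribution bound on Markov reference ensembles
#'
#' Quantifies how much of a spectrum correlation between *random* sequences
#' is attributable to tandem-repeat words: for each G+C level, replicate
#' sequences are simulated from the first-order reference model, and for
#' every within-level replicate pair the summed contribution of the 16
#' b <= 2 STR words to the pairwise Pearson correlation is computed. The
#' maximum over pairs and levels (per word length) is the significance
#' reference against which genomic STR contributions are judged.
#'
#' @param ks integer vector of word lengths.
#' @param gc_levels G+C fractions of the reference models.
#' @param length replicate length in bp (default 10 Mbp; a desk-scale
#'   stand-in for much longer reference simulations).
#' @param n_replicates replicates per level (default 5).
#' @param seed master seed.
#' @param order Markov model order (default 1).
#' @return data.frame with one row per `k`: `k`, `max_contribution`
#'   (fraction), `max_percent`, and the G+C level attaining the maximum.
#' @export
str_reference_bound <- function(ks = c(7, 11),
                                gc_levels = c(0.25, 1 / 3, 0.42, 0.50),
                                length = 1e7, n_replicates = 5, seed = 1,
                                order = 1) {
  set.seed(seed)
  level_seeds <- sample.int(.Machine$integer.max - 1L, length(gc_levels))
  best <- stats::setNames(rep(-Inf, length(ks)), paste0("k", ks))
  best_gc <- stats::setNames(rep(NA_real_, length(ks)), paste0("k", ks))
  sets <- lapply(ks, function(k)
    c(set_words(enumerate_str_words(k, 1)), set_words(enumerate_str_words(k, 2))))
  for (li in seq_along(gc_levels)) {
    model <- markov_model(order = order, gc = gc_levels[li])
    set.seed(level_seeds[li])
    rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
    seqs <- lapply(rep_seeds, function(s)
      simulate_markov_sequence(model, length, seed = s))
    for (ki in seq_along(ks)) {
      spectra <- lapply(seqs, compute_spectrum, k = ks[ki])
      pairs <- utils::combn(n_replicates, 2)
      for (q in seq_len(ncol(pairs))) {
        v <- contribution(spectra[[pairs[1, q]]], spectra[[pairs[2, q]]],
                          sets[[ki]])
        if (v > best[ki]) {
          best[ki] <- v
          best_gc[ki] <- gc_levels[li]
        }
      }
    }
  }
  data.frame(k = ks, max_contribution = unname(best),
             max_percent = unname(100 * best), gc_at_max = unname(best_gc),
             row.names = NULL)
}
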