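## Centered frequency vectors for a spectrum pair; shared k enforced.
centered_pair <- function(x, y) {
  stopifnot(inherits(x, "kmer_spectrum"), inherits(y, "kmer_spectrum"))
  if (x$k != y$k)
    stop(sprintf("cannot compare spectra of different word lengths (k=%d vs k=%d)",
                 x$k, y$k))
  fx <- spectrum_frequencies(x)
  fy <- spectrum_frequencies(y)
  list(k = x$k, dx = fx - mean(fx), dy = fy - mean(fy))
}

#' Pearson correlation between two k-mer spectra
#'
#' Counts are converted to relative frequencies (`count / total_windows`)
#' and the standard Pearson coefficient is computed over the
#' `4^k`-dimensional frequency vectors. The covariance numerator is retained
#' so that [contribution()] decompositions reproduce it exactly.
#'
#' @param x,y `kmer_spectrum` objects with equal `k`.
#' @return object of class `kmer_correlation` with fields `r`, `k`,
#'   `numerator` (sum of centered cross-products), `denominator`, `labels`.
#' @export
pearson_correlation <- function(x, y) {
  cp <- centered_pair(x, y)
  ssx <- sum(cp$dx^2)
  ssy <- sum(cp$dy^2)
  if (ssx == 0 || ssy == 0)
    stop("zero variance in a spectrum: Pearson correlation undefined")
  num <- sum(cp$dx * cp$dy)
  structure(list(r = num / sqrt(ssx * ssy), k = cp$k, numerator = num,
                 denominator = sqrt(ssx * ssy),
                 labels = c(x$label %||% "x", y$label %||% "y")),
            class = "kmer_correlation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.kmer_correlation <- function(x, ...) {
  cat(sprintf("kmer_correlation: r = %.4f (k=%d; %s vs %s)\n",
              x$r, x$k, x$labels[1], x$labels[2]))
  invisible(x)
}

#' Contribution of a word set to a spectrum correlation
#'
#' The correlation decomposition assigns to a word set S the share
#' `c(S) = sum_\{w in S\} (x_w - mean(x)) (y_w - mean(y)) / sum_\{all w\} ...`
#' of the covariance numerator of the Pearson correlation between the two
#' frequency vectors. Contributions are exactly additive: over any partition
#' of word space they sum to 1. Individual contributions may be negative
#' (anticorrelated words) and percentages are `100 *` fraction.
#'
#' @param x,y `kmer_spectrum` objects with equal `k`.
#' @param set a `word_set` (same `k`), or character vector of words.
#' @return contribution fraction (scalar).
#' @export
contribution <- function(x, y, set) {
  cp <- centered_pair(x, y)
  idx <- set_indices(set, cp$k)
  denom <- sum(cp$dx * cp$dy)
  if (denom == 0) stop("zero covariance between spectra: contribution undefined")
  if (length(idx) == 0L) return(0)
  sum(cp$dx[idx + 1L] * cp$dy[idx + 1L]) / denom
}

set_indices <- function(set, k) {
  if (inherits(set, "word_set")) {
    if (set$k != k) stop("word set k does not match spectrum k")
    set$indices
  } else if (is.character(set)) {
    if (length(set) == 0L) return(integer(0))
    if (any(nchar(set) != k)) stop("word length does not match spectrum k")
    unique(word_to_index(set))
  } else {
    stop("set must be a word_set or character vector")
  }
}

#' Mismatch-tolerant contribution of a single word
#'
#' With `max_mm = 0` this is the contribution of the word alone; with
#' `max_mm = 1` the word's Hamming-distance-1 neighbors are pooled with it
#' (e.g. AAAAGAA is counted towards AAAAAAA), the denominator being
#' unchanged.
#'
#' @param x,y `kmer_spectrum` objects with equal `k`.
#' @param word a single word of length `k`.
#' @param max_mm 0 or 1 allowed mismatches.
#' @return contribution fraction of the pooled word set.
#' @export
mismatch_contribution <- function(x, y, word, max_mm = 0) {
  stopifnot(length(word) == 1L, max_mm %in% c(0, 1))
  words <- if (max_mm == 0) word else c(word, hamming1_neighbors(word))
  contribution(x, y, words)
}

#' Per-word 0-mm/1-mm contribution and ratio table
#'
#' For each word, reports the exact-word contribution `c0`, the
#' contribution `c1` of the word pooled with its Hamming-1 neighborhood,
#' their ratio `c1/c0`, and the rank of the word in the descending ordering
#' of all `4^k` single-word contributions (competition ranking). Rows with
#' `c0 = 0` are flagged (`ratio_defined = FALSE`) rather than divided.
#'
#' @param x,y `kmer_spectrum` objects with equal `k`.
#' @param words character vector of words of length `k`.
#' @return data.frame with columns `word`, `c0`, `c1`, `ratio`,
#'   `ratio_defined`, `rank`.
#' @export
contribution_ratio_table <- function(x, y, words) {
  cp <- centered_pair(x, y)
  denom <- sum(cp$dx * cp$dy)
  if (denom == 0) stop("zero covariance between spectra")
  products <- cp$dx * cp$dy / denom
  idx <- word_to_index(words)
  c0 <- products[idx + 1L]
  c1 <- vapply(words, function(w) {
    nb <- word_to_index(c(w, hamming1_neighbors(w)))
    sum(products[nb + 1L])
  }, numeric(1))
  ## competition rank among all 4^k words by descending contribution
  rank_of <- vapply(c0, function(v) sum(products > v) + 1L, numeric(1))
  data.frame(word = words, c0 = c0, c1 = unname(c1),
             ratio = ifelse(c0 != 0, c1 / c0, NA_real_),
             ratio_defined = c0 != 0, rank = as.integer(rank_of),
             row.names = NULL)
}

#' Contributions of a grouping of word sets
#'
#' Computes one contribution per word set of a grouping (e.g. the STR unit
#' length partition slice b = 1/2/3, the extended base-code families, or
#' G+C-content bins). Sets within one grouping must be disjoint. For the
#' STR b-partition (and any grouping with `remaining = TRUE`) a
#' "remaining words" row with contribution `1 - sum(groups)` is appended.
#'
#' @param x,y `kmer_spectrum` objects with equal `k`.
#' @param grouping named list of `word_set` objects, or one of the shortcut
#'   strings `"str_b"` (unit lengths 1..3), `"families"` (extended
#'   base-code families), `"gc"` (default G+C bins).
#' @param remaining append the complementary "remaining words" row
#'   (default: TRUE for `"str_b"`, FALSE otherwise unless set).
#' @return data.frame of class `contribution_table` with columns `set`,
#'   `n_words`, `contribution`.
#' @export
grouped_contributions <- function(x, y, grouping = "str_b", remaining = NULL) {
  k <- x$k
  if (is.character(grouping) && length(grouping) == 1L) {
    grouping <- switch(grouping,
      str_b = {
        if (is.null(remaining)) remaining <- TRUE
        sets <- lapply(1:3, function(b) enumerate_str_words(k, b))
        names(sets) <- paste0("b", 1:3)
        sets
      },
      families = word_family_sets(k)[c("polyW", "polyS", "homoW", "homoS",
                                       "homoR", "homoY", "homoK", "homoM")],
      gc = gc_bin_sets(k),
      stop("unknown grouping shortcut"))
  }
  if (is.null(remaining)) remaining <- FALSE
  if (is.null(names(grouping)))
    names(grouping) <- vapply(grouping, function(s) s$name, character(1))
  all_idx <- unlist(lapply(grouping, function(s) set_indices(s, k)))
  if (anyDuplicated(all_idx))
    stop("word sets within a grouping must be disjoint")
  contribs <- vapply(grouping, function(s) contribution(x, y, s), numeric(1))
  df <- data.frame(set = names(grouping),
                   n_words = vapply(grouping, length, integer(1)),
                   contribution = unname(contribs), row.names = NULL)
  if (remaining) {
    df <- rbind(df, data.frame(set = "remaining",
                               n_words = 4^k - length(all_idx),
                               contribution = 1 - sum(contribs)))
  }
  class(df) <- c("contribution_table", class(df))
  df
}

#' Mean correlation with Markov reference subtracted
#'
#' Averages the Pearson coefficients of a collection of real spectrum pairs,
#' averages the reference coefficients (e.g. replicate-pair correlations of
#' a Markov ensemble), and reports their difference with the quadrature
#' combination of the two standard deviations. Because reference
#' correlations may be negative, the difference may exceed 1.
#'
#' @param real_r numeric vector of real-pair Pearson coefficients, or list
#'   of `kmer_correlation` objects.
#' @param ref_r numeric vector of reference coefficients, or a
#'   `reference_ensemble` (pairwise correlations are computed).
#' @param label optional group-pair label.
#' @return data.frame with `mean_real`, `sd_real`, `mean_ref`, `sd_ref`,
#'   `difference`, `error`.
#' @export
mean_correlation_with_reference <- function(real_r, ref_r, label = NULL) {
  as_r <- function(v) {
    if (inherits(v, "reference_ensemble")) return(ensemble_pairwise(v)$values)
    if (is.list(v)) return(vapply(v, function(ci) ci$r, numeric(1)))
    as.numeric(v)
  }
  real <- as_r(real_r)
  ref <- as_r(ref_r)
  if (length(real) == 0L) stop("no real correlation values supplied")
  if (length(ref) == 0L) stop("no reference correlation values supplied")
  sd0 <- function(v) if (length(v) > 1) stats::sd(v) else 0
  data.frame(label = label %||% NA_character_,
             mean_real = mean(real), sd_real = sd0(real),
             mean_ref = mean(ref), sd_ref = sd0(ref),
             difference = mean(real) - mean(ref),
             error = sqrt(sd0(real)^2 + sd0(ref)^2))
}
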