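#' Compute a k-mer spectrum
#'
#' Counts every length-`k` window (overlapping, step 1) composed solely of
#' A/C/G/T on the given strand of the supplied sequences. Windows containing
#' any other letter (e.g. N) are skipped, and windows never span two
#' sequences. Counts are stored as an unnamed vector of length `4^k` in
#' base-4 word order (see [word_to_index()]).
#'
#' @param sequences a character vector, `Biostrings::DNAStringSet`, or list
#'   of sequences. May be empty (yields an all-zero spectrum).
#' @param k word length, `1 <= k <= 11`.
#' @param label optional source descriptor (organism, region class).
#' @return an object of class `kmer_spectrum` with fields `k`, `counts`
#'   (length `4^k`), `total_windows`, `label`.
#' @export
compute_spectrum <- function(sequences, k, label = NULL) {
  if (k < 1 || k > 11) stop("k must be between 1 and 11")
  k <- as.integer(k)
  if (is.list(sequences)) sequences <- unlist(lapply(sequences, as.character))
  if (is.character(sequences) || length(sequences) == 0L) {
    sequences <- Biostrings::DNAStringSet(toupper(as.character(sequences)))
  }
  if (length(sequences) == 0L) {
    counts <- numeric(4^k)
  } else {
    counts <- as.numeric(Biostrings::oligonucleotideFrequency(
      sequences, width = k, step = 1, with.labels = FALSE,
      simplify.as = "collapsed"))
  }
  new_spectrum(k, counts, label)
}

new_spectrum <- function(k, counts, label = NULL, total_windows = sum(counts)) {
  stopifnot(length(counts) == 4^k)
  structure(list(k = as.integer(k), counts = counts,
                 total_windows = total_windows, label = label),
            class = "kmer_spectrum")
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat(sprintf("kmer_spectrum: k=%d, %s valid windows%s\n", x$k,
              format(x$total_windows, big.mark = ","),
              if (is.null(x$label)) "" else paste0(" [", x$label, "]")))
  invisible(x)
}

#' Relative word frequencies of a spectrum
#'
#' @param spectrum a `kmer_spectrum`.
#' @return numeric vector of length `4^k`: `counts / total_windows` (zeros
#'   if the spectrum has no valid windows).
#' @export
spectrum_frequencies <- function(spectrum) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  if (spectrum$total_windows == 0) return(numeric(length(spectrum$counts)))
  spectrum$counts / spectrum$total_windows
}

#' Look up counts of specific words in a spectrum
#'
#' @param spectrum a `kmer_spectrum`.
#' @param words character vector of words of length `k`.
#' @return named numeric vector of counts.
#' @export
spectrum_counts <- function(spectrum, words) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  if (any(nchar(words) != spectrum$k)) stop("word length does not match k")
  stats::setNames(spectrum$counts[word_to_index(words) + 1L], words)
}

#' Write a spectrum as TSV (word, count)
#'
#' @param spectrum a `kmer_spectrum`.
#' @param path output file path.
#' @param zeros include words with zero counts (default TRUE).
#' @export
write_spectrum_tsv <- function(spectrum, path, zeros = TRUE) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  keep <- if (zeros) seq_along(spectrum$counts) else which(spectrum$counts > 0)
  df <- data.frame(word = index_to_word(keep - 1L, spectrum$k),
                   count = spectrum$counts[keep])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a spectrum from TSV written by [write_spectrum_tsv()]
#'
#' @param path TSV file with columns `word` and `count`.
#' @param k word length; inferred from the file if missing.
#' @param label optional label.
#' @return a `kmer_spectrum`.
#' @export
read_spectrum_tsv <- function(path, k = NULL, label = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "numeric"))
  if (is.null(k)) k <- nchar(df$word[1])
  counts <- numeric(4^k)
  counts[word_to_index(df$word) + 1L] <- df$count
  new_spectrum(k, counts, label)
}

#' Single-strand G+C fraction of sequences
#'
#' @param sequences character vector or `DNAStringSet`.
#' @return fraction of G/C among A/C/G/T letters.
#' @export
gc_fraction <- function(sequences) {
  sp <- compute_spectrum(sequences, 1)
  if (sp$total_windows == 0) return(NA_real_)
  sum(sp$counts[c(2, 3)]) / sp$total_windows
}
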