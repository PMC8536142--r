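#' @useDynLib strdecomp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Convert DNA words to spectrum indices
#'
#' Words are mapped to 0-based integers by reading them as base-4 numbers
#' with A=0, C=1, G=2, T=3 and the first character most significant. This is
#' the order in which [compute_spectrum()] stores counts (identical to the
#' column order of `Biostrings::oligonucleotideFrequency`).
#'
#' @param words character vector of same-length DNA words over ACGT.
#' @return integer vector of 0-based indices into a `4^k` spectrum.
#' @seealso [index_to_word()]
#' @export
word_to_index <- function(words) {
  stopifnot(is.character(words), length(words) >= 1L)
  k <- unique(nchar(words))
  if (length(k) != 1L) stop("all words must have the same length")
  m <- matrix(match(unlist(strsplit(words, "", fixed = TRUE)), DNA_BASES) - 1L,
              nrow = k)
  if (anyNA(m)) stop("words must contain only A, C, G, T")
  as.integer(colSums(m * 4^((k - 1):0)))
}

#' Convert spectrum indices back to DNA words
#'
#' @param idx integer vector of 0-based indices.
#' @param k word length.
#' @return character vector of DNA words.
#' @export
index_to_word <- function(idx, k) {
  stopifnot(all(idx >= 0), all(idx < 4^k))
  out <- matrix("", nrow = k, ncol = length(idx))
  rest <- as.numeric(idx)
  for (pos in k:1) {
    out[pos, ] <- DNA_BASES[rest %% 4 + 1]
    rest <- rest %/% 4
  }
  apply(out, 2, paste0, collapse = "")
}

#' Reverse complement of DNA words
#'
#' @param words character vector of DNA words over ACGT.
#' @return character vector of reverse-complemented words.
#' @examples
#' reverse_complement("ACACACA")  # "TGTGTGT"
#' @export
reverse_complement <- function(words) {
  if (!all(grepl("^[ACGT]+$", words)))
    stop("words must contain only A, C, G, T")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(words)))
}

#' Shift sequence of a tandem-repeat word
#'
#' For a word that is the length-`k` prefix of an infinite tandem repeat with
#' unit length `b`, returns the length-`k` prefix of the same infinite repeat
#' started one position later (a cyclic rotation of the unit). For a
#' homopolymer (`b = 1`) the shift sequence equals the word itself.
#'
#' @param word a single DNA word.
#' @param b repeat unit length; `word` must have period `b`.
#' @return the shifted word (same length).
#' @examples
#' shift_word("ACACACA", 2)  # "CACACAC"
#' @export
shift_word <- function(word, b) {
  stopifnot(length(word) == 1L, b >= 1)
  k <- nchar(word)
  if (b > k) stop("unit length b exceeds word length")
  unit <- substr(word, 1L, b)
  full <- strrep(unit, ceiling((k + 1) / b) + 1L)
  if (substr(full, 1L, k) != word)
    stop(sprintf("'%s' is not periodic with unit length %d", word, b))
  substr(full, 2L, k + 1L)
}

## smallest p such that word[i] == word[i - p] for all i > p
minimal_period <- function(word) {
  ch <- strsplit(word, "", fixed = TRUE)[[1]]
  k <- length(ch)
  for (p in 1:k) {
    if (p == k || all(ch[(p + 1):k] == ch[1:(k - p)])) return(p)
  }
  k
}

#' A named set of k-mer words
#'
#' Word sets carry the word length `k`, the member words as 0-based spectrum
#' indices, and optional family metadata. They are the unit of
#' [contribution()] grouping.
#'
#' @param name set label.
#' @param k word length.
#' @param words character vector of member words (alternative to `indices`).
#' @param indices 0-based member indices (alternative to `words`).
#' @param family optional family class label (e.g. `"polyW"`).
#' @param b optional repeat unit length for STR families.
#' @return an object of class `word_set`.
#' @export
word_set <- function(name, k, words = NULL, indices = NULL,
                     family = NULL, b = NULL) {
  if (is.null(indices)) {
    if (length(words) == 0L) {
      indices <- integer(0)
    } else {
      if (!all(nchar(words) == k)) stop("all members must have length k")
      indices <- word_to_index(words)
    }
  }
  indices <- sort(unique(as.integer(indices)))
  structure(list(name = name, k = as.integer(k), indices = indices,
                 family = family, b = b),
            class = "word_set")
}

#' @export
print.word_set <- function(x, ...) {
  cat(sprintf("word_set '%s': k=%d, %d words", x$name, x$k, length(x$indices)))
  if (!is.null(x$b)) cat(sprintf(", unit length b=%d", x$b))
  cat("\n")
  if (length(x$indices) > 0 && length(x$indices) <= 16)
    cat(" ", paste(set_words(x), collapse = " "), "\n")
  invisible(x)
}

#' @export
length.word_set <- function(x) length(x$indices)

#' Member words of a word set
#' @param set a `word_set`.
#' @return character vector of member words.
#' @export
set_words <- function(set) {
  stopifnot(inherits(set, "word_set"))
  if (length(set$indices) == 0L) return(character(0))
  index_to_word(set$indices, set$k)
}

#' Enumerate tandem-repeat words of a given unit length
#'
#' Returns all k-mers whose minimal period is exactly `b`, i.e. the length-k
#' prefixes of infinite tandem repeats generated by a unit of minimal length
#' `b`. For any `k >= 3` this yields 4 words for `b = 1` (the homopolymers)
#' and 12 words for `b = 2`; `b = 3` yields 60 words for `k >= 4`.
#'
#' @param k word length.
#' @param b repeat unit length, `1 <= b <= 3 <= k` (larger `b` up to `k`
#'   accepted).
#' @return a `word_set` of STR words.
#' @export
enumerate_str_words <- function(k, b) {
  stopifnot(k >= 1)
  if (b > k) stop("unit length b exceeds word length k")
  if (b < 1) stop("unit length b must be >= 1")
  units <- index_to_word(0:(4^b - 1), b)
  words <- unique(vapply(units, function(u)
    substr(strrep(u, ceiling(k / b)), 1L, k), character(1)))
  words <- words[vapply(words, minimal_period, integer(1)) == b]
  word_set(sprintf("b%d", b), k, words = words, family = "str", b = as.integer(b))
}

#' Extended base-code STR word families
#'
#' Returns the named STR families used throughout the analysis: the four
#' homopolymer singletons polyA/C/G/T, the pairs polyW = \{polyA, polyT\} and
#' polyS = \{polyC, polyG\}, and the six unit-length-2 families homoW, homoS,
#' homoR, homoY, homoK, homoM -- each the pair of b = 2 repeat words over the
#' indicated base class (W = \{A,T\}, S = \{C,G\}, R = \{A,G\}, Y = \{C,T\},
#' K = \{G,T\}, M = \{A,C\}); e.g. homoR contains (AG)n and (GA)n. The union
#' of the poly singletons and homo pairs is the full set of b <= 2 STR words.
#'
#' @param k word length (>= 3).
#' @return named list of `word_set` objects.
#' @export
word_family_sets <- function(k) {
  stopifnot(k >= 3)
  rep_word <- function(unit) substr(strrep(unit, k), 1L, k)
  fam <- function(name, units, b) {
    word_set(name, k, words = vapply(units, rep_word, character(1)),
             family = name, b = b)
  }
  classes <- list(W = c("A", "T"), S = c("C", "G"), R = c("A", "G"),
                  Y = c("C", "T"), K = c("G", "T"), M = c("A", "C"))
  out <- list(
    polyA = fam("polyA", "A", 1L), polyC = fam("polyC", "C", 1L),
    polyG = fam("polyG", "G", 1L), polyT = fam("polyT", "T", 1L),
    polyW = fam("polyW", c("A", "T"), 1L),
    polyS = fam("polyS", c("C", "G"), 1L)
  )
  for (cl in c("W", "S", "R", "Y", "K", "M")) {
    bases <- classes[[cl]]
    units <- c(paste0(bases[1], bases[2]), paste0(bases[2], bases[1]))
    out[[paste0("homo", cl)]] <- fam(paste0("homo", cl), units, 2L)
  }
  out
}

#' Hamming-distance-1 neighborhood of a word
#'
#' All words differing from `word` at exactly one position; there are `3 k`
#' of them and the word itself is excluded.
#'
#' @param word a single DNA word over ACGT.
#' @return character vector of `3 * nchar(word)` neighbor words.
#' @export
hamming1_neighbors <- function(word) {
  stopifnot(length(word) == 1L)
  if (!grepl("^[ACGT]+$", word)) stop("word must contain only A, C, G, T")
  ch <- strsplit(word, "", fixed = TRUE)[[1]]
  k <- length(ch)
  out <- character(3L * k)
  i <- 0L
  for (pos in 1:k) {
    for (sub in setdiff(DNA_BASES, ch[pos])) {
      repl <- ch
      repl[pos] <- sub
      i <- i + 1L
      out[i] <- paste0(repl, collapse = "")
    }
  }
  out
}

## G+C letter count for every word index 0..4^k-1, vectorized over digits
gc_count_by_index <- function(k) {
  n <- 4^k
  idx <- seq_len(n) - 1
  gc <- integer(n)
  rest <- idx
  for (pos in 1:k) {
    digit <- rest %% 4
    gc <- gc + (digit == 1L | digit == 2L)
    rest <- rest %/% 4
  }
  gc
}

#' Export word-set definitions as JSON
#'
#' @param sets a `word_set` or list of `word_set` objects.
#' @param path output JSON path.
#' @export
word_sets_to_json <- function(sets, path) {
  if (inherits(sets, "word_set")) sets <- list(sets)
  out <- lapply(sets, function(s)
    list(name = s$name, k = s$k, family = s$family, b = s$b,
         words = set_words(s)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Partition word space into G+C-content bins
#'
#' Words are binned by their percentage of G/C letters. With bin edges
#' `e1 < e2 < ...` (percent), the bins are `[0, e1)`, `[e1, e2)`, ...,
#' `[e_last, 100]`; they are disjoint and exhaustive.
#'
#' @param k word length.
#' @param edges increasing numeric vector of percentages strictly inside
#'   (0, 100).
#' @return list of `word_set` objects, one per bin.
#' @export
gc_bin_sets <- function(k, edges = seq(10, 90, by = 10)) {
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  if (any(edges <= 0 | edges >= 100)) stop("bin edges must lie inside (0, 100)")
  gc_pct <- gc_count_by_index(k) / k * 100
  bin <- findInterval(gc_pct, edges) + 1L
  labels <- c(sprintf("GC<%g%%", edges),
              sprintf("GC>=%g%%", edges[length(edges)]))
  lapply(seq_along(labels), function(i)
    word_set(labels[i], k, indices = which(bin == i) - 1L, family = "gc_bin"))
}
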