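#' Classify the strand pattern of an STR word's contribution values
#'
#' Compares the contribution (or any per-word value) of a tandem-repeat word
#' with the values of its inverse complement and of its shift sequence. Two
#' values are "nearly equal" when their relative difference
#' `|a - b| / max(|a|, |b|)` is at most `tol`. The call is
#' `"inv_compl"` when word and inverse complement agree but the shift does
#' not, `"shift"` for the converse, `"ambiguous"` when all pairwise values
#' agree, and `"own"` otherwise. For homoW/homoS words at odd `k` the
#' inverse complement *is* the shift sequence, and the call is the
#' structural `"inv_compl_eq_shift"`.
#'
#' @param values named numeric vector of per-word values; must contain the
#'   word, its inverse complement and its shift sequence.
#' @param word the tandem-repeat word to classify.
#' @param b repeat unit length of the word.
#' @param tol relative tolerance for "nearly equal" (default 0.25).
#' @return object of class `pattern_call`: list with `word`, `call`,
#'   `values` (word, inv_compl, shift), `tol`.
#' @export
classify_strand_pattern <- function(values, word, b, tol = 0.25) {
  rc <- reverse_complement(word)
  sh <- shift_word(word, b)
  need <- unique(c(word, rc, sh))
  if (!all(need %in% names(values)))
    stop("values missing for: ", paste(setdiff(need, names(values)),
                                       collapse = ", "))
  v <- values[need]
  near <- function(a, b) {
    m <- max(abs(a), abs(b))
    if (m == 0) TRUE else abs(a - b) / m <= tol
  }
  vals <- c(word = unname(values[word]), inv_compl = unname(values[rc]),
            shift = unname(values[sh]))
  if (rc == sh) {
    call <- "inv_compl_eq_shift"
  } else {
    eq_rc <- near(vals["word"], vals["inv_compl"])
    eq_sh <- near(vals["word"], vals["shift"])
    eq_all <- eq_rc && eq_sh && near(vals["inv_compl"], vals["shift"])
    call <- if (eq_all) "ambiguous"
            else if (eq_rc && !eq_sh) "inv_compl"
            else if (eq_sh && !eq_rc) "shift"
            else if (eq_rc && eq_sh) "ambiguous"
            else "own"
  }
  structure(list(word = word, call = call, values = vals, tol = tol),
            class = "pattern_call")
}

#' @export
print.pattern_call <- function(x, ...) {
  cat(sprintf("pattern_call: %s -> %s (word %.3g, inv_compl %.3g, shift %.3g; tol %g)\n",
              x$word, x$call, x$values["word"], x$values["inv_compl"],
              x$values["shift"], x$tol))
  invisible(x)
}

#' Single-mismatch deviation profile of an STR family word
#'
#' Every Hamming-1 neighbor of the family word contributes its spectrum
#' count to the base substituted at the mismatch position. Counts are
#' reported as percentages of the total neighbor mass. Neighbors that are
#' themselves members of the same family set are excluded from the
#' attribution. Homopolymer words yield three percentages (the original
#' base cannot appear as a substitution); unit-length-2 words yield four.
#'
#' @param spectrum a `kmer_spectrum` with `k` equal to the word length.
#' @param word the STR family word.
#' @param family optional `word_set` whose members are excluded from the
#'   neighbor attribution (defaults to the single word itself).
#' @return object of class `deviation_profile`: list with `word`,
#'   `percent` (named, sorted descending), `counts`, `total`, `empty` flag.
#' @export
deviation_profile <- function(spectrum, word, family = NULL) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  if (nchar(word) != spectrum$k) stop("word length does not match spectrum k")
  nb <- hamming1_neighbors(word)
  if (!is.null(family)) nb <- setdiff(nb, set_words(family))
  ch <- strsplit(word, "", fixed = TRUE)[[1]]
  nb_ch <- strsplit(nb, "", fixed = TRUE)
  sub_base <- vapply(nb_ch, function(x) x[which(x != ch)[1]], character(1))
  cnt <- spectrum$counts[word_to_index(nb) + 1L]
  bases <- intersect(DNA_BASES, unique(sub_base))
  counts <- vapply(bases, function(bb) sum(cnt[sub_base == bb]), numeric(1))
  total <- sum(counts)
  percent <- if (total > 0) 100 * counts / total else counts * NA_real_
  ord <- order(percent, decreasing = TRUE)
  structure(list(word = word, percent = percent[ord], counts = counts[ord],
                 total = total, empty = total == 0),
            class = "deviation_profile")
}

#' @export
print.deviation_profile <- function(x, ...) {
  if (x$empty) {
    cat(sprintf("deviation_profile: %s (empty: no neighbor occurrences)\n",
                x$word))
  } else {
    cat(sprintf("deviation_profile: %s -> %s\n", x$word,
                paste(sprintf("%s %.1f%%", names(x$percent), x$percent),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Ambiguity and strong-tendency flags for a deviation profile
#'
#' A profile of a homopolymer ("poly") family is ambiguous when all three
#' percentages lie in \[30, 40\]; a unit-length-2 ("duo") profile is
#' ambiguous when all four lie in \[20, 30\] with at most one value equal to
#' 30 after rounding to whole percent. A strong tendency is flagged when
#' any value exceeds 42.5.
#'
#' @param profile a `deviation_profile`, or a numeric vector of
#'   percentages.
#' @param type `"poly"` or `"duo"`; inferred from the number of values if
#'   missing.
#' @return list with logical `ambiguous` and `strong_tendency`.
#' @export
classify_ambiguity <- function(profile, type = NULL) {
  p <- if (inherits(profile, "deviation_profile")) profile$percent
       else as.numeric(profile)
  if (any(is.na(p))) return(list(ambiguous = NA, strong_tendency = NA))
  if (is.null(type)) type <- if (length(p) <= 3) "poly" else "duo"
  type <- match.arg(type, c("poly", "duo"))
  if (type == "poly") {
    amb <- all(p >= 30 & p <= 40)
  } else {
    r <- round(p)
    amb <- all(r >= 20 & r <= 30) && sum(r == 30) <= 1
  }
  list(ambiguous = amb, strong_tendency = any(p > 42.5))
}

## family word -> deterministic expected top ranks from the deviation rules
## Rule 1: highest rank is a W base (A if the word contains G, T if it
##   contains C; for a homopolymer the other W base). Unit-2 words place the
##   two W bases on ranks 1-2 with the word's own W base first when present,
##   defaulting to A; (GT)n is the recorded illustrating exception with A
##   first. Rule 2: for homoR/homoY and polyW the second rank is the
##   class-matching S base (G for R-words, C for Y-words). Rule 3: for
##   polyW ranks 1 and 2 are swapped.
deviation_rule_table <- function() {
  list(
    polyA = c("G", "T"), polyT = c("C", "A"),
    polyC = "T", polyG = "A",
    AT = c("A", "T"), TA = c("T", "A"),     # homoW
    CG = c("A", "T"), GC = c("A", "T"),     # homoS (no W base: A first)
    AC = c("A", "T"), CA = c("A", "T"),     # homoM (own W base A)
    GT = c("A", "T"), TG = c("T", "A"),     # homoK; (GT)n recorded exception
    AG = c("A", "G"), GA = c("A", "G"),     # homoR: rule 2 second rank G
    CT = c("T", "C"), TC = c("T", "C")      # homoY: rule 2 second rank C
  )
}

#' Expected deviation ranking of an STR family under the rule engine
#'
#' Applies the deviation rules in order (1 to 3) to a b <= 2 STR family and
#' returns the expected top-ranked substituted bases. Rule 1 places a W
#' base first (A if the repeat contains G, T if it contains C; both W bases
#' on ranks 1-2 for unit-2 repeats, own W base first, with the recorded
#' (GT)n exception). Rule 2 sets the second rank to the class-matching S
#' base for homoR/homoY and polyW. Rule 3 swaps the first two ranks for
#' polyW. For polyS families only the first rank is determined.
#'
#' @param family a family name (`"polyA"`..`"polyT"`), a unit-2 repeat unit
#'   (e.g. `"TG"` for (TG)n), or a b <= 2 STR word (e.g. `"TGTGTGT"`).
#' @return object of class `rule_expectation`: list with `family`,
#'   `ranked` (character vector of expected bases, highest first), or a
#'   "no rule" result (`ranked = NULL`) outside the rule domain.
#' @export
expected_deviation_ranking <- function(family) {
  tab <- deviation_rule_table()
  key <- family
  if (!key %in% names(tab) && grepl("^[ACGT]+$", family)) {
    p <- minimal_period(family)
    if (p == 1) key <- paste0("poly", substr(family, 1, 1))
    else if (p == 2) key <- substr(family, 1, 2)
  }
  ranked <- tab[[key]]
  structure(list(family = family, key = if (!is.null(ranked)) key else NA,
                 ranked = ranked),
            class = "rule_expectation")
}

#' @export
print.rule_expectation <- function(x, ...) {
  if (is.null(x$ranked)) {
    cat(sprintf("rule_expectation: %s -> no rule\n", x$family))
  } else {
    cat(sprintf("rule_expectation: %s -> %s\n", x$family,
                paste(sprintf("%s (%d.)", x$ranked, seq_along(x$ranked)),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Rule coverage of a collection of deviation profiles
#'
#' For each profile, the observed top ranks are compared with the rule
#' expectation of its family. Reports the fractions of profiles whose
#' ranking matches the expectation, that are ambiguous, and that are
#' covered by neither.
#'
#' @param profiles list of `deviation_profile` objects.
#' @param families optional vector/list of family identifiers parallel to
#'   `profiles` (defaults to the profile words).
#' @return list with `n`, `covered`, `ambiguous`, `uncovered` fractions and
#'   a per-profile data.frame `detail`.
#' @export
rule_coverage <- function(profiles, families = NULL) {
  if (length(profiles) == 0L) stop("no profiles supplied")
  if (is.null(families))
    families <- vapply(profiles, function(p) p$word, character(1))
  detail <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    exp <- expected_deviation_ranking(families[[i]])
    type <- if (length(p$percent) <= 3) "poly" else "duo"
    flags <- classify_ambiguity(p, type)
    matched <- if (p$empty || is.null(exp$ranked)) FALSE else
      identical(names(p$percent)[seq_along(exp$ranked)], exp$ranked)
    amb <- isTRUE(flags$ambiguous)
    data.frame(word = p$word, family = as.character(families[[i]]),
               matched = matched & !amb, ambiguous = amb,
               uncovered = !matched & !amb)
  })
  detail <- do.call(rbind, detail)
  n <- nrow(detail)
  list(n = n, covered = sum(detail$matched) / n,
       ambiguous = sum(detail$ambiguous) / n,
       uncovered = sum(detail$uncovered) / n, detail = detail)
}

#' Split genomes into high/low-correlation subsets
#'
#' Algorithmic stand-in for a visual two-way grouping of a genome-genome
#' correlation matrix: starting from the genome with the highest mean
#' off-diagonal correlation, genomes whose mean correlation against the
#' current high-correlation pool exceeds `threshold` are absorbed until the
#' pool is stable. Pool members are labelled `"S1"`, the rest `"S2"`.
#'
#' @param corr square symmetric correlation matrix (no NaN).
#' @param threshold pool-admission threshold on the mean correlation to the
#'   pool (default 0.5).
#' @return character vector of `"S1"`/`"S2"` labels (named if `corr` has
#'   row names).
#' @export
bipartition_subsets <- function(corr, threshold = 0.5) {
  corr <- as.matrix(corr)
  if (nrow(corr) != ncol(corr)) stop("correlation matrix must be square")
  if (any(is.na(corr))) stop("correlation matrix contains NA/NaN")
  if (max(abs(corr - t(corr))) > 1e-8) stop("correlation matrix must be symmetric")
  n <- nrow(corr)
  if (n == 1L) return(stats::setNames("S1", rownames(corr)))
  off <- corr
  diag(off) <- NA
  pool <- which.max(rowMeans(off, na.rm = TRUE))
  repeat {
    outside <- setdiff(seq_len(n), pool)
    if (length(outside) == 0L) break
    mean_to_pool <- vapply(outside, function(i)
      mean(corr[i, pool]), numeric(1))
    add <- outside[mean_to_pool > threshold]
    if (length(add) == 0L) break
    pool <- c(pool, add)
  }
  labels <- rep("S2", n)
  labels[pool] <- "S1"
  stats::setNames(labels, rownames(corr))
}
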