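#' Markov reference models for random genome sequence
#'
#' Constructs the zero- or first-order Markov models used as null references
#' for spectrum correlations. Order 0 is parameterized by a target G+C
#' content (or explicit base probabilities). Order 1 defaults to a
#' strand-symmetric reversible chain built from a symmetric dinucleotide
#' distribution with a like-class persistence factor `lambda`: the joint
#' probability of two adjacent bases in the same W/S class (W = \{A,T\},
#' S = \{C,G\}) is boosted by `lambda` relative to independence, and base
#' weights are solved so that the stationary G+C content matches `gc`
#' exactly. `lambda = 1` reduces to an order-0 model written as a chain.
#'
#' The stationary distribution always satisfies p(A) = p(T) and
#' p(C) = p(G), so spectra of simulated sequences are strand-symmetric in
#' expectation (Chargaff's second parity rule).
#'
#' @param order Markov order, 0 or 1.
#' @param gc target G+C content as a fraction in (0, 1).
#' @param lambda like-class nearest-neighbour persistence (order 1 only);
#'   default 1.2, in the range of dinucleotide odds ratios of real genomes.
#' @param p optional explicit base probabilities (A,C,G,T), order 0.
#' @param trans optional explicit 4x4 transition matrix, order 1 (its
#'   stationary distribution overrides `gc`).
#' @return an object of class `markov_model` with fields `order`, `p`
#'   (stationary/base probabilities), `trans` (order 1), `gc`.
#' @export
markov_model <- function(order = 1, gc = 0.5, lambda = 1.2,
                         p = NULL, trans = NULL) {
  if (!order %in% c(0, 1)) stop("order must be 0 or 1")
  if (order == 0) {
    if (is.null(p)) p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    if (length(p) != 4 || any(p < 0) || abs(sum(p) - 1) > 1e-12)
      stop("base probabilities must be 4 nonnegative values summing to 1")
    model <- list(order = 0L, p = p, trans = NULL,
                  gc = sum(p[c(2, 3)]))
  } else {
    if (is.null(trans)) {
      if (gc <= 0 || gc >= 1) stop("gc must lie strictly inside (0, 1)")
      ## class weights a (W) and b (S): marginal P(S) of the symmetric joint
      ## {WW: a^2*lambda, WS/SW: a*b, SS: b^2*lambda} must equal gc
      f <- function(a) {
        b <- 1 - a
        (b^2 * lambda + a * b) / (a^2 * lambda + 2 * a * b + b^2 * lambda) - gc
      }
      a <- stats::uniroot(f, c(1e-9, 1 - 1e-9), tol = 1e-14)$root
      wts <- c(a / 2, (1 - a) / 2, (1 - a) / 2, a / 2)  # A,C,G,T
      cls <- c(1L, 2L, 2L, 1L)
      joint <- outer(wts, wts) * ifelse(outer(cls, cls, "=="), lambda, 1)
      joint <- joint / sum(joint)
      p <- rowSums(joint)
      trans <- joint / p
    } else {
      trans <- as.matrix(trans)
      if (any(trans < 0) || any(abs(rowSums(trans) - 1) > 1e-12))
        stop("transition matrix rows must be probabilities summing to 1")
      p <- stationary_distribution(trans)
    }
    model <- list(order = 1L, p = p, trans = trans, gc = sum(p[c(2, 3)]))
  }
  structure(model, class = "markov_model")
}

stationary_distribution <- function(trans) {
  e <- eigen(t(trans))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("markov_model: order %d, G+C %.1f%%\n", x$order, 100 * x$gc))
  invisible(x)
}

#' Simulate a random sequence from a Markov model
#'
#' @param model a `markov_model`.
#' @param length number of bases to simulate (>= 1).
#' @param seed optional integer seed; identical `seed` + `model` + `length`
#'   yields an identical sequence.
#' @return a single character string of A/C/G/T of the requested length.
#' @export
simulate_markov_sequence <- function(model, length, seed = NULL) {
  stopifnot(inherits(model, "markov_model"), length >= 1)
  if (!is.null(seed)) set.seed(seed)
  trans <- if (model$order == 1) model$trans else diag(4)
  simulate_markov_cpp(as.integer(length), model$p, trans, model$order)
}

#' Expected k-mer spectrum under a Markov model
#'
#' Expected (fractional) count of word `w` in a sequence of the given length
#' is `(length - k + 1) * P(w)`, where `P(w)` is the product of base
#' probabilities (order 0) or the stationary initial probability times the
#' transition products (order 1).
#'
#' @param model a `markov_model`.
#' @param k word length.
#' @param length sequence length in bp.
#' @return a `kmer_spectrum` with fractional expected counts.
#' @export
expected_markov_spectrum <- function(model, k, length) {
  stopifnot(inherits(model, "markov_model"), k >= 1, k <= 11, length >= k)
  prob <- model$p
  if (k > 1) {
    for (m in 2:k) {
      prev_last <- (seq_len(4^(m - 1)) - 1L) %% 4L
      if (model$order == 1) {
        step <- model$trans[prev_last + 1L, ]       # 4^(m-1) x 4
      } else {
        step <- matrix(model$p, nrow = 4^(m - 1), ncol = 4, byrow = TRUE)
      }
      prob <- as.numeric(t(step * prob))            # index = old*4 + new
    }
  }
  new_spectrum(k, (length - k + 1) * prob,
               label = sprintf("expected order-%d G+C %.0f%%",
                               model$order, 100 * model$gc))
}

#' Build a replicate ensemble of Markov reference spectra
#'
#' Simulates `n_replicates` independent sequences from `model`, computes
#' their k-mer spectra and stores them. Downstream statistics (pairwise
#' correlations, word-set contributions) are evaluated per replicate pair
#' and summarized as mean and standard deviation. A master seed
#' deterministically spawns per-replicate child seeds.
#'
#' @param model a `markov_model`.
#' @param k word length.
#' @param length replicate sequence length in bp.
#' @param n_replicates number of replicates (>= 2).
#' @param seed master seed.
#' @return an object of class `reference_ensemble` with fields `spectra`
#'   (list of `kmer_spectrum`), `model`, `k`, `length`, `seeds`.
#' @export
build_reference_ensemble <- function(model, k, length, n_replicates = 5,
                                     seed = 1) {
  stopifnot(n_replicates >= 2)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  spectra <- lapply(seq_len(n_replicates), function(i) {
    seq <- simulate_markov_sequence(model, length, seed = seeds[i])
    compute_spectrum(seq, k,
                     label = sprintf("ref order-%d G+C %.0f%% rep %d",
                                     model$order, 100 * model$gc, i))
  })
  structure(list(spectra = spectra, model = model, k = as.integer(k),
                 length = length, seeds = seeds),
            class = "reference_ensemble")
}

#' @export
print.reference_ensemble <- function(x, ...) {
  cat(sprintf("reference_ensemble: %d replicates, k=%d, %s bp, %s\n",
              length(x$spectra), x$k, format(x$length, big.mark = ","),
              format(x$model)))
  invisible(x)
}

#' @export
format.markov_model <- function(x, ...) {
  sprintf("order-%d Markov G+C %.1f%%", x$order, 100 * x$gc)
}

#' Evaluate a statistic over all replicate pairs of an ensemble
#'
#' @param ensemble a `reference_ensemble`.
#' @param fn function of two `kmer_spectrum` objects returning a scalar
#'   (default: Pearson correlation).
#' @return list with `values` (one per unordered replicate pair), `mean`,
#'   `sd`.
#' @export
ensemble_pairwise <- function(ensemble,
                              fn = function(x, y) pearson_correlation(x, y)$r) {
  stopifnot(inherits(ensemble, "reference_ensemble"))
  n <- length(ensemble$spectra)
  pairs <- utils::combn(n, 2)
  values <- apply(pairs, 2, function(ij)
    fn(ensemble$spectra[[ij[1]]], ensemble$spectra[[ij[2]]]))
  list(values = values, mean = mean(values), sd = stats::sd(values))
}
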