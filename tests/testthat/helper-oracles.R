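# Independent brute-force oracles. These deliberately avoid the package's
# vectorized/indexed code paths: plain substring scans, per-base masks and
# direct formula sums.

# naive overlapping-window scan; windows with non-ACGT letters are skipped
naive_spectrum_counts <- function(sequences, k) {
  words <- index_to_word(0:(4^k - 1), k)
  counts <- stats::setNames(numeric(4^k), words)
  for (s in sequences) {
    s <- toupper(s)
    n <- nchar(s)
    if (n < k) next
    for (i in 1:(n - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (grepl("^[ACGT]+$", w)) counts[w] <- counts[w] + 1
    }
  }
  counts
}

# direct textbook Pearson on frequency vectors
oracle_pearson <- function(x, y) {
  fx <- x$counts / x$total_windows
  fy <- y$counts / y$total_windows
  sum((fx - mean(fx)) * (fy - mean(fy))) /
    sqrt(sum((fx - mean(fx))^2) * sum((fy - mean(fy))^2))
}

# term-by-term contribution of a set of words
oracle_contribution <- function(x, y, words) {
  fx <- x$counts / x$total_windows
  fy <- y$counts / y$total_windows
  dx <- fx - mean(fx)
  dy <- fy - mean(fy)
  tot <- sum(dx * dy)
  sum(vapply(words, function(w) {
    i <- word_to_index(w) + 1L
    dx[i] * dy[i]
  }, numeric(1))) / tot
}

# per-base region labeling: for every base of every chromosome decide
# genic/exonic/CDS/intronic/intergenic membership directly
oracle_region_masks <- function(chromosomes, features) {
  masks <- list()
  for (ci in seq_len(nrow(chromosomes))) {
    id <- chromosomes$id[ci]
    len <- chromosomes$length[ci]
    g <- e <- cd <- logical(len)
    ft <- features[features$chrom == id, , drop = FALSE]
    intron_any <- logical(len)
    for (i in seq_len(nrow(ft))) {
      span <- (ft$start[i] + 1):(ft$end[i])
      if (ft$type[i] == "gene") g[span] <- TRUE
      if (ft$type[i] == "exon") e[span] <- TRUE
      if (ft$type[i] == "CDS") cd[span] <- TRUE
    }
    genes <- ft[ft$type == "gene", , drop = FALSE]
    for (i in seq_len(nrow(genes))) {
      span <- (genes$start[i] + 1):(genes$end[i])
      ex <- ft[ft$type == "exon" & ft$gene_id == genes$gene_id[i], ,
               drop = FALSE]
      in_ex <- logical(len)
      for (j in seq_len(nrow(ex))) in_ex[(ex$start[j] + 1):(ex$end[j])] <- TRUE
      intron_any[span] <- intron_any[span] | !in_ex[span]
    }
    masks[[id]] <- list(genic = g, exonic = e, CDS = cd,
                        intronic = intron_any & !e, intergenic = !g)
  }
  masks
}

region_set_to_mask <- function(rs, chromosomes) {
  masks <- list()
  for (ci in seq_len(nrow(chromosomes))) {
    id <- chromosomes$id[ci]
    m <- logical(chromosomes$length[ci])
    iv <- rs$intervals[rs$intervals$chrom == id, , drop = FALSE]
    for (i in seq_len(nrow(iv))) m[(iv$start[i] + 1):(iv$end[i])] <- TRUE
    masks[[id]] <- m
  }
  masks
}

# random annotation fixture with (possibly overlapping) genes
random_annotation <- function(chrom_len = 10000L, n_genes = 20L, seed = 1) {
  set.seed(seed)
  feats <- list()
  for (g in seq_len(n_genes)) {
    gstart <- sample.int(chrom_len - 500L, 1) - 1L
    glen <- sample(100:500, 1)
    gend <- min(gstart + glen, chrom_len)
    gid <- sprintf("g%03d", g)
    feats[[length(feats) + 1L]] <- data.frame(
      chrom = "chr1", start = gstart, end = gend, strand = sample(c("+", "-"), 1),
      type = "gene", gene_id = gid)
    n_ex <- sample(1:3, 1)
    breaks <- sort(sample(gstart:(gend - 1L), 2L * n_ex))
    for (e in seq_len(n_ex)) {
      es <- breaks[2 * e - 1]
      ee <- breaks[2 * e]
      if (ee <= es) ee <- es + 1L
      ee <- min(ee, gend)
      feats[[length(feats) + 1L]] <- data.frame(
        chrom = "chr1", start = es, end = ee, strand = "+",
        type = "exon", gene_id = gid)
      feats[[length(feats) + 1L]] <- data.frame(
        chrom = "chr1", start = es, end = ee, strand = "+",
        type = "CDS", gene_id = gid)
    }
  }
  genome_annotation(data.frame(id = "chr1", length = chrom_len),
                    do.call(rbind, feats))
}

random_dna <- function(n, seed = NULL, letters = c("A", "C", "G", "T")) {
  if (!is.null(seed)) set.seed(seed)
  paste0(sample(letters, n, replace = TRUE), collapse = "")
}

# small spectrum with given named counts over word space of length k
toy_spectrum <- function(k, counts_named = NULL, base = 0, label = NULL) {
  counts <- rep(base, 4^k)
  if (!is.null(counts_named))
    counts[word_to_index(names(counts_named)) + 1L] <- counts_named
  strdecomp:::new_spectrum(k, counts, label)
}
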